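## Bayesian univariate animal model: model/prior/MCMC specifications and the
## Gibbs-sampled fit.

#' Inverse-gamma shape and scale from (V, nu)
#'
#' Converts the (V, nu) parameterization of a univariate inverse-Wishart
#' variance prior into the shape/scale of the equivalent inverse-gamma:
#' `shape = nu / 2`, `scale = nu * V / 2`. The package default `V = 1`,
#' `nu = 0.002` therefore corresponds to inverse-gamma(0.001, 0.001), a
#' weakly informative prior.
#'
#' @param V positive prior scale parameter.
#' @param nu positive prior degree-of-belief parameter.
#' @return Named numeric vector with elements `shape` and `scale`.
#' @examples
#' inverse_gamma_shape_scale(1, 0.002)  # shape 0.001, scale 0.001
#' @export
inverse_gamma_shape_scale <- function(V, nu) {
  if (!is.numeric(V) || !is.numeric(nu) || length(V) != 1 || length(nu) != 1 ||
      !is.finite(V) || !is.finite(nu) || V <= 0 || nu <= 0) {
    stop("V and nu must be single positive numbers", call. = FALSE)
  }
  c(shape = nu / 2, scale = nu * V / 2)
}

#' Animal-model specification
#'
#' Describes the mean and random structure of the univariate animal model.
#' An intercept is always included; `fixed_effects` names additional
#' covariate columns in the phenotype table (e.g. `condition` = weight /
#' length, `clutch_size`). `genetic = TRUE` adds the additive genetic effect
#' with covariance proportional to the pedigree relationship matrix;
#' `extra_random` names grouping columns (e.g. `"patch"`, the common rearing
#' environment) modelled with identity covariance. At most one
#' pedigree-structured effect is allowed by construction.
#'
#' @param response name of the phenotype column (seconds fanning per 300-s
#'   window).
#' @param fixed_effects character vector of covariate column names.
#' @param genetic include the pedigree-structured additive genetic effect?
#' @param extra_random character vector of identity-covariance random-effect
#'   grouping columns.
#' @return A list of class `fh_model_spec`.
#' @export
model_spec <- function(response = "fanning_s", fixed_effects = character(),
                       genetic = TRUE, extra_random = character()) {
  structure(list(response = response,
                 fixed_effects = as.character(fixed_effects),
                 genetic = isTRUE(genetic),
                 extra_random = as.character(extra_random)),
            class = "fh_model_spec")
}

#' Variance-component priors
#'
#' One (V, nu) pair per variance component (see
#' [inverse_gamma_shape_scale()]). `V` and `nu` set the default used for
#' every component; `components` may override individual components by name
#' (`"genetic"`, `"residual"`, or an extra random-effect name such as
#' `"patch"`).
#'
#' @param V,nu default prior scale and degree of belief (defaults 1 and
#'   0.002: weakly informative).
#' @param components optional named list of `c(V = , nu = )` overrides.
#' @return A list of class `fh_prior_spec`.
#' @export
prior_spec <- function(V = 1, nu = 0.002, components = list()) {
  invisible(inverse_gamma_shape_scale(V, nu))  # validates
  pr <- structure(list(default = c(V = V, nu = nu), components = components),
                  class = "fh_prior_spec")
  pr
}

#' @noRd
prior_for <- function(priors, name) {
  x <- priors$components[[name]]
  if (is.null(x)) x <- priors$default
  c(V = unname(x[["V"]]), nu = unname(x[["nu"]]))
}

#' MCMC schedule
#'
#' Iteration count, burn-in, thinning interval and RNG seed for a Gibbs run.
#' The default schedule (13 000 iterations, burn-in 3000, thinning 10) is
#' the short schedule used for the perturbation refits; headline analyses
#' use longer runs (see the package vignette for the full schedules).
#'
#' @param n_iterations total iterations.
#' @param burn_in iterations discarded before storage (must be `<
#'   n_iterations`).
#' @param thin storage interval (`>= 1`); `floor((n_iterations - burn_in) /
#'   thin)` samples are kept.
#' @param seed integer RNG seed; identical seed and inputs give
#'   bit-identical chains.
#' @return A list of class `fh_mcmc_config`.
#' @export
mcmc_config <- function(n_iterations = 13000, burn_in = 3000, thin = 10, seed = 1) {
  stopifnot(is.numeric(n_iterations), is.numeric(burn_in), is.numeric(thin),
            is.numeric(seed), length(seed) == 1)
  n_iterations <- as.integer(n_iterations)
  burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  if (burn_in < 0 || burn_in >= n_iterations) stop("need 0 <= burn_in < n_iterations", call. = FALSE)
  if (thin < 1) stop("thin must be >= 1", call. = FALSE)
  if ((n_iterations - burn_in) %/% thin < 1) stop("no samples would be stored", call. = FALSE)
  structure(list(n_iterations = n_iterations, burn_in = burn_in, thin = thin,
                 seed = as.integer(seed)),
            class = "fh_mcmc_config")
}

#' Fit the univariate animal model by Gibbs sampling
#'
#' Fits `y = X b + Z_a a + Z_p p + e` with `a ~ N(0, A * V_A)` (breeding
#' values, `A` the additive relationship matrix), optional identity-
#' covariance random effects (e.g. patch), and `e ~ N(0, I * V_R)`, using a
#' single-chain Gibbs sampler: one joint multivariate-Gaussian draw of all
#' location effects per iteration and inverse-gamma full-conditional draws
#' of every variance component. Fixed effects have a flat prior. Breeding
#' values are sampled for the phenotyped individuals (the prior restricted
#' to them is the corresponding submatrix of `A`, so posterior summaries are
#' unaffected).
#'
#' @param phenotypes data frame with one row per individual: an `id` column,
#'   the response column, and any covariate / grouping columns named in
#'   `spec`. Rows with missing covariates are an error.
#' @param A [additive_relationship_matrix()] covering every phenotyped
#'   individual; may be `NULL` when `spec$genetic` is `FALSE`.
#' @param spec a [model_spec()].
#' @param priors a [prior_spec()].
#' @param cfg an [mcmc_config()].
#' @return An object of class `fh_chains`: thinned post-burn-in samples of
#'   the fixed effects and variance components (`V_A`, optional extras,
#'   `V_R`), plus posterior-mean random effects and a config echo.
#' @export
fit_animal_model <- function(phenotypes, A = NULL, spec = model_spec(),
                             priors = prior_spec(), cfg = mcmc_config()) {
  stopifnot(inherits(spec, "fh_model_spec"), inherits(priors, "fh_prior_spec"),
            inherits(cfg, "fh_mcmc_config"))
  phenotypes <- as.data.frame(phenotypes)
  if (!"id" %in% names(phenotypes)) stop("phenotype table needs an 'id' column", call. = FALSE)
  if (!spec$response %in% names(phenotypes)) {
    stop("response column '", spec$response, "' not found", call. = FALSE)
  }
  if (anyDuplicated(phenotypes$id)) {
    stop("one response value per individual required (duplicated ids)", call. = FALSE)
  }
  y <- as.numeric(phenotypes[[spec$response]])
  if (anyNA(y)) stop("missing response values", call. = FALSE)
  n <- length(y)

  ## fixed-effect design
  if (length(spec$fixed_effects) > 0) {
    miss <- setdiff(spec$fixed_effects, names(phenotypes))
    if (length(miss) > 0) stop("covariate(s) not found: ", paste(miss, collapse = ", "), call. = FALSE)
    covs <- phenotypes[spec$fixed_effects]
    if (anyNA(covs)) stop("missing covariate values", call. = FALSE)
    X <- model.matrix(~ ., data = covs)
  } else {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  }

  random <- list()
  if (spec$genetic) {
    if (is.null(A)) stop("a relationship matrix is required for the genetic effect", call. = FALSE)
    ids <- as.character(phenotypes$id)
    if (!all(ids %in% rownames(A))) {
      stop("phenotyped individual(s) missing from the relationship matrix: ",
           paste(setdiff(ids, rownames(A)), collapse = ", "), call. = FALSE)
    }
    A_obs <- as.matrix(unclass(A))[ids, ids, drop = FALSE]
    Ainv <- tryCatch(chol2inv(chol(A_obs)),
                     error = function(e) stop("relationship matrix is not positive definite",
                                              call. = FALSE))
    Ainv <- (Ainv + t(Ainv)) / 2
    dimnames(Ainv) <- list(ids, ids)
    Z <- diag(n)
    colnames(Z) <- ids
    random <- c(random, list(list(name = "A", Z = Z, Ginv = Ainv,
                                  prior = prior_for(priors, "genetic"))))
  }
  for (nm in spec$extra_random) {
    if (!nm %in% names(phenotypes)) stop("random-effect column not found: ", nm, call. = FALSE)
    f <- factor(phenotypes[[nm]])
    Z <- matrix(0, n, nlevels(f), dimnames = list(NULL, levels(f)))
    ok <- !is.na(f)  # individuals without a level (e.g. wild-caught fathers
                     # with no rearing patch) contribute no effect
    Z[cbind(which(ok), as.integer(f[ok]))] <- 1
    random <- c(random, list(list(name = nm, Z = Z, Ginv = NULL,
                                  prior = prior_for(priors, nm))))
  }

  pr <- list(residual = prior_for(priors, "residual"))
  fit <- gibbs_lmm(y, X, random, priors = c(pr), cfg = cfg)

  structure(list(samples = fit$samples,
                 ranef_means = fit$ranef_means,
                 fixed = colnames(X),
                 vcomp = grep("^V_", colnames(fit$samples), value = TRUE),
                 n_obs = n,
                 response = spec$response,
                 spec = spec, config = cfg),
            class = "fh_chains")
}

#' Fit the intercept + individual-ID repeatability model
#'
#' Gibbs fit of `y = mu + u_id + e` on repeated observations of the same
#' males, the model behind the repeatability estimate (variance explained by
#' individual ID divided by the total variance). By default the prior
#' splits the observed phenotypic variance evenly between the ID and
#' residual components (`V = var(y) / 2`, `nu = 1` each).
#'
#' @param observations data frame with columns `id` and the response.
#' @param response response column name.
#' @param cfg an [mcmc_config()].
#' @param priors optional [prior_spec()]; the default is the even split
#'   described above.
#' @return An `fh_chains` object with components `V_ID` and `V_R`.
#' @export
fit_repeatability_model <- function(observations, response = "fanning_s",
                                    cfg = mcmc_config(500000, 5000, 100),
                                    priors = NULL) {
  observations <- as.data.frame(observations)
  stopifnot("id" %in% names(observations), response %in% names(observations))
  y <- as.numeric(observations[[response]])
  if (is.null(priors)) {
    vh <- var(y) / 2
    priors <- prior_spec(V = vh, nu = 1)
  }
  f <- factor(observations$id)
  if (nlevels(f) < 2) stop("need at least two individuals", call. = FALSE)
  Z <- model.matrix(~ 0 + f)
  colnames(Z) <- levels(f)
  X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  fit <- gibbs_lmm(y, X, list(list(name = "ID", Z = Z, Ginv = NULL,
                                   prior = prior_for(priors, "ID"))),
                   priors = list(residual = prior_for(priors, "residual")),
                   cfg = cfg)
  structure(list(samples = fit$samples, ranef_means = fit$ranef_means,
                 fixed = "(Intercept)", vcomp = c("V_ID", "V_R"),
                 n_obs = length(y), response = response,
                 spec = NULL, config = cfg),
            class = "fh_chains")
}

#' @export
print.fh_chains <- function(x, ...) {
  cat(sprintf("Posterior chains: %d stored samples, %d observations\n",
              nrow(x$samples), x$n_obs))
  cat("Parameters:", paste(colnames(x$samples), collapse = ", "), "\n")
  pt <- vapply(colnames(x$samples), function(p)
    posterior_summary(x$samples[, p])$estimate, numeric(1))
  print(round(pt, 4))
  invisible(x)
}

#' @export
as.matrix.fh_chains <- function(x, ...) x$samples
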