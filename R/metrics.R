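## Derived quantitative-genetic statistics: heritability, repeatability,
## evolvability, pMCMC, parent-offspring regression.

#' Summarize a posterior sample as point estimate + 95% credible interval
#'
#' The default point estimate is the kernel-density posterior mode (the
#' density is evaluated on the sample range, so the mode always lies inside
#' it); `method = "mean"` gives the posterior mean. The interval is the
#' highest-posterior-density interval.
#'
#' @param x numeric posterior sample.
#' @param method `"mode"` (default) or `"mean"`.
#' @param prob interval probability (default 0.95).
#' @param ci `"hpd"` (default) for the highest-posterior-density interval or
#'   `"quantile"` for the equal-tailed interval.
#' @return A list of class `fh_summary`: `estimate`, `ci_low`, `ci_high`,
#'   `method`, `prob`.
#' @export
posterior_summary <- function(x, method = c("mode", "mean"), prob = 0.95,
                              ci = c("hpd", "quantile")) {
  method <- match.arg(method)
  ci <- match.arg(ci)
  x <- as.numeric(x)
  if (length(x) == 0 || anyNA(x)) stop("empty or missing posterior sample", call. = FALSE)
  if (length(x) == 1 || sd(x) < 1e-12) {
    est <- x[1]
    return(structure(list(estimate = est, ci_low = est, ci_high = est,
                          method = method, prob = prob), class = "fh_summary"))
  }
  est <- switch(method,
    mode = {
      d <- density(x, from = min(x), to = max(x))
      d$x[which.max(d$y)]
    },
    mean = mean(x))
  bounds <- if (ci == "hpd") {
    h <- coda::HPDinterval(coda::mcmc(x), prob = prob)
    c(h[1, "lower"], h[1, "upper"])
  } else {
    unname(quantile(x, c((1 - prob) / 2, 1 - (1 - prob) / 2)))
  }
  structure(list(estimate = est, ci_low = bounds[1], ci_high = bounds[2],
                 method = method, prob = prob),
            class = "fh_summary")
}

#' @export
print.fh_summary <- function(x, ...) {
  cat(sprintf("%.4f (%.0f%% CI %.4f-%.4f, %s)\n", x$estimate, 100 * x$prob,
              x$ci_low, x$ci_high, x$method))
  invisible(x)
}

#' Heritability from printed variance components
#'
#' The worked-table arithmetic: additive genetic variance divided by total
#' phenotypic variance.
#'
#' @param v_a additive genetic variance (seconds^2), `0 <= v_a <= v_total`.
#' @param v_total total phenotypic variance (seconds^2), `> 0`.
#' @return `v_a / v_total`.
#' @examples
#' heritability_from_components(3142.21, 3280.78)  # 0.96 to 2 dp
#' @export
heritability_from_components <- function(v_a, v_total) {
  if (!is.finite(v_total) || v_total <= 0) stop("v_total must be positive", call. = FALSE)
  if (!is.finite(v_a) || v_a < 0) stop("v_a must be non-negative", call. = FALSE)
  if (v_a > v_total) stop("v_a exceeds v_total", call. = FALSE)
  v_a / v_total
}

#' @noRd
ratio_posterior <- function(chains, numerator) {
  s <- if (inherits(chains, "fh_chains")) chains$samples else as.matrix(chains)
  if (nrow(s) == 0) stop("empty chains", call. = FALSE)
  vc <- grep("^V_", colnames(s), value = TRUE)
  if (!numerator %in% vc) {
    stop("chains do not contain a ", numerator, " component", call. = FALSE)
  }
  s[, numerator] / rowSums(s[, vc, drop = FALSE])
}

#' Posterior heritability from animal-model chains
#'
#' Per posterior sample, `h2_t = V_A,t / (sum of all variance components)_t`
#' (the denominator includes any extra random effect such as patch, plus the
#' residual), summarized with [posterior_summary()]. Computing the ratio per
#' sample and then summarizing is not the same as the ratio of summaries;
#' the latter is the printed-table arithmetic done by
#' [heritability_from_components()].
#'
#' @param chains an `fh_chains` object from [fit_animal_model()].
#' @param method point-estimate method, `"mode"` (default) or `"mean"`.
#' @param ci interval type, `"hpd"` (default) or `"quantile"`.
#' @return An `fh_summary` (values necessarily in `[0, 1]`).
#' @export
heritability_posterior <- function(chains, method = c("mode", "mean"),
                                   ci = c("hpd", "quantile")) {
  posterior_summary(ratio_posterior(chains, "V_A"), method = match.arg(method),
                    ci = match.arg(ci))
}

#' Posterior repeatability from repeated-measures chains
#'
#' Per posterior sample, `r_t = V_ID,t / (V_ID,t + V_R,t)`: the variance
#' explained by individual identity divided by the total variance.
#'
#' @inheritParams heritability_posterior
#' @param chains an `fh_chains` object from [fit_repeatability_model()].
#' @return An `fh_summary`.
#' @export
repeatability_posterior <- function(chains, method = c("mode", "mean"),
                                    ci = c("hpd", "quantile")) {
  posterior_summary(ratio_posterior(chains, "V_ID"), method = match.arg(method),
                    ci = match.arg(ci))
}

#' Evolvability: mean-standardized additive genetic variance
#'
#' `CV_A = 100 * sqrt(V_A) / mean` (percent) and `I_A = (CV_A / 100)^2 =
#' V_A / mean^2`; both standardize the additive variance by the trait mean
#' rather than the phenotypic variance.
#'
#' @param v_a additive genetic variance (seconds^2), `>= 0`.
#' @param trait_mean trait mean (seconds), `> 0`.
#' @return A list of class `fh_evolvability`: `I_A`, `CV_A`, `V_A`,
#'   `trait_mean`.
#' @examples
#' evolvability(3142.21, 39.47)  # CV_A 142.02, I_A 2.02
#' @export
evolvability <- function(v_a, trait_mean) {
  if (!is.finite(trait_mean) || trait_mean <= 0) stop("trait_mean must be positive", call. = FALSE)
  if (!is.finite(v_a) || v_a < 0) stop("v_a must be non-negative", call. = FALSE)
  cva <- 100 * sqrt(v_a) / trait_mean
  structure(list(I_A = (cva / 100)^2, CV_A = cva, V_A = v_a, trait_mean = trait_mean),
            class = "fh_evolvability")
}

#' @export
print.fh_evolvability <- function(x, ...) {
  cat(sprintf("CV_A = %.2f%%  I_A = %.2f  (V_A = %.2f s^2, mean = %.2f s)\n",
              x$CV_A, x$I_A, x$V_A, x$trait_mean))
  invisible(x)
}

#' Two-sided MCMC sign probability for a coefficient
#'
#' `pMCMC = 2 * min(Pr(sample > 0), Pr(sample < 0))`, floored at
#' `2 / length(chain)` (a chain can never put a tail probability below one
#' sample's worth).
#'
#' @param coefficient_chain numeric posterior sample of a coefficient.
#' @return pMCMC in `(0, 1]`.
#' @examples
#' pmcmc(c(1, -1, 2, 3))  # 0.5
#' @export
pmcmc <- function(coefficient_chain) {
  x <- as.numeric(coefficient_chain)
  n <- length(x)
  if (n == 0) stop("empty chain", call. = FALSE)
  p <- 2 * min(mean(x > 0), mean(x < 0))
  min(1, max(p, 2 / n))
}

#' Father-son family-mean regression
#'
#' Ordinary least squares of son family means on father values: the classic
#' parent-offspring resemblance cross-check of the animal model. The raw
#' slope, its standard error and the t statistic on `families - 2` degrees
#' of freedom are returned, as reported for the father-son scatter.
#'
#' @param father_values numeric, one value per family.
#' @param son_family_means numeric, matching family means of sons.
#' @return List with `slope`, `slope_se`, `t`, `df`. A perfectly collinear
#'   input gives `t = Inf`.
#' @export
parent_offspring_regression <- function(father_values, son_family_means) {
  x <- as.numeric(father_values)
  y <- as.numeric(son_family_means)
  if (length(x) != length(y)) stop("paired per-family values required", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 families", call. = FALSE)
  if (var(x) == 0) stop("father values are constant (zero predictor variance)", call. = FALSE)
  fit <- lm(y ~ x)
  sm <- summary(fit)$coefficients
  slope <- sm["x", "Estimate"]
  se <- sm["x", "Std. Error"]
  tval <- if (se == 0) Inf * sign(slope) else slope / se
  list(slope = slope, slope_se = se, t = tval, df = length(x) - 2L)
}
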