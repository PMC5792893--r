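## Fanning across the care period: quadratic fixed effects of day with
## per-fish random intercept, slope and curvature.

#' Default day coding for the observation schedule
#'
#' Observation days run from the day after fertilization to five days after
#' hatching: egg days ED1, ED3, ED5 and fry days FD1, FD3, FD5. Eggs hatch
#' after day 5, so the codes are ED1 = 1, ED3 = 3, ED5 = 5, FD1 = 6,
#' FD3 = 8, FD5 = 10.
#'
#' @return Named numeric vector mapping day labels to numeric codes.
#' @export
day_codes <- function() {
  c(ED1 = 1, ED3 = 3, ED5 = 5, FD1 = 6, FD3 = 8, FD5 = 10)
}

#' @noRd
day_to_numeric <- function(day, day_map = day_codes()) {
  if (is.numeric(day)) return(as.numeric(day))
  d <- suppressWarnings(as.numeric(as.character(day)))
  lab <- as.character(day)
  use_map <- is.na(d)
  unknown <- use_map & !(lab %in% names(day_map))
  if (any(unknown)) {
    stop("unknown day label(s): ", paste(unique(lab[unknown]), collapse = ", "),
         call. = FALSE)
  }
  d[use_map] <- day_map[lab[use_map]]
  d
}

#' Fit the quadratic random-slope trajectory model
#'
#' Gibbs fit of
#' `y = b0 + b1 day + b2 day^2 + u0_fish + u1_fish day + u2_fish day^2 + e`
#' with mutually independent Gaussian random intercept, slope and curvature
#' per fish. A negative `b2` with a vertex near the hatching day captures
#' the rise of fanning to a peak at hatching and its subsequent decline.
#'
#' @param data data frame with columns `id` (fish), `day` (label or numeric
#'   code) and the response `fanning_s`; needs >= 5 fish, >= 3 distinct
#'   days, and >= 2 distinct days per fish.
#' @param cfg an [mcmc_config()].
#' @param priors a [prior_spec()]; component names `u0`, `u1`, `u2`,
#'   `residual`.
#' @param day_map label-to-code map, see [day_codes()].
#' @return An `fh_chains` object with fixed effects `(Intercept)`, `day`,
#'   `day_sq` and variance components `V_u0`, `V_u1`, `V_u2`, `V_R`.
#' @export
fit_quadratic_trajectory <- function(data, cfg = mcmc_config(),
                                     priors = prior_spec(),
                                     day_map = day_codes()) {
  data <- as.data.frame(data)
  stopifnot(all(c("id", "day", "fanning_s") %in% names(data)))
  d <- day_to_numeric(data$day, day_map)
  y <- as.numeric(data$fanning_s)
  f <- factor(data$id)
  if (nlevels(f) < 5) stop("need at least 5 fish", call. = FALSE)
  if (length(unique(d)) < 3) {
    stop("need at least 3 distinct days to identify a quadratic", call. = FALSE)
  }
  per_fish <- tapply(d, f, function(z) length(unique(z)))
  if (any(per_fish < 2)) {
    stop("every fish needs observations on at least 2 distinct days", call. = FALSE)
  }

  X <- cbind("(Intercept)" = 1, day = d, day_sq = d^2)
  Zf <- model.matrix(~ 0 + f)
  colnames(Zf) <- levels(f)
  random <- list(
    list(name = "u0", Z = Zf, Ginv = NULL, prior = prior_for(priors, "u0")),
    list(name = "u1", Z = Zf * d, Ginv = NULL, prior = prior_for(priors, "u1")),
    list(name = "u2", Z = Zf * d^2, Ginv = NULL, prior = prior_for(priors, "u2"))
  )
  fit <- gibbs_lmm(y, X, random,
                   priors = list(residual = prior_for(priors, "residual")),
                   cfg = cfg)
  structure(list(samples = fit$samples, ranef_means = fit$ranef_means,
                 fixed = colnames(X), vcomp = c("V_u0", "V_u1", "V_u2", "V_R"),
                 n_obs = length(y), response = "fanning_s",
                 spec = NULL, config = cfg),
            class = "fh_chains")
}
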