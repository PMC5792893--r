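## Observation-window sampling-error robustness analysis: derive an
## empirical distribution of 5-minute-window deviations from an hour-long
## record, perturb every phenotype with resampled deviations, refit the
## animal model, and summarize the resulting heritability distribution.

#' Deviations of window fanning proportions from the hour-wide proportion
#'
#' Tiles an hour-long behavioural record into consecutive non-overlapping
#' observation windows (default 300 s, i.e. 12 windows per hour) and
#' returns, for each window, the difference between the window's fanning
#' proportion and the proportion of time spent fanning across the whole
#' record. With `n_windows = 11` only the first 11 windows are kept (the
#' whole-record proportion is still taken over the full hour).
#'
#' @param hour_record either a per-second 0/1 fanning indicator vector, or a
#'   data frame of fanning bout intervals with columns `start_s`, `end_s`
#'   (seconds from the start of the record).
#' @param window_seconds window length in seconds (default 300).
#' @param n_windows number of windows to keep (default: as many full
#'   windows as the record holds).
#' @param record_seconds total record length; defaults to the indicator
#'   length, or 3600 for a bout-interval record.
#' @return A list of class `fh_deviations`: `deviations` (proportion scale,
#'   each in `[-1, 1]`), `window_seconds`, `overall_proportion`.
#' @export
deviation_distribution <- function(hour_record, window_seconds = 300,
                                   n_windows = NULL, record_seconds = NULL) {
  if (is.data.frame(hour_record)) {
    stopifnot(all(c("start_s", "end_s") %in% names(hour_record)))
    total <- if (is.null(record_seconds)) {
      rs <- attr(hour_record, "record_seconds")
      if (is.null(rs)) 3600 else rs
    } else record_seconds
    bouts <- hour_record
  } else {
    x <- as.numeric(hour_record)
    total <- if (is.null(record_seconds)) length(x) else record_seconds
    ## turn the indicator into bout intervals for the shared overlap code
    r <- rle(x > 0)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    bouts <- data.frame(start_s = starts[r$values], end_s = ends[r$values])
  }
  max_w <- floor(total / window_seconds)
  if (max_w < 1) stop("record is shorter than one window", call. = FALSE)
  if (is.null(n_windows)) n_windows <- max_w
  if (n_windows < 1 || n_windows > max_w) {
    stop("n_windows must be between 1 and ", max_w, call. = FALSE)
  }

  overlap <- function(a0, a1) {
    sum(pmax(0, pmin(bouts$end_s, a1) - pmax(bouts$start_s, a0)))
  }
  overall <- overlap(0, total) / total
  w0 <- (seq_len(n_windows) - 1) * window_seconds
  props <- vapply(w0, function(s) overlap(s, s + window_seconds) / window_seconds,
                  numeric(1))
  structure(list(deviations = props - overall,
                 window_seconds = window_seconds,
                 overall_proportion = overall),
            class = "fh_deviations")
}

#' Perturb phenotypes with resampled observation-window deviations
#'
#' Adds to every phenotype value an independently resampled (with
#' replacement) deviation, converted from the proportion scale to seconds
#' (`deviation * window_seconds`), and clips the result to `[0,
#' window_seconds]`: fanning is not allowed to be less than 0 or greater
#' than 300 s.
#'
#' @param phenotypes phenotype data frame.
#' @param dist a [deviation_distribution()].
#' @param seed integer RNG seed.
#' @param column response column to perturb.
#' @return The phenotype table with the perturbed response.
#' @export
perturb_phenotypes <- function(phenotypes, dist, seed = 1, column = "fanning_s") {
  stopifnot(inherits(dist, "fh_deviations"), column %in% names(phenotypes))
  y <- as.numeric(phenotypes[[column]])
  if (any(y < 0 | y > dist$window_seconds)) {
    stop("phenotype values outside [0, ", dist$window_seconds, "]", call. = FALSE)
  }
  set.seed(seed)
  dev <- sample(dist$deviations, length(y), replace = TRUE)
  phenotypes[[column]] <- pmin(dist$window_seconds,
                               pmax(0, y + dev * dist$window_seconds))
  phenotypes
}

#' Perturb-refit robustness study of the heritability estimate
#'
#' Repeats `n_replicates` times: perturb every phenotype with resampled
#' observation-window deviations, refit the animal model at a reduced MCMC
#' schedule, and record the posterior heritability point estimate. The
#' resulting distribution shows how sensitive the heritability estimate is
#' to sampling error of the short observation window. Replicates whose
#' refit fails are recorded, not fatal. Deterministic given `seed`
#' (per-replicate sub-seeds are drawn from the master seed).
#'
#' @inheritParams fit_animal_model
#' @param dist a [deviation_distribution()].
#' @param n_replicates number of perturb-refit cycles (the headline run
#'   uses 1000).
#' @param refit_cfg [mcmc_config()] for the refits; the default is the
#'   reduced schedule (13 000 iterations, burn-in 3000, thinning 10).
#' @param seed master RNG seed.
#' @param method point-estimate method passed to
#'   [heritability_posterior()].
#' @return A list of class `fh_perturbation`: `h2_estimates` (NA for failed
#'   replicates), `n_replicates`, `n_failed`, `seed`.
#' @export
perturbation_study <- function(phenotypes, A, spec = model_spec(),
                               priors = prior_spec(), dist,
                               n_replicates = 1000,
                               refit_cfg = mcmc_config(13000, 3000, 10),
                               seed = 1, method = "mode") {
  stopifnot(inherits(dist, "fh_deviations"), n_replicates >= 1)
  set.seed(seed)
  seeds_perturb <- sample.int(.Machine$integer.max - 1L, n_replicates)
  seeds_fit <- sample.int(.Machine$integer.max - 1L, n_replicates)
  h2 <- rep(NA_real_, n_replicates)
  for (r in seq_len(n_replicates)) {
    h2[r] <- tryCatch({
      pert <- perturb_phenotypes(phenotypes, dist, seed = seeds_perturb[r])
      cfg_r <- mcmc_config(refit_cfg$n_iterations, refit_cfg$burn_in,
                           refit_cfg$thin, seed = seeds_fit[r])
      fit <- fit_animal_model(pert, A, spec, priors, cfg_r)
      heritability_posterior(fit, method = method)$estimate
    }, error = function(e) NA_real_)
  }
  structure(list(h2_estimates = h2, n_replicates = n_replicates,
                 n_failed = sum(is.na(h2)), seed = seed),
            class = "fh_perturbation")
}

#' Summarize a perturbation study
#'
#' Range, sample skewness (standardized third moment) and the 5th
#' percentile (linear-interpolation quantile) of the replicate heritability
#' estimates; a strongly left-skewed distribution with a high 5th
#' percentile indicates robustness to observation-window sampling error.
#'
#' @param result an [perturbation_study()] result (or a numeric vector of
#'   estimates).
#' @return List with `min`, `max`, `skewness`, `percentile_05`, `n`.
#' @export
summarize_perturbation <- function(result) {
  x <- if (inherits(result, "fh_perturbation")) result$h2_estimates else as.numeric(result)
  x <- x[!is.na(x)]
  if (length(x) < 2) stop("need at least 2 successful replicates", call. = FALSE)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  skew <- if (s2 == 0) 0 else mean((x - m)^3) / s2^1.5
  list(min = min(x), max = max(x), skewness = skew,
       percentile_05 = unname(quantile(x, 0.05, type = 7)), n = length(x))
}

#' @export
print.fh_perturbation <- function(x, ...) {
  ok <- sum(!is.na(x$h2_estimates))
  cat(sprintf("Perturbation study: %d replicates (%d failed)\n",
              x$n_replicates, x$n_failed))
  if (ok >= 2) {
    s <- summarize_perturbation(x)
    cat(sprintf("h2 range %.3f-%.3f, skewness %.2f, 5th percentile %.3f\n",
                s$min, s$max, s$skewness, s$percentile_05))
  }
  invisible(x)
}
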