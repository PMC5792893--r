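## MCMC convergence diagnostics: lag autocorrelation and a
## Heidelberger-Welch stationarity test.

#' Sample autocorrelation at a given lag
#'
#' Standard sample autocorrelation (autocovariance at the lag divided by the
#' sample variance, both with divisor `n`). Thinning schedules are chosen to
#' keep this below 0.1 at lag 1 for the variance components.
#'
#' @param chain numeric sample sequence.
#' @param lag positive integer lag, less than the chain length.
#' @return Autocorrelation in `[-1, 1]`.
#' @export
lag_autocorrelation <- function(chain, lag = 1) {
  chain <- as.numeric(chain)
  lag <- as.integer(lag)
  if (lag < 1 || lag >= length(chain)) stop("need chain length > lag >= 1", call. = FALSE)
  if (var(chain) == 0) stop("chain has zero variance; autocorrelation undefined", call. = FALSE)
  drop(acf(chain, lag.max = lag, plot = FALSE, demean = TRUE)$acf[lag + 1])
}

#' Asymptotic CDF of the Cramer-von Mises statistic
#'
#' Four-term Bessel-function series for the limiting distribution of the
#' one-sample Cramer-von Mises statistic.
#' @noRd
pcramer <- function(q) {
  if (!is.finite(q) || q <= 0) return(0)
  # the 4-term series loses accuracy far in the upper tail; the CDF at 2 is
  # already 0.9999872, so clamp there
  if (q > 2) return(1)
  k <- 0:3
  term <- gamma(k + 0.5) * sqrt(4 * k + 1) / (gamma(0.5) * factorial(k)) *
    exp(-(4 * k + 1)^2 / (16 * q)) * besselK((4 * k + 1)^2 / (16 * q), 0.25)
  min(1, max(0, sum(term) / (pi * sqrt(q))))
}

#' Spectral density at frequency zero via an AR fit
#' @noRd
spectrum0_ar <- function(x) {
  x <- x - mean(x)
  if (var(x) == 0) return(0)
  fit <- ar(x, aic = TRUE, order.max = min(30L, length(x) - 1L))
  if (length(fit$ar) == 0) return(fit$var.pred)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Cramer-von Mises stationarity p-value for one window
#' @noRd
cvm_stationarity <- function(x) {
  n <- length(x)
  half <- x[(n %/% 2 + 1):n]
  s0 <- spectrum0_ar(half)
  if (s0 <= 0) s0 <- var(x)
  B <- cumsum(x) - seq_len(n) * mean(x)
  stat <- sum(B^2) / (n^2 * s0)
  list(stat = stat, p_value = 1 - pcramer(stat))
}

#' Heidelberger-Welch stationarity test
#'
#' Tests an MCMC chain for stationarity with a Cramer-von Mises statistic on
#' the standardized cumulative-sum (Brownian-bridge) process; the long-run
#' variance is the spectral density at zero, estimated by an AR fit to the
#' second half of the tested window. Following the standard iterative
#' procedure, if the full chain fails at level `alpha` the initial 10% is
#' discarded and the test repeated, up to a maximum discard of 50%;
#' `pass` reports whether any window passed and `start_fraction` the
#' fraction discarded. `p_value` is the full-chain (first-window) p-value,
#' which is the quantity with nominal size `alpha` under stationarity.
#'
#' @param chain numeric sample sequence of length >= 100 with nonzero
#'   variance.
#' @param alpha test level (default 0.05).
#' @return A list of class `fh_heidel`: `pass`, `p_value`, `stat`,
#'   `start_fraction`, `alpha`, and the per-window p-values.
#' @export
heidelberg_stationarity <- function(chain, alpha = 0.05) {
  chain <- as.numeric(chain)
  n <- length(chain)
  if (n < 100) stop("chain too short for a stationarity test (need >= 100)", call. = FALSE)
  if (var(chain) == 0) stop("chain has zero variance; stationarity test undefined", call. = FALSE)
  fracs <- seq(0, 0.5, by = 0.1)
  pvals <- rep(NA_real_, length(fracs))
  pass <- FALSE
  start_fraction <- NA_real_
  stat0 <- NA_real_
  for (i in seq_along(fracs)) {
    x <- chain[(floor(fracs[i] * n) + 1):n]
    res <- cvm_stationarity(x)
    pvals[i] <- res$p_value
    if (i == 1) stat0 <- res$stat
    if (res$p_value > alpha) {
      pass <- TRUE
      start_fraction <- fracs[i]
      break
    }
  }
  structure(list(pass = pass, p_value = pvals[1], stat = stat0,
                 start_fraction = start_fraction, alpha = alpha,
                 window_p_values = pvals),
            class = "fh_heidel")
}

#' @export
print.fh_heidel <- function(x, ...) {
  cat(sprintf("Heidelberger-Welch stationarity: %s (p = %.3f%s)\n",
              if (x$pass) "passed" else "FAILED", x$p_value,
              if (isTRUE(x$start_fraction > 0))
                sprintf(", after discarding initial %.0f%%", 100 * x$start_fraction)
              else ""))
  invisible(x)
}

#' Convergence diagnostics for every parameter of a fit
#'
#' Lag-1 autocorrelation and the Heidelberger-Welch stationarity test for
#' each stored parameter chain.
#'
#' @param chains an `fh_chains` object (or samples matrix).
#' @param alpha stationarity-test level.
#' @return Data frame with one row per parameter: `lag1_autocorrelation`,
#'   `heidel_pass`, `heidel_p_value`.
#' @export
diagnostics_report <- function(chains, alpha = 0.05) {
  s <- if (inherits(chains, "fh_chains")) chains$samples else as.matrix(chains)
  out <- data.frame(parameter = colnames(s),
                    lag1_autocorrelation = NA_real_,
                    heidel_pass = NA, heidel_p_value = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(ncol(s))) {
    x <- s[, i]
    if (var(x) == 0) next
    out$lag1_autocorrelation[i] <- lag_autocorrelation(x, 1)
    h <- heidelberg_stationarity(x, alpha)
    out$heidel_pass[i] <- h$pass
    out$heidel_p_value[i] <- h$p_value
  }
  out
}
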