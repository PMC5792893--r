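test_that("window deviations follow the forced arithmetic cases", {
  # constant 50% fanning: every window equals the hour-wide proportion
  x <- rep(c(1, 0), 1800)
  dd <- deviation_distribution(x)
  expect_length(dd$deviations, 12)
  expect_equal(dd$deviations, rep(0, 12), tolerance = 1e-12)
  expect_equal(dd$overall_proportion, 0.5)

  # fanning the entire first 30 minutes only: six +0.5 and six -0.5
  x <- c(rep(1, 1800), rep(0, 1800))
  dd <- deviation_distribution(x)
  expect_equal(sort(unique(dd$deviations)), c(-0.5, 0.5))
  expect_equal(sum(dd$deviations > 0), 6)

  # bout-interval input gives the same result as its indicator expansion
  bouts <- data.frame(start_s = c(0, 1000), end_s = c(600, 1600))
  ind <- rep(0, 3600); ind[c(1:600, 1001:1600)] <- 1
  expect_equal(deviation_distribution(bouts)$deviations,
               deviation_distribution(ind)$deviations)

  expect_error(deviation_distribution(rep(1, 100)), "shorter than one window")
})

test_that("deviations from tiling windows sum to zero; 11-window option drops one", {
  for (s in 1:5) {
    hr <- simulate_hour_record(seed = s)
    dd <- deviation_distribution(hr)
    expect_length(dd$deviations, 12)
    expect_lt(abs(sum(dd$deviations)), 1e-12)
    expect_true(all(abs(dd$deviations) <= 1))
    d11 <- deviation_distribution(hr, n_windows = 11)
    expect_length(d11$deviations, 11)
    expect_equal(d11$deviations, dd$deviations[1:11])
  }
})

test_that("perturbation clips to the observation window and respects zero deviations", {
  mk <- function(dev) structure(list(deviations = dev, window_seconds = 300,
                                     overall_proportion = 0.4),
                                class = "fh_deviations")
  ph <- data.frame(id = c("a", "b"), fanning_s = c(290, 10))
  up <- perturb_phenotypes(ph, mk(0.2), seed = 1)    # +60 s -> clipped to 300
  expect_equal(up$fanning_s, c(300, 70))
  down <- perturb_phenotypes(ph, mk(-0.1), seed = 1)  # -30 s -> clipped at 0
  expect_equal(down$fanning_s, c(260, 0))
  same <- perturb_phenotypes(ph, mk(rep(0, 5)), seed = 1)
  expect_equal(same$fanning_s, ph$fanning_s)
  expect_error(perturb_phenotypes(data.frame(fanning_s = 301), mk(0), 1), "outside")

  # always within [0, 300] whatever the deviations
  set.seed(2)
  for (i in 1:20) {
    ph <- data.frame(fanning_s = runif(30, 0, 300))
    out <- perturb_phenotypes(ph, mk(runif(12, -1, 1)), seed = i)
    expect_true(all(out$fanning_s >= 0 & out$fanning_s <= 300))
  }
})

test_that("zero-deviation perturbation study reproduces the unperturbed estimate", {
  d <- study_dataset(seed = 1)
  zero <- structure(list(deviations = rep(0, 12), window_seconds = 300,
                         overall_proportion = 0.4), class = "fh_deviations")
  base <- fit_animal_model(d$phenotypes, d$A, cfg = mcmc_config(13000, 3000, 10, seed = 5))
  h0 <- heritability_posterior(base)$estimate
  ps <- perturbation_study(d$phenotypes, d$A, dist = zero, n_replicates = 10, seed = 6)
  expect_equal(ps$n_failed, 0)
  expect_lt(abs(mean(ps$h2_estimates) - h0), 0.05)
})

test_that("single-replicate study is reproducible from its derived sub-seeds", {
  d <- study_dataset(seed = 2)
  dd <- deviation_distribution(simulate_hour_record(seed = 3))
  ps <- perturbation_study(d$phenotypes, d$A, dist = dd, n_replicates = 1, seed = 11)
  set.seed(11)
  s_pert <- sample.int(.Machine$integer.max - 1L, 1)
  s_fit <- sample.int(.Machine$integer.max - 1L, 1)
  pert <- perturb_phenotypes(d$phenotypes, dd, seed = s_pert)
  fit <- fit_animal_model(pert, d$A, cfg = mcmc_config(13000, 3000, 10, seed = s_fit))
  expect_equal(ps$h2_estimates, heritability_posterior(fit)$estimate)
})

test_that("wider deviations do not increase the mean heritability estimate", {
  d <- study_dataset(seed = 1)
  dd <- deviation_distribution(simulate_hour_record(seed = 4))
  means <- sapply(c(1, 2, 4), function(k) {
    dk <- structure(list(deviations = pmin(1, pmax(-1, k * dd$deviations)),
                         window_seconds = 300, overall_proportion = dd$overall_proportion),
                    class = "fh_deviations")
    ps <- perturbation_study(d$phenotypes, d$A, dist = dk, n_replicates = 40, seed = 21)
    mean(ps$h2_estimates, na.rm = TRUE)
  })
  expect_lte(means[2], means[1] + 0.02)
  expect_lte(means[3], means[2] + 0.02)
})

test_that("perturbation summaries compute range, skewness and the 5th percentile", {
  s <- summarize_perturbation(c(0.5, 0.5, 0.5))
  expect_equal(unlist(s[c("min", "max", "skewness", "percentile_05")]),
               c(min = 0.5, max = 0.5, skewness = 0, percentile_05 = 0.5))
  expect_lt(summarize_perturbation(c(0.1, 0.9, 0.9, 0.9, 0.9))$skewness, 0)
  expect_error(summarize_perturbation(c(0.5, NA)), "at least 2")

  # Beta(9, 1) draws: 5th percentile near the analytic quantile
  set.seed(5)
  x <- rbeta(1000, 9, 1)
  expect_lt(abs(summarize_perturbation(x)$percentile_05 - qbeta(0.05, 9, 1)), 0.02)
})
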