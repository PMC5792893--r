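test_that("inverse-gamma shape/scale conversion follows the (V, nu) rule", {
  expect_equal(inverse_gamma_shape_scale(1, 0.002), c(shape = 0.001, scale = 0.001))
  expect_equal(inverse_gamma_shape_scale(1, 2), c(shape = 1, scale = 1))
  expect_equal(inverse_gamma_shape_scale(4, 2), c(shape = 1, scale = 4))
  expect_error(inverse_gamma_shape_scale(0, 1), "positive")
  expect_error(inverse_gamma_shape_scale(1, -1), "positive")
})

test_that("MCMC schedule invariants are enforced", {
  cfg <- mcmc_config(10000, 1000, 5, seed = 3)
  expect_equal(cfg$thin, 5L)
  expect_error(mcmc_config(100, 100, 1), "burn_in")
  expect_error(mcmc_config(100, 10, 0), "thin")
  expect_error(mcmc_config(100, 99, 10), "stored")
})

test_that("degenerate inputs are rejected with model errors", {
  ped <- generate_pedigree(3, 2)
  A <- additive_relationship_matrix(ped)
  ph <- data.frame(id = ped$id[grepl("son|sire", ped$id)], fanning_s = 5)
  expect_error(fit_animal_model(ph, A, cfg = quick_cfg()), "zero phenotypic variance")

  ph$fanning_s <- rnorm(nrow(ph))
  ph$c1 <- 1:nrow(ph)
  ph$c2 <- 2 * ph$c1  # collinear
  expect_error(
    fit_animal_model(ph, A, model_spec(fixed_effects = c("c1", "c2")), cfg = quick_cfg()),
    "singular design")

  expect_error(fit_animal_model(rbind(ph, ph), A, cfg = quick_cfg()), "duplicated ids")
  ph2 <- ph
  ph2$id[1] <- "stranger"
  expect_error(fit_animal_model(ph2, A, cfg = quick_cfg()), "missing from the relationship matrix")
})

test_that("chains are bit-identical given the same seed and differ otherwise", {
  d <- study_dataset(seed = 2)
  f1 <- fit_animal_model(d$phenotypes, d$A, cfg = quick_cfg(seed = 9, n = 5000, burn = 500))
  f2 <- fit_animal_model(d$phenotypes, d$A, cfg = quick_cfg(seed = 9, n = 5000, burn = 500))
  f3 <- fit_animal_model(d$phenotypes, d$A, cfg = quick_cfg(seed = 10, n = 5000, burn = 500))
  expect_identical(f1$samples, f2$samples)
  expect_false(identical(f1$samples, f3$samples))
  expect_true(all(f1$samples[, c("V_A", "V_R")] > 0))
})

test_that("with no genetic effect the residual posterior matches the conjugate closed form", {
  set.seed(3)
  y <- rnorm(50, 10, 2)
  df <- data.frame(id = sprintf("i%02d", 1:50), fanning_s = y)
  fit <- fit_animal_model(df, A = NULL, model_spec(genetic = FALSE), prior_spec(),
                          mcmc_config(11000, 1000, 1, seed = 5))
  ve <- fit$samples[, "V_R"]
  # flat prior on the intercept integrates out: IG(a + (n-1)/2, b + S/2)
  S <- sum((y - mean(y))^2)
  cdf <- function(q) pgamma(1 / q, shape = 0.001 + 49 / 2, rate = 0.001 + S / 2,
                            lower.tail = FALSE)
  ks <- suppressWarnings(stats::ks.test(ve, cdf))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("posteriors concentrate at the prior when nu is large", {
  d <- study_dataset(seed = 4)
  strong <- prior_spec(V = 2, nu = 1e6)
  fit <- fit_animal_model(d$phenotypes, d$A, priors = strong,
                          cfg = quick_cfg(seed = 11, n = 5000, burn = 500))
  expect_equal(mean(fit$samples[, "V_A"]), 2, tolerance = 0.05)
  expect_equal(mean(fit$samples[, "V_R"]), 2, tolerance = 0.05)
})

test_that("posterior summaries are exchangeable under phenotype row permutation", {
  d <- study_dataset(seed = 5)
  cfg <- quick_cfg(seed = 12, n = 200000, burn = 10000, thin = 20)
  f1 <- fit_animal_model(d$phenotypes, d$A, cfg = cfg)
  set.seed(99)
  f2 <- fit_animal_model(d$phenotypes[sample(nrow(d$phenotypes)), ], d$A, cfg = cfg)
  h1 <- mean(f1$samples[, "V_A"] / rowSums(f1$samples[, c("V_A", "V_R")]))
  h2 <- mean(f2$samples[, "V_A"] / rowSums(f2$samples[, c("V_A", "V_R")]))
  # the posterior is wide at 13 families; Monte-Carlo error of the mean at
  # this chain length is ~0.03 per fit
  expect_equal(h1, h2, tolerance = 0.1)
  expect_equal(mean(f1$samples[, "(Intercept)"]), mean(f2$samples[, "(Intercept)"]),
               tolerance = 1.5)
})

test_that("a balanced design recovers a moderate true heritability", {
  ped <- generate_pedigree(100, 4)
  A <- additive_relationship_matrix(ped)
  ph <- simulate_ed5_phenotypes(ped, generator_config("recovery", h2_true = 0.5,
                                                      seed = 5001))
  fit <- fit_animal_model(ph, A, cfg = mcmc_config(50000, 5000, 20, seed = 7001))
  h <- heritability_posterior(fit)
  expect_lt(abs(h$estimate - 0.5), 0.2)
  expect_true(h$ci_low <= 0.5 && 0.5 <= h$ci_high)
})

test_that("the repeatability model recovers a high intraclass correlation", {
  obs <- simulate_repeat_observations(30, r_true = 0.9, v_total = 2000, seed = 31)
  fit <- fit_repeatability_model(obs, cfg = mcmc_config(30000, 3000, 10, seed = 32))
  expect_named(fit$ranef_means, "ID")
  r <- repeatability_posterior(fit)
  expect_lt(abs(r$estimate - 0.9), 0.15)
})
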