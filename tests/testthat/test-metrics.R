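test_that("component-ratio heritability reproduces the worked-table arithmetic", {
  expect_equal(round(heritability_from_components(3142.21, 3280.78), 2), 0.96)
  expect_equal(round(heritability_from_components(3192.59, 3543.40), 2), 0.90)
  expect_equal(heritability_from_components(0, 123), 0)
  expect_error(heritability_from_components(5, 4), "exceeds")
  expect_error(heritability_from_components(1, 0), "positive")
})

test_that("evolvability matches the worked-table values and its identity", {
  ev <- evolvability(3142.21, 39.47)
  expect_equal(round(ev$CV_A, 2), 142.02)
  expect_equal(round(ev$I_A, 2), 2.02)
  expect_equal(evolvability(0, 10)$CV_A, 0)
  expect_equal(evolvability(0, 10)$I_A, 0)
  expect_error(evolvability(1, 0), "positive")
  expect_error(evolvability(-1, 1), "non-negative")

  # I_A = (CV_A/100)^2 for any input
  set.seed(1)
  for (i in 1:50) {
    ev <- evolvability(rexp(1, 1e-3), rexp(1, 1e-2))
    expect_equal(ev$I_A, (ev$CV_A / 100)^2, tolerance = 1e-12)
  }
})

test_that("posterior heritability handles degenerate and exact chains", {
  mk <- function(va, vr) list(samples = cbind(V_A = va, V_R = vr))
  const <- mk(rep(3, 100), rep(1, 100))
  h <- heritability_posterior(structure(const, class = "fh_chains"))
  expect_equal(h$estimate, 0.75)
  expect_equal(c(h$ci_low, h$ci_high), c(0.75, 0.75))

  set.seed(2)
  v <- rexp(500) + 1
  equal <- structure(mk(v, v), class = "fh_chains")
  expect_equal(heritability_posterior(equal)$estimate, 0.5)

  zero <- structure(mk(rep(0, 100), rexp(100) + 1), class = "fh_chains")
  expect_equal(heritability_posterior(zero)$estimate, 0)

  expect_error(heritability_posterior(structure(list(samples = cbind(V_R = 1)),
                                                class = "fh_chains")), "V_A")
})

test_that("repeatability ratio mirrors the heritability ratio on V_ID", {
  mk <- function(vi, vr) structure(list(samples = cbind(V_ID = vi, V_R = vr)),
                                   class = "fh_chains")
  expect_equal(repeatability_posterior(mk(rep(9, 50), rep(1, 50)))$estimate, 0.9)
  expect_equal(repeatability_posterior(mk(rep(0, 50), rep(2, 50)))$estimate, 0)
})

test_that("posterior ratios always lie in [0, 1] and summaries are coherent", {
  set.seed(3)
  for (i in 1:20) {
    s <- cbind(V_A = rexp(300, 1 / 50), V_patch = rexp(300, 1 / 5), V_R = rexp(300, 1 / 20))
    h <- heritability_posterior(structure(list(samples = s), class = "fh_chains"))
    expect_gte(h$estimate, 0); expect_lte(h$estimate, 1)
    expect_gte(h$ci_low, 0); expect_lte(h$ci_high, 1)
    expect_lte(h$ci_low, h$ci_high)
  }
})

test_that("mode and mean point estimates agree on unimodal chains", {
  set.seed(4)
  for (i in 1:10) {
    x <- rnorm(3000, runif(1, 0.3, 0.7), 0.05)
    m1 <- posterior_summary(x, "mode")$estimate
    m2 <- posterior_summary(x, "mean")$estimate
    expect_lt(abs(m1 - m2), 0.05)
  }
})

test_that("pMCMC follows the two-sided sign-fraction convention", {
  expect_equal(pmcmc(c(1, -1, 2, 3)), 0.5)
  expect_equal(pmcmc(rep(1, 1000)), 0.002)  # floored at 2/n
  set.seed(5)
  z <- rnorm(10000)
  expect_gt(pmcmc(z), 0.9)
  # invariant to positive rescaling
  expect_equal(pmcmc(z * 37.5), pmcmc(z))
  expect_error(pmcmc(numeric(0)), "empty")
})

test_that("father-son regression behaves at its edge cases", {
  x <- c(1, 2, 3, 4)
  r <- suppressWarnings(parent_offspring_regression(x, x))  # perfect-fit lm warning
  expect_equal(r$slope, 1)
  expect_gt(r$t, 1e6)  # numerically collinear: enormous t, guarded
  expect_equal(r$df, 2L)
  expect_error(parent_offspring_regression(rep(1, 5), rnorm(5)), "constant")
  expect_error(parent_offspring_regression(1:2, 1:2), "3 families")
})

test_that("father-son regression recovers resemblance under high heritability", {
  slopes <- ses <- numeric(8)
  for (i in 1:8) {
    ped <- generate_pedigree(13, 2)
    ph <- simulate_ed5_phenotypes(ped, generator_config("recovery", n_sires = 13,
                                                        sons_per_sire = 2,
                                                        h2_true = 0.96, seed = 40 + i))
    fathers <- ph[grepl("^sire", ph$id), ]
    sons <- ph[grepl("^son", ph$id), ]
    fam_of <- sub("^son(\\d+)\\..*$", "\\1", sons$id)
    sm <- tapply(sons$fanning_s, fam_of, mean)
    fv <- fathers$fanning_s[order(sub("^sire", "", fathers$id))]
    r <- parent_offspring_regression(fv, sm[order(names(sm))])
    slopes[i] <- r$slope; ses[i] <- r$slope_se
  }
  # theory for a single-parent regression: E[slope] = h2 / 2 = 0.48
  # (oracle simulation: mean 0.471, sd 0.225 over 200 replicates)
  expect_lt(abs(mean(slopes) - 0.48), 3 * 0.225 / sqrt(length(slopes)))
  expect_true(all(ses > 0))
})
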