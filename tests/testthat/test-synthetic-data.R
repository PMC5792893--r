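test_that("generated pedigrees carry the intended family structure", {
  ped <- generate_pedigree(13, 2)
  expect_equal(nrow(ped), 52)

  A <- additive_relationship_matrix(generate_pedigree(1, 1))
  expect_equal(A["sire001", "son001.1"], 0.5)

  A2 <- additive_relationship_matrix(generate_pedigree(2, 3))
  expect_equal(A2["son001.1", "son001.2"], 0.5)   # full sibs within family
  expect_equal(A2["son001.1", "son002.1"], 0)     # unrelated across families

  Ah <- additive_relationship_matrix(generate_pedigree(2, 2, dams_known = FALSE))
  expect_equal(Ah["son001.1", "son001.2"], 0.25)  # half-sib coding
})

test_that("generator configuration validates its variance partition", {
  expect_error(generator_config("study", h2_true = 1.2), "h2_true")
  expect_error(generator_config("study", patch_variance_fraction = 1), "patch_variance")
  expect_error(generator_config("study", nonsense = 1), "unknown")
  cfg <- generator_config("study", n_sires = 4)
  expect_equal(cfg$n_sires, 4)
  expect_equal(cfg$trait_mean, 39.47)
  expect_equal(cfg$v_p_total, 3280.78)
})

test_that("simulated phenotypes stay in range and match their target moments", {
  ped <- generate_pedigree(13, 2)
  ph <- suppressWarnings(simulate_ed5_phenotypes(ped, generator_config("study", seed = 1)))
  expect_true(all(ph$fanning_s >= 0 & ph$fanning_s <= 300))
  expect_equal(nrow(ph), 39)  # 13 fathers + 26 sons
  expect_true(all(is.na(ph$patch[grepl("^sire", ph$id)])))

  # zero total variance: every value is the (clipped) mean
  flat <- simulate_ed5_phenotypes(ped, generator_config("study", v_p_total = 0, seed = 2))
  expect_true(all(flat$fanning_s == 39.47))

  # on the latent scale, large cohorts match the configured moments within 3 SE
  big <- generate_pedigree(150, 4)
  cfg <- generator_config("recovery", n_sires = 150, seed = 3)
  ph2 <- simulate_ed5_phenotypes(big, cfg, include_fathers = FALSE)
  lat <- attr(ph2, "truth")$latent
  n <- length(lat)
  expect_lt(abs(mean(lat) - cfg$trait_mean), 3 * sqrt(cfg$v_p_total / n))
  expect_lt(abs(var(lat) - cfg$v_p_total) / cfg$v_p_total, 3 * sqrt(2 / (n - 1)) + 0.1)
  expect_lt(attr(ph2, "truth")$clipped_fraction, 0.05)
})

test_that("heavy clipping triggers the diagnostic warning", {
  ped <- generate_pedigree(13, 2)
  expect_warning(simulate_ed5_phenotypes(ped, generator_config("study", seed = 4)),
                 "clipped")
})

test_that("zero heritability leaves no father-son resemblance", {
  ped <- generate_pedigree(40, 2)
  ph <- simulate_ed5_phenotypes(ped, generator_config("recovery", n_sires = 40,
                                                      sons_per_sire = 2,
                                                      h2_true = 0, seed = 5))
  fathers <- ph[grepl("^sire", ph$id), ]
  sons <- ph[grepl("^son", ph$id), ]
  fam <- sub("^son(\\d+)\\..*", "\\1", sons$id)
  sm <- tapply(sons$fanning_s, fam, mean)
  r <- parent_offspring_regression(fathers$fanning_s[order(sub("^sire", "", fathers$id))],
                                   sm[order(names(sm))])
  expect_true(abs(r$slope) <= 2.5 * r$slope_se)
})

test_that("true breeding values correlate with their posterior means", {
  ped <- generate_pedigree(100, 4)
  A <- additive_relationship_matrix(ped)
  ph <- simulate_ed5_phenotypes(ped, generator_config("recovery", h2_true = 0.9, seed = 6))
  fit <- fit_animal_model(ph, A, cfg = mcmc_config(20000, 2000, 10, seed = 7))
  truth <- attr(ph, "truth")$breeding_values
  est <- fit$ranef_means$A
  expect_gt(cor(truth[names(est)], est), 0.5)
})

test_that("simulated trajectories peak at hatching and degenerate cleanly", {
  ped <- generate_pedigree(13, 2)
  td <- simulate_trajectories(ped, generator_config("study", seed = 8))
  expect_true(all(td$fanning_s >= 0 & td$fanning_s <= 300))
  expect_equal(nrow(td), 26 * 6)
  egg_means <- tapply(td$fanning_s, td$day_code, mean)[c("1", "3", "5")]
  expect_equal(names(which.max(egg_means)), "5")

  # zero noise and zero random effects: all fish share one curve
  quietcfg <- generator_config("study", trajectory = list(
    beta0 = -43.75, beta1 = 37.9, beta2 = -3.79,
    sd_intercept = 0, sd_slope = 0, sd_curv = 0, sd_resid = 0), seed = 9)
  td0 <- simulate_trajectories(ped, quietcfg)
  per_day <- tapply(td0$fanning_s, td0$day_code, function(v) length(unique(v)))
  expect_true(all(per_day == 1))
})

test_that("repeated observations reproduce the intraclass correlation", {
  obs <- simulate_repeat_observations(100, r_true = 0.93, v_total = 2000, seed = 10)
  expect_equal(nrow(obs), 200)
  expect_lt(abs(icc_anova(obs) - 0.93), 0.05)

  # r = 1: both observations identical
  dup <- simulate_repeat_observations(10, r_true = 1, v_total = 500, seed = 11)
  expect_equal(dup$fanning_s[dup$obs == 1], dup$fanning_s[dup$obs == 2])

  # r = 0: between-observation correlation CI covers 0 most of the time
  cover <- sapply(1:40, function(s) {
    o <- simulate_repeat_observations(30, r_true = 0, v_total = 500, seed = 100 + s)
    ci <- stats::cor.test(o$fanning_s[o$obs == 1], o$fanning_s[o$obs == 2])$conf.int
    ci[1] <= 0 && 0 <= ci[2]
  })
  expect_gte(mean(cover), 0.9)
})

test_that("hour records behave like an alternating renewal process", {
  hr <- simulate_hour_record(seed = 12)
  expect_identical(hr, simulate_hour_record(seed = 12))
  expect_true(all(hr$end_s > hr$start_s))
  expect_true(all(hr$start_s >= 0 & hr$end_s <= 3600))

  # vanishing fanning when gaps dominate
  sparse <- simulate_hour_record(mean_bout_s = 1, mean_gap_s = 1e9, seed = 13)
  prop <- sum(sparse$end_s - sparse$start_s) / 3600
  expect_lt(prop, 0.05)

  # equal means: long-run proportion 0.5 within 3 SE over 100 records
  props <- sapply(1:100, function(s) {
    h <- simulate_hour_record(20, 20, seed = 200 + s)
    sum(h$end_s - h$start_s) / 3600
  })
  expect_lt(abs(mean(props) - 0.5), 3 * sd(props) / sqrt(100))
})
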