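## Synthetic study-like datasets with known ground truth: pedigrees, peak-day
## phenotypes under a chosen heritability, longitudinal trajectories,
## repeated observations and hour-long bout records.

#' Generator configuration
#'
#' Bundles every parameter of the synthetic-data generator. The `"study"`
#' preset emulates the study conditions: 13 wild-caught sires with 2
#' laboratory-reared sons each, peak-day fanning with mean 39.47 s and total
#' phenotypic variance 3280.78 s^2, heritability 0.95, a small common
#' rearing-environment (patch) component (2.35% of variance), covariates
#' (condition = weight/length, clutch size) with zero effect, a fanning
#' trajectory rising to a peak at the hatching day (day code 5) then
#' declining, and an hour record in which fanning occupies about 40% of
#' time. Values at that scale are clipped to [0, 300] s, which produces a
#' realistic share of non-fanning (zero) observations. The `"recovery"`
#' preset uses a large balanced design (100 sires x 4 sons) at a scale
#' where clipping is negligible (< 1%), for unbiased parameter-recovery
#' checks.
#'
#' @param preset `"study"` or `"recovery"`.
#' @param ... named overrides of any configuration field.
#' @return A list of class `fh_generator_config` with fields `n_sires`,
#'   `sons_per_sire`, `h2_true`, `trait_mean`, `v_p_total`,
#'   `patch_variance_fraction`, `n_patches`, `condition_beta`,
#'   `clutch_beta`, `trajectory` (list: `beta0`, `beta1`, `beta2`,
#'   `sd_intercept`, `sd_slope`, `sd_curv`, `sd_resid`), `bout` (list:
#'   `mean_bout_s`, `mean_gap_s`), `seed`.
#' @export
generator_config <- function(preset = c("study", "recovery"), ...) {
  preset <- match.arg(preset)
  cfg <- switch(preset,
    study = list(
      n_sires = 13, sons_per_sire = 2,
      h2_true = 0.95, trait_mean = 39.47, v_p_total = 3280.78,
      patch_variance_fraction = 0.0235, n_patches = 6,
      condition_beta = 0, clutch_beta = 0,
      trajectory = list(beta0 = -43.75, beta1 = 37.9, beta2 = -3.79,
                        sd_intercept = 15, sd_slope = 3, sd_curv = 0.4,
                        sd_resid = 18),
      bout = list(mean_bout_s = 3, mean_gap_s = 4.5),
      seed = 1),
    recovery = list(
      n_sires = 100, sons_per_sire = 4,
      h2_true = 0.5, trait_mean = 150, v_p_total = 3000,
      patch_variance_fraction = 0, n_patches = 0,
      condition_beta = 0, clutch_beta = 0,
      trajectory = list(beta0 = -43.75, beta1 = 37.9, beta2 = -3.79,
                        sd_intercept = 15, sd_slope = 3, sd_curv = 0.4,
                        sd_resid = 18),
      bout = list(mean_bout_s = 3, mean_gap_s = 4.5),
      seed = 1))
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad) > 0) stop("unknown generator field(s): ", paste(bad, collapse = ", "),
                            call. = FALSE)
  cfg[names(dots)] <- dots
  if (cfg$h2_true < 0 || cfg$h2_true > 1) stop("h2_true must be in [0, 1]", call. = FALSE)
  if (cfg$patch_variance_fraction < 0 || cfg$patch_variance_fraction >= 1) {
    stop("patch_variance_fraction must be in [0, 1)", call. = FALSE)
  }
  if (cfg$v_p_total < 0) stop("v_p_total must be >= 0", call. = FALSE)
  if (cfg$patch_variance_fraction > 0 && cfg$n_patches < 2) {
    stop("a patch variance fraction > 0 needs n_patches >= 2", call. = FALSE)
  }
  structure(cfg, class = "fh_generator_config")
}

#' Generate a study-design pedigree
#'
#' Unrelated, non-inbred founder sires; one founder dam per family;
#' `sons_per_sire` sons per family. With known dams the sons within a
#' family are full sibs (additive relatedness 0.5); `dams_known = FALSE`
#' drops the dams so sons are coded as half sibs (0.25), since a study may
#' not record dams in its animal model.
#'
#' @param n_sires,sons_per_sire counts (>= 1).
#' @param seed optional RNG seed (the layout is deterministic; kept for
#'   interface symmetry).
#' @param dams_known record the shared dam of each family?
#' @return A [pedigree()] in topological order.
#' @export
generate_pedigree <- function(n_sires, sons_per_sire, seed = NULL, dams_known = TRUE) {
  stopifnot(n_sires >= 1, sons_per_sire >= 1)
  sires <- sprintf("sire%03d", seq_len(n_sires))
  dams <- sprintf("dam%03d", seq_len(n_sires))
  sons <- as.vector(t(outer(seq_len(n_sires), seq_len(sons_per_sire),
                            function(i, j) sprintf("son%03d.%d", i, j))))
  son_sire <- rep(sires, each = sons_per_sire)
  son_dam <- if (dams_known) rep(dams, each = sons_per_sire) else rep(NA_character_, length(sons))
  if (dams_known) {
    pedigree(c(sires, dams, sons),
             c(rep(NA, 2 * n_sires), son_sire),
             c(rep(NA, 2 * n_sires), son_dam))
  } else {
    pedigree(c(sires, sons), c(rep(NA, n_sires), son_sire),
             c(rep(NA, n_sires), son_dam))
  }
}

#' Simulate peak-day (ED5) phenotypes with known ground truth
#'
#' Draws breeding values multivariate-normal with covariance
#' `A * V_A` where `V_A = h2_true * v_p_total * (1 - patch_variance_fraction)`,
#' adds patch effects (`V_patch = patch_variance_fraction * v_p_total`,
#' patches assigned round-robin across families to sons), covariate effects
#' and residuals (`V_R = v_p_total * (1 - patch_variance_fraction) *
#' (1 - h2_true)`), then clips to [0, 300] s. Sires and sons are
#' phenotyped; dams are not (as in the study design). The latent (unclipped)
#' ground truth is attached for oracle checks.
#'
#' @param ped a [pedigree()], e.g. from [generate_pedigree()].
#' @param cfg a [generator_config()].
#' @param include_fathers phenotype the founder sires as well as the sons?
#' @return Phenotype data frame (`id`, `day = "ED5"`, `fanning_s`,
#'   `condition`, `clutch_size`, `patch`) with attribute `truth`: a list
#'   holding the breeding values, patch effects, variance partition and the
#'   clipped fraction. Clipping above 10% triggers a diagnostic warning.
#' @export
simulate_ed5_phenotypes <- function(ped, cfg = generator_config(), include_fathers = TRUE) {
  stopifnot(inherits(ped, "fh_pedigree"), inherits(cfg, "fh_generator_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  A <- additive_relationship_matrix(ped)
  ids <- ped$id
  n_all <- length(ids)

  pf <- cfg$patch_variance_fraction
  v_a <- cfg$h2_true * cfg$v_p_total * (1 - pf)
  v_patch <- pf * cfg$v_p_total
  v_r <- cfg$v_p_total * (1 - pf) * (1 - cfg$h2_true)

  a <- if (v_a > 0) {
    drop(t(chol(unclass(A))) %*% rnorm(n_all)) * sqrt(v_a)
  } else {
    rep(0, n_all)
  }
  names(a) <- ids

  is_son <- grepl("^son", ids)
  is_sire <- grepl("^sire", ids)
  keep <- if (include_fathers) is_son | is_sire else is_son
  pheno_ids <- ids[keep]
  np <- length(pheno_ids)

  patch <- rep(NA_character_, np)
  patch_eff <- rep(0, np)
  patch_levels <- character(0)
  if (cfg$n_patches > 0) {
    patch_levels <- sprintf("patch%02d", seq_len(cfg$n_patches))
    sons_here <- grepl("^son", pheno_ids)
    assign <- rep_len(seq_len(cfg$n_patches), sum(sons_here))
    patch[sons_here] <- patch_levels[assign]
    eff <- rnorm(cfg$n_patches, 0, sqrt(v_patch))
    patch_eff[sons_here] <- eff[assign]
  }

  condition <- rnorm(np, 1.1, 0.15)
  clutch_size <- rnorm(np, 150, 30)
  latent <- cfg$trait_mean + a[pheno_ids] + patch_eff +
    cfg$condition_beta * (condition - 1.1) +
    cfg$clutch_beta * (clutch_size - 150) +
    rnorm(np, 0, sqrt(v_r))
  fanning <- pmin(300, pmax(0, latent))
  clipped <- mean(fanning != latent)
  if (clipped > 0.10) {
    warning(sprintf("%.0f%% of simulated values were clipped to [0, 300]", 100 * clipped),
            call. = FALSE)
  }

  out <- data.frame(id = pheno_ids, day = "ED5", fanning_s = unname(fanning),
                    condition = condition, clutch_size = clutch_size,
                    patch = patch, stringsAsFactors = FALSE)
  attr(out, "truth") <- list(breeding_values = a, patch_effects = patch_eff,
                             v_a = v_a, v_patch = v_patch, v_r = v_r,
                             clipped_fraction = clipped, latent = latent)
  out
}

#' Simulate per-fish fanning trajectories over the care period
#'
#' Each son gets a quadratic curve `beta0 + u0 + (beta1 + u1) day +
#' (beta2 + u2) day^2` with independent Gaussian fish-level deviations and
#' residual noise, evaluated at the six observation days and clipped to
#' [0, 300] s. The default coefficients put the population peak at day code
#' 5 (the hatching day).
#'
#' @inheritParams simulate_ed5_phenotypes
#' @param day_map day label-to-code map, see [day_codes()].
#' @return Long-format data frame (`id`, `day` label, `day_code`,
#'   `fanning_s`) with attribute `truth` (the generating coefficients).
#' @export
simulate_trajectories <- function(ped, cfg = generator_config(), day_map = day_codes()) {
  stopifnot(inherits(ped, "fh_pedigree"), inherits(cfg, "fh_generator_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  tr <- cfg$trajectory
  sons <- ped$id[grepl("^son", ped$id)]
  if (length(sons) == 0) sons <- ped$id[!is.na(ped$sire)]
  nf <- length(sons)
  u0 <- rnorm(nf, 0, tr$sd_intercept)
  u1 <- rnorm(nf, 0, tr$sd_slope)
  u2 <- rnorm(nf, 0, tr$sd_curv)
  d <- rep(day_map, times = nf)
  fish <- rep(seq_len(nf), each = length(day_map))
  latent <- tr$beta0 + u0[fish] + (tr$beta1 + u1[fish]) * d +
    (tr$beta2 + u2[fish]) * d^2 + rnorm(length(d), 0, tr$sd_resid)
  out <- data.frame(id = sons[fish], day = rep(names(day_map), times = nf),
                    day_code = unname(d),
                    fanning_s = pmin(300, pmax(0, latent)),
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- tr
  out
}

#' Simulate repeated short observations of the same males
#'
#' Two observations per male with a consistent male effect:
#' `male ~ N(0, r_true * v_total)`, residual `~ N(0, (1 - r_true) *
#' v_total)`, so the intraclass correlation equals `r_true`. Values are
#' left on the latent (unclipped) scale so closed-form ICC oracles apply
#' exactly.
#'
#' @param n_males number of males (>= 2).
#' @param r_true true repeatability in [0, 1].
#' @param v_total total variance (seconds^2).
#' @param seed RNG seed.
#' @param mean trait mean (seconds).
#' @return Data frame (`id`, `obs`, `fanning_s`).
#' @export
simulate_repeat_observations <- function(n_males = 5, r_true = 0.93,
                                         v_total = 3280.78, seed = 1, mean = 120) {
  stopifnot(n_males >= 2, r_true >= 0, r_true <= 1, v_total >= 0)
  set.seed(seed)
  male <- rnorm(n_males, 0, sqrt(r_true * v_total))
  idx <- rep(seq_len(n_males), each = 2)
  data.frame(id = sprintf("male%03d", idx),
             obs = rep(1:2, times = n_males),
             fanning_s = mean + male[idx] + rnorm(2 * n_males, 0, sqrt((1 - r_true) * v_total)),
             stringsAsFactors = FALSE)
}

#' Simulate an hour-long fanning bout record
#'
#' Alternating exponential fanning bouts and gaps, truncated at 3600 s. The
#' initial state is drawn with the stationary probability
#' `mean_bout_s / (mean_bout_s + mean_gap_s)` so the expected fanning
#' proportion matches the renewal-theory value from the start of the
#' record.
#'
#' @param mean_bout_s,mean_gap_s positive mean bout and gap lengths in
#'   seconds.
#' @param seed RNG seed.
#' @return Data frame of fanning bout intervals (`start_s`, `end_s`) with
#'   attribute `record_seconds = 3600`.
#' @export
simulate_hour_record <- function(mean_bout_s = 3, mean_gap_s = 4.5, seed = 1) {
  stopifnot(mean_bout_s > 0, mean_gap_s > 0)
  set.seed(seed)
  total <- 3600
  fanning <- runif(1) < mean_bout_s / (mean_bout_s + mean_gap_s)
  t <- 0
  starts <- ends <- numeric(0)
  while (t < total) {
    len <- rexp(1, 1 / if (fanning) mean_bout_s else mean_gap_s)
    t2 <- min(total, t + len)
    if (fanning) {
      starts <- c(starts, t)
      ends <- c(ends, t2)
    }
    t <- t2
    fanning <- !fanning
  }
  out <- data.frame(start_s = starts, end_s = ends)
  attr(out, "record_seconds") <- total
  out
}
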