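## Umbrella pipeline: A-matrix -> animal model(s) -> diagnostics -> derived
## statistics -> optional perturbation study, with a reproducible JSON
## summary.

#' Pipeline run configuration
#'
#' Collects every input and setting of [run_pipeline()]. `pedigree`,
#' `phenotypes` and `hour_record` may be file paths or in-memory objects.
#' All randomness flows from the single master `seed` (sub-seeds for each
#' stage are derived from it and echoed in the summary).
#'
#' @param pedigree path to a pedigree file or a [pedigree()] object.
#' @param phenotypes path to a phenotype file or a data frame.
#' @param day observation day analysed (rows with other days are dropped
#'   for the animal models).
#' @param fixed_effects covariates of the corrected model; covariates
#'   absent from the table are ignored with a message.
#' @param patch fit the corrected model with the patch random effect (if a
#'   `patch` column exists)?
#' @param priors a [prior_spec()].
#' @param mcmc an [mcmc_config()] for the headline fits (its seed is
#'   overridden by a sub-seed of `seed`).
#' @param hour_record optional bout-interval file/data frame for the
#'   perturbation study.
#' @param n_perturb number of perturb-refit replicates (0 disables the
#'   study).
#' @param refit_mcmc [mcmc_config()] for the perturbation refits.
#' @param point_method `"mode"` or `"mean"` point estimates.
#' @param out_dir optional output directory (chains CSV, text report and
#'   JSON summary are written there).
#' @param seed master seed.
#' @param quiet suppress progress messages?
#' @return A list of class `fh_run_config`.
#' @export
run_config <- function(pedigree, phenotypes, day = "ED5",
                       fixed_effects = c("condition", "clutch_size"),
                       patch = TRUE, priors = prior_spec(),
                       mcmc = mcmc_config(200000, 10000, 20),
                       hour_record = NULL, n_perturb = 0,
                       refit_mcmc = mcmc_config(13000, 3000, 10),
                       point_method = "mode", out_dir = NULL, seed = 1,
                       quiet = FALSE) {
  structure(list(pedigree = pedigree, phenotypes = phenotypes, day = day,
                 fixed_effects = fixed_effects, patch = patch, priors = priors,
                 mcmc = mcmc, hour_record = hour_record, n_perturb = n_perturb,
                 refit_mcmc = refit_mcmc, point_method = point_method,
                 out_dir = out_dir, seed = as.integer(seed), quiet = quiet),
            class = "fh_run_config")
}

#' @noRd
stage_msg <- function(quiet, ...) {
  if (!quiet) message(format(Sys.time(), "[%H:%M:%S] "), ...)
}

#' @noRd
summary_block <- function(s) {
  list(point = s$estimate, ci_low = s$ci_low, ci_high = s$ci_high, method = s$method)
}

#' Run the full heritability pipeline
#'
#' Executes the analysis sequence: build the additive relationship matrix,
#' fit the uncorrected animal model (intercept + genetic effect) on the
#' chosen day's phenotypes, run convergence diagnostics, derive
#' heritability and evolvability, then (when covariates/patch are present)
#' fit the corrected model and report pMCMC for each covariate, and
#' optionally run the observation-window perturbation study. Diagnostic
#' failures (lag-1 autocorrelation >= 0.1, Heidelberger-Welch fail) are
#' reported as warnings, not aborts. The JSON summary is byte-identical
#' across reruns with the same inputs and seed.
#'
#' @param cfg a [run_config()].
#' @return (Invisibly) a list with the summary list, the fitted chains and
#'   the perturbation result; written to `cfg$out_dir` when given
#'   (`summary.json`, `report.txt`, `chains_uncorrected.csv`,
#'   `chains_corrected.csv`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "fh_run_config"))
  quiet <- isTRUE(cfg$quiet)
  set.seed(cfg$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 4)

  ped <- if (inherits(cfg$pedigree, "fh_pedigree")) cfg$pedigree else read_pedigree(cfg$pedigree)
  pheno <- if (is.data.frame(cfg$phenotypes)) cfg$phenotypes else read_phenotypes(cfg$phenotypes)
  stage_msg(quiet, "inputs: ", nrow(ped), " pedigree entries, ", nrow(pheno), " phenotype rows")

  day_rows <- as.character(pheno$day) == as.character(cfg$day)
  focal <- pheno[day_rows, , drop = FALSE]
  if (nrow(focal) == 0) stop("no phenotype rows for day ", cfg$day, call. = FALSE)

  ## at least two sire families among the phenotyped individuals
  sire_of <- setNames(ped$sire, ped$id)
  fams <- unique(stats::na.omit(sire_of[as.character(focal$id)]))
  if (length(fams) < 2) stop("insufficient families: need phenotyped offspring of >= 2 sires",
                             call. = FALSE)

  stage_msg(quiet, "building additive relationship matrix")
  A <- additive_relationship_matrix(ped)

  stage_msg(quiet, "fitting uncorrected animal model")
  cfg_unc <- mcmc_config(cfg$mcmc$n_iterations, cfg$mcmc$burn_in, cfg$mcmc$thin,
                         seed = sub_seeds[1])
  fit_unc <- fit_animal_model(focal, A, model_spec(), cfg$priors, cfg_unc)

  diag_unc <- diagnostics_report(fit_unc)
  if (any(abs(diag_unc$lag1_autocorrelation) >= 0.1, na.rm = TRUE)) {
    warning("lag-1 autocorrelation >= 0.1 for: ",
            paste(diag_unc$parameter[abs(diag_unc$lag1_autocorrelation) >= 0.1],
                  collapse = ", "), call. = FALSE)
  }
  if (any(!diag_unc$heidel_pass, na.rm = TRUE)) {
    warning("Heidelberger-Welch stationarity failed for: ",
            paste(diag_unc$parameter[!diag_unc$heidel_pass], collapse = ", "),
            call. = FALSE)
  }

  h2_unc <- heritability_posterior(fit_unc, method = cfg$point_method)
  va_unc <- posterior_summary(fit_unc$samples[, "V_A"], method = cfg$point_method)
  vr_unc <- posterior_summary(fit_unc$samples[, "V_R"], method = cfg$point_method)
  mu_unc <- posterior_summary(fit_unc$samples[, "(Intercept)"], method = cfg$point_method)
  ev <- evolvability(va_unc$estimate, mu_unc$estimate)

  summary <- list(
    n_phenotyped = nrow(focal), n_pedigree = nrow(ped), day = cfg$day,
    uncorrected = list(
      h2 = summary_block(h2_unc), V_A = va_unc$estimate, V_R = vr_unc$estimate,
      predicted_mean = mu_unc$estimate, CV_A = ev$CV_A, I_A = ev$I_A),
    diagnostics = list(uncorrected = diag_unc),
    seeds = list(master = cfg$seed, uncorrected = sub_seeds[1],
                 corrected = sub_seeds[2], perturbation = sub_seeds[3]),
    config = list(mcmc = unclass(cfg$mcmc), refit_mcmc = unclass(cfg$refit_mcmc),
                  priors = list(default = as.list(cfg$priors$default)),
                  point_method = cfg$point_method, day = cfg$day))

  ## corrected model: available covariates as fixed effects, patch random
  fit_cor <- NULL
  fixed <- intersect(cfg$fixed_effects, names(focal))
  fixed <- fixed[vapply(fixed, function(f) !anyNA(focal[[f]]), logical(1))]
  use_patch <- isTRUE(cfg$patch) && "patch" %in% names(focal) && any(!is.na(focal$patch))
  if (length(fixed) > 0 || use_patch) {
    stage_msg(quiet, "fitting corrected animal model")
    cfg_cor <- mcmc_config(cfg$mcmc$n_iterations, cfg$mcmc$burn_in, cfg$mcmc$thin,
                           seed = sub_seeds[2])
    spec_cor <- model_spec(fixed_effects = fixed,
                           extra_random = if (use_patch) "patch" else character())
    fit_cor <- fit_animal_model(focal, A, spec_cor, cfg$priors, cfg_cor)
    h2_cor <- heritability_posterior(fit_cor, method = cfg$point_method)
    va_cor <- posterior_summary(fit_cor$samples[, "V_A"], method = cfg$point_method)
    mu_cor <- posterior_summary(fit_cor$samples[, "(Intercept)"], method = cfg$point_method)
    corrected <- list(h2 = summary_block(h2_cor), V_A = va_cor$estimate,
                      predicted_mean = mu_cor$estimate)
    if (use_patch) {
      pp <- 100 * ratio_posterior(fit_cor, "V_patch")
      corrected$patch_percent <- summary_block(posterior_summary(pp, method = cfg$point_method))
    }
    if (length(fixed) > 0) {
      corrected$pMCMC <- lapply(setNames(fixed, fixed), function(f)
        pmcmc(fit_cor$samples[, f]))
    }
    summary$corrected <- corrected
    summary$diagnostics$corrected <- diagnostics_report(fit_cor)
  }

  ## perturbation study
  pert <- NULL
  if (cfg$n_perturb > 0) {
    if (is.null(cfg$hour_record)) stop("perturbation study requires an hour record", call. = FALSE)
    hr <- if (is.data.frame(cfg$hour_record)) cfg$hour_record else {
      b <- read_delimited(cfg$hour_record)
      names(b) <- tolower(names(b))
      b
    }
    stage_msg(quiet, "running perturbation study (", cfg$n_perturb, " replicates)")
    dist <- deviation_distribution(hr)
    pert <- perturbation_study(focal, A, model_spec(), cfg$priors, dist,
                               n_replicates = cfg$n_perturb,
                               refit_cfg = cfg$refit_mcmc,
                               seed = sub_seeds[3], method = cfg$point_method)
    summary$perturbation <- c(summarize_perturbation(pert),
                              list(n_failed = pert$n_failed))
  }

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_chains(fit_unc, file.path(cfg$out_dir, "chains_uncorrected.csv"))
    if (!is.null(fit_cor)) write_chains(fit_cor, file.path(cfg$out_dir, "chains_corrected.csv"))
    jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
    writeLines(pipeline_report(summary), file.path(cfg$out_dir, "report.txt"))
    stage_msg(quiet, "wrote outputs to ", cfg$out_dir)
  }

  invisible(list(summary = summary, uncorrected = fit_unc, corrected = fit_cor,
                 perturbation = pert))
}

#' @noRd
pipeline_report <- function(s) {
  lines <- c(
    "Fanning heritability pipeline",
    sprintf("phenotyped individuals: %d (day %s); pedigree size: %d",
            s$n_phenotyped, s$day, s$n_pedigree),
    sprintf("h2 (uncorrected): %.2f (95%% CI %.2f-%.2f)",
            s$uncorrected$h2$point, s$uncorrected$h2$ci_low, s$uncorrected$h2$ci_high),
    sprintf("V_A %.2f s^2, V_R %.2f s^2, predicted mean %.2f s",
            s$uncorrected$V_A, s$uncorrected$V_R, s$uncorrected$predicted_mean),
    sprintf("CV_A %.2f%%, I_A %.2f", s$uncorrected$CV_A, s$uncorrected$I_A))
  if (!is.null(s$corrected)) {
    lines <- c(lines, sprintf("h2 (corrected): %.2f (95%% CI %.2f-%.2f)",
                              s$corrected$h2$point, s$corrected$h2$ci_low,
                              s$corrected$h2$ci_high))
    if (!is.null(s$corrected$patch_percent)) {
      lines <- c(lines, sprintf("patch: %.2f%% of variance (CI %.2f-%.2f%%)",
                                s$corrected$patch_percent$point,
                                s$corrected$patch_percent$ci_low,
                                s$corrected$patch_percent$ci_high))
    }
    for (f in names(s$corrected$pMCMC)) {
      lines <- c(lines, sprintf("pMCMC(%s) = %.3f", f, s$corrected$pMCMC[[f]]))
    }
  }
  if (!is.null(s$perturbation)) {
    lines <- c(lines, sprintf(
      "perturbation: h2 in [%.2f, %.2f], skewness %.2f, 5th percentile %.2f (%d failed)",
      s$perturbation$min, s$perturbation$max, s$perturbation$skewness,
      s$perturbation$percentile_05, s$perturbation$n_failed))
  }
  lines
}
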