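# Shared fixtures and independent oracles.

# Short MCMC schedule for unit tests (estimates at n <= 50 stabilize well
# before this).
quick_cfg <- function(seed = 1, n = 20000, burn = 2000, thin = 10) {
  mcmc_config(n, burn, thin, seed = seed)
}

# A random valid pedigree: founders first, later individuals draw known or
# unknown parents from earlier individuals (acyclic by construction).
random_pedigree <- function(n = 20, n_founders = 6, p_unknown = 0.2, seed = 1) {
  set.seed(seed)
  id <- sprintf("i%03d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in (n_founders + 1):n) {
    pool <- id[seq_len(i - 1)]
    pick <- sample(pool, 2)
    if (runif(1) > p_unknown) sire[i] <- pick[1]
    if (runif(1) > p_unknown) dam[i] <- pick[2]
  }
  pedigree(id, sire, dam)
}

# Gene-dropping oracle for expected relatedness: drop distinct founder
# alleles down the pedigree n_drops times; A[i,j] = 2 * kinship estimated
# from identity of randomly transmitted alleles. Returns the estimate and
# its Monte-Carlo standard error per pair.
gene_drop_amatrix <- function(ped, n_drops = 2e5, seed = 1) {
  set.seed(seed)
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  P <- matrix(0L, n_drops, n)  # paternal allele ids
  M <- matrix(0L, n_drops, n)  # maternal allele ids
  for (i in idx) {
    if (si[i] > 0L) {
      u <- runif(n_drops) < 0.5
      P[, i] <- ifelse(u, P[, si[i]], M[, si[i]])
    } else {
      P[, i] <- 2L * i - 1L  # unique founder allele
    }
    if (di[i] > 0L) {
      u <- runif(n_drops) < 0.5
      M[, i] <- ifelse(u, P[, di[i]], M[, di[i]])
    } else {
      M[, i] <- 2L * i
    }
  }
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  SE <- matrix(0, n, n)
  for (i in idx) {
    for (j in idx[idx <= i]) {
      if (i == j) {
        v <- 1 + (P[, i] == M[, i])
      } else {
        v <- 0.5 * ((P[, i] == P[, j]) + (P[, i] == M[, j]) +
                    (M[, i] == P[, j]) + (M[, i] == M[, j]))
      }
      A[i, j] <- A[j, i] <- mean(v)
      SE[i, j] <- SE[j, i] <- stats::sd(v) / sqrt(n_drops)
    }
  }
  list(A = A, SE = SE)
}

# Study-like dataset at the emulated design scale, with its relationship matrix.
study_dataset <- function(seed = 1, ...) {
  ped <- generate_pedigree(13, 2)
  A <- additive_relationship_matrix(ped)
  ph <- suppressWarnings(
    simulate_ed5_phenotypes(ped, generator_config("study", seed = seed, ...)))
  list(ped = ped, A = A, phenotypes = ph)
}

# Closed-form intraclass correlation from a one-way ANOVA with 2
# observations per group.
icc_anova <- function(obs) {
  f <- factor(obs$id)
  fit <- stats::aov(fanning_s ~ f, data = obs)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  (ms[1] - ms[2]) / (ms[1] + ms[2])
}
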