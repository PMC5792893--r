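## Internal Gibbs-sampling engine shared by the animal model, the
## repeatability model and the trajectory model.
##
## Model: y = X b + sum_k Z_k u_k + e, flat prior on b,
##        u_k ~ N(0, G_k v_k), e ~ N(0, I ve),
##        v_k, ve ~ inverse-gamma with shape/scale from (V, nu).
##
## With a single random component the location update is reduced once per
## fit to a diagonal problem by a generalized eigendecomposition of the
## pencil (W'W, blockdiag(0, G^-1)), making each iteration O(m); with
## several components a dense Cholesky of the location precision is taken
## every iteration (fine at the small sizes those models have).

#' @noRd
gibbs_lmm <- function(y, X, random = list(), priors, cfg) {
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n) stop("design/response dimension mismatch", call. = FALSE)
  if (qr(X)$rank < p) stop("singular design: collinear covariates", call. = FALSE)
  vy <- var(y)
  if (!is.finite(vy) || vy <= 0) stop("zero phenotypic variance in the response", call. = FALSE)

  K <- length(random)
  res_prior <- inverse_gamma_shape_scale(priors$residual[["V"]], priors$residual[["nu"]])
  init_ve <- vy / (K + 1)

  if (K <= 1) {
    Z <- if (K == 1) random[[1]]$Z else NULL
    W <- cbind(X, Z)
    m <- ncol(W)
    q <- m - p
    M1 <- crossprod(W)
    M2 <- matrix(0, m, m)
    if (K == 1) {
      G <- random[[1]]$Ginv
      if (is.null(G)) G <- diag(q)
      M2[(p + 1):m, (p + 1):m] <- G
    }
    R <- chol(M1 + M2)
    Rinv <- backsolve(R, diag(m))
    Kmat <- crossprod(Rinv, M1 %*% Rinv)
    ee <- eigen((Kmat + t(Kmat)) / 2, symmetric = TRUE)
    lambda <- pmin(pmax(ee$values, 0), 1)
    Phi <- Rinv %*% ee$vectors
    cvec <- drop(crossprod(Phi, crossprod(W, y)))

    if (K == 1) {
      rp <- inverse_gamma_shape_scale(random[[1]]$prior[["V"]], random[[1]]$prior[["nu"]])
    } else {
      rp <- c(shape = 0, scale = 0)
    }
    ## group repeated pencil eigenvalues so one evaluation of the collapsed
    ## variance posterior costs O(#distinct eigenvalues)
    o <- order(lambda)
    ls <- lambda[o]
    cs <- cvec[o]^2
    grp <- cumsum(c(TRUE, diff(ls) > 1e-9))
    lam_u <- as.numeric(tapply(ls, grp, mean))
    cnt <- as.numeric(tapply(ls, grp, length))
    sc <- as.numeric(tapply(cs, grp, sum))
    set.seed(cfg$seed)
    fit <- gibbs_spectral_cpp(lambda, cvec, lam_u, cnt, sc, sum(y^2), n, q,
                              Phi[seq_len(p), , drop = FALSE],
                              res_prior[["shape"]], res_prior[["scale"]],
                              rp[["shape"]], rp[["scale"]],
                              cfg$n_iterations, cfg$burn_in, cfg$thin,
                              init_ve, init_ve)
    ranef_means <- list()
    if (K == 1) {
      u <- drop(Phi %*% fit$eta_mean)[(p + 1):m]
      names(u) <- colnames(Z)
      ranef_means[[random[[1]]$name]] <- u
    }
    vnames <- if (K == 1) paste0("V_", random[[1]]$name) else character(0)
  } else {
    Zs <- lapply(random, `[[`, "Z")
    W <- do.call(cbind, c(list(X), Zs))
    sizes <- vapply(Zs, ncol, integer(1))
    offsets <- p + c(0L, cumsum(sizes))[seq_len(K)]  # 0-based for C++
    ginv <- lapply(random, function(r) if (is.null(r$Ginv)) diag(ncol(r$Z)) else r$Ginv)
    pri <- vapply(random, function(r)
      inverse_gamma_shape_scale(r$prior[["V"]], r$prior[["nu"]]), numeric(2))
    set.seed(cfg$seed)
    fit <- gibbs_general_cpp(y, W, crossprod(W), crossprod(W, y), ginv,
                             offsets, sizes, pri["shape", ], pri["scale", ],
                             res_prior[["shape"]], res_prior[["scale"]],
                             cfg$n_iterations, cfg$burn_in, cfg$thin,
                             rep(init_ve, K), init_ve, p)
    ranef_means <- list()
    for (k in seq_len(K)) {
      u <- fit$theta_mean[(offsets[k] + 1):(offsets[k] + sizes[k])]
      names(u) <- colnames(Zs[[k]])
      ranef_means[[random[[k]]$name]] <- u
    }
    vnames <- paste0("V_", vapply(random, `[[`, character(1), "name"))
  }

  samples <- fit$samples
  colnames(samples) <- c(colnames(X), vnames, "V_R")
  list(samples = samples, ranef_means = ranef_means)
}
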