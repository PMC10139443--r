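#' Per-individual inbreeding coefficients by EM
#'
#' For each individual, maximises the likelihood
#' `sum_s log sum_g GL(g) prior(g | p_s, F)` over the inbreeding coefficient
#' `F`, with the prior of [call_genotypes()].  For `F >= 0` the prior is the
#' mixture `(1-F) HWE + F (1-p, 0, p)` and EM on the latent identity-by-descent
#' indicator is used (monotone log-likelihood); if the EM solution hits the
#' zero boundary, the negative range is searched directly and the better
#' likelihood kept.  Estimates are clipped to `[-1, 1]`.
#'
#' @param glm a `gl_matrix`.
#' @param p per-site allele frequencies (defaults to `glm$maf`), in (0, 1):
#'   monomorphic sites are uninformative and dropped.
#' @param tol convergence tolerance on `|delta F|`.
#' @param max_iter EM iteration cap.
#' @return numeric vector of inbreeding coefficients, with attribute
#'   `loglik` (list of per-individual EM log-likelihood trajectories).
#' @export
inbreeding_em <- function(glm, p = NULL, tol = 1e-6, max_iter = 200) {
  stopifnot(inherits(glm, "gl_matrix"))
  if (is.null(p)) p <- glm$maf
  use <- p > 1e-6 & p < 1 - 1e-6
  if (!any(use)) stop("no polymorphic sites available")
  p <- p[use]
  n <- length(glm$ind)
  hwe <- cbind((1 - p)^2, 2 * p * (1 - p), p^2)
  ibd <- cbind(1 - p, 0, p)
  Fhat <- numeric(n)
  trajs <- vector("list", n)
  for (i in seq_len(n)) {
    L <- exp(glm$gl[use, i, , drop = TRUE])
    if (!is.matrix(L)) L <- matrix(L, nrow = 1)
    L[glm$missing[use, i], ] <- 1
    num_h <- rowSums(L * hwe)
    num_b <- rowSums(L * ibd)
    f <- 0.1
    ll <- numeric(0)
    for (it in seq_len(max_iter)) {
      tot <- (1 - f) * num_h + f * num_b
      ll <- c(ll, sum(log(tot)))
      z <- f * num_b / tot
      f_new <- mean(z)
      if (abs(f_new - f) < tol) { f <- f_new; break }
      f <- f_new
    }
    lfun <- function(ff) {
      pr <- genotype_prior(p, ff)
      sum(log(rowSums(L * pr)))
    }
    if (f < 1e-4) { # EM at the boundary: look on the negative side too
      opt <- stats::optimize(lfun, c(-1, 0), maximum = TRUE)
      if (opt$objective > lfun(f)) f <- opt$maximum
    }
    Fhat[i] <- max(-1, min(1, f))
    trajs[[i]] <- ll
  }
  names(Fhat) <- glm$ind
  attr(Fhat, "loglik") <- trajs
  Fhat
}

#' Genotype-likelihood PCA
#'
#' Iterative PCA in the spirit of low-coverage covariance estimation from
#' genotype likelihoods: posterior mean dosages are computed from the GLs
#' under per-individual allele frequencies, the frequencies are re-estimated
#' from a rank-`n_axes` reconstruction, and the standardised individual
#' covariance matrix
#' `C_ij = (1/S) sum_s (E[g_is] - 2 p_s)(E[g_js] - 2 p_s) / (2 p_s (1-p_s))`
#' is eigendecomposed.
#'
#' @param glm a `gl_matrix`.
#' @param n_axes number of leading axes for the frequency reconstruction.
#' @param tol convergence tolerance on the covariance change.
#' @param max_iter iteration cap; non-convergence yields a warning and the
#'   last iterate.
#' @return list with `cov`, `values`, `vectors`, `scores` (individuals x
#'   axes), `var_frac` (fraction of total variance per axis) and `iterations`.
#' @export
pca_gl <- function(glm, n_axes = 2, tol = 1e-6, max_iter = 100) {
  stopifnot(inherits(glm, "gl_matrix"))
  n <- length(glm$ind)
  if (n < 2 || nrow(glm$sites) < 2) stop("need at least 2 individuals and 2 sites")
  p <- pmin(pmax(glm$maf, 1e-4), 1 - 1e-4)
  S <- length(p)
  L0 <- t(exp(glm$gl[, , 1, drop = TRUE])); L1 <- t(exp(glm$gl[, , 2, drop = TRUE]))
  L2 <- t(exp(glm$gl[, , 3, drop = TRUE]))    # n x S
  miss <- t(glm$missing)
  Pi <- matrix(p, n, S, byrow = TRUE)
  C_old <- matrix(0, n, n)
  denom <- sqrt(2 * p * (1 - p))
  it <- 0
  repeat {
    it <- it + 1
    w0 <- L0 * (1 - Pi)^2; w1 <- L1 * 2 * Pi * (1 - Pi); w2 <- L2 * Pi^2
    Eg <- (w1 + 2 * w2) / (w0 + w1 + w2)
    Eg[miss] <- 2 * matrix(p, n, S, byrow = TRUE)[miss]
    M <- sweep(Eg, 2L, 2 * p, "-")
    M <- sweep(M, 2L, denom, "/")
    C <- tcrossprod(M) / S
    if (max(abs(C - C_old)) < tol || it >= max_iter) break
    C_old <- C
    # rank-K reconstruction of individual allele frequencies
    sv <- svd(M, nu = n_axes, nv = n_axes)
    R <- sv$u %*% (diag(sv$d[seq_len(n_axes)], n_axes) %*% t(sv$v))
    R <- sweep(R, 2L, denom, "*")
    Pi <- sweep(R, 2L, 2 * p, "+") / 2
    Pi <- pmin(pmax(Pi, 1e-4), 1 - 1e-4)
  }
  if (it >= max_iter && max(abs(C - C_old)) >= tol)
    warning("PCA iteration did not converge; returning last iterate")
  eg <- eigen(C, symmetric = TRUE)
  var_frac <- pmax(eg$values, 0) / sum(pmax(eg$values, 0))
  scores <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), n)
  rownames(scores) <- rownames(eg$vectors) <- glm$ind
  list(cov = C, values = eg$values, vectors = eg$vectors,
       scores = scores[, seq_len(min(n_axes, n)), drop = FALSE],
       var_frac = var_frac, iterations = it)
}

#' Admixture proportions by EM on genotype likelihoods
#'
#' Maximises
#' `l(Q, F) = sum_is log sum_g GL_is(g) Binom(g; 2, q_is)` with
#' `q_is = sum_k Q_ik F_ks` over admixture proportions `Q` (rows on the
#' simplex) and cluster allele frequencies `F`, by the standard EM that
#' attributes expected derived/ancestral allele copies to clusters.  Several
#' seeded restarts are run and the best likelihood kept; within a run the
#' log-likelihood is non-decreasing.  Clusters are reported sorted by total
#' mass so labels are deterministic.
#'
#' @param glm a `gl_matrix`.
#' @param K number of clusters (`1 <= K <= n`).
#' @param seed integer seed for the restarts.
#' @param tol relative log-likelihood tolerance.
#' @param max_iter EM iteration cap per restart.
#' @param n_restarts number of random restarts.
#' @return list with `Q` (individuals x K), `F` (K x sites), `loglik`
#'   (trajectory of the best run), `restart_loglik`.
#' @export
admixture_em <- function(glm, K, seed = 1, tol = 1e-7, max_iter = 1000,
                         n_restarts = 5) {
  stopifnot(inherits(glm, "gl_matrix"))
  n <- length(glm$ind)
  if (K < 1 || K > n) stop("K must be between 1 and the number of individuals")
  S <- nrow(glm$sites)
  L0 <- t(exp(glm$gl[, , 1, drop = TRUE])); L1 <- t(exp(glm$gl[, , 2, drop = TRUE]))
  L2 <- t(exp(glm$gl[, , 3, drop = TRUE]))
  best <- NULL
  restart_ll <- numeric(n_restarts)
  for (rs in seq_len(n_restarts)) {
    init <- with_seed(seed + rs - 1L, {
      Qr <- matrix(stats::rgamma(n * K, 1), n, K)
      Fr <- matrix(stats::runif(K * S, 0.05, 0.95), K, S)
      list(Q = Qr / rowSums(Qr), F = Fr)
    })
    Q <- init$Q; Fk <- init$F
    ll <- numeric(0)
    for (it in seq_len(max_iter)) {
      q <- Q %*% Fk                       # n x S
      q <- pmin(pmax(q, 1e-9), 1 - 1e-9)
      a0 <- L0 * (1 - q)^2; a1 <- L1 * 2 * q * (1 - q); a2 <- L2 * q^2
      tot <- a0 + a1 + a2
      ll_new <- sum(log(tot))
      d <- (a1 + 2 * a2) / tot            # expected derived copies
      Fk_new <- Fk; Q_new <- Q
      sumQ <- matrix(0, n, K)
      for (k in seq_len(K)) {
        wd <- sweep(d / q, 1L, Q[, k], "*") * matrix(Fk[k, ], n, S, byrow = TRUE)
        wa <- sweep((2 - d) / (1 - q), 1L, Q[, k], "*") *
          matrix(1 - Fk[k, ], n, S, byrow = TRUE)
        Fk_new[k, ] <- colSums(wd) / pmax(colSums(wd) + colSums(wa), 1e-300)
        sumQ[, k] <- rowSums(wd) + rowSums(wa)
      }
      Q_new <- sumQ / (2 * S)
      Q_new <- Q_new / rowSums(Q_new)
      Fk <- pmin(pmax(Fk_new, 1e-6), 1 - 1e-6)
      Q <- Q_new
      ll <- c(ll, ll_new)
      if (it > 1 && abs(ll_new - ll[it - 1L]) <= tol * abs(ll[it - 1L])) break
    }
    restart_ll[rs] <- ll[length(ll)]
    if (is.null(best) || restart_ll[rs] > best$ll_final) {
      best <- list(Q = Q, F = Fk, loglik = ll, ll_final = restart_ll[rs])
    }
  }
  ord <- order(-colSums(best$Q))
  Q <- best$Q[, ord, drop = FALSE]
  Fk <- best$F[ord, , drop = FALSE]
  rownames(Q) <- glm$ind
  colnames(Q) <- rownames(Fk) <- paste0("cluster", seq_len(K))
  list(Q = Q, F = Fk, loglik = best$loglik, restart_loglik = restart_ll)
}
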