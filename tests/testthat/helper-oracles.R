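# Independent oracle implementations used to cross-check the package's
# estimators on tiny instances.  These deliberately share no code with R/.

# exhaustive SAF: sum over all genotype configurations of prod GL * prod
# multiplicity, divided by choose(2n, j)
oracle_saf_bruteforce <- function(gl) {
  gl <- as.matrix(gl)
  n <- nrow(gl)
  lin <- exp(gl)
  configs <- as.matrix(expand.grid(rep(list(0:2), n)))
  out <- numeric(2 * n + 1)
  for (r in seq_len(nrow(configs))) {
    g <- configs[r, ]
    j <- sum(g)
    contrib <- prod(lin[cbind(seq_len(n), g + 1)]) * prod(choose(2, g))
    out[j + 1] <- out[j + 1] + contrib
  }
  out <- out / choose(2 * n, 0:(2 * n))
  log(out) - max(log(out))
}

# dense simplex grid search for a 3-class SFS (single diploid)
oracle_sfs_grid_3 <- function(saf_lin, res = 1e-3) {
  best <- NULL; best_ll <- -Inf
  for (a in seq(0, 1, by = res)) {
    b <- seq(0, 1 - a, by = res)
    for (bb in b) {
      phi <- c(a, bb, 1 - a - bb)
      ll <- sum(log(saf_lin %*% phi))
      if (ll > best_ll) { best_ll <- ll; best <- phi }
    }
  }
  list(phi = best, ll = best_ll)
}

# direct maximisation over the simplex via softmax + nlminb, multi-start
oracle_sfs_direct <- function(lik_matrix, n_starts = 8, seed = 1) {
  K <- ncol(lik_matrix)
  obj <- function(z) {
    phi <- exp(z - max(z)); phi <- phi / sum(phi)
    -sum(log(pmax(lik_matrix %*% phi, 1e-300)))
  }
  best <- NULL
  set.seed(seed)
  for (s in seq_len(n_starts)) {
    z0 <- rnorm(K)
    r <- nlminb(z0, obj)
    if (is.null(best) || r$objective < best$objective) best <- r
  }
  phi <- exp(best$par - max(best$par))
  list(phi = phi / sum(phi), ll = -best$objective)
}

# Tajima's D coded directly from the 1989 constants
oracle_tajima <- function(S, pi_sum, n) {
  if (S == 0) return(NA_real_)
  i <- 1:(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- (2 * (n^2 + n + 3)) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (pi_sum - S / a1) / sqrt((c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1))
}

# classic phase-unknown two-locus EM on hard genotype pairs
oracle_r2_genotypes <- function(g1, g2, iters = 2000) {
  n <- length(g1)
  h <- rep(0.25, 4)  # 00 01 10 11
  for (it in seq_len(iters)) {
    cnt <- numeric(4)
    for (i in seq_len(n)) {
      a <- g1[i]; b <- g2[i]
      if (a == 1 && b == 1) {
        # double het: split between cis (00/11) and trans (01/10)
        pc <- h[1] * h[4]; pt <- h[2] * h[3]
        w <- pc / (pc + pt)
        cnt[1] <- cnt[1] + w; cnt[4] <- cnt[4] + w
        cnt[2] <- cnt[2] + (1 - w); cnt[3] <- cnt[3] + (1 - w)
      } else {
        # unambiguous phases
        ha <- if (a == 0) c(0, 0) else if (a == 2) c(1, 1) else c(0, 1)
        hb <- if (b == 0) c(0, 0) else if (b == 2) c(1, 1) else c(0, 1)
        for (k in 1:2) {
          idx <- 1 + 2 * ha[k] + hb[k]
          cnt[idx] <- cnt[idx] + 1
        }
      }
    }
    h_new <- cnt / (2 * n)
    if (max(abs(h_new - h)) < 1e-12) { h <- h_new; break }
    h <- h_new
  }
  p1 <- h[3] + h[4]; p2 <- h[2] + h[4]
  D <- h[4] - p1 * p2
  list(h = h, D = D, r2 = D^2 / (p1 * (1 - p1) * p2 * (1 - p2)))
}

# second jackknife implementation (explicit loop)
oracle_jackknife <- function(values, block) {
  m <- length(values)
  B <- m %/% block
  id <- pmin(ceiling(seq_len(m) / block), B)
  thetas <- vapply(seq_len(B), function(b) mean(values[id != b]), 0)
  sqrt((B - 1) / B * sum((thetas - mean(thetas))^2))
}

# ---- fixture builders -----------------------------------------------------

# certain log-GL matrix (individuals x 3) from a dosage vector
gl_certain <- function(g, cert = 40) {
  out <- matrix(-cert, length(g), 3)
  out[cbind(seq_along(g), g + 1)] <- 0
  out
}

# noisy GLs: simulate reads at given depth for individuals with dosages g
gl_noisy <- function(g, depth = 6, eps = 0.01, seed = 1) {
  set.seed(seed)
  out <- matrix(0, length(g), 3)
  for (i in seq_along(g)) {
    d <- rpois(1, depth)
    if (d == 0) next
    p_alt <- g[i] / 2
    reads_alt <- rbinom(1, d, p_alt * (1 - eps) + (1 - p_alt) * eps)
    ll <- c(
      reads_alt * log(eps) + (d - reads_alt) * log(1 - eps),
      d * log(0.5),
      reads_alt * log(1 - eps) + (d - reads_alt) * log(eps))
    out[i, ] <- ll - max(ll)
  }
  out
}

# quick gl_matrix from a three-population simulation
sim_glm <- function(model, n_per_pop = 4, L = 5e4, mu = 2e-7, seed = 1,
                    depth = 8, eps = 0.005) {
  cfg <- sim_config(n_per_pop = n_per_pop, L = L, mu = mu, rec = 0, seed = seed)
  h <- simulate_genotypes(model, cfg)
  pile <- simulate_reads(h, depth, eps, seed + 1000)
  list(haps = h, glm = gl_matrix(pile))
}

two_pop_model <- function(N = 1000, T_split = 4000) {
  # Central merges early so effectively two demes (Andes, North) remain distinct
  three_pop_model("constant", N_anc = N, T_split_N = T_split, T_split_C = 1,
                  N_final = c(Andes = N, Central = N, North = N))
}

default_test_model <- function() {
  three_pop_model("constant", N_anc = 1000, T_split_N = 6000, T_split_C = 2000,
                  N_final = c(Andes = 1500, Central = 800, North = 600))
}
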