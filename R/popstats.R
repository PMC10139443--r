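#' Per-site expected diversity components
#'
#' Combines each site's SAF vector with the genome-wide SFS as an empirical
#' prior: the posterior over allele-count classes is
#' `P(j | D) \propto phi_j SAF(j)`.  Reports the posterior expectations of
#' pairwise diversity `pi` (heterozygosity `j (2n - j) / C(2n, 2)`), of the
#' per-site Watterson estimator (probability the site is segregating divided
#' by `a_{2n}`), and the segregation probability itself.  Both statistics are
#' invariant to folding.
#'
#' @param saf a `saf_set` or log-SAF matrix.
#' @param sfs an `sfs_1d` with matching `n_chr`.
#' @return data.frame with columns `pi`, `theta_w`, `p_seg`, one row per site.
#' @export
site_thetas <- function(saf, sfs) {
  A <- if (inherits(saf, "saf_set")) saf$saf else as.matrix(saf)
  stopifnot(inherits(sfs, "sfs_1d"))
  n_chr <- ncol(A) - 1L
  if (sfs$n_chr != n_chr) stop("SAF and SFS dimensions disagree")
  Alin <- exp(A)
  if (sfs$folded) Alin <- fold_saf_matrix(Alin, n_chr)
  W <- sweep(Alin, 2L, sfs$probs, "*")
  post <- W / rowSums(W)
  K <- ncol(post)
  j <- 0:(K - 1L)
  pi_class <- j * (n_chr - j) / choose(n_chr, 2)
  seg_class <- as.numeric(j != 0 & j != n_chr)
  if (sfs$folded) seg_class <- as.numeric(j != 0)  # class 0 holds both fixed states
  a_n <- sum(1 / seq_len(n_chr - 1L))
  data.frame(pi = as.vector(post %*% pi_class),
             p_seg = as.vector(post %*% seg_class),
             theta_w = as.vector(post %*% seg_class) / a_n)
}

#' Tajima's D
#'
#' Classic normalised difference between mean pairwise diversity and the
#' Watterson estimator, with the standard constants computed from the number
#' of sampled chromosomes.
#'
#' @param S number of segregating sites in the window.
#' @param pi_sum summed pairwise diversity over the window.
#' @param n number of sampled chromosomes (`>= 4`).
#' @return Tajima's D, or `NA` when `S = 0` (undefined).
#' @export
tajimas_d <- function(S, pi_sum, n) {
  stopifnot(n >= 4, S >= 0)
  if (S == 0) return(NA_real_)
  a1 <- sum(1 / seq_len(n - 1L))
  a2 <- sum(1 / seq_len(n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_sum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Windowed diversity statistics
#'
#' Sums per-site `pi` and segregation probabilities in sliding windows and
#' reports `pi`, Watterson's theta and Tajima's D per window.
#'
#' @param positions site positions (bp, 0-based) on one contig.
#' @param thetas per-site table from [site_thetas()].
#' @param n_chr number of sampled chromosomes.
#' @param window,step window size and step in bp.
#' @param min_sites minimum number of sites with data for a window to be kept.
#' @return data.frame of windows with `start`, `end`, `n_sites`, `S`, `pi`,
#'   `theta_w`, `tajima_d`.
#' @export
theta_windows <- function(positions, thetas, n_chr, window = 20000,
                          step = 20000, min_sites = 1) {
  o <- order(positions)
  positions <- positions[o]
  thetas <- thetas[o, , drop = FALSE]
  starts <- seq(0, max(positions), by = step)
  cs_pi <- cumsum(c(0, thetas$pi))
  cs_seg <- cumsum(c(0, thetas$p_seg))
  out <- lapply(starts, function(st) {
    i1 <- findInterval(st - 0.5, positions) + 1L
    i2 <- findInterval(st + window - 0.5, positions)
    n_sites <- i2 - i1 + 1L
    if (n_sites < max(1L, min_sites)) return(NULL)
    S <- cs_seg[i2 + 1L] - cs_seg[i1]
    pi_sum <- cs_pi[i2 + 1L] - cs_pi[i1]
    data.frame(start = st, end = st + window, n_sites = n_sites, S = S,
               pi = pi_sum, theta_w = S / sum(1 / seq_len(n_chr - 1L)),
               tajima_d = tajimas_d(S, pi_sum, n_chr))
  })
  do.call(rbind, out)
}

#' Per-site Fst variance components
#'
#' Posterior-expected sample allele frequencies are computed per site from
#' the pair of SAF vectors and the joint 2D-SFS prior, then turned into
#' per-site numerator/denominator components.  The default is the
#' Hudson-type estimator of Bhatia et al.:
#' `alpha = (p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)`,
#' `beta = p1(1-p2) + p2(1-p1)`; global weighted Fst is the ratio of sums
#' `sum(alpha) / sum(beta)`.  A Reynolds-type between-over-total variance
#' ratio is available behind `method = "reynolds"`.
#'
#' @param saf1,saf2 `saf_set`s (or log-SAF matrices) over the same sites.
#' @param sfs2d an `sfs_2d` prior for the pair.
#' @param method `"hudson"` (default) or `"reynolds"`.
#' @return data.frame with per-site `alpha`, `beta` and the posterior
#'   frequencies `p1`, `p2`.
#' @export
fst_components <- function(saf1, saf2, sfs2d, method = c("hudson", "reynolds")) {
  method <- match.arg(method)
  A1 <- if (inherits(saf1, "saf_set")) saf1$saf else as.matrix(saf1)
  A2 <- if (inherits(saf2, "saf_set")) saf2$saf else as.matrix(saf2)
  stopifnot(inherits(sfs2d, "sfs_2d"), nrow(A1) == nrow(A2))
  n1 <- ncol(A1) - 1L; n2 <- ncol(A2) - 1L
  if (n1 <= 1 || n2 <= 1) stop("need more than one chromosome per population")
  if (!all(sfs2d$n_chr == c(n1, n2))) stop("SAF and 2D-SFS dimensions disagree")
  # expand a folded prior symmetrically over each orbit
  pr <- sfs2d$probs
  if (sfs2d$folded) {
    rep_of <- fold_map_2d(n1, n2, sfs2d$convention)
    K <- length(rep_of)
    orbit_n <- tabulate(rep_of, nbins = K)[rep_of]
    pr <- matrix(as.vector(pr)[rep_of] / orbit_n, n1 + 1L, n2 + 1L)
  }
  L1 <- exp(A1); L2 <- exp(A2)
  # posterior expectations of j1 and j2
  prv <- as.vector(pr)
  i1 <- rep(0:n1, times = n2 + 1L)
  i2 <- rep(0:n2, each = n1 + 1L)
  W <- (L1[, i1 + 1L, drop = FALSE] * L2[, i2 + 1L, drop = FALSE])
  W <- sweep(W, 2L, prv, "*")
  rs <- rowSums(W)
  p1 <- as.vector(W %*% i1) / rs / n1
  p2 <- as.vector(W %*% i2) / rs / n2
  q1 <- 1 - p1; q2 <- 1 - p2
  if (method == "hudson") {
    alpha <- (p1 - p2)^2 - p1 * q1 / (n1 - 1) - p2 * q2 / (n2 - 1)
    beta <- p1 * q2 + p2 * q1
  } else {
    # between-population variance component over total (Reynolds-type)
    h1 <- p1 * q1 * n1 / (n1 - 1)
    h2 <- p2 * q2 * n2 / (n2 - 1)
    alpha <- (p1 - p2)^2 - h1 / n1 - h2 / n2
    beta <- alpha + h1 + h2
  }
  data.frame(alpha = alpha, beta = beta, p1 = p1, p2 = p2)
}

#' Weighted (ratio-of-sums) global Fst
#'
#' @param comp per-site components from [fst_components()].
#' @param weighted ratio of sums (default) or mean of per-site ratios.
#' @return a single Fst value.
#' @export
global_fst <- function(comp, weighted = TRUE) {
  if (weighted) sum(comp$alpha) / sum(comp$beta)
  else mean(comp$alpha / comp$beta, na.rm = TRUE)
}

#' Population branch statistic scan
#'
#' Computes, in sliding windows, the ratio-of-sums Fst for the three
#' population pairs, transforms each to a branch length
#' `T = -log(1 - Fst)` (negative window Fst is clamped to 0 first), and
#' reports the population branch statistic
#' `PBS_A = (T_AB + T_AC - T_BC) / 2` for each of the three populations.
#' Windows with fewer than `min_sites` data sites are excluded; the highest
#' `top_fraction` of windows per population (over retained, finite windows)
#' is flagged.  A window Fst of 1 or more yields an infinite branch length;
#' it is reported with a warning and excluded from the top-fraction ranking.
#'
#' @param positions site positions (bp, 0-based), one contig, sorted with the
#'   component tables.
#' @param comp_ab,comp_ac,comp_bc per-site components from
#'   [fst_components()] for the pairs (A,B), (A,C), (B,C), covering the same
#'   sites.
#' @param window,step window and step in bp (defaults 5000 / 500).
#' @param min_sites minimum sites with data per window (default 4000, the
#'   scale used for dense all-site data; lower it for SNP-only input).
#' @param top_fraction fraction of windows to flag per population.
#' @param pop_names names of populations A, B, C.
#' @return data.frame of windows: `start`, `end`, `n_sites`, pairwise
#'   `fst_*`, `pbs_*` and logical `top_*` flags.
#' @export
pbs_scan <- function(positions, comp_ab, comp_ac, comp_bc,
                     window = 5000, step = 500, min_sites = 4000,
                     top_fraction = 0.001,
                     pop_names = c("A", "B", "C")) {
  S <- length(positions)
  stopifnot(nrow(comp_ab) == S, nrow(comp_ac) == S, nrow(comp_bc) == S)
  o <- order(positions)
  positions <- positions[o]
  cs <- function(x) cumsum(c(0, x[o]))
  a_ab <- cs(comp_ab$alpha); b_ab <- cs(comp_ab$beta)
  a_ac <- cs(comp_ac$alpha); b_ac <- cs(comp_ac$beta)
  a_bc <- cs(comp_bc$alpha); b_bc <- cs(comp_bc$beta)
  starts <- seq(0, max(positions), by = step)
  i1 <- findInterval(starts - 0.5, positions) + 1L
  i2 <- findInterval(starts + window - 0.5, positions)
  n_sites <- i2 - i1 + 1L
  keep <- n_sites >= max(1L, min_sites)
  i1 <- i1[keep]; i2 <- i2[keep]; starts <- starts[keep]; n_sites <- n_sites[keep]
  wfst <- function(a, b) {
    num <- a[i2 + 1L] - a[i1]
    den <- b[i2 + 1L] - b[i1]
    pmax(num / den, 0)
  }
  fst_ab <- wfst(a_ab, b_ab); fst_ac <- wfst(a_ac, b_ac); fst_bc <- wfst(a_bc, b_bc)
  tt <- function(f) -log(1 - pmin(f, 1))
  t_ab <- tt(fst_ab); t_ac <- tt(fst_ac); t_bc <- tt(fst_bc)
  if (any(!is.finite(c(t_ab, t_ac, t_bc))))
    warning("window Fst >= 1 produced an infinite branch length; such windows are excluded from top-fraction ranking")
  pbs_a <- (t_ab + t_ac - t_bc) / 2
  pbs_b <- (t_ab + t_bc - t_ac) / 2
  pbs_c <- (t_ac + t_bc - t_ab) / 2
  flag <- function(x) {
    ok <- is.finite(x)
    k <- ceiling(top_fraction * sum(ok))
    out <- rep(FALSE, length(x))
    if (k > 0 && any(ok)) {
      thr <- sort(x[ok], decreasing = TRUE)[min(k, sum(ok))]
      out[ok] <- x[ok] >= thr
      # resolve ties beyond k deterministically by rank
      if (sum(out) > k) {
        ord <- order(-x, seq_along(x))
        out[] <- FALSE
        out[ord[seq_len(k)]] <- TRUE
        out[!is.finite(x)] <- FALSE
      }
    }
    out
  }
  res <- data.frame(start = starts, end = starts + window, n_sites = n_sites,
                    fst_ab = fst_ab, fst_ac = fst_ac, fst_bc = fst_bc,
                    t_ab = t_ab, t_ac = t_ac, t_bc = t_bc,
                    pbs_a = pbs_a, pbs_b = pbs_b, pbs_c = pbs_c,
                    top_a = flag(pbs_a), top_b = flag(pbs_b), top_c = flag(pbs_c))
  names(res) <- sub("_a$", paste0("_", pop_names[1]),
                sub("_b$", paste0("_", pop_names[2]),
                sub("_c$", paste0("_", pop_names[3]), names(res))))
  res
}
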