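#' Site-allele-frequency likelihood at one site
#'
#' Computes, by dynamic programming over individuals, the likelihood of one
#' population's read data at a site conditional on every possible derived (or
#' minor) allele count `j = 0..2n`.  Each individual contributes its genotype
#' likelihood triple weighted by the within-individual allele-count
#' multiplicity (1, 2, 1); the convolution is divided by `choose(2n, j)` so
#' entries are proportional to `P(data | j)` under random assignment of the
#' `j` alleles among the `2n` chromosomes.
#'
#' @param gl numeric matrix individuals x 3 of log-scaled genotype likelihood
#'   triples (hom-ancestral, het, hom-derived) for one population at one site.
#' @param missing optional logical vector; missing individuals are skipped, so
#'   the returned vector has length `2m + 1` for `m` non-missing individuals.
#' @param F optional per-individual inbreeding coefficients used as priors;
#'   positive values down-weight the heterozygote multiplicity to `2(1 - F)`.
#' @return log-scaled, max-normalised numeric vector of length `2m + 1`.
#' @export
saf_site <- function(gl, missing = NULL, F = 0) {
  gl <- as.matrix(gl)
  n <- nrow(gl)
  if (is.null(missing)) missing <- rep(FALSE, n)
  use <- which(!missing)
  if (!length(use)) stop("site with all individuals missing")
  F <- rep_len(F, n)
  h <- 1
  log_scale <- 0
  for (i in use) {
    tri <- exp(gl[i, ] - max(gl[i, ]))
    w <- c(tri[1], 2 * (1 - max(0, F[i])) * tri[2], tri[3])
    h <- .convolve3(h, w)
    m <- max(h)
    log_scale <- log_scale + log(m) + max(gl[i, ])
    h <- h / m
  }
  m2 <- length(use)
  out <- log(h) - lchoose(2 * m2, 0:(2 * m2))
  out - max(out)
}

.convolve3 <- function(h, w) {
  out <- numeric(length(h) + 2L)
  out[seq_along(h)] <- h * w[1]
  out[seq_along(h) + 1L] <- out[seq_along(h) + 1L] + h * w[2]
  out[seq_along(h) + 2L] <- out[seq_along(h) + 2L] + h * w[3]
  out
}

#' SAF records for every site of a population
#'
#' @param glm a `gl_matrix`.
#' @param pop_sel logical or index vector choosing the population's
#'   individuals (default: all).
#' @param F per-individual inbreeding priors.
#' @param project_to even integer `2n'`; sites with missing individuals are
#'   down-projected to this common size (hypergeometric projection with a
#'   uniform count prior) and sites with fewer than `n'` diploids are dropped.
#'   Default `NULL` keeps only sites with complete data.
#' @return a `saf_set`: list with `saf` (matrix sites x (2n+1), log-scaled),
#'   `site_idx` (indices into `glm$sites`), `n_chr` (the common 2n).
#' @export
saf_population <- function(glm, pop_sel = NULL, F = 0, project_to = NULL) {
  stopifnot(inherits(glm, "gl_matrix"))
  if (is.null(pop_sel)) pop_sel <- seq_along(glm$ind)
  gl <- glm$gl[, pop_sel, , drop = FALSE]
  miss <- glm$missing[, pop_sel, drop = FALSE]
  n <- length(seq_along(glm$ind)[pop_sel])
  S <- dim(gl)[1]
  full <- 2L * n
  n_chr <- if (is.null(project_to)) full else as.integer(project_to)
  if (n_chr %% 2L != 0L || n_chr < 2L || n_chr > full)
    stop("project_to must be an even count of chromosomes <= 2n")
  out <- matrix(NA_real_, S, n_chr + 1L)
  keep <- logical(S)
  for (s in seq_len(S)) {
    m <- sum(!miss[s, ])
    if (2L * m < n_chr) next
    v <- saf_site(gl[s, , , drop = TRUE], miss[s, ])
    if (2L * m > n_chr) v <- project_saf(v, n_chr)
    out[s, ] <- v
    keep[s] <- TRUE
  }
  structure(list(saf = out[keep, , drop = FALSE], site_idx = which(keep),
                 n_chr = n_chr, pop_sel = pop_sel),
            class = "saf_set")
}

#' Hypergeometric down-projection of a SAF vector
#'
#' @param saf log-scaled SAF vector over `0..2n`.
#' @param n_chr_to target chromosome count `2m < 2n`.
#' @return log-scaled, max-normalised SAF vector over `0..2m`.
#' @export
project_saf <- function(saf, n_chr_to) {
  n_from <- length(saf) - 1L
  if (n_chr_to == n_from) return(saf - max(saf))
  if (n_chr_to > n_from) stop("can only project downward")
  lin <- exp(saf - max(saf))
  out <- numeric(n_chr_to + 1L)
  for (k in 0:n_chr_to) {
    w <- stats::dhyper(k, 0:n_from, n_from - (0:n_from), n_chr_to)
    w <- if (sum(w) > 0) w / sum(w) else w
    out[k + 1L] <- sum(lin * w)
  }
  log(out) - max(log(out))
}

# fold map for a 1D spectrum over 0..n_chr: representative class of j is
# min(j, n_chr - j)
fold_saf_matrix <- function(A, n_chr) {
  half <- n_chr %/% 2L
  Af <- A[, 1:(half + 1L), drop = FALSE]
  for (j in 0:half) {
    conj <- n_chr - j
    if (conj != j) Af[, j + 1L] <- Af[, j + 1L] + A[, conj + 1L]
  }
  Af
}

#' EM estimation of the 1D site frequency spectrum
#'
#' Maximises `sum_s log sum_j phi_j SAF_s(j)` over the probability simplex by
#' EM.  With `folded = TRUE` the SAF classes `j` and `2n - j` are collapsed
#' first and the spectrum is estimated over minor-allele classes `0..n`.
#' The log-likelihood is non-decreasing at every iteration.
#'
#' @param saf a `saf_set` or a numeric matrix sites x (2n+1) of log-scaled
#'   SAF vectors.
#' @param folded estimate the folded (minor-allele) spectrum.
#' @param tol relative log-likelihood change for convergence.
#' @param max_iter EM iteration cap (default 400).
#' @return an `sfs_1d`: list with `counts` (expected site counts per class),
#'   `probs`, `folded`, `n_chr`, `loglik` trajectory, `iterations`.
#' @export
em_sfs_1d <- function(saf, folded = TRUE, tol = 1e-8, max_iter = 400) {
  A <- if (inherits(saf, "saf_set")) saf$saf else as.matrix(saf)
  if (!nrow(A)) stop("no SAF records supplied")
  n_chr <- ncol(A) - 1L
  Alin <- exp(A)
  if (folded) Alin <- fold_saf_matrix(Alin, n_chr)
  K <- ncol(Alin)
  phi <- rep(1 / K, K)
  ll <- numeric(0)
  for (it in seq_len(max_iter)) {
    W <- sweep(Alin, 2L, phi, "*")
    rs <- rowSums(W)
    ll_new <- sum(log(rs))
    phi <- colSums(W / rs) / nrow(Alin)
    ll <- c(ll, ll_new)
    if (it > 1 && abs(ll_new - ll[it - 1L]) <= tol * abs(ll[it - 1L])) break
  }
  structure(list(counts = phi * nrow(Alin), probs = phi, folded = folded,
                 n_chr = n_chr, total_sites = nrow(Alin), loglik = ll,
                 iterations = length(ll)),
            class = "sfs_1d")
}

#' @export
print.sfs_1d <- function(x, ...) {
  cat("sfs_1d (", if (x$folded) "folded" else "unfolded", "), 2n = ", x$n_chr,
      ", ", x$total_sites, " sites, ", x$iterations, " EM iterations\n", sep = "")
  print(round(x$counts, 3))
  invisible(x)
}

# orbit representatives for joint folding over a (K1 x K2) grid
# convention "pooled": fold cell (i, j) with (n1-i, n2-j) by overall minor
# allele; ties broken toward the lexicographically smaller cell.
fold_map_2d <- function(n1, n2, convention = c("pooled", "perpop")) {
  convention <- match.arg(convention)
  K1 <- n1 + 1L; K2 <- n2 + 1L
  idx <- matrix(seq_len(K1 * K2), K1, K2)
  rep_of <- integer(K1 * K2)
  for (j in 0:n2) for (i in 0:n1) {
    cell <- idx[i + 1L, j + 1L]
    if (convention == "pooled") {
      ci <- n1 - i; cj <- n2 - j
      tot <- i + j; ctot <- ci + cj
      choose_self <- tot < ctot || (tot == ctot && (i < ci || (i == ci && j <= cj)))
      rep_of[cell] <- if (choose_self) cell else idx[ci + 1L, cj + 1L]
    } else {
      ri <- min(i, n1 - i); rj <- min(j, n2 - j)
      rep_of[cell] <- idx[ri + 1L, rj + 1L]
    }
  }
  rep_of
}

#' EM estimation of the joint 2D site frequency spectrum
#'
#' As [em_sfs_1d()] with the frequency distribution over the joint
#' `(j1, j2)` grid of two populations.  Sites are processed in chunks and the
#' expected-count accumulators summed, so genome-scale inputs can be streamed.
#' Folding combines each cell with its complementary cell; under the default
#' `"pooled"` convention the complement is `(2n1 - j1, 2n2 - j2)` (overall
#' minor allele across the pooled pair), under `"perpop"` each axis is folded
#' by its own minor allele.
#'
#' @param saf1,saf2 `saf_set`s (or log-SAF matrices) for the two populations
#'   covering the same sites in the same order.
#' @param folded fold the spectrum.
#' @param convention folding convention, `"pooled"` (default) or `"perpop"`.
#' @param tol,max_iter EM controls.
#' @param chunk_size sites per accumulation chunk.
#' @return an `sfs_2d`: list with `counts` (matrix (2n1+1) x (2n2+1) of
#'   expected site counts; folded mass sits on the representative cells),
#'   `probs`, `folded`, `loglik`, `iterations`.
#' @export
em_sfs_2d <- function(saf1, saf2, folded = TRUE,
                      convention = c("pooled", "perpop"),
                      tol = 1e-8, max_iter = 400, chunk_size = 5000L) {
  convention <- match.arg(convention)
  A1 <- if (inherits(saf1, "saf_set")) saf1$saf else as.matrix(saf1)
  A2 <- if (inherits(saf2, "saf_set")) saf2$saf else as.matrix(saf2)
  if (nrow(A1) != nrow(A2)) stop("the two SAF sets must cover the same sites")
  if (!nrow(A1)) stop("no SAF records supplied")
  n1 <- ncol(A1) - 1L; n2 <- ncol(A2) - 1L
  S <- nrow(A1)
  K <- (n1 + 1L) * (n2 + 1L)
  rep_of <- if (folded) fold_map_2d(n1, n2, convention) else seq_len(K)
  reps <- sort(unique(rep_of))
  L1 <- exp(A1); L2 <- exp(A2)
  chunks <- split(seq_len(S), ceiling(seq_len(S) / chunk_size))
  phi <- numeric(K)
  if (folded) phi[reps] <- 1 / length(reps) else phi[] <- 1 / K
  ll <- numeric(0)
  for (it in seq_len(max_iter)) {
    acc <- numeric(K)
    ll_new <- 0
    for (ch in chunks) {
      # site x cell joint likelihood via row-wise outer products
      W <- (L1[ch, rep(1:(n1 + 1L), times = n2 + 1L), drop = FALSE] *
            L2[ch, rep(1:(n2 + 1L), each = n1 + 1L), drop = FALSE])
      if (folded) {
        # fold the likelihood onto representatives
        Wf <- W
        move <- which(rep_of != seq_len(K))
        for (cell in move) {
          Wf[, rep_of[cell]] <- Wf[, rep_of[cell]] + W[, cell]
          Wf[, cell] <- 0
        }
        W <- Wf
      }
      W <- sweep(W, 2L, phi, "*")
      rs <- rowSums(W)
      ll_new <- ll_new + sum(log(rs))
      acc <- acc + colSums(W / rs)
    }
    phi <- acc / S
    ll <- c(ll, ll_new)
    if (it > 1 && abs(ll_new - ll[it - 1L]) <= tol * abs(ll[it - 1L])) break
  }
  structure(list(counts = matrix(phi * S, n1 + 1L, n2 + 1L),
                 probs = matrix(phi, n1 + 1L, n2 + 1L),
                 folded = folded, convention = convention,
                 n_chr = c(n1, n2), total_sites = S,
                 loglik = ll, iterations = length(ll)),
            class = "sfs_2d")
}

#' @export
print.sfs_2d <- function(x, ...) {
  cat("sfs_2d (", if (x$folded) paste0("folded/", x$convention) else "unfolded",
      "), 2n = (", x$n_chr[1], ", ", x$n_chr[2], "), ", x$total_sites,
      " sites, ", x$iterations, " EM iterations\n", sep = "")
  invisible(x)
}

#' Remove sites inside (flank-expanded) genic intervals
#'
#' Expands every interval by `flank` bp on both sides, merges overlaps, and
#' drops the sites that fall inside any merged interval.  Intervals are
#' 0-based half-open, per contig.
#'
#' @param sites data.frame with columns `contig` and `position` (0-based).
#' @param genes data.frame with columns `contig`, `start`, `end` (0-based,
#'   half-open).
#' @param flank expansion in bp (default 1000).
#' @return logical vector, `TRUE` for retained sites.
#' @export
mask_genic <- function(sites, genes, flank = 1000) {
  keep <- rep(TRUE, nrow(sites))
  if (is.null(genes) || !nrow(genes)) return(keep)
  for (ct in unique(genes$contig)) {
    g <- genes[genes$contig == ct, , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(start = pmax(0, g$start - flank) + 1L,
                                           end = g$end + flank))
    sel <- which(sites$contig == ct)
    if (!length(sel)) next
    pos <- IRanges::IRanges(start = sites$position[sel] + 1L, width = 1L)
    hit <- IRanges::overlapsAny(pos, ir)
    keep[sel[hit]] <- FALSE
  }
  keep
}
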