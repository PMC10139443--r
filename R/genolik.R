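#' Genotype likelihoods from a read pileup
#'
#' Computes the likelihood of each diploid genotype from per-base read counts
#' under a symmetric base-error model: a read from an allele `a` reports `a`
#' with probability `1 - epsilon`, else one of the three other bases uniformly.
#' Heterozygotes emit each allele with probability 1/2.
#'
#' @param counts integer vector of length 4 (A, C, G, T counts), or a matrix
#'   with 4 columns (one row per site/individual cell).
#' @param alleles integer pair indexing the two alleles (1=A..4=T); genotypes
#'   are ordered (hom-allele1, het, hom-allele2).
#' @param epsilon base error rate in (0, 1).
#' @return numeric vector (or matrix) of log-scaled likelihood triples,
#'   max-normalised so the largest entry is 0.  Zero-read cells give a flat
#'   `(0, 0, 0)` triple with attribute handling left to the caller (see
#'   [gl_matrix()]).
#' @examples
#' gl_from_pileup(c(2, 0, 0, 0), c(1, 2), 0.01)
#' @export
gl_from_pileup <- function(counts, alleles, epsilon) {
  if (epsilon <= 0 || epsilon >= 1) stop("epsilon must be in (0, 1)")
  if (length(alleles) != 2L || alleles[1] == alleles[2])
    stop("alleles must be two distinct base indices")
  cm <- if (is.matrix(counts)) counts else matrix(counts, nrow = 1)
  if (ncol(cm) != 4L) stop("counts must have 4 base columns")
  p_match <- 1 - epsilon
  p_mis <- epsilon / 3
  # per-base emission probs under each genotype
  out <- matrix(0, nrow(cm), 3L)
  for (b in 1:4) {
    nb <- cm[, b]
    e1 <- if (b == alleles[1]) p_match else p_mis
    e2 <- if (b == alleles[2]) p_match else p_mis
    eh <- 0.5 * (e1 + e2)
    out[, 1] <- out[, 1] + nb * log(e1)
    out[, 2] <- out[, 2] + nb * log(eh)
    out[, 3] <- out[, 3] + nb * log(e2)
  }
  out <- out - apply(out, 1L, max)
  if (is.matrix(counts)) out else out[1L, ]
}

#' Build a genotype-likelihood matrix from a simulated pileup
#'
#' Applies [gl_from_pileup()] at every site/individual, estimates the minor
#' allele frequency by EM, and orients each triple as (hom-major, het,
#' hom-minor).  Cells with zero reads are flat and flagged missing.
#'
#' @param pileup a `read_pileup` from [simulate_reads()].
#' @param epsilon base error rate used for the likelihood model; defaults to
#'   the pileup's simulated error rate (floored at 1e-4 so the model stays
#'   proper).
#' @return a `gl_matrix`: list with `gl` (array sites x individuals x 3,
#'   log-scaled, max 0), `sites` (data.frame contig/position/major/minor/ref),
#'   `ind`, `pop`, `depth`, `missing` (logical matrix) and `maf` (EM minor
#'   allele frequency per site).
#' @export
gl_matrix <- function(pileup, epsilon = NULL) {
  stopifnot(inherits(pileup, "read_pileup"))
  if (is.null(epsilon)) epsilon <- max(pileup$error_rate, 1e-4)
  S <- dim(pileup$counts)[1]
  n <- dim(pileup$counts)[2]
  bases <- c("A", "C", "G", "T")
  ref_i <- match(pileup$ref, bases)
  alt_i <- match(pileup$alt, bases)
  gl <- array(0, dim = c(S, n, 3L))
  depth <- apply(pileup$counts, c(1, 2), sum)
  for (s in seq_len(S)) {
    cm <- pileup$counts[s, , , drop = TRUE]
    if (n == 1L) cm <- matrix(cm, nrow = 1)
    gl[s, , ] <- gl_from_pileup(cm, c(ref_i[s], alt_i[s]), epsilon)
  }
  missing <- depth == 0L
  gl[is.na(gl)] <- 0
  # orient by estimated frequency of the alt allele
  p_alt <- estimate_maf_matrix(gl, missing)
  swap <- p_alt > 0.5
  if (any(swap)) {
    gl[swap, , ] <- gl[swap, , 3:1, drop = FALSE]
    p_alt[swap] <- 1 - p_alt[swap]
  }
  major <- ifelse(swap, pileup$alt, pileup$ref)
  minor <- ifelse(swap, pileup$ref, pileup$alt)
  sites <- data.frame(contig = if (!is.null(pileup$contig)) pileup$contig else "contig01",
                      position = pileup$positions,
                      major = major, minor = minor, ref = pileup$ref,
                      stringsAsFactors = FALSE)
  structure(list(gl = gl, sites = sites, ind = pileup$ind,
                 pop = pileup$pop, depth = depth, missing = missing,
                 maf = p_alt, epsilon = epsilon),
            class = "gl_matrix")
}

#' @export
print.gl_matrix <- function(x, ...) {
  cat("gl_matrix:", nrow(x$sites), "sites x", length(x$ind), "individuals;",
      sprintf("%.1f%% missing cells\n", 100 * mean(x$missing)))
  invisible(x)
}

# gl_matrix from hard genotypes (certain likelihoods); used widely in tests
# and by pipelines that start from called data
gl_from_genotypes <- function(geno, positions = seq_len(ncol(geno)) * 10L,
                              pop = NULL, contig = "contig01", cert = 1e9) {
  S <- ncol(geno); n <- nrow(geno)
  gl <- array(-cert, dim = c(S, n, 3L))
  for (g in 0:2) for (i in seq_len(n)) {
    sel <- which(geno[i, ] == g)
    gl[sel, i, g + 1L] <- 0
  }
  miss <- is.na(geno)
  for (i in seq_len(n)) if (any(miss[i, ])) gl[which(miss[i, ]), i, ] <- 0
  structure(list(gl = gl,
                 sites = data.frame(contig = contig, position = positions,
                                    major = "A", minor = "C", ref = "A",
                                    stringsAsFactors = FALSE),
                 ind = if (is.null(rownames(geno)))
                   sprintf("ind%02d", seq_len(n)) else rownames(geno),
                 pop = if (is.null(pop)) factor(rep("Pop1", n)) else pop,
                 depth = matrix(ifelse(t(miss), 0L, 30L), S, n),
                 missing = t(miss), maf = colMeans(geno, na.rm = TRUE) / 2,
                 epsilon = 1e-4),
            class = "gl_matrix")
}

# EM for the minor allele frequency across all sites of a GL array
estimate_maf_matrix <- function(gl, missing, tol = 1e-6, max_iter = 100) {
  S <- dim(gl)[1]
  L0 <- exp(gl[, , 1, drop = FALSE][, , 1, drop = TRUE])
  L1 <- exp(gl[, , 2, drop = FALSE][, , 1, drop = TRUE])
  L2 <- exp(gl[, , 3, drop = FALSE][, , 1, drop = TRUE])
  if (S == 1L) { L0 <- matrix(L0, 1); L1 <- matrix(L1, 1); L2 <- matrix(L2, 1) }
  ok <- !missing
  n_ok <- rowSums(ok)
  if (any(n_ok == 0)) stop("site with no non-missing individuals")
  p <- rep(0.2, S)
  for (it in seq_len(max_iter)) {
    w0 <- (1 - p)^2 * L0
    w1 <- 2 * p * (1 - p) * L1
    w2 <- p^2 * L2
    tot <- w0 + w1 + w2
    eg <- (w1 + 2 * w2) / tot
    eg[!ok] <- 0
    p_new <- rowSums(eg) / (2 * n_ok)
    delta <- max(abs(p_new - p))
    p <- p_new
    if (delta < tol) break
  }
  p
}

#' EM estimate of the allele frequency at one site
#'
#' Maximises the site likelihood `prod_i sum_g GL_i(g) HWE(g | p)` over the
#' alternative/minor allele frequency `p` by EM on the expected dosage.  The
#' log-likelihood is non-decreasing across iterations.
#'
#' @param gl numeric matrix individuals x 3 of log-scaled genotype
#'   likelihoods ordered (hom-major, het, hom-minor).
#' @param missing optional logical vector flagging missing individuals.
#' @param tol convergence tolerance on `|delta p|`.
#' @param max_iter iteration cap.
#' @return the frequency estimate in `[0, 1]`.
#' @export
estimate_maf <- function(gl, missing = NULL, tol = 1e-8, max_iter = 200) {
  gl <- as.matrix(gl)
  if (is.null(missing)) missing <- rowSums(gl != 0) == 0 & FALSE
  if (all(missing)) stop("site with no non-missing individuals")
  a <- array(gl, dim = c(1L, nrow(gl), 3L))
  estimate_maf_matrix(aperm(a, c(1, 2, 3)), matrix(missing, nrow = 1),
                      tol = tol, max_iter = max_iter)
}

# site log-likelihood at frequency p (HWE), summing over non-missing individuals
site_loglik_at_p <- function(gl, p, missing = NULL) {
  gl <- as.matrix(gl)
  if (is.null(missing)) missing <- rep(FALSE, nrow(gl))
  L <- exp(gl[!missing, , drop = FALSE])
  sum(log(L[, 1] * (1 - p)^2 + L[, 2] * 2 * p * (1 - p) + L[, 3] * p^2))
}

#' Likelihood-ratio SNP test
#'
#' Tests polymorphism at a site: twice the log-likelihood gap between the EM
#' frequency estimate and the nearer monomorphic null (p = 0 or 1), referred
#' to a chi-square with 1 df.
#'
#' @param gl individuals x 3 log-GL matrix at one site.
#' @param p_hat frequency estimate from [estimate_maf()].
#' @param missing optional missingness flags.
#' @return list with `lrt`, `p_value`.
#' @export
snp_test <- function(gl, p_hat, missing = NULL) {
  ll_alt <- site_loglik_at_p(gl, p_hat, missing)
  ll_null <- max(site_loglik_at_p(gl, 0, missing),
                 site_loglik_at_p(gl, 1, missing))
  lrt <- max(0, 2 * (ll_alt - ll_null))
  list(lrt = lrt, p_value = stats::pchisq(lrt, df = 1, lower.tail = FALSE))
}

# genotype prior with inbreeding, clipped at zero and renormalised
genotype_prior <- function(p, F) {
  q <- p  # p = minor/alt frequency; ordering (hom-major, het, hom-minor)
  pr <- cbind((1 - q)^2 + q * (1 - q) * F,
              2 * q * (1 - q) * (1 - F),
              q^2 + q * (1 - q) * F)
  pr[pr < 0] <- 0
  pr / rowSums(pr)
}

#' Posterior genotype calling with an inbreeding-aware prior
#'
#' Combines genotype likelihoods with a Hardy-Weinberg prior extended by a
#' per-individual inbreeding coefficient and calls the maximum a posteriori
#' genotype when its posterior reaches the confidence threshold; the call is
#' set to missing otherwise.
#'
#' @param glm a `gl_matrix`.
#' @param p per-site minor allele frequencies (defaults to `glm$maf`).
#' @param F per-individual inbreeding coefficients in `[-1, 1]` (default 0).
#' @param confidence posterior required to emit a call (default 0.95).
#' @return integer matrix individuals x sites of minor-allele dosages with
#'   `NA` for no-calls.
#' @export
call_genotypes <- function(glm, p = NULL, F = 0, confidence = 0.95) {
  stopifnot(inherits(glm, "gl_matrix"))
  if (is.null(p)) p <- glm$maf
  if (any(p < 0 | p > 1)) stop("allele frequencies must be in [0, 1]")
  n <- length(glm$ind)
  F <- rep_len(F, n)
  if (any(F < -1 | F > 1)) stop("inbreeding coefficients must be in [-1, 1]")
  S <- nrow(glm$sites)
  geno <- matrix(NA_integer_, n, S)
  for (i in seq_len(n)) {
    pr <- genotype_prior(p, F[i])
    post <- exp(glm$gl[, i, , drop = TRUE]) * pr
    if (S == 1L) post <- matrix(post, nrow = 1)
    post <- post / rowSums(post)
    top <- max.col(post, ties.method = "first")
    conf <- post[cbind(seq_len(S), top)]
    call <- ifelse(conf >= confidence, top - 1L, NA_integer_)
    call[glm$missing[, i]] <- NA_integer_
    geno[i, ] <- call
  }
  rownames(geno) <- glm$ind
  geno
}

#' Site filter configuration
#'
#' @param snp_p_threshold SNP likelihood-ratio p-value cutoff.
#' @param min_maf minimum minor allele frequency.
#' @param prune_dist minimum distance (bp) between retained SNPs.
#' @param max_missing maximum fraction of individuals missing a call.
#' @param require_within_location drop sites with no data in any single
#'   sampling location.
#' @return a `site_filter_config` list.
#' @export
site_filter_config <- function(snp_p_threshold = 1e-6, min_maf = 0.05,
                               prune_dist = 500, max_missing = 0.20,
                               require_within_location = TRUE) {
  stopifnot(snp_p_threshold > 0, snp_p_threshold <= 1,
            min_maf >= 0, min_maf <= 0.5, prune_dist >= 0,
            max_missing >= 0, max_missing <= 1)
  structure(list(snp_p_threshold = snp_p_threshold, min_maf = min_maf,
                 prune_dist = prune_dist, max_missing = max_missing,
                 require_within_location = require_within_location),
            class = "site_filter_config")
}

#' SNP selection, distance pruning, and missingness filtering
#'
#' Applies the fixed filter order: likelihood-ratio SNP test, minimum minor
#' allele frequency, greedy left-to-right distance pruning (anchored at the
#' first SNP of each contig), then missingness rules on the called genotype
#' matrix (global missing fraction, and optionally any sampling location with
#' no data at all).
#'
#' @param glm a `gl_matrix`.
#' @param config a [site_filter_config()].
#' @param geno optional called genotype matrix (individuals x sites) for the
#'   missingness rules; when absent those rules are skipped.
#' @param location per-individual sampling-location labels (defaults to
#'   `glm$pop`).
#' @return integer vector of retained site indices, with an `attrition`
#'   attribute recording counts in/out per filter step.
#' @export
prune_and_filter <- function(glm, config = site_filter_config(), geno = NULL,
                             location = NULL) {
  stopifnot(inherits(glm, "gl_matrix"))
  if (is.null(location)) location <- glm$pop
  S <- nrow(glm$sites)
  keep <- seq_len(S)
  attrition <- c(input = S)
  # SNP LRT + MAF
  pv <- vapply(keep, function(s) {
    snp_test(glm$gl[s, , , drop = TRUE], glm$maf[s], glm$missing[s, ])$p_value
  }, 0)
  keep <- keep[pv[keep] < config$snp_p_threshold]
  attrition["snp_test"] <- length(keep)
  keep <- keep[pmin(glm$maf[keep], 1 - glm$maf[keep]) >= config$min_maf]
  attrition["maf"] <- length(keep)
  # greedy distance pruning per contig
  if (length(keep) && config$prune_dist > 0) {
    pruned <- integer(0)
    for (ct in unique(glm$sites$contig[keep])) {
      ks <- keep[glm$sites$contig[keep] == ct]
      ks <- ks[order(glm$sites$position[ks])]
      last <- -Inf
      for (s in ks) {
        if (glm$sites$position[s] - last >= config$prune_dist) {
          pruned <- c(pruned, s)
          last <- glm$sites$position[s]
        }
      }
    }
    keep <- sort(pruned)
  }
  attrition["prune"] <- length(keep)
  if (!is.null(geno) && length(keep)) {
    miss <- is.na(geno[, keep, drop = FALSE])
    keep <- keep[colMeans(miss) <= config$max_missing]
    attrition["max_missing"] <- length(keep)
    if (config$require_within_location && length(keep)) {
      miss <- is.na(geno[, keep, drop = FALSE])
      loc_all_missing <- vapply(seq_along(keep), function(j) {
        any(tapply(miss[, j], location, all))
      }, TRUE)
      keep <- keep[!loc_all_missing]
    }
    attrition["within_location"] <- length(keep)
  }
  attr(keep, "attrition") <- attrition
  keep
}

#' Per-region allele frequencies with the reference forced major
#'
#' Re-estimates, per region, the EM frequency of the non-reference allele with
#' the reference allele fixed as the major allele, for reporting frequencies
#' at designated loci (e.g. insecticide-resistance positions).
#'
#' @param glm a `gl_matrix`.
#' @param site_idx integer site indices or positions to report (matched
#'   against `glm$sites$position` when `by = "position"`).
#' @param region per-individual region labels (defaults to `glm$pop`).
#' @param by `"index"` or `"position"`.
#' @return data.frame with one row per site x region and column `freq`, the
#'   non-reference allele frequency.
#' @export
freq_at_sites <- function(glm, site_idx, region = NULL, by = c("index", "position")) {
  by <- match.arg(by)
  if (is.null(region)) region <- glm$pop
  if (by == "position") {
    idx <- match(site_idx, glm$sites$position)
    if (anyNA(idx)) stop("site not found at position(s) ",
                         paste(site_idx[is.na(idx)], collapse = ", "))
  } else {
    idx <- site_idx
    if (any(idx < 1 | idx > nrow(glm$sites))) stop("site index out of range")
  }
  res <- list()
  for (s in idx) {
    # orient triple so the reference allele is "major"
    triple <- glm$gl[s, , , drop = TRUE]
    if (glm$sites$major[s] != glm$sites$ref[s]) triple <- triple[, 3:1]
    for (rg in levels(factor(region))) {
      sel <- region == rg & !glm$missing[s, ]
      f <- if (!any(sel)) NA_real_ else estimate_maf(triple[sel, , drop = FALSE])
      res[[length(res) + 1L]] <- data.frame(
        contig = glm$sites$contig[s], position = glm$sites$position[s],
        region = rg, freq = f, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}
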