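#' Per-location allele count table
#'
#' Counts the two alleles of every site within each sampling location from a
#' called genotype matrix, the input format of F-statistics (and of
#' Treemix-style count files).
#'
#' @param geno called genotype matrix individuals x sites (minor-allele
#'   dosages, `NA` = missing).
#' @param location per-individual location labels.
#' @return a `count_table`: list with `a1` (major-allele counts, sites x
#'   locations), `a2` (minor), `n` (`a1 + a2`), `locations`.
#' @export
count_table <- function(geno, location) {
  location <- factor(location)
  S <- ncol(geno)
  locs <- levels(location)
  a2 <- matrix(0L, S, length(locs), dimnames = list(NULL, locs))
  n <- matrix(0L, S, length(locs), dimnames = list(NULL, locs))
  for (j in seq_along(locs)) {
    g <- geno[location == locs[j], , drop = FALSE]
    a2[, j] <- colSums(g, na.rm = TRUE)
    n[, j] <- 2L * colSums(!is.na(g))
  }
  structure(list(a1 = n - a2, a2 = a2, n = n, locations = locs),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", nrow(x$a2), "sites x", length(x$locations), "locations\n")
  invisible(x)
}

# per-site sample frequencies for one location; sites with n < 2 become NA
.ct_freq <- function(ct, pop) {
  j <- match(pop, ct$locations)
  if (is.na(j)) stop("unknown location: ", pop)
  n <- ct$n[, j]
  f <- ifelse(n >= 2L, ct$a2[, j] / n, NA_real_)
  list(p = f, n = n)
}

#' f2 drift distance between two populations
#'
#' Average over sites of `(pA - pB)^2` minus the finite-sample
#' heterozygosity corrections `pA(1-pA)/(nA-1) + pB(1-pB)/(nB-1)`; sites with
#' fewer than two sampled alleles in either population are skipped.
#'
#' @param ct a [count_table()].
#' @param A,B location names.
#' @param correction apply the finite-sample correction terms.
#' @return the f2 estimate, with attribute `n_used` (sites used) and
#'   `per_site` (per-site values).
#' @export
f2_hat <- function(ct, A, B, correction = TRUE) {
  fa <- .ct_freq(ct, A); fb <- .ct_freq(ct, B)
  use <- !is.na(fa$p) & !is.na(fb$p)
  pa <- fa$p[use]; pb <- fb$p[use]
  na <- fa$n[use]; nb <- fb$n[use]
  v <- (pa - pb)^2
  if (correction) v <- v - pa * (1 - pa) / (na - 1) - pb * (1 - pb) / (nb - 1)
  structure(mean(v), n_used = sum(use), per_site = v)
}

#' Delete-one block jackknife standard error
#'
#' Splits per-site values into consecutive blocks of `block` sites (a
#' trailing partial block is merged into the last full block), recomputes the
#' mean with each block deleted, and returns
#' `SE = sqrt((B-1)/B * sum_b (theta_(b) - mean(theta_(b)))^2)`.
#'
#' @param values per-site values, in genome order.
#' @param block block size in SNPs (default 500).
#' @return the jackknife SE, with attribute `n_blocks`.
#' @export
jackknife_se <- function(values, block = 500) {
  m <- length(values)
  B <- m %/% block
  if (B < 2) stop("need at least 2 jackknife blocks")
  id <- pmin(ceiling(seq_len(m) / block), B)  # partial tail merged into last
  tot <- sum(values)
  bs <- tapply(values, id, sum)
  bn <- tabulate(id, nbins = B)
  theta_b <- (tot - bs) / (m - bn)
  se <- sqrt((B - 1) / B * sum((theta_b - mean(theta_b))^2))
  structure(se, n_blocks = B)
}

#' f3 admixture statistic with block-jackknife errors
#'
#' Per-site `f3_s = (pA - pB)(pA - pC) - pA(1-pA)/(nA-1)`; the estimate is
#' the mean over sites, the standard error comes from a delete-one block
#' jackknife over consecutive blocks of `block` SNPs, and `Z = f3 / SE`.
#' A significantly negative f3 (`Z <= -3`) indicates that population `A` is
#' admixed from sources related to `B` and `C`.
#'
#' @param ct a [count_table()].
#' @param A target population; `B`, `C` the reference pair.
#' @param block jackknife block size in SNPs.
#' @param correction apply the target-heterozygosity correction; the
#'   denominator convention is `nA - 1` by default, `nA` with
#'   `denom = "n"`.
#' @param denom correction denominator convention.
#' @return an `f3_result`: list with `triplet`, `f3`, `se`, `z`,
#'   `significant` (`Z <= -3`), `n_sites`, `n_blocks`, `block`.
#' @export
f3_hat <- function(ct, A, B, C, block = 500, correction = TRUE,
                   denom = c("n-1", "n")) {
  denom <- match.arg(denom)
  fa <- .ct_freq(ct, A); fb <- .ct_freq(ct, B); fc <- .ct_freq(ct, C)
  use <- !is.na(fa$p) & !is.na(fb$p) & !is.na(fc$p)
  pa <- fa$p[use]; pb <- fb$p[use]; pc <- fc$p[use]
  na <- fa$n[use]
  v <- (pa - pb) * (pa - pc)
  if (correction) {
    dd <- if (denom == "n-1") na - 1 else na
    v <- v - pa * (1 - pa) / dd
  }
  if (sum(use) < 2 * block) stop("need at least 2 jackknife blocks (", 2 * block,
                                 " usable SNPs); got ", sum(use))
  se <- jackknife_se(v, block)
  f3 <- mean(v)
  z <- f3 / as.numeric(se)
  structure(list(triplet = sprintf("%s; %s, %s", A, B, C), f3 = f3,
                 se = as.numeric(se), z = z, significant = z <= -3,
                 n_sites = sum(use), n_blocks = attr(se, "n_blocks"),
                 block = block),
            class = "f3_result")
}

#' @export
print.f3_result <- function(x, ...) {
  cat(sprintf("f3(%s) = %.6g  SE = %.3g  Z = %.4g%s  (%d SNPs, %d blocks)\n",
              x$triplet, x$f3, x$se, x$z,
              if (x$significant) "  [significant admixture]" else "",
              x$n_sites, x$n_blocks))
  invisible(x)
}

#' All-triplet f3 scan
#'
#' @param ct a [count_table()].
#' @param targets optional subset of target populations.
#' @param block jackknife block size.
#' @return data.frame mirroring published F3 tables: `pop_a`, `pop_b`,
#'   `pop_c`, `f3`, `se`, `z`, `significant`.
#' @export
f3_scan <- function(ct, targets = NULL, block = 500) {
  locs <- ct$locations
  if (is.null(targets)) targets <- locs
  out <- list()
  for (A in targets) for (B in locs) for (C in locs) {
    if (A == B || A == C || B >= C) next
    r <- f3_hat(ct, A, B, C, block = block)
    out[[length(out) + 1L]] <- data.frame(pop_a = A, pop_b = B, pop_c = C,
                                          f3 = r$f3, se = r$se, z = r$z,
                                          significant = r$significant,
                                          stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
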