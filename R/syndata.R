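#' @useDynLib glpopgen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# run expr with a temporarily-seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulate haplotypes under a demographic model
#'
#' Draws genealogies from the backward-time coalescent with the model's
#' splits, size changes, growth, migration and admixture, recombination at
#' rate `config$rec`, and infinite-sites mutation at rate `config$mu`.
#' Deterministic given `config$seed`.
#'
#' @param model a [three_pop_model()] or [single_pop_model()].
#' @param config a [sim_config()].  Sequence mode supports at most 64
#'   haplotypes (32 diploids) in total.
#' @return a `haplotype_set` (or a list of them when `config$n_rep > 1`) with
#'   fields `positions` (0-based bp, strictly increasing), `haps` (binary
#'   matrix, haplotypes x sites, 1 = derived), `pop` (deme label per
#'   haplotype), `ref`/`alt` (ancestral/derived base per site) and `L`.
#' @export
simulate_genotypes <- function(model, config) {
  stopifnot(inherits(model, "demographic_model"), inherits(config, "sim_config"))
  cm <- compile_model(model, 2L * config$n_per_pop)
  reps <- cpp_coalescent_seq(cm$n_samp, cm$epochs, cm$events, cm$mig,
                             config$L, config$mu, config$rec,
                             config$n_rep, as.double(config$seed))
  pop <- factor(rep(cm$pops, cm$n_samp), levels = cm$pops)
  bases <- c("A", "C", "G", "T")
  out <- vector("list", config$n_rep)
  for (k in seq_len(config$n_rep)) {
    r <- reps[[k]]
    pos <- as.integer(floor(r$pos))
    keep <- !duplicated(pos)
    pos <- pos[keep]
    haps <- r$haps[, keep, drop = FALSE]
    o <- order(pos)
    pos <- pos[o]
    haps <- haps[, o, drop = FALSE]
    alle <- with_seed(config$seed + 7L * k, {
      ref <- sample(bases, length(pos), replace = TRUE)
      alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
      list(ref = ref, alt = unname(alt))
    })
    out[[k]] <- structure(list(positions = pos, haps = haps, pop = pop,
                               ref = alle$ref, alt = alle$alt, L = config$L,
                               contig = sprintf("contig%02d", k)),
                          class = "haplotype_set")
  }
  if (config$n_rep == 1L) out[[1L]] else out
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("haplotype_set:", nrow(x$haps), "haplotypes x", length(x$positions),
      "segregating sites over", x$L, "bp\n")
  print(table(x$pop))
  invisible(x)
}

#' Tabulate the joint site frequency spectrum by simulation
#'
#' Simulates `n_sims` independent single-site genealogies and accumulates the
#' expected branch length subtending every joint derived-allele-count class
#' across the sampled demes; with `theta_site > 0` it additionally drops
#' Poisson mutations on the branches and returns integer SNP counts per class.
#' Branch lengths give (up to a constant) the expected unlinked-site SFS under
#' the infinite-sites model; counts give a finite observed SFS.
#'
#' @param model a demographic model.
#' @param n_per_pop diploids sampled per deme.
#' @param n_sims number of independent genealogies.
#' @param seed integer seed.
#' @param theta_site per-locus scaled mutation rate (mu x locus length); 0
#'   disables mutation dropping.
#' @return list with `len` and `cnt` arrays (one dimension per deme, class
#'   `0..2n`), `pops`, and `tree_len_mean` (mean total tree length in
#'   generations).
#' @export
simulate_sfs <- function(model, n_per_pop, n_sims, seed, theta_site = 0) {
  stopifnot(inherits(model, "demographic_model"), n_sims >= 1)
  cm <- compile_model(model, 2L * n_per_pop)
  res <- cpp_coalescent_sfs(cm$n_samp, cm$epochs, cm$events, cm$mig,
                            theta_site, as.integer(n_sims), as.double(seed))
  dims <- res$dim
  len <- array(res$len, dim = dims)
  cnt <- array(res$cnt, dim = dims)
  list(len = len, cnt = cnt, pops = cm$pops, n_samp = cm$n_samp,
       tree_len_mean = res$tree_len_mean)
}

#' Simulate read pileups over a haplotype set
#'
#' Per site and diploid individual, sequencing depth is Poisson with the given
#' mean; each read reports a uniformly chosen one of the individual's two true
#' alleles with probability `1 - error_rate`, otherwise one of the three other
#' bases uniformly.  Individuals are formed by pairing consecutive haplotypes
#' within each deme.
#'
#' @param haps a `haplotype_set`.
#' @param mean_depth mean sequencing depth (x coverage), `>= 0`.
#' @param error_rate per-base error probability in `[0, 1)`.
#' @param seed integer seed.
#' @return a `read_pileup`: integer array `sites x individuals x 4` of base
#'   counts (A, C, G, T order) plus site/individual metadata.
#' @export
simulate_reads <- function(haps, mean_depth, error_rate, seed) {
  stopifnot(inherits(haps, "haplotype_set"))
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  if (mean_depth < 0) stop("mean_depth must be >= 0")
  n_hap <- nrow(haps$haps)
  if (n_hap %% 2L != 0L) stop("need an even number of haplotypes")
  n_ind <- n_hap %/% 2L
  S <- length(haps$positions)
  bases <- c("A", "C", "G", "T")
  ref_i <- match(haps$ref, bases)
  alt_i <- match(haps$alt, bases)
  h1 <- haps$haps[seq(1L, n_hap, by = 2L), , drop = FALSE]
  h2 <- haps$haps[seq(2L, n_hap, by = 2L), , drop = FALSE]
  counts <- array(0L, dim = c(S, n_ind, 4L))
  with_seed(seed, {
    depth <- matrix(stats::rpois(S * n_ind, mean_depth), nrow = S)
    for (i in seq_len(n_ind)) {
      for (s in seq_len(S)) {
        d <- depth[s, i]
        if (d == 0L) next
        pick <- stats::runif(d) < 0.5
        true_allele <- ifelse(pick, h1[i, s], h2[i, s])  # 0 anc / 1 der
        base <- ifelse(true_allele == 1L, alt_i[s], ref_i[s])
        err <- stats::runif(d) < error_rate
        if (any(err)) {
          n_err <- sum(err)
          shift <- sample.int(3L, n_err, replace = TRUE)
          base[err] <- ((base[err] - 1L + shift) %% 4L) + 1L
        }
        counts[s, i, ] <- counts[s, i, ] + tabulate(base, nbins = 4L)
      }
    }
  })
  ind_pop <- haps$pop[seq(1L, n_hap, by = 2L)]
  structure(list(counts = counts, positions = haps$positions,
                 ref = haps$ref, alt = haps$alt,
                 ind = sprintf("%s_%02d", as.character(ind_pop),
                               stats::ave(rep(1, n_ind), ind_pop, FUN = seq_along)),
                 pop = ind_pop, mean_depth = mean_depth,
                 error_rate = error_rate, contig = haps$contig),
            class = "read_pileup")
}

#' @export
print.read_pileup <- function(x, ...) {
  cat("read_pileup:", dim(x$counts)[1], "sites x", dim(x$counts)[2],
      "individuals, mean depth", x$mean_depth, "\n")
  invisible(x)
}

#' True genotype matrix of a haplotype set
#'
#' @param haps a `haplotype_set`.
#' @return integer matrix individuals x sites with derived-allele dosages 0/1/2.
#' @export
true_genotypes <- function(haps) {
  n_hap <- nrow(haps$haps)
  h1 <- haps$haps[seq(1L, n_hap, by = 2L), , drop = FALSE]
  h2 <- haps$haps[seq(2L, n_hap, by = 2L), , drop = FALSE]
  g <- h1 + h2
  rownames(g) <- sprintf("ind%02d", seq_len(nrow(g)))
  g
}
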