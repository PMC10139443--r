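# Reproducible simulation studies bundled with the package.  Each experiment
# generates data under known truth, runs the relevant pipeline stages, and
# returns summary recovery statistics.  The defaults are the desk-scale study
# conditions used by the package's validation suite.

#' Selection-scan sensitivity experiment
#'
#' Simulates three diverged demes, forces a hard-sweep-like frequency
#' perturbation (derived allele pushed to near fixation) in the North deme
#' over a 5-kb target region, runs the full genotype-likelihood pipeline
#' (reads -> GLs -> SAF -> 2D-SFS -> Fst -> PBS scan), and asks whether a
#' window overlapping the target exceeds the genome-wide 99.9th percentile
#' of North's PBS.
#'
#' @param n_rep replicates.
#' @param seed integer seed.
#' @param L genome length per replicate (bp).
#' @param depth,error_rate read-simulation settings.
#' @return list with `hits` (logical per replicate), `hit_rate`.
#' @export
experiment_pbs_sensitivity <- function(n_rep = 10, seed = 1, L = 2e5,
                                       depth = 6, error_rate = 0.005) {
  target <- c(100000, 105000)
  hits <- logical(n_rep)
  for (k in seq_len(n_rep)) {
    sd_k <- seed + 900L + k
    tp <- three_pop_model("constant", N_anc = 1000, T_split_N = 6000,
                          T_split_C = 2000,
                          N_final = c(Andes = 1500, Central = 800, North = 600))
    h <- simulate_genotypes(tp, sim_config(n_per_pop = 6, L = L, mu = 3e-7,
                                           seed = sd_k))
    north <- which(h$pop == "North")
    sel <- which(h$positions >= target[1] & h$positions < target[2])
    h$haps[north, sel] <- with_seed(sd_k + 5L, {
      block <- h$haps[north, sel, drop = FALSE]
      push <- matrix(stats::runif(length(block)) < 0.995, nrow(block))
      block[push] <- 1L
      block
    })
    pile <- simulate_reads(h, depth, error_rate, sd_k + 1L)
    glm <- gl_matrix(pile)
    safs <- lapply(c("Andes", "Central", "North"), function(p)
      saf_population(glm, glm$pop == p))
    names(safs) <- c("Andes", "Central", "North")
    common <- Reduce(intersect, lapply(safs, `[[`, "site_idx"))
    saf_of <- function(p) safs[[p]]$saf[match(common, safs[[p]]$site_idx), , drop = FALSE]
    A <- saf_of("Andes"); C <- saf_of("Central"); N <- saf_of("North")
    comp <- function(x, y) fst_components(x, y, em_sfs_2d(x, y))
    scan <- pbs_scan(glm$sites$position[common], comp(A, C), comp(A, N),
                     comp(C, N), window = 5000, step = 500, min_sites = 15,
                     pop_names = c("Andes", "Central", "North"))
    q999 <- stats::quantile(scan$pbs_North[is.finite(scan$pbs_North)], 0.999)
    hits[k] <- any(scan$start < target[2] & scan$end > target[1] &
                     scan$pbs_North >= q999, na.rm = TRUE)
  }
  list(hits = hits, hit_rate = mean(hits))
}

#' F3 admixture-detection experiment
#'
#' Simulates a deme founded as a 50/50 mixture of two deeply diverged
#' sources and tests that f3(Admixed; source1, source2) is significantly
#' negative (Z <= -3); also simulates clean three-population trees and
#' reports the tree f3 values (expected non-negative within error).
#'
#' @param n_rep admixture replicates.
#' @param n_tree tree replicates.
#' @param seed integer seed.
#' @return list with `z_admixed`, `detect_rate`, `tree_f3`, `tree_se`.
#' @export
experiment_f3_admixture <- function(n_rep = 10, n_tree = 5, seed = 1) {
  z <- numeric(n_rep)
  for (k in seq_len(n_rep)) {
    m_adm <- three_pop_model("constant", N_anc = 800, T_split_N = 9000,
                             T_split_C = 6000,
                             N_final = c(Andes = 800, Central = 800, North = 800),
                             admixture = list(sources = c("Andes", "North"),
                                              alpha = 0.5, time = 60, N = 800))
    h <- simulate_genotypes(m_adm, sim_config(n_per_pop = 6, L = 4e5,
                                              mu = 2e-7, seed = seed + 1200L + k))
    ct <- count_table(true_genotypes(h), h$pop[seq(1, nrow(h$haps), 2)])
    z[k] <- f3_hat(ct, "Admixed", "Andes", "North", block = 200)$z
  }
  tree_f3 <- tree_se <- numeric(n_tree)
  for (k in seq_len(n_tree)) {
    tp <- three_pop_model("constant", N_anc = 800, T_split_N = 6000,
                          T_split_C = 3000,
                          N_final = c(Andes = 800, Central = 800, North = 800))
    h <- simulate_genotypes(tp, sim_config(n_per_pop = 6, L = 3e5, mu = 2e-7,
                                           seed = seed + 1300L + k))
    ct <- count_table(true_genotypes(h), h$pop[seq(1, nrow(h$haps), 2)])
    r <- f3_hat(ct, "Andes", "Central", "North", block = 200)
    tree_f3[k] <- r$f3; tree_se[k] <- r$se
  }
  list(z_admixed = z, detect_rate = mean(z <= -3),
       tree_f3 = tree_f3, tree_se = tree_se)
}

# the desk-scale constant-variant truth shared by the demographic experiments
.desk_truth <- function() {
  list(par = c(N_anc = 1500, N_Andes = 1200, N_Central = 800, N_North = 600,
               T_split_C = 1500, T_split_N = 4000),
       model = three_pop_model("constant", N_anc = 1500, T_split_N = 4000,
                               T_split_C = 1500,
                               N_final = c(Andes = 1200, Central = 800,
                                           North = 600)),
       n_loci = 2000, theta_site = 1e-4, n_per_pop = 8)
}

.desk_truth_resize <- function() {
  list(model = three_pop_model("resize", N_anc = 1500, T_split_N = 4000,
                               T_split_C = 1500,
                               N_final = c(Andes = 1200, Central = 800,
                                           North = 600),
                               N_init = c(Andes = 400, Central = 400,
                                          North = 400),
                               T_resize = c(Andes = 1000, Central = 700,
                                            North = 1000)),
       n_loci = 2000, theta_site = 1e-4, n_per_pop = 8)
}

#' Split-time-ordering recovery experiment
#'
#' Fits the constant and resize model variants to data simulated under
#' desk-scale truths and reports whether each fit recovers the split
#' ordering `T_N > T_C` (and the recovered ratio).
#'
#' @param n_constant,n_resize replicate fits per variant.
#' @param seed integer seed.
#' @param n_sims,maxit,polish_n_sims fit settings (see [fit_model()]).
#' @return list with `ordered` (logical), `ratio` (fitted T_N / T_C),
#'   `order_rate`.
#' @export
experiment_split_ordering <- function(n_constant = 4, n_resize = 3, seed = 1,
                                      n_sims = 1000, maxit = 300,
                                      polish_n_sims = 6000) {
  ordered <- logical(0); ratio <- numeric(0)
  run1 <- function(variant, truth, k) {
    obs <- sfs_counts(truth$model, truth$n_per_pop, truth$n_loci,
                      truth$theta_site, seed + 5100L + k)
    fit <- fit_model(obs, variant, n_restarts = 2, n_sims = n_sims,
                     seed = seed + 620L + k, maxit = maxit,
                     polish_n_sims = polish_n_sims, polish_maxit = 100)
    fit$par[["T_split_N"]] / fit$par[["T_split_C"]]
  }
  for (k in seq_len(n_constant)) {
    r <- run1("constant", .desk_truth(), k)
    ordered <- c(ordered, r > 1); ratio <- c(ratio, r)
  }
  for (k in seq_len(n_resize)) {
    r <- run1("resize", .desk_truth_resize(), 100L + k)
    ordered <- c(ordered, r > 1); ratio <- c(ratio, r)
  }
  list(ordered = ordered, ratio = ratio, order_rate = mean(ordered))
}

#' Parametric-bootstrap coverage experiment
#'
#' Repeatedly simulates data under the desk-scale constant-variant truth,
#' fits the model, runs the parametric bootstrap, and reports the fraction
#' of (replicate x parameter) checks for which the 95% interval covers the
#' generating value.
#'
#' @param n_rep calibration replicates.
#' @param n_boot bootstrap replicates per fit.
#' @param seed integer seed.
#' @param n_sims,maxit,polish_n_sims fit settings.
#' @return list with `cover` (matrix replicates x parameters), `coverage`.
#' @export
experiment_bootstrap_coverage <- function(n_rep = 3, n_boot = 8, seed = 1,
                                          n_sims = 2500, maxit = 300,
                                          polish_n_sims = 10000) {
  truth <- .desk_truth()
  cover <- NULL
  for (k in seq_len(n_rep)) {
    obs <- sfs_counts(truth$model, truth$n_per_pop, truth$n_loci,
                      truth$theta_site, seed + 5100L + k)
    # the calibration fit uses a higher simulation budget than the bootstrap
    # refits: random restarts must locate the global basin on the Monte-Carlo
    # surface, whereas refits start at the parent MLE and only track it
    fit <- fit_model(obs, "constant", n_restarts = 3, n_sims = n_sims,
                     seed = seed + 620L + k, maxit = maxit,
                     polish_n_sims = polish_n_sims, polish_maxit = 150)
    fit <- parametric_bootstrap(fit,
                                list(n_loci = truth$n_loci,
                                     theta_site = truth$theta_site),
                                reps = n_boot, seed = seed + 720L + k,
                                n_restarts = 1, n_sims = 1000, maxit = maxit,
                                polish_n_sims = 4000,
                                polish_maxit = 100)
    ci <- fit$bootstrap$ci
    cov_k <- truth$par >= ci["2.5%", names(truth$par)] &
      truth$par <= ci["97.5%", names(truth$par)]
    cover <- rbind(cover, cov_k)
  }
  list(cover = cover, coverage = mean(cover))
}

#' Structure-recovery experiment
#'
#' Simulates two deeply diverged demes plus one F1 cross individual at low
#' coverage, then checks that the leading PCA axis separates the demes with
#' no overlap and that K = 2 admixture proportions recover cluster
#' membership for unadmixed individuals and ~50/50 ancestry for the F1.
#'
#' @param seed integer seed.
#' @return list with `pc1_gap` (positive = zero overlap), `q_err_unadmixed`,
#'   `q_err_f1`, `var_frac`.
#' @export
experiment_structure_recovery <- function(seed = 1) {
  m <- three_pop_model("constant", N_anc = 800, T_split_N = 6000, T_split_C = 1,
                       N_final = c(Andes = 800, Central = 800, North = 800))
  cfg <- sim_config(n_per_pop = c(6, 1, 6), L = 6e4, mu = 2e-7, rec = 0,
                    seed = seed + 77L)
  h <- simulate_genotypes(m, cfg)
  ia <- which(h$pop == "Andes"); inn <- which(h$pop == "North")
  h$haps <- rbind(h$haps, h$haps[c(ia[1], inn[1]), ])
  h$pop <- factor(c(as.character(h$pop), "F1", "F1"),
                  levels = c(levels(h$pop), "F1"))
  pile <- simulate_reads(h, 8, 0.005, seed + 78L)
  glm <- gl_matrix(pile)
  lab <- as.character(glm$pop)
  pca <- pca_gl(glm, n_axes = 2)
  pc1 <- pca$scores[, 1]
  a <- pc1[lab == "Andes"]; b <- pc1[lab == "North"]
  gap <- max(min(b) - max(a), min(a) - max(b))
  adm <- admixture_em(glm, K = 2, seed = seed + 3L, n_restarts = 3)
  Q <- adm$Q
  k_a <- which.max(colMeans(Q[lab == "Andes", , drop = FALSE]))
  q_true <- ifelse(lab == "Andes", 1, ifelse(lab == "North", 0, NA))
  unadm <- !is.na(q_true)
  list(pc1_gap = gap,
       q_err_unadmixed = mean(abs(Q[unadm, k_a] - q_true[unadm])),
       q_err_f1 = abs(Q[lab == "F1", k_a] - 0.5),
       var_frac = pca$var_frac)
}

#' LD-decay recovery experiment
#'
#' (a) Self-consistency: pairs generated exactly from the decay curve
#' (lambda = 5e-4, max = 0.6, min = 0.1) with small noise are refitted and
#' the relative parameter errors reported.  (b) Monotonicity: single-deme
#' sequences simulated at three recombination rates; the fitted decay rate
#' must increase.
#'
#' @param seed integer seed.
#' @param n_pairs synthetic pairs for the self-consistency fit.
#' @return list with `rel_err` (lambda, max, min), `lambdas` (monotone
#'   check), `monotone`.
#' @export
experiment_ld_recovery <- function(seed = 1, n_pairs = 3000) {
  pairs <- with_seed(seed + 60L, {
    d <- stats::runif(n_pairs, 0, 10000)
    r2 <- 0.1 + 0.5 * exp(-5e-4 * d) + stats::rnorm(n_pairs, 0, 0.02)
    data.frame(dist = d, r2 = pmin(pmax(r2, 0), 1))
  })
  fit <- fit_decay(pairs, bin_size = 100, n_boot = 50, seed = seed)
  rel_err <- c(lambda = abs(fit$lambda - 5e-4) / 5e-4,
               r2_max = abs(fit$r2_max - 0.6) / 0.6,
               r2_min = abs(fit$r2_min - 0.1) / 0.1)
  lam_at <- function(rec, s) {
    m <- single_pop_model(1000)
    h <- simulate_genotypes(m, sim_config(n_per_pop = 12, L = 5e4, mu = 4e-7,
                                          rec = rec, seed = s))
    geno <- true_genotypes(h)
    keep <- colMeans(geno) / 2 >= 0.1 & colMeans(geno) / 2 <= 0.9
    glm <- gl_from_genotypes(geno[, keep, drop = FALSE],
                             positions = h$positions[keep])
    pr <- collect_pairs(glm, max_dist = 10000, subsample = 0.5, seed = s)
    fit_decay(pr, bin_size = 1000, n_boot = 0, seed = s)$lambda
  }
  lambdas <- vapply(c(2e-8, 4e-7, 4e-6), lam_at, 0, s = seed + 71L)
  list(rel_err = rel_err, fit = fit, lambdas = lambdas,
       monotone = all(diff(lambdas) > 0))
}
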