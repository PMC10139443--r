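test_that("the SAF dynamic programme equals exhaustive enumeration", {
  # single diploid: SAF proportional to the GL triple
  tri <- matrix(log(c(0.7, 0.2, 0.1)), 1, 3)
  saf <- saf_site(tri)
  expect_equal(exp(saf) / max(exp(saf)), c(0.7, 0.2, 0.1) / 0.7, tolerance = 1e-12)

  # certain hom-ancestral + certain het: all mass at j = 1
  saf2 <- saf_site(gl_certain(c(0, 1)))
  expect_equal(which.max(saf2), 2L)
  expect_true(all(saf2[-2] < log(1e-10)))

  # DP vs brute force for 2..4 individuals with random noisy likelihoods
  set.seed(8)
  for (n in 2:4) {
    gl <- matrix(log(runif(3 * n, 0.01, 1)), n, 3)
    gl <- gl - apply(gl, 1, max)
    expect_equal(saf_site(gl), oracle_saf_bruteforce(gl), tolerance = 1e-10)
  }
})

test_that("SAF respects missing individuals and projection", {
  gl <- gl_certain(c(0, 1, 2))
  saf <- saf_site(gl, missing = c(FALSE, TRUE, FALSE))
  expect_length(saf, 5)  # 2 diploids remain
  expect_error(saf_site(gl, missing = rep(TRUE, 3)), "missing")
  v <- saf_site(gl_certain(c(0, 1)))
  expect_equal(project_saf(v, 4), v - max(v))
  expect_length(project_saf(v, 2), 3)
})

test_that("1D-SFS EM matches direct maximisation on tiny instances", {
  # two sites, one diploid, certain opposite homozygotes -> phi = (0.5, 0, 0.5)
  saf <- rbind(log(c(1, 1e-12, 1e-12)), log(c(1e-12, 1e-12, 1)))
  fit <- em_sfs_1d(saf, folded = FALSE, tol = 1e-12, max_iter = 2000)
  expect_equal(fit$probs, c(0.5, 0, 0.5), tolerance = 1e-6)
  expect_true(all(diff(fit$loglik) >= -1e-9))

  # all sites identical -> point mass
  saf2 <- matrix(rep(log(c(1e-12, 1, 1e-12)), 5), 5, 3, byrow = TRUE)
  fit2 <- em_sfs_1d(saf2, folded = FALSE)
  expect_equal(fit2$probs[2], 1, tolerance = 1e-6)

  # random one-diploid SAFs vs dense simplex grid search (resolution 1e-3)
  set.seed(12)
  saf3 <- matrix(log(runif(3 * 40, 0.05, 1)), 40, 3)
  saf3 <- saf3 - apply(saf3, 1, max)
  fit3 <- em_sfs_1d(saf3, folded = FALSE, tol = 1e-14, max_iter = 5000)
  oracle <- oracle_sfs_grid_3(exp(saf3), res = 1e-3)
  expect_lt(sum(abs(fit3$probs - oracle$phi)), 1e-3 + 3e-3)

  # larger instance (n = 3 diploids) vs softmax direct search
  tp <- single_pop_model(1000)
  h <- simulate_genotypes(tp, sim_config(n_per_pop = 3, L = 3e4, mu = 2e-7, seed = 3))
  pile <- simulate_reads(h, 6, 0.01, 4)
  glm <- gl_matrix(pile)
  ss <- saf_population(glm)
  keep <- seq_len(min(200, nrow(ss$saf)))
  fit4 <- em_sfs_1d(ss$saf[keep, ], folded = FALSE, tol = 1e-14, max_iter = 8000)
  oracle4 <- oracle_sfs_direct(exp(ss$saf[keep, ]), n_starts = 6)
  expect_lt(sum(abs(fit4$probs - oracle4$phi)), 1e-3)
  expect_error(em_sfs_1d(matrix(0, 0, 3)), "no SAF")
})

test_that("folding conserves total mass and collapses symmetric classes", {
  set.seed(5)
  saf <- matrix(log(runif(5 * 30, 0.05, 1)), 30, 5)
  f_unf <- em_sfs_1d(saf, folded = FALSE)
  f_fol <- em_sfs_1d(saf, folded = TRUE)
  expect_equal(sum(f_unf$counts), 30, tolerance = 1e-6)
  expect_equal(sum(f_fol$counts), 30, tolerance = 1e-6)
  expect_length(f_fol$counts, 3)  # floor(4/2) + 1
})

test_that("2D-SFS EM matches marginals, point masses, and a direct-search oracle", {
  # single site certain (j1, j2) = (1, 0) -> point mass there
  s1 <- matrix(log(c(1e-12, 1, 1e-12)), 1, 3)
  s2 <- matrix(log(c(1, 1e-12, 1e-12)), 1, 3)
  fit <- em_sfs_2d(s1, s2, folded = FALSE, max_iter = 500)
  expect_equal(fit$probs[2, 1], 1, tolerance = 1e-6)

  # independent populations: 2D marginals equal the 1D fits
  set.seed(21)
  A1 <- matrix(log(runif(3 * 60, 0.05, 1)), 60, 3)
  A2 <- matrix(log(runif(3 * 60, 0.05, 1)), 60, 3)
  f2d <- em_sfs_2d(A1, A2, folded = FALSE, tol = 1e-13, max_iter = 5000)
  o <- oracle_sfs_direct(
    exp(A1)[, rep(1:3, times = 3)] * exp(A2)[, rep(1:3, each = 3)],
    n_starts = 6)
  expect_lt(sum(abs(as.vector(f2d$probs) - o$phi)), 2e-3)
  expect_true(all(diff(f2d$loglik) >= -1e-9))
  expect_error(em_sfs_2d(A1, A2[1:10, ]), "same sites")
})

test_that("folded 2D estimation leaves mass only on representative cells", {
  set.seed(31)
  A1 <- matrix(log(runif(3 * 50, 0.05, 1)), 50, 3)
  A2 <- matrix(log(runif(5 * 50, 0.05, 1)), 50, 5)
  f <- em_sfs_2d(A1, A2, folded = TRUE)
  rep_of <- glpopgen:::fold_map_2d(2, 4, "pooled")
  off_orbit <- setdiff(seq_len(15), unique(rep_of))
  expect_true(all(as.vector(f$probs)[off_orbit] == 0))
  expect_equal(sum(f$counts), 50, tolerance = 1e-6)
})

test_that("the unfolded spectrum from a constant population follows 1/i", {
  m <- single_pop_model(1000)
  s <- simulate_sfs(m, n_per_pop = 5, n_sims = 20000, seed = 17)
  sfs <- s$len[2:10]  # classes 1..9 of 0..10
  ratio <- (sfs / sfs[1]) / (1 / (1:9))
  expect_lt(max(abs(ratio - 1)), 0.1)
})

test_that("genic masking removes flank-expanded intervals and merges overlaps", {
  sites <- data.frame(contig = "c1", position = c(3999L, 4100L, 5500L, 6999L, 7000L))
  genes <- data.frame(contig = "c1", start = 5000L, end = 6000L)
  keep <- mask_genic(sites, genes, flank = 1000)
  expect_equal(sites$position[keep], c(3999L, 7000L))
  # no genes -> identity
  expect_true(all(mask_genic(sites, genes[0, , drop = FALSE])))
  # overlapping expanded intervals merge seamlessly
  genes2 <- data.frame(contig = "c1", start = c(1000L, 2500L), end = c(2000L, 3000L))
  keep2 <- mask_genic(data.frame(contig = "c1", position = c(499L, 2250L, 4100L)),
                      genes2, flank = 500)
  expect_equal(keep2, c(TRUE, FALSE, TRUE))
})
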