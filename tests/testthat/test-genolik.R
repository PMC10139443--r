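test_that("pileup genotype likelihoods match hand-computed products", {
  # reads [A, A], alleles (A, C), eps = 0.01
  tri <- gl_from_pileup(c(2, 0, 0, 0), c(1, 2), 0.01)
  lin <- exp(tri) * 0.9801  # unnormalise: hom-major likelihood is 0.99^2
  expect_equal(lin, c(0.9801, 0.246678, 1.111e-5), tolerance = 1e-3)
  expect_equal(max(tri), 0)

  # reads [A, C]: only the het explains both bases as eps -> 0
  tri2 <- gl_from_pileup(c(1, 1, 0, 0), c(1, 2), 1e-9)
  expect_equal(which.max(tri2), 2L)
  expect_lt(tri2[1], log(1e-6))
  expect_lt(tri2[3], log(1e-6))

  # zero reads: flat triple
  expect_equal(gl_from_pileup(c(0, 0, 0, 0), c(1, 2), 0.01), c(0, 0, 0))
  expect_error(gl_from_pileup(c(1, 0, 0, 0), c(2, 2), 0.01), "distinct")
})

test_that("allele-frequency EM matches a grid-search oracle and handles edge cases", {
  # certain hom-major for everyone -> 0; two certain hets -> 0.5
  expect_equal(estimate_maf(gl_certain(c(0, 0, 0, 0))), 0, tolerance = 1e-6)
  expect_equal(estimate_maf(gl_certain(c(1, 1))), 0.5, tolerance = 1e-6)

  # noisy GLs from truth p = 0.3 vs direct grid maximisation
  set.seed(4)
  g <- rbinom(10, 2, 0.3)
  gl <- gl_noisy(g, depth = 6, eps = 0.01, seed = 9)
  p_em <- estimate_maf(gl)
  grid <- seq(0, 1, by = 0.001)
  ll <- vapply(grid, function(p) {
    L <- exp(gl)
    sum(log(L[, 1] * (1 - p)^2 + L[, 2] * 2 * p * (1 - p) + L[, 3] * p^2))
  }, 0)
  expect_equal(p_em, grid[which.max(ll)], tolerance = 2e-3)
  expect_error(estimate_maf(gl_certain(c(0, 1)), missing = c(TRUE, TRUE)),
               "missing")
})

test_that("the SNP likelihood-ratio test separates monomorphic from polymorphic sites", {
  mono <- gl_certain(rep(0, 10))
  r <- snp_test(mono, estimate_maf(mono))
  expect_equal(r$lrt, 0, tolerance = 1e-8)
  expect_equal(r$p_value, 1)

  balanced <- gl_certain(rep(1, 10))
  r2 <- snp_test(balanced, estimate_maf(balanced))
  expect_lt(r2$p_value, 1e-6)

  # marginal site: decision agrees with direct likelihood evaluation
  gl <- gl_noisy(c(0, 0, 0, 1, 0, 0), depth = 3, eps = 0.05, seed = 2)
  p_hat <- estimate_maf(gl)
  r3 <- snp_test(gl, p_hat)
  ll_at <- function(p) {
    L <- exp(gl)
    sum(log(L[, 1] * (1 - p)^2 + L[, 2] * 2 * p * (1 - p) + L[, 3] * p^2))
  }
  lrt_direct <- 2 * (ll_at(p_hat) - max(ll_at(0), ll_at(1)))
  expect_equal(r3$lrt, max(0, lrt_direct), tolerance = 1e-6)
})

test_that("genotype calling applies the inbreeding-aware posterior threshold", {
  # GL (1, 0.25, 1e-5) linear, p = 0.5, F = 0: max posterior 0.662 -> no call
  gl <- array(log(c(1, 0.25, 1e-5)), dim = c(1, 1, 3))
  glm <- structure(list(gl = gl,
                        sites = data.frame(contig = "c1", position = 0L,
                                           major = "A", minor = "C", ref = "A"),
                        ind = "i1", pop = factor("P1"),
                        depth = matrix(5L, 1, 1),
                        missing = matrix(FALSE, 1, 1), maf = 0.5,
                        epsilon = 0.01), class = "gl_matrix")
  post <- c(1, 0.25, 1e-5) * c(0.25, 0.5, 0.25)
  expect_equal(max(post / sum(post)), 0.6667, tolerance = 1e-3)
  expect_true(is.na(call_genotypes(glm, p = 0.5, F = 0)[1, 1]))
  # certain GL always called
  glm$gl <- array(c(0, -40, -80), dim = c(1, 1, 3))
  expect_equal(unname(call_genotypes(glm, p = 0.5, F = 0)[1, 1]), 0L)
  # F = 1 removes all het prior mass
  glm$gl <- array(0, dim = c(1, 1, 3))
  glm$missing <- matrix(FALSE, 1, 1)
  expect_true(is.na(call_genotypes(glm, p = 0.5, F = 1, confidence = 0.4)[1, 1]) ||
              call_genotypes(glm, p = 0.5, F = 1, confidence = 0.4)[1, 1] != 1L)
  expect_error(call_genotypes(glm, p = 1.5), "\\[0, 1\\]")
})

test_that("on deep error-free data, called genotypes equal the truth", {
  tp <- default_test_model()
  h <- simulate_genotypes(tp, sim_config(n_per_pop = 3, L = 2e4, mu = 3e-7, seed = 31))
  pile <- simulate_reads(h, mean_depth = 30, error_rate = 0.001, seed = 32)
  glm <- gl_matrix(pile)
  truth <- true_genotypes(h)
  # orient truth dosages to the minor allele used by the GL matrix
  swap <- glm$sites$major != glm$sites$ref
  truth[, swap] <- 2L - truth[, swap]
  called <- call_genotypes(glm)
  ok <- !is.na(called)
  expect_gt(mean(ok), 0.95)
  expect_equal(called[ok], truth[ok])
})

test_that("greedy pruning and missingness rules follow the documented order", {
  g <- matrix(0L, 12, 4)
  glm <- gl_from_genotypes(rbind(g1 = c(1, 1, 0, 1), g2 = c(1, 0, 1, 1),
                                 g3 = c(0, 1, 1, 1), g4 = c(1, 1, 1, 0),
                                 g5 = c(1, 1, 0, 1), g6 = c(0, 1, 1, 1)),
                           positions = c(100L, 400L, 700L, 1300L))
  # positions 100, 400, 700, 1300 with 500-bp pruning -> keep 100, 700, 1300
  keep <- prune_and_filter(glm, site_filter_config(snp_p_threshold = 1,
                                                   min_maf = 0,
                                                   prune_dist = 500))
  expect_equal(glm$sites$position[keep], c(100L, 700L, 1300L))

  # missingness: site missing in 3/12 samples (25%) dropped at the 20% rule
  geno <- matrix(1L, 12, 3)
  geno[1:3, 2] <- NA_integer_
  glm2 <- gl_from_genotypes(matrix(1L, 12, 3), positions = c(0L, 600L, 1200L))
  keep2 <- prune_and_filter(glm2, site_filter_config(snp_p_threshold = 1,
                                                     min_maf = 0, prune_dist = 0),
                            geno = geno,
                            location = rep(c("L1", "L2"), each = 6))
  expect_false(2L %in% keep2)

  # site missing in every individual of one location dropped despite low
  # global missingness
  geno3 <- matrix(1L, 12, 2)
  geno3[1:2, 1] <- NA_integer_
  keep3 <- prune_and_filter(glm2, site_filter_config(snp_p_threshold = 1,
                                                     min_maf = 0, prune_dist = 0,
                                                     max_missing = 0.5),
                            geno = cbind(geno3, 1L),
                            location = rep(c("L1", "L2", "L3", "L4", "L5", "L6"), 2))
  # individuals 1, 7 form location L1; make them both missing at site 1
  geno4 <- matrix(1L, 12, 3)
  geno4[c(1, 7), 1] <- NA_integer_
  keep4 <- prune_and_filter(glm2, site_filter_config(snp_p_threshold = 1,
                                                     min_maf = 0, prune_dist = 0,
                                                     max_missing = 0.5),
                            geno = geno4,
                            location = rep(c("L1", "L2", "L3", "L4", "L5", "L6"), 2))
  expect_false(1L %in% keep4)
  expect_true(all(c(2L, 3L) %in% keep4))
  att <- attr(keep4, "attrition")
  expect_equal(unname(att["input"]), 3)
})

test_that("forced-reference allele frequencies hit the fixed endpoints and recover truth", {
  geno <- rbind(a = c(0, 2), b = c(0, 2), c = c(0, 2), d = c(0, 2))
  glm <- gl_from_genotypes(geno, positions = c(10L, 20L))
  fr <- freq_at_sites(glm, c(1, 2))
  expect_equal(fr$freq[fr$position == 10], 0, tolerance = 1e-6)
  expect_equal(fr$freq[fr$position == 20], 1, tolerance = 1e-6)
  expect_error(freq_at_sites(glm, 999, by = "position"), "not found")

  # simulated region at truth 0.41, depth 10
  set.seed(77)
  g <- rbinom(40, 2, 0.41)
  gl <- gl_noisy(g, depth = 10, eps = 0.01, seed = 78)
  p_hat <- estimate_maf(gl)
  se <- sqrt(0.41 * 0.59 / 80)
  expect_lt(abs(p_hat - 0.41), 3 * se + 0.02)
})

test_that("BEAGLE round-trip preserves normalised likelihood triples", {
  tp <- default_test_model()
  sim <- sim_glm(tp, n_per_pop = 2, L = 1e4, mu = 3e-7, seed = 55)
  glm <- sim$glm
  path <- tempfile(fileext = ".beagle")
  write_beagle(glm, path)
  back <- read_beagle(path)
  expect_equal(back$sites$position, glm$sites$position)
  expect_equal(back$sites$major, glm$sites$major)
  # normalised linear triples agree
  a <- exp(glm$gl); a <- a / array(rep(rowSums(a, dims = 2), 3), dim = dim(a))
  b <- exp(back$gl); b <- b / array(rep(rowSums(b, dims = 2), 3), dim = dim(b))
  expect_lt(max(abs(a - b)), 1e-9)
  expect_equal(back$missing, unname(glm$missing), ignore_attr = TRUE)
})
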