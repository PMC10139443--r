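test_that("haplotype-frequency EM reproduces closed-form r2 on certain genotypes", {
  # all haplotypes AB or ab (50/50): perfect LD
  g <- c(rep(0, 5), rep(2, 5))
  r <- r2_em(gl_certain(g), gl_certain(g))
  expect_equal(r$r2, 1, tolerance = 1e-6)

  # haplotype counts AB=40, Ab=10, aB=10, ab=40 -> D = 0.15, r2 = 0.36
  hap1 <- c(rep(1, 40), rep(1, 10), rep(0, 10), rep(0, 40))
  hap2 <- c(rep(1, 40), rep(0, 10), rep(1, 10), rep(0, 40))
  set.seed(50)
  o <- sample(100); o2 <- sample(100)
  g1 <- hap1[o] + hap1[o2]; g2 <- hap2[o] + hap2[o2]
  r2 <- r2_em(gl_certain(g1), gl_certain(g2), tol = 1e-12, max_iter = 3000)
  oracle <- oracle_r2_genotypes(g1, g2)
  expect_equal(r2$r2, oracle$r2, tolerance = 1e-6)
  expect_equal(r2$h, oracle$h, tolerance = 1e-4)
  # EM under random pairing keeps D near the haplotype-draw value
  expect_lt(abs(r2$D) , 0.3)
  expect_true(all(diff(r2$loglik) >= -1e-8))

  # invariance under allele-label swap at one site
  r_sw <- r2_em(gl_certain(2 - g1), gl_certain(g2), tol = 1e-12, max_iter = 3000)
  expect_equal(r_sw$r2, r2$r2, tolerance = 1e-6)

  # monomorphic site -> undefined
  expect_true(is.na(r2_em(gl_certain(rep(0, 10)), gl_certain(rbinom(10, 2, 0.5)))$r2))
})

test_that("EM on noisy likelihoods agrees with the phase-unknown genotype EM", {
  set.seed(51)
  hapA <- rbinom(60, 1, 0.5)
  hapB <- ifelse(runif(60) < 0.8, hapA, 1 - hapA)  # strong LD
  g1 <- hapA[1:30] + hapA[31:60]
  g2 <- hapB[1:30] + hapB[31:60]
  fit <- r2_em(gl_certain(g1, cert = 60), gl_certain(g2, cert = 60),
               tol = 1e-13, max_iter = 5000)
  oracle <- oracle_r2_genotypes(g1, g2)
  expect_equal(fit$r2, oracle$r2, tolerance = 1e-5)
})

test_that("pair collection respects the distance bound and subsampling", {
  geno <- matrix(rep(c(0L, 1L, 2L, 1L), 25), 4, 25)
  set.seed(3); geno <- matrix(rbinom(100, 2, 0.4), 4, 25)
  glm <- gl_from_genotypes(geno, positions = c(0L, 5000L, 9999L, 10000L, 10001L,
                                               seq(30000L, by = 400L, length.out = 20)))
  pairs <- collect_pairs(glm, max_dist = 10000, subsample = 1)
  # site 1 (pos 0) pairs with pos 5000, 9999, 10000 but not 10001
  p1 <- pairs[pairs$site1 == 1, ]
  expect_true(all(c(2, 3, 4) %in% p1$site2))
  expect_false(5 %in% p1$site2)
  # subsample = 1 equals exact enumeration count (minus monomorphic skips)
  pos <- glm$sites$position
  full <- sum(outer(pos, pos, function(a, b) b - a) > 0 &
              outer(pos, pos, function(a, b) b - a) <= 10000)
  mono <- colMeans(geno) / 2 %in% c(0, 1)
  expect_lte(nrow(pairs), full)
  expect_gt(nrow(pairs), 0.5 * full)
  # seeded subsample reproducible
  s1 <- collect_pairs(glm, max_dist = 10000, subsample = 0.4, seed = 9)
  s2 <- collect_pairs(glm, max_dist = 10000, subsample = 0.4, seed = 9)
  expect_identical(s1, s2)
})

test_that("decay-curve fitting is self-consistent and degenerates gracefully", {
  set.seed(60)
  d <- runif(3000, 0, 10000)
  r2 <- 0.1 + (0.6 - 0.1) * exp(-5e-4 * d) + rnorm(3000, 0, 0.02)
  pairs <- data.frame(dist = d, r2 = pmin(pmax(r2, 0), 1))
  fit <- fit_decay(pairs, bin_size = 100, n_boot = 50, seed = 1)
  expect_lt(abs(fit$lambda - 5e-4) / 5e-4, 0.10)
  expect_lt(abs(fit$r2_max - 0.6) / 0.6, 0.10)
  expect_lt(abs(fit$r2_min - 0.1) / 0.1, 0.10)
  expect_true(fit$ci["2.5%", "lambda"] <= fit$lambda + 1e-9)
  expect_true(fit$ci["97.5%", "lambda"] >= fit$lambda - 1e-9)

  # distance-independent data: lambda ~ 0, flat curve
  flat <- data.frame(dist = runif(2000, 0, 10000),
                     r2 = pmin(pmax(rnorm(2000, 0.3, 0.05), 0), 1))
  fit0 <- fit_decay(flat, bin_size = 500, n_boot = 0, seed = 2)
  expect_lt(fit0$lambda * 10000, 0.5)  # negligible decay over the whole range
  expect_lt(abs(fit0$r2_max - fit0$r2_min), 0.05)
})

test_that("simulated recombination increases the fitted decay rate monotonically", {
  lam_at <- function(rec, seed) {
    m <- single_pop_model(1000)
    h <- simulate_genotypes(m, sim_config(n_per_pop = 12, L = 5e4, mu = 4e-7,
                                          rec = rec, seed = seed))
    geno <- true_genotypes(h)
    keep <- colMeans(geno) / 2 >= 0.1 & colMeans(geno) / 2 <= 0.9
    glm <- gl_from_genotypes(geno[, keep, drop = FALSE],
                             positions = h$positions[keep])
    pairs <- collect_pairs(glm, max_dist = 10000, subsample = 0.5, seed = seed)
    fit_decay(pairs, bin_size = 1000, n_boot = 0, seed = seed)$lambda
  }
  lams <- vapply(c(2e-8, 4e-7, 4e-6), lam_at, 0, seed = 71)
  expect_true(all(diff(lams) > 0))
})

test_that("the model check classifies decay rates against the observed interval", {
  obs <- structure(list(lambda = 5e-4,
                        ci = matrix(c(4e-4, 6e-4, 0.5, 0.7, 0.05, 0.15), 2, 3,
                                    dimnames = list(c("2.5%", "97.5%"),
                                                    c("lambda", "rmax", "rmin")))),
                   class = "ld_decay_fit")
  sims <- list(constant = c(1e-4, 1.2e-4), growth = c(6e-4, 6e-4),
               resize = c(4.6e-4, 5.2e-4))
  res <- model_fit_check(obs, sims)
  expect_true(res$consistent[res$model == "resize"])
  expect_true(res$consistent[res$model == "growth"])  # median on the CI edge counts
  expect_false(res$consistent[res$model == "constant"])
  expect_equal(res$model[res$closest], "resize")
  expect_gt(res$distance_to_ci[res$model == "constant"], 0)
})
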