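test_that("per-site theta components match the closed forms", {
  # certain j = 1 with 2n = 4: pi = 1*3/6 = 0.5
  saf <- matrix(log(c(1e-300, 1, 1e-300, 1e-300, 1e-300)), 1, 5)
  sfs <- structure(list(probs = rep(0.2, 5), folded = FALSE, n_chr = 4),
                   class = "sfs_1d")
  th <- site_thetas(saf, sfs)
  expect_equal(th$pi, 0.5)
  expect_equal(th$theta_w, 1 / (1 + 1/2 + 1/3))
  # certain monomorphic: both zero
  saf0 <- matrix(log(c(1, rep(1e-300, 4))), 1, 5)
  th0 <- site_thetas(saf0, sfs)
  expect_equal(th0$pi, 0, tolerance = 1e-12)
  expect_equal(th0$theta_w, 0, tolerance = 1e-12)
  # posterior matches brute-force Bayes on a random SAF
  set.seed(3)
  v <- runif(5)
  safr <- matrix(log(v) - max(log(v)), 1, 5)
  phi <- runif(5); phi <- phi / sum(phi)
  sfsr <- structure(list(probs = phi, folded = FALSE, n_chr = 4), class = "sfs_1d")
  post <- v * phi / sum(v * phi)
  expect_equal(site_thetas(safr, sfsr)$pi,
               sum(post * (0:4) * (4 - (0:4)) / 6), tolerance = 1e-12)
  expect_error(site_thetas(safr, structure(list(probs = rep(1/3, 3),
                                                folded = FALSE, n_chr = 2),
                                           class = "sfs_1d")),
               "disagree")
})

test_that("Tajima's D matches an independently coded implementation", {
  expect_equal(tajimas_d(3, 5/3, 4), oracle_tajima(3, 5/3, 4), tolerance = 1e-12)
  set.seed(9)
  for (k in 1:20) {
    n <- sample(4:40, 1); S <- sample(1:200, 1); pis <- runif(1, 0, S)
    expect_equal(tajimas_d(S, pis, n), oracle_tajima(S, pis, n), tolerance = 1e-12)
  }
  # pi = S/a1 -> D = 0; S = 0 -> undefined
  a1 <- sum(1 / (1:9))
  expect_equal(tajimas_d(5, 5 / a1, 10), 0, tolerance = 1e-12)
  expect_true(is.na(tajimas_d(0, 0, 10)))
})

test_that("Hudson Fst components reproduce the hand example and limits", {
  # p1 = 0.2, p2 = 0.8, n1 = n2 = 10 -> alpha 0.324444, beta 0.68
  make_saf <- function(j, n_chr) {
    v <- rep(1e-300, n_chr + 1); v[j + 1] <- 1
    matrix(log(v), 1, n_chr + 1)
  }
  s1 <- make_saf(2, 10); s2 <- make_saf(8, 10)
  prior <- structure(list(probs = matrix(1 / 121, 11, 11), folded = FALSE,
                          convention = "pooled", n_chr = c(10, 10)),
                     class = "sfs_2d")
  comp <- fst_components(s1, s2, prior)
  expect_equal(comp$alpha, 0.324444, tolerance = 1e-5)
  expect_equal(comp$beta, 0.68, tolerance = 1e-10)
  expect_equal(comp$alpha / comp$beta, 0.47712, tolerance = 1e-4)
  # equal frequencies, large n: alpha ~ 0
  s3 <- make_saf(100, 200)
  prior2 <- structure(list(probs = matrix(1 / 201^2, 201, 201), folded = FALSE,
                           convention = "pooled", n_chr = c(200, 200)),
                      class = "sfs_2d")
  comp2 <- fst_components(s3, s3, prior2)
  expect_lt(abs(comp2$alpha), 0.01)
  # weighted vs unweighted global Fst
  comp3 <- data.frame(alpha = c(0.1, 0.3), beta = c(0.5, 0.5))
  expect_equal(global_fst(comp3), 0.4)
  expect_equal(global_fst(comp3, weighted = FALSE), mean(c(0.2, 0.6)))
})

test_that("PBS windows satisfy the hand example and the algebraic identity", {
  t_ab <- -log(1 - 0.2); t_ac <- -log(1 - 0.2); t_bc <- -log(1 - 0.1)
  expect_equal((t_ab + t_ac - t_bc) / 2, 0.1704633, tolerance = 1e-6)

  # construct per-site components yielding exactly those window Fsts
  S <- 200
  pos <- seq(0L, by = 50L, length.out = S)
  mk <- function(f) data.frame(alpha = rep(f, S), beta = rep(1, S))
  scan <- pbs_scan(pos, mk(0.2), mk(0.2), mk(0.1), window = 5000, step = 500,
                   min_sites = 10)
  expect_equal(scan$pbs_A[1], 0.1704633, tolerance = 1e-6)
  expect_equal(scan$pbs_A + scan$pbs_B, scan$t_ab, tolerance = 1e-14)

  # all Fst = 0 -> all PBS = 0 (negative estimates clamped first)
  scan0 <- pbs_scan(pos, mk(0), mk(0), mk(-0.05), window = 5000, step = 500,
                    min_sites = 10)
  expect_true(all(scan0$pbs_A == 0))
  # window bookkeeping: [start, start + window) exactly
  expect_equal(scan$n_sites[1], sum(pos >= 0 & pos < 5000))
  expect_equal(scan$n_sites[2], sum(pos >= 500 & pos < 5500))
})

test_that("Fst >= 1 windows give infinite branch lengths and are excluded from ranking", {
  S <- 100
  pos <- seq(0L, by = 50L, length.out = S)
  alpha <- rep(1, S); beta <- rep(1, S)
  comp_hot <- data.frame(alpha = alpha, beta = beta)       # Fst = 1
  comp_ok <- data.frame(alpha = rep(0.1, S), beta = rep(1, S))
  expect_warning(
    scan <- pbs_scan(pos, comp_hot, comp_ok, comp_ok, window = 5000,
                     step = 5000, min_sites = 5),
    "infinite")
  expect_true(any(!is.finite(scan$pbs_A)))
  expect_false(any(scan$top_A[!is.finite(scan$pbs_A)]))
})

test_that("top-fraction flagging marks the expected share of neutral windows", {
  set.seed(14)
  S <- 4000
  pos <- sort(sample.int(4e5, S))
  rnd <- function() data.frame(alpha = pmax(rnorm(S, 0.05, 0.02), 0),
                               beta = runif(S, 0.8, 1.2))
  scan <- pbs_scan(pos, rnd(), rnd(), rnd(), window = 5000, step = 500,
                   min_sites = 10, top_fraction = 0.01)
  frac <- mean(scan$top_A)
  n_fin <- sum(is.finite(scan$pbs_A))
  expect_equal(sum(scan$top_A), ceiling(0.01 * n_fin))
})

test_that("windowed theta table aggregates per-site values", {
  th <- data.frame(pi = rep(0.5, 100), p_seg = rep(1, 100),
                   theta_w = rep(0.5, 100))
  pos <- seq(0L, by = 100L, length.out = 100)
  tw <- theta_windows(pos, th, n_chr = 10, window = 2000, step = 2000,
                      min_sites = 5)
  expect_equal(tw$n_sites[1], 20)
  expect_equal(tw$pi[1], 10)
  expect_equal(tw$S[1], 20)
  expect_equal(tw$tajima_d[1], oracle_tajima(20, 10, 10), tolerance = 1e-12)
})
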