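test_that("single-population coalescent matches analytic expectations", {
  m <- single_pop_model(1000)
  # 2 haplotypes: total tree length is 2 * T2, E[T2] = 2N
  s <- simulate_sfs(m, n_per_pop = 1, n_sims = 20000, seed = 42)
  t2_mean <- s$tree_len_mean / 2
  se <- 2000 / sqrt(20000)  # T2 ~ Exp(mean 2N)
  expect_lt(abs(t2_mean - 2000), 4 * se)

  # pairwise diversity per bp ~ 4 N mu (theta), via mutation dropping
  mu_site <- 1e-4
  s2 <- simulate_sfs(m, n_per_pop = 1, n_sims = 20000, seed = 7,
                     theta_site = mu_site)
  pi_hat <- sum(s2$cnt) / 20000
  theta <- 4 * 1000 * mu_site
  expect_lt(abs(pi_hat - theta) / theta, 0.1)
})

test_that("Watterson's prediction E[S] = theta L a_n holds", {
  N <- 800; mu_site <- 5e-4; n_hap <- 10
  m <- single_pop_model(N)
  s <- simulate_sfs(m, n_per_pop = n_hap / 2, n_sims = 10000, seed = 11,
                    theta_site = mu_site)
  a_n <- sum(1 / seq_len(n_hap - 1))
  expected_S <- 4 * N * mu_site * a_n
  observed_S <- sum(s$cnt) / 10000
  expect_lt(abs(observed_S - expected_S) / expected_S, 0.1)
})

test_that("simulation is deterministic given the seed", {
  tp <- default_test_model()
  cfg <- sim_config(n_per_pop = 3, L = 2e4, mu = 2e-7, rec = 1e-7, seed = 99)
  h1 <- simulate_genotypes(tp, cfg)
  h2 <- simulate_genotypes(tp, cfg)
  expect_identical(h1$positions, h2$positions)
  expect_identical(h1$haps, h2$haps)
  expect_identical(h1$ref, h2$ref)
  s1 <- simulate_sfs(tp, 4, 500, seed = 3, theta_site = 0.01)
  s2 <- simulate_sfs(tp, 4, 500, seed = 3, theta_site = 0.01)
  expect_identical(s1$len, s2$len)
  expect_identical(s1$cnt, s2$cnt)
})

test_that("haplotype sets are polymorphic with strictly increasing positions", {
  tp <- default_test_model()
  h <- simulate_genotypes(tp, sim_config(n_per_pop = 3, L = 5e4, mu = 3e-7, seed = 2))
  expect_true(all(colSums(h$haps) >= 1))
  expect_true(all(colSums(h$haps) <= nrow(h$haps) - 1))
  expect_false(is.unsorted(h$positions, strictly = TRUE))
  expect_true(all(h$ref != h$alt))
})

test_that("a vanishing split time gives panmixia (Fst ~ 0) and Fst grows with split time", {
  fst_at_split <- function(T_split, seed) {
    m <- three_pop_model("constant", N_anc = 500, T_split_N = max(T_split, 2),
                         T_split_C = 1,
                         N_final = c(Andes = 500, Central = 500, North = 500))
    s <- simulate_sfs(m, n_per_pop = c(4, 1, 4), n_sims = 3000, seed = seed)
    # Hudson Fst from the joint branch-length spectrum of Andes vs North
    m2 <- apply(s$len, c(1, 3), sum)
    n1 <- nrow(m2) - 1; n2 <- ncol(m2) - 1
    j1 <- rep(0:n1, times = n2 + 1); j2 <- rep(0:n2, each = n1 + 1)
    w <- as.vector(m2)
    p1 <- j1 / n1; p2 <- j2 / n2
    alpha <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    beta <- p1 * (1 - p2) + p2 * (1 - p1)
    sum(w * alpha) / sum(w * beta)
  }
  f0 <- fst_at_split(2, 21)
  expect_lt(abs(f0), 0.05)
  grid <- vapply(c(500, 2000, 8000), fst_at_split, 0, seed = 22)
  expect_true(all(diff(grid) > 0))
  expect_gt(grid[3], 0.5)
})

test_that("read simulation follows the Poisson depth / base-error model", {
  tp <- default_test_model()
  h <- simulate_genotypes(tp, sim_config(n_per_pop = 2, L = 5e4, mu = 3e-7, seed = 5))
  S <- length(h$positions)
  pile <- simulate_reads(h, mean_depth = 5, error_rate = 0, seed = 1)
  depth <- apply(pile$counts, c(1, 2), sum)
  n_cells <- length(depth)
  expect_gt(n_cells, 1e3)
  se <- sqrt(5 / n_cells)
  expect_lt(abs(mean(depth) - 5), 3 * se)
  # with error 0, every read matches one of the two true alleles
  bases <- c("A", "C", "G", "T")
  for (s in sample.int(S, 25)) {
    allowed <- match(c(h$ref[s], h$alt[s]), bases)
    expect_true(all(pile$counts[s, , setdiff(1:4, allowed)] == 0))
  }
  # depth 0 -> empty pileups
  pile0 <- simulate_reads(h, mean_depth = 0, error_rate = 0.01, seed = 2)
  expect_true(all(pile0$counts == 0))
})

test_that("invalid models are rejected with informative errors", {
  expect_error(three_pop_model("constant", N_anc = 100, T_split_N = 10,
                               T_split_C = 50,
                               N_final = c(Andes = 1, Central = 1, North = 1)),
               "T_split_N > T_split_C")
  expect_error(three_pop_model("constant", N_anc = -5, T_split_N = 100,
                               T_split_C = 50,
                               N_final = c(Andes = 1, Central = 1, North = 1)),
               "positive")
  expect_error(three_pop_model("resize", N_anc = 100, T_split_N = 100,
                               T_split_C = 50,
                               N_final = c(Andes = 10, Central = 10, North = 10),
                               N_init = c(Andes = 5, Central = 5, North = 5),
                               T_resize = c(Andes = 20, Central = 60, North = 20)),
               "T_resize")
  expect_error(simulate_reads(structure(list(haps = matrix(0, 2, 1)),
                                        class = "haplotype_set"),
                              mean_depth = 2, error_rate = 1, seed = 1),
               "error_rate")
})

test_that("an admixed deme draws ancestry from both sources", {
  m <- three_pop_model("constant", N_anc = 800, T_split_N = 8000, T_split_C = 6000,
                       N_final = c(Andes = 800, Central = 800, North = 800),
                       admixture = list(sources = c("Andes", "North"),
                                        alpha = 0.5, time = 100, N = 800))
  cfg <- sim_config(n_per_pop = 4, L = 1e5, mu = 3e-7, seed = 13)
  h <- simulate_genotypes(m, cfg)
  expect_true("Admixed" %in% levels(h$pop))
  g <- true_genotypes(h)
  pop_i <- h$pop[seq(1, nrow(h$haps), 2)]
  pA <- colMeans(g[pop_i == "Andes", , drop = FALSE]) / 2
  pN <- colMeans(g[pop_i == "North", , drop = FALSE]) / 2
  pX <- colMeans(g[pop_i == "Admixed", , drop = FALSE]) / 2
  # a 50/50 mixture shares drift with both deeply diverged sources, so its
  # frequencies correlate with each source more than the sources do with
  # each other
  expect_gt(cor(pX, pA), cor(pA, pN) + 0.1)
  expect_gt(cor(pX, pN), cor(pA, pN) + 0.1)
})
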