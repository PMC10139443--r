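test_that("composite log-likelihood follows the counting rules", {
  mk_set <- function(m_list, kind = "count") {
    structure(m_list, n_per_pop = 1, kind = kind, class = "sfs_set")
  }
  keys <- c("Andes_Central", "Andes_North", "Central_North")
  obs <- mk_set(setNames(list(matrix(c(0, 12, 15, 9), 2, 2),
                              matrix(c(0, 20, 0, 0), 2, 2),
                              matrix(c(0, 0, 30, 0), 2, 2)), keys))
  expd <- mk_set(setNames(list(matrix(c(0, 0.3, 0.5, 0.2), 2, 2),
                               matrix(c(0, 1, 0, 0), 2, 2),
                               matrix(c(0, 0, 1, 0), 2, 2)), keys), "prob")
  # hand sum over retained entries (count >= 10), conditioned on the retained
  # support: cells 0.3 and 0.5 renormalise to 0.375 and 0.625
  expect_equal(composite_ll(obs, expd),
               12 * log(0.375) + 15 * log(0.625), tolerance = 1e-12)
  # without renormalisation the plain truncated sum is returned
  expect_equal(composite_ll(obs, expd, renormalise = FALSE),
               12 * log(0.3) + 15 * log(0.5), tolerance = 1e-12)
  # count 9 contributes nothing; raising it to 10 retains the whole support
  obs2 <- obs; obs2[["Andes_Central"]][2, 2] <- 10
  expect_equal(composite_ll(obs2, expd),
               12 * log(0.3) + 15 * log(0.5) + 10 * log(0.2), tolerance = 1e-12)
  # observed proportional to expected attains the multinomial maximum
  m <- matrix(c(0, 30, 50, 20), 2, 2)
  obs3 <- mk_set(setNames(list(m, m, m), keys))
  p_best <- m / sum(m)
  expd_best <- mk_set(setNames(list(p_best, p_best, p_best), keys), "prob")
  ll_best <- composite_ll(obs3, expd_best, min_count = 10)
  shift <- matrix(c(0, 0.4, 0.4, 0.2), 2, 2)
  expd_off <- mk_set(setNames(list(shift, shift, shift), keys), "prob")
  expect_gt(ll_best, composite_ll(obs3, expd_off, min_count = 10))
  expect_error(composite_ll(mk_set(setNames(list(m * 0, m * 0, m * 0), keys)),
                            expd_best), "excluded")
})

test_that("simulated expected spectra obey the neutral 1/i law and common random numbers", {
  m <- single_pop_model(1000)
  s <- simulate_sfs(m, n_per_pop = 4, n_sims = 20000, seed = 5)
  sfs <- s$len[2:8]
  expect_lt(max(abs((sfs / sfs[1]) * (1:7) - 1)), 0.12)

  tp <- default_test_model()
  e1 <- expected_sfs(tp, 4, 2000, seed = 9)
  e2 <- expected_sfs(tp, 4, 2000, seed = 9)
  expect_identical(e1, e2)
  # Monte-Carlo error shrinks with n_sims (sqrt scaling, checked loosely)
  err_at <- function(n_sims, seed) {
    ea <- expected_sfs(tp, 4, n_sims, seed)
    eb <- expected_sfs(tp, 4, n_sims, seed + 1000)
    mean(abs(ea[["Andes_Central"]] - eb[["Andes_Central"]]))
  }
  e_small <- mean(vapply(1:3, function(k) err_at(500, k * 17), 0))
  e_large <- mean(vapply(1:3, function(k) err_at(4500, k * 17), 0))
  expect_lt(e_large, e_small / 2)
})

test_that("the composite likelihood prefers the truth over perturbed parameters", {
  truth <- three_pop_model("constant", N_anc = 1000, T_split_N = 8000,
                           T_split_C = 3000,
                           N_final = c(Andes = 2000, Central = 800, North = 600))
  obs <- sfs_counts(truth, 8, n_loci = 5000, theta_site = 0.002, seed = 301)
  ll_at <- function(model) composite_ll(obs, expected_sfs(model, 8, 4000, 77))
  ll_truth <- ll_at(truth)
  perturb <- function(field, factor) {
    par <- list(N_anc = 1000, T_split_N = 8000, T_split_C = 3000,
                N_final = c(Andes = 2000, Central = 800, North = 600))
    if (field == "N_anc") par$N_anc <- par$N_anc * factor
    if (field == "T_split_N") par$T_split_N <- par$T_split_N * factor
    if (field == "N_Andes") par$N_final["Andes"] <- par$N_final["Andes"] * factor
    three_pop_model("constant", N_anc = par$N_anc, T_split_N = par$T_split_N,
                    T_split_C = par$T_split_C, N_final = par$N_final)
  }
  for (f in c("N_anc", "N_Andes")) {
    expect_lt(ll_at(perturb(f, 4)), ll_truth)
    expect_lt(ll_at(perturb(f, 1 / 4)), ll_truth)
  }
  expect_lt(ll_at(perturb("T_split_N", 4)), ll_truth)
  expect_lt(ll_at(perturb("T_split_N", 1 / 2)), ll_truth)  # stays above T_split_C
})

test_that("degenerate bounds return the fixed point and bootstrap reps = 0 is a no-op", {
  truth <- three_pop_model("constant", N_anc = 800, T_split_N = 5000,
                           T_split_C = 2000,
                           N_final = c(Andes = 1000, Central = 700, North = 500))
  obs <- sfs_counts(truth, 4, n_loci = 2000, theta_site = 0.002, seed = 11)
  fixed <- c(N_anc = 800, N_Andes = 1000, N_Central = 700, N_North = 500,
             T_split_C = 2000, T_split_N = 5000)
  fit <- fit_model(obs, "constant", bounds = list(lower = fixed, upper = fixed),
                   n_sims = 1000, seed = 2)
  expect_equal(fit$par[names(fixed)], fixed)
  expect_true(is.finite(fit$loglik))
  expect_identical(parametric_bootstrap(fit, list(n_loci = 10, theta_site = 1e-3),
                                        reps = 0), fit)
})

test_that("model variants are nested in attainable likelihood", {
  truth <- three_pop_model("constant", N_anc = 800, T_split_N = 5000,
                           T_split_C = 2000,
                           N_final = c(Andes = 1000, Central = 700, North = 500))
  obs <- sfs_counts(truth, 4, n_loci = 4000, theta_site = 0.002, seed = 21)
  par_c <- c(N_anc = 800, N_Andes = 1000, N_Central = 700, N_North = 500,
             T_split_C = 2000, T_split_N = 5000)
  fitc <- fit_model(obs, "constant", bounds = list(lower = par_c, upper = par_c),
                    n_sims = 2000, seed = 31)
  # a growth model with vanishing rates reproduces the constant fit
  par_g <- c(par_c, r_Andes = 1e-9, r_Central = 1e-9, r_North = 1e-9)
  fitg <- fit_model(obs, "growth", bounds = list(lower = par_g, upper = par_g),
                    n_sims = 2000, seed = 31)
  expect_equal(fitg$loglik, fitc$loglik, tolerance = 1e-6)
  # a resize model with a size change equal to the final size is constant too
  par_r <- c(par_c, N_init_Andes = 1000, N_init_Central = 700, N_init_North = 500,
             T_resize_Andes = 2500, T_resize_Central = 1000, T_resize_North = 2500)
  fitr <- fit_model(obs, "resize", bounds = list(lower = par_r, upper = par_r),
                    n_sims = 2000, seed = 31)
  # the resize schedule consumes the random-number stream differently, so the
  # agreement is within Monte-Carlo error rather than exact
  expect_equal(fitr$loglik, fitc$loglik, tolerance = 1e-3)
})

test_that("a small fit recovers the split-time ordering and bootstrap is deterministic", {
  truth <- three_pop_model("constant", N_anc = 1000, T_split_N = 8000,
                           T_split_C = 3000,
                           N_final = c(Andes = 2000, Central = 800, North = 600))
  obs <- sfs_counts(truth, 6, n_loci = 8000, theta_site = 0.002, seed = 41)
  fit <- fit_model(obs, "constant", n_restarts = 2, n_sims = 2000, seed = 43,
                   maxit = 100)
  expect_gt(fit$par[["T_split_N"]], fit$par[["T_split_C"]])
  expect_lt(abs(log(fit$par[["T_split_N"]] / 8000)), log(2.2))
  bs1 <- parametric_bootstrap(fit, list(n_loci = 2000, theta_site = 0.002),
                              reps = 3, seed = 7, n_restarts = 2, maxit = 40)
  bs2 <- parametric_bootstrap(fit, list(n_loci = 2000, theta_site = 0.002),
                              reps = 3, seed = 7, n_restarts = 2, maxit = 40)
  expect_identical(bs1$bootstrap$ci, bs2$bootstrap$ci)
  expect_true(all(bs1$bootstrap$ci["2.5%", ] <= bs1$bootstrap$ci["50%", ] + 1e-9))
})
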