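# pair keys used throughout the demographic-inference interface
.pairs3 <- list(c("Andes", "Central"), c("Andes", "North"), c("Central", "North"))
.pair_key <- function(p) paste(p, collapse = "_")

# marginalise a 3D joint spectrum (array over Andes x Central x North classes)
# into the three pairwise folded 2D spectra, dropping pair-monomorphic cells
.pairwise_folded <- function(arr3, normalise) {
  dims <- dim(arr3)
  out <- list()
  margins <- list(c(1, 2), c(1, 3), c(2, 3))
  for (k in seq_along(.pairs3)) {
    m <- apply(arr3, margins[[k]], sum)
    n1 <- nrow(m) - 1L; n2 <- ncol(m) - 1L
    rep_of <- fold_map_2d(n1, n2, "pooled")
    v <- as.vector(m)
    f <- numeric(length(v))
    for (cell in seq_along(v)) f[rep_of[cell]] <- f[rep_of[cell]] + v[cell]
    fm <- matrix(f, n1 + 1L, n2 + 1L)
    fm[1L, 1L] <- 0                     # pair-monomorphic mass excluded
    if (normalise) {
      tot <- sum(fm)
      if (tot > 0) fm <- fm / tot
    }
    out[[.pair_key(.pairs3[[k]])]] <- fm
  }
  out
}

#' Expected pairwise 2D-SFS under a demographic model
#'
#' Simulates `n_sims` unlinked single-site genealogies under the model
#' (common random numbers: a fixed `seed` yields the same genealogy stream,
#' so the likelihood surface over parameters is smooth) and tabulates the
#' expected branch lengths per joint allele-count class.  The three pairwise
#' folded 2D spectra among Andes, Central and North are returned, normalised
#' over polymorphic entries.
#'
#' @param model a [three_pop_model()].
#' @param n_per_pop diploids per deme.
#' @param n_sims number of simulated genealogies.
#' @param seed integer seed.
#' @return an `sfs_set`: named list of three folded 2D probability matrices
#'   (`Andes_Central`, `Andes_North`, `Central_North`), with attributes
#'   `n_per_pop` and `kind = "prob"`.
#' @export
expected_sfs <- function(model, n_per_pop, n_sims, seed) {
  stopifnot(n_sims >= 1)
  sim <- simulate_sfs(model, n_per_pop, n_sims, seed)
  out <- .pairwise_folded(sim$len, normalise = TRUE)
  attr(out, "n_per_pop") <- n_per_pop
  attr(out, "kind") <- "prob"
  attr(out, "tree_len_mean") <- sim$tree_len_mean
  class(out) <- "sfs_set"
  out
}

#' Observed pairwise 2D-SFS counts simulated under a model
#'
#' As [expected_sfs()] but drops Poisson infinite-sites mutations
#' (`theta_site` per locus) on the simulated genealogies and returns integer
#' SNP counts per class: a synthetic observed dataset for demographic
#' inference.
#'
#' @param model a [three_pop_model()].
#' @param n_per_pop diploids per deme.
#' @param n_loci number of unlinked loci simulated.
#' @param theta_site scaled mutation rate per locus (`mu * locus length`).
#' @param seed integer seed.
#' @return an `sfs_set` of count matrices (`kind = "count"`).
#' @export
sfs_counts <- function(model, n_per_pop, n_loci, theta_site, seed) {
  sim <- simulate_sfs(model, n_per_pop, n_loci, seed, theta_site = theta_site)
  out <- .pairwise_folded(sim$cnt, normalise = FALSE)
  attr(out, "n_per_pop") <- n_per_pop
  attr(out, "kind") <- "count"
  attr(out, "n_snps") <- sum(sim$cnt)
  attr(out, "n_loci") <- n_loci
  attr(out, "theta_site") <- theta_site
  class(out) <- "sfs_set"
  out
}

#' Composite log-likelihood of observed SFS counts
#'
#' Multinomial composite log-likelihood `sum_e m_e log p_e` over the retained
#' entries of the three pairwise folded spectra.  Entries with observed count
#' below `min_count` are excluded; expected probabilities of zero are floored
#' at `p_floor`.  By default the expected probabilities are renormalised over
#' the retained support (the conditional multinomial): without this, the
#' criterion rewards parameters that push probability mass into the excluded
#' cells, which biases the estimates (see the methods vignette).
#'
#' @param obs an `sfs_set` of counts.
#' @param expd an `sfs_set` of probabilities with matching dimensions.
#' @param min_count exclusion threshold on observed counts (default 10).
#' @param p_floor floor for zero expected probabilities.
#' @param renormalise condition on the retained support (default `TRUE`).
#' @return the composite log-likelihood (a single number).
#' @export
composite_ll <- function(obs, expd, min_count = 10, p_floor = 1e-12,
                         renormalise = TRUE) {
  ll <- 0
  used <- 0L
  for (key in names(obs)) {
    m <- obs[[key]]
    p <- expd[[key]]
    if (is.null(p) || !all(dim(m) == dim(p)))
      stop("observed and expected spectra do not match for pair ", key)
    keep <- m >= min_count
    used <- used + sum(keep)
    if (any(keep)) {
      pk <- pmax(p[keep], p_floor)
      if (renormalise) pk <- pk / sum(pk)
      ll <- ll + sum(m[keep] * log(pk))
    }
  }
  if (used == 0L) stop("all SFS entries were excluded by min_count")
  ll
}

# ---- parameter transforms -------------------------------------------------

.par_names <- function(variant) {
  base <- c("N_anc", "N_Andes", "N_Central", "N_North", "T_split_C", "T_split_N")
  switch(variant,
         constant = base,
         growth = c(base, "r_Andes", "r_Central", "r_North"),
         resize = c(base, "N_init_Andes", "N_init_Central", "N_init_North",
                    "T_resize_Andes", "T_resize_Central", "T_resize_North"))
}

# natural named vector -> unconstrained optimisation vector
.encode_par <- function(par, variant) {
  th <- c(log(par[["N_anc"]]), log(par[["N_Andes"]]), log(par[["N_Central"]]),
          log(par[["N_North"]]), log(par[["T_split_C"]]),
          log(par[["T_split_N"]] - par[["T_split_C"]]))
  if (variant == "growth")
    th <- c(th, log(par[["r_Andes"]]), log(par[["r_Central"]]), log(par[["r_North"]]))
  if (variant == "resize") {
    found <- c(par[["T_split_N"]], par[["T_split_C"]], par[["T_split_N"]])
    tr <- c(par[["T_resize_Andes"]], par[["T_resize_Central"]], par[["T_resize_North"]])
    th <- c(th, log(par[["N_init_Andes"]]), log(par[["N_init_Central"]]),
            log(par[["N_init_North"]]), stats::qlogis(tr / found))
  }
  unname(th)
}

# unconstrained vector -> natural named vector (always a valid model)
.decode_par <- function(th, variant) {
  T_C <- exp(th[5]); T_N <- T_C + exp(th[6])
  par <- c(N_anc = exp(th[1]), N_Andes = exp(th[2]), N_Central = exp(th[3]),
           N_North = exp(th[4]), T_split_C = T_C, T_split_N = T_N)
  if (variant == "growth")
    par <- c(par, r_Andes = exp(th[7]), r_Central = exp(th[8]), r_North = exp(th[9]))
  if (variant == "resize") {
    found <- c(T_N, T_C, T_N)
    fr <- stats::plogis(th[10:12])
    par <- c(par, N_init_Andes = exp(th[7]), N_init_Central = exp(th[8]),
             N_init_North = exp(th[9]),
             T_resize_Andes = fr[1] * found[1],
             T_resize_Central = fr[2] * found[2],
             T_resize_North = fr[3] * found[3])
  }
  par
}

.par_to_model <- function(par, variant) {
  three_pop_model(variant,
    N_anc = par[["N_anc"]],
    T_split_N = par[["T_split_N"]], T_split_C = par[["T_split_C"]],
    N_final = c(Andes = par[["N_Andes"]], Central = par[["N_Central"]],
                North = par[["N_North"]]),
    r = if (variant == "growth")
      c(Andes = par[["r_Andes"]], Central = par[["r_Central"]],
        North = par[["r_North"]]) else NULL,
    N_init = if (variant == "resize")
      c(Andes = par[["N_init_Andes"]], Central = par[["N_init_Central"]],
        North = par[["N_init_North"]]) else NULL,
    T_resize = if (variant == "resize")
      c(Andes = par[["T_resize_Andes"]], Central = par[["T_resize_Central"]],
        North = par[["T_resize_North"]]) else NULL)
}

#' Default parameter bounds for demographic fitting
#'
#' @param variant model variant.
#' @return list with named `lower` and `upper` natural-parameter vectors.
#' @export
default_bounds <- function(variant = c("constant", "growth", "resize")) {
  variant <- match.arg(variant)
  lower <- c(N_anc = 100, N_Andes = 100, N_Central = 100, N_North = 100,
             T_split_C = 500, T_split_N = 1000)
  upper <- c(N_anc = 20000, N_Andes = 20000, N_Central = 20000, N_North = 20000,
             T_split_C = 20000, T_split_N = 40000)
  if (variant == "growth") {
    lower <- c(lower, r_Andes = 1e-6, r_Central = 1e-6, r_North = 1e-6)
    upper <- c(upper, r_Andes = 5e-3, r_Central = 5e-3, r_North = 5e-3)
  }
  if (variant == "resize") {
    lower <- c(lower, N_init_Andes = 100, N_init_Central = 100, N_init_North = 100,
               T_resize_Andes = NA, T_resize_Central = NA, T_resize_North = NA)
    upper <- c(upper, N_init_Andes = 20000, N_init_Central = 20000,
               N_init_North = 20000,
               T_resize_Andes = NA, T_resize_Central = NA, T_resize_North = NA)
    # resize times are parameterised as fractions of the founding time
  }
  list(lower = lower, upper = upper)
}

# draw one restart start point log-uniformly within bounds
.draw_start <- function(bounds, variant) {
  nm <- .par_names(variant)
  par <- numeric(length(nm)); names(par) <- nm
  for (p in nm) {
    lo <- bounds$lower[[p]]; hi <- bounds$upper[[p]]
    if (is.na(lo)) next                     # resize fractions drawn below
    par[p] <- if (lo == hi) lo else exp(stats::runif(1, log(lo), log(hi)))
  }
  if (par[["T_split_N"]] <= par[["T_split_C"]])
    par[["T_split_N"]] <- par[["T_split_C"]] * stats::runif(1, 1.1, 2.5)
  if (variant == "resize") {
    found <- c(par[["T_split_N"]], par[["T_split_C"]], par[["T_split_N"]])
    fr <- stats::runif(3, 0.1, 0.9)
    par[c("T_resize_Andes", "T_resize_Central", "T_resize_North")] <- fr * found
  }
  par
}

#' Fit a demographic model to observed SFS counts
#'
#' Maximises the composite likelihood of [composite_ll()] over the model
#' parameters by derivative-free direct search (Nelder-Mead) on transformed
#' parameters (logs; split times as `log T_C` and `log (T_N - T_C)`; resize
#' times as logit fractions of the founding time, so every proposal is a
#' valid model).  `n_restarts` starts are drawn log-uniformly within
#' `bounds`; the expected SFS inside the objective uses common random
#' numbers, so the surface is deterministic given `seed`.
#'
#' @param obs an `sfs_set` of observed counts.
#' @param variant model variant to fit.
#' @param bounds parameter bounds (see [default_bounds()]); equal lower and
#'   upper bounds fix every parameter and skip optimisation.
#' @param n_restarts number of random restarts.
#' @param n_sims genealogies per expected-SFS evaluation.
#' @param seed integer seed (drives both the restart draws and the
#'   common-random-numbers stream).
#' @param min_count SFS-entry exclusion threshold.
#' @param maxit Nelder-Mead iteration cap per restart.
#' @param reltol Nelder-Mead relative convergence tolerance.
#' @param polish_n_sims optional larger simulation budget for a final
#'   Nelder-Mead polish from the best restart (reduces Monte-Carlo
#'   distortion of the optimum).
#' @param polish_maxit iteration cap for the polish stage.
#' @param start optional list of named start vectors overriding the random
#'   restarts.
#' @return a `fit_result`: list with `variant`, `par` (named MLE), `loglik`,
#'   `restarts` (per-restart table), `settings`.
#' @export
fit_model <- function(obs, variant = c("constant", "growth", "resize"),
                      bounds = NULL, n_restarts = 20, n_sims = 1e4,
                      seed = 1, min_count = 10, maxit = 300, reltol = 1e-9,
                      polish_n_sims = NULL, polish_maxit = 150, start = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(obs, "sfs_set"))
  if (is.null(bounds)) bounds <- default_bounds(variant)
  n_per_pop <- attr(obs, "n_per_pop")
  sim_seed <- (as.integer(seed) * 97L) %% .Machine$integer.max
  # The normalised SFS shape is invariant to rescaling every size and time by
  # a common factor, so the mutation scale anchors the fit: the total SNP
  # count is Poisson with mean n_loci * theta_site * E[tree length].
  anchor <- !is.null(attr(obs, "n_snps"))
  objective_at <- function(th, ns) {
    par <- .decode_par(th, variant)
    model <- tryCatch(.par_to_model(par, variant), error = function(e) NULL)
    if (is.null(model)) return(-1e18)
    expd <- expected_sfs(model, n_per_pop, ns, sim_seed)
    ll <- composite_ll(obs, expd, min_count = min_count)
    if (anchor) {
      lambda <- attr(obs, "n_loci") * attr(obs, "theta_site") *
        attr(expd, "tree_len_mean")
      ll <- ll + attr(obs, "n_snps") * log(lambda) - lambda
    }
    ll
  }
  objective <- function(th) objective_at(th, n_sims)
  fixed <- !anyNA(bounds$lower) && !anyNA(bounds$upper) &&
    all(bounds$lower == bounds$upper)
  if (fixed) {
    par <- bounds$lower[.par_names(variant)]
    ll <- objective(.encode_par(par, variant))
    return(structure(list(variant = variant, par = par, loglik = ll,
                          restarts = data.frame(restart = 0L, loglik = ll,
                                                converged = TRUE),
                          settings = list(n_sims = n_sims, seed = seed,
                                          min_count = min_count,
                                          n_per_pop = n_per_pop),
                          bounds = bounds),
                     class = "fit_result"))
  }
  starts <- with_seed(seed, {
    if (!is.null(start)) start
    else lapply(seq_len(n_restarts), function(i) .draw_start(bounds, variant))
  })
  best <- NULL
  rows <- list()
  # one restart = repeated Nelder-Mead cycles; re-inflating the simplex at
  # the previous optimum guards against premature simplex collapse
  run_restart <- function(th0) {
    best_r <- NULL
    for (cyc in 1:3) {
      res <- stats::optim(th0, objective, method = "Nelder-Mead",
                          control = list(fnscale = -1, maxit = maxit,
                                         reltol = reltol))
      if (!is.null(best_r) && res$value < best_r$value) { res <- best_r }
      improved <- is.null(best_r) || res$value > best_r$value + 0.5
      best_r <- res
      th0 <- res$par
      if (!improved) break
    }
    best_r
  }
  for (i in seq_along(starts)) {
    th0 <- .encode_par(starts[[i]], variant)
    res <- tryCatch(run_restart(th0), error = function(e) NULL)
    if (is.null(res)) {
      rows[[i]] <- data.frame(restart = i, loglik = NA_real_, converged = FALSE)
      next
    }
    rows[[i]] <- data.frame(restart = i, loglik = res$value,
                            converged = res$convergence == 0)
    if (is.null(best) || res$value > best$value) best <- res
  }
  if (is.null(best)) stop("all restarts failed")
  # optional high-precision polish: the cheap stage localises the optimum,
  # a larger simulation budget then removes Monte-Carlo distortion
  if (!is.null(polish_n_sims) && polish_n_sims > n_sims) {
    pol <- tryCatch(
      stats::optim(best$par, function(th) objective_at(th, polish_n_sims),
                   method = "Nelder-Mead",
                   control = list(fnscale = -1, maxit = polish_maxit,
                                  reltol = reltol)),
      error = function(e) NULL)
    if (!is.null(pol)) best <- pol
  }
  structure(list(variant = variant, par = .decode_par(best$par, variant),
                 loglik = best$value, restarts = do.call(rbind, rows),
                 settings = list(n_sims = n_sims, seed = seed,
                                 min_count = min_count, n_per_pop = n_per_pop,
                                 maxit = maxit),
                 bounds = bounds),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Demographic fit (", x$variant, "), composite log-likelihood ",
      sprintf("%.2f", x$loglik), "\n", sep = "")
  print(round(x$par, 4))
  if (!is.null(x$bootstrap)) {
    cat("parametric bootstrap (", nrow(x$bootstrap$par), " successful reps):\n", sep = "")
    print(round(x$bootstrap$ci, 2))
  }
  invisible(x)
}

#' Parametric bootstrap of a demographic fit
#'
#' Re-simulates `reps` observed datasets at the fitted parameters (matching
#' the original data's locus count and mutation scale), refits each with a
#' reduced number of restarts centred at the MLE, and attaches 2.5/97.5
#' percentile intervals per parameter.
#'
#' @param fit a `fit_result`.
#' @param data_settings list with `n_loci` and `theta_site` used to simulate
#'   each bootstrap dataset.
#' @param reps number of bootstrap replicates; `reps = 0` returns the fit
#'   unchanged.
#' @param seed integer seed.
#' @param n_restarts restarts per refit.
#' @param n_sims genealogies per objective evaluation in the refits
#'   (defaults to the original fit's setting).
#' @param maxit Nelder-Mead cap per refit.
#' @param polish_n_sims,polish_maxit high-precision polish settings passed to
#'   each refit (see [fit_model()]).
#' @param refit_starts `"mle"` starts each refit at the parent MLE (plus
#'   jittered copies); `"random"` re-draws restart points exactly as the
#'   original fit did, so the refit replicates the estimator in distribution
#'   (required for calibrated intervals when the likelihood surface has flat
#'   ridges).
#' @param interval type of 95% interval reported in `ci`: `"basic"`
#'   (reflected around the MLE; corrects first-order estimator bias, the
#'   default) or `"percentile"` (the raw refit quantiles; both are kept in
#'   the result).
#' @return the `fit_result` with a `bootstrap` element: `par` (successful
#'   replicate estimates), `ci` (2.5%, 50%, 97.5% per parameter),
#'   `n_failed`.
#' @export
parametric_bootstrap <- function(fit, data_settings, reps = 100, seed = 1,
                                 n_restarts = 5, n_sims = NULL, maxit = 250,
                                 polish_n_sims = NULL, polish_maxit = 100,
                                 interval = c("basic", "percentile"),
                                 refit_starts = c("mle", "random")) {
  stopifnot(inherits(fit, "fit_result"))
  interval <- match.arg(interval)
  refit_starts <- match.arg(refit_starts)
  if (reps == 0) return(fit)
  if (is.null(n_sims)) n_sims <- fit$settings$n_sims
  model <- .par_to_model(fit$par, fit$variant)
  n_per_pop <- fit$settings$n_per_pop
  rows <- list()
  n_failed <- 0L
  for (b in seq_len(reps)) {
    bseed <- (as.integer(seed) + 131L * b) %% .Machine$integer.max
    obs_b <- sfs_counts(model, n_per_pop, data_settings$n_loci,
                        data_settings$theta_site, bseed)
    starts <- if (refit_starts == "random") NULL else with_seed(bseed + 1L, {
      c(list(fit$par),
        lapply(seq_len(max(0L, n_restarts - 1L)), function(i) {
          jit <- fit$par * exp(stats::rnorm(length(fit$par), 0, 0.3))
          # keep split ordering and resize fractions valid via re-encoding
          .decode_par(.encode_par_safe(jit, fit$par, fit$variant), fit$variant)
        }))
    })
    ft <- tryCatch(
      fit_model(obs_b, fit$variant, bounds = fit$bounds, n_sims = n_sims,
                n_restarts = n_restarts,
                seed = bseed + 2L, min_count = fit$settings$min_count,
                maxit = maxit, polish_n_sims = polish_n_sims,
                polish_maxit = polish_maxit, start = starts),
      error = function(e) NULL)
    if (is.null(ft)) { n_failed <- n_failed + 1L; next }
    rows[[length(rows) + 1L]] <- ft$par
  }
  if (!length(rows)) stop("every bootstrap refit failed")
  par_mat <- do.call(rbind, rows)
  q <- apply(par_mat, 2L, stats::quantile, probs = c(0.025, 0.5, 0.975))
  # basic (reflected) intervals correct first-order estimator bias, which
  # percentile intervals double; the refit distribution is kept for both
  ci_basic <- rbind(`2.5%` = 2 * fit$par - q["97.5%", ],
                    `50%` = 2 * fit$par - q["50%", ],
                    `97.5%` = 2 * fit$par - q["2.5%", ])
  fit$bootstrap <- list(par = par_mat,
                        ci = if (interval == "basic") ci_basic else q,
                        ci_percentile = q, ci_basic = ci_basic,
                        interval = interval, n_failed = n_failed,
                        reps = reps, seed = seed)
  fit
}

# jittered vector may violate ordering constraints; fall back to the MLE's
# encoding for any non-finite transform entry
.encode_par_safe <- function(jit, mle, variant) {
  th <- tryCatch(.encode_par(jit, variant), error = function(e) NULL)
  th0 <- .encode_par(mle, variant)
  if (is.null(th) || any(!is.finite(th))) return(th0)
  th
}
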