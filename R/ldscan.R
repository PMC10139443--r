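#' Two-locus r2 from genotype likelihoods by haplotype EM
#'
#' EM over the four haplotype frequencies of a pair of biallelic sites,
#' assuming random mating (an individual's two haplotypes are independent
#' draws).  The E-step computes each individual's posterior over ordered
#' haplotype pairs from the product of the two sites' genotype likelihoods;
#' the M-step re-estimates the haplotype frequencies from expected counts.
#' The log-likelihood is non-decreasing.  From the fitted frequencies,
#' `D = h11 - pA pB` and `r2 = D^2 / (pA(1-pA) pB(1-pB))`.
#'
#' @param gl1,gl2 individuals x 3 log-GL matrices for the two sites.
#' @param tol relative log-likelihood tolerance.
#' @param max_iter EM cap.
#' @return list with `r2`, `D`, `h` (frequencies of haplotypes 00, 01, 10,
#'   11), `p1`, `p2`, `iterations`, `loglik`; `r2` is `NA` when either site
#'   is (near) monomorphic.
#' @export
r2_em <- function(gl1, gl2, tol = 1e-9, max_iter = 500) {
  L1 <- exp(as.matrix(gl1)); L2 <- exp(as.matrix(gl2))
  n <- nrow(L1)
  if (n < 2) stop("need at least 2 individuals")
  # ordered haplotype pairs: haplotype index 1..4 = (00, 01, 10, 11)
  hx <- cbind(c(0, 0, 1, 1), c(0, 1, 0, 1))  # allele at site1, site2
  h <- rep(0.25, 4)
  ll <- numeric(0)
  pair_g1 <- outer(hx[, 1], hx[, 1], "+")    # genotype at site1 for pair (x,y)
  pair_g2 <- outer(hx[, 2], hx[, 2], "+")
  for (it in seq_len(max_iter)) {
    counts <- numeric(4)
    ll_new <- 0
    W <- matrix(0, n, 16)
    k <- 0
    for (x in 1:4) for (y in 1:4) {
      k <- k + 1
      W[, k] <- h[x] * h[y] * L1[, pair_g1[x, y] + 1L] * L2[, pair_g2[x, y] + 1L]
    }
    rs <- rowSums(W)
    ll_new <- sum(log(rs))
    P <- W / rs
    k <- 0
    for (x in 1:4) for (y in 1:4) {
      k <- k + 1
      counts[x] <- counts[x] + sum(P[, k])
      counts[y] <- counts[y] + sum(P[, k])
    }
    h <- counts / (2 * n)
    ll <- c(ll, ll_new)
    if (it > 1 && abs(ll_new - ll[it - 1L]) <= tol * max(1, abs(ll[it - 1L]))) break
  }
  p1 <- h[3] + h[4]; p2 <- h[2] + h[4]
  D <- h[4] - p1 * p2
  denom <- p1 * (1 - p1) * p2 * (1 - p2)
  r2 <- if (denom < 1e-12) NA_real_ else D^2 / denom
  list(r2 = r2, D = D, h = h, p1 = p1, p2 = p2,
       iterations = length(ll), loglik = ll)
}

#' r2 for site pairs within a maximum distance
#'
#' Enumerates SNP pairs on the same contig separated by at most `max_dist`
#' bp, optionally keeps a seeded random subsample, and estimates `r2` for
#' each by [r2_em()].  Pairs where either site is monomorphic are skipped.
#'
#' @param glm a `gl_matrix` (sites sorted by position).
#' @param max_dist maximum pair distance in bp (default 10 kb).
#' @param subsample fraction of pairs to keep (default 0.10).
#' @param seed integer seed for the subsample.
#' @param site_sel optional site indices to restrict to.
#' @return data.frame with `site1`, `site2`, `dist`, `r2`, `iterations`.
#' @export
collect_pairs <- function(glm, max_dist = 10000, subsample = 0.10, seed = 1,
                          site_sel = NULL) {
  stopifnot(inherits(glm, "gl_matrix"))
  idx <- if (is.null(site_sel)) seq_len(nrow(glm$sites)) else sort(site_sel)
  pos <- glm$sites$position[idx]
  ct <- glm$sites$contig[idx]
  i_list <- list()
  for (i in seq_along(idx)) {
    j <- i + 1L
    while (j <= length(idx) && ct[j] == ct[i] && pos[j] - pos[i] <= max_dist) {
      i_list[[length(i_list) + 1L]] <- c(i, j)
      j <- j + 1L
    }
  }
  if (!length(i_list)) {
    return(data.frame(site1 = integer(0), site2 = integer(0),
                      dist = numeric(0), r2 = numeric(0),
                      iterations = integer(0)))
  }
  pr <- do.call(rbind, i_list)
  if (subsample < 1) {
    keep <- with_seed(seed, sample.int(nrow(pr), max(1L, round(subsample * nrow(pr)))))
    pr <- pr[sort(keep), , drop = FALSE]
  }
  out <- vector("list", nrow(pr))
  for (k in seq_len(nrow(pr))) {
    i <- pr[k, 1]; j <- pr[k, 2]
    fit <- r2_em(glm$gl[idx[i], , , drop = TRUE], glm$gl[idx[j], , , drop = TRUE])
    out[[k]] <- data.frame(site1 = idx[i], site2 = idx[j],
                           dist = pos[j] - pos[i], r2 = fit$r2,
                           iterations = fit$iterations)
  }
  res <- do.call(rbind, out)
  res[!is.na(res$r2), , drop = FALSE]
}

#' Fit an LD decay curve
#'
#' Bins pairs by distance, computes the mean `r2` per bin, and fits by
#' weighted nonlinear least squares the three-parameter curve
#' `r2(d) = r2_min + (r2_max - r2_min) exp(-lambda d)` (bins weighted by
#' pair count).  Pair-level bootstrap resampling gives 95% percentile
#' confidence intervals.  When the fitted amplitude `r2_max - r2_min` is
#' below 1e-4 the decay rate is degenerate and reported as 0 with a flat
#' curve.
#'
#' @param pairs data.frame from [collect_pairs()] (columns `dist`, `r2`).
#' @param bin_size distance bin width in bp (default 100).
#' @param n_boot bootstrap resamples (default 100).
#' @param seed integer seed.
#' @param level bootstrap summary verbosity passed through to the result
#'   (an opaque configuration key; it does not change the estimates).
#' @return an `ld_decay_fit`: list with `lambda`, `r2_max`, `r2_min`, `ci`
#'   (2.5/97.5 percentiles per parameter), `bin_size`, `n_pairs`,
#'   `n_boot`, `level`.
#' @export
fit_decay <- function(pairs, bin_size = 100, n_boot = 100, seed = 1, level = 10) {
  if (nrow(pairs) < 4) stop("too few pairs to fit a decay curve")
  fit_once <- function(df) {
    bin <- floor(df$dist / bin_size)
    d <- (unique(sort(bin)) + 0.5) * bin_size
    mean_r2 <- tapply(df$r2, bin, mean)
    w <- tapply(df$r2, bin, length)
    if (length(d) < 2) stop("need at least 2 populated distance bins")
    dat <- data.frame(d = d, y = as.numeric(mean_r2), w = as.numeric(w))
    amp0 <- max(dat$y[1] - min(dat$y), 1e-3)
    st <- list(rmax = max(dat$y[1], 1e-3), rmin = max(min(dat$y), 1e-4),
               lambda = 2 / max(dat$d))
    ft <- minpack.lm::nlsLM(y ~ rmin + (rmax - rmin) * exp(-lambda * d),
                            data = dat, start = st, weights = dat$w,
                            lower = c(rmax = 0, rmin = 0, lambda = 0),
                            upper = c(rmax = 1, rmin = 1, lambda = Inf),
                            control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(ft)
    if (cf[["rmax"]] < cf[["rmin"]]) cf[c("rmax", "rmin")] <- cf[c("rmin", "rmax")]
    # no decay detectable across the observed distance range: the effective
    # amplitude at the first bin midpoint decides degeneracy
    amp_eff <- (cf[["rmax"]] - cf[["rmin"]]) * exp(-cf[["lambda"]] * dat$d[1])
    if (amp_eff < 0.01) {
      flat <- sum(dat$y * dat$w) / sum(dat$w)
      cf <- c(rmax = flat, rmin = flat, lambda = 0)
    }
    cf
  }
  est <- tryCatch(fit_once(pairs), error = function(e)
    stop("LD decay fit failed: ", conditionMessage(e), " (", nrow(pairs),
         " pairs, bin size ", bin_size, ")", call. = FALSE))
  boot <- NULL
  if (n_boot > 0) {
    boot <- with_seed(seed, {
      t(vapply(seq_len(n_boot), function(b) {
        res <- pairs[sample.int(nrow(pairs), replace = TRUE), , drop = FALSE]
        tryCatch(fit_once(res), error = function(e) c(rmax = NA, rmin = NA, lambda = NA))
      }, c(rmax = 0, rmin = 0, lambda = 0)))
    })
  }
  ci <- if (!is.null(boot))
    apply(boot, 2L, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  else NULL
  structure(list(lambda = unname(est[["lambda"]]), r2_max = unname(est[["rmax"]]),
                 r2_min = unname(est[["rmin"]]), ci = ci, boot = boot,
                 bin_size = bin_size, n_pairs = nrow(pairs), n_boot = n_boot,
                 level = level),
            class = "ld_decay_fit")
}

#' @export
print.ld_decay_fit <- function(x, ...) {
  cat(sprintf("LD decay fit: lambda = %.4g, r2_max = %.3f, r2_min = %.3f (%d pairs)\n",
              x$lambda, x$r2_max, x$r2_min, x$n_pairs))
  if (!is.null(x$ci)) {
    cat("95% bootstrap CIs:\n")
    print(round(x$ci, 5))
  }
  invisible(x)
}

#' Post hoc model check against an observed LD decay rate
#'
#' Compares, for each candidate demographic model, the decay rates obtained
#' from data simulated under that model with the observed fit: a model is
#' `consistent` when its simulated decay-rate summary (the median across
#' replicates) falls within the observed 95% CI (closed interval), and the
#' distance to the nearer CI bound is reported otherwise.  Models are ranked
#' by `|lambda_sim - lambda_obs|`; the nearest is flagged `closest`.
#'
#' @param obs_fit an `ld_decay_fit` for the observed data (needs `ci`).
#' @param sim_lambdas named list: per model, a numeric vector of decay rates
#'   from simulated replicates.
#' @return data.frame with `model`, `lambda_sim`, `consistent`,
#'   `distance_to_ci`, `closest`.
#' @export
model_fit_check <- function(obs_fit, sim_lambdas) {
  stopifnot(inherits(obs_fit, "ld_decay_fit"), !is.null(obs_fit$ci))
  lo <- obs_fit$ci["2.5%", "lambda"]
  hi <- obs_fit$ci["97.5%", "lambda"]
  rows <- lapply(names(sim_lambdas), function(m) {
    lam <- stats::median(sim_lambdas[[m]], na.rm = TRUE)
    cons <- lam >= lo && lam <= hi
    data.frame(model = m, lambda_sim = lam, consistent = cons,
               distance_to_ci = if (cons) 0 else min(abs(lam - lo), abs(lam - hi)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$closest <- abs(out$lambda_sim - obs_fit$lambda) ==
    min(abs(out$lambda_sim - obs_fit$lambda))
  out[order(abs(out$lambda_sim - obs_fit$lambda)), ]
}
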