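#' Three-population demographic model
#'
#' Describes the demographic history used by the simulator and by SFS-based
#' demographic inference: an ancestral population splits twice, giving the
#' rooted topology ((Andes, Central), North).  Backward in time, Central
#' merges into Andes at `T_split_C` and North merges into the common ancestor
#' at `T_split_N`; beyond `T_split_N` the single ancestral population has
#' diploid size `N_anc`.  Between the two splits the joint Andes/Central
#' lineage keeps the Andes branch's size history.
#'
#' Three nested variants are supported:
#' \describe{
#'   \item{constant}{each population keeps a constant diploid size
#'     (`N_final`); 6 free parameters.}
#'   \item{growth}{each population grows exponentially at per-generation rate
#'     `r` from its founding to the present, ending at `N_final`; 9 free
#'     parameters.}
#'   \item{resize}{each population has present size `N_final` back to
#'     `T_resize`, and size `N_init` from `T_resize` back to its founding;
#'     12 free parameters.}
#' }
#' Setting `fix_anc = TRUE` ties `N_anc` to the Andes branch size at the root,
#' removing one parameter (some parameterizations in the literature count the
#' ancestral size as shared with the pre-split lineage).
#'
#' @param variant one of `"constant"`, `"growth"`, `"resize"`.
#' @param N_anc diploid ancestral population size.
#' @param T_split_N generations ago at which North diverged (the older split).
#' @param T_split_C generations ago at which Central diverged from Andes.
#' @param N_final named numeric of present-day diploid sizes for
#'   `Andes`, `Central`, `North`.
#' @param r per-generation exponential growth rates (growth variant), same
#'   names as `N_final`.
#' @param N_init diploid sizes at founding (resize variant).
#' @param T_resize generations ago of the instantaneous resize events
#'   (resize variant); each must predate its population's founding.
#' @param migration optional square matrix of per-generation migration
#'   fractions `m[i, j]` (backward rate of a lineage in `i` moving to `j`),
#'   with dimnames among the population names.
#' @param admixture optional list with elements `sources` (two population
#'   names), `alpha` (proportion drawn from the first source), `time`
#'   (generations ago of the founding pulse) and `N` (diploid size of the
#'   admixed deme).  Adds a fourth sampled deme named `"Admixed"`.
#' @param fix_anc tie `N_anc` to the pre-split Andes lineage size.
#' @return an object of class `demographic_model`.
#' @examples
#' m <- three_pop_model("constant", N_anc = 1000, T_split_N = 6750,
#'                      T_split_C = 5000,
#'                      N_final = c(Andes = 2000, Central = 800, North = 600))
#' @export
three_pop_model <- function(variant = c("constant", "growth", "resize"),
                            N_anc, T_split_N, T_split_C, N_final,
                            r = NULL, N_init = NULL, T_resize = NULL,
                            migration = NULL, admixture = NULL,
                            fix_anc = FALSE) {
  variant <- match.arg(variant)
  pops <- c("Andes", "Central", "North")
  N_final <- .named3(N_final, pops, "N_final")
  if (fix_anc) N_anc <- N_final[["Andes"]]
  if (!is.numeric(N_anc) || length(N_anc) != 1L || N_anc <= 0)
    stop("invalid model: N_anc must be a single positive size")
  if (!(T_split_N > T_split_C && T_split_C > 0))
    stop("invalid model: split times must satisfy T_split_N > T_split_C > 0")
  if (any(N_final <= 0)) stop("invalid model: all sizes must be positive")
  founding <- c(Andes = T_split_N, Central = T_split_C, North = T_split_N)
  if (variant == "growth") {
    r <- .named3(r, pops, "r")
  } else if (variant == "resize") {
    N_init <- .named3(N_init, pops, "N_init")
    T_resize <- .named3(T_resize, pops, "T_resize")
    if (any(N_init <= 0)) stop("invalid model: all sizes must be positive")
    if (any(T_resize <= 0) || any(T_resize >= founding[pops]))
      stop("invalid model: T_resize must lie inside (0, founding time)")
  }
  if (!is.null(admixture)) {
    stopifnot(is.list(admixture))
    if (!all(c("sources", "alpha", "time", "N") %in% names(admixture)))
      stop("admixture spec needs sources, alpha, time, N")
    if (admixture$alpha < 0 || admixture$alpha > 1)
      stop("invalid model: admixture proportion must be in [0, 1]")
    if (!all(admixture$sources %in% pops) || length(admixture$sources) != 2L)
      stop("admixture sources must be two of Andes/Central/North")
    if (admixture$time <= 0 || admixture$time >= T_split_C)
      stop("invalid model: admixture time must predate sampling and precede T_split_C")
  }
  if (!is.null(migration)) {
    migration <- as.matrix(migration)
    if (nrow(migration) != ncol(migration) || any(migration < 0))
      stop("migration must be a square non-negative matrix")
  }
  structure(list(kind = "three_pop", variant = variant, pops = pops,
                 N_anc = N_anc, T_split_N = T_split_N, T_split_C = T_split_C,
                 N_final = N_final, r = r, N_init = N_init,
                 T_resize = T_resize, migration = migration,
                 admixture = admixture, fix_anc = fix_anc),
            class = "demographic_model")
}

.named3 <- function(x, pops, what) {
  if (is.null(x)) stop("invalid model: ", what, " is required for this variant")
  if (is.null(names(x))) names(x) <- pops[seq_along(x)]
  if (!all(pops %in% names(x))) stop(what, " must be named for ", paste(pops, collapse = ", "))
  x[pops]
}

#' Single-population model
#'
#' Degenerate one-deme model, mostly used for analytic checks (expected
#' coalescence times, the 1/i neutral frequency spectrum) and for simulating
#' unstructured data.
#'
#' @param N diploid population size.
#' @param growth optional backward list of `(time, N, g)` epochs; by default a
#'   single constant epoch.
#' @return an object of class `demographic_model`.
#' @export
single_pop_model <- function(N, growth = NULL) {
  if (N <= 0) stop("invalid model: N must be positive")
  structure(list(kind = "single", variant = "constant", pops = "Pop1",
                 N = N, epochs = growth), class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  if (x$kind == "single") {
    cat("Single-population coalescent model, diploid N =", x$N, "\n")
  } else {
    cat("Three-population model ((Andes,Central),North), variant:", x$variant, "\n")
    cat("  T_split_N =", x$T_split_N, " T_split_C =", x$T_split_C,
        " N_anc =", x$N_anc, "\n")
    cat("  N_final:", paste(names(x$N_final), x$N_final, sep = "=", collapse = " "), "\n")
    if (!is.null(x$admixture))
      cat("  admixed deme: ", paste(x$admixture$sources, collapse = "+"),
          " alpha=", x$admixture$alpha, " t=", x$admixture$time, "\n", sep = "")
  }
  invisible(x)
}

#' Simulation configuration
#'
#' @param n_per_pop diploid individuals sampled per deme (recycled across
#'   demes if scalar).
#' @param L sequence length in bp.
#' @param mu mutation rate per bp per generation.
#' @param rec recombination (crossover) rate per bp per generation; the
#'   default corresponds to 2.97 cM/Mb.
#' @param seed integer random seed.
#' @param n_rep number of independent replicates.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_per_pop = 8, L = 1e6, mu = 2.9e-9, rec = 0,
                       seed = 1, n_rep = 1) {
  if (L < 1) stop("L must be >= 1")
  if (mu < 0 || rec < 0) stop("mu and rec must be non-negative")
  if (any(n_per_pop < 1)) stop("need at least one diploid per sampled deme")
  structure(list(n_per_pop = n_per_pop, L = L, mu = mu, rec = rec,
                 seed = as.integer(seed), n_rep = as.integer(n_rep)),
            class = "sim_config")
}

# ---- compile a demographic_model to the C++ engine's representation --------

# sampled_pops: names of demes lineages are sampled from
compile_model <- function(model, n_hap_per_pop) {
  stopifnot(inherits(model, "demographic_model"))
  if (model$kind == "single") {
    epochs <- model$epochs
    if (is.null(epochs)) epochs <- matrix(c(0, model$N, 0), nrow = 1)
    return(list(pops = "Pop1", n_samp = n_hap_per_pop[1],
                epochs = list(epochs),
                events = matrix(numeric(0), ncol = 6),
                mig = matrix(0, 1, 1)))
  }
  pops <- model$pops
  has_adm <- !is.null(model$admixture)
  if (has_adm) pops <- c(pops, "Admixed")
  np <- length(pops)
  founding <- c(Andes = model$T_split_N, Central = model$T_split_C,
                North = model$T_split_N)
  epochs <- vector("list", np)
  for (i in seq_len(3)) {
    p <- model$pops[i]
    rows <- switch(model$variant,
      constant = matrix(c(0, model$N_final[[p]], 0), nrow = 1),
      growth = matrix(c(0, model$N_final[[p]], -model$r[[p]]), nrow = 1),
      resize = rbind(c(0, model$N_final[[p]], 0),
                     c(model$T_resize[[p]], model$N_init[[p]], 0)))
    if (p == "Andes")
      rows <- rbind(rows, c(model$T_split_N, model$N_anc, 0))
    epochs[[i]] <- rows
  }
  ev <- rbind(c(model$T_split_C, 0, 1, 0, 0, 0),   # Central -> Andes
              c(model$T_split_N, 0, 2, 0, 0, 0))   # North  -> Andes(=ancestor)
  if (has_adm) {
    adm <- model$admixture
    epochs[[4]] <- matrix(c(0, adm$N, 0), nrow = 1)
    s1 <- match(adm$sources[1], model$pops) - 1L
    s2 <- match(adm$sources[2], model$pops) - 1L
    ev <- rbind(c(adm$time, 1, 3, s1, s2, adm$alpha), ev)
  }
  ev <- ev[order(ev[, 1]), , drop = FALSE]
  mig <- matrix(0, np, np)
  if (!is.null(model$migration)) {
    mm <- model$migration
    idx <- match(rownames(mm), pops)
    if (any(is.na(idx))) stop("migration dimnames must match population names")
    mig[idx, idx] <- mm
    diag(mig) <- 0
  }
  n_samp <- rep_len(n_hap_per_pop, np)
  list(pops = pops, n_samp = as.integer(n_samp), epochs = epochs,
       events = ev, mig = mig)
}
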