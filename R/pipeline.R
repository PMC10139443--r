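# ---- file formats ---------------------------------------------------------

.base_code <- function(b) match(b, c("A", "C", "G", "T")) - 1L

#' Write genotype likelihoods in BEAGLE-GL format
#'
#' One row per site: `marker` (`contig_position`, 1-based), numeric codes of
#' the two alleles (0=A..3=T), then three scaled likelihoods per individual
#' summing to 1.
#'
#' @param glm a `gl_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_beagle <- function(glm, path) {
  stopifnot(inherits(glm, "gl_matrix"))
  S <- nrow(glm$sites); n <- length(glm$ind)
  lin <- exp(glm$gl)
  lin <- lin / array(rep(rowSums(lin, dims = 2), 3L), dim = dim(lin))
  cols <- list(marker = sprintf("%s_%d", glm$sites$contig, glm$sites$position + 1L),
               allele1 = .base_code(glm$sites$major),
               allele2 = .base_code(glm$sites$minor))
  df <- as.data.frame(cols)
  for (i in seq_len(n)) {
    block <- matrix(lin[, i, ], ncol = 3L)
    df[[paste0(glm$ind[i], "_AA")]] <- block[, 1]
    df[[paste0(glm$ind[i], "_Aa")]] <- block[, 2]
    df[[paste0(glm$ind[i], "_aa")]] <- block[, 3]
  }
  utils::write.table(format(df, digits = 12, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BEAGLE-GL file
#'
#' @param path input path.
#' @return a `gl_matrix` (depth unknown; cells whose three scaled likelihoods
#'   are equal are flagged missing).
#' @export
read_beagle <- function(path) {
  df <- tryCatch(utils::read.table(path, header = TRUE, sep = "\t",
                                   stringsAsFactors = FALSE, check.names = FALSE),
                 error = function(e) stop("cannot parse BEAGLE file ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  if (ncol(df) < 6 || (ncol(df) - 3) %% 3 != 0)
    stop("malformed BEAGLE file ", path, ": expected 3 + 3k columns, got ", ncol(df))
  n <- (ncol(df) - 3L) %/% 3L
  S <- nrow(df)
  mk <- strsplit(df[[1]], "_(?=[^_]+$)", perl = TRUE)
  contig <- vapply(mk, `[`, "", 1L)
  pos1 <- suppressWarnings(as.integer(vapply(mk, `[`, "", 2L)))
  bad <- which(is.na(pos1))
  if (length(bad)) stop("malformed BEAGLE file ", path, ": bad marker at line ",
                        bad[1] + 1L)
  bases <- c("A", "C", "G", "T")
  gl <- array(0, dim = c(S, n, 3L))
  missing <- matrix(FALSE, S, n)
  ind <- character(n)
  for (i in seq_len(n)) {
    block <- as.matrix(df[, 3L + (i - 1L) * 3L + 1:3, drop = FALSE])
    ind[i] <- sub("_AA$", "", colnames(df)[3L + (i - 1L) * 3L + 1L])
    missing[, i] <- abs(block[, 1] - block[, 2]) < 1e-12 &
      abs(block[, 2] - block[, 3]) < 1e-12
    lg <- log(pmax(block, 1e-300))
    gl[, i, ] <- lg - apply(lg, 1L, max)
  }
  sites <- data.frame(contig = contig, position = pos1 - 1L,
                      major = bases[df[[2]] + 1L], minor = bases[df[[3]] + 1L],
                      ref = bases[df[[2]] + 1L], stringsAsFactors = FALSE)
  maf <- estimate_maf_matrix(gl, missing)
  structure(list(gl = gl, sites = sites, ind = ind,
                 pop = factor(rep("unknown", n)), depth = NULL,
                 missing = missing, maf = maf, epsilon = NA_real_),
            class = "gl_matrix")
}

#' Write called genotypes as VCF
#'
#' Minimal VCFv4.2 with GT fields; positions are emitted 1-based.
#'
#' @param geno genotype matrix individuals x sites (0/1/2 minor-allele
#'   dosage, `NA` missing).
#' @param sites data.frame with `contig`, `position` (0-based), `major`,
#'   `minor` (used as REF/ALT).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, sites, path) {
  stopifnot(nrow(sites) == ncol(geno))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=glpopgen",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  ids <- rownames(geno)
  if (is.null(ids)) ids <- sprintf("ind%02d", seq_len(nrow(geno)))
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", ids), collapse = "\t"), con)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  for (s in seq_len(nrow(sites))) {
    g <- geno[, s]
    gt <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
    writeLines(paste(c(sites$contig[s], sites$position[s] + 1L, ".",
                       sites$major[s], sites$minor[s], ".", "PASS", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a VCF of hard genotypes
#'
#' @param path input path.
#' @return list with `geno` (individuals x sites dosage matrix) and `sites`.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("malformed VCF ", path, ": missing #CHROM header line")
  cols <- strsplit(lines[hdr], "\t")[[1]]
  ids <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  geno <- matrix(NA_integer_, length(ids), length(body))
  rownames(geno) <- ids
  sites <- data.frame(contig = character(length(body)),
                      position = integer(length(body)),
                      major = character(length(body)),
                      minor = character(length(body)),
                      stringsAsFactors = FALSE)
  for (k in seq_along(body)) {
    f <- strsplit(body[k], "\t")[[1]]
    if (length(f) != 9 + length(ids))
      stop("malformed VCF ", path, ": wrong field count at line ", hdr + k)
    sites$contig[k] <- f[1]
    sites$position[k] <- as.integer(f[2]) - 1L
    sites$major[k] <- f[4]
    sites$minor[k] <- f[5]
    gt <- sub(":.*", "", f[-(1:9)])
    g <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L, "0|1" = 1L,
           "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)[gt]
    geno[, k] <- unname(g)
  }
  list(geno = geno, sites = sites)
}

#' Write/read a Treemix-style allele-count table
#'
#' Space-separated, header of population names, one line per site with
#' `a1,a2` count fields per population.
#'
#' @param ct a [count_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_treemix <- function(ct, path) {
  stopifnot(inherits(ct, "count_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(ct$locations, collapse = " "), con)
  for (s in seq_len(nrow(ct$a1))) {
    writeLines(paste(sprintf("%d,%d", ct$a1[s, ], ct$a2[s, ]), collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_treemix
#' @export
read_treemix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("malformed Treemix file ", path, ": no data lines")
  locs <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  S <- length(lines) - 1L
  a1 <- a2 <- matrix(0L, S, length(locs), dimnames = list(NULL, locs))
  for (k in seq_len(S)) {
    f <- strsplit(trimws(lines[k + 1L]), "\\s+")[[1]]
    if (length(f) != length(locs))
      stop("malformed Treemix file ", path, ": wrong field count at line ", k + 1L)
    parts <- strsplit(f, ",")
    a1[k, ] <- as.integer(vapply(parts, `[`, "", 1L))
    a2[k, ] <- as.integer(vapply(parts, `[`, "", 2L))
  }
  structure(list(a1 = a1, a2 = a2, n = a1 + a2, locations = locs),
            class = "count_table")
}

#' Write/read an SFS table
#'
#' Whitespace-delimited flat vector (or row-flattened matrix) with a header
#' line carrying population ids, chromosome counts and the folded flag.
#'
#' @param x an `sfs_1d`, `sfs_2d`, or matrix with attributes.
#' @param pops population id(s).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sfs_table <- function(x, pops, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(x, "sfs_1d")) {
    writeLines(sprintf("# pop=%s n_chr=%d folded=%d", pops[1], x$n_chr,
                       as.integer(x$folded)), con)
    writeLines(paste(format(x$counts, digits = 10), collapse = " "), con)
  } else if (inherits(x, "sfs_2d")) {
    writeLines(sprintf("# pops=%s,%s n_chr=%d,%d folded=%d", pops[1], pops[2],
                       x$n_chr[1], x$n_chr[2], as.integer(x$folded)), con)
    for (i in seq_len(nrow(x$counts)))
      writeLines(paste(format(x$counts[i, ], digits = 10), collapse = " "), con)
  } else stop("unsupported SFS object")
  invisible(path)
}

#' @rdname write_sfs_table
#' @export
read_sfs_table <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1]
  if (!startsWith(hdr, "#")) stop("malformed SFS table ", path, ": missing header at line 1")
  vals <- lapply(lines[-1], function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  folded <- grepl("folded=1", hdr)
  if (length(vals) == 1L) {
    list(counts = vals[[1]], folded = folded, header = hdr)
  } else {
    list(counts = do.call(rbind, vals), folded = folded, header = hdr)
  }
}

#' Read a BED file of intervals
#'
#' @param path BED path (0-based half-open).
#' @return data.frame with `contig`, `start`, `end`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("malformed BED ", path, ": fewer than 3 columns")
  data.frame(contig = df[[1]], start = df[[2]], end = df[[3]],
             stringsAsFactors = FALSE)
}

# ---- orchestration --------------------------------------------------------

#' Default pipeline configuration
#'
#' @param out_dir output directory.
#' @param seed master seed; stage seeds are derived from it.
#' @return nested configuration list; unknown keys passed to
#'   [run_pipeline()] are rejected.
#' @export
pipeline_config <- function(out_dir = tempfile("glpopgen_run_"), seed = 1) {
  list(
    out_dir = out_dir,
    seed = as.integer(seed),
    stages = c("syndata", "genolik", "sfs", "popstats", "structure",
               "fstats", "ldscan"),
    syndata = list(variant = "resize", n_per_pop = 4, L = 1e5, mu = 2e-7,
                   rec = 0, mean_depth = 8, error_rate = 0.005),
    genolik = list(snp_p_threshold = 1e-6, min_maf = 0.05, prune_dist = 500,
                   max_missing = 0.20),
    sfs = list(folded = TRUE, max_iter = 400),
    popstats = list(window = 5000, step = 500, min_sites = 10,
                    top_fraction = 0.001),
    structure = list(n_axes = 2, K = 3, n_restarts = 3),
    fstats = list(block = 100),
    ldscan = list(max_dist = 10000, subsample = 1.0, bin_size = 500,
                  n_boot = 50)
  )
}

.default_model_for <- function(variant) {
  three_pop_model(variant,
    N_anc = 1000, T_split_N = 6750, T_split_C = 5000,
    N_final = c(Andes = 2000, Central = 800, North = 600),
    r = if (variant == "growth") c(Andes = 2e-4, Central = 2e-4, North = 2e-4) else NULL,
    N_init = if (variant == "resize") c(Andes = 500, Central = 400, North = 300) else NULL,
    T_resize = if (variant == "resize") c(Andes = 2000, Central = 1000, North = 500) else NULL)
}

#' Run the synthetic-data analysis pipeline
#'
#' Executes the requested stages in dependency order
#' (syndata -> genolik -> {sfs -> popstats, structure, fstats, ldscan}),
#' writing each stage's tables to `config$out_dir` together with a manifest
#' (file, producing stage, md5 checksum) and a run log (stage timings, seeds,
#' site-attrition counts).  Outputs are byte-identical across reruns with the
#' same configuration.
#'
#' @param config configuration list from [pipeline_config()] (possibly with
#'   modified values); unknown keys are rejected.
#' @param model optional [three_pop_model()] overriding the built-in default
#'   for the configured variant.
#' @return the output directory, invisibly; side effect: files and
#'   `manifest.tsv` / `run_log.txt` under `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), model = NULL) {
  ref <- pipeline_config()
  bad <- setdiff(names(config), names(ref))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  for (sec in intersect(names(config), names(ref))) {
    if (is.list(ref[[sec]])) {
      bad <- setdiff(names(config[[sec]]), names(ref[[sec]]))
      if (length(bad)) stop("unknown config keys in ", sec, ": ",
                            paste(bad, collapse = ", "))
    }
  }
  cfg <- utils::modifyList(ref, config)
  stages <- cfg$stages
  deps <- list(genolik = "syndata", sfs = "genolik", popstats = "sfs",
               structure = "genolik", fstats = "genolik", ldscan = "genolik")
  for (st in stages) {
    need <- deps[[st]]
    if (!is.null(need) && !all(need %in% stages))
      stop("stage '", st, "' requires stage '", need, "'")
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  logline <- character(0)
  t_start <- Sys.time()
  note <- function(...) logline <<- c(logline, sprintf(...))
  emit <- function(stage, file) manifest[[length(manifest) + 1L]] <<-
    data.frame(stage = stage, file = basename(file), md5 = tools::md5sum(file)[[1]])
  note("run started; master seed %d", cfg$seed)

  ok <- TRUE
  tryCatch({
    # syndata
    if (is.null(model)) model <- .default_model_for(cfg$syndata$variant)
    sc <- sim_config(n_per_pop = cfg$syndata$n_per_pop, L = cfg$syndata$L,
                     mu = cfg$syndata$mu, rec = cfg$syndata$rec,
                     seed = cfg$seed)
    haps <- simulate_genotypes(model, sc)
    note("syndata: %d segregating sites, seed %d", length(haps$positions), cfg$seed)
    geno_true <- true_genotypes(haps)
    f <- file.path(cfg$out_dir, "truth.vcf")
    sites_true <- data.frame(contig = haps$contig, position = haps$positions,
                             major = haps$ref, minor = haps$alt,
                             stringsAsFactors = FALSE)
    write_vcf(geno_true, sites_true, f); emit("syndata", f)

    # genolik
    glm <- NULL
    if ("genolik" %in% stages) {
      pile <- simulate_reads(haps, cfg$syndata$mean_depth,
                             cfg$syndata$error_rate, cfg$seed + 1L)
      glm <- gl_matrix(pile)
      f <- file.path(cfg$out_dir, "genolik.beagle")
      write_beagle(glm, f); emit("genolik", f)
      geno <- call_genotypes(glm)
      fc <- site_filter_config(snp_p_threshold = cfg$genolik$snp_p_threshold,
                               min_maf = cfg$genolik$min_maf,
                               prune_dist = cfg$genolik$prune_dist,
                               max_missing = cfg$genolik$max_missing)
      keep <- prune_and_filter(glm, fc, geno)
      att <- attr(keep, "attrition")
      note("genolik: filter attrition %s",
           paste(names(att), att, sep = "=", collapse = ", "))
      f <- file.path(cfg$out_dir, "called.vcf")
      write_vcf(geno[, keep, drop = FALSE], glm$sites[keep, ], f)
      emit("genolik", f)
    }

    pops <- levels(glm$pop)
    safs <- sfs1 <- list()
    if ("sfs" %in% stages) {
      for (p in pops) {
        safs[[p]] <- saf_population(glm, glm$pop == p)
        sfs1[[p]] <- em_sfs_1d(safs[[p]], folded = cfg$sfs$folded,
                               max_iter = cfg$sfs$max_iter)
        f <- file.path(cfg$out_dir, paste0("sfs1d_", p, ".txt"))
        write_sfs_table(sfs1[[p]], p, f); emit("sfs", f)
      }
    }

    if ("popstats" %in% stages) {
      pair_comp <- list()
      common <- Reduce(intersect, lapply(safs, `[[`, "site_idx"))
      for (k in seq_along(.pairs3)) {
        pr <- .pairs3[[k]]
        s1 <- safs[[pr[1]]]; s2 <- safs[[pr[2]]]
        i1 <- match(common, s1$site_idx); i2 <- match(common, s2$site_idx)
        sfs2 <- em_sfs_2d(s1$saf[i1, , drop = FALSE], s2$saf[i2, , drop = FALSE],
                          folded = cfg$sfs$folded, max_iter = cfg$sfs$max_iter)
        f <- file.path(cfg$out_dir, paste0("sfs2d_", .pair_key(pr), ".txt"))
        write_sfs_table(sfs2, pr, f); emit("popstats", f)
        pair_comp[[.pair_key(pr)]] <-
          fst_components(s1$saf[i1, , drop = FALSE], s2$saf[i2, , drop = FALSE], sfs2)
      }
      pos <- glm$sites$position[common]
      scan <- pbs_scan(pos, pair_comp[["Andes_Central"]],
                       pair_comp[["Andes_North"]], pair_comp[["Central_North"]],
                       window = cfg$popstats$window, step = cfg$popstats$step,
                       min_sites = cfg$popstats$min_sites,
                       top_fraction = cfg$popstats$top_fraction,
                       pop_names = c("Andes", "Central", "North"))
      f <- file.path(cfg$out_dir, "pbs_windows.tsv")
      utils::write.table(scan, f, sep = "\t", quote = FALSE, row.names = FALSE)
      emit("popstats", f)
      for (p in pops) {
        th <- site_thetas(safs[[p]], sfs1[[p]])
        tw <- theta_windows(glm$sites$position[safs[[p]]$site_idx], th,
                            safs[[p]]$n_chr, window = 4 * cfg$popstats$window,
                            step = 4 * cfg$popstats$window,
                            min_sites = cfg$popstats$min_sites)
        f <- file.path(cfg$out_dir, paste0("theta_windows_", p, ".tsv"))
        utils::write.table(tw, f, sep = "\t", quote = FALSE, row.names = FALSE)
        emit("popstats", f)
      }
    }

    if ("structure" %in% stages) {
      pca <- pca_gl(glm, n_axes = cfg$structure$n_axes)
      f <- file.path(cfg$out_dir, "pca_covariance.tsv")
      utils::write.table(round(pca$cov, 10), f, sep = "\t", quote = FALSE)
      emit("structure", f)
      adm <- admixture_em(glm, K = cfg$structure$K, seed = cfg$seed + 2L,
                          n_restarts = cfg$structure$n_restarts)
      f <- file.path(cfg$out_dir, "admixture_Q.tsv")
      utils::write.table(round(adm$Q, 8), f, sep = "\t", quote = FALSE)
      emit("structure", f)
      note("structure: PC1 %.1f%%, PC2 %.1f%% of variance",
           100 * pca$var_frac[1], 100 * pca$var_frac[2])
    }

    if ("fstats" %in% stages) {
      geno <- call_genotypes(glm)
      ct <- count_table(geno, glm$pop)
      use <- rowSums(ct$n >= 2) == length(pops) &
        pmin(rowSums(ct$a2), rowSums(ct$a1)) > 0
      ct2 <- structure(list(a1 = ct$a1[use, , drop = FALSE],
                            a2 = ct$a2[use, , drop = FALSE],
                            n = ct$n[use, , drop = FALSE],
                            locations = ct$locations), class = "count_table")
      f <- file.path(cfg$out_dir, "counts.treemix")
      write_treemix(ct2, f); emit("fstats", f)
      if (nrow(ct2$a1) >= 2 * cfg$fstats$block) {
        f3 <- f3_scan(ct2, block = cfg$fstats$block)
        f <- file.path(cfg$out_dir, "f3.tsv")
        utils::write.table(f3, f, sep = "\t", quote = FALSE, row.names = FALSE)
        emit("fstats", f)
      } else note("fstats: too few SNPs for jackknife blocks; f3 skipped")
    }

    if ("ldscan" %in% stages) {
      pairs <- collect_pairs(glm, max_dist = cfg$ldscan$max_dist,
                             subsample = cfg$ldscan$subsample,
                             seed = cfg$seed + 3L)
      f <- file.path(cfg$out_dir, "ld_pairs.tsv")
      utils::write.table(pairs, f, sep = "\t", quote = FALSE, row.names = FALSE)
      emit("ldscan", f)
      if (nrow(pairs) >= 10) {
        fit <- fit_decay(pairs, bin_size = cfg$ldscan$bin_size,
                         n_boot = cfg$ldscan$n_boot, seed = cfg$seed + 4L)
        f <- file.path(cfg$out_dir, "ld_decay.tsv")
        utils::write.table(
          data.frame(lambda = fit$lambda, r2_max = fit$r2_max,
                     r2_min = fit$r2_min, n_pairs = fit$n_pairs),
          f, sep = "\t", quote = FALSE, row.names = FALSE)
        emit("ldscan", f)
      }
    }
  }, error = function(e) {
    ok <<- FALSE
    unlink(list.files(cfg$out_dir, full.names = TRUE))
    stop("pipeline failed (partial outputs removed): ", conditionMessage(e),
         call. = FALSE)
  })

  note("run finished in %.1f s", as.numeric(difftime(Sys.time(), t_start, units = "secs")))
  man <- do.call(rbind, manifest)
  utils::write.table(man, file.path(cfg$out_dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(logline, file.path(cfg$out_dir, "run_log.txt"))
  invisible(cfg$out_dir)
}
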