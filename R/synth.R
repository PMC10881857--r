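#' Simulation configuration for synthetic multi-omic cohorts
#'
#' Defines the generative model for a three-block (CpG methylation, transcript
#' counts, miRNA counts) cohort with sparse shared latent factors, planted
#' typed regulatory pairs, missingness in the methylation block and
#' proportional-hazards survival. All downstream stages of the pipeline can be
#' exercised against the returned ground truth.
#'
#' The latent model is: per feature, value = loading x factor + unit Gaussian
#' noise, mapped monotonically to the observed scale (inverse-logit for beta
#' values; negative-binomial counts with log-mean proportional to the latent
#' value). Monotone maps preserve the ordering of mutual information, so
#' planted dependencies survive the transform. Regulatory pairs receive an
#' extra pair-specific shared latent (strength `pair_strength`), a signal
#' class distinct from the factors so that threshold calibration has its own
#' target.
#'
#' @param n_samples Number of samples.
#' @param n_cpg,n_transcript,n_mirna Features per block.
#' @param n_factors Number of shared latent factors (may be 0).
#' @param loading_sparsity Fraction in (0, 1] of each block's features loaded
#'   per factor.
#' @param factor_strength Loading magnitude (signal s.d. relative to unit
#'   noise). At strength s, two features loaded on the same factor have latent
#'   correlation s^2 / (s^2 + 1).
#' @param n_regulatory_pairs Named integer vector over the four edge types
#'   `cpg_transcript`, `cpg_mirna`, `tf_transcript`, `mirna_transcript`.
#' @param pair_strength Shared-latent strength for planted regulatory pairs.
#' @param missing_rate Fraction in [0, 1) of CpG entries set missing.
#' @param hazard_coefficients Named numeric vector (feature id -> log hazard
#'   ratio per s.d.) used by [simulate_survival()].
#' @param censoring_rate Target fraction of censored samples (independent
#'   exponential censoring).
#' @param promoter_cpg_fraction Fraction of CpGs placed inside the promoter
#'   window of their annotated gene; the remainder are placed inside enhancer
#'   intervals.
#' @param seed Integer master seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 200, n_cpg = 60, n_transcript = 60,
                       n_mirna = 30, n_factors = 3, loading_sparsity = 0.1,
                       factor_strength = 5,
                       n_regulatory_pairs = c(cpg_transcript = 8, cpg_mirna = 4,
                                              tf_transcript = 8,
                                              mirna_transcript = 8),
                       pair_strength = 3, missing_rate = 0.05,
                       hazard_coefficients = numeric(),
                       censoring_rate = 0.3, promoter_cpg_fraction = 1,
                       seed = 1L) {
  if (n_samples < 1 || n_cpg < 1 || n_transcript < 1 || n_mirna < 1) {
    stop("dimensions must be positive")
  }
  if (n_factors < 0) stop("n_factors must be >= 0")
  if (loading_sparsity <= 0 || loading_sparsity > 1) {
    stop("loading_sparsity must be in (0, 1]")
  }
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  allowed <- c("cpg_transcript", "cpg_mirna", "tf_transcript", "mirna_transcript")
  if (length(n_regulatory_pairs) &&
      !all(names(n_regulatory_pairs) %in% allowed)) {
    stop("edge-type labels must be among: ", paste(allowed, collapse = ", "))
  }
  structure(list(n_samples = as.integer(n_samples), n_cpg = as.integer(n_cpg),
                 n_transcript = as.integer(n_transcript),
                 n_mirna = as.integer(n_mirna),
                 n_factors = as.integer(n_factors),
                 loading_sparsity = loading_sparsity,
                 factor_strength = factor_strength,
                 n_regulatory_pairs = n_regulatory_pairs,
                 pair_strength = pair_strength, missing_rate = missing_rate,
                 hazard_coefficients = hazard_coefficients,
                 censoring_rate = censoring_rate,
                 promoter_cpg_fraction = promoter_cpg_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

pad_id <- function(prefix, i, n) sprintf("%s%0*d", prefix, nchar(as.character(n)), i)

synth_feature_ids <- function(config) {
  list(cpg = pad_id("cpg", seq_len(config$n_cpg), config$n_cpg),
       transcript = pad_id("tx", seq_len(config$n_transcript), config$n_transcript),
       mirna = pad_id("mir", seq_len(config$n_mirna), config$n_mirna))
}

synth_gene_of_transcript <- function(tx_ids) sub("^tx", "gene", tx_ids)
synth_gene_of_mirna <- function(mir_ids) sub("^mir", "mirg", mir_ids)

#' Simulate an aligned three-block multi-omic dataset
#'
#' @param config A [sim_config()].
#' @return List with `blocks` (named list of [omics_block()]: `cpg` beta
#'   values with missingness, `transcript` and `mirna` raw counts), `metadata`
#'   (data.frame: sample, subtype), `truth` (ground truth: per-block loading
#'   matrices, loaded feature ids per factor, planted regulatory pairs, the
#'   factor score matrix, and the latent Gaussian blocks used downstream for
#'   oracle checks).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  ids <- synth_feature_ids(config)
  samples <- pad_id("s", seq_len(n), n)
  R <- config$n_factors
  fmat <- matrix(stats::rnorm(n * max(R, 1)), n, max(R, 1))
  if (R == 0) fmat <- fmat[, 0, drop = FALSE]

  make_block <- function(p, fids) {
    L <- matrix(0, p, max(R, 0))
    loaded <- vector("list", R)
    if (R > 0) {
      m <- max(1L, round(config$loading_sparsity * p))
      for (r in seq_len(R)) {
        idx <- sample.int(p, m)
        L[idx, r] <- config$factor_strength * sample(c(-1, 1), m, replace = TRUE)
        loaded[[r]] <- fids[idx]
      }
    }
    Z <- matrix(stats::rnorm(p * n), p, n)
    if (R > 0) Z <- Z + L %*% t(fmat)
    dimnames(Z) <- list(fids, samples)
    rownames(L) <- fids
    list(L = L, Z = Z, loaded = loaded)
  }
  bc <- make_block(config$n_cpg, ids$cpg)
  bt <- make_block(config$n_transcript, ids$transcript)
  bm <- make_block(config$n_mirna, ids$mirna)
  latent <- list(cpg = bc$Z, transcript = bt$Z, mirna = bm$Z)

  # planted regulatory pairs: shared pair-specific latent added to both ends
  kinds <- list(cpg_transcript = c("cpg", "transcript"),
                cpg_mirna = c("cpg", "mirna"),
                tf_transcript = c("transcript", "transcript"),
                mirna_transcript = c("mirna", "transcript"))
  used <- list(cpg = character(), transcript = character(), mirna = character())
  pairs <- list()
  for (type in names(config$n_regulatory_pairs)) {
    k <- config$n_regulatory_pairs[[type]]
    if (k <= 0) next
    ka <- kinds[[type]][1]; kb <- kinds[[type]][2]
    for (i in seq_len(k)) {
      # prefer features not yet in any pair; fall back to reuse (hub nodes)
      avail_a <- setdiff(ids[[ka]], used[[ka]])
      if (length(avail_a) == 0) avail_a <- ids[[ka]]
      a <- sample(avail_a, 1)
      avail_b <- setdiff(ids[[kb]], c(used[[kb]], a))
      if (length(avail_b) == 0) avail_b <- setdiff(ids[[kb]], a)
      b <- sample(avail_b, 1)
      if (any(vapply(pairs, function(d) {
        (d$a == a & d$b == b) | (d$a == b & d$b == a)
      }, logical(1)))) next
      used[[ka]] <- c(used[[ka]], a); used[[kb]] <- c(used[[kb]], b)
      g <- stats::rnorm(n)
      latent[[ka]][a, ] <- latent[[ka]][a, ] + config$pair_strength * g
      latent[[kb]][b, ] <- latent[[kb]][b, ] + config$pair_strength * g
      pairs[[length(pairs) + 1L]] <- data.frame(a = a, b = b, type = type,
                                                stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(a = character(), b = character(), type = character(),
               stringsAsFactors = FALSE)

  # monotone maps to the observed scales
  beta <- stats::plogis(latent$cpg)
  if (config$missing_rate > 0) {
    mask <- matrix(stats::runif(length(beta)) < config$missing_rate,
                   nrow(beta), ncol(beta))
    beta[mask] <- NA_real_
  }
  to_counts <- function(Z, base_range) {
    p <- nrow(Z)
    mu0 <- stats::runif(p, log(base_range[1]), log(base_range[2]))
    mu <- exp(mu0 + 0.3 * Z)
    cnt <- matrix(stats::rnbinom(length(mu), size = 10, mu = mu), p, ncol(Z))
    dimnames(cnt) <- dimnames(Z)
    cnt
  }
  tx_counts <- to_counts(latent$transcript, c(50, 500))
  mir_counts <- to_counts(latent$mirna, c(20, 200))

  subtype <- if (R > 0) ifelse(fmat[, 1] > 0, "subtype1", "subtype2")
             else rep(c("subtype1", "subtype2"), length.out = n)
  metadata <- data.frame(sample = samples, subtype = subtype,
                         stringsAsFactors = FALSE)

  truth <- list(
    factor_loadings = list(cpg = bc$L, transcript = bt$L, mirna = bm$L),
    loaded_features = list(cpg = bc$loaded, transcript = bt$loaded,
                           mirna = bm$loaded),
    regulatory_pairs = pairs,
    factor_scores = fmat,
    latent = latent)

  list(blocks = list(cpg = omics_block(beta, "cpg"),
                     transcript = omics_block(tx_counts, "transcript"),
                     mirna = omics_block(mir_counts, "mirna")),
       metadata = metadata, truth = truth)
}

#' Simulate toy genomic annotation, regulatory priors and enhancer intervals
#'
#' Places each transcript on a toy two-chromosome genome with strand and TSS,
#' assigns each CpG to a gene and a genomic position (inside the gene's
#' promoter window for a `promoter_cpg_fraction` of CpGs, inside a dedicated
#' enhancer interval otherwise), flags TF-coding transcripts, and emits target
#' lists from which every planted regulatory pair is recoverable.
#'
#' Coordinates are 1-based closed (the package-internal convention); use
#' [write_bed()] for 0-based half-open BED export.
#'
#' @param config A [sim_config()].
#' @param truth Ground truth from [simulate_dataset()].
#' @return List: `transcripts` (transcript, gene, chrom, start, end, strand,
#'   tss, is_tf), `cpg_map` (cpg, gene, chrom, start, end), `mirnas` (mirna,
#'   gene), `tf_targets`, `mirna_targets`, `enhancers` (chrom, start, end,
#'   name), `priors` (a, b, type).
#' @export
simulate_annotation <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  ids <- synth_feature_ids(config)
  tx <- ids$transcript
  genes <- synth_gene_of_transcript(tx)
  p <- length(tx)
  chrom <- rep(c("chr1", "chr2"), length.out = p)
  slot <- stats::ave(seq_len(p), chrom, FUN = seq_along)
  # lay genes on a 20 kb grid so promoters/enhancers never collide
  start <- 20000L * slot + 5000L
  end <- start + 2000L
  strand <- sample(c("+", "-"), p, replace = TRUE)
  tss <- ifelse(strand == "+", start, end)
  pairs <- truth$regulatory_pairs
  tf_sources <- unique(pairs$a[pairs$type == "tf_transcript"])
  is_tf <- tx %in% tf_sources
  transcripts <- data.frame(transcript = tx, gene = genes, chrom = chrom,
                            start = start, end = end, strand = strand,
                            tss = tss, is_tf = is_tf, stringsAsFactors = FALSE)

  # CpG -> gene: planted cpg_transcript pairs map to the paired gene;
  # the rest get a random gene
  cpgs <- ids$cpg
  gene_of <- stats::setNames(sample(genes, length(cpgs), replace = TRUE), cpgs)
  ct <- pairs[pairs$type == "cpg_transcript", , drop = FALSE]
  if (nrow(ct)) {
    gene_of[ct$a] <- genes[match(ct$b, tx)]
  }
  g_idx <- match(gene_of, genes)
  in_promoter <- stats::runif(length(cpgs)) < config$promoter_cpg_fraction
  pos <- integer(length(cpgs))
  enh <- list()
  for (i in seq_along(cpgs)) {
    t_i <- g_idx[i]
    if (in_promoter[i]) {
      # anywhere within [TSS - 1000, TSS] (strand-reflected)
      off <- sample.int(1000L, 1L)
      pos[i] <- if (strand[t_i] == "+") tss[t_i] - off else tss[t_i] + off
    } else {
      # a private 200 bp enhancer 6-8 kb downstream of the gene body
      e_start <- end[t_i] + 6000L + sample.int(2000L, 1L)
      enh[[length(enh) + 1L]] <- data.frame(
        chrom = chrom[t_i], start = e_start, end = e_start + 199L,
        name = paste0("enh_", cpgs[i]), stringsAsFactors = FALSE)
      pos[i] <- e_start + 100L
    }
  }
  cpg_map <- data.frame(cpg = cpgs, gene = unname(gene_of),
                        chrom = chrom[g_idx], start = pos, end = pos + 1L,
                        stringsAsFactors = FALSE)
  enhancers <- if (length(enh)) do.call(rbind, enh) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               name = character(), stringsAsFactors = FALSE)

  mirnas <- data.frame(mirna = ids$mirna,
                       gene = synth_gene_of_mirna(ids$mirna),
                       stringsAsFactors = FALSE)
  tfp <- pairs[pairs$type == "tf_transcript", , drop = FALSE]
  tf_targets <- data.frame(tf_gene = genes[match(tfp$a, tx)],
                           target_gene = genes[match(tfp$b, tx)],
                           stringsAsFactors = FALSE)
  mtp <- pairs[pairs$type == "mirna_transcript", , drop = FALSE]
  mirna_targets <- data.frame(mirna = mtp$a,
                              target_gene = genes[match(mtp$b, tx)],
                              stringsAsFactors = FALSE)
  list(transcripts = transcripts, cpg_map = cpg_map, mirnas = mirnas,
       tf_targets = tf_targets, mirna_targets = mirna_targets,
       enhancers = enhancers,
       priors = pairs[, c("a", "b", "type"), drop = FALSE])
}

#' Simulate gene sets concentrated on factor-loaded genes
#'
#' One "signal" set per latent factor, built from the genes of that factor's
#' loaded transcripts, plus background sets of random genes. With no factors
#' only background sets are emitted.
#'
#' @param config A [sim_config()].
#' @param truth Ground truth from [simulate_dataset()].
#' @param n_background Number of random background sets.
#' @return List: `collection` (a list with `sets` and `descriptions`, GMT-
#'   writable via [write_gmt()]) and `enriched_sets` (ids of the signal sets).
#' @export
simulate_gene_sets <- function(config, truth, n_background = 20) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  tx <- synth_feature_ids(config)$transcript
  genes <- synth_gene_of_transcript(tx)
  sets <- list(); desc <- character()
  enriched <- character()
  loaded <- truth$loaded_features$transcript
  for (r in seq_along(loaded)) {
    g <- unique(synth_gene_of_transcript(loaded[[r]]))
    if (length(g) < 2) next
    id <- sprintf("FACTOR%d_SET", r)
    sets[[id]] <- g
    desc[id] <- sprintf("genes loaded on latent factor %d", r)
    enriched <- c(enriched, id)
  }
  for (b in seq_len(n_background)) {
    id <- sprintf("BACKGROUND_%02d", b)
    size <- min(length(genes), sample(10:20, 1))
    sets[[id]] <- sample(genes, size)
    desc[id] <- "random background set"
  }
  list(collection = list(sets = sets, descriptions = desc),
       enriched_sets = enriched)
}

#' Simulate survival outcomes under a proportional-hazards exponential model
#'
#' The linear predictor is the sum of `hazard_coefficients` times the
#' standardized observed feature values (missing methylation entries are
#' mean-filled for the predictor). Event times are exponential with rate
#' `lambda0 * exp(eta)`; censoring is independent exponential with rate chosen
#' so that the expected censored fraction at eta = 0 equals `censoring_rate`.
#'
#' @param config A [sim_config()]; `hazard_coefficients` names must be feature
#'   ids present in `blocks`.
#' @param blocks Named list of [omics_block()] from [simulate_dataset()].
#' @param lambda0 Baseline hazard rate.
#' @return data.frame: sample, time, event (1 = death observed).
#' @export
simulate_survival <- function(config, blocks, lambda0 = 0.1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  all_vals <- do.call(rbind, lapply(blocks, function(b) b$values))
  samples <- colnames(blocks[[1]]$values)
  n <- length(samples)
  beta <- config$hazard_coefficients
  if (length(beta) && !all(names(beta) %in% rownames(all_vals))) {
    stop("unknown feature in hazard_coefficients: ",
         paste(setdiff(names(beta), rownames(all_vals)), collapse = ", "))
  }
  eta <- rep(0, n)
  for (f in names(beta)) {
    x <- all_vals[f, ]
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    eta <- eta + beta[[f]] * as.numeric(scale(x))
  }
  t_event <- stats::rexp(n, rate = lambda0 * exp(eta))
  q <- config$censoring_rate
  if (q >= 1) {
    time <- stats::rexp(n, rate = lambda0)
    event <- rep(0L, n)
  } else if (q <= 0) {
    time <- t_event
    event <- rep(1L, n)
  } else {
    t_cens <- stats::rexp(n, rate = lambda0 * q / (1 - q))
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
  }
  data.frame(sample = samples, time = time, event = event,
             stringsAsFactors = FALSE)
}

#' Write gene sets in GMT format
#' @param collection List with `sets` (named list of gene-id vectors) and
#'   optional `descriptions`.
#' @param path Output path.
#' @export
write_gmt <- function(collection, path) {
  ids <- names(collection$sets)
  desc <- collection$descriptions
  if (is.null(desc)) desc <- stats::setNames(rep("na", length(ids)), ids)
  lines <- vapply(ids, function(id) {
    paste(c(id, desc[[id]], collection$sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from GMT
#' @param path GMT file (set id, description, then gene ids, tab-separated).
#' @return List with `sets` and `descriptions`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1)
  list(sets = stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])), ids),
       descriptions = stats::setNames(vapply(parts, `[[`, character(1), 2), ids))
}
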