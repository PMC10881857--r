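#' Remove features with zero counts across all samples
#'
#' The low-count filter for count blocks: a feature survives if it has a
#' nonzero count in at least one sample. Feature order is preserved and the
#' filter is idempotent.
#'
#' @param block A count [omics_block()] (`transcript` or `mirna`).
#' @return Filtered `omics_block`.
#' @export
filter_low_counts <- function(block) {
  stopifnot(inherits(block, "omics_block"))
  if (block$omic_kind == "cpg") {
    stop("low-count filter applies to count blocks, not cpg")
  }
  keep <- rowSums(block$values) > 0
  omics_block(block$values[keep, , drop = FALSE], block$omic_kind,
              block$scale_state)
}

#' TMM scaling factors between samples
#'
#' Trimmed mean of M-values normalization: per-sample scaling factors from
#' doubly trimmed (30% on log-ratios M, 5% on log-abundance A),
#' precision-weighted means of log-ratios to a reference sample (the sample
#' whose 75th percentile is closest to the mean 75th percentile). Factors are
#' normalized to multiply to 1 (geometric mean 1). Computed with
#' \pkg{edgeR}'s published recipe.
#'
#' @param block A count `omics_block` with at least two samples.
#' @return Named numeric vector of per-sample factors.
#' @export
tmm_factors <- function(block) {
  stopifnot(inherits(block, "omics_block"))
  m <- block$values
  if (ncol(m) < 2) stop("TMM requires at least 2 samples")
  if (any(m < 0)) stop("counts must be non-negative")
  if (any(colSums(m) == 0)) stop("all-zero sample")
  f <- edgeR::calcNormFactors(m, method = "TMM")
  stats::setNames(as.numeric(f), colnames(m))
}

#' Apply TMM normalization to a count block
#'
#' Divides each sample by its effective library size (library size times TMM
#' factor), scaled to the mean library size so values stay count-like.
#'
#' @param block A count `omics_block`.
#' @return Normalized `omics_block` (`scale_state = "normalized"`).
#' @export
tmm_normalize <- function(block) {
  f <- tmm_factors(block)
  lib <- colSums(block$values) * f
  v <- sweep(block$values, 2, lib / mean(lib), "/")
  omics_block(v, block$omic_kind, "normalized")
}

#' Median normalization between samples
#'
#' Each sample is rescaled so the medians of its nonzero features are equal
#' across samples (to the geometric mean of the per-sample medians). The
#' standard miRNA-seq between-sample normalization used here.
#'
#' @param block A `mirna` count `omics_block`.
#' @return Normalized `omics_block`.
#' @export
median_normalize <- function(block) {
  stopifnot(inherits(block, "omics_block"))
  m <- block$values
  if (any(colSums(m != 0) == 0)) stop("sample with all-zero counts")
  med <- apply(m, 2, function(x) stats::median(x[x != 0]))
  target <- exp(mean(log(med)))
  v <- sweep(m, 2, target / med, "*")
  omics_block(v, block$omic_kind, "normalized")
}

#' Remove CpG probes with more than 25% missing values
#'
#' Strict inequality: a probe with exactly 25% missing entries is retained.
#'
#' @param block A `cpg` `omics_block`.
#' @param max_missing Maximum tolerated missing fraction (default 0.25).
#' @return Filtered `omics_block`.
#' @export
filter_missing_probes <- function(block, max_missing = 0.25) {
  stopifnot(inherits(block, "omics_block"), block$omic_kind == "cpg")
  frac <- rowMeans(is.na(block$values))
  keep <- frac <= max_missing
  omics_block(block$values[keep, , drop = FALSE], block$omic_kind,
              block$scale_state)
}

#' k-nearest-neighbour imputation of missing entries
#'
#' Neighbours are features: a missing entry of feature f at sample s is
#' replaced by the mean value at s of the k features nearest to f — candidates
#' are features observed at s, ranked by Euclidean distance over the samples
#' co-observed with f (scaled to the root mean square per co-observed sample,
#' so candidates with different overlaps are comparable). Observed entries
#' are never altered.
#'
#' @param block An `omics_block` (any kind) with missing fraction at most
#'   `max_missing` per feature.
#' @param k Number of neighbours (default 10).
#' @return Complete `omics_block`.
#' @export
knn_impute <- function(block, k = 10) {
  stopifnot(inherits(block, "omics_block"))
  m <- block$values
  if (!anyNA(m)) return(block)
  for (i in which(apply(m, 1, anyNA))) {
    obs <- !is.na(m[i, ])
    for (s in which(!obs)) {
      cand <- which(!is.na(m[, s]) & seq_len(nrow(m)) != i)
      if (k > length(cand)) {
        stop("k must be smaller than the number of candidate neighbour ",
             "features (", length(cand), ")")
      }
      d <- vapply(cand, function(j) {
        co <- obs & !is.na(m[j, ])
        if (!any(co)) return(Inf)
        sqrt(mean((m[i, co] - m[j, co])^2))
      }, numeric(1))
      nn <- cand[order(d)][seq_len(k)]
      m[i, s] <- mean(m[nn, s])
    }
  }
  omics_block(m, block$omic_kind, block$scale_state)
}

#' Convert beta values to M-values
#'
#' M = log2((beta + offset) / (1 - beta + offset)). With the default offset 0,
#' beta is clipped to [1e-6, 1 - 1e-6] to avoid infinities without changing
#' mid-range values.
#'
#' @param block A `cpg` `omics_block` with values in [0, 1].
#' @param offset Stabilizing offset (default 0, with clipping).
#' @return `omics_block` with `scale_state = "mvalue"`.
#' @export
beta_to_mvalue <- function(block, offset = 0) {
  stopifnot(inherits(block, "omics_block"))
  b <- block$values
  rng <- range(b, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) stop("beta values must lie in [0, 1]")
  if (offset == 0) b <- pmin(pmax(b, 1e-6), 1 - 1e-6)
  m <- log2((b + offset) / (1 - b + offset))
  omics_block(m, block$omic_kind, "mvalue")
}

#' Full preprocessing chain for one block
#'
#' Counts: zero-count filter, TMM (transcripts) or median (miRNA)
#' normalization, log2(x + 1). Methylation: missing-probe filter, kNN
#' imputation, M-value transform.
#'
#' @param block An `omics_block`.
#' @param knn_k Neighbours for imputation.
#' @return A numeric matrix (features x samples) ready for scaling.
#' @export
preprocess_block <- function(block, knn_k = 10) {
  stopifnot(inherits(block, "omics_block"))
  if (block$omic_kind == "cpg") {
    b <- filter_missing_probes(block)
    if (anyNA(b$values)) b <- knn_impute(b, k = knn_k)
    beta_to_mvalue(b)$values
  } else {
    b <- filter_low_counts(block)
    b <- if (block$omic_kind == "transcript") tmm_normalize(b)
         else median_normalize(b)
    log2(b$values + 1)
  }
}
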