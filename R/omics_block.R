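#' Construct an omics block
#'
#' An `omics_block` holds one omic's features-by-samples matrix together with
#' the omic kind and its position in the preprocessing chain. Methylation
#' (`"cpg"`) blocks may contain missing entries before imputation; count
#' blocks (`"transcript"`, `"mirna"`) may not.
#'
#' @param values Numeric matrix, features in rows, samples in columns. Must
#'   carry row and column names (feature and sample ids).
#' @param omic_kind One of `"cpg"`, `"transcript"`, `"mirna"`.
#' @param scale_state One of `"raw"`, `"normalized"`, `"mvalue"`.
#' @return An object of class `omics_block`.
#' @export
omics_block <- function(values, omic_kind = c("cpg", "transcript", "mirna"),
                        scale_state = c("raw", "normalized", "mvalue")) {
  omic_kind <- match.arg(omic_kind)
  scale_state <- match.arg(scale_state)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix (features x samples)")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("'values' must have feature rownames and sample colnames")
  }
  if (anyDuplicated(colnames(values))) stop("sample ids must be unique")
  if (anyDuplicated(rownames(values))) stop("feature ids must be unique")
  if (anyNA(values) && omic_kind != "cpg") {
    stop("missing entries are only allowed in cpg blocks")
  }
  structure(list(values = values, omic_kind = omic_kind,
                 scale_state = scale_state),
            class = "omics_block")
}

#' @export
print.omics_block <- function(x, ...) {
  cat(sprintf("omics_block [%s, %s]: %d features x %d samples",
              x$omic_kind, x$scale_state, nrow(x$values), ncol(x$values)))
  n_na <- sum(is.na(x$values))
  if (n_na > 0) cat(sprintf(" (%d missing entries)", n_na))
  cat("\n")
  invisible(x)
}

#' @export
dim.omics_block <- function(x) dim(x$values)

feature_ids <- function(block) rownames(block$values)
sample_ids <- function(block) colnames(block$values)

#' Write an omics matrix as TSV
#'
#' Features in rows, samples in columns, header row of sample ids, missing
#' entries encoded as `NA`.
#'
#' @param block An `omics_block` or a plain matrix with dimnames.
#' @param path Output file path.
#' @export
write_block_tsv <- function(block, path) {
  m <- if (inherits(block, "omics_block")) block$values else block
  df <- data.frame(feature = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read an omics matrix from TSV
#'
#' @param path TSV written by [write_block_tsv()] (first column feature ids,
#'   remaining columns samples).
#' @param omic_kind,scale_state Passed to [omics_block()]; if `omic_kind` is
#'   `NULL` a bare matrix is returned.
#' @export
read_block_tsv <- function(path, omic_kind = NULL, scale_state = "raw") {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (is.null(omic_kind)) return(m)
  omics_block(m, omic_kind, scale_state)
}
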