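# Internal coordinate convention: 1-based, closed intervals (GRanges).
# BED files are 0-based half-open and are converted on read/write.

intervals_to_granges <- function(df, strand = NULL) {
  s <- if (!is.null(strand)) strand else
    if ("strand" %in% names(df)) df$strand else "*"
  s[!s %in% c("+", "-")] <- "*"
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start, end = df$end),
                         strand = s)
}

#' Promoter windows for a transcript table
#'
#' The promoter of a transcript is the 1,000 bp window upstream of and up to
#' its transcription start site: `[TSS - 1000, TSS]` on the plus strand,
#' `[TSS, TSS + 1000]` on the minus strand, clipped at position 1. Transcripts
#' with unknown strand are skipped with a warning.
#'
#' @param transcripts data.frame with columns transcript, gene, chrom, tss,
#'   strand.
#' @param upstream Window size in bp (default 1000).
#' @return data.frame: transcript, gene, chrom, start, end, strand.
#' @export
promoter_regions <- function(transcripts, upstream = 1000) {
  known <- transcripts$strand %in% c("+", "-")
  if (any(!known)) {
    warning(sum(!known), " transcript(s) with unknown strand skipped")
    transcripts <- transcripts[known, , drop = FALSE]
  }
  plus <- transcripts$strand == "+"
  start <- ifelse(plus, pmax(1, transcripts$tss - upstream), transcripts$tss)
  end <- ifelse(plus, transcripts$tss, transcripts$tss + upstream)
  data.frame(transcript = transcripts$transcript, gene = transcripts$gene,
             chrom = transcripts$chrom, start = start, end = end,
             strand = transcripts$strand, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Classify CpG sites as promoter, enhancer or none
#'
#' A CpG overlapping any promoter window is a `promoter`; otherwise a CpG
#' overlapping any enhancer interval is an `enhancer`; otherwise `none`.
#' Promoter takes precedence when both overlap. Overlap is strand-agnostic
#' and requires matching chromosomes. Computed with GenomicRanges.
#'
#' @param cpgs data.frame: cpg, chrom, start, end.
#' @param promoters data.frame from [promoter_regions()].
#' @param enhancers data.frame: chrom, start, end (1-based closed; use
#'   [read_bed()] for BED input), may be empty or NULL.
#' @return data.frame: cpg, element_type, transcripts (comma-separated ids of
#'   overlapping promoters, or NA).
#' @export
classify_cpg <- function(cpgs, promoters, enhancers = NULL) {
  gr_c <- intervals_to_granges(cpgs)
  ov_p <- if (nrow(promoters)) {
    GenomicRanges::findOverlaps(gr_c, intervals_to_granges(promoters),
                                ignore.strand = TRUE)
  } else NULL
  ov_e <- if (!is.null(enhancers) && nrow(enhancers)) {
    GenomicRanges::findOverlaps(gr_c, intervals_to_granges(enhancers),
                                ignore.strand = TRUE)
  } else NULL
  type <- rep("none", nrow(cpgs))
  tx <- rep(NA_character_, nrow(cpgs))
  if (!is.null(ov_e)) type[unique(S4Vectors::queryHits(ov_e))] <- "enhancer"
  if (!is.null(ov_p)) {
    qh <- S4Vectors::queryHits(ov_p); sh <- S4Vectors::subjectHits(ov_p)
    type[unique(qh)] <- "promoter"
    agg <- tapply(promoters$transcript[sh], qh,
                  function(v) paste(unique(v), collapse = ","))
    tx[as.integer(names(agg))] <- unname(agg)
  }
  data.frame(cpg = cpgs$cpg, element_type = type, transcripts = tx,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Midpoint distance between two genomic intervals
#'
#' Distance between the interval midpoints, with midpoint
#' `floor((start + end) / 2)`. Intervals on different chromosomes are flagged
#' with `NA`.
#'
#' @param a,b Lists or one-row data.frames with `chrom`, `start`, `end`.
#' @return Absolute distance in bp, or NA for a chromosome mismatch.
#' @export
midpoint_distance <- function(a, b) {
  if (a$chrom != b$chrom) return(NA_integer_)
  mid <- function(x) floor((x$start + x$end) / 2)
  abs(mid(a) - mid(b))
}

#' Midpoint distances from a central gene to a set of CpG sites
#'
#' @param gene One-row data.frame or list with chrom, start, end.
#' @param cpgs data.frame: cpg, chrom, start, end.
#' @return data.frame: cpg, distance (NA across chromosomes).
#' @export
cpg_gene_distances <- function(gene, cpgs) {
  d <- vapply(seq_len(nrow(cpgs)), function(i) {
    as.numeric(midpoint_distance(gene, cpgs[i, , drop = FALSE]))
  }, numeric(1))
  data.frame(cpg = cpgs$cpg, distance = d, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Read a BED file into the internal 1-based closed convention
#'
#' @param path BED path (0-based half-open on disk; ENCODE enhancer schema:
#'   chrom, start, end, optional name).
#' @return data.frame: chrom, start, end, name.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- gr$name
  if (is.null(nm)) nm <- rep(NA_character_, length(gr))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             name = nm, row.names = NULL, stringsAsFactors = FALSE)
}

#' Write 1-based closed intervals as a BED file
#'
#' @param df data.frame: chrom, start, end, optional name.
#' @param path Output path (written 0-based half-open).
#' @export
write_bed <- function(df, path) {
  gr <- intervals_to_granges(df)
  if ("name" %in% names(df)) gr$name <- df$name
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
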