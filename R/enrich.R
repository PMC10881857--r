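#' Map multi-omic features to gene ids
#'
#' Transcripts map through the transcript annotation, CpG probes through the
#' probe-to-gene map (possibly one-to-many), miRNAs through the
#' precursor-to-gene table. Unmapped features are reported, never silently
#' dropped.
#'
#' @param features Character vector of feature ids (any mix of omics).
#' @param annotation Annotation list as from [simulate_annotation()]
#'   (`transcripts`, `cpg_map`, `mirnas` tables).
#' @return List: `genes` (unique mapped gene ids) and `unmapped`.
#' @export
map_features_to_genes <- function(features, annotation) {
  genes <- character(); unmapped <- character()
  for (f in features) {
    hit <- c(annotation$transcripts$gene[annotation$transcripts$transcript == f],
             annotation$cpg_map$gene[annotation$cpg_map$cpg == f],
             annotation$mirnas$gene[annotation$mirnas$mirna == f])
    if (length(hit)) genes <- c(genes, hit) else unmapped <- c(unmapped, f)
  }
  list(genes = unique(genes), unmapped = unmapped)
}

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability of observing at least the seen overlap between a
#' query gene list and a gene set, drawn from a finite universe.
#'
#' @param query Character vector of query genes (subset of `universe`).
#' @param set Character vector of set genes (subset of `universe`).
#' @param universe Character vector, the gene universe.
#' @return Raw p-value, `P(X >= overlap)`.
#' @export
ora_hypergeometric <- function(query, set, universe) {
  if (length(query) == 0) stop("empty query")
  query <- unique(query); set <- unique(set); universe <- unique(universe)
  stopifnot(all(query %in% universe), all(set %in% universe))
  k <- length(intersect(query, set))
  stats::phyper(k - 1, length(set), length(universe) - length(set),
                length(query), lower.tail = FALSE)
}

#' Over-representation analysis across a gene-set collection
#'
#' Runs [ora_hypergeometric()] per set and applies Bonferroni adjustment
#' (raw p times the number of sets, capped at 1).
#'
#' @param query Query gene ids.
#' @param collection List with `sets` (named list of gene vectors).
#' @param universe Gene universe.
#' @return data.frame: set, overlap, set_size, query_size, universe_size,
#'   p, p_adj.
#' @export
ora_test <- function(query, collection, universe) {
  query <- unique(query)
  sets <- collection$sets
  p <- vapply(sets, function(s) ora_hypergeometric(query, intersect(s, universe),
                                                   universe), numeric(1))
  data.frame(set = names(sets),
             overlap = vapply(sets, function(s) length(intersect(query, s)), 0L),
             set_size = vapply(sets, function(s) length(intersect(s, universe)), 0L),
             query_size = length(query), universe_size = length(unique(universe)),
             p = p, p_adj = pmin(1, p * length(sets)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fisher's exact test on a 2x2 category-by-subtype table
#'
#' Two-sided exact p by hypergeometric enumeration (via [stats::fisher.test]).
#'
#' @param tab 2x2 non-negative integer matrix.
#' @return Two-sided p-value.
#' @export
fisher_category_association <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2), all(tab >= 0), all(tab == round(tab)))
  if (sum(tab) == 0) stop("all-zero table")
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' GSEA enrichment score (weighted Kolmogorov-Smirnov running sum)
#'
#' Walks the ranked gene list: at a set member ("hit") the running sum rises
#' by the member's absolute weight (weight exponent 1) normalized by the total
#' hit weight; at a non-member it falls by 1/(N - Nh). The enrichment score
#' is the signed maximum deviation from zero. In the degenerate case where
#' the set covers the entire list the score is defined as 0.
#'
#' @param genes Character vector, the ranked gene list (no duplicates),
#'   strongest association first.
#' @param weights Numeric ranking scores aligned with `genes` (default rank
#'   weights 1).
#' @param set Character vector of set members.
#' @return Enrichment score in [-1, 1].
#' @export
gsea_enrichment_score <- function(genes, set, weights = NULL) {
  if (anyDuplicated(genes)) stop("ranked list contains duplicate genes")
  if (length(set) == 0) stop("empty set")
  hits <- genes %in% set
  if (!any(hits)) {
    warning("set is disjoint from the ranked list; ES undefined")
    return(NA_real_)
  }
  if (all(hits)) return(0)
  if (is.null(weights)) weights <- rep(1, length(genes))
  w <- abs(weights)
  inc <- ifelse(hits, w / sum(w[hits]), -1 / sum(!hits))
  rs <- cumsum(inc)
  rs[which.max(abs(rs))]
}

#' Permutation p-value for a GSEA enrichment score
#'
#' Gene-label permutation: the set is re-drawn uniformly among list positions;
#' p = (1 + #\{|ES*| >= |ES|\}) / (n_permutations + 1).
#'
#' @param genes Ranked gene list.
#' @param set Set members.
#' @param weights Optional ranking scores.
#' @param n_permutations At least 100 (default 999).
#' @param seed Seed for the permutation draws.
#' @return List: `es`, `p`, `n_permutations`.
#' @export
gsea_permutation_p <- function(genes, set, weights = NULL,
                               n_permutations = 999, seed = 1) {
  stopifnot(n_permutations >= 100)
  es <- gsea_enrichment_score(genes, set, weights)
  if (is.na(es)) return(list(es = NA_real_, p = NA_real_,
                             n_permutations = n_permutations))
  nh <- sum(genes %in% set)
  set.seed(seed)
  hits_ge <- 0L
  for (b in seq_len(n_permutations)) {
    perm_set <- sample(genes, nh)
    if (abs(gsea_enrichment_score(genes, perm_set, weights)) >= abs(es)) {
      hits_ge <- hits_ge + 1L
    }
  }
  list(es = es, p = (1 + hits_ge) / (n_permutations + 1),
       n_permutations = n_permutations)
}

#' Signed group-difference ranking statistic for GSEA
#'
#' Per gene: (mean in group 1 - mean in group 2) / pooled s.d. Used to rank
#' transcripts before the running-sum walk.
#'
#' @param values Matrix features x samples.
#' @param groups Two-level factor or character vector over samples.
#' @return Named numeric vector sorted decreasing (strongest up-association
#'   first).
#' @export
rank_by_group_difference <- function(values, groups) {
  groups <- as.factor(groups)
  stopifnot(nlevels(groups) == 2, ncol(values) == length(groups))
  g1 <- groups == levels(groups)[1]
  m1 <- rowMeans(values[, g1, drop = FALSE])
  m2 <- rowMeans(values[, !g1, drop = FALSE])
  v1 <- apply(values[, g1, drop = FALSE], 1, stats::var)
  v2 <- apply(values[, !g1, drop = FALSE], 1, stats::var)
  n1 <- sum(g1); n2 <- sum(!g1)
  sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  stat <- (m1 - m2) / pmax(sp, .Machine$double.eps)
  sort(stat, decreasing = TRUE)
}
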