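EDGE_TYPES <- c("cpg_transcript", "cpg_mirna", "tf_transcript",
                "mirna_transcript", "untyped")

#' Equal-frequency discretization
#'
#' Assigns each value to one of `n_bins` quantile bins of (near-)equal size;
#' bin sizes differ by at most 1 and ties are broken by stable input order.
#'
#' @param values Numeric vector.
#' @param n_bins Number of bins (>= 2).
#' @return Integer labels in 1..n_bins.
#' @export
discretize_equal_frequency <- function(values, n_bins) {
  stopifnot(n_bins >= 2)
  n <- length(values)
  if (length(unique(values)) == 1) {
    warning("constant vector: single bin")
    return(rep(1L, n))
  }
  r <- rank(values, ties.method = "first")
  as.integer(ceiling(r * n_bins / n))
}

#' Plug-in mutual information of two label vectors
#'
#' MI in nats from the joint empirical distribution:
#' \eqn{\sum_{xy} p_{xy} \log(p_{xy} / (p_x p_y))}. Zero exactly when the
#' empirical table factorizes.
#'
#' @param x,y Equal-length discrete label vectors.
#' @return Non-negative MI in nats.
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  tab <- table(x, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  e <- outer(px, py)
  nz <- p > 0
  max(0, sum(p[nz] * log(p[nz] / e[nz])))
}

#' Pairwise mutual-information matrix over a node set
#'
#' Each feature is discretized once into `floor(sqrt(n_samples))`
#' equal-frequency bins; plug-in MI is computed for every pair.
#'
#' @param values Numeric matrix, features x samples.
#' @param nodes Feature ids (rows of `values`) to include; default all.
#' @param n_bins Bin count override (default `floor(sqrt(ncol(values)))`).
#' @return Symmetric MI matrix with zero diagonal.
#' @export
pairwise_mi_matrix <- function(values, nodes = rownames(values),
                               n_bins = NULL) {
  stopifnot(all(nodes %in% rownames(values)))
  if (is.null(n_bins)) n_bins <- max(2L, floor(sqrt(ncol(values))))
  lab <- lapply(nodes, function(f) {
    suppressWarnings(discretize_equal_frequency(values[f, ], n_bins))
  })
  p <- length(nodes)
  mi <- matrix(0, p, p, dimnames = list(nodes, nodes))
  if (p >= 2) {
    for (i in seq_len(p - 1)) for (j in (i + 1):p) {
      mi[i, j] <- mi[j, i] <- mutual_information(lab[[i]], lab[[j]])
    }
  }
  mi
}

#' Data-processing-inequality pruning of an MI matrix
#'
#' ARACNE's indirect-edge rule: in every fully connected triangle the weakest
#' edge is marked for removal if its MI is below `(1 - epsilon)` times the
#' smaller of the other two (strict inequality, so all-equal triangles are
#' kept at `epsilon = 0`). All triangles are scanned against the original
#' matrix, so the result is order-independent.
#'
#' @param mi Symmetric MI matrix (zero diagonal); entries > 0 are edges.
#' @param epsilon Tolerance in [0, 1) (default 0).
#' @return Logical matrix: TRUE where the edge is kept.
#' @export
dpi_prune <- function(mi, epsilon = 0) {
  stopifnot(epsilon >= 0)
  p <- nrow(mi)
  keep <- mi > 0
  drop <- matrix(FALSE, p, p)
  if (p >= 3) {
    for (i in seq_len(p - 2)) for (j in (i + 1):(p - 1)) {
      if (!keep[i, j]) next
      for (k in (j + 1):p) {
        if (!keep[i, k] || !keep[j, k]) next
        w <- c(mi[i, j], mi[i, k], mi[j, k])
        mn <- which.min(w)
        others <- w[-mn]
        if (w[mn] < (1 - epsilon) * min(others)) {
          if (mn == 1) drop[i, j] <- drop[j, i] <- TRUE
          else if (mn == 2) drop[i, k] <- drop[k, i] <- TRUE
          else drop[j, k] <- drop[k, j] <- TRUE
        }
      }
    }
  }
  out <- keep & !drop
  dimnames(out) <- dimnames(mi)
  out
}

#' Calibrate MI thresholds from regulatory priors
#'
#' Computes MI for every known (prior) regulatory pair, per edge type, and
#' records the per-type median (median, not mean, so outliers cannot dominate
#' the threshold). All pairwise two-sample Kolmogorov-Smirnov comparisons of
#' the per-type MI distributions are run at a Bonferroni-corrected alpha; if
#' no pair differs significantly the scheme is merged and the single global
#' threshold is the lowest per-type median (the permissive choice that admits
#' the most interactions).
#'
#' @param values Numeric matrix, features x samples.
#' @param priors data.frame with columns `a`, `b`, `type` (edge-type labels
#'   among the four regulatory types).
#' @param alpha Family significance level for the KS comparison (default
#'   0.05, Bonferroni-split across the type pairs).
#' @param n_bins Bin count override for the MI estimate.
#' @return Object of class `threshold_scheme`: `medians`, `ks_pvalues`,
#'   `merged`, `global_threshold`, `mi_values` (per-type MI samples).
#' @export
calibrate_thresholds <- function(values, priors, alpha = 0.05, n_bins = NULL) {
  if (is.null(priors) || nrow(priors) == 0) stop("empty priors")
  stopifnot(all(c("a", "b", "type") %in% names(priors)))
  ok <- priors$a %in% rownames(values) & priors$b %in% rownames(values)
  priors <- priors[ok, , drop = FALSE]
  if (nrow(priors) == 0) stop("no prior pair matches the data features")
  if (is.null(n_bins)) n_bins <- max(2L, floor(sqrt(ncol(values))))
  mi_of <- function(a, b) {
    mutual_information(
      suppressWarnings(discretize_equal_frequency(values[a, ], n_bins)),
      suppressWarnings(discretize_equal_frequency(values[b, ], n_bins)))
  }
  mi_values <- lapply(split(priors, priors$type), function(d) {
    mapply(mi_of, d$a, d$b)
  })
  small <- lengths(mi_values) < 3
  if (any(small)) {
    warning("edge types excluded (< 3 prior pairs): ",
            paste(names(mi_values)[small], collapse = ", "))
    mi_values <- mi_values[!small]
  }
  if (length(mi_values) == 0) stop("no edge type has >= 3 prior pairs")
  medians <- vapply(mi_values, stats::median, numeric(1))
  types <- names(mi_values)
  ks <- numeric(0)
  if (length(types) >= 2) {
    cmb <- utils::combn(types, 2)
    ks <- apply(cmb, 2, function(pr) {
      suppressWarnings(stats::ks.test(mi_values[[pr[1]]],
                                      mi_values[[pr[2]]])$p.value)
    })
    names(ks) <- apply(cmb, 2, paste, collapse = "|")
  }
  alpha_adj <- if (length(ks)) alpha / length(ks) else alpha
  merged <- length(ks) == 0 || all(ks >= alpha_adj)
  structure(list(medians = medians, ks_pvalues = ks, merged = merged,
                 global_threshold = if (merged) min(medians) else NA_real_,
                 alpha = alpha, mi_values = mi_values),
            class = "threshold_scheme")
}

#' @export
print.threshold_scheme <- function(x, ...) {
  cat("MI threshold scheme (per-type medians of prior-pair MI):\n")
  print(round(x$medians, 4))
  if (x$merged) {
    cat(sprintf("distributions indistinguishable (KS): merged, global threshold %.4f\n",
                x$global_threshold))
  } else {
    cat("distributions differ (KS): per-type thresholds kept\n")
  }
  invisible(x)
}

#' Threshold applicable to one edge type under a calibration scheme
#' @param scheme A [calibrate_thresholds()] result.
#' @param type Edge-type label (untyped edges use the lowest per-type median).
#' @return Numeric threshold.
#' @export
edge_threshold <- function(scheme, type) {
  if (scheme$merged) return(scheme$global_threshold)
  if (type %in% names(scheme$medians)) scheme$medians[[type]]
  else min(scheme$medians)
}

classify_edge_type <- function(a, b, kinds, annotation, priors) {
  hit <- priors$type[(priors$a == a & priors$b == b) |
                       (priors$a == b & priors$b == a)]
  if (length(hit)) return(hit[1])
  ka <- kinds[[a]]; kb <- kinds[[b]]
  pair <- sort(c(ka, kb))
  tx <- annotation$transcripts
  if (identical(pair, c("cpg", "transcript"))) {
    cpg <- if (ka == "cpg") a else b
    t <- if (ka == "cpg") b else a
    g <- annotation$cpg_map$gene[annotation$cpg_map$cpg == cpg]
    if (length(g) && any(tx$gene[tx$transcript == t] %in% g)) {
      return("cpg_transcript")
    }
  } else if (identical(pair, c("transcript", "transcript"))) {
    if (any(tx$is_tf[tx$transcript %in% c(a, b)])) return("tf_transcript")
  } else if (identical(pair, c("mirna", "transcript"))) {
    mir <- if (ka == "mirna") a else b
    t <- if (ka == "mirna") b else a
    tg <- annotation$mirna_targets$target_gene[annotation$mirna_targets$mirna == mir]
    if (any(tx$gene[tx$transcript == t] %in% tg)) return("mirna_transcript")
  }
  "untyped"
}

feature_kinds <- function(features, annotation) {
  vapply(features, function(f) {
    if (f %in% annotation$transcripts$transcript) "transcript"
    else if (f %in% annotation$cpg_map$cpg) "cpg"
    else if (f %in% annotation$mirnas$mirna) "mirna"
    else "unknown"
  }, character(1))
}

#' Construct an MI network object
#'
#' @param nodes data.frame with columns `id`, `kind`, `is_tf`.
#' @param edges data.frame with columns `a`, `b`, `mi`, `type`.
#' @param thresholds Named numeric vector of applied thresholds.
#' @param merged Whether a single merged threshold was applied.
#' @return Object of class `mi_network`.
#' @export
mi_network <- function(nodes, edges, thresholds = numeric(), merged = FALSE) {
  stopifnot(all(c("id", "kind") %in% names(nodes)))
  if (nrow(edges)) {
    stopifnot(all(c("a", "b", "mi", "type") %in% names(edges)))
    if (any(edges$a == edges$b)) stop("self-edges are not allowed")
    if (any(edges$mi < 0)) stop("edge weights must be non-negative")
    stopifnot(all(edges$type %in% EDGE_TYPES))
  }
  structure(list(nodes = nodes, edges = edges, thresholds = thresholds,
                 merged = merged), class = "mi_network")
}

#' @export
print.mi_network <- function(x, ...) {
  cat(sprintf("mi_network: %d nodes, %d edges", nrow(x$nodes), nrow(x$edges)))
  if (nrow(x$edges)) {
    cat(" (", paste(sprintf("%s: %d", names(table(x$edges$type)),
                            as.integer(table(x$edges$type))), collapse = ", "),
        ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Build the regulatory subnetwork for one enriched function
#'
#' Nodes are the stability-retained features annotated to the function's
#' genes, plus the retained features sharing a nonzero loading on any SGCCA
#' component with those seeds ("covarying" features). Edges are the MI pairs
#' that survive data-processing-inequality pruning and the calibrated
#' per-type thresholds; edge types come from the priors and annotation
#' (probe-gene overlap, TF flags, miRNA target lists), otherwise `untyped`.
#'
#' @param function_genes Gene ids of the enriched function.
#' @param stable_features Stability-retained feature ids.
#' @param model Fitted [sgcca()] object.
#' @param values Numeric matrix, features x samples (all blocks stacked).
#' @param annotation Annotation list (see [simulate_annotation()]).
#' @param priors Regulatory prior pairs (a, b, type).
#' @param scheme A [calibrate_thresholds()] result.
#' @param epsilon DPI tolerance.
#' @return An [mi_network()].
#' @export
build_function_subnetwork <- function(function_genes, stable_features, model,
                                      values, annotation, priors, scheme,
                                      epsilon = 0) {
  feat_genes <- lapply(stable_features, function(f) {
    map_features_to_genes(f, annotation)$genes
  })
  seeds <- stable_features[vapply(feat_genes, function(g) {
    any(g %in% function_genes)
  }, logical(1))]
  nodes <- seeds
  if (length(seeds) && !is.null(model)) {
    all_load <- do.call(rbind, model$loadings)
    seed_rows <- all_load[rownames(all_load) %in% seeds, , drop = FALSE]
    comps <- which(colSums(seed_rows != 0) > 0)
    if (length(comps)) {
      covar <- rownames(all_load)[rowSums(
        all_load[, comps, drop = FALSE] != 0) > 0]
      nodes <- union(seeds, intersect(covar, stable_features))
    }
  }
  nodes <- intersect(nodes, rownames(values))
  kinds <- feature_kinds(nodes, annotation)
  tf <- annotation$transcripts$transcript[annotation$transcripts$is_tf]
  node_df <- data.frame(id = nodes, kind = unname(kinds),
                        is_tf = nodes %in% tf, stringsAsFactors = FALSE)
  empty_edges <- data.frame(a = character(), b = character(), mi = numeric(),
                            type = character(), stringsAsFactors = FALSE)
  if (length(nodes) == 0) {
    warning("empty node set for this function")
    return(mi_network(node_df, empty_edges, merged = scheme$merged))
  }
  if (length(nodes) == 1) {
    return(mi_network(node_df, empty_edges, merged = scheme$merged))
  }
  mi <- pairwise_mi_matrix(values, nodes)
  keep <- dpi_prune(mi, epsilon)
  edges <- list()
  for (i in seq_len(length(nodes) - 1)) for (j in (i + 1):length(nodes)) {
    if (!keep[i, j]) next
    ty <- classify_edge_type(nodes[i], nodes[j], kinds, annotation, priors)
    if (mi[i, j] >= edge_threshold(scheme, ty)) {
      edges[[length(edges) + 1L]] <- data.frame(
        a = nodes[i], b = nodes[j], mi = mi[i, j], type = ty,
        stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else empty_edges
  thr <- vapply(EDGE_TYPES, function(t) edge_threshold(scheme, t), numeric(1))
  mi_network(node_df, edges, thresholds = thr, merged = scheme$merged)
}
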