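mi_network_to_igraph <- function(network) {
  g <- igraph::graph_from_data_frame(
    if (nrow(network$edges)) network$edges[, c("a", "b")] else
      data.frame(a = character(), b = character()),
    directed = FALSE, vertices = data.frame(name = network$nodes$id))
  igraph::V(g)$kind <- network$nodes$kind
  igraph::V(g)$is_tf <- as.logical(network$nodes$is_tf)
  if (nrow(network$edges)) {
    igraph::E(g)$mi <- network$edges$mi
    igraph::E(g)$type <- network$edges$type
  }
  g
}

#' Export an MI network to SIF or GraphML
#'
#' SIF lines are `node <TAB> interaction-type <TAB> node` (isolated nodes as
#' bare names); GraphML carries MI weights, edge types, node kinds and TF
#' flags as attributes and round-trips exactly through [read_network()].
#'
#' @param network An [mi_network()].
#' @param path Output path.
#' @param format `"sif"` or `"graphml"`.
#' @export
export_network <- function(network, path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(network, "mi_network"))
  if (format == "sif") {
    e <- network$edges
    lines <- if (nrow(e)) sprintf("%s\t%s\t%s", e$a, e$type, e$b) else character()
    isolated <- setdiff(network$nodes$id, c(e$a, e$b))
    writeLines(c(lines, isolated), path)
  } else {
    g <- mi_network_to_igraph(network)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a network written by [export_network()]
#'
#' @param path Input path.
#' @param format `"sif"` or `"graphml"`.
#' @return An [mi_network()] (SIF carries no MI weights; they read back as 0,
#'   and node kinds as "unknown").
#' @export
read_network <- function(path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  if (format == "sif") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    is_edge <- lengths(parts) == 3
    edges <- if (any(is_edge)) {
      do.call(rbind, lapply(parts[is_edge], function(p) {
        data.frame(a = p[1], b = p[3], mi = 0, type = p[2],
                   stringsAsFactors = FALSE)
      }))
    } else data.frame(a = character(), b = character(), mi = numeric(),
                      type = character(), stringsAsFactors = FALSE)
    ids <- unique(c(unlist(lapply(parts[is_edge], `[`, c(1, 3))),
                    unlist(parts[!is_edge])))
    nodes <- data.frame(id = ids, kind = "unknown", is_tf = FALSE,
                        stringsAsFactors = FALSE)
    mi_network(nodes, edges)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- data.frame(id = igraph::V(g)$name,
                        kind = igraph::V(g)$kind,
                        is_tf = as.logical(igraph::V(g)$is_tf),
                        stringsAsFactors = FALSE)
    el <- igraph::as_edgelist(g)
    edges <- if (nrow(el)) {
      data.frame(a = el[, 1], b = el[, 2], mi = igraph::E(g)$mi,
                 type = igraph::E(g)$type, stringsAsFactors = FALSE)
    } else data.frame(a = character(), b = character(), mi = numeric(),
                      type = character(), stringsAsFactors = FALSE)
    mi_network(nodes, edges)
  }
}

#' Default pipeline configuration
#'
#' All tunable parameters of the pipeline with their defaults; any element
#' can be overridden through `...` (or by passing a YAML file to
#' [run_pipeline()]). The sizes target a desk-scale synthetic cohort.
#'
#' @param ... Named overrides, possibly nested lists.
#' @return Named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    outdir = file.path(tempdir(), "omicnets_run"),
    synth = list(),                 # overrides for sim_config()
    knn_k = 10,
    n_components = 3,
    sparsity = NULL,                # NULL = cross-validate
    cv_grid = c(0.05, 0.1, 0.2, 0.4, 0.8),
    cv_folds = 5,
    stability = list(n_iterations = 100, subsample_fraction = 0.5,
                     threshold = 0.70),
    ks_alpha = 0.05,
    dpi_epsilon = 0,
    ora_alpha = 0.05,
    gsea_permutations = 199,
    cox_terms = NULL,               # NULL = main effects of top stable transcripts
    stages = c("simulate", "preprocess", "scale", "cv", "sgcca", "stability",
               "enrich", "network", "topology", "annotate", "cox"))
  ov <- list(...)
  for (nm in names(ov)) {
    if (is.list(ov[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(ov[[nm]])] <- ov[[nm]]
    } else cfg[[nm]] <- ov[[nm]]
  }
  cfg
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full multi-omic network pipeline on synthetic data
#'
#' Executes, in order: data simulation, per-block preprocessing, eigenvalue
#' scaling, sparsity cross-validation, SGCCA, stability selection, enrichment
#' (ORA + GSEA), MI threshold calibration and function subnetworks, topology
#' summaries, CpG classification, and Cox screening. Every artifact is
#' written under `config$outdir` and listed, with an md5 checksum, in
#' `manifest.json`. A rerun with the same config reproduces every stochastic
#' stage exactly.
#'
#' @param config A [pipeline_config()] list, or a path to a YAML file of
#'   overrides.
#' @return Invisible list with the fitted objects, per-stage outputs and the
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) {
    config <- do.call(pipeline_config, yaml::read_yaml(config))
  }
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  done <- character()
  res <- list(config = config)
  stage <- function(name, expr) {
    if (!name %in% config$stages) return(invisible(NULL))
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    done <<- c(done, name)
  }
  on_file <- function(path) { files <<- c(files, path); path }

  # -- simulate ---------------------------------------------------------
  dataset <- annotation <- gene_sets <- surv <- NULL
  stage("simulate", {
    scfg <- do.call(sim_config, c(config$synth, list(seed = config$seed)))
    dataset <- simulate_dataset(scfg)
    annotation <- simulate_annotation(scfg, dataset$truth)
    gene_sets <- simulate_gene_sets(scfg, dataset$truth)
    surv <- simulate_survival(scfg, dataset$blocks)
    for (b in names(dataset$blocks)) {
      on_file(write_block_tsv(dataset$blocks[[b]],
                              file.path(outdir, paste0(b, "_raw.tsv"))))
    }
    on_file(write_tsv(dataset$metadata, file.path(outdir, "metadata.tsv")))
    on_file(write_tsv(surv, file.path(outdir, "survival.tsv")))
    on_file(write_gmt(gene_sets$collection, file.path(outdir, "gene_sets.gmt")))
    on_file(write_tsv(annotation$priors, file.path(outdir, "priors.tsv")))
    if (nrow(annotation$enhancers)) {
      on_file(write_bed(annotation$enhancers,
                        file.path(outdir, "enhancers.bed")))
    }
  })
  res$dataset <- dataset; res$annotation <- annotation
  res$gene_sets <- gene_sets; res$survival_data <- surv

  # -- preprocess + scale ----------------------------------------------
  prep <- scaled <- NULL
  stage("preprocess", {
    prep <- lapply(dataset$blocks, preprocess_block, knn_k = config$knn_k)
    for (b in names(prep)) {
      on_file(write_block_tsv(prep[[b]],
                              file.path(outdir, paste0(b, "_preprocessed.tsv"))))
    }
  })
  stage("scale", {
    scaled <- lapply(prep, function(m) scale_block_by_leading_eigenvalue(t(m)))
  })
  res$preprocessed <- prep

  # -- sparsity CV + SGCCA + stability ---------------------------------
  sparsity <- config$sparsity
  stage("cv", {
    if (is.null(sparsity)) {
      cv <- cross_validate_sparsity(scaled, grid = config$cv_grid,
                                    k_folds = config$cv_folds,
                                    seed = config$seed + 10L)
      on_file(write_tsv(cv, file.path(outdir, "cv_sparsity.tsv")))
      sparsity <- select_sparsity(cv)
      res$cv <- cv
    }
  })
  if (is.null(sparsity)) sparsity <- rep(0.2, length(scaled))
  res$sparsity <- sparsity
  fit <- stab <- NULL
  stage("sgcca", {
    nc <- min(config$n_components, nrow(scaled[[1]]) - 1)
    fit <- sgcca(scaled, sparsity = sparsity, n_components = nc)
    lt <- do.call(rbind, lapply(names(fit$loadings), function(b) {
      l <- fit$loadings[[b]]
      idx <- which(l != 0, arr.ind = TRUE)
      if (!nrow(idx)) return(NULL)
      data.frame(block = b, component = colnames(l)[idx[, 2]],
                 feature = rownames(l)[idx[, 1]], loading = l[idx],
                 stringsAsFactors = FALSE)
    }))
    on_file(write_tsv(lt, file.path(outdir, "sgcca_loadings.tsv")))
  })
  res$fit <- fit
  stage("stability", {
    stab <- stability_select(scaled, sparsity = sparsity,
                              n_iterations = config$stability$n_iterations,
                              subsample_fraction = config$stability$subsample_fraction,
                              threshold = config$stability$threshold,
                              seed = config$seed + 20L)
    on_file(write_tsv(data.frame(feature = names(stab$selection_frequency),
                                 frequency = stab$selection_frequency),
                      file.path(outdir, "stability_frequencies.tsv")))
  })
  res$stability <- stab

  # -- enrichment -------------------------------------------------------
  ora <- gsea <- NULL
  universe <- unique(c(annotation$transcripts$gene, annotation$mirnas$gene,
                       annotation$cpg_map$gene))
  stage("enrich", {
    mapped <- map_features_to_genes(stab$retained, annotation)
    query <- intersect(mapped$genes, universe)
    if (length(query) == 0) stop("no stability-retained feature maps to a gene")
    ora <- ora_test(query, gene_sets$collection, universe)
    ora <- ora[order(ora$p), ]
    on_file(write_tsv(ora, file.path(outdir, "ora.tsv")))
    ranked <- rank_by_group_difference(prep$transcript,
                                       dataset$metadata$subtype)
    genes_ranked <- annotation$transcripts$gene[
      match(names(ranked), annotation$transcripts$transcript)]
    sig <- ora$set[ora$p_adj < config$ora_alpha]
    gsea <- do.call(rbind, lapply(sig, function(s) {
      gs <- intersect(gene_sets$collection$sets[[s]], genes_ranked)
      if (length(gs) == 0) return(NULL)
      r <- gsea_permutation_p(genes_ranked, gs, weights = ranked,
                              n_permutations = config$gsea_permutations,
                              seed = config$seed + 30L)
      data.frame(set = s, es = r$es, p_perm = r$p, stringsAsFactors = FALSE)
    }))
    if (!is.null(gsea)) on_file(write_tsv(gsea, file.path(outdir, "gsea.tsv")))
  })
  res$ora <- ora; res$gsea <- gsea

  # -- MI networks ------------------------------------------------------
  networks <- list(); scheme <- NULL
  all_values <- if (is.null(prep)) NULL else do.call(rbind, unname(prep))
  stage("network", {
    scheme <- calibrate_thresholds(all_values, annotation$priors,
                                    alpha = config$ks_alpha)
    sig <- ora$set[ora$p_adj < config$ora_alpha]
    if (length(sig) == 0) sig <- ora$set[1]
    for (s in sig) {
      net <- build_function_subnetwork(gene_sets$collection$sets[[s]],
                                       stab$retained, fit, all_values,
                                       annotation, annotation$priors, scheme,
                                       epsilon = config$dpi_epsilon)
      networks[[s]] <- net
      on_file(export_network(net, file.path(outdir, paste0("net_", s, ".sif")),
                             "sif"))
      on_file(export_network(net,
                             file.path(outdir, paste0("net_", s, ".graphml")),
                             "graphml"))
    }
  })
  res$threshold_scheme <- scheme; res$networks <- networks

  # -- topology ---------------------------------------------------------
  stage("topology", {
    if (!is.null(config$input_sif)) {
      networks <- stats::setNames(lapply(config$input_sif, read_network,
                                         format = "sif"),
                                  tools::file_path_sans_ext(
                                    basename(config$input_sif)))
    }
    keep <- names(networks)[vapply(networks, function(n) nrow(n$nodes) > 0,
                                   logical(1))]
    if (length(keep)) {
      summ <- do.call(rbind, lapply(keep, function(s) {
        summarize_network(as_igraph_network(networks[[s]]), id = s)
      }))
      res$topology <- summ
      res$topology_group <- summarize_group(summ, id = "all")
      on_file(write_topology_table(summ, file.path(outdir, "topology.tsv")))
      on_file(write_tsv(res$topology_group,
                        file.path(outdir, "topology_group.tsv")))
    }
  })

  # -- annotation -------------------------------------------------------
  stage("annotate", {
    prom <- promoter_regions(annotation$transcripts)
    cls <- classify_cpg(annotation$cpg_map, prom, annotation$enhancers)
    res$cpg_classification <- cls
    on_file(write_tsv(cls, file.path(outdir, "cpg_classification.tsv")))
  })

  # -- Cox screening ----------------------------------------------------
  stage("cox", {
    terms <- config$cox_terms
    feats <- t(all_values)  # samples x features
    if (is.null(terms)) {
      cand <- intersect(stab$retained, colnames(feats))
      cand <- cand[feature_kinds(cand, annotation) == "transcript"]
      terms <- utils::head(cand, 3)
    }
    if (length(terms)) {
      design <- build_interaction_design(feats, terms)
      cox <- cox_fit(design, surv)
      res$cox <- cox
      on_file(write_tsv(cox_report(cox), file.path(outdir, "cox.tsv")))
    }
  })

  manifest <- list(
    package = "omicnets",
    version = as.character(utils::packageVersion("omicnets")),
    seed = config$seed,
    parameters = config[setdiff(names(config), "outdir")],
    stages_completed = done,
    files = lapply(stats::setNames(files, basename(files)), function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    }))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  res$manifest <- manifest
  invisible(res)
}
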