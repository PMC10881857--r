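#' Scale a block by the square root of its leading covariance eigenvalue
#'
#' After scaling, the sample covariance of the block has leading eigenvalue 1,
#' so each omic contributes to the multi-block objective in proportion to its
#' relative (not absolute) variance.
#'
#' @param x Numeric matrix, samples x features, column-centered.
#' @return Matrix of the same shape.
#' @export
scale_block_by_leading_eigenvalue <- function(x) {
  x <- as.matrix(x)
  xc <- sweep(x, 2, colMeans(x))
  d1 <- svd(xc, nu = 0, nv = 0)$d[1]
  lam <- d1^2 / (nrow(x) - 1)
  if (lam <= .Machine$double.eps) stop("zero-variance block cannot be scaled")
  x / sqrt(lam)
}

#' Project a vector onto the L1/L2 constraint set
#'
#' Returns the unit-L2 vector with L1 norm at most `l1_bound` maximizing the
#' inner product with `v`: soft-threshold then L2-normalize, with the
#' threshold found by bisection (the LASSO-style sparsity projection used in
#' sparse canonical correlation).
#'
#' @param v Nonzero numeric vector.
#' @param l1_bound L1 bound, at least 1 (a unit-L2 vector has L1 norm >= 1).
#' @return Unit-L2 numeric vector with `sum(abs(.)) <= l1_bound` (up to
#'   bisection tolerance).
#' @export
project_l1_l2 <- function(v, l1_bound) {
  if (all(v == 0)) stop("cannot project the zero vector")
  if (l1_bound < 1) stop("l1_bound must be >= 1")
  soft <- function(lam) {
    u <- sign(v) * pmax(abs(v) - lam, 0)
    nrm <- sqrt(sum(u^2))
    if (nrm == 0) NULL else u / nrm
  }
  u <- soft(0)
  if (sum(abs(u)) <= l1_bound) return(u)
  # L1 norm of the normalized soft-thresholded vector decreases in the
  # threshold: bisect for the smallest feasible threshold
  lo <- 0; hi <- max(abs(v))
  for (it in 1:100) {
    mid <- (lo + hi) / 2
    u_mid <- soft(mid)
    if (!is.null(u_mid) && sum(abs(u_mid)) <= l1_bound) hi <- mid else lo <- mid
  }
  u <- soft(hi)
  if (is.null(u)) { # bound so tight only the largest coordinate survives
    i <- which.max(abs(v))
    u <- numeric(length(v)); u[i] <- sign(v[i])
    names(u) <- names(v)
  }
  u
}

default_design <- function(n_blocks) {
  d <- matrix(1, n_blocks, n_blocks)
  diag(d) <- 0
  d
}

#' Fit sparse generalized canonical correlation (SGCCA, centroid scheme)
#'
#' Block-coordinate ascent maximizing
#' \deqn{\sum_{j<k} c_{jk}\,|\mathrm{cov}(X_j a_j, X_k a_k)|}
#' over per-block weight vectors constrained to unit L2 norm and L1 norm at
#' most \eqn{s_j \sqrt{p_j}} (sparsity \eqn{s_j \in (0,1]}, RGCCA
#' convention). The absolute value (centroid scheme) lets negatively
#' correlated block pairs contribute. Later components are obtained after
#' deflating each block by regression on its own component score.
#'
#' Blocks are column-centered internally (centers stored for projection of
#' new samples); eigenvalue scaling is a separate prior step, see
#' [scale_block_by_leading_eigenvalue()].
#'
#' @param blocks Named list of sample-aligned numeric matrices (samples x
#'   features, same row order).
#' @param sparsity Numeric in (0, 1], recycled per block.
#' @param n_components Number of components.
#' @param design Symmetric non-negative block-weight matrix with zero
#'   diagonal; default fully connected (all off-diagonal 1).
#' @param tol Relative objective-change convergence tolerance.
#' @param max_iter Maximum sweeps per component.
#' @return Object of class `sgcca`: `loadings` (per block, features x
#'   components), `scores` (per block, samples x components), `ave`,
#'   `objective_trace` (per component), `sparsity`, `design`, `scheme`,
#'   `centers`, `degenerate` flag.
#' @export
sgcca <- function(blocks, sparsity = 1, n_components = 1, design = NULL,
                  tol = 1e-8, max_iter = 1000) {
  stopifnot(is.list(blocks), length(blocks) >= 2)
  blocks <- lapply(blocks, as.matrix)
  n <- nrow(blocks[[1]])
  if (!all(vapply(blocks, nrow, 0L) == n)) stop("blocks are not sample-aligned")
  J <- length(blocks)
  if (is.null(names(blocks))) names(blocks) <- paste0("block", seq_len(J))
  if (is.null(design)) design <- default_design(J)
  if (!isSymmetric(unname(design)) || any(design < 0) || any(diag(design) != 0)) {
    stop("design must be symmetric, non-negative, zero diagonal")
  }
  sparsity <- rep_len(sparsity, J)
  if (any(sparsity <= 0 | sparsity > 1)) stop("sparsity must be in (0, 1]")
  ncmax <- min(n - 1, min(vapply(blocks, ncol, 0L)))
  if (n_components > ncmax) {
    stop("n_components exceeds deflation capacity (max ", ncmax, ")")
  }
  centers <- lapply(blocks, colMeans)
  X0 <- Map(function(b, ce) sweep(b, 2, ce), blocks, centers)
  X <- X0
  p <- vapply(X, ncol, 0L)
  l1 <- pmax(1, sparsity * sqrt(p))

  loadings <- lapply(seq_len(J), function(j) {
    matrix(0, p[j], n_components,
           dimnames = list(colnames(X[[j]]), paste0("comp", seq_len(n_components))))
  })
  names(loadings) <- names(blocks)
  scores <- lapply(seq_len(J), function(j) {
    matrix(0, n, n_components,
           dimnames = list(rownames(blocks[[j]]), paste0("comp", seq_len(n_components))))
  })
  names(scores) <- names(blocks)
  traces <- vector("list", n_components)
  degenerate <- FALSE

  objective <- function(Y) {
    obj <- 0
    for (j in seq_len(J - 1)) for (k in (j + 1):J) {
      if (design[j, k] > 0) {
        obj <- obj + design[j, k] * abs(crossprod(Y[[j]], Y[[k]])[1]) / (n - 1)
      }
    }
    obj
  }

  for (h in seq_len(n_components)) {
    a <- lapply(seq_len(J), function(j) {
      v <- svd(X[[j]], nu = 0, nv = 1)$v[, 1]
      project_l1_l2(v, l1[j])
    })
    Y <- lapply(seq_len(J), function(j) X[[j]] %*% a[[j]])
    trace <- objective(Y)
    for (it in seq_len(max_iter)) {
      for (j in seq_len(J)) {
        z <- numeric(n)
        for (k in seq_len(J)) {
          if (k == j || design[j, k] == 0) next
          s <- sign(crossprod(Y[[j]], Y[[k]])[1])
          if (s == 0) s <- 1
          z <- z + design[j, k] * s * Y[[k]]
        }
        g <- crossprod(X[[j]], z)[, 1] / (n - 1)
        if (all(abs(g) < .Machine$double.eps)) { degenerate <- TRUE; next }
        a[[j]] <- project_l1_l2(g, l1[j])
        Y[[j]] <- X[[j]] %*% a[[j]]
      }
      obj <- objective(Y)
      trace <- c(trace, obj)
      last <- trace[length(trace) - 1]
      if (abs(obj - last) < tol * max(abs(last), .Machine$double.eps)) break
    }
    traces[[h]] <- trace
    for (j in seq_len(J)) {
      loadings[[j]][, h] <- a[[j]]
      scores[[j]][, h] <- Y[[j]]
      ss <- sum(Y[[j]]^2)
      if (ss > 0) { # deflate block by regression on its own score
        X[[j]] <- X[[j]] - Y[[j]] %*% (crossprod(Y[[j]], X[[j]]) / ss)
      }
    }
  }

  fit <- structure(list(loadings = loadings, scores = scores,
                        sparsity = stats::setNames(sparsity, names(blocks)),
                        n_components = n_components, scheme = "centroid",
                        design = design, objective_trace = traces,
                        centers = centers, degenerate = degenerate),
                   class = "sgcca")
  fit$ave <- compute_ave(fit, blocks)
  fit
}

#' Average variance explained per block and component
#'
#' AVE of block j, component h, is the mean over block-j variables of the
#' squared Pearson correlation between the variable and the block's component
#' score. Constant variables contribute 0 with a warning.
#'
#' @param model A fitted [sgcca()] object.
#' @param blocks The blocks the model was fitted on (or new aligned blocks).
#' @return Matrix blocks x components of AVE values in [0, 1].
#' @export
compute_ave <- function(model, blocks) {
  stopifnot(inherits(model, "sgcca"))
  out <- matrix(NA_real_, length(blocks), model$n_components,
                dimnames = list(names(blocks),
                                paste0("comp", seq_len(model$n_components))))
  for (j in seq_along(blocks)) {
    x <- as.matrix(blocks[[j]])
    const <- apply(x, 2, stats::sd) == 0
    if (any(const)) warning("constant variables contribute 0 to AVE")
    for (h in seq_len(model$n_components)) {
      sc <- model$scores[[j]][, h]
      if (stats::sd(sc) == 0) { out[j, h] <- 0; next }
      r2 <- rep(0, ncol(x))
      r2[!const] <- stats::cor(x[, !const, drop = FALSE], sc)^2
      out[j, h] <- mean(r2)
    }
  }
  out
}

#' @export
print.sgcca <- function(x, ...) {
  cat("Sparse generalized CCA (centroid scheme)\n")
  cat(sprintf("blocks: %s\n", paste(names(x$loadings), collapse = ", ")))
  cat(sprintf("components: %d; sparsity: %s\n", x$n_components,
              paste(signif(x$sparsity, 3), collapse = ", ")))
  nsel <- vapply(x$loadings, function(l) sum(l[, 1] != 0), 0L)
  cat(sprintf("features selected (comp 1): %s\n",
              paste(nsel, collapse = ", ")))
  cat(sprintf("objective (comp 1): %.6g in %d sweeps\n",
              utils::tail(x$objective_trace[[1]], 1),
              length(x$objective_trace[[1]]) - 1L))
  if (x$degenerate) cat("NOTE: degenerate fit (zero gradient encountered)\n")
  invisible(x)
}

#' @export
summary.sgcca <- function(object, ...) {
  cat("Sparse generalized CCA (centroid scheme)\n\nAVE (block x component):\n")
  print(round(object$ave, 4))
  cat("\nSelected features per block and component:\n")
  print(vapply(object$loadings, function(l) colSums(l != 0),
               numeric(object$n_components)))
  invisible(object)
}

#' Extract loadings from an SGCCA fit
#' @param object A fitted [sgcca()] object.
#' @param block Block name or index (default all blocks, as a list).
#' @param ... Unused.
#' @export
coef.sgcca <- function(object, block = NULL, ...) {
  if (is.null(block)) object$loadings else object$loadings[[block]]
}

#' Project new samples onto fitted SGCCA loadings
#' @param object A fitted [sgcca()] object.
#' @param newblocks Named list of matrices with the same features per block.
#' @param ... Unused.
#' @return Per-block list of score matrices (samples x components).
#' @export
predict.sgcca <- function(object, newblocks, ...) {
  stopifnot(all(names(object$loadings) %in% names(newblocks)))
  out <- lapply(names(object$loadings), function(j) {
    x <- sweep(as.matrix(newblocks[[j]]), 2, object$centers[[j]])
    x %*% object$loadings[[j]]
  })
  stats::setNames(out, names(object$loadings))
}

#' @export
plot.sgcca <- function(x, comps = c(1, 2), block = 1, ...) {
  s <- x$scores[[block]]
  if (x$n_components < 2) {
    graphics::plot(s[, 1], ylab = "component 1 score", xlab = "sample",
                   main = "SGCCA scores", ...)
  } else {
    graphics::plot(s[, comps[1]], s[, comps[2]],
                   xlab = paste("component", comps[1]),
                   ylab = paste("component", comps[2]),
                   main = "SGCCA scores", ...)
  }
  invisible(x)
}

#' Cross-validate the sparsity parameter per block
#'
#' For each block and each grid value, fits a single component on k-1 folds
#' (candidate sparsity for that block, dense for the others), then records the
#' number of selected features and the block's AVE on the held-out fold
#' (held-out samples projected onto the training loadings).
#'
#' @param blocks Named list of sample-aligned matrices.
#' @param grid Sparsity grid in (0, 1].
#' @param k_folds Number of folds (>= 2); every fold must have >= 3 samples.
#' @param design Optional design matrix.
#' @param seed Seed for the fold assignment.
#' @return data.frame: block, sparsity, mean_ave, se_ave, mean_n_selected.
#' @export
cross_validate_sparsity <- function(blocks, grid = seq(0.01, 0.99, by = 0.01),
                                    k_folds = 5, design = NULL, seed = 1) {
  stopifnot(k_folds >= 2, all(grid > 0 & grid <= 1))
  n <- nrow(blocks[[1]])
  set.seed(seed)
  fold <- sample(rep(seq_len(k_folds), length.out = n))
  if (min(table(fold)) < 3) stop("each fold must contain at least 3 samples")
  J <- length(blocks)
  if (is.null(names(blocks))) names(blocks) <- paste0("block", seq_len(J))
  res <- list()
  for (j in seq_len(J)) {
    for (s in grid) {
      sp <- rep(1, J); sp[j] <- s
      ave_f <- nsel_f <- numeric(k_folds)
      for (f in seq_len(k_folds)) {
        tr <- fold != f
        fit <- sgcca(lapply(blocks, function(b) b[tr, , drop = FALSE]),
                     sparsity = sp, n_components = 1, design = design)
        nsel_f[f] <- sum(fit$loadings[[j]][, 1] != 0)
        xte <- sweep(blocks[[j]][!tr, , drop = FALSE], 2, fit$centers[[j]])
        sc <- xte %*% fit$loadings[[j]][, 1]
        if (stats::sd(sc) == 0) { ave_f[f] <- 0; next }
        keep <- apply(xte, 2, stats::sd) > 0
        r2 <- rep(0, ncol(xte))
        r2[keep] <- stats::cor(xte[, keep, drop = FALSE], sc)^2
        ave_f[f] <- mean(r2)
      }
      res[[length(res) + 1L]] <- data.frame(
        block = names(blocks)[j], sparsity = s, mean_ave = mean(ave_f),
        se_ave = stats::sd(ave_f) / sqrt(k_folds),
        mean_n_selected = mean(nsel_f), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}

#' Select sparsity per block from a cross-validation table
#'
#' One-standard-error parsimony rule: among grid values whose mean AVE is
#' within one standard error of the block's maximum, pick the one selecting
#' the fewest features; ties broken toward smaller sparsity.
#'
#' @param cv_table Output of [cross_validate_sparsity()].
#' @return Named numeric vector (one sparsity per block).
#' @export
select_sparsity <- function(cv_table) {
  stopifnot(nrow(cv_table) > 0)
  out <- vapply(split(cv_table, cv_table$block), function(tb) {
    best <- which.max(tb$mean_ave)
    cand <- tb[tb$mean_ave >= tb$mean_ave[best] - tb$se_ave[best], , drop = FALSE]
    cand <- cand[order(cand$mean_n_selected, cand$sparsity), , drop = FALSE]
    cand$sparsity[1]
  }, numeric(1))
  out[unique(cv_table$block)]
}

#' Build a stability-selection result from selection counts
#'
#' @param counts Named integer vector: times each feature was selected.
#' @param n_iterations Number of subsampling iterations.
#' @param threshold Retention threshold on the selection frequency; features
#'   with frequency at least `threshold` are retained.
#' @return Object of class `stability_result` with `selection_frequency`,
#'   `retained`, `n_iterations`, `retention_threshold`.
#' @export
stability_result <- function(counts, n_iterations, threshold = 0.70) {
  freq <- counts / n_iterations
  structure(list(selection_frequency = freq,
                 retained = names(freq)[freq >= threshold],
                 n_iterations = n_iterations,
                 retention_threshold = threshold),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("stability selection: %d/%d features retained (>= %d%% of %d iterations)\n",
              length(x$retained), length(x$selection_frequency),
              round(100 * x$retention_threshold), x$n_iterations))
  invisible(x)
}

#' Stability selection by half-sample subsampling
#'
#' Repeatedly fits a single SGCCA component on random subsamples and counts,
#' per feature, the iterations in which its loading is nonzero. Features
#' selected in at least `threshold` of the iterations are retained.
#'
#' @param blocks Named list of sample-aligned matrices.
#' @param sparsity Per-block sparsity (fixed across iterations).
#' @param n_iterations Number of subsample fits (default 100).
#' @param subsample_fraction Fraction of samples per fit (default 0.5).
#' @param threshold Retention frequency threshold (default 0.70).
#' @param design Optional design matrix.
#' @param seed Seed for the subsample draws.
#' @return A [stability_result()].
#' @export
stability_select <- function(blocks, sparsity, n_iterations = 100,
                             subsample_fraction = 0.5, threshold = 0.70,
                             design = NULL, seed = 1) {
  n <- nrow(blocks[[1]])
  m <- floor(n * subsample_fraction)
  if (m < 3) stop("subsample smaller than 3 samples")
  feats <- unlist(lapply(blocks, colnames), use.names = FALSE)
  counts <- stats::setNames(integer(length(feats)), feats)
  set.seed(seed)
  for (it in seq_len(n_iterations)) {
    idx <- sample.int(n, m)
    fit <- sgcca(lapply(blocks, function(b) b[idx, , drop = FALSE]),
                 sparsity = sparsity, n_components = 1, design = design)
    sel <- unlist(lapply(fit$loadings, function(l) rownames(l)[l[, 1] != 0]),
                  use.names = FALSE)
    counts[sel] <- counts[sel] + 1L
  }
  stability_result(counts, n_iterations, threshold)
}
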