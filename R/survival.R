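#' Build a Cox design matrix with interaction terms
#'
#' Columns are the requested main effects and products of standardized
#' features. Terms use `:` syntax, e.g. `c("A", "B", "A:B", "A:B:C")`.
#' Features are standardized (mean 0, s.d. 1) before products are formed.
#' Duplicate terms are collapsed with a warning.
#'
#' @param features Numeric matrix, samples x features, with column names.
#' @param terms Character vector of term specifications.
#' @param standardize Standardize features first (default TRUE).
#' @return Numeric matrix samples x terms, with term names as column names.
#' @export
build_interaction_design <- function(features, terms, standardize = TRUE) {
  features <- as.matrix(features)
  if (anyDuplicated(terms)) {
    warning("duplicate terms collapsed")
    terms <- unique(terms)
  }
  x <- if (standardize) scale(features) else features
  out <- matrix(NA_real_, nrow(features), length(terms),
                dimnames = list(rownames(features), terms))
  for (t in terms) {
    parts <- strsplit(t, ":", fixed = TRUE)[[1]]
    missing <- setdiff(parts, colnames(features))
    if (length(missing)) {
      stop("unknown feature(s) in term '", t, "': ",
           paste(missing, collapse = ", "))
    }
    out[, t] <- apply(x[, parts, drop = FALSE], 1, prod)
  }
  out
}

#' Cox proportional-hazards fit (Breslow partial likelihood)
#'
#' Maximizes the Breslow partial likelihood by Newton-Raphson (via
#' \pkg{survival}) and reports per-term Wald tests. Collinear or constant
#' columns and event-free data are rejected up front.
#'
#' @param design Numeric covariate matrix, samples x terms.
#' @param surv data.frame with columns `time` (positive) and `event` (0/1),
#'   rows aligned with `design`.
#' @param ties Tie handling, `"breslow"` (default) or `"efron"`.
#' @return Object of class `cox_screen`: `coefficients`, `se`, `z`, `p`,
#'   `loglik` (null and fitted partial log-likelihood), `converged`, and the
#'   underlying `survival::coxph` fit.
#' @export
cox_fit <- function(design, surv, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  design <- as.matrix(design)
  stopifnot(nrow(design) == nrow(surv), all(surv$time > 0),
            all(surv$event %in% c(0, 1)))
  if (sum(surv$event) == 0) stop("no events: cannot fit a Cox model")
  sds <- apply(design, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s): ", paste(colnames(design)[sds == 0],
                                       collapse = ", "))
  }
  dq <- qr(design)
  if (dq$rank < ncol(design)) {
    drop <- colnames(design)[-dq$pivot[seq_len(dq$rank)]]
    stop("collinear column(s): ", paste(drop, collapse = ", "))
  }
  fit <- survival::coxph(survival::Surv(surv$time, surv$event) ~ design,
                         ties = ties)
  cf <- summary(fit)$coefficients
  nm <- sub("^design", "", rownames(cf))
  structure(list(coefficients = stats::setNames(cf[, "coef"], nm),
                 se = stats::setNames(cf[, "se(coef)"], nm),
                 z = stats::setNames(cf[, "z"], nm),
                 p = stats::setNames(cf[, "Pr(>|z|)"], nm),
                 loglik = fit$loglik,
                 converged = fit$iter < survival::coxph.control()$iter.max,
                 n = nrow(design), n_events = sum(surv$event), ties = ties,
                 fit = fit),
            class = "cox_screen")
}

#' @export
print.cox_screen <- function(x, ...) {
  cat(sprintf("Cox screen (%s ties): %d samples, %d events\n", x$ties, x$n,
              x$n_events))
  tab <- data.frame(beta = x$coefficients, HR = exp(x$coefficients),
                    se = x$se, z = x$z, p = x$p)
  print(round(tab, 4))
  invisible(x)
}

#' Tabulate a Cox screen as a report data.frame
#'
#' @param x A [cox_fit()] result.
#' @param bh Add a Benjamini-Hochberg adjusted column (off by default; the
#'   screens are reported raw).
#' @return data.frame: term, beta, se, z, p (and p_bh if requested).
#' @export
cox_report <- function(x, bh = FALSE) {
  stopifnot(inherits(x, "cox_screen"))
  out <- data.frame(term = names(x$coefficients), beta = x$coefficients,
                    se = x$se, z = x$z, p = x$p, row.names = NULL,
                    stringsAsFactors = FALSE)
  if (bh) out$p_bh <- stats::p.adjust(out$p, "BH")
  out
}
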