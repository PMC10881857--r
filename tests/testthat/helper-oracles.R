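# Independent brute-force oracles used across the suite. These deliberately
# re-derive quantities from first principles (enumeration, grid search) and
# never call the implementation paths they check.

# exhaustive shortest paths / betweenness / closeness for tiny graphs ------
oracle_graph_metrics <- function(adj) {
  n <- nrow(adj)
  # all shortest path lengths by BFS
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    D[s, s] <- 0
    frontier <- s; d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- integer()
      for (v in frontier) {
        for (w in which(adj[v, ] > 0)) {
          if (D[s, w] > d) { D[s, w] <- d; nxt <- c(nxt, w) }
        }
      }
      frontier <- unique(nxt)
    }
  }
  # all shortest paths enumerated recursively for betweenness
  all_shortest_paths <- function(s, t) {
    if (s == t) return(list(s))
    out <- list()
    for (v in which(adj[s, ] > 0)) {
      if (is.finite(D[v, t]) && D[v, t] == D[s, t] - 1) {
        for (p in all_shortest_paths(v, t)) out <- c(out, list(c(s, p)))
      }
    }
    out
  }
  btw <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(D[s, t]) || D[s, t] == 0) next
    paths <- all_shortest_paths(s, t)
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      onpath <- sum(vapply(paths, function(p) v %in% p, logical(1)))
      btw[v] <- btw[v] + onpath / length(paths)
    }
  }
  if (n >= 3) btw <- btw / ((n - 1) * (n - 2) / 2)
  aspl <- closeness <- numeric(n)
  for (i in seq_len(n)) {
    d <- D[i, -i]; reach <- is.finite(d) & d > 0
    aspl[i] <- if (any(reach)) mean(d[reach]) else NA_real_
    closeness[i] <- if (any(reach)) sum(reach) / sum(d[reach]) else 0
  }
  list(D = D, betweenness = btw, aspl = aspl, closeness = closeness)
}

# hypergeometric upper tail by direct enumeration --------------------------
oracle_hyper_p <- function(overlap, set_size, query_size, universe_size) {
  ks <- max(0, query_size + set_size - universe_size):min(set_size, query_size)
  probs <- choose(set_size, ks) * choose(universe_size - set_size,
                                         query_size - ks) /
    choose(universe_size, query_size)
  sum(probs[ks >= overlap])
}

# two-sided Fisher exact p by enumeration over tables with fixed margins ---
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(ks, function(k) {
    choose(c1, k) * choose(n - c1, r1 - k) / choose(n, r1)
  }, numeric(1))
  p_obs <- probs[ks == tab[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Breslow partial log-likelihood written out, for brute-force maximization -
oracle_partial_loglik <- function(beta, x, time, event) {
  eta <- as.matrix(x) %*% beta
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + eta[i] - log(sum(exp(eta[risk])))
  }
  as.numeric(ll)
}

# brute-force kNN imputation matching the documented neighbour definition --
oracle_knn_impute <- function(m, k) {
  out <- m
  for (i in which(apply(m, 1, anyNA))) {
    obs <- !is.na(m[i, ])
    for (s in which(!obs)) {
      cand <- which(!is.na(m[, s]) & seq_len(nrow(m)) != i)
      d <- vapply(cand, function(j) {
        co <- obs & !is.na(m[j, ])
        if (!any(co)) return(Inf)
        sqrt(mean((m[i, co] - m[j, co])^2))
      }, numeric(1))
      nn <- cand[order(d)][seq_len(k)]
      out[i, s] <- mean(m[nn, s])
    }
  }
  out
}

# the published TMM recipe, recomputed from scratch ------------------------
oracle_tmm_factors <- function(counts) {
  lib <- colSums(counts)
  uq <- apply(counts, 2, function(x) stats::quantile(x / sum(x), 0.75))
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(s) {
    if (s == ref) return(1)
    o <- counts[, s]; r <- counts[, ref]
    keep <- o > 0 & r > 0
    o <- o[keep]; r <- r[keep]
    M <- log2((o / lib[s]) / (r / lib[ref]))
    A <- (log2(o / lib[s]) + log2(r / lib[ref])) / 2
    w <- 1 / ((lib[s] - o) / (lib[s] * o) + (lib[ref] - r) / (lib[ref] * r))
    keepM <- rank(M) > floor(length(M) * 0.3) &
      rank(M) <= length(M) - floor(length(M) * 0.3)
    keepA <- rank(A) > floor(length(A) * 0.05) &
      rank(A) <= length(A) - floor(length(A) * 0.05)
    kk <- keepM & keepA
    2^(sum(M[kk] * w[kk]) / sum(w[kk]))
  }, numeric(1))
  f / exp(mean(log(f)))
}

# star graph (1 hub + n-1 leaves) as igraph --------------------------------
star_graph <- function(n) {
  edges <- data.frame(a = rep("hub", n - 1), b = paste0("leaf", seq_len(n - 1)))
  as_igraph_network(edges, nodes = c("hub", paste0("leaf", seq_len(n - 1))))
}

small_sim <- function(...) {
  args <- list(...)
  defaults <- list(n_samples = 60, n_cpg = 20, n_transcript = 20, n_mirna = 12,
                   n_factors = 2, seed = 11,
                   n_regulatory_pairs = c(cpg_transcript = 4, cpg_mirna = 3,
                                          tf_transcript = 4,
                                          mirna_transcript = 4))
  do.call(sim_config, utils::modifyList(defaults, args))
}
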