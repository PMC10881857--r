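test_that("equal-frequency discretization balances bin sizes", {
  lab <- discretize_equal_frequency(rnorm(10), 5)
  expect_true(all(table(lab) == 2))
  expect_warning(lc <- discretize_equal_frequency(rep(3, 8), 4), "constant")
  expect_true(all(lc == 1))
  # heavy ties: sizes still differ by at most 1
  lab_t <- discretize_equal_frequency(c(rep(1, 7), rep(2, 6)), 4)
  expect_lte(diff(range(table(lab_t))), 1)
  expect_error(discretize_equal_frequency(1:5, 1), "n_bins")
})

test_that("plug-in MI matches closed forms and hand computation", {
  # identity over b equal bins: MI = ln(b)
  for (b in 2:5) {
    x <- rep(seq_len(b), each = 20)
    expect_equal(mutual_information(x, x), log(b), tolerance = 1e-12)
  }
  # explicit 2x2 joint table: p = (0.4, 0.1 / 0.1, 0.4)
  x <- c(rep(1, 40), rep(1, 10), rep(2, 10), rep(2, 40))
  y <- c(rep(1, 40), rep(2, 10), rep(1, 10), rep(2, 40))
  hand <- sum(c(0.4, 0.1, 0.1, 0.4) *
                log(c(0.4, 0.1, 0.1, 0.4) / c(0.25, 0.25, 0.25, 0.25)))
  expect_equal(mutual_information(x, y), hand, tolerance = 1e-12)
  # independent shuffled labels: MI near 0
  set.seed(1)
  a <- sample(rep(1:4, 250)); b <- sample(rep(1:4, 250))
  expect_lt(mutual_information(a, b), 0.05)
  # empirical independence gives exactly 0
  xi <- rep(1:2, each = 2); yi <- rep(1:2, times = 2)
  expect_equal(mutual_information(xi, yi), 0)
  expect_error(mutual_information(1:3, 1:4), "length")
})

test_that("pairwise MI matrix is symmetric with identity coupling maxima", {
  set.seed(6)
  v <- matrix(rnorm(4 * 100), 4, 100,
              dimnames = list(paste0("f", 1:4), paste0("s", 1:100)))
  v["f4", ] <- v["f1", ]  # duplicated feature
  mi <- pairwise_mi_matrix(v)
  expect_identical(mi, t(mi))
  expect_true(all(diag(mi) == 0))
  nb <- floor(sqrt(100))
  expect_equal(mi["f1", "f4"], log(nb), tolerance = 1e-10)
  # 2-node consistency with the scalar estimator
  mi2 <- pairwise_mi_matrix(v, nodes = c("f1", "f2"))
  l1 <- discretize_equal_frequency(v["f1", ], nb)
  l2 <- discretize_equal_frequency(v["f2", ], nb)
  expect_equal(mi2["f1", "f2"], mutual_information(l1, l2))
  # MI(x, x) is maximal in its row
  expect_true(mi["f1", "f4"] >= max(mi["f1", c("f2", "f3")]))
})

test_that("DPI pruning removes the weak edge of chain triangles only", {
  # simulated chain X -> Y -> Z
  set.seed(4)
  y <- rnorm(400)
  x <- y + rnorm(400, sd = 0.5)
  z <- y + rnorm(400, sd = 0.5)
  v <- rbind(x = x, y = y, z = z)
  colnames(v) <- paste0("s", 1:400)
  mi <- pairwise_mi_matrix(v)
  expect_lt(mi["x", "z"], min(mi["x", "y"], mi["y", "z"]))
  keep <- dpi_prune(mi)
  expect_false(keep["x", "z"])
  expect_true(keep["x", "y"] && keep["y", "z"])
  # idempotent: masking the pruned matrix and pruning again changes nothing
  mi2 <- mi * keep
  expect_equal(dpi_prune(mi2), mi2 > 0, ignore_attr = TRUE)

  # all-equal triangle survives at epsilon = 0 (strict rule)
  eq <- matrix(0.5, 3, 3); diag(eq) <- 0
  expect_true(all(dpi_prune(eq)[upper.tri(eq)]))
  # 2-node graph unchanged
  two <- matrix(c(0, 0.3, 0.3, 0), 2, 2)
  expect_equal(dpi_prune(two), two > 0, ignore_attr = TRUE)
  # output is always a subset of input edges
  set.seed(10)
  m <- matrix(runif(36), 6, 6); m <- (m + t(m)) / 2; diag(m) <- 0
  expect_true(all(m[!dpi_prune(m)] >= 0))
  expect_true(all((dpi_prune(m) & m > 0) == dpi_prune(m)))
})

test_that("threshold calibration takes per-type medians and merges on KS", {
  set.seed(14)
  n <- 60
  mk_dep <- function(rho) {
    g <- rnorm(n)
    rbind(g + rnorm(n, sd = rho), g + rnorm(n, sd = rho))
  }
  # two types with literally identical prior-pair MI samples: merged
  feats <- do.call(rbind, lapply(1:4, function(i) mk_dep(0.5)))
  rownames(feats) <- paste0("f", 1:8)
  colnames(feats) <- paste0("s", 1:n)
  pri <- data.frame(a = paste0("f", c(1, 3, 5, 7)),
                    b = paste0("f", c(2, 4, 6, 8)),
                    type = rep(c("cpg_transcript", "mirna_transcript"),
                               each = 2))
  pri2 <- rbind(pri, transform(pri[1:4, ],
                               type = rep(c("mirna_transcript",
                                            "cpg_transcript"), each = 2)))
  # give each type >= 3 pairs with a shared subset so distributions coincide
  pri_same <- data.frame(a = rep(paste0("f", c(1, 3, 5, 7)), 2),
                         b = rep(paste0("f", c(2, 4, 6, 8)), 2),
                         type = rep(c("cpg_transcript", "mirna_transcript"),
                                    each = 4))
  sch <- calibrate_thresholds(feats, pri_same)
  expect_true(sch$merged)
  expect_equal(unname(sch$medians[1]), unname(sch$medians[2]))
  expect_equal(sch$global_threshold, min(sch$medians))

  # strongly shifted MI distributions: not merged, distinct medians
  tight <- do.call(rbind, lapply(1:25, function(i) mk_dep(0.1)))
  loose <- matrix(rnorm(50 * n), 50, n)
  all_f <- rbind(tight, loose)
  rownames(all_f) <- paste0("g", 1:100)
  colnames(all_f) <- paste0("s", 1:n)
  pri_shift <- data.frame(
    a = paste0("g", c(seq(1, 49, 2), seq(51, 99, 2))),
    b = paste0("g", c(seq(2, 50, 2), seq(52, 100, 2))),
    type = rep(c("tf_transcript", "cpg_mirna"), each = 25))
  sch2 <- calibrate_thresholds(all_f, pri_shift)
  expect_false(sch2$merged)
  expect_gt(sch2$medians[["tf_transcript"]], sch2$medians[["cpg_mirna"]])
  # untyped edges use the lowest per-type median
  expect_equal(edge_threshold(sch2, "untyped"), min(sch2$medians))

  # median of three known MI values
  v3 <- rbind(a1 = rnorm(n), b1 = rnorm(n), a2 = rnorm(n), b2 = rnorm(n),
              a3 = rnorm(n), b3 = rnorm(n))
  colnames(v3) <- paste0("s", 1:n)
  p3 <- data.frame(a = c("a1", "a2", "a3"), b = c("b1", "b2", "b3"),
                   type = "cpg_transcript")
  s3 <- calibrate_thresholds(v3, p3)
  mis <- sort(s3$mi_values$cpg_transcript)
  expect_equal(unname(s3$medians[["cpg_transcript"]]), unname(mis[2]))

  expect_error(calibrate_thresholds(feats, pri[0, ]), "empty")
  expect_warning(calibrate_thresholds(feats, pri_same[c(1:4, 5), ]),
                 "excluded")
})

test_that("threshold filtering is monotone: raising thresholds never adds edges", {
  set.seed(22)
  v <- matrix(rnorm(6 * 80), 6, 80,
              dimnames = list(paste0("f", 1:6), paste0("s", 1:80)))
  mi <- pairwise_mi_matrix(v)
  th <- sort(unique(mi[upper.tri(mi)]))
  prev <- Inf
  for (t in c(th[2], th[4], max(th) + 1)) {
    n_edges <- sum(mi[upper.tri(mi)] >= t)
    expect_lte(n_edges, prev)
    prev <- n_edges
  }
})

test_that("function subnetworks recover a planted star", {
  set.seed(30)
  n <- 200
  hub <- rnorm(n)
  leaves <- sapply(1:3, function(i) hub + rnorm(n, sd = 0.4))
  noise <- matrix(rnorm(3 * n), 3, n)
  vals <- rbind(t(cbind(hub, leaves)), noise)
  rownames(vals) <- c("tx1", "cpg1", "cpg2", "mir1", "tx2", "cpg3", "mir2")
  colnames(vals) <- paste0("s", 1:n)
  ann <- list(
    transcripts = data.frame(transcript = c("tx1", "tx2"),
                             gene = c("gH", "gN"), is_tf = c(TRUE, FALSE),
                             stringsAsFactors = FALSE),
    cpg_map = data.frame(cpg = c("cpg1", "cpg2", "cpg3"),
                         gene = c("gH", "gH", "gN"), stringsAsFactors = FALSE),
    mirnas = data.frame(mirna = c("mir1", "mir2"), gene = c("mgA", "mgB"),
                        stringsAsFactors = FALSE),
    mirna_targets = data.frame(mirna = "mir1", target_gene = "gH",
                               stringsAsFactors = FALSE))
  pri <- data.frame(a = c("cpg1", "cpg2", "mir1"), b = "tx1",
                    type = c("cpg_transcript", "cpg_transcript",
                             "mirna_transcript"), stringsAsFactors = FALSE)
  # fixed scheme: threshold between the background-MI and the planted-MI range
  sch <- structure(list(medians = c(cpg_transcript = 0.55,
                                    mirna_transcript = 0.55),
                        ks_pvalues = numeric(), merged = TRUE,
                        global_threshold = 0.55, alpha = 0.05),
                   class = "threshold_scheme")
  net <- build_function_subnetwork(
    function_genes = c("gH", "mgA"),
    stable_features = c("tx1", "cpg1", "cpg2", "mir1"),
    model = NULL, values = vals, annotation = ann, priors = pri,
    scheme = sch)
  expect_setequal(net$nodes$id, c("tx1", "cpg1", "cpg2", "mir1"))
  edges <- net$edges
  # hub-leaf edges present, leaf-leaf edges pruned by DPI
  pairs <- paste(pmin(edges$a, edges$b), pmax(edges$a, edges$b))
  expect_setequal(pairs, c("cpg1 tx1", "cpg2 tx1", "mir1 tx1"))
  expect_setequal(unique(edges$type[edges$a %in% c("cpg1", "cpg2") |
                                      edges$b %in% c("cpg1", "cpg2")]),
                  "cpg_transcript")

  # single-node function: one node, no edges
  net1 <- build_function_subnetwork("gN", "tx2", NULL, vals, ann, pri, sch)
  expect_equal(nrow(net1$nodes), 1)
  expect_equal(nrow(net1$edges), 0)

  # threshold above every MI value: edgeless network
  sch_hi <- sch
  sch_hi$merged <- TRUE
  sch_hi$global_threshold <- 10
  net0 <- build_function_subnetwork(c("gH", "mgA"),
                                    c("tx1", "cpg1", "cpg2", "mir1"),
                                    NULL, vals, ann, pri, sch_hi)
  expect_equal(nrow(net0$edges), 0)
  expect_warning(build_function_subnetwork("gZ", "tx9", NULL, vals, ann, pri,
                                           sch), "empty")
})

test_that("mi_network validates its invariants", {
  nd <- data.frame(id = c("a", "b"), kind = "transcript", is_tf = FALSE)
  expect_error(mi_network(nd, data.frame(a = "a", b = "a", mi = 1,
                                         type = "untyped")), "self-edges")
  expect_error(mi_network(nd, data.frame(a = "a", b = "b", mi = -1,
                                         type = "untyped")), "non-negative")
  expect_error(mi_network(nd, data.frame(a = "a", b = "b", mi = 1,
                                         type = "bogus")), "type")
})
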