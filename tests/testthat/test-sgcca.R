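rand_block <- function(n, p, seed) {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("s", seq_len(n)), paste0("v", seq_len(p))))
  m
}

test_that("eigenvalue scaling yields unit leading covariance eigenvalue", {
  x <- rand_block(10, 5, 1)
  y <- scale_block_by_leading_eigenvalue(x)
  lam <- eigen(cov(y))$values[1]
  expect_equal(lam, 1, tolerance = 1e-8)
  # scaling a unit-eigenvalue block by 2 halves all entries
  expect_equal(scale_block_by_leading_eigenvalue(2 * y), y, tolerance = 1e-8)
  # idempotent
  expect_equal(scale_block_by_leading_eigenvalue(y), y, tolerance = 1e-8)
  expect_error(scale_block_by_leading_eigenvalue(matrix(1, 5, 3)),
               "zero-variance")
})

test_that("L1/L2 projection matches its constrained-maximization definition", {
  # inactive constraint: pure L2 normalization
  v <- c(1, -2, 3)
  expect_equal(project_l1_l2(v, sqrt(3)), v / sqrt(sum(v^2)))
  # tightest bound: all mass on the largest coordinate
  expect_equal(project_l1_l2(c(3, 4), 1), c(0, 1))
  expect_equal(project_l1_l2(c(-5, 4), 1), c(-1, 0))

  # brute-force threshold scan oracle
  v <- c(1, 2, 3); bound <- 1.5
  u <- project_l1_l2(v, bound)
  grid <- seq(0, max(v), length.out = 20001)
  best <- NULL; best_ip <- -Inf
  for (lam in grid) {
    s <- sign(v) * pmax(abs(v) - lam, 0)
    if (all(s == 0)) next
    s <- s / sqrt(sum(s^2))
    if (sum(abs(s)) <= bound + 1e-9 && sum(s * v) > best_ip) {
      best <- s; best_ip <- sum(s * v)
    }
  }
  expect_equal(u, best, tolerance = 1e-4)
  expect_equal(sum(u^2), 1, tolerance = 1e-10)
  expect_lte(sum(abs(u)), bound + 1e-6)
  expect_error(project_l1_l2(c(0, 0), 2), "zero vector")

  # property: unit L2 norm and feasible L1 norm across random draws
  set.seed(5)
  for (i in 1:50) {
    p <- sample(3:20, 1)
    v <- rnorm(p)
    bound <- runif(1, 1, sqrt(p))
    u <- project_l1_l2(v, bound)
    expect_equal(sum(u^2), 1, tolerance = 1e-9)
    expect_lte(sum(abs(u)), bound + 1e-6)
  }
})

test_that("dense two-block SGCCA reproduces the SVD covariance direction", {
  x <- rand_block(30, 8, 2); y <- rand_block(30, 6, 3)
  fit <- sgcca(list(A = x, B = y), sparsity = 1, n_components = 1)
  sv <- svd(crossprod(sweep(x, 2, colMeans(x)), sweep(y, 2, colMeans(y))))
  expect_equal(abs(sum(fit$loadings$A[, 1] * sv$u[, 1])), 1, tolerance = 1e-6)
  expect_equal(abs(sum(fit$loadings$B[, 1] * sv$v[, 1])), 1, tolerance = 1e-6)
  # objective equals the leading covariance
  expect_equal(tail(fit$objective_trace[[1]], 1), sv$d[1] / (30 - 1),
               tolerance = 1e-6)
})

test_that("two copies of a one-factor block recover its leading direction", {
  set.seed(9)
  f <- rnorm(40)
  x <- outer(f, c(3, -2, 1, 0.5)) + matrix(rnorm(160, sd = 0.2), 40, 4)
  colnames(x) <- paste0("v", 1:4); rownames(x) <- paste0("s", 1:40)
  fit <- sgcca(list(A = x, B = x), sparsity = 1, n_components = 1)
  v1 <- svd(sweep(x, 2, colMeans(x)))$v[, 1]
  expect_equal(abs(sum(fit$loadings$A[, 1] * v1)), 1, tolerance = 1e-4)
})

test_that("objective trace is non-decreasing and rescaling leaves loadings alone", {
  set.seed(31)
  for (i in 1:20) {
    blocks <- list(A = rand_block(15, 5, 100 + i), B = rand_block(15, 4, 200 + i),
                   C = rand_block(15, 6, 300 + i))
    fit <- sgcca(blocks, sparsity = runif(1, 0.3, 1), n_components = 2)
    for (tr in fit$objective_trace) expect_true(all(diff(tr) > -1e-8))
  }
  # post eigenvalue scaling, multiplying a block by a positive constant and
  # re-scaling gives identical loadings
  a <- scale_block_by_leading_eigenvalue(rand_block(20, 5, 7))
  b <- scale_block_by_leading_eigenvalue(rand_block(20, 4, 8))
  f1 <- sgcca(list(A = a, B = b), sparsity = 0.6)
  f2 <- sgcca(list(A = scale_block_by_leading_eigenvalue(7 * a), B = b),
              sparsity = 0.6)
  expect_equal(f1$loadings$A, f2$loadings$A, tolerance = 1e-6)
})

test_that("degenerate designs and bad inputs are flagged", {
  blocks <- list(A = rand_block(10, 3, 1), B = rand_block(10, 3, 2))
  d0 <- matrix(0, 2, 2)
  fit <- sgcca(blocks, sparsity = 1, design = d0)
  expect_true(fit$degenerate)
  expect_equal(tail(fit$objective_trace[[1]], 1), 0)
  expect_error(sgcca(list(A = rand_block(10, 3, 1), B = rand_block(9, 3, 2))),
               "aligned")
  expect_error(sgcca(blocks, n_components = 50), "deflation capacity")
  expect_error(sgcca(blocks, sparsity = 0), "sparsity")
})

test_that("planted two-block factor is recovered under tight sparsity", {
  set.seed(77)
  n <- 200
  f <- rnorm(n)
  mk <- function(p, nload, seed) {
    set.seed(seed)
    z <- matrix(rnorm(n * p), n, p)
    z[, 1:nload] <- z[, 1:nload] + outer(f, rep(5, nload))
    colnames(z) <- paste0("v", 1:p); rownames(z) <- paste0("s", 1:n)
    scale_block_by_leading_eigenvalue(z)
  }
  blocks <- list(A = mk(30, 5, 1), B = mk(30, 5, 2))
  fit <- sgcca(blocks, sparsity = 5 / sqrt(30) / sqrt(30) + 0.2, n_components = 1)
  selA <- names(which(fit$loadings$A[, 1] != 0))
  expect_gte(length(intersect(selA, paste0("v", 1:5))), 4)
})

test_that("AVE equals the mean squared variable-score correlation", {
  x <- rand_block(25, 3, 4)
  fit <- sgcca(list(A = x, B = x + matrix(rnorm(75, sd = 0.1), 25, 3)),
               sparsity = 1)
  ave <- fit$ave
  xc <- sweep(x, 2, colMeans(x))
  manual <- mean(cor(xc, fit$scores$A[, 1])^2)
  expect_equal(unname(ave["A", 1]), manual, tolerance = 1e-10)
  expect_true(all(ave >= 0 & ave <= 1))

  # score equal to one variable: that variable contributes 1
  one <- cor(x[, 1], fit$scores$A[, 1])^2
  fit1 <- sgcca(list(A = x[, 1, drop = FALSE], B = x[, 1, drop = FALSE]),
                sparsity = 1)
  expect_equal(unname(fit1$ave[1, 1]), 1, tolerance = 1e-10)
  # constant variable warns and contributes 0
  xx <- cbind(x, const = 1)
  expect_warning(av <- compute_ave(fit, list(A = xx[, c(1, 4)], B = x)),
                 "constant")
})

test_that("sparsity cross-validation honours the table contract", {
  set.seed(15)
  blocks <- list(A = rand_block(40, 6, 61), B = rand_block(40, 5, 62))
  cv1 <- cross_validate_sparsity(blocks, grid = 0.5, k_folds = 4, seed = 2)
  expect_equal(nrow(cv1), 2)          # one row per block for a 1-point grid
  cv <- cross_validate_sparsity(blocks, grid = c(0.3, 1), k_folds = 4, seed = 2)
  expect_equal(cv$mean_n_selected[cv$sparsity == 1 & cv$block == "A"], 6)
  expect_equal(cv$mean_n_selected[cv$sparsity == 1 & cv$block == "B"], 5)
  expect_error(cross_validate_sparsity(blocks, grid = 0.5, k_folds = 20),
               "at least 3 samples")

  # strong planted signal: held-out AVE at generous sparsity beats the
  # tightest sparsity
  f <- rnorm(60)
  xa <- outer(f, rep(4, 2))
  xa <- cbind(xa, matrix(rnorm(60 * 6), 60, 6))
  colnames(xa) <- paste0("a", 1:8); rownames(xa) <- paste0("s", 1:60)
  xb <- cbind(outer(f, rep(4, 2)), matrix(rnorm(60 * 6), 60, 6))
  colnames(xb) <- paste0("b", 1:8); rownames(xb) <- paste0("s", 1:60)
  cvp <- cross_validate_sparsity(list(A = xa, B = xb), grid = c(0.05, 0.5),
                                 k_folds = 5, seed = 3)
  a_rows <- cvp[cvp$block == "A", ]
  expect_gte(a_rows$mean_ave[a_rows$sparsity == 0.5],
             a_rows$mean_ave[a_rows$sparsity == 0.05])
})

test_that("sparsity selection applies the one-SE parsimony rule", {
  tb <- data.frame(block = "A", sparsity = 0.5, mean_ave = 0.4, se_ave = 0.1,
                   mean_n_selected = 3)
  expect_equal(unname(select_sparsity(tb)), 0.5)
  tb2 <- data.frame(block = "A", sparsity = c(0.2, 0.8),
                    mean_ave = c(0.5, 0.5), se_ave = c(0.01, 0.01),
                    mean_n_selected = c(50, 10))
  expect_equal(unname(select_sparsity(tb2)), 0.8)
  tb3 <- data.frame(block = "A", sparsity = c(0.9, 0.5, 0.1),
                    mean_ave = c(0.80, 0.79, 0.50), se_ave = c(0.02, 0.02, 0.02),
                    mean_n_selected = c(100, 20, 5))
  expect_equal(unname(select_sparsity(tb3)), 0.5) # the 20-feature row
})

test_that("stability retention uses the at-least-70% rule", {
  counts <- c(a = 70L, b = 69L, c = 100L, d = 0L)
  sr <- stability_result(counts, n_iterations = 100, threshold = 0.70)
  expect_true(all(c("a", "c") %in% sr$retained))
  expect_false("b" %in% sr$retained)
  expect_equal(unname(sr$selection_frequency["a"]), 0.7)
})

test_that("stability frequencies are reproducible under a master seed", {
  blocks <- list(A = rand_block(30, 5, 91), B = rand_block(30, 4, 92))
  s1 <- stability_select(blocks, sparsity = 0.5, n_iterations = 15, seed = 4)
  s2 <- stability_select(blocks, sparsity = 0.5, n_iterations = 15, seed = 4)
  expect_identical(s1$selection_frequency, s2$selection_frequency)
  expect_error(stability_select(blocks, sparsity = 0.5,
                                subsample_fraction = 0.05),
               "smaller than 3")
})
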