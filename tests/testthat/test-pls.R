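test_that("PLS1 weights equal the normalized cross-covariance oracle", {
  set.seed(13)
  for (i in 1:20) {
    n <- sample(10:50, 1L)
    p <- sample(5:200, 1L)
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(sprintf("r%02d", 1:n), sprintf("g%03d", 1:p)))
    y <- rnorm(n)
    fit <- fit_pls1(x, y)
    expect_gte(abs_cosine(fit$weights[, 1L], oracle_pls1_weights(x, y)),
               1 - 1e-8)
    expect_gte(cor(fit$scores[, 1L], y), 0)  # sign convention
    expect_equal(sum(fit$weights[, 1L]^2), 1, tolerance = 1e-10)
  }
})

test_that("single-gene PLS1 reduces to simple regression R^2", {
  set.seed(2)
  x <- matrix(rnorm(30), 30, 1, dimnames = list(NULL, "g1"))
  y <- 0.5 * x[, 1L] + rnorm(30, sd = 0.5)
  fit <- fit_pls1(x, y)
  expect_equal(fit$variance_explained, 100 * cor(x[, 1L], y)^2,
               tolerance = 1e-10)
})

test_that("PLS1 rejects degenerate inputs", {
  x <- matrix(rnorm(50), 10, 5)
  expect_error(fit_pls1(x, rep(1, 10)), class = "degenerate_response")
  expect_error(fit_pls1(x, rnorm(10), k = 20), class = "invalid_argument")
  expect_error(fit_pls1(x, rnorm(9)), class = "shape_error")
})

test_that("variance explained is invariant to y rescaling and joint row permutation", {
  set.seed(4)
  x <- matrix(rnorm(40 * 30), 40, 30)
  y <- rnorm(40)
  v0 <- fit_pls1(x, y)$variance_explained
  expect_equal(fit_pls1(x, 3.7 * y)$variance_explained, v0, tolerance = 1e-10)
  perm <- sample(40)
  expect_equal(fit_pls1(x[perm, ], y[perm])$variance_explained, v0,
               tolerance = 1e-10)
})

test_that("multi-component fit decomposes X and y and matches mixOmics", {
  set.seed(6)
  x <- matrix(rnorm(30 * 12), 30, 12,
              dimnames = list(NULL, sprintf("g%02d", 1:12)))
  y <- rnorm(30)
  fit <- fit_pls1(x, y, k = 3L)
  # reconstruction: X_c = Z P' + E, y_c = Z b + e
  xc <- sweep(x, 2L, colMeans(x), "-")
  expect_equal(xc, fit$scores %*% t(fit$loadings) + fit$E, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(y - mean(y), as.numeric(fit$scores %*% fit$b) + fit$e,
               tolerance = 1e-8)
  # scores of successive components are orthogonal
  zz <- crossprod(fit$scores)
  expect_lt(max(abs(zz[upper.tri(zz)])) / min(diag(zz)), 1e-8)

  skip_if_not_installed("mixOmics")
  ref <- mixOmics::pls(x, y, ncomp = 3L, scale = FALSE, mode = "regression")
  for (k in 1:3) {
    expect_gte(abs_cosine(fit$weights[, k], ref$loadings$X[, k]), 1 - 1e-6)
  }
})

test_that("null_variance_explained separates signal from noise and counts correctly", {
  inst <- planted_instance(n_regions = 60L, n_genes = 300L, n_planted = 40L,
                           seed = 21L)
  nd <- null_variance_explained(inst$x, inst$y, n_iter = 500L, seed = 1L)
  expect_lte(nd$p, 0.01)
  expect_length(nd$null, 500L)

  # pure-noise response: p should not be small
  set.seed(22)
  y_noise <- rnorm(60)
  nd0 <- null_variance_explained(inst$x, y_noise, n_iter = 500L, seed = 2L)
  expect_gt(nd0$p, 0.05)

  # empirical p arithmetic: add-one smoothing on direct counts
  expect_equal(nd$p, (1 + sum(nd$null >= nd$observed)) / (1 + 500))

  # both resampling flavours run; unknown method errors
  nd_b <- null_variance_explained(inst$x, inst$y, n_iter = 100L,
                                  method = "bootstrap", seed = 3L)
  expect_true(nd_b$p <= 1 && nd_b$p > 0)
  expect_error(null_variance_explained(inst$x, inst$y, method = "spin"))
})

test_that("bootstrap gene stats: chunked identity, reproducibility, planted z", {
  inst <- planted_instance(n_regions = 50L, n_genes = 200L, n_planted = 30L,
                           seed = 42L)
  gs1 <- bootstrap_gene_weights(inst$x, inst$y, n_boot = 300L, seed = 11L)
  # chunking must not change results (same seed, different chunk size)
  gs2 <- bootstrap_gene_weights(inst$x, inst$y, n_boot = 300L, seed = 11L,
                                chunk = 37L)
  expect_equal(gs1$se, gs2$se, tolerance = 1e-12)
  expect_identical(gs1, bootstrap_gene_weights(inst$x, inst$y, n_boot = 300L,
                                               seed = 11L))

  # planted genes dominate the z distribution
  planted <- inst$truth$planted_gene_ids
  expect_gt(median(abs(gs1$z[gs1$gene %in% planted])),
            median(abs(gs1$z[!gs1$gene %in% planted])))

  # bootstrap SE agrees with a naive per-replicate refit loop (replicate
  # cross-covariances on the original-norm scale, sign-aligned)
  set.seed(77)
  x_small <- inst$x[, 1:25]
  gs_small <- bootstrap_gene_weights(x_small, inst$y, n_boot = 400L, seed = 5L)
  w_ref <- oracle_pls1_weights(x_small, inst$y)
  xc <- sweep(x_small, 2L, colMeans(x_small), "-")
  nw0 <- sqrt(sum(crossprod(xc, inst$y - mean(inst$y))^2))
  reps <- withr::with_seed(5L, {
    sapply(1:400, function(b) {
      repeat {
        idx <- sample.int(50, 50, replace = TRUE)
        if (length(unique(idx)) >= 3L) break
      }
      xb <- x_small[idx, ]
      yb <- inst$y[idx]
      wb <- as.numeric(crossprod(sweep(xb, 2L, colMeans(xb), "-"),
                                 yb - mean(yb))) / nw0
      if (sum(wb * w_ref) < 0) wb <- -wb
      wb
    })
  })
  expect_equal(gs_small$se, apply(reps, 1L, sd), tolerance = 1e-8)
})

test_that("zero-variance bootstrap weights get SE 0, p 0 and a flag", {
  # with 3 regions, every replicate with 3 distinct regions is a permutation
  # of the data, so the aligned weight is identical in all replicates
  set.seed(8)
  x <- matrix(rnorm(6), 3, 2, dimnames = list(NULL, c("g1", "g2")))
  y <- c(-1, 0.2, 1)
  gs <- bootstrap_gene_weights(x, y, n_boot = 100L, seed = 1L)
  expect_equal(gs$se, c(0, 0), tolerance = 1e-15)
  expect_true(all(gs$degenerate))
  expect_equal(gs$p, c(0, 0))
})

test_that("VIP identity holds and equal weights give VIP 1", {
  set.seed(9)
  x <- matrix(rnorm(30 * 50), 30, 50, dimnames = list(NULL, sprintf("g%02d", 1:50)))
  y <- rnorm(30)
  fit <- fit_pls1(x, y)
  vip <- compute_vip(fit)
  expect_equal(mean(vip^2), 1, tolerance = 1e-10)
  fit2 <- fit_pls1(x, y, k = 2L)
  expect_equal(mean(compute_vip(fit2)^2), 1, tolerance = 1e-10)

  # four genes with equal |weight|: columns proportional to +-y
  y4 <- rnorm(30)
  x4 <- cbind(g1 = y4, g2 = -y4, g3 = 2 * y4, g4 = -2 * y4)
  x4 <- sweep(x4, 2L, c(1, 1, 2, 2), "/")  # equal cross-covariances
  vip4 <- compute_vip(fit_pls1(x4, y4))
  expect_equal(unname(vip4), rep(1, 4), tolerance = 1e-10)
})

test_that("gene selection applies both thresholds and flips with y", {
  inst <- planted_instance(n_regions = 50L, n_genes = 150L, n_planted = 25L,
                           seed = 3L)
  gs <- bootstrap_gene_weights(inst$x, inst$y, n_boot = 200L, seed = 2L)
  sel <- select_genes(gs)
  expect_identical(sel$vip_cut, 1)
  expect_identical(sel$alpha, 0.05)
  expect_length(intersect(sel$pls1_plus, sel$pls1_minus), 0L)
  both <- gs[gs$gene %in% c(sel$pls1_plus, sel$pls1_minus), ]
  expect_true(all(both$vip > 1 & both$p < 0.05))

  # flipping the response swaps PLS1+ and PLS1-
  gs_neg <- bootstrap_gene_weights(inst$x, -inst$y, n_boot = 200L, seed = 2L)
  sel_neg <- select_genes(gs_neg)
  expect_setequal(sel_neg$pls1_plus, sel$pls1_minus)
  expect_setequal(sel_neg$pls1_minus, sel$pls1_plus)

  # boundary: VIP exactly 1 everywhere -> strict inequality selects nothing
  eq <- data.frame(gene = c("a", "b"), weight = c(1, -1), p = c(0.01, 0.01),
                   vip = c(1, 1))
  sel_eq <- select_genes(eq)
  expect_length(sel_eq$pls1_plus, 0L)
  expect_length(sel_eq$pls1_minus, 0L)

  # BH adjustment never selects more than raw p
  sel_bh <- select_genes(gs, adjust = "BH")
  expect_lte(length(sel_bh$pls1_plus), length(sel$pls1_plus))
})
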