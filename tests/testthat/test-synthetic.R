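test_that("make_expression plants structure on factor 1 and is reproducible", {
  gen <- make_expression(50, 500, n_latent = 2L, noise_sd = 0.3,
                         n_planted = 50L, seed = 7L)
  x <- gen$expression
  tr <- gen$truth
  expect_identical(dim(x), c(50L, 500L))
  expect_length(tr$planted_gene_ids, 50L)
  expect_true(all(tr$planted_gene_ids %in% colnames(x)))

  # planted genes correlate with factor 1 more strongly than background
  f1 <- tr$factors[, 1L]
  cors <- abs(cor(x, f1)[, 1L])
  expect_gt(mean(cors[tr$planted_gene_ids]),
            mean(cors[setdiff(colnames(x), tr$planted_gene_ids)]))

  # bit-reproducible
  gen2 <- make_expression(50, 500, n_latent = 2L, noise_sd = 0.3,
                          n_planted = 50L, seed = 7L)
  expect_identical(gen$expression, gen2$expression)
  expect_identical(gen$truth$planted_gene_ids, gen2$truth$planted_gene_ids)
})

test_that("noiseless expression has numerical rank n_latent", {
  for (k in c(1L, 3L)) {
    gen <- make_expression(40, 100, n_latent = k, noise_sd = 0,
                           n_planted = 0L, seed = 2L)
    sv <- svd(gen$expression, nu = 0, nv = 0)$d
    expect_lt(sv[k + 1L] / sv[1L], 1e-10)
  }
})

test_that("make_expression rejects bad dimensions", {
  expect_error(make_expression(0, 10), class = "invalid_argument")
  expect_error(make_expression(10, 10, n_planted = 20), class = "invalid_argument")
  expect_error(make_expression(2, 10, n_latent = 5), class = "invalid_argument")
})

test_that("make_cohort plants the group atrophy difference in w-score units", {
  n_r <- 40L
  map <- sin(seq(0, 3 * pi, length.out = n_r))
  coh <- make_cohort(50, 200, 200, atrophy_map = map, effect = 1.5, seed = 11L)
  expect_identical(nrow(coh), 450L)
  expect_true(all(coh$duration[coh$group == "control"] == 0))
  expect_true(all(coh$duration[coh$group != "control"] > 0))
  expect_true(all(coh$age > 0))

  th <- as.matrix(coh[, attr(coh, "region_labels")])
  tr <- attr(coh, "truth")
  diff_map <- colMeans(th[coh$group == "genetic", ]) -
    colMeans(th[coh$group == "sporadic", ])
  # regress the mm difference on the two planted maps: the atrophy-map
  # coefficient recovers effect * noise_sd
  fit <- lm(diff_map ~ tr$atrophy_map + tr$sporadic_map)
  est <- coef(fit)[2L]
  se <- summary(fit)$coefficients[2L, 2L]
  expect_lt(abs(est - 1.5 * tr$noise_sd), 4 * se + 1e-3)

  # null effect: groups exchangeable, contrast t centered on 0
  coh0 <- make_cohort(30, 60, 60, atrophy_map = map, effect = 0, seed = 12L)
  th0 <- as.matrix(coh0[, attr(coh0, "region_labels")])
  tvals <- vapply(seq_len(n_r), function(r) {
    oracle_two_sample_t(th0[coh0$group == "genetic", r],
                        th0[coh0$group == "sporadic", r])
  }, numeric(1L))
  expect_lt(abs(mean(tvals)), 0.5)
})

test_that("make_cohort validates arguments", {
  expect_error(make_cohort(5, 5, 5, rnorm(10), 1), class = "invalid_argument")
  expect_error(make_cohort(20, 5, 5, 3.5, 1), class = "invalid_argument")
})

test_that("receptor atlas attains its planted correlations", {
  map <- smooth_map <- sin(seq(0, 4 * pi, length.out = 200))
  targets <- c(0.8, -0.5, 0.0)
  atlas <- make_receptor_atlas(map, targets, seed = 3L)
  r_hat <- cor(map, unclass(atlas))[1L, ]
  expect_true(all(abs(r_hat - targets) < 0.15))

  # target 0: independence within +-3/sqrt(n)
  expect_lt(abs(r_hat[3L]), 3 / sqrt(200) + 0.05)

  # 15 targets get the canonical receptor names across 5 systems
  atlas15 <- make_receptor_atlas(rnorm(60), rep(0.1, 15), seed = 1L)
  expect_identical(ncol(atlas15), 15L)
  expect_identical(length(unique(attr(atlas15, "systems"))), 5L)
})

test_that("receptor atlas correlations converge with region count", {
  map <- rnorm(1000)
  targets <- c(0.6, -0.3, 0.2, 0.0)
  atlas <- make_receptor_atlas(map, targets, seed = 5L)
  r_hat <- cor(map, unclass(atlas))[1L, ]
  expect_lt(mean(abs(r_hat - targets)), 0.05)
  expect_error(make_receptor_atlas(map, c(0.5, 1.0)), class = "invalid_argument")
})

test_that("make_pathology_sets plants the exact overlap", {
  bg <- gene_labels <- sprintf("G%04d", 1:500)
  sig <- bg[1:50]
  ps <- make_pathology_sets(bg, sig, overlap_fraction = 1, set_size = 200,
                            seed = 4L)
  expect_identical(length(intersect(ps, sig)), 50L)
  expect_length(ps, 200L)

  ps0 <- make_pathology_sets(bg, sig, overlap_fraction = 0, set_size = 200,
                             seed = 4L)
  expect_length(intersect(ps0, sig), 0L)

  ps_half <- make_pathology_sets(bg, sig, overlap_fraction = 0.5,
                                 set_size = 100, seed = 9L)
  expect_identical(length(intersect(ps_half, sig)), 25L)
  expect_identical(ps_half, make_pathology_sets(bg, sig, 0.5, 100, seed = 9L))

  expect_error(make_pathology_sets(bg, c(sig, "NOT_THERE"), 0.5, 100),
               class = "consistency_error")
})
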