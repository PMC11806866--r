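#' Single-response partial least squares (PLS1) fit
#'
#' Decomposes a centered region-by-gene matrix `X` and contrast vector `y`
#' as `X = Z V' + E`, `y = Z b + e` via NIPALS with X-deflation. For a
#' single response the first weight vector is the normalized
#' cross-covariance `Xc' yc`, i.e. the gene combination whose score
#' maximally covaries with the contrast map. The sign of each component is
#' fixed so that `cor(Z[, 1], y) >= 0`. The variance explained reported for
#' the model is `100 * R^2` of `y` regressed on the first component score.
#'
#' @param x Region x gene matrix (aligned with `y`).
#' @param y A `contrast_map` or numeric region vector.
#' @param k Number of components (default 1; components beyond the first
#'   are obtained by deflation).
#' @param center Center columns of `x` and `y` before fitting (default
#'   TRUE; weights are always reported on the centered scale).
#' @return An object of class `pls1_fit`: list with `k`, `scores` (Z,
#'   n x k), `weights` (V, p x k, unit-norm columns), `loadings` (P, p x k),
#'   `b` (k coefficients), `E`, `e`, `variance_explained` (PLS1, percent),
#'   `variance_explained_by_component`, `sign_convention`, `genes`,
#'   `regions`.
#' @export
fit_pls1 <- function(x, y, k = 1L, center = TRUE) {
  y <- contrast_values(y, x)
  k <- assert_count(k, "k")
  n <- nrow(x); p <- ncol(x)
  if (n < 3L) stop_cortexpls("need at least 3 regions", "invalid_argument")
  if (k > min(n - 1L, p)) {
    stop_cortexpls("k must be <= min(n - 1, p)", "invalid_argument")
  }
  if (stats::sd(y) < .Machine$double.eps) {
    stop_cortexpls("constant response: contrast map has zero variance",
                   "degenerate_response")
  }
  Xc <- if (center) sweep(x, 2L, colMeans(x), "-") else x
  yc <- if (center) y - mean(y) else y

  V <- matrix(0, p, k); P <- matrix(0, p, k); Z <- matrix(0, n, k)
  b <- numeric(k)
  Xd <- Xc; yd <- yc
  for (comp in seq_len(k)) {
    w <- crossprod(Xd, yd)                 # p x 1 cross-covariance
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps) {
      stop_cortexpls("zero cross-covariance: no further components",
                     "degenerate_response")
    }
    w <- w / nw
    z <- Xd %*% w
    zz <- sum(z^2)
    pl <- crossprod(Xd, z) / zz
    bk <- sum(z * yd) / zz
    if (sum(z * yc) < 0) {                 # sign: cor(Z, original y) >= 0
      w <- -w; z <- -z; pl <- -pl; bk <- -bk
    }
    V[, comp] <- w; Z[, comp] <- z; P[, comp] <- pl; b[comp] <- bk
    Xd <- Xd - z %*% t(pl)
    yd <- yd - z * bk
  }
  ssy <- sum(yc^2)
  varexp_comp <- 100 * colSums((Z %*% diag(b, k, k))^2) / ssy
  dimnames(V) <- list(colnames(x), paste0("PLS", seq_len(k)))
  dimnames(P) <- dimnames(V)
  dimnames(Z) <- list(rownames(x), paste0("PLS", seq_len(k)))

  structure(list(
    k = k, scores = Z, weights = V, loadings = P, b = b,
    E = Xd, e = as.numeric(yd),
    variance_explained = varexp_comp[1L],
    variance_explained_by_component = varexp_comp,
    sign_convention = "cor(scores[,1], y) >= 0",
    genes = colnames(x), regions = rownames(x)
  ), class = "pls1_fit")
}

#' @export
print.pls1_fit <- function(x, ...) {
  cat("PLS1 fit:", length(x$regions), "regions x", length(x$genes), "genes,",
      x$k, "component(s)\n")
  cat(sprintf("  PLS1 variance explained in y: %.2f%%\n",
              x$variance_explained))
  invisible(x)
}

# Fast PLS1 variance explained for a batch of response vectors sharing X.
# Y: n x B matrix of responses. Returns length-B vector of 100 * R^2 of
# each y on its first component score. Scores z = Xc (Xc' yc); the weight
# normalization cancels in the correlation.
pls1_varexp_batch <- function(Xc, Y) {
  Yc <- sweep(Y, 2L, colMeans(Y), "-")
  W <- crossprod(Xc, Yc)                   # p x B
  Z <- Xc %*% W                            # n x B
  Zc <- sweep(Z, 2L, colMeans(Z), "-")
  num <- colSums(Zc * Yc)^2
  den <- colSums(Zc^2) * colSums(Yc^2)
  out <- ifelse(den > 0, 100 * num / den, 0)
  as.numeric(out)
}

#' Resampling null for PLS1 variance explained
#'
#' Re-draws the contrast vector `n_iter` times — `"permute"` shuffles its
#' regional values without replacement, `"bootstrap"` resamples them with
#' replacement — while the expression rows stay fixed, refits PLS1 and
#' records the variance explained. The empirical p-value uses add-one
#' smoothing: `p = (1 + #{null >= observed}) / (1 + n_iter)`.
#'
#' @param x Region x gene matrix.
#' @param y Contrast map or numeric region vector.
#' @param n_iter Number of null draws (default 5000).
#' @param method `"permute"` (default) or `"bootstrap"`.
#' @param seed Integer seed.
#' @param chunk Internal batch size for the vectorized refits.
#' @return An object of class `null_distribution`: list with `observed`,
#'   `null` (length `n_iter`), `n_iterations`, `p`, `method`, `seed`.
#' @export
null_variance_explained <- function(x, y, n_iter = 5000L,
                                    method = c("permute", "bootstrap"),
                                    seed = 1L, chunk = 500L) {
  method <- match.arg(method)
  n_iter <- assert_count(n_iter, "n_iter", min = 100L)
  y <- contrast_values(y, x)
  observed <- fit_pls1(x, y, k = 1L)$variance_explained
  Xc <- sweep(x, 2L, colMeans(x), "-")
  n <- nrow(x)

  null_vals <- withr::with_seed(seed, {
    vals <- numeric(n_iter)
    done <- 0L
    while (done < n_iter) {
      m <- min(chunk, n_iter - done)
      Y <- vapply(seq_len(m), function(i) {
        if (method == "permute") sample(y) else sample(y, n, replace = TRUE)
      }, numeric(n))
      vals[(done + 1L):(done + m)] <- pls1_varexp_batch(Xc, Y)
      done <- done + m
    }
    vals
  })
  p <- (1 + sum(null_vals >= observed)) / (1 + n_iter)
  structure(list(observed = observed, null = null_vals,
                 n_iterations = n_iter, p = p, method = method, seed = seed),
            class = "null_distribution")
}

#' Bootstrap standard errors, z-scores and p-values for PLS1 gene weights
#'
#' Regions are resampled with replacement jointly in `X` and `y`; PLS1 is
#' refit on each replicate and the replicate weight vector is sign-aligned
#' to the original (flipped when their dot product is negative) before
#' accumulating. The per-gene bootstrap SE is the SD of aligned replicate
#' weights; `z = original weight / SE` and two-sided normal p-values follow.
#' Replicates with fewer than 3 distinct regions are redrawn. Genes whose
#' aligned weight never varies but is nonzero get `SE = 0`, `p = 0` and a
#' degeneracy flag.
#'
#' Replicate weights are kept on the cross-covariance scale and divided by
#' the norm of the *original* cross-covariance (one constant), so the SE is
#' expressed on the same scale as the reported unit-norm weights. Dividing
#' each replicate by its own norm instead would couple the genes through a
#' replicate-specific factor and makes the z statistics anticonservative
#' under the null; the constant scaling leaves `z` equal to the plain
#' bootstrap ratio of the raw statistic.
#'
#' Each replicate's (centered) cross-covariance is computed as
#' `X' (c * y - c * mean_b(y))` with `c` the resample counts, so a whole
#' chunk of replicates reduces to one matrix product; results are identical
#' to refitting replicate by replicate.
#'
#' @param x Region x gene matrix.
#' @param y Contrast map or numeric region vector.
#' @param n_boot Number of bootstrap replicates (default 5000).
#' @param seed Integer seed.
#' @param vip_from Optional `pls1_fit` to take VIP scores from; by default
#'   a fresh single-component fit of `x`/`y`.
#' @param chunk Internal batch size.
#' @return An object of class `gene_stats`: data.frame with columns `gene`,
#'   `weight`, `se`, `z`, `p`, `vip`, `degenerate`; attributes `n_boot`,
#'   `seed`, `n_redrawn`.
#' @export
bootstrap_gene_weights <- function(x, y, n_boot = 5000L, seed = 1L,
                                   vip_from = NULL, chunk = 500L) {
  n_boot <- assert_count(n_boot, "n_boot", min = 100L)
  y <- contrast_values(y, x)
  fit <- vip_from %||% fit_pls1(x, y, k = 1L)
  w0 <- stats::setNames(fit$weights[, 1L], fit$genes)
  vip <- compute_vip(fit)
  n <- nrow(x); p <- ncol(x)
  # norm of the original (centered) cross-covariance: the one constant used
  # to put every replicate on the unit-norm weight scale
  xc0 <- sweep(x, 2L, colMeans(x), "-")
  nw0 <- sqrt(sum(crossprod(xc0, y - mean(y))^2))
  if (nw0 < .Machine$double.eps) {
    stop_cortexpls("zero cross-covariance between x and y",
                   "degenerate_response")
  }

  acc_mean <- numeric(p); acc_m2 <- numeric(p)  # Welford accumulators
  n_redrawn <- 0L

  withr::with_seed(seed, {
    done <- 0L
    while (done < n_boot) {
      m <- min(chunk, n_boot - done)
      # counts matrix: n x m, column b = resample counts of each region
      Cnt <- matrix(0, n, m)
      for (b in seq_len(m)) {
        repeat {
          idx <- sample.int(n, n, replace = TRUE)
          if (length(unique(idx)) >= 3L) break
          n_redrawn <- n_redrawn + 1L
        }
        tb <- tabulate(idx, n)
        Cnt[, b] <- tb
      }
      cy <- Cnt * y                          # n x m, c * y
      ybar <- colSums(cy) / n
      V <- cy - sweep(Cnt, 2L, ybar, "*")    # c*y - c*mean_b(y)
      W <- crossprod(x, V) / nw0             # p x m, original-norm scale
      flip <- as.numeric(crossprod(W, w0)) < 0
      if (any(flip)) W[, flip] <- -W[, flip]
      for (b in seq_len(m)) {                # Welford update per replicate
        done <- done + 1L
        delta <- W[, b] - acc_mean
        acc_mean <- acc_mean + delta / done
        acc_m2 <- acc_m2 + delta * (W[, b] - acc_mean)
      }
    }
  })

  se <- sqrt(acc_m2 / (n_boot - 1L))
  degenerate <- se < .Machine$double.eps & abs(w0) > 0
  z <- ifelse(se > 0, w0 / se, ifelse(abs(w0) > 0, Inf, 0))
  pval <- ifelse(degenerate, 0, 2 * stats::pnorm(-abs(z)))

  out <- data.frame(gene = names(w0), weight = as.numeric(w0),
                    se = se, z = z, p = pval, vip = as.numeric(vip),
                    degenerate = degenerate, stringsAsFactors = FALSE)
  attr(out, "n_boot") <- n_boot
  attr(out, "seed") <- seed
  attr(out, "n_redrawn") <- n_redrawn
  class(out) <- c("gene_stats", "data.frame")
  out
}

#' Variable importance in projection (VIP)
#'
#' `VIP_j = sqrt(p * sum_k(SSY_k * (w_jk / ||w_k||)^2) / sum_k(SSY_k))`,
#' where `SSY_k` is the response variance captured by component `k`. For a
#' one-component model this reduces to `sqrt(p) * |w_j| / ||w||`, and the
#' mean of `VIP^2` over genes is exactly 1.
#'
#' @param model A `pls1_fit`.
#' @return Named numeric vector of per-gene VIP scores.
#' @export
compute_vip <- function(model) {
  stopifnot(inherits(model, "pls1_fit"))
  ssy_k <- model$variance_explained_by_component
  if (sum(ssy_k) <= 0) {
    stop_cortexpls("model explains zero response variance", "degenerate_model")
  }
  W <- model$weights                         # unit-norm columns
  p <- nrow(W)
  contrib <- W^2 %*% (ssy_k / sum(ssy_k))
  stats::setNames(sqrt(p * as.numeric(contrib)), rownames(W))
}

#' Select PLS1+ / PLS1- gene sets
#'
#' PLS1+ genes have positive weight, VIP above `vip_cut` and p below
#' `alpha`; PLS1- analogously with negative weight. Thresholds follow the
#' convention VIP > 1, uncorrected p < 0.05; BH-FDR adjustment is available
#' via `adjust = "BH"`.
#'
#' @param stats A `gene_stats` data.frame.
#' @param vip_cut VIP threshold (strict inequality; default 1).
#' @param alpha p-value threshold (strict; default 0.05).
#' @param adjust `"none"` (default) or `"BH"` — p-values adjusted before
#'   thresholding.
#' @return An object of class `gene_selection`: list with `pls1_plus`,
#'   `pls1_minus` (character vectors), `weights` (signed weights of selected
#'   genes), `vip_cut`, `alpha`, `adjust`.
#' @export
select_genes <- function(stats, vip_cut = 1, alpha = 0.05,
                         adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  need <- c("gene", "weight", "p", "vip")
  if (!all(need %in% colnames(stats))) {
    stop_cortexpls("stats must contain gene, weight, p and vip columns",
                   "invalid_argument")
  }
  pv <- if (adjust == "BH") bh_fdr(stats$p) else stats$p
  sig <- stats$vip > vip_cut & pv < alpha
  plus <- stats$gene[sig & stats$weight > 0]
  minus <- stats$gene[sig & stats$weight < 0]
  structure(list(
    pls1_plus = plus, pls1_minus = minus,
    weights = stats::setNames(stats$weight[sig], stats$gene[sig]),
    vip_cut = vip_cut, alpha = alpha, adjust = adjust
  ), class = "gene_selection")
}

#' @export
print.gene_selection <- function(x, ...) {
  cat("PLS1 gene selection: ", length(x$pls1_plus), " PLS1+, ",
      length(x$pls1_minus), " PLS1- (VIP > ", x$vip_cut,
      ", p < ", x$alpha, ", adjust = ", x$adjust, ")\n", sep = "")
  invisible(x)
}

# Coerce a contrast_map / named vector to plain numeric aligned with x rows.
contrast_values <- function(y, x) {
  if (inherits(y, "contrast_map") || (is.data.frame(y) && "t" %in% names(y))) {
    v <- stats::setNames(y$t, y$region)
  } else {
    v <- y
  }
  if (!is.null(names(v)) && !is.null(rownames(x))) {
    if (!all(rownames(x) %in% names(v))) {
      stop_cortexpls("contrast map regions do not cover the expression rows",
                     "alignment_error")
    }
    v <- v[rownames(x)]
  }
  if (length(v) != nrow(x)) {
    stop_cortexpls("response length must match the number of regions",
                   "shape_error")
  }
  as.numeric(v)
}
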