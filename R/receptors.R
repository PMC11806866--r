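#' Spatial correlations between a contrast map and receptor density maps
#'
#' One correlation per receptor column, with a parametric (t-based) p-value
#' or a region-shuffle permutation p-value, plus BH-FDR q-values across
#' receptors. Constant receptor columns are flagged and get `NA`
#' correlations.
#'
#' @param y Contrast map (`contrast_map` or named numeric vector), aligned
#'   with the atlas rows.
#' @param atlas Regions x receptors matrix (e.g. from
#'   [make_receptor_atlas()]).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param null `"parametric"` (default) or `"shuffle"` (permute regions of
#'   `y`, two-sided on |r|).
#' @param n_null Number of shuffle draws (>= 1000 recommended).
#' @param seed Seed for the shuffle null.
#' @return data.frame with columns `receptor`, `system`, `r`, `p`, `q`,
#'   `constant`.
#' @export
correlate_receptors <- function(y, atlas, method = c("pearson", "spearman"),
                                null = c("parametric", "shuffle"),
                                n_null = 1000L, seed = 1L) {
  method <- match.arg(method)
  null <- match.arg(null)
  yv <- contrast_values(y, atlas)
  n <- nrow(atlas)
  if (n < 5L) stop_cortexpls("need at least 5 regions", "invalid_argument")
  systems <- attr(atlas, "systems") %||%
    stats::setNames(rep("unknown", ncol(atlas)), colnames(atlas))

  const <- apply(atlas, 2L, function(col) stats::sd(col) < .Machine$double.eps)
  r <- rep(NA_real_, ncol(atlas))
  p <- rep(NA_real_, ncol(atlas))

  if (null == "shuffle") {
    n_null <- assert_count(n_null, "n_null", min = 100L)
    perms <- withr::with_seed(seed, {
      vapply(seq_len(n_null), function(i) sample(yv), numeric(n))
    })
  }
  for (j in seq_len(ncol(atlas))) {
    if (const[j]) next
    r[j] <- stats::cor(yv, atlas[, j], method = method)
    if (null == "parametric") {
      p[j] <- stats::cor.test(yv, atlas[, j], method = method,
                              exact = FALSE)$p.value
    } else {
      r_null <- suppressWarnings(
        as.numeric(stats::cor(perms, atlas[, j], method = method)))
      p[j] <- (1 + sum(abs(r_null) >= abs(r[j]))) / (1 + n_null)
    }
  }
  q <- rep(NA_real_, length(p))
  q[!is.na(p)] <- bh_fdr(p[!is.na(p)])
  data.frame(receptor = colnames(atlas),
             system = unname(systems[colnames(atlas)]),
             r = r, p = p, q = q, constant = const,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' All-subsets dominance analysis of receptor predictors
#'
#' Decomposes the full-model OLS R^2 of the contrast map on all receptor
#' columns into per-receptor total dominance: for every subset `S` not
#' containing predictor `i`, the increment `R^2(S + i) - R^2(S)` is
#' averaged within each subset size and then across sizes. Total dominances
#' sum exactly to the full-model R^2; relative importance expresses each as
#' a percentage of it. Receptor columns are z-scored before regression for
#' conditioning (R^2 is scale invariant).
#'
#' @param y Contrast map or numeric region vector.
#' @param atlas Regions x receptors matrix, at most 20 columns (the
#'   all-subsets enumeration fits 2^m models).
#' @return An object of class `dominance_result`: data.frame with columns
#'   `receptor`, `system`, `total_dominance`, `relative_importance_pct`,
#'   plus attributes `r2_full` and `n_subsets`.
#' @export
dominance_analysis <- function(y, atlas) {
  yv <- contrast_values(y, atlas)
  m <- ncol(atlas)
  n <- nrow(atlas)
  if (m > 20L) {
    stop_cortexpls(paste0(
      "dominance analysis enumerates 2^m subsets; m = ", m,
      " predictors is too many — pre-select at most 20"), "invalid_argument")
  }
  if (n <= m + 1L) {
    stop_cortexpls("need more regions than predictors + 1", "invalid_argument")
  }
  X <- scale(unclass(atlas)[, , drop = FALSE])
  if (any(!is.finite(X))) {
    stop_cortexpls("constant receptor column: rank-deficient design",
                   "degenerate_design")
  }
  yc <- yv - mean(yv)
  ssy <- sum(yc^2)
  if (ssy < .Machine$double.eps) {
    stop_cortexpls("constant response", "degenerate_response")
  }
  C <- crossprod(X)                        # m x m (X already centered/scaled)
  g <- as.numeric(crossprod(X, yc))        # m
  if (qr(C)$rank < m) {
    stop_cortexpls("rank-deficient full design", "degenerate_design")
  }

  n_subsets <- bitwShiftL(1L, m) - 1L
  r2 <- numeric(n_subsets + 1L)            # indexed by mask + 1; empty = 0
  members <- lapply(seq_len(n_subsets), function(mask) {
    which(bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) > 0L)
  })
  for (mask in seq_len(n_subsets)) {
    s <- members[[mask]]
    r2[mask + 1L] <- sum(g[s] * solve(C[s, s, drop = FALSE], g[s])) / ssy
  }
  r2_full <- r2[n_subsets + 1L]

  # increments averaged within subset size, then across sizes
  total <- numeric(m)
  sizes <- vapply(members, length, integer(1L))
  for (i in seq_len(m)) {
    bit <- bitwShiftL(1L, i - 1L)
    inc_by_size <- numeric(m)              # sizes 0 .. m-1
    cnt_by_size <- numeric(m)
    # empty subset
    inc_by_size[1L] <- r2[bit + 1L]
    cnt_by_size[1L] <- 1
    for (mask in seq_len(n_subsets)) {
      if (bitwAnd(mask, bit) > 0L) next
      sz <- sizes[mask] + 1L               # slot for |S| = sizes[mask]
      inc_by_size[sz] <- inc_by_size[sz] + r2[bitwOr(mask, bit) + 1L] - r2[mask + 1L]
      cnt_by_size[sz] <- cnt_by_size[sz] + 1
    }
    total[i] <- mean(inc_by_size[cnt_by_size > 0] / cnt_by_size[cnt_by_size > 0])
  }

  systems <- attr(atlas, "systems") %||%
    stats::setNames(rep("unknown", m), colnames(atlas))
  out <- data.frame(
    receptor = colnames(atlas),
    system = unname(systems[colnames(atlas)]),
    total_dominance = total,
    relative_importance_pct = 100 * total / r2_full,
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "r2_full") <- r2_full
  attr(out, "n_subsets") <- n_subsets
  class(out) <- c("dominance_result", "data.frame")
  out
}

#' Read a receptor atlas from TSV
#'
#' Expects region rows (label in the first column) and receptor columns;
#' an optional first data row named `system` maps each receptor to its
#' neurotransmitter system.
#'
#' @param path Path to the TSV.
#' @return A `receptor_atlas` matrix.
#' @export
read_receptor_atlas <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  labels <- as.character(dt[[1L]])
  systems <- NULL
  if (labels[1L] == "system") {
    systems <- stats::setNames(as.character(dt[1L, -1L]), colnames(dt)[-1L])
    dt <- dt[-1L, , drop = FALSE]
    labels <- labels[-1L]
  }
  x <- vapply(dt[, -1L, drop = FALSE], function(col) as.numeric(col),
              numeric(length(labels)))
  dimnames(x) <- list(labels, colnames(dt)[-1L])
  if (anyNA(x)) stop_cortexpls("missing values in receptor atlas", "parse_error")
  if (anyDuplicated(colnames(x))) {
    stop_cortexpls("duplicate receptor names", "parse_error")
  }
  structure(x,
            systems = systems %||%
              stats::setNames(rep("unknown", ncol(x)), colnames(x)),
            class = c("receptor_atlas", "matrix", "array"))
}

#' Write a receptor atlas to TSV (with a `system` metadata row)
#' @param atlas A `receptor_atlas`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_receptor_atlas <- function(atlas, path) {
  systems <- attr(atlas, "systems") %||%
    stats::setNames(rep("unknown", ncol(atlas)), colnames(atlas))
  header <- paste(c("region", colnames(atlas)), collapse = "\t")
  sys_row <- paste(c("system", unname(systems[colnames(atlas)])), collapse = "\t")
  data_rows <- vapply(seq_len(nrow(atlas)), function(i) {
    paste(c(rownames(atlas)[i],
            format(unclass(atlas)[i, ], digits = 15, trim = TRUE,
                   scientific = FALSE)), collapse = "\t")
  }, character(1L))
  writeLines(c(header, sys_row, data_rows), path)
  invisible(path)
}
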