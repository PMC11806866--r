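#' Upper hypergeometric tail probability for gene-set overlap
#'
#' `P(X >= overlap)` where `X` counts the intersection of a random
#' `query_size`-subset of the background with a fixed target set of
#' `target_size` genes.
#'
#' @param overlap Observed overlap count.
#' @param query_size,target_size,background_size Set sizes.
#' @return Probability in [0, 1].
#' @export
hypergeometric_tail <- function(overlap, query_size, target_size,
                                background_size) {
  overlap <- assert_count(overlap, "overlap", min = 0L)
  query_size <- assert_count(query_size, "query_size", min = 0L)
  target_size <- assert_count(target_size, "target_size", min = 0L)
  background_size <- assert_count(background_size, "background_size", min = 1L)
  if (overlap > min(query_size, target_size) ||
      query_size > background_size || target_size > background_size) {
    stop_cortexpls("inconsistent counts for the hypergeometric tail",
                   "invalid_argument")
  }
  stats::phyper(overlap - 1L, target_size, background_size - target_size,
                query_size, lower.tail = FALSE)
}

#' Permutation test for overlap between a query gene set and a target list
#'
#' Draws `n_perm` random gene sets of the query's size uniformly without
#' replacement from the background, counts their overlap with the target
#' list (restricted to the background first), and reports the one-sided
#' (enrichment) empirical p-value with add-one smoothing:
#' `p = (1 + #{null >= observed}) / (1 + n_perm)`.
#'
#' @param query Character vector of query genes (must lie in `background`).
#' @param target Character vector of target (e.g. pathology-related) genes.
#' @param background Character vector: the gene universe to sample from.
#' @param n_perm Number of random draws (default 1000).
#' @param seed Integer seed.
#' @return An object of class `permutation_result`: list with `observed`,
#'   `null` (integer vector), `p`, `query_size`, `target_size_raw`,
#'   `target_size` (after restriction), `background_size`, `n_perm`, `seed`.
#' @export
permutation_overlap_test <- function(query, target, background,
                                     n_perm = 1000L, seed = 1L) {
  n_perm <- assert_count(n_perm, "n_perm", min = 100L)
  query <- unique(canonical_symbols(query))
  target <- unique(canonical_symbols(target))
  background <- unique(canonical_symbols(background))
  missing <- setdiff(query, background)
  if (length(missing)) {
    stop_cortexpls(
      paste0("query genes missing from background: ",
             paste(utils::head(missing, 5L), collapse = ", "),
             if (length(missing) > 5L) ", ..."),
      "consistency_error"
    )
  }
  target_raw <- length(target)
  target <- intersect(target, background)
  observed <- length(intersect(query, target))

  null_counts <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      length(intersect(sample(background, length(query)), target))
    }, integer(1L))
  })
  p <- (1 + sum(null_counts >= observed)) / (1 + n_perm)
  structure(list(observed = observed, null = null_counts, p = p,
                 query_size = length(query), target_size_raw = target_raw,
                 target_size = length(target),
                 background_size = length(background),
                 n_perm = n_perm, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("Permutation overlap test: observed ", x$observed, " of query ",
      x$query_size, " vs target ", x$target_size, " (background ",
      x$background_size, "); p = ", format(x$p), " [", x$n_perm,
      " draws]\n", sep = "")
  invisible(x)
}

#' Over-representation analysis against a gene-set collection
#'
#' Hypergeometric enrichment of a query gene set in each term of a GMT-style
#' collection, with BH-FDR q-values across terms. Every term is intersected
#' with the background before testing.
#'
#' @param query Character vector of query genes (subset of `background`).
#' @param terms Named list of character vectors (e.g. from [read_gmt()]).
#' @param background Character vector: the gene universe.
#' @param q_threshold Significance threshold on the BH-FDR q-value
#'   (default 0.05).
#' @return data.frame with columns `term`, `term_size`, `overlap`,
#'   `overlap_genes` (comma-separated), `p`, `q`, `significant`; attribute
#'   `background_size`.
#' @export
ora <- function(query, terms, background, q_threshold = 0.05) {
  if (!length(terms)) {
    stop_cortexpls("empty term collection", "invalid_argument")
  }
  if (is.null(names(terms))) {
    stop_cortexpls("terms must be a named list", "invalid_argument")
  }
  q_threshold <- assert_number(q_threshold, "q_threshold", 0, 1)
  query <- unique(canonical_symbols(query))
  background <- unique(canonical_symbols(background))
  missing <- setdiff(query, background)
  if (length(missing)) {
    stop_cortexpls(
      paste0("query genes missing from background: ",
             paste(utils::head(missing, 5L), collapse = ", ")),
      "consistency_error"
    )
  }
  bg_n <- length(background)
  rows <- lapply(names(terms), function(nm) {
    term <- intersect(unique(canonical_symbols(terms[[nm]])), background)
    ov <- intersect(query, term)
    p <- hypergeometric_tail(length(ov), length(query), length(term), bg_n)
    data.frame(term = nm, term_size = length(term), overlap = length(ov),
               overlap_genes = paste(sort(ov), collapse = ","),
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out$significant <- out$q < q_threshold
  attr(out, "background_size") <- bg_n
  attr(out, "q_threshold") <- q_threshold
  out
}

#' Benjamini-Hochberg FDR q-values
#'
#' Step-up adjustment: `q_(i) = min_(j >= i) min(1, p_(j) * m / j)` on the
#' ascending order statistics, returned in the original order (delegates to
#' [stats::p.adjust()] after validation).
#'
#' @param pvalues Numeric vector of p-values in [0, 1].
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (!is.numeric(pvalues) || anyNA(pvalues) ||
      any(pvalues < 0) || any(pvalues > 1)) {
    stop_cortexpls("p-values must be numeric in [0, 1] with no NAs",
                   "invalid_argument")
  }
  stats::p.adjust(pvalues, method = "BH")
}
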