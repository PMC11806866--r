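# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_cortexpls <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "cortexpls_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min) {
    stop_cortexpls(
      sprintf("`%s` must be a single integer >= %d (got %s)", name, min,
              paste(format(x), collapse = ", ")),
      "invalid_argument"
    )
  }
  as.integer(x)
}

assert_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    stop_cortexpls(
      sprintf("`%s` must be a single number in [%s, %s]", name, format(min), format(max)),
      "invalid_argument"
    )
  }
  as.numeric(x)
}

# Column-center a matrix; returns list(x = centered, mean = colmeans).
center_cols <- function(x) {
  mu <- colMeans(x)
  list(x = sweep(x, 2L, mu, "-"), mean = mu)
}

# Region labels used by every synthetic generator, zero-padded for stable
# lexicographic order.
region_labels <- function(n) sprintf("region_%03d", seq_len(n))

gene_labels <- function(p) sprintf("GENE%05d", seq_len(p))

# Canonical gene-symbol form: uppercase, no surrounding whitespace.
canonical_symbols <- function(x) toupper(trimws(as.character(x)))

# Smoothed standard-normal noise along a 1-D ordering: moving average over a
# window, rescaled to unit SD. Gives spatially autocorrelated region maps.
smooth_noise <- function(n, window = max(3L, round(n / 10))) {
  e <- stats::rnorm(n + window - 1L)
  s <- stats::filter(e, rep(1 / window, window), sides = 1L)
  s <- as.numeric(s[window:(n + window - 1L)])
  s <- s - mean(s)
  sd_s <- stats::sd(s)
  if (sd_s < .Machine$double.eps) s else s / sd_s
}

write_tsv_file <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}
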