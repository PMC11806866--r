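#' Read a region-by-gene expression matrix from delimited text
#'
#' Expects one header row and one label column. Orientation is
#' auto-detected when `transpose_if_needed = TRUE`: the matrix is stored with
#' regions as rows, and a file with more rows than columns (genes as rows) is
#' transposed. Duplicate gene symbols are rejected; rows or columns
#' containing missing values are dropped with a message.
#'
#' @param path Path to a TSV/CSV file.
#' @param transpose_if_needed Transpose when the file appears to have genes
#'   as rows.
#' @return Numeric matrix, regions as rows (rownames = region labels,
#'   colnames = canonical gene symbols).
#' @export
read_expression <- function(path, transpose_if_needed = TRUE) {
  dt <- data.table::fread(path, header = TRUE)  # keeps duplicate headers
  if (ncol(dt) < 2L) {
    stop_cortexpls("expression file needs a label column plus data columns",
                   "parse_error")
  }
  labels <- as.character(dt[[1L]])
  vals <- as.list(dt)[-1L]

  non_num <- !vapply(vals, is.numeric, logical(1L))
  if (any(non_num)) {
    j <- which(non_num)[1L]
    col <- suppressWarnings(as.numeric(vals[[j]]))
    i <- which(is.na(col) & !is.na(vals[[j]]))[1L]
    stop_cortexpls(
      sprintf("non-numeric cell at row %s, column '%s'",
              ifelse(is.na(i), "?", i), names(vals)[j]),
      "parse_error"
    )
  }
  x <- do.call(cbind, vals)
  rownames(x) <- labels

  if (transpose_if_needed && nrow(x) > ncol(x)) {
    x <- t(x)
  }
  colnames(x) <- canonical_symbols(colnames(x))

  dup <- colnames(x)[duplicated(colnames(x))]
  if (length(dup)) {
    stop_cortexpls(
      paste0("duplicated gene column(s): ",
             paste(unique(dup), collapse = ", ")),
      "duplicate_gene_error"
    )
  }

  bad_col <- colSums(is.na(x)) > 0L
  if (any(bad_col)) {
    message(sum(bad_col), " gene column(s) dropped for missing values")
    x <- x[, !bad_col, drop = FALSE]
  }
  bad_row <- rowSums(is.na(x)) > 0L
  if (any(bad_row)) {
    message(sum(bad_row), " region row(s) dropped for missing values")
    x <- x[!bad_row, , drop = FALSE]
  }
  if (nrow(x) < 3L) {
    stop_cortexpls("need at least 3 regions after validation", "parse_error")
  }
  x
}

#' Write an expression matrix (regions as rows) to TSV
#' @param x Numeric matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  df <- data.frame(region = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE)
  write_tsv_file(df, path)
}

#' Align an expression matrix and a contrast map on shared region labels
#'
#' Both inputs are restricted and reordered to the intersection of their
#' region labels; the expression matrix's original region order is kept.
#'
#' @param x Expression matrix (regions as rows, rownames set).
#' @param y A contrast map (`contrast_map` data.frame with a `region`
#'   column) or any named numeric region vector.
#' @return List with elements `x` and `y`, both restricted to the common
#'   regions in `x`'s order.
#' @export
align_regions <- function(x, y) {
  x_labs <- rownames(x)
  if (is.data.frame(y)) {
    y_labs <- as.character(y$region)
  } else {
    y_labs <- names(y)
  }
  if (is.null(x_labs) || is.null(y_labs)) {
    stop_cortexpls("both inputs need region labels", "alignment_error")
  }
  common <- x_labs[x_labs %in% y_labs]
  if (length(common) < 3L) {
    stop_cortexpls(
      sprintf("fewer than 3 shared region labels (x e.g. %s; y e.g. %s)",
              paste(utils::head(x_labs, 3L), collapse = ","),
              paste(utils::head(y_labs, 3L), collapse = ",")),
      "alignment_error"
    )
  }
  x2 <- x[common, , drop = FALSE]
  if (is.data.frame(y)) {
    y2 <- y[match(common, y_labs), , drop = FALSE]
    rownames(y2) <- NULL
    for (a in c("df", "target", "reference", "sign_convention")) {
      attr(y2, a) <- attr(y, a)
    }
  } else {
    y2 <- y[match(common, y_labs)]
  }
  list(x = x2, y = y2)
}

#' Standardize expression columns (genes)
#'
#' @param x Expression matrix (regions x genes).
#' @param mode `"center"` (per-gene mean 0), `"zscore"` (mean 0, SD 1;
#'   constant genes dropped with a warning) or `"none"`.
#' @return Standardized matrix.
#' @export
column_standardize <- function(x, mode = c("center", "zscore", "none")) {
  mode <- match.arg(mode)
  if (mode == "none") return(x)
  if (nrow(x) < 2L) stop_cortexpls("need >= 2 regions", "invalid_argument")
  xc <- sweep(x, 2L, colMeans(x), "-")
  if (mode == "center") return(xc)
  sds <- apply(x, 2L, stats::sd)
  const <- sds < .Machine$double.eps
  if (any(const)) {
    warning(sum(const), " constant gene column(s) dropped under zscore")
    xc <- xc[, !const, drop = FALSE]
    sds <- sds[!const]
  }
  sweep(xc, 2L, sds, "/")
}

#' Read a gene list (one symbol per line)
#' @param path Path to a text file.
#' @return Character vector of canonical (uppercased, trimmed) symbols.
#' @export
read_gene_list <- function(path) {
  x <- canonical_symbols(readLines(path, warn = FALSE))
  x[nzchar(x)]
}

#' Write a gene list, one symbol per line
#' @param genes Character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(canonical_symbols(genes), path)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' GMT is tab-separated: set name, description, then member symbols.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors (canonical symbols).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3L) {
      stop_cortexpls("GMT line needs name, description and >= 1 member",
                     "parse_error")
    }
    unique(canonical_symbols(f[-(1:2)]))
  })
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 1L)
  sets
}

#' Write a GMT gene-set collection
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop_cortexpls("every gene set needs a name", "invalid_argument")
  }
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- mapply(function(nm, desc, members) {
    paste(c(nm, desc, canonical_symbols(members)), collapse = "\t")
  }, names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}
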