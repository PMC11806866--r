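#' Compare PLS1 gene selections across genetic forms
#'
#' For every pair of forms, the shared genes are the intersection of their
#' significant gene sets (`pls1_plus` union `pls1_minus`); each shared gene
#' is concordant when its weight sign class matches across the pair and
#' discordant otherwise. Also reports the all-forms intersection and an
#' upset-style membership matrix.
#'
#' @param selections Named list (>= 2 entries) of `gene_selection` objects,
#'   one per genetic form.
#' @return An object of class `concordance_table`: list with `pairs`
#'   (data.frame: `form_a`, `form_b`, `n_shared`, `n_concordant`,
#'   `n_discordant`, `concordance`), `shared_genes` (per-pair data.frames
#'   with per-gene signs), `all_forms_intersection` (character),
#'   `membership` (genes x forms 0/1 matrix).
#' @export
compare_selections <- function(selections) {
  if (length(selections) < 2L || is.null(names(selections))) {
    stop_cortexpls("need a named list of >= 2 selections", "invalid_argument")
  }
  forms <- names(selections)
  sig_sets <- lapply(selections, function(s) {
    stopifnot(inherits(s, "gene_selection"))
    union(s$pls1_plus, s$pls1_minus)
  })
  empty <- vapply(sig_sets, length, integer(1L)) == 0L
  if (any(empty)) {
    warning("form(s) with empty selection: ",
            paste(forms[empty], collapse = ", "))
  }
  sign_of <- function(s, genes) {
    ifelse(genes %in% s$pls1_plus, 1L, ifelse(genes %in% s$pls1_minus, -1L, 0L))
  }

  combos <- utils::combn(forms, 2L, simplify = FALSE)
  shared_genes <- list()
  pairs <- do.call(rbind, lapply(combos, function(fp) {
    a <- fp[1L]; b <- fp[2L]
    shared <- sort(intersect(sig_sets[[a]], sig_sets[[b]]))
    sa <- sign_of(selections[[a]], shared)
    sb <- sign_of(selections[[b]], shared)
    conc <- sa == sb
    shared_genes[[paste(a, b, sep = "|")]] <<- data.frame(
      gene = shared, sign_a = sa, sign_b = sb, concordant = conc,
      stringsAsFactors = FALSE
    )
    data.frame(form_a = a, form_b = b, n_shared = length(shared),
               n_concordant = sum(conc), n_discordant = sum(!conc),
               concordance = if (length(shared)) mean(conc) else NA_real_,
               stringsAsFactors = FALSE)
  }))

  all_genes <- sort(Reduce(union, sig_sets))
  membership <- vapply(forms, function(f) {
    as.integer(all_genes %in% sig_sets[[f]])
  }, integer(length(all_genes)))
  if (length(all_genes)) rownames(membership) <- all_genes

  structure(list(
    pairs = pairs,
    shared_genes = shared_genes,
    all_forms_intersection = sort(Reduce(intersect, sig_sets)),
    membership = membership
  ), class = "concordance_table")
}

#' @export
print.concordance_table <- function(x, ...) {
  cat("Cross-form concordance:\n")
  print(x$pairs, row.names = FALSE)
  cat("All-forms intersection:", length(x$all_forms_intersection), "gene(s)\n")
  invisible(x)
}
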