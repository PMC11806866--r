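#!/usr/bin/env Rscript
# Stage 6 — shared transcriptional signatures across genetic forms.
#
# Intersects the significant PLS1 gene sets of every pair of genetic
# forms, labels shared genes as sign-concordant or discordant, and writes
# the pairwise table, the per-pair shared-gene lists, and an upset-style
# membership matrix.

suppressPackageStartupMessages(library(cortexpls))
dir.create("results/crossform", recursive = TRUE, showWarnings = FALSE)

selections <- list()
for (gf in list.files("results/pls", "^genes_.*\\.tsv$", full.names = TRUE)) {
  form <- sub("^genes_(.*)\\.tsv$", "\\1", basename(gf))
  gtab <- data.table::fread(gf, data.table = FALSE)
  sel <- structure(list(
    pls1_plus = gtab$gene[gtab$selected == "plus"],
    pls1_minus = gtab$gene[gtab$selected == "minus"],
    weights = setNames(gtab$weight[gtab$selected != "no"],
                       gtab$gene[gtab$selected != "no"]),
    vip_cut = 1, alpha = 0.05, adjust = "none"
  ), class = "gene_selection")
  selections[[form]] <- sel
}
stopifnot(length(selections) >= 2L)

ct <- compare_selections(selections)
data.table::fwrite(ct$pairs, "results/crossform/pairs.tsv", sep = "\t")
for (pair in names(ct$shared_genes)) {
  fn <- sprintf("results/crossform/shared_%s.tsv", gsub("\\|", "_", pair))
  data.table::fwrite(ct$shared_genes[[pair]], fn, sep = "\t")
}
data.table::fwrite(
  data.frame(gene = rownames(ct$membership), ct$membership, check.names = FALSE),
  "results/crossform/membership.tsv", sep = "\t")

print(ct)
message(sprintf(
  "shared across all %d forms: %d genes; pairwise concordance %s",
  length(selections), length(ct$all_forms_intersection),
  paste(sprintf("%s-%s %.2f", ct$pairs$form_a, ct$pairs$form_b,
                ct$pairs$concordance), collapse = "; ")))
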