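#!/usr/bin/env Rscript
# Stage 5 — pathology-related gene enrichment.
#
# Tests each form's significant PLS1 gene set for overlap with the two
# synthetic pathology lists via the 1,000-draw random-gene-set permutation
# null (background = the 2,000-gene expression universe), and runs a small
# over-representation analysis against a GMT collection built from the
# planted truth.

suppressPackageStartupMessages(library(cortexpls))
dir.create("results/enrichment", recursive = TRUE, showWarnings = FALSE)

seed <- 20260928L
expr_genes <- colnames(read_expression("results/inputs/expression.tsv"))
pathology <- list(
  tdp43_synthetic = read_gene_list("results/inputs/pathology_tdp43_synthetic.txt"),
  tau_synthetic = read_gene_list("results/inputs/pathology_tau_synthetic.txt")
)
truth <- jsonlite::read_json("results/inputs/truth.json", simplifyVector = TRUE)

# GMT collection for the ORA demonstration: the planted signature plus
# random sets, all drawn from the expression universe
terms <- withr::with_seed(seed + 40L, list(
  planted_component = truth$planted_gene_ids,
  random_small = sample(expr_genes, 100L),
  random_large = sample(expr_genes, 400L)
))
write_gmt(terms, "results/enrichment/terms_synthetic.gmt")

rows <- list()
for (gf in list.files("results/pls", "^genes_.*\\.tsv$", full.names = TRUE)) {
  form <- sub("^genes_(.*)\\.tsv$", "\\1", basename(gf))
  gtab <- data.table::fread(gf, data.table = FALSE)
  sig <- gtab$gene[gtab$selected != "no"]
  if (!length(sig)) next
  for (pn in names(pathology)) {
    pr <- permutation_overlap_test(sig, pathology[[pn]], expr_genes,
                                   n_perm = 1000L, seed = seed + 30L)
    rows[[paste(form, pn)]] <- data.frame(
      form = form, pathology = pn, query = pr$query_size,
      target = pr$target_size, observed = pr$observed,
      expected = pr$query_size * pr$target_size / pr$background_size,
      p = pr$p)
    message(sprintf(
      "[%s vs %s] observed overlap %d (chance expectation %.1f), permutation p = %.3g",
      form, pn, pr$observed,
      pr$query_size * pr$target_size / pr$background_size, pr$p))
  }
  res <- ora(sig, read_gmt("results/enrichment/terms_synthetic.gmt"), expr_genes)
  data.table::fwrite(res, sprintf("results/enrichment/ora_%s.tsv", form),
                     sep = "\t")
  message(sprintf("[%s] ORA: %d/%d terms significant at q < 0.05 (top: %s, q = %.3g)",
                  form, sum(res$significant), nrow(res),
                  res$term[which.min(res$q)], min(res$q)))
}
data.table::fwrite(do.call(rbind, rows), "results/enrichment/overlap_tests.tsv",
                   sep = "\t")
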