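#!/usr/bin/env Rscript
# Stage 4 — neurotransmitter receptor mapping.
#
# Correlates each form's contrast map with the 15 receptor/transporter
# density maps (Pearson, BH-FDR across receptors) and decomposes the
# full-model R^2 over receptors with all-subsets dominance analysis
# (2^15 = 32,768 OLS fits per form).

suppressPackageStartupMessages(library(cortexpls))
dir.create("results/receptors", recursive = TRUE, showWarnings = FALSE)

atlas <- read_receptor_atlas("results/inputs/receptors.tsv")
contrast_files <- list.files("results/signature", "^contrast_.*\\.tsv$",
                             full.names = TRUE)
for (cf in contrast_files) {
  form <- sub("^contrast_(.*)\\.tsv$", "\\1", basename(cf))
  cm <- data.table::fread(cf, data.table = FALSE)
  al <- align_regions(unclass(atlas), setNames(cm$t, cm$region))
  atl <- structure(al$x, systems = attr(atlas, "systems"),
                   class = c("receptor_atlas", "matrix", "array"))

  corr <- correlate_receptors(al$y, atl)
  dom <- dominance_analysis(al$y, atl)
  data.table::fwrite(corr, sprintf("results/receptors/correlations_%s.tsv", form),
                     sep = "\t")
  data.table::fwrite(as.data.frame(dom),
                     sprintf("results/receptors/dominance_%s.tsv", form),
                     sep = "\t")

  top_c <- corr[which.max(abs(corr$r)), ]
  top_d <- dom[which.max(dom$total_dominance), ]
  message(sprintf(
    "[%s] strongest spatial correlation: %s (%s) r = %+.2f (q = %.3g); top dominance: %s (%.1f%% of full-model R^2 = %.2f)",
    form, top_c$receptor, top_c$system, top_c$r, top_c$q,
    top_d$receptor, top_d$relative_importance_pct, attr(dom, "r2_full")))
}
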