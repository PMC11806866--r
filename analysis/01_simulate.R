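#!/usr/bin/env Rscript
# Stage 1 — simulate the study inputs.
#
# Generates the full set of pipeline inputs with known planted structure:
# a 100-region x 2,000-gene expression matrix whose first latent factor
# carries 200 planted genes, a cohort with 172 controls, 117 sporadic
# patients and three genetic arms sized like the study population
# (32 / 11 / 13), a 15-receptor density atlas with planted spatial
# correlations, and two synthetic pathology gene lists. Everything is
# written under results/inputs/ as plain text so the later stages (and any
# outside tool) can consume it.

suppressPackageStartupMessages(library(cortexpls))

seed <- 20260928L
dir.create("results/inputs", recursive = TRUE, showWarnings = FALSE)

gen <- make_expression(n_regions = 100L, n_genes = 2000L, n_latent = 3L,
                       noise_sd = 0.5, n_planted = 200L, seed = seed)
expr <- gen$expression
atrophy <- setNames(gen$truth$factors[, 1L], rownames(expr))
write_expression(expr, "results/inputs/expression.tsv")
write_input(list(planted_gene_ids = gen$truth$planted_gene_ids,
                 seed = seed), "results/inputs/truth.json")

# one genetic arm per form; controls + sporadic come from the first call
forms <- list(C9orf72 = list(n = 32L, effect = 1.5),
              GRN = list(n = 11L, effect = 1.2),
              MAPT = list(n = 13L, effect = 1.2))
cohorts <- lapply(seq_along(forms), function(i) {
  make_cohort(172L, 117L, forms[[i]]$n, atrophy_map = atrophy,
              effect = forms[[i]]$effect, seed = seed + i,
              genetic_label = names(forms)[i])
})
subjects <- cohorts[[1L]]
extra <- do.call(rbind, lapply(cohorts[-1L], function(cc) {
  cc[!(cc$group %in% c("control", "sporadic")), , drop = FALSE]
}))
labs <- attr(subjects, "region_labels")
subjects <- rbind(subjects, extra)
subjects$subject_id <- sprintf("sub_%04d", seq_len(nrow(subjects)))
attr(subjects, "region_labels") <- labs
write_input(subjects, "results/inputs/subjects.tsv")

targets <- c(0.6, -0.4, 0.3, 0.2, -0.2, 0.5, 0.1, -0.1, 0.0,
             0.4, -0.3, 0.2, -0.5, 0.3, 0.0)
atlas <- make_receptor_atlas(atrophy, targets, seed = seed + 10L)
write_receptor_atlas(atlas, "results/inputs/receptors.tsv")

# pathology lists planted against the known signature genes
write_gene_list(make_pathology_sets(colnames(expr), gen$truth$planted_gene_ids,
                                    overlap_fraction = 0.4, set_size = 400L,
                                    seed = seed + 20L),
                "results/inputs/pathology_tdp43_synthetic.txt")
write_gene_list(make_pathology_sets(colnames(expr), gen$truth$planted_gene_ids,
                                    overlap_fraction = 0.05, set_size = 400L,
                                    seed = seed + 21L),
                "results/inputs/pathology_tau_synthetic.txt")

message(sprintf(
  "simulated: %d x %d expression (200 planted genes), %d subjects (%s), 15 receptors",
  nrow(expr), ncol(expr), nrow(subjects),
  paste(names(table(subjects$group)), table(subjects$group),
        sep = "=", collapse = ", ")))
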