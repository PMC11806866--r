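#!/usr/bin/env Rscript
# Stage 2 — cortical atrophy signatures.
#
# Fits the per-region w-score model (thickness ~ age + sex) on the control
# arm, converts every subject to w-scores, and derives one per-region
# t-statistic contrast map per genetic form (form vs sporadic, adjusting
# for disease duration). Writes contrast_<form>.tsv (+ JSON metadata).

suppressPackageStartupMessages(library(cortexpls))
dir.create("results/signature", recursive = TRUE, showWarnings = FALSE)

subjects <- data.table::fread("results/inputs/subjects.tsv", data.table = FALSE)
controls <- subjects[subjects$group == "control", ]
model <- fit_wscore_model(controls)
message(sprintf("w-score model: %d controls, %d regions; mean residual SD %.3f mm",
                model$n_controls, length(model$regions), mean(model$resid_sd)))

wsc <- apply_wscore(model, subjects)
forms <- setdiff(unique(subjects$group), c("control", "sporadic"))
for (f in forms) {
  cm <- compute_contrast(wsc, subjects$group, subjects$duration, f, "sporadic")
  write_contrast(cm, sprintf("results/signature/contrast_%s.tsv", f))
  message(sprintf("[%s] contrast: %d regions, df = %d, mean t = %+.2f, min t = %+.2f",
                  f, nrow(cm), attr(cm, "df"), mean(cm$t), min(cm$t)))
}
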