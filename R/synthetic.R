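#' Synthetic region-by-gene expression matrix with planted structure
#'
#' Generates a low-rank, spatially structured expression matrix
#' `X = S %*% t(G) + noise`, where `S` holds `n_latent` smooth spatial factors
#' over a 1-D ordering of regions (sinusoids plus smoothed noise, mimicking
#' the anterior-posterior expression gradients seen in cortical
#' transcriptomes) and `G` holds per-gene loadings. The first `n_planted`
#' genes (before column shuffling) load predominantly on factor 1, so any
#' downstream map aligned with factor 1 has a known "true" gene signature.
#' Gene columns are randomly reordered; the planted identities are recorded
#' in the returned truth object.
#'
#' @param n_regions Number of cortical regions (rows).
#' @param n_genes Number of genes (columns).
#' @param n_latent Number of latent spatial factors (>= 1).
#' @param noise_sd Standard deviation of i.i.d. Gaussian measurement noise.
#' @param n_planted Number of genes loading predominantly on factor 1.
#' @param seed Integer seed; the call is deterministic given the seed.
#' @param planted_loading_mean Mean absolute loading of planted genes on
#'   factor 1 (random sign, so planted genes split into positively and
#'   negatively associated sets).
#' @param background_loading_sd SD of background loadings on every factor.
#'
#' @return A list with elements `expression` (numeric matrix, regions x genes,
#'   dimnames set) and `truth` (class `synthetic_truth`): planted gene ids,
#'   planted sign per planted gene, the spatial factors `S`, loadings `G`,
#'   and the seed.
#' @export
make_expression <- function(n_regions, n_genes, n_latent = 3L, noise_sd = 0.5,
                            n_planted = 0L, seed = 1L,
                            planted_loading_mean = 1.5,
                            background_loading_sd = 0.3) {
  n_regions <- assert_count(n_regions, "n_regions")
  n_genes <- assert_count(n_genes, "n_genes")
  n_latent <- assert_count(n_latent, "n_latent")
  n_planted <- assert_count(n_planted, "n_planted", min = 0L)
  noise_sd <- assert_number(noise_sd, "noise_sd", min = 0)
  if (n_planted > n_genes) {
    stop_cortexpls("n_planted must not exceed n_genes", "invalid_argument")
  }
  if (n_regions < n_latent) {
    stop_cortexpls("n_regions must be >= n_latent", "invalid_argument")
  }

  withr::with_seed(seed, {
    t_pos <- seq_len(n_regions) / n_regions
    S <- vapply(seq_len(n_latent), function(k) {
      phase <- stats::runif(1L, 0, 2 * pi)
      f <- sin(pi * k * t_pos + phase) + 0.5 * smooth_noise(n_regions)
      f <- f - mean(f)
      f / stats::sd(f)
    }, numeric(n_regions))

    G <- matrix(stats::rnorm(n_genes * n_latent, sd = background_loading_sd),
                n_genes, n_latent)
    planted_sign <- integer(0)
    if (n_planted > 0L) {
      planted_sign <- sample(c(-1L, 1L), n_planted, replace = TRUE)
      G[seq_len(n_planted), 1L] <- planted_sign *
        stats::rnorm(n_planted, mean = planted_loading_mean, sd = 0.2)
    }

    X <- S %*% t(G)
    if (noise_sd > 0) {
      X <- X + matrix(stats::rnorm(n_regions * n_genes, sd = noise_sd),
                      n_regions, n_genes)
    }

    genes <- gene_labels(n_genes)
    ord <- sample.int(n_genes)
    X <- X[, ord, drop = FALSE]
    G <- G[ord, , drop = FALSE]
    colnames(X) <- genes[ord]
    rownames(X) <- region_labels(n_regions)
    rownames(G) <- genes[ord]

    truth <- structure(list(
      planted_gene_ids = genes[seq_len(n_planted)],
      planted_sign = stats::setNames(planted_sign,
                                     genes[seq_len(n_planted)][seq_along(planted_sign)]),
      factors = structure(S, dimnames = list(rownames(X), NULL)),
      loadings = G,
      noise_sd = noise_sd,
      seed = seed
    ), class = "synthetic_truth")

    list(expression = X, truth = truth)
  })
}

#' Synthetic subject cohort with a planted group atrophy pattern
#'
#' Simulates per-subject regional cortical thickness for a control arm, an
#' "apparently sporadic" patient arm, and one genetic patient arm. Controls
#' follow `thickness = baseline + age_slope * (age - 60) + sex_effect * sex +
#' noise` per region. The genetic arm is additionally shifted by
#' `effect * noise_sd * atrophy_map` and the sporadic arm by
#' `sporadic_effect * noise_sd * sporadic_map` (a distinct smooth map drawn
#' internally), so `effect` is expressed in units of the within-group noise
#' SD — i.e. in w-score units. Covariates: age ~ Uniform(45, 80) years,
#' sex ~ Bernoulli(0.5) coded 0/1, disease duration ~ Gamma with mean 3.9 and
#' SD 2.7 years for patients (controls have duration 0).
#'
#' @param n_controls,n_sporadic,n_genetic Arm sizes; `n_controls >= 10`.
#' @param atrophy_map Numeric vector (one value per region) giving the
#'   spatial pattern of the genetic-arm shift.
#' @param effect Planted group effect size in w-score (noise-SD) units.
#' @param seed Integer seed.
#' @param genetic_label Group label for the genetic arm.
#' @param sporadic_effect Amplitude of the sporadic arm's own (distinct)
#'   atrophy map, in the same units; defaults to half of `effect`.
#' @param noise_sd Within-subject regional thickness noise SD in mm.
#' @param baseline_mm Mean cortical thickness in mm around which regional
#'   baselines vary.
#'
#' @return A `data.frame` (one row per subject) with columns `subject_id`,
#'   `group`, `age`, `sex`, `duration`, then one thickness column per region.
#'   Attributes: `region_labels`, `truth` (planted maps, effects, seed).
#' @export
make_cohort <- function(n_controls, n_sporadic, n_genetic, atrophy_map,
                        effect, seed = 1L, genetic_label = "genetic",
                        sporadic_effect = effect / 2, noise_sd = 0.15,
                        baseline_mm = 2.5) {
  n_controls <- assert_count(n_controls, "n_controls", min = 10L)
  n_sporadic <- assert_count(n_sporadic, "n_sporadic", min = 0L)
  n_genetic <- assert_count(n_genetic, "n_genetic", min = 0L)
  effect <- assert_number(effect, "effect")
  noise_sd <- assert_number(noise_sd, "noise_sd", min = 1e-8)
  if (!is.numeric(atrophy_map) || length(atrophy_map) < 2L) {
    stop_cortexpls("atrophy_map must be a numeric vector of region values",
                   c("shape_error", "invalid_argument"))
  }
  n_regions <- length(atrophy_map)
  regions <- names(atrophy_map) %||% region_labels(n_regions)

  withr::with_seed(seed, {
    baseline <- baseline_mm + 0.3 * smooth_noise(n_regions)
    sporadic_map <- smooth_noise(n_regions)

    n_total <- n_controls + n_sporadic + n_genetic
    group <- rep(c("control", "sporadic", genetic_label),
                 c(n_controls, n_sporadic, n_genetic))
    age <- stats::runif(n_total, 45, 80)
    sex <- stats::rbinom(n_total, 1L, 0.5)
    # Gamma matching the cohort's duration mean 3.9 y, SD 2.7 y.
    dur_shape <- (3.9 / 2.7)^2
    duration <- ifelse(group == "control", 0,
                       stats::rgamma(n_total, shape = dur_shape,
                                     rate = dur_shape / 3.9))

    pred <- outer(rep(1, n_total), baseline) +
      (-0.01) * (age - 60) + 0.08 * sex
    shift <- matrix(0, n_total, n_regions)
    shift[group == genetic_label, ] <- matrix(effect * noise_sd * atrophy_map,
                                              n_genetic, n_regions, byrow = TRUE)
    shift[group == "sporadic", ] <- matrix(sporadic_effect * noise_sd * sporadic_map,
                                           n_sporadic, n_regions, byrow = TRUE)
    thick <- pred + shift +
      matrix(stats::rnorm(n_total * n_regions, sd = noise_sd), n_total, n_regions)
    colnames(thick) <- regions

    out <- data.frame(
      subject_id = sprintf("sub_%04d", seq_len(n_total)),
      group = group, age = age, sex = sex, duration = duration,
      stringsAsFactors = FALSE
    )
    out <- cbind(out, as.data.frame(thick))
    attr(out, "region_labels") <- regions
    attr(out, "truth") <- list(
      atrophy_map = stats::setNames(atrophy_map, regions),
      sporadic_map = stats::setNames(sporadic_map, regions),
      effect = effect, sporadic_effect = sporadic_effect,
      noise_sd = noise_sd, baseline = stats::setNames(baseline, regions),
      age_slope = -0.01, sex_effect = 0.08, seed = seed
    )
    out
  })
}

# The 15 receptor/transporter maps spanning 5 neurotransmitter systems used
# as the default synthetic atlas layout.
receptor_systems_default <- function() {
  c("5HT1A" = "serotonin", "5HT1B" = "serotonin", "5HT2A" = "serotonin",
    "5HT4" = "serotonin", "5HT6" = "serotonin", "5HTT" = "serotonin",
    "A4B2" = "acetylcholine", "M1" = "acetylcholine", "VACHT" = "acetylcholine",
    "D1" = "dopamine", "D2" = "dopamine", "DAT" = "dopamine",
    "GABAA" = "GABA",
    "MGLUR5" = "glutamate", "NMDA" = "glutamate")
}

#' Synthetic receptor-density atlas with planted spatial correlations
#'
#' Each receptor column is built as
#' `r * z(atrophy_map) + sqrt(1 - r^2) * z(noise)` (both parts standardized),
#' so its expected Pearson correlation with the atrophy map equals the
#' target `r`. Columns are then shifted/scaled to positive pseudo-density
#' units; correlations are unaffected.
#'
#' @param atrophy_map Numeric region vector the correlations are planted
#'   against.
#' @param target_correlations Numeric vector of targets, each strictly inside
#'   (-1, 1); one synthetic receptor per target. If unnamed and of length 15,
#'   the canonical receptor names/systems are attached.
#' @param seed Integer seed.
#' @return A numeric matrix (regions x receptors) of class `receptor_atlas`
#'   with attributes `systems` (neurotransmitter system per receptor) and
#'   `target_correlations`.
#' @export
make_receptor_atlas <- function(atrophy_map, target_correlations, seed = 1L) {
  if (!is.numeric(atrophy_map) || length(atrophy_map) < 5L) {
    stop_cortexpls("atrophy_map must be a numeric vector with >= 5 regions",
                   "invalid_argument")
  }
  if (any(!is.finite(target_correlations)) || any(abs(target_correlations) >= 1)) {
    stop_cortexpls("every target correlation must lie strictly inside (-1, 1)",
                   "invalid_argument")
  }
  n <- length(atrophy_map)
  m <- length(target_correlations)
  regions <- names(atrophy_map) %||% region_labels(n)

  rec_names <- names(target_correlations)
  systems <- NULL
  if (is.null(rec_names)) {
    if (m == 15L) {
      rec_names <- names(receptor_systems_default())
      systems <- unname(receptor_systems_default())
    } else {
      rec_names <- sprintf("receptor_%02d", seq_len(m))
    }
  }
  if (is.null(systems)) {
    canon <- receptor_systems_default()
    systems <- ifelse(rec_names %in% names(canon), canon[rec_names], "unknown")
  }

  z <- as.numeric(scale(atrophy_map))
  atlas <- withr::with_seed(seed, {
    vapply(seq_len(m), function(j) {
      r <- target_correlations[j]
      eps <- as.numeric(scale(stats::rnorm(n)))
      mix <- r * z + sqrt(1 - r^2) * eps
      10 + 2 * mix  # positive pseudo-density units
    }, numeric(n))
  })
  dimnames(atlas) <- list(regions, rec_names)
  structure(atlas,
            systems = stats::setNames(systems, rec_names),
            target_correlations = stats::setNames(as.numeric(target_correlations),
                                                  rec_names),
            seed = seed,
            class = c("receptor_atlas", "matrix", "array"))
}

#' Synthetic pathology-related gene list with a planted overlap
#'
#' Builds a gene list of `set_size` symbols containing exactly
#' `round(overlap_fraction * length(signature_genes))` members of the
#' signature, with the remainder sampled uniformly (without replacement) from
#' the background excluding the signature.
#'
#' @param background Character vector: the gene universe.
#' @param signature_genes Character vector, a subset of `background`.
#' @param overlap_fraction Fraction of signature genes to insert, in [0, 1].
#' @param set_size Total size of the returned list.
#' @param seed Integer seed.
#' @return Character vector of gene symbols with attribute
#'   `planted_overlap` (the inserted signature genes).
#' @export
make_pathology_sets <- function(background, signature_genes, overlap_fraction,
                                set_size, seed = 1L) {
  background <- canonical_symbols(background)
  signature_genes <- canonical_symbols(signature_genes)
  overlap_fraction <- assert_number(overlap_fraction, "overlap_fraction", 0, 1)
  set_size <- assert_count(set_size, "set_size")
  if (!all(signature_genes %in% background)) {
    bad <- utils::head(setdiff(signature_genes, background), 5L)
    stop_cortexpls(
      paste0("signature_genes must be a subset of background; offending: ",
             paste(bad, collapse = ", ")),
      "consistency_error"
    )
  }
  if (set_size > length(background)) {
    stop_cortexpls("set_size exceeds the background size", "invalid_argument")
  }
  n_in <- round(overlap_fraction * length(signature_genes))
  if (n_in > set_size) {
    stop_cortexpls("overlap_fraction * |signature| exceeds set_size",
                   "invalid_argument")
  }
  pool <- setdiff(background, signature_genes)
  if (set_size - n_in > length(pool)) {
    stop_cortexpls("not enough non-signature background genes to fill the set",
                   "invalid_argument")
  }
  withr::with_seed(seed, {
    inserted <- sample(signature_genes, n_in)
    rest <- sample(pool, set_size - n_in)
    out <- sample(c(inserted, rest))  # shuffle so planted genes are not first
    attr(out, "planted_overlap") <- inserted
    out
  })
}

#' Write synthetic pipeline inputs to disk
#'
#' Writes an expression matrix, subject table or receptor atlas as TSV with
#' a header row and the region label as the first column; gene lists as
#' one-symbol-per-line text; truth objects as JSON.
#'
#' @param x Object to write.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_input <- function(x, path) {
  if (is.matrix(x)) {
    df <- data.frame(region = rownames(x), as.data.frame(unclass(x)),
                     check.names = FALSE)
    write_tsv_file(df, path)
  } else if (is.data.frame(x)) {
    write_tsv_file(x, path)
  } else if (is.character(x)) {
    writeLines(x, path)
  } else if (inherits(x, "synthetic_truth") || is.list(x)) {
    write_json_file(lapply(unclass(x), function(v) {
      if (is.matrix(v)) apply(v, 1L, identity, simplify = FALSE) else v
    }), path)
  } else {
    stop_cortexpls("unsupported object type for write_input", "invalid_argument")
  }
  invisible(path)
}
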