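#' Default pipeline configuration
#'
#' Returns the full configuration list with the analysis defaults:
#' 5,000 bootstrap replicates for gene weights and for the variance
#' explained null, 1,000 permutations for pathology overlap, VIP > 1,
#' p < 0.05, q < 0.05, center-only gene standardization. A user config
#' (nested list or YAML file) overrides any subset of keys.
#'
#' @param overrides Optional nested list (or path to a YAML file) of
#'   settings to merge over the defaults.
#' @return Nested configuration list.
#' @export
default_config <- function(overrides = NULL) {
  cfg <- list(
    seed = 1L,
    synthetic = list(
      enabled = TRUE,
      n_regions = 100L, n_genes = 2000L, n_latent = 3L,
      noise_sd = 0.5, n_planted = 200L,
      n_controls = 172L, n_sporadic = 117L,
      forms = list(C9orf72 = list(n = 32L, effect = 1.5)),
      receptor_targets = c(0.6, -0.4, 0.3, 0.2, -0.2, 0.5,
                           0.1, -0.1, 0.0, 0.4, -0.3, 0.2,
                           -0.5, 0.3, 0.0),
      pathology = list(overlap_fraction = 0.4, set_size = 400L)
    ),
    inputs = list(expression = NULL, subjects = NULL, receptors = NULL,
                  pathology_lists = NULL, gmt = NULL),
    contrast = list(reference_group = "sporadic"),
    standardize = "center",
    pls = list(k = 1L, n_boot = 5000L, n_iter_null = 5000L,
               null_method = "permute", vip_cut = 1, alpha = 0.05,
               adjust = "none"),
    receptors = list(method = "pearson", null = "parametric",
                     n_null = 1000L),
    enrichment = list(n_perm = 1000L, q_threshold = 0.05)
  )
  if (is.character(overrides) && length(overrides) == 1L) {
    overrides <- yaml::read_yaml(overrides)
  }
  modifyList(cfg, overrides %||% list())
}

#' Run the full imaging-transcriptomics pipeline
#'
#' Orchestrates: synthetic-data generation (or reading user inputs) ->
#' w-score normalization -> per-form contrast maps -> region alignment and
#' gene standardization -> PLS1 fit, variance-explained null, bootstrap
#' gene statistics, VIP and PLS1+/- selection -> receptor correlations and
#' dominance analysis -> pathology-overlap permutation tests (and optional
#' ORA against a GMT collection) -> cross-form concordance. Every stage's
#' tables are written under `outdir` as TSV/JSON; reruns of an identical
#' config are byte-identical.
#'
#' @param config Nested list from [default_config()] (or a YAML path /
#'   partial override list).
#' @param outdir Output directory (created if absent). `NULL` skips all
#'   file output.
#' @param quiet Suppress per-stage log lines.
#' @return Invisibly, a list with all stage results plus the `manifest` of
#'   files written.
#' @export
run_pipeline <- function(config = list(), outdir = NULL, quiet = FALSE) {
  cfg <- default_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  manifest <- character(0)
  emit <- function(obj, name, writer = write_tsv_file) {
    if (is.null(outdir)) return(invisible(NULL))
    path <- file.path(outdir, name)
    writer(obj, path)
    manifest <<- c(manifest, name)
  }
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  seed <- assert_count(cfg$seed, "seed")
  # stage-specific seeds derived deterministically, kept < 2^31
  sub_seed <- function(off) as.integer((seed * 1000L + off) %% .Machine$integer.max)

  ## ---- inputs ----
  truth <- NULL
  if (isTRUE(cfg$synthetic$enabled)) {
    sy <- cfg$synthetic
    gen <- make_expression(sy$n_regions, sy$n_genes, sy$n_latent,
                           sy$noise_sd, sy$n_planted, seed = sub_seed(1L))
    expr <- gen$expression
    truth <- gen$truth
    atrophy <- stats::setNames(truth$factors[, 1L], rownames(expr))
    forms <- names(sy$forms)
    cohorts <- lapply(seq_along(sy$forms), function(i) {
      f <- sy$forms[[i]]
      make_cohort(sy$n_controls, sy$n_sporadic, f$n, atrophy_map = atrophy,
                  effect = f$effect, seed = sub_seed(2L + i),
                  genetic_label = forms[i])
    })
    # shared controls + sporadic arm from the first cohort; genetic arms
    # from each per-form call
    subjects <- cohorts[[1L]]
    if (length(cohorts) > 1L) {
      extra <- do.call(rbind, lapply(cohorts[-1L], function(cc) {
        cc[!(cc$group %in% c("control", "sporadic")), , drop = FALSE]
      }))
      region_labs <- attr(subjects, "region_labels")
      subjects <- rbind(subjects, extra)
      subjects$subject_id <- sprintf("sub_%04d", seq_len(nrow(subjects)))
      attr(subjects, "region_labels") <- region_labs
    }
    atlas <- make_receptor_atlas(atrophy, sy$receptor_targets,
                                 seed = sub_seed(10L))
    say("synthetic inputs: %d regions x %d genes; %d subjects; %d receptors",
        nrow(expr), ncol(expr), nrow(subjects), ncol(atlas))
  } else {
    inp <- cfg$inputs
    expr <- read_expression(inp$expression)
    subjects <- data.table::fread(inp$subjects, data.table = FALSE)
    atlas <- if (!is.null(inp$receptors)) read_receptor_atlas(inp$receptors)
    forms <- setdiff(unique(subjects$group),
                     c("control", cfg$contrast$reference_group))
    say("inputs read: %d regions x %d genes; %d subjects",
        nrow(expr), ncol(expr), nrow(subjects))
  }

  ## ---- cortical signature ----
  controls <- subjects[subjects$group == "control", , drop = FALSE]
  wmodel <- fit_wscore_model(controls)
  wsc <- apply_wscore(wmodel, subjects)
  say("w-score model fit on %d controls (%d regions)",
      wmodel$n_controls, length(wmodel$regions))

  ref <- cfg$contrast$reference_group
  contrasts <- lapply(forms, function(f) {
    compute_contrast(wsc, subjects$group, subjects$duration, f, ref)
  })
  names(contrasts) <- forms
  for (f in forms) {
    emit(contrasts[[f]], sprintf("contrast_%s.tsv", f), write_contrast)
  }

  ## ---- PLS per form ----
  expr_std <- column_standardize(expr, cfg$standardize)
  pls_res <- list()
  selections <- list()
  for (i in seq_along(forms)) {
    f <- forms[i]
    al <- align_regions(expr_std, contrasts[[f]])
    fit <- fit_pls1(al$x, al$y, k = cfg$pls$k)
    nullv <- null_variance_explained(al$x, al$y, cfg$pls$n_iter_null,
                                     method = cfg$pls$null_method,
                                     seed = sub_seed(20L + i))
    gstats <- bootstrap_gene_weights(al$x, al$y, cfg$pls$n_boot,
                                     seed = sub_seed(40L + i), vip_from = fit)
    sel <- select_genes(gstats, cfg$pls$vip_cut, cfg$pls$alpha,
                        adjust = cfg$pls$adjust)
    say("[%s] PLS1 varexp %.1f%% (null p = %.4g); %d PLS1+, %d PLS1-",
        f, fit$variance_explained, nullv$p,
        length(sel$pls1_plus), length(sel$pls1_minus))
    gtab <- as.data.frame(gstats)
    gtab$selected <- ifelse(gtab$gene %in% sel$pls1_plus, "plus",
                            ifelse(gtab$gene %in% sel$pls1_minus, "minus", "no"))
    emit(gtab, sprintf("genes_%s.tsv", f))
    emit(list(form = f, variance_explained = fit$variance_explained,
              p_null = nullv$p, null_method = nullv$method,
              n_iter_null = nullv$n_iterations,
              n_boot = attr(gstats, "n_boot"),
              n_plus = length(sel$pls1_plus), n_minus = length(sel$pls1_minus),
              vip_cut = sel$vip_cut, alpha = sel$alpha,
              seed_null = nullv$seed, seed_boot = attr(gstats, "seed")),
         sprintf("pls_summary_%s.json", f), write_json_file)
    pls_res[[f]] <- list(fit = fit, null = nullv, stats = gstats, selection = sel)
    selections[[f]] <- sel
  }

  ## ---- receptor mapping ----
  receptor_res <- NULL
  if (!is.null(atlas)) {
    receptor_res <- lapply(forms, function(f) {
      al <- align_regions(unclass(atlas), contrasts[[f]])
      atl <- structure(al$x, systems = attr(atlas, "systems"),
                       class = c("receptor_atlas", "matrix", "array"))
      corr <- correlate_receptors(al$y, atl, method = cfg$receptors$method,
                                  null = cfg$receptors$null,
                                  n_null = cfg$receptors$n_null,
                                  seed = sub_seed(60L))
      dom <- dominance_analysis(al$y, atl)
      emit(corr, sprintf("receptor_correlations_%s.tsv", f))
      emit(as.data.frame(dom), sprintf("dominance_%s.tsv", f))
      list(correlations = corr, dominance = dom)
    })
    names(receptor_res) <- forms
    say("receptor mapping done for %d form(s)", length(forms))
  }

  ## ---- pathology overlap ----
  background <- colnames(expr)
  pathology <- list()
  if (isTRUE(cfg$synthetic$enabled)) {
    first_sel <- selections[[1L]]
    sig <- union(first_sel$pls1_plus, first_sel$pls1_minus)
    if (length(sig)) {
      pathology$TDP43_synthetic <- make_pathology_sets(
        background, sig, cfg$synthetic$pathology$overlap_fraction,
        cfg$synthetic$pathology$set_size, seed = sub_seed(70L))
      pathology$tau_synthetic <- make_pathology_sets(
        background, sig, 0.05, cfg$synthetic$pathology$set_size,
        seed = sub_seed(71L))
    }
  } else if (!is.null(cfg$inputs$pathology_lists)) {
    pathology <- lapply(cfg$inputs$pathology_lists, read_gene_list)
  }
  overlap_res <- list()
  if (length(pathology)) {
    for (f in forms) {
      sig <- union(selections[[f]]$pls1_plus, selections[[f]]$pls1_minus)
      if (!length(sig)) next
      for (pname in names(pathology)) {
        pr <- permutation_overlap_test(sig, pathology[[pname]], background,
                                       n_perm = cfg$enrichment$n_perm,
                                       seed = sub_seed(80L))
        overlap_res[[paste(f, pname, sep = "|")]] <- pr
        emit(list(form = f, pathology = pname, observed = pr$observed,
                  p = pr$p, query_size = pr$query_size,
                  target_size = pr$target_size,
                  target_size_raw = pr$target_size_raw,
                  background_size = pr$background_size,
                  n_perm = pr$n_perm, seed = pr$seed,
                  null_histogram = as.list(table(pr$null))),
             sprintf("overlap_%s_%s.json", f, pname), write_json_file)
        say("[%s vs %s] overlap %d, p = %.4g", f, pname, pr$observed, pr$p)
      }
    }
  }

  ## ---- optional ORA ----
  ora_res <- NULL
  if (!is.null(cfg$inputs$gmt)) {
    terms <- read_gmt(cfg$inputs$gmt)
    ora_res <- lapply(forms, function(f) {
      sig <- union(selections[[f]]$pls1_plus, selections[[f]]$pls1_minus)
      if (!length(sig)) return(NULL)
      res <- ora(sig, terms, background, cfg$enrichment$q_threshold)
      emit(res, sprintf("ora_%s.tsv", f))
      res
    })
    names(ora_res) <- forms
  }

  ## ---- cross-form ----
  concordance <- NULL
  if (length(selections) >= 2L) {
    concordance <- compare_selections(selections)
    emit(concordance$pairs, "crossform_pairs.tsv")
    if (nrow(concordance$membership)) {
      emit(data.frame(gene = rownames(concordance$membership),
                      concordance$membership, check.names = FALSE),
           "crossform_membership.tsv")
    }
  }

  emit(cfg, "config.json", write_json_file)
  say("pipeline complete in %.1f s; %d artifact(s)",
      as.numeric(difftime(Sys.time(), t0, units = "secs")), length(manifest))

  invisible(list(
    config = cfg, truth = truth, subjects = subjects,
    wscore_model = wmodel, wscores = wsc, contrasts = contrasts,
    pls = pls_res, selections = selections, receptors = receptor_res,
    pathology = pathology, overlap = overlap_res, ora = ora_res,
    concordance = concordance, manifest = manifest
  ))
}
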