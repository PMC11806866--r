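#' Fit a per-region w-score normalization model on controls
#'
#' For every region, ordinary least squares of cortical thickness on
#' intercept, age and sex in the control arm. The residual SD (the w-score
#' denominator) uses an `n - 3` denominator (three fitted parameters).
#' Controls with missing covariates are dropped with a warning.
#'
#' @param controls Subject table (`data.frame`) with columns `age`, `sex`
#'   and one thickness column per region. Non-region columns
#'   (`subject_id`, `group`, `age`, `sex`, `duration`) are ignored as
#'   thickness.
#' @return An object of class `wscore_model`: list with `coef` (3 x regions:
#'   intercept, age, sex), `resid_sd`, `regions`, `n_controls`.
#' @export
fit_wscore_model <- function(controls) {
  th <- thickness_matrix(controls)
  keep <- stats::complete.cases(controls$age, controls$sex)
  if (!all(keep)) {
    warning(sum(!keep), " control(s) dropped for missing covariates")
    controls <- controls[keep, , drop = FALSE]
    th <- th[keep, , drop = FALSE]
  }
  n <- nrow(th)
  if (n < 4L) {
    stop_cortexpls("need at least 4 controls to fit the w-score model",
                   "insufficient_data")
  }
  X <- cbind(intercept = 1, age = controls$age, sex = controls$sex)
  qrX <- qr(X)
  if (qrX$rank < 3L) {
    # name the offending covariate: constant column beyond the intercept
    culprit <- c("age", "sex")[c(stats::sd(controls$age) < .Machine$double.eps,
                                 stats::sd(controls$sex) < .Machine$double.eps)]
    stop_cortexpls(
      paste0("degenerate control design; constant covariate(s): ",
             paste(if (length(culprit)) culprit else "unknown", collapse = ", ")),
      "degenerate_design"
    )
  }
  B <- qr.coef(qrX, th)                      # 3 x n_regions
  resid <- th - X %*% B
  resid_sd <- sqrt(colSums(resid^2) / (n - 3L))
  if (any(resid_sd <= 0)) {
    stop_cortexpls("zero residual SD in at least one region",
                   "degenerate_design")
  }
  structure(list(coef = B, resid_sd = resid_sd,
                 regions = colnames(th), n_controls = n),
            class = "wscore_model")
}

#' Apply a w-score model to subjects
#'
#' `w = (observed - predicted(age, sex)) / residual SD`, per region and
#' subject.
#'
#' @param model A `wscore_model`.
#' @param subjects Subject table with the same region columns as the model.
#' @return Numeric matrix (subjects x regions) of w-scores, with subject ids
#'   as rownames.
#' @export
apply_wscore <- function(model, subjects) {
  stopifnot(inherits(model, "wscore_model"))
  th <- thickness_matrix(subjects)
  if (!identical(colnames(th), model$regions)) {
    if (all(model$regions %in% colnames(th))) {
      th <- th[, model$regions, drop = FALSE]
    } else {
      stop_cortexpls("subject regions do not match the w-score model",
                     "shape_error")
    }
  }
  X <- cbind(1, subjects$age, subjects$sex)
  pred <- X %*% model$coef
  w <- sweep(th - pred, 2L, model$resid_sd, "/")
  rownames(w) <- subjects$subject_id %||% rownames(th)
  w
}

#' Per-region case-control contrast map from w-scores
#'
#' For each region, OLS of the w-score on a group indicator (target coded 1,
#' reference 0) and disease duration; returns the t-statistic of the group
#' term. Positive t means thicker cortex (higher w) in the target group.
#' All regions share one design matrix, so the fit is vectorized.
#'
#' @param wscores Subjects x regions w-score matrix.
#' @param groups Character vector of group labels, one per row of `wscores`.
#' @param duration Numeric disease-duration vector, one per row.
#' @param target_group,reference_group Labels of the two groups compared.
#' @return A `contrast_map`: data.frame with columns `region` and `t`, plus
#'   attributes `df`, `target`, `reference`, `sign_convention`.
#' @export
compute_contrast <- function(wscores, groups, duration,
                             target_group, reference_group) {
  sel <- groups %in% c(target_group, reference_group)
  if (sum(groups == target_group) < 2L || sum(groups == reference_group) < 2L) {
    stop_cortexpls("each contrasted group needs at least 2 subjects",
                   "insufficient_data")
  }
  if (anyNA(duration[sel])) {
    stop_cortexpls("duration must be available for all contrasted subjects",
                   "invalid_argument")
  }
  W <- wscores[sel, , drop = FALSE]
  g <- as.numeric(groups[sel] == target_group)
  d <- duration[sel]
  n <- nrow(W)

  X <- cbind(1, g, d)
  qrX <- qr(X)
  rank <- qrX$rank
  # duration may be constant (e.g. all zero in synthetic nulls): drop it
  if (rank < 3L) {
    X <- cbind(1, g)
    qrX <- qr(X)
    rank <- qrX$rank
    if (rank < 2L) {
      stop_cortexpls("contrast design is rank deficient", "degenerate_design")
    }
  }
  p <- ncol(X)
  df <- n - p
  if (df < 1L) stop_cortexpls("not enough subjects for the contrast",
                              "insufficient_data")
  B <- qr.coef(qrX, W)                        # p x regions
  resid <- W - X %*% B
  sigma2 <- colSums(resid^2) / df
  xtx_inv_gg <- solve(crossprod(X))[2L, 2L]   # variance factor of group term
  se <- sqrt(sigma2 * xtx_inv_gg)
  tval <- ifelse(se > 0, B[2L, ] / se, 0)

  out <- data.frame(region = colnames(W), t = as.numeric(tval),
                    stringsAsFactors = FALSE)
  attr(out, "df") <- df
  attr(out, "target") <- target_group
  attr(out, "reference") <- reference_group
  attr(out, "sign_convention") <-
    "positive t = thicker cortex (higher w-score) in target group"
  class(out) <- c("contrast_map", "data.frame")
  out
}

#' Write a contrast map as TSV plus JSON metadata
#' @param y A `contrast_map`.
#' @param path Output TSV path; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_contrast <- function(y, path) {
  write_tsv_file(as.data.frame(y), path)
  write_json_file(list(
    target = attr(y, "target"), reference = attr(y, "reference"),
    df = attr(y, "df"), sign_convention = attr(y, "sign_convention")
  ), paste0(path, ".json"))
  invisible(path)
}

# Extract the thickness block (region columns) of a subject table.
thickness_matrix <- function(subjects) {
  reserved <- c("subject_id", "group", "age", "sex", "duration")
  regions <- attr(subjects, "region_labels") %||%
    setdiff(colnames(subjects), reserved)
  if (length(regions) < 2L) {
    stop_cortexpls("subject table has no thickness columns", "shape_error")
  }
  as.matrix(subjects[, regions, drop = FALSE])
}
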