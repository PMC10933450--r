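# Normative modelling: per-ROI least squares on healthy controls with
# sex, age, age^2 and total intracranial volume as covariates, then
# atrophy-positive z-scoring of all subjects against that model.

covariate_design <- function(df, age_center) {
  agec <- df$age - age_center
  cbind(intercept = 1, sex = as.numeric(df$sex), age = agec,
        age2 = agec^2, tiv = as.numeric(df$tiv))
}

#' Fit the normative covariate model on healthy controls
#'
#' For every ROI an ordinary least-squares regression of the raw measure on
#' sex, age, centered-age squared and total intracranial volume is fitted on
#' the control group only (controls-only estimation avoids leaking patient
#' effects into the reference model). The residual standard deviation
#' (denominator n - 5) is the normative scale of each ROI.
#'
#' @param controls A morphometry table (see [read_morphometry()]) or plain
#'   data frame with columns `sex`, `age`, `tiv` and one numeric column per
#'   ROI; rows are healthy controls.
#' @param rois ROI column names; defaults to the table's ROI attribute or
#'   all columns other than the covariates.
#' @param center_age Center age on the control mean before squaring
#'   (default TRUE; reduces collinearity between age and age^2).
#' @return Object of class `normative_model`: 5 x R coefficient matrix,
#'   per-ROI residual sd, the age centering constant and the control count.
#' @export
fit_normative <- function(controls, rois = NULL, center_age = TRUE) {
  df <- as.data.frame(controls)
  if (is.null(rois)) rois <- roi_columns(df)
  miss <- setdiff(c("sex", "age", "tiv"), names(df))
  if (length(miss)) stop("missing covariate column(s): ",
                         paste(miss, collapse = ", "))
  n <- nrow(df)
  if (n < 6L) stop("need at least 6 controls to fit 5 coefficients")
  age_center <- if (center_age) mean(df$age) else 0
  X <- covariate_design(df, age_center)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X))
    stop("collinear covariate design; cannot fit normative model")
  Y <- as.matrix(df[rois])
  if (!all(is.finite(Y))) stop("non-finite ROI measures in controls")
  coef <- qr.coef(qr_x, Y)
  resid <- Y - X %*% coef
  sigma <- sqrt(colSums(resid^2) / (n - ncol(X)))
  degenerate <- sigma < 1e-8
  if (any(degenerate))
    stop("degenerate ROI (residual sd < 1e-8): ",
         paste(rois[degenerate], collapse = ", "))
  structure(
    list(coef = coef, sigma = setNames(sigma, rois), rois = rois,
         age_center = age_center, n_controls = n),
    class = "normative_model")
}

#' @export
print.normative_model <- function(x, ...) {
  cat("Normative model:", length(x$rois), "ROIs fitted on", x$n_controls,
      "controls\n")
  invisible(x)
}

#' Atrophy-positive normative z-scores
#'
#' z = -(observed - predicted) / residual-sd. The sign flip makes the
#' z-score increase as regional thickness or volume decreases, so larger z
#' means more atrophy and regional enlargement yields negative z.
#'
#' @param model A [fit_normative()] model.
#' @param subjects Morphometry table or data frame containing the model's
#'   covariates and ROI columns; any group.
#' @return Numeric matrix (subjects x ROIs) with an
#'   `orientation = "atrophy-positive"` attribute; rows named by
#'   `subject_id` when available.
#' @export
compute_zscores <- function(model, subjects) {
  stopifnot(inherits(model, "normative_model"))
  df <- as.data.frame(subjects)
  miss <- setdiff(model$rois, names(df))
  if (length(miss)) stop("subjects lack ROI column(s): ",
                         paste(miss, collapse = ", "))
  X <- covariate_design(df, model$age_center)
  pred <- X %*% model$coef
  Z <- -(as.matrix(df[model$rois]) - pred)
  Z <- sweep(Z, 2, model$sigma, "/")
  rownames(Z) <- if ("subject_id" %in% names(df)) df$subject_id
                 else rownames(df)
  attr(Z, "orientation") <- "atrophy-positive"
  Z
}

#' Invert z-scores back to raw measures
#'
#' measure = predicted - z * residual-sd. Used by the synthetic generator to
#' plant z-scores on the raw scale (so the pipeline's regression step is
#' genuinely exercised) and by the round-trip invariance tests.
#'
#' @inheritParams compute_zscores
#' @param Z Atrophy-positive z-score matrix over the model's ROIs.
#' @param covariates Data frame with `sex`, `age`, `tiv` rows aligned to
#'   `Z`.
#' @return Matrix of raw measures (subjects x ROIs).
#' @export
zscores_to_measures <- function(model, Z, covariates) {
  stopifnot(inherits(model, "normative_model"))
  X <- covariate_design(as.data.frame(covariates), model$age_center)
  pred <- X %*% model$coef
  out <- pred - sweep(as.matrix(Z), 2, model$sigma, "*")
  attr(out, "orientation") <- NULL
  out
}

#' Restrict a z-score matrix to the modelling ROI subset
#'
#' @param Z z-score matrix with ROI column names.
#' @param roi_list Character vector of ROI names (no duplicates); result
#'   columns follow this order. The full matrix should be kept separately
#'   for characterization of regions outside the modelling subset.
#' @return Column subset of `Z`.
#' @export
select_modeling_rois <- function(Z, roi_list) {
  if (anyDuplicated(roi_list))
    stop("duplicated ROI in roi_list: ",
         paste(unique(roi_list[duplicated(roi_list)]), collapse = ", "))
  unknown <- setdiff(roi_list, colnames(Z))
  if (length(unknown)) stop("unknown ROI(s): ",
                            paste(unknown, collapse = ", "))
  out <- Z[, roi_list, drop = FALSE]
  attr(out, "orientation") <- attr(Z, "orientation")
  out
}

#' Merge z-score columns into region groups
#'
#' Each group column is the unweighted mean of its member columns; used to
#' down-sample the feature space (e.g. 23 regions to 13 lobe-level
#' features).
#'
#' @param Z z-score matrix with ROI column names.
#' @param merge_map Named list mapping group name to member ROI names; the
#'   groups must not overlap.
#' @return Matrix with one column per group.
#' @export
merge_rois <- function(Z, merge_map = default_lobe_map()) {
  members <- unlist(merge_map, use.names = FALSE)
  if (anyDuplicated(members))
    stop("merge groups overlap on: ",
         paste(unique(members[duplicated(members)]), collapse = ", "))
  unknown <- setdiff(members, colnames(Z))
  if (length(unknown)) stop("unknown ROI(s): ",
                            paste(unknown, collapse = ", "))
  out <- vapply(merge_map,
                function(m) rowMeans(Z[, m, drop = FALSE]),
                numeric(nrow(Z)))
  if (nrow(Z) == 1L) out <- matrix(out, nrow = 1,
                                   dimnames = list(rownames(Z),
                                                   names(merge_map)))
  rownames(out) <- rownames(Z)
  attr(out, "orientation") <- attr(Z, "orientation")
  out
}
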