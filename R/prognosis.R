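# Surgical-prognosis classification: per-subtype support-vector
# sub-classifiers (and pooled baselines) under k-fold cross-validation,
# with per-training-fold standardization and PCA, Youden-index summary and
# a permutation null.

#' Control parameters for the prognosis classifier
#'
#' @param kernel `"auto"` (chosen per stratum by inner cross-validation) or
#'   one of `"linear"`, `"radial"`, `"polynomial"`.
#' @param pca_var Cumulative explained-variance target for the PCA
#'   reduction (default 0.95); `NULL` disables PCA.
#' @param n_folds Outer cross-validation folds (default 10).
#' @param inner_folds Folds of the inner kernel-selection loop.
#' @param class_weights Inverse-frequency class weights (default FALSE,
#'   plain unweighted hinge loss).
#' @param cost SVM cost parameter.
#' @param stratify_folds Stratify the outer folds by outcome (default
#'   FALSE).
#' @return List of class `prognosis_control`.
#' @export
prognosis_control <- function(kernel = "auto", pca_var = 0.95, n_folds = 10,
                              inner_folds = 5, class_weights = FALSE,
                              cost = 1, stratify_folds = FALSE) {
  kernel <- match.arg(kernel, c("auto", "linear", "radial", "polynomial"))
  if (!is.null(pca_var) && (pca_var <= 0 || pca_var > 1))
    stop("pca_var must be in (0, 1]")
  structure(list(kernel = kernel, pca_var = pca_var, n_folds = n_folds,
                 inner_folds = inner_folds, class_weights = class_weights,
                 cost = cost, stratify_folds = stratify_folds),
            class = "prognosis_control")
}

#' Build a numeric feature matrix from clinical (and MRI) variables
#'
#' Categorical variables are one-hot encoded (one indicator per level),
#' logicals become 0/1, numeric columns pass through, and an optional MRI
#' z-score block is appended. Standardization is deliberately NOT applied
#' here: it is fitted per training fold at cross-validation time.
#'
#' @param clin Clinical table rows to featurize (typically the surgical arm
#'   with known outcome).
#' @param Z Optional z-score matrix (MRI block), rows aligned by
#'   `subject_id`.
#' @param exclude Columns never used as features.
#' @return List with `X` (numeric matrix, rownames = subject ids) and
#'   `provenance` (per-feature `"clinical"` or `"mri"`).
#' @export
build_features <- function(clin, Z = NULL,
                           exclude = c("subject_id", "treatment_arm",
                                       "outcome")) {
  df <- as.data.frame(clin)
  vars <- setdiff(names(df), exclude)
  if (!length(vars)) stop("no feature columns left after exclusions")
  cols <- list()
  for (v in vars) {
    x <- df[[v]]
    if (all(is.na(x))) stop("feature column all-missing: ", v)
    if (is.numeric(x)) {
      cols[[v]] <- as.numeric(x)
    } else if (is.logical(x)) {
      cols[[v]] <- as.numeric(x)
    } else {
      x <- factor(x)
      for (lv in levels(x))
        cols[[paste0(v, "_", lv)]] <- as.numeric(x == lv)
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- if ("subject_id" %in% names(df)) df$subject_id
                 else rownames(df)
  prov <- rep("clinical", ncol(X))
  if (!is.null(Z)) {
    Z <- as.matrix(Z)
    idx <- match(rownames(X), rownames(Z))
    if (anyNA(idx)) stop("MRI block lacks rows for some subjects")
    X <- cbind(X, Z[idx, , drop = FALSE])
    prov <- c(prov, rep("mri", ncol(Z)))
  }
  if (!all(is.finite(X))) stop("non-finite entries in feature matrix")
  list(X = X, provenance = prov)
}

#' PCA reduction to a cumulative explained-variance target
#'
#' Fitted on training rows only; returns the smallest component count
#' whose cumulative explained variance reaches the target, plus a
#' transform applicable to held-out rows.
#'
#' @param X Numeric matrix (training rows).
#' @param variance_target Cumulative explained-variance target in (0, 1].
#' @return List with `scores` (reduced training matrix), `n_components`,
#'   `explained` (cumulative proportions) and `transform(newdata)`.
#' @export
reduce_pca <- function(X, variance_target = 0.95) {
  if (variance_target <= 0 || variance_target > 1)
    stop("variance_target must be in (0, 1]")
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  ev <- ev[ev > 1e-12]
  cum <- cumsum(ev) / sum(ev)
  ncomp <- which(cum >= variance_target - 1e-12)[1]
  list(scores = pc$x[, seq_len(ncomp), drop = FALSE],
       n_components = ncomp, explained = cum,
       transform = function(newdata) {
         nd <- sweep(as.matrix(newdata), 2, pc$center)
         nd %*% pc$rotation[, seq_len(ncomp), drop = FALSE]
       })
}

#' Youden index
#'
#' J = sensitivity + specificity - 1, the balanced summary of a binary
#' classifier's operating point.
#'
#' @param sensitivity,specificity Proportions in [0, 1].
#' @return J in [-1, 1].
#' @examples
#' youden(0.4787, 0.8103)
#' @export
youden <- function(sensitivity, specificity) {
  if (any(sensitivity < 0 | sensitivity > 1) ||
      any(specificity < 0 | specificity > 1))
    stop("sensitivity and specificity must lie in [0, 1]")
  sensitivity + specificity - 1
}

scale_train_test <- function(train, test) {
  mu <- colMeans(train)
  sdv <- apply(train, 2, sd)
  sdv[sdv == 0] <- 1
  list(train = sweep(sweep(train, 2, mu), 2, sdv, "/"),
       test = sweep(sweep(test, 2, mu), 2, sdv, "/"))
}

fit_svm <- function(X, y, kernel, config) {
  weights <- if (config$class_weights) {
    tb <- table(y)
    w <- as.numeric(sum(tb) / (length(tb) * tb))
    names(w) <- names(tb)
    w
  } else NULL
  e1071::svm(X, y, kernel = kernel, cost = config$cost,
             class.weights = weights, scale = FALSE)
}

choose_kernel <- function(X, y, config) {
  if (config$kernel != "auto") return(config$kernel)
  kernels <- c("linear", "radial", "polynomial")
  nf <- min(config$inner_folds, min(table(y)))
  if (nf < 2) return("linear")
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep(seq_len(nf), length.out = length(idx)))
  }
  acc <- vapply(kernels, function(kn) {
    correct <- 0
    for (fd in seq_len(nf)) {
      tr <- fold != fd
      if (length(unique(y[tr])) < 2) return(-Inf)
      m <- fit_svm(X[tr, , drop = FALSE], y[tr], kn, config)
      correct <- correct +
        sum(predict(m, X[!tr, , drop = FALSE]) == y[!tr])
    }
    correct / length(y)
  }, numeric(1))
  kernels[which.max(acc)]
}

confusion_metrics <- function(truth, pred, positive = "effective") {
  tp <- sum(truth == positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  tn <- sum(truth != positive & pred != positive)
  fp <- sum(truth != positive & pred == positive)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  list(tp = tp, fn = fn, tn = tn, fp = fp,
       sensitivity = sens, specificity = spec,
       accuracy = (tp + tn) / max(1, tp + tn + fp + fn),
       youden = if (is.na(sens) || is.na(spec)) NA_real_
                else youden(sens, spec))
}

make_folds <- function(y, n_folds, stratify) {
  n <- length(y)
  if (!stratify) return(sample(rep(seq_len(n_folds), length.out = n)))
  fold <- integer(n)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep(seq_len(n_folds), length.out = length(idx)))
  }
  fold
}

run_cv <- function(X, y, strata, config) {
  n <- nrow(X)
  fold <- make_folds(y, config$n_folds, config$stratify_folds)
  pred <- factor(rep(NA, n), levels = levels(y))
  skipped <- character(0)
  for (fd in seq_len(config$n_folds)) {
    test_idx <- which(fold == fd)
    if (!length(test_idx)) next
    for (s in unique(strata[test_idx])) {
      tr <- which(fold != fd & strata == s)
      te <- test_idx[strata[test_idx] == s]
      if (length(tr) < 4L || length(unique(y[tr])) < 2L) {
        skipped <- unique(c(skipped, as.character(s)))
        next
      }
      sc <- scale_train_test(X[tr, , drop = FALSE], X[te, , drop = FALSE])
      xtr <- sc$train; xte <- sc$test
      if (!is.null(config$pca_var)) {
        pca <- reduce_pca(xtr, config$pca_var)
        xtr <- pca$scores
        xte <- pca$transform(xte)
      }
      kn <- choose_kernel(xtr, y[tr], config)
      m <- fit_svm(xtr, y[tr], kn, config)
      pred[te] <- predict(m, xte)
    }
  }
  list(pred = pred, fold = fold, skipped = skipped)
}

prediction_report <- function(y, pred, fold, strata, config, skipped) {
  use <- !is.na(pred)
  overall <- confusion_metrics(y[use], pred[use])
  per_fold <- lapply(sort(unique(fold)), function(fd) {
    sel <- use & fold == fd
    cm <- confusion_metrics(y[sel], pred[sel])
    data.frame(fold = fd, tp = cm$tp, fn = cm$fn, tn = cm$tn, fp = cm$fp)
  })
  per_stratum <- lapply(sort(unique(strata)), function(s) {
    sel <- use & strata == s
    cm <- confusion_metrics(y[sel], pred[sel])
    data.frame(stratum = as.character(s), n = sum(sel),
               sensitivity = cm$sensitivity, specificity = cm$specificity,
               accuracy = cm$accuracy, youden = cm$youden,
               stringsAsFactors = FALSE)
  })
  structure(
    list(overall = overall,
         per_stratum = do.call(rbind, per_stratum),
         fold_counts = do.call(rbind, per_fold),
         n_used = sum(use), n_total = length(y),
         skipped_strata = skipped, config = config),
    class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  o <- x$overall
  cat(sprintf(
    "Cross-validated prediction (n = %d): acc %.2f%%, sens %.2f%%, spec %.2f%%, J = %.3f\n",
    x$n_used, 100 * o$accuracy, 100 * o$sensitivity, 100 * o$specificity,
    o$youden))
  if (length(x$skipped_strata))
    cat("skipped strata:", paste(x$skipped_strata, collapse = ", "), "\n")
  invisible(x)
}

#' Subtype-stratified cross-validated outcome prediction
#'
#' Within each outer fold one support-vector sub-classifier is trained per
#' subtype on that subtype's training members (standardization and PCA
#' refitted on the training rows only); held-out subjects are predicted by
#' their own subtype's sub-classifier and metrics are pooled over folds.
#' Strata whose training folds contain a single outcome class are skipped
#' with a warning and excluded from the pooled metrics.
#'
#' @param X Feature matrix (see [build_features()]).
#' @param outcomes Factor or character of `effective` / `ineffective`.
#' @param subtypes Subtype label per subject.
#' @param config A [prognosis_control()] list.
#' @param seed Optional RNG seed (fold assignment and kernel selection).
#' @return A `prediction_report`.
#' @export
evaluate_stratified <- function(X, outcomes, subtypes,
                                config = prognosis_control(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- as.matrix(X)
  y <- factor(as.character(outcomes), levels = c("ineffective", "effective"))
  if (anyNA(y)) stop("outcomes must be effective/ineffective")
  strata <- as.character(subtypes)
  cv <- run_cv(X, y, strata, config)
  if (length(cv$skipped))
    warning("single-class stratum skipped: ",
            paste(cv$skipped, collapse = ", "))
  prediction_report(y, cv$pred, cv$fold, strata, config, cv$skipped)
}

#' Pooled (non-stratified) cross-validated outcome prediction
#'
#' Baseline with a single classifier over all subjects; with the same seed
#' the outer folds match those of [evaluate_stratified()], so the two are
#' directly comparable.
#'
#' @inheritParams evaluate_stratified
#' @export
evaluate_pooled <- function(X, outcomes, config = prognosis_control(),
                            seed = NULL) {
  evaluate_stratified(X, outcomes, rep("pooled", nrow(as.matrix(X))),
                      config = config, seed = seed)
}

#' Permutation test of the cross-validated Youden index
#'
#' The outcome labels are permuted and the full cross-validation repeated;
#' p = (1 + #\{permuted J >= observed J\}) / (1 + n_perm).
#'
#' @inheritParams evaluate_stratified
#' @param subtypes Subtype labels, or NULL for the pooled classifier.
#' @param n_perm Number of permutations (>= 100; fewer gives an unstable
#'   p and is refused).
#' @return List with `p`, `observed_J` and the permuted `null_J` values.
#' @export
permutation_test <- function(X, outcomes, subtypes = NULL,
                             config = prognosis_control(), n_perm = 1000,
                             seed = NULL) {
  if (n_perm < 100) stop("n_perm < 100 gives an unstable p; refusing")
  if (!is.null(seed)) set.seed(seed)
  X <- as.matrix(X)
  if (is.null(subtypes)) subtypes <- rep("pooled", nrow(X))
  run <- function(y) {
    rep <- suppressWarnings(
      evaluate_stratified(X, y, subtypes, config = config))
    rep$overall$youden
  }
  obs <- run(outcomes)
  null_J <- vapply(seq_len(n_perm), function(i) run(sample(outcomes)),
                   numeric(1))
  ok <- !is.na(null_J)
  p <- (1 + sum(null_J[ok] >= obs)) / (1 + sum(ok))
  list(p = p, observed_J = obs, null_J = null_J)
}
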