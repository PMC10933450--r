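# Synthetic cohort generator. Emulates the statistical structure the
# analysis assumes: a healthy-control population following a linear
# covariate model, three trajectory subtypes with known event orderings
# (left-hippocampus-first, right-hippocampus-first, frontal-cortex-first),
# a fourth no-atrophy subtype with amygdala enlargement, and
# subtype-dependent treatment outcomes. Ground truth (orderings, stages,
# labels, outcome probabilities) is returned for recovery testing.

rtruncnorm_upper <- function(n, mean, sd, upper) {
  u <- runif(n, 0, pnorm(upper, mean, sd))
  qnorm(u, mean, sd)
}

rtruncnorm_range <- function(n, mean, sd, lower, upper) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

# True covariate model of the generator: per-ROI linear coefficients on
# (1, sex, age, age^2, tiv) plus a noise sd. Volumes in mm^3, thickness in
# mm, TIV in cm^3. Plausible magnitudes; tests never depend on the exact
# values.
true_covariate_model <- function(rois) {
  vol_means <- c(Hippocampus = 4200, Amygdala = 1700, Caudate = 3600,
                 Putamen = 5100, Pallidum = 1800, Thalamus = 7600)
  base <- sub("^(Left|Right)_", "", rois)
  volume <- base %in% names(vol_means)
  mu <- ifelse(volume, vol_means[base], 2.5)
  coef <- rbind(
    intercept = ifelse(volume, mu * 0.85, 2.45),
    sex       = ifelse(volume, mu * 0.03, 0.01),
    age       = ifelse(volume, -mu * 0.002, -0.004),
    age2      = ifelse(volume, -mu * 2e-5, -2e-5),
    tiv       = ifelse(volume, mu * 0.4 / 1470, 5e-5))
  colnames(coef) <- rois
  sigma <- ifelse(volume, mu * 0.05, 0.1)
  names(sigma) <- rois
  list(coef = coef, sigma = sigma,
       rois = rois, age_center = 0)
}

draw_covariates <- function(n, prefix) {
  data.frame(
    subject_id = sprintf("%s%04d", prefix, seq_len(n)),
    sex = rbinom(n, 1, 0.5),
    age = rtruncnorm_range(n, 26.4, 6.7, 18, 60),
    tiv = rnorm(n, 1470, 140),
    stringsAsFactors = FALSE)
}

predict_true <- function(tm, cov) {
  X <- cbind(1, cov$sex, cov$age, cov$age^2, cov$tiv)
  X %*% tm$coef
}

#' Ground truth of a synthetic cohort
#'
#' Builds the hidden generating structure: an event set over the modelling
#' ROIs, three valid event orderings whose first events are the left
#' hippocampus, the right hippocampus and a frontal cortical region at the
#' lowest threshold (the remaining order is randomized per seed), subtype
#' fractions with the fourth mass given to the no-atrophy "normal"
#' subtype, and per-(subtype, treatment-arm) seizure-freedom
#' probabilities.
#'
#' @param config Optional list overriding any of: `rois` (full ROI set),
#'   `modeling_rois`, `thresholds`, `z_max`, `fractions` (length 4, sums to
#'   1), `start_biomarkers` (length 3), `outcome_probs` (list with `OG`,
#'   `MG` length-4 probability vectors), `loss_probs` (same shape),
#'   `amygdala_z_mean`, `amygdala_z_sd`.
#' @param seed Optional RNG seed.
#' @return Object of class `ground_truth`.
#' @export
make_ground_truth <- function(config = list(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- utils::modifyList(list(
    rois = default_roi_set(),
    modeling_rois = default_modeling_rois(),
    thresholds = c(1, 2, 3),
    z_max = 5,
    fractions = c(0.287, 0.382, 0.139, 0.192),
    start_biomarkers = c("Left_Hippocampus", "Right_Hippocampus",
                         "Left_superiorfrontal"),
    outcome_probs = list(OG = c(0.692, 0.722, 0.632, 0.450),
                         MG = c(0.0909, 0.1316, 0.1579, 0.3929)),
    loss_probs = list(OG = c(3 / 55, 3 / 57, 0, 1 / 21),
                      MG = c(8 / 30, 18 / 56, 3 / 22, 8 / 36)),
    arm_probs_og = c(55 / 85, 57 / 113, 19 / 41, 21 / 57),
    amygdala_z_mean = -1.5,
    amygdala_z_sd = 0.8
  ), config)
  if (abs(sum(cfg$fractions) - 1) > 1e-9)
    stop("subtype fractions must sum to 1")
  if (!all(cfg$modeling_rois %in% cfg$rois))
    stop("modeling_rois must be a subset of rois")
  if (!all(cfg$start_biomarkers %in% cfg$modeling_rois))
    stop("unknown ROI among start_biomarkers")
  for (p in unlist(cfg$outcome_probs))
    if (p < 0 || p > 1) stop("outcome probability outside [0, 1]")
  es <- build_event_set(cfg$modeling_rois, cfg$thresholds, cfg$z_max)
  orderings <- lapply(cfg$start_biomarkers, function(bm) {
    ord <- random_ordering(es)
    first <- es$events$event[es$events$biomarker == bm][1]  # lowest z
    ord <- c(first, ord[ord != first])
    ord
  })
  structure(
    list(event_set = es, orderings = orderings,
         fractions = cfg$fractions,
         outcome_probs = cfg$outcome_probs, loss_probs = cfg$loss_probs,
         arm_probs_og = cfg$arm_probs_og,
         rois = cfg$rois, modeling_rois = cfg$modeling_rois,
         covariate_model = true_covariate_model(cfg$rois),
         amygdala_z_mean = cfg$amygdala_z_mean,
         amygdala_z_sd = cfg$amygdala_z_sd,
         seed = seed),
    class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground truth:", length(x$orderings), "trajectories + normal subtype;",
      length(x$rois), "ROIs (", length(x$modeling_rois), "modelled ), E =",
      x$event_set$E, "\n")
  cat("fractions:", paste(sprintf("%.3f", x$fractions), collapse = " "),
      "\n")
  invisible(x)
}

#' Simulate a morphometry + clinical cohort from ground truth
#'
#' Controls follow the generator's linear covariate model with normal
#' noise. Each patient draws a subtype from the ground-truth fractions;
#' trajectory subjects draw a stage uniformly on 1..E and modelled-ROI
#' z-scores around the trajectory value with unit sd, while "normal"
#' subjects draw all modelled z below 1 and enlarged (negative-z)
#' amygdalae. Planted z-scores are mapped back to the raw measurement
#' scale through the covariate model, so the analysis pipeline's
#' regression and z-scoring steps are genuinely exercised. Clinical
#' columns (onset age, duration, lateralization, hippocampal-sclerosis
#' flag, febrile history, aura, treatment arm) follow subtype-specific
#' distributions.
#'
#' @param gt A [make_ground_truth()] object.
#' @param n_patients,n_controls Cohort sizes (defaults 296 and 81).
#' @param seed Optional RNG seed.
#' @return List of class `synth_cohort`: `morphometry` (controls +
#'   patients), `clinical` (patients), `truth` (per-subject true subtype
#'   and stage) and `z_true` (patients x ROIs planted z-scores).
#' @export
simulate_cohort <- function(gt, n_patients = 296, n_controls = 81,
                            seed = NULL) {
  stopifnot(inherits(gt, "ground_truth"))
  if (n_patients < 1 || n_controls < 1) stop("need at least one subject")
  if (!is.null(seed)) set.seed(seed)
  tm <- gt$covariate_model
  rois <- gt$rois
  R <- length(rois)
  es <- gt$event_set
  E <- es$E

  ctrl <- draw_covariates(n_controls, "ctrl")
  ctrl_meas <- predict_true(tm, ctrl) +
    matrix(rnorm(n_controls * R), n_controls) %*% diag(tm$sigma)
  colnames(ctrl_meas) <- rois

  pat <- draw_covariates(n_patients, "pat")
  subtype <- sample.int(4, n_patients, replace = TRUE, prob = gt$fractions)
  stage <- ifelse(subtype == 4L, 0L, sample.int(E, n_patients,
                                                replace = TRUE))
  G <- lapply(gt$orderings, expected_trajectory, es = es)

  Ztrue <- matrix(rnorm(n_patients * R), n_patients, R,
                  dimnames = list(pat$subject_id, rois))
  mcols <- match(gt$modeling_rois, rois)
  amy <- intersect(c("Left_Amygdala", "Right_Amygdala"), rois)
  for (i in seq_len(n_patients)) {
    if (subtype[i] == 4L) {
      Ztrue[i, mcols] <- rtruncnorm_upper(length(mcols), 0, 1, 1)
      if (length(amy))
        Ztrue[i, amy] <- rnorm(length(amy), gt$amygdala_z_mean,
                               gt$amygdala_z_sd)
    } else {
      g <- G[[subtype[i]]][, stage[i] + 1L]
      Ztrue[i, mcols] <- rnorm(length(mcols), g, 1)
    }
  }
  pat_meas <- predict_true(tm, pat) - sweep(Ztrue, 2, tm$sigma, "*")

  morph <- rbind(
    data.frame(subject_id = ctrl$subject_id, group = "control",
               sex = ctrl$sex, age = ctrl$age, tiv = ctrl$tiv,
               as.data.frame(ctrl_meas), stringsAsFactors = FALSE),
    data.frame(subject_id = pat$subject_id, group = "patient",
               sex = pat$sex, age = pat$age, tiv = pat$tiv,
               as.data.frame(pat_meas), stringsAsFactors = FALSE))
  rownames(morph) <- NULL
  attr(morph, "roi_columns") <- rois
  class(morph) <- c("morphometry_table", "data.frame")

  onset_mean <- c(12.3, 16, 20.1, 18.5)
  onset_sd <- c(7.7, 9.7, 7.0, 11.4)
  dur_mean <- c(13.2, 11.8, 8.3, 8.9)
  dur_sd <- c(9.1, 8.8, 6.5, 7.0)
  p_left <- c(79 / 85, 8 / 113, 0.5, 36 / 57)
  p_hs <- c(0.953, 0.929, 0.39, 0.421)
  p_feb <- c(0.494, 0.434, 0.220, 0.123)
  p_aura <- c(0.729, 0.735, 0.683, 0.526)
  s <- subtype
  clinical <- data.frame(
    subject_id = pat$subject_id,
    age_of_onset = pmax(rnorm(n_patients, onset_mean[s], onset_sd[s]), 1),
    illness_duration = pmax(rnorm(n_patients, dur_mean[s], dur_sd[s]), 0.5),
    seizure_lateralization = ifelse(runif(n_patients) < p_left[s],
                                    "left", "right"),
    hs_on_mri = runif(n_patients) < p_hs[s],
    febrile_history = runif(n_patients) < p_feb[s],
    aura = runif(n_patients) < p_aura[s],
    treatment_arm = ifelse(runif(n_patients) < gt$arm_probs_og[s],
                           "OG", "MG"),
    stringsAsFactors = FALSE)
  class(clinical) <- c("clinical_table", "data.frame")

  structure(
    list(morphometry = morph, clinical = clinical,
         truth = data.frame(subject_id = pat$subject_id, subtype = subtype,
                            stage = stage, stringsAsFactors = FALSE),
         z_true = Ztrue),
    class = "synth_cohort")
}

#' Simulate treatment outcomes from subtype-dependent rates
#'
#' Each treated subject's outcome is Bernoulli with the ground-truth
#' per-(subtype, arm) seizure-freedom probability; a subject may then be
#' lost to follow-up with the configured per-(subtype, arm) probability.
#'
#' @param gt A [make_ground_truth()] object.
#' @param clinical Clinical table with a `treatment_arm` column.
#' @param subtypes Integer vector of true subtypes aligned with
#'   `clinical` rows (e.g. `cohort$truth$subtype`).
#' @param lost Apply loss-to-follow-up thinning (default TRUE).
#' @param seed Optional RNG seed.
#' @return The clinical table with an added `outcome` column
#'   (`effective`/`ineffective`/`lost`).
#' @export
simulate_outcomes <- function(gt, clinical, subtypes, lost = TRUE,
                              seed = NULL) {
  stopifnot(inherits(gt, "ground_truth"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(clinical)
  if (length(subtypes) != n)
    stop("subtypes must align with the clinical rows")
  arm <- clinical$treatment_arm
  if (!all(arm %in% c("OG", "MG"))) stop("treatment_arm must be OG or MG")
  p <- ifelse(arm == "OG", gt$outcome_probs$OG[subtypes],
              gt$outcome_probs$MG[subtypes])
  outcome <- ifelse(runif(n) < p, "effective", "ineffective")
  if (lost) {
    pl <- ifelse(arm == "OG", gt$loss_probs$OG[subtypes],
                 gt$loss_probs$MG[subtypes])
    outcome[runif(n) < pl] <- "lost"
  }
  clinical$outcome <- outcome
  clinical
}
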