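# Tabular I/O (CSV with header, UTF-8, "." decimal; TSV auto-detected by
# extension), model-artifact serialization, and the end-to-end pipeline
# driver.

read_table_auto <- function(path) {
  if (grepl("\\.tsv$", path, ignore.case = TRUE))
    read.delim(path, stringsAsFactors = FALSE)
  else read.csv(path, stringsAsFactors = FALSE)
}

roi_columns <- function(df) {
  rois <- attr(df, "roi_columns")
  if (!is.null(rois)) return(rois)
  setdiff(names(df)[vapply(df, is.numeric, TRUE)],
          c("sex", "age", "tiv"))
}

#' Read a per-subject regional morphometry table
#'
#' Expects a header with `subject_id`, `group` (patient/control), `sex`,
#' `age`, `tiv`; every remaining numeric column is treated as an ROI
#' measure (mm^3 for subcortical volumes, mm for cortical thickness).
#'
#' @param path CSV or TSV file.
#' @return A `morphometry_table` data frame with the detected ROI columns
#'   recorded in `attr(, "roi_columns")`.
#' @export
read_morphometry <- function(path) {
  df <- read_table_auto(path)
  mandatory <- c("subject_id", "group", "sex", "age", "tiv")
  miss <- setdiff(mandatory, names(df))
  if (length(miss))
    stop("morphometry table missing column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(df$subject_id))
    stop("duplicated subject_id in morphometry table")
  if (!all(df$group %in% c("patient", "control")))
    stop("group must be 'patient' or 'control'")
  rois <- setdiff(names(df), mandatory)
  for (r in rois) {
    if (!is.numeric(df[[r]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[r]]))))[1]
      stop("non-numeric ROI value in column ", r, ", row ", bad)
    }
    if (anyNA(df[[r]]) || any(!is.finite(df[[r]])))
      stop("non-finite ROI value in column ", r, ", row ",
           which(!is.finite(df[[r]]))[1])
  }
  attr(df, "roi_columns") <- rois
  class(df) <- c("morphometry_table", "data.frame")
  df
}

#' Write a morphometry table
#' @param df Morphometry table.
#' @param path Output CSV path.
#' @export
write_morphometry <- function(df, path) {
  write.csv(as.data.frame(df), path, row.names = FALSE)
  invisible(path)
}

clinical_enums <- list(
  seizure_lateralization = c("left", "right"),
  treatment_arm = c("OG", "MG"),
  outcome = c("effective", "ineffective", "lost"))

#' Read a per-subject clinical table
#'
#' Requires `subject_id`; recognised enum columns
#' (`seizure_lateralization`, `treatment_arm`, `outcome`) are validated
#' against their legal tokens; additional categorical or continuous
#' columns pass through untouched.
#'
#' @param path CSV or TSV file.
#' @return A `clinical_table` data frame.
#' @export
read_clinical <- function(path) {
  df <- read_table_auto(path)
  if (!"subject_id" %in% names(df))
    stop("clinical table missing column(s): subject_id")
  if (anyDuplicated(df$subject_id))
    stop("duplicated subject_id in clinical table")
  for (v in intersect(names(clinical_enums), names(df))) {
    bad <- setdiff(unique(df[[v]][!is.na(df[[v]])]), clinical_enums[[v]])
    if (length(bad))
      stop("illegal token(s) in ", v, ": ", paste(bad, collapse = ", "))
  }
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Write a clinical table
#' @param df Clinical table.
#' @param path Output CSV path.
#' @export
write_clinical <- function(df, path) {
  write.csv(as.data.frame(df), path, row.names = FALSE)
  invisible(path)
}

#' Serialize a fitted model (and optional normative model) to JSON
#'
#' The artifact round-trips losslessly through [load_model()] and carries
#' enough metadata (event set, fractions, sigma, seed, iteration counts)
#' to reproduce a run.
#'
#' @param model A [subtype_model()].
#' @param path Output `.json` path.
#' @param normative Optional [fit_normative()] model stored alongside.
#' @param metadata Optional named list (seed, iteration counts, notes).
#' @export
save_model <- function(model, path, normative = NULL, metadata = list()) {
  stopifnot(inherits(model, "subtype_model"))
  es <- model$es
  obj <- list(
    event_set = list(biomarkers = es$biomarkers,
                     thresholds = es$thresholds, z_max = es$z_max),
    orderings = model$orderings,
    fractions = model$f,
    sigma = model$sigma,
    loglik = model$loglik,
    metadata = metadata)
  if (!is.null(normative)) {
    obj$normative <- list(
      coef = as.list(as.data.frame(normative$coef)),
      coef_rows = rownames(normative$coef),
      sigma = as.list(normative$sigma),
      rois = normative$rois,
      age_center = normative$age_center,
      n_controls = normative$n_controls)
  }
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Load a serialized model artifact
#'
#' @param path JSON artifact written by [save_model()].
#' @return List with `model` (a [subtype_model()]), `normative` (or NULL)
#'   and `metadata`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  th <- obj$event_set$thresholds
  if (!is.list(th)) th <- apply(th, 1, identity, simplify = FALSE)
  es <- build_event_set(obj$event_set$biomarkers, th, obj$event_set$z_max)
  ords <- obj$orderings
  if (is.matrix(ords)) ords <- apply(ords, 1, identity, simplify = FALSE)
  model <- subtype_model(lapply(ords, as.integer), es,
                         f = obj$fractions, sigma = obj$sigma)
  model$loglik <- if (is.null(obj$loglik)) NA_real_ else obj$loglik
  normative <- NULL
  if (!is.null(obj$normative)) {
    no <- obj$normative
    coef <- as.matrix(as.data.frame(no$coef))
    rownames(coef) <- no$coef_rows
    colnames(coef) <- no$rois
    normative <- structure(
      list(coef = coef, sigma = setNames(unlist(no$sigma), no$rois),
           rois = no$rois, age_center = no$age_center,
           n_controls = no$n_controls),
      class = "normative_model")
  }
  list(model = model, normative = normative, metadata = obj$metadata)
}

pipeline_log <- function(stage, t0) {
  message(sprintf("[%s] done in %.1fs", stage,
                  as.numeric(proc.time()["elapsed"]) - t0))
}

run_stage <- function(stage, expr) {
  t0 <- as.numeric(proc.time()["elapsed"])
  res <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
  pipeline_log(stage, t0)
  res
}

#' Run the full analysis pipeline from a declarative config
#'
#' Stages: simulate (or read), normative z-scoring, model fitting with
#' optional CVIC model-order selection, individual assignment,
#' characterization statistics, and (when outcomes are present) prognosis
#' classification. Each stage is logged with its wall time; any failure
#' aborts with the stage name.
#'
#' @param config Named list or path to a YAML file. Recognised blocks:
#'   `simulate` (`n_patients`, `n_controls`) or `input` (`morphometry`,
#'   `clinical` paths); `zscore` (`modeling_rois`, `thresholds`, `z_max`);
#'   `fit` (`k`, `k_range`, `n_folds`, plus [sustain_control()]
#'   overrides); `predict` (`enable`, `features`, [prognosis_control()]
#'   overrides).
#' @param outdir Output directory (created if absent).
#' @param seed RNG seed for the whole run; a fixed (config, seed) pair
#'   gives identical outputs.
#' @return Invisible list of the in-memory artifacts.
#' @export
run_pipeline <- function(config, outdir, seed = 1) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)

  gt <- NULL
  if (!is.null(config$simulate)) {
    dat <- run_stage("simulate", {
      gt <- make_ground_truth(config$simulate$ground_truth %||% list())
      sim <- simulate_cohort(gt,
                             n_patients = config$simulate$n_patients %||% 296,
                             n_controls = config$simulate$n_controls %||% 81)
      sim$clinical <- simulate_outcomes(gt, sim$clinical,
                                        sim$truth$subtype)
      write_morphometry(sim$morphometry,
                        file.path(outdir, "morphometry.csv"))
      write_clinical(sim$clinical, file.path(outdir, "clinical.csv"))
      jsonlite::write_json(
        list(fractions = gt$fractions, orderings = gt$orderings,
             truth = sim$truth),
        file.path(outdir, "ground_truth.json"), digits = NA)
      sim$ground_truth <- gt
      sim
    })
    gt <- dat$ground_truth
    morph <- dat$morphometry
    clin <- dat$clinical
  } else if (!is.null(config$input)) {
    morph <- run_stage("read", read_morphometry(config$input$morphometry))
    clin <- if (!is.null(config$input$clinical))
      run_stage("read_clinical", read_clinical(config$input$clinical))
    else NULL
  } else stop("config needs a 'simulate' or 'input' block")

  zcfg <- config$zscore %||% list()
  zres <- run_stage("zscore", {
    controls <- morph[morph$group == "control", , drop = FALSE]
    patients <- morph[morph$group == "patient", , drop = FALSE]
    attr(controls, "roi_columns") <- attr(morph, "roi_columns")
    attr(patients, "roi_columns") <- attr(morph, "roi_columns")
    nm <- fit_normative(controls)
    Zfull <- compute_zscores(nm, patients)
    rois <- zcfg$modeling_rois %||% default_modeling_rois()
    Zmod <- select_modeling_rois(Zfull, rois)
    write.csv(data.frame(subject_id = rownames(Zfull), Zfull,
                         check.names = FALSE),
              file.path(outdir, "zscores.csv"), row.names = FALSE)
    list(normative = nm, Zfull = Zfull, Zmod = Zmod,
         controlsZ = compute_zscores(nm, controls))
  })

  fcfg <- config$fit %||% list()
  es <- build_event_set(colnames(zres$Zmod),
                        zcfg$thresholds %||% c(1, 2, 3),
                        zcfg$z_max %||% 5)
  ctrl_args <- fcfg[intersect(names(fcfg), names(formals(sustain_control)))]
  control <- do.call(sustain_control, ctrl_args)

  cvic <- NULL
  k_range <- fcfg$k_range %||% fcfg$k %||% 3
  if (length(k_range) > 1) {
    cvic <- run_stage("model_order", {
      rep <- select_model_order(zres$Zmod, es, k_range = k_range,
                                n_folds = fcfg$n_folds %||% 3,
                                control = control)
      write.csv(rep$table, file.path(outdir, "cvic.csv"),
                row.names = FALSE)
      rep
    })
    k_use <- cvic$selected_k
  } else k_use <- k_range

  model <- run_stage("fit", {
    m <- fit_subtypes(zres$Zmod, es, k = k_use, control = control)
    save_model(m, file.path(outdir, "model.json"),
               normative = zres$normative,
               metadata = list(seed = seed, k = k_use,
                               mcmc_iter = control$mcmc_iter,
                               n_starts = control$n_starts,
                               features = colnames(zres$Zmod)))
    m
  })

  assign <- run_stage("assign", {
    a <- assign_individuals(model, zres$Zmod)
    write.csv(as.data.frame(a), file.path(outdir, "assignments.csv"),
              row.names = FALSE)
    a
  })

  characterization <- run_stage("characterize", {
    res <- list(stage_corr = tryCatch(
      stage_atrophy_correlation(assign, zres$Zmod),
      error = function(e) NULL))
    rows <- do.call(rbind, lapply(split(seq_len(nrow(assign)),
                                        assign$label), function(idx) {
      if (length(idx) < 2L) return(NULL)
      cmp <- roiwise_group_comparison(zres$Zfull[idx, , drop = FALSE],
                                      zres$controlsZ)
      cmp$label <- assign$label[idx[1]]
      cmp
    }))
    write.csv(rows, file.path(outdir, "roi_contrasts.csv"),
              row.names = FALSE)
    if (!is.null(clin)) {
      cc <- clinical_compare(clin, assign$label, mode = "one_vs_all")
      write.csv(cc, file.path(outdir, "clinical_comparison.csv"),
                row.names = FALSE)
      res$clinical <- cc
      if ("outcome" %in% names(clin)) {
        sf <- lapply(c("OG", "MG"), function(a)
          seizure_freedom_table(clin, assign$label, arm = a))
        names(sf) <- c("OG", "MG")
        write.csv(do.call(rbind, Map(function(d, a)
          cbind(arm = a, d), sf, names(sf))),
          file.path(outdir, "seizure_freedom.csv"), row.names = FALSE)
        res$seizure_freedom <- sf
      }
    }
    res$roi_contrasts <- rows
    res
  })

  prognosis <- NULL
  pcfg <- config$predict %||% list()
  if (isTRUE(pcfg$enable) && !is.null(clin) &&
      "outcome" %in% names(clin)) {
    prognosis <- run_stage("predict", {
      sel <- clin$treatment_arm == "OG" &
        clin$outcome %in% c("effective", "ineffective")
      feats <- build_features(clin[sel, , drop = FALSE],
                              Z = if (identical(pcfg$features,
                                                "clinical+mri"))
                                zres$Zmod else NULL)
      pc_args <- pcfg[intersect(names(pcfg),
                                names(formals(prognosis_control)))]
      pctrl <- do.call(prognosis_control, pc_args)
      strat <- suppressWarnings(
        evaluate_stratified(feats$X, clin$outcome[sel],
                            assign$label[sel], config = pctrl))
      pooled <- suppressWarnings(
        evaluate_pooled(feats$X, clin$outcome[sel], config = pctrl))
      out <- list(
        stratified = strat$overall, pooled = pooled$overall,
        n = strat$n_total)
      jsonlite::write_json(out, file.path(outdir, "prognosis.json"),
                           digits = NA, auto_unbox = TRUE, pretty = TRUE)
      list(stratified = strat, pooled = pooled)
    })
  }

  invisible(list(ground_truth = gt, morphometry = morph, clinical = clin,
                 normative = zres$normative, zscores = zres$Zfull,
                 model = model, cvic = cvic, assignment = assign,
                 characterization = characterization,
                 prognosis = prognosis))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
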