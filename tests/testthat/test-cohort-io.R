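# Tabular I/O, artifact serialization and the pipeline driver.

test_that("morphometry tables round-trip and validate their schema", {
  df <- data.frame(
    subject_id = paste0("s", 1:5), group = c("control", "control",
                                             "patient", "patient",
                                             "patient"),
    sex = c(0, 1, 0, 1, 0), age = c(25, 31, 44, 22, 37),
    tiv = c(1450, 1500, 1390, 1600, 1480),
    Left_Hippocampus = c(4100, 4200, 3800, 4000, 3500),
    Right_Hippocampus = c(4150, 4180, 3900, 4050, 3600))
  path <- withr::local_tempfile(fileext = ".csv")
  write_morphometry(df, path)
  back <- read_morphometry(path)
  expect_equal(as.data.frame(back)[names(df)], df, ignore_attr = TRUE)
  expect_equal(attr(back, "roi_columns"),
               c("Left_Hippocampus", "Right_Hippocampus"))

  df2 <- df[setdiff(names(df), "tiv")]
  p2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df2, p2, row.names = FALSE)
  expect_error(read_morphometry(p2), "tiv")

  df3 <- df
  df3$Left_Hippocampus <- as.character(df3$Left_Hippocampus)
  df3$Left_Hippocampus[3] <- "oops"
  p3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df3, p3, row.names = FALSE)
  expect_error(read_morphometry(p3), "row 3")

  # TSV auto-detection by extension
  p4 <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, p4, sep = "\t", row.names = FALSE)
  expect_equal(as.data.frame(read_morphometry(p4))[names(df)], df,
               ignore_attr = TRUE)
})

test_that("generator output loads with 76 detected ROI columns", {
  gt <- make_ground_truth(seed = 101)
  co <- simulate_cohort(gt, n_patients = 300, n_controls = 30, seed = 102)
  path <- withr::local_tempfile(fileext = ".csv")
  write_morphometry(co$morphometry, path)
  back <- read_morphometry(path)
  expect_equal(length(attr(back, "roi_columns")), 76)
  expect_equal(nrow(back), 330)
})

test_that("clinical tables round-trip, validate enums and join cleanly", {
  gt <- make_ground_truth(seed = 103)
  co <- simulate_cohort(gt, n_patients = 60, n_controls = 10, seed = 104)
  clin <- simulate_outcomes(gt, co$clinical, co$truth$subtype, seed = 105)
  path <- withr::local_tempfile(fileext = ".csv")
  write_clinical(clin, path)
  back <- read_clinical(path)
  expect_equal(as.data.frame(back), as.data.frame(clin),
               ignore_attr = TRUE, tolerance = 1e-12)

  # zero orphans against the morphometry patients
  patients <- co$morphometry$subject_id[co$morphometry$group == "patient"]
  expect_true(all(back$subject_id %in% patients))

  bad <- clin
  bad$outcome[2] <- "unknown_token"
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_clinical(bad, p2)
  expect_error(read_clinical(p2), "unknown_token")
})

test_that("model artifacts serialize losslessly", {
  es <- build_event_set(paste0("b", 1:4), thresholds = c(1, 2), z_max = 5)
  set.seed(106)
  m <- subtype_model(list(random_ordering(es), random_ordering(es)), es,
                     f = c(0.4, 0.6), sigma = c(1, 1, 0.8, 1.2))
  m$loglik <- -1234.5678
  ctrl <- data.frame(subject_id = paste0("c", 1:30), sex = rbinom(30, 1, 0.5),
                     age = runif(30, 20, 50), tiv = rnorm(30, 1470, 100))
  for (b in es$biomarkers) ctrl[[b]] <- rnorm(30, 2.5, 0.3)
  nm <- fit_normative(ctrl, rois = es$biomarkers)

  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path, normative = nm,
             metadata = list(seed = 7, mcmc_iter = 1000))
  art <- load_model(path)
  expect_equal(art$model$orderings, m$orderings)
  expect_equal(art$model$f, m$f)
  expect_equal(art$model$sigma, m$sigma)
  expect_equal(art$model$loglik, m$loglik)
  expect_equal(art$model$es$biomarkers, es$biomarkers)
  expect_equal(art$model$es$thresholds, es$thresholds)
  expect_equal(art$normative$coef, nm$coef, tolerance = 1e-12)
  expect_equal(art$normative$sigma, nm$sigma, tolerance = 1e-12)
  expect_equal(art$normative$age_center, nm$age_center)
  expect_equal(art$metadata$seed, 7)
})

demo_config <- function() {
  list(
    simulate = list(
      n_patients = 90, n_controls = 50,
      ground_truth = list(
        modeling_rois = c("Left_Hippocampus", "Right_Hippocampus",
                          "Left_Thalamus", "Right_Thalamus",
                          "Left_superiorfrontal", "Right_superiorfrontal",
                          "Left_entorhinal", "Left_precentral"),
        thresholds = c(1, 2))),
    zscore = list(
      modeling_rois = c("Left_Hippocampus", "Right_Hippocampus",
                        "Left_Thalamus", "Right_Thalamus",
                        "Left_superiorfrontal", "Right_superiorfrontal",
                        "Left_entorhinal", "Left_precentral"),
      thresholds = c(1, 2)),
    fit = list(k = 2, n_starts = 2, n_starts_split = 2, n_splits = 2,
               mcmc_iter = 1500),
    predict = list(enable = TRUE, kernel = "linear", pca_var = 0.95,
                   n_folds = 4))
}

test_that("the demo pipeline runs end-to-end and is seed-deterministic", {
  cfg <- demo_config()
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  suppressWarnings(suppressMessages(run_pipeline(cfg, out1, seed = 7)))
  suppressWarnings(suppressMessages(run_pipeline(cfg, out2, seed = 7)))

  for (f in c("morphometry.csv", "clinical.csv", "zscores.csv",
              "model.json", "assignments.csv", "roi_contrasts.csv",
              "seizure_freedom.csv"))
    expect_true(file.exists(file.path(out1, f)), label = f)

  # byte-identical assignment tables across reruns of the same seed
  expect_identical(readLines(file.path(out1, "assignments.csv")),
                   readLines(file.path(out2, "assignments.csv")))

  # single k: no CVIC comparison, but subjects are still assigned
  expect_false(file.exists(file.path(out1, "cvic.csv")))
  a <- read.csv(file.path(out1, "assignments.csv"))
  expect_equal(nrow(a), 90)
  expect_true(all(a$label %in% c("trajectory_1", "trajectory_2",
                                 "normal")))
})

test_that("pipeline failures name the failing stage", {
  cfg <- list(input = list(morphometry = "does_not_exist.csv"))
  out <- withr::local_tempdir()
  suppressWarnings(
    expect_error(suppressMessages(run_pipeline(cfg, out)), "stage 'read'"))
})
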