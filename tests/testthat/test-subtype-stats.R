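# Characterization statistics: correlations, contrasts, FDR, contingency.

fake_assignment <- function(labels, stages) {
  a <- data.frame(subject_id = as.character(seq_along(labels)),
                  label = labels, stage = stages,
                  stringsAsFactors = FALSE)
  class(a) <- c("subject_assignment", "data.frame")
  a
}

test_that("stage-atrophy correlation is 1 for monotone data, null for noise", {
  st <- 1:40
  a <- fake_assignment(rep("trajectory_1", 40), st)
  Z <- cbind(r1 = st + 0.5, r2 = st * 2)
  res <- stage_atrophy_correlation(a, Z)
  expect_equal(res$rho, 1)

  set.seed(71)
  a2 <- fake_assignment(rep("trajectory_1", 100),
                        sample(1:30, 100, replace = TRUE))
  Z2 <- cbind(r1 = rnorm(100), r2 = rnorm(100))
  res2 <- stage_atrophy_correlation(a2, Z2)
  expect_lt(abs(res2$rho), 0.3)
  expect_gt(res2$p, 0.001)

  expect_error(stage_atrophy_correlation(
    fake_assignment(rep("trajectory_1", 10), rep(3, 10)),
    cbind(r1 = rnorm(10))), "constant")
  expect_error(stage_atrophy_correlation(a, Z, roi = "nope"), "unknown")
})

test_that("trajectory subtypes show stage-dependent atrophy in synthesis", {
  gt <- make_ground_truth(seed = 72)
  co <- simulate_cohort(gt, n_patients = 296, n_controls = 5, seed = 73)
  tr <- co$truth$subtype <= 3
  a <- fake_assignment(paste0("trajectory_", co$truth$subtype[tr]),
                       co$truth$stage[tr])
  res <- stage_atrophy_correlation(a, co$z_true[tr, gt$modeling_rois])
  expect_equal(nrow(res), 3)
  expect_true(all(res$rho > 0.5))
})

test_that("ROI-wise contrasts detect a planted shift and control the FDR", {
  set.seed(74)
  Za <- matrix(rnorm(50 * 76), 50, 76,
               dimnames = list(NULL, paste0("r", 1:76)))
  Zb <- matrix(rnorm(50 * 76), 50, 76,
               dimnames = list(NULL, paste0("r", 1:76)))
  Zb[, 5] <- Zb[, 5] + 2
  res <- roiwise_group_comparison(Za, Zb)
  expect_lt(res$q[5], 0.01)
  expect_lt(sum(res$q[-5] < 0.05), 4)

  same <- roiwise_group_comparison(Za, Za)
  expect_true(all(same$t == 0))
  expect_true(all(same$q == 1))

  # BH step-up identity on the reported q values
  ord <- order(res$p)
  m <- nrow(res)
  qmanual <- rev(cummin(rev(res$p[ord] * m / seq_len(m))))
  expect_equal(res$q[ord], pmin(qmanual, 1), tolerance = 1e-12)

  expect_error(roiwise_group_comparison(Za[1, , drop = FALSE], Zb),
               "n >= 2")
})

test_that("clinical comparisons reproduce closed-form contrasts", {
  set.seed(75)
  n1 <- 85; n2 <- 211
  x1 <- as.numeric(scale(rnorm(n1))) * 7 + 12.3
  x2 <- as.numeric(scale(rnorm(n2))) * 7 + 18.0
  clin <- data.frame(subject_id = as.character(1:(n1 + n2)),
                     onset = c(x1, x2))
  labels <- rep(c("g1", "g2"), c(n1, n2))
  res <- clinical_compare(clin, labels, mode = "one_vs_all")
  expect_lt(res$p[res$contrast == "omnibus"], 0.001)
  tg1 <- res$statistic[res$contrast == "g1_vs_rest" & res$test == "t"]
  expect_lt(res$p[res$contrast == "g1_vs_rest" & res$test == "t"], 0.001)
  # with two groups, F = t^2
  expect_equal(res$statistic[res$contrast == "omnibus"], tg1^2,
               tolerance = 1e-9)

  # duplicated identical groups: pairwise contrasts are exactly null
  clin2 <- data.frame(subject_id = as.character(1:40),
                      v = rep(rnorm(20), 2),
                      cat = rep(sample(c("x", "y"), 20, replace = TRUE),
                                2))
  res2 <- clinical_compare(clin2, rep(c("a", "b"), each = 20),
                           mode = "pairwise")
  expect_equal(res2$statistic[res2$test == "lsd_t"], 0, tolerance = 1e-12)
  expect_equal(res2$p[res2$test == "lsd_t"], 1, tolerance = 1e-12)
  expect_equal(res2$statistic[res2$test == "chisq"], 0, tolerance = 1e-12)

  # identical proportions in a 4 x 2 table give chi-square ~ 0
  clin3 <- data.frame(subject_id = as.character(1:80),
                      cat = rep(rep(c("p", "q"), each = 10), 4))
  res3 <- clinical_compare(clin3, rep(c("s1", "s2", "s3", "s4"),
                                      each = 20), mode = "one_vs_all")
  expect_true(all(abs(res3$statistic[res3$test == "chisq"]) < 1e-12))
})

test_that("single-level variables are skipped with a warning", {
  clin <- data.frame(subject_id = as.character(1:20),
                     flat = rep("same", 20), ok = rnorm(20))
  expect_warning(res <- clinical_compare(clin, rep(c("a", "b"), 10)),
                 "single level")
  expect_false(any(res$variable == "flat"))
})

test_that("seizure-freedom tables use loss-excluded denominators", {
  clin <- data.frame(
    subject_id = as.character(1:12),
    treatment_arm = rep("MG", 12),
    outcome = c(rep("effective", 4), rep("ineffective", 6),
                rep("lost", 2)))
  labels <- c("s1", "s1", "s2", "s2", "s1", "s1", "s1", "s2", "s2", "s2",
              "s1", "s2")
  res <- seizure_freedom_table(clin, labels, arm = "MG")
  expect_equal(res$effective, c(2, 2))
  expect_equal(res$ineffective, c(3, 3))
  expect_equal(res$rate, c(40, 40))

  # all-effective degenerate table: rates 100, chi-square 0
  allok <- seizure_freedom_table(counts = cbind(c(5, 7, 3), c(0, 0, 0)))
  expect_true(all(allok$rate == 100))
  expect_true(all(allok$chi_sq == 0))
})

test_that("the 2x2 chi-square equals its closed form on random tables", {
  set.seed(76)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 20) + 1, 2)
    res <- seizure_freedom_table(counts = tab)
    a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
    n <- sum(tab)
    closed <- n * (a * d - b * cc)^2 /
      ((a + b) * (cc + d) * (a + cc) * (b + d))
    expect_equal(res$chi_sq[1], closed, tolerance = 1e-10)
    # cross-check against stats::chisq.test without continuity correction
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(res$chi_sq[1], unname(ref$statistic), tolerance = 1e-10)
  }
})
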