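# Fitting machinery: greedy ascent, MCMC, hierarchical splitting, CVIC,
# assignment and consistency metrics.

test_that("greedy fit matches exhaustive enumeration on clean data", {
  es <- build_event_set(paste0("b", 1:3), thresholds = 1, z_max = 3)
  set.seed(51)
  truth <- c(2, 1, 3)
  g <- expected_trajectory(truth, es)
  stages <- sample(0:es$E, 200, replace = TRUE)
  Z <- t(vapply(stages, function(s) g[, s + 1], numeric(3)))  # noise-free
  colnames(Z) <- es$biomarkers

  fit <- greedy_fit_single(Z, es, n_starts = 5, seed = 52)
  expect_equal(fit$ordering, truth)

  orderings <- all_valid_orderings(es)
  expect_equal(length(orderings), 6)
  lls <- vapply(orderings, function(o) sum(subject_loglik(Z, o, es)),
                numeric(1))
  expect_equal(orderings[[which.max(lls)]], fit$ordering)
  expect_equal(max(lls), fit$loglik, tolerance = 1e-9)

  # ascent property: the fit beats any random ordering
  set.seed(53)
  for (i in 1:20)
    expect_gte(fit$loglik + 1e-9,
               sum(subject_loglik(Z, random_ordering(es), es)))
})

test_that("greedy fit is seed-stable on well-separated data", {
  es <- build_event_set(paste0("b", 1:4), thresholds = c(1, 2), z_max = 5)
  set.seed(54)
  truth <- random_ordering(es)
  g <- expected_trajectory(truth, es)
  Z <- draw_from_trajectory(g, sample(1:es$E, 150, replace = TRUE),
                            sigma = 0.3)
  f1 <- greedy_fit_single(Z, es, n_starts = 4, seed = 55)
  f2 <- greedy_fit_single(Z, es, n_starts = 4, seed = 56)
  expect_equal(f1$ordering, f2$ordering)
  expect_equal(f1$ordering, truth)
})

test_that("MCMC on uninformative data mixes to a uniform ordering posterior", {
  es <- build_event_set(paste0("b", 1:6), thresholds = 1, z_max = 5)
  Z <- matrix(1.5, 40, 6, dimnames = list(NULL, es$biomarkers))
  set.seed(57)
  init <- subtype_model(list(random_ordering(es)), es)
  mc <- mcmc_sample(Z, init, n_iter = 50000, thin = 50, seed = 58)

  pv <- positional_variance(mc, 1)
  expect_equal(unname(rowSums(pv)), rep(1, 6), tolerance = 1e-12)
  expect_lt(max(abs(pv - 1 / 6)), 0.05)

  # chi-square goodness of fit of event 1's position distribution
  counts <- tabulate(mc$orderings[[1]][, 1], 6)
  gof <- suppressWarnings(stats::chisq.test(counts))
  expect_gt(gof$p.value, 0.01)

  # every stored sample respects threshold order
  some <- mc$orderings[[1]][seq(1, nrow(mc$orderings[[1]]), by = 100), ,
                            drop = FALSE]
  for (i in seq_len(nrow(some)))
    expect_true(is_valid_ordering(some[i, ], es))

  # the chain's ML ordering is at least as good as the initial state
  init_ll <- mixture_loglik(Z, init)$loglik
  expect_gte(mc$ml_loglik, init_ll - 1e-9)
})

test_that("k = 1 fit reduces exactly to greedy plus MCMC", {
  es <- build_event_set(paste0("b", 1:3), thresholds = c(1, 2))
  set.seed(59)
  truth <- random_ordering(es)
  Z <- draw_from_trajectory(expected_trajectory(truth, es),
                            sample(1:es$E, 80, replace = TRUE))
  ctrl <- sustain_control(n_starts = 3, mcmc_iter = 2000)
  m <- fit_subtypes(Z, es, k = 1, control = ctrl, seed = 60)

  set.seed(60)
  g <- greedy_fit_single(Z, es, n_starts = 3, sigma = ctrl$sigma,
                         max_sweeps = ctrl$max_sweeps)
  mc <- mcmc_sample(Z, subtype_model(list(g$ordering), es),
                    n_iter = ctrl$mcmc_iter, thin = ctrl$thin)
  expect_equal(m$orderings, mc$ml_orderings)
  expect_equal(m$f, 1)
})

test_that("two well-separated trajectories are recovered with high ARI", {
  es <- build_event_set(paste0("b", 1:6), thresholds = c(1, 2, 3))
  opp <- opposite_orderings(es)
  g1 <- expected_trajectory(opp[[1]], es)
  g2 <- expected_trajectory(opp[[2]], es)
  set.seed(61)
  lab <- rep(1:2, each = 150)
  stages <- sample(3:15, 300, replace = TRUE)
  Z <- rbind(draw_from_trajectory(g1, stages[1:150]),
             draw_from_trajectory(g2, stages[151:300]))
  ctrl <- sustain_control(n_starts = 3, n_starts_split = 2, n_splits = 2,
                          mcmc_iter = 3000)
  m <- fit_subtypes(Z, es, k = 2, control = ctrl, seed = 62)
  a <- assign_individuals(m, Z)
  expect_gte(adjusted_rand(lab, a$map_trajectory), 0.9)
  if (requireNamespace("mclust", quietly = TRUE))
    expect_equal(adjusted_rand(lab, a$map_trajectory),
                 mclust::adjustedRandIndex(lab, a$map_trajectory),
                 tolerance = 1e-12)

  # EM split refinement is monotone in the classification log-likelihood
  tr <- attr(m, "em_trace")
  expect_true(all(diff(tr) >= -1e-6))
})

test_that("CVIC penalizes overfitting single-trajectory data", {
  es <- build_event_set(paste0("b", 1:6), thresholds = 1, z_max = 5)
  set.seed(63)
  truth <- random_ordering(es)
  Z <- draw_from_trajectory(expected_trajectory(truth, es),
                            sample(1:es$E, 120, replace = TRUE))
  ctrl <- sustain_control(n_starts = 3, n_starts_split = 2, n_splits = 2,
                          mcmc_iter = 2000)
  rep <- select_model_order(Z, es, k_range = 1:2, n_folds = 3,
                            control = ctrl, seed = 64)
  cv1 <- rep$table$cvic[rep$table$k == 1]
  cv2 <- rep$table$cvic[rep$table$k == 2]
  expect_lte(cv1, cv2)
  expect_true(all(is.finite(rep$table$cvic)))
  expect_equal(colSums(-2 * rep$per_fold), setNames(rep$table$cvic,
                                                    colnames(rep$per_fold)),
               tolerance = 1e-9)
  expect_error(select_model_order(Z, es, k_range = 1:2, n_folds = 1),
               "n_folds")
})

test_that("individuals are assigned to mode stage and the normal rule fires", {
  es <- build_event_set(paste0("b", 1:4), thresholds = c(1, 2), z_max = 5)
  set.seed(65)
  o1 <- random_ordering(es)
  o2 <- rev_ord <- NULL
  repeat {
    o2 <- random_ordering(es)
    if (!identical(o2, o1)) break
  }
  m <- subtype_model(list(o1, o2), es, f = c(0.5, 0.5), sigma = 0.1)

  # subject with all z-scores 0.2 is "normal" at stage 0
  a0 <- assign_individuals(m, matrix(0.2, 1, 4,
                                     dimnames = list("s0", es$biomarkers)))
  expect_equal(a0$label, "normal")
  expect_equal(a0$stage, 0L)

  # a subject exactly on trajectory c at stage k recovers (c, k)
  g2 <- expected_trajectory(o2, es)
  for (k in c(2, 5, 8)) {
    Z <- matrix(g2[, k + 1], 1, 4, dimnames = list("s", es$biomarkers))
    a <- assign_individuals(m, Z)
    if (any(Z >= 1)) {
      expect_equal(a$map_trajectory, 2L)
      expect_equal(a$stage, k)
    }
  }
})

test_that("positional variance is a row-stochastic summary of the chain", {
  es <- build_event_set(paste0("b", 1:5), thresholds = 1, z_max = 3)
  set.seed(66)
  ord <- random_ordering(es)
  # degenerate chain stuck at one ordering -> permutation matrix
  stuck <- structure(
    list(orderings = list(matrix(rep(ord, each = 50), 50, 5)), es = es),
    class = "mcmc_samples")
  pv <- positional_variance(stuck, 1)
  expect_equal(unname(rowSums(pv)), rep(1, 5))
  expect_true(all(pv %in% c(0, 1)))
  expect_equal(unname(pv[cbind(ord, 1:5)]), rep(1, 5))
  empty <- structure(list(orderings = list(matrix(0L, 0, 5)), es = es),
                     class = "mcmc_samples")
  expect_error(positional_variance(empty, 1), "empty")
})

test_that("assignment consistency matches labels up to permutation", {
  set.seed(67)
  n <- 300
  a <- data.frame(
    subject_id = as.character(1:n),
    label = sample(c("trajectory_1", "trajectory_2", "trajectory_3"),
                   n, replace = TRUE),
    stage = sample(0:20, n, replace = TRUE))
  class(a) <- c("subject_assignment", "data.frame")

  same <- assignment_consistency(a, a)
  expect_equal(same$agreement, 100)
  expect_equal(same$stage_rho, 1)

  # relabelled copy still agrees perfectly
  b <- a
  b$label <- c(trajectory_1 = "trajectory_2", trajectory_2 = "trajectory_3",
               trajectory_3 = "trajectory_1")[a$label]
  expect_equal(assignment_consistency(a, b)$agreement, 100)

  # independently shuffled labels agree only near chance
  c_ <- a
  c_$label <- sample(a$label)
  shuf <- assignment_consistency(a, c_)
  expect_lt(shuf$agreement, 60)
  expect_gt(shuf$agreement, 15)

  expect_error(assignment_consistency(a, a[1:10, ]), "different subject")
})

test_that("refits on subsamples assign consistently with the full model", {
  es <- build_event_set(paste0("b", 1:6), thresholds = c(1, 2))
  opp <- opposite_orderings(es)
  set.seed(68)
  lab <- rep(1:2, each = 120)
  stages <- sample(2:10, 240, replace = TRUE)
  Z <- rbind(
    draw_from_trajectory(expected_trajectory(opp[[1]], es), stages[1:120]),
    draw_from_trajectory(expected_trajectory(opp[[2]], es),
                         stages[121:240]))
  rownames(Z) <- as.character(1:240)
  ctrl <- sustain_control(n_starts = 2, n_starts_split = 2, n_splits = 2,
                          mcmc_iter = 2000)
  full <- fit_subtypes(Z, es, 2, control = ctrl, seed = 69)
  a_full <- assign_individuals(full, Z)
  for (s in 1:2) {
    keep <- sample(240, 216)
    refit <- fit_subtypes(Z[keep, ], es, 2, control = ctrl, seed = 70 + s)
    a_re <- assign_individuals(refit, Z)
    cons <- assignment_consistency(a_full, a_re)
    expect_gte(cons$agreement, 90)
  }
})
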