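# Model fitting: greedy multi-start ascent over event orderings, MCMC for
# ordering uncertainty, hierarchical cluster splitting with hard EM over
# the number of subtypes, and cross-validated model-order selection.

#' Control parameters for model fitting
#'
#' @param n_starts Random restarts of the greedy ascent (default 25, the
#'   conventional setting for this model family).
#' @param n_starts_split Greedy restarts used for each half of a candidate
#'   cluster split (smaller; splits are refined by EM afterwards).
#' @param n_splits Random bipartitions tried per cluster when adding a
#'   subtype.
#' @param mcmc_iter MCMC iterations (default 1e5; published analyses use
#'   1e6, a reduced profile of 1e4 is adequate for simulation work).
#' @param thin Store every `thin`-th MCMC sample (default 10).
#' @param sigma Biomarker noise sd (default 1: inputs are normative
#'   z-scores).
#' @param em_max_iter Maximum hard-EM sweeps per split candidate.
#' @param max_sweeps Maximum steepest-ascent sweeps per greedy start.
#' @param cv_samples MCMC samples over which out-of-sample log-likelihood
#'   is averaged during model-order selection.
#' @return A list of class `sustain_control`.
#' @export
sustain_control <- function(n_starts = 25, n_starts_split = 3, n_splits = 5,
                            mcmc_iter = 1e5, thin = 10, sigma = 1,
                            em_max_iter = 10, max_sweeps = 200,
                            cv_samples = 50) {
  structure(list(n_starts = n_starts, n_starts_split = n_starts_split,
                 n_splits = n_splits, mcmc_iter = as.integer(mcmc_iter),
                 thin = as.integer(thin), sigma = sigma,
                 em_max_iter = em_max_iter, max_sweeps = max_sweeps,
                 cv_samples = cv_samples),
            class = "sustain_control")
}

check_Z <- function(Z, es) {
  Z <- as.matrix(Z)
  if (ncol(Z) != length(es$biomarkers))
    stop("Z must have one column per event-set biomarker")
  if (!is.null(colnames(Z)) && !identical(colnames(Z), es$biomarkers))
    stop("Z columns do not match the event set biomarkers")
  if (!all(is.finite(Z))) stop("Z must be finite")
  Z
}

greedy_one <- function(Z, es, start, sigma, max_sweeps) {
  res <- cpp_greedy(Z, start - 1L, es$events$bio_index - 1L, es$events$z,
                    length(es$biomarkers), es$z_max, sigma, max_sweeps)
  list(ordering = as.integer(res$ord) + 1L, loglik = res$loglik)
}

#' Greedy multi-start fit of a single event ordering
#'
#' From each random valid start the ascent tries every valid relocation of
#' every event and applies the best improvement until no move improves; the
#' best ordering across starts is returned.
#'
#' @param Z Subjects x biomarkers z-score matrix (modelled biomarkers).
#' @param es Event set.
#' @param n_starts Number of random restarts.
#' @param sigma Biomarker noise sd (scalar or per-biomarker).
#' @param max_sweeps Cap on ascent sweeps per start.
#' @param seed Optional RNG seed.
#' @return List with `ordering`, `loglik`, and `start_logliks` (final
#'   log-likelihood per start).
#' @export
greedy_fit_single <- function(Z, es, n_starts = 25, sigma = 1,
                              max_sweeps = 200, seed = NULL) {
  if (n_starts < 1L) stop("n_starts must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  Z <- check_Z(Z, es)
  sigma <- sigma_vec(sigma, length(es$biomarkers))
  best <- NULL
  lls <- numeric(n_starts)
  for (s in seq_len(n_starts)) {
    fit <- greedy_one(Z, es, random_ordering(es), sigma, max_sweeps)
    lls[s] <- fit$loglik
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  best$start_logliks <- lls
  best
}

#' MCMC over event orderings of a fitted subtype model
#'
#' Metropolis sampling: per iteration one subtype and one event are chosen
#' uniformly and the event is relocated to a uniformly chosen valid
#' position; the move is accepted with probability min(1, exp(delta
#' log-likelihood)). Mixture fractions are held fixed so the chain is a
#' pure ordering sampler. Proposals are drawn from valid moves only, so
#' threshold order can never be violated.
#'
#' @param Z z-score matrix over the model's biomarkers.
#' @param model A [subtype_model()] used as the initial state.
#' @param n_iter Number of iterations.
#' @param thin Store every `thin`-th sample.
#' @param seed Optional RNG seed.
#' @return Object of class `mcmc_samples`: per-subtype sample matrices
#'   (stored samples x E, event ids by position), total log-likelihood
#'   trace, acceptance rate, and the maximum-likelihood orderings over the
#'   chain.
#' @export
mcmc_sample <- function(Z, model, n_iter, thin = 10, seed = NULL) {
  stopifnot(inherits(model, "subtype_model"))
  if (n_iter < 1) stop("n_iter must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  Z <- check_Z(Z, model$es)
  es <- model$es
  res <- cpp_mcmc(Z, lapply(model$orderings, function(o) o - 1L), model$f,
                  es$events$bio_index - 1L, es$events$z,
                  length(es$biomarkers), es$z_max, model$sigma,
                  as.integer(n_iter), as.integer(thin))
  structure(
    list(orderings = lapply(res$samples, function(m) m + 1L),
         trace = res$trace,
         accept_rate = res$accept_rate,
         ml_orderings = lapply(res$ml_ords, function(o) as.integer(o) + 1L),
         ml_loglik = res$ml_loglik,
         n_iter = n_iter, thin = thin, es = es),
    class = "mcmc_samples")
}

#' @export
print.mcmc_samples <- function(x, ...) {
  cat("MCMC samples:", nrow(x$orderings[[1]]), "stored x",
      length(x$orderings), "subtype(s); acceptance rate",
      sprintf("%.3f", x$accept_rate), "\n")
  invisible(x)
}

hard_assign <- function(LL, f) {
  M <- sweep(LL, 2, log(f), "+")
  max.col(M, ties.method = "first")
}

classification_loglik <- function(LL, assign, f) {
  sum(LL[cbind(seq_len(nrow(LL)), assign)] + log(f)[assign])
}

# Hard EM: alternate (i) hard reassignment of all subjects under current
# fractions, (ii) greedy refit of each cluster's ordering on its members,
# (iii) fraction update to assignment proportions. The classification
# log-likelihood is non-decreasing; iteration stops when assignments are
# stable.
em_refine <- function(Z, es, orderings, sigma, em_max_iter, max_sweeps) {
  n <- nrow(Z)
  C <- length(orderings)
  LL <- vapply(orderings, function(S)
    drop(cpp_subject_logliks(Z, S - 1L, es$events$bio_index - 1L,
                             es$events$z, length(es$biomarkers), es$z_max,
                             sigma)), numeric(n))
  # Fractions get a half-subject floor so a cluster that loses all its
  # members under hard assignment keeps a vanishing (but valid) mass
  # instead of invalidating the candidate.
  floor_fractions <- function(tab) {
    w <- pmax(tab, 0.5)
    w / sum(w)
  }
  f <- rep(1 / C, C)
  assign <- hard_assign(LL, f)
  trace <- numeric(0)
  for (it in seq_len(em_max_iter)) {
    tab <- tabulate(assign, C)
    f <- floor_fractions(tab)
    for (c in seq_len(C)) {
      idx <- which(assign == c)
      if (!length(idx)) next
      # warm-started partial ascent: a few passes per EM iteration suffice
      # (generalized EM; the classification log-likelihood stays monotone)
      fit <- greedy_one(Z[idx, , drop = FALSE], es, orderings[[c]], sigma,
                        min(3L, max_sweeps))
      orderings[[c]] <- fit$ordering
      LL[, c] <- drop(cpp_subject_logliks(
        Z, fit$ordering - 1L, es$events$bio_index - 1L, es$events$z,
        length(es$biomarkers), es$z_max, sigma))
    }
    new_assign <- hard_assign(LL, f)
    trace <- c(trace, classification_loglik(LL, new_assign, f))
    if (all(new_assign == assign)) { assign <- new_assign; break }
    assign <- new_assign
  }
  list(orderings = orderings, f = floor_fractions(tabulate(assign, C)),
       assign = assign, LL = LL, em_trace = trace)
}

finalize_model <- function(Z, es, orderings, f, control) {
  model <- subtype_model(orderings, es, f = f, sigma = control$sigma)
  mc <- mcmc_sample(Z, model, n_iter = control$mcmc_iter,
                    thin = control$thin)
  model$orderings <- mc$ml_orderings
  model$mcmc <- mc
  model$loglik <- mixture_loglik(Z, model)$loglik
  model
}

fit_hierarchy <- function(Z, es, kmax, control) {
  Z <- check_Z(Z, es)
  n <- nrow(Z)
  if (kmax > n) stop("k exceeds the number of subjects")
  sigma <- sigma_vec(control$sigma, length(es$biomarkers))
  control$sigma <- sigma
  levels <- vector("list", kmax)

  g1 <- greedy_fit_single(Z, es, n_starts = control$n_starts, sigma = sigma,
                          max_sweeps = control$max_sweeps)
  levels[[1]] <- finalize_model(Z, es, list(g1$ordering), 1, control)

  k <- 1L
  while (k < kmax) {
    base <- levels[[k]]
    LL <- subject_loglik_matrix(Z, base)
    if (is.null(dim(LL))) LL <- matrix(LL, nrow = n)
    assign <- hard_assign(LL, base$f)
    best <- NULL
    for (c_split in seq_len(k)) {
      members <- which(assign == c_split)
      if (length(members) < 4L) next
      for (try in seq_len(control$n_splits)) {
        repeat {
          side <- runif(length(members)) < 0.5
          if (sum(side) >= 2 && sum(!side) >= 2) break
        }
        halves <- lapply(list(members[side], members[!side]), function(idx)
          greedy_fit_single(Z[idx, , drop = FALSE], es,
                            n_starts = control$n_starts_split,
                            sigma = sigma,
                            max_sweeps = control$max_sweeps)$ordering)
        cand_ords <- c(base$orderings[-c_split], halves)
        em <- em_refine(Z, es, cand_ords, sigma, control$em_max_iter,
                        control$max_sweeps)
        if (is.null(em)) next
        total <- {
          M <- sweep(em$LL, 2, log(em$f), "+")
          m <- apply(M, 1, max)
          sum(m + log(rowSums(exp(M - m))))
        }
        if (is.null(best) || total > best$total)
          best <- list(total = total, em = em)
      }
    }
    if (is.null(best))
      stop("no valid cluster split found when growing to k = ", k + 1)
    k <- k + 1L
    levels[[k]] <- finalize_model(Z, es, best$em$orderings, best$em$f,
                                  control)
    attr(levels[[k]], "em_trace") <- best$em$em_trace
  }
  levels
}

#' Fit a k-subtype progression model
#'
#' Hierarchical construction: the (k-1)-subtype solution's clusters are
#' candidate-split by random bipartition, each half fitted by greedy
#' ascent, refined by hard EM over all subjects, and the split with the
#' highest total likelihood is kept. Mixture fractions are set to the
#' converged assignment proportions, after which MCMC is run for ordering
#' uncertainty; the returned orderings are the maximum-likelihood sequences
#' over the chain.
#'
#' @inheritParams greedy_fit_single
#' @param k Number of subtypes (k = 1 reduces to a single greedy fit plus
#'   MCMC).
#' @param control A [sustain_control()] list.
#' @return A [subtype_model()] with `$mcmc` samples attached; models for
#'   1..k are available through `attr(, "levels")`.
#' @export
fit_subtypes <- function(Z, es, k, control = sustain_control(),
                         seed = NULL) {
  if (k < 1L) stop("k must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  levels <- fit_hierarchy(Z, es, k, control)
  model <- levels[[k]]
  attr(model, "levels") <- levels
  model
}

#' Select the number of subtypes by CVIC
#'
#' Subjects are split into folds without stratification; for every fold the
#' hierarchy is fitted on the training folds and the held-out
#' log-likelihood, averaged over MCMC samples of the training fit, is
#' recorded for each candidate k. CVIC(k) is -2 times the summed
#' out-of-sample log-likelihood across folds; the selected k minimizes
#' CVIC.
#'
#' @inheritParams fit_subtypes
#' @param k_range Candidate subtype counts.
#' @param n_folds Number of cross-validation folds (>= 2).
#' @return Object of class `cvic_report`: a table of CVIC and
#'   out-of-sample log-likelihood per k, the per-fold values and the
#'   selected k.
#' @export
select_model_order <- function(Z, es, k_range = 2:6, n_folds = 10,
                               control = sustain_control(), seed = NULL) {
  if (n_folds < 2L) stop("n_folds must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  Z <- check_Z(Z, es)
  n <- nrow(Z)
  k_range <- sort(unique(as.integer(k_range)))
  kmax <- max(k_range)
  fold <- sample(rep(seq_len(n_folds), length.out = n))
  if (min(tabulate(fold, n_folds)) < kmax)
    stop("a fold has fewer subjects than the largest candidate k")
  per_fold <- matrix(NA_real_, n_folds, length(k_range),
                     dimnames = list(NULL, paste0("k", k_range)))
  for (fd in seq_len(n_folds)) {
    train <- Z[fold != fd, , drop = FALSE]
    test <- Z[fold == fd, , drop = FALSE]
    levels <- fit_hierarchy(train, es, kmax, control)
    for (j in seq_along(k_range)) {
      model <- levels[[k_range[j]]]
      samp <- model$mcmc$orderings
      n_stored <- nrow(samp[[1]])
      take <- unique(round(seq(1, n_stored,
                               length.out = min(control$cv_samples,
                                                n_stored))))
      lls <- vapply(take, function(s) {
        m <- model
        m$orderings <- lapply(samp, function(S) as.integer(S[s, ]))
        m$mcmc <- NULL
        mixture_loglik(test, m)$loglik
      }, numeric(1))
      per_fold[fd, j] <- mean(lls)
    }
  }
  oos <- colSums(per_fold)
  cvic <- -2 * oos
  structure(
    list(table = data.frame(k = k_range, cvic = unname(cvic),
                            oos_loglik = unname(oos)),
         per_fold = per_fold, n_folds = n_folds,
         selected_k = k_range[which.min(cvic)]),
    class = "cvic_report")
}

#' @export
print.cvic_report <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat("selected k =", x$selected_k, "\n")
  invisible(x)
}

#' Assign individuals to subtype and stage
#'
#' The subtype posterior follows from the mixture; the stage is the maximum
#' a-posteriori stage (uniform prior) within the maximum-likelihood
#' trajectory, restricted to stages 1..E. Subjects whose modelled z-scores
#' are all below 1 are assigned the label `"normal"` with stage 0 (the
#' no-atrophy rule).
#'
#' @param model A fitted [subtype_model()].
#' @param Z z-score matrix over the model's biomarkers.
#' @param normal_threshold z-score below which a region counts as
#'   unaffected (default 1).
#' @return Object of class `subject_assignment`: data frame with
#'   `subject_id`, `label` (`"trajectory_1"`.. or `"normal"`), `stage`, and
#'   one posterior column per trajectory.
#' @export
assign_individuals <- function(model, Z, normal_threshold = 1) {
  stopifnot(inherits(model, "subtype_model"))
  Z <- check_Z(Z, model$es)
  es <- model$es
  mix <- mixture_loglik(Z, model)
  C <- length(model$orderings)
  map_subtype <- max.col(mix$posterior, ties.method = "first")
  n <- nrow(Z)
  stage <- integer(n)
  for (c in seq_len(C)) {
    idx <- which(map_subtype == c)
    if (!length(idx)) next
    D <- cpp_stage_logdens(Z[idx, , drop = FALSE],
                           model$orderings[[c]] - 1L,
                           es$events$bio_index - 1L, es$events$z,
                           length(es$biomarkers), es$z_max, model$sigma)
    stage[idx] <- max.col(D[, -1, drop = FALSE], ties.method = "first")
  }
  label <- paste0("trajectory_", map_subtype)
  normal <- rowSums(Z >= normal_threshold) == 0
  label[normal] <- "normal"
  stage[normal] <- 0L
  out <- data.frame(
    subject_id = if (is.null(rownames(Z))) as.character(seq_len(n))
                 else rownames(Z),
    label = label, stage = stage, map_trajectory = map_subtype,
    stringsAsFactors = FALSE)
  post <- as.data.frame(mix$posterior)
  names(post) <- paste0("prob_trajectory_", seq_len(C))
  out <- cbind(out, post)
  class(out) <- c("subject_assignment", "data.frame")
  out
}

#' Positional variance of an MCMC ordering chain
#'
#' Entry (e, p) is the fraction of stored MCMC samples that place event e
#' at sequence position p; each row sums to one. The matrix is the standard
#' uncertainty display for inferred orderings.
#'
#' @param samples An [mcmc_sample()] result.
#' @param subtype Subtype index.
#' @return E x E matrix, rows named by event label.
#' @export
positional_variance <- function(samples, subtype = 1) {
  stopifnot(inherits(samples, "mcmc_samples"))
  M <- samples$orderings[[subtype]]
  if (is.null(M) || nrow(M) == 0) stop("empty MCMC sample store")
  E <- ncol(M)
  pv <- matrix(0, E, E)
  for (p in seq_len(E)) {
    tab <- tabulate(M[, p], E)
    pv[, p] <- tab / nrow(M)
  }
  rownames(pv) <- samples$es$events$label
  colnames(pv) <- seq_len(E)
  pv
}

label_confusion_agreement <- function(la, lb) {
  # Maximum-agreement matching of trajectory labels (the subtype indices
  # are arbitrary across fits); "normal" is rule-defined and matched to
  # itself. Exhaustive over permutations: C is small.
  ta <- sort(unique(la[la != "normal"]))
  tb <- sort(unique(lb[lb != "normal"]))
  base <- sum(la == "normal" & lb == "normal")
  if (!length(ta) || !length(tb)) {
    best <- base
    map <- character(0)
  } else {
    conf <- table(factor(la, levels = ta), factor(lb, levels = tb))
    small <- if (length(ta) <= length(tb)) "rows" else "cols"
    ka <- nrow(conf); kb <- ncol(conf)
    perms <- function(v) {
      if (length(v) <= 1) return(list(v))
      out <- list()
      for (i in seq_along(v))
        for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
      out
    }
    best <- -Inf; map <- NULL
    if (small == "rows") {
      for (p in perms(seq_len(kb))) {
        sel <- p[seq_len(min(ka, kb))]
        agree <- sum(conf[cbind(seq_len(min(ka, kb)), sel)])
        if (agree > best) { best <- agree; map <- tb[sel] }
      }
    } else {
      for (p in perms(seq_len(ka))) {
        sel <- p[seq_len(min(ka, kb))]
        agree <- sum(conf[cbind(sel, seq_len(min(ka, kb)))])
        if (agree > best) { best <- agree; map <- ta[sel] }
      }
    }
    best <- best + base
  }
  list(agreement = 100 * best / length(la), mapping = map)
}

#' Agreement between two subtype/stage assignments
#'
#' Trajectory labels are matched across the two assignments by
#' maximum-agreement permutation (subtype indices are arbitrary); the
#' `"normal"` label is rule-defined and compared directly. Stage agreement
#' is the Spearman rank correlation.
#'
#' @param a,b Two [assign_individuals()] results over the same subjects.
#' @return List with `agreement` (percent identical labels after
#'   matching), `stage_rho` and `stage_p`.
#' @export
assignment_consistency <- function(a, b) {
  if (nrow(a) != nrow(b) || !setequal(a$subject_id, b$subject_id))
    stop("assignments cover different subject sets")
  b <- b[match(a$subject_id, b$subject_id), ]
  m <- label_confusion_agreement(a$label, b$label)
  ct <- suppressWarnings(cor.test(a$stage, b$stage, method = "spearman",
                                  exact = FALSE))
  list(agreement = m$agreement, stage_rho = unname(ct$estimate),
       stage_p = ct$p.value, mapping = m$mapping)
}
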