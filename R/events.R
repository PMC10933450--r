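#' Define the event set of a z-score progression model
#'
#' An event is a (biomarker, z-threshold) pair; it "occurs" once the
#' biomarker's atrophy-positive z-score crosses that threshold. The stage
#' axis runs over the integers 0..E where E is the total event count.
#'
#' @param biomarkers Character vector of biomarker (ROI) names.
#' @param thresholds Either a numeric vector applied to every biomarker
#'   (default `c(1, 2, 3)`, the usual z-score waypoints) or a list with one
#'   strictly increasing numeric vector per biomarker.
#' @param z_max Plateau z-score reached at the end of the stage axis
#'   (default 5). Every threshold must lie strictly below it.
#' @return An object of class `event_set`: biomarker names, per-biomarker
#'   thresholds, `z_max`, the event table and the event count `E`.
#' @examples
#' es <- build_event_set(c("Left_Hippocampus", "Right_Hippocampus"))
#' es$E  # 6 events, stage axis 0..6
#' @export
build_event_set <- function(biomarkers, thresholds = c(1, 2, 3), z_max = 5) {
  if (length(biomarkers) < 1L) stop("need at least one biomarker")
  if (anyDuplicated(biomarkers)) stop("duplicated biomarker names")
  B <- length(biomarkers)
  if (!is.list(thresholds)) thresholds <- rep(list(as.numeric(thresholds)), B)
  if (length(thresholds) != B)
    stop("thresholds must be one vector, or one vector per biomarker")
  for (i in seq_len(B)) {
    th <- thresholds[[i]]
    if (length(th) < 1L) stop("each biomarker needs at least one threshold")
    if (any(diff(th) <= 0))
      stop("thresholds must be strictly increasing (biomarker ",
           biomarkers[i], ")")
    if (any(th >= z_max))
      stop("thresholds must lie below z_max (biomarker ", biomarkers[i], ")")
  }
  events <- data.frame(
    event     = seq_len(sum(lengths(thresholds))),
    biomarker = rep(biomarkers, lengths(thresholds)),
    bio_index = rep(seq_len(B), lengths(thresholds)),
    z         = unlist(thresholds, use.names = FALSE)
  )
  events$label <- paste0(events$biomarker, "_z", events$z)
  structure(
    list(biomarkers = biomarkers, thresholds = thresholds, z_max = z_max,
         events = events, E = nrow(events)),
    class = "event_set")
}

#' @export
print.event_set <- function(x, ...) {
  cat("Event set: ", length(x$biomarkers), " biomarkers, E = ", x$E,
      " events, z_max = ", x$z_max, "\n", sep = "")
  invisible(x)
}

#' Check that an ordering is a valid event sequence
#'
#' A valid ordering is a permutation of the event ids `1..E` in which each
#' biomarker's thresholds appear in increasing order.
#'
#' @param ordering Integer vector of event ids by sequence position.
#' @param es An [build_event_set()] object.
#' @return `TRUE` or `FALSE`.
#' @export
is_valid_ordering <- function(ordering, es) {
  E <- es$E
  if (length(ordering) != E || !setequal(ordering, seq_len(E))) return(FALSE)
  pos <- match(seq_len(E), ordering)
  for (b in seq_along(es$biomarkers)) {
    ids <- es$events$event[es$events$bio_index == b]
    if (is.unsorted(pos[ids], strictly = TRUE)) return(FALSE)
  }
  TRUE
}

assert_ordering <- function(ordering, es) {
  if (!is_valid_ordering(ordering, es))
    stop("invalid event ordering for this event set")
  invisible(as.integer(ordering))
}

#' Draw a uniformly random valid event ordering
#'
#' Positions are permuted uniformly, then within each biomarker the
#' occupied positions are re-filled with that biomarker's thresholds in
#' increasing order, which yields a valid ordering.
#'
#' @inheritParams is_valid_ordering
#' @return Integer vector of event ids.
#' @export
random_ordering <- function(es) {
  ord <- sample.int(es$E)
  for (b in seq_along(es$biomarkers)) {
    ids <- es$events$event[es$events$bio_index == b]
    slots <- which(ord %in% ids)
    ord[slots] <- ids  # slots ascending; ids already in threshold order
  }
  ord
}

sigma_vec <- function(sigma, B) {
  sigma <- as.numeric(sigma)
  if (length(sigma) == 1L) sigma <- rep(sigma, B)
  if (length(sigma) != B) stop("sigma must have length 1 or B")
  if (any(sigma <= 0)) stop("sigma must be positive")
  sigma
}

#' Expected biomarker trajectory of an event ordering
#'
#' For a biomarker with events at positions p1 < ... < pT and thresholds
#' z1 < ... < zT, the expected z-score over stages is the piecewise-linear
#' interpolant through (0, 0), (p1, z1), ..., (pT, zT) and (E, z_max),
#' evaluated at integer stages; when the last event occupies position E its
#' threshold anchor takes precedence over the z_max anchor.
#'
#' @inheritParams is_valid_ordering
#' @return A `B x (E+1)` matrix `g[b, k]`, rows named by biomarker, columns
#'   by stage `0..E`. Rows are non-decreasing.
#' @examples
#' es <- build_event_set(c("b1", "b2"), thresholds = c(1, 2), z_max = 3)
#' expected_trajectory(c(1, 2, 3, 4), es)["b1", ]  # 0 1 2 2.5 3
#' @export
expected_trajectory <- function(ordering, es) {
  ordering <- assert_ordering(ordering, es)
  G <- cpp_trajectory(ordering - 1L, es$events$bio_index - 1L, es$events$z,
                      length(es$biomarkers), es$z_max)
  dimnames(G) <- list(es$biomarkers, as.character(0:es$E))
  G
}

#' Stage likelihoods of one subject under an ordering
#'
#' Element k of the result is the product over biomarkers of the normal
#' density of the subject's z-score around the expected trajectory value at
#' stage k; a uniform prior over stages 0..E gives the stage posterior.
#'
#' @param z_row Numeric vector of atrophy-positive z-scores, one per
#'   biomarker of the event set (in event-set order).
#' @inheritParams is_valid_ordering
#' @param sigma Biomarker noise standard deviation(s); scalar or length-B
#'   vector (default 1, appropriate for normative z-scores).
#' @return List with `log_density` (length E+1) and `posterior`
#'   (normalized, sums to one).
#' @export
stage_likelihoods <- function(z_row, ordering, es, sigma = 1) {
  ordering <- assert_ordering(ordering, es)
  B <- length(es$biomarkers)
  if (length(z_row) != B) stop("z_row must have one value per biomarker")
  if (!all(is.finite(z_row))) stop("z_row must be finite")
  sigma <- sigma_vec(sigma, B)
  D <- cpp_stage_logdens(matrix(as.numeric(z_row), nrow = 1), ordering - 1L,
                         es$events$bio_index - 1L, es$events$z, B, es$z_max,
                         sigma)
  ld <- drop(D)
  post <- exp(ld - max(ld))
  list(log_density = setNames(ld, as.character(0:es$E)),
       posterior = setNames(post / sum(post), as.character(0:es$E)))
}

#' Stage-marginal log-likelihood of subjects under an ordering
#'
#' log[ (1/(E+1)) * sum_k prod_b N(z_b; g(b,k), sigma_b) ], computed with
#' log-sum-exp stabilisation.
#'
#' @param Z Numeric matrix (subjects x biomarkers) or a single z vector.
#' @inheritParams stage_likelihoods
#' @return Numeric vector, one log-likelihood per subject.
#' @export
subject_loglik <- function(Z, ordering, es, sigma = 1) {
  if (is.null(dim(Z))) Z <- matrix(as.numeric(Z), nrow = 1)
  ordering <- assert_ordering(ordering, es)
  B <- length(es$biomarkers)
  if (ncol(Z) != B) stop("Z must have one column per biomarker")
  if (!all(is.finite(Z))) stop("Z must be finite")
  sigma <- sigma_vec(sigma, B)
  drop(cpp_subject_logliks(Z, ordering - 1L, es$events$bio_index - 1L,
                           es$events$z, B, es$z_max, sigma))
}

#' Construct a subtype mixture model
#'
#' @param orderings List of valid event orderings, one per subtype.
#' @param f Mixture fractions (non-negative, summing to one). Default
#'   uniform.
#' @inheritParams stage_likelihoods
#' @param es An [build_event_set()] object shared by all subtypes.
#' @return An object of class `subtype_model`.
#' @export
subtype_model <- function(orderings, es, f = NULL, sigma = 1) {
  if (length(orderings) < 1L) stop("need at least one subtype ordering")
  orderings <- lapply(orderings, assert_ordering, es = es)
  C <- length(orderings)
  if (is.null(f)) f <- rep(1 / C, C)
  if (length(f) != C || any(f < 0) || abs(sum(f) - 1) > 1e-8)
    stop("mixture fractions must be non-negative and sum to one")
  structure(
    list(orderings = orderings, f = as.numeric(f),
         sigma = sigma_vec(sigma, length(es$biomarkers)),
         es = es, loglik = NA_real_, mcmc = NULL),
    class = "subtype_model")
}

#' @export
print.subtype_model <- function(x, ...) {
  cat("Subtype model: C =", length(x$orderings), "trajectories, E =",
      x$es$E, "events\n")
  cat("fractions:", paste(sprintf("%.3f", x$f), collapse = " "), "\n")
  if (is.finite(x$loglik)) cat("log-likelihood:", format(x$loglik), "\n")
  invisible(x)
}

subject_loglik_matrix <- function(Z, model) {
  vapply(model$orderings,
         function(S) subject_loglik(Z, S, model$es, model$sigma),
         numeric(nrow(Z)))
}

#' Mixture log-likelihood and subtype posteriors
#'
#' Total log-likelihood `sum_j log sum_c f_c L_jc` of a z-score matrix under
#' a subtype mixture, with the per-subject subtype posteriors
#' `P(c | x_j) = f_c L_jc / sum_c' f_c' L_jc'`.
#'
#' @param Z Subjects x biomarkers z-score matrix (modelled biomarkers, in
#'   event-set order).
#' @param model A [subtype_model()].
#' @return List with `loglik` (scalar), `subject_loglik` (n x C matrix of
#'   per-subtype stage-marginal log-likelihoods) and `posterior` (n x C,
#'   rows sum to one).
#' @export
mixture_loglik <- function(Z, model) {
  stopifnot(inherits(model, "subtype_model"))
  if (is.null(dim(Z))) Z <- matrix(as.numeric(Z), nrow = 1)
  LL <- subject_loglik_matrix(Z, model)
  if (is.null(dim(LL))) LL <- matrix(LL, nrow = 1)
  M <- sweep(LL, 2, log(model$f), "+")
  m <- apply(M, 1, max)
  lse <- m + log(rowSums(exp(M - m)))
  post <- exp(M - lse)
  list(loglik = sum(lse), subject_loglik = LL, posterior = post)
}
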