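# Shared test utilities: independent oracles and small generators.

# All valid event orderings by exhaustive permutation + validity filter.
all_valid_orderings <- function(es) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  Filter(function(o) is_valid_ordering(o, es), perms(seq_len(es$E)))
}

# Naive stage-marginal log-likelihood, no log-sum-exp tricks.
naive_subject_loglik <- function(z, ordering, es, sigma = 1) {
  g <- expected_trajectory(ordering, es)
  sig <- rep(sigma, length.out = length(es$biomarkers))
  lik <- vapply(0:es$E, function(k)
    prod(dnorm(z, g[, k + 1], sig)), numeric(1))
  log(mean(lik))
}

# Adjusted Rand index (closed form).
adjusted_rand <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  ea <- b * cc / n2
  (a - ea) / ((b + cc) / 2 - ea)
}

# Two structurally opposite (well-separated) orderings: biomarker-by-
# biomarker progression in opposite biomarker order.
opposite_orderings <- function(es) {
  ids <- function(b) which(es$events$bio_index == b)
  B <- length(es$biomarkers)
  list(unlist(lapply(seq_len(B), ids)),
       unlist(lapply(rev(seq_len(B)), ids)))
}

# z-score draws around a trajectory at given stages.
draw_from_trajectory <- function(g, stages, sigma = 1) {
  B <- nrow(g)
  Z <- t(vapply(stages, function(s) rnorm(B, g[, s + 1], sigma),
                numeric(B)))
  colnames(Z) <- rownames(g)
  Z
}

# Best-permutation trajectory-label recovery fraction against true integer
# labels (1..C), for assignments restricted to trajectory subjects.
label_recovery <- function(true_labels, assigned_labels, C) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- 0
  for (p in perms(seq_len(C))) {
    mapped <- paste0("trajectory_", p[true_labels])
    best <- max(best, mean(mapped == assigned_labels))
  }
  best
}
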