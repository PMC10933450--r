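# Subtype characterization: stage-atrophy correlations, ROI-wise group
# contrasts with Benjamini-Hochberg FDR, one-vs-all and pairwise clinical
# comparisons (ANOVA + LSD / Pearson chi-square), and seizure-freedom
# contingency statistics.

#' Spearman correlation between stage and atrophy burden
#'
#' For every trajectory subtype, the Spearman correlation between the
#' assigned stage and a per-subject atrophy summary (by default the mean
#' modelled z-score; alternatively a single ROI column of `Z`).
#'
#' @param assign An [assign_individuals()] result.
#' @param Z z-score matrix aligned to the assignment's subjects.
#' @param roi Optional ROI name; when NULL the row mean of `Z` is used.
#' @return Data frame with one row per trajectory subtype: `label`, `n`,
#'   `rho`, `p`.
#' @export
stage_atrophy_correlation <- function(assign, Z, roi = NULL) {
  stopifnot(inherits(assign, "subject_assignment"))
  value <- if (is.null(roi)) rowMeans(Z) else {
    if (!roi %in% colnames(Z)) stop("unknown ROI: ", roi)
    Z[, roi]
  }
  labels <- setdiff(sort(unique(assign$label)), "normal")
  out <- lapply(labels, function(lb) {
    idx <- which(assign$label == lb)
    if (length(idx) < 3L)
      stop("fewer than 3 staged subjects in ", lb)
    if (sd(value[idx]) == 0 || sd(assign$stage[idx]) == 0)
      stop("constant input: correlation undefined in ", lb)
    ct <- suppressWarnings(cor.test(assign$stage[idx], value[idx],
                                    method = "spearman", exact = FALSE))
    data.frame(label = lb, n = length(idx), rho = unname(ct$estimate),
               p = ct$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' ROI-wise two-sample contrasts between two z-score groups
#'
#' Per-ROI two-sided two-sample t-test (pooled variance by default),
#' Benjamini-Hochberg adjusted across ROIs. ROIs with zero pooled variance
#' are flagged degenerate rather than tested.
#'
#' @param Z_a,Z_b z-score matrices with identical ROI columns (group a
#'   rows, group b rows).
#' @param var_equal Pooled-variance t (default TRUE); FALSE gives Welch.
#' @return Data frame: `roi`, group means, `t`, `df`, `p`, `q`,
#'   `degenerate`.
#' @export
roiwise_group_comparison <- function(Z_a, Z_b, var_equal = TRUE) {
  Z_a <- as.matrix(Z_a); Z_b <- as.matrix(Z_b)
  if (!identical(colnames(Z_a), colnames(Z_b)))
    stop("groups have different ROI columns")
  na <- nrow(Z_a); nb <- nrow(Z_b)
  if (na < 2L || nb < 2L) stop("each group needs n >= 2")
  ma <- colMeans(Z_a); mb <- colMeans(Z_b)
  va <- apply(Z_a, 2, var); vb <- apply(Z_b, 2, var)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(ma))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  degenerate <- se == 0
  tval <- ifelse(degenerate & ma == mb, 0,
                 (ma - mb) / ifelse(se == 0, NA, se))
  p <- 2 * pt(-abs(tval), df)
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- p.adjust(p[ok], method = "BH")
  data.frame(roi = colnames(Z_a), mean_a = ma, mean_b = mb, t = tval,
             df = df, p = p, q = q, degenerate = degenerate & !(ma == mb),
             row.names = NULL, stringsAsFactors = FALSE)
}

pearson_chisq <- function(tab) {
  # Pearson chi-square without continuity correction.
  tab <- as.matrix(tab)
  exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  contrib <- ifelse(exp_tab > 0, (tab - exp_tab)^2 / exp_tab, 0)
  stat <- sum(contrib)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}

#' Clinical comparisons between subtypes
#'
#' Continuous variables: one-way ANOVA across all subtypes plus the
#' requested contrasts — one-vs-all pooled two-sample t-tests (the squared
#' t is also reported as an F) or pairwise least-significant-difference
#' t-tests sharing the pooled ANOVA error term. Categorical variables:
#' Pearson chi-square without continuity correction. p-values are
#' Benjamini-Hochberg adjusted within the returned family of contrasts.
#' Variables with a single observed level are skipped with a warning.
#'
#' @param clin Clinical table (or data frame); `subject_id` is ignored.
#' @param labels Subtype label per row of `clin`.
#' @param mode `"one_vs_all"` or `"pairwise"`.
#' @param variables Columns to compare; defaults to all except
#'   `subject_id`.
#' @return Tidy data frame, one row per (variable, contrast).
#' @export
clinical_compare <- function(clin, labels,
                             mode = c("one_vs_all", "pairwise"),
                             variables = NULL) {
  mode <- match.arg(mode)
  df <- as.data.frame(clin)
  if (length(labels) != nrow(df))
    stop("labels must align with clinical rows")
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) stop("need at least 2 subtype labels")
  if (is.null(variables))
    variables <- setdiff(names(df), c("subject_id", "outcome"))
  groups <- sort(unique(labels))
  rows <- list()
  for (v in variables) {
    x <- df[[v]]
    continuous <- is.numeric(x)
    if (!continuous) x <- as.character(x)
    keep <- !is.na(x)
    if (length(unique(x[keep])) < 2L) {
      warning("variable ", v, " has a single level; skipped")
      next
    }
    if (continuous) {
      grand <- split(x[keep], labels[keep])
      k <- length(grand); N <- sum(keep)
      means <- vapply(grand, mean, 0); ns <- lengths(grand)
      sse <- sum(vapply(grand, function(g) sum((g - mean(g))^2), 0))
      mse <- sse / (N - k)
      ssb <- sum(ns * (means - mean(x[keep]))^2)
      fstat <- (ssb / (k - 1)) / mse
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, contrast = "omnibus", test = "anova_F",
        statistic = fstat, p = pf(fstat, k - 1, N - k, lower.tail = FALSE),
        stringsAsFactors = FALSE)
      if (mode == "one_vs_all") {
        for (g in groups) {
          a <- x[keep & labels == g]; b <- x[keep & labels != g]
          if (length(a) < 2L || length(b) < 2L) next
          sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
            (length(a) + length(b) - 2)
          tstat <- (mean(a) - mean(b)) /
            sqrt(sp2 * (1 / length(a) + 1 / length(b)))
          dfree <- length(a) + length(b) - 2
          rows[[length(rows) + 1]] <- data.frame(
            variable = v, contrast = paste0(g, "_vs_rest"), test = "t",
            statistic = tstat, p = 2 * pt(-abs(tstat), dfree),
            stringsAsFactors = FALSE)
        }
      } else {
        for (i in seq_len(k - 1)) for (j in (i + 1):k) {
          tstat <- (means[i] - means[j]) /
            sqrt(mse * (1 / ns[i] + 1 / ns[j]))
          rows[[length(rows) + 1]] <- data.frame(
            variable = v,
            contrast = paste0(names(grand)[i], "_vs_", names(grand)[j]),
            test = "lsd_t", statistic = unname(tstat),
            p = 2 * pt(-abs(tstat), N - k), stringsAsFactors = FALSE)
        }
      }
    } else {
      if (mode == "one_vs_all") {
        for (g in groups) {
          tab <- table(x[keep], factor(labels[keep] == g,
                                       levels = c(FALSE, TRUE)))
          if (any(dim(tab) < 2)) next
          cs <- pearson_chisq(tab)
          rows[[length(rows) + 1]] <- data.frame(
            variable = v, contrast = paste0(g, "_vs_rest"),
            test = "chisq", statistic = cs$statistic, p = cs$p,
            stringsAsFactors = FALSE)
        }
      } else {
        for (i in seq_along(groups)[-length(groups)])
          for (j in (which(groups == groups[i]) + 1):length(groups)) {
            sel <- keep & labels %in% groups[c(i, j)]
            tab <- table(x[sel], labels[sel])
            if (any(dim(tab) < 2)) next
            cs <- pearson_chisq(tab)
            rows[[length(rows) + 1]] <- data.frame(
              variable = v,
              contrast = paste0(groups[i], "_vs_", groups[j]),
              test = "chisq", statistic = cs$statistic, p = cs$p,
              stringsAsFactors = FALSE)
          }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no comparable variables")
  out$q <- p.adjust(out$p, method = "BH")
  out
}

#' Seizure-freedom rates and one-vs-rest chi-square tests
#'
#' Per-subtype follow-up seizure-freedom rate within a treatment arm
#' (denominator excludes subjects lost to follow-up), the pooled rate of
#' the remaining subtypes, and the uncorrected Pearson chi-square of each
#' subtype-vs-rest 2x2 table.
#'
#' @param clin Clinical table with `treatment_arm` and `outcome` columns
#'   (ignored when `counts` is given).
#' @param labels Subtype label per clinical row.
#' @param arm `"OG"` (operative) or `"MG"` (medication).
#' @param counts Optional matrix of effective/ineffective counts (rows =
#'   subtypes, columns `effective`, `ineffective`) bypassing `clin`.
#' @return Data frame per subtype: counts, `rate` and `rest_rate` (percent),
#'   `chi_sq`, `p`; overall k x 2 chi-square in
#'   `attr(, "overall")`.
#' @export
seizure_freedom_table <- function(clin = NULL, labels = NULL,
                                  arm = c("OG", "MG"), counts = NULL) {
  if (is.null(counts)) {
    arm <- match.arg(arm)
    df <- as.data.frame(clin)
    if (!all(c("treatment_arm", "outcome") %in% names(df)))
      stop("clinical table needs treatment_arm and outcome columns")
    sel <- df$treatment_arm == arm & df$outcome %in%
      c("effective", "ineffective")
    if (!any(df$treatment_arm == arm)) stop("empty treatment arm: ", arm)
    lab <- as.character(labels)[sel]
    eff <- df$outcome[sel] == "effective"
    subtypes <- sort(unique(as.character(labels)))
    counts <- t(vapply(subtypes, function(s)
      c(effective = sum(eff[lab == s]),
        ineffective = sum(!eff[lab == s])), numeric(2)))
  } else {
    counts <- as.matrix(counts)
    colnames(counts) <- c("effective", "ineffective")
    if (is.null(rownames(counts)))
      rownames(counts) <- paste0("subtype_", seq_len(nrow(counts)))
  }
  tot_eff <- sum(counts[, 1]); tot_ine <- sum(counts[, 2])
  out <- data.frame(
    subtype = rownames(counts),
    effective = counts[, 1], ineffective = counts[, 2],
    rate = 100 * counts[, 1] / rowSums(counts),
    rest_rate = 100 * (tot_eff - counts[, 1]) /
      (tot_eff + tot_ine - rowSums(counts)),
    chi_sq = NA_real_, p = NA_real_,
    row.names = NULL, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(counts))) {
    tab <- rbind(counts[i, ], c(tot_eff, tot_ine) - counts[i, ])
    if (any(rowSums(tab) == 0)) next
    cs <- pearson_chisq(tab)
    out$chi_sq[i] <- cs$statistic
    out$p[i] <- cs$p
  }
  if (all(colSums(counts) > 0) && nrow(counts) > 1)
    attr(out, "overall") <- pearson_chisq(counts)
  out
}
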