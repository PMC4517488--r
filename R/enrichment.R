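# Group-enrichment scores and the statistics layer: the per-factor
# X/Y score (mean over group I or II relative to all promoters), the
# expression-quintile occupancy correlation, hypergeometric overlap
# tests, Welch t-tests, and whisker-box summaries.

#' Score a factor's enrichment at group I promoters
#'
#' For per-promoter tag counts of one factor,
#' `x = mean(group I) / mean(all)` and `y = mean(group II) / mean(all)`.
#' The factor is called enriched at group I when x exceeds y by at
#' least 10% (`x >= 1.1 * y`). Both scores are scale-invariant:
#' multiplying all counts by a constant changes nothing.
#'
#' @param factor_counts Named numeric vector of per-promoter counts.
#' @param groupI_ids,groupII_ids,all_ids Promoter id sets (non-empty).
#' @param factor_name Optional label carried into the result.
#' @return data.frame row: `factor_name`, `x_score`, `y_score`,
#'   `call` (`"enriched_I"` or `"not_enriched"`).
#' @export
enrichment_score <- function(factor_counts, groupI_ids, groupII_ids,
                             all_ids, factor_name = NA_character_) {
  if (!length(groupI_ids) || !length(groupII_ids) || !length(all_ids)) {
    stop("all three id sets must be non-empty")
  }
  get <- function(ids) {
    v <- factor_counts[ids]
    if (anyNA(v)) stop("counts missing for some promoter ids")
    v
  }
  m_all <- mean(get(all_ids))
  if (m_all == 0) stop("mean count over all promoters is zero")
  x <- mean(get(groupI_ids)) / m_all
  y <- mean(get(groupII_ids)) / m_all
  data.frame(factor_name = factor_name, x_score = x, y_score = y,
             call = if (x >= 1.1 * y) "enriched_I" else "not_enriched")
}

#' Enrichment scores for a table of factors
#'
#' @param count_table Matrix or data.frame of per-promoter counts,
#'   rows named by promoter id, one column per factor.
#' @inheritParams enrichment_score
#' @return data.frame with one [enrichment_score()] row per factor.
#' @export
enrichment_table <- function(count_table, groupI_ids, groupII_ids, all_ids) {
  count_table <- as.matrix(count_table)
  do.call(rbind, lapply(colnames(count_table), function(f) {
    enrichment_score(stats::setNames(count_table[, f],
                                     rownames(count_table)),
                     groupI_ids, groupII_ids, all_ids, factor_name = f)
  }))
}

#' Split promoters (excluding group I) into expression quintiles
#'
#' Promoters are ordered by expression, ties broken by their stable
#' input order, and cut into five contiguous classes whose sizes
#' differ by at most one.
#'
#' @param expression Named numeric vector of promoter expression.
#' @param groupI_ids Promoter ids to exclude before splitting.
#' @return Named integer vector of quintiles (1 = lowest expression).
#' @export
expression_quintiles <- function(expression, groupI_ids = character(0)) {
  keep <- setdiff(names(expression), groupI_ids)
  if (length(keep) < 5L) stop("need at least 5 promoters outside group I")
  e <- expression[keep]
  ord <- order(e, seq_along(e))                  # stable tie-break
  sizes <- tabulate(rep_len(1:5, length(e)), 5L) # sizes differ by <= 1
  q <- integer(length(e))
  q[ord] <- rep(1:5, times = sizes)
  stats::setNames(q, keep)
}

#' Correlation of two factors' occupancy across expression quintiles
#'
#' Promoters outside group I are split into expression quintiles and
#' the Pearson correlation between the five quintile means of the two
#' factors is returned — the quantitative form of comparing metagene
#' profiles per expression class.
#'
#' @param expression Named per-promoter expression vector.
#' @param groupI_ids Promoters excluded from the quintile split.
#' @param factor_a_counts,factor_b_counts Named per-promoter counts.
#' @return Pearson `r` between the quintile means.
#' @export
quintile_correlation <- function(expression, groupI_ids,
                                 factor_a_counts, factor_b_counts) {
  q <- expression_quintiles(expression, groupI_ids)
  ids <- names(q)
  a <- factor_a_counts[ids]
  b <- factor_b_counts[ids]
  if (anyNA(a) || anyNA(b)) stop("counts missing for some promoters")
  ma <- tapply(a, q, mean)
  mb <- tapply(b, q, mean)
  if (stats::sd(ma) == 0 || stats::sd(mb) == 0) {
    stop("zero variance across quintiles")
  }
  stats::cor(as.numeric(ma), as.numeric(mb))
}

#' Hypergeometric overlap test
#'
#' Probability of drawing at least `n_overlap` feature-positive
#' promoters when `n_sample` promoters are drawn without replacement
#' from a population of `n_population` containing `n_feature`
#' positives — the standard test for, e.g., CpG-island enrichment of a
#' bound-promoter set.
#'
#' @param n_population,n_feature,n_sample,n_overlap Counts satisfying
#'   `n_overlap <= min(n_feature, n_sample) <= n_population`.
#' @param alternative `"greater"` (upper tail, default) or
#'   `"two.sided"` (doubling rule, capped at 1).
#' @return The p-value.
#' @export
hypergeom_overlap_test <- function(n_population, n_feature, n_sample,
                                   n_overlap,
                                   alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (n_feature > n_population || n_sample > n_population ||
      n_overlap > min(n_feature, n_sample) ||
      n_overlap < max(0L, n_feature + n_sample - n_population) ||
      any(c(n_population, n_feature, n_sample, n_overlap) < 0)) {
    stop("inconsistent hypergeometric counts")
  }
  upper <- stats::phyper(n_overlap - 1, n_feature,
                         n_population - n_feature, n_sample,
                         lower.tail = FALSE)
  if (alternative == "greater") return(upper)
  lower <- stats::phyper(n_overlap, n_feature, n_population - n_feature,
                         n_sample)
  min(1, 2 * min(upper, lower))
}

#' Welch's unpaired two-sample t-test
#'
#' The unequal-variance form of the unpaired t-test, appropriate when
#' comparing a small promoter class against a much larger one. Errors
#' when both samples are degenerate (zero variance).
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @return List with `t` (statistic), `df` (Welch-Satterthwaite
#'   degrees of freedom) and `p` (two-sided).
#' @export
unpaired_t_test <- function(values_a, values_b) {
  na <- length(values_a); nb <- length(values_b)
  if (na < 2L || nb < 2L) stop("each group needs at least 2 values")
  va <- stats::var(values_a); vb <- stats::var(values_b)
  if (va + vb == 0) stop("degenerate samples: zero variance in both groups")
  se2 <- va / na + vb / nb
  t <- (mean(values_a) - mean(values_b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Whisker-box summary
#'
#' The five numbers drawn in the package's box plots: 5% whisker,
#' lower quartile, median, upper quartile, 95% whisker.
#'
#' @param values Numeric vector (length >= 1, no NAs).
#' @return Named numeric vector `p5, q1, median, q3, p95`,
#'   non-decreasing.
#' @export
box_summary <- function(values) {
  if (length(values) == 0L || anyNA(values)) {
    stop("values must be non-empty and free of NAs")
  }
  q <- stats::quantile(values, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
  stats::setNames(q, c("p5", "q1", "median", "q3", "p95"))
}
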