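#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Two-sided nonparametric comparison of two independent samples. The exact
#' p-value (by enumeration of rank arrangements) is used when the combined
#' sample size is at most 12 and there are no ties; otherwise the normal
#' approximation with tie correction (and continuity correction) is used,
#' as in the standard large-sample Mann-Whitney test.
#'
#' @param x,y Numeric samples.
#' @return A one-row tibble: `statistic` (U for the first sample),
#'   `p_value`, `method`, `significant` (at 0.05).
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("empty sample")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= 12 && !ties
  ht <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE, alternative = "two.sided"))
  tibble(statistic = unname(ht$statistic),
         p_value = ht$p.value,
         method = if (exact) "exact" else "normal approximation (tie-corrected)",
         significant = ht$p.value < 0.05)
}

#' Spearman rank correlation
#'
#' Rank correlation with mid-ranks for ties; the p-value uses the
#' asymptotic t approximation.
#'
#' @param x,y Paired numeric samples, n >= 3.
#' @return A one-row tibble: `rho`, `statistic` (t), `p_value`,
#'   `significant`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) abort("samples must be paired")
  n <- length(x)
  if (n < 3) abort("need at least 3 pairs")
  if (sd(x) == 0 || sd(y) == 0) abort("constant input: ranks undefined")
  rho <- cor(rank(x), rank(y))
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), n - 2, lower.tail = FALSE)
  p <- min(p, 1)
  tibble(rho = rho, statistic = tstat, p_value = p, significant = p < 0.05)
}

#' Mixed repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Split-plot ANOVA with one between-subject factor (group) and one
#' within-subject factor (the repeated measures: frequency components,
#' feature points, transfer-function samples, or correlation lags). The
#' within-subject effect and the interaction are tested with
#' Greenhouse-Geisser-corrected degrees of freedom to compensate for
#' non-sphericity: epsilon is computed from the eigenvalues of the
#' double-centred pooled within-group covariance as
#' `(sum lambda)^2 / ((k - 1) * sum lambda^2)`, floored at `1/(k - 1)` and
#' capped at 1.
#'
#' @param measures Numeric matrix, subjects in rows, repeated measures in
#'   columns.
#' @param group Factor (or vector) of group labels, one per subject.
#' @return A tibble of class `rm_anova` with one row per effect
#'   (`group`, `measure`, `measure:group`): `df1`, `df2`, `statistic` (F),
#'   `epsilon`, `p_value`, `significant`. Between-subject rows carry
#'   epsilon 1.
#' @export
rm_anova_gg <- function(measures, group) {
  measures <- as.matrix(measures)
  n <- nrow(measures)
  k <- ncol(measures)
  group <- factor(group)
  if (length(group) != n) abort("one group label per subject required")
  if (any(table(group) < 2)) abort("need at least two subjects per group")
  if (k < 2) abort("need at least two repeated measures")
  g <- nlevels(group)

  grand <- mean(measures)
  subj_means <- rowMeans(measures)
  meas_means <- colMeans(measures)
  cell_means <- apply(measures, 2, function(col) tapply(col, group, mean))
  cell_means <- matrix(cell_means, nrow = g)   # g x k
  group_means <- tapply(subj_means, group, mean)
  n_per <- as.vector(table(group))

  ss_between_subj <- k * sum((subj_means - grand)^2)
  ss_group <- k * sum(n_per * (group_means - grand)^2)
  ss_subj_within <- ss_between_subj - ss_group

  ss_total <- sum((measures - grand)^2)
  ss_measure <- n * sum((meas_means - grand)^2)
  ss_cells <- sum(n_per * (cell_means - grand)^2)   # n_per recycles over rows
  ss_interaction <- ss_cells - ss_group - ss_measure
  ss_within_subj <- ss_total - ss_between_subj
  ss_error_within <- ss_within_subj - ss_measure - ss_interaction

  df_group <- g - 1
  df_subj <- n - g
  df_meas <- k - 1
  df_int <- (g - 1) * (k - 1)
  df_err <- (n - g) * (k - 1)

  # Greenhouse-Geisser epsilon from the pooled within-group covariance
  centred <- measures - cell_means[as.integer(group), , drop = FALSE]
  S <- crossprod(centred) / max(n - g, 1)
  C <- S - matrix(rowMeans(S), k, k) - matrix(colMeans(S), k, k, byrow = TRUE) +
    mean(S)
  lam <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  eps <- if (sum(lam^2) > 0) sum(lam)^2 / ((k - 1) * sum(lam^2)) else 1
  eps <- min(max(eps, 1 / (k - 1)), 1)

  f_group <- (ss_group / df_group) / (ss_subj_within / df_subj)
  f_meas <- (ss_measure / df_meas) / (ss_error_within / df_err)
  f_int <- (ss_interaction / df_int) / (ss_error_within / df_err)

  p_group <- pf(f_group, df_group, df_subj, lower.tail = FALSE)
  p_meas <- pf(f_meas, eps * df_meas, eps * df_err, lower.tail = FALSE)
  p_int <- pf(f_int, eps * df_int, eps * df_err, lower.tail = FALSE)

  out <- tibble(
    effect = c("group", "measure", "measure:group"),
    df1 = c(df_group, eps * df_meas, eps * df_int),
    df2 = c(df_subj, eps * df_err, eps * df_err),
    statistic = c(f_group, f_meas, f_int),
    epsilon = c(1, eps, eps),
    p_value = c(p_group, p_meas, p_int))
  out$significant <- out$p_value < 0.05
  class(out) <- c("rm_anova", class(out))
  out
}

#' Log-transform a sample if it fails a normality screen
#'
#' Normality is screened with the Shapiro-Wilk test at the 0.05 level; only
#' samples that fail are log-transformed (requiring strictly positive
#' values), matching the convention of transforming non-normally
#' distributed variables before parametric analysis.
#'
#' @param x Numeric sample (n between 3 and 5000 for the screen).
#' @return A list: `values` (possibly transformed), `transformed` (flag),
#'   `shapiro_p`.
#' @export
log_transform_if_nonnormal <- function(x) {
  if (length(x) < 3) abort("need at least 3 values")
  p <- shapiro.test(x)$p.value
  if (p >= 0.05) return(list(values = x, transformed = FALSE, shapiro_p = p))
  if (any(x <= 0))
    abort("non-normal sample contains non-positive values: log transform undefined")
  list(values = log(x), transformed = TRUE, shapiro_p = p)
}
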