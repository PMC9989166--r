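#' Zero-safe log transform
#'
#' Attack durations are log transformed before testing to meet normality
#' assumptions; sessions without any attack score exactly 0, which the plain
#' log cannot handle. When zeros are present a constant
#' `c = sqrt(Q1 / Q3)` (square root of the ratio of the first to the third
#' quartile of the full value set, quartiles by linear interpolation) is
#' added before taking the natural log. Without zeros `c = 0`. A degenerate
#' first quartile of 0 falls back to half the smallest positive value, with a
#' warning.
#'
#' @param values non-negative numeric values, not all zero.
#' @return A list of class `transform_result`: `transformed`, `constant`,
#'   `q1`, `q3`.
#' @examples
#' zero_safe_log(c(0, 1, 2, 4, 4))$constant  # sqrt(1/4) = 0.5
#' @export
zero_safe_log <- function(values) {
  values <- as.numeric(values)
  if (anyNA(values) || any(values < 0))
    stop_invalid("values must be non-negative and non-missing")
  if (all(values == 0)) stop_invalid("all values are zero")
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  if (min(values) > 0) {
    cc <- 0
  } else if (q[1] > 0) {
    cc <- sqrt(q[1] / q[2])
  } else {
    cc <- min(values[values > 0]) / 2
    warning("first quartile is 0; falling back to half the smallest positive value")
  }
  structure(list(transformed = log(values + cc), constant = cc,
                 q1 = q[1], q3 = q[2]),
            class = "transform_result")
}

welch_core <- function(m1, s1, n1, m2, s2, n2) {
  v1 <- s1^2 / n1; v2 <- s2^2 / n2
  se2 <- v1 + v2
  if (se2 == 0) stop_invalid("both group variances are zero")
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  structure(list(t = t, df = df, p = p,
                 means = c(m1, m2), sds = c(s1, s2), ns = c(n1, n2)),
            class = "welch_result")
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("Welch two-sample t-test: t(%.1f) = %.3f, p = %.4g\n",
              x$df, x$t, x$p))
  cat(sprintf("  group 1: mean %.3f, sd %.3f, n %d; group 2: mean %.3f, sd %.3f, n %d\n",
              x$means[1], x$sds[1], x$ns[1], x$means[2], x$sds[2], x$ns[2]))
  invisible(x)
}

#' Welch two-sample t-test
#'
#' Unequal-variance t-test with Welch-Satterthwaite degrees of freedom and a
#' two-sided p-value.
#'
#' @param a,b numeric vectors (n >= 2 each; at least one group with nonzero
#'   variance).
#' @return A list of class `welch_result`: `t`, `df`, `p`, group `means`,
#'   `sds`, `ns`.
#' @export
welch_t <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop_invalid("each group needs at least 2 values")
  welch_core(mean(a), stats::sd(a), length(a),
             mean(b), stats::sd(b), length(b))
}

#' Welch t-test from summary statistics
#'
#' Identical formulas to [welch_t()], computed from group means, standard
#' deviations and sizes — the form needed to check published
#' mean±SD tables.
#'
#' @param m1,sd1,n1 mean, sd, n of group 1.
#' @param m2,sd2,n2 mean, sd, n of group 2.
#' @return A `welch_result`.
#' @examples
#' welch_t_from_summary(3577, 570, 19, 3060, 694, 17)  # t = 2.43, df = 31.1
#' @export
welch_t_from_summary <- function(m1, sd1, n1, m2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop_invalid("each group needs n >= 2")
  if (sd1 < 0 || sd2 < 0) stop_invalid("sds must be non-negative")
  welch_core(m1, sd1, n1, m2, sd2, n2)
}

#' Mixed (split-plot) two-way repeated-measures ANOVA
#'
#' One between-subject factor and one within-subject factor, with the classic
#' split-plot error strata: the between effect is tested against
#' subjects-within-groups, the within and interaction effects against the
#' within-subject residual. Subjects missing any within-factor level are
#' dropped (complete-case) and counted in the result.
#'
#' @param table data frame in long format.
#' @param value,subject,between,within column names.
#' @return A list of class `anova_table`: `effects` (data frame with SS, df,
#'   MS, F, p for between, within, interaction), `errors` (data frame with
#'   the two error strata), `cell_means`, `cell_ns`, `n_dropped`,
#'   `n_subjects`.
#' @export
mixed_rm_anova <- function(table, value = "attack_duration_s",
                           subject = "animal_id", between = "genotype",
                           within = "treatment") {
  for (col in c(value, subject, between, within))
    if (!col %in% names(table))
      stop_invalid(sprintf("column '%s' not found", col))
  df <- data.frame(y = as.numeric(table[[value]]),
                   s = as.character(table[[subject]]),
                   a = as.character(table[[between]]),
                   b = as.character(table[[within]]),
                   stringsAsFactors = FALSE)
  df <- df[stats::complete.cases(df), ]
  blev <- sort(unique(df$b))
  nb <- length(blev)
  if (nb < 2L) stop_invalid("within factor needs at least 2 levels")
  # complete-case: keep subjects observed exactly once at every within level
  tab <- table(df$s, df$b)
  complete <- rownames(tab)[apply(tab == 1L, 1L, all)]
  n_dropped <- length(unique(df$s)) - length(complete)
  df <- df[df$s %in% complete, ]
  alev <- sort(unique(df$a))
  na_ <- length(alev)
  if (na_ < 2L) stop_invalid("between factor needs at least 2 levels")
  geno_of_subj <- tapply(df$a, df$s, function(z) z[1L])
  n_i <- table(factor(geno_of_subj, levels = alev))
  if (any(n_i < 2L))
    stop_invalid("each between-factor level needs >= 2 complete subjects")

  S <- length(complete)
  N <- nrow(df)
  grand <- mean(df$y)
  subj_mean <- tapply(df$y, df$s, mean)
  a_mean <- tapply(df$y, df$a, mean)
  b_mean <- tapply(df$y, df$b, mean)
  cell_mean <- tapply(df$y, list(df$a, df$b), mean)
  cell_n <- tapply(df$y, list(df$a, df$b), length)

  ss_total <- sum((df$y - grand)^2)
  ss_subjects <- nb * sum((subj_mean - grand)^2)
  ss_a <- nb * sum(as.numeric(n_i) * (a_mean[alev] - grand)^2)
  ss_subj_within <- ss_subjects - ss_a
  ss_b <- S * sum((b_mean - grand)^2)
  ss_ab <- sum(cell_n * (cell_mean -
                           outer(a_mean[alev], rep(0, nb), `+`) -
                           matrix(b_mean[blev], na_, nb, byrow = TRUE) +
                           grand)^2)
  ss_resid <- ss_total - ss_subjects - ss_b - ss_ab

  df_a <- na_ - 1L
  df_sw <- S - na_
  df_b <- nb - 1L
  df_ab <- (na_ - 1L) * (nb - 1L)
  df_res <- (S - na_) * (nb - 1L)

  eff <- data.frame(
    effect = c(between, within, paste0(between, ":", within)),
    SS = c(ss_a, ss_b, ss_ab),
    df = c(df_a, df_b, df_ab),
    MS = c(ss_a / df_a, ss_b / df_b, ss_ab / df_ab),
    F = c((ss_a / df_a) / (ss_subj_within / df_sw),
          (ss_b / df_b) / (ss_resid / df_res),
          (ss_ab / df_ab) / (ss_resid / df_res)),
    stringsAsFactors = FALSE)
  eff$p <- stats::pf(eff$F, eff$df, c(df_sw, df_res, df_res),
                     lower.tail = FALSE)
  err <- data.frame(
    stratum = c("subjects_within_groups", "within_residual"),
    SS = c(ss_subj_within, ss_resid),
    df = c(df_sw, df_res),
    MS = c(ss_subj_within / df_sw, ss_resid / df_res))
  structure(list(effects = eff, errors = err,
                 cell_means = cell_mean, cell_ns = cell_n,
                 between = between, within = within,
                 n_subjects = S, n_dropped = n_dropped),
            class = "anova_table")
}

#' @export
print.anova_table <- function(x, ...) {
  cat(sprintf("Mixed two-way RM ANOVA (%d complete subjects%s)\n",
              x$n_subjects,
              if (x$n_dropped) sprintf(", %d dropped", x$n_dropped) else ""))
  eff <- x$effects
  for (i in seq_len(nrow(eff)))
    cat(sprintf("  %-24s F(%d,%d) = %.3f, p = %.4g\n", eff$effect[i],
                eff$df[i],
                if (i == 1L) x$errors$df[1L] else x$errors$df[2L],
                eff$F[i], eff$p[i]))
  invisible(x)
}

#' Tukey HSD post-hoc on the genotype-by-treatment cell means
#'
#' All pairwise comparisons of the between x within cell means using the
#' studentized-range distribution (Tukey-Kramer standard errors for unequal
#' cell sizes). Comparisons that differ in the within factor use the
#' within-subject residual mean square; comparisons differing only in the
#' between factor use the subjects-within-groups mean square, as is standard
#' split-plot practice.
#'
#' @param anova an `anova_table` from [mixed_rm_anova()].
#' @return A data frame of class `tukey_hsd`: the two cells, difference,
#'   standard error, q statistic, degrees of freedom and adjusted p per pair.
#' @export
tukey_hsd <- function(anova) {
  if (!inherits(anova, "anova_table")) stop_invalid("not an anova_table")
  cm <- anova$cell_means
  cn <- anova$cell_ns
  cells <- expand.grid(a = rownames(cm), b = colnames(cm),
                       stringsAsFactors = FALSE)
  k <- nrow(cells)
  if (k < 2L) stop_invalid("need at least 2 cells")
  res <- list()
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    ai <- cells$a[i]; bi <- cells$b[i]; aj <- cells$a[j]; bj <- cells$b[j]
    same_within <- bi == bj
    ms <- if (same_within) anova$errors$MS[1L] else anova$errors$MS[2L]
    dfe <- if (same_within) anova$errors$df[1L] else anova$errors$df[2L]
    diffm <- cm[ai, bi] - cm[aj, bj]
    se <- sqrt(ms / 2 * (1 / cn[ai, bi] + 1 / cn[aj, bj]))
    q <- abs(diffm) / se
    res[[length(res) + 1L]] <- data.frame(
      cell1 = paste(ai, bi, sep = ":"), cell2 = paste(aj, bj, sep = ":"),
      diff = diffm, se = se, q = q, df = dfe,
      p_adj = stats::ptukey(q, nmeans = k, df = dfe, lower.tail = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("tukey_hsd", "data.frame")
  out
}

#' Sidak multiple-comparison adjustment
#'
#' `p_adj = 1 - (1 - p)^m`, clipped to `[0, 1]`; monotone in both `p` and
#' `m`.
#'
#' @param pvals p-values in `[0, 1]`.
#' @param m number of comparisons (defaults to `length(pvals)`, must be at
#'   least that).
#' @return Adjusted p-values.
#' @examples
#' sidak_adjust(0.0253, m = 2)  # 0.0500
#' @export
sidak_adjust <- function(pvals, m = length(pvals)) {
  pvals <- as.numeric(pvals)
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop_invalid("p-values must lie in [0, 1]")
  if (m < length(pvals)) stop_invalid("'m' must be >= number of p-values")
  pmin(pmax(1 - (1 - pvals)^m, 0), 1)
}
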