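new_test_result <- function(statistic, df1, df2 = NA_real_, p, method,
                            epsilon = NA_real_) {
  structure(list(statistic = statistic, df1 = df1, df2 = df2, p = p,
                 method = method, epsilon = epsilon),
            class = "thg_test")
}

#' @export
print.thg_test <- function(x, ...) {
  dfs <- if (is.na(x$df2)) sprintf("%.4g", x$df1) else
    sprintf("%.4g, %.4g", x$df1, x$df2)
  eps <- if (is.na(x$epsilon)) "" else sprintf(", eps = %.4g", x$epsilon)
  cat(sprintf("%s: statistic = %.4g (df = %s), p = %.4g%s\n",
              x$method, x$statistic, dfs, x$p, eps))
  invisible(x)
}

#' Two-tailed tail probability of Student's t
#'
#' `p = 2 P(T_df >= |t|)` evaluated through the regularized incomplete beta
#' function (the survival function underlying [stats::pt()]); the degrees of
#' freedom may be fractional, as produced by Welch or Greenhouse-Geisser
#' corrected tests.
#'
#' @param t Observed statistic.
#' @param df Degrees of freedom (> 0, real-valued).
#' @return Two-tailed p-value.
#' @examples
#' t_sf(1.921, 6)   # 0.1031
#' @export
t_sf <- function(t, df) {
  if (any(df <= 0)) stop("df must be > 0")
  2 * pt(abs(t), df, lower.tail = FALSE)
}

#' Upper tail probability of the F distribution
#'
#' `p = P(F_{df1, df2} >= F)` via the regularized incomplete beta function
#' ([stats::pf()]); fractional degrees of freedom are accepted.
#'
#' @param f Observed statistic (>= 0).
#' @param df1,df2 Degrees of freedom (> 0, real-valued).
#' @return Upper-tail p-value.
#' @examples
#' f_sf(0.982, 3, 12)          # 0.434
#' f_sf(2.978, 1.196, 7.173)   # 0.125
#' @export
f_sf <- function(f, df1, df2) {
  if (any(df1 <= 0) || any(df2 <= 0)) stop("dfs must be > 0")
  if (any(f < 0)) stop("F must be >= 0")
  pf(f, df1, df2, lower.tail = FALSE)
}

#' Two-sample t test (pooled or Welch)
#'
#' Classical two-sample comparison with either the pooled-variance statistic
#' (`df = n1 + n2 - 2`) or the Welch-Satterthwaite approximation with
#' fractional df. If both samples have zero variance and equal means the
#' convention `t = 0, p = 1` applies.
#'
#' @param x,y Numeric samples (each n >= 2).
#' @param variant `"pooled"` or `"welch"`.
#' @return A `thg_test` result (two-tailed p).
#' @export
two_sample_t <- function(x, y, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("each sample needs n >= 2")
  v1 <- var(x); v2 <- var(y)
  md <- mean(x) - mean(y)
  if (v1 == 0 && v2 == 0) {
    if (md == 0)
      return(new_test_result(0, if (variant == "pooled") n1 + n2 - 2 else
        NA_real_, p = 1, method = paste0(variant, " t-test")))
    return(new_test_result(sign(md) * Inf, n1 + n2 - 2, p = 0,
                           method = paste0(variant, " t-test")))
  }
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tt <- md / se
  new_test_result(tt, df, p = t_sf(tt, df),
                  method = paste0(variant, " t-test"))
}

#' One-way analysis of variance
#'
#' Between/within decomposition over k independent groups:
#' `F = MS_between / MS_within` with `df = (k - 1, N - k)`. If all values
#' are identical the convention `F = 0, p = 1` applies.
#'
#' @param groups List of numeric samples (>= 2 groups, each n >= 2).
#' @return A `thg_test` result.
#' @export
one_way_anova <- function(groups) {
  k <- length(groups)
  if (k < 2) stop("need at least 2 groups")
  if (any(lengths(groups) < 2)) stop("each group needs n >= 2")
  all_v <- unlist(groups)
  N <- length(all_v)
  grand <- mean(all_v)
  ss_b <- sum(lengths(groups) *
                (vapply(groups, mean, numeric(1)) - grand)^2)
  ss_w <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1; df2 <- N - k
  if (ss_w == 0 && ss_b == 0)
    return(new_test_result(0, df1, df2, 1, "one-way ANOVA"))
  if (ss_w == 0)
    return(new_test_result(Inf, df1, df2, 0, "one-way ANOVA"))
  f <- (ss_b / df1) / (ss_w / df2)
  new_test_result(f, df1, df2, f_sf(f, df1, df2), "one-way ANOVA")
}

# Greenhouse-Geisser epsilon from the pooled within-group covariance of the
# k within-subject levels: eps = tr(M)^2 / ((k-1) tr(M^2)) with
# M = C S C' for orthonormal contrasts C.
gg_epsilon <- function(data, group) {
  k <- ncol(data)
  groups <- split(seq_len(nrow(data)), group)
  S <- matrix(0, k, k)
  dfp <- 0
  for (g in groups) {
    if (length(g) < 2) next
    Yg <- data[g, , drop = FALSE]
    Yc <- sweep(Yg, 2, colMeans(Yg))
    S <- S + crossprod(Yc)
    dfp <- dfp + length(g) - 1
  }
  if (dfp == 0) stop("need at least one group with n >= 2")
  S <- S / dfp
  C <- contr.helmert(k)
  C <- qr.Q(qr(C))                       # orthonormal contrast basis
  M <- t(C) %*% S %*% C
  tr <- sum(diag(M))
  eps <- tr^2 / ((k - 1) * sum(M * M))
  max(eps, 1 / (k - 1))
}

#' Mixed repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Split-plot design: one between-subject factor (e.g. MS vs non-MS donor
#' group) and one within-subject factor (e.g. bath sodium concentration),
#' every donor measured at every level. Reports the within-subject main
#' effect and the group-by-level interaction, each with classical and
#' Greenhouse-Geisser corrected p-values; the GG epsilon is estimated from
#' the pooled within-group covariance of the levels and multiplies both
#' degrees of freedom, producing the fractional dfs seen in corrected
#' reports. The between-group main effect is included for completeness.
#'
#' @param data Numeric matrix, rows = donors, columns = within levels
#'   (complete: no missing cells; incomplete rows are an error).
#' @param group Factor/vector of between-group labels, one per row.
#' @return A list of class `thg_rm_anova` with `thg_test` entries `within`,
#'   `interaction` (both GG-corrected; uncorrected versions in
#'   `within_uncorrected`, `interaction_uncorrected`), `between`, and the
#'   common `epsilon`.
#' @export
mixed_rm_anova_gg <- function(data, group) {
  data <- as.matrix(data)
  if (anyNA(data)) stop("incomplete donor rows are not supported")
  k <- ncol(data)
  if (k < 2) stop("need >= 2 within-subject levels")
  N <- nrow(data)
  group <- as.factor(group)
  if (length(group) != N) stop("one group label per donor row")
  g <- nlevels(group)
  grand <- mean(data)
  subj_means <- rowMeans(data)
  level_means <- colMeans(data)
  group_means <- as.numeric(tapply(subj_means, group, mean))
  n_g <- tabulate(group)

  ss_subj <- k * sum((subj_means - grand)^2)
  ss_group <- k * sum(n_g * (group_means - grand)^2)
  ss_subj_err <- ss_subj - ss_group
  ss_level <- N * sum((level_means - grand)^2)
  cell_means <- matrix(0, g, k)
  for (j in seq_len(k))
    cell_means[, j] <- as.numeric(tapply(data[, j], group, mean))
  inter_dev <- sweep(sweep(cell_means, 1, group_means), 2,
                     level_means) + grand
  ss_inter <- sum(n_g * inter_dev^2)
  fitted <- cell_means[as.integer(group), , drop = FALSE] +
    (subj_means - group_means[as.integer(group)])
  ss_within_err <- sum((data - fitted)^2)

  df_level <- k - 1
  df_inter <- (g - 1) * (k - 1)
  df_werr <- (N - g) * (k - 1)
  df_group <- g - 1
  df_serr <- N - g
  ms_werr <- ss_within_err / df_werr
  eps <- gg_epsilon(data, group)

  f_level <- (ss_level / df_level) / ms_werr
  f_inter <- if (df_inter > 0) (ss_inter / df_inter) / ms_werr else NA_real_
  f_group <- if (df_group > 0)
    (ss_group / df_group) / (ss_subj_err / df_serr) else NA_real_

  res <- list(
    within = new_test_result(
      f_level, eps * df_level, eps * df_werr,
      f_sf(f_level, eps * df_level, eps * df_werr),
      "within effect (GG corrected)", epsilon = eps),
    interaction = if (df_inter > 0) new_test_result(
      f_inter, eps * df_inter, eps * df_werr,
      f_sf(f_inter, eps * df_inter, eps * df_werr),
      "group x level interaction (GG corrected)", epsilon = eps),
    within_uncorrected = new_test_result(
      f_level, df_level, df_werr, f_sf(f_level, df_level, df_werr),
      "within effect"),
    interaction_uncorrected = if (df_inter > 0) new_test_result(
      f_inter, df_inter, df_werr, f_sf(f_inter, df_inter, df_werr),
      "group x level interaction"),
    between = if (df_group > 0) new_test_result(
      f_group, df_group, df_serr, f_sf(f_group, df_group, df_serr),
      "between groups"),
    epsilon = eps)
  class(res) <- "thg_rm_anova"
  res
}

#' @export
print.thg_rm_anova <- function(x, ...) {
  cat(sprintf("Mixed repeated-measures ANOVA (GG epsilon = %.4g)\n",
              x$epsilon))
  print(x$within)
  if (!is.null(x$interaction)) print(x$interaction)
  if (!is.null(x$between)) print(x$between)
  invisible(x)
}

#' Group summary and the standard three comparisons
#'
#' Assembles the statistical report for a swelling-density experiment:
#' per group-by-condition mean, SD, SEM and n, plus (when the design allows)
#' the three standard comparisons -- the baseline MS vs non-MS two-sample
#' t test at the first condition level, the mixed repeated-measures ANOVA
#' (with GG correction) of density across condition levels, and the pooled
#' t test of ALLN-treated vs untreated observations across donors and
#' levels.
#'
#' @param samples A `data.frame` with columns `donor`, `group`, `treatment`
#'   (`"none"` / `"ALLN"`), `level` (condition level, e.g. sodium mM) and
#'   `density` (per mm^3).
#' @param baseline_level Condition level used for the baseline comparison
#'   (default: the lowest).
#' @param variant t-test variant for the baseline comparison.
#' @return A list of class `thg_group_report`: `summary` (the per-cell
#'   table), `baseline`, `sodium` (the RM-ANOVA), `alln` (or NULL where the
#'   design lacks that arm).
#' @export
group_report <- function(samples, baseline_level = NULL,
                         variant = "pooled") {
  need <- c("donor", "group", "treatment", "level", "density")
  if (!all(need %in% names(samples)))
    stop("samples must have columns donor, group, treatment, level, density")
  if (!nrow(samples)) stop("empty sample table")
  agg <- aggregate(density ~ group + treatment + level, samples,
                   function(v) c(mean = mean(v), sd = sd(v),
                                 sem = sd(v) / sqrt(length(v)),
                                 n = length(v)))
  summary <- cbind(agg[c("group", "treatment", "level")],
                   as.data.frame(agg$density))
  untreated <- samples[samples$treatment == "none", ]
  if (is.null(baseline_level)) baseline_level <- min(samples$level)

  baseline <- NULL
  base <- untreated[untreated$level == baseline_level, ]
  gs <- unique(base$group)
  if (length(gs) == 2) {
    baseline <- two_sample_t(base$density[base$group == gs[1]],
                             base$density[base$group == gs[2]],
                             variant = variant)
    baseline$method <- sprintf("%s vs %s baseline (%s)", gs[1], gs[2],
                               baseline$method)
  }

  sodium <- NULL
  wide <- tryCatch({
    w <- reshape_wide(untreated)
    if (ncol(w$data) >= 2 && nrow(w$data) >= 4 &&
        length(unique(w$group)) >= 2) w else NULL
  }, error = function(e) NULL)
  if (!is.null(wide))
    sodium <- mixed_rm_anova_gg(wide$data, wide$group)

  alln <- NULL
  if (any(samples$treatment == "ALLN")) {
    tr <- samples$density[samples$treatment == "ALLN"]
    un <- untreated$density
    if (length(tr) >= 2 && length(un) >= 2) {
      alln <- two_sample_t(un, tr, variant = "pooled")
      alln$method <- paste("untreated vs ALLN pooled over donors x levels",
                           "(pooled t-test)")
    }
  }
  structure(list(summary = summary, baseline = baseline, sodium = sodium,
                 alln = alln),
            class = "thg_group_report")
}

# donors x levels wide matrix from a long table (complete designs only)
reshape_wide <- function(long) {
  donors <- unique(long$donor)
  levels_ <- sort(unique(long$level))
  m <- matrix(NA_real_, length(donors), length(levels_),
              dimnames = list(donors, levels_))
  for (i in seq_len(nrow(long)))
    m[match(long$donor[i], donors), match(long$level[i], levels_)] <-
      long$density[i]
  if (anyNA(m)) stop("incomplete donor x level table")
  grp <- long$group[match(donors, long$donor)]
  list(data = m, group = grp)
}

#' @export
print.thg_group_report <- function(x, ...) {
  cat("Group summary:\n")
  print(x$summary, row.names = FALSE)
  if (!is.null(x$baseline)) print(x$baseline)
  if (!is.null(x$sodium)) print(x$sodium)
  if (!is.null(x$alln)) print(x$alln)
  invisible(x)
}
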