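# Group comparisons of morphology parameter tables: descriptive mean +- SD,
# unpaired t-test (2 groups) or one-way ANOVA with Tukey HSD (>= 3 groups),
# significance at p < alpha (strict).

#' Compare a morphology parameter across groups
#'
#' Drops missing values per group, reports per-group n, mean and SD (n-1
#' denominator), then tests: two groups get a two-sided unpaired t-test
#' (pooled variance by default, Welch with `welch = TRUE`); three or more
#' groups get a one-way ANOVA F-test plus Tukey HSD adjusted p-values
#' (studentized-range distribution) for all pairs. Pooled-variance t is
#' the default because classic ANOVA + Tukey assumes homoscedasticity and
#' the two are used side by side. Significance uses the strict inequality
#' `p < alpha`. No multiple-testing control is applied across parameters.
#'
#' If every group has zero within-group variance but the means differ, the
#' comparison is degenerate: p is reported as 0 with `@degenerate = TRUE`.
#'
#' @param table data.frame holding the metric column and a group column
#'   (e.g. from [metricsToDataFrame()] with a `group` column added).
#' @param metricName name of the metric column to compare.
#' @param groupColumn name of the group label column.
#' @param alpha significance level.
#' @param welch use Welch's t-test instead of pooled variance (two groups
#'   only).
#' @return A [GroupComparison-class].
#' @examples
#' df <- data.frame(mean_rod_length = c(7, 8, 9, 12, 13, 14),
#'                  group = rep(c("ctl", "fccp"), each = 3))
#' compareGroups(df, "mean_rod_length")
#' @export
compareGroups <- function(table, metricName, groupColumn = "group",
                          alpha = 0.05, welch = FALSE) {
  stopifnot(is.data.frame(table))
  if (!metricName %in% names(table))
    stop("metric column '", metricName, "' not found")
  if (!groupColumn %in% names(table))
    stop("group column '", groupColumn, "' not found")
  v <- table[[metricName]]
  g <- as.character(table[[groupColumn]])
  keep <- is.finite(v)
  v <- v[keep]; g <- g[keep]
  lev <- unique(g)  # first-appearance order, stable under relabeling
  ns <- vapply(lev, function(l) sum(g == l), 0L)
  if (length(lev) < 2L)
    stop("need at least 2 groups, got ", length(lev))
  short <- lev[ns < 2L]
  if (length(short))
    stop("group '", short[1L], "' has fewer than 2 finite values")
  gs <- data.frame(
    group = lev,
    n = ns,
    mean = vapply(lev, function(l) mean(v[g == l]), 0),
    sd = vapply(lev, function(l) sd(v[g == l]), 0),
    row.names = NULL)
  gf <- factor(g, levels = lev)
  allConstant <- all(gs$sd == 0)
  unequalMeans <- length(unique(gs$mean)) > 1L
  degenerate <- allConstant && unequalMeans
  tukey <- data.frame(pair = character(0), mean_diff = numeric(0),
                      p_adj = numeric(0))
  if (length(lev) == 2L) {
    test <- "t_test"
    if (degenerate) {
      statistic <- Inf
      p <- 0
    } else {
      tt <- t.test(v[g == lev[1L]], v[g == lev[2L]],
                   var.equal = !welch)
      statistic <- unname(tt$statistic)
      p <- tt$p.value
    }
  } else {
    test <- "anova"
    if (degenerate) {
      statistic <- Inf
      p <- 0
      for (i in seq_len(length(lev) - 1L))
        for (j in seq.int(i + 1L, length(lev)))
          tukey <- rbind(tukey, data.frame(
            pair = paste(lev[j], lev[i], sep = "-"),
            mean_diff = gs$mean[j] - gs$mean[i],
            p_adj = as.numeric(gs$mean[j] != gs$mean[i]) * 0))
    } else {
      fit <- aov(v ~ gf)
      an <- anova(fit)
      statistic <- an[["F value"]][1L]
      p <- an[["Pr(>F)"]][1L]
      tk <- TukeyHSD(fit)$gf
      tukey <- data.frame(pair = rownames(tk),
                          mean_diff = unname(tk[, "diff"]),
                          p_adj = unname(tk[, "p adj"]),
                          row.names = NULL)
    }
  }
  new("GroupComparison", metricName = metricName, groupStats = gs,
      test = test, statistic = statistic, pValue = p, tukey = tukey,
      alpha = alpha, significant = p < alpha,
      degenerate = degenerate)
}

#' Compare every morphology parameter across groups
#'
#' Convenience wrapper running [compareGroups()] for each of the 18
#' parameters that has at least two finite values in every group.
#'
#' @param table data.frame from [metricsToDataFrame()] with a group
#'   column.
#' @param groupColumn name of the group label column.
#' @param alpha significance level.
#' @param welch passed to [compareGroups()].
#' @return Named list of [GroupComparison-class] objects.
#' @export
compareAllMetrics <- function(table, groupColumn = "group", alpha = 0.05,
                              welch = FALSE) {
  out <- list()
  for (m in morphologyParameterNames()) {
    res <- tryCatch(
      compareGroups(table, m, groupColumn = groupColumn, alpha = alpha,
                    welch = welch),
      error = function(e) NULL)
    if (!is.null(res)) out[[m]] <- res
  }
  out
}

#' Plain-text significance summary of group comparisons
#'
#' @param comparisons list from [compareAllMetrics()] (or a single
#'   [GroupComparison-class]).
#' @return Character vector of summary lines, one per parameter.
#' @export
significanceSummary <- function(comparisons) {
  if (is(comparisons, "GroupComparison"))
    comparisons <- list(comparisons)
  vapply(comparisons, function(cmp) {
    sprintf("%s: %s statistic=%.4g p=%.4g -> %s",
            cmp@metricName, cmp@test, cmp@statistic, cmp@pValue,
            if (cmp@significant) "significant" else "ns")
  }, "")
}
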