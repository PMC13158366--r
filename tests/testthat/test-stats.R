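# Fixed 3-group fixture (n = 5 each) used against a closed-form oracle.
fixture3 <- function() {
  data.frame(
    value = c(4.1, 5.2, 4.8, 5.5, 4.4,
              6.3, 7.1, 6.8, 7.4, 6.0,
              5.0, 5.9, 5.4, 6.2, 5.1),
    group = rep(c("ctl", "mutA", "mutB"), each = 5))
}

# Closed-form one-way ANOVA and Tukey HSD computed from sums only.
anovaOracle <- function(df) {
  sp <- split(df$value, df$group)
  k <- length(sp); N <- nrow(df)
  ni <- vapply(sp, length, 0L)
  mi <- vapply(sp, mean, 0)
  grand <- mean(df$value)
  ssb <- sum(ni * (mi - grand)^2)
  ssw <- sum(vapply(sp, function(v) sum((v - mean(v))^2), 0))
  mse <- ssw / (N - k)
  Fstat <- (ssb / (k - 1)) / mse
  p <- stats::pf(Fstat, k - 1, N - k, lower.tail = FALSE)
  pairs <- utils::combn(names(sp), 2)
  tukey <- apply(pairs, 2, function(pr) {
    d <- mi[pr[2]] - mi[pr[1]]
    se <- sqrt(mse / 2 * (1 / ni[pr[1]] + 1 / ni[pr[2]]))
    q <- abs(d) / se
    stats::ptukey(q, k, N - k, lower.tail = FALSE)
  })
  list(F = Fstat, p = p, tukey = tukey,
       pairNames = apply(pairs, 2, function(pr)
         paste(pr[2], pr[1], sep = "-")))
}

test_that("two identical groups give t = 0 and p = 1", {
  df <- data.frame(value = c(1, 2, 3, 1, 2, 3),
                   group = rep(c("a", "b"), each = 3))
  cmp <- compareGroups(df, "value")
  expect_equal(cmp@statistic, 0)
  expect_equal(cmp@pValue, 1)
  expect_false(cmp@significant)
})

test_that("the pooled t-test matches its closed form", {
  df <- data.frame(value = c(4.1, 5.2, 4.8, 5.5, 4.4,
                             6.3, 7.1, 6.8, 7.4, 6.0),
                   group = rep(c("ctl", "mut"), each = 5))
  cmp <- compareGroups(df, "value")
  a <- df$value[1:5]; b <- df$value[6:10]
  spool <- sqrt(((4 * var(a)) + (4 * var(b))) / 8)
  tOracle <- (mean(a) - mean(b)) / (spool * sqrt(2 / 5))
  pOracle <- 2 * stats::pt(abs(tOracle), 8, lower.tail = FALSE)
  expect_equal(cmp@statistic, tOracle, tolerance = 1e-8)
  expect_equal(cmp@pValue, pOracle, tolerance = 1e-8)
  # Welch variant has different degrees of freedom, hence a different p
  cmpW <- compareGroups(df, "value", welch = TRUE)
  expect_false(identical(cmp@pValue, cmpW@pValue))
})

test_that("ANOVA F, p and Tukey HSD match the closed-form oracle", {
  df <- fixture3()
  cmp <- compareGroups(df, "value")
  orc <- anovaOracle(df)
  expect_identical(cmp@test, "anova")
  expect_equal(cmp@statistic, unname(orc$F), tolerance = 1e-8)
  expect_equal(cmp@pValue, unname(orc$p), tolerance = 1e-8)
  expect_equal(nrow(cmp@tukey), 3L)
  got <- setNames(cmp@tukey$p_adj, cmp@tukey$pair)
  expect_equal(unname(got[orc$pairNames]), unname(orc$tukey),
               tolerance = 1e-8)
})

test_that("for two groups the ANOVA F equals the pooled t squared", {
  df <- data.frame(value = c(4.1, 5.2, 4.8, 5.5, 4.4,
                             6.3, 7.1, 6.8, 7.4, 6.0),
                   group = rep(c("a", "b"), each = 5))
  tcmp <- compareGroups(df, "value")
  fit <- aov(value ~ group, data = df)
  Fstat <- anova(fit)[["F value"]][1]
  expect_equal(Fstat, tcmp@statistic^2, tolerance = 1e-10)
})

test_that("Tukey adjusted p-values dominate unadjusted pairwise p", {
  # the unadjusted pairwise p uses the same pooled MSE as Tukey, so the
  # dominance p_adj >= p_raw is exact
  df <- fixture3()
  cmp <- compareGroups(df, "value")
  sp <- split(df$value, df$group)
  N <- nrow(df); k <- length(sp)
  mse <- sum(vapply(sp, function(v) sum((v - mean(v))^2), 0)) / (N - k)
  for (i in seq_len(nrow(cmp@tukey))) {
    pr <- strsplit(cmp@tukey$pair[i], "-")[[1]]
    a <- sp[[pr[1]]]; b <- sp[[pr[2]]]
    tt <- abs(mean(a) - mean(b)) /
      sqrt(mse * (1 / length(a) + 1 / length(b)))
    raw <- 2 * stats::pt(tt, N - k, lower.tail = FALSE)
    expect_gte(cmp@tukey$p_adj[i] + 1e-12, raw)
  }
})

test_that("significance uses a strict inequality at alpha", {
  df <- fixture3()
  cmp <- compareGroups(df, "value", alpha = 0.05)
  # exactly at the boundary: alpha equal to p is not significant
  cmpAtP <- compareGroups(df, "value", alpha = cmp@pValue)
  expect_false(cmpAtP@significant)
  cmpAbove <- compareGroups(df, "value", alpha = cmp@pValue + 1e-12)
  expect_true(cmpAbove@significant)
})

test_that("group labels can be permuted without changing the statistics", {
  df <- fixture3()
  cmp1 <- compareGroups(df, "value")
  perm <- df[sample(nrow(df)), ]
  cmp2 <- compareGroups(perm, "value")
  expect_equal(cmp1@statistic, cmp2@statistic)
  expect_equal(cmp1@pValue, cmp2@pValue)
  t1 <- cmp1@tukey[order(cmp1@tukey$pair), ]
  t2 <- cmp2@tukey[order(cmp2@tukey$pair), ]
  expect_equal(t1$p_adj, t2$p_adj)
})

test_that("degenerate zero-variance groups report p = 0 with a flag", {
  df <- data.frame(value = c(1, 1, 1, 2, 2, 2),
                   group = rep(c("a", "b"), each = 3))
  cmp <- compareGroups(df, "value")
  expect_true(cmp@degenerate)
  expect_equal(cmp@pValue, 0)
  expect_true(cmp@significant)
})

test_that("undersized or missing groups raise errors naming the group", {
  df <- data.frame(value = c(1, 2, 3, NA, NA, 4),
                   group = rep(c("a", "b"), each = 3))
  expect_error(compareGroups(df, "value"), "'b'")
  expect_error(compareGroups(data.frame(value = 1:4,
                                        group = rep("a", 4)), "value"),
               "at least 2 groups")
  # SD uses the n-1 denominator
  df2 <- data.frame(value = c(1, 2, 3, 7, 8, 10),
                    group = rep(c("a", "b"), each = 3))
  cmp <- compareGroups(df2, "value")
  expect_equal(cmp@groupStats$sd[1], sd(c(1, 2, 3)))
})

test_that("compareAllMetrics runs across the full parameter table", {
  set.seed(2)
  recs <- c(
    lapply(1:4, function(i) {
      computeMetrics(buildGraph(skeletonImage(randomSkel(i))), unitId = i)
    }),
    lapply(5:8, function(i) {
      computeMetrics(buildGraph(skeletonImage(randomSkel(i))), unitId = i)
    }))
  tab <- metricsToDataFrame(recs)
  tab$group <- rep(c("g1", "g2"), each = 4)
  out <- compareAllMetrics(tab)
  expect_true(length(out) >= 5)
  expect_true(all(vapply(out, function(x) is(x, "GroupComparison"), TRUE)))
  lines <- significanceSummary(out)
  expect_length(lines, length(out))
  expect_true(all(grepl("p=", lines)))
})
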