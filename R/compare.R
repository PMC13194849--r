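## Two-group baseline comparisons (the Tables 1-2 style statistics):
## Shapiro-Wilk normality gate, then t-test or Mann-Whitney U for continuous
## variables; Fisher's exact test for categorical ones (Monte-Carlo for
## larger-than-2x2 tables).

#' Two-group covariate comparison table
#'
#' For each column of `data`: continuous variables are gated per group by the
#' Shapiro-Wilk test at `alpha = 0.05` — if both groups are compatible with
#' normality a two-sided t-test is used, otherwise a two-sided Mann-Whitney U
#' test; categorical variables use Fisher's exact test (exact for 2x2,
#' seeded Monte-Carlo with `fisher_B` draws for r x c). Descriptives are
#' mean +/- SD for normal-gated, median (IQR) otherwise, and counts for
#' categorical variables.
#'
#' @param data data.frame of covariates.
#' @param group two-level grouping vector.
#' @param fisher_B Monte-Carlo draws for r x c Fisher tests (>= 1e5).
#' @param seed seed for the Monte-Carlo Fisher test.
#' @return data.frame: `variable`, `type`, `test`, `p`, `group1`, `group2`
#'   (descriptive strings).
#' @export
compare_groups <- function(data, group, fisher_B = 1e5, seed = 1L) {
  g <- droplevels(as.factor(group))
  assert_that(nlevels(g) == 2, "group must have exactly two levels")
  assert_that(all(table(g) >= 1), "each group must be non-empty")
  assert_that(nrow(data) == length(g), "data rows must match group length")
  lv <- levels(g)
  rows <- lapply(names(data), function(nm) {
    x <- data[[nm]]
    if (is.numeric(x)) {
      x1 <- x[g == lv[1]]; x2 <- x[g == lv[2]]
      normal <- length(x1) >= 3 && length(x2) >= 3 &&
        length(unique(x1)) > 1 && length(unique(x2)) > 1 &&
        shapiro.test(x1)$p.value > 0.05 && shapiro.test(x2)$p.value > 0.05
      if (normal) {
        p <- t.test(x1, x2)$p.value
        test <- "t-test"
        d1 <- sprintf("%.2f ± %.2f", mean(x1), sd(x1))
        d2 <- sprintf("%.2f ± %.2f", mean(x2), sd(x2))
      } else {
        p <- suppressWarnings(wilcox.test(x1, x2)$p.value)
        test <- "Mann-Whitney U"
        q1 <- quantile(x1, c(0.5, 0.25, 0.75)); q2 <- quantile(x2, c(0.5, 0.25, 0.75))
        d1 <- sprintf("%.2f (%.2f, %.2f)", q1[1], q1[2], q1[3])
        d2 <- sprintf("%.2f (%.2f, %.2f)", q2[1], q2[2], q2[3])
      }
      data.frame(variable = nm, type = "continuous", test = test, p = p,
                 group1 = d1, group2 = d2)
    } else {
      tab <- table(factor(x), g)
      p <- if (nrow(tab) <= 2 && ncol(tab) == 2) {
        fisher.test(tab)$p.value
      } else {
        with_seed(derive_seed(seed, 811),
                  fisher.test(tab, simulate.p.value = TRUE,
                              B = max(fisher_B, 1e5))$p.value)
      }
      fmt <- function(col) paste(sprintf("%s:%d", rownames(tab), tab[, col]),
                                 collapse = ", ")
      data.frame(variable = nm, type = "categorical", test = "Fisher exact",
                 p = p, group1 = fmt(1), group2 = fmt(2))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
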