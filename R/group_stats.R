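# Univariate group comparisons with the dispatch rules of the clinical
# tables: normality- and variance-gated t-test vs Mann-Whitney U for
# continuous variables, chi-square vs Fisher's exact for categorical ones,
# and Spearman correlation of model features with the class label.

#' Compare a continuous variable between two groups
#'
#' Dispatch: Shapiro-Wilk per group and Levene's test (absolute deviations
#' from the group mean), both at alpha = 0.05. If every group is normal and
#' variances are homogeneous, a two-sided pooled t-test is used and groups
#' are summarized as mean +/- SD; otherwise a Mann-Whitney U test (normal
#' approximation, no continuity correction) with median (IQR) summaries.
#' A zero-variance group forces the Mann-Whitney branch, flagged.
#'
#' @param values numeric vector.
#' @param groups two-level factor/vector, each group n >= 3.
#' @param alpha dispatch significance level (default 0.05).
#' @return a `group_comparison`: `test`, `statistic`, `p`, `summaries`
#'   (per-group strings), `dispatch` (log of the gate decisions), `flags`.
#' @export
compare_continuous <- function(values, groups, alpha = 0.05) {
  groups <- as.factor(groups)
  lev <- levels(groups)
  if (length(lev) != 2L) stop("exactly two groups required")
  g1 <- values[groups == lev[1]]
  g2 <- values[groups == lev[2]]
  if (length(g1) < 3L || length(g2) < 3L) stop("each group needs n >= 3")

  flags <- character(0)
  zero_var <- stats::sd(g1) == 0 || stats::sd(g2) == 0
  if (zero_var) flags <- c(flags, "zero-variance-group")
  normal <- if (zero_var) FALSE else {
    p1 <- stats::shapiro.test(g1)$p.value
    p2 <- stats::shapiro.test(g2)$p.value
    p1 > alpha && p2 > alpha
  }
  homo <- if (zero_var || !normal) NA else levene_test(values, groups)$p > alpha
  dispatch <- list(normal = normal, homogeneous = homo)

  if (isTRUE(normal) && isTRUE(homo)) {
    ht <- stats::t.test(g1, g2, var.equal = TRUE)
    test <- "t-test"
    statistic <- unname(ht$statistic)
    p <- ht$p.value
    summaries <- stats::setNames(
      sprintf("%.2f ± %.2f", c(mean(g1), mean(g2)), c(stats::sd(g1), stats::sd(g2))),
      lev)
  } else {
    ht <- stats::wilcox.test(g1, g2, exact = FALSE, correct = FALSE)
    test <- "Mann-Whitney U"
    statistic <- unname(ht$statistic)
    p <- ht$p.value
    fmt <- function(v) sprintf("%.2f (%.2f-%.2f)", stats::median(v),
                               stats::quantile(v, 0.25), stats::quantile(v, 0.75))
    summaries <- stats::setNames(c(fmt(g1), fmt(g2)), lev)
  }
  structure(list(test = test, statistic = statistic, p = p,
                 summaries = summaries, dispatch = dispatch, flags = flags),
            class = "group_comparison")
}

#' Levene's test for homogeneity of variance
#'
#' One-way ANOVA on absolute deviations from the group center.
#'
#' @param values numeric vector.
#' @param groups group factor.
#' @param center "mean" (classic Levene) or "median" (Brown-Forsythe).
#' @return list with `statistic` (F) and `p`.
#' @export
levene_test <- function(values, groups, center = c("mean", "median")) {
  center <- match.arg(center)
  groups <- as.factor(groups)
  ctr <- tapply(values, groups, if (center == "mean") mean else stats::median)
  z <- abs(values - ctr[groups])
  a <- stats::anova(stats::lm(z ~ groups))
  list(statistic = a$`F value`[1], p = a$`Pr(>F)`[1])
}

#' Compare a categorical variable between groups
#'
#' Dispatch for a 2 x 2 table: Pearson chi-square without continuity
#' correction when every expected and observed cell count is >= 5, else
#' Fisher's exact test. Non-2x2 tables use chi-square when all expected
#' counts are >= 5 and Fisher's exact otherwise. Zero-margin rows/columns
#' are dropped with a warning.
#'
#' @param tab matrix of non-negative counts (groups x categories).
#' @return a `group_comparison` (summaries are count (percent) strings per
#'   group).
#' @export
compare_categorical <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("dropping zero-margin rows/columns")
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L) stop("need a table of at least 2 x 2")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  use_chisq <- if (nrow(tab) == 2L && ncol(tab) == 2L) {
    all(expected >= 5) && all(tab >= 5)
  } else {
    all(expected >= 5)
  }
  if (use_chisq) {
    ht <- stats::chisq.test(tab, correct = FALSE)
    test <- "chi-square"
    statistic <- unname(ht$statistic)
  } else {
    ht <- stats::fisher.test(tab)
    test <- "Fisher exact"
    statistic <- NA_real_
  }
  pct <- sweep(tab, 1, rowSums(tab), "/") * 100
  summaries <- apply(tab, 1, function(r) paste(sprintf("%d", r), collapse = "/"))
  structure(list(test = test, statistic = statistic, p = ht$p.value,
                 summaries = summaries,
                 dispatch = list(expected = expected, chisq = use_chisq),
                 flags = character(0)),
            class = "group_comparison")
}

#' Spearman correlation of a feature with the class label
#'
#' Rank correlation with average ranks for ties; labels coded 0/1.
#'
#' @param values numeric feature vector.
#' @param labels 0/1 vector, both classes present, n >= 4.
#' @return scalar `r_s` (NA with a warning for a constant feature).
#' @export
spearman_vs_label <- function(values, labels) {
  labels <- as.integer(labels)
  if (length(values) < 4L) stop("need n >= 4")
  if (length(unique(labels)) < 2L) stop("labels contain a single class")
  if (stats::sd(values) == 0) {
    warning("constant feature: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(values, labels, method = "spearman")
}
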