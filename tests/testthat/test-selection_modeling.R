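test_that("correlation filter removes duplicated and clustered features", {
  set.seed(1)
  x <- data.frame(a = rnorm(20))
  x$b <- x$a                      # exact duplicate
  x$c <- rnorm(20)
  out <- correlation_filter(x, 0.95)
  expect_identical(length(out$kept), 2L)
  expect_true("c" %in% out$kept)
  expect_true(xor("a" %in% out$kept, "b" %in% out$kept))
  expect_match(out$log$reason, "high correlation")

  # weakly correlated table passes untouched
  set.seed(2)
  y <- as.data.frame(matrix(rnorm(200), 20, 10))
  out2 <- correlation_filter(y, 0.95)
  expect_identical(out2$kept, names(y))
  expect_identical(nrow(out2$log), 0L)
})

test_that("the filter drops the member with the larger mean correlation first", {
  # A sits between B and C, so A has the largest mean |r| and goes first
  set.seed(3)
  base <- rnorm(6)
  x <- data.frame(B = base + rnorm(6, sd = 0.01),
                  A = base,
                  C = base + rnorm(6, sd = 0.012))
  x$A <- (x$B + x$C) / 2 + rnorm(6, sd = 1e-4)
  out <- correlation_filter(x, 0.95)
  expect_identical(out$log$feature[1], "A")
  C <- abs(cor(as.matrix(out$x)))
  diag(C) <- 0
  expect_lte(max(C), 0.95 + 1e-12)
})

test_that("zero-variance features are removed first and logged", {
  set.seed(4)
  x <- data.frame(z = rep(1, 15), a = rnorm(15), b = rnorm(15))
  out <- correlation_filter(x)
  expect_false("z" %in% out$kept)
  expect_identical(out$log$reason[1], "zero variance")
})

test_that("LASSO selection finds the informative feature and is deterministic", {
  for (rep in 1:20) {
    set.seed(1000 + rep)
    n <- 72
    labels <- rep(c(0L, 1L), length.out = n)
    x <- as.data.frame(matrix(rnorm(n * 20), n, 20))
    names(x) <- paste0("noise", 1:20)
    x$signal <- labels + rnorm(n, sd = 0.3)
    sel <- lasso_select(x, labels, folds = 10, seed = 7)
    expect_true("signal" %in% sel$selected)
  }
  # determinism
  set.seed(99)
  x2 <- as.data.frame(matrix(rnorm(60 * 8), 60, 8))
  lab2 <- rep(c(0L, 1L), 30)
  s1 <- lasso_select(x2, lab2, folds = 5, seed = 3)
  s2 <- lasso_select(x2, lab2, folds = 5, seed = 3)
  expect_identical(s1$selected, s2$selected)
  expect_identical(length(s1$per_fold), 5L)
})

test_that("LASSO on pure noise selects little, and input contracts are enforced", {
  set.seed(5)
  x <- as.data.frame(matrix(rnorm(80 * 15), 80, 15))
  labels <- rep(c(0L, 1L), 40)
  sel <- lasso_select(x, labels, folds = 10, seed = 11)
  expect_lte(length(sel$selected), 3L)
  expect_error(lasso_select(x, rep(1L, 80), seed = 1), "single class")
  expect_error(lasso_select(x[1:6, ], labels[1:6], folds = 10, seed = 1),
               "fewer folds")
})

test_that("stepwise logistic recovers a sparse true model", {
  hits <- 0
  for (rep in 1:20) {
    set.seed(2000 + rep)
    n <- 500
    x <- as.data.frame(matrix(rnorm(n * 20), n, 20))
    names(x) <- paste0("f", 1:20)
    eta <- -2 * x$f1 + 3 * x$f2
    y <- rbinom(n, 1, plogis(eta))
    m <- forward_stepwise_logistic(x, y)
    # support recovery = both generating features entered (at entry_p = 0.05
    # a stray noise feature is admitted at the nominal rate by design)
    if (all(c("f1", "f2") %in% names(m$coefficients))) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("stepwise coefficient estimates are close to the generating model", {
  set.seed(11)
  n <- 500
  x <- as.data.frame(matrix(rnorm(n * 20), n, 20))
  names(x) <- paste0("f", 1:20)
  y <- rbinom(n, 1, plogis(-2 * x$f1 + 3 * x$f2))
  m <- forward_stepwise_logistic(x, y)
  expect_true(all(c("f1", "f2") %in% names(m$coefficients)))
  expect_lt(abs(m$coefficients[["f1"]] + 2), 0.5)
  expect_lt(abs(m$coefficients[["f2"]] - 3), 0.5)
})

test_that("stepwise handles null candidates and separation", {
  set.seed(13)
  x <- as.data.frame(matrix(rnorm(60 * 5), 60, 5))
  y <- rep(c(0L, 1L), 30)
  m0 <- forward_stepwise_logistic(x, y)
  expect_identical(length(m0$coefficients), 0L)
  expect_true("intercept-only" %in% m0$flags)

  # perfectly separating feature
  xs <- data.frame(sep = c(rnorm(30, -3), rnorm(30, 3)),
                   junk = rnorm(60))
  ys <- rep(c(0L, 1L), each = 30)
  ms <- forward_stepwise_logistic(xs, ys)
  expect_true("sep" %in% names(ms$coefficients))
  expect_true("separation-ridge-refit" %in% ms$flags)
  expect_true(all(is.finite(unlist(ms$coefficients))))
})

test_that("predict_model reproduces printed worked-example arithmetic", {
  # single-feature model of the Table-4 shape: Y = 8.33 - 13.80 * SRE
  m <- model_spec(8.33, c(grlm_ShortRunEmphasis = -13.80))
  y_neg <- predict_model(m, c(grlm_ShortRunEmphasis = 0.68))$Y
  y_pos <- predict_model(m, c(grlm_ShortRunEmphasis = 0.53))$Y
  expect_equal(y_neg, -1.054, tolerance = 1e-9)
  expect_equal(y_pos, 1.016, tolerance = 1e-9)
  expect_gt(y_pos, y_neg)  # negative coefficient: decreasing in SRE

  m0 <- model_spec(2.5, setNames(numeric(0), character(0)))
  expect_equal(predict_model(m0, c(anything = 1))$Y, 2.5)
  expect_error(predict_model(m, c(other = 1)), "missing model feature")
})

test_that("AUC equals the brute-force concordant-pair statistic", {
  # worked 6-point set
  sc <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.2)
  lb <- c(1, 1, 0, 1, 0, 0)
  r <- roc_analysis(sc, lb)
  expect_equal(r$auc, 8 / 9, tolerance = 1e-12)
  expect_equal(r$auc, oracle_auc(sc, lb), tolerance = 1e-12)

  set.seed(21)
  for (i in 1:50) {
    n <- sample(10:60, 1)
    lb <- c(0, 1, rbinom(n - 2, 1, 0.5))
    sc <- round(rnorm(n), 1)  # ties on purpose
    expect_equal(roc_analysis(sc, lb)$auc, oracle_auc(sc, lb),
                 tolerance = 1e-12)
  }
})

test_that("ROC analysis handles perfect, reversed, and constant scores", {
  lb <- c(1, 1, 1, 0, 0, 0)
  perf <- roc_analysis(as.numeric(lb), lb)
  expect_equal(perf$auc, 1)
  expect_equal(perf$sensitivity, 100)
  expect_equal(perf$specificity, 100)
  expect_equal(roc_analysis(-as.numeric(lb), lb)$auc, 0)

  cst <- roc_analysis(rep(2, 6), lb)
  expect_equal(cst$auc, 0.5)
  expect_true(is.na(cst$threshold))
  expect_true("constant-scores" %in% cst$flags)
})

test_that("ROC is invariant under strictly increasing score transforms", {
  set.seed(31)
  sc <- rnorm(40)
  lb <- rbinom(40, 1, 0.5)
  lb[1:2] <- c(0, 1)
  a <- roc_analysis(sc, lb)
  b <- roc_analysis(exp(sc), lb)
  expect_equal(a$auc, b$auc, tolerance = 1e-12)
  expect_equal(a$sensitivity, b$sensitivity)
  expect_equal(a$specificity, b$specificity)
})

test_that("test-set evaluation freezes the training threshold", {
  set.seed(41)
  x <- data.frame(f = c(rnorm(40, 0), rnorm(40, 1.2)))
  y <- rep(c(0L, 1L), each = 40)
  m <- forward_stepwise_logistic(x, y)
  tr <- roc_analysis(predict_model(m, x)$Y, y)
  m$threshold <- tr$threshold
  same <- evaluate_on_test(m, x, y)
  expect_equal(same$auc, tr$auc, tolerance = 1e-12)
  expect_equal(same$sensitivity, tr$sensitivity)
  expect_equal(same$specificity, tr$specificity)

  # on fresh data the frozen threshold generally differs from test-optimal
  set.seed(42)
  x2 <- data.frame(f = c(rnorm(30, 0), rnorm(30, 1.2)))
  y2 <- rep(c(0L, 1L), each = 30)
  ev <- evaluate_on_test(m, x2, y2)
  expect_equal(ev$threshold, tr$threshold)
  expect_true(ev$auc >= 0 && ev$auc <= 1)
})

test_that("model specs serialize to byte-identical JSON and round-trip", {
  m <- model_spec(1.25, c(a = -2, b = 0.5), threshold = 0.3, map_name = "ESER")
  p1 <- tempfile(fileext = ".json")
  p2 <- tempfile(fileext = ".json")
  write_model_spec(m, p1)
  write_model_spec(m, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  back <- read_model_spec(p1)
  expect_equal(back$intercept, m$intercept)
  expect_equal(back$coefficients, m$coefficients)
  expect_equal(back$threshold, m$threshold)
})
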