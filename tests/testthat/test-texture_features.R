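qroi <- function(levels, L) {
  structure(list(levels = levels, L = L, constant = FALSE, range = c(1, L)),
            class = "quantized_roi")
}

test_that("quantization follows the stated min-max binning rule", {
  m <- matrix(c(0, 50, 100, 999), 2, 2)
  v <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  q <- quantize(m, v, L = 4)
  expect_identical(q$levels[1, 1], 1L)
  expect_identical(q$levels[2, 1], 3L)  # floor(0.5 * 4) + 1
  expect_identical(q$levels[1, 2], 4L)
  expect_true(is.na(q$levels[2, 2]))

  # affine transforms of the map leave the quantized ROI unchanged
  q2 <- quantize(2.5 * m + 11, v, L = 4)
  expect_identical(q$levels, q2$levels)

  qc <- quantize(matrix(5, 2, 2), matrix(TRUE, 2, 2), L = 4)
  expect_true(qc$constant)
  expect_true(all(qc$levels == 1L))
  expect_error(quantize(m, matrix(FALSE, 2, 2), 4), ">= 2 valid")
})

test_that("GLCM features match hand-enumerated pairs on tiny images", {
  # [[1,1],[2,2]] at angle 0 only: P(1,1)=P(2,2)=0.5
  lev <- matrix(c(1L, 2L, 1L, 2L), 2, 2)
  P <- kinetexture:::glcm_matrix(lev, 2L, c(0L, 1L))
  p <- P / sum(P)
  expect_equal(sum(p), 1)
  f <- kinetexture:::glcm_features_one(P)
  expect_equal(unname(f["Energy"]), 0.5)
  expect_equal(unname(f["Contrast"]), 0)
  expect_equal(unname(f["MaximumProbability"]), 0.5)

  # constant ROI degenerate limits
  fc <- glcm_features(qroi(matrix(1L, 3, 3), 4L))
  expect_equal(unname(fc["Contrast"]), 0)
  expect_equal(unname(fc["Dissimilarity"]), 0)
  expect_equal(unname(fc["Energy"]), 1)
  expect_equal(unname(fc["MaximumProbability"]), 1)
  expect_equal(unname(fc["Homogeneity"]), 1)
})

test_that("GLCM features equal the brute-force pair enumerator on random ROIs", {
  set.seed(101)
  for (i in 1:200) {
    q <- random_roi(8, 5)
    got <- glcm_features(q)
    want <- oracle_glcm(q$levels, q$L)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("per-angle GLCM matrices are symmetric distributions", {
  set.seed(7)
  q <- random_roi(8, 6)
  for (off in kinetexture:::angle_offsets()) {
    P <- kinetexture:::glcm_matrix(q$levels, q$L, off)
    if (sum(P) == 0) next
    p <- P / sum(P)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(p, t(p), tolerance = 1e-12)
    expect_lte(sum(p^2), 1)
  }
})

test_that("GRLM features match hand enumeration and closed forms", {
  # row [1,1,2] at 0 degrees: runs (1, len 2), (2, len 1)
  lev <- matrix(c(1L, 1L, 2L), 1, 3)
  r <- kinetexture:::grlm_matrix(lev, 2L, 0)
  f <- kinetexture:::grlm_features_one(r, 3L)
  expect_equal(unname(f["ShortRunEmphasis"]), 0.625)
  expect_equal(unname(f["LongRunEmphasis"]), 2.5)
  expect_equal(unname(f["RunPercentage"]), 2 / 3)

  # constant n-pixel row: a single run, SRE = 1/n^2, LRE = n^2
  n <- 7L
  lev2 <- matrix(1L, 1, n)
  f2 <- kinetexture:::grlm_features_one(kinetexture:::grlm_matrix(lev2, 1L, 0), n)
  expect_equal(unname(f2["ShortRunEmphasis"]), 1 / n^2)
  expect_equal(unname(f2["LongRunEmphasis"]), n^2)
})

test_that("GRLM features equal the brute-force run enumerator on random ROIs", {
  set.seed(202)
  for (i in 1:200) {
    q <- random_roi(8, 5)
    expect_equal(grlm_features(q), oracle_grlm(q$levels), tolerance = 1e-9)
  }
})

test_that("angle-averaged matrix features are invariant to rotation and mirroring", {
  set.seed(303)
  for (i in 1:20) {
    q <- random_roi(8, 5)
    rot <- qroi(t(apply(q$levels, 2, rev)), q$L)       # 90-degree rotation
    mir <- qroi(q$levels[, ncol(q$levels):1, drop = FALSE], q$L)
    expect_equal(glcm_features(q), glcm_features(rot), tolerance = 1e-9)
    expect_equal(glcm_features(q), glcm_features(mir), tolerance = 1e-9)
    expect_equal(grlm_features(q), grlm_features(rot), tolerance = 1e-9)
    expect_equal(grlm_features(q), grlm_features(mir), tolerance = 1e-9)
  }
})

test_that("histogram features use population moments and Pearson kurtosis", {
  m <- matrix(c(1, 2, 3, 4), 2, 2)
  v <- matrix(TRUE, 2, 2)
  f <- histogram_features(m, v)
  expect_equal(unname(f["Mean"]), 2.5)
  expect_equal(unname(f["Variance"]), 1.25)

  sym <- histogram_features(matrix(c(-3, 0, 3, 0), 2, 2), v)
  expect_equal(unname(sym["Skewness"]), 0)

  set.seed(5)
  z <- matrix(rnorm(1000), 25, 40)
  fz <- histogram_features(z, matrix(TRUE, 25, 40))
  expect_lt(abs(fz["Kurtosis"] - 3), 0.5)

  fconst <- histogram_features(matrix(2, 2, 2), v)
  expect_true(is.nan(fconst[["Skewness"]]))
  expect_true(is.nan(fconst[["Kurtosis"]]))
})

test_that("wavelet filter banks satisfy orthonormal identities", {
  for (wv in c("harr", "deubechies2", "symlet4")) {
    f <- wavelet_filters(wv)
    expect_equal(sum(f$lo), sqrt(2), tolerance = 1e-9)
    expect_equal(sum(f$lo^2), 1, tolerance = 1e-9)
    expect_lt(abs(sum(f$hi)), 1e-9)   # vanishing moment
    expect_equal(sum(f$hi^2), 1, tolerance = 1e-9)
    expect_lt(abs(sum(f$lo * f$hi)), 1e-9)
  }
})

test_that("DWT details vanish on constants and shift only the approximation", {
  mask <- matrix(TRUE, 12, 12)
  const <- matrix(4, 12, 12)
  for (wv in c("harr", "deubechies2", "symlet4")) {
    f <- dwt_features(const, mask, wv)
    expect_true(all(abs(f[c("HH1", "VH1", "DH1", "HH2", "VH2", "DH2")]) < 1e-9))
    expect_gt(f[["L"]], 0)
  }
  set.seed(9)
  m <- matrix(rnorm(144), 12, 12)
  f1 <- dwt_features(m, mask, "harr")
  f2 <- dwt_features(m + 100, mask, "harr")
  nm_detail <- c("HH1", "VH1", "DH1", "HH2", "VH2", "DH2")
  expect_equal(f1[nm_detail], f2[nm_detail], tolerance = 1e-9)
  expect_gt(f2[["L"]], f1[["L"]])
})

test_that("haar separates horizontal from vertical structure", {
  a <- 10; b <- 2
  x <- matrix(c(a, b, a, b), 2, 2)   # [[a,a],[b,b]]: horizontal edge
  f <- wavelet_filters("harr")
  lv <- kinetexture:::dwt2_level(x, f$lo, f$hi)
  expect_equal(abs(lv$H[1, 1]), abs(a - b), tolerance = 1e-12)
  expect_equal(lv$V[1, 1], 0, tolerance = 1e-12)
  expect_equal(lv$D[1, 1], 0, tolerance = 1e-12)
  # transpose flips the role of H and V
  lv2 <- kinetexture:::dwt2_level(t(x), f$lo, f$hi)
  expect_equal(abs(lv2$V[1, 1]), abs(a - b), tolerance = 1e-12)
  expect_equal(lv2$H[1, 1], 0, tolerance = 1e-12)
})

test_that("extract_all returns the canonical 55 features with family counts 4/19/11/21", {
  cs <- generate_case(1, seed = 61, grid = 64, axes_range = c(8, 20))
  m <- compute_map(cs$series, cs$mask, "ESER")
  f <- extract_all(m$map, m$validity, cs$mask$mask)
  expect_identical(names(f), feature_names())
  expect_identical(length(f), 55L)
  expect_equal(sum(startsWith(names(f), "hist_")), 4)
  expect_equal(sum(startsWith(names(f), "glcm_")), 19)
  expect_equal(sum(startsWith(names(f), "grlm_")), 11)
  expect_equal(sum(startsWith(names(f), "harr_")) +
               sum(startsWith(names(f), "deubechies2_")) +
               sum(startsWith(names(f), "symlet4_")), 21)
  expect_true(all(is.finite(f)))
})

test_that("short-run emphasis does not increase with heterogeneity amplitude", {
  # the patch field grows relative to fixed noise as h rises, lengthening runs
  for (s in c(5, 6, 7)) {
    sre <- vapply(c(0.05, 0.15, 0.30, 0.45), function(h) {
      tr <- kinetic_truth(S0 = 100, A = 1.6, t_p = 1, w = 0.12, h = h, ell = 3)
      cs <- generate_case(1, seed = s, truth = tr)
      m <- compute_map(cs$series, cs$mask, "ESER")
      q <- quantize(m$map, m$validity, 8)
      grlm_features(q)[["ShortRunEmphasis"]]
    }, numeric(1))
    expect_true(all(diff(sre) <= 1e-9))
  }
})
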