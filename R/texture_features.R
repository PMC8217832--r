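# The 55-feature texture engine applied to one kinetic parameter map
# restricted to the lesion: 4 histogram features on raw values, 19 GLCM
# (Haralick-family) and 11 GRLM (run-length) features on the quantized ROI,
# and 21 two-level DWT subband features (7 per wavelet: harr, deubechies2,
# symlet4). All entropies use the natural log; kurtosis is the Pearson
# (non-excess) convention; the DWT subband statistic is the mean absolute
# coefficient.

#' Quantize a map over its valid lesion pixels
#'
#' Linear min-max scaling of valid values to integer levels `1..L`:
#' `level = floor((x - min) / (max - min) * L) + 1`, with the maximum
#' clamped to `L`. A constant map is flagged; its pixels all map to level 1
#' and downstream matrix features take their documented degenerate values.
#'
#' @param map numeric matrix.
#' @param validity logical matrix of admissible pixels.
#' @param L number of gray levels (>= 2, default 8).
#' @param mode "minmax" (default) or "raw-integer" (levels are the rounded
#'   raw values shifted to a 1-based range; for conventions in which the
#'   run-length gray level keeps the map's native scale).
#' @return a `quantized_roi`: `levels` (integer matrix, NA outside the
#'   valid region), `L`, `constant` flag, `range` used for scaling.
#' @export
quantize <- function(map, validity, L = 8L, mode = c("minmax", "raw-integer")) {
  mode <- match.arg(mode)
  if (sum(validity) < 2L) stop("need >= 2 valid pixels to quantize")
  stopifnot(L >= 2L)
  v <- map[validity]
  rng <- range(v)
  constant <- rng[1] == rng[2]
  lev <- matrix(NA_integer_, nrow(map), ncol(map))
  if (mode == "minmax") {
    if (constant) {
      lev[validity] <- 1L
    } else {
      q <- floor((v - rng[1]) / (rng[2] - rng[1]) * L) + 1L
      lev[validity] <- as.integer(pmin(q, L))
    }
    L_eff <- as.integer(L)
  } else {
    q <- round(v)
    q <- as.integer(q - min(q) + 1L)
    lev[validity] <- q
    L_eff <- max(1L, max(q))
    constant <- constant || L_eff == 1L
  }
  structure(list(levels = lev, L = L_eff, constant = constant, range = rng),
            class = "quantized_roi")
}

# Offsets for the four angles, chessboard distance 1, in (drow, dcol):
# 0 deg = along a row; 90 deg = along a column; 45/135 deg = diagonals.
angle_offsets <- function() {
  list(`0` = c(0L, 1L), `45` = c(-1L, 1L), `90` = c(-1L, 0L), `135` = c(-1L, -1L))
}

glcm_feature_names <- function() {
  sub("^glcm_", "", grep("^glcm_", feature_names(), value = TRUE))
}

grlm_feature_names <- function() {
  sub("^grlm_", "", grep("^grlm_", feature_names(), value = TRUE))
}

# Co-occurrence counts for one offset: symmetric, in-mask pairs only.
glcm_matrix <- function(levels, L, offset) {
  nr <- nrow(levels)
  nc <- ncol(levels)
  dr <- offset[1]
  dc <- offset[2]
  r1 <- max(1L, 1L - dr):min(nr, nr - dr)
  c1 <- max(1L, 1L - dc):min(nc, nc - dc)
  a <- levels[r1, c1, drop = FALSE]
  b <- levels[r1 + dr, c1 + dc, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(matrix(0, L, L))
  counts <- matrix(0, L, L)
  tab <- table(factor(a[ok], levels = 1:L), factor(b[ok], levels = 1:L))
  counts <- counts + tab + t(tab)  # symmetrize
  counts
}

glcm_features_one <- function(P) {
  # P: symmetric co-occurrence count matrix; normalized here.
  L <- nrow(P)
  p <- P / sum(P)
  i <- matrix(1:L, L, L)
  j <- t(i)
  px <- rowSums(p)
  mu_x <- sum((1:L) * px)
  sd_x <- sqrt(sum(((1:L) - mu_x)^2 * px))
  xlogx <- function(x) ifelse(x > 0, x * log(x), 0)

  autoc <- sum(i * j * p)
  contrast <- sum((i - j)^2 * p)
  correlation <- if (sd_x > 0) (autoc - mu_x^2) / sd_x^2 else 0
  cp <- sum((i + j - 2 * mu_x)^4 * p)
  cs <- sum((i + j - 2 * mu_x)^3 * p)
  dissim <- sum(abs(i - j) * p)
  energy <- sum(p^2)
  entropy <- -sum(xlogx(p))
  homog <- sum(p / (1 + (i - j)^2))
  maxprob <- max(p)
  variance <- sum((i - mu_x)^2 * p)

  # sum / difference distributions
  psum <- vapply(2:(2 * L), function(k) sum(p[i + j == k]), numeric(1))
  pdiff <- vapply(0:(L - 1), function(k) sum(p[abs(i - j) == k]), numeric(1))
  ks <- 2:(2 * L)
  kd <- 0:(L - 1)
  sum_avg <- sum(ks * psum)
  sum_var <- sum((ks - sum_avg)^2 * psum)
  sum_ent <- -sum(xlogx(psum))
  diff_avg <- sum(kd * pdiff)
  diff_var <- sum((kd - diff_avg)^2 * pdiff)
  diff_ent <- -sum(xlogx(pdiff))

  hx <- -sum(xlogx(px))
  pxpy <- outer(px, px)
  hxy1 <- -sum(p[pxpy > 0] * log(pxpy[pxpy > 0]))
  hxy2 <- -sum(xlogx(pxpy))
  imc1 <- if (hx > 0) (entropy - hxy1) / hx else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - entropy)), 0))
  idn <- sum(p / (1 + abs(i - j) / L))

  c(Autocorrelation = autoc, Contrast = contrast, Correlation = correlation,
    ClusterProminence = cp, ClusterShade = cs, Dissimilarity = dissim,
    Energy = energy, Entropy = entropy, Homogeneity = homog,
    MaximumProbability = maxprob, Variance = variance, SumAverage = sum_avg,
    SumVariance = sum_var, SumEntropy = sum_ent, DifferenceVariance = diff_var,
    DifferenceEntropy = diff_ent, InformationMeasureCorrelation1 = imc1,
    InformationMeasureCorrelation2 = imc2, InverseDifferenceNormalized = idn)
}

#' GLCM texture features
#'
#' For each of the four angles (0, 45, 90, 135 degrees; distance 1) a
#' symmetric, normalized co-occurrence matrix is built from in-mask pixel
#' pairs only, the 19 Haralick-family features of the canonical list are
#' computed, and each feature is averaged over the angles that produced at
#' least one pair.
#'
#' @param q a `quantized_roi`.
#' @return named numeric vector of 19 features (all `NaN` if no angle has
#'   an admissible pair).
#' @export
glcm_features <- function(q) {
  per_angle <- list()
  for (off in angle_offsets()) {
    P <- glcm_matrix(q$levels, q$L, off)
    if (sum(P) > 0) per_angle[[length(per_angle) + 1L]] <- glcm_features_one(P)
  }
  if (length(per_angle) == 0L) {
    out <- rep(NaN, 19L)
    names(out) <- glcm_feature_names()
    return(out)
  }
  Reduce(`+`, per_angle) / length(per_angle)
}

# Runs of equal levels along each scan line of one angle; NA (out of mask)
# breaks runs. Returns a matrix of counts r[g, l], g = 1..L, l = 1..max run.
grlm_matrix <- function(levels, L, angle) {
  nr <- nrow(levels)
  nc <- ncol(levels)
  lines <- switch(as.character(angle),
    `0` = lapply(seq_len(nr), function(r) levels[r, ]),
    `90` = lapply(seq_len(nc), function(c) levels[, c]),
    `45` = lapply(seq_len(nr + nc - 1L), function(s) {
      # anti-diagonals: r + c = s + 1, traversed with increasing c
      c0 <- max(1L, s + 1L - nr):min(nc, s)
      levels[cbind(s + 1L - c0, c0)]
    }),
    `135` = lapply((1L - nc):(nr - 1L), function(k) {
      # diagonals: r - c = k, traversed with increasing c
      c0 <- max(1L, 1L - k):min(nc, nr - k)
      levels[cbind(c0 + k, c0)]
    }))
  r_mat <- matrix(0, L, max(nr, nc))
  for (v in lines) {
    if (length(v) == 0L) next
    rl <- rle(ifelse(is.na(v), -1L, v))
    keep <- rl$values != -1L
    g <- rl$values[keep]
    l <- rl$lengths[keep]
    for (t in seq_along(g)) r_mat[g[t], l[t]] <- r_mat[g[t], l[t]] + 1
  }
  r_mat
}

grlm_features_one <- function(r_mat, n_pixels) {
  N_r <- sum(r_mat)
  g <- matrix(seq_len(nrow(r_mat)), nrow(r_mat), ncol(r_mat))
  l <- t(matrix(seq_len(ncol(r_mat)), ncol(r_mat), nrow(r_mat)))
  c(ShortRunEmphasis = sum(r_mat / l^2) / N_r,
    LongRunEmphasis = sum(r_mat * l^2) / N_r,
    GrayLevelNonuniformity = sum(rowSums(r_mat)^2) / N_r,
    RunLengthNonuniformity = sum(colSums(r_mat)^2) / N_r,
    RunPercentage = N_r / n_pixels,
    LowGrayLevelRunEmphasis = sum(r_mat / g^2) / N_r,
    HighGrayLevelRunEmphasis = sum(r_mat * g^2) / N_r,
    ShortRunLowGrayLevelEmphasis = sum(r_mat / (g^2 * l^2)) / N_r,
    ShortRunHighGrayLevelEmphasis = sum(r_mat * g^2 / l^2) / N_r,
    LongRunLowGrayLevelEmphasis = sum(r_mat * l^2 / g^2) / N_r,
    LongRunHighGrayLevelEmphasis = sum(r_mat * g^2 * l^2) / N_r)
}

#' GRLM (run-length) texture features
#'
#' Runs are maximal constant-level segments along each scan line of the
#' four angles, broken at mask boundaries; the 11 standard run-length
#' features are computed per angle and averaged.
#'
#' @param q a `quantized_roi`.
#' @return named numeric vector of 11 features.
#' @export
grlm_features <- function(q) {
  n_px <- sum(!is.na(q$levels))
  if (n_px < 1L) stop("need >= 1 valid pixel for run-length features")
  feats <- lapply(c(0, 45, 90, 135), function(a) {
    grlm_features_one(grlm_matrix(q$levels, q$L, a), n_px)
  })
  Reduce(`+`, feats) / length(feats)
}

#' Histogram (first-order) features
#'
#' Mean, population variance (divisor n), skewness `m3 / m2^1.5`, and
#' Pearson kurtosis `m4 / m2^2` (normal => 3), computed on the raw
#' (unquantized) valid map values.
#'
#' @param map numeric matrix.
#' @param validity logical matrix of admissible pixels.
#' @return named numeric vector of 4 features; skewness/kurtosis are `NaN`
#'   for a zero-variance input.
#' @export
histogram_features <- function(map, validity) {
  v <- map[validity]
  if (length(v) < 2L) stop("need >= 2 valid pixels for histogram features")
  m <- mean(v)
  m2 <- mean((v - m)^2)
  if (m2 > 0) {
    skew <- mean((v - m)^3) / m2^1.5
    kurt <- mean((v - m)^4) / m2^2
  } else {
    skew <- NaN
    kurt <- NaN
  }
  c(Mean = m, Variance = m2, Skewness = skew, Kurtosis = kurt)
}

#' Wavelet filter bank coefficients
#'
#' Orthonormal decomposition lowpass filters for the three wavelets used by
#' the engine (names as spelled in the feature list); the highpass filter
#' is the quadrature mirror of the lowpass.
#'
#' @param wavelet one of "harr", "deubechies2", "symlet4".
#' @return list with `lo` and `hi` numeric filter vectors.
#' @export
wavelet_filters <- function(wavelet = c("harr", "deubechies2", "symlet4")) {
  wavelet <- match.arg(wavelet)
  lo <- switch(wavelet,
    harr = c(1, 1) / sqrt(2),
    deubechies2 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
    symlet4 = c(-0.07576571478927333, -0.02963552764599851,
                0.49761866763201545, 0.80373875180591614,
                0.29785779560527736, -0.09921954357684722,
                -0.012603967262037833, 0.0322231006040427))
  n <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(n) - 1L)
  list(lo = lo, hi = hi)
}

# One analysis step along a vector: symmetric (whole-sample reflection)
# extension, correlation-form filtering, dyadic downsampling. Output length
# floor((n + lf - 1) / 2).
dwt_step_1d <- function(v, f) {
  lf <- length(f)
  n <- length(v)
  sym_idx <- function(k) {
    m <- 2L * n
    k <- ((k - 1L) %% m) + 1L
    ifelse(k <= n, k, m - k + 1L)
  }
  ext <- v[sym_idx((2L - lf):(n + lf - 1L))]  # length n + 2*(lf - 1)
  y <- numeric(n + lf - 1L)
  for (j in seq_len(lf)) {
    y <- y + f[j] * ext[j:(j + n + lf - 2L)]
  }
  y[seq(2L, length(y), by = 2L)]
}

dwt2_level <- function(x, lo, hi) {
  # filter along rows-dimension (dim 1) first, then columns-dimension
  colwise <- function(m, f) {
    r <- apply(m, 2, dwt_step_1d, f = f)
    if (is.null(dim(r))) r <- matrix(r, nrow = 1L)
    r
  }
  Lr <- colwise(x, lo)               # lowpass along dim1
  Hr <- colwise(x, hi)               # highpass along dim1 (vertical variation)
  rowwise <- function(m, f) {
    r <- apply(m, 1, dwt_step_1d, f = f)
    if (is.null(dim(r))) r <- matrix(r, nrow = 1L)
    t(r)
  }
  list(A = rowwise(Lr, lo),  # low/low
       H = rowwise(Hr, lo),  # high along dim1, low along dim2: horizontal edges
       V = rowwise(Lr, hi),  # vertical edges
       D = rowwise(Hr, hi))  # diagonal
}

#' Two-level DWT subband features for one wavelet
#'
#' The map is cropped to the lesion bounding box, out-of-mask pixels are
#' imputed with the in-mask mean, the crop is mean-padded to at least
#' 8 x 8, and a two-level separable DWT (symmetric boundary extension) is
#' taken. Each feature is the mean absolute coefficient of one subband:
#' `L` (level-2 approximation), `HH1/VH1/DH1` (level-1 horizontal /
#' vertical / diagonal detail), `HH2/VH2/DH2` (level-2 details).
#'
#' @param map numeric matrix.
#' @param mask logical matrix (lesion support; non-finite map pixels are
#'   treated as out of mask).
#' @param wavelet one of "harr", "deubechies2", "symlet4".
#' @return named numeric vector of 7 features (`L, HH1, VH1, DH1, HH2,
#'   VH2, DH2`).
#' @export
dwt_features <- function(map, mask, wavelet = "harr") {
  mask <- mask & is.finite(map)
  if (!any(mask)) stop("empty mask for DWT features")
  rr <- range(which(rowSums(mask) > 0))
  cc <- range(which(colSums(mask) > 0))
  crop <- map[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  mcrop <- mask[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  mu <- mean(crop[mcrop])
  crop[!mcrop] <- mu
  nr <- max(nrow(crop), 8L)
  nc <- max(ncol(crop), 8L)
  padded <- matrix(mu, nr, nc)
  padded[seq_len(nrow(crop)), seq_len(ncol(crop))] <- crop

  f <- wavelet_filters(wavelet)
  l1 <- dwt2_level(padded, f$lo, f$hi)
  l2 <- dwt2_level(l1$A, f$lo, f$hi)
  mav <- function(m) mean(abs(m))
  c(L = mav(l2$A), HH1 = mav(l1$H), VH1 = mav(l1$V), DH1 = mav(l1$D),
    HH2 = mav(l2$H), VH2 = mav(l2$V), DH2 = mav(l2$D))
}

#' Extract the full 55-feature vector from one kinetic map
#'
#' Histogram and DWT features are computed on the raw map values; GLCM and
#' GRLM features on the quantized ROI.
#'
#' @param map numeric matrix (one kinetic parameter map).
#' @param validity logical matrix of admissible pixels.
#' @param mask logical lesion mask (defaults to `validity`).
#' @param config a `run_config` (supplies the quantization level count).
#' @param quantize_mode passed to [quantize()].
#' @return named numeric vector of 55 features in [feature_names()] order.
#' @export
extract_all <- function(map, validity, mask = validity, config = run_config(),
                        quantize_mode = "minmax") {
  if (inherits(mask, "lesion_mask")) mask <- mask$mask
  fam <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("%s features failed: %s", what, conditionMessage(e)))
    })
  }
  h <- fam("histogram", histogram_features(map, validity))
  q <- fam("quantization",
           quantize(map, validity, L = config$quantization_levels,
                    mode = quantize_mode))
  g <- fam("GLCM", glcm_features(q))
  r <- fam("GRLM", grlm_features(q))
  w <- unlist(lapply(c("harr", "deubechies2", "symlet4"), function(wv) {
    fam("DWT", dwt_features(map, mask & validity, wv))
  }))
  out <- c(h, g, r, w)
  names(out) <- feature_names()
  out
}
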