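# Seeded two-class synthetic DCE cohort generator.
#
# Each case is a 96x96 single-slice scene: an elliptical lesion whose pixels
# follow a piecewise kinetic model (linear rise to a peak, then geometric
# washout), background tissue with mild uniform enhancement, and additive
# noise. Class structure: HER2-positive lesions enhance early and wash out,
# with strong short-range spatial heterogeneity; HER2-negative lesions
# enhance persistently and are smooth. Heterogeneity enters as a
# multiplicative exp(h * g) factor on the wash-in amplitude and the washout
# rate, with g a shared two-band patch-mosaic field (discretized smoothed
# noise) of characteristic scale ell: piecewise-constant kinetic
# subcompartments with sharp boundaries, amplitude controlled by h.

#' Kinetic ground-truth parameters for one lesion
#'
#' @param S0 baseline (precontrast) signal intensity, arbitrary units, > 0.
#' @param A wash-in amplitude as a fraction of `S0` (> 0): the noise-free
#'   peak is `S0 * (1 + A)`.
#' @param t_p time-to-peak phase index in 1..8.
#' @param w per-phase washout fraction in [0, 1): after the peak the signal
#'   decays geometrically by `(1 - w)` per phase.
#' @param h heterogeneity amplitude in [0, 1): log-sd of the multiplicative
#'   per-pixel field applied to `A` and `w`.
#' @param ell heterogeneity correlation length in pixels (>= 1).
#' @return a `kinetic_truth` list.
#' @export
kinetic_truth <- function(S0 = 100, A = 1.5, t_p = 2L, w = 0, h = 0, ell = 4) {
  stopifnot(S0 > 0, A > 0 || (A == 0 && h == 0), t_p >= 1, t_p <= 8,
            w >= 0, w < 1, h >= 0, h < 1, ell >= 1)
  structure(list(S0 = S0, A = A, t_p = as.integer(t_p), w = w,
                 h = h, ell = ell),
            class = "kinetic_truth")
}

#' Evaluate the noise-free kinetic time course
#'
#' Piecewise model: `SI(0) = S0`; linear rise to `S0 * (1 + A)` at phase
#' `t_p`; geometric decay by `(1 - w)` per phase after the peak. Exact and
#' noise-free, so the seven kinetic parameters are known in closed form.
#'
#' @param truth a `kinetic_truth` (or list with S0, A, t_p, w).
#' @param t phase index or vector of indices in 0..8.
#' @return signal intensity at each `t`.
#' @export
sample_timecourse <- function(truth, t) {
  if (any(t < 0 | t > 8 | t != floor(t))) {
    stop("phase index t must be an integer in 0..8")
  }
  rise <- truth$S0 * (1 + truth$A * t / truth$t_p)
  decay <- truth$S0 * (1 + truth$A) * (1 - truth$w)^(t - truth$t_p)
  ifelse(t <= truth$t_p, rise, decay)
}

#' Default class-conditional priors for the synthetic cohort
#'
#' The positive class is an early-peak washout lesion (peak at phase 1,
#' washout 8--18% per phase) with strong, short-range heterogeneity; the
#' negative class is a persistent enhancer (peak at phase 6--8, washout
#' below 2%) with weak, long-range heterogeneity. An early positive-class
#' peak is required for heterogeneity to reach the early-ratio (ESER) map at
#' all: with a linear rise peaking at or after phase 2 the ratio is
#' identically 50% whatever the per-pixel amplitude.
#'
#' @param label 1 (positive) or 0 (negative).
#' @return a function `(void) -> kinetic_truth` sampling from the prior
#'   using the current RNG stream.
#' @export
class_prior <- function(label) {
  if (label == 1L) {
    function() kinetic_truth(S0 = stats::runif(1, 80, 120),
                             A = stats::runif(1, 1.2, 2.0),
                             t_p = 1L,
                             w = stats::runif(1, 0.08, 0.18),
                             h = stats::runif(1, 0.25, 0.40),
                             ell = stats::runif(1, 2, 4))
  } else {
    function() kinetic_truth(S0 = stats::runif(1, 80, 120),
                             A = stats::runif(1, 0.8, 1.6),
                             t_p = sample(6:8, 1),
                             w = stats::runif(1, 0, 0.02),
                             h = stats::runif(1, 0.05, 0.15),
                             ell = stats::runif(1, 6, 10))
  }
}

# Smoothed standardized Gaussian random field (separable Gaussian kernel,
# sd = ell pixels), mean 0 / sd 1 over the grid. Consumes the current RNG.
smooth_field <- function(nr, nc, ell) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (ell > 0) {
    r <- max(1L, ceiling(3 * ell))
    k <- stats::dnorm(-r:r, sd = ell)
    k <- k / sum(k)
    pad_conv <- function(m) {
      # replicate-pad rows, convolve columns of the padded matrix
      idx <- c(rep(1L, r), seq_len(nrow(m)), rep(nrow(m), r))
      mp <- m[idx, , drop = FALSE]
      out <- matrix(0, nrow(m), ncol(m))
      for (j in seq_along(k)) {
        out <- out + k[j] * mp[j:(j + nrow(m) - 1L), , drop = FALSE]
      }
      out
    }
    z <- pad_conv(z)
    z <- t(pad_conv(t(z)))
  }
  (z - mean(z)) / stats::sd(z)
}

# Patch-mosaic heterogeneity field: a smoothed Gaussian field discretized
# into equal-probability bands (each band replaced by its normal-score
# midpoint), then standardized. Yields piecewise-constant subregions of
# characteristic size ell with sharp boundaries -- a caricature of discrete
# tumor subcompartments (viable rim / necrotic core / septa) rather than a
# smoothly varying perfusion gradient. Sharp patch boundaries are what let
# matrix texture move the way heterogeneous tumors do: long constant runs
# inside patches (low short-run emphasis) with large gray-level jumps
# across boundaries (high contrast).
patch_field <- function(nr, nc, ell, n_bands = 2L) {
  g <- smooth_field(nr, nc, ell)
  band <- findInterval(rank(g, ties.method = "first") / (nr * nc),
                       seq_len(n_bands - 1L) / n_bands) + 1L
  v <- stats::qnorm((band - 0.5) / n_bands)
  v <- matrix(v, nr, nc)
  (v - mean(v)) / stats::sd(v)
}

# Rasterize an ellipse mask; axes in pixels (full lengths), theta radians.
ellipse_mask <- function(nr, nc, center, axes, theta) {
  a <- axes[1] / 2
  b <- axes[2] / 2
  rr <- matrix(seq_len(nr), nr, nc) - center[1]
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - center[2]
  x <- cos(theta) * rr + sin(theta) * cc
  y <- -sin(theta) * rr + cos(theta) * cc
  (x / a)^2 + (y / b)^2 <= 1
}

#' Generate one synthetic DCE case
#'
#' Deterministic given `seed`. The lesion is a random ellipse (axes 8--25
#' px) on a `grid` x `grid` scene; per-pixel wash-in amplitude and washout
#' rate are modulated by `exp(h * g)` with `g` one shared two-band
#' patch-mosaic field of characteristic scale `ell` (sharp-boundary kinetic
#' subcompartments); background tissue enhances mildly and uniformly;
#' zero-mean noise is added at signal-to-noise ratio `snr` (baseline signal
#' / noise sd; `Inf` for noise-free).
#'
#' @param label 1 (HER2-positive) or 0 (HER2-negative).
#' @param seed integer seed for this case.
#' @param grid scene side length in pixels (default 96).
#' @param snr baseline-to-noise ratio (default 50; `Inf` = noise-free).
#' @param noise_model "gaussian" (default) or "rician".
#' @param truth optional fixed `kinetic_truth` overriding the class prior.
#' @param axes_range full ellipse-axis range in pixels (default c(8, 25)).
#' @return a `synthetic_case` list: `series`, `mask`, `label`, `truth`.
#' @export
generate_case <- function(label, seed, grid = 96L, snr = 50,
                          noise_model = c("gaussian", "rician"),
                          truth = NULL, axes_range = c(8, 25)) {
  noise_model <- match.arg(noise_model)
  if (grid < 2 * axes_range[2]) {
    stop(sprintf("grid %d too small for ellipse axes up to %g", grid, axes_range[2]))
  }
  set.seed(as.integer(seed))
  if (is.null(truth)) truth <- class_prior(as.integer(label))()

  axes <- stats::runif(2, axes_range[1], axes_range[2])
  center <- grid / 2 + stats::runif(2, -grid / 8, grid / 8)
  theta <- stats::runif(1, 0, pi)
  mask <- ellipse_mask(grid, grid, center, axes, theta)

  # one shared compartment field: subregions differ coherently in wash-in
  # amplitude and washout rate (e.g. viable rim vs necrotic-prone core)
  g <- patch_field(grid, grid, truth$ell)
  A_px <- truth$A * exp(truth$h * g)
  w_px <- pmin(truth$w * exp(truth$h * g), 0.9)

  S0_bg <- stats::runif(1, 50, 80)
  bg_enh <- 0.2  # background enhances 20% linearly over the 8 post phases

  t <- 0:8
  phases <- vector("list", 9L)
  for (k in seq_len(9L)) {
    les <- if (t[k] <= truth$t_p) {
      truth$S0 * (1 + A_px * t[k] / truth$t_p)
    } else {
      truth$S0 * (1 + A_px) * (1 - w_px)^(t[k] - truth$t_p)
    }
    bg <- S0_bg * (1 + bg_enh * t[k] / 8)
    img <- matrix(bg, grid, grid)
    img[mask] <- les[mask]
    if (is.finite(snr)) {
      sd_n <- truth$S0 / snr
      if (noise_model == "gaussian") {
        img <- img + matrix(stats::rnorm(grid * grid, sd = sd_n), grid, grid)
      } else {
        n1 <- matrix(stats::rnorm(grid * grid, sd = sd_n), grid, grid)
        n2 <- matrix(stats::rnorm(grid * grid, sd = sd_n), grid, grid)
        img <- sqrt((img + n1)^2 + n2^2)
      }
    }
    phases[[k]] <- pmax(img, 0)
  }

  case_id <- sprintf("case_%s_s%d", if (label == 1L) "pos" else "neg",
                     as.integer(seed))
  structure(list(series = dce_series(phases, case_id = case_id),
                 mask = lesion_mask(mask, case_id = case_id),
                 label = as.integer(label),
                 truth = truth),
            class = "synthetic_case")
}

#' Generate a two-class synthetic cohort
#'
#' Child seeds are derived deterministically from the master seed, so equal
#' master seeds give identical cohorts and manifests.
#'
#' @param n_pos,n_neg class sizes (defaults 48 / 54).
#' @param seed master seed.
#' @param ... passed to [generate_case()] (grid, snr, noise_model, ...).
#' @return list with `cases` (list of `synthetic_case`) and `manifest`
#'   (data.frame: case_id, label, seed, and the truth parameters).
#' @export
generate_cohort <- function(n_pos = 48L, n_neg = 54L, seed = 42L, ...) {
  stopifnot(n_pos >= 1L, n_neg >= 1L)
  labels <- c(rep(1L, n_pos), rep(0L, n_neg))
  n <- length(labels)
  child <- (as.double(seed) * 1009L + 7919 * seq_len(n)) %% 2147483647
  cases <- vector("list", n)
  for (i in seq_len(n)) {
    cases[[i]] <- generate_case(labels[i], seed = child[i], ...)
    cases[[i]]$series$case_id <- sprintf("case%03d_%s", i,
                                         if (labels[i] == 1L) "pos" else "neg")
    cases[[i]]$mask$case_id <- cases[[i]]$series$case_id
  }
  manifest <- do.call(rbind, lapply(seq_len(n), function(i) {
    tr <- cases[[i]]$truth
    data.frame(case_id = cases[[i]]$series$case_id, label = labels[i],
               seed = child[i], S0 = tr$S0, A = tr$A, t_p = tr$t_p,
               w = tr$w, h = tr$h, ell = tr$ell)
  }))
  list(cases = cases, manifest = manifest)
}

#' Stratified train/test split with per-stratum round-half-up
#'
#' With the default 48/54 cohort and `train_frac = 0.7` this gives 34/38
#' training and 14/16 test cases.
#'
#' @param labels 0/1 vector.
#' @param train_frac training fraction (default 0.7).
#' @param seed split seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, train_frac = 0.7, seed = 1L) {
  set.seed(as.integer(seed))
  train <- integer(0)
  for (g in unique(labels)) {
    idx <- which(labels == g)
    n_tr <- floor(train_frac * length(idx) + 0.5)  # round half up
    train <- c(train, sort(sample(idx, n_tr)))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}
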