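# The seven semiquantitative kinetic parameter maps, per pixel over the
# lesion. With s_t the signal at phase t (t = 0 precontrast) and
# s_peak = max(s_1..s_8):
#
#   E_initial = (s_1 - s_0) / s_0 * 100%
#   E_peak    = (s_peak - s_0) / s_0 * 100%
#   ESER      = (s_1 - s_0) / (s_2 - s_0) * 100%
#   MSI       = max_{i=0..7} (s_{i+1} - s_i)            [intensity units]
#   SEP       = (s_2 - s_0) / s_0 * 100%
#   SER       = (s_peak - s_0) / (s_8 - s_0) * 100%
#   SI_slope  = (s_8 - s_mean) / s_mean * 100%,  s_mean = (s_1 + s_2) / 2
#
# Pixels whose denominator magnitude falls below eps * (case max post
# intensity) are marked invalid (NaN) instead of evaluated; invalid pixels
# are excluded from lesion means and texture extraction.

#' Compute one kinetic parameter map
#'
#' @param series a `dce_series`.
#' @param mask a `lesion_mask` (or logical matrix) on the same grid.
#' @param which one of [kinetic_map_names()].
#' @param eps relative denominator admissibility threshold (default 1e-6,
#'   scaled by the case's maximum postcontrast intensity).
#' @return list with `map` (matrix, NaN where invalid/out of mask) and
#'   `validity` (logical matrix, TRUE where the value is admissible).
#' @export
compute_map <- function(series, mask, which, eps = 1e-6) {
  if (inherits(mask, "lesion_mask")) mask <- mask$mask
  if (!identical(dim(mask), dim(series))) stop("mask shape does not match series")
  if (!any(mask)) stop("empty lesion mask")
  which <- match.arg(which, kinetic_map_names())

  s <- vapply(series$phases, function(p) p[mask], numeric(sum(mask)))  # npx x 9
  if (is.null(dim(s))) s <- matrix(s, nrow = 1L)
  scale_ref <- max(s[, 2:9])
  tol <- eps * max(scale_ref, .Machine$double.eps)

  s0 <- s[, 1]
  s1 <- s[, 2]
  s2 <- s[, 3]
  s8 <- s[, 9]
  s_peak <- apply(s[, 2:9, drop = FALSE], 1, max)

  ratio <- function(num, den) {
    ok <- abs(den) > tol
    v <- rep(NaN, length(num))
    v[ok] <- num[ok] / den[ok] * 100
    list(v = v, ok = ok)
  }
  r <- switch(which,
    E_initial = ratio(s1 - s0, s0),
    E_peak    = ratio(s_peak - s0, s0),
    ESER      = ratio(s1 - s0, s2 - s0),
    SEP       = ratio(s2 - s0, s0),
    SER       = ratio(s_peak - s0, s8 - s0),
    SI_slope  = ratio(s8 - (s1 + s2) / 2, (s1 + s2) / 2),
    MSI       = {
      d <- s[, 2:9, drop = FALSE] - s[, 1:8, drop = FALSE]
      list(v = apply(d, 1, max), ok = rep(TRUE, nrow(s)))
    })

  map <- matrix(NaN, nrow(mask), ncol(mask))
  map[mask] <- r$v
  validity <- matrix(FALSE, nrow(mask), ncol(mask))
  validity[mask] <- r$ok
  list(map = map, validity = validity)
}

#' Compute all seven kinetic parameter maps
#'
#' @inheritParams compute_map
#' @return a `kinetic_map_set`: named lists `maps` and `validity` over the
#'   seven map names, plus the lesion `mask`.
#' @export
compute_all_maps <- function(series, mask, eps = 1e-6) {
  nm <- kinetic_map_names()
  out <- lapply(nm, function(w) compute_map(series, mask, w, eps = eps))
  names(out) <- nm
  structure(list(maps = lapply(out, `[[`, "map"),
                 validity = lapply(out, `[[`, "validity"),
                 mask = if (inherits(mask, "lesion_mask")) mask$mask else mask),
            class = "kinetic_map_set")
}

#' Lesion mean of a kinetic map
#'
#' Arithmetic mean over valid pixels only.
#'
#' @param map numeric matrix.
#' @param validity logical matrix of admissible pixels.
#' @return scalar mean.
#' @export
lesion_mean <- function(map, validity) {
  v <- map[validity]
  if (length(v) == 0L) stop("no valid pixels for lesion mean")
  mean(v)
}

#' Lesion means of all seven maps
#'
#' @param maps a `kinetic_map_set`.
#' @return named numeric vector of length 7 (Table-3-style summary input).
#' @export
lesion_means <- function(maps) {
  vapply(kinetic_map_names(),
         function(nm) lesion_mean(maps$maps[[nm]], maps$validity[[nm]]),
         numeric(1))
}
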