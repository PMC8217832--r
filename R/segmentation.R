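# Subtraction-image lesion delineation: Otsu threshold inside an optional
# ROI box, connected-component selection, hole filling.

#' Subtraction image
#'
#' Pixel-wise difference between postcontrast phase `k` and the precontrast
#' phase; may contain negative values.
#'
#' @param series a `dce_series`.
#' @param k postcontrast phase index in 1..8 (default 3: the third-phase
#'   subtraction is the delineation substrate).
#' @return a `subtraction_image` list: `image` (matrix), `k`, `case_id`.
#' @export
subtraction_image <- function(series, k = 3L) {
  if (k < 1 || k > 8 || k != floor(k)) stop("subtraction phase k must be in 1..8")
  structure(list(image = series$phases[[k + 1L]] - series$phases[[1L]],
                 k = as.integer(k), case_id = series$case_id),
            class = "subtraction_image")
}

#' Otsu threshold over a 256-bin histogram
#'
#' Deterministic threshold maximizing between-class variance of the 256-bin
#' histogram of `values`; ties broken toward the lowest boundary. The
#' returned value is a bin edge: foreground is `values > threshold`.
#'
#' @param values numeric vector with at least 2 distinct values.
#' @param n_bins histogram resolution (default 256).
#' @return scalar threshold.
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  values <- values[is.finite(values)]
  rng <- range(values)
  if (length(values) < 2L || rng[1] == rng[2]) {
    stop("Otsu threshold undefined for constant input")
  }
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(values, edges, rightmost.closed = TRUE), 1L), n_bins)
  cnt <- tabulate(bin, nbins = n_bins)
  p <- cnt / sum(cnt)
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)[-n_bins]
  mu0 <- cumsum(p * mids)[-n_bins]
  mu_t <- sum(p * mids)
  w1 <- 1 - w0
  ok <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, n_bins - 1L)
  sigma_b[ok] <- (mu_t * w0[ok] - mu0[ok])^2 / (w0[ok] * w1[ok])
  t_idx <- which.max(sigma_b)
  edges[t_idx + 1L]
}

#' Label 8-connected foreground components
#'
#' @param mask logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 8L) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 8L) {
    dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L)
    dc <- c(0L, 0L, -1L, 1L)
  }
  cur <- 0L
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack) > 0) {
      idx <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- (idx - 1L) %% nr + 1L
      c <- (idx - 1L) %/% nr + 1L
      for (j in seq_along(dr)) {
        r2 <- r + dr[j]
        c2 <- c + dc[j]
        if (r2 >= 1L && r2 <= nr && c2 >= 1L && c2 <= nc) {
          idx2 <- (c2 - 1L) * nr + r2
          if (mask[idx2] && lab[idx2] == 0L) {
            lab[idx2] <- cur
            stack <- c(stack, idx2)
          }
        }
      }
    }
  }
  lab
}

#' Fill interior holes of a binary mask
#'
#' A hole is background not 4-connected to the image border.
#'
#' @param mask logical matrix.
#' @return logical matrix with holes filled.
#' @export
fill_holes <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  bg <- !mask
  # flood the background from the border with a virtual border seed
  padded <- matrix(FALSE, nr + 2L, nc + 2L)
  padded[2:(nr + 1L), 2:(nc + 1L)] <- bg
  padded[1, ] <- TRUE; padded[nr + 2L, ] <- TRUE
  padded[, 1] <- TRUE; padded[, nc + 2L] <- TRUE
  lab <- label_components(padded, connectivity = 4L)
  outside <- lab == lab[1, 1]
  mask | !outside[2:(nr + 1L), 2:(nc + 1L)]
}

#' Segment the lesion on a subtraction image
#'
#' Otsu threshold within `roi_box`; keep the 8-connected foreground
#' component containing `seed_point` if given, else the largest; fill
#' holes. The ROI box and seed point stand in for the operator interaction
#' of a semi-automatic workflow.
#'
#' @param sub a `subtraction_image`.
#' @param roi_box optional `c(r0, c0, r1, c1)` (1-based, inclusive);
#'   default whole image.
#' @param seed_point optional `c(r, c)` inside the target lesion.
#' @param min_pixels minimum lesion size (default 16).
#' @return a `lesion_mask` satisfying the mask invariants.
#' @export
segment_lesion <- function(sub, roi_box = NULL, seed_point = NULL,
                           min_pixels = 16L) {
  img <- sub$image
  nr <- nrow(img)
  nc <- ncol(img)
  if (is.null(roi_box)) roi_box <- c(1L, 1L, nr, nc)
  if (roi_box[1] < 1 || roi_box[2] < 1 || roi_box[3] > nr || roi_box[4] > nc ||
      roi_box[1] > roi_box[3] || roi_box[2] > roi_box[4]) {
    stop("roi_box out of image bounds")
  }
  roi <- matrix(FALSE, nr, nc)
  roi[roi_box[1]:roi_box[3], roi_box[2]:roi_box[4]] <- TRUE
  vals <- img[roi]
  if (length(unique(vals)) < 2L) {
    stop("segmentation failure: ROI is constant, no Otsu threshold exists")
  }
  thr <- otsu_threshold(vals)
  fg <- roi & img > thr
  if (!any(fg)) stop("segmentation failure: empty foreground after thresholding")
  lab <- label_components(fg, connectivity = 8L)
  if (!is.null(seed_point)) {
    sel <- lab[seed_point[1], seed_point[2]]
    if (sel == 0L) stop("segmentation failure: seed point not in foreground")
  } else {
    sizes <- tabulate(lab[lab > 0L])
    sel <- which.max(sizes)
  }
  m <- fill_holes(lab == sel)
  if (sum(m) < min_pixels) {
    stop(sprintf("segmentation failure: component has %d px, need >= %d",
                 sum(m), min_pixels))
  }
  lesion_mask(m, case_id = sub$case_id)
}

#' Dice overlap coefficient between two binary masks
#'
#' @param a,b logical matrices (or `lesion_mask` objects).
#' @return Dice coefficient in [0, 1].
#' @export
dice <- function(a, b) {
  if (inherits(a, "lesion_mask")) a <- a$mask
  if (inherits(b, "lesion_mask")) b <- b$mask
  2 * sum(a & b) / (sum(a) + sum(b))
}
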