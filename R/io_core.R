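# Domain containers and plain-text serialization for the pipeline.
#
# A "case" on disk is a directory:
#   <case_id>/phases.csv  - H*W rows x 9 columns (t0..t8), row-major pixel order
#   <case_id>/mask.csv    - H*W rows x 1 column (0/1), same pixel order
#   <case_id>/meta.json   - case_id, dims, label, pixel spacing, generator truth
# Feature tables are CSV with columns: case_id, label, then the 55 canonical
# feature names (see feature_names()).

#' Construct a 9-phase DCE series
#'
#' Bundles the nine co-registered single-slice images of one dynamic
#' contrast-enhanced acquisition: one precontrast phase (t = 0) and eight
#' postcontrast phases (t = 1..8), all on one pixel grid in arbitrary
#' scanner units.
#'
#' @param phases a list of 9 numeric matrices of identical dimensions, or an
#'   H x W x 9 numeric array; element/slab `t + 1` is phase `t`.
#' @param case_id case identifier string.
#' @param pixel_spacing optional numeric length-2 (mm per pixel, row/col).
#' @return an object of class `dce_series` with fields `phases` (list of 9
#'   matrices), `case_id`, `pixel_spacing`.
#' @export
dce_series <- function(phases, case_id = "case", pixel_spacing = NULL) {
  if (is.array(phases) && length(dim(phases)) == 3L) {
    phases <- lapply(seq_len(dim(phases)[3]), function(k) phases[, , k])
  }
  if (!is.list(phases)) {
    stop("`phases` must be a list of matrices or a 3D array")
  }
  if (length(phases) != 9L) {
    stop(sprintf("%d phases, expected 9", length(phases)))
  }
  phases <- lapply(phases, function(p) {
    p <- as.matrix(p)
    storage.mode(p) <- "double"
    p
  })
  d0 <- dim(phases[[1]])
  for (k in seq_along(phases)) {
    if (!identical(dim(phases[[k]]), d0)) {
      stop("all phases must share an identical shape")
    }
    if (any(!is.finite(phases[[k]]))) stop("phase intensities must be finite")
    if (any(phases[[k]] < 0)) stop("phase intensities must be >= 0")
  }
  structure(
    list(phases = phases, case_id = as.character(case_id),
         pixel_spacing = pixel_spacing),
    class = "dce_series"
  )
}

#' @export
dim.dce_series <- function(x) dim(x$phases[[1]])

#' Construct a lesion mask
#'
#' A binary 2D region on the same grid as its series. Validation of the
#' single-component and minimum-size invariants is performed by
#' [validate_lesion_mask()] (segmentation and the generator always return
#' masks that satisfy them).
#'
#' @param mask logical or 0/1 numeric matrix.
#' @param case_id case identifier string.
#' @return an object of class `lesion_mask` with fields `mask` (logical
#'   matrix) and `case_id`.
#' @export
lesion_mask <- function(mask, case_id = "case") {
  mask <- as.matrix(mask)
  if (is.numeric(mask)) mask <- mask != 0
  if (!is.logical(mask)) stop("`mask` must be logical or 0/1 numeric")
  structure(list(mask = mask, case_id = as.character(case_id)),
            class = "lesion_mask")
}

#' Validate a lesion mask against its series
#'
#' Checks the mask invariants: same shape as the series, at least
#' `min_pixels` foreground pixels, and exactly one 8-connected component.
#'
#' @param mask a `lesion_mask`.
#' @param series a `dce_series`, or NULL to skip the shape check.
#' @param min_pixels minimum foreground pixel count (default 16).
#' @return the mask, invisibly; errors otherwise.
#' @export
validate_lesion_mask <- function(mask, series = NULL, min_pixels = 16L) {
  m <- mask$mask
  if (!is.null(series) && !identical(dim(m), dim(series))) {
    stop("mask shape does not match series shape")
  }
  n_fg <- sum(m)
  if (n_fg < min_pixels) {
    stop(sprintf("lesion has %d pixels, need >= %d", n_fg, min_pixels))
  }
  lab <- label_components(m)
  if (max(lab) != 1L) {
    stop(sprintf("lesion mask has %d 8-connected components, expected 1", max(lab)))
  }
  invisible(mask)
}

#' Pipeline run configuration
#'
#' One place for every tunable the pipeline consumes, so a run is fully
#' described by (config, seed).
#'
#' @param seed integer master seed for all randomized stages.
#' @param quantization_levels gray levels L for GLCM/GRLM quantization (>= 2).
#' @param correlation_threshold Pearson filter cutoff in (0, 1].
#' @param cv_folds folds for the LASSO cross-validation (>= 2).
#' @param entry_p,removal_p forward-stepwise entry/removal p-values.
#' @param segmentation_phase subtraction phase used for lesion delineation.
#' @param out_dir output directory for pipeline artifacts.
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 42L, quantization_levels = 8L,
                       correlation_threshold = 0.95, cv_folds = 10L,
                       entry_p = 0.05, removal_p = 0.10,
                       segmentation_phase = 3L, out_dir = NULL) {
  stopifnot(quantization_levels >= 2L,
            correlation_threshold > 0, correlation_threshold <= 1,
            cv_folds >= 2L, entry_p > 0, entry_p < 1,
            removal_p >= entry_p, removal_p < 1,
            segmentation_phase >= 1L, segmentation_phase <= 8L)
  structure(list(seed = as.integer(seed),
                 quantization_levels = as.integer(quantization_levels),
                 correlation_threshold = correlation_threshold,
                 cv_folds = as.integer(cv_folds),
                 entry_p = entry_p, removal_p = removal_p,
                 segmentation_phase = as.integer(segmentation_phase),
                 out_dir = out_dir),
            class = "run_config")
}

#' Write a case to a plain-text fixture directory
#'
#' @param series a `dce_series`.
#' @param dir parent directory; the case is written to `dir/<case_id>/`.
#' @param mask optional `lesion_mask`.
#' @param label optional 0/1 class label (1 = HER2-positive).
#' @param truth optional named list of generator parameters.
#' @return the case directory path, invisibly.
#' @export
write_case <- function(series, dir, mask = NULL, label = NULL, truth = NULL) {
  cdir <- file.path(dir, series$case_id)
  dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(series)
  ph <- vapply(series$phases, as.vector, numeric(prod(d)))  # row-major per column
  colnames(ph) <- paste0("t", 0:8)
  utils::write.csv(as.data.frame(ph), file.path(cdir, "phases.csv"),
                   row.names = FALSE)
  if (!is.null(mask)) {
    utils::write.csv(data.frame(mask = as.integer(mask$mask)),
                     file.path(cdir, "mask.csv"), row.names = FALSE)
  }
  meta <- list(case_id = series$case_id, height = d[1], width = d[2],
               pixel_spacing = series$pixel_spacing,
               label = label, truth = truth)
  jsonlite::write_json(meta, file.path(cdir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(cdir)
}

#' Read a case from a fixture directory
#'
#' @param path a case directory written by [write_case()].
#' @return a list with `series` (`dce_series`), `mask` (`lesion_mask` or
#'   NULL), `label` (integer or NULL), `truth` (list or NULL).
#' @export
read_case <- function(path) {
  if (!dir.exists(path)) stop(sprintf("case directory not found: %s", path))
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  ph <- utils::read.csv(file.path(path, "phases.csv"))
  if (ncol(ph) != 9L) {
    stop(sprintf("%d phases, expected 9", ncol(ph)))
  }
  d <- c(meta$height, meta$width)
  if (nrow(ph) != prod(d)) stop("phase pixel count does not match meta dims")
  phases <- lapply(seq_len(9L), function(k) matrix(ph[[k]], d[1], d[2]))
  series <- dce_series(phases, case_id = meta$case_id,
                       pixel_spacing = meta$pixel_spacing)
  mask <- NULL
  mfile <- file.path(path, "mask.csv")
  if (file.exists(mfile)) {
    mv <- utils::read.csv(mfile)$mask
    if (length(mv) != prod(d)) stop("mask shape does not match series shape")
    mask <- lesion_mask(matrix(mv != 0, d[1], d[2]), case_id = meta$case_id)
  }
  label <- if (!is.null(meta$label) && !is.na(meta$label)) as.integer(meta$label)
  truth <- if (!is.null(meta$truth)) as.list(meta$truth)
  list(series = series, mask = mask, label = label, truth = truth)
}

#' Canonical 55-feature column order
#'
#' Histogram (4), GLCM (19), GRLM (11), then DWT 7 x {harr, deubechies2,
#' symlet4} (21), named `<family>_<Feature>` / `<wavelet>_<subband>`.
#'
#' @return character vector of length 55.
#' @export
feature_names <- function() {
  c(paste0("hist_", c("Mean", "Variance", "Skewness", "Kurtosis")),
    paste0("glcm_", c("Autocorrelation", "Contrast", "Correlation",
                      "ClusterProminence", "ClusterShade", "Dissimilarity",
                      "Energy", "Entropy", "Homogeneity", "MaximumProbability",
                      "Variance", "SumAverage", "SumVariance", "SumEntropy",
                      "DifferenceVariance", "DifferenceEntropy",
                      "InformationMeasureCorrelation1",
                      "InformationMeasureCorrelation2",
                      "InverseDifferenceNormalized")),
    paste0("grlm_", c("ShortRunEmphasis", "LongRunEmphasis",
                      "GrayLevelNonuniformity", "RunLengthNonuniformity",
                      "RunPercentage", "LowGrayLevelRunEmphasis",
                      "HighGrayLevelRunEmphasis",
                      "ShortRunLowGrayLevelEmphasis",
                      "ShortRunHighGrayLevelEmphasis",
                      "LongRunLowGrayLevelEmphasis",
                      "LongRunHighGrayLevelEmphasis")),
    as.vector(t(outer(c("harr", "deubechies2", "symlet4"),
                      c("L", "HH1", "VH1", "DH1", "HH2", "VH2", "DH2"),
                      paste, sep = "_"))))
}

#' Names of the seven kinetic parameter maps
#' @return character vector of length 7.
#' @export
kinetic_map_names <- function() {
  c("E_initial", "E_peak", "ESER", "MSI", "SEP", "SER", "SI_slope")
}

#' Write a feature table to CSV
#'
#' @param table data.frame with columns `case_id`, `label`, and the 55
#'   canonical features in [feature_names()] order.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  table <- validate_feature_table(table, require_label = FALSE)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(format(table, digits = 12, trim = TRUE, scientific = NA),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table from CSV
#'
#' @param path CSV path written by [write_feature_table()].
#' @param require_label error if the label column is absent/empty (set when
#'   reading a table for training).
#' @return validated data.frame.
#' @export
read_feature_table <- function(path, require_label = FALSE) {
  if (!file.exists(path)) stop(sprintf("feature table not found: %s", path))
  tb <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_feature_table(tb, require_label = require_label)
}

validate_feature_table <- function(tb, require_label = FALSE) {
  want <- c("case_id", "label", feature_names())
  missing_cols <- setdiff(setdiff(want, "label"), names(tb))
  if (length(missing_cols) > 0) {
    stop(sprintf("feature table is missing columns: %s",
                 paste(utils::head(missing_cols, 5), collapse = ", ")))
  }
  if (anyDuplicated(tb$case_id)) {
    stop(sprintf("duplicate case_id in feature table: %s",
                 tb$case_id[duplicated(tb$case_id)][1]))
  }
  has_label <- "label" %in% names(tb) && !all(is.na(tb$label))
  if (require_label && !has_label) {
    stop("feature table has no usable label column (required for training)")
  }
  if (!"label" %in% names(tb)) tb$label <- NA_integer_
  tb[, want]
}
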