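# M-mode pipeline: most-hyperechoic contiguous line -> sub-pleural texture
# scores -> seashore (negative) vs stratosphere/barcode (positive) call.
#
# The texture statistic is the per-row temporal coefficient of variation:
# barcode rows are constant along the sweep (cv ~ 0), seashore rows carry
# fully developed speckle (cv ~ 0.52 for Rayleigh), so a cv threshold well
# between the two separates the signs and is invariant to global intensity
# rescaling.

#' M-mode pipeline parameters
#'
#' @param line_threshold Pleural-line pixels must exceed `line_threshold`
#'   times the whole-image mean intensity.
#' @param min_contiguity Minimum fraction of time columns above threshold for
#'   a row to count as a contiguous line.
#' @param margin_rows Rows at the top of the image excluded from the line
#'   search (near-field / skin reverberation guard).
#' @param gap Rows skipped below the detected line before texture scoring.
#' @param cv_threshold Per-row temporal coefficient of variation below which a
#'   row counts as barcode-like.
#' @param barcode_threshold Minimum barcode row fraction for a positive
#'   (stratosphere) call.
#' @param epsilon Rows with temporal mean below `epsilon` are scored cv = 0
#'   (an echo-free row is static, not granular).
#' @return A named list of class `mmode_params`.
#' @export
mmode_params <- function(line_threshold = 1.5, min_contiguity = 0.6,
                         margin_rows = 5, gap = 3, cv_threshold = 0.1,
                         barcode_threshold = 0.6, epsilon = 0.02) {
  structure(as.list(environment()), class = "mmode_params")
}

#' Detect the pleural line on an M-mode image
#'
#' Selects the most hyperechoic contiguous horizontal line: among rows (below
#' the top `margin_rows` guard) whose contiguity — fraction of time columns
#' with intensity at least `line_threshold` times the image mean — reaches
#' `min_contiguity`, the row with the highest mean intensity wins.
#'
#' @param image An [mmode_image()].
#' @param params An [mmode_params()].
#' @return A `pleural_line_fit` (see [detect_pleural_line()]); the lateral
#'   span is the full sweep.
#' @export
detect_pleural_line_mmode <- function(image, params = mmode_params()) {
  stopifnot(inherits(image, "mmode_image"))
  px <- image$pixels
  H <- nrow(px); W <- ncol(px)
  not_found <- structure(
    list(found = FALSE, depth_row = NA_integer_, span_start = NA_integer_,
         span_end = NA_integer_, brightness = NA_real_, contiguity = NA_real_),
    class = "pleural_line_fit"
  )
  thr <- params$line_threshold * mean(px)
  if (thr <= 0) return(not_found)
  rows <- (params$margin_rows + 1L):H
  if (length(rows) < 1L) return(not_found)
  contiguity <- rowMeans(px[rows, , drop = FALSE] >= thr)
  brightness <- rowMeans(px[rows, , drop = FALSE])
  ok <- contiguity >= params$min_contiguity
  if (!any(ok)) return(not_found)
  best <- which(ok)[which.max(brightness[ok])]
  structure(
    list(found = TRUE, depth_row = as.integer(rows[best]),
         span_start = 1L, span_end = as.integer(W),
         brightness = brightness[best], contiguity = contiguity[best]),
    class = "pleural_line_fit"
  )
}

#' Score sub-pleural M-mode texture
#'
#' Over rows from `depth_row + gap` to the bottom edge, computes the per-row
#' temporal coefficient of variation (sd/mean along the time axis; rows with
#' mean below `epsilon` score cv = 0).  Returns the mean cv (`granularity`)
#' and the fraction of rows with cv below `cv_threshold`
#' (`barcode_fraction`).
#'
#' @param image An [mmode_image()].
#' @param line A found `pleural_line_fit`.
#' @param params An [mmode_params()].
#' @return List of class `mmode_texture_scores`: `granularity`,
#'   `barcode_fraction`, `row_cv` (per-row values).
#' @export
score_subpleural_texture <- function(image, line, params = mmode_params()) {
  if (!isTRUE(line$found)) ptx_abort("no_line", "pleural line was not found")
  px <- image$pixels
  H <- nrow(px)
  r0 <- line$depth_row + params$gap
  if (H - r0 + 1L < 8L) {
    ptx_abort("insufficient_depth",
              "fewer than 8 rows below the pleural line: cannot score texture")
  }
  sub <- px[r0:H, , drop = FALSE]
  m <- rowMeans(sub)
  s <- apply(sub, 1L, sd)
  cv <- ifelse(m < params$epsilon, 0, s / m)
  structure(
    list(granularity = mean(cv),
         barcode_fraction = mean(cv < params$cv_threshold),
         row_cv = cv),
    class = "mmode_texture_scores"
  )
}

#' Classify an M-mode image
#'
#' No detectable pleural line gives an indeterminate call.  Otherwise a
#' barcode row fraction of at least `barcode_threshold` is read as the
#' stratosphere sign (positive for pneumothorax); anything more granular is
#' the seashore sign (negative).
#'
#' @param image An [mmode_image()].
#' @param params An [mmode_params()].
#' @return A `ptx_call` with the line fit and texture scores as evidence.
#' @export
classify_mmode <- function(image, params = mmode_params()) {
  stopifnot(inherits(image, "mmode_image"))
  line <- detect_pleural_line_mmode(image, params)
  if (!line$found) {
    return(new_ptx_call(image$exam_id, "indeterminate", "no_pleural_line",
                        list(line = line), params))
  }
  scores <- tryCatch(
    score_subpleural_texture(image, line, params),
    ptxcad_error_insufficient_depth = function(e) e
  )
  if (inherits(scores, "condition")) {
    return(new_ptx_call(image$exam_id, "indeterminate", "insufficient_depth",
                        list(line = line), params))
  }
  label <- if (scores$barcode_fraction >= params$barcode_threshold) "positive" else "negative"
  new_ptx_call(image$exam_id, label, NA_character_,
               list(line = line, texture = scores), params)
}
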