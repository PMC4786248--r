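# B-mode pneumothorax pipeline:
#   rib shadows -> intercostal space -> pleural line -> sliding -> reverberation
# then a three-way call (positive / negative / indeterminate).
#
# Static-structure stages (shadows, pleural line, reverberation) run on the
# temporal median frame, which is robust to pleural sliding.  Motion is
# estimated by 1-D normalized cross-correlation of sub-pleural strips at
# integer lateral shifts.

#' B-mode pipeline parameters
#'
#' All detection thresholds in one object.  The defaults are calibrated for
#' intensities normalized to `[0, 1]`; distances are in pixels.
#'
#' @param shadow_factor A column belongs to a rib shadow when its mean deep
#'   intensity falls below `shadow_factor` times the deep-half global mean.
#' @param min_shadow_width Minimum shadow width (px).
#' @param min_space_width Minimum usable intercostal-space width (px).
#' @param space_margin Margin shaved off each side of the inter-rib gap (px).
#' @param line_threshold Pleural-line pixels must exceed `line_threshold`
#'   times the mean intensity of the search region.
#' @param min_contiguity Minimum fraction of space columns above threshold for
#'   a row to count as a contiguous line.
#' @param strip_offset Rows between the detected line and the motion strip.
#' @param strip_height Height of the motion strip (rows).
#' @param max_shift Maximum lateral shift searched (px).
#' @param amp_threshold Minimum sliding amplitude (px) to call sliding.
#' @param subpleural_gap Rows skipped below the line before scoring
#'   reverberation penetration.
#' @param artifact_threshold Sub-pleural pixels count as artifact when they
#'   exceed `artifact_threshold` times the pleural-line brightness.
#' @param penetration_threshold Minimum per-column penetration score for a
#'   column to join an artifact band.
#' @param min_band_width Minimum artifact-band width (px).
#' @return A named list of class `bmode_params`.
#' @export
bmode_params <- function(shadow_factor = 0.5, min_shadow_width = 8,
                         min_space_width = 20, space_margin = 4,
                         line_threshold = 1.5, min_contiguity = 0.6,
                         strip_offset = 2, strip_height = 6, max_shift = 10,
                         amp_threshold = 1.5, subpleural_gap = 4,
                         artifact_threshold = 0.5, penetration_threshold = 0.5,
                         min_band_width = 3) {
  structure(as.list(environment()), class = "bmode_params")
}

#' Temporal median frame of a clip
#' @param clip A [bmode_clip()].
#' @return `H x W` matrix.
#' @export
median_frame <- function(clip) {
  T <- n_frames(clip)
  if (T == 1L) return(clip_frame(clip, 1L))
  H <- dim(clip$frames)[2]; W <- dim(clip$frames)[3]
  m <- matrix(clip$frames, T, H * W)
  # columnwise sort in one order() call, then take the middle element(s)
  sm <- matrix(m[order(col(m), m)], T, H * W)
  med <- if (T %% 2L == 1L) sm[(T + 1L) %/% 2L, ] else {
    (sm[T %/% 2L, ] + sm[T %/% 2L + 1L, ]) / 2
  }
  matrix(med, H, W)
}

# maximal runs of TRUE in a logical vector, as (start, end) 1-based inclusive
logical_runs <- function(x, min_len = 1L) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  data.frame(start = starts[keep], end = ends[keep])
}

#' Detect rib shadows
#'
#' On the temporal median frame, a rib shadow is a maximal run of columns
#' (width >= `min_shadow_width`) whose mean intensity over the deep half of
#' the image falls below `shadow_factor` times the deep-half global mean.
#' Each shadow carries the depth row of the brightest structure above it (the
#' rib cap) and a contrast score
#' `1 - mean(deep inside) / mean(deep outside)`, floored at 0.
#'
#' @param clip A [bmode_clip()].
#' @param params A [bmode_params()].
#' @return A tibble of class `rib_shadow_set` with columns `start`, `end`
#'   (inclusive column interval), `cap_depth_row`, `shadow_contrast`.  An
#'   empty tibble is a valid result.
#' @export
detect_rib_shadows <- function(clip, params = bmode_params()) {
  med <- if (inherits(clip, "bmode_clip")) median_frame(clip) else clip
  H <- nrow(med); W <- ncol(med)
  deep_rows <- (H %/% 2 + 1L):H
  deep <- med[deep_rows, , drop = FALSE]
  col_mean <- colMeans(deep)
  global_mean <- mean(deep)
  is_shadow <- col_mean < params$shadow_factor * global_mean
  runs <- logical_runs(is_shadow, params$min_shadow_width)
  if (nrow(runs) == 0L) {
    out <- tibble(start = integer(), end = integer(),
                  cap_depth_row = integer(), shadow_contrast = numeric())
    return(structure(out, class = c("rib_shadow_set", class(out))))
  }
  shallow <- med[seq_len(min(deep_rows) - 1L), , drop = FALSE]
  inside <- rep(FALSE, W)
  for (i in seq_len(nrow(runs))) inside[runs$start[i]:runs$end[i]] <- TRUE
  out_mean <- if (any(!inside)) mean(deep[, !inside, drop = FALSE]) else NA_real_
  rows <- purrr::map(seq_len(nrow(runs)), function(i) {
    cols <- runs$start[i]:runs$end[i]
    cap <- which.max(rowMeans(shallow[, cols, drop = FALSE]))
    contrast <- if (is.na(out_mean) || out_mean <= 0) 0 else {
      max(0, 1 - mean(deep[, cols, drop = FALSE]) / out_mean)
    }
    tibble(start = runs$start[i], end = runs$end[i],
           cap_depth_row = as.integer(cap), shadow_contrast = contrast)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("rib_shadow_set", class(out)))
}

#' Locate the intercostal space
#'
#' The widest gap between two consecutive rib shadows, shrunk by
#' `space_margin` on each side.  Two discrete rib shadows are required: with
#' fewer than two shadows, or a shrunk gap narrower than `min_space_width`,
#' the space is not found.
#'
#' @param shadows A `rib_shadow_set` from [detect_rib_shadows()].
#' @param image_width Image width (columns).
#' @param params A [bmode_params()].
#' @return List of class `intercostal_space`: `found`, `start`, `end`
#'   (inclusive columns).
#' @export
locate_intercostal_space <- function(shadows, image_width, params = bmode_params()) {
  not_found <- structure(list(found = FALSE, start = NA_integer_, end = NA_integer_),
                         class = "intercostal_space")
  if (nrow(shadows) < 2L) return(not_found)
  sh <- shadows[order(shadows$start), ]
  gap_start <- sh$end[-nrow(sh)] + 1L
  gap_end <- sh$start[-1L] - 1L
  widths <- gap_end - gap_start + 1L
  i <- which.max(widths)
  start <- gap_start[i] + params$space_margin
  end <- gap_end[i] - params$space_margin
  if (end - start + 1L < params$min_space_width) return(not_found)
  structure(list(found = TRUE, start = as.integer(start), end = as.integer(end)),
            class = "intercostal_space")
}

#' Detect the pleural line
#'
#' Scans rows strictly below the deepest rib cap for a hyperechoic,
#' contiguous horizontal line across the intercostal space: among rows whose
#' contiguity (fraction of space columns with intensity at least
#' `line_threshold` times the search-region mean) reaches `min_contiguity`,
#' the row with the highest mean intensity over the space wins.
#'
#' @param clip A [bmode_clip()].
#' @param space An `intercostal_space` from [locate_intercostal_space()].
#' @param shadows The `rib_shadow_set` (supplies the rib cap depths).
#' @param params A [bmode_params()].
#' @return List of class `pleural_line_fit`: `found`, `depth_row`,
#'   `span_start`, `span_end`, `brightness`, `contiguity`.
#' @export
detect_pleural_line <- function(clip, space, shadows, params = bmode_params()) {
  not_found <- structure(
    list(found = FALSE, depth_row = NA_integer_, span_start = NA_integer_,
         span_end = NA_integer_, brightness = NA_real_, contiguity = NA_real_),
    class = "pleural_line_fit"
  )
  if (!isTRUE(space$found)) return(not_found)
  med <- median_frame(clip)
  H <- nrow(med)
  top <- if (nrow(shadows) > 0L) max(shadows$cap_depth_row) + 1L else 2L
  if (top >= H) return(not_found)
  cols <- space$start:space$end
  region <- med[top:H, cols, drop = FALSE]
  thr <- params$line_threshold * mean(region)
  if (thr <= 0) return(not_found)
  contiguity <- rowMeans(region >= thr)
  brightness <- rowMeans(region)
  ok <- contiguity >= params$min_contiguity
  if (!any(ok)) return(not_found)
  best <- which(ok)[which.max(brightness[ok])]
  structure(
    list(found = TRUE, depth_row = as.integer(top + best - 1L),
         span_start = space$start, span_end = space$end,
         brightness = brightness[best], contiguity = contiguity[best]),
    class = "pleural_line_fit"
  )
}

# integer-shift NCC displacement of frame B relative to frame A:
# positive d means the content of B sits d columns to the right of A.
ncc_shift <- function(a, b, max_shift) {
  W <- ncol(a)
  cand <- seq(-max_shift, max_shift)
  cand <- cand[order(abs(cand), cand)]  # prefer the smallest displacement on ties
  best_d <- 0L; best_r <- -Inf
  for (d in cand) {
    ia <- max(1L, 1L - d):min(W, W - d)   # columns of a
    ib <- ia + d                           # aligned columns of b
    va <- as.vector(a[, ia, drop = FALSE])
    vb <- as.vector(b[, ib, drop = FALSE])
    if (sd(va) < 1e-12 || sd(vb) < 1e-12) next
    r <- stats::cor(va, vb)
    if (is.finite(r) && r > best_r + 1e-12) {
      best_r <- r; best_d <- d
    }
  }
  list(shift = as.integer(best_d), score = best_r)
}

#' Measure pleural sliding
#'
#' For each consecutive frame pair, extracts a sub-pleural strip
#' (`strip_height` rows starting `strip_offset` rows below the detected line,
#' restricted to the space columns) and estimates the lateral displacement
#' maximizing normalized cross-correlation over integer shifts up to
#' `max_shift`.  The sliding amplitude is half the peak-to-peak excursion of
#' the cumulated displacement trajectory; sliding is detected when the
#' amplitude reaches `amp_threshold` *and* the displacement sequence reverses
#' direction at least once ("to and fro" — a monotone drift is not sliding).
#'
#' @param clip A [bmode_clip()] with at least 3 frames.
#' @param line A found `pleural_line_fit`.
#' @param space The `intercostal_space`.
#' @param params A [bmode_params()].
#' @return List of class `sliding_result`: `displacements` (length T-1,
#'   signed px), `amplitude_px`, `sign_changes`, `sliding_detected`.
#' @export
measure_sliding <- function(clip, line, space, params = bmode_params()) {
  T <- n_frames(clip)
  if (T < 3L) {
    ptx_abort("too_few_frames", "sliding needs at least 3 frames ('to and fro')")
  }
  if (!isTRUE(line$found)) ptx_abort("no_line", "pleural line was not found")
  H <- dim(clip)[2]
  r0 <- min(line$depth_row + params$strip_offset, H - 1L)
  rows <- r0:min(H, r0 + params$strip_height - 1L)
  cols <- space$start:space$end
  disp <- vapply(seq_len(T - 1L), function(t) {
    a <- clip$frames[t, rows, cols, drop = TRUE]
    b <- clip$frames[t + 1L, rows, cols, drop = TRUE]
    ncc_shift(a, b, params$max_shift)$shift
  }, integer(1))
  traj <- cumsum(c(0L, disp))
  amplitude <- (max(traj) - min(traj)) / 2
  nz <- disp[disp != 0L]
  sign_changes <- if (length(nz) >= 2L) sum(diff(sign(nz)) != 0) else 0L
  structure(
    list(displacements = disp, amplitude_px = amplitude,
         sign_changes = as.integer(sign_changes),
         sliding_detected = amplitude >= params$amp_threshold && sign_changes >= 1L),
    class = "sliding_result"
  )
}

#' Detect sub-pleural reverberation artifacts
#'
#' On the temporal median frame, each space column gets a penetration score:
#' the fraction of rows between `depth_row + subpleural_gap` and the bottom
#' edge whose intensity reaches `artifact_threshold` times the pleural-line
#' brightness.  Artifact bands are maximal column runs (width >=
#' `min_band_width`) whose scores all exceed `penetration_threshold`;
#' reverberation is detected iff at least one band exists.
#'
#' @inheritParams measure_sliding
#' @return List of class `reverb_result`: `scores` (per space column),
#'   `artifact_bands` (tibble start/end in image columns),
#'   `reverberation_detected`.
#' @export
detect_reverberation <- function(clip, line, space, params = bmode_params()) {
  if (!isTRUE(line$found)) ptx_abort("no_line", "pleural line was not found")
  med <- median_frame(clip)
  H <- nrow(med)
  r0 <- line$depth_row + params$subpleural_gap
  cols <- space$start:space$end
  if (r0 > H) {
    scores <- rep(0, length(cols))
  } else {
    sub <- med[r0:H, cols, drop = FALSE]
    scores <- colMeans(sub >= params$artifact_threshold * line$brightness)
  }
  runs <- logical_runs(scores > params$penetration_threshold, params$min_band_width)
  bands <- tibble(start = as.integer(space$start + runs$start - 1L),
                  end = as.integer(space$start + runs$end - 1L))
  structure(
    list(scores = scores, artifact_bands = bands,
         reverberation_detected = nrow(bands) > 0L),
    class = "reverb_result"
  )
}

#' Three-way decision rule
#'
#' The pure decision table behind [classify_bmode()]: no pleural line means
#' indeterminate (dominating); detected sliding or detected reverberation
#' means negative for pneumothorax; otherwise positive.
#'
#' @param line_found,sliding_detected,reverberation_detected Logical scalars.
#' @return `"positive"`, `"negative"`, or `"indeterminate"`.
#' @export
bmode_decision <- function(line_found, sliding_detected, reverberation_detected) {
  if (!isTRUE(line_found)) return("indeterminate")
  if (isTRUE(sliding_detected) || isTRUE(reverberation_detected)) return("negative")
  "positive"
}

new_ptx_call <- function(exam_id, label, reason = NA_character_,
                         evidence = list(), params = NULL) {
  structure(
    list(exam_id = exam_id, label = label, reason = reason,
         evidence = evidence, params = params),
    class = "ptx_call"
  )
}

#' @export
print.ptx_call <- function(x, ...) {
  cat(sprintf("<ptx_call> %s: %s%s\n",
              if (nzchar(x$exam_id)) x$exam_id else "(unnamed)", x$label,
              if (!is.na(x$reason)) paste0(" (", x$reason, ")") else ""))
  invisible(x)
}

#' Classify a B-mode clip
#'
#' Runs the full pipeline (rib shadows, intercostal space, pleural line,
#' sliding, reverberation) and applies [bmode_decision()].  Clips on which
#' the pleural line cannot be localized — including clips with fewer than two
#' rib shadows or too few frames for motion analysis — come back
#' indeterminate with a recorded reason, never as an error.
#'
#' @param clip A [bmode_clip()].
#' @param params A [bmode_params()].
#' @return A `ptx_call` with label, reason, and the four stage results as
#'   evidence.
#' @export
classify_bmode <- function(clip, params = bmode_params()) {
  stopifnot(inherits(clip, "bmode_clip"))
  shadows <- detect_rib_shadows(clip, params)
  space <- locate_intercostal_space(shadows, dim(clip)[3], params)
  evidence <- list(shadows = shadows, space = space, line = NULL,
                   sliding = NULL, reverb = NULL)
  if (!space$found) {
    return(new_ptx_call(clip$exam_id, "indeterminate", "no_intercostal_space",
                        evidence, params))
  }
  line <- detect_pleural_line(clip, space, shadows, params)
  evidence$line <- line
  if (!line$found) {
    return(new_ptx_call(clip$exam_id, "indeterminate", "no_pleural_line",
                        evidence, params))
  }
  sliding <- tryCatch(
    measure_sliding(clip, line, space, params),
    ptxcad_error_too_few_frames = function(e) e
  )
  if (inherits(sliding, "condition")) {
    return(new_ptx_call(clip$exam_id, "indeterminate", "too_few_frames",
                        evidence, params))
  }
  evidence$sliding <- sliding
  reverb <- detect_reverberation(clip, line, space, params)
  evidence$reverb <- reverb
  label <- bmode_decision(TRUE, sliding$sliding_detected, reverb$reverberation_detected)
  new_ptx_call(clip$exam_id, label, NA_character_, evidence, params)
}
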