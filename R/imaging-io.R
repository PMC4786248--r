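# Canonical in-memory image model + readers/writers shared by both pipelines.
#
# Conventions: arrays are indexed (row, col) = (depth, lateral/time), 1-based;
# row 1 is the skin surface.  Intensities live in [0, 1], rescaled from 8-/16-
# bit sources by the dtype maximum so that thresholds transfer across depths.

#' Construct a B-mode cine clip
#'
#' A `bmode_clip` is a time-ordered stack of grayscale frames indexed
#' `(t, depth_row, lateral_col)` with intensities in `[0, 1]`; row 1 is the
#' skin surface and depth increases with the row index.
#'
#' @param frames 3-D numeric array `(T, H, W)`, or a list of `H x W` matrices.
#' @param frame_rate_hz Acquisition frame rate in Hz (default 20).
#' @param exam_id Identifier string.
#' @return A `bmode_clip` object.
#' @export
bmode_clip <- function(frames, frame_rate_hz = 20, exam_id = "") {
  if (is.list(frames)) {
    shapes <- unique(lapply(frames, dim))
    if (length(shapes) != 1L) {
      ptx_abort("frame_shape_mismatch", "all frames must share one (H, W) shape")
    }
    frames <- aperm(
      array(unlist(frames), dim = c(shapes[[1]], length(frames))),
      c(3L, 1L, 2L)
    )
  }
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    ptx_abort("bad_frames", "`frames` must be a (T, H, W) array or list of matrices")
  }
  if (dim(frames)[1] < 1L) ptx_abort("no_frames", "clip must contain at least one frame")
  if (anyNA(frames) || min(frames) < 0 || max(frames) > 1) {
    ptx_abort("intensity_range", "frame intensities must lie in [0, 1] with no NA")
  }
  if (!is.numeric(frame_rate_hz) || frame_rate_hz <= 0) {
    ptx_abort("bad_frame_rate", "`frame_rate_hz` must be a positive number")
  }
  structure(
    list(frames = frames, frame_rate_hz = frame_rate_hz, exam_id = as.character(exam_id)),
    class = "bmode_clip"
  )
}

#' @export
print.bmode_clip <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<bmode_clip> %s: %d frames of %d x %d (depth x lateral), %.3g Hz\n",
    if (nzchar(x$exam_id)) x$exam_id else "(unnamed)", d[1], d[2], d[3], x$frame_rate_hz
  ))
  invisible(x)
}

#' @export
dim.bmode_clip <- function(x) dim(x$frames)

#' Number of frames in a clip
#' @param clip A [bmode_clip()].
#' @return Integer frame count.
#' @export
n_frames <- function(clip) dim(clip$frames)[1]

# t-th frame as an H x W matrix
clip_frame <- function(clip, t) clip$frames[t, , , drop = TRUE]

#' Construct an M-mode image
#'
#' A single grayscale image indexed `(depth_row, time_col)`, intensities in
#' `[0, 1]`, at least 8 x 8 pixels.
#'
#' @param pixels Numeric matrix `(H, W)`.
#' @param sweep_seconds Optional sweep duration in seconds.
#' @param exam_id Identifier string.
#' @return An `mmode_image` object.
#' @export
mmode_image <- function(pixels, sweep_seconds = NULL, exam_id = "") {
  if (!is.matrix(pixels)) ptx_abort("bad_pixels", "`pixels` must be a matrix")
  if (nrow(pixels) < 8L || ncol(pixels) < 8L) {
    ptx_abort("image_too_small", "M-mode image must be at least 8 x 8 pixels")
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1) {
    ptx_abort("intensity_range", "intensities must lie in [0, 1] with no NA")
  }
  if (!is.null(sweep_seconds) && sweep_seconds <= 0) {
    ptx_abort("bad_sweep", "`sweep_seconds` must be positive when given")
  }
  structure(
    list(pixels = pixels, sweep_seconds = sweep_seconds, exam_id = as.character(exam_id)),
    class = "mmode_image"
  )
}

#' @export
print.mmode_image <- function(x, ...) {
  cat(sprintf(
    "<mmode_image> %s: %d x %d (depth x time)\n",
    if (nzchar(x$exam_id)) x$exam_id else "(unnamed)", nrow(x$pixels), ncol(x$pixels)
  ))
  invisible(x)
}

#' Construct exam metadata
#'
#' Per-exam sidecar record: imaging mode, transducer, optional ACEP 5-point
#' image-quality score, optional reference label.  Optionals stay `NA` when
#' unset — they are never defaulted to a label.
#'
#' @param exam_id Identifier string.
#' @param mode `"B"` or `"M"`.
#' @param transducer `"linear"`, `"phased"`, or `"unknown"`.
#' @param quality_score Integer 1-5 or `NA`.
#' @param reference_label `"positive"`, `"negative"`, `"indeterminate"`, or `NA`.
#' @return An `exam_metadata` object.
#' @export
exam_metadata <- function(exam_id, mode, transducer = "unknown",
                          quality_score = NA_integer_, reference_label = NA_character_) {
  if (!mode %in% c("B", "M")) {
    ptx_abort("unknown_mode", sprintf("unknown imaging mode '%s' (expected B or M)", mode))
  }
  if (!transducer %in% c("linear", "phased", "unknown")) {
    ptx_abort("unknown_transducer", sprintf("unknown transducer '%s'", transducer))
  }
  if (!is.na(quality_score)) {
    if (!quality_score %in% 1:5) {
      ptx_abort("quality_range", "quality_score must be an integer in 1..5 (ACEP scale)")
    }
    quality_score <- as.integer(quality_score)
  }
  if (!is.na(reference_label) && !reference_label %in% c("positive", "negative", "indeterminate")) {
    ptx_abort("bad_label", sprintf("unknown reference label '%s'", reference_label))
  }
  structure(
    list(
      exam_id = as.character(exam_id), mode = mode, transducer = transducer,
      quality_score = quality_score, reference_label = reference_label
    ),
    class = "exam_metadata"
  )
}

# ---- readers ----------------------------------------------------------------

# normalize an image array read by png/tiff to a [0,1] grayscale matrix
as_gray_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (length(dim(x)) == 3L) {
    # color planes -> Rec.601 luma; ignore alpha plane if present
    r <- x[, , 1]
    g <- if (dim(x)[3] >= 2) x[, , 2] else r
    b <- if (dim(x)[3] >= 3) x[, , 3] else r
    return(0.299 * r + 0.587 * g + 0.114 * b)
  }
  ptx_abort("bad_image", "unsupported image layout")
}

read_one_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    lapply(pages, as_gray_matrix)
  } else if (ext == "png") {
    list(as_gray_matrix(png::readPNG(path)))
  } else {
    ptx_abort("bad_format", sprintf("unsupported image format '.%s' (PNG or TIFF expected)", ext))
  }
}

#' Read a B-mode cine clip
#'
#' Accepts a multi-page grayscale TIFF, or a directory of PNG frames named
#' with zero-padded indices (read in filename order).  8-/16-bit inputs are
#' rescaled to `[0, 1]` by the reader; color frames are converted to luma.
#'
#' @param path Multi-page TIFF file or a directory of PNG frames.
#' @param frame_rate_hz Frame rate to record on the clip (default 20).
#' @param exam_id Identifier; defaults to the file/directory base name.
#' @return A [bmode_clip()].
#' @export
read_bmode_clip <- function(path, frame_rate_hz = 20, exam_id = NULL) {
  if (!file.exists(path)) ptx_abort("missing_path", sprintf("no such path: %s", path))
  exam_id <- exam_id %||% sub("\\.[^.]*$", "", basename(path))
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L) ptx_abort("no_frames", sprintf("no PNG frames found in %s", path))
    frames <- lapply(files, function(f) as_gray_matrix(png::readPNG(f)))
  } else {
    frames <- read_one_image(path)
    if (length(frames) == 0L) ptx_abort("no_frames", sprintf("no readable frames in %s", path))
  }
  shapes <- unique(lapply(frames, dim))
  if (length(shapes) != 1L) {
    ptx_abort("frame_shape_mismatch", sprintf(
      "frames of mismatched shape in %s: %s", path,
      paste(vapply(shapes, paste, "", collapse = "x"), collapse = " vs ")
    ))
  }
  bmode_clip(frames, frame_rate_hz = frame_rate_hz, exam_id = exam_id)
}

#' Read an M-mode still image
#'
#' Single-image grayscale PNG or TIFF; intensities normalized to `[0, 1]`,
#' orientation preserved (row 1 = shallowest depth).  Multi-page input is
#' rejected with a pointer to [read_bmode_clip()].
#'
#' @param path PNG or single-page TIFF file.
#' @param sweep_seconds Optional sweep duration in seconds.
#' @param exam_id Identifier; defaults to the file base name.
#' @return An [mmode_image()].
#' @export
read_mmode_image <- function(path, sweep_seconds = NULL, exam_id = NULL) {
  if (!file.exists(path) || dir.exists(path)) {
    ptx_abort("missing_path", sprintf("no such file: %s", path))
  }
  exam_id <- exam_id %||% sub("\\.[^.]*$", "", basename(path))
  pages <- read_one_image(path)
  if (length(pages) > 1L) {
    ptx_abort("multipage_input",
              "multi-page input: this is a cine clip, use read_bmode_clip()")
  }
  mmode_image(pages[[1]], sweep_seconds = sweep_seconds, exam_id = exam_id)
}

#' Write a clip to a multi-page TIFF
#'
#' 8-bit grayscale; re-reading reproduces intensities within 1/255 per pixel.
#'
#' @param clip A [bmode_clip()].
#' @param path Output `.tiff` path.
#' @return `path`, invisibly.
#' @export
write_bmode_clip <- function(clip, path) {
  stopifnot(inherits(clip, "bmode_clip"))
  pages <- lapply(seq_len(n_frames(clip)), function(t) clip_frame(clip, t))
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Write an M-mode image to PNG
#'
#' @param image An [mmode_image()].
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
write_mmode_image <- function(image, path) {
  stopifnot(inherits(image, "mmode_image"))
  png::writePNG(image$pixels, path)
  invisible(path)
}

#' Read a JSON metadata sidecar
#'
#' Expects keys `exam_id`, `mode`, and optionally `transducer`,
#' `quality_score`, `reference_label`.  Unset optionals come back as `NA`.
#'
#' @param path JSON file path.
#' @return An [exam_metadata()].
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) ptx_abort("missing_path", sprintf("no such file: %s", path))
  j <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) ptx_abort("malformed_json", sprintf("malformed JSON in %s: %s", path, conditionMessage(e)))
  )
  if (is.null(j$exam_id) || is.null(j$mode)) {
    ptx_abort("missing_field", "metadata requires at least exam_id and mode")
  }
  exam_metadata(
    exam_id = j$exam_id, mode = j$mode,
    transducer = j$transducer %||% "unknown",
    quality_score = j$quality_score %||% NA_integer_,
    reference_label = j$reference_label %||% NA_character_
  )
}

#' Write a metadata sidecar as JSON
#' @param meta An [exam_metadata()].
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  stopifnot(inherits(meta, "exam_metadata"))
  x <- meta[c("exam_id", "mode", "transducer", "quality_score", "reference_label")]
  x <- x[!vapply(x, function(v) is.null(v) || all(is.na(v)), TRUE)]
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a per-exam ratings table
#'
#' CSV with columns `exam_id`, `rater_id`, `label`
#' (positive/negative/indeterminate) and `quality_score`; one row per
#' (exam, rater) pair, duplicates rejected.
#'
#' @param path CSV file path.
#' @return A tibble with one row per (exam_id, rater_id).
#' @export
read_ratings_table <- function(path) {
  if (!file.exists(path)) ptx_abort("missing_path", sprintf("no such file: %s", path))
  x <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("exam_id", "rater_id", "label", "quality_score")
  missing <- setdiff(needed, names(x))
  if (length(missing) > 0L) {
    ptx_abort("missing_field", paste("ratings CSV lacks columns:", paste(missing, collapse = ", ")))
  }
  bad <- setdiff(unique(x$label), c("positive", "negative", "indeterminate"))
  if (length(bad) > 0L) {
    ptx_abort("bad_label", paste("labels outside the three-value vocabulary:", paste(bad, collapse = ", ")))
  }
  dup <- duplicated(x[c("exam_id", "rater_id")])
  if (any(dup)) {
    ptx_abort("duplicate_rating", sprintf(
      "duplicated (exam_id, rater_id) rows: %s",
      paste(unique(x$exam_id[dup]), collapse = ", ")
    ))
  }
  ok <- !is.na(x$quality_score)
  if (any(!x$quality_score[ok] %in% 1:5)) {
    ptx_abort("quality_range", "quality_score must be in 1..5 (ACEP scale)")
  }
  as_tibble(x[needed])
}
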