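#' Convert a photograph to a binary image matrix
#'
#' Reads a PNG or JPEG raster, compares each pixel's intensity on a selected
#' channel against a threshold, and returns a [bwm] matrix: a pixel becomes
#' black when its normalized intensity is strictly below `threshold_value`,
#' otherwise white. For PNG images with an alpha channel, transparency is
#' assigned first (transparent pixels are excluded from every downstream
#' metric); see *Alpha semantics* below. The binary matrix can be resampled
#' to a smaller working resolution in the same call.
#'
#' @section Alpha semantics:
#' Two rules are provided because the method description and conventional
#' PNG semantics disagree:
#' * `alpha_rule = "above"` (default): a pixel whose alpha value is strictly
#'   **above** `threshold_value` becomes transparent — the literal rule of
#'   the original method description.
#' * `alpha_rule = "below"`: a pixel whose alpha value is strictly **below**
#'   `threshold_value` becomes transparent — conventional PNG semantics
#'   (alpha = 1 is opaque). Use this for images whose background was erased
#'   in an external editor.
#' Images without an alpha channel (all JPEGs) are fully opaque under either
#' rule.
#'
#' @param path path to a `.png`, `.jpg` or `.jpeg` file.
#' @param channel which channel intensity to threshold: `"rgb_average"`
#'   (default), `"red"`, `"green"` or `"blue"`. Grayscale images return the
#'   single gray channel for every selector.
#' @param threshold_value intensity cutoff in `[0, 1]`; default 0.5. Pixels
#'   strictly below it are black; a pixel exactly at the threshold is white.
#' @param alpha_rule `"above"` or `"below"`; see *Alpha semantics*.
#' @param invert logical; swap black and white after thresholding.
#' @param compress_method resampling method applied after thresholding:
#'   `"none"` (default), `"proportional"`, `"width_fixed"`, `"height_fixed"`
#'   or `"frame_fixed"`.
#' @param compress_rate scale factor in `(0, 1]` for `"proportional"`.
#' @param target_width,target_height target dimensions in pixels for the
#'   fixed methods.
#' @param height_size,width_size optional physical frame size (cm) carried on
#'   the result.
#'
#' @return A [bwm] object of the resampled dimensions.
#' @seealso [threshold_image_list()], [resample_bwm()], [image_information()]
#' @examples
#' path <- tempfile(fileext = ".png")
#' render_image(make_fixture("chessboard", 6, 6), path)
#' threshold_image(path)
#' @export
threshold_image <- function(path,
                            channel = c("rgb_average", "red", "green", "blue"),
                            threshold_value = 0.5,
                            alpha_rule = c("above", "below"),
                            invert = FALSE,
                            compress_method = c(
                              "none", "proportional", "width_fixed",
                              "height_fixed", "frame_fixed"
                            ),
                            compress_rate = NULL,
                            target_width = NULL,
                            target_height = NULL,
                            height_size = NULL,
                            width_size = NULL) {
  channel <- match.arg(channel)
  alpha_rule <- match.arg(alpha_rule)
  compress_method <- match.arg(compress_method)
  check_threshold(threshold_value)
  ras <- read_raster(path)
  intensity <- switch(channel,
    red = ras$r,
    green = ras$g,
    blue = ras$b,
    rgb_average = (ras$r + ras$g + ras$b) / 3
  )
  cells <- matrix(
    ifelse(intensity < threshold_value, 1L, 0L),
    nrow = nrow(intensity)
  )
  if (isTRUE(invert)) cells <- 1L - cells
  if (!is.null(ras$alpha)) {
    transparent <- switch(alpha_rule,
      above = ras$alpha > threshold_value,
      below = ras$alpha < threshold_value
    )
    cells[transparent] <- NA_integer_
  }
  m <- bwm(cells, height_size = height_size, width_size = width_size)
  resample_bwm(m,
    compress_method = compress_method, compress_rate = compress_rate,
    target_width = target_width, target_height = target_height
  )
}

check_threshold <- function(threshold_value) {
  if (!is.numeric(threshold_value) || length(threshold_value) != 1L ||
    is.na(threshold_value) || threshold_value < 0 || threshold_value > 1) {
    stop_param("'threshold_value' must be a single number in [0, 1]")
  }
}

#' Convert several photographs to a list of binary matrices
#'
#' Applies [threshold_image()] to each path in turn, preserving order. By
#' default the first failing file aborts the whole batch with an error that
#' names the offending path; with `skip_errors = TRUE` failing files are
#' logged to standard error and returned as `NULL` entries.
#'
#' @param paths non-empty character vector of image paths.
#' @param ... arguments forwarded to [threshold_image()].
#' @param skip_errors log-and-continue instead of fail-fast.
#' @return A list of [bwm] objects (or `NULL` for skipped failures), one per
#'   input path, in input order.
#' @export
threshold_image_list <- function(paths, ..., skip_errors = FALSE) {
  if (length(paths) == 0L) {
    stop_param("'paths' must contain at least one file")
  }
  lapply(paths, function(p) {
    tryCatch(
      threshold_image(p, ...),
      error = function(e) {
        msg <- sprintf("failed to process '%s': %s", p, conditionMessage(e))
        if (isTRUE(skip_errors)) {
          message(msg)
          NULL
        } else {
          stop_input(msg)
        }
      }
    )
  })
}

# raster reading --------------------------------------------------------------

# Returns r/g/b (and alpha if present) as [0,1] matrices, rows = image rows
# top-down. Grayscale images replicate the gray channel into r, g and b, so
# every channel selector returns the single gray channel.
read_raster <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop_input(sprintf("file not found: '%s'", as.character(path)[1L]))
  }
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = tryCatch(png::readPNG(path), error = function(e) {
      stop_input(sprintf("cannot decode '%s' as PNG: %s", path, conditionMessage(e)))
    }),
    jpg = ,
    jpeg = read_jpeg_array(path),
    stop_input(sprintf(
      "unsupported image format '.%s' for '%s' (PNG, JPG and JPEG are supported)",
      ext, path
    ))
  )
  if (is.matrix(arr)) arr <- array(arr, dim = c(dim(arr), 1L))
  chan <- function(k) matrix(arr[, , k], nrow = dim(arr)[1L])
  nc <- dim(arr)[3L]
  if (nc == 1L) { # gray
    list(r = chan(1L), g = chan(1L), b = chan(1L), alpha = NULL)
  } else if (nc == 2L) { # gray + alpha
    list(r = chan(1L), g = chan(1L), b = chan(1L), alpha = chan(2L))
  } else if (nc == 3L) {
    list(r = chan(1L), g = chan(2L), b = chan(3L), alpha = NULL)
  } else {
    list(r = chan(1L), g = chan(2L), b = chan(3L), alpha = chan(4L))
  }
}

read_jpeg_array <- function(path) {
  img <- tryCatch(
    EBImage::readImage(path),
    error = function(e) {
      stop_input(sprintf("cannot decode '%s' as JPEG: %s", path, conditionMessage(e)))
    }
  )
  dat <- EBImage::imageData(img) # width x height (x channels)
  if (length(dim(dat)) == 2L) {
    array(t(dat), dim = c(ncol(dat), nrow(dat), 1L))
  } else {
    aperm(dat, c(2L, 1L, 3L))
  }
}

# resampling ------------------------------------------------------------------

#' Resample a binary matrix by nearest-neighbor lookup
#'
#' Reduces (or generally remaps) a binary matrix to a target resolution.
#' Each target cell takes the state of the source cell containing the
#' nearest source-pixel center: source index `floor((i + 0.5) * src/dst)`
#' (0-based). The domain stays strictly `{1, 0, NA}` — no interpolation.
#'
#' Target dimensions by method: `"proportional"` multiplies both dimensions
#' by `compress_rate`; `"width_fixed"` sets the width and scales the height
#' to preserve the aspect ratio; `"height_fixed"` is symmetric;
#' `"frame_fixed"` sets both. Scaled dimensions are rounded half away from
#' zero with a floor of 1.
#'
#' @inheritParams threshold_image
#' @param m a [bwm] object.
#' @return A [bwm] of the target dimensions, carrying `m`'s physical scale.
#' @export
resample_bwm <- function(m,
                         compress_method = c(
                           "none", "proportional", "width_fixed",
                           "height_fixed", "frame_fixed"
                         ),
                         compress_rate = NULL,
                         target_width = NULL,
                         target_height = NULL) {
  compress_method <- match.arg(compress_method)
  if (compress_method == "none") {
    return(m)
  }
  nr <- nrow(m)
  nc <- ncol(m)
  dims <- switch(compress_method,
    proportional = {
      if (is.null(compress_rate) || !is.numeric(compress_rate) ||
        length(compress_rate) != 1L || is.na(compress_rate) ||
        compress_rate <= 0 || compress_rate > 1) {
        stop_param("'compress_rate' must be a single number in (0, 1]")
      }
      c(scale_dim(nr, compress_rate), scale_dim(nc, compress_rate))
    },
    width_fixed = {
      check_target(target_width, "target_width")
      c(scale_dim(nr, target_width / nc), as.integer(target_width))
    },
    height_fixed = {
      check_target(target_height, "target_height")
      c(as.integer(target_height), scale_dim(nc, target_height / nr))
    },
    frame_fixed = {
      check_target(target_width, "target_width")
      check_target(target_height, "target_height")
      c(as.integer(target_height), as.integer(target_width))
    }
  )
  if (identical(dims, c(nr, nc))) {
    return(m)
  }
  ri <- nn_index(dims[1L], nr)
  ci <- nn_index(dims[2L], nc)
  as_bwm(unclass(m)[ri, ci, drop = FALSE], template = m)
}

# round half away from zero, floor 1
scale_dim <- function(n, rate) {
  max(1L, as.integer(floor(n * rate + 0.5)))
}

check_target <- function(x, name) {
  if (is.null(x) || !is.numeric(x) || length(x) != 1L || is.na(x) || x < 1) {
    stop_param(sprintf("'%s' must be a single positive integer", name))
  }
}

# 1-based source indices for nearest-neighbor resampling dst -> src
nn_index <- function(dst, src) {
  pmin(src, floor((seq_len(dst) - 0.5) * src / dst) + 1L)
}

# summary ---------------------------------------------------------------------

#' Summary counts and fractions of a binary matrix
#'
#' @param m a [bwm] object (any 1/0/NA matrix is accepted).
#' @return A list of class `bw_info`: `n_rows`, `n_cols`, `n_black`,
#'   `n_white`, `n_transparent` and the corresponding fractions of all cells
#'   (fractions sum to 1).
#' @export
image_information <- function(m) {
  n <- length(m)
  nb <- sum(m == 1L, na.rm = TRUE)
  nw <- sum(m == 0L, na.rm = TRUE)
  nt <- sum(is.na(m))
  structure(
    list(
      n_rows = nrow(m), n_cols = ncol(m),
      n_black = nb, n_white = nw, n_transparent = nt,
      fraction_black = nb / n, fraction_white = nw / n,
      fraction_transparent = nt / n
    ),
    class = "bw_info"
  )
}

#' @export
print.bw_info <- function(x, ...) {
  cat(sprintf("%d x %d image matrix (%d cells)\n", x$n_rows, x$n_cols, x$n_rows * x$n_cols))
  cat(sprintf("  black:       %8d  (%.6f)\n", x$n_black, x$fraction_black))
  cat(sprintf("  white:       %8d  (%.6f)\n", x$n_white, x$fraction_white))
  cat(sprintf("  transparent: %8d  (%.6f)\n", x$n_transparent, x$fraction_transparent))
  invisible(x)
}

# CSV serialization -----------------------------------------------------------

#' Read and write the 1/0/NA matrix CSV dialect
#'
#' `write_bwm()` serializes a binary matrix as comma-separated rows of the
#' tokens `1`, `0` and `NA`. `read_bwm()` parses that dialect back; the round
#' trip is lossless for the cell states. The physical scale is not stored in
#' the file; pass it to `read_bwm()` if needed.
#'
#' @param m a [bwm] object.
#' @param path file path.
#' @param height_size,width_size optional physical scale (cm) attached to the
#'   matrix returned by `read_bwm()`.
#' @return `read_bwm()` returns a [bwm]; `write_bwm()` returns `path`
#'   invisibly.
#' @export
write_bwm <- function(m, path) {
  cells <- unclass(m)
  tokens <- matrix(as.character(cells), nrow(cells))
  tokens[is.na(cells)] <- "NA"
  writeLines(apply(tokens, 1L, paste, collapse = ","), path)
  invisible(path)
}

#' @rdname write_bwm
#' @export
read_bwm <- function(path, height_size = NULL, width_size = NULL) {
  if (!file.exists(path)) {
    stop_input(sprintf("file not found: '%s'", path))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    stop_format(sprintf("'%s' contains no matrix rows", path))
  }
  rows <- strsplit(lines, ",", fixed = TRUE)
  nc <- length(rows[[1L]])
  out <- matrix(NA_integer_, nrow = length(rows), ncol = nc)
  for (i in seq_along(rows)) {
    toks <- trimws(rows[[i]])
    if (length(toks) != nc) {
      stop_format(sprintf(
        "ragged row %d in '%s': expected %d fields, found %d",
        i, path, nc, length(toks)
      ))
    }
    ok <- toks %in% c("0", "1", "NA")
    if (!all(ok)) {
      j <- which(!ok)[1L]
      stop_format(sprintf(
        "malformed token '%s' at row %d, column %d in '%s' (expected 1, 0 or NA)",
        toks[j], i, j, path
      ))
    }
    out[i, toks == "1"] <- 1L
    out[i, toks == "0"] <- 0L
  }
  bwm(out, height_size = height_size, width_size = width_size)
}
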