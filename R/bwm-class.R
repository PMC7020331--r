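#' Binary image matrix
#'
#' The central container of bwmetrics: a 2-D grid in which every cell is
#' black (`1L`), white (`0L`) or transparent (`NA`). Row 1 is the top image
#' row, column 1 the left image column. An optional physical scale records
#' the height and width (in cm) of the photographed frame, so that
#' height-based metrics can be reported in field units.
#'
#' @param cells integer (or coercible) matrix over `{1, 0, NA}`; 1 = black,
#'   0 = white, `NA` = transparent (non-subject pixels, e.g. erased
#'   background).
#' @param height_size optional physical height of the imaged frame, in cm.
#' @param width_size optional physical width of the imaged frame, in cm.
#'
#' @return An object of class `bwm`: an integer matrix with attributes
#'   `height_size` and `width_size`.
#' @examples
#' m <- bwm(matrix(c(1, 0, NA, 1), 2, 2), height_size = 100)
#' summary(m)
#' @export
bwm <- function(cells, height_size = NULL, width_size = NULL) {
  if (!is.matrix(cells)) {
    stop_param("'cells' must be a matrix")
  }
  if (nrow(cells) < 1L || ncol(cells) < 1L) {
    stop_param("'cells' must have at least one row and one column")
  }
  storage.mode(cells) <- "integer"
  bad <- !(is.na(cells) | cells == 0L | cells == 1L)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop_format(sprintf(
      "invalid cell value at row %d, column %d: cells must be 1, 0 or NA",
      idx[1L], idx[2L]
    ))
  }
  check_scale(height_size, "height_size")
  check_scale(width_size, "width_size")
  structure(cells,
    height_size = height_size, width_size = width_size,
    class = c("bwm", "matrix", "array")
  )
}

check_scale <- function(x, name) {
  if (!is.null(x) && (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)) {
    stop_param(sprintf("'%s' must be a single positive number (cm)", name))
  }
  invisible(x)
}

#' @export
is_bwm <- function(x) inherits(x, "bwm")

as_bwm <- function(cells, template = NULL) {
  bwm(cells,
    height_size = if (!is.null(template)) attr(template, "height_size"),
    width_size = if (!is.null(template)) attr(template, "width_size")
  )
}

#' @export
print.bwm <- function(x, ...) {
  hs <- attr(x, "height_size")
  ws <- attr(x, "width_size")
  cat(sprintf(
    "<bwm> %d x %d binary image matrix%s\n", nrow(x), ncol(x),
    if (is.null(hs) && is.null(ws)) {
      ""
    } else {
      sprintf(
        " (frame %s x %s cm)",
        if (is.null(hs)) "?" else format(hs),
        if (is.null(ws)) "?" else format(ws)
      )
    }
  ))
  info <- image_information(x)
  cat(sprintf(
    "  black %d (%.4f)  white %d (%.4f)  transparent %d (%.4f)\n",
    info$n_black, info$fraction_black,
    info$n_white, info$fraction_white,
    info$n_transparent, info$fraction_transparent
  ))
  invisible(x)
}

#' @export
summary.bwm <- function(object, ...) image_information(object)

#' Plot a binary image matrix
#'
#' Renders black cells black, white cells white and transparent cells grey,
#' in image orientation (row 1 at the top).
#'
#' @param x a [bwm] object.
#' @param ... passed to [graphics::image()].
#' @export
plot.bwm <- function(x, ...) {
  m <- unclass(x)
  m[is.na(m)] <- 2L
  # image() draws row 1 at the bottom with x/y swapped; reorient to picture
  z <- t(m[rev(seq_len(nrow(m))), , drop = FALSE])
  graphics::image(
    x = seq_len(nrow(z)), y = seq_len(ncol(z)), z = z,
    zlim = c(0, 2), col = c("white", "black", "grey70"),
    asp = 1, axes = FALSE, xlab = "", ylab = "", useRaster = TRUE, ...
  )
  invisible(x)
}

# condition helpers -----------------------------------------------------------

stop_param <- function(msg) {
  stop(errorCondition(msg, class = c("bw_param_error", "bw_error")))
}

stop_format <- function(msg) {
  stop(errorCondition(msg, class = c("bw_format_error", "bw_error")))
}

stop_undefined <- function(msg) {
  stop(errorCondition(msg, class = c("bw_undefined_error", "bw_error")))
}

stop_input <- function(msg) {
  stop(errorCondition(msg, class = c("bw_input_error", "bw_error")))
}

stop_usage <- function(msg) {
  stop(errorCondition(msg, class = c("bw_usage_error", "bw_error")))
}
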