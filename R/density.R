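#' Denseness: black-pixel proportion among non-transparent pixels
#'
#' Denseness is the proportion of black cells among all non-transparent
#' cells. For a canopy photograph (vegetation dark against sky) it is the
#' canopy closure; canopy openness is `1 - denseness_total(m)`.
#'
#' @param m a [bwm] object.
#' @return A fraction in `[0, 1]`.
#' @examples
#' denseness_total(make_fixture("chessboard", 6, 6)) # 0.5
#' @export
denseness_total <- function(m) {
  opaque <- sum(!is.na(m))
  if (opaque == 0L) {
    stop_undefined("denseness is undefined: all cells are transparent")
  }
  sum(m == 1L, na.rm = TRUE) / opaque
}

#' Denseness by row or column sections
#'
#' Splits the matrix into consecutive bands of `section_size` rows
#' (`denseness_row()`) or columns (`denseness_column()`) and reports the
#' black fraction among non-transparent cells in each band. Bands are
#' anchored at the top (rows) or left (columns); the last band may be
#' shorter and is kept. A band with no non-transparent cell reports `NA`.
#'
#' @param m a [bwm] object.
#' @param section_size rows (or columns) per section, between 1 and the axis
#'   length.
#' @return A data frame with one row per section: `section_index`, `start`,
#'   `end` (1-based, inclusive) and `fraction_black`.
#' @export
denseness_row <- function(m, section_size) {
  section_density(m, section_size, axis = "row")
}

#' @rdname denseness_row
#' @export
denseness_column <- function(m, section_size) {
  section_density(m, section_size, axis = "column")
}

section_density <- function(m, section_size, axis) {
  n <- if (axis == "row") nrow(m) else ncol(m)
  check_section_size(section_size, n)
  bounds <- section_bounds(n, section_size)
  frac <- vapply(seq_len(nrow(bounds)), function(i) {
    band <- if (axis == "row") {
      m[bounds$start[i]:bounds$end[i], , drop = FALSE]
    } else {
      m[, bounds$start[i]:bounds$end[i], drop = FALSE]
    }
    opaque <- sum(!is.na(band))
    if (opaque == 0L) NA_real_ else sum(band == 1L, na.rm = TRUE) / opaque
  }, numeric(1L))
  data.frame(
    section_index = seq_len(nrow(bounds)),
    start = bounds$start, end = bounds$end,
    fraction_black = frac
  )
}

check_section_size <- function(section_size, n) {
  if (!is.numeric(section_size) || length(section_size) != 1L ||
    is.na(section_size) || section_size < 1 || section_size > n) {
    stop_param(sprintf("'section_size' must be an integer between 1 and %d", n))
  }
}

# consecutive [start, end] bands of width `size` tiling 1..n; last may be short
section_bounds <- function(n, size) {
  size <- as.integer(size)
  start <- seq.int(1L, n, by = size)
  data.frame(start = start, end = pmin(start + size - 1L, n))
}

#' Height below which a given proportion of denseness occurs
#'
#' Scans rows from the bottom of the image, accumulating black-cell counts,
#' and returns the physical height of the top edge of the first row at which
#' the cumulative share of black cells reaches `proportion`. Heights are
#' whole-row granular: `height_size / n_rows` cm per row, measured from the
#' bottom edge.
#'
#' @param m a [bwm] object with at least one black cell.
#' @param proportion target cumulative share of denseness, in `(0, 1]`.
#' @param height_size physical frame height in cm; defaults to the scale
#'   stored on `m`, and to `n_rows` (row units) when no scale is available.
#' @return Height in cm (or rows when no scale is given).
#' @examples
#' veg <- make_fixture("silhouette", 50, 80, seed = 7)
#' height_proportion(veg, proportion = 0.75, height_size = 100)
#' @export
height_proportion <- function(m, proportion, height_size = NULL) {
  if (!is.numeric(proportion) || length(proportion) != 1L || is.na(proportion) ||
    proportion <= 0 || proportion > 1) {
    stop_param("'proportion' must be a single number in (0, 1]")
  }
  height_size <- height_size %||% attr(m, "height_size") %||% nrow(m)
  check_scale(height_size, "height_size")
  black_per_row <- rowSums(unclass(m) == 1L, na.rm = TRUE)
  total <- sum(black_per_row)
  if (total == 0L) {
    stop_undefined("height_proportion is undefined: the image has no black cells")
  }
  # cumulative share scanning upward from the bottom row
  cum_share <- cumsum(rev(black_per_row)) / total
  rows_from_bottom <- which(cum_share >= proportion)[1L]
  rows_from_bottom / nrow(m) * height_size
}

`%||%` <- function(a, b) if (is.null(a)) b else a
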