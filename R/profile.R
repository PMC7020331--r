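#' Per-column crest heights
#'
#' The crest height of a column is the number of whole rows from the bottom
#' edge of the image to the top edge of the topmost black cell in that
#' column; a column with no black cell has crest height 0 (ground level).
#'
#' @param m a [bwm] object.
#' @return Integer vector of length `ncol(m)`, values in `0..nrow(m)`.
#' @export
crest_heights <- function(m) {
  cells <- unclass(m)
  nr <- nrow(cells)
  vapply(seq_len(ncol(cells)), function(j) {
    black <- which(!is.na(cells[, j]) & cells[, j] == 1L)
    if (length(black) == 0L) 0L else nr - black[1L] + 1L
  }, integer(1L))
}

#' Maximum black-pixel height
#'
#' The highest crest over all columns, scaled to cm when a frame height is
#' available (`height_size / n_rows` cm per row), otherwise in rows.
#'
#' @param m a [bwm] object with at least one black cell.
#' @param height_size physical frame height (cm); defaults to the scale on
#'   `m`, else row units.
#' @return Height of the highest black pixel (top edge of its row).
#' @export
height_maximum <- function(m, height_size = NULL) {
  ch <- crest_heights(m)
  if (max(ch) == 0L) {
    stop_undefined("height_maximum is undefined: the image has no black cells")
  }
  height_size <- height_size %||% attr(m, "height_size")
  if (is.null(height_size)) {
    return(max(ch))
  }
  check_scale(height_size, "height_size")
  max(ch) / nrow(m) * height_size
}

#' Altitudinal profile: per-section crest statistics
#'
#' Groups columns left to right into sections of `section_width` columns
#' (the last may be shorter) and reports the mean and sample standard
#' deviation of the column crest heights in each section. Heights are in cm
#' when a frame height is available, otherwise in rows. Columns without any
#' black cell contribute crest height 0.
#'
#' @param m a [bwm] object.
#' @param section_width columns per section, between 1 and `ncol(m)`.
#' @param height_size physical frame height (cm); defaults to the scale on
#'   `m`, else row units.
#' @return A list of class `bw_height_profile`: `crest_heights` (per column,
#'   scaled), `section_stats` (data frame `section_index`, `start`, `end`,
#'   `mean_height`, `sd_height`), `unit` (`"cm"` or `"rows"`).
#' @export
altitudinal_profile <- function(m, section_width, height_size = NULL) {
  check_section_size_width(section_width, ncol(m))
  height_size <- height_size %||% attr(m, "height_size")
  unit <- if (is.null(height_size)) "rows" else "cm"
  scale <- if (is.null(height_size)) 1 else {
    check_scale(height_size, "height_size")
    height_size / nrow(m)
  }
  ch <- crest_heights(m) * scale
  bounds <- section_bounds(ncol(m), section_width)
  stats_df <- data.frame(
    section_index = seq_len(nrow(bounds)),
    start = bounds$start, end = bounds$end,
    mean_height = NA_real_, sd_height = NA_real_
  )
  for (i in seq_len(nrow(bounds))) {
    h <- ch[bounds$start[i]:bounds$end[i]]
    stats_df$mean_height[i] <- mean(h)
    stats_df$sd_height[i] <- if (length(h) > 1L) stats::sd(h) else NA_real_
  }
  structure(
    list(crest_heights = ch, section_stats = stats_df, unit = unit),
    class = "bw_height_profile"
  )
}

check_section_size_width <- function(section_width, n) {
  if (!is.numeric(section_width) || length(section_width) != 1L ||
    is.na(section_width) || section_width < 1 || section_width > n) {
    stop_param(sprintf("'section_width' must be an integer between 1 and %d", n))
  }
}

#' @export
print.bw_height_profile <- function(x, ...) {
  cat(sprintf(
    "Altitudinal profile (%s): %d column(s), %d section(s)\n",
    x$unit, length(x$crest_heights), nrow(x$section_stats)
  ))
  print(x$section_stats, row.names = FALSE)
  invisible(x)
}

#' Topline: length of the crest polyline
#'
#' The polyline joining consecutive columns' crest points (x at each column
#' center, y at the column's crest height), summed as Euclidean segment
#' lengths. In pixel units (no scale) a flat crest of `w` columns has length
#' `w - 1`. When both a frame height and width are given, x is scaled by
#' `width_size / n_cols` and y by `height_size / n_rows` and the result is
#' in cm. Columns without black cells participate with crest height 0 (the
#' crest drops to the soil line). Supplying only one of the two scales is an
#' error — a mixed pixel/cm length would be meaningless.
#'
#' @param m a [bwm] object with at least one black cell and at least one
#'   column.
#' @param height_size,width_size physical frame size (cm); default to the
#'   scales on `m`. Give both or neither.
#' @return Total polyline length (cm, or pixels when no scale is given).
#' @export
topline <- function(m, height_size = NULL, width_size = NULL) {
  ch <- crest_heights(m)
  if (max(ch) == 0L) {
    stop_undefined("topline is undefined: the image has no black cells")
  }
  height_size <- height_size %||% attr(m, "height_size")
  width_size <- width_size %||% attr(m, "width_size")
  if (is.null(height_size) != is.null(width_size)) {
    stop_param("give both 'height_size' and 'width_size', or neither (pixel units)")
  }
  sy <- if (is.null(height_size)) 1 else height_size / nrow(m)
  sx <- if (is.null(width_size)) 1 else width_size / ncol(m)
  if (length(ch) == 1L) {
    return(0)
  }
  dy <- diff(ch) * sy
  sum(sqrt(sx^2 + dy^2))
}
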