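#' Run-length ("hole") analysis of same-color pixel sequences
#'
#' Finds every maximal run of a single color within each row
#' (`hole_runs_row()`) or each column (`hole_runs_column()`). A run never
#' spans a transparent cell: transparency marks non-subject regions, so a
#' hole cannot continue across one. In a vegetation or nest-wall photograph,
#' white runs are the light holes of the structure.
#'
#' @param m a [bwm] object.
#' @param color `"white"` (default, the conventional hole color) or
#'   `"black"`.
#' @return A data frame with one row per run: `line_index` (row or column,
#'   1-based), `color`, `start` (1-based position within the line) and
#'   `length`. Zero rows when the color is absent.
#' @examples
#' m <- bwm(matrix(c(0, 0, 1, 0, 1), 1, 5))
#' hole_runs_row(m, "white") # runs of length 2 and 1
#' @export
hole_runs_row <- function(m, color = c("white", "black")) {
  color <- match.arg(color)
  target <- if (color == "black") 1L else 0L
  cells <- unclass(m)
  recs <- lapply(seq_len(nrow(cells)), function(i) {
    line_runs(cells[i, ], target, i)
  })
  out <- do.call(rbind, recs)
  out$color <- rep(color, nrow(out))
  out
}

#' @rdname hole_runs_row
#' @export
hole_runs_column <- function(m, color = c("white", "black")) {
  color <- match.arg(color)
  target <- if (color == "black") 1L else 0L
  cells <- unclass(m)
  recs <- lapply(seq_len(ncol(cells)), function(j) {
    line_runs(cells[, j], target, j)
  })
  out <- do.call(rbind, recs)
  out$color <- rep(color, nrow(out))
  out
}

# maximal runs of `target` in one line; NA (transparent) terminates runs.
# Encodes the line so rle() treats each NA as a unique separator.
line_runs <- function(line, target, index) {
  is_t <- !is.na(line) & line == target
  r <- rle(is_t)
  len <- r$lengths
  ends <- cumsum(len)
  keep <- r$values
  data.frame(
    line_index = rep(index, sum(keep)),
    color = character(sum(keep)),
    start = (ends - len + 1L)[keep],
    length = len[keep]
  )
}

#' Summary of hole runs within a section of lines
#'
#' Summarizes the runs of one color over a contiguous block of rows or
#' columns: run count, mean/sd/min/max run length and the total number of
#' cells covered by runs. The standard deviation is the sample sd (n - 1
#' denominator); with fewer than two runs it is `NA`, and with no runs all
#' statistics are `NA`.
#'
#' @param m a [bwm] object.
#' @param color `"white"` or `"black"`.
#' @param axis `"row"` or `"column"`.
#' @param start,end 1-based inclusive bounds of the section along the axis.
#' @return A list of class `bw_section_summary` with fields `n_runs`,
#'   `mean_length`, `sd_length`, `min_length`, `max_length`,
#'   `total_cells_in_runs`.
#' @export
hole_section_summary <- function(m, color = c("white", "black"),
                                 axis = c("row", "column"), start, end) {
  color <- match.arg(color)
  axis <- match.arg(axis)
  n <- if (axis == "row") nrow(m) else ncol(m)
  if (!is.numeric(start) || !is.numeric(end) || length(start) != 1L ||
    length(end) != 1L || is.na(start) || is.na(end) ||
    start < 1 || end > n || start > end) {
    stop_param(sprintf("section bounds must satisfy 1 <= start <= end <= %d", n))
  }
  runs <- if (axis == "row") hole_runs_row(m, color) else hole_runs_column(m, color)
  runs <- runs[runs$line_index >= start & runs$line_index <= end, , drop = FALSE]
  k <- nrow(runs)
  structure(
    list(
      n_runs = k,
      mean_length = if (k > 0L) mean(runs$length) else NA_real_,
      sd_length = if (k > 1L) stats::sd(runs$length) else NA_real_,
      min_length = if (k > 0L) min(runs$length) else NA_integer_,
      max_length = if (k > 0L) max(runs$length) else NA_integer_,
      total_cells_in_runs = sum(runs$length)
    ),
    class = "bw_section_summary"
  )
}

#' @export
print.bw_section_summary <- function(x, ...) {
  cat(sprintf(
    "%d run(s); length mean %s, sd %s, min %s, max %s; %d cell(s) in runs\n",
    x$n_runs, format(x$mean_length), format(x$sd_length),
    format(x$min_length), format(x$max_length), x$total_cells_in_runs
  ))
  invisible(x)
}

#' Light gap: edge distances to the first and last black pixel per row
#'
#' For every row, the number of cells before the first black cell scanning
#' from the left edge, and after the last black cell scanning from the
#' right. A row with no black cell reports both distances as the full row
#' width, flagged in the `no_black` column, so batch outputs stay
#' rectangular.
#'
#' @param m a [bwm] object.
#' @return A data frame with one row per image row: `row`, `left_distance`,
#'   `right_distance`, `no_black`.
#' @export
light_gap <- function(m) {
  cells <- unclass(m)
  nc <- ncol(cells)
  res <- t(vapply(seq_len(nrow(cells)), function(i) {
    black <- which(!is.na(cells[i, ]) & cells[i, ] == 1L)
    if (length(black) == 0L) {
      c(nc, nc, 1L)
    } else {
      c(black[1L] - 1L, nc - black[length(black)], 0L)
    }
  }, integer(3L)))
  data.frame(
    row = seq_len(nrow(cells)),
    left_distance = res[, 1L],
    right_distance = res[, 2L],
    no_black = as.logical(res[, 3L])
  )
}
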