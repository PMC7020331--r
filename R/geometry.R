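#' Remap a square matrix into its inscribed disk
#'
#' Compresses a square binary matrix into the inscribed disk of the same
#' grid, for circular subjects (hemispherical canopy frames, dome-shaped
#' nests). The map preserves angles about the grid center and rescales each
#' radial ray so that the square's boundary lands on the disk boundary:
#' an output cell at polar position `(r, theta)` inside the disk takes the
#' value of the source cell nearest to `(r * b(theta) / R, theta)`, where
#' `R = n/2` and `b(theta)` is the distance from the center to the square's
#' edge along `theta`. Cells whose centers fall outside the disk become
#' transparent. The grid center is the point `(n/2, n/2)` in continuous
#' cell coordinates (a cell corner for even `n`, a cell center for odd `n`).
#'
#' @param m a square [bwm] object.
#' @return A [bwm] of the same size whose cells outside the inscribed disk
#'   are transparent.
#' @seealso [stretch_to_square()] for the inverse map.
#' @export
compress_to_circle <- function(m) {
  n <- nrow(m)
  if (n != ncol(m)) {
    stop_param("compress_to_circle requires a square matrix")
  }
  cells <- unclass(m)
  cx <- n / 2
  R <- n / 2
  centers <- seq_len(n) - 0.5
  dy <- matrix(centers - cx, n, n) # row offset from center, varies down rows
  dx <- t(dy) # column offset, varies across columns
  r <- sqrt(dx^2 + dy^2)
  inside <- r <= R
  out <- matrix(NA_integer_, n, n)
  # radial stretch factor toward the square boundary: b(theta)/R = r / max(|dx|,|dy|)
  mx <- pmax(abs(dx), abs(dy))
  f <- ifelse(mx > 0, r / mx, 1)
  src_row <- clamp_index(floor(cx + dy * f) + 1L, n)
  src_col <- clamp_index(floor(cx + dx * f) + 1L, n)
  out[inside] <- cells[cbind(src_row[inside], src_col[inside])]
  as_bwm(out, template = m)
}

clamp_index <- function(i, n) pmin.int(pmax.int(as.integer(i), 1L), n)

#' Remap a circular matrix back to a full square
#'
#' Inverse of [compress_to_circle()]: each output cell of the full square
#' looks up, by nearest neighbor, the disk cell at the radially shrunk
#' position `(r * R / b(theta), theta)`. Corner regions are filled from
#' values near the disk boundary, so the geometry introduces no transparent
#' cells; transparent cells genuinely inside the input disk are preserved.
#'
#' @param c_m a square [bwm] whose cells outside the inscribed disk are all
#'   transparent (the [compress_to_circle()] invariant).
#' @return A [bwm] of the same size.
#' @export
stretch_to_square <- function(c_m) {
  n <- nrow(c_m)
  if (n != ncol(c_m)) {
    stop_param("stretch_to_square requires a square matrix")
  }
  cells <- unclass(c_m)
  cx <- n / 2
  R <- n / 2
  centers <- seq_len(n) - 0.5
  dy <- matrix(centers - cx, n, n)
  dx <- t(dy)
  r <- sqrt(dx^2 + dy^2)
  # check the invariant: outside-disk cells must be transparent
  outside <- r > R
  if (any(!is.na(cells[outside]))) {
    stop_param("input violates the circular invariant: non-transparent cells outside the inscribed disk")
  }
  # shrink factor R/b(theta) = max(|dx|,|dy|)/r; source radius = max(|dx|,|dy|) <= R
  f <- ifelse(r > 0, pmax(abs(dx), abs(dy)) / r, 1)
  out <- matrix(NA_integer_, n, n)
  # nearest-neighbor lookup; walk slightly inward if the lookup cell is an
  # outside-disk transparent cell (floor jitter at the disk boundary)
  shrink <- c(1, 0.98, 0.95, 0.9)
  pending <- matrix(TRUE, n, n)
  for (s in shrink) {
    src_row <- clamp_index(floor(cx + dy * f * s) + 1L, n)
    src_col <- clamp_index(floor(cx + dx * f * s) + 1L, n)
    src_r <- sqrt((src_row - 0.5 - cx)^2 + (src_col - 0.5 - cx)^2)
    ok <- pending & (src_r <= R | s == shrink[length(shrink)])
    out[ok] <- cells[cbind(src_row[ok], src_col[ok])]
    pending <- pending & !ok
    if (!any(pending)) break
  }
  as_bwm(out, template = c_m)
}
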