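#' Mean same-color-neighbor proportion (SCNP)
#'
#' For every interior cell (marginal rows and columns excluded as centers;
#' marginal cells still count as neighbors) that is not transparent, the
#' SCNP is the number of its 4 orthogonal (von Neumann) neighbors sharing
#' its color, divided by the number of its non-transparent orthogonal
#' neighbors. `scnp_mean()` averages the SCNP over all such interior cells.
#'
#' The 4-neighbor system and the interior-centers-with-marginal-neighbors
#' convention are pinned down by the method's worked 6x6 examples: the
#' side-split half-black grid has mean SCNP exactly 0.875 under this
#' convention (0.8125 under 8 neighbors), and the chessboard has 0.
#'
#' @param m a [bwm] object with at least 3 rows and 3 columns.
#' @return Mean SCNP, a fraction in `[0, 1]`.
#' @examples
#' scnp_mean(make_fixture("chessboard", 6, 6)) # 0
#' scnp_mean(make_fixture("halves", 6, 6)) # 0.875
#' @export
scnp_mean <- function(m) {
  cells <- unclass(m)
  nr <- nrow(cells)
  nc <- ncol(cells)
  if (nr < 3L || nc < 3L) {
    stop_undefined("scnp_mean needs at least a 3 x 3 matrix (no interior cells)")
  }
  ri <- 2:(nr - 1L)
  ci <- 2:(nc - 1L)
  center <- cells[ri, ci, drop = FALSE]
  up <- cells[ri - 1L, ci, drop = FALSE]
  down <- cells[ri + 1L, ci, drop = FALSE]
  left <- cells[ri, ci - 1L, drop = FALSE]
  right <- cells[ri, ci + 1L, drop = FALSE]
  same <- same_count(center, up) + same_count(center, down) +
    same_count(center, left) + same_count(center, right)
  valid <- (!is.na(up)) + (!is.na(down)) + (!is.na(left)) + (!is.na(right))
  use <- !is.na(center) & valid > 0L
  if (!any(use)) {
    stop_undefined("scnp_mean is undefined: no interior cell has a non-transparent neighbor")
  }
  mean(same[use] / valid[use])
}

# elementwise: 1 where both non-NA and equal, else 0
same_count <- function(a, b) {
  out <- (a == b)
  out[is.na(out)] <- FALSE
  out
}

#' Construct an extremal reference arrangement
#'
#' Builds the minimally or maximally aggregated arrangement used to
#' standardize the aggregation index, for a given grid size, black-cell
#' count and transparency pattern.
#'
#' `mode = "max"` fills the non-transparent cells with black in row-major
#' order (top-left first) until `n_black` cells are placed — with no
#' transparency this stacks full black rows on one image side, the most
#' aggregated arrangement. `mode = "min"` fills black into the chessboard
#' parity classes: cells with even row + column index first (row-major
#' within a class), overflowing into the other class — at half density this
#' is the perfect chessboard, the least aggregated arrangement. Both are
#' constructive archetypes; the maximum is verified exhaustively on small
#' grids in the test suite.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param n_black number of black cells to place.
#' @param transparent_mask optional logical matrix (`TRUE` = transparent);
#'   transparent cells are never filled.
#' @param mode `"min"` or `"max"`.
#' @return A [bwm] with exactly `n_black` black cells and the given
#'   transparency pattern.
#' @export
reference_extreme <- function(n_rows, n_cols, n_black,
                              transparent_mask = NULL,
                              mode = c("max", "min")) {
  mode <- match.arg(mode)
  if (is.null(transparent_mask)) {
    transparent_mask <- matrix(FALSE, n_rows, n_cols)
  }
  stopifnot(is.logical(transparent_mask), nrow(transparent_mask) == n_rows,
    ncol(transparent_mask) == n_cols)
  capacity <- sum(!transparent_mask)
  if (n_black < 0 || n_black > capacity) {
    stop_param(sprintf(
      "'n_black' (%d) must be between 0 and the number of non-transparent cells (%d)",
      n_black, capacity
    ))
  }
  # row-major enumeration of cell indices
  idx <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))[, c("row", "col")]
  open <- !transparent_mask[cbind(idx$row, idx$col)]
  idx <- idx[open, , drop = FALSE]
  if (mode == "min") {
    even_parity <- (idx$row + idx$col) %% 2L == 0L
    idx <- rbind(idx[even_parity, , drop = FALSE], idx[!even_parity, , drop = FALSE])
  }
  cells <- matrix(0L, n_rows, n_cols)
  cells[transparent_mask] <- NA_integer_
  if (n_black > 0) {
    fill <- idx[seq_len(n_black), , drop = FALSE]
    cells[cbind(fill$row, fill$col)] <- 1L
  }
  bwm(cells)
}

#' Standardized pixel aggregation index
#'
#' The aggregation index summarizes how clumped the black and white pixels
#' of an image are. The observed mean same-color-neighbor proportion
#' ([scnp_mean()]) is standardized against two constructed references that
#' share the image's dimensions, black-pixel count and transparency
#' pattern: a minimally aggregated arrangement (chessboard-parity fill,
#' index 0) and a maximally aggregated one (side-stacked fill, index 1):
#'
#' `adjusted = (observed - ref_min) / (ref_max - ref_min)`
#'
#' For a single-color image (or any case where the two references coincide)
#' the adjusted index is undefined and reported as `NA` with a `degenerate`
#' flag; the non-adjusted mean SCNP is still returned.
#'
#' @param m a [bwm] object on which [scnp_mean()] is defined.
#' @return A list of class `bw_aggregation`: `non_adjusted`,
#'   `reference_min`, `reference_max`, `adjusted`, `degenerate`.
#' @examples
#' aggregation_index(make_fixture("chessboard", 6, 6)) # adjusted 0
#' aggregation_index(make_fixture("halves", 6, 6)) # adjusted 1
#' @export
aggregation_index <- function(m) {
  observed <- scnp_mean(m)
  mask <- is.na(unclass(m))
  n_black <- sum(unclass(m) == 1L, na.rm = TRUE)
  ref_min <- scnp_mean(reference_extreme(nrow(m), ncol(m), n_black, mask, "min"))
  ref_max <- scnp_mean(reference_extreme(nrow(m), ncol(m), n_black, mask, "max"))
  degenerate <- isTRUE(all.equal(ref_min, ref_max))
  structure(
    list(
      non_adjusted = observed,
      reference_min = ref_min,
      reference_max = ref_max,
      adjusted = if (degenerate) NA_real_ else (observed - ref_min) / (ref_max - ref_min),
      degenerate = degenerate
    ),
    class = "bw_aggregation"
  )
}

#' @export
print.bw_aggregation <- function(x, ...) {
  cat("adjusted_aggregation non_adjusted_aggregation\n")
  cat(sprintf("%.7f            %.7f\n", x$adjusted, x$non_adjusted))
  if (x$degenerate) {
    cat("(adjusted index undefined: minimal and maximal references coincide)\n")
  }
  invisible(x)
}
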