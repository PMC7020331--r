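#' Deterministic synthetic binary-image fixtures
#'
#' Generates the archetypal patterns every metric in the package can be
#' exercised on, without any photograph:
#'
#' * `"chessboard"` — alternating parity grid (cell black when row + column
#'   is even), the minimally aggregated half-density pattern;
#' * `"halves"` — one side solid black (`orientation` = `"left"`,
#'   `"right"`, `"top"` or `"bottom"`), the maximally aggregated
#'   half-density pattern;
#' * `"random"` — i.i.d. black cells with probability `density`;
#' * `"silhouette"` — a vegetation-profile emulation: per-column crest
#'   heights follow a seeded bounded random walk (first crest uniform over
#'   the middle third of the height, steps uniform on -2..2, clamped to
#'   `[0, n_rows]`), with black below the crest;
#' * `"disk"` — a black inscribed disk on a transparent background
#'   (circular-subject emulation).
#'
#' `seed` fully determines the `"random"` and `"silhouette"` outputs; the
#' global RNG state is left untouched.
#'
#' @param kind one of `"chessboard"`, `"halves"`, `"random"`,
#'   `"silhouette"`, `"disk"`.
#' @param n_rows,n_cols grid dimensions.
#' @param density black-cell probability for `"random"`; default 0.5.
#' @param orientation black side for `"halves"`; default `"left"`.
#' @param seed integer seed, required for `"random"` and `"silhouette"`.
#' @param height_size,width_size optional physical scale (cm) carried on the
#'   result.
#' @return A [bwm] object.
#' @examples
#' make_fixture("chessboard", 6, 6)
#' make_fixture("silhouette", 40, 60, seed = 1)
#' @export
make_fixture <- function(kind = c("chessboard", "halves", "random", "silhouette", "disk"),
                         n_rows, n_cols,
                         density = 0.5,
                         orientation = c("left", "right", "top", "bottom"),
                         seed = NULL,
                         height_size = NULL, width_size = NULL) {
  kind <- match.arg(kind)
  orientation <- match.arg(orientation)
  if (!is.numeric(n_rows) || !is.numeric(n_cols) || n_rows < 1 || n_cols < 1) {
    stop_param("'n_rows' and 'n_cols' must be positive integers")
  }
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  cells <- switch(kind,
    chessboard = outer(seq_len(n_rows), seq_len(n_cols),
      function(i, j) as.integer((i + j) %% 2L == 0L)
    ),
    halves = {
      cells <- matrix(0L, n_rows, n_cols)
      switch(orientation,
        left = cells[, seq_len(ceiling(n_cols / 2))] <- 1L,
        right = cells[, (floor(n_cols / 2) + 1L):n_cols] <- 1L,
        top = cells[seq_len(ceiling(n_rows / 2)), ] <- 1L,
        bottom = cells[(floor(n_rows / 2) + 1L):n_rows, ] <- 1L
      )
      cells
    },
    random = {
      if (!is.numeric(density) || density < 0 || density > 1) {
        stop_param("'density' must be in [0, 1]")
      }
      with_fixture_seed(seed, {
        matrix(as.integer(stats::runif(n_rows * n_cols) < density), n_rows, n_cols)
      })
    },
    silhouette = with_fixture_seed(seed, {
      lo <- floor(n_rows / 3)
      hi <- max(lo + 1L, floor(2 * n_rows / 3))
      crest <- integer(n_cols)
      crest[1L] <- sample(lo:hi, 1L)
      if (n_cols > 1L) {
        steps <- sample(-2:2, n_cols - 1L, replace = TRUE)
        for (j in 2:n_cols) {
          crest[j] <- min(max(crest[j - 1L] + steps[j - 1L], 0L), n_rows)
        }
      }
      cells <- matrix(0L, n_rows, n_cols)
      for (j in seq_len(n_cols)) {
        if (crest[j] > 0L) cells[(n_rows - crest[j] + 1L):n_rows, j] <- 1L
      }
      cells
    }),
    disk = {
      if (n_rows != n_cols) {
        stop_param("'disk' fixtures must be square")
      }
      n <- n_rows
      centers <- seq_len(n) - 0.5
      d <- outer(centers - n / 2, centers - n / 2, function(a, b) sqrt(a^2 + b^2))
      cells <- matrix(NA_integer_, n, n)
      cells[d <= n / 2] <- 1L
      cells
    }
  )
  bwm(cells, height_size = height_size, width_size = width_size)
}

# run expr under a private RNG stream, restoring the caller's state
with_fixture_seed <- function(seed, expr) {
  if (is.null(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_param("'seed' (a single integer) is required for this fixture kind")
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Render a binary matrix as a PNG or JPEG image
#'
#' Writes black cells as (0,0,0), white cells as (255,255,255). For PNG,
#' transparent cells are encoded in an alpha channel whose polarity matches
#' the `alpha_rule` that will be used to read the file back (see
#' [threshold_image()]), so that `threshold_image(render_image(m))` recovers
#' `m` exactly; matrices without transparency are written as plain
#' grayscale. JPEG output is lossy and supports no transparency.
#'
#' @param m a [bwm] object.
#' @param path output path ending in `.png`, `.jpg` or `.jpeg`.
#' @param alpha_rule polarity used to encode transparency in PNG alpha:
#'   `"above"` writes transparent cells with alpha 1 and opaque cells with
#'   alpha 0 (matching the default reading rule); `"below"` writes
#'   conventional alpha (transparent 0, opaque 1).
#' @param quality JPEG quality (ignored for PNG).
#' @return `path`, invisibly.
#' @export
render_image <- function(m, path, alpha_rule = c("above", "below"), quality = 95) {
  alpha_rule <- match.arg(alpha_rule)
  cells <- unclass(m)
  gray <- matrix(1, nrow(cells), ncol(cells))
  gray[!is.na(cells) & cells == 1L] <- 0
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (anyNA(cells)) {
      alpha_t <- if (alpha_rule == "above") 1 else 0
      alpha <- matrix(1 - alpha_t, nrow(cells), ncol(cells))
      alpha[is.na(cells)] <- alpha_t
      arr <- array(c(gray, gray, gray, alpha), dim = c(dim(cells), 4L))
      png::writePNG(arr, path)
    } else {
      png::writePNG(gray, path)
    }
  } else if (ext %in% c("jpg", "jpeg")) {
    if (anyNA(cells)) {
      stop_param("JPEG cannot encode transparent cells; use PNG")
    }
    img <- EBImage::Image(t(gray))
    EBImage::writeImage(img, path, quality = quality)
  } else {
    stop_param(sprintf("unsupported output format '.%s' (use png, jpg or jpeg)", ext))
  }
  invisible(path)
}
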