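#' Construct a glyph raster
#'
#' A glyph raster is the binary ink image of a single symbol: a rectangular
#' 0/1 matrix (1 = ink) together with the 0-based row-major coordinates of
#' its ink pixels. All shape metrics in the package operate on this type.
#'
#' @param grid Numeric or logical matrix; nonzero/\code{TRUE} entries are ink.
#' @param glyph_id Character scalar identifying the glyph.
#' @return An object of class \code{glyph_raster} with elements
#'   \code{glyph_id}, \code{grid} (integer 0/1 matrix) and \code{ink_pixels}
#'   (two-column matrix of 0-based (row, col) ink coordinates).
#' @examples
#' g <- glyph_raster(matrix(c(0, 1, 1, 0), 2, 2), "toy")
#' pixel_count(g)
#' @export
glyph_raster <- function(grid, glyph_id = "glyph") {
  if (!is.matrix(grid) || length(grid) == 0L)
    stop("'grid' must be a non-empty matrix", call. = FALSE)
  if (is.logical(grid)) grid <- grid * 1L
  if (!is.numeric(grid) || anyNA(grid))
    stop("'grid' must be a numeric 0/1 matrix without NAs", call. = FALSE)
  storage.mode(grid) <- "integer"
  if (!all(grid %in% c(0L, 1L)))
    stop("'grid' entries must be 0 or 1; use binarize() for grayscale input",
         call. = FALSE)
  idx <- which(grid == 1L, arr.ind = TRUE)
  ink <- cbind(row = idx[, 1L] - 1L, col = idx[, 2L] - 1L)
  structure(
    list(glyph_id = as.character(glyph_id)[1L], grid = grid, ink_pixels = ink),
    class = "glyph_raster"
  )
}

#' @export
print.glyph_raster <- function(x, ...) {
  cat(sprintf("<glyph_raster '%s'>  %d x %d canvas, %d ink pixels\n",
              x$glyph_id, nrow(x$grid), ncol(x$grid), nrow(x$ink_pixels)))
  invisible(x)
}

#' @export
plot.glyph_raster <- function(x, ...) {
  graphics::image(t(x$grid[nrow(x$grid):1, , drop = FALSE]),
                  col = c("white", "black"), axes = FALSE, asp = 1,
                  main = x$glyph_id, ...)
  invisible(x)
}

is_glyph_raster <- function(x) inherits(x, "glyph_raster")

stopifnot_inked <- function(g) {
  if (!is_glyph_raster(g)) stop("expected a glyph_raster", call. = FALSE)
  if (nrow(g$ink_pixels) == 0L)
    stop(sprintf("glyph '%s' has no ink pixels", g$glyph_id), call. = FALSE)
  invisible(g)
}

#' Binarize a grayscale image into a glyph raster
#'
#' Dark pixels become ink: \code{grid[i, j] = 1} iff
#' \code{image[i, j] < threshold}. Values are expected on \code{[0, 1]}
#' (0 = black), the convention of \code{png::readPNG}.
#'
#' @param image Numeric matrix with values in \code{[0, 1]}.
#' @param threshold Ink threshold, default 0.5.
#' @param glyph_id Identifier for the resulting glyph.
#' @return A \code{\link{glyph_raster}}. A glyph with zero ink pixels is
#'   returned as-is but rejected by all metric operations.
#' @export
binarize <- function(image, threshold = 0.5, glyph_id = "glyph") {
  if (!is.matrix(image) || length(image) == 0L)
    stop("'image' must be a non-empty matrix", call. = FALSE)
  if (anyNA(image)) stop("'image' contains NAs", call. = FALSE)
  glyph_raster((image < threshold) * 1L, glyph_id = glyph_id)
}
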