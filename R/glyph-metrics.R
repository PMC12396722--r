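#' Ink-pixel count of a glyph
#'
#' The simplest shape scalar: the number of ink pixels of the binarized
#' glyph. Writing systems in the Semitic family show their strongest
#' grapho-phonemic systematicity under this metric.
#'
#' @param g A \code{\link{glyph_raster}} with at least one ink pixel.
#' @return Integer count of ink pixels.
#' @export
pixel_count <- function(g) {
  stopifnot_inked(g)
  nrow(g$ink_pixels)
}

#' Perimeter of a glyph
#'
#' Default method counts exposed pixel edges under 4-connectivity: for each
#' ink pixel, the number of its four neighbours that are off-canvas or blank.
#' This is integer-exact and resolution-stable (a filled n-by-n square has
#' perimeter 4n at every n). The \code{"contour"} method instead estimates
#' the length of the iso-contour through pixel centres by marching-squares
#' segment lengths, which shortcuts diagonals and is closer to the continuum
#' boundary length of smooth shapes.
#'
#' @param g A \code{\link{glyph_raster}}.
#' @param method \code{"edge"} (default) or \code{"contour"}.
#' @return Non-negative perimeter length (integer for \code{"edge"}).
#' @export
perimeter <- function(g, method = c("edge", "contour")) {
  stopifnot_inked(g)
  method <- match.arg(method)
  m <- g$grid
  # zero-pad so border pixels expose edges
  p <- matrix(0L, nrow(m) + 2L, ncol(m) + 2L)
  p[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
  nr <- nrow(p); nc <- ncol(p)
  if (method == "edge") {
    up    <- p[1:(nr - 2L), 2:(nc - 1L)]
    down  <- p[3:nr,        2:(nc - 1L)]
    left  <- p[2:(nr - 1L), 1:(nc - 2L)]
    right <- p[2:(nr - 1L), 3:nc]
    sum((m == 1L) * ((1L - up) + (1L - down) + (1L - left) + (1L - right)))
  } else {
    # marching squares over 2x2 windows; code = tl + 2*tr + 4*bl + 8*br
    tl <- p[1:(nr - 1L), 1:(nc - 1L)]
    tr <- p[1:(nr - 1L), 2:nc]
    bl <- p[2:nr,        1:(nc - 1L)]
    br <- p[2:nr,        2:nc]
    code <- tl + 2L * tr + 4L * bl + 8L * br
    s <- sqrt(2) / 2
    # segment length contributed by each of the 16 configurations
    seg <- c(0, s, s, 1, s, 1, sqrt(2), s, s, sqrt(2), 1, s, 1, s, s, 0)
    sum(seg[code + 1L])
  }
}

#' Perimetric complexity of a glyph
#'
#' Perimeter squared divided by ink area. Translation-invariant and, for the
#' exposed-edge perimeter, exactly 16 for any filled square. More intricate,
#' boundary-rich shapes score higher. Chinese characters show their
#' strongest characto-syllabic systematicity under this metric.
#'
#' @inheritParams perimeter
#' @return Positive number, \code{perimeter(g)^2 / pixel_count(g)}.
#' @export
perimetric_complexity <- function(g, method = c("edge", "contour")) {
  perimeter(g, method = match.arg(method))^2 / pixel_count(g)
}

#' Hausdorff distance between two glyphs
#'
#' The largest nearest-neighbour Euclidean distance between the two ink
#' point sets, taken in both directions. With \code{align = TRUE} (default)
#' each point set is first centred on its centroid, so the distance measures
#' shape difference rather than placement on the canvas. Hangul shows its
#' strongest grapho-phonemic systematicity under this metric.
#'
#' @param a,b \code{\link{glyph_raster}} objects, each with ink.
#' @param align Centre both point sets on their centroids first.
#' @return Non-negative number; 0 iff the (aligned) point sets coincide.
#' @export
hausdorff_distance <- function(a, b, align = TRUE) {
  stopifnot_inked(a); stopifnot_inked(b)
  A <- matrix(as.numeric(a$ink_pixels), ncol = 2L)
  B <- matrix(as.numeric(b$ink_pixels), ncol = 2L)
  if (isTRUE(align)) {
    A <- sweep(A, 2L, colMeans(A))
    B <- sweep(B, 2L, colMeans(B))
  }
  dr <- outer(A[, 1L], B[, 1L], "-")
  dc <- outer(A[, 2L], B[, 2L], "-")
  D <- sqrt(dr * dr + dc * dc)
  max(max(apply(D, 1L, min)), max(apply(D, 2L, min)))
}

#' Pairwise distance between two glyphs under a named metric
#'
#' \code{pixel_count_distance} and \code{pc_distance} are absolute
#' differences of the per-glyph scalars; \code{glyph_distance} dispatches on
#' a metric name and is what the material-scoring and design stages call.
#'
#' @param a,b \code{\link{glyph_raster}} objects.
#' @param metric One of \code{"pixel"}, \code{"pc"}, \code{"hausdorff"}.
#' @param ... Passed on to the underlying metric (e.g. \code{align}).
#' @return Non-negative number; symmetric in \code{a}, \code{b}.
#' @export
glyph_distance <- function(a, b, metric = c("pixel", "pc", "hausdorff"), ...) {
  metric <- match.arg(metric)
  switch(metric,
    pixel = pixel_count_distance(a, b),
    pc = pc_distance(a, b, ...),
    hausdorff = hausdorff_distance(a, b, ...)
  )
}

#' @rdname glyph_distance
#' @export
pixel_count_distance <- function(a, b) {
  abs(pixel_count(a) - pixel_count(b))
}

#' @rdname glyph_distance
#' @export
pc_distance <- function(a, b, ...) {
  abs(perimetric_complexity(a, ...) - perimetric_complexity(b, ...))
}

#' All metric names understood by the package
#' @return Character vector \code{c("pixel", "pc", "hausdorff")}.
#' @export
glyph_metrics <- function() c("pixel", "pc", "hausdorff")
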