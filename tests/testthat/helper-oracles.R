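# Independent reference implementations used to cross-check the package.
# These deliberately use the most literal textbook formulations.

# Hausdorff distance by exhaustive double loop over both point sets
brute_force_hausdorff <- function(A, B) {
  directed <- function(P, Q) {
    worst <- 0
    for (i in seq_len(nrow(P))) {
      best <- Inf
      for (j in seq_len(nrow(Q))) {
        d <- sqrt((P[i, 1] - Q[j, 1])^2 + (P[i, 2] - Q[j, 2])^2)
        if (d < best) best <- d
      }
      if (best > worst) worst <- best
    }
    worst
  }
  max(directed(A, B), directed(B, A))
}

# point-set matrix -> glyph_raster on a canvas that contains it
points_to_glyph <- function(pts, id = "pts") {
  m <- matrix(0L, max(pts[, 1]) + 1L, max(pts[, 2]) + 1L)
  m[pts + 1L] <- 1L
  glyph_raster(m, id)
}

# Pearson r and two-sided p from the definitional formulas
textbook_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}

# Spearman rho as Pearson on average ranks, t-approximation p
textbook_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  textbook_pearson(rx, ry)
}

# small glyph fixtures used across test files
filled_square <- function(n) glyph_raster(matrix(1L, n, n), sprintf("sq%d", n))

plus_sign_glyph <- function() {
  m <- matrix(0L, 5, 5)
  m[3, 2:4] <- 1L
  m[2:4, 3] <- 1L
  glyph_raster(m, "plus")
}
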