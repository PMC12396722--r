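test_that("binarize thresholds grayscale into ink with dark-is-ink convention", {
  expect_equal(pixel_count(binarize(matrix(0, 3, 3))), 9)
  white <- binarize(matrix(1, 3, 3))
  expect_equal(nrow(white$ink_pixels), 0)
  expect_error(pixel_count(white), "no ink")
  checker <- matrix(rep(c(0, 1), 8), 4, 4)
  expect_equal(pixel_count(binarize(checker)), 8)
  expect_error(binarize(matrix(numeric(0), 0, 0)), "non-empty")
})

test_that("pixel count and its pairwise distance follow the ink area", {
  expect_equal(pixel_count(filled_square(10)), 100)
  single <- glyph_raster(matrix(c(1, 0, 0, 0), 2, 2))
  expect_equal(pixel_count(single), 1)
  expect_equal(pixel_count(plus_sign_glyph()), 5)
  expect_equal(pixel_count_distance(filled_square(10), filled_square(10)), 0)
  # 100 vs 37 ink pixels
  m <- matrix(0L, 10, 10); m[seq_len(37)] <- 1L
  expect_equal(pixel_count_distance(filled_square(10), glyph_raster(m)), 63)
})

test_that("perimeter counts exposed 4-connectivity edges", {
  expect_equal(perimeter(glyph_raster(matrix(1L, 1, 1))), 4)
  expect_equal(perimeter(filled_square(2)), 8)
  expect_equal(perimeter(plus_sign_glyph()), 12)
  # border pixels expose edges at the canvas boundary
  expect_equal(perimeter(filled_square(5)), 20)
})

test_that("perimetric complexity matches closed forms and ignores position", {
  for (n in c(1, 3, 7, 20))
    expect_equal(perimetric_complexity(filled_square(n)), 16)
  expect_equal(perimetric_complexity(plus_sign_glyph()), 144 / 5)
  expect_equal(pc_distance(filled_square(4), plus_sign_glyph()), 28.8 - 16)
  # translate the plus sign within a larger canvas: PC unchanged
  m <- matrix(0L, 12, 12)
  m[8, 7:9] <- 1L; m[7:9, 8] <- 1L
  expect_equal(pc_distance(plus_sign_glyph(), glyph_raster(m)), 0)
})

test_that("contour perimeter shortcuts diagonals", {
  # n-by-n square: four straight sides of length n with the four corners
  # cut to sqrt(2)/2 diagonals
  for (n in 2:5)
    expect_equal(perimeter(filled_square(n), method = "contour"),
                 4 * n - 4 + 2 * sqrt(2))
  # a lone pixel is a diamond through the 4 surrounding cell midpoints
  expect_equal(perimeter(glyph_raster(matrix(1L, 1, 1)), method = "contour"),
               2 * sqrt(2))
  # the plus sign contour is a pure diamond of diagonal steps
  expect_equal(perimeter(plus_sign_glyph(), method = "contour"), 6 * sqrt(2))
})

test_that("hausdorff distance handles identity, single points and alignment", {
  g <- plus_sign_glyph()
  expect_equal(hausdorff_distance(g, g), 0)
  A <- points_to_glyph(cbind(0, 0))
  B <- points_to_glyph(cbind(3, 4))
  expect_equal(hausdorff_distance(A, B, align = FALSE), 5)
  expect_equal(hausdorff_distance(A, B, align = TRUE), 0)
  # alignment makes translated copies coincide
  m <- matrix(0L, 12, 12); m[8, 7:9] <- 1L; m[7:9, 8] <- 1L
  expect_equal(hausdorff_distance(g, glyph_raster(m)), 0)
})

test_that("hausdorff distance equals the brute-force double loop exactly", {
  set.seed(11)
  rand_points <- function() {
    n <- sample(3:50, 1)
    unique(cbind(sample(0:30, n, TRUE), sample(0:30, n, TRUE)))
  }
  for (i in 1:100) {
    A <- rand_points(); B <- rand_points()
    expect_identical(
      hausdorff_distance(points_to_glyph(A), points_to_glyph(B), align = FALSE),
      brute_force_hausdorff(A, B))
  }
})

test_that("hausdorff (unaligned) satisfies the triangle inequality", {
  set.seed(7)
  for (i in 1:40) {
    gs <- lapply(1:3, function(k)
      points_to_glyph(unique(cbind(sample(0:20, 15, TRUE),
                                   sample(0:20, 15, TRUE)))))
    dab <- hausdorff_distance(gs[[1]], gs[[2]], align = FALSE)
    dbc <- hausdorff_distance(gs[[2]], gs[[3]], align = FALSE)
    dac <- hausdorff_distance(gs[[1]], gs[[3]], align = FALSE)
    expect_lte(dac, dab + dbc + 1e-12)
  }
})

test_that("scalar-feature distances are symmetric pseudo-metrics", {
  set.seed(3)
  lib <- generate_glyph_library(n_glyphs = 6, seed = 3)
  gs <- lib$glyphs
  for (f in list(pixel_count_distance, pc_distance)) {
    for (i in 1:5) {
      abc <- sample(gs, 3)
      expect_equal(f(abc[[1]], abc[[2]]), f(abc[[2]], abc[[1]]))
      expect_lte(abs(f(abc[[1]], abc[[3]]) - f(abc[[2]], abc[[3]])),
                 f(abc[[1]], abc[[2]]) + 1e-9)
    }
  }
})

test_that("empty glyphs are rejected by every metric", {
  empty <- binarize(matrix(1, 4, 4))
  g <- filled_square(3)
  expect_error(pixel_count(empty), "no ink")
  expect_error(perimeter(empty), "no ink")
  expect_error(hausdorff_distance(g, empty), "no ink")
  expect_error(pixel_count_distance(empty, g), "no ink")
})

test_that("PGM round-trip and manifest loading reproduce the glyphs", {
  dir <- withr::local_tempdir()
  lib <- generate_glyph_library(n_glyphs = 3, canvas = c(20, 20), seed = 5)
  paths <- character(3)
  for (i in 1:3) {
    paths[i] <- file.path(dir, sprintf("g%d.pgm", i))
    write_pgm(lib$glyphs[[i]], paths[i])
  }
  back <- read_glyph(paths[1], glyph_id = lib$glyphs[[1]]$glyph_id)
  expect_identical(back$grid, lib$glyphs[[1]]$grid)
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(data.frame(glyph_id = names(lib$glyphs),
                              path = basename(paths),
                              script = "roundtrip"),
                   manifest, row.names = FALSE)
  lib2 <- read_glyph_library(manifest)
  expect_equal(lib2$name, "roundtrip")
  expect_identical(lib2$glyphs[[2]]$grid, lib$glyphs[[2]]$grid)
})

test_that("PNG glyphs load through the png package", {
  dir <- withr::local_tempdir()
  img <- matrix(1, 9, 9)
  img[3:7, 3:7] <- 0
  path <- file.path(dir, "sq.png")
  png::writePNG(img, path)
  g <- read_glyph(path)
  expect_equal(pixel_count(g), 25)
  expect_equal(perimetric_complexity(g), 16)
})

test_that("pairwise_distances agrees with direct metric calls in both layouts", {
  lib <- generate_glyph_library(n_glyphs = 5, canvas = c(24, 24), seed = 9)
  for (mt in glyph_metrics()) {
    M <- pairwise_distances(lib, mt)
    expect_true(isSymmetric(M))
    expect_equal(diag(M), setNames(rep(0, 5), names(lib$glyphs)))
    expect_equal(M["g01", "g03"],
                 glyph_distance(lib$glyphs[["g01"]], lib$glyphs[["g03"]], mt))
    long <- pairwise_distances(lib, mt, long = TRUE)
    expect_equal(nrow(long), choose(5, 2))
    expect_equal(long$value[long$glyph_a == "g01" & long$glyph_b == "g03"],
                 M["g01", "g03"])
  }
})
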