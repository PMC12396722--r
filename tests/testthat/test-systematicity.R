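toy_library <- function() {
  glyph_library(list(
    filled_square_id("a1", 3), filled_square_id("a2", 5),
    filled_square_id("b1", 4), filled_square_id("b2", 8),
    filled_square_id("c1", 2), filled_square_id("c2", 9)),
    name = "toy")
}
filled_square_id <- function(id, n) glyph_raster(matrix(1L, n, n), id)

toy_pd <- function() {
  phonetic_distance_table(data.frame(
    phoneme_1 = c("p", "k", "m"), phoneme_2 = c("b", "g", "n"),
    euclidean = c(1, 1.5, 2.2), cosine = c(0.2, 0.3, 0.9),
    jaccard = c(0.3, 0.4, 0.9), feature_edit = c(1L, 2L, 5L)))
}

test_that("pair_distance_vectors aligns phonetic and glyph distances by pair", {
  lib <- toy_library()
  pd <- toy_pd()
  m <- material(data.frame(phoneme_1 = c("p", "k", "m"),
                           phoneme_2 = c("b", "g", "n"),
                           glyph_L1 = c("a1", "b1", "c1"),
                           glyph_L2 = c("a2", "b2", "c2")),
                intended_metric = "pixel")
  v <- pair_distance_vectors(m, pd, lib, metric = "pixel")
  expect_equal(v$phonetic, c(1, 1.5, 2.2))
  expect_equal(v$glyph, c(25 - 9, 64 - 16, 81 - 4))
  # unordered phoneme lookup
  m2 <- material(data.frame(phoneme_1 = c("b", "g", "n"),
                            phoneme_2 = c("p", "k", "m"),
                            glyph_L1 = c("a1", "b1", "c1"),
                            glyph_L2 = c("a2", "b2", "c2")),
                 intended_metric = "pixel")
  expect_equal(pair_distance_vectors(m2, pd, lib, metric = "pixel")$phonetic,
               v$phonetic)
  bad <- material(data.frame(phoneme_1 = c("z", "k", "m"),
                             phoneme_2 = c("q", "g", "n"),
                             glyph_L1 = c("a1", "b1", "c1"),
                             glyph_L2 = c("a2", "b2", "c2")),
                  intended_metric = "pixel")
  expect_error(pair_distance_vectors(bad, pd, lib), "missing")
})

test_that("score_systematicity matches its closed-form extremes", {
  x <- c(1, 2, 3, 4, 5)
  s <- score_systematicity(x, 2 * x + 1)
  expect_equal(s$pearson_r, 1)
  s2 <- score_systematicity(x, -x)
  expect_equal(s2$pearson_r, -1)
  expect_equal(s2$spearman_rho, -1)
  s3 <- score_systematicity(x, c(1, 3, 2, 5, 4))
  expect_equal(s3$spearman_rho, 0.8)
  expect_error(score_systematicity(x, rep(2, 5)), "constant")
  expect_error(score_systematicity(1:2, 1:2), "at least 3")
})

test_that("scores match the textbook formulas to 1e-12", {
  set.seed(31)
  for (i in 1:100) {
    x <- runif(10); y <- runif(10)
    s <- score_systematicity(x, y)
    pe <- textbook_pearson(x, y)
    sp <- textbook_spearman(x, y)
    expect_equal(s$pearson_r, pe$r, tolerance = 1e-12)
    expect_equal(s$pearson_p, pe$p, tolerance = 1e-12)
    expect_equal(s$spearman_rho, sp$r, tolerance = 1e-12)
    expect_equal(s$spearman_p, sp$p, tolerance = 1e-12)
  }
})

test_that("scoring a material is invariant to pair order and deterministic", {
  pl <- plant_material_library(phonetic_distance_fixture(), "pixel",
                               n_decoys = 0, seed = 8)
  pd <- phonetic_distance_fixture()
  s1 <- score_material(pl$material, pd, pl$library)
  perm <- sample(nrow(pl$material))
  m2 <- material(as.data.frame(pl$material)[perm, ],
                 intended_metric = "pixel")
  s2 <- score_material(m2, pd, pl$library)
  expect_equal(s1$pearson_r, s2$pearson_r)
  expect_equal(s1$spearman_p, s2$spearman_p)
  s3 <- score_material(pl$material, pd, pl$library)
  expect_identical(s1, s3)
})

test_that("cross-validation grid has the right shape and exclusivity gating", {
  pd <- phonetic_distance_fixture()
  mats <- lapply(glyph_metrics(), function(mt)
    plant_material_library(pd, mt, n_decoys = 0, seed = 17)$material)
  libs <- lapply(glyph_metrics(), function(mt)
    plant_material_library(pd, mt, n_decoys = 0, seed = 17)$library)
  # merge the three planted libraries under unique ids
  all_glyphs <- list()
  for (k in 1:3) {
    for (g in libs[[k]]$glyphs) {
      g$glyph_id <- paste0(glyph_metrics()[k], "_", g$glyph_id)
      all_glyphs[[g$glyph_id]] <- g
    }
    df <- as.data.frame(mats[[k]])
    df$glyph_L1 <- paste0(glyph_metrics()[k], "_", df$glyph_L1)
    df$glyph_L2 <- paste0(glyph_metrics()[k], "_", df$glyph_L2)
    mats[[k]] <- material(df, attr(mats[[k]], "material_type"),
                          glyph_metrics()[k])
  }
  lib <- glyph_library(unname(all_glyphs), "merged")
  cv <- crossval_matrix(mats, pd, lib)
  expect_equal(dim(cv), c(3, 3))
  expect_equal(rownames(cv), glyph_metrics())
  sm <- summary(cv)
  expect_equal(nrow(sm), 9)
  # diagonal strongly significant by construction
  expect_true(all(sm$pearson_p[sm$intended] < 0.001))
  chk <- exclusivity_check(cv)
  expect_equal(nrow(chk), 3)
  expect_type(chk$pass, "logical")
})

test_that("exclusivity_check applies the pass rule to the Pearson p grid", {
  fake_cell <- function(r, p) structure(
    list(pearson_r = r, pearson_p = p, spearman_rho = r, spearman_p = p,
         n = 10), class = "systematicity_score")
  mk_cv <- function(pmat) {
    cells <- matrix(vector("list", 9), 3,
                    dimnames = list(glyph_metrics(),
                                    c("english", "chinese", "korean")))
    for (i in 1:3) for (j in 1:3)
      cells[[i, j]] <- fake_cell(0.5, pmat[i, j])
    structure(cells, class = "systematicity_crossval",
              intended = glyph_metrics())
  }
  # clean diagonal: everything passes
  p_good <- matrix(0.2, 3, 3); diag(p_good) <- 1e-5
  expect_true(all(exclusivity_check(mk_cv(p_good))$pass))
  # everything significant: nothing is exclusive
  p_bad <- matrix(0.001, 3, 3)
  chk <- exclusivity_check(mk_cv(p_bad))
  expect_false(any(chk$pass))
  expect_match(chk$reason[1], "off-metric")
  # the published Table-2-style Pearson grid passes for all three materials
  p_paper <- matrix(c(1e-5, 0.19, 0.32,
                      0.19, 1e-5, 0.10,
                      0.07, 0.15, 1e-5), 3, 3)
  expect_true(all(exclusivity_check(mk_cv(p_paper))$pass))
})

test_that("under the null the Pearson test rejects at close to its level", {
  pd <- phonetic_distance_fixture()
  set.seed(99)
  p <- replicate(2000, {
    glyph_d <- runif(10, 1, 50)  # glyph distances independent of phonetics
    score_systematicity(pd$euclidean, glyph_d)$pearson_p
  })
  expect_gte(mean(p < 0.05), 0.03)
  expect_lte(mean(p < 0.05), 0.07)
})
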