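## Synthetic glyph construction
##
## Glyphs are built from a small set of primitives chosen so the three shape
## metrics stay partially decoupled and individually steerable:
##   - compact irregular blobs grown cell-by-cell (exact ink-pixel control
##     -> pixel count),
##   - single-pixel boundary teeth, each +1 area / +2 perimeter
##     (-> perimetric complexity),
##   - one-pixel-wide arms extending away from the body (-> Hausdorff).
## Teeth and bulk growth avoid the neighbourhood of the glyph's farthest-
## from-centroid pixel so they leave a tuned Hausdorff distance alone.

ink_coords <- function(m) which(m == 1L, arr.ind = TRUE)

neighbor_count_grid <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  p[1:nr, 2:(nc + 1L)] + p[3:(nr + 2L), 2:(nc + 1L)] +
    p[2:(nr + 1L), 1:nc] + p[2:(nr + 1L), 3:(nc + 2L)]
}

# drop candidate cells near the ink pixel farthest from the centroid: that
# tip is what a tuned Hausdorff distance hangs on, so growth and teeth must
# leave its neighbourhood alone
drop_near_tip <- function(cand, m, radius = 3) {
  if (nrow(cand) == 0L) return(cand)
  pts <- ink_coords(m)
  ctr <- colMeans(pts)
  tip <- pts[which.max((pts[, 1L] - ctr[1L])^2 + (pts[, 2L] - ctr[2L])^2), ]
  d <- sqrt((cand[, 1L] - tip[1L])^2 + (cand[, 2L] - tip[2L])^2)
  cand[d > radius, , drop = FALSE]
}

# background cells 4-adjacent to ink with >= min_nb ink neighbours
growth_candidates <- function(m, min_nb = 1L, protect_tip = FALSE) {
  nb <- neighbor_count_grid(m)
  cand <- which(m == 0L & nb >= min_nb, arr.ind = TRUE)
  if (protect_tip) cand <- drop_near_tip(cand, m)
  cand
}

# grow the blob by k cells; prefers concave sites (>= 2 ink neighbours) so
# the perimeter barely moves, falls back to any adjacent site
grow_pixels <- function(m, k, protect_tip = FALSE) {
  for (i in seq_len(k)) {
    cand <- growth_candidates(m, 2L, protect_tip)
    if (nrow(cand) == 0L) cand <- growth_candidates(m, 1L, protect_tip)
    if (nrow(cand) == 0L) cand <- growth_candidates(m, 1L, FALSE)
    if (nrow(cand) == 0L) stop("canvas full: cannot grow glyph", call. = FALSE)
    pick <- cand[sample.int(nrow(cand), 1L), ]
    m[pick[1L], pick[2L]] <- 1L
  }
  m
}

# compact irregular blob with exactly n_pixels ink, grown from a seed cell
blob_grid <- function(canvas, n_pixels, at = NULL) {
  m <- matrix(0L, canvas[1L], canvas[2L])
  if (is.null(at))
    at <- c(sample(seq(canvas[1L] %/% 3, 2L * canvas[1L] %/% 3), 1L),
            sample(seq(canvas[2L] %/% 3, 2L * canvas[2L] %/% 3), 1L))
  m[at[1L], at[2L]] <- 1L
  if (n_pixels > 1L) m <- grow_pixels(m, n_pixels - 1L)
  m
}

# one tooth: a background cell with exactly one ink neighbour (+1 area,
# +2 exposed-edge perimeter); NULL if no admissible site
add_tooth <- function(m, protect_tip = TRUE) {
  nb <- neighbor_count_grid(m)
  cand <- which(m == 0L & nb == 1L, arr.ind = TRUE)
  if (protect_tip) cand <- drop_near_tip(cand, m)
  if (nrow(cand) == 0L) return(NULL)
  pick <- cand[sample.int(nrow(cand), 1L), ]
  m[pick[1L], pick[2L]] <- 1L
  m
}

pc_of <- function(m) {
  g <- glyph_raster(m)
  perimetric_complexity(g)
}

# nudge PC(B) - PC(A) toward target by sprinkling teeth on whichever glyph
# closes the gap; stops within one tooth-step of the target
tune_pc_pair <- function(mA, mB, target, max_steps = 400L) {
  for (i in seq_len(max_steps)) {
    d <- pc_of(mB) - pc_of(mA)
    if (abs(d - target) < 1) break
    if (d < target) {
      nxt <- add_tooth(mB)
      if (is.null(nxt)) break
      mB <- nxt
    } else {
      nxt <- add_tooth(mA)
      if (is.null(nxt)) break
      mA <- nxt
    }
  }
  list(A = mA, B = mB)
}

# 1-px arm from the blob's extreme cell in the direction with most room
arm_direction <- function(m) {
  pts <- ink_coords(m)
  room <- c(north = min(pts[, 1L]) - 1L,
            south = nrow(m) - max(pts[, 1L]),
            west = min(pts[, 2L]) - 1L,
            east = ncol(m) - max(pts[, 2L]))
  names(room)[which.max(room)]
}

extend_arm <- function(m, dir) {
  pts <- ink_coords(m)
  step <- switch(dir, north = c(-1L, 0L), south = c(1L, 0L),
                 west = c(0L, -1L), east = c(0L, 1L))
  along <- if (dir %in% c("north", "south")) 1L else 2L
  # furthest ink cell in the arm direction becomes the tip to extend
  proj <- pts[, along] * (if (dir %in% c("north", "west")) -1L else 1L)
  tip <- pts[which.max(proj), ]
  nxt <- tip + step
  if (nxt[1L] < 1L || nxt[1L] > nrow(m) || nxt[2L] < 1L || nxt[2L] > ncol(m))
    return(NULL)
  m[nxt[1L], nxt[2L]] <- 1L
  m
}

# square satellite block detached from the body at `gap` cells beyond the
# body's extreme in direction `dir`; NULL if it does not fit the canvas
place_satellite <- function(m, dir, gap, side = 5L) {
  pts <- ink_coords(m)
  half <- side %/% 2L
  if (dir %in% c("north", "south")) {
    edge <- if (dir == "north") min(pts[, 1L]) else max(pts[, 1L])
    mid <- round(mean(range(pts[, 2L])))
    r0 <- if (dir == "north") edge - gap - side else edge + gap + 1L
    rows <- r0:(r0 + side - 1L); cols <- (mid - half):(mid - half + side - 1L)
  } else {
    edge <- if (dir == "west") min(pts[, 2L]) else max(pts[, 2L])
    mid <- round(mean(range(pts[, 1L])))
    c0 <- if (dir == "west") edge - gap - side else edge + gap + 1L
    cols <- c0:(c0 + side - 1L); rows <- (mid - half):(mid - half + side - 1L)
  }
  if (min(rows) < 1L || max(rows) > nrow(m) ||
      min(cols) < 1L || max(cols) > ncol(m)) return(NULL)
  m[rows, cols] <- 1L
  m
}

# place the same satellite on A (at the base gap) and on B at increasing
# gaps until the aligned Hausdorff distance reaches target; both glyphs get
# identical extra ink and perimeter, so pixel and PC differences are
# untouched by construction
tune_satellite_pair <- function(mA, mB, target, base_gap = 2L, side = 5L) {
  dir <- arm_direction(mA)
  A <- place_satellite(mA, dir, base_gap, side)
  if (is.null(A)) stop("canvas too small for satellite", call. = FALSE)
  gA <- glyph_raster(A)
  best <- NULL
  for (gap in base_gap:(max(dim(mB)))) {
    B <- place_satellite(mB, dir, gap, side)
    if (is.null(B)) break
    best <- B
    if (hausdorff_distance(gA, glyph_raster(B)) >= target) break
  }
  if (is.null(best)) stop("canvas too small for satellite", call. = FALSE)
  list(A = A, B = best)
}

# extend an arm on B until the aligned Hausdorff distance to A reaches
# target (or the canvas runs out); returns B
tune_arm_pair <- function(mA, mB, target, max_steps = 60L) {
  gA <- glyph_raster(mA)
  dir <- arm_direction(mB)
  for (i in seq_len(max_steps)) {
    if (hausdorff_distance(gA, glyph_raster(mB)) >= target) break
    nxt <- extend_arm(mB, dir)
    if (is.null(nxt)) {
      dir <- arm_direction(mB)  # try the next roomiest direction
      nxt <- extend_arm(mB, dir)
      if (is.null(nxt)) break
    }
    mB <- nxt
  }
  mB
}

# decoy glyph: random blob + random arm + random teeth
random_decoy <- function(canvas, size_range = c(80L, 260L),
                         arm_range = c(0L, 14L), teeth_range = c(0L, 30L)) {
  m <- blob_grid(canvas, sample(size_range[1L]:size_range[2L], 1L))
  arm <- sample(arm_range[1L]:arm_range[2L], 1L)
  if (arm > 0L) {
    dir <- arm_direction(m)
    for (i in seq_len(arm)) {
      nxt <- extend_arm(m, dir)
      if (is.null(nxt)) break
      m <- nxt
    }
  }
  for (i in seq_len(sample(teeth_range[1L]:teeth_range[2L], 1L))) {
    nxt <- add_tooth(m)
    if (is.null(nxt)) break
    m <- nxt
  }
  m
}

# straight stroke fully on empty cells; used by the planted stroke ladder
place_free_stroke <- function(m, len, tries = 500L) {
  for (i in seq_len(tries)) {
    horiz <- sample(c(TRUE, FALSE), 1L)
    if (horiz) {
      r <- sample.int(nrow(m), 1L)
      c0 <- sample.int(ncol(m) - len + 1L, 1L)
      cells <- cbind(r, c0:(c0 + len - 1L))
    } else {
      c0 <- sample.int(ncol(m), 1L)
      r <- sample.int(nrow(m) - len + 1L, 1L)
      cells <- cbind(r:(r + len - 1L), c0)
    }
    if (all(m[cells] == 0L)) {
      m[cells] <- 1L
      return(m)
    }
  }
  stop("infeasible plant: no room for a free stroke", call. = FALSE)
}

#' Generate a synthetic glyph library
#'
#' Glyphs are unions of randomly placed straight strokes (optionally
#' roughened with single-pixel boundary teeth), emulating small archaic-
#' script letter inventories: stroke count drives ink area, jaggedness
#' drives perimetric complexity, stroke placement drives Hausdorff
#' distance. An optional \code{plant} adds glyph pairs in which pair i's
#' second glyph carries \code{i} extra fixed-length strokes on free cells,
#' giving an exactly increasing pixel-count-distance ladder
#' (ids \code{plant<i>a} / \code{plant<i>b}).
#'
#' @param n_glyphs Number of random glyphs (>= 20 for use with the design
#'   stage).
#' @param canvas \code{c(rows, cols)}, at least 16 x 16.
#' @param stroke_count_range Range of strokes per glyph.
#' @param stroke_thickness Stroke thickness in pixels.
#' @param jag_teeth Range of boundary teeth per glyph.
#' @param plant Optional \code{list(n_pairs =, stroke_len =)} ladder spec.
#' @param seed Integer seed; output is reproducible from it.
#' @param name Library name.
#' @return A \code{\link{glyph_library}}.
#' @export
generate_glyph_library <- function(n_glyphs = 40L, canvas = c(64L, 64L),
                                   stroke_count_range = c(2L, 8L),
                                   stroke_thickness = 2L,
                                   jag_teeth = c(0L, 20L),
                                   plant = NULL, seed = 1L,
                                   name = "synthetic") {
  if (any(canvas < 16L)) stop("canvas must be at least 16 x 16", call. = FALSE)
  set.seed(seed)
  glyphs <- vector("list", n_glyphs)
  for (i in seq_len(n_glyphs)) {
    m <- matrix(0L, canvas[1L], canvas[2L])
    k <- sample(stroke_count_range[1L]:stroke_count_range[2L], 1L)
    for (s in seq_len(k)) {
      len <- sample(seq(canvas[1L] %/% 4, (3L * canvas[1L]) %/% 4), 1L)
      horiz <- sample(c(TRUE, FALSE), 1L)
      th <- stroke_thickness
      if (horiz) {
        r <- sample.int(canvas[1L] - th + 1L, 1L)
        c0 <- sample.int(canvas[2L] - len + 1L, 1L)
        m[r:(r + th - 1L), c0:(c0 + len - 1L)] <- 1L
      } else {
        c0 <- sample.int(canvas[2L] - th + 1L, 1L)
        r <- sample.int(canvas[1L] - len + 1L, 1L)
        m[r:(r + len - 1L), c0:(c0 + th - 1L)] <- 1L
      }
    }
    for (t in seq_len(sample(jag_teeth[1L]:jag_teeth[2L], 1L))) {
      nxt <- add_tooth(m, protect_tip = FALSE)
      if (is.null(nxt)) break
      m <- nxt
    }
    glyphs[[i]] <- glyph_raster(m, sprintf("g%02d", i))
  }
  if (!is.null(plant)) {
    np <- plant$n_pairs
    sl <- if (is.null(plant$stroke_len)) 8L else plant$stroke_len
    for (i in seq_len(np)) {
      base <- random_decoy(canvas, size_range = c(60L, 160L),
                           arm_range = c(0L, 0L), teeth_range = c(0L, 10L))
      partner <- base
      for (s in seq_len(i)) partner <- place_free_stroke(partner, sl)
      glyphs <- c(glyphs, list(glyph_raster(base, sprintf("plant%da", i)),
                               glyph_raster(partner, sprintf("plant%db", i))))
    }
  }
  glyph_library(glyphs, name = name)
}

#' Generate a random binary phoneme feature space
#'
#' Random binary feature vectors with the given density of active features.
#' By the binary identity, pairwise Euclidean distance squared equals the
#' feature edit distance on the result. Duplicate or all-zero vectors are
#' resampled up to a retry cap, then an error is raised (e.g. density 1
#' makes every vector identical).
#'
#' @param n_phonemes Number of phonemes (labels \code{p01}, \code{p02}, ...).
#' @param n_features Number of binary features, >= 2.
#' @param density Probability a feature is active.
#' @param seed Integer seed.
#' @param max_retries Resampling attempts per offending vector.
#' @return A \code{\link{phoneme_feature_table}}.
#' @export
generate_feature_space <- function(n_phonemes, n_features, density = 0.5,
                                   seed = 1L, max_retries = 100L) {
  if (n_features < 2L) stop("need at least 2 features", call. = FALSE)
  set.seed(seed)
  draw <- function() stats::rbinom(n_features, 1L, density)
  m <- t(replicate(n_phonemes, draw()))
  keys <- apply(m, 1L, paste, collapse = "")
  for (try in seq_len(max_retries)) {
    bad <- duplicated(keys) | rowSums(m) == 0L
    if (!any(bad)) break
    for (i in which(bad)) {
      m[i, ] <- draw()
      keys[i] <- paste(m[i, ], collapse = "")
    }
  }
  if (any(duplicated(keys) | rowSums(m) == 0L))
    stop("degenerate feature space: could not make phoneme vectors ",
         "distinct and non-zero (density too extreme?)", call. = FALSE)
  rownames(m) <- sprintf("p%02d", seq_len(n_phonemes))
  phoneme_feature_table(m)
}

planted_metric_range <- function(metric, canvas) {
  switch(metric,
    pixel = c(30, 140),
    pc = c(6, 30),
    hausdorff = c(5, min(16, canvas[1L] / 4))
  )
}

#' Plant a glyph library realizing a prescribed systematicity
#'
#' Constructs one symbol pair per phoneme pair such that the pairs' glyph
#' distances under \code{target_metric} are an affine map of the phonetic
#' distances (plus optional noise), while the other two metrics are steered
#' toward independent random targets so they carry no systematicity. The
#' planted pairs are embedded among random decoy glyphs. The returned
#' material scores r close to 1 under the target metric at zero noise and
#' passes the cross-metric exclusivity check with high probability.
#'
#' @param pd A \code{\link{phonetic_distance_table}} (e.g.
#'   \code{\link{phonetic_distance_fixture}}) supplying the phoneme pairs
#'   and distances, or a positive numeric vector of phonetic distances (an
#'   internal table with placeholder phoneme labels is then built).
#' @param target_metric Metric to plant the systematicity under.
#' @param phonetic_metric Distance column of \code{pd} to use.
#' @param n_decoys Number of random decoy glyphs added (>= 0; 20 keeps the
#'   library usable by the design stage).
#' @param canvas Canvas size.
#' @param noise SD of Gaussian noise added to the mapped target distances,
#'   in metric units; 0 gives the cleanest plant.
#' @param seed Integer seed.
#' @return List of class \code{planted_material} with elements
#'   \code{library} (\code{\link{glyph_library}}), \code{material}
#'   (\code{\link{material}}), and \code{phonetic} (the distance table
#'   used).
#' @export
plant_material_library <- function(pd, target_metric = c("pixel", "pc", "hausdorff"),
                                   phonetic_metric = "euclidean",
                                   n_decoys = 20L, canvas = c(64L, 64L),
                                   noise = 0, seed = 1L) {
  target_metric <- match.arg(target_metric)
  if (is.numeric(pd)) {
    vals <- pd
    pd <- phonetic_distance_table(data.frame(
      phoneme_1 = sprintf("x%02d", seq_along(vals)),
      phoneme_2 = sprintf("y%02d", seq_along(vals)),
      euclidean = vals, cosine = 0, jaccard = 0, feature_edit = 0L))
    phonetic_metric <- "euclidean"
  }
  d <- pd[[phonetic_metric]]
  if (any(d <= 0)) stop("phonetic distances must be positive", call. = FALSE)
  if (max(d) == min(d)) stop("phonetic distances must vary", call. = FALSE)
  set.seed(seed)
  rng <- planted_metric_range(target_metric, canvas)
  t <- rng[1L] + (d - min(d)) / (max(d) - min(d)) * (rng[2L] - rng[1L])
  if (noise > 0) t <- pmax(rng[1L] / 2, t + stats::rnorm(length(t), 0, noise))
  n <- length(t)
  glyphs <- list()
  mk <- function(m, id) glyph_raster(m, id)
  for (i in seq_len(n)) {
    ha_rand <- stats::runif(1L, 5, 12)      # off-target Hausdorff level
    pc_rand <- stats::runif(1L, -12, 12)    # off-target PC difference
    if (target_metric == "pixel") {
      sA <- sample(100:200, 1L)
      mA <- blob_grid(canvas, sA)
      mB <- blob_grid(canvas, sA + round(t[i]))
      mB <- tune_arm_pair(mA, mB, ha_rand)
      tuned <- tune_pc_pair(mA, mB, pc_rand)
      mA <- tuned$A; mB <- tuned$B
      # teeth perturbed the counts; restore the exact planted difference
      diff <- sum(mB) - sum(mA)
      want <- round(t[i])
      if (diff < want) mB <- grow_pixels(mB, want - diff, protect_tip = TRUE)
      if (diff > want) mA <- grow_pixels(mA, diff - want, protect_tip = TRUE)
    } else if (target_metric == "pc") {
      mA <- blob_grid(canvas, sample(100:240, 1L))
      mB <- blob_grid(canvas, sample(100:240, 1L))
      mB <- tune_arm_pair(mA, mB, ha_rand)
      tuned <- tune_pc_pair(mA, mB, t[i])
      mA <- tuned$A; mB <- tuned$B
    } else {
      # identical bases, then independent random bulk growth scrambles the
      # pixel difference; the displaced satellite alone sets the Hausdorff
      # distance and cancels out of the pixel and PC differences
      ctr <- canvas %/% 2L + sample(-3:3, 2L, replace = TRUE)
      mA <- blob_grid(canvas, sample(120:200, 1L), at = ctr)
      mB <- mA
      mA <- grow_pixels(mA, sample(0:60, 1L))
      mB <- grow_pixels(mB, sample(0:60, 1L))
      tuned <- tune_pc_pair(mA, mB, pc_rand)
      sat <- tune_satellite_pair(tuned$A, tuned$B, t[i])
      mA <- sat$A; mB <- sat$B
    }
    glyphs[[2L * i - 1L]] <- mk(mA, sprintf("t%02da", i))
    glyphs[[2L * i]] <- mk(mB, sprintf("t%02db", i))
  }
  for (j in seq_len(n_decoys))
    glyphs[[2L * n + j]] <- mk(random_decoy(canvas), sprintf("d%02d", j))
  lib <- glyph_library(glyphs, name = sprintf("planted-%s", target_metric))
  mat <- material(data.frame(phoneme_1 = pd$phoneme_1[seq_len(n)],
                             phoneme_2 = pd$phoneme_2[seq_len(n)],
                             glyph_L1 = sprintf("t%02da", seq_len(n)),
                             glyph_L2 = sprintf("t%02db", seq_len(n)),
                             stringsAsFactors = FALSE),
                  material_type = material_type_for_metric(target_metric),
                  intended_metric = target_metric)
  structure(list(library = lib, material = mat, phonetic = pd),
            class = "planted_material")
}

#' @export
print.planted_material <- function(x, ...) {
  cat(sprintf("<planted_material>  target metric: %s, library of %d glyphs\n",
              attr(x$material, "intended_metric"), length(x$library)))
  invisible(x)
}

#' Simulate forced-choice survey responses
#'
#' Each participant answers every choice question by drawing a
#' systematicity type from their group's preference weights
#' (i.i.d. multinomial per choice), and the follow-up symbol-to-phoneme
#' assignment is consistent with the designed orientation with probability
#' \code{assignment_accuracy}. Group sizes default to the study's 271
#' British, 308 Chinese and 266 Korean participants; weights default to
#' uniform (chance-level responding).
#'
#' @param n_per_group Named integer vector, group -> number of participants.
#' @param n_questions Choice questions per participant.
#' @param weights Named list, group -> probability triple over
#'   \code{c("english", "chinese", "korean")}, each summing to 1. Groups
#'   absent from the list respond uniformly.
#' @param assignment_accuracy Probability a record's follow-up assignment
#'   matches the designed orientation.
#' @param seed Integer seed.
#' @return A \code{\link{response_set}}.
#' @export
simulate_responses <- function(n_per_group = c(UK = 271L, CN = 308L, KR = 266L),
                               n_questions = 10L, weights = list(),
                               assignment_accuracy = 0.5, seed = 1L) {
  set.seed(seed)
  types <- systematicity_types()
  out <- lapply(names(n_per_group), function(g) {
    w <- if (g %in% names(weights)) weights[[g]] else rep(1 / 3, 3L)
    if (length(w) != 3L || abs(sum(w) - 1) > 1e-8)
      stop("weights for group ", g, " must be a probability triple",
           call. = FALSE)
    np <- n_per_group[[g]]
    n <- np * n_questions
    data.frame(
      participant_id = rep(sprintf("%s%04d", g, seq_len(np)),
                           each = n_questions),
      group = g,
      question_id = rep(seq_len(n_questions), times = np),
      chosen_type = sample(types, n, replace = TRUE, prob = w),
      assignment_consistent = stats::runif(n) < assignment_accuracy,
      stringsAsFactors = FALSE)
  })
  response_set(do.call(rbind, out))
}
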