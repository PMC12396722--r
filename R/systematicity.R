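#' Construct a stimulus material
#'
#' A material is a set of matched (phoneme pair, symbol pair) items — ten in
#' the forced-choice design — with the orientation convention that glyph L1
#' encodes phoneme P1 and L2 encodes P2. Each material carries the glyph
#' metric it was designed to maximize systematicity under: pixel count for
#' the English-type material, perimetric complexity for the Chinese-type,
#' Hausdorff distance for the Korean-type.
#'
#' @param pairs Data frame with columns \code{phoneme_1}, \code{phoneme_2},
#'   \code{glyph_L1}, \code{glyph_L2}.
#' @param material_type One of \code{"english"}, \code{"chinese"},
#'   \code{"korean"}, or another label for synthetic studies.
#' @param intended_metric The glyph metric the material targets.
#' @param n_pairs_required If not \code{NULL}, enforce this number of pairs
#'   (the survey design uses 10). \code{NULL} accepts any n >= 3.
#' @return An object of class \code{material} (a data frame with attributes
#'   \code{material_type} and \code{intended_metric}).
#' @export
material <- function(pairs, material_type = "custom",
                     intended_metric = c("pixel", "pc", "hausdorff"),
                     n_pairs_required = NULL) {
  intended_metric <- match.arg(intended_metric)
  need <- c("phoneme_1", "phoneme_2", "glyph_L1", "glyph_L2")
  if (!all(need %in% names(pairs)))
    stop("missing columns: ", paste(setdiff(need, names(pairs)), collapse = ", "),
         call. = FALSE)
  pairs <- as.data.frame(pairs)[need]
  if (nrow(pairs) < 3L) stop("a material needs at least 3 pairs", call. = FALSE)
  if (!is.null(n_pairs_required) && nrow(pairs) != n_pairs_required)
    stop("material must have exactly ", n_pairs_required, " pairs",
         call. = FALSE)
  gl <- c(pairs$glyph_L1, pairs$glyph_L2)
  if (anyDuplicated(gl))
    stop("glyphs must be distinct across the material's symbol pairs",
         call. = FALSE)
  structure(pairs, class = c("material", "data.frame"),
            material_type = as.character(material_type)[1L],
            intended_metric = intended_metric)
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("<material '%s'>  %d pairs, intended metric: %s\n",
              attr(x, "material_type"), nrow(x), attr(x, "intended_metric")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Read / write materials as CSV
#'
#' Long-format CSV with columns \code{pair_index}, \code{phoneme_1},
#' \code{phoneme_2}, \code{glyph_L1}, \code{glyph_L2}, \code{material_type},
#' \code{intended_metric}.
#'
#' @param path CSV file path.
#' @param m A \code{\link{material}} (for writing).
#' @return \code{read_material}: a \code{\link{material}};
#'   \code{write_material}: \code{path}, invisibly.
#' @export
read_material <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  material(df, material_type = df$material_type[1L],
           intended_metric = df$intended_metric[1L])
}

#' @rdname read_material
#' @export
write_material <- function(m, path) {
  stopifnot(inherits(m, "material"))
  out <- data.frame(pair_index = seq_len(nrow(m)), as.data.frame(m),
                    material_type = attr(m, "material_type"),
                    intended_metric = attr(m, "intended_metric"))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Matched phonetic and glyph distance vectors of a material
#'
#' Element i of each vector belongs to pair i: the phonetic distance between
#' (P1, P2) looked up in the distance table (unordered), and the glyph
#' distance between (L1, L2) under the named metric.
#'
#' @param m A \code{\link{material}}.
#' @param pd A \code{\link{phonetic_distance_table}} covering the material's
#'   phoneme pairs.
#' @param lib A \code{\link{glyph_library}} containing the material's glyphs.
#' @param metric Glyph metric; defaults to the material's intended metric.
#' @param phonetic_metric Which distance column of \code{pd} to use.
#' @param ... Passed to the glyph metric.
#' @return List with numeric vectors \code{phonetic} and \code{glyph}, both
#'   of length \code{nrow(m)}.
#' @export
pair_distance_vectors <- function(m, pd, lib,
                                  metric = attr(m, "intended_metric"),
                                  phonetic_metric = "euclidean", ...) {
  stopifnot(inherits(m, "material"), inherits(pd, "phonetic_distance_table"))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  lookup <- stats::setNames(pd[[phonetic_metric]], key(pd$phoneme_1, pd$phoneme_2))
  wanted <- key(m$phoneme_1, m$phoneme_2)
  if (any(!wanted %in% names(lookup)))
    stop("phoneme pairs missing from distance table: ",
         paste(unique(wanted[!wanted %in% names(lookup)]), collapse = ", "),
         call. = FALSE)
  g1 <- library_glyphs(lib, m$glyph_L1)
  g2 <- library_glyphs(lib, m$glyph_L2)
  gd <- mapply(function(a, b) glyph_distance(a, b, metric = metric, ...), g1, g2)
  list(phonetic = unname(lookup[wanted]), glyph = unname(gd))
}

#' Score grapho-phonemic systematicity
#'
#' Pearson and Spearman correlation between matched phonetic and glyph
#' distance vectors, with two-sided p-values (Pearson: t distribution on
#' n - 2 df; Spearman: t approximation on rho, average ranks for ties).
#'
#' @param x,y Numeric vectors of equal length n >= 3 (phonetic and glyph
#'   distances), neither constant.
#' @return Object of class \code{systematicity_score}: list with
#'   \code{pearson_r}, \code{pearson_p}, \code{spearman_rho},
#'   \code{spearman_p}, \code{n}.
#' @export
score_systematicity <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: constant vector", call. = FALSE)
  pe <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  sp <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE,
                    alternative = "two.sided"))
  structure(list(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
                 spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
                 n = length(x)),
            class = "systematicity_score")
}

#' @export
print.systematicity_score <- function(x, ...) {
  cat(sprintf("systematicity (n = %d): r = %.2f (p = %.3g), rho = %.2f (p = %.3g)\n",
              x$n, x$pearson_r, x$pearson_p, x$spearman_rho, x$spearman_p))
  invisible(x)
}

#' Score a material against a glyph metric
#'
#' Convenience wrapper: builds the matched distance vectors and scores them.
#'
#' @inheritParams pair_distance_vectors
#' @return A \code{\link{score_systematicity}} result.
#' @export
score_material <- function(m, pd, lib, metric = attr(m, "intended_metric"),
                           phonetic_metric = "euclidean", ...) {
  v <- pair_distance_vectors(m, pd, lib, metric = metric,
                             phonetic_metric = phonetic_metric, ...)
  score_systematicity(v$phonetic, v$glyph)
}

#' Cross-validation matrix of materials against all metrics
#'
#' Scores each material under each of the three glyph metrics. In a
#' well-designed stimulus set every material shows significant systematicity
#' exclusively under its intended metric.
#'
#' @param materials List of materials with distinct intended metrics.
#' @param pd A \code{\link{phonetic_distance_table}}.
#' @param lib A \code{\link{glyph_library}}.
#' @param metrics Row metrics; default all three.
#' @param ... Passed to the glyph metrics.
#' @return Object of class \code{systematicity_crossval}: a metrics x
#'   materials matrix of \code{systematicity_score} objects (list matrix).
#' @export
crossval_matrix <- function(materials, pd, lib, metrics = glyph_metrics(),
                            ...) {
  stopifnot(is.list(materials), length(materials) >= 1L)
  intended <- vapply(materials, attr, character(1L), "intended_metric")
  if (anyDuplicated(intended))
    stop("materials must have distinct intended metrics", call. = FALSE)
  labels <- vapply(materials, attr, character(1L), "material_type")
  cells <- matrix(vector("list", length(metrics) * length(materials)),
                  nrow = length(metrics),
                  dimnames = list(metrics, labels))
  for (i in seq_along(metrics)) for (j in seq_along(materials)) {
    cells[[i, j]] <- score_material(materials[[j]], pd, lib,
                                    metric = metrics[i], ...)
  }
  structure(cells, class = "systematicity_crossval", intended = intended)
}

#' @export
print.systematicity_crossval <- function(x, ...) {
  fmt <- function(s) sprintf("r=%.2f (%.3g)", s$pearson_r, s$pearson_p)
  m <- matrix(vapply(x, fmt, character(1L)), nrow = nrow(x),
              dimnames = dimnames(x))
  cat("Cross-validation of grapho-phonemic systematicity (Pearson)\n")
  print(m, quote = FALSE)
  invisible(x)
}

#' Extract a numeric summary of a cross-validation matrix
#'
#' @param object A \code{\link{crossval_matrix}} result.
#' @param ... Unused.
#' @return Data frame with one row per (metric, material) cell:
#'   \code{metric}, \code{material_type}, \code{intended} (logical),
#'   \code{pearson_r}, \code{pearson_p}, \code{spearman_rho},
#'   \code{spearman_p}.
#' @export
summary.systematicity_crossval <- function(object, ...) {
  metrics <- rownames(object); mats <- colnames(object)
  intended <- attr(object, "intended")
  do.call(rbind, lapply(seq_along(mats), function(j) {
    do.call(rbind, lapply(seq_along(metrics), function(i) {
      s <- object[[i, j]]
      data.frame(metric = metrics[i], material_type = mats[j],
                 intended = metrics[i] == intended[j],
                 pearson_r = s$pearson_r, pearson_p = s$pearson_p,
                 spearman_rho = s$spearman_rho, spearman_p = s$spearman_p,
                 stringsAsFactors = FALSE)
    }))
  }))
}

#' Cross-metric exclusivity check
#'
#' A material passes iff its intended-metric Pearson p-value is below
#' \code{alpha} and every off-metric Pearson p-value is at or above
#' \code{alpha}. Exclusivity is judged on Pearson only; Spearman is reported
#' by the cross-validation matrix but not gated, since rank correlations of
#' partially coupled shape metrics routinely reach significance off-target.
#'
#' @param cv A \code{\link{crossval_matrix}} result.
#' @param alpha Significance level, default 0.05.
#' @return Data frame with one row per material: \code{material_type},
#'   \code{intended_metric}, \code{pass}, \code{reason}.
#' @export
exclusivity_check <- function(cv, alpha = 0.05) {
  stopifnot(inherits(cv, "systematicity_crossval"))
  metrics <- rownames(cv); mats <- colnames(cv)
  intended <- attr(cv, "intended")
  out <- lapply(seq_along(mats), function(j) {
    p <- vapply(seq_along(metrics), function(i) cv[[i, j]]$pearson_p,
                numeric(1L))
    names(p) <- metrics
    on_ok <- p[intended[j]] < alpha
    off <- p[setdiff(metrics, intended[j])]
    off_ok <- all(off >= alpha)
    reason <- if (on_ok && off_ok) "exclusive systematicity" else paste(
      c(if (!on_ok) sprintf("intended metric %s not significant (p=%.3g)",
                            intended[j], p[intended[j]]),
        if (!off_ok) sprintf("off-metric significant: %s",
                             paste(sprintf("%s (p=%.3g)",
                                           names(off)[off < alpha],
                                           off[off < alpha]),
                                   collapse = ", "))),
      collapse = "; ")
    data.frame(material_type = mats[j], intended_metric = intended[j],
               pass = on_ok && off_ok, reason = reason,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
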