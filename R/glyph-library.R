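#' Construct a glyph library
#'
#' An ordered, uniquely named collection of glyph rasters, typically one
#' script. The stimulus-design stage needs at least 20 glyphs (10 symbol
#' pairs).
#'
#' @param glyphs List of \code{\link{glyph_raster}} objects.
#' @param name Library name (e.g. a script name).
#' @return An object of class \code{glyph_library}.
#' @export
glyph_library <- function(glyphs, name = "library") {
  if (!is.list(glyphs) || length(glyphs) == 0L)
    stop("'glyphs' must be a non-empty list of glyph_raster objects",
         call. = FALSE)
  ok <- vapply(glyphs, is_glyph_raster, logical(1L))
  if (!all(ok)) stop("all elements must be glyph_raster objects", call. = FALSE)
  ids <- vapply(glyphs, function(g) g$glyph_id, character(1L))
  if (anyDuplicated(ids))
    stop("glyph_ids must be unique; duplicated: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  names(glyphs) <- ids
  structure(list(name = as.character(name)[1L], glyphs = glyphs),
            class = "glyph_library")
}

#' @export
print.glyph_library <- function(x, ...) {
  cat(sprintf("<glyph_library '%s'>  %d glyphs\n", x$name, length(x$glyphs)))
  invisible(x)
}

#' @export
length.glyph_library <- function(x) length(x$glyphs)

#' Look up glyphs by id
#' @param lib A \code{\link{glyph_library}}.
#' @param ids Character vector of glyph ids.
#' @return A list of \code{glyph_raster} objects in the order of \code{ids}.
#' @export
library_glyphs <- function(lib, ids) {
  stopifnot(inherits(lib, "glyph_library"))
  missing <- setdiff(ids, names(lib$glyphs))
  if (length(missing))
    stop("glyphs not in library '", lib$name, "': ",
         paste(missing, collapse = ", "), call. = FALSE)
  lib$glyphs[ids]
}

#' Read a single glyph image (PNG or PGM)
#'
#' PNG is read through the \pkg{png} package (multi-channel images are
#' collapsed to luminance by averaging); PGM (both ASCII P2 and binary P5)
#' with a built-in reader. The grayscale image is then binarized with
#' \code{\link{binarize}}.
#'
#' @param path Image file; extension decides the format.
#' @param glyph_id Identifier; defaults to the file name without extension.
#' @param threshold Binarization threshold on \code{[0, 1]} grayscale.
#' @return A \code{\link{glyph_raster}}.
#' @export
read_glyph <- function(path, glyph_id = NULL,
                       threshold = 0.5) {
  if (is.null(glyph_id))
    glyph_id <- sub("\\.[^.]*$", "", basename(path))
  ext <- tolower(sub(".*\\.", "", path))
  img <- switch(ext,
    png = {
      x <- png::readPNG(path)
      if (length(dim(x)) == 3L) {
        # drop alpha if present, average colour channels
        nc <- min(dim(x)[3L], 3L)
        apply(x[, , seq_len(nc), drop = FALSE], c(1L, 2L), mean)
      } else x
    },
    pgm = read_pgm(path),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  binarize(img, threshold = threshold, glyph_id = glyph_id)
}

#' Load a glyph library from a manifest CSV
#'
#' The manifest has columns \code{glyph_id}, \code{path} (relative to the
#' manifest's directory unless absolute), and optionally \code{script} used
#' as the library name.
#'
#' @param manifest Path to the manifest CSV.
#' @param threshold Binarization threshold passed to \code{\link{read_glyph}}.
#' @return A \code{\link{glyph_library}}.
#' @export
read_glyph_library <- function(manifest, threshold = 0.5) {
  df <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  if (!all(c("glyph_id", "path") %in% names(df)))
    stop("manifest needs columns 'glyph_id' and 'path'", call. = FALSE)
  base <- dirname(manifest)
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", df$path), df$path,
                  file.path(base, df$path))
  glyphs <- Map(read_glyph, paths, df$glyph_id,
                MoreArgs = list(threshold = threshold))
  name <- if ("script" %in% names(df)) df$script[1L] else "library"
  glyph_library(unname(glyphs), name = name)
}

# Minimal PGM reader: P2 (ASCII) and P5 (8/16-bit binary). Returns a
# grayscale matrix on [0, 1].
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  raw_all <- readBin(con, "raw", file.info(path)$size)
  txt_head <- rawToChar(raw_all[seq_len(min(length(raw_all), 4096L))])
  magic <- substr(txt_head, 1L, 2L)
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path, call. = FALSE)
  # tokenizer over the header (comments start with '#', run to end of line)
  pos <- 3L; tokens <- character(0L)
  n <- length(raw_all)
  while (length(tokens) < 3L && pos <= n) {
    ch <- rawToChar(raw_all[pos])
    if (ch == "#") {
      while (pos <= n && rawToChar(raw_all[pos]) != "\n") pos <- pos + 1L
    } else if (grepl("[0-9]", ch)) {
      start <- pos
      while (pos <= n && grepl("[0-9]", rawToChar(raw_all[pos]))) pos <- pos + 1L
      tokens <- c(tokens, rawToChar(raw_all[start:(pos - 1L)]))
    } else pos <- pos + 1L
  }
  wd <- as.integer(tokens[1L]); ht <- as.integer(tokens[2L])
  maxval <- as.integer(tokens[3L])
  if (magic == "P2") {
    vals <- scan(text = rawToChar(raw_all[pos:n]), what = integer(),
                 comment.char = "#", quiet = TRUE)
  } else {
    pos <- pos + 1L  # single whitespace byte after maxval
    if (maxval < 256L) {
      vals <- as.integer(raw_all[pos:(pos + wd * ht - 1L)])
    } else {
      by <- raw_all[pos:(pos + 2L * wd * ht - 1L)]
      vals <- as.integer(by[c(TRUE, FALSE)]) * 256L + as.integer(by[c(FALSE, TRUE)])
    }
  }
  if (length(vals) < wd * ht) stop("truncated PGM: ", path, call. = FALSE)
  matrix(vals[seq_len(wd * ht)] / maxval, nrow = ht, ncol = wd, byrow = TRUE)
}

#' Write a glyph raster as an ASCII PGM file
#'
#' Ink pixels are written black (0), background white (maxval).
#'
#' @param g A \code{\link{glyph_raster}}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_pgm <- function(g, path) {
  stopifnot(is_glyph_raster(g))
  vals <- 255L * (1L - t(g$grid))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(g$grid), nrow(g$grid)), "255"), con)
  write(vals, con, ncolumns = ncol(g$grid))
  invisible(path)
}

#' Pairwise glyph distances within a library
#'
#' @param lib A \code{\link{glyph_library}}.
#' @param metric Metric name, see \code{\link{glyph_distance}}.
#' @param long If \code{TRUE} return a long-format data frame
#'   (\code{glyph_a}, \code{glyph_b}, \code{metric}, \code{value}) over
#'   unordered pairs; otherwise a symmetric matrix.
#' @param ... Passed to the metric.
#' @return Data frame or numeric matrix of pairwise distances.
#' @export
pairwise_distances <- function(lib, metric = c("pixel", "pc", "hausdorff"),
                               long = FALSE, ...) {
  stopifnot(inherits(lib, "glyph_library"))
  metric <- match.arg(metric)
  ids <- names(lib$glyphs)
  k <- length(ids)
  M <- matrix(0, k, k, dimnames = list(ids, ids))
  if (metric %in% c("pixel", "pc")) {
    f <- if (metric == "pixel") pixel_count else function(g) perimetric_complexity(g, ...)
    v <- vapply(lib$glyphs, f, numeric(1L))
    M <- abs(outer(v, v, "-"))
    dimnames(M) <- list(ids, ids)
  } else {
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      M[i, j] <- M[j, i] <-
        hausdorff_distance(lib$glyphs[[i]], lib$glyphs[[j]], ...)
    }
  }
  if (!long) return(M)
  idx <- which(upper.tri(M), arr.ind = TRUE)
  data.frame(glyph_a = ids[idx[, 1L]], glyph_b = ids[idx[, 2L]],
             metric = metric, value = M[idx], stringsAsFactors = FALSE)
}
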