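#' Construct a phoneme feature table
#'
#' Maps each phoneme label to a fixed-length numeric feature vector
#' (typically binary phonological features: voicing, place, manner, ...).
#'
#' @param x Data frame whose first column is the phoneme label and whose
#'   remaining columns are numeric features, or a numeric matrix with
#'   rownames as labels.
#' @return An object of class \code{phoneme_feature_table}: a numeric matrix
#'   (phonemes x features) with unique rownames.
#' @export
phoneme_feature_table <- function(x) {
  if (is.data.frame(x)) {
    labels <- as.character(x[[1L]])
    m <- as.matrix(x[, -1L, drop = FALSE])
  } else if (is.matrix(x)) {
    labels <- rownames(x)
    m <- x
  } else stop("'x' must be a data frame or matrix", call. = FALSE)
  if (is.null(labels) || anyDuplicated(labels))
    stop("phoneme labels must be present and unique", call. = FALSE)
  if (!is.numeric(m) || anyNA(m))
    stop("features must be numeric without NAs", call. = FALSE)
  if (nrow(m) < 2L) stop("need at least 2 phonemes", call. = FALSE)
  if (ncol(m) < 1L) stop("need at least 1 feature", call. = FALSE)
  rownames(m) <- labels
  structure(m, class = c("phoneme_feature_table", "matrix", "array"))
}

#' Read a phoneme feature table from CSV
#'
#' First column: phoneme label; remaining columns: numeric features.
#'
#' @param path CSV file path.
#' @return A \code{\link{phoneme_feature_table}}.
#' @export
read_feature_table <- function(path) {
  phoneme_feature_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

check_same_length <- function(u, v) {
  if (length(u) != length(v))
    stop("feature vectors differ in length (", length(u), " vs ",
         length(v), ")", call. = FALSE)
}

#' Phonetic distances between feature vectors
#'
#' Four metrics over phoneme feature vectors: Euclidean norm of the
#' difference; cosine distance \code{1 - cos(u, v)}; Jaccard distance on the
#' supports of binary vectors; and feature edit distance, the number of
#' positions in which the vectors differ. For binary vectors
#' \code{euclidean^2 == feature_edit} exactly.
#'
#' @param u,v Numeric feature vectors of equal length. \code{jaccard_distance}
#'   requires binary (0/1) vectors and errors otherwise.
#' @return Non-negative scalar distance; cosine and Jaccard lie in
#'   \code{[0, 1]} for non-negative input.
#' @export
euclidean_distance <- function(u, v) {
  check_same_length(u, v)
  sqrt(sum((u - v)^2))
}

#' @rdname euclidean_distance
#' @export
cosine_distance <- function(u, v) {
  check_same_length(u, v)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop("cosine distance undefined for a zero vector", call. = FALSE)
  1 - sum(u * v) / (nu * nv)
}

#' @rdname euclidean_distance
#' @export
jaccard_distance <- function(u, v) {
  check_same_length(u, v)
  if (!all(u %in% c(0, 1)) || !all(v %in% c(0, 1)))
    stop("jaccard_distance requires binary (0/1) vectors", call. = FALSE)
  un <- sum(u == 1 | v == 1)
  if (un == 0)
    stop("jaccard distance undefined when both supports are empty",
         call. = FALSE)
  1 - sum(u == 1 & v == 1) / un
}

#' @rdname euclidean_distance
#' @export
feature_edit_distance <- function(u, v) {
  check_same_length(u, v)
  sum(u != v)
}

#' Construct a phonetic distance table
#'
#' A table of pairwise phonetic distances under the four metrics, either
#' supplied directly (as the published distance table is) or computed from a
#' feature table with \code{\link{phonetic_distances}}.
#'
#' @param rows Data frame with columns \code{phoneme_1}, \code{phoneme_2},
#'   \code{euclidean}, \code{cosine}, \code{jaccard}, \code{feature_edit}.
#' @return An object of class \code{phonetic_distance_table} (a data frame).
#' @export
phonetic_distance_table <- function(rows) {
  need <- c("phoneme_1", "phoneme_2", "euclidean", "cosine", "jaccard",
            "feature_edit")
  if (!all(need %in% names(rows)))
    stop("missing columns: ", paste(setdiff(need, names(rows)), collapse = ", "),
         call. = FALSE)
  rows <- as.data.frame(rows)[need]
  num <- rows[c("euclidean", "cosine", "jaccard", "feature_edit")]
  if (any(num < 0)) stop("distances must be non-negative", call. = FALSE)
  if (any(rows$cosine > 1 + 1e-9) || any(rows$jaccard > 1 + 1e-9))
    stop("cosine and jaccard distances must lie in [0, 1]", call. = FALSE)
  if (any(rows$feature_edit != round(rows$feature_edit)))
    stop("feature_edit must be integer", call. = FALSE)
  class(rows) <- c("phonetic_distance_table", "data.frame")
  rows
}

#' Compute a phonetic distance table from a feature table
#'
#' All unordered phoneme pairs, under all four metrics. With non-binary
#' features the Jaccard column is \code{NA} (Jaccard applies to binary
#' vectors only).
#'
#' @param ft A \code{\link{phoneme_feature_table}}.
#' @param round_digits Digits to round distances to; the published table
#'   prints 2. \code{NULL} keeps full precision.
#' @return A \code{\link{phonetic_distance_table}}.
#' @export
phonetic_distances <- function(ft, round_digits = 2L) {
  stopifnot(inherits(ft, "phoneme_feature_table"))
  labels <- rownames(ft)
  binary <- all(ft %in% c(0, 1))
  pairs <- utils::combn(length(labels), 2L)
  rows <- apply(pairs, 2L, function(ij) {
    u <- ft[ij[1L], ]; v <- ft[ij[2L], ]
    c(euclidean = euclidean_distance(u, v),
      cosine = cosine_distance(u, v),
      jaccard = if (binary) jaccard_distance(u, v) else NA_real_,
      feature_edit = feature_edit_distance(u, v))
  })
  out <- data.frame(phoneme_1 = labels[pairs[1L, ]],
                    phoneme_2 = labels[pairs[2L, ]],
                    t(rows), stringsAsFactors = FALSE)
  if (!is.null(round_digits)) {
    cols <- c("euclidean", "cosine", "jaccard")
    out[cols] <- lapply(out[cols], round, digits = round_digits)
  }
  if (!binary) {
    # bypass the [0,1] checks' NA comparison by filling then restoring
    tmp <- out; tmp$jaccard <- 0
    res <- phonetic_distance_table(tmp)
    res$jaccard <- NA_real_
    return(res)
  }
  phonetic_distance_table(out)
}

#' The published ten-row phonetic distance table
#'
#' Ten consonant pairs (/g s/, /h m/, /k s/, /p h/, /b k/, /p g/, /b m/,
#' /h s/, /k g/, /p b/) with their pairwise distances under the four
#' metrics, chosen so the Euclidean distances are evenly spread over
#' \code{[1, 2.24]}. This table is the phonetic input to the stimulus-design
#' stage.
#'
#' @return A \code{\link{phonetic_distance_table}} with 10 rows.
#' @export
phonetic_distance_fixture <- function() {
  path <- system.file("extdata", "phonetic_distances.csv",
                      package = "graphophon", mustWork = TRUE)
  phonetic_distance_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Correlations between the Euclidean column and the other metrics
#'
#' Pearson r between the table's Euclidean distances and each of the cosine,
#' Jaccard and feature-edit columns, rounded to two decimals. On the
#' published ten-row table these are 0.97, 0.97 and 0.90.
#'
#' @param t A \code{\link{phonetic_distance_table}} with at least 3 rows.
#' @return Named numeric vector \code{c(cosine=, jaccard=, feature_edit=)}.
#' @export
table_correlations <- function(t) {
  stopifnot(inherits(t, "phonetic_distance_table"))
  if (nrow(t) < 3L) stop("need at least 3 rows", call. = FALSE)
  others <- c("cosine", "jaccard", "feature_edit")
  sapply(stats::setNames(others, others), function(col) {
    if (stats::sd(t$euclidean) == 0 || stats::sd(t[[col]]) == 0)
      stop("correlation undefined: constant column", call. = FALSE)
    round(stats::cor(t$euclidean, t[[col]]), 2L)
  })
}
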