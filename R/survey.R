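#' Systematicity type labels and the default group designation
#'
#' The forced-choice survey offers three symbol-pair options per question,
#' one per systematicity type. Each language group has a designated
#' ("intended") type: British participants the English-type (pixel count),
#' Chinese participants the Chinese-type (perimetric complexity), Korean
#' participants the Korean-type (Hausdorff).
#'
#' @return \code{systematicity_types}: \code{c("english", "chinese",
#'   "korean")}. \code{default_designation}: named character vector mapping
#'   groups \code{UK}, \code{CN}, \code{KR} to their intended types.
#' @export
systematicity_types <- function() c("english", "chinese", "korean")

#' @rdname systematicity_types
#' @export
default_designation <- function() {
  c(UK = "english", CN = "chinese", KR = "korean")
}

#' Construct a forced-choice response set
#'
#' Long-format records of the survey's choice questions: one row per
#' participant x question, with the chosen systematicity type and whether
#' the follow-up symbol-to-phoneme assignment matched the material's
#' L1-to-P1 orientation.
#'
#' @param records Data frame with columns \code{participant_id},
#'   \code{group}, \code{question_id}, \code{chosen_type} and optionally
#'   \code{assignment_consistent} (logical).
#' @return An object of class \code{response_set} (a data frame).
#' @export
response_set <- function(records) {
  need <- c("participant_id", "group", "question_id", "chosen_type")
  if (!all(need %in% names(records)))
    stop("missing columns: ",
         paste(setdiff(need, names(records)), collapse = ", "), call. = FALSE)
  records <- as.data.frame(records)
  if (!all(records$chosen_type %in% systematicity_types()))
    stop("chosen_type must be one of: ",
         paste(systematicity_types(), collapse = ", "), call. = FALSE)
  if (anyDuplicated(records[c("participant_id", "question_id")]))
    stop("duplicate participant x question records", call. = FALSE)
  counts <- table(records$participant_id)
  if (length(unique(counts)) > 1L)
    stop("all participants must answer the same set of questions",
         call. = FALSE)
  class(records) <- c("response_set", "data.frame")
  records
}

#' @export
print.response_set <- function(x, ...) {
  cat(sprintf("<response_set>  %d participants x %d questions, groups: %s\n",
              length(unique(x$participant_id)),
              length(unique(x$question_id)),
              paste(names(table(x$group)), collapse = ", ")))
  invisible(x)
}

#' Read a response set from CSV
#' @param path CSV with the \code{\link{response_set}} columns.
#' @return A \code{response_set}.
#' @export
read_responses <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("assignment_consistent" %in% names(df))
    df$assignment_consistent <- as.logical(df$assignment_consistent)
  response_set(df)
}

#' Preference proportions of a group
#'
#' Fraction of a group's choice records selecting each systematicity type.
#'
#' @param r A \code{\link{response_set}}.
#' @param group Group label present in \code{r}.
#' @return Named numeric vector over the three types, summing to 1.
#' @export
preference_proportions <- function(r, group) {
  stopifnot(inherits(r, "response_set"))
  if (!group %in% r$group) stop("unknown group: ", group, call. = FALSE)
  ch <- r$chosen_type[r$group == group]
  tab <- table(factor(ch, levels = systematicity_types()))
  stats::setNames(as.vector(tab) / length(ch), systematicity_types())
}

#' Intended-selection rate per group
#'
#' For each group, the fraction of choices equal to the type designated for
#' that group. Chance level is 1/3.
#'
#' @param r A \code{\link{response_set}}.
#' @param designation Named character vector, group -> designated type; must
#'   cover every group present.
#' @return Named numeric vector of per-group rates.
#' @export
intended_rate <- function(r, designation = default_designation()) {
  stopifnot(inherits(r, "response_set"))
  groups <- unique(r$group)
  missing <- setdiff(groups, names(designation))
  if (length(missing))
    stop("designation missing for group(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  vapply(stats::setNames(groups, groups), function(g) {
    mean(r$chosen_type[r$group == g] == designation[[g]])
  }, numeric(1L))
}

#' Follow-up assignment consistency rate
#'
#' Fraction of records whose follow-up symbol-to-phoneme assignment matched
#' the designed L1-to-P1 orientation. Chance level is 1/2 (two
#' orientations).
#'
#' @param r A \code{\link{response_set}} with \code{assignment_consistent}.
#' @return Proportion in \code{[0, 1]}.
#' @export
mapping_consistency_rate <- function(r) {
  stopifnot(inherits(r, "response_set"))
  if (is.null(r$assignment_consistent) || anyNA(r$assignment_consistent))
    stop("assignment_consistent must be populated", call. = FALSE)
  mean(r$assignment_consistent)
}

#' Monte Carlo null distribution of type-choice proportions
#'
#' Each replicate draws \code{n_participants * n_questions} i.i.d. uniform
#' choices over the three systematicity types and records the resulting
#' type proportions; 10,000 replicates by default. This is the chance-level
#' reference against which observed group preferences are judged.
#'
#' @param n_participants,n_questions Size of the group being mimicked.
#' @param reps Number of replicates.
#' @param seed Integer seed; replicates are reproducible from it.
#' @return Object of class \code{permutation_null}: list with
#'   \code{replicates} (reps x 3 matrix, each row summing to 1), and the
#'   generating parameters.
#' @export
permutation_null <- function(n_participants, n_questions = 10L,
                             reps = 10000L, seed = 1L) {
  if (reps < 1L) stop("reps must be >= 1", call. = FALSE)
  set.seed(seed)
  n <- n_participants * n_questions
  counts <- stats::rmultinom(reps, size = n, prob = rep(1 / 3, 3L))
  reps_mat <- t(counts) / n
  colnames(reps_mat) <- systematicity_types()
  structure(list(replicates = reps_mat, reps = as.integer(reps),
                 n_participants = as.integer(n_participants),
                 n_questions = as.integer(n_questions),
                 seed = as.integer(seed)),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("<permutation_null>  %d replicates of %d x %d uniform choices\n",
              x$reps, x$n_participants, x$n_questions))
  print(round(apply(x$replicates, 2L, stats::quantile,
                    c(0.025, 0.5, 0.975)), 4L))
  invisible(x)
}

#' @param x A \code{permutation_null}.
#' @param observed Optional named list/vector of observed proportions (or a
#'   groups x types matrix) overplotted as points.
#' @param ... Passed to \code{boxplot}.
#' @rdname permutation_null
#' @export
plot.permutation_null <- function(x, observed = NULL, ...) {
  graphics::boxplot(x$replicates, ylab = "proportion of choices",
                    main = "Monte Carlo permutation null", ...)
  graphics::abline(h = 1 / 3, lty = 2, col = "grey50")
  if (!is.null(observed)) {
    obs <- if (is.matrix(observed)) observed else
      matrix(observed, nrow = 1L, dimnames = list(NULL, names(observed)))
    for (i in seq_len(nrow(obs)))
      graphics::points(seq_len(ncol(obs)),
                       obs[i, colnames(x$replicates)],
                       pch = 19, col = i + 1L)
  }
  invisible(x)
}

#' Monte Carlo p-value for an observed type proportion
#'
#' Two-sided with tie-inclusive counting and add-one smoothing: the
#' fraction of replicates whose deviation from chance (1/3) is at least as
#' large as the observed deviation, out of \code{reps + 1}.
#'
#' @param null A \code{\link{permutation_null}}.
#' @param observed Observed proportion of choices for \code{type}.
#' @param type Which systematicity type's null column to use.
#' @return p-value in \code{(0, 1]}.
#' @export
permutation_p_value <- function(null, observed,
                                type = c("english", "chinese", "korean")) {
  stopifnot(inherits(null, "permutation_null"))
  type <- match.arg(type)
  dev <- abs(null$replicates[, type] - 1 / 3)
  (sum(dev >= abs(observed - 1 / 3)) + 1) / (null$reps + 1)
}

#' Per-question preference vectors, Table-3 style
#'
#' For each group: the per-question proportion preferring each of the three
#' types, plus the per-question intended-selection proportion, giving
#' 4 vectors per group (12 for the three groups), each of length
#' \code{n_questions}. "Selecting as intended" requires, in addition to
#' choosing the group's designated type, that the follow-up
#' symbol-to-phoneme assignment matched the designed orientation (set
#' \code{intended_requires_assignment = FALSE} for choice-only); this is
#' what distinguishes the intended vector from the designated type's
#' preference vector.
#'
#' @param r A \code{\link{response_set}}.
#' @param designation Group -> intended type mapping.
#' @param intended_requires_assignment Condition the intended vector on the
#'   follow-up assignment as well.
#' @return Numeric matrix, one row per vector (rownames like
#'   \code{"KR preferring korean"}, \code{"KR selecting korean (intended)"}),
#'   one column per question.
#' @export
question_preference_matrix <- function(r, designation = default_designation(),
                                       intended_requires_assignment = TRUE) {
  stopifnot(inherits(r, "response_set"))
  groups <- intersect(names(designation), unique(r$group))
  if (length(groups) == 0L) stop("no designated group present", call. = FALSE)
  questions <- sort(unique(r$question_id))
  by_gq <- function(g, f) {
    sub <- r[r$group == g, , drop = FALSE]
    got <- sort(unique(sub$question_id))
    if (!identical(got, questions))
      stop("group ", g, " is missing questions", call. = FALSE)
    vapply(questions, function(q) f(sub[sub$question_id == q, , drop = FALSE]),
           numeric(1L))
  }
  rows <- list()
  for (g in groups) {
    for (ty in systematicity_types()) {
      rows[[sprintf("%s preferring %s", g, ty)]] <-
        by_gq(g, function(d) mean(d$chosen_type == ty))
    }
    ty <- designation[[g]]
    rows[[sprintf("%s selecting %s (intended)", g, ty)]] <-
      if (intended_requires_assignment) {
        if (is.null(r$assignment_consistent))
          stop("assignment_consistent needed for the intended vector",
               call. = FALSE)
        by_gq(g, function(d)
          mean(d$chosen_type == ty & d$assignment_consistent))
      } else by_gq(g, function(d) mean(d$chosen_type == ty))
  }
  out <- do.call(rbind, rows)
  colnames(out) <- paste0("q", questions)
  out
}

#' Pairwise correlation matrix of preference vectors
#'
#' Pearson r with two-sided t-test p-values over all pairs of row vectors
#' (n = number of questions per correlation). Cells involving a constant
#' vector are \code{NA}.
#'
#' @param vectors Numeric matrix, vectors in rows (e.g. from
#'   \code{\link{question_preference_matrix}}), at least 3 columns.
#' @return Object of class \code{preference_correlation}: list with
#'   symmetric matrices \code{r} (unit diagonal) and \code{p}.
#' @export
preference_correlation_matrix <- function(vectors) {
  if (!is.matrix(vectors) || ncol(vectors) < 3L)
    stop("'vectors' must be a matrix with at least 3 columns", call. = FALSE)
  k <- nrow(vectors)
  R <- diag(1, k); P <- diag(0, k)
  dimnames(R) <- dimnames(P) <- list(rownames(vectors), rownames(vectors))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    if (stats::sd(vectors[i, ]) == 0 || stats::sd(vectors[j, ]) == 0) {
      R[i, j] <- R[j, i] <- NA_real_
      P[i, j] <- P[j, i] <- NA_real_
    } else {
      ct <- stats::cor.test(vectors[i, ], vectors[j, ])
      R[i, j] <- R[j, i] <- unname(ct$estimate)
      P[i, j] <- P[j, i] <- ct$p.value
    }
  }
  structure(list(r = R, p = P), class = "preference_correlation")
}

significance_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***",
                              ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

#' @export
print.preference_correlation <- function(x, ...) {
  m <- matrix(sprintf("%.2f%s", x$r, significance_stars(x$p)),
              nrow = nrow(x$r), dimnames = dimnames(x$r))
  m[is.na(x$r)] <- "NA"
  m[upper.tri(m)] <- ""
  cat("Correlation matrix (* p<.05, ** p<.01, *** p<.001)\n")
  print(m, quote = FALSE)
  invisible(x)
}
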