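#' Grouped score counts
#'
#' Construct the grouped representation of a scored cohort: one row per
#' distinct score value, with the number of outcome-positive (`n_pos`) and
#' outcome-negative (`n_neg`) patients at that score. Scores must be strictly
#' increasing and counts non-negative.
#'
#' @param score Integer vector of distinct score values, strictly increasing.
#' @param n_pos,n_neg Non-negative integer counts per score.
#' @return A data frame of class `grouped_counts`.
#' @examples
#' grouped_counts(0:2, c(1, 4, 10), c(9, 6, 2))
#' @export
grouped_counts <- function(score, n_pos, n_neg) {
  if (length(score) != length(n_pos) || length(score) != length(n_neg)) {
    stop("score, n_pos and n_neg must have equal length", call. = FALSE)
  }
  if (length(score) && any(diff(score) <= 0)) {
    stop("scores must be strictly increasing", call. = FALSE)
  }
  if (any(n_pos < 0) || any(n_neg < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  structure(
    data.frame(score = as.integer(score), n_pos = as.integer(n_pos),
               n_neg = as.integer(n_neg)),
    class = c("grouped_counts", "data.frame")
  )
}

as_grouped_counts <- function(x) {
  if (inherits(x, "grouped_counts")) return(x)
  if (is.data.frame(x) && all(c("score", "n_pos", "n_neg") %in% names(x))) {
    return(grouped_counts(x$score, x$n_pos, x$n_neg))
  }
  stop("expected grouped counts (columns score, n_pos, n_neg)", call. = FALSE)
}

check_both_classes <- function(counts) {
  if (sum(counts$n_pos) < 1L || sum(counts$n_neg) < 1L) {
    stop("grouped counts need at least one positive and one negative patient",
         call. = FALSE)
  }
  invisible(counts)
}

#' Expand grouped counts to per-patient scores and labels
#'
#' Inverse of grouping: replicates each score by its positive and negative
#' counts, yielding the per-patient form the DeLong machinery needs.
#'
#' @param counts A [grouped_counts] object (or data frame with the same
#'   columns).
#' @return A list with numeric `scores` and integer 0/1 `labels`, positives
#'   first within each score value.
#' @export
expand_counts <- function(counts) {
  counts <- as_grouped_counts(counts)
  list(
    scores = rep(counts$score, times = counts$n_pos + counts$n_neg),
    labels = unlist(lapply(seq_len(nrow(counts)), function(i) {
      rep(c(1L, 0L), times = c(counts$n_pos[i], counts$n_neg[i]))
    }), use.names = FALSE) %||% integer()
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write grouped counts as delimited text
#'
#' Three-column CSV interchange (`score,n_pos,n_neg`) for grouped score
#' counts.
#'
#' @param path Path to a CSV file.
#' @param counts A [grouped_counts] object.
#' @return `read_grouped_counts()` returns a [grouped_counts] object;
#'   `write_grouped_counts()` returns `path` invisibly.
#' @export
read_grouped_counts <- function(path) {
  x <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  grouped_counts(x$score, x$n_pos, x$n_neg)
}

#' @rdname read_grouped_counts
#' @export
write_grouped_counts <- function(counts, path) {
  counts <- as_grouped_counts(counts)
  utils::write.csv(counts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
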