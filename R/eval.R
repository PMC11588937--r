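#' Dice coefficient between two binary masks
#'
#' `2 |R & Y| / (|R| + |Y|)`, relating the overlap of the reference mask R and
#' the predicted mask Y to their combined areas. Defined as 1 when both masks
#' are empty (degenerate frames).
#'
#' @param r,y Binary masks (logical or 0/1) of identical shape.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(r, y) {
  if (!all(dim(r) == dim(y))) stop("masks must have the same shape")
  s <- sum(r != 0) + sum(y != 0)
  if (s == 0) return(1)
  2 * sum(r != 0 & y != 0) / s
}

#' Per-frame, per-muscle Dice of a propagated mask sequence
#'
#' @param reference,predicted Integer label arrays `height x width x n_frames`.
#' @return Data frame with columns `frame` (0-based), `muscle`, `dice`.
#' @export
dice_sequence <- function(reference, predicted) {
  if (!all(dim(reference) == dim(predicted))) stop("mask sequences must match")
  n <- dim(reference)[3]
  labs <- muscle_labels()
  out <- expand.grid(frame = seq_len(n) - 1L, muscle = names(labs),
                     stringsAsFactors = FALSE)
  out$dice <- mapply(function(t, m) {
    dice(reference[, , t + 1] == labs[m], predicted[, , t + 1] == labs[m])
  }, out$frame, out$muscle)
  out
}

#' Cohort classification report
#'
#' Summarizes predicted versus reference contraction labels at muscle and
#' subject level: a subject counts as correct only when all three of its
#' muscles are classified correctly (mirroring per-subject circle summaries
#' of cohort accuracy).
#'
#' @param predicted,reference Character vectors of labels
#'   (`"contracted"`/`"relaxed"`), aligned element-wise.
#' @param subject Vector identifying the subject/video of each element.
#' @return An `evaluation_report`: list with `muscle_accuracy`,
#'   `subject_accuracy`, `confusion` (2x2 table) and `per_subject` data frame.
#' @export
classification_report <- function(predicted, reference, subject) {
  n <- length(predicted)
  if (n == 0) stop("empty input")
  if (length(reference) != n || length(subject) != n)
    stop("predicted, reference and subject must be aligned")
  correct <- predicted == reference
  per_subj <- vapply(split(correct, subject), all, logical(1))
  rep <- list(
    muscle_accuracy = mean(correct),
    subject_accuracy = mean(per_subj),
    confusion = table(reference = reference, predicted = predicted),
    per_subject = data.frame(subject = names(per_subj),
                             all_correct = unname(per_subj),
                             n_correct = vapply(split(correct, subject), sum,
                                                numeric(1)),
                             row.names = NULL, stringsAsFactors = FALSE)
  )
  structure(rep, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Muscle-level accuracy:  %.1f%%\n", 100 * x$muscle_accuracy))
  cat(sprintf("Subject-level accuracy: %.1f%% (all three muscles correct)\n",
              100 * x$subject_accuracy))
  cat("\nConfusion (reference x predicted):\n")
  print(x$confusion)
  invisible(x)
}
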