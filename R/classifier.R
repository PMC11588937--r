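#' Classifier parameters for contraction assessment
#'
#' Thresholds on the distribution overlaps and displacements applied to the
#' exercise-phase samples before the overlap computation. The displacements
#' guard against spuriously low overlaps from narrow, nearly coincident
#' distributions: each default moves the exercise values towards the resting
#' distribution, so a genuine effect must exceed the displacement to register.
#'
#' The shipped defaults (`t_th = 24.5`, `t_com = 25.5`, `d_th = -1`,
#' `d_com = 6`) are the values calibrated on the original clinical cohort of
#' manually segmented videos; they are retained as sensible defaults for data
#' acquired under a comparable protocol.
#'
#' @param t_th Overlap threshold (percent) for the thickness criterion.
#' @param t_com Overlap threshold (percent) for the center-of-mass criterion.
#' @param d_th Displacement in pixels added to exercise thickness values.
#' @param d_com Displacement in pixels added to exercise center-of-mass values.
#' @param positions Lateral measurement positions, see [measurement_positions()].
#' @return Object of class `classifier_params`.
#' @export
classifier_params <- function(t_th = 24.5, t_com = 25.5, d_th = -1, d_com = 6,
                              positions = measurement_positions()) {
  if (t_th < 0 || t_th > 100 || t_com < 0 || t_com > 100)
    stop("thresholds must be in [0, 100]")
  structure(list(t_th = t_th, t_com = t_com, d_th = d_th, d_com = d_com,
                 positions = measurement_positions(positions)),
            class = "classifier_params")
}

#' @export
print.classifier_params <- function(x, ...) {
  cat(sprintf("Contraction classifier parameters: t_th = %g, t_com = %g, d_th = %g, d_com = %g\n",
              x$t_th, x$t_com, x$d_th, x$d_com))
  invisible(x)
}

# Pull the four pooled samples for one muscle out of a measurement series.
muscle_samples <- function(series, muscle, rest_phases = c("rest1", "rest2")) {
  s <- series[series$muscle == muscle, , drop = FALSE]
  rest <- s[s$phase %in% rest_phases, , drop = FALSE]
  exer <- s[s$phase == "exercise", , drop = FALSE]
  out <- list(rest_th = rest$thickness_px[!is.na(rest$thickness_px)],
              ex_th = exer$thickness_px[!is.na(exer$thickness_px)],
              rest_com = rest$com_px[!is.na(rest$com_px)],
              ex_com = exer$com_px[!is.na(exer$com_px)])
  if (!length(out$rest_th) || !length(out$ex_th) ||
      !length(out$rest_com) || !length(out$ex_com))
    stop("phase without measurements for muscle ", muscle)
  out
}

# Core decision rule shared by the retrospective and real-time paths.
overlap_decision <- function(rest_th, ex_th, rest_com, ex_com, params) {
  delta_th <- distribution_overlap(rest_th, ex_th + params$d_th)
  delta_com <- distribution_overlap(ex_com + params$d_com, rest_com)
  list(delta_th = delta_th, delta_com = delta_com,
       label = if (delta_th < params$t_th || delta_com < params$t_com)
         "contracted" else "relaxed")
}

#' Retrospective contraction classification
#'
#' For each muscle, pools the thickness and lateral center-of-mass
#' measurements of the resting phases (A) and the exercise phase (B), shifts
#' the exercise samples by the displacements, computes the two distribution
#' overlaps and applies the OR rule: a muscle is *contracted* iff
#' `delta_th < t_th` or `delta_com < t_com`. Thickness is assumed to increase
#' during contraction (rest is distribution A, exercise B); the center of
#' mass is expected to decrease (exercise is A, rest B).
#'
#' @param series A `measurement_series` from [extract_series()].
#' @param params A [classifier_params()].
#' @param rest_phases Which resting phases form the reference distribution;
#'   the retrospective default pools both, the real-time mode uses rest1 only.
#' @param muscles Muscles to classify (default: all present in the series).
#' @return An `overlap_result`: data frame with columns `muscle`, `delta_th`,
#'   `delta_com`, `label`.
#' @export
classify_contraction <- function(series, params = classifier_params(),
                                 rest_phases = c("rest1", "rest2"),
                                 muscles = intersect(names(muscle_labels()),
                                                     unique(series$muscle))) {
  rows <- lapply(muscles, function(m) {
    sm <- muscle_samples(series, m, rest_phases)
    d <- overlap_decision(sm$rest_th, sm$ex_th, sm$rest_com, sm$ex_com, params)
    data.frame(muscle = m, delta_th = d$delta_th, delta_com = d$delta_com,
               label = d$label, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("overlap_result", "data.frame"))
}

# Candidate thresholds for one overlap dimension: exact midpoints between
# consecutive distinct observed values, plus one candidate below the minimum
# and one above the maximum (half a grid step outside).
threshold_candidates <- function(delta) {
  u <- sort(unique(delta))
  c(u[1] - 0.5, if (length(u) > 1) (u[-length(u)] + u[-1]) / 2, u[length(u)] + 0.5)
}

# Exhaustive threshold-pair search for fixed displacements. Scores every
# candidate pair by (1) correct OR-rule classifications, (2) margin (minimum
# distance from any point to its nearest threshold), ties towards smaller
# thresholds. y: logical, TRUE = contracted.
calibrate_thresholds <- function(delta_th, delta_com, y) {
  cth <- threshold_candidates(delta_th)   # length I
  ccom <- threshold_candidates(delta_com) # length J
  A <- outer(delta_th, cth, `<`) * 1      # n x I  (thickness criterion fires)
  B <- outer(delta_com, ccom, `<`) * 1    # n x J
  # correct counts for all threshold pairs via two rank-n matmuls:
  # contracted points are correct unless neither criterion fires
  nc_c <- t(1 - A[y, , drop = FALSE]) %*% (1 - B[y, , drop = FALSE])
  ok_r <- t(1 - A[!y, , drop = FALSE]) %*% (1 - B[!y, , drop = FALSE])
  correct <- (sum(y) - nc_c) + ok_r       # I x J
  acc_max <- max(correct)
  idx <- which(correct == acc_max, arr.ind = TRUE)
  M1 <- abs(outer(delta_th, cth[idx[, 1]], `-`))   # n x K
  M2 <- abs(outer(delta_com, ccom[idx[, 2]], `-`))
  marg <- apply(pmin(M1, M2), 2, min)
  cand <- data.frame(acc = acc_max, margin = marg,
                     t_th = cth[idx[, 1]], t_com = ccom[idx[, 2]])
  cand[order(-cand$margin, cand$t_th, cand$t_com), , drop = FALSE][1, ]
}

#' Calibrate contraction-classifier thresholds and displacements
#'
#' Fits [classifier_params()] to a labelled cohort of per-muscle measurement
#' series by exhaustive grid search: displacements on integer grids
#' (`d_th` in -5..5, `d_com` in -10..10 by default), and for each displacement
#' pair the overlaps are recomputed and every threshold pair on the grid of
#' midpoints between observed overlap values is scored by
#' (1) the number of correctly classified muscles under the OR rule,
#' (2) the margin (minimum distance from any point to its nearest threshold),
#' (3) the smallest total displacement magnitude `|d_th| + |d_com|`.
#' Remaining ties are resolved towards the smallest `d_th`, `d_com`, `t_th`,
#' `t_com`, making the fit deterministic.
#'
#' @param series_list List of `measurement_series`, each restricted to (or
#'   containing) a single muscle; elements may also be full series together
#'   with `muscles` naming which muscle each point refers to.
#' @param labels Reference labels, `"contracted"`/`"relaxed"` (or logical),
#'   one per element of `series_list`. Both classes must be present.
#' @param muscles Optional character vector naming the muscle of each series
#'   element; by default the single muscle present in each element.
#' @param d_th_grid,d_com_grid Integer displacement search grids.
#' @param positions Measurement positions stored in the fitted parameters.
#' @return An object of class `contraction_classifier` with components
#'   `params` (the fitted [classifier_params()]), `accuracy`, `margin`,
#'   `deltas` (training overlaps at the fitted displacements), `labels`.
#'   Supports `print()`, `summary()`, `coef()` and `predict()`.
#' @export
calibrate_classifier <- function(series_list, labels,
                                 muscles = NULL,
                                 d_th_grid = -5:5, d_com_grid = -10:10,
                                 positions = measurement_positions()) {
  n <- length(series_list)
  if (is.logical(labels)) labels <- ifelse(labels, "contracted", "relaxed")
  if (length(labels) != n) stop("labels must match series_list")
  y <- labels == "contracted"
  if (!any(y) || all(y)) stop("cannot calibrate: both classes must be present")
  if (is.null(muscles))
    muscles <- vapply(series_list, function(s) {
      u <- unique(s$muscle)
      if (length(u) != 1L) stop("each series element must hold a single muscle")
      u
    }, character(1))

  samp <- lapply(seq_len(n), function(i)
    muscle_samples(series_list[[i]], muscles[i]))

  best <- NULL
  for (d_com in d_com_grid) for (d_th in d_th_grid) {
    dth <- vapply(samp, function(s)
      distribution_overlap(s$rest_th, s$ex_th + d_th), numeric(1))
    dcom <- vapply(samp, function(s)
      distribution_overlap(s$ex_com + d_com, s$rest_com), numeric(1))
    cand <- calibrate_thresholds(dth, dcom, y)
    cand$d_th <- d_th; cand$d_com <- d_com
    if (is.null(best) ||
        cand$acc > best$acc ||
        (cand$acc == best$acc && cand$margin > best$margin) ||
        (cand$acc == best$acc && cand$margin == best$margin &&
           (abs(cand$d_th) + abs(cand$d_com)) < (abs(best$d_th) + abs(best$d_com))))
      best <- cand
  }

  params <- classifier_params(best$t_th, best$t_com, best$d_th, best$d_com,
                              positions)
  dth <- vapply(samp, function(s)
    distribution_overlap(s$rest_th, s$ex_th + best$d_th), numeric(1))
  dcom <- vapply(samp, function(s)
    distribution_overlap(s$ex_com + best$d_com, s$rest_com), numeric(1))
  structure(list(
    params = params,
    accuracy = best$acc / n,
    margin = best$margin,
    deltas = data.frame(muscle = muscles, delta_th = dth, delta_com = dcom,
                        label = labels, stringsAsFactors = FALSE),
    labels = labels,
    call = match.call()
  ), class = "contraction_classifier")
}

#' @export
print.contraction_classifier <- function(x, ...) {
  cat("Calibrated contraction classifier\n")
  print(x$params)
  cat(sprintf("  training accuracy: %.1f%% (n = %d muscles), margin %.2f\n",
              100 * x$accuracy, nrow(x$deltas), x$margin))
  invisible(x)
}

#' @export
summary.contraction_classifier <- function(object, ...) {
  print(object)
  cat("\nTraining overlaps:\n")
  print(object$deltas)
  invisible(object)
}

#' @export
coef.contraction_classifier <- function(object, ...) {
  p <- object$params
  c(t_th = p$t_th, t_com = p$t_com, d_th = p$d_th, d_com = p$d_com)
}

#' Predict contraction labels with a calibrated classifier
#'
#' @param object A fitted [calibrate_classifier()] object.
#' @param newdata A single `measurement_series` or a list of them.
#' @param ... Passed to [classify_contraction()] (e.g. `rest_phases`).
#' @return An `overlap_result` data frame (rows concatenated over list input).
#' @export
predict.contraction_classifier <- function(object, newdata, ...) {
  if (inherits(newdata, "data.frame")) newdata <- list(newdata)
  out <- do.call(rbind, lapply(newdata, classify_contraction,
                               params = object$params, ...))
  rownames(out) <- NULL
  structure(out, class = c("overlap_result", "data.frame"))
}
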