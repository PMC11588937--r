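#' Lateral measurement positions
#'
#' The four lateral positions at which muscle thickness is measured, expressed
#' as fractions of the image width from the left image border.
#'
#' @param positions Strictly increasing numeric vector with values in (0, 1).
#' @return Validated numeric vector of class `measurement_positions`.
#' @export
measurement_positions <- function(positions = c(0.2, 0.4, 0.6, 0.8)) {
  if (any(positions <= 0 | positions >= 1)) stop("positions must be in (0, 1)")
  if (is.unsorted(positions, strictly = TRUE)) stop("positions must be strictly increasing")
  structure(as.numeric(positions), class = "measurement_positions")
}

# fractions of width -> 1-based column indices
position_columns <- function(positions, width) {
  floor(positions * width) + 1L
}

#' Muscle thickness from a label mask
#'
#' Thickness is the mean over the measurement positions of the number of
#' pixels carrying the muscle's label in that position's column (a vertical
#' measurement along the segmentation mask). Positions whose column contains
#' no labeled pixel are excluded from the mean; if the label is absent at all
#' positions the result is missing (`NA`).
#'
#' @param mask 2-D integer label image (rows = axial depth, columns = lateral).
#' @param label Muscle label (1 = OE, 2 = OI, 3 = TrA).
#' @param positions A [measurement_positions()] vector.
#' @return Thickness in pixels, or `NA_real_` if the muscle is absent.
#' @export
muscle_thickness <- function(mask, label, positions = measurement_positions()) {
  stopifnot(is.matrix(mask))
  cols <- position_columns(positions, ncol(mask))
  counts <- colSums(mask[, cols, drop = FALSE] == label)
  counts <- counts[counts > 0]
  if (!length(counts)) return(NA_real_)
  mean(counts)
}

#' Lateral center of mass of a muscle mask
#'
#' Unweighted mean of the 0-based column indices of all pixels carrying the
#' label (binary mass; image intensity is not used). Only the lateral
#' coordinate is meaningful for contraction assessment: a shift towards the
#' left image border decreases it.
#'
#' @inheritParams muscle_thickness
#' @return Column coordinate in pixels (0-based), or `NA_real_` if absent.
#' @export
lateral_center_of_mass <- function(mask, label) {
  stopifnot(is.matrix(mask))
  cnt <- colSums(mask == label)
  tot <- sum(cnt)
  if (tot == 0) return(NA_real_)
  sum(cnt * (seq_len(ncol(mask)) - 1)) / tot
}

#' Extract per-frame measurement series from a mask sequence
#'
#' Applies [muscle_thickness()] and [lateral_center_of_mass()] to every frame
#' and muscle. Frames where a muscle is absent yield missing values, not
#' zeros.
#'
#' @param masks Integer array `height x width x n_frames` with labels 0--3.
#' @param phases A [phase_schedule()] aligned with the mask sequence.
#' @param positions A [measurement_positions()] vector.
#' @param frame_rate Frames per second; defaults to the schedule's.
#' @return A `measurement_series`: data frame with columns `frame` (0-based),
#'   `phase`, `muscle`, `thickness_px`, `com_px`, and attributes `frame_rate`
#'   and `image_width`.
#' @export
extract_series <- function(masks, phases, positions = measurement_positions(),
                           frame_rate = attr(phases, "frame_rate")) {
  if (length(dim(masks)) != 3L || dim(masks)[3] == 0L)
    stop("empty mask sequence")
  n <- dim(masks)[3]
  if (!is.null(attr(phases, "n_frames")) && attr(phases, "n_frames") != n)
    stop("mask sequence and phase schedule disagree on frame count")
  ph <- frame_phases(phases)
  labs <- muscle_labels()
  out <- vector("list", length(labs))
  for (m in seq_along(labs)) {
    th <- numeric(n); com <- numeric(n)
    for (t in seq_len(n)) {
      th[t] <- muscle_thickness(masks[, , t], labs[m], positions)
      com[t] <- lateral_center_of_mass(masks[, , t], labs[m])
    }
    out[[m]] <- data.frame(
      frame = seq_len(n) - 1L,
      phase = ph,
      muscle = names(labs)[m],
      thickness_px = th,
      com_px = com,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, frame_rate = frame_rate, image_width = dim(masks)[2],
            class = c("measurement_series", "data.frame"))
}

#' Plot a measurement series
#'
#' Thickness and lateral center of mass over time, one panel per measure,
#' with phase boundaries marked.
#'
#' @param x A `measurement_series`.
#' @param ... Ignored.
#' @return `x`, invisibly.
#' @export
plot.measurement_series <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  cols <- c(OE = "#1b9e77", OI = "#d95f02", TrA = "#7570b3")
  bounds <- tapply(x$frame, x$phase, max)
  for (meas in c("thickness_px", "com_px")) {
    graphics::plot(NA, xlim = range(x$frame), ylim = range(x[[meas]], na.rm = TRUE),
                   xlab = "frame", ylab = sub("_px", " (px)", meas))
    for (m in unique(x$muscle)) {
      s <- x[x$muscle == m, ]
      graphics::lines(s$frame, s[[meas]], col = cols[[m]])
    }
    graphics::abline(v = bounds[c("rest1", "exercise")] + 0.5, lty = 3)
    if (meas == "thickness_px")
      graphics::legend("topleft", legend = unique(x$muscle), bty = "n",
                       col = cols[unique(x$muscle)], lty = 1, cex = 0.8)
  }
  invisible(x)
}
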