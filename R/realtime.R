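#' Split the exercise phase into approximately one-second blocks
#'
#' Consecutive blocks of `round(frame_rate)` frames starting at exercise
#' onset. A final partial block is merged into the previous block unless it
#' is strictly longer than half a block; an exercise phase shorter than one
#' block forms a single block.
#'
#' @param start,end Exercise phase as a half-open 0-based frame range.
#' @param frame_rate Frames per second (> 0).
#' @return Data frame with columns `start` (inclusive) and `end` (exclusive),
#'   0-based frame indices tiling `[start, end)` without overlap.
#' @export
blockize <- function(start, end, frame_rate) {
  if (frame_rate <= 0) stop("frame_rate must be > 0")
  n <- end - start
  if (n <= 0) stop("empty exercise phase")
  L <- max(1L, round(frame_rate))
  if (n <= L) return(data.frame(start = start, end = end))
  k <- n %/% L
  r <- n %% L
  ends <- start + seq_len(k) * L
  if (r > 0) {
    if (2 * r > L) ends <- c(ends, start + n)   # keep the partial block
    else ends[k] <- start + n                   # merge into the previous one
  }
  data.frame(start = c(start, ends[-length(ends)]), end = ends)
}

#' Assess a single measurement block against the first resting period
#'
#' Applies the same displacement + overlap + OR-threshold rule as
#' [classify_contraction()], with the exercise distributions replaced by the
#' block's samples and the resting reference restricted to rest1.
#'
#' @param block_th,block_com Thickness and center-of-mass samples of the
#'   block (missing values allowed).
#' @param rest_th,rest_com Non-empty reference samples from the first resting
#'   period.
#' @param params A [classifier_params()].
#' @return `"contracted"`, `"relaxed"`, or `"no-data"` if the block holds no
#'   usable measurement.
#' @export
assess_block <- function(block_th, block_com, rest_th, rest_com,
                         params = classifier_params()) {
  block_th <- block_th[!is.na(block_th)]
  block_com <- block_com[!is.na(block_com)]
  if (!length(block_th) || !length(block_com)) return("no-data")
  rest_th <- rest_th[!is.na(rest_th)]
  rest_com <- rest_com[!is.na(rest_com)]
  if (!length(rest_th) || !length(rest_com)) stop("empty rest1 reference")
  overlap_decision(rest_th, block_th, rest_com, block_com, params)$label
}

#' Simulated real-time contraction assessment
#'
#' Classifies each muscle once per (approximately) one-second block of the
#' exercise phase, using only the first resting period as reference --
#' mimicking an online setting where the second rest has not yet happened --
#' and scores the per-block labels against the retrospective reference label.
#' Blocks without usable data are labelled `"no-data"` and excluded from the
#' denominator of `fraction_correct`.
#'
#' @param series A `measurement_series` from [extract_series()].
#' @param params A [classifier_params()].
#' @param reference_labels Named character vector (per muscle) of
#'   retrospective labels, e.g. from [classify_contraction()].
#' @param frame_rate Frames per second; defaults to the series attribute.
#' @return A `realtime_assessment`: list with one element per muscle, each a
#'   list with `reference`, `blocks` (data frame `start`, `end`, `label`,
#'   `frames_used`) and `fraction_correct`.
#' @export
run_realtime <- function(series, params = classifier_params(),
                         reference_labels,
                         frame_rate = attr(series, "frame_rate")) {
  if (is.null(frame_rate)) stop("frame_rate is required")
  ex_frames <- sort(unique(series$frame[series$phase == "exercise"]))
  if (!length(ex_frames)) stop("empty exercise phase")
  blocks <- blockize(min(ex_frames), max(ex_frames) + 1L, frame_rate)
  muscles <- intersect(names(muscle_labels()), unique(series$muscle))
  out <- lapply(muscles, function(m) {
    s <- series[series$muscle == m, , drop = FALSE]
    r1 <- s[s$phase == "rest1", , drop = FALSE]
    rest_th <- r1$thickness_px[!is.na(r1$thickness_px)]
    rest_com <- r1$com_px[!is.na(r1$com_px)]
    if (!length(rest_th) || !length(rest_com))
      stop("phase without measurements: rest1 for muscle ", m)
    lab <- character(nrow(blocks))
    used <- integer(nrow(blocks))
    for (b in seq_len(nrow(blocks))) {
      inb <- s$frame >= blocks$start[b] & s$frame < blocks$end[b]
      lab[b] <- assess_block(s$thickness_px[inb], s$com_px[inb],
                             rest_th, rest_com, params)
      used[b] <- sum(inb & !is.na(s$thickness_px) & !is.na(s$com_px))
    }
    scored <- lab != "no-data"
    list(reference = unname(reference_labels[m]),
         blocks = data.frame(start = blocks$start, end = blocks$end,
                             label = lab, frames_used = used,
                             stringsAsFactors = FALSE),
         fraction_correct = if (any(scored))
           mean(lab[scored] == reference_labels[m]) else NA_real_)
  })
  names(out) <- muscles
  structure(out, frame_rate = frame_rate, class = "realtime_assessment")
}

#' @export
print.realtime_assessment <- function(x, ...) {
  cat("Real-time contraction assessment (1-second blocks, rest1 reference)\n")
  for (m in names(x)) {
    cat(sprintf("  %-4s reference %-10s  correct blocks: %s\n", m,
                x[[m]]$reference,
                ifelse(is.na(x[[m]]$fraction_correct), "n/a",
                       sprintf("%.0f%%", 100 * x[[m]]$fraction_correct))))
  }
  invisible(x)
}
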