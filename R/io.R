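#' Read and write video and mask stacks as multi-page TIFF
#'
#' Videos are stored as 8-bit grayscale multi-page TIFF; since the phantom
#' generator already quantizes to 8-bit levels, write-then-read reproduces
#' the array bit-exactly. Masks are stored as 8-bit label TIFF with values
#' 0 (background), 1 (OE), 2 (OI), 3 (TrA); any other label is an error.
#'
#' @param x Numeric array `height x width x n_frames` (video, values in
#'   `[0,1]`) or integer label array (masks).
#' @param path File path.
#' @return `read_*` return the array; `write_*` return `path` invisibly.
#' @name stack_io
NULL

#' @rdname stack_io
#' @export
write_video_stack <- function(x, path) {
  stopifnot(length(dim(x)) == 3)
  pages <- lapply(seq_len(dim(x)[3]), function(t) round(255 * x[, , t]) / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname stack_io
#' @export
read_video_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
}

#' @rdname stack_io
#' @export
write_mask_stack <- function(x, path) {
  stopifnot(length(dim(x)) == 3)
  if (!all(x %in% 0:3)) stop("unknown label value: masks must contain only 0-3")
  pages <- lapply(seq_len(dim(x)[3]), function(t) x[, , t] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname stack_io
#' @export
read_mask_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  m <- array(as.integer(round(255 * unlist(pages))),
             dim = c(dim(pages[[1]]), length(pages)))
  if (!all(m %in% 0:3)) stop("unknown label value: masks must contain only 0-3")
  m
}

#' Read and write measurement series as CSV
#'
#' Columns `frame`, `phase`, `muscle`, `thickness_px`, `com_px`; missing
#' measurements are empty cells and survive a round-trip.
#'
#' @param series A `measurement_series` from [extract_series()].
#' @param path File path.
#' @param frame_rate,image_width Metadata restored onto the series attributes
#'   when reading (optional).
#' @return `read_measurements` returns a `measurement_series`;
#'   `write_measurements` returns `path` invisibly.
#' @name measurement_io
NULL

#' @rdname measurement_io
#' @export
write_measurements <- function(series, path) {
  utils::write.csv(as.data.frame(series)[, c("frame", "phase", "muscle",
                                             "thickness_px", "com_px")],
                   path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname measurement_io
#' @export
read_measurements <- function(path, frame_rate = NULL, image_width = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(frame = "integer", phase = "character",
                                       muscle = "character",
                                       thickness_px = "numeric",
                                       com_px = "numeric"))
  structure(df, frame_rate = frame_rate, image_width = image_width,
            class = c("measurement_series", "data.frame"))
}

#' Read and write classifier parameters as JSON
#'
#' @param params A [classifier_params()] object.
#' @param path File path.
#' @return `read_params` returns a [classifier_params()]; `write_params`
#'   returns `path` invisibly.
#' @name params_io
NULL

#' @rdname params_io
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "classifier_params"))
  jsonlite::write_json(list(t_th = params$t_th, t_com = params$t_com,
                            d_th = params$d_th, d_com = params$d_com,
                            positions = as.numeric(params$positions)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname params_io
#' @export
read_params <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  classifier_params(p$t_th, p$t_com, p$d_th, p$d_com,
                    if (!is.null(p$positions)) p$positions
                    else measurement_positions())
}

#' Read and write a phase schedule as JSON
#'
#' Phases are stored as 0-based half-open frame ranges together with the
#' frame rate.
#'
#' @param phases A [phase_schedule()].
#' @param path File path.
#' @return `read_phases` returns a `phase_schedule`; `write_phases` returns
#'   `path` invisibly.
#' @name phases_io
NULL

#' @rdname phases_io
#' @export
write_phases <- function(phases, path) {
  jsonlite::write_json(list(
    frame_rate = attr(phases, "frame_rate"),
    n_frames = attr(phases, "n_frames"),
    phases = stats::setNames(lapply(seq_len(nrow(phases)), function(i)
      c(phases$start[i], phases$end[i])), phases$phase)
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname phases_io
#' @export
read_phases <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$phases) || is.null(p$frame_rate))
    stop("missing phase metadata")
  ph <- p$phases
  out <- data.frame(phase = names(ph),
                    start = vapply(ph, `[`, numeric(1), 1),
                    end = vapply(ph, `[`, numeric(1), 2),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, n_frames = as.integer(max(out$end)),
            frame_rate = p$frame_rate,
            class = c("phase_schedule", "data.frame"))
}

#' Write a simulated phantom to a directory
#'
#' Writes `video.tif` (8-bit grayscale), `masks.tif` (8-bit labels),
#' `phases.json` and `truth.json` (ground-truth contraction labels and the
#' generating configuration).
#'
#' @param sim A `phantom_sim` from [simulate_sequence()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(sim, dir) {
  stopifnot(inherits(sim, "phantom_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_video_stack(sim$video, file.path(dir, "video.tif"))
  write_mask_stack(sim$masks, file.path(dir, "masks.tif"))
  write_phases(sim$truth$phases, file.path(dir, "phases.json"))
  cfg <- sim$truth$config
  cfg$.geometry <- NULL
  jsonlite::write_json(list(contracted = as.list(sim$truth$contracted),
                            config = unclass(cfg)),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
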