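#' Configuration of the synthetic ultrasound phantom
#'
#' Builds a validated configuration for [simulate_sequence()]. The phantom
#' emulates a transverse ultrasound view of the three stacked lateral
#' abdominal muscles (OE above OI above TrA) during a rest--exercise--rest
#' protocol: an initial resting phase, an exercise phase during which
#' contracted muscles thicken and shift laterally, and a second rest.
#' Muscles are rendered as horizontal bands (rows = axial depth, columns =
#' lateral position) with undulating fascia interfaces, tissue texture that
#' moves with the muscle, and multiplicative speckle noise.
#'
#' @param image_height,image_width Frame size in pixels.
#' @param frame_rate Frames per second (> 0).
#' @param rest1_s,exercise_s,rest2_s Phase durations in seconds (>= 0).
#' @param rest_thickness Named numeric vector (OE, OI, TrA): resting muscle
#'   thickness in pixels (>= 1).
#' @param thickening_factor Named numeric vector: multiplicative thickness
#'   change at full contraction (1 = no thickening). Values strictly between
#'   1 and 1.1 are rejected as ambiguous (see Details).
#' @param lateral_shift Named numeric vector: lateral translation in pixels at
#'   full contraction; negative = towards the left image border. Non-zero
#'   magnitudes below 3 px are rejected as ambiguous.
#' @param transition_s Duration in seconds of the raised-cosine ramp between
#'   rest and full contraction. Both ramps lie inside the exercise phase, so
#'   rest frames are geometrically identical across the two resting phases.
#' @param speckle_sigma Amplitude of multiplicative speckle noise in `[0, 1]`;
#'   each pixel becomes `clean * (1 + speckle_sigma * g)` with standard normal
#'   `g`, clipped to `[0, 1]`.
#' @param drift_px Global lateral transducer drift in pixels (0 = off). All
#'   muscles (and the tissue texture) shift by this amount, ramped in over
#'   `transition_s` starting at `drift_onset_s`. Emulates probe slippage.
#' @param drift_onset_s Onset of the drift, in seconds from video start.
#' @param interface_undulation_px Amplitude in pixels of the low-frequency
#'   sinusoidal undulation of the muscle interfaces.
#' @param seed Integer seed; identical seeds give bit-identical output.
#'
#' @details
#' Ground-truth contraction labels are defined from the configured dynamics:
#' a muscle is *contracted* iff `thickening_factor >= 1.1` or
#' `|lateral_shift| >= 3` px. Configurations with non-zero dynamics below
#' these guards are rejected so that recovery tests have unambiguous truth.
#'
#' @return An object of class `phantom_config`.
#' @seealso [simulate_sequence()], [phase_schedule()]
#' @export
phantom_config <- function(image_height = 128L, image_width = 160L,
                           frame_rate = 20,
                           rest1_s = 10, exercise_s = 10, rest2_s = 4,
                           rest_thickness = c(OE = 18, OI = 22, TrA = 12),
                           thickening_factor = c(OE = 1, OI = 1, TrA = 1),
                           lateral_shift = c(OE = 0, OI = 0, TrA = 0),
                           transition_s = 0.5,
                           speckle_sigma = 0.05,
                           drift_px = 0, drift_onset_s = 0,
                           interface_undulation_px = 2,
                           seed = 1L) {
  mus <- names(muscle_labels())
  fix_names <- function(x, what) {
    if (length(x) == 1L) x <- rep(x, 3L)
    if (length(x) != 3L) stop(what, " must have length 3 (OE, OI, TrA)")
    if (is.null(names(x))) names(x) <- mus
    x <- x[mus]
    if (anyNA(x)) stop(what, " must be named OE, OI, TrA")
    x
  }
  rest_thickness <- fix_names(rest_thickness, "rest_thickness")
  thickening_factor <- fix_names(thickening_factor, "thickening_factor")
  lateral_shift <- fix_names(lateral_shift, "lateral_shift")

  if (frame_rate <= 0) stop("frame_rate must be > 0")
  if (any(c(rest1_s, exercise_s, rest2_s) < 0)) stop("durations must be >= 0")
  if (any(rest_thickness < 1)) stop("rest_thickness must be >= 1 px")
  if (any(thickening_factor < 0)) stop("thickening_factor must be >= 0")
  if (speckle_sigma < 0 || speckle_sigma > 1) stop("speckle_sigma must be in [0, 1]")
  if (interface_undulation_px < 0) stop("interface_undulation_px must be >= 0")
  if (transition_s < 0) stop("transition_s must be >= 0")

  amb_f <- thickening_factor > 1 & thickening_factor < 1.1
  amb_s <- abs(lateral_shift) > 0 & abs(lateral_shift) < 3
  if (any(amb_f | amb_s))
    stop("ambiguous contraction effect: thickening_factor in (1, 1.1) or ",
         "0 < |lateral_shift| < 3 px gives no unambiguous ground-truth label")

  cfg <- structure(list(
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    frame_rate = frame_rate,
    rest1_s = rest1_s, exercise_s = exercise_s, rest2_s = rest2_s,
    rest_thickness = rest_thickness,
    thickening_factor = thickening_factor,
    lateral_shift = lateral_shift,
    transition_s = transition_s,
    speckle_sigma = speckle_sigma,
    drift_px = drift_px, drift_onset_s = drift_onset_s,
    interface_undulation_px = interface_undulation_px,
    seed = as.integer(seed)
  ), class = "phantom_config")

  geo <- phantom_geometry(cfg)   # validates band placement, errors on overflow
  cfg$.geometry <- geo
  cfg
}

# Static band layout: centers of the three bands, checked against maximal
# contraction so that bands can never collide or leave the image.
phantom_geometry <- function(cfg) {
  h <- cfg$rest_thickness
  gap <- 16       # resting background gap between adjacent bands (px)
  top_margin <- 12
  centers <- numeric(3)
  centers[1] <- top_margin + h[1] / 2
  centers[2] <- centers[1] + h[1] / 2 + gap + h[2] / 2
  centers[3] <- centers[2] + h[2] / 2 + gap + h[3] / 2
  amp <- cfg$interface_undulation_px
  hmax <- h * pmax(cfg$thickening_factor, 1)
  # worst-case extents at full contraction, including undulation + fascia rows
  tops <- centers - hmax / 2 - amp - 2
  bottoms <- centers + hmax / 2 + amp + 2
  if (bottoms[1] > tops[2] || bottoms[2] > tops[3])
    stop("geometry overflow: muscle bands would overlap at full contraction")
  if (tops[1] < 5 || bottoms[3] > cfg$image_height - 4)
    stop("geometry overflow: muscle bands do not fit within image_height")
  list(centers = centers, lat_margin = 10,
       und_cycles = c(1.5, 2.0, 2.5), und_phase = c(0, 1.3, 2.6))
}

#' Frame schedule of the rest--exercise--rest protocol
#'
#' Converts the configured phase durations into three contiguous half-open
#' frame ranges. Boundaries are `round(frame_rate * cumulative seconds)` with
#' banker's rounding (round-half-even); frame indices are 0-based.
#'
#' @param config A [phantom_config()].
#' @return A `phase_schedule`: data frame with columns `phase`
#'   (rest1/exercise/rest2), `start` (inclusive) and `end` (exclusive), plus
#'   attributes `n_frames` and `frame_rate`.
#' @export
phase_schedule <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  b <- round(config$frame_rate *
               cumsum(c(config$rest1_s, config$exercise_s, config$rest2_s)))
  if (b[3] == 0) stop("empty schedule: video has zero frames")
  out <- data.frame(
    phase = c("rest1", "exercise", "rest2"),
    start = c(0, b[1], b[2]),
    end = b,
    stringsAsFactors = FALSE
  )
  structure(out, n_frames = as.integer(b[3]), frame_rate = config$frame_rate,
            class = c("phase_schedule", "data.frame"))
}

#' Per-frame phase labels
#'
#' @param phases A [phase_schedule()].
#' @return Character vector of length `n_frames` with values
#'   rest1/exercise/rest2; element `i` describes 0-based frame `i - 1`.
#' @export
frame_phases <- function(phases) {
  n <- attr(phases, "n_frames")
  out <- character(n)
  for (i in seq_len(nrow(phases))) {
    idx <- seq.int(phases$start[i], length.out = phases$end[i] - phases$start[i])
    out[idx + 1L] <- phases$phase[i]
  }
  out
}

# Activation level in [0,1] for a vector of frame times (seconds): 0 at rest,
# raised-cosine ramps of length transition_s just inside the exercise phase.
phantom_activation <- function(times, cfg) {
  t_on <- cfg$rest1_s
  t_off <- cfg$rest1_s + cfg$exercise_s
  tr <- min(cfg$transition_s, cfg$exercise_s / 2)
  a <- numeric(length(times))
  inside <- times >= t_on & times < t_off
  a[inside] <- 1
  if (tr > 0) {
    up <- inside & times < t_on + tr
    a[up] <- 0.5 * (1 - cos(pi * (times[up] - t_on) / tr))
    dn <- inside & times >= t_off - tr
    a[dn] <- 0.5 * (1 - cos(pi * (t_off - times[dn]) / tr))
  }
  a
}

# Transducer drift in px for a vector of frame times.
phantom_drift <- function(times, cfg) {
  if (cfg$drift_px == 0) return(numeric(length(times)))
  tr <- max(cfg$transition_s, 1e-9)
  s <- clamp((times - cfg$drift_onset_s) / tr, 0, 1)
  cfg$drift_px * 0.5 * (1 - cos(pi * s))
}

#' Simulate a synthetic ultrasound sequence with ground truth
#'
#' Renders the phantom video (grayscale, values in `[0, 1]` quantized to
#' 8-bit levels), the noise-free label masks (0 = background, 1 = OE,
#' 2 = OI, 3 = TrA) and the ground-truth contraction labels. Identical seeds
#' give bit-identical output.
#'
#' @param config A [phantom_config()].
#' @return An object of class `phantom_sim`: list with elements
#'   \describe{
#'     \item{video}{numeric array `height x width x n_frames` in `[0, 1]`}
#'     \item{masks}{integer array of the same shape with labels 0--3
#'       (the noise-free clean masks)}
#'     \item{truth}{list: `contracted` (named logical per muscle),
#'       `phases` (the [phase_schedule()]), `config`}
#'   }
#' @export
simulate_sequence <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  cfg <- config
  geo <- cfg$.geometry
  phases <- phase_schedule(cfg)
  n <- attr(phases, "n_frames")
  H <- cfg$image_height; W <- cfg$image_width
  mus <- names(muscle_labels())
  h_rest <- cfg$rest_thickness

  contracted <- cfg$thickening_factor >= 1.1 | abs(cfg$lateral_shift) >= 3
  names(contracted) <- mus

  times <- (seq_len(n) - 1L) / cfg$frame_rate
  act <- phantom_activation(times, cfg)
  drift <- phantom_drift(times, cfg)

  with_seed(cfg$seed, {
    # tissue textures, attached to muscle-local coordinates so that they
    # translate and stretch with the band (gives optical flow something to track)
    band_w <- ceiling(W - 2 * geo$lat_margin) + 2L
    tex <- lapply(seq_len(3), function(m) {
      t0 <- matrix(stats::rnorm(ceiling(h_rest[m]) * band_w),
                   ceiling(h_rest[m]), band_w)
      t0 <- as.matrix(EBImage::gblur(t0, sigma = 1.2))
      0.13 * t0 / stats::sd(t0)
    })
    bg0 <- matrix(stats::rnorm(H * W), H, W)
    bg_tex <- 0.08 * as.matrix(EBImage::gblur(bg0, sigma = 1.5)) /
      stats::sd(as.matrix(EBImage::gblur(bg0, sigma = 1.5)))
    speckle <- if (cfg$speckle_sigma > 0) stats::rnorm(H * W * n) else NULL

    base_int <- c(0.35, 0.50, 0.42)  # mean echogenicity per muscle
    video <- array(0, dim = c(H, W, n))
    masks <- array(0L, dim = c(H, W, n))
    R0 <- matrix(seq_len(H) - 1, H, W)          # 0-based row coordinate
    c0 <- seq_len(W) - 1                        # 0-based column coordinate

    for (t in seq_len(n)) {
      a <- act[t]
      frame <- matrix(0.12, H, W) +
        matrix(bilinear_sample(bg_tex, rep(c0 - drift[t], each = H),
                               rep(seq_len(H) - 1, W)), H, W)
      frame[3:4, ] <- 0.9   # skin line
      mask <- matrix(0L, H, W)
      for (m in seq_len(3)) {
        h_t <- h_rest[m] * (1 + a * (cfg$thickening_factor[m] - 1))
        s_t <- a * cfg$lateral_shift[m] + drift[t]
        c_rest <- c0 - s_t   # lateral coordinate in the muscle's rest frame
        und <- cfg$interface_undulation_px *
          sin(2 * pi * geo$und_cycles[m] * c_rest / W + geo$und_phase[m])
        top <- geo$centers[m] - h_t / 2 + und
        in_lat <- c_rest >= geo$lat_margin & c_rest < (W - geo$lat_margin)
        top_m <- matrix(rep(top, each = H), H, W)
        lat_m <- matrix(rep(in_lat, each = H), H, W)
        band <- lat_m & R0 >= top_m & R0 < (top_m + h_t)
        mask[band] <- m
        # texture sampled in band-local coordinates
        idx <- which(band)
        if (length(idx)) {
          r_i <- (idx - 1) %% H
          col_i <- (idx - 1) %/% H + 1
          v <- (r_i - top[col_i]) / h_t
          tx <- (c_rest[col_i] - geo$lat_margin) / (W - 2 * geo$lat_margin) *
            (ncol(tex[[m]]) - 1)
          ty <- v * (nrow(tex[[m]]) - 1)
          frame[idx] <- base_int[m] + bilinear_sample(tex[[m]], tx, ty)
        }
        # bright fascia lines hugging the band interfaces
        fas <- lat_m & ((R0 >= top_m - 2 & R0 < top_m) |
                          (R0 >= top_m + h_t & R0 < top_m + h_t + 2))
        frame[fas] <- pmax(frame[fas], 0.88)
      }
      if (!is.null(speckle)) {
        g <- speckle[((t - 1) * H * W + 1):(t * H * W)]
        frame <- frame * (1 + cfg$speckle_sigma * g)
      }
      video[, , t] <- round(255 * clamp(frame, 0, 1)) / 255
      masks[, , t] <- mask
    }
  })

  structure(list(
    video = video,
    masks = masks,
    truth = list(contracted = contracted, phases = phases, config = cfg)
  ), class = "phantom_sim")
}

#' @export
print.phantom_sim <- function(x, ...) {
  d <- dim(x$video)
  cat("Synthetic ultrasound phantom\n")
  cat(sprintf("  frames: %d (%g fps), size %d x %d px\n",
              d[3], x$truth$config$frame_rate, d[1], d[2]))
  cat(sprintf("  contracted: %s\n",
              paste(names(which(x$truth$contracted)), collapse = ", ")))
  invisible(x)
}

#' Simulate a labelled cohort of phantom videos
#'
#' Generates `n_videos` phantoms (three muscles each) in which exactly half of
#' the muscles are contracted: half of those thicken by a factor drawn
#' uniformly from `[1.2, 1.6]`, the other half shift left by 3--8 px; relaxed
#' muscles have no dynamics. Assignment of effects to muscles is shuffled
#' deterministically from `seed`; video `v` uses phantom seed
#' `seed * 1000 + v`.
#'
#' @param n_videos Number of phantom videos (3 muscles each).
#' @param seed Integer seed controlling effect assignment and speckle.
#' @param config Named list of [phantom_config()] arguments shared by all
#'   videos (sizes, durations, noise); effect sizes and seeds are filled in
#'   per video.
#' @return List with `sims` (list of `phantom_sim`) and `labels` (data frame
#'   `video`, `muscle`, `contracted`).
#' @export
phantom_cohort <- function(n_videos = 10L, seed = 1L,
                           config = list(image_height = 96L, image_width = 128L,
                                         frame_rate = 10,
                                         rest1_s = 4, exercise_s = 4, rest2_s = 2,
                                         rest_thickness = c(OE = 12, OI = 14, TrA = 9),
                                         speckle_sigma = 0.05)) {
  n_mus <- 3L * n_videos
  assign <- with_seed(seed, {
    contracted <- sample(rep(c(TRUE, FALSE), length.out = n_mus))
    thick_mode <- sample(rep(c(TRUE, FALSE), length.out = sum(contracted)))
    factors <- rep(1, n_mus); shifts <- rep(0, n_mus)
    idx <- which(contracted)
    factors[idx[thick_mode]] <- stats::runif(sum(thick_mode), 1.2, 1.6)
    shifts[idx[!thick_mode]] <- stats::runif(sum(!thick_mode), -8, -3)
    list(contracted = contracted, factors = factors, shifts = shifts)
  })
  mus <- names(muscle_labels())
  sims <- lapply(seq_len(n_videos), function(v) {
    i <- (v - 1L) * 3L + 1:3
    cfg <- do.call(phantom_config, c(config, list(
      thickening_factor = stats::setNames(assign$factors[i], mus),
      lateral_shift = stats::setNames(assign$shifts[i], mus),
      seed = seed * 1000L + v)))
    simulate_sequence(cfg)
  })
  list(sims = sims,
       labels = data.frame(video = rep(seq_len(n_videos), each = 3L),
                           muscle = rep(mus, n_videos),
                           contracted = assign$contracted,
                           stringsAsFactors = FALSE))
}
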