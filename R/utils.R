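#' Muscle label encoding
#'
#' The three lateral abdominal muscles are encoded in label masks as
#' OE (obliquus externus) = 1, OI (obliquus internus) = 2 and
#' TrA (transversus abdominis) = 3; 0 is background.
#'
#' @return Named integer vector mapping muscle name to mask label.
#' @export
muscle_labels <- function() c(OE = 1L, OI = 2L, TrA = 3L)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Bilinear sampling of a matrix at fractional 0-based coordinates.
# x: column coordinate, y: row coordinate (vectors of equal length).
# outside = "clamp" replicates border pixels, "zero" returns 0 for samples
# whose 0-based coordinates fall outside [0, dim - 1].
# Requires at least a 2 x 2 image (clamping keeps x0+1, y0+1 in range).
bilinear_sample <- function(img, x, y, outside = "clamp") {
  h <- nrow(img); w <- ncol(img)
  if (outside == "zero") {
    inside <- x >= 0 & x <= (w - 1) & y >= 0 & y <= (h - 1)
  }
  x <- pmin(pmax(x, 0), w - 1 - 1e-7)
  y <- pmin(pmax(y, 0), h - 1 - 1e-7)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  i00 <- y0 + 1 + x0 * h   # column-major linear index (1-based)
  v <- img[i00] * (1 - fx) * (1 - fy) + img[i00 + 1] * (1 - fx) * fy +
    img[i00 + h] * fx * (1 - fy) + img[i00 + h + 1] * fx * fy
  if (outside == "zero") v[!inside] <- 0
  v
}

# Mean-pool an image by a factor of two (used for optical-flow pyramids).
pyr_down <- function(img) {
  h <- 2L * (nrow(img) %/% 2L)
  w <- 2L * (ncol(img) %/% 2L)
  img <- img[seq_len(h), seq_len(w), drop = FALSE]
  0.25 * (img[seq(1, h, 2), seq(1, w, 2)] + img[seq(2, h, 2), seq(1, w, 2)] +
            img[seq(1, h, 2), seq(2, w, 2)] + img[seq(2, h, 2), seq(2, w, 2)])
}
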