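# Independent oracle for the overlap statistic: percentiles recomputed by hand
# from sorted order statistics, and a full scan over every integer alpha.
manual_percentile <- function(x, q) {
  x <- sort(x)
  h <- (length(x) - 1) * q / 100
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo + 1] + (h - lo) * (x[hi + 1] - x[lo + 1])
}

overlap_oracle <- function(a, b) {
  for (alpha in 0:100) {
    if (manual_percentile(a, alpha) >= manual_percentile(b, 100 - alpha))
      return(100 - alpha)
  }
  0
}

# random sample from a mix of distribution families, for property tests
random_sample <- function(n) {
  switch(sample(4, 1),
         rnorm(n, runif(1, -5, 5), runif(1, 0.1, 3)),
         runif(n, -10, 10),
         rexp(n, runif(1, 0.2, 2)),
         sample(-5:15, n, replace = TRUE))   # ties and integers
}
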