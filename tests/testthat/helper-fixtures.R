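# Shared fixtures: small phantom configurations and an independent
# triple-loop LRN oracle used by several test files.

noiseless_config <- function(seed = 1L, image_size = 96L) {
  phantom_config(image_size = image_size,
                 liver_intensity_mean = 1, liver_intensity_sd = 0,
                 confounder_count = 0L, lesion_probability = 0,
                 noise_sd = 0, background_intensity_mean = 0, seed = seed)
}

# Brute-force LRN: explicit loops over x, y and the channel window.
lrn_oracle <- function(a, k, alpha, beta, n) {
  d <- dim(a)
  out <- array(NA_real_, d)
  half <- n %/% 2
  for (x in seq_len(d[1]))
    for (y in seq_len(d[2]))
      for (i in seq_len(d[3])) {
        lo <- max(1, i - half); hi <- min(d[3], i + half)
        s <- 0
        for (j in lo:hi) s <- s + a[x, y, j]^2
        out[x, y, i] <- a[x, y, i] / (k + alpha * s)^beta
      }
  out
}

# Dice between two binary matrices/arrays.
dice_of <- function(a, b) {
  2 * sum(a == 1 & b == 1) / (2 * sum(a == 1 & b == 1) +
                              sum(a == 1 & b == 0) + sum(a == 0 & b == 1))
}
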