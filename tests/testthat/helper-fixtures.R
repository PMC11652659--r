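# shared fixtures built in code

printed_prep_ms <- c(0, 22.98, 46.66, 70.34, Inf)

# noiseless forward-model series at the printed preparation set
forward_series <- function(a = 0.8, b = 0.2, traff2 = 80,
                           prep = printed_prep_ms) {
  e <- exp(-prep / traff2)
  e[is.infinite(prep)] <- 0
  weighted_series(a * e + b, prep)
}

# replicate a single-voxel signal into an image grid with Gaussian noise
noisy_voxel_grid <- function(signal, prep, n, sigma, seed) {
  set.seed(seed)
  side <- ceiling(sqrt(n))
  arr <- array(rep(signal, each = side^2), c(side, side, length(prep)))
  arr <- arr + stats::rnorm(length(arr), 0, sigma)
  weighted_series(arr, prep)
}
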