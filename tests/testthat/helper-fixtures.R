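# Shared fixtures: all synthetic, built in code at test time.

# A render spec over the standard 19 x 19 array; noiseless by default so
# recovery checks are exact up to 8-bit quantization.
quiet_spec <- function(noise_sd = 0, seed = 11L, ...) {
  render_spec(noise_sd = noise_sd, seed = seed, ...)
}

# Reference disk with unit parameters: disk_intensity(R, .) = pi * log(2).
unit_disk <- function(alpha = 0) emitter_disk(R = 1, sigma = 1, I0 = 1,
                                              r0 = 1, alpha = alpha)

# Tiny hand-built RGB image (integer array) for channel-extraction tests.
rgb_image <- function(r, g, b) {
  stopifnot(all(dim(r) == dim(g)), all(dim(g) == dim(b)))
  px <- array(0L, dim = c(dim(g), 3L))
  px[, , 1] <- r; px[, , 2] <- g; px[, , 3] <- b
  px
}
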