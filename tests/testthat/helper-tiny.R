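# small configurations shared across tests: 16-px inputs, 2..32 filters,
# cheap enough to build and run everywhere
tiny_config <- function(variant = "tmdunet", ...) {
  network_config(variant, input_size = 16L, input_channels = 1L,
                 base_filters = 2L, node_filters = c(2L, 4L, 8L, 16L, 32L),
                 ...)
}

rand_image <- function(size = 16L, channels = 1L, seed = 1L) {
  set.seed(seed)
  if (channels == 1L) array(runif(size * size), c(size, size, 1L))
  else array(runif(size * size * channels), c(size, size, channels))
}

rand_mask <- function(size = 16L, p = 0.3, seed = 1L) {
  set.seed(seed)
  matrix(rbinom(size * size, 1L, p), size, size)
}
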