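# Small phantom builders shared across tests; reduced grids keep the
# default suite fast while preserving the geometry of the full-size
# phantom (same spacing, radii and segment proportions).

small_spec <- function(plaques = list(), noise_sigma = 0, seed = 1L, ...) {
  phantom_spec(shape = c(40, 40, 48), spacing = c(1.5, 1.5, 1),
               z_ima = 6, z_bif = 42, plaques = plaques,
               noise_sigma = noise_sigma, seed = seed, ...)
}

# A plaque covering a given fraction of the small spec's segment.
frac_plaque <- function(wall, fraction, z_ima = 6, z_bif = 42) {
  L <- z_bif - z_ima
  plaque_spec(wall, c(z_ima, z_ima + fraction * L))
}
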