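# Shared fixtures: everything is generated in code at test time.

# Small phantom spec for fast unit tests (24^3 at 2 mm).
tiny_spec <- function(...) {
  phantom_spec(shape = c(24L, 24L, 24L), cavity_radius_mm = c(6, 9), ...)
}

# Noise-free variant: piecewise-constant tissues, exact ellipsoid cavity,
# air and blood always present.
noise_free_spec <- function(shape = c(32L, 32L, 32L), ...) {
  phantom_spec(shape = shape, cavity_radius_mm = c(8, 12), tissue_sd = 0,
               noise_sd = 0, bias_amplitude = 0, cavity_irregularity = 0,
               p_air = 1, p_blood = 1, ...)
}

# Tiny network for smoke tests.
tiny_arch <- function(...) {
  architecture_config(stem_channels = 8L, growth_rate = 2L,
                      units_per_block = 2L, levels = 2L, ...)
}

# Reduced desk-scale architecture used in the phantom experiments.
reduced_arch <- function() {
  architecture_config(stem_channels = 12L, growth_rate = 3L,
                      units_per_block = 2L, levels = 2L)
}

# Binary mask labelmap from an array-like of 0/1.
mk_mask <- function(values, spacing = c(1, 1, 1), affine = NULL) {
  labelmap(array(values * 1, dim = if (is.null(dim(values)))
    c(length(values), 1L, 1L) else dim(values)), spacing, affine)
}

# Random binary 8^3 mask.
random_mask8 <- function(p = 0.5) {
  mk_mask(array(runif(8^3) < p, c(8, 8, 8)))
}

# Build a 4-channel study from one array replicated with channel offsets so
# channels are not identical.
study_from_array <- function(a, spacing = c(1, 1, 1)) {
  a <- as.array(a)
  multimodal_study("toy",
                   image_volume(a, spacing),
                   image_volume(a * 1.5, spacing),
                   image_volume(a + 0 * a, spacing),
                   image_volume(a * 0.5, spacing))
}

# Normalized phantom case pair (study + reference) for trainer tests.
phantom_case <- function(spec, seed) {
  ph <- generate_phantom(spec, seed)
  list(study = zscore_normalize(ph$study)$study, reference = ph$reference,
       raw = ph$study, brain = ph$brain, components = ph$components)
}
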