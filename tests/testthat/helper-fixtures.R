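# shared fixtures for the suite; everything is generated in code

# calibrated T2-channel parameters used throughout the worked examples
fixture_params_t2 <- function() surface_params("T2", Tc = 126.97, rho = 0.00116)
fixture_params_t1 <- function() surface_params("T1", Tc = 870, rho = 0.000087)

# small phantom layout: 11 rectangular ROIs whose gamma radius
# distributions span the corpus-callosum range (~0.55-1.15 um mean) and
# are narrow enough that the first-order surface-relaxation expansion is
# a good approximation, as in the targeted acquisitions
fixture_phantom_specs <- function(n_axons = 2000) {
  means <- seq(0.55, 1.15, length.out = 11)
  specs <- lapply(means, function(mu) {
    list(n = n_axons, family = "gamma", shape = 16, scale = mu / 16)
  })
  names(specs) <- paste0("roi", seq_along(specs))
  specs
}

fixture_phantom_rois <- function() phantom_rois(c(16, 16, 2), 11)
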