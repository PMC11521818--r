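# Shared fixtures: fast coarse-grid generator configs and hand-built toy
# spectra used across test files.

# coarse 3 nm grid keeps spectra generation fast while covering every
# index band region
fast_config <- function(n_samples = 60, seed = 1, noise_sd = 0.005, ...) {
  generator_config(n_samples = n_samples, wavelength_step = 3,
                   noise_sd = noise_sd, seed = seed, ...)
}

# a spectrum holding chosen reflectances at chosen wavelengths, linear
# in between (the grid is exactly the given nodes)
toy_spectrum <- function(wavelengths, reflectance, chlorophyll = NULL,
                         id = "toy") {
  spectrum_record(id, wavelengths, reflectance, chlorophyll)
}

# flat spectrum at a constant reflectance over 400-1000 nm
flat_spectrum <- function(value, id = "flat") {
  toy_spectrum(seq(400, 1000, by = 50), rep(value, 13), id = id)
}

# random piecewise spectrum on a dense grid, reflectance in (lo, hi)
random_spectrum <- function(seed, lo = 0.05, hi = 0.95, id = NULL) {
  set.seed(seed)
  wl <- seq(400, 1000, by = 5)
  k <- stats::spline(seq(400, 1000, length.out = 12),
                     runif(12, lo, hi), xout = wl)$y
  toy_spectrum(wl, pmin(hi, pmax(lo, k)),
               id = if (is.null(id)) paste0("rand", seed) else id)
}
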