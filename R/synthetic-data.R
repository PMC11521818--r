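#' Configuration for the synthetic leaf-spectra generator
#'
#' Defines the study conditions the generator emulates: a 400--1000 nm grid
#' at 0.6 nm resolution, a left-skewed chlorophyll distribution (mean 2479.8,
#' SD 632.5 ug/g, skewness -1, truncated to 321.1--3713.1 ug/g), carotenoid
#' co-variation with chlorophyll, and additive measurement noise.
#'
#' @param n_samples number of leaf samples (>= 1); the emulated field
#'   campaign collected 540.
#' @param wavelength_start,wavelength_stop,wavelength_step grid in nm
#'   (defaults 400, 1000, 0.6).
#' @param chl_mean,chl_sd mean and SD of chlorophyll in ug/g fresh weight.
#' @param chl_skewness target sample skewness (negative = left skew). The
#'   skew-normal family attains |skewness| < 0.9953; targets beyond that are
#'   clamped to the attainable boundary.
#' @param chl_bounds numeric length-2; values are truncated (by rejection)
#'   to this interval.
#' @param carotenoid_ratio_range range of the relative carotenoid level
#'   (dimensionless, controls the blue absorption depth).
#' @param carotenoid_cor correlation between chlorophyll and the carotenoid
#'   level on the latent Gaussian scale.
#' @param noise_sd SD of additive measurement noise, reflectance fraction.
#' @param seed integer RNG seed.
#' @return An object of class \code{generator_config}.
#' @export
generator_config <- function(n_samples = 540,
                             wavelength_start = 400,
                             wavelength_stop = 1000,
                             wavelength_step = 0.6,
                             chl_mean = 2479.8,
                             chl_sd = 632.5,
                             chl_skewness = -1.00,
                             chl_bounds = c(321.1, 3713.1),
                             carotenoid_ratio_range = c(0.2, 0.5),
                             carotenoid_cor = 0.6,
                             noise_sd = 0.005,
                             seed = 1L) {
  if (!is.numeric(n_samples) || n_samples < 1)
    chl_stop("chlorospec_config_error", "n_samples must be >= 1")
  if (wavelength_step <= 0)
    chl_stop("chlorospec_config_error", "wavelength_step must be > 0")
  if (wavelength_stop <= wavelength_start)
    chl_stop("chlorospec_config_error", "wavelength_stop must exceed wavelength_start")
  if (length(chl_bounds) != 2 || chl_bounds[1] >= chl_bounds[2])
    chl_stop("chlorospec_config_error", "chl_bounds must be an increasing pair")
  if (chl_sd <= 0) chl_stop("chlorospec_config_error", "chl_sd must be > 0")
  if (noise_sd < 0) chl_stop("chlorospec_config_error", "noise_sd must be >= 0")
  if (length(carotenoid_ratio_range) != 2 ||
      carotenoid_ratio_range[1] > carotenoid_ratio_range[2])
    chl_stop("chlorospec_config_error", "carotenoid_ratio_range must be ordered")
  if (abs(carotenoid_cor) > 1)
    chl_stop("chlorospec_config_error", "carotenoid_cor must be in [-1, 1]")
  structure(list(n_samples = as.integer(n_samples),
                 wavelength_start = wavelength_start,
                 wavelength_stop = wavelength_stop,
                 wavelength_step = wavelength_step,
                 chl_mean = chl_mean, chl_sd = chl_sd,
                 chl_skewness = chl_skewness, chl_bounds = chl_bounds,
                 carotenoid_ratio_range = carotenoid_ratio_range,
                 carotenoid_cor = carotenoid_cor,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("generator_config:", x$n_samples, "samples,",
      sprintf("%g-%g nm @ %g nm", x$wavelength_start, x$wavelength_stop,
              x$wavelength_step), "\n")
  cat(sprintf("  chlorophyll: mean %g, sd %g, skew %g, bounds [%g, %g] ug/g\n",
              x$chl_mean, x$chl_sd, x$chl_skewness,
              x$chl_bounds[1], x$chl_bounds[2]))
  cat(sprintf("  noise sd %g, seed %d\n", x$noise_sd, x$seed))
  invisible(x)
}

wavelength_grid <- function(config) {
  seq(config$wavelength_start, config$wavelength_stop,
      by = config$wavelength_step)
}

# Skew-normal shape from target skewness via moment inversion.
# gamma1(delta) = (4-pi)/2 * (b*delta)^3 / (1 - b^2 delta^2)^(3/2), b = sqrt(2/pi).
sn_delta_from_skewness <- function(gamma1) {
  if (gamma1 == 0) return(0)
  b <- sqrt(2 / pi)
  g <- abs(gamma1)
  gmax <- (4 - pi) / 2 * b^3 / (1 - b^2)^1.5  # ~0.99527, attainable supremum
  delta_max <- 1 - 1e-6
  if (g >= gmax) return(sign(gamma1) * delta_max)
  f <- function(d) (4 - pi) / 2 * (b * d)^3 / (1 - b^2 * d^2)^1.5 - g
  d <- stats::uniroot(f, c(1e-9, delta_max), tol = 1e-12)$root
  sign(gamma1) * d
}

#' Draw chlorophyll labels from the configured skew-normal
#'
#' Samples chlorophyll contents (ug/g fresh weight) from a skew-normal
#' distribution moment-matched to the configured mean, SD and skewness, and
#' truncated to \code{chl_bounds} by rejection.
#'
#' @param config a [generator_config()].
#' @return Numeric vector of length \code{n_samples}; deterministic for a
#'   fixed seed.
#' @export
#' @examples
#' chl <- sample_chlorophyll(generator_config(n_samples = 10, seed = 7))
sample_chlorophyll <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  delta <- sn_delta_from_skewness(config$chl_skewness)
  b <- sqrt(2 / pi)
  omega <- config$chl_sd / sqrt(1 - b^2 * delta^2)
  xi <- config$chl_mean - omega * b * delta
  lo <- config$chl_bounds[1]; hi <- config$chl_bounds[2]
  n <- config$n_samples
  with_seed(config$seed, {
    out <- numeric(0)
    guard <- 0L
    while (length(out) < n) {
      m <- max(n - length(out), 16L)
      u0 <- abs(rnorm(m)); u1 <- rnorm(m)
      z <- delta * u0 + sqrt(1 - delta^2) * u1
      x <- xi + omega * z
      out <- c(out, x[x >= lo & x <= hi])
      guard <- guard + 1L
      if (guard > 10000L)
        chl_stop("chlorospec_config_error",
                 "chl_bounds reject nearly all draws; check configuration")
    }
    out[seq_len(n)]
  })
}

# Latent carotenoid level correlated with chlorophyll, mapped into the
# configured ratio range via the Gaussian cdf.
sample_carotenoid <- function(chl, config) {
  s <- if (length(chl) > 1) sd(chl) else 0
  z1 <- (chl - mean(chl)) / max(s, 1e-12, na.rm = TRUE)
  rho <- config$carotenoid_cor
  z2 <- rnorm(length(chl))
  zc <- rho * z1 + sqrt(max(0, 1 - rho^2)) * z2
  rng <- config$carotenoid_ratio_range
  rng[1] + (rng[2] - rng[1]) * pnorm(zc)
}

gaussian_band <- function(wl, center, width) exp(-0.5 * ((wl - center) / width)^2)

# Noise-free reflectance model: a NIR plateau with a water feature, a
# visible level set by the green shoulder minus pigment absorption bands
# (chlorophyll near 430 and 670 nm, carotenoid near 470 nm), joined by a
# logistic red edge whose inflection moves to longer wavelengths with
# increasing chlorophyll.
reflectance_shape <- function(wl, chlorophyll, carotenoid) {
  green <- 0.17 + 0.42 * exp(-chlorophyll / 2200)
  red_floor <- 0.04 + 0.38 * exp(-chlorophyll / 900)
  depth_chl <- green - red_floor
  depth_car <- 0.30 * carotenoid
  vis <- green -
    depth_chl * (0.9 * gaussian_band(wl, 430, 16) + gaussian_band(wl, 670, 24)) -
    depth_car * gaussian_band(wl, 470, 16)
  nir <- 0.80 - 0.04 * gaussian_band(wl, 960, 28) - 5e-5 * (wl - 750)
  edge <- 698 + 24 * (1 - exp(-chlorophyll / 1500))
  s <- plogis((wl - edge) / 7)
  vis * (1 - s) + nir * s
}

# Additive measurement noise: white per-band noise plus a smooth
# low-frequency component (random sinusoids), each at noise_sd.
spectrum_noise <- function(wl, noise_sd) {
  if (noise_sd == 0) return(rep(0, length(wl)))
  white <- rnorm(length(wl), sd = noise_sd)
  k <- 4L
  freq <- runif(k, 1 / 400, 1 / 80)   # cycles per nm: periods 80-400 nm
  phase <- runif(k, 0, 2 * pi)
  amp <- rnorm(k)
  smooth <- drop(sin(outer(wl, 2 * pi * freq) + rep(phase, each = length(wl))) %*% amp)
  smooth <- smooth / sqrt(k / 2)      # unit variance, then scale
  white + noise_sd * smooth
}

#' Construct a single leaf spectrum record
#'
#' @param sample_id identifier string.
#' @param wavelengths strictly increasing nm grid.
#' @param reflectance reflectance fractions in \[0, 1\], same length as grid.
#' @param chlorophyll chlorophyll a+b label in ug/g fresh weight, or NULL.
#' @param metadata free-form named list (year, plot, irrigated flag, ...).
#' @return An object of class \code{spectrum_record}.
#' @export
spectrum_record <- function(sample_id, wavelengths, reflectance,
                            chlorophyll = NULL, metadata = list()) {
  wavelengths <- as.numeric(wavelengths)
  reflectance <- as.numeric(reflectance)
  if (length(wavelengths) < 2 || any(diff(wavelengths) <= 0))
    chl_stop("chlorospec_domain_error", "wavelengths must be strictly increasing")
  if (length(reflectance) != length(wavelengths))
    chl_stop("chlorospec_domain_error", "reflectance length must match the grid")
  if (any(!is.finite(reflectance)) || any(reflectance < 0 | reflectance > 1))
    chl_stop("chlorospec_domain_error", "reflectance must lie in [0, 1]")
  if (!is.null(chlorophyll) && (!is.finite(chlorophyll) || chlorophyll < 0))
    chl_stop("chlorospec_domain_error", "chlorophyll must be >= 0 when present")
  structure(list(sample_id = as.character(sample_id),
                 wavelengths = wavelengths, reflectance = reflectance,
                 chlorophyll = chlorophyll, metadata = metadata),
            class = "spectrum_record")
}

#' @export
print.spectrum_record <- function(x, ...) {
  cat(sprintf("spectrum_record '%s': %d bands, %g-%g nm%s\n", x$sample_id,
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              if (is.null(x$chlorophyll)) ""
              else sprintf(", chlorophyll %.1f ug/g", x$chlorophyll)))
  invisible(x)
}

#' Simulate one leaf reflectance spectrum
#'
#' Builds a noise-free reflectance profile from a smooth NIR plateau minus
#' pigment absorption features (chlorophyll bands near 430 and 670 nm, a
#' carotenoid band near 470 nm, a water feature near 960 nm), a green
#' reflectance shoulder near 550 nm whose height decreases with chlorophyll,
#' and a logistic red edge between ~680 and 750 nm whose inflection
#' wavelength increases monotonically with chlorophyll; then adds smooth
#' plus white measurement noise at \code{config$noise_sd} and clips to
#' \[0, 1\].
#'
#' @param chlorophyll chlorophyll content, ug/g fresh weight (>= 0).
#' @param carotenoid relative carotenoid level (dimensionless, ~0.2--0.5).
#' @param config a [generator_config()]; set \code{noise_sd = 0} for the
#'   deterministic noise-free profile.
#' @param seed RNG seed for the noise draw; NULL uses the current stream.
#' @param sample_id identifier for the returned record.
#' @return A [spectrum_record()].
#' @export
#' @examples
#' cfg <- generator_config(noise_sd = 0)
#' sp <- simulate_spectrum(3000, 0.35, cfg)
simulate_spectrum <- function(chlorophyll, carotenoid = 0.35,
                              config = generator_config(), seed = NULL,
                              sample_id = "sim") {
  if (!is.finite(chlorophyll) || chlorophyll < 0)
    chl_stop("chlorospec_domain_error", "chlorophyll must be >= 0")
  wl <- wavelength_grid(config)
  refl <- reflectance_shape(wl, chlorophyll, carotenoid)
  noise <- with_seed(seed, spectrum_noise(wl, config$noise_sd))
  refl <- pmin(1, pmax(0, refl + noise))
  spectrum_record(sample_id, wl, refl, chlorophyll,
                  metadata = list(carotenoid = carotenoid))
}

#' Construct a spectra set from records sharing one grid
#'
#' @param records list of [spectrum_record()] objects with identical
#'   wavelength grids and unique sample ids.
#' @return An object of class \code{spectra_set}.
#' @export
spectra_set <- function(records) {
  if (length(records) < 1)
    chl_stop("chlorospec_domain_error", "spectra_set must be non-empty")
  if (!all(vapply(records, inherits, logical(1), "spectrum_record")))
    chl_stop("chlorospec_input_error", "all records must be spectrum_record objects")
  grid <- records[[1]]$wavelengths
  same <- vapply(records, function(r) identical(r$wavelengths, grid), logical(1))
  if (!all(same))
    chl_stop("chlorospec_domain_error", "all records must share one wavelength grid")
  ids <- vapply(records, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids))
    chl_stop("chlorospec_domain_error", "sample ids must be unique")
  structure(list(records = records, wavelengths = grid),
            class = "spectra_set")
}

#' @export
length.spectra_set <- function(x) length(x$records)

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("spectra_set: %d spectra, %d bands (%g-%g nm)\n",
              length(x$records), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Reflectance matrix of a spectra set
#' @param spectra a [spectra_set()].
#' @return samples x wavelengths matrix with sample ids as row names.
#' @export
reflectance_matrix <- function(spectra) {
  stopifnot(inherits(spectra, "spectra_set"))
  m <- t(vapply(spectra$records, `[[`, numeric(length(spectra$wavelengths)),
                "reflectance"))
  rownames(m) <- vapply(spectra$records, `[[`, character(1), "sample_id")
  colnames(m) <- sprintf("wl_%.1f", spectra$wavelengths)
  m
}

#' Chlorophyll labels of a spectra set
#' @param spectra a [spectra_set()].
#' @return Numeric vector (NA where a record is unlabelled).
#' @export
chlorophyll_labels <- function(spectra) {
  vapply(spectra$records,
         function(r) if (is.null(r$chlorophyll)) NA_real_ else r$chlorophyll,
         numeric(1))
}

#' Generate a full synthetic leaf-spectra dataset
#'
#' Draws chlorophyll labels and correlated carotenoid levels, simulates one
#' spectrum per sample, and assembles a [spectra_set()]. Fully reproducible
#' given \code{config$seed}.
#'
#' @param config a [generator_config()].
#' @return A [spectra_set()] of \code{n_samples} labelled records.
#' @export
#' @examples
#' set <- generate_dataset(generator_config(n_samples = 5, seed = 3))
generate_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  chl <- sample_chlorophyll(config)
  wl <- wavelength_grid(config)
  with_seed(config$seed + 1L, {
    car <- sample_carotenoid(chl, config)
    records <- vector("list", config$n_samples)
    for (i in seq_len(config$n_samples)) {
      refl <- reflectance_shape(wl, chl[i], car[i])
      refl <- pmin(1, pmax(0, refl + spectrum_noise(wl, config$noise_sd)))
      records[[i]] <- spectrum_record(sprintf("S%04d", i), wl, refl, chl[i],
                                      metadata = list(carotenoid = car[i]))
    }
    spectra_set(records)
  })
}

#' Invert the Arnon relation into synthetic absorbances
#'
#' Fixture generator: produces an [absorbance_sample()] whose 644/663 nm
#' absorbances recover the requested chlorophyll when fed back through
#' [arnon_chlorophyll()] (exactly when \code{noise_sd = 0}). The a/b band
#' split uses a fixed 663:644 absorbance ratio of 2.5; A470 is filled in as
#' a plausible carotenoid proxy.
#'
#' @param chlorophyll target chlorophyll a+b, ug/g fresh weight (>= 0).
#' @param V extract volume, ml (> 0).
#' @param w fresh weight, g (> 0).
#' @param noise_sd SD of additive absorbance noise (absorbance units).
#' @param seed RNG seed for the noise draw.
#' @param sample_id identifier.
#' @return An [absorbance_sample()].
#' @export
simulate_absorbance <- function(chlorophyll, V = 10, w = 1, noise_sd = 0,
                                seed = NULL, sample_id = "sim") {
  if (!is.finite(chlorophyll) || chlorophyll < 0)
    chl_stop("chlorospec_domain_error", "chlorophyll must be >= 0")
  if (V <= 0 || w <= 0)
    chl_stop("chlorospec_domain_error", "V and w must be positive")
  total <- chlorophyll * w / V            # = 20.2*A644 + 8.02*A663
  ratio <- 2.5                            # A663 / A644, chlorophyll-a dominant
  A644 <- total / (20.2 + 8.02 * ratio)
  A663 <- ratio * A644
  A470 <- 0.45 * A663
  if (noise_sd > 0) {
    eps <- with_seed(seed, rnorm(3, sd = noise_sd))
    A644 <- max(0, A644 + eps[1])
    A663 <- max(0, A663 + eps[2])
    A470 <- max(0, A470 + eps[3])
  }
  absorbance_sample(A644 = A644, A663 = A663, V = V, w = w, A470 = A470,
                    sample_id = sample_id)
}

#' Write a spectra set to CSV
#'
#' Header: \code{sample_id,chlorophyll,wl_400.0,wl_400.6,...}; reflectance
#' written as fractions with '.' decimal separator.
#'
#' @param spectra a [spectra_set()].
#' @param path destination file.
#' @return \code{path}, invisibly.
#' @export
write_spectra_csv <- function(spectra, path) {
  m <- reflectance_matrix(spectra)
  df <- data.frame(sample_id = rownames(m),
                   chlorophyll = chlorophyll_labels(spectra),
                   m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a spectra set from CSV
#'
#' Inverse of [write_spectra_csv()]; wavelengths are recovered from the
#' \code{wl_*} column names.
#'
#' @param path CSV file written by [write_spectra_csv()] (or matching its
#'   layout).
#' @return A [spectra_set()].
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  wl_cols <- grep("^wl_", names(df), value = TRUE)
  if (length(wl_cols) < 2)
    chl_stop("chlorospec_input_error", "no wl_* reflectance columns found")
  wl <- as.numeric(sub("^wl_", "", wl_cols))
  records <- lapply(seq_len(nrow(df)), function(i) {
    chl <- if ("chlorophyll" %in% names(df) && is.finite(df$chlorophyll[i]))
      df$chlorophyll[i] else NULL
    spectrum_record(df$sample_id[i], wl, as.numeric(df[i, wl_cols]), chl)
  })
  spectra_set(records)
}
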