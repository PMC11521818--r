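# Kaiser-normalized Varimax by iterative pairwise (Jacobi) rotations.
# The closed-form optimal angle is applied to every column pair per sweep
# until all rotation angles fall below eps; this climbs reliably even when
# leading eigenvalues are nearly equal and the rotation start is arbitrary.
varimax_rotate <- function(L, normalize = TRUE, eps = 1e-6, max_sweeps = 500) {
  p <- nrow(L); k <- ncol(L)
  if (k < 2) return(list(loadings = L, rotmat = diag(k)))
  h <- if (normalize) sqrt(pmax(rowSums(L^2), 1e-300)) else rep(1, p)
  A <- L / h
  R <- diag(k)
  for (sweep in seq_len(max_sweeps)) {
    max_phi <- 0
    for (j in seq_len(k - 1)) {
      for (l in (j + 1):k) {
        x <- A[, j]; y <- A[, l]
        u <- x^2 - y^2; v <- 2 * x * y
        num <- sum(2 * u * v) - 2 * sum(u) * sum(v) / p
        den <- sum(u^2 - v^2) - (sum(u)^2 - sum(v)^2) / p
        phi <- atan2(num, den) / 4
        if (abs(phi) > eps) {
          cs <- cos(phi); sn <- sin(phi)
          A[, c(j, l)] <- cbind(x * cs + y * sn, -x * sn + y * cs)
          R[, c(j, l)] <- cbind(R[, j] * cs + R[, l] * sn,
                                -R[, j] * sn + R[, l] * cs)
          max_phi <- max(max_phi, abs(phi))
        }
      }
    }
    if (max_phi < eps) break
  }
  list(loadings = A * h, rotmat = R)
}

#' PCA with Varimax rotation of leaf spectra
#'
#' Standardizes reflectance per wavelength (z-score), runs PCA on the
#' correlation scale, retains components by the Kaiser eigenvalue > 1 rule
#' (or a forced count), and applies a Kaiser-normalized Varimax rotation to
#' the component loadings (eigenvector times singular value, i.e. the
#' wavelength--component correlations). Orthogonal rotation preserves the
#' per-wavelength communalities and the total explained variance.
#'
#' @param reflectance samples x wavelengths matrix (e.g. from
#'   [reflectance_matrix()]), or a [spectra_set()].
#' @param n_components force the retained component count; NULL (default)
#'   applies the Kaiser criterion.
#' @param wavelengths nm grid for the columns; recovered from \code{wl_*}
#'   column names or the spectra set when NULL.
#' @return An object of class \code{loadings_matrix}: list with
#'   \code{wavelengths}, \code{loadings} (wavelengths x components),
#'   \code{explained_variance} (per retained component, after rotation),
#'   \code{eigenvalues}, \code{rotmat}.
#' @export
pca_varimax <- function(reflectance, n_components = NULL, wavelengths = NULL) {
  if (inherits(reflectance, "spectra_set")) {
    if (is.null(wavelengths)) wavelengths <- reflectance$wavelengths
    reflectance <- reflectance_matrix(reflectance)
  }
  if (nrow(reflectance) < 2 || ncol(reflectance) < 2)
    chl_stop("chlorospec_decomposition_error",
             "need at least 2 samples and 2 wavelengths")
  sds <- apply(reflectance, 2, sd)
  if (any(sds < 1e-12))
    chl_stop("chlorospec_decomposition_error",
             "constant (zero-variance) wavelength columns; cannot standardize")
  if (is.null(wavelengths)) {
    wl_names <- colnames(reflectance)
    wavelengths <- if (!is.null(wl_names) && all(grepl("^wl_", wl_names)))
      as.numeric(sub("^wl_", "", wl_names)) else seq_len(ncol(reflectance))
  }
  pc <- stats::prcomp(reflectance, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  k <- if (is.null(n_components)) max(1L, sum(ev > 1)) else as.integer(n_components)
  k <- min(k, length(ev))
  loadings <- pc$rotation[, seq_len(k), drop = FALSE] %*%
    diag(pc$sdev[seq_len(k)], k, k)
  vm <- varimax_rotate(loadings, normalize = TRUE, eps = 1e-6)
  loadings <- vm$loadings
  rotmat <- vm$rotmat
  # canonical sign: the largest-magnitude loading of each component is
  # positive, so results do not depend on sample order
  for (j in seq_len(k)) {
    if (loadings[which.max(abs(loadings[, j])), j] < 0)
      loadings[, j] <- -loadings[, j]
  }
  colnames(loadings) <- paste0("RC", seq_len(k))
  expl <- colSums(loadings^2) / ncol(reflectance)
  structure(list(wavelengths = wavelengths, loadings = loadings,
                 explained_variance = expl, eigenvalues = ev, rotmat = rotmat,
                 n_components = k),
            class = "loadings_matrix")
}

#' @export
print.loadings_matrix <- function(x, ...) {
  cat(sprintf("loadings_matrix: %d wavelengths x %d rotated components\n",
              length(x$wavelengths), x$n_components))
  cat("  explained variance:",
      paste(sprintf("%.3f", x$explained_variance), collapse = ", "), "\n")
  invisible(x)
}

#' Per-wavelength relative-SD profile by chlorophyll group
#'
#' For each chlorophyll interval, computes the per-wavelength relative
#' standard deviation (SD/mean) of reflectance over the samples whose label
#' falls in the interval. High-relative-SD regions (notably near the 670 nm
#' chlorophyll absorption) flag pigment-sensitive wavelengths.
#'
#' @param spectra a labelled [spectra_set()].
#' @param group_bounds list of \code{c(lo, hi)} chlorophyll intervals in
#'   ug/g; defaults to the nested 750--1500 / 750--2500 / 750--3500 groups.
#' @return An object of class \code{sd_profile}: list with
#'   \code{wavelengths}, \code{group_bounds}, \code{relative_sd}
#'   (wavelengths x groups matrix) and per-group sample counts.
#' @export
sd_profile <- function(spectra,
                       group_bounds = list(c(750, 1500), c(750, 2500),
                                           c(750, 3500))) {
  stopifnot(inherits(spectra, "spectra_set"))
  if (length(group_bounds) < 1)
    chl_stop("chlorospec_grouping_error", "need at least one group")
  m <- reflectance_matrix(spectra)
  chl <- chlorophyll_labels(spectra)
  prof <- sapply(group_bounds, function(b) {
    idx <- which(!is.na(chl) & chl >= b[1] & chl <= b[2])
    if (length(idx) < 2)
      chl_stop("chlorospec_grouping_error",
               sprintf("group [%g, %g] has fewer than 2 samples", b[1], b[2]))
    mu <- colMeans(m[idx, , drop = FALSE])
    s <- apply(m[idx, , drop = FALSE], 2, sd)
    ifelse(mu > 0, s / mu, NA_real_)
  })
  colnames(prof) <- vapply(group_bounds,
                           function(b) sprintf("%g-%g", b[1], b[2]),
                           character(1))
  ns <- vapply(group_bounds,
               function(b) sum(!is.na(chl) & chl >= b[1] & chl <= b[2]),
               numeric(1))
  structure(list(wavelengths = spectra$wavelengths, group_bounds = group_bounds,
                 relative_sd = prof, n_per_group = ns),
            class = "sd_profile")
}

local_extrema <- function(v) {
  n <- length(v)
  if (n < 3) return(list(maxima = integer(0), minima = integer(0)))
  i <- 2:(n - 1)
  list(maxima = i[v[i] > v[i - 1] & v[i] >= v[i + 1]],
       minima = i[v[i] < v[i - 1] & v[i] <= v[i + 1]])
}

#' Pick index-construction wavelengths from rotated loadings
#'
#' Selects the \code{n_max} wavelengths at local maxima of the first rotated
#' component's loading curve with the largest loadings, and the \code{n_min}
#' local minima with the smallest, ties broken toward shorter wavelengths.
#' These are the bands from which CHLI-style ratio indices are constructed
#' (516, 551 and 763 nm on the study data). The SD profile, when given, is
#' carried along in the result for inspection; selection itself uses the
#' loadings extrema.
#'
#' @param loadings a [pca_varimax()] result.
#' @param sd optional [sd_profile()] attached to the result for reference.
#' @param n_max,n_min number of maxima / minima to return (>= 1).
#' @return An object of class \code{wavelength_set}: list with \code{maxima}
#'   and \code{minima} (nm).
#' @export
pick_wavelengths <- function(loadings, sd = NULL, n_max = 2, n_min = 1) {
  stopifnot(inherits(loadings, "loadings_matrix"))
  if (n_max < 1 || n_min < 1)
    chl_stop("chlorospec_selection_error", "n_max and n_min must be >= 1")
  v <- loadings$loadings[, 1]
  wl <- loadings$wavelengths
  ex <- local_extrema(v)
  if (length(ex$maxima) < n_max || length(ex$minima) < n_min)
    chl_stop("chlorospec_selection_error",
             sprintf("requested %d maxima / %d minima but found %d / %d",
                     n_max, n_min, length(ex$maxima), length(ex$minima)))
  # order by loading value, ties toward shorter wavelength
  mx <- ex$maxima[order(-v[ex$maxima], wl[ex$maxima])][seq_len(n_max)]
  mn <- ex$minima[order(v[ex$minima], wl[ex$minima])][seq_len(n_min)]
  structure(list(maxima = sort(wl[mx]), minima = sort(wl[mn]),
                 sd_profile = sd),
            class = "wavelength_set")
}

#' @export
print.wavelength_set <- function(x, ...) {
  cat("wavelength_set: maxima", paste(round(x$maxima, 1), collapse = ", "),
      "nm; minima", paste(round(x$minima, 1), collapse = ", "), "nm\n")
  invisible(x)
}

#' Multicollinearity screening by VIF and tolerance
#'
#' For each feature j, regresses it on all other features and reports
#' VIF_j = 1/(1 - R2_j) and tolerance_j = 1/VIF_j. Features with VIF > 5 or
#' tolerance < 0.1 are flagged as collinear. A feature perfectly explained
#' by the others gets an infinite VIF (zero tolerance) and a flag rather
#' than an error.
#'
#' @param features a [feature_table()] or a numeric samples x features
#'   matrix/data.frame (non-feature columns \code{sample_id}/
#'   \code{chlorophyll} are ignored).
#' @param vif_threshold,tolerance_threshold flag cut-offs (defaults 5, 0.1).
#' @return An object of class \code{collinearity_report}: data.frame with
#'   \code{feature}, \code{tolerance}, \code{vif}, \code{flagged}.
#' @export
collinearity <- function(features, vif_threshold = 5, tolerance_threshold = 0.1) {
  x <- if (inherits(features, "feature_table")) feature_matrix(features)
       else as.matrix(features)
  p <- ncol(x)
  if (p < 2)
    chl_stop("chlorospec_input_error", "need at least two features")
  if (nrow(x) < p + 2)
    chl_stop("chlorospec_input_error", "need at least features + 2 samples")
  vif <- vapply(seq_len(p), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    tss <- sum((x[, j] - mean(x[, j]))^2)
    if (tss < 1e-24) return(Inf)        # constant feature
    r2 <- 1 - sum(fit$residuals^2) / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  tol <- ifelse(is.infinite(vif), 0, 1 / vif)
  nms <- colnames(x)
  if (is.null(nms)) nms <- paste0("x", seq_len(p))
  structure(data.frame(feature = nms, tolerance = tol, vif = vif,
                       flagged = vif > vif_threshold | tol < tolerance_threshold,
                       stringsAsFactors = FALSE),
            thresholds = c(vif = vif_threshold, tolerance = tolerance_threshold),
            class = c("collinearity_report", "data.frame"))
}
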