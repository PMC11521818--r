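#' Reflectance at a nominal wavelength
#'
#' Looks a nominal band up on the spectrum's grid, linearly interpolating
#' between the two bracketing grid points (exact when the nominal hits a
#' grid point).
#'
#' @param spectrum a [spectrum_record()].
#' @param nominal wavelength in nm; must lie within the grid range.
#' @return Reflectance fraction.
#' @export
#' @examples
#' sp <- spectrum_record("a", c(500, 501), c(0.2, 0.4))
#' band(sp, 500.5)  # 0.3
band <- function(spectrum, nominal) {
  stopifnot(inherits(spectrum, "spectrum_record"))
  wl <- spectrum$wavelengths
  if (any(nominal < wl[1] | nominal > wl[length(wl)]))
    chl_stop("chlorospec_range_error",
             sprintf("band %s nm outside grid [%g, %g]",
                     paste(nominal, collapse = ","), wl[1], wl[length(wl)]))
  stats::approx(wl, spectrum$reflectance, xout = nominal, method = "linear")$y
}

#' Red edge position by four-band linear interpolation
#'
#' \deqn{REP = 700 + 40 \frac{(\rho_{670}+\rho_{780})/2 - \rho_{700}}
#'                           {\rho_{740}-\rho_{700}}}
#' the interpolated wavelength of maximum slope on the red edge, in nm.
#'
#' @param spectrum a [spectrum_record()] covering 670--780 nm.
#' @return REP in nm.
#' @export
red_edge_position <- function(spectrum) {
  r <- band(spectrum, c(670, 700, 740, 780))
  denom <- r[3] - r[2]
  if (abs(denom) < 1e-12)
    chl_stop("chlorospec_undefined_index",
             "REP undefined: rho740 equals rho700", index = "REP")
  700 + 40 * ((r[1] + r[4]) / 2 - r[2]) / denom
}

# formula table: each entry computes the index from a band() accessor.
index_formulas <- function(ndvi_bands = c(nir = 780, red = 670),
                           literature_variants = FALSE) {
  safe_div <- function(num, den, name) {
    if (abs(den) < 1e-12)
      chl_stop("chlorospec_undefined_index",
               sprintf("%s undefined: zero denominator", name), index = name)
    num / den
  }
  msr705 <- if (literature_variants) {
    function(b) safe_div(b(750) - b(445), b(705) - b(445), "mSR705")
  } else {
    function(b) safe_div(b(750) - b(445), b(705) + b(445), "mSR705")
  }
  vrei2 <- if (literature_variants) {
    function(b) safe_div(b(734) - b(747), b(715) + b(726), "VREI2")
  } else {
    function(b) safe_div(b(757) - b(720), b(757) + b(720), "VREI2")
  }
  list(
    NDVI = function(b) safe_div(b(ndvi_bands[["nir"]]) - b(ndvi_bands[["red"]]),
                                b(ndvi_bands[["nir"]]) + b(ndvi_bands[["red"]]),
                                "NDVI"),
    REP = NULL,  # handled by red_edge_position()
    NDVI705 = function(b) safe_div(b(750) - b(705), b(750) + b(705), "NDVI705"),
    mSR705 = msr705,
    mNDVI705 = function(b) safe_div(b(750) - b(705),
                                    b(750) + b(705) - 2 * b(445), "mNDVI705"),
    PRI = function(b) safe_div(b(531) - b(570), b(531) + b(570), "PRI"),
    MCARI = function(b) {
      if (abs(b(670)) < 1e-12)
        chl_stop("chlorospec_undefined_index",
                 "MCARI undefined: zero rho670", index = "MCARI")
      ((b(700) - b(670)) - 0.2 * (b(700) - b(550))) * (b(700) / b(670))
    },
    CHLI1 = function(b) safe_div(b(551) + b(763), b(763) - b(551), "CHLI1"),
    CHLI2 = function(b) safe_div(b(763) - b(516), b(551), "CHLI2"),
    CHLI3 = function(b) safe_div(b(516) + b(551), b(763), "CHLI3"),
    VREI2 = vrei2
  )
}

#' The eleven-index catalog
#'
#' Catalog of the spectral indices computed by the pipeline: NDVI, REP,
#' NDVI705, mSR705, mNDVI705, PRI, MCARI, VREI2 and the three CHLI
#' chlorophyll indices built on the 516/551/763 nm bands selected by PCA
#' and SD profiling:
#' CHLI1 = (rho551+rho763)/(rho763-rho551),
#' CHLI2 = (rho763-rho516)/rho551,
#' CHLI3 = (rho516+rho551)/rho763.
#'
#' @param names subset of index names to retain (default: all eleven, in
#'   the canonical order NDVI, REP, NDVI705, mSR705, mNDVI705, PRI, MCARI,
#'   VREI2, CHLI1, CHLI2, CHLI3).
#' @param ndvi_bands named pair \code{c(nir=, red=)} of NDVI bands; defaults
#'   to 780/670 nm, consistent with the REP band set.
#' @param literature_variants if TRUE, substitute the Sims--Gamon mSR705
#'   (difference denominator) and the Vogelmann VREI2 band set for the
#'   printed forms.
#' @return An object of class \code{index_catalog}: data.frame of index
#'   names and required bands, with the formula closures attached.
#' @export
index_catalog <- function(names = NULL,
                          ndvi_bands = c(nir = 780, red = 670),
                          literature_variants = FALSE) {
  bands <- list(
    NDVI = unname(ndvi_bands), REP = c(670, 700, 740, 780),
    NDVI705 = c(705, 750),
    mSR705 = c(445, 705, 750), mNDVI705 = c(445, 705, 750),
    PRI = c(531, 570), MCARI = c(550, 670, 700),
    VREI2 = if (literature_variants) c(715, 726, 734, 747) else c(720, 757),
    CHLI1 = c(551, 763), CHLI2 = c(516, 551, 763), CHLI3 = c(516, 551, 763))
  all_names <- c("NDVI", "REP", "NDVI705", "mSR705", "mNDVI705", "PRI",
                 "MCARI", "VREI2", "CHLI1", "CHLI2", "CHLI3")
  keep <- if (is.null(names)) all_names else {
    bad <- setdiff(names, all_names)
    if (length(bad))
      chl_stop("chlorospec_catalog_error",
               paste("unknown index name(s):", paste(bad, collapse = ", ")))
    names
  }
  df <- data.frame(name = keep,
                   required_bands = I(unname(bands[keep])),
                   stringsAsFactors = FALSE)
  structure(df,
            formulas = index_formulas(ndvi_bands, literature_variants),
            class = c("index_catalog", "data.frame"))
}

#' Compute one spectral index
#'
#' @param spectrum a [spectrum_record()] whose grid covers the index bands.
#' @param name index name (see [index_catalog()]).
#' @param catalog an [index_catalog()].
#' @return The index value (dimensionless; nm for REP). Zero denominators
#'   raise a classed \code{chlorospec_undefined_index} error carrying the
#'   index name.
#' @export
#' @examples
#' cfg <- generator_config(noise_sd = 0)
#' sp <- simulate_spectrum(2500, 0.35, cfg)
#' compute_index(sp, "CHLI1")
compute_index <- function(spectrum, name, catalog = index_catalog()) {
  if (!name %in% catalog$name)
    chl_stop("chlorospec_catalog_error", paste("unknown index:", name))
  if (name == "REP") return(red_edge_position(spectrum))
  f <- attr(catalog, "formulas")[[name]]
  f(function(nm) band(spectrum, nm))
}

#' Assemble the feature table of index values
#'
#' One row per sample, one column per catalog index, plus the chlorophyll
#' target copied from the record labels. Rows on which any index is
#' undefined (zero denominator) are dropped with a warning under the
#' default policy, or abort under \code{policy = "fail"}.
#'
#' @param spectra a [spectra_set()].
#' @param catalog an [index_catalog()].
#' @param policy \code{"drop"} (default) or \code{"fail"}.
#' @return A \code{feature_table}: data.frame with \code{sample_id}, the
#'   index columns and \code{chlorophyll}; feature names are kept in
#'   \code{attr(, "feature_names")}.
#' @export
compute_feature_table <- function(spectra, catalog = index_catalog(),
                                  policy = c("drop", "fail")) {
  policy <- match.arg(policy)
  stopifnot(inherits(spectra, "spectra_set"))
  nms <- catalog$name
  rows <- lapply(spectra$records, function(rec) {
    vals <- tryCatch(
      vapply(nms, function(nm) compute_index(rec, nm, catalog), numeric(1)),
      chlorospec_undefined_index = function(e) {
        if (policy == "fail")
          chl_stop("chlorospec_undefined_index",
                   sprintf("sample '%s': %s", rec$sample_id, conditionMessage(e)),
                   index = e$index)
        warning(sprintf("dropping sample '%s': %s", rec$sample_id,
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
    vals
  })
  keep <- !vapply(rows, is.null, logical(1))
  vals <- do.call(rbind, rows[keep])
  df <- data.frame(
    sample_id = vapply(spectra$records[keep], `[[`, character(1), "sample_id"),
    vals,
    chlorophyll = chlorophyll_labels(spectra)[keep],
    check.names = FALSE, stringsAsFactors = FALSE)
  feature_table(df, feature_names = nms)
}

#' Construct / validate a feature table
#'
#' @param df data.frame with a \code{sample_id} column, feature columns and
#'   optionally a \code{chlorophyll} target column.
#' @param feature_names the feature column names; defaults to every column
#'   except \code{sample_id} and \code{chlorophyll}.
#' @return The data.frame with class \code{feature_table}.
#' @export
feature_table <- function(df, feature_names = NULL) {
  if (is.null(feature_names))
    feature_names <- setdiff(names(df), c("sample_id", "chlorophyll"))
  if (anyDuplicated(feature_names))
    chl_stop("chlorospec_input_error", "duplicated feature names")
  if (!all(feature_names %in% names(df)))
    chl_stop("chlorospec_input_error", "feature_names not all present in df")
  structure(df, feature_names = feature_names,
            class = c("feature_table", "data.frame"))
}

#' Feature matrix of a feature table
#' @param ft a [feature_table()].
#' @return Numeric samples x features matrix.
#' @export
feature_matrix <- function(ft) {
  m <- as.matrix(as.data.frame(ft)[, attr(ft, "feature_names"), drop = FALSE])
  rownames(m) <- ft$sample_id
  m
}

#' Write / read a feature table as CSV
#'
#' Header: \code{sample_id,<features...>,chlorophyll}.
#' @param ft a [feature_table()].
#' @param path file path.
#' @return \code{path} (write) or a [feature_table()] (read).
#' @export
write_feature_csv <- function(ft, path) {
  utils::write.csv(as.data.frame(ft), path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df))
    chl_stop("chlorospec_input_error", "feature CSV needs a sample_id column")
  feature_table(df)
}
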