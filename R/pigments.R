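#' Construct a spectrophotometer absorbance sample
#'
#' Bundles the absorbance readings used for the spectrophotometric
#' chlorophyll determination: 470 nm (carotenoid region, carried as data but
#' not used by the chlorophyll relation), 644 nm and 663 nm, together with
#' the extract volume and tissue fresh weight.
#'
#' @param A644,A663 absorbances (dimensionless, >= 0) at 644 and 663 nm.
#' @param V tissue-extract volume in ml (> 0).
#' @param w fresh weight of tissue in g (> 0).
#' @param A470 absorbance at 470 nm (>= 0); optional carotenoid proxy.
#' @param sample_id optional identifier.
#' @return An object of class \code{absorbance_sample}.
#' @seealso [arnon_chlorophyll()]
#' @export
#' @examples
#' absorbance_sample(A644 = 0.5, A663 = 0.8, V = 10, w = 2)
absorbance_sample <- function(A644, A663, V, w, A470 = 0, sample_id = NA_character_) {
  if (any(!is.finite(c(A644, A663, A470))) || any(c(A644, A663, A470) < 0))
    chl_stop("chlorospec_domain_error", "absorbances must be finite and >= 0")
  if (!is.finite(V) || V <= 0)
    chl_stop("chlorospec_domain_error", "extract volume V must be > 0 ml")
  if (!is.finite(w) || w <= 0)
    chl_stop("chlorospec_domain_error", "fresh weight w must be > 0 g")
  structure(list(sample_id = sample_id, A470 = A470, A644 = A644,
                 A663 = A663, V = V, w = w),
            class = "absorbance_sample")
}

#' Total chlorophyll (a+b) from absorbances (Arnon relation)
#'
#' Computes chlorophyll a+b in ug/g fresh weight from the 644 and 663 nm
#' absorbances of an 80% acetone extract:
#' \deqn{(20.2 A_{644} + 8.02 A_{663}) \cdot V / w}
#' where V is the extract volume (ml) and w the fresh weight (g). The
#' result is linear in each absorbance and in V/w.
#'
#' @param x an [absorbance_sample()], or a data.frame with columns
#'   \code{A644, A663, V_ml, w_g} (e.g. from [read_absorbance_csv()]).
#' @return Chlorophyll a+b in ug/g fresh weight (vector for data.frame input).
#' @export
#' @examples
#' arnon_chlorophyll(absorbance_sample(A644 = 1, A663 = 1, V = 1, w = 1))  # 28.22
arnon_chlorophyll <- function(x) {
  UseMethod("arnon_chlorophyll")
}

#' @export
arnon_chlorophyll.absorbance_sample <- function(x) {
  (20.2 * x$A644 + 8.02 * x$A663) * x$V / x$w
}

#' @export
arnon_chlorophyll.data.frame <- function(x) {
  need <- c("A644", "A663", "V_ml", "w_g")
  if (!all(need %in% names(x)))
    chl_stop("chlorospec_input_error",
             paste("absorbance table needs columns:", paste(need, collapse = ", ")))
  if (any(x$A644 < 0 | x$A663 < 0))
    chl_stop("chlorospec_domain_error", "negative absorbance")
  if (any(x$V_ml <= 0 | x$w_g <= 0))
    chl_stop("chlorospec_domain_error", "V and w must be positive")
  (20.2 * x$A644 + 8.02 * x$A663) * x$V_ml / x$w_g
}

#' Read an absorbance table from CSV
#'
#' Expected header: \code{sample_id,A470,A644,A663,V_ml,w_g}.
#'
#' @param path CSV file path.
#' @return data.frame with those columns.
#' @export
read_absorbance_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "A470", "A644", "A663", "V_ml", "w_g")
  if (!all(need %in% names(df)))
    chl_stop("chlorospec_input_error",
             paste("expected columns:", paste(need, collapse = ", ")))
  df[need]
}

#' Write an absorbance table to CSV
#' @param df data.frame with columns \code{sample_id,A470,A644,A663,V_ml,w_g}.
#' @param path destination file.
#' @return \code{path}, invisibly.
#' @export
write_absorbance_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
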