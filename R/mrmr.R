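#' Discretize a continuous vector into bins
#'
#' Equal-frequency binning assigns rank-based labels so bin sizes differ by
#' at most one when values are distinct (tied values always share a label,
#' which also makes the labels invariant to row permutation). Equal-width
#' binning splits the observed range into \code{n_bins} equal intervals.
#' When fewer distinct values than bins exist, the bin count falls back to
#' the number of distinct values with a warning.
#'
#' @param values numeric vector.
#' @param n_bins number of bins (>= 2).
#' @param scheme \code{"frequency"} (default) or \code{"width"}.
#' @return Integer labels in \code{0:(n_bins-1)}.
#' @export
#' @examples
#' table(discretize(1:100, 10))  # ten bins of ten
discretize <- function(values, n_bins = 10, scheme = c("frequency", "width")) {
  scheme <- match.arg(scheme)
  if (n_bins < 2)
    chl_stop("chlorospec_config_error", "n_bins must be >= 2")
  n_distinct <- length(unique(values))
  if (n_distinct < n_bins) {
    warning(sprintf("only %d distinct values; falling back to %d bin(s)",
                    n_distinct, max(1L, n_distinct)), call. = FALSE)
    n_bins <- max(1L, n_distinct)
  }
  if (n_bins == 1L) return(rep(0L, length(values)))
  if (scheme == "frequency") {
    r <- rank(values, ties.method = "average")
    lab <- as.integer(floor((r - 0.5) * n_bins / length(values)))
    pmin(pmax(lab, 0L), n_bins - 1L)
  } else {
    breaks <- seq(min(values), max(values), length.out = n_bins + 1)
    as.integer(.bincode(values, breaks, include.lowest = TRUE)) - 1L
  }
}

#' Plug-in mutual information between two discrete vectors
#'
#' Plug-in estimate from the joint contingency table, in bits (log base 2),
#' optionally with the Miller--Madow bias correction
#' (subtracting \eqn{(K_{xy}-K_x-K_y+1)/(2N\ln 2)}, K = occupied cells) and
#' clamped at zero. Symmetric in its arguments and zero for empirically
#' independent tables.
#'
#' @param x,y discrete (integer/factor) vectors of equal length >= 2.
#' @param correction \code{"none"} (raw plug-in, default) or
#'   \code{"miller-madow"}.
#' @return Mutual information in bits (>= 0).
#' @export
#' @examples
#' x <- rep(0:1, each = 50)
#' mutual_information(x, x)  # 1 bit
mutual_information <- function(x, y, correction = c("none", "miller-madow")) {
  correction <- match.arg(correction)
  if (length(x) != length(y))
    chl_stop("chlorospec_input_error", "x and y must have equal length")
  if (length(x) < 2)
    chl_stop("chlorospec_input_error", "need at least 2 observations")
  tab <- table(x, y)
  n <- sum(tab)
  pxy <- tab / n
  px <- rowSums(pxy); py <- colSums(pxy)
  nz <- pxy > 0
  mi <- sum(pxy[nz] * log2(pxy[nz] / outer(px, py)[nz]))
  if (correction == "miller-madow") {
    kxy <- sum(nz); kx <- sum(px > 0); ky <- sum(py > 0)
    mi <- mi + (kx + ky - kxy - 1) / (2 * n * log(2))
  }
  max(0, mi)
}

# G-test of independence on the joint table: G = 2 N ln(2) MI_plugin,
# df = (kx-1)(ky-1). Used to decide whether an estimated relevance is
# distinguishable from zero.
mi_independence_p <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  mi_raw <- mutual_information(x, y, correction = "none")
  df <- (sum(rowSums(tab) > 0) - 1) * (sum(colSums(tab) > 0) - 1)
  if (df < 1) return(1)
  stats::pchisq(2 * n * log(2) * mi_raw, df = df, lower.tail = FALSE)
}

#' Minimum-redundancy maximum-relevance feature ranking
#'
#' Ranks features for a continuous target by greedy forward selection on
#' discretized mutual information. Relevance is the (Miller--Madow
#' corrected) MI of a feature with the target; a relevance is set to zero
#' when the G-test of independence on the joint table is not significant at
#' \code{alpha}, so features statistically indistinguishable from noise get
#' importance 0 and rank last. The first selected feature's importance is
#' its relevance; subsequent step scores are, for the quotient (MIQ)
#' scheme, relevance divided by the mean MI with the already-selected set
#' (floored at \code{eps}), or relevance minus that mean for the difference
#' (MID) scheme. Importances are floored at zero.
#'
#' @param features a [feature_table()] or numeric matrix/data.frame of
#'   features.
#' @param target continuous target vector; taken from the table's
#'   \code{chlorophyll} column when NULL.
#' @param n_bins,scheme discretization settings (see [discretize()]);
#'   defaults: 10 equal-frequency bins, robust to the skewed chlorophyll
#'   distribution.
#' @param variant \code{"quotient"} (MIQ, default) or \code{"difference"}
#'   (MID).
#' @param alpha significance level of the relevance independence test.
#' @param eps floor on the redundancy denominator (bits).
#' @return An object of class \code{mrmr_ranking}: data.frame with
#'   \code{feature}, \code{importance}, \code{relevance}, \code{redundancy}
#'   in rank order.
#' @export
mrmr_rank <- function(features, target = NULL, n_bins = 10,
                      scheme = c("frequency", "width"),
                      variant = c("quotient", "difference"),
                      alpha = 0.05, eps = 1e-12) {
  scheme <- match.arg(scheme)
  variant <- match.arg(variant)
  if (inherits(features, "feature_table")) {
    if (is.null(target)) target <- features$chlorophyll
    x <- feature_matrix(features)
  } else x <- as.matrix(features)
  if (ncol(x) < 1)
    chl_stop("chlorospec_input_error", "need at least one feature")
  if (is.null(target) || length(target) != nrow(x))
    chl_stop("chlorospec_input_error", "target missing or of wrong length")
  p <- ncol(x)
  nms <- colnames(x)
  if (is.null(nms)) nms <- paste0("x", seq_len(p))
  dx <- lapply(seq_len(p), function(j) discretize(x[, j], n_bins, scheme))
  dy <- discretize(target, n_bins, scheme)

  relevance <- vapply(dx, function(d)
    mutual_information(d, dy, correction = "miller-madow"), numeric(1))
  pvals <- vapply(dx, function(d) mi_independence_p(d, dy), numeric(1))
  relevance[pvals > alpha] <- 0

  # pairwise feature MI, corrected, computed lazily
  mi_pair <- matrix(NA_real_, p, p)
  pair_mi <- function(i, j) {
    if (is.na(mi_pair[i, j])) {
      v <- mutual_information(dx[[i]], dx[[j]], correction = "miller-madow")
      mi_pair[i, j] <<- v; mi_pair[j, i] <<- v
    }
    mi_pair[i, j]
  }

  active <- which(relevance >= eps)
  inactive <- setdiff(seq_len(p), active)
  selected <- integer(0)
  importance <- numeric(p)
  while (length(active)) {
    if (!length(selected)) {
      score <- relevance[active]
    } else {
      score <- vapply(active, function(j) {
        red <- mean(vapply(selected, function(k) pair_mi(j, k), numeric(1)))
        if (variant == "quotient") relevance[j] / max(red, eps)
        else relevance[j] - red
      }, numeric(1))
    }
    # ties broken toward the earlier column for a deterministic order
    best <- active[order(-score, active)][1]
    importance[best] <- max(0, score[match(best, active)])
    selected <- c(selected, best)
    active <- setdiff(active, best)
  }
  order_all <- c(selected, inactive)  # zero-relevance features rank last
  redundancy <- vapply(seq_along(order_all), function(i) {
    j <- order_all[i]
    prev <- order_all[seq_len(i - 1)]
    prev <- prev[prev %in% selected]
    if (!length(prev) || !(j %in% selected)) NA_real_
    else mean(vapply(prev, function(k) pair_mi(j, k), numeric(1)))
  }, numeric(1))
  structure(data.frame(feature = nms[order_all],
                       importance = importance[order_all],
                       relevance = relevance[order_all],
                       redundancy = redundancy,
                       stringsAsFactors = FALSE),
            variant = variant, n_bins = n_bins, alpha = alpha,
            class = c("mrmr_ranking", "data.frame"))
}

#' Write an MRMR ranking to CSV
#'
#' Two columns, \code{feature,importance}, in rank order.
#' @param ranking an [mrmr_rank()] result.
#' @param path destination file.
#' @return \code{path}, invisibly.
#' @export
write_mrmr_csv <- function(ranking, path) {
  utils::write.csv(as.data.frame(ranking)[, c("feature", "importance")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
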