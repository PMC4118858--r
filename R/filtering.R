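# Probe-set filtering feeding the unsupervised analysis: an expressed-probe
# intensity filter (linear scale), a variance filter against the median
# probe variance (log2 scale), and nested lists of the most variant probes
# ranked by robust coefficient of variation.

#' Filtering parameters
#'
#' @param intensity_threshold linear-scale intensity a probe must exceed to
#'   count as expressed in a sample (default 15).
#' @param min_expressed_fraction minimum fraction of samples in which a probe
#'   must be expressed (default 0.10; the comparison is `>=`).
#' @param variance_alpha one-sided significance level for the
#'   variance-above-median test (default 0.01).
#' @param list_fractions fractions of the most variant probes defining the
#'   nested lists (default 1%, 5%, 10%, 20%, 30%, 40%, 50%).
#' @return a list of class `filter_params`.
#' @export
filter_params <- function(intensity_threshold = 15,
                          min_expressed_fraction = 0.10,
                          variance_alpha = 0.01,
                          list_fractions = c(0.01, 0.05, 0.10, 0.20,
                                             0.30, 0.40, 0.50)) {
  stopifnot(all(list_fractions > 0), all(list_fractions <= 1),
            variance_alpha > 0, variance_alpha < 1,
            min_expressed_fraction > 0, min_expressed_fraction <= 1)
  structure(list(intensity_threshold = intensity_threshold,
                 min_expressed_fraction = min_expressed_fraction,
                 variance_alpha = variance_alpha,
                 list_fractions = sort(list_fractions)),
            class = "filter_params")
}

#' Keep probes expressed in a minimum fraction of samples
#'
#' A probe is expressed in a sample when its LINEAR normalized intensity
#' exceeds `intensity_threshold` (strict `>`); it is kept when the fraction
#' of such samples is at least `min_expressed_fraction` (`>=`).
#'
#' @param x an `expr_matrix`.
#' @param params a [filter_params()].
#' @return character vector of kept probe ids.
#' @export
filter_expressed <- function(x, params = filter_params()) {
  validate_expression_matrix(x)
  frac <- rowMeans(x$values > params$intensity_threshold)
  keep <- x$probe_ids[frac >= params$min_expressed_fraction]
  if (length(keep) == 0L)
    stop("no probe passes the expression filter; review intensity_threshold (",
         params$intensity_threshold, ") and min_expressed_fraction")
  keep
}

#' Keep probes whose variance significantly exceeds the median variance
#'
#' Per-probe variances are computed on log2 intensities. With m the median
#' of these variances treated as the null variance, each probe's statistic
#' (n-1) * s^2 / m is referred to the chi-squared law with n-1 degrees of
#' freedom (one-sided upper tail); probes with p < `variance_alpha` are kept.
#'
#' @param x an `expr_matrix` with at least 3 samples.
#' @param params a [filter_params()].
#' @return character vector of kept probe ids.
#' @export
filter_high_variance <- function(x, params = filter_params()) {
  validate_expression_matrix(x)
  n <- ncol(x$values)
  if (n < 3L) stop("variance filter needs >= 3 samples")
  lv <- log2(x$values)
  s2 <- apply(lv, 1L, stats::var)
  m <- stats::median(s2)
  if (m <= 0) stop("median probe variance is zero; variance test undefined")
  p <- stats::pchisq((n - 1) * s2 / m, df = n - 1, lower.tail = FALSE)
  keep <- x$probe_ids[p < params$variance_alpha]
  if (length(keep) == 0L)
    stop("no probe passes the variance filter at alpha = ", params$variance_alpha)
  keep
}

#' Robust coefficient of variation
#'
#' rCV = (1.4826 * median(|x - median(x)|)) / |median(x)|: the
#' consistency-scaled MAD divided by the absolute median. Scale-invariant
#' (multiplying all values by c > 0 leaves it unchanged).
#'
#' @param values numeric vector with at least 2 values and non-zero median.
#' @return the robust CV (0 for a constant vector).
#' @export
robust_cv <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("robust_cv needs >= 2 values")
  med <- stats::median(values)
  if (med == 0) stop("robust_cv undefined: median is zero")
  stats::mad(values, constant = 1.4826) / abs(med)
}

#' Build nested lists of the most variant probes
#'
#' Probes are ranked by decreasing robust CV of their log2 intensities
#' (ties broken by probe id, lexicographically); the list for fraction f
#' contains the top `ceiling(f * P)` probes, extended to include any probes
#' tied with the boundary rCV (so lists may slightly exceed the nominal
#' count). Lists are nested by construction.
#'
#' @param x an `expr_matrix`, typically already restricted to the probes
#'   passing [filter_expressed()] and [filter_high_variance()].
#' @param params a [filter_params()]; its `list_fractions` define the lists.
#' @return named list (fraction as name) of ordered probe-id vectors.
#' @export
build_variant_lists <- function(x, params = filter_params()) {
  validate_expression_matrix(x)
  lv <- log2(x$values)
  rcv <- apply(lv, 1L, robust_cv)
  ord <- order(-rcv, x$probe_ids)
  rcv <- rcv[ord]
  ids <- x$probe_ids[ord]
  P <- length(ids)
  out <- lapply(params$list_fractions, function(f) {
    k <- ceiling(f * P)
    if (k == 0L) stop("fraction ", f, " yields an empty probe list")
    while (k < P && rcv[k + 1L] == rcv[k]) k <- k + 1L  # boundary ties kept
    ids[seq_len(k)]
  })
  names(out) <- format(params$list_fractions, trim = TRUE)
  out
}
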