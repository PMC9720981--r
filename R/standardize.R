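#' Trimmed-mean/SD standardization
#'
#' Standardizes a vector by the mean and sample standard deviation of its
#' two-tailed trimmed set: with \code{k = floor(trim_fraction * n)}, the
#' lowest k and highest k order statistics are removed, and every original
#' value (including the trimmed ones) is transformed as
#' \code{(x - trimmed_mean) / trimmed_sd}. The SD uses the n-1 denominator
#' over the trimmed set. \code{trim_fraction = 0} reduces to the ordinary
#' z-score.
#'
#' @param values Numeric vector, length >= 3, no missing values.
#' @param trim_fraction Proportion trimmed from each tail, in [0, 0.5).
#' @param feature Optional feature name used in error messages.
#' @return List with \code{standardized} (same length/order as input),
#'   \code{trimmed_mean}, \code{trimmed_sd}.
#' @export
trimmed_standardize <- function(values, trim_fraction = 0.10, feature = "feature") {
  if (length(values) < 3)
    stop_immflow("need at least 3 values to standardize '%s'", feature,
                 class = "immflow_insufficient_samples_error")
  if (anyNA(values) || any(!is.finite(values)))
    stop_immflow("non-finite values in '%s'", feature, class = "immflow_data_error")
  if (trim_fraction < 0 || trim_fraction >= 0.5)
    stop_immflow("trim_fraction must be in [0, 0.5), got %g", trim_fraction,
                 class = "immflow_config_error")
  n <- length(values)
  k <- floor(trim_fraction * n)
  s <- sort(values)
  trimmed <- if (k > 0) s[(k + 1):(n - k)] else s
  m <- mean(trimmed)
  sd_t <- stats::sd(trimmed)
  if (!is.finite(sd_t) || sd_t == 0)
    stop_immflow("degenerate feature '%s': trimmed set has zero variance", feature,
                 class = "immflow_degenerate_error")
  list(standardized = (values - m) / sd_t, trimmed_mean = m, trimmed_sd = sd_t)
}
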