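#' First-order intensity features (18)
#'
#' Statistics of the raw masked intensities, plus the two histogram features
#' (Entropy, Uniformity) computed on the discretized gray levels. Variance and
#' the higher moments are population (biased) moments; Kurtosis is the
#' non-excess Pearson form (a normal distribution scores 3). Percentiles use
#' the standard linear-interpolation definition.
#'
#' @param d a `discretized_region` from [discretize_fbw()] or
#'   [discretize_fbc()]
#' @return data.frame with columns `family`, `name`, `value` (18 rows)
#' @export
firstorder_features <- function(d) {
  x <- d$raw
  n <- length(x)
  stopifnot(n >= 1L)
  p <- tabulate(d$levels, d$ng) / n
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  qs <- stats::quantile(x, c(0.10, 0.25, 0.75, 0.90), names = FALSE, type = 7)
  in_robust <- x >= qs[1] & x <= qs[4]
  xr <- x[in_robust]
  if (n < 2L || m2 == 0)
    rs_log("warning", "degenerate region (constant or single voxel): ",
           "Skewness/Kurtosis undefined (NaN)")
  skew <- if (n < 2L || m2 == 0) NaN else mean((x - mu)^3) / m2^1.5
  kurt <- if (n < 2L || m2 == 0) NaN else mean((x - mu)^4) / m2^2
  feature_rows("firstorder", c(
    "Energy" = sum(x^2),
    "Total Energy" = d$voxel_volume * sum(x^2),
    "Entropy" = .entropy2(p),
    "Minimum" = min(x),
    "10th Percentile" = qs[1],
    "90th Percentile" = qs[4],
    "Maximum" = max(x),
    "Mean" = mu,
    "Median" = stats::median(x),
    "Interquartile Range" = qs[3] - qs[2],
    "Range" = max(x) - min(x),
    "Mean Absolute Deviation" = mean(abs(x - mu)),
    "Robust Mean Absolute Deviation" = mean(abs(xr - mean(xr))),
    "Root Mean Squared" = sqrt(mean(x^2)),
    "Skewness" = skew,
    "Kurtosis" = kurt,
    "Variance" = m2,
    "Uniformity" = sum(p^2)))
}
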