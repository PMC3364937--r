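# Distribution summaries and two-sample release comparisons.

#' Summarize the distribution of a per-term quality measure
#'
#' Quartiles use the linear-interpolation convention between order
#' statistics (`stats::quantile` type 7); outliers are values lying more
#' than 1.5 interquartile ranges beyond the nearer quartile. `NA` values
#' (undefined per-term ratios) are dropped before summarizing.
#'
#' @param values numeric vector of per-term measure values; at least one
#'   defined value is required.
#' @return list with elements `q1`, `median`, `q3`, `mean`, `outliers`
#'   (the outlying values) and `n`.
#' @examples
#' summarizeDistribution(c(rep(0.1, 9), 0.9))
#' @export
summarizeDistribution <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values))
    stop("no defined values to summarize")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[[3L]] - q[[1L]]
  out <- values[values < q[[1L]] - 1.5 * iqr | values > q[[3L]] + 1.5 * iqr]
  list(q1 = q[[1L]], median = q[[2L]], q3 = q[[3L]], mean = mean(values),
       outliers = out, n = length(values))
}

#' Compare a quality measure between two evaluation intervals
#'
#' Two-sided Mann-Whitney U test (Wilcoxon rank-sum with tie correction)
#' of the per-term values of one interval against another; the returned U
#' statistic counts wins of the first sample. Significance is flagged at
#' the 0.05 level.
#'
#' @param valuesA,valuesB numeric vectors of per-term values (`NA`
#'   dropped); each must retain at least one value.
#' @return list with elements `U`, `p` and `significant`.
#' @examples
#' compareIntervals(c(1, 2, 3), c(4, 5, 6))
#' @export
compareIntervals <- function(valuesA, valuesB) {
  valuesA <- valuesA[!is.na(valuesA)]
  valuesB <- valuesB[!is.na(valuesB)]
  stopifnot(length(valuesA) >= 1L, length(valuesB) >= 1L)
  wt <- suppressWarnings(wilcox.test(valuesA, valuesB,
                                     alternative = "two.sided"))
  list(U = unname(wt$statistic), p = wt$p.value,
       significant = wt$p.value < 0.05)
}
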