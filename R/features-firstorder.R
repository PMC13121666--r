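# Intensity discretization and IBSI-aligned first-order features.

#' Discretize in-mask intensities to a fixed number of gray levels
#'
#' Equal-width bins over the in-mask intensity range (fixed-bin-number
#' scheme): bin = ceiling((v - min) / width) with the minimum mapped to bin
#' 1, so bins are left-open/right-closed and the maximum lands in
#' `bin_count`. A constant region maps entirely to bin 1. Values outside the
#' mask are 0.
#'
#' @param volume 3-D numeric array.
#' @param mask logical array of the same shape.
#' @param bin_count number of gray levels (>= 2).
#' @return integer array with values in 1..bin_count inside the mask.
#' @export
discretize <- function(volume, mask, bin_count = 32) {
  if (bin_count < 2) stopf("bin_count must be >= 2")
  idx <- which(mask)
  if (!length(idx)) stopf("empty mask: nothing to discretize")
  v <- volume[idx]
  if (any(!is.finite(v))) stopf("non-finite intensities inside the mask")
  lo <- min(v); hi <- max(v)
  out <- array(0L, dim(volume))
  if (hi - lo <= 0) {
    out[idx] <- 1L
    return(out)
  }
  w <- (hi - lo) / bin_count
  b <- pmax(1L, as.integer(ceiling((v - lo) / w)))
  out[idx] <- pmin(b, as.integer(bin_count))
  out
}

FIRSTORDER_FEATURES <- c(
  "Energy", "TotalEnergy", "Entropy", "Minimum", "Percentile10",
  "Percentile90", "Maximum", "Mean", "Median", "InterquartileRange",
  "Range", "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
  "RootMeanSquared", "Skewness", "Kurtosis", "Variance", "Uniformity"
)

#' First-order intensity statistics
#'
#' The 18-feature IBSI first-order set. Conventions: population (biased)
#' variance; skewness of a constant region is 0 and kurtosis 0 (0/0 guarded);
#' entropy and uniformity are computed on the fixed-bin-number discretized
#' histogram (`bin_count` levels); percentiles are linear-interpolation
#' (type 7) quantiles.
#'
#' @param values numeric vector of in-mask intensities.
#' @param bin_count histogram levels for Entropy/Uniformity.
#' @param voxel_volume mm^3 per voxel (for TotalEnergy).
#' @return named numeric vector of length 18.
#' @export
first_order_features <- function(values, bin_count = 32, voxel_volume = 1) {
  if (!length(values)) stopf("empty region: no values for first-order features")
  v <- as.numeric(values)
  n <- length(v)
  m <- mean(v)
  qs <- quantile(v, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE, type = 7)
  lo <- min(v); hi <- max(v)
  # fixed-bin-number histogram (same scheme as discretize())
  if (hi - lo > 0) {
    w <- (hi - lo) / bin_count
    b <- pmin(pmax(1L, as.integer(ceiling((v - lo) / w))), as.integer(bin_count))
  } else b <- rep(1L, n)
  p <- tabulate(b, bin_count) / n
  p <- p[p > 0]
  robust <- v[v >= qs[1] & v <= qs[5]]
  c(
    Energy = sum(v^2),
    TotalEnergy = voxel_volume * sum(v^2),
    Entropy = -sum(p * log2(p)),
    Minimum = lo,
    Percentile10 = qs[1],
    Percentile90 = qs[5],
    Maximum = hi,
    Mean = m,
    Median = qs[3],
    InterquartileRange = qs[4] - qs[2],
    Range = hi - lo,
    MeanAbsoluteDeviation = mean(abs(v - m)),
    RobustMeanAbsoluteDeviation = mean(abs(robust - mean(robust))),
    RootMeanSquared = sqrt(mean(v^2)),
    Skewness = pop_skewness(v),
    Kurtosis = pop_kurtosis(v),
    Variance = mean((v - m)^2),
    Uniformity = sum(p^2)
  )
}
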