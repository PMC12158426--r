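#' Compute age-centered delta-age
#'
#' The raw residual (predicted minus chronological age) is centered within
#' chronological-age bins: ages are binned at `binWidth`-year resolution,
#' bins with fewer than `minBin` members merged with their nearest
#' neighbouring bin, and the bin mean residual subtracted.  The population
#' mean delta-age is then exactly zero at every age, so delta-age carries
#' no information about chronological age itself.
#'
#' @param predicted predicted ages.
#' @param age chronological ages.
#' @param binWidth bin width in years (default 1).
#' @param minBin minimum individuals per bin before merging (default 50).
#' @return A [DeltaAgeResult-class].
#' @export
computeDeltaAge <- function(predicted, age, binWidth = 1, minBin = 50) {
  if (!length(predicted)) stop("computeDeltaAge: empty input")
  if (length(predicted) != length(age))
    stop("computeDeltaAge: lengths differ")
  raw <- predicted - age
  bins <- floor(age / binWidth) * binWidth
  merged <- mergeSmallBins(bins, minBin)
  bins <- merged$bins
  mu <- tapply(raw, bins, mean)
  centered <- raw - mu[as.character(bins)]
  new("DeltaAgeResult",
      predictedAge = as.numeric(predicted),
      deltaAge = as.numeric(centered),
      ageBin = as.numeric(bins),
      binMeans = setNames(as.numeric(mu), names(mu)))
}

#' @rdname accessors
#' @export
setMethod("deltaAge", "DeltaAgeResult", function(x) x@deltaAge)

#' @rdname accessors
#' @export
setMethod("predictedAge", "DeltaAgeResult", function(x) x@predictedAge)

setMethod("show", "DeltaAgeResult", function(object) {
  cat("DeltaAgeResult with", length(object@deltaAge), "individuals in",
      length(object@binMeans), "age bins\n")
  cat("  sd(deltaAge):", sprintf("%.2f", sd(object@deltaAge)), "years\n")
})
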