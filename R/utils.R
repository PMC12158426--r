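## deterministic TSV writer: fixed number formatting, no quoting surprises
writeTsv <- function(df, path) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- sprintf("%.10g", df[[j]])
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA")
  invisible(path)
}

## merge bins with fewer than minBin members into their nearest
## neighbouring bin (by bin value; ties to the lower bin), repeatedly
mergeSmallBins <- function(binValues, minBin) {
  lev <- sort(unique(binValues))
  map <- setNames(lev, as.character(lev))
  repeat {
    counts <- table(factor(binValues, levels = lev))
    small <- which(counts < minBin)
    if (!length(small) || length(lev) == 1) break
    i <- small[which.min(counts[small])]
    if (i == 1) j <- 2
    else if (i == length(lev)) j <- length(lev) - 1
    else j <- if (counts[i - 1] <= counts[i + 1]) i - 1 else i + 1
    binValues[binValues == lev[i]] <- lev[j]
    map[map == lev[i]] <- lev[j]
    lev <- lev[-i]
  }
  list(bins = binValues, map = map)
}

isCount <- function(x) is.numeric(x) && length(x) == 1 && x == round(x)
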