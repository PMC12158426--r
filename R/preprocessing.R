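#' One-hot encode a multiple-choice column
#'
#' Each answer option becomes a binary indicator column; a missing answer
#' propagates to missing across all derived columns.  Derived columns are
#' standardized downstream like any trait.
#'
#' @param column vector of option labels (or factor / integer codes into
#'   `options`).
#' @param options character vector of allowed options, in display order.
#' @return n x length(options) numeric matrix named by option.
#' @export
encodeMultichoice <- function(column, options) {
  if (is.factor(column)) column <- as.character(column)
  if (is.numeric(column)) column <- options[column]
  bad <- setdiff(unique(column[!is.na(column)]), options)
  if (length(bad))
    stop("encodeMultichoice: values outside options: ",
         paste(bad, collapse = ", "))
  out <- matrix(NA_real_, length(column), length(options),
                dimnames = list(NULL, options))
  ok <- !is.na(column)
  for (j in seq_along(options)) out[ok, j] <- as.numeric(column[ok] == options[j])
  out
}

#' Standardize a trait matrix to mean 0, SD 1
#'
#' Column means and sample SDs (n-1 divisor) are computed on non-missing
#' entries; zero-variance columns are dropped with a warning.  The
#' returned scaler can be re-applied to held-out data with [applyScaler()].
#'
#' @param x numeric matrix (individuals x traits), may contain NA.
#' @return list with `z` (standardized matrix), `scaler` (data.frame of
#'   column, mean, sd) and `dropped` (names of zero-variance columns).
#' @export
standardizeTraits <- function(x) {
  x <- as.matrix(x)
  nObs <- colSums(!is.na(x))
  if (any(nObs == 0))
    stop("standardizeTraits: all-missing column(s): ",
         paste(colnames(x)[nObs == 0], collapse = ", "))
  if (any(nObs < 2))
    stop("standardizeTraits: columns need >= 2 non-missing values")
  mu <- colMeans(x, na.rm = TRUE)
  sdv <- apply(x, 2, sd, na.rm = TRUE)
  drop <- which(sdv == 0 | !is.finite(sdv))
  if (length(drop)) {
    warning("standardizeTraits: dropping zero-variance column(s): ",
            paste(colnames(x)[drop], collapse = ", "))
    x <- x[, -drop, drop = FALSE]
    mu <- mu[-drop]; sdv <- sdv[-drop]
  }
  z <- sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
  list(z = z,
       scaler = data.frame(column = colnames(x), mean = unname(mu),
                           sd = unname(sdv), stringsAsFactors = FALSE),
       dropped = names(drop))
}

#' Re-apply stored scaler parameters
#'
#' @param x matrix whose columns match `scaler$column`.
#' @param scaler a scaler data.frame from [standardizeTraits()].
#' @return standardized matrix.
#' @export
applyScaler <- function(x, scaler) {
  x <- as.matrix(x)[, scaler$column, drop = FALSE]
  sweep(sweep(x, 2, scaler$mean, "-"), 2, scaler$sd, "/")
}

#' Exclude individuals with too many missing values
#'
#' Rows missing strictly more than `maxMissing` cells are excluded (a row
#' with exactly `maxMissing` missing cells is kept).
#'
#' @param x matrix (individuals x traits).
#' @param maxMissing maximum tolerated missing-cell count per row
#'   (default 15).
#' @return list with `kept` and `excluded` row indices and the per-row
#'   missing counts.
#' @export
filterByMissingness <- function(x, maxMissing = 15) {
  if (maxMissing < 0) stop("filterByMissingness: maxMissing must be >= 0")
  m <- rowSums(is.na(as.matrix(x)))
  keep <- which(m <= maxMissing)
  list(kept = keep, excluded = which(m > maxMissing), missingCounts = m)
}

#' K-nearest-neighbour imputation
#'
#' Each missing cell is replaced by the mean of that column over the `k`
#' nearest rows (among rows observing that column), with squared Euclidean
#' distance computed over mutually observed columns and rescaled by the
#' number of shared columns, so rows with more missingness are not
#' artificially near.  Ties are broken toward the lower row index;
#' observed cells are never altered.  If no usable donor exists the column
#' mean is used.
#'
#' For cohorts larger than `maxDonors` rows the donor pool is thinned
#' deterministically to every ceiling(n/maxDonors)-th row (the target row
#' itself is never a donor), which bounds the quadratic donor scan while
#' leaving results for small matrices exact.
#'
#' @param x standardized matrix (individuals x traits) with missing cells.
#' @param k neighbour count, 0 < k < nrow(x); defaults to 10.
#' @param maxDonors upper bound on the donor pool (default 20000).
#' @return completed matrix.
#' @export
knnImpute <- function(x, k = 10, maxDonors = 20000) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (!isCount(k) || k <= 0 || k >= n)
    stop("knnImpute: k must satisfy 0 < k < n")
  if (!anyNA(x)) return(x)
  if (n > maxDonors) {
    donors <- seq.int(1L, n, by = as.integer(ceiling(n / maxDonors)))
  } else donors <- seq_len(n)
  out <- knn_impute_cpp(x, as.integer(k), as.integer(donors) - 1L)
  dimnames(out) <- dimnames(x)
  out
}

#' Full preprocessing chain for a raw trait table
#'
#' Applies the fixed order encode -> standardize -> filter -> impute:
#' multiple-choice traits are one-hot encoded, all columns standardized to
#' mean 0 / SD 1, individuals missing more than `maxMissing` cells of the
#' raw trait panel excluded, and the remaining missing cells KNN-imputed.
#'
#' @param traits raw trait matrix (individuals x traits; multichoice as
#'   option codes).
#' @param metadata trait metadata with `trait`, `type`, `cluster`,
#'   `options` columns (as from [traitData()]).
#' @param maxMissing missingness filter threshold (raw cells per row).
#' @param k imputation neighbour count.
#' @return list with the completed standardized matrix `X`, `scaler`,
#'   `columnInfo` (derived column -> parent trait and cluster), `kept` and
#'   `excluded` row indices.
#' @export
preprocessTraits <- function(traits, metadata, maxMissing = 15, k = 10) {
  traits <- as.matrix(traits)
  metadata <- as.data.frame(metadata)
  stopifnot(all(colnames(traits) %in% metadata$trait))
  cols <- list(); parent <- character(0)
  for (id in colnames(traits)) {
    m <- metadata[metadata$trait == id, , drop = FALSE]
    if (identical(m$type, "multichoice")) {
      opts <- strsplit(m$options, ",")[[1]]
      enc <- encodeMultichoice(traits[, id], opts)
      colnames(enc) <- paste0(id, ".", opts)
      for (j in seq_len(ncol(enc))) {
        cols[[colnames(enc)[j]]] <- enc[, j]
        parent <- c(parent, id)
      }
    } else {
      cols[[id]] <- traits[, id]
      parent <- c(parent, id)
    }
  }
  Xe <- do.call(cbind, cols)
  rownames(Xe) <- rownames(traits)
  std <- standardizeTraits(Xe)
  parent <- parent[match(std$scaler$column, names(cols))]
  ## filter counts raw (pre-encoding) missing cells, as collected
  flt <- filterByMissingness(traits, maxMissing)
  Z <- std$z[flt$kept, , drop = FALSE]
  Xc <- knnImpute(Z, k = k)
  info <- data.frame(column = std$scaler$column, parent = parent,
                     cluster = metadata$cluster[match(parent, metadata$trait)],
                     stringsAsFactors = FALSE)
  list(X = Xc, scaler = std$scaler, columnInfo = info,
       kept = flt$kept, excluded = flt$excluded,
       missingCounts = flt$missingCounts)
}
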