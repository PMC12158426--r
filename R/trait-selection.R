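## fast simple linear regression of each column of X on age using
## pairwise-complete rows; returns slope, p, n per column
slopeScan <- function(X, age) {
  p <- ncol(X)
  slope <- pval <- rep(NA_real_, p)
  nUsed <- integer(p)
  for (j in seq_len(p)) {
    ok <- !is.na(X[, j]) & !is.na(age)
    nj <- sum(ok)
    nUsed[j] <- nj
    if (nj < 3) next
    a <- age[ok]; y <- X[ok, j]
    va <- var(a)
    if (va == 0 || var(y) == 0) next
    b <- cov(a, y) / va
    res <- y - mean(y) - b * (a - mean(a))
    se <- sqrt(sum(res^2) / (nj - 2) / ((nj - 1) * va))
    tt <- b / se
    slope[j] <- b
    pval[j] <- 2 * pt(abs(tt), nj - 2, lower.tail = FALSE)
  }
  data.frame(column = colnames(X), slope = slope, raw_p = pval,
             n_used = nUsed, stringsAsFactors = FALSE)
}

#' Scan every trait for linear association with age
#'
#' Per-trait simple linear regression on age over pairwise-complete rows;
#' multiple-choice traits are expanded into per-option indicator columns
#' first.  P-values are Bonferroni-adjusted over all scanned columns.
#' Columns with fewer than 3 complete pairs (or zero variance) are flagged
#' untestable rather than raising an error.
#'
#' @param traits raw trait matrix (individuals x traits).
#' @param age chronological ages.
#' @param metadata trait metadata (needed to expand multichoice traits);
#'   optional if all traits are continuous.
#' @return data.frame with per-column `trait` (parent trait), `column`,
#'   `slope`, `raw_p`, `adjusted_p`, `n_used`, `untestable`.
#' @export
ageRegressionScan <- function(traits, age, metadata = NULL) {
  traits <- as.matrix(traits)
  stopifnot(length(age) == nrow(traits))
  parent <- colnames(traits)
  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata)
    mc <- metadata$trait[metadata$type == "multichoice"]
    mc <- intersect(mc, colnames(traits))
    if (length(mc)) {
      keep <- setdiff(colnames(traits), mc)
      cols <- traits[, keep, drop = FALSE]
      parent <- keep
      for (id in mc) {
        opts <- strsplit(metadata$options[metadata$trait == id], ",")[[1]]
        enc <- encodeMultichoice(traits[, id], opts)
        colnames(enc) <- paste0(id, ".", opts)
        cols <- cbind(cols, enc)
        parent <- c(parent, rep(id, length(opts)))
      }
      traits <- cols
    }
  }
  sc <- slopeScan(traits, age)
  sc$trait <- parent
  sc$untestable <- is.na(sc$raw_p)
  sc$adjusted_p <- pmin(1, sc$raw_p * sum(!sc$untestable))
  sc[, c("trait", "column", "slope", "raw_p", "adjusted_p", "n_used",
         "untestable")]
}

#' Select age-sensitive traits under the eligibility criteria
#'
#' Keeps traits whose adjusted p-value is strictly below `alpha` (for a
#' multichoice trait: any of its option columns) with a non-zero slope and
#' no exclusion flag set.  Exclusion flags encode the three curation
#' criteria: the trait must not reflect societal norms, must not be a
#' function of elapsed time, and must not be derived from age itself (the
#' basal-metabolic-rate situation: an outstanding age predictor that is
#' excluded because age enters its formula).
#'
#' @param scan result of [ageRegressionScan()].
#' @param alpha significance threshold on the adjusted p-value
#'   (default 1e-3).
#' @param metadata trait metadata carrying logical `flagSocietal`,
#'   `flagElapsedTime`, `flagAgeDerived`.
#' @return list with `kept` (trait ids) and `rejected` (data.frame of
#'   trait, reason).
#' @export
selectAgeSensitive <- function(scan, alpha = 1e-3, metadata) {
  metadata <- as.data.frame(metadata)
  for (f in c("flagSocietal", "flagElapsedTime", "flagAgeDerived")) {
    v <- metadata[[f]]
    if (is.null(v) || !is.logical(v) || anyNA(v))
      stop("selectAgeSensitive: metadata flag '", f,
           "' must be logical without NA")
  }
  if (!nrow(scan))
    return(list(kept = character(0),
                rejected = data.frame(trait = character(0),
                                      reason = character(0))))
  kept <- character(0)
  rejected <- data.frame(trait = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  for (id in unique(scan$trait)) {
    rows <- scan[scan$trait == id, , drop = FALSE]
    m <- metadata[metadata$trait == id, , drop = FALSE]
    reason <- NULL
    if (nrow(m) == 1 && isTRUE(m$flagAgeDerived)) reason <- "age_derived"
    else if (nrow(m) == 1 && isTRUE(m$flagSocietal)) reason <- "societal"
    else if (nrow(m) == 1 && isTRUE(m$flagElapsedTime)) reason <- "elapsed_time"
    else if (all(rows$untestable)) reason <- "untestable"
    else {
      ok <- !rows$untestable & rows$adjusted_p < alpha & rows$slope != 0
      if (!any(ok)) reason <- "not_significant"
    }
    if (is.null(reason)) kept <- c(kept, id)
    else rejected <- rbind(rejected, data.frame(trait = id, reason = reason,
                                                stringsAsFactors = FALSE))
  }
  list(kept = kept, rejected = rejected)
}

#' Phenotype-count vs complete-participant tradeoff
#'
#' For each k, the number of individuals with zero missing values among
#' the top-k ranked traits — the curve whose elbow sets the inclusion
#' threshold when panel size trades off against cohort size.
#'
#' @param traits raw trait matrix.
#' @param rankedTraits trait ids ordered by scan significance.
#' @return data.frame with `k`, `trait`, `completeCount`; the count is
#'   monotone non-increasing in k.
#' @export
completenessTradeoff <- function(traits, rankedTraits) {
  traits <- as.matrix(traits)
  stopifnot(all(rankedTraits %in% colnames(traits)))
  miss <- is.na(traits[, rankedTraits, drop = FALSE])
  cum <- rep(0L, nrow(traits))
  counts <- integer(length(rankedTraits))
  for (k in seq_along(rankedTraits)) {
    cum <- cum + miss[, k]
    counts[k] <- sum(cum == 0L)
  }
  data.frame(k = seq_along(rankedTraits), trait = rankedTraits,
             completeCount = counts, stringsAsFactors = FALSE)
}

#' Pairwise trait correlation, distances and cluster assignment
#'
#' Pearson correlations on pairwise-complete rows, rescaled Euclidean
#' distances, an average-linkage tree on distance `1 - r`, and cluster
#' labels from cutting the tree at `nClusters`.  Zero-variance columns
#' yield missing correlations with a warning and are assigned no cluster.
#'
#' @param x standardized trait matrix (multichoice already expanded).
#' @param nClusters cluster count at which the tree is cut (default 10).
#' @return list with `pearson`, `euclidean`, `linkage` (hclust) and
#'   `clusterLabels` (named by column).
#' @export
traitCorrelation <- function(x, nClusters = 10) {
  x <- as.matrix(x)
  sds <- apply(x, 2, sd, na.rm = TRUE)
  bad <- which(sds == 0 | !is.finite(sds))
  if (length(bad))
    warning("traitCorrelation: zero-variance column(s), correlations ",
            "undefined: ", paste(colnames(x)[bad], collapse = ", "))
  r <- suppressWarnings(cor(x, use = "pairwise.complete.obs"))
  diag(r) <- 1
  p <- ncol(x)
  n <- nrow(x)
  if (!anyNA(x)) {
    S <- crossprod(x)
    sq <- diag(S)
    eu2 <- outer(sq, sq, "+") - 2 * S
    eu2[eu2 < 0] <- 0
    eu <- sqrt(eu2)
    dimnames(eu) <- dimnames(r)
    diag(eu) <- 0
  } else {
    eu <- matrix(0, p, p, dimnames = dimnames(r))
    for (i in seq_len(p)) {
      for (j in seq_len(p)) {
        if (j <= i) next
        ok <- !is.na(x[, i]) & !is.na(x[, j])
        m <- sum(ok)
        eu[i, j] <- eu[j, i] <-
          if (m) sqrt(sum((x[ok, i] - x[ok, j])^2) * n / m) else NA_real_
      }
    }
  }
  good <- setdiff(seq_len(p), bad)
  lab <- rep(NA_integer_, p)
  names(lab) <- colnames(x)
  hc <- NULL
  if (length(good) >= 2) {
    d <- 1 - r[good, good, drop = FALSE]
    d[is.na(d)] <- 2  # uncorrelatable pairs are maximally distant
    hc <- hclust(as.dist(d), method = "average")
    lab[good] <- cutree(hc, k = min(nClusters, length(good)))
  } else lab[good] <- 1L
  list(pearson = r, euclidean = eu, linkage = hc, clusterLabels = lab)
}
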