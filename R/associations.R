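#' Covariate-adjusted linear association of one outcome with many predictors
#'
#' One consistent engine for the environmental and genotype scans: each
#' predictor column is tested in the linear model
#' `outcome ~ predictor + covariates` (ordinary least squares, exact via
#' Frisch-Waugh residualization).  Rows with missing outcome, predictor or
#' covariates are dropped per predictor.  Constant predictors are flagged
#' untestable.
#'
#' @param y outcome vector.
#' @param X predictor matrix (individuals x predictors).
#' @param covariates optional covariate matrix/data.frame.
#' @return data.frame with `id`, `beta`, `se`, `p`, `n`, `untestable`.
#' @export
linearAssociation <- function(y, X, covariates = NULL) {
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == nrow(X))
  }
  ids <- colnames(X)
  if (is.null(ids)) ids <- paste0("x", seq_len(ncol(X)))
  out <- data.frame(id = ids, beta = NA_real_, se = NA_real_, p = NA_real_,
                    n = NA_integer_, untestable = FALSE,
                    stringsAsFactors = FALSE)
  baseOk <- !is.na(y)
  if (!is.null(covariates)) baseOk <- baseOk & complete.cases(covariates)
  q <- if (is.null(covariates)) 0L else ncol(covariates)
  for (j in seq_len(ncol(X))) {
    ok <- baseOk & !is.na(X[, j])
    n <- sum(ok)
    out$n[j] <- n
    if (n < q + 3) { out$untestable[j] <- TRUE; next }
    xj <- X[ok, j]
    yj <- y[ok]
    if (var(xj) == 0) { out$untestable[j] <- TRUE; next }
    if (q > 0) {
      Z <- cbind(1, covariates[ok, , drop = FALSE])
      qr_ <- qr(Z)
      xj <- qr.resid(qr_, xj)
      yj <- qr.resid(qr_, yj)
      if (sum(xj^2) < 1e-12) { out$untestable[j] <- TRUE; next }
    } else {
      xj <- xj - mean(xj)
      yj <- yj - mean(yj)
    }
    sxx <- sum(xj^2)
    beta <- sum(xj * yj) / sxx
    df <- n - 2L - q
    rss <- sum((yj - beta * xj)^2)
    se <- sqrt(rss / df / sxx)
    out$beta[j] <- beta
    out$se[j] <- se
    out$p[j] <- 2 * pt(abs(beta / se), df, lower.tail = FALSE)
  }
  out
}

expandFactors <- function(tab, standardize = TRUE) {
  cols <- list()
  for (nm in names(tab)) {
    v <- tab[[nm]]
    if (is.factor(v) || is.character(v)) {
      v <- as.factor(v)
      lev <- levels(v)
      for (l in lev[-1]) {   # first level is the reference
        ind <- as.numeric(v == l)
        ind[is.na(v)] <- NA
        cols[[paste0(nm, ".", l)]] <- ind
      }
    } else {
      x <- as.numeric(v)
      if (standardize && sd(x, na.rm = TRUE) > 0)
        x <- (x - mean(x, na.rm = TRUE)) / sd(x, na.rm = TRUE)
      cols[[nm]] <- x
    }
  }
  do.call(cbind, cols)
}

#' Scan environmental factors for association with delta-age
#'
#' Each factor enters a linear model of delta-age on the factor plus
#' covariates.  Numeric factors are standardized (effects in years per SD)
#' unless `standardize = FALSE` (years per unit); categorical factors are
#' expanded into per-level indicators against the first level.
#' Significance uses the fixed scan threshold (default 1e-5).
#'
#' @param delta delta-age values.
#' @param factors data.frame of environmental factors.
#' @param threshold significance threshold on the p-value (default 1e-5).
#' @param covariates optional covariates (e.g. age).
#' @param standardize standardize numeric factors (default TRUE).
#' @return data.frame with `id`, `beta`, `se`, `p`, `n`, `significant`,
#'   `untestable`.
#' @export
scanEnvironment <- function(delta, factors, threshold = 1e-5,
                            covariates = NULL, standardize = TRUE) {
  X <- expandFactors(as.data.frame(factors), standardize = standardize)
  res <- linearAssociation(delta, X, covariates)
  res$significant <- !res$untestable & res$p < threshold
  attr(res, "covariates") <- if (is.null(covariates)) character(0)
                             else colnames(as.data.frame(covariates))
  res
}

#' Association of delta-age with parental age at death
#'
#' Regression of parental age at death on delta-age over complete pairs;
#' a negative coefficient means people predicted biologically younger had
#' parents who lived longer.
#'
#' @param delta delta-age values.
#' @param parentAge parental age at death.
#' @return one-row data.frame with `beta`, `se`, `p`, `r`, `n`.
#' @export
parentalLifespanAssociation <- function(delta, parentAge) {
  ok <- !is.na(delta) & !is.na(parentAge)
  if (sum(ok) < 10)
    stop("parentalLifespanAssociation: fewer than 10 complete pairs")
  res <- linearAssociation(parentAge[ok],
                           matrix(delta[ok], ncol = 1,
                                  dimnames = list(NULL, "deltaAge")))
  res$r <- cor(delta[ok], parentAge[ok])
  res[, c("beta", "se", "p", "r", "n")]
}

#' Genotype dosage scan against delta-age
#'
#' Per-SNP linear model `deltaAge ~ dosage + covariates` at the
#' genome-wide threshold (default 1e-9).  Monomorphic SNPs are flagged
#' untestable.  Estimates are equivariant under allele recoding
#' (0/1/2 -> 2/1/0 flips the sign, preserves magnitude and p).
#'
#' @param delta delta-age values.
#' @param genotypes dosage matrix (individuals x SNPs, values 0/1/2).
#' @param covariates optional covariate table.
#' @param threshold significance threshold (default 1e-9).
#' @return data.frame with `id`, `beta`, `se`, `p`, `maf`, `n`,
#'   `significant`, `untestable`.
#' @export
snpScan <- function(delta, genotypes, covariates = NULL,
                    threshold = 1e-9) {
  G <- as.matrix(genotypes)
  bad <- G[!is.na(G)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("snpScan: dosages must be 0, 1 or 2")
  res <- linearAssociation(delta, G, covariates)
  res$maf <- colMeans(G, na.rm = TRUE) / 2
  res$maf <- pmin(res$maf, 1 - res$maf)
  res$significant <- !res$untestable & !is.na(res$p) & res$p < threshold
  res[, c("id", "beta", "se", "p", "maf", "n", "significant", "untestable")]
}

#' Healthy-subcohort mask
#'
#' Individuals with none of the listed diagnoses.  Associations that
#' vanish in this subcohort flag disease-susceptibility effects rather
#' than general-aging effects.
#'
#' @param diagnoses logical matrix/data.frame (individuals x diseases).
#' @param criteria diagnosis names to exclude on (default: all columns).
#' @return logical mask with attribute `excludedFraction`.
#' @export
healthySubset <- function(diagnoses, criteria = NULL) {
  D <- as.matrix(diagnoses)
  if (is.null(criteria)) criteria <- colnames(D)
  unknown <- setdiff(criteria, colnames(D))
  if (length(unknown))
    stop("healthySubset: unknown diagnosis flag(s): ",
         paste(unknown, collapse = ", "))
  mask <- rowSums(D[, criteria, drop = FALSE], na.rm = TRUE) == 0
  attr(mask, "excludedFraction") <- 1 - mean(mask)
  mask
}

#' Mean delta-age per group across age bins
#'
#' Supports genotype-by-age and habit-by-age displays: mean delta-age and
#' its standard error per (group, age-bin).
#'
#' @param delta delta-age values.
#' @param age chronological ages.
#' @param groups categorical labels.
#' @param binWidth age-bin width in years (default 5).
#' @return data.frame with `group`, `ageBin`, `mean`, `se`, `n`.
#' @export
groupProfile <- function(delta, age, groups, binWidth = 5) {
  stopifnot(length(delta) == length(age), length(age) == length(groups))
  bin <- floor(age / binWidth) * binWidth + binWidth / 2
  key <- interaction(groups, bin, drop = TRUE)
  agg <- data.frame(
    group = tapply(as.character(groups), key, `[`, 1),
    ageBin = as.numeric(tapply(bin, key, `[`, 1)),
    mean = as.numeric(tapply(delta, key, mean)),
    se = as.numeric(tapply(delta, key, function(v)
      sd(v) / sqrt(length(v)))),
    n = as.integer(tapply(delta, key, length)),
    stringsAsFactors = FALSE)
  rownames(agg) <- NULL
  agg[order(agg$group, agg$ageBin), , drop = FALSE]
}
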