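#' Build cluster-dropout clock variants
#'
#' For each trait cluster k, the full clock pipeline is refit on the trait
#' set minus cluster k — component selection included — and delta-age is
#' recomputed with fresh per-age centering.  A hit whose association with
#' delta-age survives every dropout cannot depend on any single organ
#' system's measurements.
#'
#' @param X complete standardized trait matrix (one sex).
#' @param age chronological ages.
#' @param clusterLabels cluster label per column of `X`.
#' @param maxComponents,cvFolds,seed passed to [fitPlsClock()].
#' @param binWidth,minBin passed to [computeDeltaAge()].
#' @param sex label stored on the models.
#' @return list with `models` (one [ClockModel-class] per dropped
#'   cluster), `deltaAges` (n x K matrix, one column per dropout) and
#'   `clusters` (the dropped cluster per column).
#' @export
buildDropoutModels <- function(X, age, clusterLabels, maxComponents = 10,
                               cvFolds = 10, seed = 1, binWidth = 1,
                               minBin = 50, sex = NA_character_) {
  X <- as.matrix(X)
  stopifnot(length(clusterLabels) == ncol(X))
  clusters <- unique(clusterLabels[!is.na(clusterLabels)])
  models <- list()
  D <- matrix(NA_real_, nrow(X), length(clusters),
              dimnames = list(rownames(X), as.character(clusters)))
  for (i in seq_along(clusters)) {
    keep <- which(is.na(clusterLabels) | clusterLabels != clusters[i])
    if (length(keep) < 2)
      stop("buildDropoutModels: dropping cluster '", clusters[i],
           "' leaves fewer than 2 traits")
    m <- fitPlsClock(X[, keep, drop = FALSE], age,
                     maxComponents = min(maxComponents, length(keep)),
                     cvFolds = cvFolds, seed = seed, sex = sex)
    pred <- predictAge(m, X[, keep, drop = FALSE])
    D[, i] <- deltaAge(computeDeltaAge(pred, age, binWidth = binWidth,
                                       minBin = minBin))
    models[[as.character(clusters[i])]] <- m
  }
  list(models = models, deltaAges = D, clusters = as.character(clusters))
}

#' Squared correlation between delta-age variants
#'
#' @param deltaMatrix matrix with one column per clock variant (full model
#'   first by convention), rows aligned across variants.
#' @return symmetric matrix of squared Pearson correlations with unit
#'   diagonal.
#' @export
crossModelCorrelation <- function(deltaMatrix) {
  M <- as.matrix(deltaMatrix)
  if (anyNA(M)) stop("crossModelCorrelation: delta-age vectors misaligned")
  R2 <- cor(M)^2
  diag(R2) <- 1
  R2
}

#' Association grid of hits across clock variants
#'
#' Re-runs the association engine for every hit against delta-age from
#' the full model, each cluster-dropout model, and the full model
#' restricted to the healthy subcohort.  Dropout columns use the
#' Bonferroni-corrected dropout threshold (default 7e-7); the full and
#' healthy columns use the scan threshold the hit was discovered at.
#'
#' @param hits data.frame with `id` and `type` (`"snp"` or `"env"`).
#' @param hitValues matrix of hit predictor values (individuals x hits).
#' @param deltaFull full-model delta-age.
#' @param deltaDropouts n x K matrix of dropout delta-ages (columns named
#'   by dropped cluster).
#' @param healthyMask logical healthy-subcohort mask.
#' @param clusterMembership named character vector mapping hit id to the
#'   trait cluster containing its target trait (NA if none).
#' @param covariates optional covariates.
#' @param snpThreshold,envThreshold,dropoutThreshold significance
#'   thresholds (defaults 1e-9, 1e-5, 7e-7).
#' @return A [DropoutGrid-class].
#' @export
dropoutAssociationGrid <- function(hits, hitValues, deltaFull,
                                   deltaDropouts, healthyMask,
                                   clusterMembership = NULL,
                                   covariates = NULL,
                                   snpThreshold = 1e-9,
                                   envThreshold = 1e-5,
                                   dropoutThreshold = 7e-7) {
  hitValues <- as.matrix(hitValues)
  stopifnot(nrow(hits) == ncol(hitValues),
            length(deltaFull) == nrow(hitValues),
            nrow(deltaDropouts) == nrow(hitValues))
  if (is.null(colnames(deltaDropouts)))
    stop("dropoutAssociationGrid: dropout columns must name their cluster")
  if (is.null(clusterMembership))
    clusterMembership <- setNames(rep(NA_character_, nrow(hits)), hits$id)
  fullThr <- ifelse(hits$type == "snp", snpThreshold, envThreshold)
  runCol <- function(delta, rows, thr) {
    res <- linearAssociation(delta[rows], hitValues[rows, , drop = FALSE],
                             if (is.null(covariates)) NULL
                             else covariates[rows, , drop = FALSE])
    res$significant <- !res$untestable & !is.na(res$p) & res$p < thr
    res
  }
  all <- seq_along(deltaFull)
  out <- list()
  r <- runCol(deltaFull, all, NA)
  r$significant <- !r$untestable & !is.na(r$p) & r$p < fullThr
  r$model <- "full"
  out[["full"]] <- r
  for (cl in colnames(deltaDropouts)) {
    r <- runCol(deltaDropouts[, cl], all, dropoutThreshold)
    r$model <- paste0("dropout:", cl)
    out[[r$model[1]]] <- r
  }
  r <- runCol(deltaFull, which(healthyMask), NA)
  r$significant <- !r$untestable & !is.na(r$p) & r$p < fullThr
  r$model <- "healthy"
  out[["healthy"]] <- r
  res <- do.call(rbind, out)
  res$hit <- rep(hits$id, length(out))
  rownames(res) <- NULL
  new("DropoutGrid",
      results = res[, c("hit", "model", "beta", "se", "p", "n",
                        "significant", "untestable")],
      clusterMembership = setNames(as.character(clusterMembership),
                                   names(clusterMembership)),
      dropoutClusters = colnames(deltaDropouts),
      thresholds = c(snp = snpThreshold, env = envThreshold,
                     dropout = dropoutThreshold))
}

setMethod("show", "DropoutGrid", function(object) {
  hits <- unique(object@results$hit)
  cat("DropoutGrid:", length(hits), "hits x",
      length(object@dropoutClusters), "dropout models (+ full, healthy)\n")
  sig <- with(object@results, tapply(significant, hit, sum))
  cat("  significant columns per hit:",
      paste(names(sig), sig, sep = "=", collapse = ", "), "\n")
})

#' Classify hits as drivers, markers or disease-linked
#'
#' Applies the attribution rules to a [DropoutGrid-class]:
#' \itemize{
#'   \item significant in the full model but not in the healthy subcohort
#'     -> `disease_linked` (the allele confers a disease that mimics
#'     accelerated aging);
#'   \item significant in full + every dropout + healthy ->
#'     `global_driver_candidate`;
#'   \item significant everywhere except exactly the dropout whose cluster
#'     contains its target trait -> `cluster_marker(k)` (the cystatin-C
#'     pattern);
#'   \item otherwise `inconclusive`.
#' }
#' The rationale text names the columns that failed.
#'
#' @param grid a [DropoutGrid-class].
#' @return data.frame with `hit`, `label`, `rationale`.
#' @export
classifyHits <- function(grid) {
  res <- grid@results
  hits <- unique(res$hit)
  out <- data.frame(hit = hits, label = NA_character_,
                    rationale = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(hits)) {
    h <- hits[i]
    rows <- res[res$hit == h, , drop = FALSE]
    sig <- setNames(rows$significant, rows$model)
    dropCols <- paste0("dropout:", grid@dropoutClusters)
    failed <- names(sig)[!sig]
    member <- grid@clusterMembership[h]
    if (!isTRUE(sig[["full"]])) {
      out$label[i] <- "inconclusive"
      out$rationale[i] <- "not significant in the full model"
    } else if (!isTRUE(sig[["healthy"]])) {
      out$label[i] <- "disease_linked"
      out$rationale[i] <- paste("lost in the healthy subcohort;",
                                "non-significant columns:",
                                paste(failed, collapse = ", "))
    } else if (all(sig[dropCols])) {
      out$label[i] <- "global_driver_candidate"
      out$rationale[i] <- "significant in full, healthy and every dropout"
    } else {
      lost <- dropCols[!sig[dropCols]]
      lostCl <- sub("^dropout:", "", lost)
      if (length(lost) == 1 &&
          (is.na(member) || identical(unname(member), lostCl))) {
        out$label[i] <- paste0("cluster_marker(", lostCl, ")")
        out$rationale[i] <- paste0("lost only in dropout of cluster '",
                                   lostCl, "'")
      } else {
        out$label[i] <- "inconclusive"
        out$rationale[i] <- paste("non-significant columns:",
                                  paste(failed, collapse = ", "))
      }
    }
  }
  out
}
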