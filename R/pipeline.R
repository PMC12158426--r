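#' Read a phenotype table and its trait metadata
#'
#' Expects `phenotypes.tsv` (header `id` + one column per trait) and
#' `metadata.tsv` (`trait`, `type`, `cluster`, `options`, flag columns) in
#' `dir`.  Individual ids must be unique; trait types must be
#' `"continuous"` or `"multichoice"`.
#'
#' @param dir directory containing the two files.
#' @return list with `traits` (matrix, rownames = ids) and `metadata`.
#' @export
readPhenotypeTable <- function(dir) {
  pf <- file.path(dir, "phenotypes.tsv")
  mf <- file.path(dir, "metadata.tsv")
  for (f in c(pf, mf)) if (!file.exists(f)) stop("missing file: ", f)
  ph <- read.delim(pf, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"id" %in% names(ph)) stop(pf, ": no 'id' column")
  dup <- ph$id[duplicated(ph$id)]
  if (length(dup))
    stop(pf, ": duplicate id(s): ", paste(unique(dup), collapse = ", "),
         " (rows ", paste(which(ph$id %in% dup) + 1, collapse = ", "), ")")
  md <- read.delim(mf, stringsAsFactors = FALSE)
  bad <- setdiff(unique(md$type), c("continuous", "multichoice"))
  if (length(bad))
    stop(mf, ": unknown trait type token(s): ", paste(bad, collapse = ", "))
  X <- as.matrix(ph[, setdiff(names(ph), "id"), drop = FALSE])
  rownames(X) <- ph$id
  extra <- setdiff(colnames(X), md$trait)
  if (length(extra))
    stop(pf, ": trait column(s) absent from metadata: ",
         paste(extra, collapse = ", "))
  list(traits = X, metadata = md)
}

#' Read a VCF-lite genotype table
#'
#' A minimal tab-separated variant format for interoperability: columns
#' `CHROM`, `POS`, `ID`, then one dosage column (0/1/2) per individual.
#' Converted on read to the individuals x SNPs dosage matrix the
#' association scans consume.
#'
#' @param path TSV file (a leading `#` on the header line is tolerated).
#' @return individuals x SNPs integer dosage matrix.
#' @export
readVcfLite <- function(path) {
  header <- sub("^#", "", readLines(path, n = 1))
  cols <- strsplit(header, "\t")[[1]]
  tab <- read.delim(path, skip = 1, header = FALSE,
                    stringsAsFactors = FALSE)
  names(tab) <- cols
  need <- c("CHROM", "POS", "ID")
  if (!all(need %in% cols))
    stop("readVcfLite: ", path, " must carry columns ",
         paste(need, collapse = ", "))
  samples <- setdiff(cols, need)
  G <- t(as.matrix(tab[, samples, drop = FALSE]))
  colnames(G) <- tab$ID
  bad <- G[!is.na(G)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("readVcfLite: dosages must be 0, 1 or 2")
  storage.mode(G) <- "integer"
  G
}

#' Read a cohort directory written by [writeCohort()]
#'
#' @param dir cohort directory.
#' @return An [AgingCohort-class] (without generative truth if
#'   `truth.tsv` is absent).
#' @export
readCohort <- function(dir) {
  tab <- readPhenotypeTable(dir)
  oc <- read.delim(file.path(dir, "outcomes.tsv"),
                   stringsAsFactors = FALSE)
  stopifnot(identical(oc$id, rownames(tab$traits)))
  gf <- file.path(dir, "genotypes.tsv")
  vf <- file.path(dir, "genotypes.vcf")
  G <- if (file.exists(gf)) {
    g <- read.delim(gf, check.names = FALSE, stringsAsFactors = FALSE)
    as.matrix(g[, setdiff(names(g), "id"), drop = FALSE])
  } else if (file.exists(vf)) {
    readVcfLite(vf)
  } else matrix(0L, nrow(tab$traits), 0)
  ef <- file.path(dir, "environment.tsv")
  env <- if (file.exists(ef)) {
    e <- read.delim(ef, stringsAsFactors = FALSE)
    e[, setdiff(names(e), "id"), drop = FALSE]
  } else data.frame(row.names = oc$id)
  disCols <- setdiff(names(oc), c("id", "age", "sex", "diedInFollowup",
                                  "parentDeathAge"))
  dis <- as.matrix(oc[, disCols, drop = FALSE]) == TRUE
  tf <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(tf)) {
    tr <- read.delim(tf, stringsAsFactors = FALSE)
    data.frame(delta_true = tr$delta_true, row.names = tr$id)
  } else data.frame(row.names = oc$id)
  rownames(G) <- rownames(dis) <- rownames(env) <- oc$id
  md <- tab$metadata
  rd <- DataFrame(md, row.names = md$trait)
  cd <- DataFrame(age = oc$age, sex = oc$sex,
                  diedInFollowup = oc$diedInFollowup,
                  parentDeathAge = oc$parentDeathAge, row.names = oc$id)
  se <- SummarizedExperiment(assays = list(traits = t(tab$traits)),
                             colData = cd, rowData = rd)
  new("AgingCohort", se, genotypes = G, environment = env,
      diagnoses = dis, truth = truth)
}

#' Run configuration for the end-to-end pipeline
#'
#' Consolidates the pipeline's constants: trait-selection alpha 1e-3,
#' environmental-scan threshold 1e-5, genome-wide SNP threshold 1e-9,
#' Bonferroni dropout threshold 7e-7, missingness filter 15 cells, KNN
#' k = 10, 10 CV folds, 10 trait clusters.
#'
#' @param cohort a [cohortConfig()] (simulate on the fly) or a directory
#'   written by [writeCohort()].
#' @param trait_alpha,env_threshold,snp_threshold,dropout_threshold
#'   significance thresholds.
#' @param max_missing,knn_k,cv_folds,max_components,n_clusters,bin_width,
#'   min_bin,delta_bin_width pipeline parameters.
#' @param seed integer master seed for analysis-stage randomness (CV
#'   folds).
#' @return validated `runConfig` list.
#' @export
runConfig <- function(cohort = cohortConfig(),
                      trait_alpha = 1e-3, env_threshold = 1e-5,
                      snp_threshold = 1e-9, dropout_threshold = 7e-7,
                      max_missing = 15, knn_k = 10, cv_folds = 10,
                      max_components = 6, n_clusters = 10,
                      bin_width = 1, min_bin = 50, delta_bin_width = 1,
                      seed = 1L) {
  thr <- c(trait_alpha, env_threshold, snp_threshold, dropout_threshold)
  if (any(thr <= 0 | thr >= 1))
    stop("runConfig: thresholds must lie in (0, 1)")
  if (max_missing < 0) stop("runConfig: max_missing must be >= 0")
  structure(list(cohort = cohort, trait_alpha = trait_alpha,
                 env_threshold = env_threshold,
                 snp_threshold = snp_threshold,
                 dropout_threshold = dropout_threshold,
                 max_missing = max_missing, knn_k = knn_k,
                 cv_folds = cv_folds, max_components = max_components,
                 n_clusters = n_clusters, bin_width = bin_width,
                 min_bin = min_bin, delta_bin_width = delta_bin_width,
                 seed = as.integer(seed)),
            class = "runConfig")
}

#' Sex-stratified clock analysis of a cohort
#'
#' The core analysis chain: scan traits for age sensitivity, apply the
#' eligibility criteria, preprocess (encode, standardize, filter, impute)
#' per sex, fit a PLS clock per sex with cross-validated component
#' selection, and compute age-centered delta-age.  Trait clusters are
#' estimated from the pooled standardized matrix.  Ground-truth fields of
#' the cohort are never read.
#'
#' @param cohort an [AgingCohort-class].
#' @param config a [runConfig()].
#' @return list with `scan`, `selection`, per-sex results (`model`,
#'   `ids`, `predicted`, `delta`), pooled `delta` (named by individual,
#'   NA for excluded rows), `clusterLabels` (estimated, per column),
#'   `columnInfo`, and `clusterOf(trait)` mapping.
#' @export
analyzeCohort <- function(cohort, config = runConfig()) {
  X <- traitMatrix(cohort)
  md <- traitData(cohort)
  age <- ages(cohort)
  sex <- sexes(cohort)
  ids <- colnames(cohort)

  scan <- ageRegressionScan(X, age, md)
  sel <- selectAgeSensitive(scan, alpha = config$trait_alpha, metadata = md)
  if (length(sel$kept) < 2)
    stop("analyzeCohort: fewer than 2 age-sensitive traits selected")

  perSex <- list()
  for (s in unique(sex)) {
    rows <- which(sex == s)
    prep <- preprocessTraits(X[rows, sel$kept, drop = FALSE], md,
                             maxMissing = config$max_missing,
                             k = config$knn_k)
    keptRows <- rows[prep$kept]
    model <- fitPlsClock(prep$X, age[keptRows],
                         maxComponents = config$max_components,
                         cvFolds = config$cv_folds,
                         seed = config$seed + match(s, c("F", "M"), 0L),
                         sex = s, scaler = prep$scaler)
    pred <- predictAge(model, prep$X)
    da <- computeDeltaAge(pred, age[keptRows],
                          binWidth = config$bin_width,
                          minBin = config$min_bin)
    perSex[[s]] <- list(rows = keptRows, ids = ids[keptRows],
                        age = age[keptRows],
                        X = prep$X, model = model, predicted = pred,
                        deltaResult = da, delta = deltaAge(da),
                        columnInfo = prep$columnInfo)
  }

  ## correlation structure estimated from the pooled standardized matrix
  common <- Reduce(intersect, lapply(perSex, function(p) colnames(p$X)))
  pooled <- do.call(rbind, lapply(perSex, function(p)
    p$X[, common, drop = FALSE]))
  tc <- traitCorrelation(pooled, nClusters = config$n_clusters)

  ## dropout clusters come from the curated metadata labels (as supplied
  ## with the trait panel); the estimated tree stands in only when the
  ## metadata carries no cluster assignment
  info <- perSex[[1]]$columnInfo
  clusterLabels <- setNames(info$cluster[match(common, info$column)],
                            common)
  if (all(is.na(clusterLabels)))
    clusterLabels <- setNames(paste0("c", tc$clusterLabels[common]), common)
  clusterOfTrait <- function(trait) {
    col <- info$column[info$parent == trait][1]
    if (is.na(col) || !col %in% names(clusterLabels)) NA_character_
    else unname(clusterLabels[col])
  }

  delta <- setNames(rep(NA_real_, length(ids)), ids)
  predicted <- setNames(rep(NA_real_, length(ids)), ids)
  for (p in perSex) {
    delta[p$rows] <- p$delta
    predicted[p$rows] <- p$predicted
  }
  list(scan = scan, selection = sel, perSex = perSex, delta = delta,
       predicted = predicted, clusterLabels = clusterLabels,
       correlation = tc, columnInfo = info,
       clusterOf = clusterOfTrait, config = config)
}

#' Dropout delta-age variants for an analyzed cohort
#'
#' Refits the clock per sex with each estimated trait cluster removed and
#' returns the pooled delta-age matrix (rows = analyzed individuals of
#' the cohort, one column per dropped cluster), alongside the per-sex
#' model lists.
#'
#' @param analysis result of [analyzeCohort()].
#' @return list with `deltaAges` (full-cohort-length matrix, NA for
#'   excluded rows), `models`, `clusters`.
#' @export
dropoutDeltaAges <- function(analysis) {
  cfg <- analysis$config
  lab <- analysis$clusterLabels
  clusters <- sort(unique(lab))
  n <- length(analysis$delta)
  D <- matrix(NA_real_, n, length(clusters),
              dimnames = list(names(analysis$delta), clusters))
  models <- list()
  for (s in names(analysis$perSex)) {
    p <- analysis$perSex[[s]]
    cols <- intersect(colnames(p$X), names(lab))
    bd <- buildDropoutModels(p$X[, cols, drop = FALSE], p$age,
                             clusterLabels = lab[cols],
                             maxComponents = cfg$max_components,
                             cvFolds = cfg$cv_folds, seed = cfg$seed,
                             binWidth = cfg$bin_width,
                             minBin = cfg$min_bin, sex = s)
    D[p$rows, bd$clusters] <- bd$deltaAges
    models[[s]] <- bd$models
  }
  list(deltaAges = D, models = models, clusters = clusters)
}

#' Run the full pipeline end to end
#'
#' simulate (or load) -> select -> preprocess -> fit clocks per sex ->
#' delta-age -> mortality analyses -> association scans -> dropout grid ->
#' hit labels, writing every stage's tables plus a JSON manifest to
#' `outDir`.  Output is a deterministic function of the configuration.
#'
#' @param config a [runConfig()].
#' @param outDir output directory.
#' @return invisible list with all stage results.
#' @export
runPipeline <- function(config, outDir) {
  stopifnot(inherits(config, "runConfig"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  warnings <- character(0)
  wh <- function(w) { warnings <<- c(warnings, conditionMessage(w))
                      invokeRestart("muffleWarning") }

  cohort <- if (inherits(config$cohort, "cohortConfig"))
    generateCohort(config$cohort)
  else readCohort(config$cohort)

  res <- withCallingHandlers({
    analysis <- analyzeCohort(cohort, config)
    age <- ages(cohort)
    died <- diedInFollowup(cohort)
    ok <- !is.na(analysis$delta)

    mortAge <- binnedMortality(age, died, binWidth = config$bin_width,
                               minBin = config$min_bin)
    gompAge <- fitGompertz(mortAge)
    mortDelta <- deltaAgeMortality(analysis$delta[ok], died[ok],
                                   binWidth = config$delta_bin_width,
                                   minBin = config$min_bin)
    yeq <- yearEquivalence(age[ok], analysis$delta[ok], died[ok])

    envScan <- scanEnvironment(analysis$delta[ok],
                               environmentData(cohort)[ok, , drop = FALSE],
                               threshold = config$env_threshold)
    par <- parentalLifespanAssociation(analysis$delta[ok],
                                       parentDeathAge(cohort)[ok])
    snps <- snpScan(analysis$delta[ok],
                    genotypes(cohort)[ok, , drop = FALSE],
                    threshold = config$snp_threshold)
    healthy <- healthySubset(diagnoses(cohort))

    drop <- dropoutDeltaAges(analysis)
    sigSnp <- snps$id[snps$significant]
    sigEnv <- envScan$id[envScan$significant]
    grid <- NULL; labels <- NULL
    if (length(sigSnp) + length(sigEnv) > 0) {
      hv <- cbind(genotypes(cohort)[, sigSnp, drop = FALSE],
                  expandFactors(environmentData(cohort))[
                    , sigEnv, drop = FALSE])
      hits <- data.frame(id = c(sigSnp, sigEnv),
                         type = c(rep("snp", length(sigSnp)),
                                  rep("env", length(sigEnv))),
                         stringsAsFactors = FALSE)
      member <- hitClusterMembership(cohort, hits$id, analysis)
      grid <- dropoutAssociationGrid(
        hits, hv[ok, , drop = FALSE], analysis$delta[ok],
        drop$deltaAges[ok, , drop = FALSE], healthy[ok],
        clusterMembership = member,
        snpThreshold = config$snp_threshold,
        envThreshold = config$env_threshold,
        dropoutThreshold = config$dropout_threshold)
      labels <- classifyHits(grid)
    }
    list(cohort = cohort, analysis = analysis, mortAge = mortAge,
         gompAge = gompAge, mortDelta = mortDelta, yearEquivalence = yeq,
         envScan = envScan, parental = par, snpScan = snps,
         healthy = healthy, dropout = drop, grid = grid, labels = labels)
  }, warning = wh)

  writePipelineOutputs(res, config, outDir, warnings)
  invisible(res)
}

## map hit ids to the estimated cluster containing their target trait
hitClusterMembership <- function(cohort, hitIds, analysis) {
  info <- metadata(cohort)$snpInfo
  member <- setNames(rep(NA_character_, length(hitIds)), hitIds)
  if (is.null(info)) return(member)
  for (h in hitIds) {
    i <- match(h, info$id)
    if (!is.na(i) && info$mode[i] == "cluster_marker")
      member[h] <- analysis$clusterOf(info$target[i])
  }
  member
}

writePipelineOutputs <- function(res, config, outDir, warnings) {
  a <- res$analysis
  writeTsv(a$scan, file.path(outDir, "scan.tsv"))
  writeTsv(data.frame(trait = a$selection$kept),
           file.path(outDir, "selected_traits.tsv"))
  writeTsv(data.frame(column = names(a$clusterLabels),
                      cluster = unname(a$clusterLabels)),
           file.path(outDir, "clusters.tsv"))
  writeTsv(data.frame(id = names(a$delta), delta_age = unname(a$delta),
                      predicted_age = unname(a$predicted)),
           file.path(outDir, "delta_age.tsv"))
  for (s in names(a$perSex)) {
    m <- a$perSex[[s]]$model
    jsonlite::write_json(
      list(sex = s, traits = m@traits, componentCount = m@componentCount,
           coefficients = as.list(m@coefficients),
           intercept = m@intercept, rmsep = m@rmsepCurve,
           calibration = as.list(m@calibration), cvFolds = m@cvFolds,
           scaler = m@scaler, seed = m@seed),
      file.path(outDir, paste0("clock_", s, ".json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  writeTsv(res$mortAge, file.path(outDir, "mortality_age.tsv"))
  writeTsv(res$mortDelta$table, file.path(outDir, "mortality_delta.tsv"))
  g <- res$gompAge
  jsonlite::write_json(
    list(age_fit = list(A = g@A, b = g@b, doubling_time = g@doublingTime,
                        ci_b = g@ciB, r_squared = g@rSquared),
         delta_fit = list(A = res$mortDelta$fit@A, b = res$mortDelta$fit@b,
                          r_squared = res$mortDelta$fit@rSquared),
         year_equivalence = res$yearEquivalence[c("ratio", "ci", "b_age",
                                                  "b_delta")]),
    file.path(outDir, "mortality_fits.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeTsv(res$envScan, file.path(outDir, "env_scan.tsv"))
  writeTsv(res$parental, file.path(outDir, "parental.tsv"))
  writeTsv(res$snpScan, file.path(outDir, "snp_scan.tsv"))
  writeTsv(res$snpScan[, c("id", "beta", "se", "p", "maf")],
           file.path(outDir, "summary_statistics.tsv"))
  R2 <- crossModelCorrelation(
    cbind(full = a$delta[!is.na(a$delta)],
          res$dropout$deltaAges[!is.na(a$delta), , drop = FALSE]))
  writeTsv(data.frame(model = rownames(R2), R2, check.names = FALSE),
           file.path(outDir, "dropout_r2.tsv"))
  if (!is.null(res$grid))
    writeTsv(res$grid@results, file.path(outDir, "dropout_grid.tsv"))
  else writeTsv(data.frame(hit = character(0), model = character(0),
                           beta = numeric(0), p = numeric(0)),
                file.path(outDir, "dropout_grid.tsv"))
  if (!is.null(res$labels))
    writeTsv(res$labels, file.path(outDir, "hit_labels.tsv"))
  else writeTsv(data.frame(hit = character(0), label = character(0)),
                file.path(outDir, "hit_labels.tsv"))
  manifest <- list(
    package_version = as.character(packageVersion("physage")),
    seed = config$seed,
    config = config[setdiff(names(config), "cohort")],
    cohort = if (inherits(config$cohort, "cohortConfig"))
      config$cohort else list(input_dir = config$cohort),
    counts = list(
      individuals = ncol(res$cohort),
      analyzed = sum(!is.na(a$delta)),
      traits_scanned = nrow(a$scan),
      traits_selected = length(a$selection$kept),
      deaths = sum(diedInFollowup(res$cohort)),
      healthy_fraction = mean(res$healthy)),
    component_counts = lapply(a$perSex, function(p)
      p$model@componentCount),
    warnings = warnings)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(outDir)
}
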