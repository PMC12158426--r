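#' AgingCohort: a cohort of individuals with traits, genotypes and outcomes
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with the additional
#' tables a biological-age study carries.  The single assay `"traits"` holds
#' the trait matrix (traits in rows, individuals in columns; multiple-choice
#' traits stored as integer option codes).  `colData` holds per-individual
#' phenotypes: `age` (years), `sex` (`"F"`/`"M"`), `diedInFollowup`,
#' `parentDeathAge`.  `rowData` holds per-trait metadata: `type`
#' (`"continuous"` or `"multichoice"`), `cluster`, the exclusion flags
#' `flagSocietal`, `flagElapsedTime`, `flagAgeDerived`, and `options`
#' (comma-separated option labels for multichoice traits).
#'
#' Extra slots:
#' \describe{
#'   \item{genotypes}{individuals x SNPs dosage matrix (0/1/2).}
#'   \item{environment}{individuals x factors data.frame.}
#'   \item{diagnoses}{individuals x diseases logical matrix.}
#'   \item{truth}{generative ground truth (e.g. `delta_true`), kept apart
#'     from the analysis-facing accessors; only [trueDelta()] reads it and
#'     no analysis stage accepts it.}
#' }
#'
#' @aliases AgingCohort-class
#' @export
setClass("AgingCohort",
  contains = "SummarizedExperiment",
  slots = c(
    genotypes = "matrix",
    environment = "data.frame",
    diagnoses = "matrix",
    truth = "data.frame"
  )
)

setValidity("AgingCohort", function(object) {
  n <- ncol(object)
  msg <- character()
  if (!"traits" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'traits' is required")
  need <- c("age", "sex", "diedInFollowup", "parentDeathAge")
  miss <- setdiff(need, colnames(SummarizedExperiment::colData(object)))
  if (length(miss))
    msg <- c(msg, paste("colData misses:", paste(miss, collapse = ", ")))
  for (nm in c("genotypes", "diagnoses")) {
    s <- slot(object, nm)
    if (length(s) && nrow(s) != n)
      msg <- c(msg, paste0("slot '", nm, "' row count != cohort size"))
  }
  if (nrow(object@environment) && nrow(object@environment) != n)
    msg <- c(msg, "environment row count != cohort size")
  if (nrow(object@truth) && nrow(object@truth) != n)
    msg <- c(msg, "truth row count != cohort size")
  g <- object@genotypes
  if (length(g) && !all(g[!is.na(g)] %in% 0:2))
    msg <- c(msg, "genotype dosages must be 0, 1 or 2")
  if (length(msg)) msg else TRUE
})

#' ClockModel: a fitted PLS age clock
#'
#' Holds the fitted sex-stratified PLS1 regression of age on standardized
#' traits: per-component X-weights (`xWeights`), X-loadings (`xLoadings`),
#' y-loadings (`yLoadings`), the collapsed coefficient vector
#' (years per SD of each trait), intercept, the cross-validated RMSEP curve
#' (first entry is the intercept-only model), the selected component count
#' and the slope-calibration applied to predictions.
#'
#' @aliases ClockModel-class
#' @export
setClass("ClockModel", slots = c(
  sex = "character",
  traits = "character",
  componentCount = "integer",
  xWeights = "matrix",
  xLoadings = "matrix",
  yLoadings = "numeric",
  coefficients = "numeric",
  intercept = "numeric",
  rmsepCurve = "data.frame",
  cvFolds = "integer",
  calibration = "numeric",
  scaler = "data.frame",
  seed = "integer"
))

setValidity("ClockModel", function(object) {
  msg <- character()
  p <- length(object@traits)
  if (length(object@coefficients) != p)
    msg <- c(msg, "coefficient vector length != trait count")
  if (object@componentCount < 1L || object@componentCount > ncol(object@xWeights))
    msg <- c(msg, "componentCount outside fitted range")
  if (!all(c("ncomp", "rmsep", "se") %in% names(object@rmsepCurve)))
    msg <- c(msg, "rmsepCurve needs columns ncomp, rmsep, se")
  if (nrow(object@rmsepCurve) && object@rmsepCurve$ncomp[1] != 0)
    msg <- c(msg, "rmsepCurve must start with the intercept-only entry")
  if (length(msg)) msg else TRUE
})

#' DeltaAgeResult: per-individual age-centered delta-age
#'
#' `deltaAge` is the residual (predicted minus chronological age) after
#' subtracting the mean residual of each chronological-age bin, so that the
#' population mean delta-age is exactly zero at every age.
#'
#' @aliases DeltaAgeResult-class
#' @export
setClass("DeltaAgeResult", slots = c(
  predictedAge = "numeric",
  deltaAge = "numeric",
  ageBin = "numeric",
  binMeans = "numeric"
))

setValidity("DeltaAgeResult", function(object) {
  n <- length(object@deltaAge)
  if (length(object@predictedAge) != n || length(object@ageBin) != n)
    return("predictedAge, deltaAge and ageBin must have equal length")
  TRUE
})

#' GompertzFit: an exponential (Gompertz) fit to binned mortality
#'
#' Mortality hazard h(t) = A * exp(b * t); `doublingTime = log(2)/b`.
#' Fitted by weighted least squares of log(rate) on bin centers with
#' death-count weights.
#'
#' @aliases GompertzFit-class
#' @export
setClass("GompertzFit", slots = c(
  A = "numeric",
  b = "numeric",
  doublingTime = "numeric",
  ciB = "numeric",
  rSquared = "numeric",
  nBins = "integer",
  seB = "numeric"
))

setValidity("GompertzFit", function(object) {
  msg <- character()
  if (length(object@ciB) != 2)
    msg <- c(msg, "ciB must be a length-2 interval")
  if (is.finite(object@b) && object@b > 0 && object@doublingTime <= 0)
    msg <- c(msg, "doublingTime must be positive when b > 0")
  if (length(object@ciB) == 2 && is.finite(object@b) &&
      !(object@ciB[1] <= object@b && object@b <= object@ciB[2]))
    msg <- c(msg, "ciB must contain b")
  if (length(msg)) msg else TRUE
})

#' DropoutGrid: hits x (full + dropout + healthy) association grid
#'
#' Long-format association results of each hit (SNP or environmental
#' factor) against delta-age from the full clock, each cluster-dropout
#' clock, and the full clock restricted to the healthy subcohort, plus the
#' map from hit to the trait cluster containing its target trait (if any).
#'
#' @aliases DropoutGrid-class
#' @export
setClass("DropoutGrid", slots = c(
  results = "data.frame",
  clusterMembership = "character",
  dropoutClusters = "character",
  thresholds = "numeric"
))

setValidity("DropoutGrid", function(object) {
  msg <- character()
  need <- c("hit", "model", "beta", "se", "p", "n", "significant")
  miss <- setdiff(need, names(object@results))
  if (length(miss))
    msg <- c(msg, paste("results misses columns:", paste(miss, collapse = ", ")))
  if (!"full" %in% object@results$model)
    msg <- c(msg, "full-model column is required")
  if (length(msg)) msg else TRUE
})
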