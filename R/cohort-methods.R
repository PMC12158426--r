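#' @rdname accessors
#' @export
setMethod("traitMatrix", "AgingCohort", function(x) t(assay(x, "traits")))

#' @rdname accessors
#' @export
setMethod("traitData", "AgingCohort", function(x)
  as.data.frame(rowData(x)))

#' @rdname accessors
#' @export
setMethod("ages", "AgingCohort", function(x) colData(x)$age)

#' @rdname accessors
#' @export
setMethod("sexes", "AgingCohort", function(x) colData(x)$sex)

#' @rdname accessors
#' @export
setMethod("genotypes", "AgingCohort", function(x) x@genotypes)

#' @rdname accessors
#' @export
setMethod("environmentData", "AgingCohort", function(x) x@environment)

#' @rdname accessors
#' @export
setMethod("diagnoses", "AgingCohort", function(x) x@diagnoses)

#' @rdname accessors
#' @export
setMethod("diedInFollowup", "AgingCohort", function(x)
  colData(x)$diedInFollowup)

#' @rdname accessors
#' @export
setMethod("parentDeathAge", "AgingCohort", function(x)
  colData(x)$parentDeathAge)

#' @rdname accessors
#' @export
setMethod("trueDelta", "AgingCohort", function(x) x@truth$delta_true)

setMethod("show", "AgingCohort", function(object) {
  cat("AgingCohort with", ncol(object), "individuals and",
      nrow(object), "traits\n")
  cat("  age range:",
      paste(round(range(colData(object)$age), 1), collapse = "-"),
      " sexes:", paste(names(table(colData(object)$sex)),
                       table(colData(object)$sex), collapse = " "), "\n")
  cat("  SNPs:", ncol(object@genotypes),
      " environment factors:", ncol(object@environment),
      " diseases:", ncol(object@diagnoses), "\n")
  cat("  deaths in follow-up:", sum(colData(object)$diedInFollowup), "\n")
})

#' Write a cohort as a directory of TSV files
#'
#' Writes `phenotypes.tsv`, `metadata.tsv`, `genotypes.tsv`,
#' `environment.tsv`, `outcomes.tsv`, `truth.tsv` and a JSON `manifest.json`
#' recording the generating configuration and seed.  All numeric output is
#' formatted deterministically so repeated writes are byte-identical.
#'
#' @param cohort an [AgingCohort-class].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  X <- traitMatrix(cohort)
  writeTsv(data.frame(id = rownames(X), X, check.names = FALSE),
           file.path(dir, "phenotypes.tsv"))
  writeTsv(traitData(cohort), file.path(dir, "metadata.tsv"))
  G <- genotypes(cohort)
  writeTsv(data.frame(id = colnames(cohort), G, check.names = FALSE),
           file.path(dir, "genotypes.tsv"))
  env <- environmentData(cohort)
  writeTsv(cbind(data.frame(id = colnames(cohort)), env),
           file.path(dir, "environment.tsv"))
  cd <- as.data.frame(colData(cohort))
  out <- cbind(data.frame(id = rownames(cd)), cd,
               as.data.frame(diagnoses(cohort)))
  writeTsv(out, file.path(dir, "outcomes.tsv"))
  writeTsv(data.frame(id = colnames(cohort), cohort@truth),
           file.path(dir, "truth.tsv"))
  cfg <- metadata(cohort)$config
  note <- list(
    seed = cfg$seed, n_individuals = cfg$n_individuals,
    age_distribution = "uniform (assumed; flagged as a modelling choice)",
    config = cfg)
  jsonlite::write_json(note, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  invisible(dir)
}
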