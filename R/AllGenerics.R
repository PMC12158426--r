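#' @name accessors
#' @title Accessors for AgingCohort and result objects
#'
#' @description Analysis-facing accessors.  `traitMatrix()` returns the
#' individuals x traits matrix (transpose of the assay), `traitData()` the
#' per-trait metadata, `ages()`, `sexes()`, `diedInFollowup()`,
#' `parentDeathAge()` the per-individual phenotypes, `genotypes()`,
#' `environmentData()` and `diagnoses()` the side tables.  `trueDelta()`
#' exposes the generator's hidden aging offset and exists only to validate
#' the pipeline against ground truth; no analysis function accepts it.
#'
#' @param x an object.
#' @return The requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("traitMatrix", function(x) standardGeneric("traitMatrix"))
#' @rdname accessors
#' @export
setGeneric("traitData", function(x) standardGeneric("traitData"))
#' @rdname accessors
#' @export
setGeneric("ages", function(x) standardGeneric("ages"))
#' @rdname accessors
#' @export
setGeneric("sexes", function(x) standardGeneric("sexes"))
#' @rdname accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
#' @rdname accessors
#' @export
setGeneric("environmentData", function(x) standardGeneric("environmentData"))
#' @rdname accessors
#' @export
setGeneric("diagnoses", function(x) standardGeneric("diagnoses"))
#' @rdname accessors
#' @export
setGeneric("diedInFollowup", function(x) standardGeneric("diedInFollowup"))
#' @rdname accessors
#' @export
setGeneric("parentDeathAge", function(x) standardGeneric("parentDeathAge"))
#' @rdname accessors
#' @export
setGeneric("trueDelta", function(x) standardGeneric("trueDelta"))
#' @rdname accessors
#' @export
setGeneric("deltaAge", function(x) standardGeneric("deltaAge"))
#' @rdname accessors
#' @export
setGeneric("predictedAge", function(x) standardGeneric("predictedAge"))
#' @rdname accessors
#' @export
setGeneric("doublingTime", function(x) standardGeneric("doublingTime"))
#' @rdname accessors
#' @export
setGeneric("componentCount", function(x) standardGeneric("componentCount"))
#' @rdname accessors
#' @export
setGeneric("rmsepCurve", function(x) standardGeneric("rmsepCurve"))
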