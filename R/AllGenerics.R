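#' @rdname ApoeCohort-class
#' @param object an object.
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))

#' @rdname ApoeCohort-class
#' @export
setGeneric("subjects", function(object) standardGeneric("subjects"))

#' @rdname ApoeCohort-class
#' @export
setGeneric("analysisSet", function(object) standardGeneric("analysisSet"))

#' @rdname ApoeCohort-class
#' @export
setGeneric("exclusionLedger", function(object) standardGeneric("exclusionLedger"))

#' Collapse duplicate samples into harmonized subject records
#'
#' @param object an [ApoeCohort-class] object.
#' @param ... further arguments for methods.
#' @export
setGeneric("harmonizeDuplicates",
           function(object, ...) standardGeneric("harmonizeDuplicates"))

#' Adjudicate one prioritized APOE genotype per subject
#'
#' @param object an [ApoeCohort-class] object with harmonized subjects.
#' @param ... further arguments for methods.
#' @export
setGeneric("adjudicate", function(object, ...) standardGeneric("adjudicate"))

#' Apply the study inclusion filters (age, diagnosis)
#'
#' @param object an [ApoeCohort-class] object.
#' @param ... further arguments for methods.
#' @export
setGeneric("applyInclusionFilters",
           function(object, ...) standardGeneric("applyInclusionFilters"))

#' Observed frequency under the misclassification model
#'
#' @param object a [MisclassModel-class] object.
#' @export
setGeneric("observedFrequency",
           function(object) standardGeneric("observedFrequency"))

#' Concordance between observed and true carrier status
#'
#' @param object a [MisclassModel-class] object.
#' @export
setGeneric("concordanceObservedTrue",
           function(object) standardGeneric("concordanceObservedTrue"))

#' Monte-Carlo estimate of observed-vs-true concordance
#'
#' @param object a [MisclassModel-class] object.
#' @param ... further arguments for methods.
#' @export
setGeneric("monteCarloConcordance",
           function(object, ...) standardGeneric("monteCarloConcordance"))

#' Normalized linkage disequilibrium D'
#'
#' @param object a [HaplotypeFreqs-class] object.
#' @export
setGeneric("dprime", function(object) standardGeneric("dprime"))

#' @rdname HaplotypeFreqs-class
#' @param object an object.
#' @export
setGeneric("haplotypeFreqs", function(object) standardGeneric("haplotypeFreqs"))
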