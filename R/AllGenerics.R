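#' @include AllClasses.R
NULL

#' Accessors for VEMap and ModelBundle objects
#'
#' \code{scores}, \code{stderrs} and \code{provenance} return the three
#' 21 x L assay matrices of a \linkS4class{VEMap}; \code{anchors} and
#' \code{wtSequence} return the normalization anchors and wild-type
#' sequence recorded in its metadata. \code{qualityCutoff},
#' \code{cvRMSE} and \code{featureImportances} expose the training
#' metadata of a \linkS4class{ModelBundle}.
#'
#' @param object a \code{VEMap} or \code{ModelBundle}
#' @return the requested component
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("scores", function(object) standardGeneric("scores"))

#' @rdname accessors
#' @export
setGeneric("stderrs", function(object) standardGeneric("stderrs"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setGeneric("anchors", function(object) standardGeneric("anchors"))

#' @rdname accessors
#' @export
setGeneric("wtSequence", function(object) standardGeneric("wtSequence"))

#' @rdname accessors
#' @export
setGeneric("qualityCutoff", function(object) standardGeneric("qualityCutoff"))

#' @rdname accessors
#' @export
setGeneric("cvRMSE", function(object) standardGeneric("cvRMSE"))

#' @rdname accessors
#' @export
setGeneric("featureImportances",
           function(object) standardGeneric("featureImportances"))

#' Reciprocal correction of apparently-adaptive scores
#'
#' Variants scoring above wild type (rescaled score > 1) in a
#' complementation-style assay are more likely mismeasured or deleterious
#' than genuinely beneficial; scores X > 1 are therefore transformed to
#' 1/X, mapping (1, Inf) into (0, 1). Scores at or below 1 are unchanged,
#' so the transform is continuous at 1 and idempotent after one pass.
#' The data.frame method also propagates standard deviations by the
#' first-order delta method (sd' = sd / X^2 for X > 1).
#'
#' @param x numeric vector of rescaled scores, or a records data.frame
#'   with columns \code{score} and \code{sd}
#' @return object of the same shape with corrected scores (and sds)
#' @export
setGeneric("correctAdaptive", function(x) standardGeneric("correctAdaptive"))
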