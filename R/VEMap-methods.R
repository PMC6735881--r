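#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname accessors
#' @export
setMethod("scores", "VEMap", function(object) assay(object, "score"))

#' @rdname accessors
#' @export
setMethod("stderrs", "VEMap", function(object) assay(object, "stderr"))

#' @rdname accessors
#' @export
setMethod("provenance", "VEMap", function(object)
    assay(object, "provenance"))

#' @rdname accessors
#' @export
setMethod("anchors", "VEMap", function(object) metadata(object)$anchors)

#' @rdname accessors
#' @export
setMethod("wtSequence", "VEMap", function(object)
    metadata(object)$sequence)

#' @rdname accessors
#' @export
setMethod("qualityCutoff", "ModelBundle", function(object)
    object@qualityCutoff)

#' @rdname accessors
#' @export
setMethod("cvRMSE", "ModelBundle", function(object) object@cvRMSE)

#' @rdname accessors
#' @export
setMethod("featureImportances", "ModelBundle", function(object)
    object@importances)

setMethod("show", "ScaleAnchors", function(object) {
    cat(sprintf("ScaleAnchors: stop median %.4g -> 0, syn median %.4g -> 1\n",
                object@stopMedian, object@synMedian))
})

setMethod("show", "ProteinContext", function(object) {
    cat(sprintf("ProteinContext: %d aa%s%s\n", nchar(object@sequence),
                if (!is.na(object@uniprotId))
                    paste0(" [", object@uniprotId, "]") else "",
                if (nrow(object@structure))
                    sprintf(", structure for %d positions",
                            nrow(object@structure)) else ""))
})

setMethod("show", "ModelBundle", function(object) {
    cat("ModelBundle (gradient boosted trees)\n")
    cat(sprintf("  quality cutoff: %.4g | 10-fold CV RMSE: %.4g | seed: %d\n",
                object@qualityCutoff, object@cvRMSE, object@seed))
    imp <- sort(object@importances, decreasing = TRUE)
    top <- utils::head(imp[imp > 0], 5L)
    cat("  top features:",
        paste(sprintf("%s (%.2f)", names(top), top), collapse = ", "), "\n")
})

setMethod("show", "VEMap", function(object) {
    pv <- assay(object, "provenance")
    cat(sprintf("VEMap: %d positions x 21 substitutions\n", ncol(object)))
    tab <- table(factor(pv, levels = c("measured", "refined", "imputed")))
    cat(sprintf("  cells: %d measured, %d refined, %d imputed, %d blank\n",
                tab[["measured"]], tab[["refined"]], tab[["imputed"]],
                sum(is.na(pv))))
    if (!is.null(metadata(object)$anchors)) show(metadata(object)$anchors)
})
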