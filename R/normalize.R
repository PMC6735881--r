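#' Fit stop/synonymous normalization anchors
#'
#' Estimates the two raw-scale anchor points of a MAVE score set: the
#' median raw score of stop (nonsense) variants, which defines complete
#' loss of function, and the median raw score of synonymous variants,
#' which defines wild-type function. Medians use the standard
#' midpoint-of-two convention for even counts.
#'
#' @param records score table as returned by \code{\link{readScoreTable}}
#' @return a \linkS4class{ScaleAnchors}
#' @export
fitAnchors <- function(records) {
    cls <- variantClass(records$alt)
    stops <- records$score[cls == "stop"]
    syns <- records$score[cls == "synonymous"]
    if (length(stops) == 0L || length(syns) == 0L)
        stop("anchor fitting needs at least one stop and one synonymous ",
             "variant; supply pre-normalized scores (prenormalized = TRUE) ",
             "if your table lacks them", call. = FALSE)
    ScaleAnchors(stats::median(stops), stats::median(syns))
}

#' Rescale scores to the stop/synonymous anchor scale
#'
#' Applies (score - stopMedian) / (synMedian - stopMedian), placing the
#' stop-variant median at 0 and the synonymous median at 1. The
#' data.frame method also rescales \code{sd} by the same factor
#' 1 / |synMedian - stopMedian| (a pure change of units).
#'
#' @param x numeric vector of raw scores, or a records data.frame
#' @param anchors a \linkS4class{ScaleAnchors}
#' @return rescaled object of the same shape
#' @examples
#' rescaleScore(0.8, ScaleAnchors(0.2, 1.4))  # 0.5
#' @export
rescaleScore <- function(x, anchors) {
    stopifnot(is(anchors, "ScaleAnchors"))
    (x - anchors@stopMedian) / (anchors@synMedian - anchors@stopMedian)
}

#' @rdname rescaleScore
#' @export
rescaleScores <- function(x, anchors) {
    stopifnot(is.data.frame(x))
    x$score <- rescaleScore(x$score, anchors)
    if ("sd" %in% names(x))
        x$sd <- x$sd / abs(anchors@synMedian - anchors@stopMedian)
    x
}

#' @rdname correctAdaptive
#' @export
setMethod("correctAdaptive", "numeric", function(x) {
    hi <- !is.na(x) & x > 1
    x[hi] <- 1 / x[hi]
    x
})

#' @rdname correctAdaptive
#' @export
setMethod("correctAdaptive", "data.frame", function(x) {
    hi <- !is.na(x$score) & x$score > 1
    if ("sd" %in% names(x))
        x$sd[hi] <- x$sd[hi] / x$score[hi]^2
    x$score[hi] <- 1 / x$score[hi]
    x
})
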