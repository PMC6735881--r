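#' Inverse-variance combination of measured and imputed scores
#'
#' A measured score m with standard error sigmaM and a model-imputed
#' score i with standard error sigmaI are combined by weighting each
#' with the inverse square of its standard error:
#' \deqn{\hat s = \frac{m/\sigma_m^2 + i/\sigma_i^2}
#'   {1/\sigma_m^2 + 1/\sigma_i^2},\qquad
#'   \hat\sigma = (1/\sigma_m^2 + 1/\sigma_i^2)^{-1/2}}
#' The combined score always lies between its inputs and the combined
#' standard error never exceeds the smaller input error.
#'
#' @param m,sigmaM measured score(s) and standard error(s), sigmaM > 0
#' @param i,sigmaI imputed score(s) and standard error(s), sigmaI > 0
#' @return list with numeric vectors \code{score} and \code{sigma}
#' @examples
#' refineScore(0.4, 0.1, 0.8, 0.2)  # score 0.48, sigma ~0.0894
#' @export
refineScore <- function(m, sigmaM, i, sigmaI) {
    if (any(sigmaM <= 0, na.rm = TRUE) || any(sigmaI <= 0, na.rm = TRUE))
        stop("standard errors must be positive for inverse-variance ",
             "weighting", call. = FALSE)
    wm <- 1 / sigmaM^2
    wi <- 1 / sigmaI^2
    list(score = (m * wm + i * wi) / (wm + wi),
         sigma = 1 / sqrt(wm + wi))
}

#' Assemble the complete variant-effect map
#'
#' Builds the 21 x L map from the post-normalization measurements, the
#' model predictions and the regularized error estimates:
#' \itemize{
#'   \item missense cells measured at or above the quality cutoff are
#'     \emph{refined}: the measured score (with its regularized sigma)
#'     is inverse-variance-combined with the model prediction (with the
#'     imputation sigma);
#'   \item missense cells never measured, or measured below the cutoff,
#'     carry the pure model prediction (\emph{imputed}); below-cutoff
#'     measurements can alternatively be refined via
#'     \code{belowCutoff = "refine"};
#'   \item the synonymous cell of each position (wild-type residue row)
#'     is fixed at score 1 where a synonymous variant was measured
#'     (\emph{measured}, with its regularized sigma) and left blank
#'     otherwise;
#'   \item stop cells carry their measured rescaled score where
#'     measured and are left blank otherwise — anchors are never
#'     imputed by the model.
#' }
#'
#' @param records measured score table (rescaled, corrected scale)
#' @param predictions prediction table from \code{\link{predictScores}}
#'   covering every missense cell
#' @param errors regularized errors from \code{\link{regularizeSigma}},
#'   aligned with \code{records} by variant id
#' @param context the \linkS4class{ProteinContext}
#' @param bundle the trained \linkS4class{ModelBundle} (supplies the
#'   cutoff and the imputation sigma)
#' @param belowCutoff what to do with measurements that failed the
#'   quality cutoff: \code{"impute"} (default, conservative) or
#'   \code{"refine"}
#' @param anchors optional \linkS4class{ScaleAnchors} recorded in the
#'   map metadata
#' @param inflation,minMeasured passed to \code{\link{imputedSigma}}
#' @return a \linkS4class{VEMap}
#' @export
assembleMap <- function(records, predictions, errors, context, bundle,
                        belowCutoff = c("impute", "refine"),
                        anchors = NULL, inflation = 1, minMeasured = 3L) {
    belowCutoff <- match.arg(belowCutoff)
    stopifnot(is(context, "ProteinContext"), is(bundle, "ModelBundle"))
    seq <- strsplit(context@sequence, "")[[1]]
    L <- length(seq)
    cutoff <- bundle@qualityCutoff

    score <- stderr <- matrix(NA_real_, 21L, L,
                              dimnames = list(MAP_SUBSTITUTIONS, NULL))
    prov <- matrix(NA_character_, 21L, L,
                   dimnames = list(MAP_SUBSTITUTIONS, NULL))

    # every missense cell needs a prediction
    cellWt <- seq[rep(seq_len(L), each = 21L)]
    cellAlt <- rep(MAP_SUBSTITUTIONS, times = L)
    cellPos <- rep(seq_len(L), each = 21L)
    isMissense <- cellAlt != "*" & cellAlt != cellWt
    cellId <- paste0(cellWt, cellPos, cellAlt)
    pidx <- match(cellId, predictions$variant)
    missing <- isMissense & is.na(pidx)
    if (any(missing))
        stop("missing prediction for missense cell(s): ",
             paste(utils::head(cellId[missing], 5L), collapse = ", "),
             if (sum(missing) > 5L) sprintf(" (and %d more)",
                                            sum(missing) - 5L),
             call. = FALSE)

    cls <- variantClass(records$alt)
    survivors <- records[cls == "missense" & records$quality >= cutoff, ,
                         drop = FALSE]
    nMeasured <- integer(L)
    tb <- table(survivors$position)
    nMeasured[as.integer(names(tb))] <- as.integer(tb)

    # imputed layer over all missense cells
    sI <- imputedSigma(bundle, cellPos[isMissense],
                       nMeasured[cellPos[isMissense]],
                       inflation = inflation, minMeasured = minMeasured)
    rowIdx <- match(cellAlt, MAP_SUBSTITUTIONS)
    mi <- cbind(rowIdx[isMissense], cellPos[isMissense])
    score[mi] <- predictions$score[pidx[isMissense]]
    stderr[mi] <- sI
    prov[mi] <- "imputed"

    # refined layer for measurements that survive the cutoff
    sigReg <- errors$sigma_regularized[match(records$variant,
                                             errors$variant)]
    refineSet <- cls == "missense" &
        (records$quality >= cutoff |
         (belowCutoff == "refine" & !is.na(records$score)))
    if (any(refineSet)) {
        rr <- records[refineSet, , drop = FALSE]
        sg <- pmax(sigReg[refineSet], 1e-6)
        ci <- cbind(match(rr$alt, MAP_SUBSTITUTIONS), rr$position)
        comb <- refineScore(rr$score, sg, score[ci], stderr[ci])
        score[ci] <- comb$score
        stderr[ci] <- comb$sigma
        prov[ci] <- "refined"
    }

    # anchors: measured synonymous cells sit in the wild-type row at 1;
    # measured stop cells keep their rescaled score; neither is imputed
    syn <- records[cls == "synonymous", , drop = FALSE]
    if (nrow(syn)) {
        ci <- cbind(match(seq[syn$position], MAP_SUBSTITUTIONS),
                    syn$position)
        score[ci] <- 1
        stderr[ci] <- sigReg[match(syn$variant, records$variant)]
        prov[ci] <- "measured"
    }
    stp <- records[cls == "stop", , drop = FALSE]
    if (nrow(stp)) {
        ci <- cbind(rep(21L, nrow(stp)), stp$position)
        score[ci] <- stp$score
        stderr[ci] <- sigReg[match(stp$variant, records$variant)]
        prov[ci] <- "measured"
    }

    VEMap(score = score, stderr = stderr, provenance = prov,
          sequence = context@sequence, anchors = anchors,
          metadata = list(seed = bundle@seed, qualityCutoff = cutoff,
                          cvRMSE = bundle@cvRMSE,
                          belowCutoff = belowCutoff))
}
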