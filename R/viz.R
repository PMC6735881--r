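#' @importFrom grDevices colorRamp rgb
NULL

#' Render a variant-effect map as an SVG heatmap
#'
#' Draws the 21-row (20 substitutions + stop) by L-column map with one
#' rect per cell, a dot overlay marking imputed cells, per-row residue
#' labels, position ticks, a two-anchor legend (0 = null-like,
#' 1 = wild-type-like) and an optional secondary-structure track. The
#' palette is monotone in score: dark at 0 rising to white at 1, scores
#' clipped to \code{clip} before mapping (values above 1 saturate at
#' the wild-type color). Cells without a value are grey. Rendering is
#' deterministic: identical map and settings give a byte-identical file.
#'
#' Layers mirror the map's landscape views: \code{"refined"} shows every
#' cell (imputed + refined + measured anchors), \code{"measured"} blanks
#' all imputed cells, and \code{"predictors"} renders an external score
#' matrix supplied via \code{predictors}.
#'
#' @param map a \linkS4class{VEMap}
#' @param path output file (.svg)
#' @param layer which landscape to draw
#' @param predictors for \code{layer = "predictors"}: data.frame with
#'   columns position, alt, score (external predictor values)
#' @param cellSize cell edge length in px
#' @param palette length-2 vector: colors at score 0 and score 1
#' @param clip numeric range scores are clipped to before coloring
#' @param structure optional data.frame (position, ss_class) drawn as a
#'   track above the heatmap
#' @return \code{path}, invisibly
#' @export
renderMap <- function(map, path, layer = c("refined", "measured",
                                           "predictors"),
                      predictors = NULL, cellSize = 12,
                      palette = c("#2B2D72", "#FFFFFF"),
                      clip = c(0, 1.2), structure = NULL) {
    layer <- match.arg(layer)
    stopifnot(is(map, "VEMap"))
    L <- ncol(map)
    if (L == 0L) stop("cannot render an empty map", call. = FALSE)

    vals <- scores(map)
    pv <- provenance(map)
    if (layer == "measured") {
        vals[!pv %in% c("measured", "refined")] <- NA_real_
    } else if (layer == "predictors") {
        if (is.null(predictors))
            stop("layer = 'predictors' needs a predictors table",
                 call. = FALSE)
        vals <- matrix(NA_real_, 21L, L,
                       dimnames = list(MAP_SUBSTITUTIONS, NULL))
        vals[cbind(match(predictors$alt, MAP_SUBSTITUTIONS),
                   predictors$position)] <- predictors$score
    }

    ramp <- colorRamp(palette)
    cellColor <- function(x) {
        if (is.na(x)) return("#BFBFBF")
        x <- min(max(x, clip[1]), clip[2])
        v <- ramp(min(max(x, 0), 1))
        rgb(v[1], v[2], v[3], maxColorValue = 255)
    }

    mLeft <- 3 * cellSize; mTop <- if (!is.null(structure))
        3 * cellSize else 1.5 * cellSize
    w <- mLeft + L * cellSize + cellSize
    h <- mTop + 21 * cellSize + 4 * cellSize
    out <- c(sprintf(
        '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
        round(w), round(h)),
        sprintf('<rect x="0" y="0" width="%d" height="%d" fill="white"/>',
                round(w), round(h)))

    if (!is.null(structure)) {
        ssCol <- c(H = "#D95F02", E = "#7570B3", C = "#BDBDBD")
        out <- c(out, sprintf(
            '<rect class="ss" x="%g" y="%g" width="%g" height="%g" fill="%s"/>',
            mLeft + (structure$position - 1) * cellSize, cellSize,
            cellSize, cellSize * 0.6,
            unname(ssCol[structure$ss_class])))
    }

    for (r in seq_len(21L)) {
        out <- c(out, sprintf(
            '<text x="%g" y="%g" font-size="%g" font-family="monospace">%s</text>',
            mLeft - cellSize, mTop + (r - 0.3) * cellSize, cellSize * 0.8,
            ifelse(MAP_SUBSTITUTIONS[r] == "*", "&#42;",
                   MAP_SUBSTITUTIONS[r])))
        for (cc in seq_len(L)) {
            out <- c(out, sprintf(
                '<rect class="cell" data-pos="%d" data-alt="%s" x="%g" y="%g" width="%g" height="%g" fill="%s" stroke="#FFFFFF" stroke-width="0.5"/>',
                cc, MAP_SUBSTITUTIONS[r], mLeft + (cc - 1) * cellSize,
                mTop + (r - 1) * cellSize, cellSize, cellSize,
                cellColor(vals[r, cc])))
            if (layer != "predictors" && !is.na(pv[r, cc]) &&
                pv[r, cc] == "imputed" && !is.na(vals[r, cc]))
                out <- c(out, sprintf(
                    '<circle class="imputed-dot" cx="%g" cy="%g" r="%g" fill="#444444"/>',
                    mLeft + (cc - 0.5) * cellSize,
                    mTop + (r - 0.5) * cellSize, cellSize * 0.12))
        }
    }
    for (cc in seq_len(L)[seq_len(L) %% 5L == 0L])
        out <- c(out, sprintf(
            '<text x="%g" y="%g" font-size="%g" font-family="monospace" text-anchor="middle">%d</text>',
            mLeft + (cc - 0.5) * cellSize, mTop + 22 * cellSize,
            cellSize * 0.7, cc))

    # legend: the two anchor scores
    ly <- mTop + 23 * cellSize
    out <- c(out,
        sprintf('<rect class="legend" x="%g" y="%g" width="%g" height="%g" fill="%s" stroke="#888888"/>',
                mLeft, ly, cellSize, cellSize, cellColor(0)),
        sprintf('<text x="%g" y="%g" font-size="%g">0 (null)</text>',
                mLeft + 1.3 * cellSize, ly + 0.8 * cellSize,
                cellSize * 0.8),
        sprintf('<rect class="legend" x="%g" y="%g" width="%g" height="%g" fill="%s" stroke="#888888"/>',
                mLeft + 7 * cellSize, ly, cellSize, cellSize,
                cellColor(1)),
        sprintf('<text x="%g" y="%g" font-size="%g">1 (wild type)</text>',
                mLeft + 8.3 * cellSize, ly + 0.8 * cellSize,
                cellSize * 0.8),
        "</svg>")
    writeLines(out, path, sep = "\n")
    invisible(path)
}
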