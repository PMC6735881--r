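# Physicochemical property scales, one value per residue:
#   hydrophobicity — Kyte-Doolittle hydropathy index
#   volume         — Zamyatnin residue volume (A^3)
#   charge         — formal charge at pH 7
#   polarity       — binary polar/nonpolar class
AA_PROPERTIES <- local({
    h <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
           E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
           M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
           Y = -1.3, V = 4.2)
    v <- c(A = 88.6, R = 173.4, N = 114.1, D = 111.1, C = 108.5,
           Q = 143.8, E = 138.4, G = 60.1, H = 153.2, I = 166.7,
           L = 166.7, K = 168.6, M = 162.9, F = 189.9, P = 112.7,
           S = 89.0, T = 116.1, W = 227.8, Y = 193.6, V = 140.0)
    ch <- c(A = 0, R = 1, N = 0, D = -1, C = 0, Q = 0, E = -1, G = 0,
            H = 0, I = 0, L = 0, K = 1, M = 0, F = 0, P = 0, S = 0,
            T = 0, W = 0, Y = 0, V = 0)
    polar <- c("S", "T", "N", "Q", "Y", "C", "D", "E", "K", "R", "H")
    p <- stats::setNames(as.numeric(AA_ALPHABET20 %in% polar), AA_ALPHABET20)
    cbind(hydrophobicity = h[AA_ALPHABET20], volume = v[AA_ALPHABET20],
          charge = ch[AA_ALPHABET20], polarity = p[AA_ALPHABET20])
})

# BLOSUM62 from Biostrings, loaded once per session
.blosum62 <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) {
            e <- new.env()
            utils::data("BLOSUM62", package = "Biostrings", envir = e)
            cache <<- e$BLOSUM62
        }
        cache
    }
})

#' Feature schema of the imputation model
#'
#' Stable ordered list of the feature columns fed to the regressor (and
#' reported by the importance summary): the positional mean of measured
#' missense scores, wild-type/substituted/delta values of four
#' physicochemical properties, the BLOSUM62 substitution score, three
#' optional external predictor scores and optional structure features
#' (secondary-structure one-hot + relative solvent accessibility). The
#' schema is fixed across proteins; optional inputs that were not
#' supplied simply yield missing values.
#'
#' @return character vector of feature names
#' @export
featureSchema <- function() {
    props <- colnames(AA_PROPERTIES)
    c("pos_mean_score",
      as.vector(t(outer(props, c("wt", "alt", "delta"), paste, sep = "_"))),
      "blosum62", "polyphen2", "provean", "sift",
      "ss_helix", "ss_strand", "ss_coil", "rsa")
}

#' Positional mean of measured missense scores
#'
#' Unweighted mean of the measured (rescaled, flip-corrected) missense
#' scores at one protein position. Stop and synonymous records are
#' excluded. When \code{exclude} names a variant, that record is left
#' out of the average — used for measured training targets so the
#' feature never contains the target's own score. Returns NA when no
#' qualifying record remains.
#'
#' @param records score table (rescaled scale)
#' @param position 1-based protein position
#' @param exclude optional variant id (compact token) to omit
#' @return scalar mean or NA
#' @export
positionalMean <- function(records, position, exclude = NULL) {
    keep <- records$position == position &
        variantClass(records$alt) == "missense"
    if (!is.null(exclude)) keep <- keep & records$variant != exclude
    s <- records$score[keep]
    if (length(s) == 0L) NA_real_ else mean(s)
}

#' Build the per-variant feature table
#'
#' Assembles one feature row per target variant for model training and
#' prediction. Targets must be missense (stop and synonymous variants
#' are anchored by normalization, not modeled). For targets that are
#' themselves measured, the positional mean excludes the target's own
#' score; for unmeasured targets all measured missense records at the
#' position contribute. Absent optional inputs (predictors, structure)
#' produce missing values, never errors — the downstream ensemble
#' tolerates missing features.
#'
#' @param records measured score table on the rescaled, corrected scale
#' @param context a \linkS4class{ProteinContext}
#' @param predictors optional predictor table from
#'   \code{\link{readPredictorTable}}
#' @param targets data.frame of variant keys (position, wt, alt); may
#'   mix measured and unmeasured variants
#' @return data.frame: \code{variant}, \code{position}, \code{wt},
#'   \code{alt}, then the \code{\link{featureSchema}} columns
#' @export
buildFeatureTable <- function(records, context, predictors = NULL,
                              targets) {
    stopifnot(is(context, "ProteinContext"))
    seq <- strsplit(context@sequence, "")[[1]]
    L <- length(seq)
    tid <- variantId(targets)

    bad <- targets$position < 1L | targets$position > L
    if (any(bad))
        stop("target position outside sequence 1..", L, ": ",
             paste(utils::head(tid[bad], 5L), collapse = ", "),
             call. = FALSE)
    bad <- seq[targets$position] != targets$wt
    if (any(bad))
        stop("wild-type residue mismatch with sequence: ",
             paste(utils::head(tid[bad], 5L), collapse = ", "),
             call. = FALSE)
    bad <- variantClass(targets$alt) != "missense"
    if (any(bad))
        stop("only missense variants are modeled; remove: ",
             paste(utils::head(tid[bad], 5L), collapse = ", "),
             call. = FALSE)

    # positional sums over measured missense records, target-excluded
    mis <- records[variantClass(records$alt) == "missense", , drop = FALSE]
    psum <- pn <- numeric(L)
    agg <- tapply(mis$score, mis$position, sum)
    cnt <- tapply(mis$score, mis$position, length)
    psum[as.integer(names(agg))] <- agg
    pn[as.integer(names(cnt))] <- cnt
    own <- mis$score[match(tid, mis$variant)]     # NA for unmeasured targets
    s <- psum[targets$position] - ifelse(is.na(own), 0, own)
    k <- pn[targets$position] - !is.na(own)
    pos_mean <- ifelse(k > 0, s / k, NA_real_)

    pw <- AA_PROPERTIES[targets$wt, , drop = FALSE]
    pa <- AA_PROPERTIES[targets$alt, , drop = FALSE]
    out <- data.frame(variant = tid, position = targets$position,
                      wt = targets$wt, alt = targets$alt,
                      pos_mean_score = pos_mean)
    for (p in colnames(AA_PROPERTIES)) {
        out[[paste0(p, "_wt")]] <- unname(pw[, p])
        out[[paste0(p, "_alt")]] <- unname(pa[, p])
        out[[paste0(p, "_delta")]] <- unname(pa[, p] - pw[, p])
    }
    out$blosum62 <- .blosum62()[cbind(targets$wt, targets$alt)]

    for (p in c("polyphen2", "provean", "sift")) {
        out[[p]] <- if (!is.null(predictors) && p %in% names(predictors))
            predictors[[p]][match(tid, predictors$variant)]
        else NA_real_
    }

    st <- context@structure
    if (nrow(st)) {
        i <- match(targets$position, st$position)
        out$ss_helix <- as.numeric(st$ss_class[i] == "H")
        out$ss_strand <- as.numeric(st$ss_class[i] == "E")
        out$ss_coil <- as.numeric(st$ss_class[i] == "C")
        out$rsa <- st$rsa[i]
    } else {
        out$ss_helix <- out$ss_strand <- out$ss_coil <- out$rsa <- NA_real_
    }
    stopifnot(all(featureSchema() %in% names(out)))
    out
}
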