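#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowData colData
NULL

#' Normalization anchors for a MAVE score set
#'
#' Holds the raw-scale medians of the two internal controls of a MAVE:
#' stop (nonsense) variants, which anchor complete loss of function, and
#' synonymous variants, which anchor wild-type function. Rescaling maps
#' the stop median to 0 and the synonymous median to 1.
#'
#' @slot stopMedian median raw score of stop variants
#' @slot synMedian median raw score of synonymous variants
#' @export
setClass("ScaleAnchors",
    representation(stopMedian = "numeric", synMedian = "numeric"))

setValidity("ScaleAnchors", function(object) {
    msg <- character()
    if (length(object@stopMedian) != 1L || !is.finite(object@stopMedian))
        msg <- c(msg, "stopMedian must be a single finite number")
    if (length(object@synMedian) != 1L || !is.finite(object@synMedian))
        msg <- c(msg, "synMedian must be a single finite number")
    if (length(msg) == 0L && object@synMedian == object@stopMedian)
        msg <- c(msg, "synMedian must differ from stopMedian (rescaling undefined)")
    if (length(msg)) msg else TRUE
})

#' @param stopMedian,synMedian raw-score medians of the two anchor classes
#' @rdname ScaleAnchors-class
#' @export
ScaleAnchors <- function(stopMedian, synMedian) {
    new("ScaleAnchors", stopMedian = as.numeric(stopMedian),
        synMedian = as.numeric(synMedian))
}

#' Wild-type protein context
#'
#' The wild-type amino-acid sequence a variant map is defined against,
#' with optional per-position structural annotations (secondary-structure
#' class and relative solvent accessibility).
#'
#' @slot sequence single amino-acid string (20-letter alphabet)
#' @slot uniprotId optional identifier (NA when unknown)
#' @slot structure data.frame with columns \code{position},
#'   \code{ss_class} (H/E/C) and \code{rsa} (0..1), possibly empty
#' @export
setClass("ProteinContext",
    representation(sequence = "character", uniprotId = "character",
                   structure = "data.frame"))

setValidity("ProteinContext", function(object) {
    msg <- character()
    if (length(object@sequence) != 1L || !nzchar(object@sequence))
        msg <- c(msg, "sequence must be a single non-empty string")
    else {
        bad <- setdiff(strsplit(object@sequence, "")[[1]], AA_ALPHABET20)
        if (length(bad))
            msg <- c(msg, paste0("sequence contains non-standard residues: ",
                                 paste(unique(bad), collapse = ", ")))
    }
    st <- object@structure
    if (nrow(st)) {
        need <- c("position", "ss_class", "rsa")
        if (!all(need %in% names(st)))
            msg <- c(msg, "structure needs columns position, ss_class, rsa")
        else {
            L <- nchar(object@sequence)
            if (any(st$position < 1L | st$position > L))
                msg <- c(msg, "structure positions outside 1..L")
            if (anyDuplicated(st$position))
                msg <- c(msg, "duplicate structure positions")
            if (!all(st$ss_class %in% c("H", "E", "C")))
                msg <- c(msg, "ss_class must be H, E or C")
            if (any(st$rsa < 0 | st$rsa > 1, na.rm = TRUE))
                msg <- c(msg, "rsa must lie in [0, 1]")
        }
    }
    if (length(msg)) msg else TRUE
})

#' @param sequence amino-acid string
#' @param uniprotId optional identifier
#' @param structure optional per-position annotation data.frame
#' @rdname ProteinContext-class
#' @export
ProteinContext <- function(sequence, uniprotId = NA_character_,
                           structure = NULL) {
    if (is.null(structure))
        structure <- data.frame(position = integer(), ss_class = character(),
                                rsa = numeric())
    new("ProteinContext", sequence = toupper(as.character(sequence)),
        uniprotId = as.character(uniprotId),
        structure = as.data.frame(structure))
}

#' Trained imputation model with its provenance
#'
#' Bundles the fitted gradient-boosted-tree ensemble together with the
#' metadata needed to reproduce and audit it: the feature schema, the
#' quality cutoff the training set was filtered at, the 10-fold
#' cross-validation RMSE on the training variants, normalized feature
#' importances and the RNG seed.
#'
#' @slot regressor fitted ensemble (opaque)
#' @slot schema ordered feature names the regressor was trained on
#' @slot qualityCutoff quality threshold applied to training records
#' @slot cvRMSE 10-fold cross-validation root-mean-squared error
#' @slot importances named nonnegative vector summing to 1
#' @slot seed RNG seed used for fold assignment and tree fitting
#' @slot params hyperparameter list (nrounds, eta, max_depth, subsample)
#' @export
setClass("ModelBundle",
    representation(regressor = "ANY", schema = "character",
                   qualityCutoff = "numeric", cvRMSE = "numeric",
                   importances = "numeric", seed = "integer",
                   params = "list"))

setValidity("ModelBundle", function(object) {
    msg <- character()
    if (length(object@cvRMSE) != 1L || object@cvRMSE < 0)
        msg <- c(msg, "cvRMSE must be a single nonnegative number")
    imp <- object@importances
    if (length(imp)) {
        if (any(imp < -1e-12)) msg <- c(msg, "importances must be nonnegative")
        if (abs(sum(imp) - 1) > 1e-6)
            msg <- c(msg, "importances must sum to 1")
        if (!setequal(names(imp), object@schema))
            msg <- c(msg, "importances must be named by the feature schema")
    }
    if (length(msg)) msg else TRUE
})

#' Complete variant-effect map
#'
#' A \linkS4class{SummarizedExperiment} with one row per substitution
#' (20 amino acids in a fixed order, then stop) and one column per
#' protein position, carrying three assays: \code{score}, \code{stderr}
#' and \code{provenance} ("measured", "imputed" or "refined"; NA for
#' cells undefined by design, i.e. unmeasured stop/synonymous cells).
#' The cell in the wild-type residue's row at each position is the
#' synonymous cell. Anchors, seed, cutoff and CV RMSE travel in
#' \code{metadata()}.
#'
#' @export
setClass("VEMap", contains = "SummarizedExperiment")

setValidity("VEMap", function(object) {
    msg <- character()
    if (!all(c("score", "stderr", "provenance") %in% assayNames(object)))
        msg <- c(msg, "assays score, stderr and provenance are required")
    if (!identical(rownames(object), MAP_SUBSTITUTIONS))
        msg <- c(msg, "rows must be the 20 amino acids (fixed order) then stop")
    if (!all(c("position", "wt") %in% names(colData(object))))
        msg <- c(msg, "colData needs position and wt")
    if ("provenance" %in% assayNames(object)) {
        pv <- assay(object, "provenance")
        if (!all(pv %in% c("measured", "imputed", "refined", NA)))
            msg <- c(msg, "provenance values must be measured/imputed/refined/NA")
    }
    if (length(msg)) msg else TRUE
})

#' @param score,stderr numeric 21 x L matrices (rows = substitutions)
#' @param provenance character 21 x L matrix
#' @param sequence wild-type sequence of length L
#' @param anchors optional \linkS4class{ScaleAnchors}
#' @param metadata extra metadata list entries (seed, cutoff, cvRMSE, ...)
#' @rdname VEMap-class
#' @export
VEMap <- function(score, stderr, provenance, sequence, anchors = NULL,
                  metadata = list()) {
    wt <- strsplit(sequence, "")[[1]]
    L <- length(wt)
    stopifnot(ncol(score) == L, all(dim(score) == dim(stderr)),
              all(dim(score) == dim(provenance)), nrow(score) == 21L)
    dimnames(score) <- dimnames(stderr) <- dimnames(provenance) <-
        list(MAP_SUBSTITUTIONS, as.character(seq_len(L)))
    md <- c(list(anchors = anchors, sequence = sequence), metadata)
    se <- SummarizedExperiment(
        assays = SimpleList(score = score, stderr = stderr,
                            provenance = provenance),
        rowData = DataFrame(substitution = MAP_SUBSTITUTIONS),
        colData = DataFrame(position = seq_len(L), wt = wt),
        metadata = md)
    new("VEMap", se)
}
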