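#' @importFrom data.table fread fwrite as.data.table setnames :=
NULL

#' Read a variant score table
#'
#' Reads the canonical delimited score-table format (comma or tab,
#' auto-detected; header required). Required columns: \code{variant}
#' (compact or HGVS-p notation) and \code{score}. Optional columns:
#' \code{sd} (per-variant dispersion across replicates), \code{n_reps}
#' (replicate count, default 1) and \code{quality} (experiment-supplied
#' quality score; defaults to \code{n_reps} when absent, since coverage
#' is the dominant quality driver in MAVE data). Missing \code{sd} is
#' kept as NA and later supplied by the error model's prior.
#'
#' Rows whose variant token fails to parse or whose score is non-finite
#' are collected; the read aborts if they exceed \code{maxErrorFrac} of
#' all rows, otherwise they are dropped with a warning. Duplicate
#' variant keys (common when MAVE exports shard by tile) are merged by
#' replicate-count-weighted mean with pooled sd.
#'
#' @param path file path, or a data.frame already in the same layout
#' @param maxErrorFrac maximum tolerated fraction of unparseable rows
#' @return data.frame with columns \code{variant}, \code{position},
#'   \code{wt}, \code{alt}, \code{score}, \code{sd}, \code{n_reps},
#'   \code{quality}; at most one row per variant key
#' @export
readScoreTable <- function(path, maxErrorFrac = 0.05) {
    dt <- if (is.data.frame(path)) as.data.table(path)
          else fread(path, header = TRUE)
    setnames(dt, tolower(names(dt)))
    for (col in c("variant", "score"))
        if (!col %in% names(dt))
            stop("score table is missing required column '", col, "'",
                 call. = FALSE)

    n_in <- nrow(dt)
    if (n_in == 0L) stop("score table has no rows", call. = FALSE)
    if (!"sd" %in% names(dt)) dt$sd <- NA_real_
    if (!"n_reps" %in% names(dt)) dt$n_reps <- 1L
    hadQuality <- "quality" %in% names(dt)
    if (!hadQuality) dt$quality <- as.numeric(dt$n_reps)

    keys <- tryParseVariant(as.character(dt$variant))
    bad <- is.na(keys$position) | !is.finite(suppressWarnings(
        as.numeric(dt$score)))
    if (sum(bad) / n_in > maxErrorFrac)
        stop(sprintf(
            "%d of %d rows rejected (limit %.0f%%); first offenders: %s",
            sum(bad), n_in, 100 * maxErrorFrac,
            paste(utils::head(dt$variant[bad], 5L), collapse = ", ")),
            call. = FALSE)
    if (any(bad))
        warning(sum(bad), " unparseable row(s) dropped: ",
                paste(utils::head(dt$variant[bad], 5L), collapse = ", "),
                call. = FALSE)

    rec <- data.table::data.table(
        position = keys$position[!bad], wt = keys$wt[!bad],
        alt = keys$alt[!bad],
        score = as.numeric(dt$score)[!bad],
        sd = as.numeric(dt$sd)[!bad],
        n_reps = as.integer(dt$n_reps)[!bad],
        quality = as.numeric(dt$quality)[!bad])
    if (any(rec$n_reps < 1L))
        stop("n_reps must be >= 1", call. = FALSE)
    if (any(rec$sd < 0, na.rm = TRUE))
        stop("sd must be nonnegative", call. = FALSE)
    if (any(!is.finite(rec$quality)))
        stop("quality must be finite", call. = FALSE)

    out <- mergeDuplicateRecords(rec)
    # default quality tracks coverage, so it follows the merged n_reps
    if (!hadQuality) out$quality <- as.numeric(out$n_reps)
    message(sprintf("read %d rows: %d records (%d merged, %d rejected)",
                    n_in, nrow(out), nrow(rec) - nrow(out), sum(bad)))
    out
}

# per-row-tolerant wrapper: NA position marks a failed parse
tryParseVariant <- function(x) {
    res <- data.frame(position = rep(NA_integer_, length(x)),
                      wt = NA_character_, alt = NA_character_)
    for (i in seq_along(x)) {
        k <- tryCatch(parseVariant(x[i]), error = function(e) NULL)
        if (!is.null(k)) res[i, ] <- k[1, ]
    }
    res
}

# merge duplicate keys: replicate-weighted mean score, pooled sd over the
# combined replicate set, summed n_reps, weighted-mean quality
mergeDuplicateRecords <- function(rec) {
    score <- sd <- n_reps <- quality <- position <- alt <- NULL # NSE
    out <- rec[, {
        w <- as.numeric(n_reps)
        N <- sum(w)
        m <- sum(w * score) / N
        s <- if (.N == 1L) sd
             else if (anyNA(sd) || N < 2) NA_real_
             else {
                 ss <- sum((w - 1) * sd^2 + w * score^2)
                 sqrt(max((ss - N * m^2) / (N - 1), 0))
             }
        list(score = m, sd = s, n_reps = as.integer(N),
             quality = sum(w * quality) / N)
    }, by = c("position", "wt", "alt")]
    data.table::setorder(out, position, alt)
    out <- as.data.frame(out)
    out$variant <- variantId(out)
    out[, c("variant", "position", "wt", "alt", "score", "sd",
            "n_reps", "quality")]
}

#' Read the wild-type protein context
#'
#' Loads the wild-type sequence from a FASTA file (first record used)
#' and optionally a per-position structure annotation table.
#'
#' @param fasta path to a FASTA file
#' @param structure optional path to a structure TSV (columns
#'   \code{position}, \code{ss_class} in H/E/C, \code{rsa} in 0..1)
#' @param uniprotId optional identifier to record
#' @return a \linkS4class{ProteinContext}
#' @export
readProteinContext <- function(fasta, structure = NULL,
                               uniprotId = NA_character_) {
    aa <- Biostrings::readAAStringSet(fasta)
    if (length(aa) == 0L) stop("FASTA file contains no records", call. = FALSE)
    seq <- as.character(aa[[1L]])
    st <- if (!is.null(structure)) readStructureTable(structure, nchar(seq))
          else NULL
    ProteinContext(seq, uniprotId = uniprotId, structure = st)
}

readStructureTable <- function(path, L) {
    st <- as.data.frame(fread(path, header = TRUE))
    setnames(st, tolower(names(st)))
    need <- c("position", "ss_class", "rsa")
    if (!all(need %in% names(st)))
        stop("structure table needs columns position, ss_class, rsa",
             call. = FALSE)
    st$position <- as.integer(st$position)
    st$rsa <- as.numeric(st$rsa)
    st[, need]
}

#' Read external predictor scores
#'
#' TSV/CSV with a \code{variant} column plus any subset of
#' \code{polyphen2}, \code{provean}, \code{sift}; blanks allowed.
#'
#' @param path file path or data.frame
#' @return data.frame keyed by variant with one column per predictor
#' @export
readPredictorTable <- function(path) {
    dt <- if (is.data.frame(path)) as.data.table(path)
          else fread(path, header = TRUE)
    setnames(dt, tolower(names(dt)))
    if (!"variant" %in% names(dt))
        stop("predictor table is missing required column 'variant'",
             call. = FALSE)
    preds <- intersect(c("polyphen2", "provean", "sift"), names(dt))
    if (length(preds) == 0L)
        stop("predictor table has none of polyphen2/provean/sift",
             call. = FALSE)
    keys <- parseVariant(as.character(dt$variant))
    out <- data.frame(variant = variantId(keys), keys)
    for (p in preds) out[[p]] <- as.numeric(dt[[p]])
    out[!duplicated(out$variant), ]
}

#' Write / read a complete variant-effect map
#'
#' The on-disk format is tab-separated long form with one row per cell:
#' \code{position}, \code{wt}, \code{alt} (20 amino acids + \code{*} per
#' position; the row where alt equals wt is the synonymous cell),
#' \code{score}, \code{stderr} (17 significant digits, lossless for
#' doubles) and \code{provenance}. \code{readVEMap} inverts it.
#'
#' @param map a \linkS4class{VEMap}
#' @param path output (or input) file path
#' @return \code{writeVEMap} returns \code{path} invisibly;
#'   \code{readVEMap} returns a \linkS4class{VEMap}
#' @export
writeVEMap <- function(map, path) {
    sc <- scores(map); se <- stderrs(map); pv <- provenance(map)
    wt <- colData(map)$wt
    L <- ncol(sc)
    pos <- rep(seq_len(L), each = 21L)
    alt <- rep(MAP_SUBSTITUTIONS, times = L)
    lines <- c("position\twt\talt\tscore\tstderr\tprovenance",
        sprintf("%d\t%s\t%s\t%s\t%s\t%s",
                pos, wt[pos], alt,
                num17(as.vector(sc)), num17(as.vector(se)),
                ifelse(is.na(as.vector(pv)), "NA", as.vector(pv))))
    writeLines(lines, path, sep = "\n")
    invisible(path)
}

num17 <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))

#' @rdname writeVEMap
#' @export
readVEMap <- function(path) {
    dt <- as.data.frame(fread(path, header = TRUE, sep = "\t",
                              na.strings = "NA"))
    need <- c("position", "wt", "alt", "score", "stderr", "provenance")
    if (!all(need %in% names(dt)))
        stop("not a VE map file (columns ", paste(need, collapse = ", "),
             " required)", call. = FALSE)
    L <- max(dt$position)
    wt <- character(L)
    wt[dt$position] <- dt$wt
    fill <- function(v, mode) {
        m <- matrix(if (mode == "c") NA_character_ else NA_real_,
                    21L, L, dimnames = list(MAP_SUBSTITUTIONS, NULL))
        m[cbind(match(dt$alt, MAP_SUBSTITUTIONS), dt$position)] <- v
        m
    }
    VEMap(score = fill(dt$score, "n"), stderr = fill(dt$stderr, "n"),
          provenance = fill(as.character(dt$provenance), "c"),
          sequence = paste(wt, collapse = ""))
}
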