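#' Configuration for the synthetic MAVE generator
#'
#' Describes a simulated deep-mutational-scanning experiment with known
#' ground truth. The generative model is additive on the normalized
#' scale: each position carries an effect drawn uniformly on
#' [0, 1.05] and each substituted residue a Gaussian offset with sd
#' \code{subEffectSd}; their clamped sum is the true missense score, so
#' a small fraction of variants lands above 1 and exercises the
#' adaptive-variant correction. Stop variants have true score 0 and
#' synonymous variants 1. Raw scores are emitted on a deliberately
#' shifted/scaled axis (stop anchor \code{stopRaw}, synonymous anchor
#' \code{synRaw}) so normalization is always non-trivial. Each included
#' variant is measured as the mean of \code{n_reps} replicate draws
#' (replicate noise sd \code{noiseSd} on the normalized scale, times a
#' per-variant lognormal factor), and its quality score is
#' \code{n_reps / (1 + variant noise sd)} — high coverage and low noise
#' mean high quality, which makes quality-cutoff selection meaningful.
#' A \code{missingness} fraction of missense cells is censored,
#' emulating variants poorly represented in the mutagenized library.
#'
#' @param L protein length (residues)
#' @param missingness fraction of missense cells censored, in [0, 1)
#' @param noiseSd replicate noise sd on the normalized score scale
#' @param subEffectSd sd of per-residue substitution effects (0 gives a
#'   purely positional truth)
#' @param stopRaw,synRaw raw-scale anchor locations
#' @param nRepsRange inclusive range replicate counts are drawn from
#' @param anchorCoverage fraction of positions contributing a stop and
#'   a synonymous variant
#' @param noiseDispersion sd (log scale) of the per-variant noise factor
#' @param seed RNG seed; identical config + seed give identical data
#' @return a \code{SynthConfig} list
#' @export
synthConfig <- function(L = 50L, missingness = 0.3, noiseSd = 0.1,
                        subEffectSd = 0.15, stopRaw = 0.15, synRaw = 1.6,
                        nRepsRange = c(1L, 8L), anchorCoverage = 0.8,
                        noiseDispersion = 0.5, seed = 1L) {
    stopifnot(L >= 2L, missingness >= 0, missingness < 1, noiseSd >= 0,
              subEffectSd >= 0, synRaw != stopRaw,
              nRepsRange[1] >= 1L, nRepsRange[2] >= nRepsRange[1])
    structure(list(L = as.integer(L), missingness = missingness,
                   noiseSd = noiseSd, subEffectSd = subEffectSd,
                   stopRaw = stopRaw, synRaw = synRaw,
                   nRepsRange = as.integer(nRepsRange),
                   anchorCoverage = anchorCoverage,
                   noiseDispersion = noiseDispersion,
                   seed = as.integer(seed)),
              class = "SynthConfig")
}

#' Generate a synthetic MAVE dataset with known truth
#'
#' Draws a wild-type sequence, the additive ground truth, and a measured
#' score table in the canonical dialect (variant, score, sd, n_reps,
#' quality) according to a \code{\link{synthConfig}}. The truth table
#' covers all 21 x L cells on the normalized scale (missense in [0,
#' 1.25], synonymous 1, stop 0), enabling exact imputation-error
#' measurement on censored cells with no external data.
#'
#' @param config a \code{\link{synthConfig}}
#' @return list with \code{scores} (measured table, raw scale),
#'   \code{truth} (position, wt, alt, true_score on normalized scale),
#'   \code{context} (\linkS4class{ProteinContext}) and \code{config}
#' @export
generateSynthData <- function(config) {
    stopifnot(inherits(config, "SynthConfig"))
    withSeed(config$seed, {
        L <- config$L
        seq <- sample(AA_ALPHABET20, L, replace = TRUE)
        posEff <- stats::runif(L, 0, 1.05)
        subEff <- stats::setNames(
            stats::rnorm(20L, 0, config$subEffectSd), AA_ALPHABET20)

        pos <- rep(seq_len(L), each = 21L)
        alt <- rep(MAP_SUBSTITUTIONS, times = L)
        wt <- seq[pos]
        truth <- ifelse(alt == "*", 0,
                 ifelse(alt == wt, 1,
                        pmin(pmax(posEff[pos] + subEff[alt], 0), 1.25)))
        truthTab <- data.frame(position = pos, wt = wt,
                               alt = ifelse(alt == wt & alt != "*", "=",
                                            alt),
                               true_score = truth)

        isMissense <- alt != "*" & alt != wt
        keep <- logical(length(alt))
        keep[isMissense] <- stats::runif(sum(isMissense)) >=
            config$missingness
        keep[!isMissense] <- stats::runif(sum(!isMissense)) <
            config$anchorCoverage

        scale <- config$synRaw - config$stopRaw
        rawTruth <- config$stopRaw + truth * scale
        n <- nrow(truthTab)
        nrep <- sample(seq(config$nRepsRange[1], config$nRepsRange[2]),
                       n, replace = TRUE)
        nf <- exp(stats::rnorm(n, 0, config$noiseDispersion))
        repSd <- nf * config$noiseSd
        obs <- vapply(seq_len(n), function(i) {
            reps <- rawTruth[i] + stats::rnorm(nrep[i], 0,
                                               repSd[i] * abs(scale))
            c(mean(reps), if (nrep[i] > 1L) stats::sd(reps) else NA_real_)
        }, numeric(2L))

        scores <- data.frame(
            variant = formatVariant(truthTab),
            score = obs[1L, ], sd = obs[2L, ], n_reps = nrep,
            quality = nrep / (1 + repSd))[keep, , drop = FALSE]
        rownames(scores) <- NULL

        list(scores = scores, truth = truthTab,
             context = ProteinContext(paste(seq, collapse = "")),
             config = config)
    })
}

#' Write a synthetic dataset to disk
#'
#' Emits \code{scores.tsv} (canonical score-table dialect),
#' \code{truth.tsv} and \code{wt.fasta} into a directory. Output is
#' byte-identical for identical config + seed.
#'
#' @param dataset result of \code{\link{generateSynthData}}
#' @param dir output directory (created if absent)
#' @return named vector of the three file paths, invisibly
#' @export
writeSynthDataset <- function(dataset, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(scores = file.path(dir, "scores.tsv"),
               truth = file.path(dir, "truth.tsv"),
               fasta = file.path(dir, "wt.fasta"))
    fwrite(dataset$scores, paths["scores"], sep = "\t", na = "NA")
    fwrite(dataset$truth, paths["truth"], sep = "\t", na = "NA")
    writeLines(c(">synthetic_wt", dataset$context@sequence),
               paths["fasta"])
    invisible(paths)
}
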