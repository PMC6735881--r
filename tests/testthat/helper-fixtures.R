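# Small in-code fixture builders shared across test files.

# canonical records data.frame from parallel vectors
makeRecords <- function(position, wt, alt, score, sd = NA_real_,
                        n_reps = 1L, quality = NULL) {
    n <- length(position)
    df <- data.frame(position = as.integer(position), wt = wt, alt = alt,
                     score = score, sd = rep_len(sd, n),
                     n_reps = as.integer(rep_len(n_reps, n)))
    df$quality <- if (is.null(quality)) as.numeric(df$n_reps)
                  else rep_len(quality, n)
    df$variant <- paste0(df$wt, df$position, df$alt)
    df[, c("variant", "position", "wt", "alt", "score", "sd", "n_reps",
           "quality")]
}

# fast GBT hyperparameters for unit tests (acceptance tests use defaults)
fastParams <- function() list(nrounds = 60L, eta = 0.1, max_depth = 3L,
                              subsample = 0.8)

# normalized + corrected records plus feature table for a synthetic map
preparedSynth <- function(config) {
    d <- generateSynthData(config)
    rec <- readScoreTable(d$scores)
    anch <- fitAnchors(rec)
    rec <- correctAdaptive(rescaleScores(rec, anch))
    seqv <- strsplit(d$context@sequence, "")[[1]]
    pos <- rep(seq_along(seqv), each = 20L)
    alt <- rep(maveImpute:::AA_ALPHABET20, times = length(seqv))
    targets <- data.frame(position = pos, wt = seqv[pos], alt = alt)
    targets <- targets[targets$alt != targets$wt, , drop = FALSE]
    feats <- buildFeatureTable(rec, d$context, targets = targets)
    list(data = d, records = rec, anchors = anch, features = feats,
         targets = targets)
}
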