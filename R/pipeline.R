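#' @importFrom jsonlite write_json toJSON
NULL

#' Assemble a pipeline configuration
#'
#' Collects every knob of the end-to-end imputation run into one
#' validated list: input paths (or in-memory equivalents), normalization
#' flags, the quality cutoff (fixed number, or NULL for automatic
#' selection against the top-20%-by-quality test set), model
#' hyperparameters, error-model constants and the pipeline seed. All
#' stages derive their randomness from this single seed, so a run is a
#' pure function of (inputs, config, seed).
#'
#' @param scores score table path or data.frame (required)
#' @param fasta FASTA path, or NULL when \code{context} is given
#' @param context optional in-memory \linkS4class{ProteinContext}
#' @param predictors optional predictor table path or data.frame
#' @param structure optional structure annotation path
#' @param outdir optional output directory; when set, the run writes
#'   \code{map.tsv}, \code{report.json}, and optionally \code{map.svg}
#'   and \code{methods.tsv}
#' @param prenormalized scores are already on the 0/1 anchor scale;
#'   skip anchor fitting and rescaling
#' @param flip apply the reciprocal correction to scores above 1
#' @param qualityCutoff fixed cutoff, or NULL for automatic selection
#' @param seed pipeline seed
#' @param model list overriding gradient-boosted-tree hyperparameters
#'   (nrounds, eta, max_depth, subsample)
#' @param error list overriding error-model constants: \code{K},
#'   \code{priorDf}, \code{lowCoverageInflation}, \code{minMeasured}
#' @param belowCutoff "impute" or "refine" for below-cutoff measurements
#' @param maxErrorFrac tolerated fraction of unparseable score rows
#' @param plot also render \code{map.svg}
#' @param compare also run the method comparison (writes
#'   \code{methods.tsv} when \code{outdir} is set)
#' @param verbose log per-stage record counts to stderr
#' @return a \code{PipelineConfig} list
#' @export
pipelineConfig <- function(scores, fasta = NULL, context = NULL,
                           predictors = NULL, structure = NULL,
                           outdir = NULL, prenormalized = FALSE,
                           flip = TRUE, qualityCutoff = NULL, seed = 42L,
                           model = list(), error = list(),
                           belowCutoff = c("impute", "refine"),
                           maxErrorFrac = 0.05, plot = FALSE,
                           compare = FALSE, verbose = TRUE) {
    if (is.null(fasta) && is.null(context))
        stop("either fasta or context is required", call. = FALSE)
    mp <- utils::modifyList(defaultModelParams(), model)
    ep <- utils::modifyList(list(K = 4L, priorDf = 2,
                                 lowCoverageInflation = 1,
                                 minMeasured = 3L), error)
    structure(list(scores = scores, fasta = fasta, context = context,
                   predictors = predictors, structure = structure,
                   outdir = outdir, prenormalized = prenormalized,
                   flip = flip, qualityCutoff = qualityCutoff,
                   seed = as.integer(seed), model = mp, error = ep,
                   belowCutoff = match.arg(belowCutoff),
                   maxErrorFrac = maxErrorFrac, plot = plot,
                   compare = compare, verbose = verbose),
              class = "PipelineConfig")
}

#' Run the end-to-end imputation and refinement pipeline
#'
#' Executes the full workflow: read and validate inputs; fit
#' stop/synonymous anchors and rescale (unless pre-normalized);
#' reciprocal-correct apparently-adaptive scores; build the feature
#' table for every missense cell; select or accept the quality cutoff;
#' train the gradient-boosted-tree model with 10-fold CV; predict every
#' missense cell; fit the error prior and regularize per-variant sigmas;
#' refine surviving measurements by inverse-variance weighting; assemble
#' the complete map; and write the map, run report and optional figure.
#'
#' @param config a \code{\link{pipelineConfig}}
#' @return list with \code{map} (\linkS4class{VEMap}), \code{bundle}
#'   (\linkS4class{ModelBundle}), \code{report} (list mirrored to
#'   report.json) and \code{comparison} (data.frame or NULL)
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "PipelineConfig"))
    say <- if (config$verbose) function(...) message(sprintf(...))
           else function(...) invisible()

    records <- readScoreTable(config$scores, config$maxErrorFrac)
    say("[read] %d records", nrow(records))

    context <- if (!is.null(config$context)) config$context
               else readProteinContext(config$fasta, config$structure)
    L <- nchar(context@sequence)
    seqv <- strsplit(context@sequence, "")[[1]]
    bad <- records$position > L | seqv[records$position] != records$wt
    if (any(bad))
        stop("record(s) inconsistent with the wild-type sequence: ",
             paste(utils::head(records$variant[bad], 5L), collapse = ", "),
             call. = FALSE)

    anch <- NULL
    if (!config$prenormalized) {
        anch <- fitAnchors(records)
        records <- rescaleScores(records, anch)
        say("[normalize] anchors: stop %.4g, syn %.4g",
            anch@stopMedian, anch@synMedian)
    } else say("[normalize] skipped (pre-normalized input)")
    if (config$flip) {
        nHi <- sum(records$score > 1, na.rm = TRUE)
        records <- correctAdaptive(records)
        say("[flip] %d apparently-adaptive score(s) reciprocal-corrected",
            nHi)
    }

    preds <- if (!is.null(config$predictors))
        readPredictorTable(config$predictors) else NULL

    # all missense cells of the map are feature targets; measured rows
    # get self-excluded positional means
    pos <- rep(seq_len(L), each = 20L)
    alt <- rep(AA_ALPHABET20, times = L)
    targets <- data.frame(position = pos, wt = seqv[pos], alt = alt)
    targets <- targets[targets$alt != targets$wt, , drop = FALSE]
    features <- buildFeatureTable(records, context, preds, targets)
    say("[features] %d target rows x %d features", nrow(features),
        length(featureSchema()))

    cutoff <- if (!is.null(config$qualityCutoff)) {
        say("[cutoff] user-supplied: %.4g", config$qualityCutoff)
        as.numeric(config$qualityCutoff)
    } else {
        co <- selectQualityCutoff(records, features, seed = config$seed,
                                  params = config$model)
        say("[cutoff] selected %.4g by test-set RMSE", co)
        as.numeric(co)
    }

    bundle <- trainModel(records, features, cutoff, seed = config$seed,
                         params = config$model)
    say("[train] CV RMSE %.4g on %d records", cvRMSE(bundle),
        sum(variantClass(records$alt) == "missense" &
            records$quality >= cutoff))

    predictions <- predictScores(bundle, features)
    say("[predict] %d missense cells scored", nrow(predictions))

    prior <- fitSigmaPrior(records)
    errors <- regularizeSigma(records, prior, K = config$error$K,
                              priorDf = config$error$priorDf)
    say("[error] sigma prior (%s) + regularization, K = %d",
        attr(prior, "form"), config$error$K)

    map <- assembleMap(records, predictions, errors, context, bundle,
                       belowCutoff = config$belowCutoff, anchors = anch,
                       inflation = config$error$lowCoverageInflation,
                       minMeasured = config$error$minMeasured)
    pv <- provenance(map)
    say("[assemble] %d refined, %d imputed, %d measured anchor cells",
        sum(pv == "refined", na.rm = TRUE),
        sum(pv == "imputed", na.rm = TRUE),
        sum(pv == "measured", na.rm = TRUE))

    comparison <- if (config$compare)
        compareMethods(records, features, cutoff = cutoff,
                       seed = config$seed, params = config$model)
    else NULL

    report <- list(
        seed = config$seed,
        prenormalized = config$prenormalized, flip = config$flip,
        anchors = if (!is.null(anch))
            list(stop_median = anch@stopMedian,
                 syn_median = anch@synMedian) else NULL,
        quality_cutoff = cutoff,
        cutoff_mode = if (is.null(config$qualityCutoff)) "auto"
                      else "user",
        cv_rmse = cvRMSE(bundle),
        importances = as.list(featureImportances(bundle)),
        model = config$model, error = config$error,
        below_cutoff = config$belowCutoff,
        n_records = nrow(records),
        n_training = sum(variantClass(records$alt) == "missense" &
                         records$quality >= cutoff),
        n_imputed = sum(pv == "imputed", na.rm = TRUE),
        n_refined = sum(pv == "refined", na.rm = TRUE))

    if (!is.null(config$outdir)) {
        dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
        writeVEMap(map, file.path(config$outdir, "map.tsv"))
        write_json(report, file.path(config$outdir, "report.json"),
                   auto_unbox = TRUE, digits = NA, pretty = TRUE,
                   null = "null")
        if (config$plot)
            renderMap(map, file.path(config$outdir, "map.svg"))
        if (!is.null(comparison))
            fwrite(comparison, file.path(config$outdir, "methods.tsv"),
                   sep = "\t")
        say("[write] outputs in %s", config$outdir)
    }
    list(map = map, bundle = bundle, report = report,
         comparison = comparison)
}
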