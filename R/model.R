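#' @importFrom xgboost xgb.train xgb.DMatrix xgb.model.dt.tree
#' @importFrom stats predict median lm sd setNames quantile
NULL

# conservative defaults for small-n tabular regression; override via
# pipelineConfig(model = list(...))
defaultModelParams <- function() {
    list(nrounds = 500L, eta = 0.05, max_depth = 3L, subsample = 0.8)
}

# run expr with a locally-set RNG seed, restoring global state after
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", globalenv())
    on.exit(if (had) assign(".Random.seed", old, globalenv())
            else if (exists(".Random.seed", globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    expr
}

# balanced fold assignment, deterministic given seed
makeFolds <- function(n, k = 10L, seed = 42L) {
    k <- min(k, n)
    withSeed(seed, sample(rep(seq_len(k), length.out = n)))
}

# numeric feature matrix in schema order; NA = missing (native xgboost)
featureMatrix <- function(features, schema = featureSchema()) {
    missing <- setdiff(schema, names(features))
    if (length(missing))
        stop("feature table is missing schema column(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
    as.matrix(features[, schema, drop = FALSE])
}

fitGBT <- function(X, y, params, seed) {
    withSeed(seed,
        xgb.train(params = list(objective = "reg:squarederror",
                                eta = params$eta,
                                max_depth = params$max_depth,
                                subsample = params$subsample,
                                nthread = 1L),
                  data = xgb.DMatrix(X, label = y, missing = NA),
                  nrounds = params$nrounds, verbose = 0L))
}

rmse <- function(pred, obs) sqrt(mean((pred - obs)^2))

#' Hold out the top 20% of variants by quality
#'
#' Splits the measured missense records into a fixed test set — the top
#' 20% ranked by quality score (size ceiling(0.2 n), quality ties broken
#' deterministically by position then substitution) — and the remaining
#' pool. The test set is the yardstick for quality-cutoff selection and
#' never enters any candidate cutoff's training set.
#'
#' @param records measured score table (rescaled, corrected scale)
#' @return list with data.frames \code{test} and \code{pool}
#' @export
selectTestSet <- function(records) {
    mis <- records[variantClass(records$alt) == "missense", , drop = FALSE]
    if (nrow(mis) < 10L)
        stop("need >= 10 measured missense records for automatic cutoff ",
             "selection; supply qualityCutoff explicitly", call. = FALSE)
    ord <- order(-mis$quality, mis$position, mis$alt)
    nTest <- ceiling(0.2 * nrow(mis))
    list(test = mis[ord[seq_len(nTest)], , drop = FALSE],
         pool = mis[ord[-seq_len(nTest)], , drop = FALSE])
}

#' Select the quality cutoff by test-set prediction error
#'
#' Scans a grid of candidate quality cutoffs (default: deciles of the
#' pool quality distribution, at most 10 trainings). For each candidate,
#' a gradient-boosted-tree model is trained on pool records with quality
#' at or above the cutoff and scored by RMSE on the fixed top-20% test
#' set from \code{\link{selectTestSet}}; the cutoff minimizing test RMSE
#' wins, ties going to the smaller cutoff (more training data).
#' Candidates leaving fewer than 10 training records are skipped.
#'
#' @param records measured score table (rescaled, corrected scale)
#' @param features feature table covering all measured missense records
#' @param cutoffs optional explicit candidate grid
#' @param seed RNG seed
#' @param params model hyperparameters (see \code{defaultModelParams})
#' @return the selected cutoff, with attribute \code{"grid"} holding the
#'   per-candidate test RMSE table
#' @export
selectQualityCutoff <- function(records, features, cutoffs = NULL,
                                seed = 42L, params = defaultModelParams()) {
    split <- selectTestSet(records)
    if (is.null(cutoffs))
        cutoffs <- sort(unique(unname(
            quantile(split$pool$quality, probs = seq(0, 0.9, by = 0.1),
                     type = 1))))
    Xtest <- featureMatrix(features[match(split$test$variant,
                                          features$variant), ])
    res <- data.frame(cutoff = cutoffs, n_train = NA_integer_,
                      test_rmse = NA_real_)
    for (i in seq_along(cutoffs)) {
        tr <- split$pool[split$pool$quality >= cutoffs[i], , drop = FALSE]
        res$n_train[i] <- nrow(tr)
        if (nrow(tr) < 10L) next
        Xtr <- featureMatrix(features[match(tr$variant, features$variant), ])
        fit <- fitGBT(Xtr, tr$score, params, seed)
        res$test_rmse[i] <- rmse(predict(fit, xgb.DMatrix(Xtest,
                                                          missing = NA)),
                                 split$test$score)
    }
    if (all(is.na(res$test_rmse)))
        stop("every candidate cutoff left fewer than 10 training records",
             call. = FALSE)
    best <- min(res$test_rmse, na.rm = TRUE)
    sel <- min(res$cutoff[!is.na(res$test_rmse) &
                          res$test_rmse <= best + 1e-12])
    structure(sel, grid = res)
}

#' Train the gradient-boosted-tree imputation model
#'
#' Fits the ensemble on measured missense records passing the quality
#' cutoff, with the rescaled flip-corrected score as target. Reports the
#' 10-fold cross-validation RMSE on those training records and feature
#' importances defined as the number of times each feature is used for
#' splitting weighted by the squared-error improvement of the split,
#' averaged over trees and normalized to sum 1. Missing feature values
#' are routed natively by the trees and never abort training.
#'
#' @param records measured score table (rescaled, corrected scale)
#' @param features feature table covering the measured missense records
#' @param cutoff quality cutoff (user-supplied or from
#'   \code{\link{selectQualityCutoff}})
#' @param seed RNG seed; identical seed + data give identical models
#' @param params hyperparameters; \code{nfolds} the CV fold count
#' @param nfolds number of cross-validation folds
#' @return a \linkS4class{ModelBundle}
#' @export
trainModel <- function(records, features, cutoff, seed = 42L,
                       params = defaultModelParams(), nfolds = 10L) {
    mis <- records[variantClass(records$alt) == "missense" &
                   records$quality >= cutoff, , drop = FALSE]
    if (nrow(mis) < 10L)
        stop("fewer than 10 training records above quality cutoff ",
             cutoff, call. = FALSE)
    if (any(!is.finite(mis$score)))
        stop("non-finite training score for variant(s): ",
             paste(mis$variant[!is.finite(mis$score)], collapse = ", "),
             call. = FALSE)
    X <- featureMatrix(features[match(mis$variant, features$variant), ])
    y <- mis$score

    folds <- makeFolds(nrow(mis), nfolds, seed)
    sqerr <- numeric(0)
    for (f in sort(unique(folds))) {
        fit <- fitGBT(X[folds != f, , drop = FALSE], y[folds != f],
                      params, seed + f)
        p <- predict(fit, xgb.DMatrix(X[folds == f, , drop = FALSE],
                                      missing = NA))
        sqerr <- c(sqerr, (p - y[folds == f])^2)
    }
    cv <- sqrt(mean(sqerr))

    fit <- fitGBT(X, y, params, seed)
    new("ModelBundle", regressor = fit, schema = featureSchema(),
        qualityCutoff = as.numeric(cutoff), cvRMSE = cv,
        importances = gainImportance(fit, featureSchema()),
        seed = as.integer(seed), params = params)
}

# split-count-weighted-by-squared-improvement importance: each split's
# Gain is its squared-error reduction, so summing Gain per feature within
# a tree is the split count weighted by per-split improvement; average
# over trees, then normalize to sum 1
gainImportance <- function(fit, schema) {
    dt <- xgb.model.dt.tree(model = fit)
    dt <- dt[dt$Feature != "Leaf", , drop = FALSE]
    imp <- setNames(numeric(length(schema)), schema)
    if (nrow(dt)) {
        ntree <- length(unique(dt$Tree))
        g <- tapply(dt$Gain, dt$Feature, sum) / ntree
        idx <- match(names(g), schema)
        if (anyNA(idx)) idx <- match(names(g), as.character(
            seq_along(schema) - 1L))  # older dumps use f-indices
        imp[idx] <- as.numeric(g)
    }
    tot <- sum(imp)
    if (tot > 0) imp / tot
    else setNames(rep(1 / length(schema), length(schema)), schema)
}

#' Predict scores for target variants
#'
#' Applies a trained \linkS4class{ModelBundle} to a feature table,
#' returning one finite imputed score per row. Works for unmeasured
#' variants (imputation) and measured ones (needed for refinement).
#' Prediction is invariant to row order and errors if the feature table
#' does not carry the bundle's schema.
#'
#' @param bundle a \linkS4class{ModelBundle}
#' @param features feature table from \code{\link{buildFeatureTable}}
#' @return data.frame: variant, position, wt, alt, score
#' @export
predictScores <- function(bundle, features) {
    stopifnot(is(bundle, "ModelBundle"))
    X <- featureMatrix(features, bundle@schema)
    p <- predict(bundle@regressor, xgb.DMatrix(X, missing = NA))
    data.frame(variant = features$variant, position = features$position,
               wt = features$wt, alt = features$alt, score = as.numeric(p))
}

#' Compare regression methods by shared-fold cross-validation
#'
#' Evaluates the gradient-boosted-tree model against a random forest, a
#' linear model and a positional-mean baseline on identical 10-fold
#' partitions of the training records, reporting each method's CV RMSE
#' sorted ascending (no winner is asserted). Methods that cannot route
#' missing values natively receive training-fold median fill plus
#' per-feature missingness indicators. A support-vector comparator can
#' be enabled when the e1071 package is available.
#'
#' @param records measured score table (rescaled, corrected scale)
#' @param features feature table covering the measured missense records
#' @param cutoff optional quality cutoff applied before comparison
#' @param seed RNG seed (also fixes the shared folds)
#' @param params GBT hyperparameters
#' @param nfolds fold count
#' @param includeSVM add an RBF support-vector comparator
#' @return data.frame (method, cv_rmse) sorted by RMSE, with the shared
#'   fold assignment in attribute \code{"folds"}
#' @export
compareMethods <- function(records, features, cutoff = NULL, seed = 42L,
                           params = defaultModelParams(), nfolds = 10L,
                           includeSVM = FALSE) {
    mis <- records[variantClass(records$alt) == "missense", , drop = FALSE]
    if (!is.null(cutoff)) mis <- mis[mis$quality >= cutoff, , drop = FALSE]
    if (nrow(mis) < 10L)
        stop("fewer than 10 records to compare methods on", call. = FALSE)
    X <- featureMatrix(features[match(mis$variant, features$variant), ])
    y <- mis$score
    folds <- makeFolds(nrow(mis), nfolds, seed)

    methods <- c("gradient_boosted_trees", "random_forest",
                 "linear_regression", "positional_mean")
    if (includeSVM) {
        if (!requireNamespace("e1071", quietly = TRUE))
            stop("includeSVM requires the e1071 package", call. = FALSE)
        methods <- c(methods, "svm_rbf")
    }
    err <- lapply(setNames(methods, methods), function(m) numeric(0))

    for (f in sort(unique(folds))) {
        tr <- folds != f; va <- folds == f
        # GBT: native missing handling
        fit <- fitGBT(X[tr, , drop = FALSE], y[tr], params, seed + f)
        err$gradient_boosted_trees <- c(err$gradient_boosted_trees,
            (predict(fit, xgb.DMatrix(X[va, , drop = FALSE],
                                      missing = NA)) - y[va])^2)
        # median-fill + indicators for the non-tree-missing methods
        filled <- medianFill(X, tr)
        dtr <- data.frame(y = y[tr], filled$X[tr, , drop = FALSE])
        dva <- data.frame(filled$X[va, , drop = FALSE])
        rf <- withSeed(seed + f,
            randomForest::randomForest(x = filled$X[tr, , drop = FALSE],
                                       y = y[tr], ntree = 500L))
        err$random_forest <- c(err$random_forest,
            (predict(rf, filled$X[va, , drop = FALSE]) - y[va])^2)
        lmfit <- lm(y ~ ., data = dtr)
        plm <- suppressWarnings(predict(lmfit, newdata = dva))
        err$linear_regression <- c(err$linear_regression, (plm - y[va])^2)
        # positional-mean baseline, recomputed within the training fold
        pm <- tapply(y[tr], mis$position[tr], mean)
        pb <- pm[as.character(mis$position[va])]
        pb[is.na(pb)] <- mean(y[tr])
        err$positional_mean <- c(err$positional_mean,
                                 (as.numeric(pb) - y[va])^2)
        if (includeSVM) {
            sv <- withSeed(seed + f,
                e1071::svm(x = filled$X[tr, , drop = FALSE], y = y[tr]))
            err$svm_rbf <- c(err$svm_rbf,
                (predict(sv, filled$X[va, , drop = FALSE]) - y[va])^2)
        }
    }
    out <- data.frame(method = methods,
                      cv_rmse = vapply(err[methods],
                                       function(e) sqrt(mean(e)), 0))
    out <- out[order(out$cv_rmse), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "folds") <- folds
    out
}

# training-fold medians fill NA; columns with any NA overall also get a
# 0/1 missingness indicator so non-tree methods keep the signal
medianFill <- function(X, trainIdx) {
    med <- apply(X[trainIdx, , drop = FALSE], 2L,
                 function(v) median(v, na.rm = TRUE))
    med[is.na(med)] <- 0
    hasNA <- colnames(X)[colSums(is.na(X)) > 0L]
    ind <- if (length(hasNA))
        `colnames<-`(1 * is.na(X[, hasNA, drop = FALSE]),
                     paste0("miss_", hasNA))
    Xf <- X
    for (j in seq_len(ncol(Xf)))
        Xf[is.na(Xf[, j]), j] <- med[j]
    # drop constant columns (rank safety for lm/svm)
    keep <- apply(Xf, 2L, function(v) length(unique(v)) > 1L)
    Xf <- Xf[, keep, drop = FALSE]
    if (!is.null(ind)) Xf <- cbind(Xf, ind)
    list(X = Xf)
}
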