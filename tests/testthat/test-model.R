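test_that("the held-out test set is the top 20% by quality", {
    set.seed(41)
    rec <- makeRecords(position = 1:100, wt = "A",
                       alt = rep(c("V", "S", "K", "M", "G"), 20),
                       score = runif(100), quality = sample(1:1000, 100))
    sp <- selectTestSet(rec)
    expect_equal(nrow(sp$test), ceiling(0.2 * nrow(rec)))
    expect_equal(nrow(sp$test) + nrow(sp$pool), nrow(rec))
    expect_length(intersect(sp$test$variant, sp$pool$variant), 0L)
    expect_true(min(sp$test$quality) >= max(sp$pool$quality))
})

test_that("test-set ties break deterministically by variant key order", {
    rec <- makeRecords(position = 1:10, wt = "A",
                       alt = rep(c("V", "S"), 5), score = runif(10),
                       quality = 5)          # all qualities equal
    rec$wt <- "A"; rec$variant <- paste0("A", 1:10, rec$alt)
    sp1 <- selectTestSet(rec)
    sp2 <- selectTestSet(rec[sample(10), ])  # row order must not matter
    expect_equal(sort(sp1$test$variant), sort(sp2$test$variant))
    expect_equal(nrow(sp1$test), 2L)
    # distinct qualities: exactly the top-quality records
    rec$quality <- 1:10
    sp <- selectTestSet(rec)
    expect_setequal(sp$test$quality, c(9, 10))
    expect_error(selectTestSet(rec[1:5, ]), "cutoff")
})

test_that("quality-cutoff selection matches a brute-force grid oracle", {
    prep <- preparedSynth(synthConfig(L = 25, seed = 43, missingness = 0.2))
    rec <- prep$records
    # make low-quality scores pure noise so filtering them must help
    mis <- variantClass(rec$alt) == "missense"
    lowq <- mis & rec$quality < median(rec$quality[mis])
    set.seed(44)
    rec$score[lowq] <- runif(sum(lowq))
    feats <- buildFeatureTable(rec, prep$data$context,
                               targets = prep$targets)
    params <- fastParams()
    sel <- selectQualityCutoff(rec, feats, seed = 5L, params = params)
    expect_gt(as.numeric(sel), min(rec$quality[mis]))

    # independent oracle: rerun the grid by direct xgboost calls
    sp <- selectTestSet(rec)
    idx <- function(v) match(v, feats$variant)
    Xte <- as.matrix(feats[idx(sp$test$variant), featureSchema()])
    grid <- attr(sel, "grid")
    oracle <- vapply(grid$cutoff, function(co) {
        tr <- sp$pool[sp$pool$quality >= co, ]
        if (nrow(tr) < 10L) return(NA_real_)
        Xtr <- as.matrix(feats[idx(tr$variant), featureSchema()])
        set.seed(5L)
        fit <- xgboost::xgb.train(
            params = list(objective = "reg:squarederror",
                          eta = params$eta, max_depth = params$max_depth,
                          subsample = params$subsample, nthread = 1L),
            data = xgboost::xgb.DMatrix(Xtr, label = tr$score,
                                        missing = NA),
            nrounds = params$nrounds, verbose = 0L)
        p <- predict(fit, xgboost::xgb.DMatrix(Xte, missing = NA))
        sqrt(mean((p - sp$test$score)^2))
    }, 0)
    expect_equal(grid$test_rmse, oracle)
    best <- min(oracle, na.rm = TRUE)
    expect_equal(as.numeric(sel),
                 min(grid$cutoff[!is.na(oracle) & oracle <= best + 1e-12]))
})

test_that("degenerate and user-supplied cutoffs behave as documented", {
    prep <- preparedSynth(synthConfig(L = 20, seed = 47, missingness = 0.1))
    rec <- prep$records
    rec$quality <- 3                      # all equal -> one-point grid
    sel <- selectQualityCutoff(rec, prep$features, seed = 1L,
                               params = fastParams())
    expect_equal(as.numeric(sel), 3)
    # a user-supplied cutoff bypasses the search entirely in the pipeline
    cfg <- pipelineConfig(scores = prep$data$scores,
                          context = prep$data$context, qualityCutoff = 0,
                          seed = 1L, model = fastParams(), verbose = FALSE)
    res <- suppressMessages(runPipeline(cfg))
    expect_equal(res$report$cutoff_mode, "user")
    expect_equal(qualityCutoff(res$bundle), 0)
})

test_that("training is deterministic and validates its inputs", {
    prep <- preparedSynth(synthConfig(L = 20, seed = 53, missingness = 0.2))
    cut <- stats::median(prep$records$quality)
    b1 <- trainModel(prep$records, prep$features, cut, seed = 9L,
                     params = fastParams())
    b2 <- trainModel(prep$records, prep$features, cut, seed = 9L,
                     params = fastParams())
    p1 <- predictScores(b1, prep$features)
    p2 <- predictScores(b2, prep$features)
    expect_identical(p1$score, p2$score)           # bit-identical
    expect_identical(cvRMSE(b1), cvRMSE(b2))
    expect_identical(featureImportances(b1), featureImportances(b2))
    expect_error(trainModel(prep$records, prep$features,
                            max(prep$records$quality) + 1, seed = 1L,
                            params = fastParams()), "fewer than 10")
    bad <- prep$records
    bad$score[which(variantClass(bad$alt) == "missense")[1]] <- NaN
    expect_error(trainModel(bad, prep$features, cutoff = 0, seed = 1L,
                            params = fastParams()), "non-finite")
})

test_that("importances are a distribution concentrated on used features", {
    prep <- preparedSynth(synthConfig(L = 20, seed = 59, missingness = 0.2))
    b <- trainModel(prep$records, prep$features, cutoff = 0, seed = 3L,
                    params = fastParams())
    imp <- featureImportances(b)
    expect_setequal(names(imp), featureSchema())
    expect_true(all(imp >= 0))
    expect_equal(sum(imp), 1)
    # features absent from every split (all-NA columns) get zero
    expect_equal(unname(imp["polyphen2"]), 0)
    expect_equal(unname(imp["rsa"]), 0)
    expect_identical(b@schema, featureSchema())   # schema round-trips
})

test_that("a single informative feature takes importance 1", {
    prep <- preparedSynth(synthConfig(L = 20, seed = 61, missingness = 0.2))
    feats <- prep$features
    sch <- featureSchema()
    feats[, setdiff(sch, "pos_mean_score")] <- NA_real_
    b <- trainModel(prep$records, feats, cutoff = 0, seed = 3L,
                    params = fastParams())
    expect_equal(unname(featureImportances(b)["pos_mean_score"]), 1)
})

test_that("prediction is complete, order-invariant and schema-checked", {
    prep <- preparedSynth(synthConfig(L = 20, seed = 67, missingness = 0.4))
    b <- trainModel(prep$records, prep$features, cutoff = 0, seed = 3L,
                    params = fastParams())
    p <- predictScores(b, prep$features)
    expect_equal(nrow(p), nrow(prep$features))     # every missense cell
    expect_true(all(is.finite(p$score)))
    shuf <- prep$features[sample(nrow(prep$features)), ]
    ps <- predictScores(b, shuf)
    expect_equal(ps$score[match(p$variant, ps$variant)], p$score)
    expect_error(predictScores(b, prep$features[, 1:6]), "missing schema")
})

test_that("method comparison shares exact fold partitions", {
    prep <- preparedSynth(synthConfig(L = 20, seed = 71, missingness = 0.2))
    cmp <- compareMethods(prep$records, prep$features, seed = 13L,
                          params = fastParams(), nfolds = 5L)
    expect_setequal(cmp$method,
        c("gradient_boosted_trees", "random_forest", "linear_regression",
          "positional_mean"))
    expect_true(all(cmp$cv_rmse >= 0))
    expect_false(is.unsorted(cmp$cv_rmse))
    folds <- attr(cmp, "folds")
    nMis <- sum(variantClass(prep$records$alt) == "missense")
    expect_length(folds, nMis)
    expect_setequal(unique(folds), 1:5)            # exact partition
    cmp2 <- compareMethods(prep$records, prep$features, seed = 13L,
                           params = fastParams(), nfolds = 5L)
    expect_identical(attr(cmp2, "folds"), folds)   # same seed, same folds
    expect_equal(cmp2$cv_rmse, cmp$cv_rmse)
})

test_that("positional-mean baseline matches a hand-computed oracle", {
    # 3-position toy set; brute-force leave-fold-out mean predictor
    rec <- makeRecords(position = rep(1:3, each = 4),
                       wt = rep(c("A", "G", "R"), each = 4),
                       alt = rep(c("V", "S", "K", "M"), 3),
                       score = c(0.1, 0.2, 0.3, 0.4,
                                 0.5, 0.6, 0.7, 0.8,
                                 0.15, 0.25, 0.35, 0.45))
    ctx <- ProteinContext("AGR")
    feats <- buildFeatureTable(rec, ctx,
                               targets = rec[, c("position", "wt", "alt")])
    cmp <- compareMethods(rec, feats, seed = 3L, params = fastParams(),
                          nfolds = 3L)
    folds <- attr(cmp, "folds")
    sq <- c()
    for (f in 1:3) {
        tr <- folds != f
        for (i in which(folds == f)) {
            same <- tr & rec$position == rec$position[i]
            mu <- if (any(same)) mean(rec$score[same])
                  else mean(rec$score[tr])
            sq <- c(sq, (mu - rec$score[i])^2)
        }
    }
    expect_equal(cmp$cv_rmse[cmp$method == "positional_mean"],
                 sqrt(mean(sq)))
})

test_that("imputation beats the positional-mean baseline on masked cells", {
    cfgS <- synthConfig(L = 40, missingness = 0.3, noiseSd = 0.1,
                        seed = 73)
    prep <- preparedSynth(cfgS)
    b <- trainModel(prep$records, prep$features, cutoff = 0, seed = 7L,
                    params = fastParams())
    p <- predictScores(b, prep$features)
    truth <- prep$data$truth
    truth$variant <- paste0(truth$wt, truth$position, truth$alt)
    masked <- setdiff(p$variant, prep$records$variant)
    tv <- correctAdaptive(truth$true_score[match(masked, truth$variant)])
    pv <- p$score[match(masked, p$variant)]
    rmseModel <- sqrt(mean((pv - tv)^2))
    # brute-force baseline: positional mean of measured missense scores
    mis <- prep$records[variantClass(prep$records$alt) == "missense", ]
    pm <- tapply(mis$score, mis$position, mean)
    base <- pm[as.character(truth$position[match(masked, truth$variant)])]
    base[is.na(base)] <- mean(mis$score)
    rmseBase <- sqrt(mean((as.numeric(base) - tv)^2))
    expect_lt(rmseModel, rmseBase)
})
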