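test_that("inverse-variance refinement reproduces the closed form", {
    r <- refineScore(0.4, 0.1, 0.8, 0.2)
    expect_equal(r$score, 0.48)
    expect_equal(r$sigma, 1 / sqrt(1 / 0.01 + 1 / 0.04))
    expect_equal(r$sigma, 0.0894, tolerance = 1e-3)
    # equal errors: simple average
    expect_equal(refineScore(0.2, 0.15, 0.6, 0.15)$score, 0.4)
    # uninformative imputation: measured value dominates
    expect_equal(refineScore(0.4, 0.1, 0.8, 1e9)$score, 0.4,
                 tolerance = 1e-6)
    expect_error(refineScore(0.4, 0, 0.8, 0.2), "positive")
})

test_that("refined values interpolate inputs and tighten the error", {
    set.seed(91)
    m <- runif(50); i <- runif(50)
    sm <- runif(50, 0.01, 0.5); si <- runif(50, 0.01, 0.5)
    r <- refineScore(m, sm, i, si)
    distinct <- abs(m - i) > 1e-12
    expect_true(all(r$score[distinct] > pmin(m, i)[distinct]))
    expect_true(all(r$score[distinct] < pmax(m, i)[distinct]))
    expect_true(all(r$sigma <= pmin(sm, si) + 1e-15))
    same <- refineScore(0.3, 0.1, 0.3, 0.4)
    expect_equal(same$score, 0.3)
})

buildMapFixture <- function(L = 20, seed = 95, missingness = 0.5,
                            belowCutoff = "impute", cutoff = NULL) {
    prep <- preparedSynth(synthConfig(L = L, seed = seed,
                                      missingness = missingness))
    rec <- prep$records
    cut <- if (is.null(cutoff)) unname(quantile(rec$quality, 0.3))
           else cutoff
    bundle <- trainModel(rec, prep$features, cut, seed = 2L,
                         params = fastParams())
    preds <- predictScores(bundle, prep$features)
    prior <- fitSigmaPrior(rec)
    errs <- regularizeSigma(rec, prior)
    map <- assembleMap(rec, preds, errs, prep$data$context, bundle,
                       belowCutoff = belowCutoff, anchors = prep$anchors)
    list(map = map, records = rec, bundle = bundle, preds = preds,
         errs = errs, context = prep$data$context)
}

test_that("the assembled map is complete with coherent provenance", {
    fx <- buildMapFixture()
    map <- fx$map
    sc <- scores(map); se <- stderrs(map); pv <- provenance(map)
    seqv <- strsplit(wtSequence(map), "")[[1]]
    L <- ncol(map)
    isMis <- outer(maveImpute:::MAP_SUBSTITUTIONS, seqv,
                   function(a, w) a != "*" & a != w)
    # every missense cell finite, with finite positive stderr
    expect_true(all(is.finite(sc[isMis])))
    expect_true(all(is.finite(se[isMis]) & se[isMis] > 0))
    expect_true(all(pv[isMis] %in% c("imputed", "refined")))
    # provenance "imputed" iff no measurement survived the cutoff
    cut <- qualityCutoff(fx$bundle)
    surv <- fx$records[variantClass(fx$records$alt) == "missense" &
                       fx$records$quality >= cut, ]
    survCells <- cbind(match(surv$alt, maveImpute:::MAP_SUBSTITUTIONS),
                       surv$position)
    expect_true(all(pv[survCells] == "refined"))
    mask <- matrix(FALSE, 21, L); mask[survCells] <- TRUE
    expect_true(all(pv[isMis & !mask] == "imputed"))
    # conservation over all 21L cells
    blanks <- sum(is.na(pv))
    expect_equal(sum(pv %in% c("measured", "refined", "imputed")) + blanks,
                 21L * L)
    expect_equal(blanks, sum(!isMis) -
                 sum(variantClass(fx$records$alt) != "missense"))
})

test_that("refined cells tighten the error below both inputs", {
    fx <- buildMapFixture()
    cut <- qualityCutoff(fx$bundle)
    surv <- fx$records[variantClass(fx$records$alt) == "missense" &
                       fx$records$quality >= cut, ]
    se <- stderrs(fx$map)
    ci <- cbind(match(surv$alt, maveImpute:::MAP_SUBSTITUTIONS),
                surv$position)
    sigM <- pmax(fx$errs$sigma_regularized[
        match(surv$variant, fx$errs$variant)], 1e-6)
    sigI <- imputedSigma(fx$bundle, surv$position)
    expect_true(all(se[ci] < pmin(sigM, sigI)))
    # and the refined score sits between measurement and prediction
    sc <- scores(fx$map)
    pred <- fx$preds$score[match(surv$variant, fx$preds$variant)]
    distinct <- abs(surv$score - pred) > 1e-12
    expect_true(all(sc[ci][distinct] >= pmin(surv$score, pred)[distinct]))
    expect_true(all(sc[ci][distinct] <= pmax(surv$score, pred)[distinct]))
})

test_that("below-cutoff measurements are imputed, not refined, by default", {
    fx <- buildMapFixture()
    cut <- qualityCutoff(fx$bundle)
    below <- fx$records[variantClass(fx$records$alt) == "missense" &
                        fx$records$quality < cut, ]
    expect_gt(nrow(below), 0L)
    pv <- provenance(fx$map)
    ci <- cbind(match(below$alt, maveImpute:::MAP_SUBSTITUTIONS),
                below$position)
    expect_true(all(pv[ci] == "imputed"))
    sc <- scores(fx$map)
    pred <- fx$preds$score[match(below$variant, fx$preds$variant)]
    expect_equal(unname(sc[ci]), pred)      # pure imputation
    # the config flag flips them to refined
    fx2 <- buildMapFixture(belowCutoff = "refine")
    below2 <- fx2$records[variantClass(fx2$records$alt) == "missense" &
                          fx2$records$quality < qualityCutoff(fx2$bundle), ]
    pv2 <- provenance(fx2$map)
    ci2 <- cbind(match(below2$alt, maveImpute:::MAP_SUBSTITUTIONS),
                 below2$position)
    expect_true(all(pv2[ci2] == "refined"))
})

test_that("anchor cells carry measured values only", {
    fx <- buildMapFixture()
    pv <- provenance(fx$map); sc <- scores(fx$map)
    rec <- fx$records
    syn <- rec[variantClass(rec$alt) == "synonymous", ]
    seqv <- strsplit(wtSequence(fx$map), "")[[1]]
    ciSyn <- cbind(match(seqv[syn$position],
                         maveImpute:::MAP_SUBSTITUTIONS), syn$position)
    expect_true(all(pv[ciSyn] == "measured"))
    expect_true(all(sc[ciSyn] == 1))        # synonymous fixed at 1
    stp <- rec[variantClass(rec$alt) == "stop", ]
    ciStp <- cbind(rep(21L, nrow(stp)), stp$position)
    expect_true(all(pv[ciStp] == "measured"))
    expect_equal(unname(sc[ciStp]), stp$score)
    # unmeasured anchor cells stay blank
    unSyn <- setdiff(seq_along(seqv), syn$position)
    ciUn <- cbind(match(seqv[unSyn], maveImpute:::MAP_SUBSTITUTIONS), unSyn)
    expect_true(all(is.na(pv[ciUn])))
})

test_that("assembly fails loudly when predictions are incomplete", {
    fx <- buildMapFixture()
    preds <- fx$preds[-(1:3), ]
    expect_error(assembleMap(fx$records, preds, fx$errs, fx$context,
                             fx$bundle),
                 "missing prediction")
})
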