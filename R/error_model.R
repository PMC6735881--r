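#' @importFrom mgcv gam s
NULL

#' Fit the score-dependent prior on measurement error
#'
#' MAVE measurement dispersion varies systematically with the function
#' score (fully deleterious and wild-type-like variants usually behave
#' differently from intermediates), so per-variant standard deviations
#' estimated from few replicates are shrunk toward a prior learned by
#' regressing dispersion on score across the whole dataset. The prior is
#' a weighted penalized spline fitted in variance space (E[s^2] = sigma^2
#' makes this unbiased for replicate-estimated sds), in two passes: a
#' first fit with degrees-of-freedom weights, then a refit with weights
#' df / sigma_hat^4 matching the sampling variance of s^2. Evaluation is
#' clamped to the observed score range, so extrapolation returns the
#' boundary value; sparse data fall back to a weighted line and then to
#' a constant.
#'
#' @param records score table (rescaled scale) with \code{sd} and
#'   \code{n_reps}; records need \code{n_reps >= 2} and finite sd to
#'   inform the fit
#' @param minRecords below this many usable records the prior degrades
#'   to the constant median sd, with a warning
#' @return a function score -> sigma (class \code{"sigmaPrior"}), with
#'   the clamping range in attributes
#' @export
fitSigmaPrior <- function(records, minRecords = 10L) {
    use <- is.finite(records$sd) & records$sd >= 0 & records$n_reps >= 2L &
        is.finite(records$score)
    dat <- records[use, , drop = FALSE]

    constantPrior <- function(value) {
        f <- function(score) rep(value, length(score))
        structure(f, class = "sigmaPrior", range = c(-Inf, Inf),
                  form = "constant")
    }
    if (nrow(dat) < minRecords) {
        fallback <- if (nrow(dat)) median(dat$sd)
                    else median(records$sd[is.finite(records$sd)])
        if (!is.finite(fallback))
            stop("no finite sd values to build an error prior from",
                 call. = FALSE)
        warning("fewer than ", minRecords, " usable sd records; ",
                "using constant prior sigma = ", signif(fallback, 4),
                call. = FALSE)
        return(constantPrior(fallback))
    }

    v <- dat$sd^2
    x <- dat$score
    df <- dat$n_reps - 1
    rng <- range(x)
    nu <- length(unique(x))
    if (nu >= 5L) {
        k <- min(5L, nu - 1L)
        fit1 <- mgcv::gam(v ~ s(x, k = k), weights = df)
        vhat <- pmax(as.numeric(predict(fit1)), 1e-10)
        fit <- mgcv::gam(v ~ s(x, k = k), weights = df / vhat^2)
        form <- "spline"
    } else if (nu >= 2L) {
        fit <- lm(v ~ x, weights = df)
        form <- "line"
    } else {
        return(constantPrior(sqrt(stats::weighted.mean(v, df))))
    }
    f <- function(score) {
        xc <- pmin(pmax(score, rng[1]), rng[2])
        sqrt(pmax(as.numeric(predict(fit, newdata = data.frame(x = xc))),
                  1e-12))
    }
    structure(f, class = "sigmaPrior", range = rng, form = form)
}

#' Regularize per-variant standard errors against the prior
#'
#' With at least \code{K} replicates the replicate-estimated standard
#' error is trusted as-is. With fewer, the measured and prior variances
#' are pooled with \code{priorDf} pseudo-degrees of freedom:
#' \deqn{\sigma_{reg}^2 = \frac{d_0 \sigma_{prior}^2 +
#'   (n-1)\,\sigma_{meas}^2}{d_0 + n - 1}}
#' so a single-replicate record (no within-variant dispersion) returns
#' the prior exactly, and the measured term dominates as replicates
#' accumulate. Records with missing sd also fall back to the prior.
#'
#' @param records score table (rescaled scale)
#' @param prior function from \code{\link{fitSigmaPrior}}
#' @param K replicate count at which the measured sd is fully trusted
#' @param priorDf pseudo-degrees of freedom of the prior
#' @return data.frame: variant, n_reps, sigma_measured, sigma_prior,
#'   sigma_regularized
#' @export
regularizeSigma <- function(records, prior, K = 4L, priorDf = 2) {
    stopifnot(K >= 2L, priorDf > 0)
    sm <- records$sd
    sp <- prior(records$score)
    n <- records$n_reps
    pooled <- sqrt((priorDf * sp^2 + (n - 1) * sm^2) / (priorDf + n - 1))
    sr <- ifelse(!is.finite(sm), sp,
          ifelse(n >= K, sm, pooled))
    data.frame(variant = records$variant, n_reps = n,
               sigma_measured = sm, sigma_prior = sp,
               sigma_regularized = sr)
}

#' Standard error attached to imputed scores
#'
#' Imputed scores carry the model's global 10-fold cross-validation RMSE
#' as their standard error (floored at 1e-6 so downstream inverse-
#' variance weights stay finite), optionally inflated at positions with
#' few measured missense variants, where the positional-mean feature is
#' weakest.
#'
#' @param bundle a trained \linkS4class{ModelBundle}
#' @param positions integer vector of target positions
#' @param measuredPerPosition optional integer vector (same length)
#'   counting measured missense variants at each target's position
#' @param inflation multiplicative factor applied where the count falls
#'   below \code{minMeasured} (default 1 = no inflation)
#' @param minMeasured coverage threshold for inflation
#' @return numeric vector of standard errors, one per position entry
#' @export
imputedSigma <- function(bundle, positions, measuredPerPosition = NULL,
                         inflation = 1, minMeasured = 3L) {
    stopifnot(is(bundle, "ModelBundle"))
    if (length(bundle@cvRMSE) != 1L || is.na(bundle@cvRMSE))
        stop("bundle is untrained (no cvRMSE)", call. = FALSE)
    base <- max(bundle@cvRMSE, 1e-6)
    out <- rep(base, length(positions))
    if (!is.null(measuredPerPosition) && inflation != 1)
        out[measuredPerPosition < minMeasured] <- base * inflation
    out
}
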