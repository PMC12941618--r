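#' Number of diffusion steps of a schedule
#' @param x a NoiseSchedule
#' @return integer T
#' @export
setGeneric("nSteps", function(x) standardGeneric("nSteps"))

#' Per-step noise rates
#' @param x a NoiseSchedule
#' @return numeric vector beta
#' @export
setGeneric("betas", function(x) standardGeneric("betas"))

#' Cumulative signal-retention factors
#' @param x a NoiseSchedule
#' @return numeric vector alpha-bar
#' @export
setGeneric("alphaBar", function(x) standardGeneric("alphaBar"))

#' Posterior variances of the reverse transition
#' @param x a NoiseSchedule
#' @return numeric vector beta-tilde
#' @export
setGeneric("posteriorVar", function(x) standardGeneric("posteriorVar"))

#' Classification accuracy
#'
#' For a square confusion matrix (rows = truth, columns = prediction) the
#' fraction of agreeing pairs, \code{sum(diag(cm))/sum(cm)}; for a
#' MetricsReport, the stored value.
#' @param x confusion matrix or MetricsReport
#' @return scalar in [0,1]
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))

#' Macro-averaged F1 score
#'
#' Unweighted mean of per-class F1 = 2PR/(P+R). Classes with neither true
#' instances nor predictions are excluded from the mean; a class with
#' instances or predictions but zero F1 denominator contributes 0.
#' @param x confusion matrix or MetricsReport
#' @return scalar in [0,1]
#' @export
setGeneric("macroF1", function(x) standardGeneric("macroF1"))

#' Cohen's kappa
#'
#' Chance-corrected agreement \eqn{(p_o - p_e)/(1 - p_e)} where \eqn{p_o} is
#' the observed agreement and \eqn{p_e} the expected agreement of the
#' marginals.
#' @param x confusion matrix or MetricsReport
#' @return scalar in [-1,1]
#' @export
setGeneric("cohenKappa", function(x) standardGeneric("cohenKappa"))

setMethod("nSteps", "NoiseSchedule", function(x) x@steps)
setMethod("betas", "NoiseSchedule", function(x) x@beta)
setMethod("alphaBar", "NoiseSchedule", function(x) x@alphaBar)
setMethod("posteriorVar", "NoiseSchedule", function(x) x@posteriorVar)

setMethod("show", "NoiseSchedule", function(object) {
    cat(sprintf("NoiseSchedule: T = %d, beta in [%.3g, %.3g], alphaBar_T = %.4g\n",
        object@steps, min(object@beta), max(object@beta),
        object@alphaBar[object@steps]))
})

setMethod("show", "PriorBundle", function(object) {
    cat(sprintf("PriorBundle: K = %d, latent dim = %d, ROI [%d,%d)x[%d,%d)\n",
        length(object@yG), length(object@rhoX),
        object@roiBox[1], object@roiBox[2], object@roiBox[3],
        object@roiBox[4]))
    cat("  yG:", format(round(object@yG, 3)), "\n")
    cat("  yL:", format(round(object@yL, 3)), "\n")
    cat("  yF:", format(round(object@yF, 3)), "\n")
})

setMethod("show", "CGADConfig", function(object) {
    d <- object@diffusion; tr <- object@training
    cat(sprintf("CGADConfig: T = %d (%s, beta %.2g..%.2g, guidance %s)\n",
        d$T, d$schedule_kind, d$beta_start, d$beta_end, d$guidance_mode))
    cat(sprintf("  training: %d epochs, batch %d, lr %.2g (%s), lambda %.2g, aux period %d\n",
        tr$epochs, tr$batch_size, tr$learning_rate, tr$lr_schedule,
        tr$lambda, tr$aux_period))
    cat(sprintf("  flags: use_cgani=%s use_hpcm=%s use_idcr=%s\n",
        tr$use_cgani, tr$use_hpcm, tr$use_idcr))
})

setMethod("show", "LossReport", function(object) {
    cat(sprintf(
        "LossReport: total %.4f = denoise %.4f + %.2g*(mmd %.4f + aux %s) + recon %.4f\n",
        object@lTotal, object@lDenoise, object@lambda, object@lMmd,
        ifelse(is.na(object@lAux), "-", sprintf("%.4f", object@lAux)),
        object@lRecon))
})

setMethod("show", "MetricsReport", function(object) {
    cat(sprintf("MetricsReport: accuracy %.4f, macro-F1 %.4f, kappa %.4f (n = %d)\n",
        object@accuracy, object@macroF1, object@kappa,
        sum(object@confusion)))
})

setMethod("show", "SynthSpec", function(object) {
    cat(sprintf(
        "SynthSpec: %d classes x %d images, %dpx, ambiguity %.2f, texture %.2f, seed %d\n",
        object@K, object@nPerClass, object@imageSize, object@ambiguity,
        object@textureNoise, object@seed))
})

setMethod("show", "CGADModel", function(object) {
    tr <- object@config@training
    cat(sprintf("CGADModel: K = %d, image %dpx, T = %d\n",
        object@config@architecture$n_classes, tr$image_size,
        object@schedule@steps))
})
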