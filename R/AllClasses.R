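#' @import methods
NULL

#' NoiseSchedule: per-step diffusion noise rates and derived quantities
#'
#' Container for a discrete diffusion noise schedule: per-step rates
#' \eqn{\beta_t \in (0,1)}, cumulative signal-retention factors
#' \eqn{\bar\alpha_t = \prod_{s \le t}(1-\beta_s)} and posterior variances
#' \eqn{\tilde\beta_t = \frac{1-\bar\alpha_{t-1}}{1-\bar\alpha_t}\,\beta_t}
#' (with the convention \eqn{\bar\alpha_0 = 1}, so \eqn{\tilde\beta_1 = 0}).
#'
#' @slot steps number of diffusion steps T
#' @slot beta numeric vector of length T, per-step noise rates in (0,1)
#' @slot alphaBar numeric vector of length T, strictly decreasing in (0,1)
#' @slot posteriorVar numeric vector of length T, \eqn{\tilde\beta_t}
#'
#' @seealso [buildSchedule()]
#' @exportClass NoiseSchedule
setClass("NoiseSchedule",
    representation(steps = "integer", beta = "numeric",
                   alphaBar = "numeric", posteriorVar = "numeric"))

setValidity("NoiseSchedule", function(object) {
    msg <- NULL
    Tn <- object@steps
    if (length(Tn) != 1L || is.na(Tn) || Tn < 1L)
        msg <- c(msg, "steps must be a single positive integer")
    else {
        if (length(object@beta) != Tn || length(object@alphaBar) != Tn ||
            length(object@posteriorVar) != Tn)
            msg <- c(msg, "beta, alphaBar, posteriorVar must have length steps")
        if (any(object@beta <= 0) || any(object@beta >= 1))
            msg <- c(msg, "beta must lie in (0,1)")
        if (any(object@alphaBar <= 0) || any(object@alphaBar >= 1))
            msg <- c(msg, "alphaBar must lie in (0,1)")
        if (Tn > 1L && any(diff(object@alphaBar) >= 0))
            msg <- c(msg, "alphaBar must be strictly decreasing")
        if (abs(object@posteriorVar[1L]) > 1e-12)
            msg <- c(msg, "posteriorVar[1] must be 0 (alphaBar_0 = 1 convention)")
    }
    if (is.null(msg)) TRUE else msg
})

#' LabelState: class-score vectors tracked through diffusion
#'
#' Bundles the clean target \eqn{y_0}, a noisy state \eqn{y_t}, the estimated
#' clean vector \eqn{\hat y_0} and the prior centre \eqn{\bar y_T} for one
#' sample. During training \eqn{y_0} is the one-hot encoding of the label.
#'
#' @slot K number of classes (>= 2)
#' @slot y0,yt,y0Hat,yBarT numeric vectors of length K
#' @exportClass LabelState
setClass("LabelState",
    representation(K = "integer", y0 = "numeric", yt = "numeric",
                   y0Hat = "numeric", yBarT = "numeric"))

setValidity("LabelState", function(object) {
    msg <- NULL
    if (object@K < 2L) msg <- c(msg, "K must be >= 2")
    for (s in c("y0", "yt", "y0Hat", "yBarT"))
        if (length(slot(object, s)) != object@K)
            msg <- c(msg, sprintf("%s must have length K", s))
    if (is.null(msg)) TRUE else msg
})

#' PriorBundle: multi-level semantic priors for one image
#'
#' Output of the prior network: global (\code{yG}), local (\code{yL}) and
#' fused (\code{yF}) class-score vectors (softmax scale), the matching raw
#' logits, the conditioning image latent \code{rhoX} and the selected
#' region-of-interest box (0-based, half-open: row_start, row_end,
#' col_start, col_end in image pixel coordinates).
#'
#' @slot yG,yL,yF numeric class-score vectors of length K
#' @slot logitsG,logitsL,logitsF raw head outputs of length K
#' @slot rhoX numeric image latent of configured dimension D
#' @slot roiBox integer vector length 4
#' @exportClass PriorBundle
setClass("PriorBundle",
    representation(yG = "numeric", yL = "numeric", yF = "numeric",
                   logitsG = "numeric", logitsL = "numeric",
                   logitsF = "numeric", rhoX = "numeric",
                   roiBox = "integer"))

setValidity("PriorBundle", function(object) {
    msg <- NULL
    K <- length(object@yG)
    if (length(object@yL) != K || length(object@yF) != K)
        msg <- c(msg, "yG, yL, yF must share length K")
    if (length(object@roiBox) != 4L)
        msg <- c(msg, "roiBox must have length 4")
    if (!all(is.finite(object@yG)) || !all(is.finite(object@yL)) ||
        !all(is.finite(object@yF)) || !all(is.finite(object@rhoX)))
        msg <- c(msg, "prior outputs must be finite")
    if (is.null(msg)) TRUE else msg
})

#' CGADConfig: schedule, architecture and training configuration
#'
#' Created by [cgadConfig()]; groups the diffusion schedule keys, the network
#' architecture keys and the optimiser/loop keys, plus the ablation flags
#' \code{use_cgani}, \code{use_hpcm}, \code{use_idcr}.
#'
#' @slot diffusion named list (T, beta_start, beta_end, schedule_kind,
#'   guidance_mode)
#' @slot architecture named list (channels, dilation sets, crop fraction,
#'   attention ratio, latent dim, denoiser width/depth, time-embedding dim)
#' @slot training named list (epochs, batch_size, learning_rate, lr_schedule,
#'   seed, aux_period, lambda, recon_enabled, flags, image_size, n_samples)
#' @exportClass CGADConfig
setClass("CGADConfig",
    representation(diffusion = "list", architecture = "list",
                   training = "list"))

setValidity("CGADConfig", function(object) {
    msg <- NULL
    d <- object@diffusion; tr <- object@training
    if (!is.numeric(d$T) || d$T < 1) msg <- c(msg, "diffusion$T must be >= 1")
    if (!(d$schedule_kind %in% "linear"))
        msg <- c(msg, "schedule_kind must be 'linear'")
    if (!(d$guidance_mode %in% c("prior_sum", "ybar_ema")))
        msg <- c(msg, "guidance_mode must be 'prior_sum' or 'ybar_ema'")
    if (tr$epochs < 1 || tr$batch_size < 1 || tr$learning_rate <= 0)
        msg <- c(msg, "epochs, batch_size, learning_rate must be positive")
    if (tr$lambda < 0) msg <- c(msg, "lambda must be >= 0")
    for (f in c("use_cgani", "use_hpcm", "use_idcr"))
        if (!is.logical(tr[[f]]) || length(tr[[f]]) != 1L)
            msg <- c(msg, sprintf("training$%s must be a single logical", f))
    if (is.null(msg)) TRUE else msg
})

#' LossReport: one logged step of the composite objective
#'
#' Holds the loss components of one optimisation step and their weighted
#' total \eqn{L_{total} = L_{denoise} + \lambda (L_{MMD} + L_{aux})}
#' (+ the reconstruction regulariser when enabled). \code{lAux} is \code{NA}
#' on steps where the periodic auxiliary branch is inactive.
#'
#' @slot lDenoise,lMmd,lAux,lRecon,lTotal scalars
#' @slot lambda weighting scalar
#' @exportClass LossReport
setClass("LossReport",
    representation(lDenoise = "numeric", lMmd = "numeric", lAux = "numeric",
                   lRecon = "numeric", lTotal = "numeric", lambda = "numeric"))

setValidity("LossReport", function(object) {
    msg <- NULL
    vals <- c(object@lDenoise, object@lMmd, object@lRecon, object@lTotal)
    if (any(!is.finite(vals))) msg <- c(msg, "loss components must be finite")
    if (object@lambda < 0) msg <- c(msg, "lambda must be >= 0")
    aux <- if (is.na(object@lAux)) 0 else object@lAux
    expect <- object@lDenoise + object@lambda * (object@lMmd + aux) +
        object@lRecon
    if (abs(object@lTotal - expect) > 1e-8 * max(1, abs(expect)))
        msg <- c(msg, "lTotal must equal the weighted combination of parts")
    if (is.null(msg)) TRUE else msg
})

#' MetricsReport: evaluation metrics and training diagnostics
#'
#' @slot confusion square integer confusion matrix (rows = truth,
#'   columns = prediction)
#' @slot accuracy,macroF1,kappa scalars derived from \code{confusion}
#' @slot curves data.frame of per-epoch diagnostics (may be empty)
#' @slot lossDelta data.frame of windowed loss-difference means with
#'   bootstrap confidence bounds (may be empty)
#' @exportClass MetricsReport
setClass("MetricsReport",
    representation(confusion = "matrix", accuracy = "numeric",
                   macroF1 = "numeric", kappa = "numeric",
                   curves = "data.frame", lossDelta = "data.frame"))

setValidity("MetricsReport", function(object) {
    msg <- NULL
    cm <- object@confusion
    if (nrow(cm) != ncol(cm)) msg <- c(msg, "confusion must be square")
    if (sum(cm) > 0) {
        if (abs(object@accuracy - sum(diag(cm)) / sum(cm)) > 1e-12)
            msg <- c(msg, "accuracy must equal trace(confusion)/total")
    }
    if (object@accuracy < 0 || object@accuracy > 1 ||
        object@macroF1 < 0 || object@macroF1 > 1 ||
        object@kappa < -1 || object@kappa > 1)
        msg <- c(msg, "metrics out of range")
    if (is.null(msg)) TRUE else msg
})

#' SynthSpec: parameters of the procedural lesion-image generator
#'
#' @slot nPerClass images generated per class
#' @slot K number of classes
#' @slot imageSize square image side in pixels
#' @slot ambiguity scalar in [0,1]; 0 = maximally separable classes, 1 =
#'   class-generating distributions identical in expectation
#' @slot textureNoise nonnegative scalar scaling the fill-texture noise
#' @slot seed integer seed; same spec + seed reproduces images byte-exactly
#' @exportClass SynthSpec
setClass("SynthSpec",
    representation(nPerClass = "integer", K = "integer",
                   imageSize = "integer", ambiguity = "numeric",
                   textureNoise = "numeric", seed = "integer"))

setValidity("SynthSpec", function(object) {
    msg <- NULL
    if (object@nPerClass < 1L) msg <- c(msg, "nPerClass must be >= 1")
    if (object@K < 2L) msg <- c(msg, "K must be >= 2")
    if (object@imageSize < 32L) msg <- c(msg, "imageSize must be >= 32")
    if (object@ambiguity < 0 || object@ambiguity > 1)
        msg <- c(msg, "ambiguity must lie in [0,1]")
    if (object@textureNoise < 0) msg <- c(msg, "textureNoise must be >= 0")
    if (is.null(msg)) TRUE else msg
})

#' CGADModel: trained or initialised model state
#'
#' Bundles the prior network, the conditional denoiser, the auxiliary-head
#' bookkeeping (EMA of the prior centre when \code{guidance_mode} is
#' \code{"ybar_ema"}), the noise schedule and the configuration.
#'
#' @slot prior list of prior-network parameter arrays
#' @slot denoiser list of denoiser parameter arrays
#' @slot schedule a [NoiseSchedule-class]
#' @slot config a [CGADConfig-class]
#' @slot yBarEma numeric length-K running estimate of the prior centre
#' @exportClass CGADModel
setClass("CGADModel",
    representation(prior = "list", denoiser = "list",
                   schedule = "NoiseSchedule", config = "CGADConfig",
                   yBarEma = "numeric"))
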