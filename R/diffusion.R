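#' Prediction confidence of a probability vector
#'
#' The maximum posterior probability of the classification head,
#' \eqn{c = \max_k p(y = k | x)}, used as a per-sample proxy for semantic
#' reliability. By construction \eqn{1/K \le c \le 1}. Downstream noise
#' modulation treats the returned value as a constant (no gradient flows
#' into it).
#'
#' @param probs length-K probability vector (nonnegative, sums to 1 within
#'   1e-6)
#' @return scalar confidence in [1/K, 1]
#' @examples
#' confidenceScore(c(0.7, 0.2, 0.1))
#' @export
confidenceScore <- function(probs) {
    if (any(!is.finite(probs)) || any(probs < 0))
        stop("probs must be nonnegative and finite")
    if (abs(sum(probs) - 1) > 1e-6)
        stop("probs must sum to 1 (tolerance 1e-6)")
    max(probs)
}

#' Confidence-guided forward diffusion of a class-score vector
#'
#' Corrupts the clean target \eqn{y_0} at step t:
#' \deqn{y_t = \sqrt{\bar\alpha_t}\, y_0 +
#'   \sqrt{1-\bar\alpha_t}\,(1-c)\,\epsilon + (1-\bar\alpha_t)\, G,}
#' where G is the guidance vector (by default the sum of the denoised
#' global and local prior score vectors) and c the prediction confidence.
#' At c = 1 the stochastic term vanishes; at c = 0 with G = 0 this is the
#' standard DDPM forward marginal.
#'
#' @param y0 length-K clean target (one-hot during training)
#' @param t step index in [1, T]
#' @param c confidence scalar
#' @param eps length-K standard-normal draw
#' @param guidance length-K guidance vector
#' @param schedule a [NoiseSchedule-class]
#' @return length-K noisy vector y_t
#' @export
forwardDiffuse <- function(y0, t, c, eps, guidance, schedule) {
    t <- checkStep(t, schedule)
    K <- length(y0)
    if (length(eps) != K || length(guidance) != K)
        stop("y0, eps and guidance must share length K")
    ab <- schedule@alphaBar[t]
    sqrt(ab) * y0 + sqrt(1 - ab) * (1 - c) * eps + (1 - ab) * guidance
}

#' Interpolated confidence-guided perturbation
#'
#' The simplified perturbation with a normalised timestep
#' \eqn{t \in [0,1]}:
#' \deqn{y_t = t\, y + (1-t)\, y_0 + (1-c)\,\epsilon.}
#' Provided for completeness; the training loop uses [forwardDiffuse()].
#'
#' @param yPred length-K current model prediction y
#' @param y0 length-K clean target
#' @param tNorm normalised timestep in [0,1]
#' @param c confidence scalar
#' @param eps length-K noise draw
#' @return length-K perturbed vector
#' @export
perturbInterpolated <- function(yPred, y0, tNorm, c, eps) {
    if (length(tNorm) != 1L || !is.finite(tNorm) || tNorm < 0 || tNorm > 1)
        stop("tNorm must lie in [0,1]")
    if (length(yPred) != length(y0) || length(eps) != length(y0))
        stop("yPred, y0 and eps must share length K")
    tNorm * yPred + (1 - tNorm) * y0 + (1 - c) * eps
}

#' Estimate the clean representation from a noisy state
#'
#' Confidence-aware denoising at step t:
#' \deqn{\hat y_0 = \frac{1}{\sqrt{\bar\alpha_t}}\left[ y_t -
#'   (1-\bar\alpha_t)\, G - (1-c)\sqrt{1-\bar\alpha_t}\,
#'   \epsilon_\theta \right].}
#' With \code{epsPred} equal to the truly injected noise and the same
#' guidance vector as in [forwardDiffuse()], this inverts the forward
#' corruption exactly.
#'
#' @param yt length-K noisy vector
#' @param t step index
#' @param c confidence scalar
#' @param epsPred length-K predicted noise
#' @param guidance length-K guidance vector (matched with the forward pass)
#' @param schedule a [NoiseSchedule-class]
#' @return length-K estimated clean vector
#' @export
estimateClean <- function(yt, t, c, epsPred, guidance, schedule) {
    t <- checkStep(t, schedule)
    K <- length(yt)
    if (length(epsPred) != K || length(guidance) != K)
        stop("yt, epsPred and guidance must share length K")
    ab <- schedule@alphaBar[t]
    (yt - (1 - ab) * guidance - (1 - c) * sqrt(1 - ab) * epsPred) / sqrt(ab)
}

#' One reverse transition step
#'
#' Draws \eqn{y_{t-1} = \mu_t(\hat y_0, y_t, G) + \sqrt{\tilde\beta_t}\,
#' \epsilon}. The posterior mean applies the standard DDPM two-coefficient
#' formula to the guidance-shifted state \eqn{z_t = y_t - (1-\bar\alpha_t)G}
#' and shifts back by \eqn{(1-\bar\alpha_{t-1})G}:
#' \deqn{\mu_t = \frac{\sqrt{\bar\alpha_{t-1}}\beta_t}{1-\bar\alpha_t}
#'   \hat y_0 + \frac{\sqrt{\alpha_t}(1-\bar\alpha_{t-1})}{1-\bar\alpha_t}
#'   z_t + (1-\bar\alpha_{t-1})\, G.}
#' This is the unique choice for which the noiseless chain is consistent
#' with the guided forward marginals. At t = 1 the posterior is degenerate
#' and the step returns \eqn{\hat y_0} exactly.
#'
#' @param y0Hat length-K estimated clean vector
#' @param yt length-K current noisy vector
#' @param t step index
#' @param guidance length-K guidance vector
#' @param noise length-K standard-normal draw
#' @param schedule a [NoiseSchedule-class]
#' @return length-K vector y_{t-1}
#' @export
posteriorStep <- function(y0Hat, yt, t, guidance, noise, schedule) {
    t <- checkStep(t, schedule)
    K <- length(y0Hat)
    if (length(yt) != K || length(guidance) != K || length(noise) != K)
        stop("y0Hat, yt, guidance and noise must share length K")
    ab_t <- schedule@alphaBar[t]
    ab_prev <- if (t == 1L) 1 else schedule@alphaBar[t - 1L]
    beta_t <- schedule@beta[t]
    alpha_t <- 1 - beta_t
    z_t <- yt - (1 - ab_t) * guidance
    mu <- sqrt(ab_prev) * beta_t / (1 - ab_t) * y0Hat +
        sqrt(alpha_t) * (1 - ab_prev) / (1 - ab_t) * z_t +
        (1 - ab_prev) * guidance
    mu + sqrt(schedule@posteriorVar[t]) * noise
}

#' Full reverse diffusion sampler
#'
#' Runs the reverse chain t = T..1. The chain is initialised from the
#' guided forward marginal with the classifier's softmax output standing
#' in for the (unknown) clean target, so no ground-truth access is needed:
#' \eqn{y_T = \sqrt{\bar\alpha_T}\, p + \sqrt{1-\bar\alpha_T}(1-c) z +
#' (1-\bar\alpha_T) G}. Each step predicts the noise with \code{denoiser},
#' forms \eqn{\hat y_0} via [estimateClean()] and transitions with
#' [posteriorStep()]. The sampler's reparameterisation noise is scaled by
#' \eqn{(1-c)}: low-confidence samples retain stochasticity to explore,
#' high-confidence samples converge on a deterministic contraction (at
#' c = 1 the chain is fully deterministic). Deterministic given
#' \code{seed}.
#'
#' @param rhoX image latent passed to the denoiser
#' @param guidance length-K guidance vector
#' @param denoiser function(yt, t, rhoX, guidance) returning a length-K
#'   noise prediction
#' @param classifierProbs length-K probability vector from the
#'   classification head; supplies the confidence and the y0 stand-in
#' @param schedule a [NoiseSchedule-class]
#' @param seed integer seed for the sampling noise
#' @param trajectory if TRUE, also return the per-step states
#' @param confidence optional override of the confidence scalar (e.g. 0
#'   for the fixed-schedule baseline); by default the maximum of
#'   \code{classifierProbs}
#' @return list with \code{y0Hat} (final estimate) and, when requested,
#'   \code{trajectory}: a (T+1) x K matrix of states y_T..y_0 (rows are
#'   steps in decreasing t; the last row is the final \eqn{\hat y_0})
#' @export
reverseSample <- function(rhoX, guidance, denoiser, classifierProbs,
                          schedule, seed, trajectory = FALSE,
                          confidence = NULL) {
    K <- length(guidance)
    if (length(classifierProbs) != K)
        stop("classifierProbs and guidance must share length K")
    c <- confidence %||% confidenceScore(classifierProbs)
    Tn <- schedule@steps
    withSeed(seed, {
        ab_T <- schedule@alphaBar[Tn]
        yt <- sqrt(ab_T) * classifierProbs +
            sqrt(1 - ab_T) * (1 - c) * stats::rnorm(K) +
            (1 - ab_T) * guidance
        traj <- if (trajectory) matrix(NA_real_, Tn + 1L, K) else NULL
        if (trajectory) traj[1L, ] <- yt
        y0_hat <- yt
        for (t in Tn:1) {
            eps_pred <- denoiser(yt, t, rhoX, guidance)
            if (length(eps_pred) != K)
                stop("denoiser output length must equal K")
            y0_hat <- estimateClean(yt, t, c, eps_pred, guidance, schedule)
            yt <- posteriorStep(y0_hat, yt, t, guidance,
                                (1 - c) * stats::rnorm(K), schedule)
            if (trajectory) traj[Tn - t + 2L, ] <- yt
        }
        out <- list(y0Hat = y0_hat)
        if (trajectory) out$trajectory <- traj
        out
    })
}

#' Export a reverse-diffusion trajectory as TSV
#'
#' Writes one row per retained step with columns
#' \code{sample_id, t, entry_0..entry_{K-1}, predicted_class, true_class}
#' (classes 0-based), for external embedding visualisation.
#'
#' @param trajectories named list of (T+1) x K matrices as returned by
#'   [reverseSample()] with \code{trajectory = TRUE}
#' @param predicted,true integer class labels (0-based), one per sample
#' @param file output path
#' @param schedule the [NoiseSchedule-class] used for sampling
#' @return invisibly, the written data.frame
#' @export
exportTrajectories <- function(trajectories, predicted, true, file,
                               schedule) {
    stopifnot(length(trajectories) == length(predicted),
              length(predicted) == length(true))
    Tn <- schedule@steps
    rows <- lapply(seq_along(trajectories), function(i) {
        tr <- trajectories[[i]]
        df <- as.data.frame(tr)
        names(df) <- paste0("entry_", seq_len(ncol(tr)) - 1L)
        cbind(sample_id = names(trajectories)[i] %||% i,
              t = c(Tn:1, 0L), df,
              predicted_class = predicted[i], true_class = true[i])
    })
    out <- do.call(rbind, rows)
    utils::write.table(out, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
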