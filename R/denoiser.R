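# Conditional noise-prediction network for label-space diffusion:
# sinusoidal time embedding, an encoder-decoder (with skip connection) over
# the conditioning latent, and a residual MLP head over the merged state.

#' Sinusoidal time embedding
#'
#' Maps an integer diffusion step to a dim-dimensional vector of sines and
#' cosines at geometrically spaced frequencies; distinct steps map to
#' distinct embeddings.
#'
#' @param t step index (>= 1)
#' @param dim embedding dimension (even)
#' @return numeric vector of length dim
#' @export
timeEmbedding <- function(t, dim) {
    if (dim %% 2 != 0) stop("dim must be even")
    half <- dim %/% 2
    freqs <- exp(-log(10000) * (seq_len(half) - 1) / max(1, half - 1))
    c(sin(t * freqs), cos(t * freqs))
}

initDenoiser <- function(arch) {
    K <- arch$n_classes; D <- arch$latent_dim
    w <- arch$denoiser_width; wh <- max(2L, w %/% 2L)
    dt <- arch$time_embed_dim
    blocks <- lapply(seq_len(arch$denoiser_depth), function(i)
        initLinear(w, w))
    names(blocks) <- paste0("h", seq_len(arch$denoiser_depth))
    c(list(enc1 = initLinear(D, w), enc2 = initLinear(w, wh),
           dec1 = initLinear(wh, w),
           inproj = initLinear(2L * K + dt + w, w)),
      blocks,
      list(out = initLinear(w, K, gain = 1)))
}

denoiserApply <- function(d, yt, t, rho, guidance, arch) {
    temb <- timeEmbedding(t, arch$time_embed_dim)
    e1 <- linearForward(rho, d$enc1); r1 <- reluForward(e1$out)
    e2 <- linearForward(r1$out, d$enc2); r2 <- reluForward(e2$out)
    dc <- linearForward(r2$out, d$dec1); r3 <- reluForward(dc$out)
    condFeat <- r3$out + r1$out  # skip connection
    xin <- c(yt, temb, condFeat, guidance)
    ip <- linearForward(xin, d$inproj); r0 <- reluForward(ip$out)
    h <- r0$out
    depth <- arch$denoiser_depth
    bc <- vector("list", depth); bm <- vector("list", depth)
    for (i in seq_len(depth)) {
        bi <- linearForward(h, d[[paste0("h", i)]])
        ri <- reluForward(bi$out)
        bc[[i]] <- bi$cache; bm[[i]] <- ri$cache
        h <- h + ri$out  # residual block
    }
    ot <- linearForward(h, d$out)
    list(out = ot$out,
         cache = list(e1 = e1$cache, m1 = r1$cache, e2 = e2$cache,
                      m2 = r2$cache, dc = dc$cache, m3 = r3$cache,
                      ip = ip$cache, m0 = r0$cache, bc = bc, bm = bm,
                      ot = ot$cache, K = length(yt), dt = arch$time_embed_dim,
                      wcond = length(condFeat)))
}

denoiserBack <- function(dEps, d, cache, arch) {
    grads <- zerosLike(d)
    ob <- linearBackward(dEps, d$out, cache$ot)
    grads$out <- list(W = ob$dW, b = ob$db)
    dh <- ob$dx
    for (i in arch$denoiser_depth:1) {
        nm <- paste0("h", i)
        dr <- reluBackward(dh, cache$bm[[i]])
        bb <- linearBackward(dr, d[[nm]], cache$bc[[i]])
        grads[[nm]] <- list(W = bb$dW, b = bb$db)
        dh <- dh + bb$dx
    }
    dr0 <- reluBackward(dh, cache$m0)
    ipb <- linearBackward(dr0, d$inproj, cache$ip)
    grads$inproj <- list(W = ipb$dW, b = ipb$db)
    K <- cache$K; dt <- cache$dt; wc <- cache$wcond
    dYt <- ipb$dx[seq_len(K)]
    dCond <- ipb$dx[K + dt + seq_len(wc)]
    dGuidance <- ipb$dx[K + dt + wc + seq_len(K)]
    # condition pathway (skip adds dCond to both r3 and r1)
    dr3 <- reluBackward(dCond, cache$m3)
    dcb <- linearBackward(dr3, d$dec1, cache$dc)
    grads$dec1 <- list(W = dcb$dW, b = dcb$db)
    dr2 <- reluBackward(dcb$dx, cache$m2)
    e2b <- linearBackward(dr2, d$enc2, cache$e2)
    grads$enc2 <- list(W = e2b$dW, b = e2b$db)
    dr1 <- reluBackward(e2b$dx + dCond, cache$m1)
    e1b <- linearBackward(dr1, d$enc1, cache$e1)
    grads$enc1 <- list(W = e1b$dW, b = e1b$db)
    list(grads = grads, dYt = dYt, dRho = e1b$dx, dGuidance = dGuidance)
}

#' Predict the injected noise
#'
#' Evaluates the conditional denoiser
#' \eqn{\epsilon_\theta(y_t, t, \rho(x), G)}. Deterministic given the
#' model parameters; differentiable in \code{yt}, \code{rhoX} and
#' \code{guidance} (gradients are used by the training loop).
#'
#' @param model a [CGADModel-class]
#' @param yt length-K noisy class-score vector
#' @param t step index in [1, T]
#' @param rhoX conditioning latent of the configured dimension
#' @param guidance length-K guidance vector
#' @return length-K noise prediction
#' @export
predictNoise <- function(model, yt, t, rhoX, guidance) {
    arch <- model@config@architecture
    K <- arch$n_classes
    if (length(yt) != K || length(guidance) != K)
        stop("yt and guidance must have length n_classes")
    if (length(rhoX) != arch$latent_dim)
        stop("rhoX must have length latent_dim")
    checkStep(t, model@schedule)
    denoiserApply(model@denoiser, yt, t, rhoX, guidance, arch)$out
}

#' Branch-specific noise prediction
#'
#' The same network as [predictNoise()] with the guidance input replaced by
#' a single prior branch (global or local), yielding the branch predictions
#' \eqn{\hat\epsilon_g} and \eqn{\hat\epsilon_l} used by the multi-view MMD
#' regulariser.
#'
#' @inheritParams predictNoise
#' @param yBranch length-K prior score vector of the branch (yG or yL)
#' @return length-K noise prediction
#' @export
predictNoiseBranch <- function(model, yt, t, rhoX, yBranch) {
    predictNoise(model, yt, t, rhoX, yBranch)
}
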