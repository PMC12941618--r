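#' Denoising regression loss
#'
#' Squared Euclidean distance between the injected and the predicted noise,
#' \eqn{\|\epsilon - \hat\epsilon\|^2} (sum over entries). For batches
#' (matrices with samples in rows) the per-sample norms are averaged.
#'
#' @param epsTrue,epsPred length-K vectors, or n x K matrices of samples
#' @return nonnegative scalar
#' @export
denoiseLoss <- function(epsTrue, epsPred) {
    if (is.matrix(epsTrue) || is.matrix(epsPred)) {
        epsTrue <- as.matrix(epsTrue); epsPred <- as.matrix(epsPred)
        if (!all(dim(epsTrue) == dim(epsPred)))
            stop("epsTrue and epsPred must share dimensions")
        return(mean(rowSums((epsTrue - epsPred)^2)))
    }
    if (length(epsTrue) != length(epsPred))
        stop("epsTrue and epsPred must share length")
    sum((epsTrue - epsPred)^2)
}

#' Gaussian kernel with bandwidth mixture
#'
#' \eqn{k(u,v) = \frac{1}{B}\sum_b \exp(-\|u-v\|^2 / (2\sigma_b^2))}.
#'
#' @param u,v numeric vectors of equal length
#' @param bandwidths positive scalars \eqn{\sigma_b}
#' @return scalar in (0, 1]
#' @export
gaussianKernel <- function(u, v, bandwidths = 1) {
    if (length(u) != length(v)) stop("u and v must share length")
    if (any(bandwidths <= 0)) stop("bandwidths must be positive")
    d2 <- sum((u - v)^2)
    mean(exp(-d2 / (2 * bandwidths^2)))
}

# Pairwise squared distances between rows of A and rows of B.
pairwiseSq <- function(A, B) {
    an <- rowSums(A^2); bn <- rowSums(B^2)
    d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
    pmax(d2, 0)
}

# Median-heuristic bandwidth mixture: 5 values geometrically spaced around
# the median pairwise distance of the joint sample.
mmdBandwidths <- function(Z) {
    d2 <- pairwiseSq(Z, Z)
    d2 <- d2[upper.tri(d2)]
    med <- stats::median(d2[d2 > 0])
    if (!is.finite(med) || med <= 0) med <- 1
    sqrt(med / 2) * 2^seq(-2, 2)
}

asSampleMatrix <- function(x) {
    if (is.matrix(x)) x else matrix(x, ncol = 1L)
}

# Mixture-kernel Gram matrix from squared distances.
kernGram <- function(d2, bw) {
    G <- 0
    for (s in bw) G <- G + exp(-d2 / (2 * s^2))
    G / length(bw)
}

#' Maximum mean discrepancy (biased V-statistic)
#'
#' \eqn{\mathrm{MMD}(X,Y) = E[k(x,x')] + E[k(y,y')] - 2E[k(x,y)]} with all
#' pairs (including self-pairs) and a Gaussian bandwidth-mixture kernel.
#' Nonnegative up to floating-point error for this estimator.
#'
#' @param x,y sample sets: numeric vectors (univariate samples) or
#'   matrices with one sample per row
#' @param bandwidths kernel bandwidths; \code{NULL} selects a 5-bandwidth
#'   mixture around the median pairwise distance of the pooled sample
#' @return scalar MMD estimate
#' @examples
#' mmdStatistic(c(0, 2), 0, bandwidths = 1)
#' @export
mmdStatistic <- function(x, y, bandwidths = NULL) {
    X <- asSampleMatrix(x); Y <- asSampleMatrix(y)
    if (nrow(X) == 0L || nrow(Y) == 0L) stop("sample sets must be nonempty")
    if (ncol(X) != ncol(Y)) stop("samples must share vector length")
    if (is.null(bandwidths)) bandwidths <- mmdBandwidths(rbind(X, Y))
    if (any(bandwidths <= 0)) stop("bandwidths must be positive")
    mean(kernGram(pairwiseSq(X, X), bandwidths)) +
        mean(kernGram(pairwiseSq(Y, Y), bandwidths)) -
        2 * mean(kernGram(pairwiseSq(X, Y), bandwidths))
}

# Gradient of mmdStatistic(X, Y) with respect to the rows of X
# (Y and the bandwidths treated as constants).
mmdGradX <- function(X, Y, bandwidths) {
    n <- nrow(X); m <- nrow(Y); B <- length(bandwidths)
    gXX <- matrix(0, n, ncol(X)); gXY <- matrix(0, n, ncol(X))
    d2xx <- pairwiseSq(X, X); d2xy <- pairwiseSq(X, Y)
    for (s in bandwidths) {
        Kxx <- exp(-d2xx / (2 * s^2)) / s^2
        Kxy <- exp(-d2xy / (2 * s^2)) / s^2
        # d/dx_a exp(-||x_a-x_j||^2/(2s^2)) = -K/s^2 * (x_a - x_j)
        gXX <- gXX - (rowSums(Kxx) * X - Kxx %*% X) / B
        gXY <- gXY - (rowSums(Kxy) * X - Kxy %*% Y) / B
    }
    2 / n^2 * gXX - 2 / (n * m) * gXY
}

#' Multi-view MMD regularisation loss
#'
#' Aligns the distributions of the branch-wise noise predictions with the
#' injected noise: \eqn{L_{MMD} = \mathrm{MMD}(\hat\epsilon_g, \epsilon) +
#' \mathrm{MMD}(\hat\epsilon_l, \epsilon)}.
#'
#' @param epsHatG,epsHatL,epsTrue batches of length-K vectors (n x K
#'   matrices) with equal batch sizes
#' @param bandwidths see [mmdStatistic()]
#' @return scalar loss
#' @export
mmdLoss <- function(epsHatG, epsHatL, epsTrue, bandwidths = NULL) {
    G <- asSampleMatrix(epsHatG); L <- asSampleMatrix(epsHatL)
    E <- asSampleMatrix(epsTrue)
    if (nrow(G) != nrow(E) || nrow(L) != nrow(E))
        stop("branch batches and noise batch must have equal sizes")
    if (is.null(bandwidths)) bandwidths <- mmdBandwidths(rbind(G, L, E))
    mmdStatistic(G, E, bandwidths) + mmdStatistic(L, E, bandwidths)
}

#' Auxiliary cross-entropy loss
#'
#' Standard cross-entropy of softmaxed logits against an integer label,
#' \eqn{-\log \mathrm{softmax}(z)_{y}}. The auxiliary branch contributes
#' this term only on training steps where the activation period fires.
#'
#' @param logits length-K vector of raw scores
#' @param label 0-based class index
#' @return nonnegative scalar
#' @examples
#' auxLoss(rep(0, 4), 0)  # log(4)
#' @export
auxLoss <- function(logits, label) {
    K <- length(logits)
    if (length(label) != 1L || label < 0 || label >= K ||
        label != floor(label))
        stop("label must be a 0-based class index below K")
    z <- logits - max(logits)
    log(sum(exp(z))) - z[label + 1L]
}

#' Prior reconstruction regulariser
#'
#' Sum over branches of the mean squared error between each denoised prior
#' and its clean counterpart, anchoring the denoised features
#' \eqn{\hat y_g, \hat y_l, \hat y_f} to the prior network outputs.
#'
#' @param denoised list of branch vectors (e.g. yG, yL, yF after denoising)
#' @param clean list of matching clean prior vectors
#' @return nonnegative scalar
#' @export
reconLoss <- function(denoised, clean) {
    if (length(denoised) != length(clean))
        stop("denoised and clean must list the same branches")
    tot <- 0
    for (i in seq_along(denoised)) {
        if (length(denoised[[i]]) != length(clean[[i]]))
            stop("branch shape mismatch in reconstruction loss")
        tot <- tot + mean((denoised[[i]] - clean[[i]])^2)
    }
    tot
}

#' Combine loss components into the training objective
#'
#' \eqn{L_{total} = L_{denoise} + \lambda (L_{MMD} + L_{aux}) + L_{recon}},
#' with \eqn{\lambda = 0.5} by default and \eqn{L_{aux}} counted only on
#' auxiliary-active steps (pass \code{NA} otherwise).
#'
#' @param lDenoise,lMmd scalars
#' @param lAux scalar or NA (inactive step)
#' @param lRecon scalar; 0 when the reconstruction constraint is disabled
#' @param lambda weighting coefficient (>= 0)
#' @return a [LossReport-class]
#' @export
totalLoss <- function(lDenoise, lMmd, lAux = NA_real_, lRecon = 0,
                      lambda = 0.5) {
    parts <- c(lDenoise = lDenoise, lMmd = lMmd, lRecon = lRecon,
               lambda = lambda)
    bad <- names(parts)[!is.finite(parts)]
    if (length(bad))
        stop("non-finite loss component: ", paste(bad, collapse = ", "))
    if (!is.na(lAux) && !is.finite(lAux))
        stop("non-finite loss component: lAux")
    if (lambda < 0) stop("lambda must be >= 0")
    aux <- if (is.na(lAux)) 0 else lAux
    new("LossReport", lDenoise = lDenoise, lMmd = lMmd,
        lAux = as.numeric(lAux), lRecon = lRecon,
        lTotal = lDenoise + lambda * (lMmd + aux) + lRecon,
        lambda = lambda)
}
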