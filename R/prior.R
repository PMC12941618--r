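# Structure-aware prior network: downsampling residual encoder, parallel
# multi-dilation context module (HPCM), sequential increasing-dilation
# refinement (IDCR), response-map ROI localisation, local pathway with
# channel attention, and the three class-score heads.

initRes <- function(cin, cout) {
    blk <- list(c1 = initConv(3L, cin, cout), c2 = initConv(3L, cout, cout))
    if (cin != cout) blk$proj <- initConv(1L, cin, cout)
    blk
}

resApply <- function(x, blk) {
    a <- convForward(x, blk$c1)
    r1 <- reluForward(a$out)
    b <- convForward(r1$out, blk$c2)
    if (!is.null(blk$proj)) {
        pr <- convForward(x, blk$proj)
        skip <- pr$out; pcache <- pr$cache
    } else { skip <- x; pcache <- NULL }
    r2 <- reluForward(b$out + skip)
    list(out = r2$out,
         cache = list(a = a$cache, m1 = r1$cache, b = b$cache,
                      p = pcache, m2 = r2$cache))
}

resBack <- function(gout, blk, cache) {
    g <- reluBackward(gout, cache$m2)
    cb <- convBackward(g, blk$c2, cache$b)
    gr1 <- reluBackward(cb$dx, cache$m1)
    ca <- convBackward(gr1, blk$c1, cache$a)
    dx <- ca$dx
    grads <- list(c1 = list(W = ca$dW, b = ca$db),
                  c2 = list(W = cb$dW, b = cb$db))
    if (!is.null(blk$proj)) {
        cp <- convBackward(g, blk$proj, cache$p)
        dx <- dx + cp$dx
        grads$proj <- list(W = cp$dW, b = cp$db)
    } else dx <- dx + g
    list(dx = dx, grads = grads)
}

initPrior <- function(arch) {
    C <- arch$base_channels
    K <- arch$n_classes
    nb <- 1L + length(arch$hpcm_rates)   # standard branch + dilated branches
    p <- list(
        stem = initConv(3L, 3L, C),
        s1 = initRes(C, C),
        s2 = initRes(C, 2L * C),
        s3 = initRes(2L * C, 4L * C),
        s4 = initRes(4L * C, 4L * C),
        hpcm = c(list(std = initConv(3L, 4L * C, C)),
                 stats::setNames(lapply(arch$hpcm_rates, function(r)
                     initConv(3L, 4L * C, C)),
                     paste0("d", arch$hpcm_rates)),
                 list(proj = initConv(1L, nb * C, 4L * C))),
        idcr = stats::setNames(lapply(arch$idcr_rates, function(r)
                   initConv(3L, 4L * C, 4L * C)),
                   paste0("d", arch$idcr_rates)),
        headG = initLinear(8L * C, K, gain = 1),
        resp = initConv(1L, 8L * C, 1L),
        rho = initLinear(4L * C, arch$latent_dim, gain = 1),
        local = list(stem = initConv(3L, 3L, C),
                     r1 = initRes(C, 2L * C),
                     se = initSE(2L * C, arch$attention_ratio),
                     headL = initLinear(2L * C, K, gain = 1)),
        headF = initLinear(10L * C, K, gain = 1)
    )
    p
}

backboneApply <- function(p, image) {
    st <- convForward(image, p$stem)
    r0 <- reluForward(st$out)
    b1 <- resApply(r0$out, p$s1); p1 <- maxpoolForward(b1$out)
    b2 <- resApply(p1$out, p$s2); p2 <- maxpoolForward(b2$out)
    b3 <- resApply(p2$out, p$s3); p3 <- maxpoolForward(b3$out)
    b4 <- resApply(p3$out, p$s4)
    list(out = b4$out,
         cache = list(st = st$cache, m0 = r0$cache,
                      b1 = b1$cache, p1 = p1$cache, b2 = b2$cache,
                      p2 = p2$cache, b3 = b3$cache, p3 = p3$cache,
                      b4 = b4$cache))
}

backboneBack <- function(gout, p, cache) {
    g4 <- resBack(gout, p$s4, cache$b4)
    g3p <- maxpoolBackward(g4$dx, cache$p3)
    g3 <- resBack(g3p, p$s3, cache$b3)
    g2p <- maxpoolBackward(g3$dx, cache$p2)
    g2 <- resBack(g2p, p$s2, cache$b2)
    g1p <- maxpoolBackward(g2$dx, cache$p1)
    g1 <- resBack(g1p, p$s1, cache$b1)
    g0 <- reluBackward(g1$dx, cache$m0)
    gs <- convBackward(g0, p$stem, cache$st)
    list(dx = gs$dx,
         grads = list(stem = list(W = gs$dW, b = gs$db),
                      s1 = g1$grads, s2 = g2$grads, s3 = g3$grads,
                      s4 = g4$grads))
}

hpcmApply <- function(hp, f, rates) {
    branches <- c(1L, rates)
    nms <- c("std", paste0("d", rates))
    outs <- vector("list", length(nms))
    caches <- vector("list", length(nms))
    masks <- vector("list", length(nms))
    for (i in seq_along(nms)) {
        cf <- convForward(f, hp[[nms[i]]], dilation = branches[i])
        rl <- reluForward(cf$out)
        outs[[i]] <- rl$out; caches[[i]] <- cf$cache; masks[[i]] <- rl$cache
    }
    conc <- array(unlist(outs), c(dim(f)[1], dim(f)[2],
                                  sum(vapply(outs, function(o) dim(o)[3],
                                             integer(1)))))
    pj <- convForward(conc, hp$proj)
    list(out = pj$out,
         cache = list(branch = caches, masks = masks, proj = pj$cache,
                      widths = vapply(outs, function(o) dim(o)[3],
                                      integer(1)),
                      nms = nms, rates = branches))
}

hpcmBack <- function(gout, hp, cache) {
    pj <- convBackward(gout, hp$proj, cache$proj)
    grads <- list(proj = list(W = pj$dW, b = pj$db))
    dx <- 0
    off <- 0L
    for (i in seq_along(cache$nms)) {
        w <- cache$widths[i]
        gbr <- pj$dx[, , off + seq_len(w), drop = FALSE]
        gbr <- reluBackward(gbr, cache$masks[[i]])
        cb <- convBackward(gbr, hp[[cache$nms[i]]], cache$branch[[i]])
        grads[[cache$nms[i]]] <- list(W = cb$dW, b = cb$db)
        dx <- dx + cb$dx
        off <- off + w
    }
    list(dx = dx, grads = grads)
}

idcrApply <- function(id, f, rates) {
    h <- f
    caches <- vector("list", length(rates))
    masks <- vector("list", length(rates) - 1L)
    nms <- paste0("d", rates)
    for (i in seq_along(rates)) {
        cf <- convForward(h, id[[nms[i]]], dilation = rates[i])
        caches[[i]] <- cf$cache
        if (i < length(rates)) {
            rl <- reluForward(cf$out)
            masks[[i]] <- rl$cache
            h <- rl$out
        } else h <- cf$out
    }
    list(out = f + h,
         cache = list(convs = caches, masks = masks, nms = nms,
                      rates = rates))
}

idcrBack <- function(gout, id, cache) {
    grads <- list()
    g <- gout
    n <- length(cache$nms)
    for (i in n:1) {
        cb <- convBackward(g, id[[cache$nms[i]]], cache$convs[[i]])
        grads[[cache$nms[i]]] <- list(W = cb$dW, b = cb$db)
        g <- cb$dx
        if (i > 1L) g <- reluBackward(g, cache$masks[[i - 1L]])
    }
    list(dx = g + gout, grads = grads)  # residual path
}

localApply <- function(lp, crop) {
    st <- convForward(crop, lp$stem)
    r0 <- reluForward(st$out)
    pl1 <- maxpoolForward(r0$out)
    b1 <- resApply(pl1$out, lp$r1)
    pl2 <- maxpoolForward(b1$out)
    se <- seForward(pl2$out, lp$se)
    gp <- gapForward(se$out)
    hd <- linearForward(gp$out, lp$headL)
    list(logits = hd$out, feat = gp$out, gates = se$gates,
         cache = list(st = st$cache, m0 = r0$cache, pl1 = pl1$cache,
                      b1 = b1$cache, pl2 = pl2$cache, se = se$cache,
                      gp = gp$cache, hd = hd$cache))
}

localBack <- function(dLogits, dFeat, lp, cache) {
    hd <- linearBackward(dLogits, lp$headL, cache$hd)
    dgap <- hd$dx + dFeat
    gse <- gapBackward(dgap, cache$gp)
    se <- seBackward(gse, lp$se, cache$se)
    g2p <- maxpoolBackward(se$dx, cache$pl2)
    g1 <- resBack(g2p, lp$r1, cache$b1)
    g1p <- maxpoolBackward(g1$dx, cache$pl1)
    g0 <- reluBackward(g1p, cache$m0)
    gs <- convBackward(g0, lp$stem, cache$st)
    list(grads = list(stem = list(W = gs$dW, b = gs$db), r1 = g1$grads,
                      se = list(W1 = se$dW1, b1 = se$db1, W2 = se$dW2,
                                b2 = se$db2),
                      headL = list(W = hd$dW, b = hd$db)))
}

#' Encode an image with the downsampling backbone
#'
#' Alternating residual blocks and max-pooling reduce the spatial size by a
#' fixed stride of 8 while widening channels (1x/2x/4x the stem width).
#'
#' @param model a [CGADModel-class]
#' @param image H x W x 3 array, channel-normalised, H and W >= 32
#' @return feature array of dimension H/8 x W/8 x 4*base_channels
#' @export
encodeBackbone <- function(model, image) {
    dm <- dim(image)
    if (length(dm) != 3L || dm[3] != 3L)
        stop("image must be an H x W x 3 array")
    if (dm[1] < 32L || dm[2] < 32L)
        stop("image must be at least 32 x 32")
    backboneApply(model@prior, image)$out
}

#' Hierarchical pyramid context module
#'
#' Parallel branches — one standard 3x3 convolution and dilated 3x3
#' convolutions at the configured rates — are concatenated channel-wise and
#' projected back to the input width. Spatial dimensions are preserved by
#' matched padding.
#'
#' @param model a [CGADModel-class]
#' @param f feature array from [encodeBackbone()]
#' @return feature array with the same H x W
#' @export
hpcmForward <- function(model, f) {
    hpcmApply(model@prior$hpcm, f, model@config@architecture$hpcm_rates)$out
}

#' Intra-scale dilated refinement module
#'
#' Sequential 3x3 dilated convolutions with progressively increasing rates
#' and a residual connection around the stack; spatial resolution is
#' preserved, the effective receptive field grows to
#' \eqn{1 + 2\sum_i r_i} for 3x3 kernels.
#'
#' @inheritParams hpcmForward
#' @return feature array with the same H x W
#' @export
idcrForward <- function(model, f) {
    idcrApply(model@prior$idcr, f, model@config@architecture$idcr_rates)$out
}

#' Fuse context features into the global prior
#'
#' Concatenates the two context-module outputs channel-wise, global-average
#' pools and projects to K class scores; also emits the single-channel
#' spatial response map used for ROI localisation.
#'
#' @param model a [CGADModel-class]
#' @param fHpcm,fIdcr spatially aligned feature arrays
#' @return list with \code{logitsG} (length K) and \code{responseMap}
#'   (H x W matrix)
#' @export
fuseGlobalPrior <- function(model, fHpcm, fIdcr) {
    if (!all(dim(fHpcm)[1:2] == dim(fIdcr)[1:2]))
        stop("feature maps must be spatially aligned")
    p <- model@prior
    fused <- array(c(fHpcm, fIdcr),
                   c(dim(fHpcm)[1], dim(fHpcm)[2],
                     dim(fHpcm)[3] + dim(fIdcr)[3]))
    gp <- gapForward(fused)
    hd <- linearForward(gp$out, p$headG)
    rp <- convForward(fused, p$resp)
    list(logitsG = hd$out, responseMap = rp$out[, , 1L])
}

#' Locate the region of interest from a response map
#'
#' Upsamples the response map bilinearly to image resolution and returns
#' the crop-size window maximising the summed response (exhaustive over all
#' positions via a summed-area table). Ties are broken by the smallest row,
#' then column. Coordinates are 0-based, half-open.
#'
#' @param responseMap single-channel matrix
#' @param cropSize integer vector (h, w) of the crop in image pixels
#' @param imageSize integer vector (H, W) of the image
#' @return integer vector (row_start, row_end, col_start, col_end)
#' @export
locateRoi <- function(responseMap, cropSize, imageSize) {
    h <- cropSize[1]; w <- cropSize[2]
    H <- imageSize[1]; W <- imageSize[2]
    if (h > H || w > W) stop("crop larger than image")
    up <- bilinearUpsample(responseMap, H, W)
    sums <- windowSums(up, h, w)
    best <- max(sums)
    tol <- 1e-9 * max(1, abs(best))
    cand <- which(sums >= best - tol, arr.ind = TRUE)
    cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
    r0 <- cand[1L, 1L] - 1L; c0 <- cand[1L, 2L] - 1L
    as.integer(c(r0, r0 + h, c0, c0 + w))
}

#' Local prior pathway on an ROI crop
#'
#' Residual feature extraction with pooling, squeeze-and-excitation channel
#' attention (gates in (0,1)) and a fully connected projection to K class
#' scores.
#'
#' @param model a [CGADModel-class]
#' @param crop crop-size x crop-size x 3 image crop
#' @return list with \code{logitsL} (length K) and \code{gates} (channel
#'   attention values)
#' @export
localPathway <- function(model, crop) {
    cs <- as.integer(model@config@training$image_size *
                     model@config@architecture$crop_fraction)
    if (!all(dim(crop)[1:2] == c(cs, cs)))
        stop("crop has wrong size; expected ", cs, " x ", cs)
    la <- localApply(model@prior$local, crop)
    list(logitsL = la$logits, gates = la$gates)
}

# Full prior pass with caches retained for backpropagation.
priorForwardFull <- function(model, image) {
    p <- model@prior
    arch <- model@config@architecture
    tr <- model@config@training
    bb <- backboneApply(p, image)
    f4 <- bb$out
    if (tr$use_hpcm) {
        hp <- hpcmApply(p$hpcm, f4, arch$hpcm_rates)
        fH <- hp$out
    } else { hp <- NULL; fH <- f4 }
    if (tr$use_idcr) {
        idc <- idcrApply(p$idcr, f4, arch$idcr_rates)
        fI <- idc$out
    } else { idc <- NULL; fI <- f4 }
    dmf <- c(dim(fH)[1], dim(fH)[2], dim(fH)[3] + dim(fI)[3])
    fused <- array(c(fH, fI), dmf)
    gpG <- gapForward(fused)
    hdG <- linearForward(gpG$out, p$headG)
    rp <- convForward(fused, p$resp)
    gpB <- gapForward(f4)
    hdR <- linearForward(gpB$out, p$rho)
    cs <- as.integer(tr$image_size * arch$crop_fraction)
    box <- locateRoi(rp$out[, , 1L], c(cs, cs), dim(image)[1:2])
    crop <- image[(box[1] + 1L):box[2], (box[3] + 1L):box[4], , drop = FALSE]
    la <- localApply(p$local, crop)
    sConcat <- c(gpG$out, la$feat)
    hdF <- linearForward(sConcat, p$headF)
    list(logitsG = hdG$out, logitsL = la$logits, logitsF = hdF$out,
         rhoX = hdR$out, roiBox = box, gates = la$gates,
        cache = list(bb = bb$cache, hp = hp, idc = idc,
                     gpG = gpG$cache, hdG = hdG$cache, gpB = gpB$cache,
                     hdR = hdR$cache, la = la, hdF = hdF$cache,
                     sConcat = sConcat, dmf = dmf, nH = dim(fH)[3]))
}

# Backpropagate head gradients through the prior network; returns parameter
# gradients in the shape of model@prior. The response head and the
# (non-differentiable) ROI selection receive no gradient.
priorBackwardFull <- function(model, fw, dLogitsG, dLogitsL, dLogitsF,
                              dRho) {
    p <- model@prior
    arch <- model@config@architecture
    tr <- model@config@training
    ca <- fw$cache
    grads <- zerosLike(p)
    lf <- linearBackward(dLogitsF, p$headF, ca$hdF)
    grads$headF <- list(W = lf$dW, b = lf$db)
    nFeatG <- ca$dmf[3]
    dsGlobal <- lf$dx[seq_len(nFeatG)]
    dsLocalF <- lf$dx[-seq_len(nFeatG)]
    lg <- linearBackward(dLogitsG, p$headG, ca$hdG)
    grads$headG <- list(W = lg$dW, b = lg$db)
    dsGlobal <- dsGlobal + lg$dx
    lb <- localBack(dLogitsL, dsLocalF, p$local, ca$la$cache)
    grads$local <- lb$grads
    dFused <- gapBackward(dsGlobal, ca$gpG)
    nH <- ca$nH
    dH <- dFused[, , seq_len(nH), drop = FALSE]
    dI <- dFused[, , nH + seq_len(ca$dmf[3] - nH), drop = FALSE]
    if (tr$use_hpcm) {
        hb <- hpcmBack(dH, p$hpcm, ca$hp$cache)
        grads$hpcm <- hb$grads
        df4 <- hb$dx
    } else df4 <- dH
    if (tr$use_idcr) {
        ib <- idcrBack(dI, p$idcr, ca$idc$cache)
        grads$idcr <- ib$grads
        df4 <- df4 + ib$dx
    } else df4 <- df4 + dI
    lr <- linearBackward(dRho, p$rho, ca$hdR)
    grads$rho <- list(W = lr$dW, b = lr$db)
    df4 <- df4 + gapBackward(lr$dx, ca$gpB)
    bb <- backboneBack(df4, p, ca$bb)
    grads$stem <- bb$grads$stem
    grads$s1 <- bb$grads$s1; grads$s2 <- bb$grads$s2
    grads$s3 <- bb$grads$s3; grads$s4 <- bb$grads$s4
    grads
}

#' Compute the multi-level semantic priors for one image
#'
#' Composes backbone encoding, the two context modules, global fusion, ROI
#' localisation and the local pathway into a [PriorBundle-class]. The
#' class-score vectors \code{yG}, \code{yL}, \code{yF} are the softmax of
#' the corresponding head logits; \code{rhoX} is the conditioning latent.
#' Deterministic for fixed parameters and input.
#'
#' @param model a [CGADModel-class]
#' @param image image_size x image_size x 3 normalised array
#' @return a [PriorBundle-class]
#' @export
priorForward <- function(model, image) {
    fw <- priorForwardFull(model, image)
    new("PriorBundle",
        yG = softmax(fw$logitsG), yL = softmax(fw$logitsL),
        yF = softmax(fw$logitsF),
        logitsG = fw$logitsG, logitsL = fw$logitsL, logitsF = fw$logitsF,
        rhoX = fw$rhoX, roiBox = fw$roiBox)
}
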