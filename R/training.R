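# Unified training loop: per iteration the prior network produces the three
# class-score priors, confidence is read (detached) from the classification
# head, confidence-guided noise is injected into each branch and into the
# one-hot target, the shared denoiser predicts the injected noise per path,
# and the composite objective (denoising regression + multi-view MMD +
# periodic auxiliary CE + reconstruction) is optimised with Adam under
# cosine-annealed learning rate.

# Forward + backward over one batch. Returns parameter gradients for the
# prior network and the denoiser, the logged LossReport, the mean injected
# noise norm, and the gradient routed into the confidence scalar (zero by
# the detachment contract; the discarded contribution is reported
# separately for diagnostics).
batchGradients <- function(model, samples, auxActive) {
    cfg <- model@config
    arch <- cfg@architecture; tr <- cfg@training
    sch <- model@schedule
    K <- arch$n_classes
    B <- length(samples)
    lambda <- tr$lambda
    gP <- zerosLike(model@prior)
    gD <- zerosLike(model@denoiser)
    per <- vector("list", B)
    noiseNorm <- 0
    yTsum <- numeric(K)
    # ---- forward ----
    for (i in seq_len(B)) {
        s <- samples[[i]]
        fw <- priorForwardFull(model, s$image)
        pG <- softmax(fw$logitsG); pL <- softmax(fw$logitsL)
        pF <- softmax(fw$logitsF)
        cDet <- max(pF)                      # detached confidence
        cEff <- if (tr$use_cgani) cDet else 0
        t_i <- sample.int(sch@steps, 1L)
        eps <- stats::rnorm(K)
        branch <- list()
        for (b in c("G", "L", "F")) {
            pb <- switch(b, G = pG, L = pL, F = pF)
            ybt <- forwardDiffuse(pb, t_i, cEff, eps, pb, sch)
            dn <- denoiserApply(model@denoiser, ybt, t_i, fw$rhoX, pb, arch)
            yhat <- estimateClean(ybt, t_i, cEff, dn$out, pb, sch)
            branch[[b]] <- list(p = pb, ybt = ybt, epsHat = dn$out,
                                cache = dn$cache, yHat = yhat)
        }
        G <- if (cfg@diffusion$guidance_mode == "prior_sum")
            branch$G$yHat + branch$L$yHat else model@yBarEma
        y0 <- oneHot(s$label, K)
        yt <- forwardDiffuse(y0, t_i, cEff, eps, G, sch)
        dnM <- denoiserApply(model@denoiser, yt, t_i, fw$rhoX, G, arch)
        ab <- sch@alphaBar[t_i]
        noiseNorm <- noiseNorm +
            sqrt(sum((sqrt(1 - ab) * (1 - cEff) * eps)^2)) / B
        yTsum <- yTsum + forwardDiffuse(y0, sch@steps, cEff, eps, G, sch) / B
        per[[i]] <- list(fw = fw, pG = pG, pL = pL, pF = pF, c = cEff,
                         t = t_i, eps = eps, branch = branch, G = G,
                         yt = yt, epsHat = dnM$out, cacheM = dnM$cache,
                         y0 = y0, label = s$label)
    }
    # ---- batch losses ----
    Eg <- t(vapply(per, function(x) x$branch$G$epsHat, numeric(K)))
    El <- t(vapply(per, function(x) x$branch$L$epsHat, numeric(K)))
    Ee <- t(vapply(per, function(x) x$eps, numeric(K)))
    bw <- mmdBandwidths(rbind(Eg, El, Ee))
    lMmd <- mmdStatistic(Eg, Ee, bw) + mmdStatistic(El, Ee, bw)
    lDen <- mean(vapply(per, function(x) sum((x$eps - x$epsHat)^2),
                        numeric(1)))
    lRec <- if (tr$recon_enabled)
        mean(vapply(per, function(x)
            mean((x$branch$G$yHat - x$pG)^2) +
            mean((x$branch$L$yHat - x$pL)^2) +
            mean((x$branch$F$yHat - x$pF)^2), numeric(1)))
        else 0
    lAux <- if (auxActive)
        mean(vapply(per, function(x)
            auxLoss(x$fw$logitsF, x$label) +
            auxLoss(x$fw$logitsG, x$label) +
            auxLoss(x$fw$logitsL, x$label), numeric(1)))
        else NA_real_
    report <- totalLoss(lDen, lMmd, lAux, lRec, lambda)
    if (!is.finite(report@lTotal))
        stop("non-finite training loss (denoise=", lDen, ", mmd=", lMmd,
             ", aux=", lAux, ", recon=", lRec, ")")
    dMmdG <- lambda * mmdGradX(Eg, Ee, bw)
    dMmdL <- lambda * mmdGradX(El, Ee, bw)
    # ---- backward ----
    cGradDiscarded <- 0
    for (i in seq_len(B)) {
        x <- per[[i]]
        ab <- sch@alphaBar[x$t]
        sa <- sqrt(ab); s1 <- sqrt(1 - ab); u <- 1 - x$c
        # main path: denoising regression
        dEpsM <- -2 * (x$eps - x$epsHat) / B
        bkM <- denoiserBack(dEpsM, model@denoiser, x$cacheM, arch)
        gD <- addParams(gD, bkM$grads)
        dYt <- bkM$dYt
        dG <- bkM$dGuidance + (1 - ab) * dYt
        dRho <- bkM$dRho
        # what detachment discards: d yt/d c = -s1*eps
        cGradDiscarded <- cGradDiscarded + sum(dYt * (-s1 * x$eps))
        dYhat <- list(G = numeric(K), L = numeric(K), F = numeric(K))
        if (cfg@diffusion$guidance_mode == "prior_sum") {
            dYhat$G <- dYhat$G + dG
            dYhat$L <- dYhat$L + dG
        }
        dLogits <- list(G = numeric(K), L = numeric(K), F = numeric(K))
        if (tr$recon_enabled) {
            for (b in c("G", "L", "F"))
                dYhat[[b]] <- dYhat[[b]] +
                    2 * (x$branch[[b]]$yHat - x$branch[[b]]$p) / (K * B)
        }
        for (b in c("G", "L", "F")) {
            br <- x$branch[[b]]
            dPb <- numeric(K)
            if (tr$recon_enabled)
                dPb <- dPb - 2 * (br$yHat - br$p) / (K * B)
            dEpsHatB <- -u * s1 / sa * dYhat[[b]]
            if (b == "G") dEpsHatB <- dEpsHatB + dMmdG[i, ]
            if (b == "L") dEpsHatB <- dEpsHatB + dMmdL[i, ]
            dYbt <- dYhat[[b]] / sa
            dPb <- dPb - (1 - ab) / sa * dYhat[[b]]
            cGradDiscarded <- cGradDiscarded +
                sum(dYhat[[b]] * (s1 / sa) * br$epsHat)
            if (any(dEpsHatB != 0)) {
                bkB <- denoiserBack(dEpsHatB, model@denoiser, br$cache, arch)
                gD <- addParams(gD, bkB$grads)
                dYbt <- dYbt + bkB$dYt
                dPb <- dPb + bkB$dGuidance
                dRho <- dRho + bkB$dRho
            }
            cGradDiscarded <- cGradDiscarded + sum(dYbt * (-s1 * x$eps))
            dPb <- dPb + (sa + 1 - ab) * dYbt
            dLogits[[b]] <- dLogits[[b]] +
                softmaxBackward(br$p, dPb)
        }
        if (auxActive) {
            dLogits$F <- dLogits$F + lambda * (x$pF - x$y0) / B
            dLogits$G <- dLogits$G + lambda * (x$pG - x$y0) / B
            dLogits$L <- dLogits$L + lambda * (x$pL - x$y0) / B
        }
        gPi <- priorBackwardFull(model, x$fw, dLogits$G, dLogits$L,
                                 dLogits$F, dRho)
        gP <- addParams(gP, gPi)
    }
    list(gradsPrior = gP, gradsDenoiser = gD, report = report,
         noiseNorm = noiseNorm, yTmean = yTsum,
         gradC = 0, gradCDiscarded = cGradDiscarded)
}

cosineLr <- function(lr0, epoch, epochs) {
    lr0 * 0.5 * (1 + cos(pi * (epoch - 1) / max(1, epochs)))
}

#' Train a CGAD model
#'
#' Runs the unified loop: per iteration the prior network is evaluated, the
#' confidence read from the classification head (detached), confidence-
#' guided noise injected per branch and into the one-hot target, the shared
#' denoiser applied, and the composite objective optimised with Adam under
#' cosine learning-rate annealing. Augmentation (rotations within +/-30
#' degrees, horizontal/vertical flips) is redrawn each epoch. Deterministic
#' given the configuration seed.
#'
#' @param config a [CGADConfig-class]
#' @param manifest dataset handle: path to a manifest CSV as written by
#'   [generateLesionDataset()] (or a data.frame with a \code{dir} attribute)
#' @param evalEvery evaluate the held-out split every this many epochs for
#'   the per-epoch accuracy curve (0 = only at the end)
#' @param verbose print per-epoch progress
#' @return list with \code{model} (trained [CGADModel-class]),
#'   \code{metrics} (final test [MetricsReport-class]), and \code{logs}
#'   (list of \code{steps} and \code{epochs} data.frames)
#' @export
trainCGAD <- function(config, manifest, evalEvery = 1L, verbose = FALSE) {
    tr <- config@training
    model <- newCGADModel(config)
    test <- loadDataset(manifest, "test", tr$image_size, augment = FALSE,
                        seed = deriveSeed(tr$seed, 5L))
    labs0 <- vapply(loadDataset(manifest, "train", tr$image_size,
                                augment = FALSE,
                                seed = deriveSeed(tr$seed, 6L)),
                    function(s) s$label, numeric(1))
    if (length(unique(labs0)) < 2L)
        stop("training split must contain at least 2 classes")
    adamP <- adamInit(model@prior)
    adamD <- adamInit(model@denoiser)
    stepRows <- list(); epochRows <- list()
    decay <- config@diffusion$ybar_decay
    withSeed(deriveSeed(tr$seed, 3L), {
        for (epoch in seq_len(tr$epochs)) {
            data <- loadDataset(manifest, "train", tr$image_size,
                                augment = TRUE,
                                seed = deriveSeed(tr$seed, 2000 + epoch))
            idx <- sample(length(data))
            auxActive <- epoch <= tr$aux_warmup ||
                ((epoch - 1L) %% tr$aux_period) == 0L
            lr <- cosineLr(tr$learning_rate, epoch, tr$epochs)
            nb <- ceiling(length(idx) / tr$batch_size)
            for (bi in seq_len(nb)) {
                take <- idx[((bi - 1L) * tr$batch_size + 1L):
                            min(bi * tr$batch_size, length(idx))]
                bg <- batchGradients(model, data[take], auxActive)
                st <- adamStep(model@prior, bg$gradsPrior, adamP, lr)
                model@prior <- st$params; adamP <- st$state
                st <- adamStep(model@denoiser, bg$gradsDenoiser, adamD, lr)
                model@denoiser <- st$params; adamD <- st$state
                model@yBarEma <- decay * model@yBarEma +
                    (1 - decay) * bg$yTmean
                r <- bg$report
                stepRows[[length(stepRows) + 1L]] <- data.frame(
                    epoch = epoch, step = bi, lr = lr,
                    l_denoise = r@lDenoise, l_mmd = r@lMmd,
                    l_aux = r@lAux, l_recon = r@lRecon,
                    l_total = r@lTotal, noise_norm = bg$noiseNorm)
            }
            acc <- NA_real_
            if (evalEvery > 0L && (epoch %% evalEvery == 0L ||
                                   epoch == tr$epochs)) {
                mr <- evaluateCGAD(model, test,
                                   seed = deriveSeed(tr$seed, 4L))
                acc <- mr@accuracy
            }
            epochRows[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                aux_active = auxActive, test_accuracy = acc)
            if (verbose)
                message(sprintf("epoch %d: total %.4f%s", epoch,
                    stepRows[[length(stepRows)]]$l_total,
                    ifelse(is.na(acc), "", sprintf(", test acc %.3f", acc))))
        }
    })
    metrics <- evaluateCGAD(model, test, seed = deriveSeed(tr$seed, 4L))
    metrics@curves <- do.call(rbind, epochRows)
    list(model = model,
         metrics = metrics,
         logs = list(steps = do.call(rbind, stepRows),
                     epochs = do.call(rbind, epochRows)))
}

#' Evaluate a model by reverse diffusion sampling
#'
#' For each image: the prior network supplies the guidance (sum of the
#' clean global and local prior score vectors) and the classification
#' head's softmax output (confidence and chain initialisation); the full
#' reverse sampler recovers the clean class-score vector, and its argmax is
#' the prediction. With the confidence-guided mechanism disabled
#' (\code{use_cgani = FALSE}) the fixed-schedule baseline sampler is used.
#' Averages \code{n_samples} sampling runs when configured.
#'
#' @param model a trained [CGADModel-class]
#' @param dataset list of samples from [loadDataset()] (deterministic
#'   pipeline: no augmentation)
#' @param seed integer seed for the sampling noise
#' @return a [MetricsReport-class]
#' @export
evaluateCGAD <- function(model, dataset, seed = 1L) {
    if (length(dataset) == 0L) stop("dataset must be nonempty")
    cfg <- model@config
    K <- cfg@architecture$n_classes
    useC <- cfg@training$use_cgani
    nS <- max(1L, cfg@training$n_samples)
    den <- function(yt, t, rho, g)
        denoiserApply(model@denoiser, yt, t, rho, g, cfg@architecture)$out
    true <- integer(length(dataset)); pred <- integer(length(dataset))
    for (i in seq_along(dataset)) {
        s <- dataset[[i]]
        fw <- priorForwardFull(model, s$image)
        pF <- softmax(fw$logitsF)
        G <- if (cfg@diffusion$guidance_mode == "prior_sum")
            softmax(fw$logitsG) + softmax(fw$logitsL) else model@yBarEma
        acc <- numeric(K)
        for (r in seq_len(nS)) {
            # fixed-schedule baseline: confidence forced to 0 so the (1-c)
            # factor is 1, as in standard DDPM
            rs <- reverseSample(fw$rhoX, G, den, pF, model@schedule,
                                seed = deriveSeed(seed, i * 131L + r),
                                confidence = if (useC) NULL else 0)
            acc <- acc + rs$y0Hat / nS
        }
        true[i] <- s$label
        pred[i] <- which.max(acc) - 1L
    }
    metricsReport(confusionFromLabels(true, pred, K))
}

#' Windowed loss-difference diagnostic with bootstrap confidence bands
#'
#' Computes the per-step difference between two training-loss series
#' (ours - baseline), averages it over consecutive windows and attaches a
#' percentile bootstrap confidence interval per window (resampling steps
#' within the window). Used to check that confidence-guided noise
#' injection does not systematically lower the noise-estimation loss.
#'
#' @param seriesOurs,seriesBaseline equal-length numeric per-step losses
#' @param level confidence level (default 0.95)
#' @param nBoot bootstrap replicates (>= 100)
#' @param seed integer seed
#' @param window window length in steps (default: one window per 10% of
#'   the series, at least 10 steps)
#' @return data.frame with columns window, step_mid, mean, lo, hi
#' @export
lossDeltaDiagnostic <- function(seriesOurs, seriesBaseline, level = 0.95,
                                nBoot = 1000L, seed = 1L, window = NULL) {
    if (length(seriesOurs) != length(seriesBaseline))
        stop("series must have equal length")
    if (nBoot < 100L) stop("nBoot must be >= 100")
    delta <- seriesOurs - seriesBaseline
    n <- length(delta)
    if (is.null(window)) window <- max(10L, n %/% 10L)
    window <- min(window, n)
    starts <- seq(1L, n, by = window)
    alpha <- (1 - level) / 2
    withSeed(seed, {
        rows <- lapply(seq_along(starts), function(wi) {
            lo <- starts[wi]; hi <- min(lo + window - 1L, n)
            d <- delta[lo:hi]; m <- length(d)
            boots <- vapply(seq_len(nBoot), function(b)
                mean(d[sample.int(m, m, replace = TRUE)]), numeric(1))
            qs <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE)
            data.frame(window = wi, step_mid = (lo + hi) / 2,
                       mean = mean(d), lo = qs[1], hi = qs[2])
        })
        do.call(rbind, rows)
    })
}

#' Component-wise ablation harness
#'
#' Trains and evaluates the four standard cells — B0 (fixed noise
#' schedule), B1 (confidence-guided noise only), B2 (B1 + pyramid context
#' module), full (B2 + intra-scale refinement) — across seeds, and reports
#' mean +/- sd of accuracy, macro-F1 and kappa per cell, the per-epoch
#' accuracy curves, the across-seed early-epoch accuracy variance for B0
#' vs B1 (training-stability comparison), and the windowed bootstrap
#' loss-difference band for B1 - B0.
#'
#' @param config base [CGADConfig-class]; flags are overridden per cell
#' @param manifest dataset handle (see [trainCGAD()])
#' @param seeds integer vector of seeds (>= 1 seed)
#' @param earlyEpochs number of initial epochs entering the stability
#'   comparison (default 10, capped at the configured epochs)
#' @param evalEvery passed to [trainCGAD()]
#' @return list with \code{table} (one row per cell), \code{curves},
#'   \code{earlyVariance} (named vector, B0 and B1), \code{lossDelta}
#'   (data.frame from [lossDeltaDiagnostic()]) and \code{runs} (per-run
#'   metrics)
#' @export
ablationRun <- function(config, manifest, seeds, earlyEpochs = 10L,
                        evalEvery = 1L) {
    if (length(seeds) < 1L) stop("at least one seed is required")
    cells <- list(
        B0 = c(use_cgani = FALSE, use_hpcm = FALSE, use_idcr = FALSE),
        B1 = c(use_cgani = TRUE, use_hpcm = FALSE, use_idcr = FALSE),
        B2 = c(use_cgani = TRUE, use_hpcm = TRUE, use_idcr = FALSE),
        full = c(use_cgani = TRUE, use_hpcm = TRUE, use_idcr = TRUE))
    runs <- list(); curves <- list(); denoiseSeries <- list()
    for (cell in names(cells)) {
        for (sd in seeds) {
            cfg <- config
            cfg@training[c("use_cgani", "use_hpcm", "use_idcr")] <-
                as.list(unname(cells[[cell]]))
            cfg@training$seed <- as.integer(sd)
            fit <- trainCGAD(cfg, manifest, evalEvery = evalEvery)
            runs[[paste(cell, sd, sep = "_")]] <- data.frame(
                cell = cell, seed = sd,
                accuracy = fit$metrics@accuracy,
                macro_f1 = fit$metrics@macroF1,
                kappa = fit$metrics@kappa)
            cv <- fit$logs$epochs
            cv$cell <- cell; cv$seed <- sd
            curves[[paste(cell, sd, sep = "_")]] <- cv
            denoiseSeries[[paste(cell, sd, sep = "_")]] <-
                fit$logs$steps$l_denoise
        }
    }
    runsDf <- do.call(rbind, runs)
    tab <- do.call(rbind, lapply(names(cells), function(cell) {
        r <- runsDf[runsDf$cell == cell, ]
        data.frame(cell = cell,
                   accuracy = mean(r$accuracy), accuracy_sd = stats::sd(r$accuracy),
                   macro_f1 = mean(r$macro_f1), macro_f1_sd = stats::sd(r$macro_f1),
                   kappa = mean(r$kappa), kappa_sd = stats::sd(r$kappa))
    }))
    curvesDf <- do.call(rbind, curves)
    ne <- min(earlyEpochs, config@training$epochs)
    earlyVar <- vapply(c("B0", "B1"), function(cell) {
        cc <- curvesDf[curvesDf$cell == cell & curvesDf$epoch <= ne &
                       !is.na(curvesDf$test_accuracy), ]
        if (nrow(cc) == 0L) return(NA_real_)
        byEpoch <- tapply(cc$test_accuracy, cc$epoch, stats::var)
        mean(byEpoch, na.rm = TRUE)
    }, numeric(1))
    # loss-difference band: mean denoise-loss series across seeds, B1 - B0
    meanSeries <- function(cell) {
        ss <- denoiseSeries[grep(paste0("^", cell, "_"),
                                 names(denoiseSeries))]
        n <- min(lengths(ss))
        rowMeans(vapply(ss, function(x) x[seq_len(n)],
                        numeric(min(lengths(ss)))))
    }
    s1 <- meanSeries("B1"); s0 <- meanSeries("B0")
    n <- min(length(s1), length(s0))
    ld <- lossDeltaDiagnostic(s1[seq_len(n)], s0[seq_len(n)],
                              seed = deriveSeed(seeds[1], 7L))
    list(table = tab, curves = curvesDf, earlyVariance = earlyVar,
         lossDelta = ld, runs = runsDf)
}
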