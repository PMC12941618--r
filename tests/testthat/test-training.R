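# Training-loop contracts on deliberately tiny configurations: short
# schedules, 32-px images and narrow networks keep each run to seconds.

trainFixture <- function() {
    fixtureDataset("train", nPerClass = 6, K = 2, imageSize = 32,
                   ambiguity = 0, seed = 55)
}

fastConfig <- function(...) {
    args <- utils::modifyList(
        list(n_classes = 2, base_channels = 4, latent_dim = 8,
             denoiser_width = 16, denoiser_depth = 2, time_embed_dim = 8,
             T = 10, image_size = 32, batch_size = 4, epochs = 2,
             seed = 3, aux_period = 2),
        list(...))
    do.call(cgadConfig, args)
}

test_that("training is deterministic given the seed", {
    mp <- trainFixture()
    f1 <- trainCGAD(fastConfig(), mp, evalEvery = 0)
    f2 <- trainCGAD(fastConfig(), mp, evalEvery = 0)
    expect_equal(f1$logs$steps$l_total, f2$logs$steps$l_total,
                 tolerance = 1e-12)
    expect_identical(f1$metrics@confusion, f2$metrics@confusion)
    # a different seed gives a different trajectory
    f3 <- trainCGAD(fastConfig(seed = 4), mp, evalEvery = 0)
    expect_false(isTRUE(all.equal(f1$logs$steps$l_total,
                                  f3$logs$steps$l_total)))
})

test_that("every logged step satisfies the loss decomposition identity", {
    mp <- trainFixture()
    fit <- trainCGAD(fastConfig(lambda = 0.5), mp, evalEvery = 0)
    st <- fit$logs$steps
    aux <- ifelse(is.na(st$l_aux), 0, st$l_aux)
    expect_equal(st$l_total,
                 st$l_denoise + 0.5 * (st$l_mmd + aux) + st$l_recon,
                 tolerance = 1e-10)
    expect_true(all(is.finite(st$l_total)))
})

test_that("the auxiliary branch fires on its configured period", {
    mp <- trainFixture()
    fit <- trainCGAD(fastConfig(epochs = 5, aux_period = 2,
                                aux_warmup = 0), mp, evalEvery = 0)
    ep <- fit$logs$epochs
    expect_equal(ep$aux_active, c(TRUE, FALSE, TRUE, FALSE, TRUE))
    st <- fit$logs$steps
    expect_true(all(is.na(st$l_aux[st$epoch == 2])))
    expect_true(all(!is.na(st$l_aux[st$epoch == 1])))
    # warmup keeps the branch on for the first epochs, then periodic
    fit2 <- trainCGAD(fastConfig(epochs = 6, aux_period = 3,
                                 aux_warmup = 2), mp, evalEvery = 0)
    expect_equal(fit2$logs$epochs$aux_active,
                 c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE))
})

test_that("confidence-guided injection attenuates noise for confident samples", {
    mp <- trainFixture()
    data <- loadDataset(mp, "train", 32, augment = FALSE, seed = 1)
    mkModel <- function(useCgani) {
        cfg <- fastConfig(use_cgani = useCgani)
        m <- newCGADModel(cfg)
        # force a confident classification head
        m@prior$headF$b <- c(12, -12)
        m
    }
    set.seed(77)
    bOn <- cgad:::batchGradients(mkModel(TRUE), data[1:4], FALSE)
    set.seed(77)
    bOff <- cgad:::batchGradients(mkModel(FALSE), data[1:4], FALSE)
    # same draws: adaptive injection must shrink the injected noise norm
    expect_lt(bOn$noiseNorm, 0.05 * bOff$noiseNorm)
    expect_gt(bOff$noiseNorm, 0)
})

test_that("no gradient reaches the confidence input (detachment)", {
    mp <- trainFixture()
    data <- loadDataset(mp, "train", 32, augment = FALSE, seed = 1)
    m <- newCGADModel(fastConfig())
    set.seed(5)
    bg <- cgad:::batchGradients(m, data[1:4], TRUE)
    expect_identical(bg$gradC, 0)
    # the dependence existed and was deliberately discarded
    expect_gt(abs(bg$gradCDiscarded), 0)
})

test_that("degenerate datasets and non-finite losses abort with diagnostics", {
    dir <- file.path(tempdir(), "cgad_oneclass")
    unlink(dir, recursive = TRUE)
    sp <- synthSpec(nPerClass = 6, K = 2, imageSize = 32, seed = 9)
    mf <- generateLesionDataset(sp, dir)
    mf$label <- 0L  # collapse to a single class
    write.csv(mf, file.path(dir, "manifest.csv"), row.names = FALSE)
    expect_error(trainCGAD(fastConfig(), file.path(dir, "manifest.csv")),
                 "2 classes")
    expect_error(evaluateCGAD(newCGADModel(fastConfig()), list()),
                 "nonempty")
})

test_that("loss-difference diagnostic handles degenerate and offset series", {
    x <- rep(1.5, 120)
    d0 <- lossDeltaDiagnostic(x, x, nBoot = 200, seed = 1, window = 40)
    expect_equal(d0$mean, rep(0, 3))
    expect_equal(d0$lo, rep(0, 3)); expect_equal(d0$hi, rep(0, 3))
    d1 <- lossDeltaDiagnostic(x + 0.1, x, nBoot = 200, seed = 1,
                              window = 40)
    expect_equal(d1$mean, rep(0.1, 3), tolerance = 1e-12)
    expect_error(lossDeltaDiagnostic(x, x[-1]), "equal length")
    expect_error(lossDeltaDiagnostic(x, x, nBoot = 10), "100")
})

test_that("bootstrap intervals cover the true mean at their nominal level", {
    # i.i.d. normal deltas: the 95% percentile interval on the windowed
    # mean should cover zero about 95% of the time
    cover <- cgad:::withSeed(31, {
        mean(vapply(1:150, function(r) {
            d <- rnorm(300, 0, 1)
            ci <- lossDeltaDiagnostic(d, rep(0, 300), nBoot = 200,
                                      seed = 1000 + r, window = 300)
            ci$lo[1] <= 0 && 0 <= ci$hi[1]
        }, logical(1)))
    })
    expect_gt(cover, 0.88)
    expect_lte(cover, 1)
})

test_that("the ablation harness populates its grid and reports", {
    mp <- trainFixture()
    res <- ablationRun(fastConfig(epochs = 2), mp, seeds = c(3, 4),
                       earlyEpochs = 2, evalEvery = 1)
    expect_equal(nrow(res$runs), 8L)     # 4 cells x 2 seeds
    expect_equal(nrow(res$table), 4L)
    expect_equal(res$table$cell, c("B0", "B1", "B2", "full"))
    expect_true(all(c("B0", "B1") %in% names(res$earlyVariance)))
    expect_true(all(is.finite(res$lossDelta$mean)))
    expect_true(all(res$lossDelta$lo <= res$lossDelta$hi))
    # every run contributed an accuracy curve
    expect_setequal(unique(res$curves$cell), c("B0", "B1", "B2", "full"))
})
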