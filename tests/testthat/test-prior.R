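test_that("backbone downsamples by stride 8 and handles degenerate input", {
    m <- tinyModel()
    f <- encodeBackbone(m, randomImage(64, seed = 2))
    expect_equal(dim(f), c(8L, 8L, 16L))  # 4 * base_channels
    # zero image with zero-initialised biases gives a zero feature map
    z <- encodeBackbone(m, array(0, c(32, 32, 3)))
    expect_true(all(z == 0))
    expect_error(encodeBackbone(m, array(0, c(16, 16, 3))), "32")
    expect_error(encodeBackbone(m, array(0, c(32, 32, 1))), "H x W x 3")
})

test_that("doubling input contrast doubles the first linear stage", {
    m <- tinyModel()
    img <- randomImage(32, seed = 3)
    pre1 <- cgad:::convForward(img, m@prior$stem)$out
    pre2 <- cgad:::convForward(2 * img, m@prior$stem)$out
    expect_equal(pre2, 2 * pre1, tolerance = 1e-12)
})

test_that("context modules preserve spatial dimensions", {
    m <- tinyModel()
    for (S in c(6L, 8L, 12L)) {
        f <- array(rnorm(S * S * 16), c(S, S, 16))
        expect_equal(dim(hpcmForward(m, f))[1:2], c(S, S))
        expect_equal(dim(idcrForward(m, f))[1:2], c(S, S))
    }
    # zero input, zero biases -> zero output
    f0 <- array(0, c(8, 8, 16))
    expect_true(all(hpcmForward(m, f0) == 0))
})

test_that("IDCR is the identity when its stack weights are zero", {
    m <- tinyModel()
    p <- m@prior
    for (nm in names(p$idcr)) { p$idcr[[nm]]$W[] <- 0; p$idcr[[nm]]$b[] <- 0 }
    m@prior <- p
    f <- array(rnorm(8 * 8 * 16), c(8, 8, 16))
    expect_equal(idcrForward(m, f), f)
})

# Gradient-probe receptive field: support of d out[centre]/d input over a
# network with positive weights and positive input (no dead units).
probeRF <- function(applyFn, backFn, S, C) {
    x <- array(1, c(S, S, C))
    fw <- applyFn(x)
    g <- array(0, dim(fw$out))
    ctr <- (S + 1) %/% 2
    g[ctr, ctr, 1] <- 1
    dx <- backFn(g, fw$cache)
    on <- apply(abs(dx) > 1e-12, c(1, 2), any)
    rows <- range(which(rowSums(on) > 0))
    cols <- range(which(colSums(on) > 0))
    c(rows[2] - rows[1] + 1L, cols[2] - cols[1] + 1L)
}

test_that("receptive fields match the dilation closed forms", {
    set.seed(8)
    C <- 2L
    mkpos <- function(l) { l$W <- abs(l$W) + 0.01; l$b[] <- 0.01; l }
    # single 3x3 branch at rate 8: RF = 1 + 2*8*(3-1)/2 * 2 = 17
    conv8 <- mkpos(cgad:::initConv(3L, C, C))
    rf <- probeRF(function(x) cgad:::convForward(x, conv8, 8L),
                  function(g, ca) cgad:::convBackward(g, conv8, ca)$dx,
                  41L, C)
    expect_equal(rf, c(17L, 17L))
    # sequential (1,2,4) stack with residual: RF = 1 + 2*(1+2+4) = 15
    id <- lapply(c(1, 2, 4), function(r) mkpos(cgad:::initConv(3L, C, C)))
    names(id) <- c("d1", "d2", "d4")
    rf <- probeRF(function(x) cgad:::idcrApply(id, x, c(1L, 2L, 4L)),
                  function(g, ca) cgad:::idcrBack(g, id, ca)$dx,
                  31L, C)
    expect_equal(rf, c(15L, 15L))
})

test_that("ROI localisation equals exhaustive window search", {
    set.seed(9)
    for (i in 1:100) {
        mp <- matrix(rnorm(16 * 16), 16, 16)
        box <- locateRoi(mp, c(5, 5), c(16, 16))
        expect_equal(box, roiOracle(mp, 5L, 5L))
    }
    # uniform map: tie-break to the top-left window
    expect_equal(locateRoi(matrix(1, 8, 8), c(3, 4), c(8, 8)),
                 c(0L, 3L, 0L, 4L))
    # smooth symmetric central peak: centred box
    d2 <- outer((1:9 - 5)^2, (1:9 - 5)^2, "+")
    pk <- exp(-d2 / 4)
    expect_equal(locateRoi(pk, c(3, 3), c(9, 9)), c(3L, 6L, 3L, 6L))
    expect_error(locateRoi(matrix(1, 4, 4), c(8, 8), c(4, 4)), "larger")
})

test_that("fusion head emits K scores and a response map", {
    m <- tinyModel(K = 3)
    fH <- array(rnorm(8 * 8 * 16), c(8, 8, 16))
    fI <- array(rnorm(8 * 8 * 16), c(8, 8, 16))
    fu <- fuseGlobalPrior(m, fH, fI)
    expect_length(fu$logitsG, 3L)
    expect_equal(dim(fu$responseMap), c(8L, 8L))
    # constant features give a spatially constant response map
    fc <- fuseGlobalPrior(m, array(1, c(8, 8, 16)), array(2, c(8, 8, 16)))
    expect_lt(diff(range(fc$responseMap)), 1e-12)
    expect_error(fuseGlobalPrior(m, fH, array(0, c(4, 4, 16))), "aligned")
})

test_that("local pathway validates crop size and bounds its gates", {
    m <- tinyModel()
    crop <- randomImage(16, seed = 10)  # 32 * 0.5
    lp <- localPathway(m, crop)
    expect_length(lp$logitsL, 2L)
    expect_true(all(lp$gates > 0 & lp$gates < 1))
    expect_error(localPathway(m, randomImage(20, seed = 1)), "wrong size")
})

test_that("the composed prior bundle is deterministic and well-formed", {
    m <- tinyModel(K = 3)
    img <- randomImage(32, seed = 11)
    b1 <- priorForward(m, img)
    b2 <- priorForward(m, img)
    expect_s4_class(b1, "PriorBundle")
    expect_identical(b1@yG, b2@yG)
    expect_identical(b1@roiBox, b2@roiBox)
    expect_length(b1@yG, 3L); expect_length(b1@yL, 3L)
    expect_length(b1@yF, 3L); expect_length(b1@rhoX, 8L)
    expect_equal(sum(b1@yG), 1, tolerance = 1e-12)
    expect_true(all(is.finite(c(b1@yG, b1@yL, b1@yF, b1@rhoX))))
    # ROI box lies inside the image with the configured size
    expect_true(b1@roiBox[1] >= 0 && b1@roiBox[2] <= 32)
    expect_equal(b1@roiBox[2] - b1@roiBox[1], 16L)
    # evaluating other images does not change this image's bundle
    invisible(priorForward(m, randomImage(32, seed = 12)))
    b3 <- priorForward(m, img)
    expect_identical(b1@yF, b3@yF)
})

test_that("encoder plus pyramid context widens the receptive field", {
    set.seed(13)
    m <- tinyModel()
    # positive-weight copies to avoid dead units in the probe
    p <- m@prior
    pos <- function(l) { l$W <- abs(l$W) + 0.01; l$b[] <- 0.01; l }
    p$stem <- pos(p$stem)
    for (nm in c("s1", "s2", "s3", "s4"))
        for (cn in names(p[[nm]])) p[[nm]][[cn]] <- pos(p[[nm]][[cn]])
    for (nm in names(p$hpcm)) p$hpcm[[nm]] <- pos(p$hpcm[[nm]])
    m@prior <- p
    img <- array(1, c(64, 64, 3))
    bb <- cgad:::backboneApply(m@prior, img)
    rates <- m@config@architecture$hpcm_rates
    hp <- cgad:::hpcmApply(m@prior$hpcm, bb$out, rates)
    probeAt <- function(out, backTo) {
        g <- array(0, dim(out)); g[4, 4, 1] <- 1
        dx <- backTo(g)
        on <- apply(abs(dx) > 1e-12, c(1, 2), any)
        sum(on)
    }
    rfEnc <- probeAt(bb$out, function(g)
        cgad:::backboneBack(g, m@prior, bb$cache)$dx)
    rfHp <- probeAt(hp$out, function(g)
        cgad:::backboneBack(cgad:::hpcmBack(g, m@prior$hpcm, hp$cache)$dx,
                            m@prior, bb$cache)$dx)
    expect_gt(rfHp, rfEnc)
})
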