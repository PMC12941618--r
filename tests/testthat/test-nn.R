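# Gradient correctness of the layer library, checked against central
# finite differences on tiny layers.

fdCheck <- function(fwd, x, gout, dxAnalytic, h = 1e-6, tol = 1e-6) {
    num <- array(0, dim(x) %||% length(x))
    for (i in seq_along(x)) {
        xp <- x; xp[i] <- x[i] + h
        xm <- x; xm[i] <- x[i] - h
        num[i] <- (sum(fwd(xp) * gout) - sum(fwd(xm) * gout)) / (2 * h)
    }
    expect_lt(max(abs(num - dxAnalytic)), tol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("dilated convolution forward/backward match finite differences", {
    set.seed(1)
    for (d in c(1L, 2L)) {
        layer <- cgad:::initConv(3L, 2L, 3L)
        x <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
        fw <- cgad:::convForward(x, layer, dilation = d)
        expect_equal(dim(fw$out), c(6L, 6L, 3L))
        gout <- array(rnorm(6 * 6 * 3), c(6, 6, 3))
        bk <- cgad:::convBackward(gout, layer, fw$cache)
        fdCheck(function(xx) cgad:::convForward(xx, layer, d)$out,
                x, gout, bk$dx)
        # weight gradient
        h <- 1e-6
        for (i in c(1L, 10L)) {
            lp <- layer; lp$W[i] <- lp$W[i] + h
            lm <- layer; lm$W[i] <- lm$W[i] - h
            num <- (sum(cgad:::convForward(x, lp, d)$out * gout) -
                    sum(cgad:::convForward(x, lm, d)$out * gout)) / (2 * h)
            expect_equal(bk$dW[i], num, tolerance = 1e-5)
        }
    }
})

test_that("1x1 convolution reduces to a per-pixel linear map", {
    set.seed(2)
    layer <- cgad:::initConv(1L, 3L, 2L)
    x <- array(rnorm(4 * 5 * 3), c(4, 5, 3))
    fw <- cgad:::convForward(x, layer)
    manual <- matrix(x, 20, 3) %*% layer$W
    expect_equal(as.vector(fw$out), as.vector(manual + rep(layer$b, each = 20)))
    gout <- array(rnorm(4 * 5 * 2), c(4, 5, 2))
    bk <- cgad:::convBackward(gout, layer, fw$cache)
    fdCheck(function(xx) cgad:::convForward(xx, layer)$out, x, gout, bk$dx)
})

test_that("max pooling selects maxima and routes gradients to them", {
    x <- array(0, c(4, 4, 1))
    x[, , 1] <- matrix(c(1, 2, 5, 0,
                         3, 4, 1, 1,
                         0, 1, 2, 2,
                         1, 0, 3, 9), 4, 4, byrow = TRUE)
    fw <- cgad:::maxpoolForward(x)
    expect_equal(fw$out[, , 1], matrix(c(4, 5, 1, 9), 2, 2, byrow = TRUE))
    g <- array(1, c(2, 2, 1))
    bk <- cgad:::maxpoolBackward(g, fw$cache)
    expect_equal(sum(bk), 4)           # one unit per window
    expect_equal(bk[4, 4, 1], 1)       # the 9
    set.seed(3)
    x <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
    fw <- cgad:::maxpoolForward(x)
    gout <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
    bk <- cgad:::maxpoolBackward(gout, fw$cache)
    fdCheck(function(xx) cgad:::maxpoolForward(xx)$out, x, gout, bk)
})

test_that("squeeze-excitation gates lie in (0,1) and backprop correctly", {
    set.seed(4)
    layer <- cgad:::initSE(4L, ratio = 2L)
    x <- array(rnorm(5 * 5 * 4), c(5, 5, 4))
    fw <- cgad:::seForward(x, layer)
    expect_true(all(fw$gates > 0 & fw$gates < 1))
    # zero-initialised gate layers give gates of exactly 0.5
    z <- layer
    z$W1[] <- 0; z$b1[] <- 0; z$W2[] <- 0; z$b2[] <- 0
    expect_equal(cgad:::seForward(x, z)$gates, rep(0.5, 4))
    # scaling one channel scales its squeeze statistic proportionally
    x2 <- x; x2[, , 2] <- 3 * x[, , 2]
    s1 <- cgad:::seForward(x, layer)$cache$s
    s2 <- cgad:::seForward(x2, layer)$cache$s
    expect_equal(s2[2], 3 * s1[2])
    expect_equal(s2[-2], s1[-2])
    gout <- array(rnorm(5 * 5 * 4), c(5, 5, 4))
    bk <- cgad:::seBackward(gout, layer, fw$cache)
    fdCheck(function(xx) cgad:::seForward(xx, layer)$out, x, gout, bk$dx,
            tol = 1e-5)
})

test_that("bilinear upsampling interpolates and preserves constants", {
    m <- matrix(2.5, 3, 3)
    expect_true(all(abs(cgad:::bilinearUpsample(m, 9, 9) - 2.5) < 1e-12))
    # upsampling a gradient stays monotone along rows
    g <- matrix(rep(1:4, each = 4), 4, 4)
    up <- cgad:::bilinearUpsample(g, 16, 16)
    expect_true(all(diff(up[, 8]) >= -1e-12))
    expect_equal(dim(up), c(16L, 16L))
})

test_that("summed-area window sums equal brute-force sums", {
    set.seed(5)
    m <- matrix(rnorm(12 * 10), 12, 10)
    ws <- cgad:::windowSums(m, 4, 3)
    for (i in c(1, 5, 9)) for (j in c(1, 4, 8)) {
        expect_equal(ws[i, j], sum(m[i:(i + 3), j:(j + 2)]),
                     tolerance = 1e-10)
    }
    expect_error(cgad:::windowSums(m, 13, 3), "larger")
})

test_that("Adam updates every double leaf and skips structural fields", {
    set.seed(6)
    params <- list(a = list(W = matrix(rnorm(4), 2, 2), b = rnorm(2),
                            k = 3L),
                   c = rnorm(3))
    st <- cgad:::adamInit(params)
    grads <- cgad:::mapParams(function(x) x * 0 + 1, params)
    up <- cgad:::adamStep(params, grads, st, lr = 0.1)
    expect_identical(up$params$a$k, 3L)
    expect_true(all(up$params$a$W < params$a$W))
    expect_true(all(up$params$c < params$c))
})
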