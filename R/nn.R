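# Minimal neural-network layer library: forward/backward passes for the
# convolutional prior network and the MLP denoiser, plus Adam. Feature maps
# are arrays [H, W, C]; convolutions use im2col + GEMM with cached gather
# indices. All backward passes are exercised by finite-difference tests.

.idxCache <- new.env(parent = emptyenv())

# Gather indices for "same"-padded k x k convolution with dilation d:
# matrix [H*W, k^2] of linear indices into the zero-padded [Hp, Wp] plane,
# output positions in column-major order.
convIndices <- function(H, W, k, d) {
    key <- paste(H, W, k, d, sep = "_")
    got <- .idxCache[[key]]
    if (!is.null(got)) return(got)
    p <- d * (k - 1L) / 2L
    Hp <- H + 2L * p
    pos_i <- rep(seq_len(H), times = W)
    pos_j <- rep(seq_len(W), each = H)
    idx <- matrix(0L, H * W, k * k)
    o <- 1L
    for (b in 0:(k - 1L)) for (a in 0:(k - 1L)) {
        idx[, o] <- (pos_j + b * d - 1L) * Hp + (pos_i + a * d)
        o <- o + 1L
    }
    out <- list(idx = idx, p = p, Hp = Hp, Wp = W + 2L * p)
    .idxCache[[key]] <- out
    out
}

# Full gather matrix [H*W, k^2*Cin] of linear indices into the padded
# [Hp, Wp, Cin] array (column c-block = plane indices + (c-1)*Hp*Wp).
convIndicesFull <- function(H, W, k, d, Cin) {
    key <- paste("f", H, W, k, d, Cin, sep = "_")
    got <- .idxCache[[key]]
    if (!is.null(got)) return(got)
    ci <- convIndices(H, W, k, d)
    k2 <- k * k
    plane <- ci$Hp * ci$Wp
    IDX <- matrix(0L, H * W, k2 * Cin)
    for (c in seq_len(Cin))
        IDX[, (c - 1L) * k2 + seq_len(k2)] <- ci$idx + (c - 1L) * plane
    out <- list(IDX = IDX, idx = ci$idx, p = ci$p, Hp = ci$Hp, Wp = ci$Wp)
    .idxCache[[key]] <- out
    out
}

initConv <- function(k, cin, cout, gain = 2) {
    list(W = matrix(stats::rnorm(k * k * cin * cout) *
                        sqrt(gain / (k * k * cin)),
                    k * k * cin, cout),
         b = numeric(cout), k = as.integer(k))
}

initLinear <- function(din, dout, gain = 2) {
    list(W = matrix(stats::rnorm(dout * din) * sqrt(gain / din), dout, din),
         b = numeric(dout))
}

convForward <- function(x, layer, dilation = 1L) {
    dm <- dim(x); H <- dm[1]; W <- dm[2]; Cin <- dm[3]
    k <- layer$k
    if (k == 1L) {  # 1x1 convolution: plain GEMM over pixels
        xm <- matrix(x, H * W, Cin)
        out_mat <- xm %*% layer$W
        out_mat <- sweep(out_mat, 2L, layer$b, "+")
        return(list(out = array(out_mat, c(H, W, ncol(layer$W))),
                    cache = list(X = xm, H = H, W = W, Cin = Cin, k = k,
                                 d = dilation)))
    }
    ci <- convIndicesFull(H, W, k, dilation, Cin)
    xp <- array(0, c(ci$Hp, ci$Wp, Cin))
    xp[ci$p + seq_len(H), ci$p + seq_len(W), ] <- x
    X <- matrix(xp[ci$IDX], H * W, k * k * Cin)
    out_mat <- X %*% layer$W
    out_mat <- sweep(out_mat, 2L, layer$b, "+")
    list(out = array(out_mat, c(H, W, ncol(layer$W))),
         cache = list(X = X, H = H, W = W, Cin = Cin, k = k, d = dilation))
}

convBackward <- function(gout, layer, cache) {
    H <- cache$H; W <- cache$W; Cin <- cache$Cin; k <- cache$k
    gmat <- matrix(gout, H * W, dim(gout)[3])
    dW <- crossprod(cache$X, gmat)
    db <- colSums(gmat)
    dX <- tcrossprod(gmat, layer$W)  # [H*W, k2*Cin]
    if (k == 1L)
        return(list(dx = array(dX, c(H, W, Cin)), dW = dW, db = db))
    k2 <- k * k
    ci <- convIndicesFull(H, W, k, cache$d, Cin)
    dxp <- matrix(0, ci$Hp * ci$Wp, Cin)
    cols0 <- k2 * (seq_len(Cin) - 1L)
    for (o in seq_len(k2)) {
        tg <- ci$idx[, o]
        dxp[tg, ] <- dxp[tg, ] + dX[, o + cols0]
    }
    rows <- ci$p + seq_len(H); cols <- ci$p + seq_len(W)
    dx <- array(dxp, c(ci$Hp, ci$Wp, Cin))[rows, cols, , drop = FALSE]
    list(dx = dx, dW = dW, db = db)
}

reluForward <- function(x) list(out = pmax(x, 0), cache = x > 0)
reluBackward <- function(gout, cache) gout * cache

maxpoolForward <- function(x) {
    dm <- dim(x); H <- dm[1]; W <- dm[2]; C <- dm[3]
    i1 <- seq(1L, H, 2L); i2 <- i1 + 1L
    j1 <- seq(1L, W, 2L); j2 <- j1 + 1L
    a <- x[i1, j1, , drop = FALSE]; b <- x[i2, j1, , drop = FALSE]
    cc <- x[i1, j2, , drop = FALSE]; d <- x[i2, j2, , drop = FALSE]
    out <- pmax(a, b, cc, d)
    m1 <- a == out
    m2 <- (b == out) & !m1
    m3 <- (cc == out) & !m1 & !m2
    m4 <- !(m1 | m2 | m3)
    list(out = out,
         cache = list(m = list(m1, m2, m3, m4), H = H, W = W, C = C))
}

maxpoolBackward <- function(gout, cache) {
    H <- cache$H; W <- cache$W
    i1 <- seq(1L, H, 2L); i2 <- i1 + 1L
    j1 <- seq(1L, W, 2L); j2 <- j1 + 1L
    dx <- array(0, c(H, W, cache$C))
    dx[i1, j1, ] <- gout * cache$m[[1]]
    dx[i2, j1, ] <- gout * cache$m[[2]]
    dx[i1, j2, ] <- gout * cache$m[[3]]
    dx[i2, j2, ] <- gout * cache$m[[4]]
    dx
}

gapForward <- function(x) {
    dm <- dim(x)
    list(out = colMeans(matrix(x, dm[1] * dm[2], dm[3])),
         cache = dm)
}

gapBackward <- function(gout, cache) {
    array(rep(gout / (cache[1] * cache[2]), each = cache[1] * cache[2]),
          cache)
}

linearForward <- function(x, layer) {
    list(out = drop(layer$W %*% x) + layer$b, cache = x)
}

linearBackward <- function(gout, layer, cache) {
    list(dx = drop(crossprod(layer$W, gout)),
         dW = tcrossprod(gout, cache), db = gout)
}

initSE <- function(C, ratio = 4L) {
    hidden <- max(1L, C %/% ratio)
    list(W1 = matrix(stats::rnorm(hidden * C) * sqrt(2 / C), hidden, C),
         b1 = numeric(hidden),
         W2 = matrix(stats::rnorm(C * hidden) * sqrt(1 / hidden), C, hidden),
         b2 = numeric(C))
}

# Squeeze-and-excitation channel gate: global pool -> bottleneck -> sigmoid.
seForward <- function(x, layer) {
    dm <- dim(x)
    s <- colMeans(matrix(x, dm[1] * dm[2], dm[3]))
    pre1 <- drop(layer$W1 %*% s) + layer$b1
    h <- pmax(pre1, 0)
    z <- drop(layer$W2 %*% h) + layer$b2
    g <- 1 / (1 + exp(-z))
    out <- sweep(x, 3L, g, "*")
    list(out = out, gates = g,
         cache = list(x = x, s = s, pre1 = pre1, h = h, g = g, dm = dm))
}

seBackward <- function(gout, layer, cache) {
    dm <- cache$dm; npix <- dm[1] * dm[2]
    dgate <- colSums(matrix(gout * cache$x, npix, dm[3]))
    dx <- sweep(gout, 3L, cache$g, "*")
    dz <- dgate * cache$g * (1 - cache$g)
    dh <- drop(crossprod(layer$W2, dz))
    dW2 <- tcrossprod(dz, cache$h)
    db2 <- dz
    dpre1 <- dh * (cache$pre1 > 0)
    ds <- drop(crossprod(layer$W1, dpre1))
    dW1 <- tcrossprod(dpre1, cache$s)
    db1 <- dpre1
    dx <- dx + array(rep(ds / npix, each = npix), dm)
    list(dx = dx, dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

# Bilinear upsampling of a matrix to H x W (half-pixel centre alignment).
bilinearUpsample <- function(mat, H, W) {
    h <- nrow(mat); w <- ncol(mat)
    src_i <- pmin(pmax((seq_len(H) - 0.5) * h / H + 0.5, 1), h)
    src_j <- pmin(pmax((seq_len(W) - 0.5) * w / W + 0.5, 1), w)
    i0 <- pmin(floor(src_i), h - 1L); i0[h == 1L] <- 1L
    j0 <- pmin(floor(src_j), w - 1L); j0[w == 1L] <- 1L
    if (h == 1L) { fi <- rep(0, H) } else fi <- src_i - i0
    if (w == 1L) { fj <- rep(0, W) } else fj <- src_j - j0
    i1 <- pmin(i0 + 1L, h); j1 <- pmin(j0 + 1L, w)
    A <- mat[i0, j0, drop = FALSE]; B <- mat[i1, j0, drop = FALSE]
    C <- mat[i0, j1, drop = FALSE]; D <- mat[i1, j1, drop = FALSE]
    wi <- matrix(fi, H, W); wj <- matrix(fj, H, W, byrow = TRUE)
    A * (1 - wi) * (1 - wj) + B * wi * (1 - wj) +
        C * (1 - wi) * wj + D * wi * wj
}

# Sum of mat over every h x w window via a summed-area table; returns the
# matrix of window sums indexed by the window's top-left position.
windowSums <- function(mat, h, w) {
    H <- nrow(mat); W <- ncol(mat)
    if (h > H || w > W) stop("window larger than matrix")
    S <- matrix(0, H + 1L, W + 1L)
    S[-1L, -1L] <- t(apply(apply(mat, 2L, cumsum), 1L, cumsum))
    i <- seq_len(H - h + 1L); j <- seq_len(W - w + 1L)
    S[i + h, j + w] - S[i, j + w] - S[i + h, j] + S[i, j]
}

# ---- nested-parameter utilities (for Adam) ----

mapParams <- function(f, a, b = NULL) {
    if (is.list(a)) {
        out <- vector("list", length(a)); names(out) <- names(a)
        nm <- names(a)
        for (i in seq_along(a)) {
            bi <- if (is.null(b)) NULL
                  else if (!is.null(nm) && nzchar(nm[i])) b[[nm[i]]]
                  else b[[i]]
            out[[i]] <- mapParams(f, a[[i]], bi)
        }
        out
    } else if (is.double(a)) {  # integer fields (e.g. kernel size) pass through
        if (is.null(b)) f(a) else f(a, b)
    } else a
}

zerosLike <- function(params) mapParams(function(x) x * 0, params)

addParams <- function(a, b) mapParams(`+`, a, b)

scaleParams <- function(a, s) mapParams(function(x) x * s, a)

adamInit <- function(params) {
    list(m = zerosLike(params), v = zerosLike(params), t = 0L)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
    state$t <- state$t + 1L
    state$m <- mapParams(function(m, g) beta1 * m + (1 - beta1) * g,
                         state$m, grads)
    state$v <- mapParams(function(v, g) beta2 * v + (1 - beta2) * g^2,
                         state$v, grads)
    bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
    upd <- mapParams(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                     state$m, state$v)
    list(params = mapParams(`-`, params, upd), state = state)
}
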