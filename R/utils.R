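# Internal helpers: seeding, softmax, numerics.

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
    if (length(seed) != 1L || !is.finite(seed))
        stop("seed must be a single finite number")
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

# Derive a stream-specific seed from a master seed; keeps results < 2^31.
deriveSeed <- function(seed, stream) {
    (as.double(seed) * 1009 + 97 * stream) %% 2147483629
}

softmax <- function(z) {
    z <- z - max(z)
    e <- exp(z)
    e / sum(e)
}

# d(loss)/d(logits) for p = softmax(logits) given d(loss)/d(p)
softmaxBackward <- function(p, dp) {
    p * (dp - sum(dp * p))
}

oneHot <- function(label, K) {
    y <- numeric(K)
    y[label + 1L] <- 1
    y
}
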