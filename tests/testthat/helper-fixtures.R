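# Shared fixtures: tiny configurations, models and datasets built in code.
# Datasets are generated once per session into the testthat temp dir.

tinyConfig <- function(K = 2, ...) {
    cgadConfig(n_classes = K, base_channels = 4L, latent_dim = 8L,
               denoiser_width = 16L, denoiser_depth = 2L,
               time_embed_dim = 8L, T = 20L, image_size = 32L,
               batch_size = 4L, epochs = 2L, seed = 1L, ...)
}

tinyModel <- function(K = 2, ...) newCGADModel(tinyConfig(K, ...))

randomImage <- function(S = 32, seed = 1) {
    set.seed(seed)
    array(stats::rnorm(S * S * 3, sd = 0.5), c(S, S, 3))
}

# Session-cached synthetic dataset; returns the manifest path.
fixtureDataset <- function(name, nPerClass, K, imageSize, ambiguity,
                           seed) {
    dir <- file.path(tempdir(), paste0("cgad_fix_", name))
    mpath <- file.path(dir, "manifest.csv")
    if (!file.exists(mpath)) {
        sp <- synthSpec(nPerClass = nPerClass, K = K,
                        imageSize = imageSize, ambiguity = ambiguity,
                        seed = seed)
        generateLesionDataset(sp, dir)
    }
    mpath
}

# Independent textbook DDPM forward marginal and posterior mean
# (two-coefficient formula), used as the reduction oracle.
ddpmForwardOracle <- function(y0, t, eps, sch) {
    ab <- alphaBar(sch)[t]
    sqrt(ab) * y0 + sqrt(1 - ab) * eps
}

ddpmPosteriorMeanOracle <- function(y0hat, yt, t, sch) {
    ab_t <- alphaBar(sch)[t]
    ab_prev <- if (t == 1) 1 else alphaBar(sch)[t - 1]
    beta_t <- betas(sch)[t]
    alpha_t <- 1 - beta_t
    sqrt(ab_prev) * beta_t / (1 - ab_t) * y0hat +
        sqrt(alpha_t) * (1 - ab_prev) / (1 - ab_t) * yt
}

# Brute-force maximal-sum window search (ROI oracle).
roiOracle <- function(mat, h, w) {
    H <- nrow(mat); W <- ncol(mat)
    best <- -Inf; bi <- 1L; bj <- 1L
    for (i in seq_len(H - h + 1L)) for (j in seq_len(W - w + 1L)) {
        s <- sum(mat[i:(i + h - 1L), j:(j + w - 1L)])
        if (s > best + 1e-12) { best <- s; bi <- i; bj <- j }
    }
    as.integer(c(bi - 1L, bi - 1L + h, bj - 1L, bj - 1L + w))
}
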