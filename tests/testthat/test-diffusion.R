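test_that("confidence is the maximum of a valid probability vector", {
    expect_equal(confidenceScore(rep(0.25, 4)), 0.25)
    expect_equal(confidenceScore(c(0, 1, 0)), 1)
    expect_equal(confidenceScore(c(0.7, 0.2, 0.1)), 0.7)
    expect_error(confidenceScore(c(0.5, 0.2)), "sum to 1")
    expect_error(confidenceScore(c(-0.1, 1.1)), "nonnegative")
})

test_that("forward diffusion evaluates the guided marginal exactly", {
    sch1 <- buildSchedule(1, 0.36, 0.36)  # alphaBar = 0.64
    yt <- forwardDiffuse(c(1, 0), 1, 0.5, c(1, 1), c(0.5, 0.5), sch1)
    expect_equal(yt, c(1.28, 0.48))
    # c = 1: noise term vanishes
    sch <- buildSchedule(10, 0.02, 0.2)
    y0 <- c(0, 1, 0)
    set.seed(1)
    eps <- rnorm(3)
    expect_equal(forwardDiffuse(y0, 4, 1, eps, rep(0, 3), sch),
                 sqrt(alphaBar(sch)[4]) * y0)
    # c = 0, guidance = 0: standard DDPM forward marginal
    expect_equal(forwardDiffuse(y0, 7, 0, eps, rep(0, 3), sch),
                 ddpmForwardOracle(y0, 7, eps, sch))
    expect_error(forwardDiffuse(y0, 11, 0.5, eps, rep(0, 3), sch), "\\[1, T\\]")
    expect_error(forwardDiffuse(y0, 3, 0.5, eps, rep(0, 2), sch), "length")
})

test_that("interpolated perturbation matches its closed form", {
    expect_equal(perturbInterpolated(c(0, 1), c(1, 0), 0, 1, c(5, 5)),
                 c(1, 0))
    expect_equal(perturbInterpolated(c(0, 1), c(1, 0), 1, 1, c(5, 5)),
                 c(0, 1))
    expect_equal(perturbInterpolated(c(0, 1), c(1, 0), 0.5, 0.5, c(2, 2)),
                 c(1.5, 1.5))
    expect_error(perturbInterpolated(c(0, 1), c(1, 0), 1.2, 1, c(0, 0)),
                 "\\[0,1\\]")
})

test_that("clean-estimate inverts the forward corruption", {
    sch1 <- buildSchedule(1, 0.36, 0.36)
    expect_equal(estimateClean(c(1.28, 0.48), 1, 0.5, c(1, 1), c(0.5, 0.5),
                               sch1), c(1, 0))
    sch <- buildSchedule(25, 0.01, 0.2)
    # c = 1: estimate ignores the predicted noise entirely
    set.seed(2)
    yt <- rnorm(4); g <- rnorm(4)
    ab <- alphaBar(sch)[9]
    expect_equal(estimateClean(yt, 9, 1, rnorm(4), g, sch),
                 (yt - (1 - ab) * g) / sqrt(ab))
    # round trip over random tuples
    for (i in 1:100) {
        K <- sample(2:6, 1)
        y0 <- rnorm(K); eps <- rnorm(K); g <- rnorm(K)
        cc <- runif(1); t <- sample(25, 1)
        yt <- forwardDiffuse(y0, t, cc, eps, g, sch)
        expect_lt(max(abs(estimateClean(yt, t, cc, eps, g, sch) - y0)),
                  1e-9)
    }
})

test_that("posterior step degenerates to the clean estimate at t = 1", {
    sch <- buildSchedule(12, 0.01, 0.15)
    set.seed(4)
    y0hat <- rnorm(3); yt <- rnorm(3)
    expect_equal(posteriorStep(y0hat, yt, 1, rnorm(3), rnorm(3), sch),
                 y0hat)
})

test_that("unguided posterior mean equals the textbook DDPM formula", {
    sch <- buildSchedule(30, 0.005, 0.1)
    set.seed(5)
    for (i in 1:50) {
        K <- sample(2:5, 1)
        y0hat <- rnorm(K); yt <- rnorm(K)
        t <- sample(2:30, 1)
        got <- posteriorStep(y0hat, yt, t, rep(0, K), rep(0, K), sch)
        expect_lt(max(abs(got - ddpmPosteriorMeanOracle(y0hat, yt, t, sch))),
                  1e-10)
    }
})

test_that("the noiseless guided chain is consistent with forward marginals", {
    sch <- buildSchedule(15, 0.01, 0.2)
    set.seed(6)
    y0 <- c(1, 0, 0); g <- rnorm(3)
    for (t in 15:2) {
        yt <- forwardDiffuse(y0, t, 1, rnorm(3), g, sch)
        ytm1 <- posteriorStep(y0, yt, t, g, rep(0, 3), sch)
        expect_equal(ytm1, forwardDiffuse(y0, t - 1, 1, rnorm(3), g, sch),
                     tolerance = 1e-12)
    }
})

test_that("injected noise magnitude is monotone non-increasing in confidence", {
    sch <- buildSchedule(20, 0.01, 0.2)
    set.seed(7)
    y0 <- c(0, 1); eps <- rnorm(2); g <- rnorm(2); t <- 13
    ab <- alphaBar(sch)[t]
    dist <- vapply(seq(0, 1, by = 0.05), function(cc) {
        yt <- forwardDiffuse(y0, t, cc, eps, g, sch)
        sqrt(sum((yt - sqrt(ab) * y0 - (1 - ab) * g)^2))
    }, numeric(1))
    expect_true(all(diff(dist) <= 1e-12))
    expect_equal(dist[length(dist)], 0)
})

test_that("reverse sampler is deterministic and recovers a planted target", {
    m <- tinyModel()
    sch <- m@schedule
    rho <- rnorm(8)
    # zero denoiser, zero guidance, c = 1: fully deterministic chain
    zden <- function(yt, t, rho, g) rep(0, 2)
    r1 <- reverseSample(rho, c(0, 0), zden, c(1, 0), sch, seed = 3)
    r2 <- reverseSample(rho, c(0, 0), zden, c(1, 0), sch, seed = 3)
    expect_identical(r1$y0Hat, r2$y0Hat)
    # at c = 1 the sampler noise is fully attenuated: the chain is the
    # deterministic affine contraction of the initial state, independent
    # of the seed, and the final estimate is the closed form y_T/sqrt(abT)
    r3 <- reverseSample(rho, c(0, 0), zden, c(1, 0), sch, seed = 99)
    expect_equal(r1$y0Hat, r3$y0Hat, tolerance = 1e-12)
    abT <- alphaBar(sch)[nSteps(sch)]
    yT <- sqrt(abT) * c(1, 0)   # init reduces to its deterministic part
    expect_equal(r1$y0Hat, yT / sqrt(abT), tolerance = 1e-9)
    # plant-and-recover: an oracle denoiser that reports, for any state it
    # is shown, the exact noise under which that state is the forward
    # corruption of a known y0 -- so every clean estimate equals y0 and
    # the final output recovers it
    y0 <- c(1, 0); g <- c(0.4, 0.6)
    probs <- c(0.7, 0.3)  # confidence c = 0.7
    ab <- alphaBar(sch)
    oracleDen <- function(yt, t, rho, gg)
        (yt - sqrt(ab[t]) * y0 - (1 - ab[t]) * gg) /
            ((1 - 0.7) * sqrt(1 - ab[t]))
    r <- reverseSample(rho, g, oracleDen, probs, sch, seed = 1,
                       trajectory = TRUE)
    expect_lt(max(abs(r$y0Hat - y0)), 1e-6)
    expect_equal(dim(r$trajectory), c(nSteps(sch) + 1L, 2L))
    # denoiser contract violation
    badden <- function(yt, t, rho, g) rep(0, 3)
    expect_error(reverseSample(rho, c(0, 0), badden, c(1, 0), sch, 1),
                 "length")
})

test_that("trajectory export writes the expected TSV layout", {
    sch <- buildSchedule(3, 0.1, 0.2)
    tra <- list(s1 = matrix(seq_len(8) / 10, 4, 2))
    f <- tempfile(fileext = ".tsv")
    exportTrajectories(tra, predicted = 1L, true = 0L, file = f,
                       schedule = sch)
    got <- read.delim(f)
    expect_equal(names(got), c("sample_id", "t", "entry_0", "entry_1",
                               "predicted_class", "true_class"))
    expect_equal(got$t, c(3, 2, 1, 0))
    expect_equal(nrow(got), 4L)
})
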