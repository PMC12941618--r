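#' Build a diffusion noise schedule
#'
#' Constructs the per-step rates \eqn{\beta_t}, the cumulative products
#' \eqn{\bar\alpha_t = \prod_{s\le t}(1-\beta_s)} and the reverse-posterior
#' variances \eqn{\tilde\beta_t = \frac{1-\bar\alpha_{t-1}}{1-\bar\alpha_t}
#' \beta_t} (convention \eqn{\bar\alpha_0 = 1}, hence
#' \eqn{\tilde\beta_1 = 0}). Only the linear ramp between \code{betaStart}
#' and \code{betaEnd} is provided.
#'
#' @param steps number of diffusion steps T (>= 1)
#' @param betaStart,betaEnd first and last per-step rates, in (0,1) with
#'   \code{betaStart <= betaEnd}
#' @param kind schedule family; only \code{"linear"}
#' @return a [NoiseSchedule-class]
#' @examples
#' sch <- buildSchedule(10)
#' alphaBar(sch)
#' @export
buildSchedule <- function(steps, betaStart = 1e-4, betaEnd = 0.02,
                          kind = c("linear")) {
    kind <- match.arg(kind)
    if (length(steps) != 1L || !is.finite(steps) || steps < 1 ||
        steps != floor(steps))
        stop("steps must be a single positive integer")
    if (betaStart <= 0 || betaEnd >= 1)
        stop("beta rates must lie in (0,1)")
    if (betaStart > betaEnd)
        stop("betaStart must not exceed betaEnd")
    steps <- as.integer(steps)
    beta <- if (steps == 1L) betaStart else
        seq(betaStart, betaEnd, length.out = steps)
    alpha_bar <- cumprod(1 - beta)
    alpha_bar_prev <- c(1, alpha_bar[-steps])
    post_var <- (1 - alpha_bar_prev) / (1 - alpha_bar) * beta
    new("NoiseSchedule", steps = steps, beta = beta, alphaBar = alpha_bar,
        posteriorVar = post_var)
}

checkStep <- function(t, schedule) {
    if (length(t) != 1L || !is.finite(t) || t < 1 || t > schedule@steps ||
        t != floor(t))
        stop("t must be an integer step index in [1, T]")
    as.integer(t)
}
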