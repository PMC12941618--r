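#' Initialise a CGAD model
#'
#' Builds the prior network and the conditional denoiser with seeded random
#' initialisation (He/Glorot scaling), and constructs the noise schedule
#' from the configuration.
#'
#' @param config a [CGADConfig-class]
#' @return a [CGADModel-class]
#' @examples
#' m <- newCGADModel(cgadConfig(n_classes = 2, base_channels = 4,
#'                              denoiser_width = 16, T = 10))
#' @export
newCGADModel <- function(config) {
    stopifnot(is(config, "CGADConfig"))
    d <- config@diffusion
    sch <- buildSchedule(d$T, d$beta_start, d$beta_end, d$schedule_kind)
    withSeed(deriveSeed(config@training$seed, 1L), {
        prior <- initPrior(config@architecture)
        den <- initDenoiser(config@architecture)
        new("CGADModel", prior = prior, denoiser = den, schedule = sch,
            config = config,
            yBarEma = numeric(config@architecture$n_classes))
    })
}
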