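#' Build a CGAD configuration
#'
#' Collects all tunable parameters: the diffusion schedule, the network
#' architecture and the training protocol, including the ablation flags.
#' Defaults are desk-scale (64 px images, T = 200, small channel widths)
#' so that a full run fits on one CPU; the large-scale protocol (224 px,
#' batch 64, 1000 epochs, T = 1000) is reachable by overriding the
#' corresponding arguments.
#'
#' @param n_classes number of classes K (>= 2)
#' @param T number of diffusion steps
#' @param beta_start,beta_end linear schedule endpoints
#' @param schedule_kind only "linear"
#' @param guidance_mode "prior_sum" (guidance = sum of denoised global and
#'   local prior score vectors) or "ybar_ema" (exponential moving average
#'   of the fully-diffused state, decay \code{ybar_decay})
#' @param ybar_decay EMA decay for guidance_mode = "ybar_ema"
#' @param image_size square input side in pixels (>= 32, multiple of 8)
#' @param base_channels backbone stem width; stages use 1x/2x/4x
#' @param hpcm_rates dilation rates of the parallel pyramid branches (a
#'   standard 3x3 branch is always included)
#' @param idcr_rates dilation rates of the sequential refinement stack
#' @param crop_fraction ROI side as a fraction of the image side
#' @param attention_ratio channel-attention bottleneck ratio
#' @param latent_dim dimension D of the conditioning latent rho(x)
#' @param denoiser_width,denoiser_depth residual MLP head of the denoiser
#' @param time_embed_dim sinusoidal time-embedding dimension (even)
#' @param epochs,batch_size,learning_rate,lr_schedule optimiser protocol
#'   (Adam, cosine annealing to 0)
#' @param seed master seed; data, noise and initialisation streams are
#'   derived from it
#' @param aux_period auxiliary cross-entropy branch activates on epochs
#'   1, 1+aux_period, 1+2*aux_period, ...
#' @param aux_warmup during the first aux_warmup epochs the auxiliary
#'   branch is active every epoch (the supervision that anchors the
#'   class-score heads while the learning rate is still high); 0 disables
#'   the warmup phase
#' @param lambda weight of the MMD + auxiliary group in the total loss
#' @param recon_enabled include the prior reconstruction regulariser
#' @param use_cgani confidence-guided noise (FALSE = fixed schedule, the
#'   ablation baseline B0 with the (1-c) factor removed)
#' @param use_hpcm,use_idcr enable the two context modules
#' @param n_samples reverse-sampling runs averaged at evaluation
#' @return a [CGADConfig-class]
#' @export
cgadConfig <- function(n_classes,
                       T = 200L, beta_start = 1e-4, beta_end = 0.02,
                       schedule_kind = "linear",
                       guidance_mode = c("prior_sum", "ybar_ema"),
                       ybar_decay = 0.99,
                       image_size = 64L, base_channels = 32L,
                       hpcm_rates = c(2L, 4L, 8L),
                       idcr_rates = c(1L, 2L, 4L),
                       crop_fraction = 0.5, attention_ratio = 4L,
                       latent_dim = 32L,
                       denoiser_width = 128L, denoiser_depth = 3L,
                       time_embed_dim = 64L,
                       epochs = 40L, batch_size = 16L,
                       learning_rate = 1e-3, lr_schedule = "cosine",
                       seed = 1L, aux_period = 5L, aux_warmup = 10L,
                       lambda = 0.5,
                       recon_enabled = TRUE,
                       use_cgani = TRUE, use_hpcm = TRUE, use_idcr = TRUE,
                       n_samples = 1L) {
    guidance_mode <- match.arg(guidance_mode)
    if (missing(n_classes) || n_classes < 2)
        stop("n_classes must be >= 2")
    if (image_size %% 8 != 0)
        stop("image_size must be a multiple of 8")
    new("CGADConfig",
        diffusion = list(T = as.integer(T), beta_start = beta_start,
                         beta_end = beta_end, schedule_kind = schedule_kind,
                         guidance_mode = guidance_mode,
                         ybar_decay = ybar_decay),
        architecture = list(n_classes = as.integer(n_classes),
                            base_channels = as.integer(base_channels),
                            hpcm_rates = as.integer(hpcm_rates),
                            idcr_rates = as.integer(idcr_rates),
                            crop_fraction = crop_fraction,
                            attention_ratio = as.integer(attention_ratio),
                            latent_dim = as.integer(latent_dim),
                            denoiser_width = as.integer(denoiser_width),
                            denoiser_depth = as.integer(denoiser_depth),
                            time_embed_dim = as.integer(time_embed_dim)),
        training = list(epochs = as.integer(epochs),
                        batch_size = as.integer(batch_size),
                        learning_rate = learning_rate,
                        lr_schedule = lr_schedule, seed = as.integer(seed),
                        aux_period = as.integer(aux_period),
                        aux_warmup = as.integer(aux_warmup),
                        lambda = lambda,
                        recon_enabled = recon_enabled,
                        use_cgani = use_cgani, use_hpcm = use_hpcm,
                        use_idcr = use_idcr,
                        image_size = as.integer(image_size),
                        n_samples = as.integer(n_samples)))
}

#' Read a configuration from a YAML file
#'
#' The file may contain any subset of the arguments of [cgadConfig()] as
#' top-level keys; missing keys take the defaults.
#'
#' @param path YAML file path
#' @return a [CGADConfig-class]
#' @export
configFromYaml <- function(path) {
    if (!requireNamespace("yaml", quietly = TRUE))
        stop("the 'yaml' package is required to read config files")
    vals <- yaml::read_yaml(path)
    known <- names(formals(cgadConfig))
    unknown <- setdiff(names(vals), known)
    if (length(unknown))
        stop("unknown config keys: ", paste(unknown, collapse = ", "))
    do.call(cgadConfig, vals)
}
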