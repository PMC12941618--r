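# cgad — confidence-guided adaptive diffusion for image classification

`cgad` classifies 2-D RGB images by running a denoising diffusion process
over **class-score vectors** rather than pixels. It is aimed at
researchers studying diffusion-based classifiers for medical-style
imagery (dermoscopy-like lesions, fundus, histopathology), and at anyone
who wants a fully inspectable, CPU-scale reference implementation of the
mechanism with exact tests around every equation.

## The method in brief

Let $y_0 \in \mathbb{R}^K$ be the one-hot label, $\bar\alpha_t$ the
cumulative signal-retention factor of a linear DDPM schedule, and
$c = \max_k p_\theta(y = k \mid x)$ the classifier's confidence. The
forward corruption injects *confidence-modulated* noise under a prior
guidance vector $G = \hat y_g + \hat y_l$ built from a global and a local
(ROI-cropped) prior head:

$$y_t = \sqrt{\bar\alpha_t}\, y_0 + \sqrt{1-\bar\alpha_t}\,(1-c)\,
\epsilon + (1-\bar\alpha_t)\, G$$

A conditional network $\epsilon_\theta(y_t, t, \rho(x), G)$ predicts the
injected noise; the clean estimate inverts the corruption,
$\hat y_0 = \bar\alpha_t^{-1/2}\big[y_t - (1-\bar\alpha_t)G -
(1-c)\sqrt{1-\bar\alpha_t}\,\epsilon_\theta\big]$, and reverse sampling
uses the DDPM posterior applied to the guidance-shifted state. Training
minimises

$$L = \lVert \epsilon - \hat\epsilon \rVert^2 +
\lambda\big(\mathrm{MMD}(\hat\epsilon_g,\epsilon) +
\mathrm{MMD}(\hat\epsilon_l,\epsilon) + L_{aux}\big) + L_{rec},
\qquad \lambda = 0.5,$$

with a periodically activated cross-entropy branch $L_{aux}$ and a
reconstruction regulariser $L_{rec}$ anchoring the denoised priors.
Confidence is detached: no gradient flows into $c$. Low-confidence
samples are perturbed (and denoised) more aggressively; confident ones
keep their semantics — an optimisation-stabilisation mechanism, not a
change of the discriminative objective.

The prior network combines a residual stride-8 encoder, a parallel
multi-dilation pyramid module, a sequential increasing-dilation
refinement stack (receptive field $1+2\sum r_i$), response-map ROI
cropping, and squeeze-and-excitation channel attention.

Because no deep-learning framework is assumed, the package ships its own
small layer library (im2col convolutions, pooling, attention, Adam) with
hand-written backward passes, each verified against finite differences
in the test suite.

## Worked example

```r
library(cgad)

## a synthetic lesion benchmark: 2 classes, fully separable (ambiguity 0)
sp <- synthSpec(nPerClass = 30, K = 2, imageSize = 64, ambiguity = 0,
                seed = 11)
generateLesionDataset(sp, "lesions")

cfg <- cgadConfig(n_classes = 2, base_channels = 8, latent_dim = 16,
                  denoiser_width = 48, denoiser_depth = 2,
                  time_embed_dim = 16, T = 200, image_size = 64,
                  batch_size = 8, epochs = 40, seed = 1, n_samples = 8)
fit <- trainCGAD(cfg, "lesions/manifest.csv")
fit$metrics
#> MetricsReport: accuracy 1.0000, macro-F1 1.0000, kappa 1.0000 (n = 12)
```

The run trains on 48 images and classifies the 12 held-out images by
full reverse diffusion (argmax of the recovered clean score vector,
averaged over 8 sampling runs); accuracy 1.0 means every held-out lesion
was assigned its generating class. A few minutes on one CPU.

The diffusion algebra is available directly:

```r
sch <- buildSchedule(1, 0.36, 0.36)        # alpha-bar = 0.64
forwardDiffuse(c(1, 0), t = 1, c = 0.5, eps = c(1, 1),
               guidance = c(0.5, 0.5), sch)
#> [1] 1.28 0.48
estimateClean(c(1.28, 0.48), 1, 0.5, c(1, 1), c(0.5, 0.5), sch)
#> [1] 1 0
```

`ablationRun()` reproduces the component-wise study design (fixed
schedule B0, adaptive noise B1, + pyramid module B2, full model) across
seeds and reports mean ± sd metrics, the B0-vs-B1 early-epoch accuracy
variance, and a windowed bootstrap confidence band of the denoising-loss
difference; `lossDeltaDiagnostic()` builds that band for any pair of
loss series.

## Package layout

* `R/diffusion.R`, `R/schedule.R` — exact diffusion algebra.
* `R/prior.R`, `R/denoiser.R`, `R/nn.R` — prior network, conditional
  denoiser, layer library with backprop.
* `R/losses.R`, `R/metrics.R` — composite objective, evaluation metrics.
* `R/training.R` — training loop, evaluation, diagnostics, ablation.
* `R/synthetic.R` — procedural lesion-image generator and loader.
* `vignettes/confidence-guided-diffusion.Rmd` — model, assumptions,
  design decisions, limitations.
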