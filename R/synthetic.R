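# Procedural generator of lesion-like multi-class images. Each class has a
# parametric lesion: an elliptical blob with class-specific eccentricity,
# mean radius, boundary irregularity (radial Fourier perturbation), fill
# texture contrast and pigment shade, rendered on a skin-tone background.
# The ambiguity parameter interpolates every class's parameters toward the
# global mean (ambiguity 1 = identical generating distributions) and
# widens the boundary blur, so Bayes difficulty is controllable.

#' Specification of a synthetic lesion dataset
#'
#' @param nPerClass images per class
#' @param K number of classes (>= 2)
#' @param imageSize square side in pixels (>= 32)
#' @param ambiguity scalar in [0,1]; 0 = well-separated classes, 1 =
#'   classes indistinguishable in expectation
#' @param textureNoise nonnegative scale of pixel-level texture noise
#' @param seed integer seed; the full dataset is a deterministic function
#'   of (spec, seed)
#' @return a [SynthSpec-class]
#' @export
synthSpec <- function(nPerClass = 50L, K = 3L, imageSize = 64L,
                      ambiguity = 0, textureNoise = 1, seed = 1L) {
    new("SynthSpec", nPerClass = as.integer(nPerClass), K = as.integer(K),
        imageSize = as.integer(imageSize), ambiguity = ambiguity,
        textureNoise = textureNoise, seed = as.integer(seed))
}

# Class-level shape/texture parameters after ambiguity interpolation.
classParams <- function(spec) {
    K <- spec@K; amb <- spec@ambiguity
    ramp <- if (K == 1L) 0.5 else (seq_len(K) - 1) / (K - 1)
    pars <- data.frame(
        eccentricity = 0.35 + 0.6 * ramp,     # minor/major axis ratio
        radius = 0.16 + 0.12 * ramp,          # mean radius, fraction of side
        irregularity = 0.03 + 0.22 * ramp,    # Fourier amplitude
        texture = 0.05 + 0.30 * ramp,         # fill texture contrast
        shade = 0.35 + 0.45 * ramp)           # pigment darkness
    for (cn in names(pars))
        pars[[cn]] <- (1 - amb) * pars[[cn]] + amb * mean(pars[[cn]])
    pars$blur <- 1.5 + 6 * amb                # boundary blur in pixels
    pars
}

# Render one lesion image (S x S x 3 array in [0,1]); RNG state supplies
# the per-image jitter.
renderLesion <- function(par, S, textureNoise) {
    cx <- S / 2 + stats::runif(1, -S / 10, S / 10)
    cy <- S / 2 + stats::runif(1, -S / 10, S / 10)
    theta0 <- stats::runif(1, 0, pi)
    rjit <- stats::runif(1, 0.9, 1.1)
    A <- par$radius * S * rjit               # semi-major axis, pixels
    B <- A * par$eccentricity                # semi-minor axis
    nharm <- 4L
    amps <- par$irregularity * stats::runif(nharm, 0.3, 1)
    phases <- stats::runif(nharm, 0, 2 * pi)
    xs <- matrix(seq_len(S) - cx, S, S, byrow = TRUE)  # column coord
    ys <- matrix(seq_len(S) - cy, S, S)                # row coord
    u <- cos(theta0) * xs + sin(theta0) * ys
    v <- -sin(theta0) * xs + cos(theta0) * ys
    rho <- sqrt((u / A)^2 + (v / B)^2)
    ang <- atan2(v, u)
    bnd <- 1
    for (m in seq_len(nharm))
        bnd <- bnd + amps[m] * cos((m + 1) * ang + phases[m])
    w <- par$blur / ((A + B) / 2)            # blur width in rho units
    mask <- 1 / (1 + exp((rho - bnd) / max(w, 1e-3)))
    # fill texture: coarse seeded noise bilinearly upsampled + fine grain
    coarse <- matrix(stats::rnorm(64), 8, 8)
    tex <- par$texture * bilinearUpsample(coarse, S, S) +
        0.03 * textureNoise * matrix(stats::rnorm(S * S), S, S)
    # smooth background with gentle illumination gradient
    bgc <- c(0.87, 0.72, 0.63)
    grad <- bilinearUpsample(matrix(stats::rnorm(16, 0, 0.03), 4, 4), S, S)
    lesc <- c(0.52, 0.33, 0.24) * (1 - par$shade * 0.8)
    img <- array(0, c(S, S, 3))
    for (ch in 1:3) {
        les <- lesc[ch] * (1 + tex)
        bg <- bgc[ch] * (1 + grad)
        img[, , ch] <- bg * (1 - mask) + les * mask
    }
    pmin(pmax(img, 0), 1)
}

#' Generate a synthetic lesion dataset
#'
#' Renders \code{nPerClass} images per class as PNG files and writes a CSV
#' manifest with columns \code{image_path, label, split} (labels 0-based,
#' stratified 80/20 train/test split). Byte-identical for the same spec.
#'
#' @param spec a [SynthSpec-class]
#' @param outDir output directory (created if missing)
#' @return the manifest data.frame, invisibly; the manifest is written to
#'   \code{file.path(outDir, "manifest.csv")}
#' @export
generateLesionDataset <- function(spec, outDir) {
    stopifnot(is(spec, "SynthSpec"))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(outDir)) stop("cannot create output directory ", outDir)
    pars <- classParams(spec)
    rows <- vector("list", spec@K * spec@nPerClass)
    i <- 0L
    for (k in seq_len(spec@K)) {
        for (j in seq_len(spec@nPerClass)) {
            i <- i + 1L
            fn <- sprintf("class%d_%04d.png", k - 1L, j)
            img <- withSeed(deriveSeed(spec@seed, i), {
                renderLesion(pars[k, ], spec@imageSize, spec@textureNoise)
            })
            png::writePNG(img, file.path(outDir, fn))
            rows[[i]] <- data.frame(image_path = fn, label = k - 1L,
                                    split = NA_character_)
        }
    }
    manifest <- do.call(rbind, rows)
    # stratified 80/20 split, deterministic given the dataset seed
    manifest$split <- withSeed(deriveSeed(spec@seed, 0L), {
        spl <- rep("train", nrow(manifest))
        for (k in seq_len(spec@K) - 1L) {
            idx <- which(manifest$label == k)
            ntest <- max(1L, round(0.2 * length(idx)))
            spl[sample(idx, ntest)] <- "test"
        }
        spl
    })
    utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                     row.names = FALSE)
    invisible(manifest)
}

rotateImage <- function(img, angleDeg) {
    S1 <- dim(img)[1]; S2 <- dim(img)[2]
    a <- angleDeg * pi / 180
    cy <- (S1 + 1) / 2; cx <- (S2 + 1) / 2
    rows <- matrix(seq_len(S1) - cy, S1, S2)
    cols <- matrix(seq_len(S2) - cx, S1, S2, byrow = TRUE)
    # inverse mapping
    src_r <- cos(a) * rows - sin(a) * cols + cy
    src_c <- sin(a) * rows + cos(a) * cols + cx
    src_r <- pmin(pmax(src_r, 1), S1)
    src_c <- pmin(pmax(src_c, 1), S2)
    r0 <- pmin(floor(src_r), S1 - 1L); c0 <- pmin(floor(src_c), S2 - 1L)
    fr <- src_r - r0; fc <- src_c - c0
    out <- array(0, dim(img))
    for (ch in seq_len(dim(img)[3])) {
        pl <- img[, , ch]
        i00 <- pl[cbind(as.vector(r0), as.vector(c0))]
        i10 <- pl[cbind(as.vector(r0 + 1L), as.vector(c0))]
        i01 <- pl[cbind(as.vector(r0), as.vector(c0 + 1L))]
        i11 <- pl[cbind(as.vector(r0 + 1L), as.vector(c0 + 1L))]
        vals <- i00 * (1 - fr) * (1 - fc) + i10 * fr * (1 - fc) +
            i01 * (1 - fr) * fc + i11 * fr * fc
        out[, , ch] <- matrix(vals, S1, S2)
    }
    out
}

resizeImage <- function(img, S) {
    if (all(dim(img)[1:2] == c(S, S))) return(img)
    out <- array(0, c(S, S, dim(img)[3]))
    for (ch in seq_len(dim(img)[3]))
        out[, , ch] <- bilinearUpsample(img[, , ch], S, S)
    out
}

centerCrop <- function(img, S) {
    H <- dim(img)[1]; W <- dim(img)[2]
    if (H == S && W == S) return(img)
    r0 <- (H - S) %/% 2L; c0 <- (W - S) %/% 2L
    img[r0 + seq_len(S), c0 + seq_len(S), , drop = FALSE]
}

# Draw one set of augmentation parameters from the current RNG stream.
augmentParams <- function() {
    list(angle = stats::runif(1, -30, 30),
         hflip = stats::runif(1) < 0.5,
         vflip = stats::runif(1) < 0.5)
}

IMG_MEAN <- c(0.485, 0.456, 0.406)
IMG_SD <- c(0.229, 0.224, 0.225)

normalizeImage <- function(img) {
    for (ch in 1:3) img[, , ch] <- (img[, , ch] - IMG_MEAN[ch]) / IMG_SD[ch]
    img
}

#' Load a dataset from a manifest
#'
#' Reads the images listed in a CSV manifest (columns \code{image_path,
#' label, split}), applies the deterministic preprocessing (resize to the
#' target side, centre crop) and, for training data when \code{augment} is
#' TRUE, random rotations within +/-30 degrees and horizontal/vertical
#' flips, then normalises channels with the fixed means
#' (0.485, 0.456, 0.406) and standard deviations (0.229, 0.224, 0.225).
#'
#' @param manifest path to a manifest CSV, or a data.frame with an
#'   attribute \code{dir} naming the image directory
#' @param split "train" or "test"
#' @param imageSize target square side
#' @param augment apply stochastic augmentation (training only)
#' @param seed seed for the augmentation draws
#' @return list of samples, each \code{list(image = array, label =
#'   integer)} in manifest order
#' @export
loadDataset <- function(manifest, split = c("train", "test"),
                        imageSize = 64L, augment = FALSE, seed = 1L) {
    split <- match.arg(split)
    if (is.character(manifest)) {
        dir <- dirname(manifest)
        mf <- utils::read.csv(manifest, stringsAsFactors = FALSE)
    } else {
        mf <- manifest
        dir <- attr(manifest, "dir") %||% "."
    }
    mf <- mf[mf$split == split, , drop = FALSE]
    if (nrow(mf) == 0L) stop("no images in split '", split, "'")
    withSeed(seed, {
        lapply(seq_len(nrow(mf)), function(i) {
            path <- file.path(dir, mf$image_path[i])
            if (!file.exists(path)) stop("missing image file: ", path)
            img <- png::readPNG(path)
            if (length(dim(img)) == 2L) img <- array(rep(img, 3),
                                                     c(dim(img), 3))
            img <- img[, , 1:3, drop = FALSE]
            img <- centerCrop(resizeImage(img, imageSize), imageSize)
            if (augment) {
                ap <- augmentParams()
                img <- rotateImage(img, ap$angle)
                if (ap$hflip) img <- img[, rev(seq_len(dim(img)[2])), ,
                                         drop = FALSE]
                if (ap$vflip) img <- img[rev(seq_len(dim(img)[1])), , ,
                                         drop = FALSE]
            }
            list(image = normalizeImage(img), label = mf$label[i])
        })
    })
}
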