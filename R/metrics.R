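#' Confusion matrix from label vectors
#'
#' @param true,pred 0-based integer class labels of equal length
#' @param K number of classes
#' @return K x K integer matrix, rows = truth, columns = prediction
#' @export
confusionFromLabels <- function(true, pred, K) {
    if (length(true) != length(pred))
        stop("true and pred must share length")
    cm <- matrix(0L, K, K)
    for (i in seq_along(true))
        cm[true[i] + 1L, pred[i] + 1L] <- cm[true[i] + 1L, pred[i] + 1L] + 1L
    cm
}

checkConfusion <- function(cm) {
    if (!is.matrix(cm) || nrow(cm) != ncol(cm))
        stop("confusion matrix must be square")
    if (any(cm < 0)) stop("confusion matrix must be nonnegative")
    cm
}

#' @describeIn accuracy fraction of agreeing pairs of a confusion matrix
#' @export
setMethod("accuracy", "matrix", function(x) {
    cm <- checkConfusion(x)
    sum(diag(cm)) / sum(cm)
})

#' @describeIn macroF1 unweighted mean of per-class F1 of a confusion matrix
#' @export
setMethod("macroF1", "matrix", function(x) {
    cm <- checkConfusion(x)
    rs <- rowSums(cm); cs <- colSums(cm)
    keep <- rs > 0 | cs > 0
    f1 <- vapply(which(keep), function(k) {
        denom <- rs[k] + cs[k]
        if (denom == 0) return(0)
        2 * cm[k, k] / denom  # = 2PR/(P+R)
    }, numeric(1))
    mean(f1)
})

#' @describeIn cohenKappa chance-corrected agreement of a confusion matrix
#' @export
setMethod("cohenKappa", "matrix", function(x) {
    cm <- checkConfusion(x)
    n <- sum(cm)
    po <- sum(diag(cm)) / n
    pe <- sum(rowSums(cm) * colSums(cm)) / n^2
    if (pe == 1) return(ifelse(po == 1, 1, 0))
    (po - pe) / (1 - pe)
})

setMethod("accuracy", "MetricsReport", function(x) x@accuracy)
setMethod("macroF1", "MetricsReport", function(x) x@macroF1)
setMethod("cohenKappa", "MetricsReport", function(x) x@kappa)

#' Assemble a MetricsReport from a confusion matrix
#'
#' @param cm square confusion matrix (rows = truth, columns = prediction)
#' @param curves optional data.frame of per-epoch diagnostics
#' @param lossDelta optional data.frame of loss-difference diagnostics
#' @return a [MetricsReport-class]
#' @export
metricsReport <- function(cm, curves = NULL, lossDelta = NULL) {
    cm <- checkConfusion(cm)
    new("MetricsReport", confusion = cm, accuracy = accuracy(cm),
        macroF1 = macroF1(cm), kappa = cohenKappa(cm),
        curves = curves %||% data.frame(),
        lossDelta = lossDelta %||% data.frame())
}
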