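#' @include scoring.R
NULL

#' Construct a confusion matrix
#'
#' @param tp,fn,fp,tn cell counts: rows are the final (pathology)
#'   diagnosis, columns the discriminant result, so `fn` is a truly
#'   positive patient the discriminant called negative.
#' @return a [ConfusionMatrix-class].
#' @examples
#' ConfusionMatrix(tp = 129, fn = 68, fp = 47, tn = 168)
#' @export
ConfusionMatrix <- function(tp, fn, fp, tn) {
    methods::new("ConfusionMatrix", tp = as.integer(tp), fn = as.integer(fn),
                 fp = as.integer(fp), tn = as.integer(tn))
}

setMethod("show", "ConfusionMatrix", function(object) {
    m <- as.matrix(object)
    cat("ConfusionMatrix (rows = final diagnosis, cols = discriminant)\n")
    print(m)
})

#' @describeIn ConfusionMatrix-class 2x2 integer matrix, rows = final
#'   diagnosis (+/-), columns = discriminant result (+/-).
#' @export
setMethod("as.matrix", "ConfusionMatrix", function(x, ...) {
    matrix(c(x@tp, x@fp, x@fn, x@tn), 2L, 2L,
           dimnames = list(diagnosis = c("+", "-"),
                           discriminant = c("+", "-")))
})

#' Tabulate predictions against true diagnoses
#'
#' @param truths,predictions equal-length vectors of class labels
#'   (`"positive"`/`"negative"`, `"+"`/`"-"` also accepted).
#' @return a [ConfusionMatrix-class] whose four cells partition the cohort.
#' @examples
#' buildConfusion(c("+", "+", "-"), c("+", "-", "-"))
#' @export
buildConfusion <- function(truths, predictions) {
    if (length(truths) == 0L)
        stop("empty input", call. = FALSE)
    if (length(truths) != length(predictions))
        stop("truths and predictions differ in length", call. = FALSE)
    tr <- normalizeClassLabel(truths)
    pr <- normalizeClassLabel(predictions)
    ConfusionMatrix(tp = sum(tr == "positive" & pr == "positive"),
                    fn = sum(tr == "positive" & pr == "negative"),
                    fp = sum(tr == "negative" & pr == "positive"),
                    tn = sum(tr == "negative" & pr == "negative"))
}

#' Coincidence rates of a confusion matrix
#'
#' Per-class agreement between discriminant result and final diagnosis:
#' the positive coincidence rate is 100 * tp / (tp + fn), the negative one
#' 100 * tn / (fp + tn), and the mean coincidence rate is their unweighted
#' average (macro / balanced accuracy). Overall accuracy
#' 100 * (tp + tn) / n is reported alongside; with unbalanced classes it
#' differs from the mean rate.
#'
#' @param x a [ConfusionMatrix-class] with at least one patient in each
#'   true class.
#' @return a [CoincidenceReport-class]; rates in percent at full precision
#'   (display rounds to 1 dp).
#' @examples
#' coincidenceRates(ConfusionMatrix(129, 68, 47, 168))
#' @export
setMethod("coincidenceRates", "ConfusionMatrix", function(x) {
    nPos <- x@tp + x@fn
    nNeg <- x@fp + x@tn
    if (nPos == 0L || nNeg == 0L)
        stop("undefined per-class rate: a true class is empty",
             call. = FALSE)
    rp <- 100 * x@tp / nPos
    rn <- 100 * x@tn / nNeg
    methods::new("CoincidenceReport",
                 ratePositive = rp, rateNegative = rn,
                 rateMean = (rp + rn) / 2,
                 accuracy = 100 * (x@tp + x@tn) / (nPos + nNeg),
                 cohortSize = as.integer(nPos + nNeg))
})

setMethod("show", "CoincidenceReport", function(object) {
    cat(sprintf(
        paste0("CoincidenceReport (n = %d)\n",
               "  positive rate: %s%%\n  negative rate: %s%%\n",
               "  mean rate:     %s%%\n  accuracy:      %s%%\n"),
        object@cohortSize, fmtFixed(object@ratePositive),
        fmtFixed(object@rateNegative), fmtFixed(object@rateMean),
        fmtFixed(object@accuracy)))
})

#' @describeIn CoincidenceReport-class flatten to a named numeric vector
#'   (`ratePositive`, `rateNegative`, `rateMean`, `accuracy`,
#'   `cohortSize`), convenient for serialization.
#' @export
setMethod("as.numeric", "CoincidenceReport", function(x, ...) {
    c(ratePositive = x@ratePositive, rateNegative = x@rateNegative,
      rateMean = x@rateMean, accuracy = x@accuracy,
      cohortSize = as.numeric(x@cohortSize))
})
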