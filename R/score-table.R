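#' @include frequency-table.R
NULL

#' Fit the discriminant score table from class-conditional frequencies
#'
#' Applies the score transform s = (log10 P + 1) x 10 to every conditional
#' frequency P(category | class) of the table, at full floating precision.
#' P = 1 maps to 10 score points, P = 0.1 to 0, and P < 0.1 to negative
#' scores. The transform is strictly increasing in P, so ranking by score
#' is ranking by likelihood.
#'
#' A zero count makes log10 undefined; by default it is a hard error
#' naming the offending cell. Supplying `smoothing` = a > 0 replaces
#' P with (count + a) / (total + a * nCategories) (additive smoothing per
#' factor block), which both removes zeros and perturbs non-zero cells
#' continuously: as a -> 0 the smoothed scores converge to the unsmoothed
#' ones.
#'
#' @param x a [FrequencyTable-class].
#' @param smoothing optional additive constant a >= 0 applied to counts.
#' @return a [ScoreTable-class] over the same scheme.
#' @examples
#' fitScoreTable(ptcFrequencyTable())
#' @export
setMethod("fitScoreTable", "FrequencyTable", function(x, smoothing = NULL) {
    p <- condFreqFrame(x, smoothing)
    for (g in classLevels()) {
        zero <- p[[g]] == 0
        if (any(zero)) {
            i <- which(zero)[1L]
            stop(sprintf(
                "log of zero probability at (%s, %s, %s); supply smoothing",
                p$factor[i], p$category[i], g), call. = FALSE)
        }
        p[[g]] <- (log10(p[[g]]) + 1) * 10
    }
    methods::new("ScoreTable", scheme = x@scheme, scores = p)
})

#' Construct a score table from given scores
#'
#' Wraps externally supplied per-category scores (e.g. a published table
#' read back from disk) in a [ScoreTable-class] without refitting.
#'
#' @param scores data.frame with columns `factor`, `category`, `positive`,
#'   `negative`.
#' @param scheme optional [RiskFactorScheme-class]; derived from row order
#'   when omitted.
#' @return a [ScoreTable-class].
#' @export
ScoreTable <- function(scores, scheme = NULL) {
    stopifnot(is.data.frame(scores))
    scores <- data.frame(factor = as.character(scores$factor),
                         category = as.character(scores$category),
                         positive = as.numeric(scores$positive),
                         negative = as.numeric(scores$negative),
                         stringsAsFactors = FALSE)
    if (is.null(scheme)) {
        fs <- lapply(unique(scores$factor), function(f) {
            list(name = f, categories = scores$category[scores$factor == f])
        })
        scheme <- RiskFactorScheme(fs)
    }
    methods::new("ScoreTable", scheme = scheme, scores = scores)
}

#' @rdname ScoreTable-class
#' @export
setMethod("scores", "ScoreTable", function(x) x@scores)

#' @rdname ScoreTable-class
#' @export
setMethod("scheme", "ScoreTable", function(x) x@scheme)

#' @rdname ScoreTable-class
#' @export
setMethod("factorNames", "ScoreTable", function(x) factorNames(x@scheme))

#' @rdname ScoreTable-class
#' @export
setMethod("categories", "ScoreTable",
          function(x, factor = NULL) categories(x@scheme, factor))

setMethod("show", "ScoreTable", function(object) {
    cat(sprintf("ScoreTable: %d factors, %d categories (1-dp display)\n",
                length(factorNames(object)), nrow(object@scores)))
    disp <- object@scores
    disp$positive <- fmtFixed(disp$positive)
    disp$negative <- fmtFixed(disp$negative)
    print(disp, row.names = FALSE)
})

#' Round a score table to display precision
#'
#' Returns a copy with both score columns rounded to `digits` decimals —
#' the form in which published score tables are printed and the form in
#' which the reference scoring sums its per-factor scores (see
#' [scorePatients()] `precision = "display"`).
#'
#' @param x a [ScoreTable-class].
#' @param digits decimal places (default 1).
#' @param mode rounding convention, see [roundDisplay()].
#' @return a [ScoreTable-class] with rounded scores.
#' @export
displayScores <- function(x, digits = 1, mode = "half-up") {
    stopifnot(methods::is(x, "ScoreTable"))
    s <- x@scores
    s$positive <- roundDisplay(s$positive, digits, mode)
    s$negative <- roundDisplay(s$negative, digits, mode)
    methods::new("ScoreTable", scheme = x@scheme, scores = s)
}
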