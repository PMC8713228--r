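#' @include AllGenerics.R
NULL

#' Risk-factor scheme
#'
#' An ordered collection of categorical clinical risk factors. Each factor
#' has a name, an ordered set of category labels, and optionally a binning
#' rule that maps a raw attribute (age in years, tumor diameter in cm, a
#' flag, a location code) onto exactly one category. The bundled
#' papillary-thyroid-cancer scheme ([ptcScheme()]) carries six factors —
#' sex, age, tumor diameter (TD), capsular invasion (CI), multifocality,
#' and tumor location (TL) — with 17 categories in total.
#'
#' @slot factors named list; each element is a list with components
#'   `name` (character), `categories` (character vector, length >= 2,
#'   unique), and `bin` (a vectorized function raw -> category label, or
#'   `NULL` when the factor is only ever supplied pre-binned).
#'
#' @param x a `RiskFactorScheme` (or an object carrying one).
#' @param factor optional factor name; if supplied, `categories()` returns
#'   that factor's labels, otherwise a named list of all of them.
#' @seealso [ptcScheme()], [binPatients()]
#' @aliases factorNames categories scheme
#' @export
setClass("RiskFactorScheme", representation(factors = "list"))

setValidity("RiskFactorScheme", function(object) {
    fs <- object@factors
    if (length(fs) < 1L)
        return("scheme must contain at least one factor")
    nms <- unname(vapply(fs, function(f) f$name %||% NA_character_,
                         character(1)))
    if (anyNA(nms) || anyDuplicated(nms))
        return("factor names must be present and unique")
    if (!identical(names(fs), nms))
        return("list names must equal the factors' own names")
    for (f in fs) {
        if (length(f$categories) < 2L)
            return(sprintf("factor '%s' needs at least 2 categories", f$name))
        if (anyDuplicated(f$categories))
            return(sprintf("duplicate category labels in factor '%s'", f$name))
        if (!is.null(f$bin) && !is.function(f$bin))
            return(sprintf("bin rule of '%s' must be a function or NULL",
                           f$name))
    }
    TRUE
})

#' Class-conditional frequency table
#'
#' Counts of patients per (factor, category, metastasis class). The class
#' totals N_positive and N_negative are a slot of their own and every
#' factor's column block must sum to them — a misaligned block is rejected
#' at construction. Conditional frequencies
#' P(category | class) = count / class total are the quantities the score
#' transform acts on.
#'
#' @slot scheme the [RiskFactorScheme-class] the rows follow, in order.
#' @slot counts data.frame with columns `factor`, `category`, `positive`,
#'   `negative` (non-negative integer counts), one row per category.
#' @slot classTotals named numeric of length 2 (`positive`, `negative`),
#'   both strictly positive.
#'
#' @param x a `FrequencyTable`.
#' @seealso [FrequencyTable()], [conditionalFrequency()], [fitScoreTable()],
#'   [ptcFrequencyTable()]
#' @aliases classTotals counts
#' @export
setClass("FrequencyTable",
    representation(scheme = "RiskFactorScheme", counts = "data.frame",
                   classTotals = "numeric"))

setValidity("FrequencyTable", function(object) {
    ct <- object@counts
    need <- c("factor", "category", "positive", "negative")
    if (!all(need %in% names(ct)))
        return(paste("counts needs columns", paste(need, collapse = ", ")))
    for (g in classLevels()) {
        v <- ct[[g]]
        if (any(!is.finite(v)) || any(v < 0) || any(v != floor(v)))
            return(sprintf("'%s' counts must be non-negative integers", g))
    }
    tot <- object@classTotals
    if (!identical(names(tot), classLevels()) || any(tot <= 0))
        return("classTotals must be named positive values (positive, negative)")
    sc <- object@scheme
    for (f in factorNames(sc)) {
        rows <- ct[ct$factor == f, , drop = FALSE]
        if (!identical(rows$category, categories(sc, f)))
            return(sprintf(
                "rows of factor '%s' must match the scheme's categories", f))
        for (g in classLevels())
            if (sum(rows[[g]]) != tot[[g]])
                return(sprintf(
                    "factor '%s' %s counts sum to %d, expected class total %d",
                    f, g, sum(rows[[g]]), as.integer(tot[[g]])))
    }
    TRUE
})

#' Per-category discriminant score table
#'
#' Additive scores s = (log10 P + 1) x 10 per (factor, category, class),
#' stored at full floating precision; one decimal place is the display
#' precision used when printing or serializing. A score of exactly 10
#' corresponds to P = 1, exactly 0 to P = 0.1, and negative scores to
#' P < 0.1.
#'
#' @slot scheme the [RiskFactorScheme-class] the rows follow.
#' @slot scores data.frame with columns `factor`, `category`, `positive`,
#'   `negative` (numeric scores).
#'
#' @param x a `ScoreTable`.
#' @seealso [fitScoreTable()], [scorePatients()], [ptcScoreTable()]
#' @aliases scores
#' @export
setClass("ScoreTable",
    representation(scheme = "RiskFactorScheme", scores = "data.frame"))

setValidity("ScoreTable", function(object) {
    sc <- object@scores
    need <- c("factor", "category", "positive", "negative")
    if (!all(need %in% names(sc)))
        return(paste("scores needs columns", paste(need, collapse = ", ")))
    if (!is.numeric(sc$positive) || !is.numeric(sc$negative))
        return("score columns must be numeric")
    for (f in factorNames(object@scheme)) {
        rows <- sc[sc$factor == f, , drop = FALSE]
        if (!identical(rows$category, categories(object@scheme, f)))
            return(sprintf(
                "rows of factor '%s' must match the scheme's categories", f))
    }
    TRUE
})

#' Confusion matrix of discriminant results against final diagnosis
#'
#' A 2x2 table with rows indexed by the final (pathology) diagnosis and
#' columns by the discriminant prediction.
#'
#' @slot tp,fn,fp,tn non-negative integer cell counts: true positives,
#'   false negatives, false positives, true negatives.
#' @param x a `ConfusionMatrix`.
#' @seealso [buildConfusion()], [coincidenceRates()]
#' @export
setClass("ConfusionMatrix",
    representation(tp = "integer", fn = "integer",
                   fp = "integer", tn = "integer"))

setValidity("ConfusionMatrix", function(object) {
    v <- c(object@tp, object@fn, object@fp, object@tn)
    if (length(v) != 4L || anyNA(v) || any(v < 0L))
        return("all four cells must be single non-negative integers")
    TRUE
})

#' Coincidence-rate report
#'
#' Per-class agreement between discriminant prediction and final diagnosis,
#' in percent. `rateMean` is the unweighted (macro) average of the two
#' per-class rates — the headline "mean coincidence rate" — which differs
#' from `accuracy`, the overall fraction of correct calls, whenever the two
#' classes are unbalanced.
#'
#' @slot ratePositive percent of true positives called positive.
#' @slot rateNegative percent of true negatives called negative.
#' @slot rateMean unweighted mean of the two per-class rates (percent).
#' @slot accuracy overall percent correct.
#' @slot cohortSize total number of patients.
#' @param x a `CoincidenceReport`.
#' @seealso [coincidenceRates()]
#' @export
setClass("CoincidenceReport",
    representation(ratePositive = "numeric", rateNegative = "numeric",
                   rateMean = "numeric", accuracy = "numeric",
                   cohortSize = "integer"))

#' Generative specification for a synthetic cohort
#'
#' Bundles everything [generateCohort()] needs: the frequency table whose
#' conditional frequencies act as the class-conditional sampling
#' distributions, the positive-class prevalence, the cohort size, and the
#' seed. Factors are drawn independently within each class — exactly the
#' assumption the product-form discriminant makes.
#'
#' @slot table a [FrequencyTable-class] (source of sampling probabilities).
#' @slot prevalence probability of the positive class, in (0, 1).
#' @slot n cohort size (>= 1).
#' @slot seed integer seed; the cohort is a pure function of the spec.
#' @param x a `CohortSpec`.
#' @seealso [CohortSpec()], [generateCohort()]
#' @export
setClass("CohortSpec",
    representation(table = "FrequencyTable", prevalence = "numeric",
                   n = "integer", seed = "integer"))

setValidity("CohortSpec", function(object) {
    p <- object@prevalence
    if (length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1)
        return("prevalence must be a single value in (0, 1)")
    if (length(object@n) != 1L || is.na(object@n) || object@n < 1L)
        return("cohort size n must be a single integer >= 1")
    if (length(object@seed) != 1L || is.na(object@seed))
        return("seed must be a single integer")
    TRUE
})

#' Exact expected performance of the discriminant
#'
#' Result of [enumerateExpectedPerformance()]: expected confusion
#' proportions and coincidence rates under the generative model, obtained
#' by exhaustive enumeration of every category combination (no sampling).
#'
#' @slot proportions 2x2 numeric matrix of joint probabilities, rows =
#'   true class, columns = predicted class; sums to 1.
#' @slot ratePositive,rateNegative,rateMean,accuracy expected rates in
#'   percent, defined as in [CoincidenceReport-class].
#' @slot nProfiles number of category combinations enumerated.
#' @param x an `ExpectedPerformance`.
#' @export
setClass("ExpectedPerformance",
    representation(proportions = "matrix", ratePositive = "numeric",
                   rateNegative = "numeric", rateMean = "numeric",
                   accuracy = "numeric", nProfiles = "integer"))

`%||%` <- function(a, b) if (is.null(a)) b else a
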