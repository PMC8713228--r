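#' @include utils.R
NULL

#' @rdname RiskFactorScheme-class
#' @export
setGeneric("factorNames", function(x) standardGeneric("factorNames"))

#' @rdname RiskFactorScheme-class
#' @export
setGeneric("categories", function(x, factor = NULL)
    standardGeneric("categories"))

#' @rdname RiskFactorScheme-class
#' @export
setGeneric("scheme", function(x) standardGeneric("scheme"))

#' @rdname FrequencyTable-class
#' @export
setGeneric("classTotals", function(x) standardGeneric("classTotals"))

#' @rdname FrequencyTable-class
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' @rdname ScoreTable-class
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname conditionalFrequency
#' @export
setGeneric("conditionalFrequency", function(x, factor, category, class)
    standardGeneric("conditionalFrequency"))

#' @rdname fitScoreTable
#' @export
setGeneric("fitScoreTable", function(x, smoothing = NULL)
    standardGeneric("fitScoreTable"))

#' @rdname coincidenceRates
#' @export
setGeneric("coincidenceRates", function(x) standardGeneric("coincidenceRates"))

#' @rdname generateCohort
#' @export
setGeneric("generateCohort", function(x, ...) standardGeneric("generateCohort"))
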