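#' @include scheme.R
NULL

#' Construct a class-conditional frequency table
#'
#' @param counts data.frame with columns `factor`, `category`, `positive`,
#'   `negative` holding non-negative integer counts, rows grouped by factor
#'   in scheme order.
#' @param scheme optional [RiskFactorScheme-class]; when omitted, a scheme
#'   without binning rules is derived from the row order of `counts`.
#' @return a validated [FrequencyTable-class]. Class totals are derived by
#'   summation within each factor block and must agree across blocks.
#' @examples
#' tab <- FrequencyTable(data.frame(
#'     factor = c("Sex", "Sex"), category = c("Female", "Male"),
#'     positive = c(144L, 53L), negative = c(178L, 37L)))
#' classTotals(tab)
#' @export
FrequencyTable <- function(counts, scheme = NULL) {
    stopifnot(is.data.frame(counts))
    counts <- data.frame(factor = as.character(counts$factor),
                         category = as.character(counts$category),
                         positive = as.numeric(counts$positive),
                         negative = as.numeric(counts$negative),
                         stringsAsFactors = FALSE)
    if (is.null(scheme)) {
        fs <- lapply(unique(counts$factor), function(f) {
            list(name = f, categories = counts$category[counts$factor == f])
        })
        scheme <- RiskFactorScheme(fs)
    }
    tot <- vapply(classLevels(), function(g) {
        per <- tapply(counts[[g]], counts$factor, sum)
        if (length(unique(per)) != 1L)
            stop(sprintf(
                "inconsistent factor-block totals for class '%s': %s", g,
                paste(names(per), per, sep = "=", collapse = ", ")),
                call. = FALSE)
        per[[1L]]
    }, numeric(1))
    methods::new("FrequencyTable", scheme = scheme, counts = counts,
                 classTotals = tot)
}

#' @rdname FrequencyTable-class
#' @export
setMethod("classTotals", "FrequencyTable", function(x) x@classTotals)

#' @rdname FrequencyTable-class
#' @export
setMethod("counts", "FrequencyTable", function(x) x@counts)

#' @rdname FrequencyTable-class
#' @export
setMethod("scheme", "FrequencyTable", function(x) x@scheme)

#' @rdname FrequencyTable-class
#' @export
setMethod("factorNames", "FrequencyTable",
          function(x) factorNames(x@scheme))

#' @rdname FrequencyTable-class
#' @export
setMethod("categories", "FrequencyTable",
          function(x, factor = NULL) categories(x@scheme, factor))

setMethod("show", "FrequencyTable", function(object) {
    tot <- object@classTotals
    cat(sprintf(
        "FrequencyTable: %d factors, %d categories; N+ = %d, N- = %d\n",
        length(factorNames(object)), nrow(object@counts),
        as.integer(tot[["positive"]]), as.integer(tot[["negative"]])))
    print(object@counts, row.names = FALSE)
})

#' Class-conditional frequency of one cell
#'
#' Returns P(category | class) = count / class total for one
#' (factor, category, class) cell.
#'
#' @param x a [FrequencyTable-class].
#' @param factor,category cell coordinates (labels).
#' @param class `"positive"` or `"negative"` (or `"+"`/`"-"`).
#' @return a probability in `[0, 1]`.
#' @examples
#' conditionalFrequency(ptcFrequencyTable(), "Sex", "Male", "positive")
#' @export
setMethod("conditionalFrequency", "FrequencyTable",
    function(x, factor, category, class) {
        class <- normalizeClassLabel(class)
        row <- x@counts$factor == factor & x@counts$category == category
        if (sum(row) != 1L)
            stop(sprintf("no such cell: (%s, %s)", factor, category),
                 call. = FALSE)
        x@counts[[class]][row] / x@classTotals[[class]]
    })

## per-class conditional-frequency columns as a data.frame keyed like
## counts(); internal workhorse for scoring, enumeration and generation
condFreqFrame <- function(x, smoothing = NULL) {
    ct <- x@counts
    out <- ct[c("factor", "category")]
    for (g in classLevels()) {
        n <- ct[[g]]
        tot <- x@classTotals[[g]]
        if (!is.null(smoothing)) {
            stopifnot(is.numeric(smoothing), smoothing >= 0)
            nCat <- ave(n, ct$factor, FUN = length)
            out[[g]] <- (n + smoothing) / (tot + smoothing * nCat)
        } else {
            out[[g]] <- n / tot
        }
    }
    out
}

#' Per-category metastasis rates within one factor
#'
#' For each category j of a factor, the percentage of patients in that
#' category whose central-compartment nodes were positive:
#' 100 * n(j, positive) / (n(j, positive) + n(j, negative)). A category
#' with no patients at all yields `NA`. These are cohort rates (they mix
#' the two class-conditional columns), not conditional frequencies.
#'
#' @param table a [FrequencyTable-class].
#' @param factor factor name.
#' @return named numeric vector of percentages, one per category.
#' @examples
#' derivedRates(ptcFrequencyTable(), "TL")
#' @export
derivedRates <- function(table, factor) {
    stopifnot(methods::is(table, "FrequencyTable"))
    ct <- counts(table)
    rows <- ct[ct$factor == factor, , drop = FALSE]
    if (nrow(rows) == 0L)
        stop("unknown factor: ", factor, call. = FALSE)
    tot <- rows$positive + rows$negative
    r <- ifelse(tot > 0, 100 * rows$positive / tot, NA_real_)
    stats::setNames(r, rows$category)
}

#' Whole-cohort metastatic rate
#'
#' 100 * N_positive / (N_positive + N_negative) for the cohort behind a
#' frequency table.
#'
#' @param table a [FrequencyTable-class].
#' @return percentage in `[0, 100]`.
#' @examples
#' metastaticRate(ptcFrequencyTable())  # 47.8 at 1 dp
#' @export
metastaticRate <- function(table) {
    stopifnot(methods::is(table, "FrequencyTable"))
    tot <- classTotals(table)
    100 * tot[["positive"]] / sum(tot)
}
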