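#' @include evaluation.R
NULL

#' Construct a cohort-generation specification
#'
#' @param table a [FrequencyTable-class]; its conditional frequencies are
#'   the class-conditional category distributions patients are drawn from.
#' @param prevalence positive-class probability in (0, 1). The default
#'   197/412 is the retrospective reference prevalence; 41/104 is the
#'   prospective alternative.
#' @param n cohort size.
#' @param seed integer seed; cohorts are byte-identical given the same
#'   spec.
#' @return a validated [CohortSpec-class].
#' @examples
#' CohortSpec(ptcFrequencyTable(), n = 100, seed = 1)
#' @export
CohortSpec <- function(table, prevalence = 197 / 412, n, seed) {
    stopifnot(methods::is(table, "FrequencyTable"))
    methods::new("CohortSpec", table = table,
                 prevalence = as.numeric(prevalence),
                 n = as.integer(n), seed = as.integer(seed))
}

setMethod("show", "CohortSpec", function(object) {
    cat(sprintf(
        "CohortSpec: n = %d, prevalence = %.4f, seed = %d, %d factors\n",
        object@n, object@prevalence, object@seed,
        length(factorNames(object@table))))
})

#' Generate a synthetic patient cohort
#'
#' Draws `n` patients from the generative model the discriminant assumes:
#' the true class first, Bernoulli(prevalence); then, within each class,
#' one category per factor independently from that class's conditional
#' frequencies, factors in scheme order. The draw order (labels, then
#' factors in scheme order) is part of the reproducibility contract —
#' identical specs give byte-identical cohorts. The caller's RNG state is
#' left untouched.
#'
#' @param x a [CohortSpec-class], or a [FrequencyTable-class] together
#'   with `prevalence`, `n`, `seed` passed on to [CohortSpec()].
#' @param ... arguments forwarded to [CohortSpec()] when `x` is a
#'   frequency table.
#' @return data.frame with columns `patient_id`, one column per factor
#'   (category labels), and `true_class` (`"positive"`/`"negative"`).
#' @examples
#' head(generateCohort(ptcFrequencyTable(), n = 5, seed = 42))
#' @export
setMethod("generateCohort", "CohortSpec", function(x, ...) {
    tab <- x@table
    sch <- scheme(tab)
    p <- condFreqFrame(tab)
    withLocalSeed(x@seed, {
        lab <- ifelse(stats::runif(x@n) < x@prevalence,
                      "positive", "negative")
        out <- data.frame(patient_id = sprintf("P%05d", seq_len(x@n)),
                          stringsAsFactors = FALSE)
        for (f in factorNames(sch)) {
            rows <- p[p$factor == f, , drop = FALSE]
            v <- character(x@n)
            for (g in classLevels()) {
                sel <- lab == g
                if (any(sel))
                    v[sel] <- sample(rows$category, sum(sel),
                                     replace = TRUE, prob = rows[[g]])
            }
            out[[f]] <- v
        }
        out$true_class <- lab
        out
    })
})

#' @rdname generateCohort
#' @export
setMethod("generateCohort", "FrequencyTable", function(x, ...) {
    generateCohort(CohortSpec(x, ...))
})

#' Tabulate a cohort back into a frequency table
#'
#' Counts patients per (factor, category, class), closing the
#' fit -> simulate -> refit loop: on a large cohort generated from a
#' table, the recovered conditional frequencies converge to the
#' generating ones and refitted scores to the generating scores.
#'
#' @param cohort data.frame of category labels, one column per factor
#'   (e.g. from [generateCohort()]).
#' @param labels class labels per patient; defaults to the cohort's
#'   `true_class` column when present.
#' @param scheme the [RiskFactorScheme-class] to tabulate against.
#' @return a [FrequencyTable-class]. Both classes must be represented.
#' @examples
#' co <- generateCohort(ptcFrequencyTable(), n = 500, seed = 7)
#' recoverFrequencies(co, scheme = ptcScheme())
#' @export
recoverFrequencies <- function(cohort, labels = cohort$true_class, scheme) {
    stopifnot(is.data.frame(cohort), nrow(cohort) > 0L)
    lab <- normalizeClassLabel(labels)
    if (length(lab) != nrow(cohort))
        stop("labels length must match the cohort", call. = FALSE)
    missing <- setdiff(classLevels(), unique(lab))
    if (length(missing))
        stop("class absent from labels: ", missing[1L], call. = FALSE)
    validateProfiles(cohort, scheme)
    rows <- do.call(rbind, lapply(factorNames(scheme), function(f) {
        cats <- categories(scheme, f)
        pos <- table(base::factor(cohort[[f]][lab == "positive"],
                                  levels = cats))
        neg <- table(base::factor(cohort[[f]][lab == "negative"],
                                  levels = cats))
        data.frame(factor = f, category = cats,
                   positive = as.integer(pos), negative = as.integer(neg),
                   stringsAsFactors = FALSE)
    }))
    FrequencyTable(rows, scheme)
}

#' Exact expected performance by exhaustive enumeration
#'
#' Iterates every category combination of the scheme (320 for the bundled
#' six-factor scheme), computes its probability under each class as the
#' product of conditional frequencies, classifies it with the score table,
#' and accumulates the exact expected confusion proportions and
#' coincidence rates under the generative model
#' (class ~ Bernoulli(prevalence), factors independent given class). No
#' sampling is involved; this is the oracle [generateCohort()] cohorts
#' converge to.
#'
#' @param table a [FrequencyTable-class] with strictly positive cells.
#' @param scores a [ScoreTable-class] over the same scheme.
#' @param prevalence positive-class probability (default 197/412).
#' @param tiePolicy,precision passed to [scorePatients()].
#' @param maxProfiles refuse to enumerate more than this many
#'   combinations (default 1e6).
#' @return an [ExpectedPerformance-class].
#' @examples
#' tab <- ptcFrequencyTable()
#' enumerateExpectedPerformance(tab, fitScoreTable(tab))
#' @export
enumerateExpectedPerformance <- function(table, scores,
                                         prevalence = 197 / 412,
                                         tiePolicy = "positive",
                                         precision = "display",
                                         maxProfiles = 1e6) {
    stopifnot(methods::is(table, "FrequencyTable"),
              methods::is(scores, "ScoreTable"),
              prevalence > 0, prevalence < 1)
    sch <- scheme(table)
    sizes <- lengths(categories(sch))
    nProf <- prod(sizes)
    if (nProf > maxProfiles)
        stop(sprintf(
            "refusing to enumerate %.0f category combinations (cap %g)",
            nProf, maxProfiles), call. = FALSE)
    grid <- do.call(expand.grid,
                    c(categories(sch),
                      list(KEEP.OUT.ATTRS = FALSE,
                           stringsAsFactors = FALSE)))
    names(grid) <- factorNames(sch)
    p <- condFreqFrame(table)
    pPos <- rep(1, nProf)
    pNeg <- rep(1, nProf)
    for (f in factorNames(sch)) {
        rows <- p[p$factor == f, , drop = FALSE]
        idx <- match(grid[[f]], rows$category)
        pPos <- pPos * rows$positive[idx]
        pNeg <- pNeg * rows$negative[idx]
    }
    if (any(pPos == 0) || any(pNeg == 0))
        stop("enumeration requires strictly positive conditional ",
             "frequencies", call. = FALSE)
    pred <- scorePatients(grid, scores, tiePolicy = tiePolicy,
                          precision = precision)$predicted
    callPos <- pred == "positive"
    rp <- sum(pPos[callPos])          # P(call + | true +)
    rn <- sum(pNeg[!callPos])         # P(call - | true -)
    prop <- matrix(c(prevalence * rp, (1 - prevalence) * (1 - rn),
                     prevalence * (1 - rp), (1 - prevalence) * rn),
                   2L, 2L,
                   dimnames = list(truth = c("+", "-"),
                                   predicted = c("+", "-")))
    methods::new("ExpectedPerformance", proportions = prop,
                 ratePositive = 100 * rp, rateNegative = 100 * rn,
                 rateMean = 100 * (rp + rn) / 2,
                 accuracy = 100 * (prevalence * rp +
                                   (1 - prevalence) * rn),
                 nProfiles = as.integer(nProf))
}

setMethod("show", "ExpectedPerformance", function(object) {
    cat(sprintf(
        paste0("ExpectedPerformance over %d profiles\n",
               "  E[positive rate]: %s%%\n  E[negative rate]: %s%%\n",
               "  E[mean rate]:     %s%%\n  E[accuracy]:      %s%%\n"),
        object@nProfiles, fmtFixed(object@ratePositive),
        fmtFixed(object@rateNegative), fmtFixed(object@rateMean),
        fmtFixed(object@accuracy)))
})
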