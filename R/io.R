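#' @include synthetic.R
NULL

## all delimited formats are UTF-8, comma-separated, header mandatory
readCsvUtf8 <- function(path, expectedHeader) {
    if (!file.exists(path))
        stop("file not found: ", path, call. = FALSE)
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    if (length(lines) == 0L || !nzchar(lines[1L]))
        stop("parse error at line 1: empty file (", path, ")",
             call. = FALSE)
    header <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
    if (!identical(header, expectedHeader))
        stop(sprintf("parse error at line 1: header is '%s', expected '%s'",
                     lines[1L], paste(expectedHeader, collapse = ",")),
             call. = FALSE)
    df <- utils::read.csv(text = lines, stringsAsFactors = FALSE,
                          check.names = FALSE)
    names(df) <- expectedHeader
    df
}

writeCsvUtf8 <- function(lines, path) {
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(lines, con)
    invisible(path)
}

#' Read / write class-conditional frequency tables
#'
#' Format: UTF-8 CSV with header
#' `factor,category,count_positive,count_negative`, one row per category,
#' rows grouped by factor. Class totals are derived by summation and
#' cross-checked across factor blocks; a block summing differently is a
#' parse error with the offending factor named.
#'
#' @param path file path.
#' @param scheme optional [RiskFactorScheme-class] to attach (e.g.
#'   [ptcScheme()] so binning rules travel with the table); derived from
#'   the file when omitted.
#' @return `readFrequencyTable()` a [FrequencyTable-class];
#'   `writeFrequencyTable()` the path, invisibly. Writing then reading is
#'   lossless and byte-identical.
#' @examples
#' tab <- ptcFrequencyTable()
#' f <- tempfile(fileext = ".csv")
#' writeFrequencyTable(tab, f)
#' identical(counts(readFrequencyTable(f)), counts(tab))
#' @export
readFrequencyTable <- function(path, scheme = NULL) {
    df <- readCsvUtf8(path, c("factor", "category",
                              "count_positive", "count_negative"))
    for (col in c("count_positive", "count_negative")) {
        v <- df[[col]]
        if (!is.numeric(v) || any(is.na(v)) || any(v != floor(v)))
            stop(sprintf(
                "parse error at line %d: non-integer %s",
                which(is.na(v) | v != floor(v))[1L] + 1L, col),
                call. = FALSE)
    }
    names(df) <- c("factor", "category", "positive", "negative")
    tryCatch(FrequencyTable(df, scheme),
             error = function(e) stop("parse error in ", path, ": ",
                                      conditionMessage(e), call. = FALSE))
}

#' @rdname readFrequencyTable
#' @param x the [FrequencyTable-class] to serialize.
#' @export
writeFrequencyTable <- function(x, path) {
    stopifnot(methods::is(x, "FrequencyTable"))
    ct <- counts(x)
    writeCsvUtf8(c("factor,category,count_positive,count_negative",
                   sprintf("%s,%s,%d,%d", ct$factor, ct$category,
                           as.integer(ct$positive),
                           as.integer(ct$negative))),
                 path)
}

#' Read / write score tables
#'
#' Format: UTF-8 CSV with header
#' `factor,category,score_positive,score_negative`. `writeScoreTable()`
#' serializes at display precision (1 decimal, half-away-from-zero by
#' default); set `digits` higher (e.g. 12) for the full-precision
#' companion file the `fit` CLI subcommand writes alongside.
#'
#' @param path file path.
#' @param scheme optional [RiskFactorScheme-class]; derived from the file
#'   when omitted.
#' @return `readScoreTable()` a [ScoreTable-class]; `writeScoreTable()`
#'   the path, invisibly.
#' @examples
#' sc <- ptcScoreTable()
#' f <- tempfile(fileext = ".csv")
#' writeScoreTable(sc, f)
#' @export
readScoreTable <- function(path, scheme = NULL) {
    df <- readCsvUtf8(path, c("factor", "category",
                              "score_positive", "score_negative"))
    names(df) <- c("factor", "category", "positive", "negative")
    if (!is.numeric(df$positive) || !is.numeric(df$negative) ||
        anyNA(df$positive) || anyNA(df$negative))
        stop("parse error in ", path, ": non-numeric score", call. = FALSE)
    ScoreTable(df, scheme)
}

#' @rdname readScoreTable
#' @param x the [ScoreTable-class] to serialize.
#' @param digits decimal places written (default 1, the display precision).
#' @param mode rounding convention for display, see [roundDisplay()].
#' @export
writeScoreTable <- function(x, path, digits = 1, mode = "half-up") {
    stopifnot(methods::is(x, "ScoreTable"))
    sc <- scores(x)
    if (digits <= 6) {
        posTxt <- fmtFixed(sc$positive, digits, mode)
        negTxt <- fmtFixed(sc$negative, digits, mode)
    } else {
        posTxt <- formatC(sc$positive, format = "g", digits = digits)
        negTxt <- formatC(sc$negative, format = "g", digits = digits)
    }
    writeCsvUtf8(c("factor,category,score_positive,score_negative",
                   sprintf("%s,%s,%s,%s", sc$factor, sc$category,
                           posTxt, negTxt)),
                 path)
}

#' Read / write patient cohorts
#'
#' Format: UTF-8 CSV with header
#' `patient_id,<factor columns...>,true_class`; factor columns hold
#' category labels in scheme order and `true_class` is
#' `positive`/`negative`. Round-trips losslessly.
#'
#' @param path file path.
#' @param scheme the [RiskFactorScheme-class] naming the factor columns
#'   (default [ptcScheme()]).
#' @return `readCohort()` a data.frame as produced by [generateCohort()];
#'   `writeCohort()` the path, invisibly.
#' @export
readCohort <- function(path, scheme = ptcScheme()) {
    hdr <- c("patient_id", factorNames(scheme), "true_class")
    df <- readCsvUtf8(path, hdr)
    df$true_class <- normalizeClassLabel(df$true_class)
    validateProfiles(df, scheme)
    df
}

#' @rdname readCohort
#' @param cohort the cohort data.frame to serialize.
#' @export
writeCohort <- function(cohort, path, scheme = ptcScheme()) {
    hdr <- c("patient_id", factorNames(scheme), "true_class")
    stopifnot(all(hdr %in% names(cohort)))
    body <- do.call(paste, c(lapply(hdr, function(cn)
        as.character(cohort[[cn]])), list(sep = ",")))
    writeCsvUtf8(c(paste(hdr, collapse = ","), body), path)
}

#' Bundled reference tables
#'
#' `ptcFrequencyTable()` loads the bundled retrospective class-conditional
#' frequency table (412 papillary thyroid cancer patients: 197 with
#' central-compartment nodal metastasis, 215 without) with the
#' [ptcScheme()] binning rules attached. `ptcScoreTable()` loads the
#' corresponding published per-category score table at its printed 1-dp
#' precision; fitting from the frequency table with [fitScoreTable()] and
#' rounding to 1 decimal reproduces it cell for cell.
#'
#' @return a [FrequencyTable-class] / [ScoreTable-class].
#' @examples
#' classTotals(ptcFrequencyTable())  # 197, 215
#' @export
ptcFrequencyTable <- function() {
    readFrequencyTable(system.file("extdata", "tableI_frequencies.csv",
                                   package = "CLNMscore", mustWork = TRUE),
                       scheme = ptcScheme())
}

#' @rdname ptcFrequencyTable
#' @export
ptcScoreTable <- function() {
    readScoreTable(system.file("extdata", "tableII_scores.csv",
                               package = "CLNMscore", mustWork = TRUE),
                   scheme = ptcScheme())
}

#' Run configuration
#'
#' A validated flat list of run options shared by the command-line
#' interface: tie policy, smoothing constant, prior flag, rounding mode,
#' seed, cohort size, prevalence, verbosity. Serializes to and from a
#' plain `key = value` text file.
#'
#' @param tiePolicy `"positive"` or `"negative"`.
#' @param smoothing additive smoothing constant, `NA` to disable.
#' @param withPriors logical; add the prior term when scoring.
#' @param rounding `"half-up"` or `"half-even"`.
#' @param seed integer RNG seed.
#' @param n cohort size for simulation.
#' @param prevalence positive-class probability in (0, 1).
#' @param verbose logical.
#' @return a named list of class `clnm_run_config`.
#' @export
runConfig <- function(tiePolicy = "positive", smoothing = NA_real_,
                      withPriors = FALSE, rounding = "half-up",
                      seed = 1L, n = 1000L, prevalence = 197 / 412,
                      verbose = FALSE) {
    cfg <- list(tiePolicy = match.arg(tiePolicy, c("positive", "negative")),
                smoothing = as.numeric(smoothing),
                withPriors = isTRUE(withPriors),
                rounding = match.arg(rounding, c("half-up", "half-even")),
                seed = as.integer(seed), n = as.integer(n),
                prevalence = as.numeric(prevalence),
                verbose = isTRUE(verbose))
    if (!is.na(cfg$smoothing) && cfg$smoothing < 0)
        stop("smoothing must be >= 0", call. = FALSE)
    if (cfg$prevalence <= 0 || cfg$prevalence >= 1)
        stop("prevalence must lie in (0, 1)", call. = FALSE)
    if (cfg$n < 1L) stop("n must be >= 1", call. = FALSE)
    class(cfg) <- "clnm_run_config"
    cfg
}

#' @rdname runConfig
#' @param path file path of a `key = value` config file.
#' @export
readRunConfig <- function(path) {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    kv <- strsplit(lines, "=", fixed = TRUE)
    keys <- trimws(vapply(kv, `[`, character(1), 1L))
    vals <- trimws(vapply(kv, function(p)
        paste(p[-1L], collapse = "="), character(1)))
    args <- stats::setNames(as.list(vals), keys)
    for (k in c("smoothing", "prevalence"))
        if (k %in% keys) args[[k]] <- as.numeric(args[[k]])
    for (k in c("seed", "n"))
        if (k %in% keys) args[[k]] <- as.integer(args[[k]])
    for (k in c("withPriors", "verbose"))
        if (k %in% keys) args[[k]] <- toupper(args[[k]]) %in%
            c("TRUE", "T", "1", "YES")
    do.call(runConfig, args)
}

#' @rdname runConfig
#' @param config a `clnm_run_config` list to serialize.
#' @export
writeRunConfig <- function(config, path) {
    stopifnot(inherits(config, "clnm_run_config"))
    fmt <- function(v) {
        if (is.numeric(v) && !is.na(v) && v == floor(v) && !is.integer(v))
            return(format(v, digits = 15))
        if (is.numeric(v)) return(format(v, digits = 15))
        as.character(v)
    }
    writeCsvUtf8(sprintf("%s = %s", names(config),
                         vapply(config, fmt, character(1))),
                 path)
}
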