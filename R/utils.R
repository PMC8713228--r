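#' Round for display
#'
#' Rounds a numeric vector at a fixed number of decimal places using either
#' round-half-away-from-zero (the convention the bundled reference tables
#' were printed with) or IEEE round-half-to-even (base [round()]).
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 1, the display precision
#'   of score tables and percentages throughout the package).
#' @param mode `"half-up"` (half away from zero) or `"half-even"`.
#' @return numeric vector rounded at `digits` decimals.
#' @examples
#' roundDisplay(c(2.25, -2.25), 1)                 # 2.3, -2.3
#' roundDisplay(c(2.25, -2.25), 1, "half-even")    # 2.2, -2.2
#' @export
roundDisplay <- function(x, digits = 1, mode = c("half-up", "half-even")) {
    mode <- match.arg(mode)
    if (mode == "half-even") return(round(x, digits))
    m <- 10^digits
    sign(x) * floor(abs(x) * m + 0.5) / m
}

## fixed-point formatting at `digits` decimals after display rounding;
## used by all writers so serialized numbers match the rounding mode
fmtFixed <- function(x, digits = 1, mode = "half-up") {
    formatC(roundDisplay(x, digits, mode), format = "f", digits = digits)
}

## evaluate `code` under set.seed(seed) without disturbing the caller's
## RNG stream; the generator contract (label first, factors in scheme
## order) lives in generateCohort(), not here
withLocalSeed <- function(seed, code) {
    if (!is.null(seed)) {
        stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
        genv <- globalenv()
        if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
            old <- get(".Random.seed", envir = genv, inherits = FALSE)
            on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
        } else {
            on.exit(suppressWarnings(rm(".Random.seed", envir = genv)),
                    add = TRUE)
        }
        set.seed(as.integer(seed))
    }
    force(code)
}

## canonical two-level class vocabulary
classLevels <- function() c("positive", "negative")

## map "+", "-", "pos", "negative", ... onto the canonical labels
normalizeClassLabel <- function(x) {
    x0 <- trimws(as.character(x))
    out <- rep(NA_character_, length(x0))
    out[x0 %in% c("positive", "pos", "+", "1")] <- "positive"
    out[x0 %in% c("negative", "neg", "-", "\u2212", "2", "0")] <- "negative"
    if (anyNA(out) || anyNA(x0)) {
        bad <- unique(x0[is.na(out)])
        stop("unknown class label(s): ", paste(bad, collapse = ", "),
             " (expected 'positive'/'+' or 'negative'/'-')", call. = FALSE)
    }
    out
}

## short rolling hash of the factor/category structure, logged by the CLI
## so score runs are auditable against the scheme they used
schemeDigest <- function(scheme) {
    s <- paste(vapply(scheme@factors, function(f) {
        paste(f$name, paste(f$categories, collapse = "|"), sep = ":")
    }, character(1)), collapse = ";")
    h <- 0
    for (b in utf8ToInt(enc2utf8(s))) h <- (h * 31 + b) %% 2147483647
    sprintf("%08x", as.integer(h))
}
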