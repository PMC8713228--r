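#' @include AllClasses.R
NULL

#' Construct a risk-factor scheme
#'
#' @param factors a list of factor descriptors; each a list with `name`,
#'   `categories` and optionally `bin` (see [RiskFactorScheme-class]).
#' @return a validated [RiskFactorScheme-class].
#' @examples
#' RiskFactorScheme(list(
#'     list(name = "Sex", categories = c("Female", "Male")),
#'     list(name = "CI", categories = c("Y", "N"))))
#' @export
RiskFactorScheme <- function(factors) {
    factors <- lapply(factors, function(f) {
        list(name = as.character(f$name),
             categories = as.character(f$categories),
             bin = f$bin %||% NULL)
    })
    names(factors) <- vapply(factors, `[[`, character(1), "name")
    methods::new("RiskFactorScheme", factors = factors)
}

#' @rdname RiskFactorScheme-class
#' @export
setMethod("factorNames", "RiskFactorScheme", function(x) names(x@factors))

#' @rdname RiskFactorScheme-class
#' @export
setMethod("categories", "RiskFactorScheme", function(x, factor = NULL) {
    if (is.null(factor))
        return(lapply(x@factors, `[[`, "categories"))
    f <- x@factors[[factor]]
    if (is.null(f))
        stop("unknown factor: ", factor, call. = FALSE)
    f$categories
})

setMethod("show", "RiskFactorScheme", function(object) {
    cat(sprintf("RiskFactorScheme with %d factors (%d categories)\n",
                length(object@factors),
                sum(lengths(categories(object)))))
    for (f in object@factors)
        cat(sprintf("  %-14s %s%s\n", f$name,
                    paste(f$categories, collapse = ", "),
                    if (is.null(f$bin)) "" else "  [binned]"))
})

## ---- the bundled six-factor papillary thyroid cancer scheme -------------

## tumor-diameter cut points in cm; bins are half-open [lo, hi) so every
## diameter maps to exactly one category and 1.6 cm lands in 1.5-2.0 cm
.tdBreaks <- c(0, 0.7, 1.0, 1.5, 2.0, Inf)
.tdLabels <- c("<0.7 cm", "0.7-1.0 cm", "1.0-1.5 cm", "1.5-2.0 cm",
               "\u22652.0 cm")
.ageLabels <- c("<45 yrs", "\u226545 yrs")
.tlLabels <- c("Upper pole", "Middle pole", "Lower pole", "Isthmus")

.binFlag <- function(x, what) {
    if (is.logical(x)) x <- ifelse(x, "Y", "N")
    x0 <- tolower(trimws(as.character(x)))
    out <- rep(NA_character_, length(x0))
    out[x0 %in% c("y", "yes", "true", "1")] <- "Y"
    out[x0 %in% c("n", "no", "false", "0")] <- "N"
    if (anyNA(out))
        stop(sprintf("invalid %s value(s): %s", what,
                     paste(unique(x0[is.na(out)]), collapse = ", ")),
             call. = FALSE)
    out
}

.binSex <- function(x) {
    x0 <- tolower(trimws(as.character(x)))
    out <- rep(NA_character_, length(x0))
    out[x0 %in% c("female", "f")] <- "Female"
    out[x0 %in% c("male", "m")] <- "Male"
    if (anyNA(out))
        stop("invalid sex value(s): ",
             paste(unique(x0[is.na(out)]), collapse = ", "), call. = FALSE)
    out
}

.binAge <- function(x) {
    x <- as.numeric(x)
    if (anyNA(x) || any(x < 0))
        stop("age must be a non-negative number of years", call. = FALSE)
    ifelse(x < 45, .ageLabels[1L], .ageLabels[2L])
}

.binDiameter <- function(x) {
    x <- as.numeric(x)
    if (anyNA(x) || any(x <= 0))
        stop("tumor diameter must be a positive length in cm", call. = FALSE)
    .tdLabels[findInterval(x, .tdBreaks, left.open = FALSE)]
}

.binLocation <- function(x) {
    x0 <- tolower(trimws(as.character(x)))
    key <- c("upper pole" = "Upper pole", "upper" = "Upper pole",
             "middle pole" = "Middle pole", "middle" = "Middle pole",
             "lower pole" = "Lower pole", "lower" = "Lower pole",
             "isthmus" = "Isthmus")
    out <- unname(key[x0])
    if (anyNA(out))
        stop("tumor location outside the vocabulary (upper pole, ",
             "middle pole, lower pole, isthmus): ",
             paste(unique(x0[is.na(out)]), collapse = ", "), call. = FALSE)
    out
}

#' The six-factor papillary thyroid cancer scheme
#'
#' The bundled scheme used throughout: Sex (Female/Male), Age (<45 / >=45
#' years), tumor diameter TD in five half-open cm bins, capsular invasion
#' CI (Y/N), Multifocality (Y/N), and tumor location TL (upper / middle /
#' lower pole, isthmus) — 17 categories in total. Binning rules are total:
#' every admissible raw value maps to exactly one category, with boundary
#' values (age 45, diameters 0.7/1.0/1.5/2.0 cm) falling into the
#' closed-lower bin carrying the ">=" or upper-range label.
#'
#' @return a [RiskFactorScheme-class] with 6 factors.
#' @examples
#' ptcScheme()
#' @export
ptcScheme <- function() {
    RiskFactorScheme(list(
        list(name = "Sex", categories = c("Female", "Male"), bin = .binSex),
        list(name = "Age", categories = .ageLabels, bin = .binAge),
        list(name = "TD", categories = .tdLabels, bin = .binDiameter),
        list(name = "CI", categories = c("Y", "N"),
             bin = function(x) .binFlag(x, "capsular invasion")),
        list(name = "Multifocality", categories = c("Y", "N"),
             bin = function(x) .binFlag(x, "multifocality")),
        list(name = "TL", categories = .tlLabels, bin = .binLocation)))
}

## raw attribute column expected per factor of the bundled scheme
.rawColumns <- c(Sex = "sex", Age = "age", TD = "diameter",
                 CI = "capsular_invasion", Multifocality = "multifocality",
                 TL = "location")

#' Bin raw patient attributes into scheme categories
#'
#' Maps raw attributes — sex, age (years), tumor diameter (cm), capsular
#' invasion flag, multifocality flag, tumor location — onto one category
#' per factor using the scheme's binning rules. Diameter and age bins are
#' half-open, so e.g. a 1.6 cm tumor bins as "1.5-2.0 cm" and a 45-year-old
#' as ">=45 yrs".
#'
#' @param raw data.frame of raw attributes, one row per patient, with
#'   columns `sex`, `age`, `diameter`, `capsular_invasion`,
#'   `multifocality`, `location` for the bundled scheme (a column per
#'   binned factor in general, named by [factorNames()] in lower case or
#'   per the mapping above). An optional `patient_id` column is carried
#'   through.
#' @param scheme a [RiskFactorScheme-class] whose factors all carry binning
#'   rules; defaults to [ptcScheme()].
#' @return data.frame of category labels, one column per factor (plus
#'   `patient_id` if present) — a patient-profile table accepted by
#'   [scorePatients()].
#' @examples
#' binPatients(data.frame(sex = "male", age = 28, diameter = 1.6,
#'                        capsular_invasion = "N", multifocality = "N",
#'                        location = "lower pole"))
#' @export
binPatients <- function(raw, scheme = ptcScheme()) {
    stopifnot(is.data.frame(raw))
    if (nrow(raw) == 0L) stop("no patients to bin", call. = FALSE)
    out <- data.frame(row.names = seq_len(nrow(raw)))
    if ("patient_id" %in% names(raw)) out$patient_id <- raw$patient_id
    for (f in factorNames(scheme)) {
        col <- if (f %in% names(.rawColumns) &&
                   .rawColumns[[f]] %in% names(raw)) .rawColumns[[f]]
               else tolower(f)
        if (!col %in% names(raw))
            stop(sprintf("missing raw attribute '%s' (factor %s)", col, f),
                 call. = FALSE)
        if (anyNA(raw[[col]]))
            stop(sprintf("missing value in raw attribute '%s'", col),
                 call. = FALSE)
        rule <- scheme@factors[[f]]$bin
        if (is.null(rule))
            stop(sprintf("factor '%s' has no binning rule", f),
                 call. = FALSE)
        out[[f]] <- rule(raw[[col]])
    }
    validateProfiles(out, scheme)
    out
}

#' Validate a patient-profile table against a scheme
#'
#' Checks that every factor of the scheme is present as a column and that
#' every value is one of that factor's category labels. Unknown or missing
#' categories are an error — scoring never imputes.
#'
#' @param profiles data.frame with one category-label column per factor.
#' @param scheme a [RiskFactorScheme-class].
#' @return the profiles, invisibly, if valid.
#' @export
validateProfiles <- function(profiles, scheme) {
    stopifnot(is.data.frame(profiles))
    for (f in factorNames(scheme)) {
        if (!f %in% names(profiles))
            stop("profiles lack a column for factor '", f, "'",
                 call. = FALSE)
        bad <- setdiff(unique(as.character(profiles[[f]])),
                       categories(scheme, f))
        if (length(bad) || anyNA(profiles[[f]]))
            stop(sprintf("factor '%s': unknown or missing category: %s", f,
                         paste(bad, collapse = ", ")), call. = FALSE)
    }
    invisible(profiles)
}
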