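## fixtures are built in code: tiny tables for hand-checkable arithmetic,
## plus the bundled reference tables loaded through the package API

## one binary factor; defaults give P(A|+) = 0.9, P(A|-) = 0.1
binaryTable <- function(posA = 9L, posB = 1L, negA = 1L, negB = 9L) {
    FrequencyTable(data.frame(
        factor = "F1", category = c("A", "B"),
        positive = c(posA, posB), negative = c(negA, negB)))
}

## raw attributes of the reference worked-example patient
workedRaw <- function() {
    data.frame(sex = "male", age = 28, diameter = 1.6,
               capsular_invasion = "N", multifocality = "N",
               location = "lower pole", stringsAsFactors = FALSE)
}

## the worked-example patient, pre-binned
workedProfile <- function() {
    data.frame(Sex = "Male", Age = "<45 yrs", TD = "1.5-2.0 cm",
               CI = "N", Multifocality = "N", TL = "Lower pole",
               stringsAsFactors = FALSE)
}

## random strictly-positive frequency table over an arbitrary small scheme
randomTable <- function(seed, nFactors = 3L, maxCats = 4L) {
    set.seed(seed)
    rows <- do.call(rbind, lapply(seq_len(nFactors), function(k) {
        nc <- sample(2:maxCats, 1L)
        data.frame(factor = paste0("F", k),
                   category = paste0("c", seq_len(nc)),
                   positive = NA_integer_, negative = NA_integer_,
                   stringsAsFactors = FALSE)
    }))
    ## draw per-factor counts summing to fixed class totals, all positive
    for (g in c("positive", "negative")) {
        tot <- if (g == "positive") 60L else 80L
        for (f in unique(rows$factor)) {
            i <- which(rows$factor == f)
            n <- length(i)
            cuts <- sort(sample(seq_len(tot - 1L), n - 1L))
            rows[[g]][i] <- diff(c(0L, cuts, tot))
        }
    }
    stopifnot(all(rows$positive > 0), all(rows$negative > 0))
    FrequencyTable(rows)
}

## random profiles drawn uniformly over a scheme's categories
randomProfiles <- function(scheme, n, seed) {
    set.seed(seed)
    out <- data.frame(row.names = seq_len(n))
    for (f in factorNames(scheme))
        out[[f]] <- sample(categories(scheme, f), n, replace = TRUE)
    out
}

## every category combination of a scheme
allProfiles <- function(scheme) {
    g <- do.call(expand.grid, c(categories(scheme),
                                list(KEEP.OUT.ATTRS = FALSE,
                                     stringsAsFactors = FALSE)))
    names(g) <- factorNames(scheme)
    g
}
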