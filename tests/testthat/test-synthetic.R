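test_that("cohort generation is a pure function of its spec", {
    spec <- CohortSpec(ptcFrequencyTable(), n = 300, seed = 7)
    a <- generateCohort(spec)
    b <- generateCohort(spec)
    expect_identical(a, b)
    ## and leaves the caller's RNG stream untouched
    set.seed(99); before <- runif(3)
    set.seed(99); invisible(generateCohort(spec)); after <- runif(3)
    expect_identical(before, after)
    ## a different seed gives a different cohort
    expect_false(identical(a, generateCohort(
        CohortSpec(ptcFrequencyTable(), n = 300, seed = 8))))
})

test_that("generative spec rejects invalid prevalence and size", {
    tab <- ptcFrequencyTable()
    expect_error(CohortSpec(tab, prevalence = 0, n = 10, seed = 1),
                 "prevalence")
    expect_error(CohortSpec(tab, prevalence = 1, n = 10, seed = 1),
                 "prevalence")
    expect_error(CohortSpec(tab, prevalence = 0.5, n = 0, seed = 1),
                 "n must be")
})

test_that("degenerate conditional frequencies pin the sampled categories", {
    tab <- FrequencyTable(data.frame(
        factor = c("Sex", "Sex"), category = c("Female", "Male"),
        positive = c(0L, 20L), negative = c(10L, 10L)))
    co <- generateCohort(tab, prevalence = 0.6, n = 500, seed = 5)
    expect_true(all(co$Sex[co$true_class == "positive"] == "Male"))
    expect_true(all(c("Female", "Male") %in%
                    co$Sex[co$true_class == "negative"]))
})

test_that("empirical frequencies concentrate on the generating values", {
    tab <- ptcFrequencyTable()
    co <- generateCohort(tab, prevalence = 197 / 412, n = 50000, seed = 11)
    pos <- co[co$true_class == "positive", ]
    empMale <- mean(pos$Sex == "Male")
    expect_lt(abs(empMale - 53 / 197), 0.01)
    ## prevalence conservation within 3 binomial sigma
    p <- 197 / 412
    se <- sqrt(p * (1 - p) / nrow(co))
    expect_lt(abs(mean(co$true_class == "positive") - p), 3 * se)
})

test_that("recovered counts tabulate the cohort exactly", {
    sch <- RiskFactorScheme(list(
        list(name = "F1", categories = c("A", "B")),
        list(name = "F2", categories = c("x", "y"))))
    co <- data.frame(F1 = c("A", "B"), F2 = c("y", "y"),
                     true_class = c("positive", "negative"))
    rec <- recoverFrequencies(co, scheme = sch)
    ct <- counts(rec)
    expect_identical(ct$positive, c(1, 0, 0, 1))
    expect_identical(ct$negative, c(0, 1, 0, 1))
    expect_error(recoverFrequencies(
        data.frame(F1 = "A", F2 = "x", true_class = "positive"),
        scheme = sch), "class absent")
})

test_that("generate -> recover -> fit returns to the generating table", {
    tab <- ptcFrequencyTable()
    co <- generateCohort(tab, prevalence = 197 / 412, n = 100000, seed = 3)
    rec <- recoverFrequencies(co, scheme = scheme(tab))
    genP <- counts(tab)
    recP <- counts(rec)
    for (g in c("positive", "negative")) {
        gen <- genP[[g]] / classTotals(tab)[[g]]
        emp <- recP[[g]] / classTotals(rec)[[g]]
        expect_lt(max(abs(gen - emp)), 0.01)
    }
    refit <- scores(fitScoreTable(rec))
    orig <- scores(fitScoreTable(tab))
    expect_lt(max(abs(refit$positive - orig$positive)), 0.5)
    expect_lt(max(abs(refit$negative - orig$negative)), 0.5)
})

test_that("enumeration matches a four-outcome hand calculation", {
    ## one binary factor, P(A|+) = 0.9, P(A|-) = 0.1, prevalence 0.5:
    ## the rule calls + on A and - on B, so both expected rates are 90%
    tab <- binaryTable(9L, 1L, 1L, 9L)
    ep <- enumerateExpectedPerformance(tab, fitScoreTable(tab),
                                       prevalence = 0.5)
    expect_equal(ep@ratePositive, 90)
    expect_equal(ep@rateNegative, 90)
    expect_equal(ep@rateMean, 90)
    expect_equal(ep@accuracy, 90)
    expect_identical(ep@nProfiles, 2L)
    expect_equal(sum(ep@proportions), 1)
    expect_equal(ep@proportions["+", "+"], 0.5 * 0.9)
    expect_equal(ep@proportions["-", "+"], 0.5 * 0.1)
})

test_that("identical class distributions tie everywhere under enumeration", {
    tab <- FrequencyTable(data.frame(
        factor = "F1", category = c("A", "B"),
        positive = c(4L, 16L), negative = c(4L, 16L)))
    ep <- enumerateExpectedPerformance(tab, fitScoreTable(tab),
                                       prevalence = 0.5)
    expect_equal(ep@ratePositive, 100)   # every tie called positive
    expect_equal(ep@rateNegative, 0)
    epNeg <- enumerateExpectedPerformance(tab, fitScoreTable(tab),
                                          prevalence = 0.5,
                                          tiePolicy = "negative")
    expect_equal(epNeg@ratePositive, 0)
    expect_equal(epNeg@rateNegative, 100)
})

test_that("enumeration refuses oversized combinatorial spaces", {
    tab <- ptcFrequencyTable()
    expect_error(enumerateExpectedPerformance(tab, fitScoreTable(tab),
                                              maxProfiles = 100),
                 "refusing to enumerate")
})

test_that("Monte-Carlo rates converge to the enumeration oracle", {
    tab <- ptcFrequencyTable()
    st <- fitScoreTable(tab)
    prev <- 197 / 412
    ep <- enumerateExpectedPerformance(tab, st, prevalence = prev)
    co <- generateCohort(tab, prevalence = prev, n = 100000, seed = 17)
    pred <- scorePatients(co, st)$predicted
    r <- coincidenceRates(buildConfusion(co$true_class, pred))
    nPos <- sum(co$true_class == "positive")
    nNeg <- nrow(co) - nPos
    seP <- 100 * sqrt(ep@ratePositive / 100 *
                      (1 - ep@ratePositive / 100) / nPos)
    seN <- 100 * sqrt(ep@rateNegative / 100 *
                      (1 - ep@rateNegative / 100) / nNeg)
    expect_lt(abs(r@ratePositive - ep@ratePositive), 3 * seP)
    expect_lt(abs(r@rateNegative - ep@rateNegative), 3 * seN)
})
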