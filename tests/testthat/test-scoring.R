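test_that("the reference worked example scores 37.0 / 30.2 and is positive", {
    fitted <- fitScoreTable(ptcFrequencyTable())
    prof <- binPatients(workedRaw())
    res <- scorePatients(prof, fitted)     # display precision (default)
    expect_equal(res$sPositive, 37.0)
    expect_equal(res$sNegative, 30.2)
    expect_identical(res$predicted, "positive")
    expect_false(res$tieBroken)
    expect_equal(res$margin, 37.0 - 30.2)
    ## full-precision sums agree on the call and on S+ at 1 dp; the
    ## negative total lands at 30.1, which is why display precision is
    ## the replication default
    full <- scorePatients(prof, fitted, precision = "full")
    expect_identical(full$predicted, "positive")
    expect_equal(roundDisplay(full$sPositive, 1), 37.0)
    expect_equal(roundDisplay(full$sNegative, 1), 30.1)
})

test_that("a low-risk profile sums the published cells and calls negative", {
    ## female, >=45, <0.7 cm, no invasion, unifocal, upper pole:
    ## independent hand-sums of the published 1-dp cells are
    ## 8.6+6.4-0.4+8.4+9.7+1.2 = 33.9 and 9.2+7.5+5.4+9.6+9.8+3.5 = 45.0
    prof <- data.frame(Sex = "Female", Age = "\u226545 yrs", TD = "<0.7 cm",
                       CI = "N", Multifocality = "N", TL = "Upper pole")
    res <- scorePatients(prof, ptcScoreTable())
    expect_equal(res$sPositive, 33.9)
    expect_equal(res$sNegative, 45.0)
    expect_identical(res$predicted, "negative")
})

test_that("profiles with identical class frequencies tie and obey policy", {
    tab <- FrequencyTable(data.frame(
        factor = "F1", category = c("A", "B"),
        positive = c(2L, 18L), negative = c(2L, 18L)))
    st <- fitScoreTable(tab)
    prof <- data.frame(F1 = c("A", "B"))
    res <- scorePatients(prof, st)
    expect_true(all(res$tieBroken))
    expect_identical(res$predicted, c("positive", "positive"))
    resNeg <- scorePatients(prof, st, tiePolicy = "negative")
    expect_identical(resNeg$predicted, c("negative", "negative"))
    ## P = 0.1 everywhere in both classes gives S+ = S- = 0
    p01 <- FrequencyTable(data.frame(
        factor = "F1", category = c("A", "B"),
        positive = c(1L, 9L), negative = c(1L, 9L)))
    r01 <- scorePatients(data.frame(F1 = "A"), fitScoreTable(p01))
    expect_equal(r01$sPositive, 0)
    expect_equal(r01$sNegative, 0)
    expect_true(r01$tieBroken)
})

test_that("the decision rule compares totals and rejects non-finite input", {
    expect_identical(classifyScores(37.0, 30.2), "positive")
    expect_identical(classifyScores(33.9, 45.0), "negative")
    expect_identical(classifyScores(0, 0), "positive")
    expect_identical(classifyScores(0, 0, tiePolicy = "negative"),
                     "negative")
    expect_error(classifyScores(NaN, 1), "finite")
    expect_error(classifyScores(1, Inf), "finite")
    expect_error(classifyScores(c(1, 2), 1), "equal length")
})

test_that("scoring errors on categories absent from the score table", {
    st <- fitScoreTable(binaryTable())
    expect_error(scorePatients(data.frame(F1 = "Z"), st),
                 "unknown or missing")
})

test_that("log joint probability is an affine twin of the score total", {
    tab <- ptcFrequencyTable()
    st <- fitScoreTable(tab)
    prof <- randomProfiles(scheme(tab), 50, seed = 4)
    lgPos <- logJointProbability(prof, tab, "positive")
    lgNeg <- logJointProbability(prof, tab, "negative")
    res <- scorePatients(prof, st, precision = "full")
    ## S_g = (lgP_g + 6) * 10 for the six-factor scheme
    expect_equal(res$sPositive, (lgPos + 6) * 10, tolerance = 1e-12)
    expect_equal(res$sNegative, (lgNeg + 6) * 10, tolerance = 1e-12)
    ## classification agrees between the two formulations
    expect_identical(res$predicted,
                     ifelse(lgPos >= lgNeg, "positive", "negative"))
    ## single factor with P = 1 has log joint probability 0
    one <- FrequencyTable(data.frame(
        factor = "F1", category = c("A", "B"),
        positive = c(4L, 0L), negative = c(0L, 4L)))
    expect_equal(logJointProbability(data.frame(F1 = "A"), one,
                                     "positive"), 0)
    expect_error(logJointProbability(data.frame(F1 = "B"), one,
                                     "positive"), "zero probability")
})

test_that("scores are invariant to factor and category reordering", {
    tab <- ptcFrequencyTable()
    prof <- randomProfiles(scheme(tab), 40, seed = 8)
    base <- scorePatients(prof, fitScoreTable(tab), precision = "full")
    ## reverse factor order and each factor's category order
    ct <- counts(tab)
    perm <- do.call(rbind, lapply(rev(unique(ct$factor)), function(f) {
        rows <- ct[ct$factor == f, , drop = FALSE]
        rows[rev(seq_len(nrow(rows))), , drop = FALSE]
    }))
    ptab <- FrequencyTable(perm)
    pres <- scorePatients(prof, fitScoreTable(ptab), precision = "full")
    expect_lt(max(abs(pres$sPositive - base$sPositive)), 1e-9)
    expect_lt(max(abs(pres$sNegative - base$sNegative)), 1e-9)
    expect_identical(pres$predicted, base$predicted)
})

test_that("an optional prior term shifts both totals by the log priors", {
    st <- fitScoreTable(ptcFrequencyTable())
    prof <- workedProfile()
    base <- scorePatients(prof, st)
    prior <- scorePatients(prof, st, priorPositive = 197 / 412)
    expect_equal(prior$sPositive - base$sPositive, 10 * log10(197 / 412))
    expect_equal(prior$sNegative - base$sNegative, 10 * log10(215 / 412))
})
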