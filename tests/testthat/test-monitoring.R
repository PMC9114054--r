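test_that("normalization maps the start value to 100% and is idempotent", {
    s <- seriesFromSamples(c(0, 15, 45), plt = c(350, 280, 70),
                           dpmo = c(15, 15, 16))
    n1 <- normalizeToStart(s, "plt_1e3_uL")
    expect_equal(n1$value_pct[1], 100)
    expect_equal(n1$value_pct, c(100, 80, 20))
    ## idempotence up to the 100x scale
    s2 <- s
    s2@data$plt_1e3_uL <- n1$value_pct
    expect_equal(normalizeToStart(s2, "plt_1e3_uL")$value_pct, n1$value_pct)
    sBad <- seriesFromSamples(c(0, 15, 45), plt = c(0, 10, 20),
                              dpmo = c(15, 15, 15))
    expect_error(normalizeToStart(sBad, "plt_1e3_uL"), "missing or zero")
    expect_error(normalizeToStart(s, "nonesuch"), "unknown parameter")
})

test_that("syringe filter applies both platelet acceptance rules", {
    res <- filterSyringes(plt = c(240000, 300000, 300000),
                          baseline = c(300000, 500000, 300000))
    expect_equal(res$accepted, c(FALSE, FALSE, TRUE))
    expect_match(res$reason[1], "absolute")
    expect_match(res$reason[2], "relative")
    expect_equal(res$reason[3], "")
    ## partition property: accepted and discarded cover the input disjointly
    set.seed(9)
    plt <- runif(200, 1e5, 6e5)
    base <- runif(200, 2e5, 6e5)
    r <- filterSyringes(plt, base)
    expect_equal(sum(r$accepted) + sum(!r$accepted), 200)
    expect_true(all(r$accepted == (plt >= 250000 & plt >= 0.7 * base)))
    ## "both" connective discards only when both rules fail
    rb <- filterSyringes(plt = c(240000, 300000, 100000),
                         baseline = c(300000, 500000, 300000),
                         connective = "both")
    expect_equal(rb$accepted, c(TRUE, TRUE, FALSE))
    expect_error(filterSyringes(1e5, 0), "baseline")
})

test_that("loop geometry ratios reproduce the circuit design values", {
    r <- loopRatios(loopSpec())
    expect_equal(r$exposure_cm2_mL, 7.5, tolerance = 1e-12)
    expect_equal(round(r$surface_ratio, 2), 3.37)
    expect_equal(r$blood_volume_mL, 160)
})

test_that("termination detector fires on platelet loss, dpMO rise or timeout", {
    ## stable flat series: no termination
    flat <- seriesFromSamples(seq(0, 120, 15), plt = rep(300, 9),
                              dpmo = rep(15, 9))
    r <- detectTermination(flat)
    expect_false(r$terminated)
    expect_true(r$rbc_stable)
    ## platelet crash to 5% at 115 min with concurrent steep dpMO rise
    tt <- c(0, 15, 45, 75, 105, 115)
    crash <- seriesFromSamples(tt, plt = c(350, 340, 330, 280, 170, 17.5),
                               dpmo = c(15, 15, 16, 17, 30, 160))
    r2 <- detectTermination(crash)
    expect_true(r2$terminated)
    expect_equal(r2$time_min, 115)
    expect_true("platelet absence" %in% r2$reasons ||
                "rapid dpMO rise" %in% r2$reasons)
    ## time limit
    long <- seriesFromSamples(c(0, 60, 120, 250), plt = rep(300, 4),
                              dpmo = rep(15, 4))
    r3 <- detectTermination(long)
    expect_true(r3$terminated)
    expect_equal(r3$time_min, 240)
    expect_equal(r3$reasons, "time limit")
    ## RBC drift beyond 5% invalidates the run
    drift <- seriesFromSamples(seq(0, 60, 15), plt = rep(300, 5),
                               dpmo = rep(15, 5),
                               rbc = c(9.5, 9.5, 9.6, 9.0, 8.7))
    expect_false(detectTermination(drift)$rbc_stable)
    expect_error(detectTermination(seriesFromSamples(c(0, 10),
                                                     plt = c(1, 1),
                                                     dpmo = c(1, 1))),
                 "3 timepoints")
})

test_that("termination is monotone under appending later timepoints", {
    tt <- c(0, 15, 45, 75, 105)
    s <- seriesFromSamples(tt, plt = c(350, 340, 330, 280, 20),
                           dpmo = c(15, 15, 16, 17, 60))
    r1 <- detectTermination(s)
    expect_true(r1$terminated)
    s2 <- seriesFromSamples(c(tt, 135, 165),
                            plt = c(350, 340, 330, 280, 20, 300, 300),
                            dpmo = c(15, 15, 16, 17, 60, 15, 15))
    r2 <- detectTermination(s2)
    expect_true(r2$terminated)
    expect_lte(r2$time_min, r1$time_min)
})

test_that("synthetic experiments are reproducible and profile-faithful", {
    a <- generateSyntheticExperiment("normal", seed = 42)
    b <- generateSyntheticExperiment("normal", seed = 42)
    expect_identical(monitoringData(a), monitoringData(b))
    expect_false(identical(monitoringData(a),
                           monitoringData(generateSyntheticExperiment(
                               "normal", seed = 43))))
    expect_error(generateSyntheticExperiment("weird"), "arg")

    ## normal profile: late thrombotic event in the 90-130 min window
    rN <- detectTermination(generateSyntheticExperiment("normal", seed = 1))
    expect_true(rN$terminated)
    expect_gte(rN$time_min, 90)
    expect_lte(rN$time_min, 130)
    expect_true(rN$rbc_stable)

    ## hypercoagulable profile: termination within the first 30 min
    rH <- detectTermination(generateSyntheticExperiment("hypercoagulable",
                                                        seed = 1))
    expect_true(rH$terminated)
    expect_lt(rH$time_min, 30)

    ## cold-activation profile: strong normalized platelet overshoot that
    ## falls back below baseline by termination
    sC <- generateSyntheticExperiment("coldActivation", seed = 1)
    plt <- normalizeToStart(sC, "plt_1e3_uL")
    expect_gt(max(plt$value_pct), 1000)
    expect_lt(plt$value_pct[nrow(plt)], 100)
})

test_that("generated aPTT honours the 400 s out-of-range cap", {
    for (seed in 1:5) {
        s <- generateSyntheticExperiment("normal", seed = seed)
        d <- monitoringData(s)
        expect_true(all(is.na(d$aptt_s) | d$aptt_s <= 400))
        atCap <- !is.na(d$aptt_s) & d$aptt_s == 400
        expect_true(all(d$aptt_oor[atCap]))
        expect_true(any(atCap))  # terminal out-of-range rise exists
        expect_true(all(is.na(d$act_s[d$act_error])))
        ## ACT decreases monotonically where measured
        act <- d$act_s[!is.na(d$act_s)]
        expect_true(all(diff(act) <= 0))
    }
})
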