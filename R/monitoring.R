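## Blood / coagulation / pressure analytics for the in-vitro loop:
## normalization, syringe acceptance filtering, loop geometry ratios,
## termination detection and a seeded synthetic experiment generator.

#' Construct an in-vitro blood loop specification
#'
#' Defaults describe the emulated test loop: a 0.12 m^2 membrane oxygenator
#' with 20 mL priming volume in a loop with 0.0356 m^2 blood-contacting
#' area and 140 mL priming volume, run at 95 mL/min with 2.5 USP/mL heparin
#' under a 4-hour experiment limit.
#'
#' @param membraneArea_m2 membrane surface area (m^2)
#' @param devicePrimingVolume_mL device priming volume (mL)
#' @param loopContactArea_m2 loop blood-contacting area (m^2)
#' @param loopPrimingVolume_mL loop priming volume (mL)
#' @param flow_mL_min flow rate (mL/min)
#' @param heparin_USP_mL heparin dose (USP/mL)
#' @param timeLimit_min experiment time limit (min)
#' @return a [LoopSpec]
#' @export
loopSpec <- function(membraneArea_m2 = 0.12, devicePrimingVolume_mL = 20,
                     loopContactArea_m2 = 0.0356,
                     loopPrimingVolume_mL = 140, flow_mL_min = 95,
                     heparin_USP_mL = 2.5, timeLimit_min = 240) {
    new("LoopSpec", membraneArea_m2 = membraneArea_m2,
        devicePrimingVolume_mL = devicePrimingVolume_mL,
        loopContactArea_m2 = loopContactArea_m2,
        loopPrimingVolume_mL = loopPrimingVolume_mL,
        flow_mL_min = flow_mL_min, heparin_USP_mL = heparin_USP_mL,
        timeLimit_min = timeLimit_min)
}

#' Loop geometry ratios
#'
#' Exposure ratio = membrane area (cm^2) over total blood volume (loop plus
#' device priming, mL); surface ratio = membrane area over loop
#' blood-contacting area. With the default loop these give 7.5 cm^2/mL and
#' 3.37.
#'
#' @param spec a [LoopSpec]
#' @return list(exposure_cm2_mL, surface_ratio, blood_volume_mL)
#' @examples
#' loopRatios(loopSpec())
#' @export
loopRatios <- function(spec) {
    vol <- spec@loopPrimingVolume_mL + spec@devicePrimingVolume_mL
    if (vol <= 0) stop("blood volume must be > 0")
    list(exposure_cm2_mL = spec@membraneArea_m2 * 1e4 / vol,
         surface_ratio = spec@membraneArea_m2 / spec@loopContactArea_m2,
         blood_volume_mL = vol)
}

#' Normalize a monitored parameter to its value at experiment start
#'
#' x(t) / x(t0) x 100, so the first timepoint maps to 100%.
#'
#' @param series a [MonitoringSeries] or its data.frame
#' @param parameter column name, e.g. "plt_1e3_uL"
#' @return data.frame(time_min, value_pct) at the sampled timepoints
#' @export
normalizeToStart <- function(series, parameter) {
    d <- if (is(series, "MonitoringSeries")) series@data else series
    if (!parameter %in% names(d)) stop("unknown parameter: ", parameter)
    ok <- !is.na(d[[parameter]])
    if (!any(ok)) stop("parameter ", parameter, " has no measurements")
    t0val <- d[[parameter]][ok][1]
    if (is.na(t0val) || t0val == 0)
        stop("start value missing or zero for ", parameter)
    data.frame(time_min = d$time_min[ok],
               value_pct = d[[parameter]][ok] / t0val * 100)
}

#' Filter syringes by platelet acceptance thresholds
#'
#' A syringe is discarded when its platelet count falls below the absolute
#' threshold (250,000 PLT/uL) or below 70% of the animal baseline; with
#' `connective = "both"` a syringe is discarded only when both rules fail.
#' The discard log records the violated rule(s) per syringe.
#'
#' @param plt platelet counts (PLT/uL), one per syringe
#' @param baseline animal baseline platelet count (PLT/uL), scalar or
#'   per-syringe
#' @param absoluteMin absolute acceptance threshold (PLT/uL)
#' @param relativeMin baseline fraction acceptance threshold
#' @param connective "either" (discard if either rule fails; default) or
#'   "both"
#' @return data.frame(plt, baseline, accepted, reason)
#' @export
filterSyringes <- function(plt, baseline, absoluteMin = 250000,
                           relativeMin = 0.70,
                           connective = c("either", "both")) {
    connective <- match.arg(connective)
    if (any(baseline <= 0)) stop("baseline must be > 0")
    baseline <- rep(baseline, length.out = length(plt))
    failAbs <- plt < absoluteMin
    failRel <- plt < relativeMin * baseline
    discard <- if (connective == "either") failAbs | failRel
               else failAbs & failRel
    reason <- character(length(plt))
    reason[failAbs & discard] <- "below absolute threshold"
    reason[failRel & discard] <- ifelse(
        nzchar(reason[failRel & discard]),
        "below absolute and relative thresholds", "below relative threshold")
    data.frame(plt = plt, baseline = baseline, accepted = !discard,
               reason = reason, stringsAsFactors = FALSE)
}

#' Detect experiment termination
#'
#' Termination fires at the earliest of: normalized platelet count below
#' `pltFloorPct` percent of start; a relative dpMO rise of at least
#' `riseFactor` (1 = +100%) within a sliding window of `windowMin` minutes;
#' or the elapsed-time limit. The red-cell stability boundary condition
#' (|RBC change from start| within `rbcTolPct` percent at every sample) is
#' evaluated as a validity flag: an unstable RBC count alters the blood
#' attenuation itself and invalidates serial CT comparison.
#'
#' @param series a [MonitoringSeries]
#' @param pltFloorPct platelet floor (% of start)
#' @param riseFactor minimum relative dpMO rise within the window
#' @param windowMin sliding window length (min)
#' @param timeLimitMin experiment time limit (min)
#' @param rbcTolPct RBC stability tolerance (% of start)
#' @return list(terminated, time_min, reasons, rbc_stable)
#' @export
detectTermination <- function(series, pltFloorPct = 10, riseFactor = 1,
                              windowMin = 10, timeLimitMin = 240,
                              rbcTolPct = 5) {
    d <- if (is(series, "MonitoringSeries")) series@data else series
    if (nrow(d) < 3) stop("need at least 3 timepoints")
    triggers <- data.frame(time = numeric(), reason = character())

    plt <- normalizeToStart(d, "plt_1e3_uL")
    low <- which(plt$value_pct < pltFloorPct)
    if (length(low))
        triggers <- rbind(triggers, data.frame(
            time = plt$time_min[low[1]], reason = "platelet absence"))

    dp <- d[!is.na(d$dpmo_mmHg), c("time_min", "dpmo_mmHg")]
    if (nrow(dp) >= 2) {
        for (i in seq_len(nrow(dp))) {
            inWin <- dp$time_min >= dp$time_min[i] - windowMin &
                dp$time_min <= dp$time_min[i]
            ref <- min(dp$dpmo_mmHg[inWin])
            if (ref > 0 && dp$dpmo_mmHg[i] / ref - 1 >= riseFactor) {
                triggers <- rbind(triggers, data.frame(
                    time = dp$time_min[i], reason = "rapid dpMO rise"))
                break
            }
        }
    }

    if (max(d$time_min) > timeLimitMin)
        triggers <- rbind(triggers, data.frame(
            time = timeLimitMin, reason = "time limit"))

    rbc <- normalizeToStart(d, "rbc_1e6_uL")
    rbcStable <- all(abs(rbc$value_pct - 100) <= rbcTolPct)

    if (!nrow(triggers))
        return(list(terminated = FALSE, time_min = NA_real_,
                    reasons = character(), rbc_stable = rbcStable))
    tmin <- min(triggers$time)
    list(terminated = TRUE, time_min = tmin,
         reasons = unique(triggers$reason[triggers$time <= tmin + 1e-9]),
         rbc_stable = rbcStable)
}

## smooth sigmoid used for pressure rises and platelet crashes
sigmoidRise <- function(t, center, width) 1 / (1 + exp(-(t - center) / width))

#' Generate a synthetic monitoring experiment
#'
#' Seeded generator of realistic loop traces emulating the three observed
#' experiment archetypes:
#' \describe{
#'   \item{normal}{stable platelet plateau to about 65 min, gradual decline,
#'     then a crash to a few percent around 110-115 min with a steep
#'     concurrent dpMO rise.}
#'   \item{coldActivation}{platelets start from a cold-activation-depressed
#'     baseline, recover far above 100% (peaking near 1700% around 80 min)
#'     as the loop rewarms, then fall; termination near 105 min driven by
#'     the dpMO rise.}
#'   \item{hypercoagulable}{pre-activated blood: immediate platelet crash
#'     and dpMO rise within the first 15 min.}
#' }
#' Sampling follows the loop protocol: blood samples at 0 and 15 min then
#' every 30 min, temperature every 15 min, pressure every minute. RBC stays
#' within a few percent of start; ACT decreases monotonically with an
#' occasional device-error flag; aPTT decreases then rises above the 400 s
#' cuvette limit before termination, stored capped at 400 s with the OOR
#' flag set.
#'
#' @param profile "normal", "coldActivation" or "hypercoagulable"
#' @param seed integer seed; same seed, same series
#' @param duration_min trace length (min)
#' @return a [MonitoringSeries]
#' @export
generateSyntheticExperiment <- function(profile = c("normal",
                                                    "coldActivation",
                                                    "hypercoagulable"),
                                        seed = 1, duration_min = 130) {
    profile <- match.arg(profile)
    set.seed(seed)
    if (profile == "hypercoagulable") duration_min <- min(duration_min, 40)
    tAll <- 0:duration_min
    bloodT <- c(0, seq(15, duration_min, by = 30))
    tempT <- seq(0, duration_min, by = 15)

    par <- switch(profile,
        normal = list(pltStart = 350, crash = 108, crashW = 3.5,
                      declineFrom = 65, declineRate = 0.009,
                      recover = 0, dpCenter = 106, dpW = 2.5,
                      dpBase = 14, dpAmp = 160, rbc = 9.5),
        coldActivation = list(pltStart = 20, crash = 95, crashW = 4,
                              declineFrom = 85, declineRate = 0.02,
                              recover = 17, dpCenter = 99, dpW = 2.5,
                              dpBase = 16, dpAmp = 420, rbc = 9.8),
        hypercoagulable = list(pltStart = 300, crash = 9, crashW = 2.5,
                               declineFrom = 0, declineRate = 0.02,
                               recover = 0, dpCenter = 10, dpW = 2,
                               dpBase = 15, dpAmp = 260, rbc = 9.0))

    pltCurve <- function(t) {
        base <- rep(1, length(t))
        if (par$recover > 0) {
            ## cold-activation recovery: rise towards recover x start
            base <- 1 + (par$recover - 1) *
                pmin(1, (t / 80)^1.6) * exp(-pmax(0, t - 80) / 25)
        } else if (par$declineRate > 0 && par$declineFrom > 0) {
            base <- exp(-pmax(0, t - par$declineFrom) * par$declineRate)
        }
        frac <- base * (1 - 0.97 * sigmoidRise(t, par$crash, par$crashW))
        pmax(frac, 0.015)
    }
    dpCurve <- function(t)
        par$dpBase + par$dpAmp * sigmoidRise(t, par$dpCenter, par$dpW)

    n <- length(tAll)
    d <- data.frame(
        time_min = tAll,
        dpmo_mmHg = dpCurve(tAll) * (1 + rnorm(n, 0, 0.015)),
        rbc_1e6_uL = NA_real_, plt_1e3_uL = NA_real_,
        act_s = NA_real_, act_error = FALSE,
        aptt_s = NA_real_, aptt_oor = FALSE, aptt_error = FALSE,
        temp_C = NA_real_, flow_mL_min = 95)

    ib <- match(bloodT, tAll)
    nb <- length(ib)
    d$rbc_1e6_uL[ib] <- par$rbc * (1 + c(0, rnorm(nb - 1, 0, 0.015)))
    d$plt_1e3_uL[ib] <- par$pltStart * pltCurve(bloodT) *
        (1 + c(0, rnorm(nb - 1, 0, 0.03)))
    ## ACT: monotone decrease from ~200 s
    act <- 200 * exp(-bloodT / 300) - cumsum(abs(rnorm(nb, 2, 1)))
    d$act_s[ib] <- pmax(act, 80)
    errIdx <- if (nb > 3) sample(2:(nb - 1), 1) else integer()
    d$act_error[ib[errIdx]] <- TRUE
    d$act_s[ib[errIdx]] <- NA_real_
    ## aPTT: decreasing, terminal out-of-range rise capped at 400 s
    aptt <- 180 * exp(-bloodT / 250) + rnorm(nb, 0, 4)
    lastWin <- bloodT > par$crash - 30
    aptt[lastWin] <- 500
    oor <- aptt > 400
    aptt[oor] <- 400
    d$aptt_s[ib] <- aptt
    d$aptt_oor[ib] <- oor
    d$temp_C[match(tempT, tAll)] <- 37 + rnorm(length(tempT), 0, 0.3)

    new("MonitoringSeries", data = d,
        baseline = list(rbc_1e6_uL = par$rbc, plt_1e3_uL = par$pltStart,
                        act_s = 200, aptt_s = 180),
        staticControl = list(rbc_1e6_uL = par$rbc * 1.01,
                             plt_1e3_uL = par$pltStart *
                                 if (profile == "hypercoagulable") 2.25 else 1.02),
        meta = list(profile = profile, seed = seed,
                    units = c(dpmo = "mmHg", rbc = "1e6/uL", plt = "1e3/uL",
                              act = "s", aptt = "s", temp = "degC",
                              flow = "mL/min")))
}
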