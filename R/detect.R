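## Serial-scan change detection: housing-edge phase-correlation alignment,
## baseline subtraction with clipping, red/white component segmentation with
## size / edge-contrast / anisotropy filters, volumetry and air-bubble
## disambiguation.

## integer-shift a 3D array, zero filling vacated voxels; out[i + s] = x[i]
shiftVolume <- function(x, shift) {
    shift <- as.integer(round(shift))
    d <- dim(x)
    out <- array(0, d)
    src <- dst <- vector("list", 3)
    for (k in 1:3) {
        s <- shift[k]
        if (abs(s) >= d[k]) return(out)
        if (s >= 0) {
            src[[k]] <- seq_len(d[k] - s)
            dst[[k]] <- seq_len(d[k] - s) + s
        } else {
            src[[k]] <- seq_len(d[k] + s) - s
            dst[[k]] <- seq_len(d[k] + s)
        }
    }
    out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
    out
}

gradientMagnitude <- function(x) {
    d <- dim(x)
    gx <- x[c(2:d[1], d[1]), , ] - x[c(1, 1:(d[1] - 1)), , ]
    gy <- x[, c(2:d[2], d[2]), ] - x[, c(1, 1:(d[2] - 1)), ]
    gz <- x[, , c(2:d[3], d[3])] - x[, , c(1, 1:(d[3] - 1))]
    sqrt(gx^2 + gy^2 + gz^2) / 2
}

## separable 3-tap (1,2,1)/4 smoothing along each axis
boxSmooth3 <- function(x) {
    d <- dim(x)
    sm1 <- function(a, k) {
        idx <- seq_len(d[k])
        lo <- c(1, idx[-d[k]])
        hi <- c(idx[-1], d[k])
        if (k == 1) (a[lo, , , drop = FALSE] + 2 * a + a[hi, , , drop = FALSE]) / 4
        else if (k == 2) (a[, lo, , drop = FALSE] + 2 * a + a[, hi, , drop = FALSE]) / 4
        else (a[, , lo, drop = FALSE] + 2 * a + a[, , hi, drop = FALSE]) / 4
    }
    sm1(sm1(sm1(x, 1), 2), 3)
}

#' Align a moving scan to a reference scan
#'
#' Estimates the integer-voxel translation between two reconstructions by
#' phase correlation restricted to a housing-edge mask (a gradient-magnitude
#' threshold on the reference selects the strong device edges, mirroring
#' manual alignment on the outer housing). The moving volume is shifted back
#' onto the reference grid. True shifts of up to `maxShift` voxels are
#' recovered to within one voxel; an ambiguous correlation peak (ratio to
#' the runner-up below `peakRatioMin`) yields a warning and zero shift.
#'
#' @param reference,moving [ReconVolume]s on the same grid
#' @param maxShift largest expected |shift| per axis (voxels)
#' @param maskQuantile gradient-magnitude quantile defining the edge mask
#' @param peakRatioMin minimum peak-to-runner-up ratio
#' @return list(shift, aligned, residual, peakRatio); `aligned` is the
#'   shifted moving [ReconVolume]
#' @export
alignScans <- function(reference, moving, maxShift = 10,
                       maskQuantile = 0.99, peakRatioMin = 1.2) {
    if (!identical(dim(reference@data), dim(moving@data)))
        stop("volumes must share one grid shape")
    if (abs(reference@voxelSize - moving@voxelSize) > 1e-9)
        stop("volumes must share one voxel size")
    ## correlate gradient-magnitude images (edge maps); the housing edges
    ## dominate. The edge mask is applied to the reference only -- masking
    ## both operands with one mask would pin the correlation peak at zero.
    ga <- gradientMagnitude(reference@data)
    gb <- gradientMagnitude(moving@data)
    mask <- ga >= quantile(ga, maskQuantile)
    ma <- (ga - mean(ga)) * mask
    mb <- gb - mean(gb)
    fa <- fft(ma)
    fb <- fft(mb)
    cross <- fb * Conj(fa)
    r <- Re(fft(cross / (Mod(cross) + 1e-12), inverse = TRUE))
    d <- dim(r)
    ## admissible shifts: wrap-around indices within +/- maxShift
    ix <- c(0:min(maxShift, d[1] - 1), d[1] - rev(seq_len(min(maxShift, d[1] - 1))))
    iy <- c(0:min(maxShift, d[2] - 1), d[2] - rev(seq_len(min(maxShift, d[2] - 1))))
    iz <- c(0:min(maxShift, d[3] - 1), d[3] - rev(seq_len(min(maxShift, d[3] - 1))))
    sub <- r[ix + 1, iy + 1, iz + 1, drop = FALSE]
    peak <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    toShift <- function(idx, tab, n) {
        raw <- tab[idx]
        if (raw > n / 2) raw - n else raw
    }
    shift <- c(toShift(peak[1], ix, d[1]),
               toShift(peak[2], iy, d[2]),
               toShift(peak[3], iz, d[3]))
    ## peak ambiguity: compare with best value outside a 1-voxel neighbourhood
    sub2 <- sub
    n1 <- pmax(peak - 1, 1)
    n2 <- pmin(peak + 1, dim(sub))
    sub2[n1[1]:n2[1], n1[2]:n2[2], n1[3]:n2[3]] <- -Inf
    second <- max(sub2)
    ratio <- if (second > 0) max(sub) / second else Inf
    if (!is.infinite(ratio) && ratio < peakRatioMin) {
        warning("ambiguous correlation peak (ratio ",
                round(ratio, 3), "); applying zero shift")
        shift <- c(0, 0, 0)
    }
    ## sub-voxel residual estimate from a 1D parabolic fit per axis
    resid <- vapply(1:3, function(k) {
        idx <- peak
        val <- function(o) {
            idx2 <- idx
            idx2[k] <- idx2[k] + o
            if (idx2[k] < 1 || idx2[k] > dim(sub)[k]) return(NA_real_)
            sub[idx2[1], idx2[2], idx2[3]]
        }
        y0 <- val(-1); y1 <- val(0); y2 <- val(1)
        if (any(is.na(c(y0, y1, y2))) || (y0 - 2 * y1 + y2) == 0) 0
        else abs(0.5 * (y0 - y2) / (y0 - 2 * y1 + y2))
    }, numeric(1))
    aligned <- moving
    aligned@data <- shiftVolume(moving@data, -shift)
    list(shift = shift, aligned = aligned,
         residual = sqrt(sum(resid^2)), peakRatio = ratio)
}

#' Baseline subtraction with grey-value clipping
#'
#' diff = follow-up minus baseline: positive change means attenuation
#' increased against free-flowing blood (red-thrombus candidate), negative
#' means it decreased (white-thrombus or air candidate). The stored `data`
#' is clipped to `clip` (default -200..+150 grey values); the unclipped
#' difference is retained for volumetry and air disambiguation.
#'
#' @param baseline,followup aligned [ReconVolume]s
#' @param clip c(low, high) grey clip range
#' @param shift alignment shift that was applied (bookkeeping)
#' @param alignResidual estimated residual misalignment (voxels)
#' @return a [DiffVolume]
#' @export
subtractBaseline <- function(baseline, followup, clip = c(-200, 150),
                             shift = c(0, 0, 0), alignResidual = 0) {
    if (!identical(dim(baseline@data), dim(followup@data)))
        stop("volume shapes differ")
    raw <- followup@data - baseline@data
    clipped <- pmin(pmax(raw, clip[1]), clip[2])
    dim(clipped) <- dim(raw)
    new("DiffVolume", data = clipped, raw = raw, clipRange = clip,
        baselineIndex = baseline@scanIndex, followupIndex = followup@scanIndex,
        shift = shift, alignResidual = alignResidual,
        voxelSize = baseline@voxelSize, origin = baseline@origin)
}

labelComponents <- function(mask, mode) {
    d <- dim(mask)
    if (mode == "3d") {
        lab <- cpp_label_cc(as.logical(mask), d, 26L)
        dim(lab) <- d
        lab
    } else {
        lab <- array(0L, d)
        offset <- 0L
        for (k in seq_len(d[3])) {
            sl <- cpp_label_cc(as.logical(mask[, , k]), c(d[1], d[2], 1L), 8L)
            nsl <- attr(sl, "n_components")
            sl[sl > 0L] <- sl[sl > 0L] + offset
            lab[, , k] <- sl
            offset <- offset + nsl
        }
        lab
    }
}

componentShapeStats <- function(coords) {
    n <- nrow(coords)
    bbox <- apply(coords, 2, range)
    bboxVol <- prod(bbox[2, ] - bbox[1, ] + 1)
    compactness <- n / bboxVol
    if (n < 4) return(list(elongation = 1, planarity = 1, thickness = 1,
                           compactness = compactness, bbox = bbox))
    ev <- sort(eigen(stats::cov(coords), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    ev <- pmax(ev, 1e-12)
    list(elongation = sqrt(ev[2] / ev[1]),  # small for line-like shapes
         planarity = sqrt(ev[3] / ev[2]),   # small for sheet-like shapes
         thickness = sqrt(ev[3]),           # sd along the smallest axis (vox)
         compactness = compactness, bbox = bbox)
}

## half-maximum volumetry: count voxels connected to the component peak whose
## smoothed magnitude exceeds half the component plateau (the median of
## values within 75% of the peak), robust to blur and to noise on the peak
halfMaxCount <- function(smoothed, coords, sign, d) {
    vals <- sign * smoothed[coords]
    pk <- which.max(vals)
    peakVal <- median(vals[vals >= 0.75 * vals[pk]])
    if (is.na(peakVal) || peakVal <= 0) return(length(vals))
    bbox <- apply(arrayIndFromLinear(coords, d), 2, range)
    margin <- 3L
    lo <- pmax(bbox[1, ] - margin, 1L)
    hi <- pmin(bbox[2, ] + margin, d)
    subArr <- sign * smoothed[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3],
                              drop = FALSE]
    subMask <- subArr >= peakVal / 2
    subd <- dim(subArr)
    lab <- cpp_label_cc(as.logical(subMask), subd, 26L)
    dim(lab) <- subd
    pkIdx <- arrayIndFromLinear(coords[pk], d) - rbind(lo) + 1L
    pkLab <- lab[pkIdx[1], pkIdx[2], pkIdx[3]]
    if (pkLab == 0L) length(vals) else sum(lab == pkLab)
}

arrayIndFromLinear <- function(i, d) {
    i0 <- i - 1L
    z <- i0 %/% (d[1] * d[2])
    rem <- i0 %% (d[1] * d[2])
    cbind(rem %% d[1] + 1L, rem %/% d[1] + 1L, z + 1L)
}

#' Segment red and white thrombotic deposits in a difference volume
#'
#' Thresholds the clipped difference at `tauPos` / `tauNeg`, labels
#' connected components (26-connectivity in 3D, 8-connectivity per slice in
#' 2D mode), discards components not larger than `minSize` voxels (strict
#' "greater than"), rejects low edge-contrast components and, optionally,
#' line/sheet-like low-compactness components (the fiber-adjacent
#' parallel-line alteration class), then classifies survivors by sign:
#' positive change = red, negative = white.
#'
#' Detection operates on a pre-smoothed copy of the unclipped difference
#' (`presmooth` passes of a separable 3-tap binomial kernel, default 2),
#' a matched-filter step that makes compact multi-voxel deposits
#' detectable at realistic reconstruction noise; with `presmooth = 0` the
#' clipped difference is thresholded voxel-by-voxel (the plain subtraction
#' semantics). Default thresholds are +/- 3 robust standard deviations
#' (1.4826 x MAD) of the detection field, floored at 5% of the clip span
#' so that near-noiseless data do not degenerate to a zero threshold.
#' Reconstruction noise after filtered back-projection is streak-correlated
#' rather than white, so suprathreshold noise clusters larger than
#' `minSize` do occur; a component is therefore also required to contain a
#' peak of at least `peakSigmaMin` robust standard deviations (the
#' cluster-forming-plus-peak rule), which separates genuine deposits from
#' correlated noise by an order of magnitude at the default conditions.
#' Reported volumes use half-maximum volumetry on the lightly smoothed
#' unclipped difference (threshold at half the component plateau, the
#' median of values within 75% of the peak), which is robust to both
#' reconstruction blur and noise.
#'
#' @param diff a [DiffVolume]
#' @param tauPos,tauNeg detection thresholds (grey); NULL for automatic
#' @param minSize minimum component size (voxels, strict >)
#' @param edgeContrastMin minimum edge-contrast score (95th percentile of
#'   the detection-field gradient magnitude over the component, divided by
#'   the robust background gradient level)
#' @param mode "3d" or "2d" (per-slice)
#' @param rejectAnisotropic drop line/sheet-like low-compactness components
#' @param presmooth binomial pre-smoothing passes for the detection field
#'   (0 = threshold the clipped difference directly)
#' @param peakSigmaMin minimum component peak in robust sd units
#' @return a [ThrombusSegmentation]
#' @export
segmentThrombi <- function(diff, tauPos = NULL, tauNeg = NULL, minSize = 30,
                           edgeContrastMin = 2, mode = c("3d", "2d"),
                           rejectAnisotropic = TRUE, presmooth = 2,
                           peakSigmaMin = 12) {
    mode <- match.arg(mode)
    clipped <- diff@data
    raw <- diff@raw
    span <- diff@clipRange[2] - diff@clipRange[1]
    floorTau <- 0.05 * span
    field <- if (presmooth > 0) raw else clipped
    for (i in seq_len(presmooth)) field <- boxSmooth3(field)
    s <- stats::mad(field)
    sEff <- max(s, floorTau / 3)
    if (is.null(tauPos)) tauPos <- max(3 * s, floorTau)
    if (is.null(tauNeg)) tauNeg <- -max(3 * s, floorTau)
    if (tauPos <= 0 || tauNeg >= 0) stop("need tauPos > 0 > tauNeg")
    if (tauPos > diff@clipRange[2] || tauNeg < diff@clipRange[1])
        stop("thresholds outside the clip range")
    d <- dim(clipped)
    smoothed <- boxSmooth3(raw)
    grad <- gradientMagnitude(field)
    gradBg <- max(stats::mad(grad, center = 0), 1e-3)
    out <- array(0L, d)
    rows <- list()
    nextId <- 0L
    voxelVol <- diff@voxelSize^3
    for (sgn in c(1, -1)) {
        mask <- if (sgn > 0) field > tauPos else field < tauNeg
        if (!any(mask)) next
        lab <- labelComponents(mask, mode)
        sizes <- tabulate(lab[lab > 0L])
        for (id in which(sizes > minSize)) {
            coords <- which(lab == id)
            if (max(sgn * field[coords]) < peakSigmaMin * sEff) next
            meanDiff <- mean(raw[coords])
            ci <- arrayIndFromLinear(coords, d)
            ## edge contrast: strong-gradient content of the component and
            ## its one-voxel shell (central differences vanish on ridges
            ## thinner than two voxels) against the background noise level
            shell <- coords
            for (k in 1:3) {
                step <- c(1L, d[1], d[1] * d[2])[k]
                up <- coords[ci[, k] < d[k]] + step
                dn <- coords[ci[, k] > 1L] - step
                shell <- c(shell, up, dn)
            }
            shell <- unique(shell)
            edgeContrast <- quantile(grad[shell], 0.95, names = FALSE) / gradBg
            if (edgeContrast < edgeContrastMin) next
            ## fiber-adjacent parallel-line artifacts are strongly
            ## anisotropic and at most about one voxel thick; genuine
            ## strand-like thrombi keep a multi-voxel cross-section
            st <- componentShapeStats(ci)
            if (rejectAnisotropic &&
                (st$elongation < 0.15 || st$planarity < 0.15) &&
                st$thickness < 0.8) next
            nextId <- nextId + 1L
            out[coords] <- nextId
            hm <- halfMaxCount(smoothed, coords, sgn, d)
            ctr <- diff@origin + (colMeans(ci) - 0.5) * diff@voxelSize
            vals <- raw[coords]
            coreDiff <- median(vals[sgn * vals >= quantile(sgn * vals, 0.5)])
            rows[[nextId]] <- data.frame(
                id = nextId,
                class = if (sgn > 0) "red" else "white",
                voxels = length(coords),
                voxels_halfmax = hm,
                volume_mm3 = hm * voxelVol,
                centroid_x = ctr[1], centroid_y = ctr[2], centroid_z = ctr[3],
                mean_diff = meanDiff,
                core_diff = coreDiff,
                edge_contrast = edgeContrast,
                elongation = st$elongation,
                planarity = st$planarity,
                thickness = st$thickness,
                compactness = st$compactness,
                bbox_x0 = st$bbox[1, 1], bbox_x1 = st$bbox[2, 1],
                bbox_y0 = st$bbox[1, 2], bbox_y1 = st$bbox[2, 2],
                bbox_z0 = st$bbox[1, 3], bbox_z1 = st$bbox[2, 3],
                stringsAsFactors = FALSE)
        }
    }
    cmp <- if (length(rows)) do.call(rbind, rows) else
        cbind(data.frame(id = integer(), class = character(),
                         voxels = integer(), voxels_halfmax = integer(),
                         volume_mm3 = numeric(), centroid_x = numeric(),
                         centroid_y = numeric(), centroid_z = numeric(),
                         mean_diff = numeric(), core_diff = numeric(),
                         edge_contrast = numeric(), elongation = numeric(),
                         planarity = numeric(), thickness = numeric(),
                         compactness = numeric(),
                         bbox_x0 = integer(), bbox_x1 = integer(),
                         bbox_y0 = integer(), bbox_y1 = integer(),
                         bbox_z0 = integer(), bbox_z1 = integer()))
    new("ThrombusSegmentation", labelVolume = out, components = cmp,
        voxelSize = diff@voxelSize, origin = diff@origin,
        params = list(tauPos = tauPos, tauNeg = tauNeg, minSize = minSize,
                      edgeContrastMin = edgeContrastMin, mode = mode,
                      rejectAnisotropic = rejectAnisotropic,
                      presmooth = presmooth, peakSigmaMin = peakSigmaMin))
}


#' Flag white components consistent with air bubbles
#'
#' The subtraction method cannot distinguish platelet/fibrin-rich (white)
#' thrombus from trapped air by sign alone: both lower the attenuation
#' against blood, but air lowers it much further. White components whose
#' core grey change is below `airLevel` are relabeled `ambiguous_air`.
#' The default corresponds to half the blood-to-air contrast under the
#' default grey scaling (blood at grey 1000), comfortably below any
#' plausible white-thrombus contrast.
#'
#' @param segmentation a [ThrombusSegmentation]
#' @param diff the [DiffVolume] it came from (unused except for validation;
#'   kept so alternative magnitude estimates can be derived)
#' @param airLevel core-change threshold (grey) separating air from white
#'   thrombus
#' @return the relabeled [ThrombusSegmentation]
#' @export
flagAirAmbiguity <- function(segmentation, diff = NULL, airLevel = -500) {
    cmp <- segmentation@components
    if (!nrow(cmp)) return(segmentation)
    hit <- cmp$class == "white" & cmp$core_diff < airLevel
    cmp$class[hit] <- "ambiguous_air"
    segmentation@components <- cmp
    segmentation
}

#' Quantify a thrombus segmentation
#'
#' Per-class totals (volume from voxel count times voxel volume, using the
#' partial-volume-corrected half-maximum counts), component counts, and
#' per-component centroids in device cylinder coordinates with a coarse
#' region assignment: "inlet_transition" near the core-to-bundle transition
#' azimuth in the lower device half, "outlet" in the top device section,
#' "bundle" elsewhere; "unknown" without a device descriptor.
#'
#' @param segmentation a [ThrombusSegmentation]
#' @param device optional [DeviceDescriptor] for region assignment
#' @return list(totals, components) where totals is a per-class data.frame
#' @export
quantifyThrombi <- function(segmentation, device = NULL) {
    cmp <- segmentation@components
    classes <- c("red", "white", "ambiguous_air")
    totals <- data.frame(
        class = classes,
        n_components = vapply(classes, function(cl) sum(cmp$class == cl), 0L),
        volume_mm3 = vapply(classes, function(cl)
            sum(cmp$volume_mm3[cmp$class == cl]), 0),
        row.names = NULL, stringsAsFactors = FALSE)
    if (!nrow(cmp))
        return(list(totals = totals,
                    components = cbind(cmp, data.frame(r_mm = numeric(),
                                                       theta_deg = numeric(),
                                                       region = character()))))
    r <- sqrt(cmp$centroid_x^2 + cmp$centroid_y^2)
    theta <- atan2(cmp$centroid_y, cmp$centroid_x) * 180 / pi
    region <- rep("unknown", nrow(cmp))
    if (!is.null(device)) {
        halfH <- device@bundleHeight / 2
        dAz <- (theta - device@inletAzimuthDeg + 180) %% 360 - 180
        nearInlet <- abs(dAz) <= 60 &
            r <= device@bundleInnerRadius +
                0.35 * (device@bundleOuterRadius - device@bundleInnerRadius) &
            cmp$centroid_z < 0
        atOutlet <- cmp$centroid_z > 0.7 * halfH
        region <- ifelse(nearInlet, "inlet_transition",
                         ifelse(atOutlet, "outlet", "bundle"))
    }
    list(totals = totals,
         components = cbind(cmp, data.frame(r_mm = r, theta_deg = theta,
                                            region = region,
                                            stringsAsFactors = FALSE)))
}
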