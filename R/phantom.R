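## Phantom construction: device geometry, material maps, thrombus insertion
## and serial growth states.

#' Material label codes used in phantom label grids
#'
#' @return named integer vector; air = 0, housing = 1, fiber = 2, blood = 3,
#'   red_thrombus = 4, white_thrombus = 5
#' @export
materialCodes <- function() {
    c(air = 0L, housing = 1L, fiber = 2L, blood = 3L,
      red_thrombus = 4L, white_thrombus = 5L)
}

materialNames <- function() names(materialCodes())

## code 6 marks homogenized-bundle voxels (mixed fiber/blood attenuation)
bundleCode <- function() 6L

#' Construct a material attenuation table
#'
#' Default coefficients respect the physically required ordering
#' red thrombus > blood > white thrombus > air (erythrocyte concentration
#' drives attenuation); the absolute values are nominal for a soft-tissue
#' regime at a fraction of a reciprocal millimetre and are freely
#' overridable.
#'
#' @param air,housing,fiber,blood,red_thrombus,white_thrombus linear
#'   attenuation coefficients (1/mm)
#' @return a [MaterialTable]
#' @examples
#' materialTable()
#' @export
materialTable <- function(air = 0, housing = 0.05, fiber = 0.04,
                          blood = 0.06, red_thrombus = 0.075,
                          white_thrombus = 0.045) {
    new("MaterialTable", mu = c(air = air, housing = housing, fiber = fiber,
                                blood = blood, red_thrombus = red_thrombus,
                                white_thrombus = white_thrombus))
}

#' Construct an oxygenator device descriptor
#'
#' The defaults describe a bench-scale neonatal-oxygenator-like device:
#' an annular bundle of 0.300 mm polypropylene fibers with 0.260 mm mean
#' gaps around an open inner blood core, inside a cylindrical housing.
#'
#' @param housingInnerRadius,housingOuterRadius housing radii (mm)
#' @param bundleInnerRadius,bundleOuterRadius bundle annulus radii (mm)
#' @param bundleHeight bundle axial extent (mm)
#' @param fiberDiameter fiber outer diameter (mm)
#' @param fiberGap mean inter-fiber gap (mm)
#' @param inletAzimuthDeg azimuth of the core-to-bundle inlet transition (deg)
#' @return a [DeviceDescriptor]
#' @export
deviceDescriptor <- function(housingInnerRadius = 7.8,
                             housingOuterRadius = 8.4,
                             bundleInnerRadius = 3.2,
                             bundleOuterRadius = 7.2,
                             bundleHeight = 10,
                             fiberDiameter = 0.300,
                             fiberGap = 0.260,
                             inletAzimuthDeg = 180) {
    new("DeviceDescriptor",
        housingInnerRadius = housingInnerRadius,
        housingOuterRadius = housingOuterRadius,
        bundleInnerRadius = bundleInnerRadius,
        bundleOuterRadius = bundleOuterRadius,
        bundleHeight = bundleHeight,
        fiberDiameter = fiberDiameter,
        fiberGap = fiberGap,
        inletAzimuthDeg = inletAzimuthDeg)
}

#' Fiber area fraction of the homogenized bundle
#'
#' Circle-packing fraction of fibers on the square lattice used by
#' [buildPhantom()]: pi (d/2)^2 / pitch^2 with pitch = diameter + gap.
#'
#' @param device a [DeviceDescriptor]
#' @return scalar in (0, 1)
#' @export
fiberVolumeFraction <- function(device) {
    pitch <- device@fiberDiameter + device@fiberGap
    pi * (device@fiberDiameter / 2)^2 / pitch^2
}

voxelCenters1D <- function(n, voxel, origin) origin + (seq_len(n) - 0.5) * voxel

#' Build a voxelized oxygenator phantom
#'
#' Generates the material label grid and matching attenuation grid for the
#' device: air outside the housing, the housing shell, a regular square
#' lattice of fibers (pitch = fiber diameter + gap) inside the bundle
#' annulus, and blood in every other voxel inside the housing. With
#' `homogenizeBundle = TRUE` the bundle annulus is not resolved into
#' individual fibers; its voxels receive the fiber-fraction-weighted mean
#' attenuation of fiber and blood instead, which is also the only supported
#' mode when the voxel size exceeds the inter-fiber gap.
#'
#' @param device a [DeviceDescriptor]
#' @param materials a [MaterialTable]
#' @param n grid size, scalar or length-3 (voxels)
#' @param voxel isotropic voxel edge length (mm)
#' @param homogenizeBundle replace the fiber lattice by its volume-weighted
#'   mean attenuation
#' @return an [AttenuationPhantom]
#' @examples
#' ph <- buildPhantom(n = 48, voxel = 0.4, homogenizeBundle = TRUE)
#' ph
#' @export
buildPhantom <- function(device = deviceDescriptor(),
                         materials = materialTable(),
                         n = 128, voxel = 0.15,
                         homogenizeBundle = FALSE) {
    if (voxel <= 0) stop("voxel size must be > 0")
    if (voxel > device@fiberGap && !homogenizeBundle)
        stop("resolution too coarse: voxel size ", voxel,
             " mm exceeds the inter-fiber gap ", device@fiberGap,
             " mm; set homogenizeBundle = TRUE or refine the grid")
    n <- as.integer(rep(n, length.out = 3))
    origin <- -n * voxel / 2
    x <- voxelCenters1D(n[1], voxel, origin[1])
    y <- voxelCenters1D(n[2], voxel, origin[2])
    z <- voxelCenters1D(n[3], voxel, origin[3])
    if (max(abs(c(range(x), range(y)))) < device@housingOuterRadius)
        stop("grid too small: housing extends beyond the field of view")

    r2 <- outer(x^2, y^2, "+")
    r <- sqrt(r2)
    codes <- materialCodes()

    ## 2D (x, y) template for the in-device axial range
    plane <- matrix(codes[["air"]], n[1], n[2])
    plane[r < device@housingOuterRadius] <- codes[["housing"]]
    plane[r < device@housingInnerRadius] <- codes[["blood"]]
    inBundle <- r >= device@bundleInnerRadius & r < device@bundleOuterRadius
    if (!homogenizeBundle) {
        pitch <- device@fiberDiameter + device@fiberGap
        ## nearest square-lattice fiber centre (lattice node at the origin)
        dx <- x - round(x / pitch) * pitch
        dy <- y - round(y / pitch) * pitch
        nearest2 <- outer(dx^2, dy^2, "+")
        fiber <- inBundle & nearest2 <= (device@fiberDiameter / 2)^2
        plane[fiber] <- codes[["fiber"]]
    }

    halfH <- device@bundleHeight / 2
    capH <- halfH + min(1, voxel * 4)  # housing extends slightly past bundle
    labels <- array(codes[["air"]], n)
    inDev <- abs(z) <= capH
    labels[, , inDev] <- plane
    ## outside the housing axial range everything is air; within the cap zone
    ## but outside the bundle height the annulus holds blood, not fiber
    capOnly <- which(inDev & abs(z) > halfH)
    if (length(capOnly) && !homogenizeBundle) {
        planeCap <- plane
        planeCap[plane == codes[["fiber"]]] <- codes[["blood"]]
        labels[, , capOnly] <- planeCap
    }

    muBundle <- numeric(0)
    if (homogenizeBundle) {
        f <- fiberVolumeFraction(device)
        muBundle <- f * materials@mu[["fiber"]] +
            (1 - f) * materials@mu[["blood"]]
        bundleMask <- array(FALSE, n)
        bundleMask[, , which(inDev & abs(z) <= halfH)] <- inBundle
        labels[bundleMask] <- bundleCode()
    }
    mu <- c(materials@mu[materialNames()], muBundle)[labels + 1L]
    dim(mu) <- n

    ph <- new("AttenuationPhantom", labels = labels, mu = mu,
              voxelSize = voxel, origin = origin, device = device,
              materials = materials, bundleMu = muBundle,
              thrombi = emptyThrombusTable())
    validObject(ph)
    ph
}

emptyThrombusTable <- function() {
    data.frame(id = integer(), class = character(), shape = character(),
               center_r = numeric(), center_theta = numeric(),
               center_z = numeric(), voxels = integer(),
               volume_mm3 = numeric(), analytic_mm3 = numeric(),
               clipped_fraction = numeric(), stringsAsFactors = FALSE)
}

#' Construct a thrombus specification
#'
#' @param class "red", "white", or "air" (air bubble, for the
#'   white-vs-air ambiguity experiments)
#' @param shape "ellipsoid" or "strand" (fiber-hugging sheath)
#' @param center c(r (mm), theta (deg), z (mm)) in device cylinder coordinates
#' @param axes ellipsoid semi-axes (mm) along x/y/z, or strand
#'   (radial thickness, arc length, axial length) in mm
#' @param firstScan first serial scan at which the thrombus is present
#' @param growthFactor reserved per-scan growth multiplier
#' @return a [ThrombusSpec]
#' @export
thrombusSpec <- function(class = c("red", "white", "air"),
                         shape = c("ellipsoid", "strand"),
                         center = c(1.5, 180, 0),
                         axes = c(0.8, 0.8, 0.8),
                         firstScan = 8, growthFactor = 1) {
    new("ThrombusSpec", type = match.arg(class), shape = match.arg(shape),
        center = center, axes = axes, firstScan = firstScan,
        growthFactor = growthFactor)
}

thrombusVoxelMask <- function(phantom, spec, scale = 1) {
    n <- dim(phantom@labels)
    voxel <- phantom@voxelSize
    x <- voxelCenters1D(n[1], voxel, phantom@origin[1])
    y <- voxelCenters1D(n[2], voxel, phantom@origin[2])
    z <- voxelCenters1D(n[3], voxel, phantom@origin[3])
    th <- spec@center[2] * pi / 180
    cx <- spec@center[1] * cos(th)
    cy <- spec@center[1] * sin(th)
    cz <- spec@center[3]
    s <- scale^(1 / 3)  # scale is a volume fraction
    if (spec@shape == "ellipsoid") {
        a <- spec@axes * s
        ex <- ((x - cx) / a[1])^2
        ey <- ((y - cy) / a[2])^2
        ez <- ((z - cz) / a[3])^2
        mask <- outer(outer(ex, ey, "+"), ez, "+") <= 1
    } else {
        ## fiber-hugging strand: a partial annular sheath centred on radius
        ## center_r with radial thickness axes[1], azimuthal arc axes[2]
        ## (arc length at center_r) and axial extent axes[3]
        r <- sqrt(outer(x^2, y^2, "+"))
        ang <- atan2(outer(rep(1, length(x)), y), outer(x, rep(1, length(y))))
        dang <- (ang - th + pi) %% (2 * pi) - pi
        arcHalf <- (spec@axes[2] * s / 2) / max(spec@center[1], 1e-6)
        plane <- abs(r - spec@center[1]) <= spec@axes[1] * s / 2 &
            abs(dang) <= arcHalf
        zmask <- abs(z - cz) <= spec@axes[3] * s / 2
        mask <- array(FALSE, n)
        mask[, , which(zmask)] <- plane
    }
    mask
}

#' Insert thrombi (or air bubbles) into a phantom
#'
#' Relabels blood voxels inside each specification's shape as red or white
#' thrombus (or air). Voxels of the shape that fall on fiber, housing or
#' outside-device air are clipped to the blood compartment and the clipped
#' fraction is recorded in the ground-truth table; a fully clipped thrombus
#' yields a warning and zero volume.
#'
#' @param phantom an [AttenuationPhantom]
#' @param specs list of [ThrombusSpec] objects (or a single spec)
#' @param scale volume fraction 0..1 applied to every spec (growth state)
#' @return a new [AttenuationPhantom]; total voxel count is conserved
#' @export
insertThrombi <- function(phantom, specs, scale = 1) {
    if (is(specs, "ThrombusSpec")) specs <- list(specs)
    if (!length(specs) || scale == 0) return(phantom)
    codes <- materialCodes()
    labels <- phantom@labels
    mu <- phantom@mu
    muTab <- phantom@materials@mu
    tab <- phantom@thrombi
    voxel <- phantom@voxelSize
    for (i in seq_along(specs)) {
        spec <- specs[[i]]
        mask <- thrombusVoxelMask(phantom, spec, scale = scale)
        total <- sum(mask)
        keep <- mask & labels == codes[["blood"]]
        kept <- sum(keep)
        if (total > 0 && kept == 0)
            warning("thrombus ", i, " is fully clipped by non-blood voxels; ",
                    "zero volume inserted")
        lab <- switch(spec@type, red = "red_thrombus",
                      white = "white_thrombus", air = "air")
        labels[keep] <- codes[[lab]]
        mu[keep] <- muTab[[lab]]
        analytic <- if (spec@shape == "ellipsoid")
            4 / 3 * pi * prod(spec@axes) * scale else prod(spec@axes) * scale
        tab <- rbind(tab, data.frame(
            id = nrow(tab) + 1L, class = spec@type, shape = spec@shape,
            center_r = spec@center[1], center_theta = spec@center[2],
            center_z = spec@center[3], voxels = kept,
            volume_mm3 = kept * voxel^3, analytic_mm3 = analytic,
            clipped_fraction = if (total > 0) 1 - kept / total else 1,
            stringsAsFactors = FALSE))
    }
    out <- phantom
    out@labels <- labels
    out@mu <- mu
    out@thrombi <- tab
    validObject(out)
    out
}

#' Default serial-scan growth schedule
#'
#' Per-scan thrombus volume fractions for `nScans` serial scans: the
#' baseline scan carries no thrombus, intermediate scans grow slowly to 15%
#' of the final volume, and the bulk (85%) appears between the last two
#' scans, emulating a late severe clotting event.
#'
#' @param nScans number of serial scans (>= 2)
#' @return numeric vector of volume fractions, length `nScans`
#' @export
defaultGrowthSchedule <- function(nScans = 8) {
    if (nScans < 2) stop("nScans must be >= 2")
    if (nScans == 2) return(c(0, 1))
    c(0, 0.15 * seq_len(nScans - 2) / (nScans - 2), 1)
}

#' Simulate a serial scan series of growing thrombi
#'
#' Returns one phantom per scan. Scan 1 is thrombus-free (the baseline
#' role); thrombus volumes follow `schedule` (a volume fraction of the
#' final size per scan), with each spec appearing no earlier than its
#' `firstScan`. The default schedule places >= 80% of the final volume
#' between the last two scans.
#'
#' @param phantom baseline [AttenuationPhantom] (no thrombi)
#' @param specs list of [ThrombusSpec]
#' @param schedule per-scan volume fractions, length `nScans`; defaults to
#'   [defaultGrowthSchedule()]
#' @param nScans number of scans
#' @return list of [AttenuationPhantom], one per scan
#' @export
simulateGrowthSeries <- function(phantom, specs, schedule = NULL, nScans = 8) {
    if (nScans < 2) stop("nScans must be >= 2")
    if (is.null(schedule)) schedule <- defaultGrowthSchedule(nScans)
    if (length(schedule) != nScans)
        stop("schedule length must equal nScans")
    if (is(specs, "ThrombusSpec")) specs <- list(specs)
    lapply(seq_len(nScans), function(i) {
        active <- Filter(function(s) i >= s@firstScan, specs)
        if (schedule[i] > 0 && length(active))
            insertThrombi(phantom, active, scale = schedule[i])
        else phantom
    })
}
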