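## Cone-beam acquisition simulation: geometry, Beer-Lambert forward
## projection with Poisson noise and detector gain structure, reference
## frames and an optional propagation-style edge-enhancement surrogate.

#' Construct a cone-beam scan geometry
#'
#' Defaults reproduce the emulated laboratory protocol: SOD 750 mm,
#' ODD 1445 mm, 1024 x 1024 detector at 0.194 mm pitch, 5000 projections
#' over 360 degrees at 7 fps.
#'
#' @param sod source-to-object distance (mm)
#' @param odd object-to-detector distance (mm)
#' @param nu,nv detector pixels
#' @param pixelPitch pixel pitch (mm)
#' @param nProjections projections over the angular range
#' @param angularRange scanned arc (degrees)
#' @param fps acquisition frame rate (1/s)
#' @param rotationDirection +1 or -1
#' @return a [ScanGeometry]
#' @export
scanGeometrySpec <- function(sod = 750, odd = 1445, nu = 1024, nv = 1024,
                             pixelPitch = 0.194, nProjections = 5000,
                             angularRange = 360, fps = 7,
                             rotationDirection = 1) {
    new("ScanGeometry", sod = sod, odd = odd, nu = as.integer(nu),
        nv = as.integer(nv), pixelPitch = pixelPitch,
        nProjections = as.integer(nProjections),
        angularRange = angularRange, fps = fps,
        rotationDirection = rotationDirection)
}

#' Bench-scale scan geometry
#'
#' A reduced geometry for desk-scale simulation studies: 256 x 256
#' detector, 400 projections, with the pixel pitch chosen so the virtual
#' detector sampling at the isocentre is `isoPixel` mm.
#'
#' @param nu,nv detector pixels
#' @param nProjections projections per 360 degrees
#' @param isoPixel virtual detector pixel size at the isocentre (mm)
#' @param sod,odd distances (mm)
#' @param fps frame rate
#' @return a [ScanGeometry]
#' @export
deskGeometry <- function(nu = 256, nv = 256, nProjections = 400,
                         isoPixel = 0.15, sod = 750, odd = 1445, fps = 7) {
    scanGeometrySpec(sod = sod, odd = odd, nu = nu, nv = nv,
                     pixelPitch = isoPixel * (sod + odd) / sod,
                     nProjections = nProjections, fps = fps)
}

geometryMagnification <- function(geometry) {
    (geometry@sod + geometry@odd) / geometry@sod
}

geometryAngles <- function(geometry) {
    n <- geometry@nProjections
    if (n == 0L) return(numeric(0))
    geometry@rotationDirection * geometry@angularRange * (seq_len(n) - 1) / n
}

#' Scan protocol summary
#'
#' Derived acquisition figures: scan duration, rotation speed and
#' geometric magnification. 5000 projections at 7 fps give 714.3 s, i.e.
#' a 12 min scan at 0.50 deg/s.
#'
#' @param geometry a [ScanGeometry]
#' @return list with duration_s, duration_min, rotation_speed_deg_s,
#'   magnification, projections_per_degree
#' @examples
#' scanProtocolSummary(scanGeometrySpec())
#' @export
scanProtocolSummary <- function(geometry) {
    if (geometry@fps <= 0) stop("frame rate must be > 0")
    dur <- geometry@nProjections / geometry@fps
    list(duration_s = dur,
         duration_min = dur / 60,
         rotation_speed_deg_s = if (dur > 0) geometry@angularRange / dur else 0,
         magnification = geometryMagnification(geometry),
         projections_per_degree = geometry@nProjections / geometry@angularRange)
}

#' Acquisition noise and artifact specification
#'
#' @param i0 empty-beam photons per detector pixel
#' @param poisson draw Poisson counting noise
#' @param darkOffset additive dark level (counts)
#' @param columnGainSigma sd of static per-column gain perturbations
#'   (shared by scan and reference frames, removed by flat-fielding)
#' @param pixelGainSigma sd of static per-pixel gain perturbations
#' @param gainDriftSigma sd of per-column gain drift between the reference
#'   frames and the scan; this uncorrected residual is the ring-artifact
#'   source surviving flat-field correction
#' @return list used by [forwardProject()] and [makeReferenceFrames()]
#' @export
noiseSpec <- function(i0 = 1e4, poisson = TRUE, darkOffset = 100,
                      columnGainSigma = 0, pixelGainSigma = 0,
                      gainDriftSigma = 0) {
    stopifnot(i0 > 0, darkOffset >= 0, columnGainSigma >= 0,
              pixelGainSigma >= 0, gainDriftSigma >= 0)
    list(i0 = i0, poisson = poisson, darkOffset = darkOffset,
         columnGainSigma = columnGainSigma, pixelGainSigma = pixelGainSigma,
         gainDriftSigma = gainDriftSigma)
}

#' Static detector gain map
#'
#' Multiplicative per-column (and optionally per-pixel) gain perturbations,
#' the classical cause of ring artifacts after reconstruction. Deterministic
#' given the seed.
#'
#' @param geometry a [ScanGeometry]
#' @param noise a [noiseSpec()]
#' @param seed integer seed
#' @return numeric (nu, nv) matrix of gains, all > 0
#' @export
makeGainMap <- function(geometry, noise = noiseSpec(), seed = 1) {
    set.seed(seed)
    colGain <- 1 + rnorm(geometry@nu, 0, noise$columnGainSigma)
    gain <- matrix(colGain, geometry@nu, geometry@nv)
    if (noise$pixelGainSigma > 0)
        gain <- gain * (1 + matrix(rnorm(length(gain), 0, noise$pixelGainSigma),
                                   nrow(gain)))
    pmax(gain, 0.05)
}

#' Flat and dark reference frames
#'
#' Flat = gain x I0 (with optional Poisson noise), dark = constant offset
#' (with optional Poisson noise); the flat exceeds the dark everywhere.
#'
#' @param geometry a [ScanGeometry]
#' @param gainMap numeric (nu, nv) gain matrix, all > 0
#' @param noise a [noiseSpec()]
#' @param seed integer seed
#' @return list(flat, dark) matrices
#' @export
makeReferenceFrames <- function(geometry, gainMap = NULL,
                                noise = noiseSpec(), seed = 1) {
    if (is.null(gainMap))
        gainMap <- matrix(1, geometry@nu, geometry@nv)
    if (any(gainMap <= 0)) stop("gain must be > 0 everywhere")
    set.seed(seed + 1L)
    flat <- gainMap * noise$i0
    dark <- matrix(noise$darkOffset, geometry@nu, geometry@nv)
    if (noise$poisson) {
        flat <- matrix(rpois(length(flat), flat), nrow(flat))
        if (noise$darkOffset > 0)
            dark <- matrix(rpois(length(dark), dark), nrow(dark))
    }
    flat <- flat + noise$darkOffset
    storage.mode(flat) <- "double"
    storage.mode(dark) <- "double"
    list(flat = flat, dark = dark)
}

## normalize projector input: a full phantom or a bare attenuation grid
asMuGrid <- function(x) {
    if (is(x, "AttenuationPhantom"))
        list(mu = x@mu, voxelSize = x@voxelSize, origin = x@origin)
    else if (is.list(x) && !is.null(x$mu)) {
        voxel <- if (is.null(x$voxelSize)) 1 else x$voxelSize
        origin <- if (is.null(x$origin)) -dim(x$mu) * voxel / 2 else x$origin
        list(mu = x$mu, voxelSize = voxel, origin = origin)
    }
    else stop("expected an AttenuationPhantom or list(mu, voxelSize, origin)")
}

## project the bounding box of the non-air voxels and verify it stays on the
## detector at every angle
checkFieldOfView <- function(phantom, geometry) {
    g <- asMuGrid(phantom)
    nz <- which(g$mu != 0, arr.ind = TRUE)
    if (!nrow(nz)) return(invisible(TRUE))
    voxel <- g$voxelSize
    lo <- g$origin + (apply(nz, 2, min) - 1) * voxel
    hi <- g$origin + apply(nz, 2, max) * voxel
    corners <- as.matrix(expand.grid(c(lo[1], hi[1]), c(lo[2], hi[2]),
                                     c(lo[3], hi[3])))
    sod <- geometry@sod
    sdd <- geometry@sod + geometry@odd
    halfU <- geometry@nu / 2 * geometry@pixelPitch
    halfV <- geometry@nv / 2 * geometry@pixelPitch
    for (a in geometryAngles(geometry)) {
        th <- a * pi / 180
        xr <- corners[, 1] * cos(th) + corners[, 2] * sin(th)
        yr <- -corners[, 1] * sin(th) + corners[, 2] * cos(th)
        m <- sdd / (sod - xr)
        if (any(sod - xr <= 0) || any(abs(yr * m) > halfU) ||
            any(abs(corners[, 3] * m) > halfV))
            stop("phantom exits the field of view at angle ",
                 round(a, 3), " deg")
    }
    invisible(TRUE)
}

#' Cone-beam forward projection of a phantom
#'
#' Ray-traced Beer-Lambert line integrals (Joseph-style trilinear sampling
#' at a fixed step of at most half a voxel) through the attenuation grid,
#' converted to detector counts gain x I0 x exp(-integral) + dark offset,
#' with optional Poisson counting noise. Deterministic given the seed.
#'
#' @param phantom an [AttenuationPhantom], or a bare attenuation grid as
#'   `list(mu, voxelSize, origin)` (e.g. an external volume read from disk)
#' @param geometry a [ScanGeometry]
#' @param noise a [noiseSpec()]
#' @param seed integer seed for gain map and Poisson draws
#' @param gainMap optional precomputed gain matrix (see [makeGainMap()])
#' @param stepFraction ray sampling step as a fraction of the voxel size
#'   (<= 0.5)
#' @return a [ProjectionStack] including matching flat/dark frames
#' @export
forwardProject <- function(phantom, geometry, noise = noiseSpec(),
                           seed = 1, gainMap = NULL, stepFraction = 0.5) {
    stopifnot(stepFraction > 0, stepFraction <= 0.5)
    g <- asMuGrid(phantom)
    checkFieldOfView(g, geometry)
    if (is.null(gainMap)) gainMap <- makeGainMap(geometry, noise, seed)
    angles <- geometryAngles(geometry)
    p <- cpp_forward_project(as.numeric(g$mu), dim(g$mu),
                             g$voxelSize, g$origin,
                             geometry@sod, geometry@sod + geometry@odd,
                             geometry@nu, geometry@nv, geometry@pixelPitch,
                             angles * pi / 180,
                             g$voxelSize * stepFraction)
    dim(p) <- c(geometry@nu, geometry@nv, length(angles))
    scanGain <- gainMap
    if (noise$gainDriftSigma > 0) {
        set.seed(seed + 3L)
        scanGain <- gainMap * pmax(1 + rnorm(geometry@nu, 0,
                                             noise$gainDriftSigma), 0.05)
    }
    counts <- as.numeric(scanGain) * noise$i0 * exp(-p)
    if (noise$poisson) {
        set.seed(seed + 2L)
        counts <- rpois(length(counts), counts)
    }
    counts <- counts + noise$darkOffset
    dim(counts) <- dim(p)
    ref <- makeReferenceFrames(geometry, gainMap, noise, seed)
    new("ProjectionStack", data = counts, angles = angles,
        flat = ref$flat, dark = ref$dark, geometry = geometry,
        i0 = noise$i0,
        provenance = list(list(stage = "forwardProject", seed = seed,
                               noise = noise, stepFraction = stepFraction)))
}

#' Line integrals without detector effects
#'
#' Convenience wrapper returning the noiseless ray-traced line integrals
#' (the ideal sinogram) of a phantom, bypassing gain, dark and noise.
#'
#' @inheritParams forwardProject
#' @return numeric array (nu, nv, nAngles) of dimensionless line integrals
#' @export
idealSinogram <- function(phantom, geometry, stepFraction = 0.5) {
    g <- asMuGrid(phantom)
    checkFieldOfView(g, geometry)
    angles <- geometryAngles(geometry)
    p <- cpp_forward_project(as.numeric(g$mu), dim(g$mu),
                             g$voxelSize, g$origin,
                             geometry@sod, geometry@sod + geometry@odd,
                             geometry@nu, geometry@nv, geometry@pixelPitch,
                             angles * pi / 180,
                             g$voxelSize * stepFraction)
    dim(p) <- c(geometry@nu, geometry@nv, length(angles))
    p
}

#' Propagation-style edge enhancement (phase-contrast surrogate)
#'
#' Adds a strength-scaled negative discrete Laplacian of each projection to
#' itself, mimicking the bright/dark fringe pairs of near-field
#' propagation-based phase contrast. Strength 0 is the identity; a uniform
#' frame is unchanged.
#'
#' @param projections numeric array (nu, nv, nAngles) or matrix (nu, nv)
#' @param strength nonnegative enhancement strength (pixels^2)
#' @return array of the same shape
#' @export
edgeEnhance <- function(projections, strength) {
    if (strength < 0) stop("strength must be >= 0")
    if (strength == 0) return(projections)
    lap2 <- function(m) {
        up <- m[c(1, seq_len(nrow(m) - 1)), , drop = FALSE]
        dn <- m[c(seq_len(nrow(m) - 1) + 1, nrow(m)), , drop = FALSE]
        lf <- m[, c(1, seq_len(ncol(m) - 1)), drop = FALSE]
        rt <- m[, c(seq_len(ncol(m) - 1) + 1, ncol(m)), drop = FALSE]
        up + dn + lf + rt - 4 * m
    }
    if (is.matrix(projections))
        return(projections - strength * lap2(projections))
    out <- projections
    for (k in seq_len(dim(projections)[3]))
        out[, , k] <- projections[, , k] - strength * lap2(projections[, , k])
    out
}
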