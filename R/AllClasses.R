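#' @useDynLib oxyCT, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats fft mad median quantile rnorm rpois runif sd setNames
#' @importFrom utils head read.csv tail write.csv
NULL

## Central S4 containers for the CT thrombus-imaging pipeline. Array axis
## convention throughout: volumes are (x, y, z) with the device axis along z
## and voxel centres at origin + (i - 0.5) * voxelSize for 1-based index i;
## projection stacks are (u, v, angle).

#' Linear attenuation coefficients per material
#'
#' Maps the six phantom materials (air, housing, fiber, blood, red_thrombus,
#' white_thrombus) to linear attenuation coefficients in 1/mm. Validity
#' enforces the physical ordering red thrombus > blood > white thrombus >
#' air: erythrocyte-rich clot attenuates more than flowing whole blood,
#' platelet/fibrin-rich clot less, air least.
#'
#' @slot mu named numeric vector of attenuation coefficients (1/mm)
#' @export
setClass("MaterialTable", representation(mu = "numeric"))

setValidity("MaterialTable", function(object) {
    need <- c("air", "housing", "fiber", "blood", "red_thrombus",
              "white_thrombus")
    mu <- object@mu
    if (!all(need %in% names(mu)))
        return(paste("missing materials:",
                     paste(setdiff(need, names(mu)), collapse = ", ")))
    if (any(!is.finite(mu)) || any(mu < 0))
        return("attenuation coefficients must be finite and >= 0")
    if (!(mu[["red_thrombus"]] > mu[["blood"]] &&
          mu[["blood"]] > mu[["white_thrombus"]] &&
          mu[["white_thrombus"]] > mu[["air"]]))
        return("ordering violated: need red_thrombus > blood > white_thrombus > air")
    TRUE
})

#' Oxygenator device geometry descriptor
#'
#' Describes a hollow-fiber membrane oxygenator with an annular fiber bundle
#' around an open inner blood core, enclosed in a cylindrical housing. Blood
#' enters through the inner core and crosses into the bundle at a punctual
#' transition at azimuth `inletAzimuthDeg` (degrees, 0 = +x axis); the outlet
#' sits at the top of the device on the opposite side.
#'
#' @slot housingInnerRadius,housingOuterRadius housing shell radii (mm)
#' @slot bundleInnerRadius,bundleOuterRadius fiber-bundle annulus radii (mm)
#' @slot bundleHeight axial extent of the fiber bundle (mm)
#' @slot fiberDiameter outer fiber diameter (mm); 0.300 for the modelled device
#' @slot fiberGap mean gap between neighbouring fibers (mm); 0.260
#' @slot inletAzimuthDeg azimuth of the core-to-bundle inlet transition (deg)
#' @export
setClass("DeviceDescriptor", representation(
    housingInnerRadius = "numeric",
    housingOuterRadius = "numeric",
    bundleInnerRadius = "numeric",
    bundleOuterRadius = "numeric",
    bundleHeight = "numeric",
    fiberDiameter = "numeric",
    fiberGap = "numeric",
    inletAzimuthDeg = "numeric"))

setValidity("DeviceDescriptor", function(object) {
    v <- c(object@housingInnerRadius, object@housingOuterRadius,
           object@bundleInnerRadius, object@bundleOuterRadius,
           object@bundleHeight, object@fiberDiameter, object@fiberGap)
    if (any(!is.finite(v)) || any(v <= 0))
        return("all geometric quantities must be finite and > 0")
    if (!(object@bundleInnerRadius < object@bundleOuterRadius))
        return("bundle inner radius must be < outer radius")
    if (!(object@bundleOuterRadius < object@housingInnerRadius))
        return("bundle outer radius must be < housing inner radius")
    if (!(object@housingInnerRadius < object@housingOuterRadius))
        return("housing inner radius must be < outer radius")
    TRUE
})

#' Voxelized attenuation phantom
#'
#' Ground-truth digital phantom: a 3D grid of material labels and the matching
#' attenuation grid (labels mapped through a [MaterialTable]). The thrombus
#' table records per-thrombus ground truth (voxel counts, analytic volumes,
#' clipping) for later recovery experiments.
#'
#' @slot labels integer 3D array of material codes (see [materialCodes()]);
#'   code 6 marks homogenized-bundle voxels
#' @slot mu numeric 3D array of attenuation (1/mm), labels mapped through
#'   the material table voxel-by-voxel
#' @slot bundleMu homogenized-bundle mean attenuation (1/mm), length 0 when
#'   the fiber lattice is resolved explicitly
#' @slot voxelSize isotropic voxel edge length (mm)
#' @slot origin world position (mm) of the grid corner; the device axis is
#'   the z axis through the grid centre
#' @slot device [DeviceDescriptor]
#' @slot materials [MaterialTable]
#' @slot thrombi data.frame of ground-truth thrombus records
#' @export
setClass("AttenuationPhantom", representation(
    labels = "array",
    mu = "array",
    voxelSize = "numeric",
    origin = "numeric",
    device = "DeviceDescriptor",
    materials = "MaterialTable",
    bundleMu = "numeric",
    thrombi = "data.frame"))

setValidity("AttenuationPhantom", function(object) {
    if (length(dim(object@labels)) != 3L) return("labels must be a 3D array")
    if (!identical(dim(object@labels), dim(object@mu)))
        return("labels and mu grids must have identical dimensions")
    if (length(object@voxelSize) != 1L || object@voxelSize <= 0)
        return("voxelSize must be a single positive number")
    if (length(object@origin) != 3L) return("origin must be length 3")
    ## spot-check the label -> mu mapping on a deterministic subsample
    idx <- unique(round(seq(1L, length(object@labels),
                            length.out = min(4096L, length(object@labels)))))
    lookup <- c(object@materials@mu[materialNames()],
                bundle = if (length(object@bundleMu)) object@bundleMu else NA_real_)
    mu <- lookup[object@labels[idx] + 1L]
    if (any(is.na(mu)) || any(abs(mu - object@mu[idx]) > 1e-12))
        return("mu grid is not the material grid mapped through the material table")
    TRUE
})

#' Specification of a single simulated thrombus
#'
#' @slot type "red" (erythrocyte-rich, attenuation above blood) or "white"
#'   (platelet/fibrin-rich, attenuation below blood); "air" is also accepted
#'   to plant an air bubble for ambiguity experiments
#' @slot shape "ellipsoid" or "strand" (fiber-hugging sheath segment)
#' @slot center cylinder coordinates c(r (mm), theta (deg), z (mm)) on the
#'   device axis frame
#' @slot axes for ellipsoids: semi-axes (mm) along (x, y, z); for strands:
#'   c(radial thickness, azimuthal arc length, axial length) in mm
#' @slot firstScan serial scan index at which the thrombus first appears
#' @slot growthFactor reserved per-scan multiplicative growth factor
#' @export
setClass("ThrombusSpec", representation(
    type = "character",
    shape = "character",
    center = "numeric",
    axes = "numeric",
    firstScan = "numeric",
    growthFactor = "numeric"))

setValidity("ThrombusSpec", function(object) {
    if (!object@type %in% c("red", "white", "air"))
        return("type must be 'red', 'white' or 'air'")
    if (!object@shape %in% c("ellipsoid", "strand"))
        return("shape must be 'ellipsoid' or 'strand'")
    if (length(object@center) != 3L) return("center must be c(r, theta, z)")
    if (length(object@axes) != 3L || any(object@axes <= 0))
        return("axes must be 3 positive numbers")
    if (object@firstScan < 1) return("firstScan must be >= 1")
    TRUE
})

#' Cone-beam scan geometry
#'
#' Circular cone-beam CT acquisition geometry. The defaults mirror the
#' laboratory setup the package emulates: source-object distance 750 mm,
#' object-detector distance 1445 mm, a 1024 x 1024 flat-panel detector with
#' 0.194 mm pixel pitch, 5000 projections over 360 degrees at 7 fps.
#'
#' @slot sod source-to-object (isocentre) distance (mm)
#' @slot odd object-to-detector distance (mm)
#' @slot nu,nv detector pixels along u (transaxial) and v (axial)
#' @slot pixelPitch detector pixel pitch (mm)
#' @slot nProjections projections per angular range
#' @slot angularRange scanned arc (degrees); FDK requires 360
#' @slot fps image acquisition frequency (frames/s)
#' @slot rotationDirection +1 counter-clockwise, -1 clockwise
#' @export
setClass("ScanGeometry", representation(
    sod = "numeric", odd = "numeric",
    nu = "integer", nv = "integer",
    pixelPitch = "numeric",
    nProjections = "integer",
    angularRange = "numeric",
    fps = "numeric",
    rotationDirection = "numeric"))

setValidity("ScanGeometry", function(object) {
    if (object@sod <= 0 || object@odd <= 0 || object@pixelPitch <= 0)
        return("distances and pixel pitch must be > 0")
    if (object@nu < 2L || object@nv < 1L)
        return("detector must be at least 2 x 1 pixels")
    if (object@nProjections < 0L) return("nProjections must be >= 0")
    if (object@angularRange <= 0) return("angularRange must be > 0")
    if (!object@rotationDirection %in% c(-1, 1))
        return("rotationDirection must be +1 or -1")
    TRUE
})

#' Stack of raw cone-beam projections
#'
#' Detector intensities (photon counts) per projection angle, together with
#' the flat (empty-beam) and dark (no-beam) reference frames needed for
#' flat-field correction and the acquisition geometry.
#'
#' @slot data numeric array (nu, nv, nAngles) of detector counts
#' @slot angles projection angles (degrees)
#' @slot flat,dark reference frames, numeric (nu, nv)
#' @slot geometry [ScanGeometry]
#' @slot i0 empty-beam photons per pixel used for simulation
#' @slot provenance list of stage parameter records
#' @export
setClass("ProjectionStack", representation(
    data = "array",
    angles = "numeric",
    flat = "matrix",
    dark = "matrix",
    geometry = "ScanGeometry",
    i0 = "numeric",
    provenance = "list"))

setValidity("ProjectionStack", function(object) {
    d <- dim(object@data)
    if (length(d) != 3L) return("data must be (u, v, angle)")
    if (d[3] != length(object@angles))
        return("stack depth must equal the number of angles")
    if (any(object@data < 0)) return("intensities must be >= 0")
    if (!identical(dim(object@flat), d[1:2]) ||
        !identical(dim(object@dark), d[1:2]))
        return("flat/dark frames must match the detector shape")
    if (any(object@flat <= object@dark))
        return("flat field must exceed dark field everywhere")
    TRUE
})

#' Reconstructed grey-value volume
#'
#' One FDK-reconstructed 3D scan. Grey values are attenuation times a global
#' grey scale chosen so that free-flowing blood maps to a fixed target
#' (default 1000), which keeps baseline-subtraction ranges comparable across
#' scans.
#'
#' @slot data numeric 3D array (x, y, z) of grey values
#' @slot voxelSize isotropic voxel size (mm)
#' @slot origin grid corner position (mm)
#' @slot scanIndex serial scan role (1 = baseline CT1, ... 8 = CT8)
#' @slot greyScale multiplicative grey scale applied to attenuation (mm)
#' @slot geometry [ScanGeometry] used for the acquisition
#' @slot provenance list of stage parameter records
#' @export
setClass("ReconVolume", representation(
    data = "array",
    voxelSize = "numeric",
    origin = "numeric",
    scanIndex = "numeric",
    greyScale = "numeric",
    geometry = "ScanGeometry",
    provenance = "list"))

setValidity("ReconVolume", function(object) {
    if (length(dim(object@data)) != 3L) return("data must be a 3D array")
    if (any(!is.finite(object@data))) return("volume contains non-finite values")
    if (object@voxelSize <= 0) return("voxelSize must be > 0")
    if (object@scanIndex < 1) return("scanIndex must be >= 1")
    TRUE
})

#' Baseline-subtraction difference volume
#'
#' Signed grey difference follow-up minus baseline, so a positive change
#' means attenuation increased relative to free-flowing blood (red-thrombus
#' candidate) and a negative change means it decreased (white-thrombus or
#' air candidate). `data` is clipped to `clipRange`; `raw` keeps the
#' unclipped difference for volumetry and air disambiguation.
#'
#' @slot data clipped difference array
#' @slot raw unclipped difference array
#' @slot clipRange c(low, high) clip limits in grey units
#' @slot baselineIndex,followupIndex scan indices of the operands
#' @slot shift integer alignment shift (voxels) applied to the follow-up
#' @slot alignResidual estimated residual misalignment (voxels)
#' @slot voxelSize voxel size (mm)
#' @slot origin grid corner (mm)
#' @export
setClass("DiffVolume", representation(
    data = "array",
    raw = "array",
    clipRange = "numeric",
    baselineIndex = "numeric",
    followupIndex = "numeric",
    shift = "numeric",
    alignResidual = "numeric",
    voxelSize = "numeric",
    origin = "numeric"))

setValidity("DiffVolume", function(object) {
    if (!identical(dim(object@data), dim(object@raw)))
        return("clipped and raw arrays must match in shape")
    if (length(object@clipRange) != 2L ||
        object@clipRange[1] >= object@clipRange[2])
        return("clipRange must be c(low, high) with low < high")
    rng <- range(object@data)
    if (rng[1] < object@clipRange[1] - 1e-9 ||
        rng[2] > object@clipRange[2] + 1e-9)
        return("clipped data exceeds the clip range")
    if (!(object@baselineIndex < object@followupIndex))
        return("baseline scan index must precede follow-up index")
    TRUE
})

#' Labeled thrombus segmentation
#'
#' Connected components of suprathreshold change in a [DiffVolume], filtered
#' by size, edge contrast and shape, and classified red / white /
#' ambiguous_air by the sign and magnitude of their grey change.
#'
#' @slot labelVolume integer array of component ids (0 = background)
#' @slot components data.frame with one row per retained component
#' @slot voxelSize voxel size (mm)
#' @slot origin grid corner (mm)
#' @slot params list of segmentation parameters actually used
#' @export
setClass("ThrombusSegmentation", representation(
    labelVolume = "array",
    components = "data.frame",
    voxelSize = "numeric",
    origin = "numeric",
    params = "list"))

setValidity("ThrombusSegmentation", function(object) {
    cmp <- object@components
    if (nrow(cmp)) {
        if (!all(c("id", "class", "voxels", "volume_mm3", "mean_diff") %in%
                 names(cmp)))
            return("components table is missing required columns")
        bad <- (cmp$class == "red" & cmp$mean_diff <= 0) |
               (cmp$class %in% c("white", "ambiguous_air") & cmp$mean_diff >= 0)
        if (any(bad))
            return("component class inconsistent with sign of mean difference")
    }
    TRUE
})

#' Extracorporeal-circuit monitoring series
#'
#' Timestamped records of trans-oxygenator pressure drop (dpMO), red cell
#' and platelet counts, ACT, aPTT (with 400 s out-of-range capping), surface
#' temperature and flow, plus the static blood-bag reference entries.
#'
#' @slot data data.frame with columns time_min, dpmo_mmHg, rbc_1e6_uL,
#'   plt_1e3_uL, act_s, act_error, aptt_s, aptt_oor, aptt_error, temp_C,
#'   flow_mL_min (NA where a quantity was not sampled at that time)
#' @slot baseline named list of blood-bag baseline values
#' @slot staticControl named list of end-of-experiment static control values
#' @slot meta list (profile name, seed, units notes)
#' @export
setClass("MonitoringSeries", representation(
    data = "data.frame",
    baseline = "list",
    staticControl = "list",
    meta = "list"))

setValidity("MonitoringSeries", function(object) {
    d <- object@data
    need <- c("time_min", "dpmo_mmHg", "rbc_1e6_uL", "plt_1e3_uL", "act_s",
              "act_error", "aptt_s", "aptt_oor", "aptt_error", "temp_C",
              "flow_mL_min")
    if (!all(need %in% names(d)))
        return(paste("missing columns:",
                     paste(setdiff(need, names(d)), collapse = ", ")))
    if (is.unsorted(d$time_min, strictly = TRUE))
        return("times must be strictly increasing")
    if (any(!is.na(d$aptt_s) & d$aptt_s > 400))
        return("aPTT values above the 400 s cuvette limit must be capped")
    if (any(!is.na(d$aptt_s) & d$aptt_s == 400 & !d$aptt_oor))
        return("aPTT at the 400 s cap requires the OOR flag")
    if (any(d$act_error & !is.na(d$act_s)))
        return("ACT error flag requires a missing value")
    if (any(d$aptt_error & !is.na(d$aptt_s)))
        return("aPTT error flag requires a missing value")
    TRUE
})

#' In-vitro blood loop specification
#'
#' Static description of the test loop: membrane area, priming volumes,
#' blood-contacting surfaces, flow and anticoagulation, and the 4-hour
#' experiment limit imposed by in-vitro blood vitality.
#'
#' @slot membraneArea_m2 oxygenator membrane surface area (m^2)
#' @slot devicePrimingVolume_mL oxygenator priming volume (mL)
#' @slot loopContactArea_m2 blood-contacting area of the rest of the loop (m^2)
#' @slot loopPrimingVolume_mL loop priming volume (mL)
#' @slot flow_mL_min blood flow rate (mL/min)
#' @slot heparin_USP_mL heparin dose (USP per mL blood)
#' @slot timeLimit_min experiment time limit (min)
#' @export
setClass("LoopSpec", representation(
    membraneArea_m2 = "numeric",
    devicePrimingVolume_mL = "numeric",
    loopContactArea_m2 = "numeric",
    loopPrimingVolume_mL = "numeric",
    flow_mL_min = "numeric",
    heparin_USP_mL = "numeric",
    timeLimit_min = "numeric"))

setValidity("LoopSpec", function(object) {
    v <- c(object@membraneArea_m2, object@devicePrimingVolume_mL,
           object@loopContactArea_m2, object@loopPrimingVolume_mL,
           object@flow_mL_min, object@heparin_USP_mL, object@timeLimit_min)
    if (any(!is.finite(v)) || any(v <= 0))
        return("all loop quantities must be finite and > 0")
    TRUE
})
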