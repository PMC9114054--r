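#' Extract the voxel/image data array from a pipeline object
#' @param x a pipeline object
#' @return numeric array
#' @export
setGeneric("volumeData", function(x) standardGeneric("volumeData"))

#' Voxel edge length in mm
#' @param x a pipeline object with a voxel grid
#' @return numeric scalar (mm)
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' World position (mm) of the voxel-grid corner
#' @param x a pipeline object with a voxel grid
#' @return numeric length-3
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' Material attenuation lookup
#' @param x a MaterialTable or object carrying one
#' @return named numeric vector of attenuation coefficients (1/mm)
#' @export
setGeneric("attenuationCoefficients",
           function(x) standardGeneric("attenuationCoefficients"))

#' Ground-truth thrombus table of a phantom
#' @param x an AttenuationPhantom
#' @return data.frame
#' @export
setGeneric("thrombusTable", function(x) standardGeneric("thrombusTable"))

#' Per-component segmentation table
#' @param x a ThrombusSegmentation
#' @return data.frame with one row per component
#' @export
setGeneric("components", function(x) standardGeneric("components"))

#' Projection angles in degrees
#' @param x a ProjectionStack
#' @return numeric vector
#' @export
setGeneric("projectionAngles", function(x) standardGeneric("projectionAngles"))

#' Scan geometry of an acquisition or reconstruction
#' @param x a ProjectionStack or ReconVolume
#' @return ScanGeometry
#' @export
setGeneric("scanGeometry", function(x) standardGeneric("scanGeometry"))

#' Monitoring record table
#' @param x a MonitoringSeries
#' @return data.frame of timestamped records
#' @export
setGeneric("monitoringData", function(x) standardGeneric("monitoringData"))

## ---- methods -------------------------------------------------------------

#' @rdname volumeData
setMethod("volumeData", "AttenuationPhantom", function(x) x@mu)
#' @rdname volumeData
setMethod("volumeData", "ReconVolume", function(x) x@data)
#' @rdname volumeData
setMethod("volumeData", "DiffVolume", function(x) x@data)
#' @rdname volumeData
setMethod("volumeData", "ProjectionStack", function(x) x@data)
#' @rdname volumeData
setMethod("volumeData", "ThrombusSegmentation", function(x) x@labelVolume)

#' @rdname voxelSize
setMethod("voxelSize", "AttenuationPhantom", function(x) x@voxelSize)
#' @rdname voxelSize
setMethod("voxelSize", "ReconVolume", function(x) x@voxelSize)
#' @rdname voxelSize
setMethod("voxelSize", "DiffVolume", function(x) x@voxelSize)
#' @rdname voxelSize
setMethod("voxelSize", "ThrombusSegmentation", function(x) x@voxelSize)

#' @rdname gridOrigin
setMethod("gridOrigin", "AttenuationPhantom", function(x) x@origin)
#' @rdname gridOrigin
setMethod("gridOrigin", "ReconVolume", function(x) x@origin)
#' @rdname gridOrigin
setMethod("gridOrigin", "DiffVolume", function(x) x@origin)

#' @rdname attenuationCoefficients
setMethod("attenuationCoefficients", "MaterialTable", function(x) x@mu)
#' @rdname attenuationCoefficients
setMethod("attenuationCoefficients", "AttenuationPhantom",
          function(x) x@materials@mu)

#' @rdname thrombusTable
setMethod("thrombusTable", "AttenuationPhantom", function(x) x@thrombi)

#' @rdname components
setMethod("components", "ThrombusSegmentation", function(x) x@components)

#' @rdname projectionAngles
setMethod("projectionAngles", "ProjectionStack", function(x) x@angles)

#' @rdname scanGeometry
setMethod("scanGeometry", "ProjectionStack", function(x) x@geometry)
#' @rdname scanGeometry
setMethod("scanGeometry", "ReconVolume", function(x) x@geometry)

#' @rdname monitoringData
setMethod("monitoringData", "MonitoringSeries", function(x) x@data)

## ---- show methods --------------------------------------------------------

setMethod("show", "MaterialTable", function(object) {
    cat("MaterialTable (1/mm):\n")
    print(round(object@mu, 4))
})

setMethod("show", "AttenuationPhantom", function(object) {
    d <- dim(object@labels)
    cat(sprintf("AttenuationPhantom %d x %d x %d @ %.3g mm voxels\n",
                d[1], d[2], d[3], object@voxelSize))
    lev <- c(materialNames(), "bundle")
    tab <- table(factor(lev[object@labels + 1L], levels = lev))
    tab <- tab[tab > 0]
    cat("  voxels:", paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                           collapse = ", "), "\n")
    if (nrow(object@thrombi))
        cat(sprintf("  %d thrombus/thrombi, total ground-truth volume %.4g mm^3\n",
                    nrow(object@thrombi), sum(object@thrombi$volume_mm3)))
})

setMethod("show", "ScanGeometry", function(object) {
    cat(sprintf(paste0("ScanGeometry: SOD %g mm, ODD %g mm (M = %.3f), ",
                       "%d x %d detector @ %g mm,\n  %d projections / %g deg",
                       " @ %g fps\n"),
                object@sod, object@odd, (object@sod + object@odd) / object@sod,
                object@nu, object@nv, object@pixelPitch,
                object@nProjections, object@angularRange, object@fps))
})

setMethod("show", "ProjectionStack", function(object) {
    d <- dim(object@data)
    cat(sprintf("ProjectionStack: %d projections of %d x %d, I0 = %g\n",
                d[3], d[1], d[2], object@i0))
})

setMethod("show", "ReconVolume", function(object) {
    d <- dim(object@data)
    cat(sprintf(paste0("ReconVolume (scan %d): %d x %d x %d @ %.3g mm, grey ",
                       "range [%.1f, %.1f]\n"),
                as.integer(object@scanIndex), d[1], d[2], d[3],
                object@voxelSize, min(object@data), max(object@data)))
})

setMethod("show", "DiffVolume", function(object) {
    cat(sprintf(paste0("DiffVolume CT%d - CT%d, clipped to [%g, %g], ",
                       "alignment shift (%s) voxels\n"),
                as.integer(object@followupIndex),
                as.integer(object@baselineIndex),
                object@clipRange[1], object@clipRange[2],
                paste(object@shift, collapse = ", ")))
})

setMethod("show", "ThrombusSegmentation", function(object) {
    cmp <- object@components
    cat(sprintf("ThrombusSegmentation: %d component(s)\n", nrow(cmp)))
    if (nrow(cmp)) {
        for (cl in unique(cmp$class))
            cat(sprintf("  %s: %d component(s), %.4g mm^3\n", cl,
                        sum(cmp$class == cl),
                        sum(cmp$volume_mm3[cmp$class == cl])))
    }
})

setMethod("show", "MonitoringSeries", function(object) {
    d <- object@data
    cat(sprintf("MonitoringSeries: %d timepoints over %.0f min (profile: %s)\n",
                nrow(d), max(d$time_min),
                if (is.null(object@meta$profile)) "n/a" else object@meta$profile))
})

setMethod("show", "LoopSpec", function(object) {
    r <- loopRatios(object)
    cat(sprintf(paste0("LoopSpec: %.2f m^2 membrane, %g + %g mL priming, ",
                       "%g mL/min;\n  exposure %.3g cm^2/mL, surface ratio %.3g\n"),
                object@membraneArea_m2, object@loopPrimingVolume_mL,
                object@devicePrimingVolume_mL, object@flow_mL_min,
                r$exposure_cm2_mL, r$surface_ratio))
})
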