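## Readers/writers for pipeline artifacts: NRRD volumes (plain-text header +
## little-endian raw payload), TIFF slice/projection stacks with JSON
## sidecars, monitoring CSV with the aPTT "OOR" token dialect, YAML run
## configuration and provenance records.

## ---- NRRD ---------------------------------------------------------------

nrrdTypeInfo <- function(type) {
    switch(type,
           "float"  = list(what = "numeric", size = 4L),
           "double" = list(what = "numeric", size = 8L),
           "int"    = list(what = "integer", size = 4L),
           "short"  = list(what = "integer", size = 2L),
           stop("unsupported NRRD type: ", type))
}

#' Write a 3D array as an NRRD file
#'
#' Plain-text NRRD header followed by raw little-endian data. Integer data
#' round-trips bit-exactly; numeric data is stored as float32 by default
#' (use type "double" for lossless doubles).
#'
#' @param x 3D array
#' @param path output .nrrd path
#' @param voxelSize isotropic voxel size (mm)
#' @param origin grid corner (mm)
#' @param type "float", "double", "int" or "short"
#' @return invisibly, the path
#' @export
writeNRRD <- function(x, path, voxelSize = 1, origin = c(0, 0, 0),
                      type = if (is.integer(x)) "int" else "float") {
    d <- dim(x)
    if (length(d) != 3L) stop("x must be a 3D array")
    info <- nrrdTypeInfo(type)
    hdr <- c("NRRD0004",
             paste0("type: ", type),
             "dimension: 3",
             paste0("sizes: ", paste(d, collapse = " ")),
             "endian: little",
             "encoding: raw",
             sprintf("space directions: (%.10g,0,0) (0,%.10g,0) (0,0,%.10g)",
                     voxelSize, voxelSize, voxelSize),
             sprintf("space origin: (%.10g,%.10g,%.10g)",
                     origin[1], origin[2], origin[3]),
             "")
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con, sep = "\n")
    if (info$what == "integer")
        writeBin(as.integer(x), con, size = info$size, endian = "little")
    else
        writeBin(as.numeric(x), con, size = info$size, endian = "little")
    invisible(path)
}

#' Read an NRRD file written by [writeNRRD()] (raw encoding)
#'
#' @param path .nrrd path
#' @return list(data, voxelSize, origin); `data` is a 3D array
#' @export
readNRRD <- function(path) {
    con <- file(path, "rb")
    on.exit(close(con))
    first <- readLines(con, n = 1)
    if (!length(first) || !grepl("^NRRD", first))
        stop("not an NRRD file: ", path)
    hdr <- first
    repeat {
        line <- readLines(con, n = 1)
        if (!length(line)) stop("truncated NRRD header in ", path)
        if (!nzchar(line)) break
        hdr <- c(hdr, line)
    }
    field <- function(key) {
        hit <- grep(paste0("^", key, ": "), hdr, value = TRUE)
        if (!length(hit)) return(NULL)
        sub(paste0("^", key, ": "), "", hit[1])
    }
    type <- field("type")
    sizes <- as.integer(strsplit(field("sizes"), " ")[[1]])
    if (length(sizes) != 3L)
        stop("expected 3 sizes, found ", length(sizes), " in ", path)
    enc <- field("encoding")
    if (!identical(enc, "raw")) stop("unsupported encoding: ", enc)
    info <- nrrdTypeInfo(type)
    n <- prod(sizes)
    data <- readBin(con, what = info$what, n = n, size = info$size,
                    endian = "little")
    if (length(data) != n)
        stop("NRRD payload mismatch: expected ", n, " values, found ",
             length(data))
    dim(data) <- sizes
    dirs <- field("space directions")
    voxel <- if (!is.null(dirs))
        as.numeric(sub("^\\(([^,]+),.*", "\\1", dirs)) else 1
    org <- field("space origin")
    origin <- if (!is.null(org))
        as.numeric(strsplit(gsub("[()]", "", org), ",")[[1]]) else c(0, 0, 0)
    list(data = data, voxelSize = voxel, origin = origin)
}

## ---- volumes ------------------------------------------------------------

#' Write a reconstructed volume (NRRD + JSON sidecar)
#'
#' @param volume a [ReconVolume]
#' @param path .nrrd output path; the sidecar is written next to it
#' @param type NRRD payload type ("double" for a lossless round trip)
#' @return invisibly, the path
#' @export
writeVolume <- function(volume, path, type = "double") {
    writeNRRD(volume@data, path, volume@voxelSize, volume@origin, type = type)
    g <- volume@geometry
    meta <- list(kind = "ReconVolume", scanIndex = volume@scanIndex,
                 greyScale = volume@greyScale,
                 geometry = list(sod = g@sod, odd = g@odd, nu = g@nu,
                                 nv = g@nv, pixelPitch = g@pixelPitch,
                                 nProjections = g@nProjections,
                                 angularRange = g@angularRange, fps = g@fps,
                                 rotationDirection = g@rotationDirection),
                 provenance = volume@provenance)
    jsonlite::write_json(meta, sidecarPath(path), auto_unbox = TRUE,
                         digits = NA, null = "null")
    invisible(path)
}

sidecarPath <- function(path) paste0(sub("\\.nrrd$", "", path), ".json")

#' Read a volume written by [writeVolume()]
#'
#' @param path .nrrd path
#' @return a [ReconVolume]
#' @export
readVolume <- function(path) {
    v <- readNRRD(path)
    meta <- jsonlite::read_json(sidecarPath(path), simplifyVector = TRUE)
    g <- meta$geometry
    geometry <- scanGeometrySpec(sod = g$sod, odd = g$odd, nu = g$nu,
                                 nv = g$nv, pixelPitch = g$pixelPitch,
                                 nProjections = g$nProjections,
                                 angularRange = g$angularRange, fps = g$fps,
                                 rotationDirection = g$rotationDirection)
    new("ReconVolume", data = v$data, voxelSize = v$voxelSize,
        origin = v$origin, scanIndex = meta$scanIndex,
        greyScale = meta$greyScale, geometry = geometry,
        provenance = if (is.null(meta$provenance)) list() else
            list(restored = meta$provenance))
}

#' Export a volume as an axial TIFF slice stack
#'
#' One 32-bit page per axial (z) slice, stacked bottom to top. TIFF
#' samples are stored normalized to [0, 1]; the value range (and whether
#' the data were integral) is recorded in the JSON sidecar so
#' [readSliceStack()] restores the original scale, bit-exactly for
#' integer-valued data.
#'
#' @param volume a [ReconVolume] or plain 3D array
#' @param path .tif output path
#' @return invisibly, the path
#' @export
writeSliceStack <- function(volume, path) {
    x <- if (is(volume, "ReconVolume")) volume@data else volume
    vmin <- min(x)
    vmax <- max(x)
    scale <- if (vmax > vmin) vmax - vmin else 1
    pages <- lapply(seq_len(dim(x)[3]),
                    function(k) t((x[, , k] - vmin) / scale))
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
    jsonlite::write_json(
        list(kind = "SliceStack", axis = "z", order = "ascending",
             nSlices = dim(x)[3], vmin = vmin, vmax = vmax,
             integer = all(x == round(x)),
             voxelSize = if (is(volume, "ReconVolume")) volume@voxelSize else NA),
        sidecarPath2(path), auto_unbox = TRUE, digits = NA)
    invisible(path)
}

sidecarPath2 <- function(path) paste0(sub("\\.tiff?$", "", path), ".json")

#' Read an axial TIFF slice stack into a 3D array
#'
#' @param path .tif path from [writeSliceStack()]
#' @return 3D array (x, y, z), rescaled via the sidecar when present
#' @export
readSliceStack <- function(path) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    d <- dim(pages[[1]])
    out <- array(0, c(d[2], d[1], length(pages)))
    for (k in seq_along(pages)) out[, , k] <- t(pages[[k]])
    sc <- sidecarPath2(path)
    if (file.exists(sc)) {
        meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
        if (!is.null(meta$vmin)) {
            out <- out * (meta$vmax - meta$vmin) + meta$vmin
            if (isTRUE(meta$integer)) out <- round(out)
        }
    }
    out
}

## ---- projections --------------------------------------------------------

#' Write a projection stack (multi-page TIFF + references + JSON sidecar)
#'
#' @param stack a [ProjectionStack]
#' @param path .tif path for the projections; flat/dark are written next to
#'   it with `_flat` / `_dark` suffixes
#' @return invisibly, the path
#' @export
writeProjections <- function(stack, path) {
    base <- sub("\\.tiff?$", "", path)
    writeSliceStack(stack@data, path)
    writeSliceStack(array(stack@flat, c(dim(stack@flat), 1L)),
                    paste0(base, "_flat.tif"))
    writeSliceStack(array(stack@dark, c(dim(stack@dark), 1L)),
                    paste0(base, "_dark.tif"))
    ## merge the stack scale sidecar with the acquisition metadata
    scale <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
    g <- stack@geometry
    meta <- list(kind = "ProjectionStack", angles = stack@angles,
                 i0 = stack@i0,
                 vmin = scale$vmin, vmax = scale$vmax,
                 integer = scale$integer,
                 geometry = list(sod = g@sod, odd = g@odd, nu = g@nu,
                                 nv = g@nv, pixelPitch = g@pixelPitch,
                                 nProjections = g@nProjections,
                                 angularRange = g@angularRange, fps = g@fps,
                                 rotationDirection = g@rotationDirection),
                 provenance = stack@provenance)
    jsonlite::write_json(meta, paste0(base, ".json"), auto_unbox = TRUE,
                         digits = NA)
    invisible(path)
}

#' Read a projection stack written by [writeProjections()]
#'
#' @param path .tif path
#' @return a [ProjectionStack]
#' @export
readProjections <- function(path) {
    base <- sub("\\.tiff?$", "", path)
    data <- readSliceStack(path)
    flat <- readSliceStack(paste0(base, "_flat.tif"))[, , 1]
    dark <- readSliceStack(paste0(base, "_dark.tif"))[, , 1]
    meta <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
    g <- meta$geometry
    geometry <- scanGeometrySpec(sod = g$sod, odd = g$odd, nu = g$nu,
                                 nv = g$nv, pixelPitch = g$pixelPitch,
                                 nProjections = g$nProjections,
                                 angularRange = g$angularRange, fps = g$fps,
                                 rotationDirection = g$rotationDirection)
    if (!identical(dim(data)[1:2], c(g$nu, g$nv)))
        stop("projection shape mismatch: expected ", g$nu, " x ", g$nv,
             ", found ", dim(data)[1], " x ", dim(data)[2])
    new("ProjectionStack", data = data, angles = meta$angles, flat = flat,
        dark = dark, geometry = geometry, i0 = meta$i0,
        provenance = list(restored = meta$provenance))
}

## ---- monitoring CSV -----------------------------------------------------

monitoringColumns <- function() {
    c("time_min", "dpmo_mmHg", "rbc_1e6_uL", "plt_1e3_uL", "act_s",
      "act_error", "aptt_s", "aptt_oor", "aptt_error", "temp_C",
      "flow_mL_min")
}

#' Write a monitoring series as CSV
#'
#' Out-of-range aPTT measurements (capped at 400 s, OOR flag) are written
#' as the token "OOR"; device errors as "error"; unsampled cells are empty.
#'
#' @param series a [MonitoringSeries]
#' @param path .csv output path
#' @return invisibly, the path
#' @export
writeMonitoringCSV <- function(series, path) {
    d <- series@data
    out <- d[setdiff(monitoringColumns(),
                     c("act_error", "aptt_oor", "aptt_error"))]
    out$aptt_s <- as.character(d$aptt_s)
    out$aptt_s[d$aptt_oor] <- "OOR"
    out$aptt_s[d$aptt_error] <- "error"
    out$act_s <- as.character(d$act_s)
    out$act_s[d$act_error] <- "error"
    write.csv(out, path, row.names = FALSE, na = "")
    invisible(path)
}

#' Read a monitoring CSV
#'
#' Accepts the dialect of [writeMonitoringCSV()]: "OOR" in the aPTT column
#' becomes 400 s with the OOR flag set, "error" becomes a missing value
#' with the error flag. Schema violations and non-numeric rows raise errors
#' naming the field and row.
#'
#' @param path .csv path
#' @return a [MonitoringSeries]
#' @export
readMonitoringCSV <- function(path) {
    d <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = "character")
    if (!nrow(d)) stop("empty monitoring file: ", path)
    need <- setdiff(monitoringColumns(),
                    c("act_error", "aptt_oor", "aptt_error"))
    missing <- setdiff(need, names(d))
    if (length(missing))
        stop("monitoring schema violation: missing field(s) ",
             paste(missing, collapse = ", "))
    numCol <- function(col) {
        x <- trimws(d[[col]])
        x[x == ""] <- NA
        out <- suppressWarnings(as.numeric(x))
        bad <- which(!is.na(x) & is.na(out))
        if (length(bad))
            stop("non-numeric value in field '", col, "' at row(s) ",
                 paste(head(bad, 5), collapse = ", "))
        out
    }
    aptt <- trimws(d$aptt_s)
    apttOOR <- aptt == "OOR" & !is.na(aptt)
    apttErr <- aptt == "error" & !is.na(aptt)
    d$aptt_s[apttOOR | apttErr] <- ""
    act <- trimws(d$act_s)
    actErr <- act == "error" & !is.na(act)
    d$act_s[actErr] <- ""
    dd <- data.frame(time_min = numCol("time_min"),
                     dpmo_mmHg = numCol("dpmo_mmHg"),
                     rbc_1e6_uL = numCol("rbc_1e6_uL"),
                     plt_1e3_uL = numCol("plt_1e3_uL"),
                     act_s = numCol("act_s"),
                     act_error = actErr,
                     aptt_s = numCol("aptt_s"),
                     aptt_oor = apttOOR,
                     aptt_error = apttErr,
                     temp_C = numCol("temp_C"),
                     flow_mL_min = numCol("flow_mL_min"))
    dd$aptt_s[apttOOR] <- 400
    new("MonitoringSeries", data = dd, baseline = list(),
        staticControl = list(), meta = list(source = path))
}

## ---- config -------------------------------------------------------------

#' Read a YAML run configuration
#'
#' @param path .yaml path
#' @return named list
#' @export
readConfig <- function(path) yaml::read_yaml(path)

#' Write a YAML run configuration
#'
#' @param config named list
#' @param path .yaml output path
#' @return invisibly, the path
#' @export
writeConfig <- function(config, path) {
    yaml::write_yaml(config, path)
    invisible(path)
}

#' Instantiate pipeline objects from a configuration list
#'
#' Recognized sections (all optional, defaults otherwise): `device`,
#' `materials`, `grid` (size, voxel, homogenizeBundle), `geometry`,
#' `noise`, `recipe`, `thrombi` (list of specs), `seed`. Grid and recipe
#' sizes are spelled `size` in YAML because YAML 1.1 resolves a bare key
#' `n` to a boolean; programmatic lists may use either spelling.
#'
#' @param config list from [readConfig()]
#' @return list(device, materials, geometry, noise, recipe, specs, grid, seed)
#' @export
configToObjects <- function(config) {
    fixSize <- function(lst) {
        lst <- as.list(lst)
        if (is.null(lst$n) && !is.null(lst$size)) lst$n <- lst$size
        lst$size <- NULL
        lst[!names(lst) %in% c("FALSE", "TRUE")]
    }
    device <- do.call(deviceDescriptor,
                      as.list(config$device %||% list()))
    materials <- do.call(materialTable,
                         as.list(config$materials %||% list()))
    geometry <- do.call(scanGeometrySpec,
                        as.list(config$geometry %||% list()))
    noise <- do.call(noiseSpec, as.list(config$noise %||% list()))
    recipe <- do.call(reconRecipe, fixSize(config$recipe %||% list()))
    specs <- lapply(config$thrombi %||% list(), function(s)
        thrombusSpec(class = s$class %||% "red",
                     shape = s$shape %||% "ellipsoid",
                     center = unlist(s$center %||% c(1.5, 180, 0)),
                     axes = unlist(s$axes %||% c(0.8, 0.8, 0.8)),
                     firstScan = s$firstScan %||% 8))
    grid <- fixSize(config$grid %||% list())
    if (is.null(grid$n)) grid$n <- 128
    if (is.null(grid$voxel)) grid$voxel <- 0.15
    list(device = device, materials = materials, geometry = geometry,
         noise = noise, recipe = recipe, specs = specs,
         grid = grid, seed = config$seed %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- provenance ---------------------------------------------------------

#' Build a provenance record for a pipeline stage
#'
#' @param stage stage name
#' @param params parameter list
#' @param inputs character vector of input file paths (hashed with MD5)
#' @param seed seed used by the stage, if any
#' @return list with stage, params, input hashes, seed, timestamp, version
#' @export
provenanceRecord <- function(stage, params = list(), inputs = character(),
                             seed = NULL) {
    hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
    list(stage = stage, params = params, inputHashes = hashes, seed = seed,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         version = as.character(utils::packageVersion("oxyCT")))
}

#' Verify the input hashes of a provenance record
#'
#' @param record a [provenanceRecord()]
#' @return TRUE if all hashed inputs still match; otherwise an error naming
#'   the first mismatching file
#' @export
verifyProvenance <- function(record) {
    for (f in names(record$inputHashes)) {
        now <- unname(tools::md5sum(f))
        if (is.na(now) || !identical(now, record$inputHashes[[f]]))
            stop("provenance hash mismatch for ", f)
    }
    TRUE
}
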