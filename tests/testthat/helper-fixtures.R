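## Shared fixtures. Expensive objects are built once per session and cached.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
    if (!exists(key, envir = .fixtureCache))
        assign(key, builder(), envir = .fixtureCache)
    get(key, envir = .fixtureCache)
}

## small homogenized phantom for cheap projector/IO tests
tinyPhantom <- function() cached("tinyPhantom", function()
    buildPhantom(n = 32, voxel = 0.6, homogenizeBundle = TRUE))

## hand-built uniform cylinder phantom (radius mm, centre mm, muValue 1/mm)
cylinderPhantom <- function(n = 64, nz = 8, voxel = 0.25, radius = 5,
                            center = c(0, 0), muValue = 0.06) {
    x <- (seq_len(n) - 0.5) * voxel - n * voxel / 2
    r <- sqrt(outer((x - center[1])^2, (x - center[2])^2, "+"))
    lab <- array(0L, c(n, n, nz))
    plane <- matrix(0L, n, n)
    plane[r < radius] <- materialCodes()[["blood"]]
    for (k in seq_len(nz)) lab[, , k] <- plane
    mt <- materialTable(blood = muValue)
    mu <- array(0, dim(lab))
    mu[lab > 0L] <- muValue
    org <- c(-n * voxel / 2, -n * voxel / 2, -nz * voxel / 2)
    new("AttenuationPhantom", labels = lab, mu = mu, voxelSize = voxel,
        origin = org, device = deviceDescriptor(), materials = mt,
        bundleMu = numeric(0), thrombi = oxyCT:::emptyThrombusTable())
}

## reconstruction of the oxygenator phantom under Poisson noise at I0 = 1e4,
## reused by the alignment tests
noisyDeviceRecon <- function() cached("noisyDeviceRecon", function() {
    ph <- buildPhantom(n = 96, voxel = 0.2, homogenizeBundle = TRUE)
    geom <- deskGeometry(nu = 192, nv = 192, nProjections = 240,
                         isoPixel = 0.2)
    st <- forwardProject(ph, geom, noiseSpec(i0 = 1e4), seed = 5)
    reconstructScan(st, reconRecipe(n = 96, voxel = 0.2, ringFilter = FALSE))
})

## synthetic DiffVolume from a raw difference array (grey units)
diffFromArray <- function(raw, voxel = 0.1, clip = c(-200, 150)) {
    clipped <- pmin(pmax(raw, clip[1]), clip[2])
    dim(clipped) <- dim(raw)
    new("DiffVolume", data = clipped, raw = raw, clipRange = clip,
        baselineIndex = 1, followupIndex = 8, shift = c(0, 0, 0),
        alignResidual = 0, voxelSize = voxel,
        origin = -dim(raw) * voxel / 2)
}

## place a compact blob of `nvox` voxels (value `value`) into an array
blobCoords <- function(nvox) {
    ## voxel offsets ordered by distance from the origin -> compact blob
    rad <- ceiling((3 * nvox / (4 * pi))^(1 / 3)) + 2
    g <- as.matrix(expand.grid(-rad:rad, -rad:rad, -rad:rad))
    g <- g[order(rowSums(g^2), seq_len(nrow(g))), ]
    g[seq_len(nvox), , drop = FALSE]
}

makeBlobDiff <- function(nvox, value, n = 48, center = NULL, voxel = 0.1) {
    raw <- array(0, c(n, n, n))
    if (is.null(center)) center <- rep(n / 2, 3)
    cc <- blobCoords(nvox) + rep(center, each = nvox)
    raw[cc] <- value
    diffFromArray(raw, voxel = voxel)
}

## independent 2D equispaced-fan-beam FBP oracle (direct convolution,
## pixel-driven backprojection, plain R loops)
fanbeamOracle2D <- function(sino, du, sod, anglesDeg, n, voxel) {
    nu <- nrow(sino)
    na <- ncol(sino)
    u <- (seq_len(nu) - (nu + 1) / 2) * du
    ws <- sino * (sod / sqrt(sod^2 + u^2))
    idx <- seq_len(nu)
    H <- outer(idx, idx, function(j, k) ramLakKernel(j - k, du))
    filt <- du * (H %*% ws)
    xs <- (seq_len(n) - 0.5) * voxel - n * voxel / 2
    out <- matrix(0, n, n)
    dth <- 2 * pi / na
    for (a in seq_len(na)) {
        th <- anglesDeg[a] * pi / 180
        ct <- cos(th); st <- sin(th)
        for (iy in seq_len(n)) {
            y <- xs[iy]
            xr <- xs * ct + y * st
            U <- sod / (sod - xr)
            fi <- (-xs * st + y * ct) * U / du + (nu + 1) / 2
            i0 <- floor(fi)
            al <- fi - i0
            ok <- i0 >= 1 & i0 < nu
            v <- numeric(n)
            v[ok] <- (1 - al[ok]) * filt[cbind(i0[ok], a)] +
                al[ok] * filt[cbind(i0[ok] + 1, a)]
            out[, iy] <- out[, iy] + dth / 2 * U^2 * v
        }
    }
    out
}

## brute-force line integral: nearest-neighbour sampling of the phantom
## grid at 1/20 voxel steps along the source-to-pixel ray, with the ray
## geometry recomputed from first principles (independent of the C++ path)
bruteRayIntegral <- function(ph, geom, iu, iv, angleDeg) {
    th <- angleDeg * pi / 180
    sod <- geom@sod
    sdd <- geom@sod + geom@odd
    src <- c(sod * cos(th), sod * sin(th), 0)
    dc <- src - sdd * c(cos(th), sin(th), 0)
    eu <- c(-sin(th), cos(th), 0)
    u <- (iu - 1 - (geom@nu - 1) / 2) * geom@pixelPitch
    v <- (iv - 1 - (geom@nv - 1) / 2) * geom@pixelPitch
    pix <- dc + u * eu + c(0, 0, v)
    dirv <- pix - src
    len <- sqrt(sum(dirv^2))
    dirv <- dirv / len
    step <- ph@voxelSize / 20
    ts <- seq(step / 2, len, by = step)
    n <- dim(ph@mu)
    acc <- 0
    for (t in ts) {
        pos <- src + t * dirv
        ijk <- floor((pos - ph@origin) / ph@voxelSize) + 1
        if (all(ijk >= 1) && all(ijk <= n))
            acc <- acc + ph@mu[ijk[1], ijk[2], ijk[3]]
    }
    acc * step
}

## monitoring series from explicit plt/dpmo samples (helper for termination)
seriesFromSamples <- function(times, plt, dpmo, rbc = NULL) {
    n <- length(times)
    if (is.null(rbc)) rbc <- rep(9.5, n)
    d <- data.frame(time_min = times, dpmo_mmHg = dpmo,
                    rbc_1e6_uL = rbc, plt_1e3_uL = plt,
                    act_s = rep(NA_real_, n), act_error = FALSE,
                    aptt_s = NA_real_, aptt_oor = FALSE, aptt_error = FALSE,
                    temp_C = 37, flow_mL_min = 95)
    new("MonitoringSeries", data = d, baseline = list(),
        staticControl = list(), meta = list())
}
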