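test_that("scan protocol: 5000 projections at 7 fps is a 12 min scan at 0.50 deg/s", {
    geom <- scanGeometrySpec()  # full protocol defaults
    p <- scanProtocolSummary(geom)
    expect_equal(p$duration_s, 5000 / 7, tolerance = 1e-12)
    expect_equal(round(p$duration_min), 12)
    expect_equal(p$rotation_speed_deg_s, 0.50, tolerance = 0.01)
    expect_equal(p$magnification, (750 + 1445) / 750, tolerance = 1e-12)
    expect_error(scanProtocolSummary(scanGeometrySpec(fps = 0)),
                 "frame rate")
    p0 <- scanProtocolSummary(scanGeometrySpec(nProjections = 0))
    expect_equal(p0$duration_s, 0)
})

test_that("empty beam: zero phantom, no noise, unit gain reproduces the flat", {
    ph <- tinyPhantom()
    ph@mu[] <- 0
    ph@labels[] <- 0L
    geom <- deskGeometry(nu = 48, nv = 32, nProjections = 12, isoPixel = 0.6)
    ns <- noiseSpec(poisson = FALSE)
    st <- forwardProject(ph, geom, ns, seed = 1,
                         gainMap = matrix(1, 48, 32))
    expect_true(all(st@data == ns$i0 + ns$darkOffset))
    expect_equal(st@data[, , 1], unname(st@flat), tolerance = 1e-12)
})

test_that("ray tracing matches dense-sampling and analytic chord oracles", {
    ph <- cylinderPhantom(n = 128, nz = 24, voxel = 0.1, radius = 6,
                          muValue = 0.06)
    geom <- deskGeometry(nu = 160, nv = 31, nProjections = 2, isoPixel = 0.1)
    p <- idealSinogram(ph, geom)
    sod <- geom@sod
    du <- 0.1
    mid <- 16  # v = 0 row
    for (iu in c(80, 81, 60, 100, 45)) {
        u <- (iu - 1 - (160 - 1) / 2) * du    # virtual detector coordinate
        b <- abs(u) * sod / sqrt(sod^2 + u^2) # fan-ray impact parameter
        if (b >= 5.8) next
        ## brute-force oracle: nearest-neighbour sampling of the voxel grid
        ## at 1/20 voxel steps along the independently recomputed ray
        brute <- bruteRayIntegral(ph, geom, iu, mid, angleDeg = 0)
        expect_equal(p[iu, mid, 1], brute,
                     tolerance = 0.005)
        ## and the analytic chord, up to the voxelization error of the grid
        chord <- 2 * sqrt(6^2 - b^2)
        expect_equal(p[iu, mid, 1], 0.06 * chord,
                     tolerance = 2 * 0.06 * 0.1 / (0.06 * chord))
    }
})

test_that("projections of a cylindrically symmetric phantom are angle-invariant", {
    ph <- cylinderPhantom(n = 64, nz = 12, voxel = 0.25, radius = 5)
    geom <- deskGeometry(nu = 96, nv = 15, nProjections = 12, isoPixel = 0.25)
    p <- idealSinogram(ph, geom)
    ref <- p[, 8, 1]
    ## every ray crosses the voxelized cylinder boundary, so the deviation
    ## is bounded by the voxelization error ~ mu x voxel
    for (a in 2:12)
        expect_lt(max(abs(p[, 8, a] - ref)), 1.5 * 0.06 * 0.25)
})

test_that("forward projection is deterministic given the seed", {
    ph <- tinyPhantom()
    geom <- deskGeometry(nu = 48, nv = 32, nProjections = 8, isoPixel = 0.6)
    nsOff <- noiseSpec(poisson = FALSE)
    a <- forwardProject(ph, geom, nsOff, seed = 1)
    b <- forwardProject(ph, geom, nsOff, seed = 99)
    expect_identical(a@data, b@data)  # noiseless part independent of seed
    nsOn <- noiseSpec(poisson = TRUE)
    c1 <- forwardProject(ph, geom, nsOn, seed = 1)
    c2 <- forwardProject(ph, geom, nsOn, seed = 1)
    c3 <- forwardProject(ph, geom, nsOn, seed = 2)
    expect_identical(c1@data, c2@data)
    expect_false(identical(c1@data, c3@data))
})

test_that("a phantom outside the field of view is rejected with the angle", {
    ph <- tinyPhantom()
    geom <- deskGeometry(nu = 12, nv = 12, nProjections = 4, isoPixel = 0.6)
    expect_error(forwardProject(ph, geom), "field of view at angle")
})

test_that("reference frames obey flat > dark and scale with the gain", {
    geom <- deskGeometry(nu = 32, nv = 16, nProjections = 4)
    ns <- noiseSpec(i0 = 1e4, poisson = FALSE, darkOffset = 100)
    ref <- makeReferenceFrames(geom, matrix(1, 32, 16), ns, seed = 1)
    expect_true(all(ref$flat - ref$dark == 1e4))
    expect_true(all(ref$dark == 100))
    gm <- matrix(1, 32, 16)
    gm[7, ] <- 1.05
    ref2 <- makeReferenceFrames(geom, gm, ns, seed = 1)
    expect_equal(unname(ref2$flat[7, 1] - ref2$dark[7, 1]), 10500)
    expect_error(makeReferenceFrames(geom, gm * 0, ns), "gain must be > 0")
})

test_that("Poisson flat frames average to the expected level", {
    geom <- deskGeometry(nu = 24, nv = 16, nProjections = 4)
    ns <- noiseSpec(i0 = 1e4, poisson = TRUE, darkOffset = 0)
    acc <- matrix(0, 24, 16)
    nFrames <- 100
    for (k in seq_len(nFrames))
        acc <- acc + makeReferenceFrames(geom, NULL, ns, seed = k)$flat
    m <- acc / nFrames
    se <- sqrt(1e4 / nFrames)
    expect_gt(mean(abs(m - 1e4) <= 3 * se), 0.99)
    expect_true(all(abs(m - 1e4) <= 6 * se))
})

test_that("edge enhancement is the identity at strength zero and on flats", {
    m <- matrix(runif(32 * 24), 32, 24)
    expect_identical(edgeEnhance(m, 0), m)
    u <- matrix(5, 32, 24)
    expect_equal(edgeEnhance(u, 0.4), u, tolerance = 1e-15)
    expect_error(edgeEnhance(m, -1), "strength")
})

test_that("edge enhancement creates an overshoot/undershoot pair at a step", {
    m <- matrix(1, 32, 24)
    m[17:32, ] <- 2            # step along the u axis between rows 16|17
    e <- edgeEnhance(m, 0.25)
    ## oracle: direct 5-point Laplacian stencil at the step
    lap16 <- (m[15, 12] + m[17, 12] + m[16, 11] + m[16, 13] - 4 * m[16, 12])
    lap17 <- (m[16, 12] + m[18, 12] + m[17, 11] + m[17, 13] - 4 * m[17, 12])
    expect_equal(e[16, 12], m[16, 12] - 0.25 * lap16)
    expect_equal(e[17, 12], m[17, 12] - 0.25 * lap17)
    expect_lt(e[16, 12], 1)    # undershoot on the low side
    expect_gt(e[17, 12], 2)    # overshoot on the high side
    expect_equal(e[5, 12], 1)  # far field untouched
})
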