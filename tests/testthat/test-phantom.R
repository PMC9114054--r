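test_that("material table enforces the attenuation ordering", {
    expect_error(materialTable(white_thrombus = 0.07),
                 "ordering violated")
    expect_error(materialTable(air = -0.1), "finite and >= 0")
    mu <- attenuationCoefficients(materialTable())
    expect_true(mu[["red_thrombus"]] > mu[["blood"]])
    expect_true(mu[["blood"]] > mu[["white_thrombus"]])
    expect_true(mu[["white_thrombus"]] > mu[["air"]])
})

test_that("fiber lattice pitch and packing fraction follow diameter + gap", {
    dev <- deviceDescriptor(fiberDiameter = 0.300, fiberGap = 0.260)
    ## closed-form circle packing on the square lattice, pitch 0.560 mm
    expect_equal(fiberVolumeFraction(dev), pi * 0.15^2 / 0.56^2,
                 tolerance = 1e-12)
    expect_equal(pi * 0.15^2 / 0.56^2, 0.2254, tolerance = 1e-3)
})

test_that("homogenized bundle attenuation is the fiber-fraction mean", {
    mt <- materialTable()
    ph <- buildPhantom(materials = mt, n = 48, voxel = 0.4,
                       homogenizeBundle = TRUE)
    f <- fiberVolumeFraction(ph@device)
    expected <- f * attenuationCoefficients(mt)[["fiber"]] +
        (1 - f) * attenuationCoefficients(mt)[["blood"]]
    bundle <- ph@mu[ph@labels == 6L]
    expect_gt(length(bundle), 0)
    expect_lt(max(abs(bundle / expected - 1)), 1e-12)
})

test_that("equal fiber and blood attenuation gives a uniform bundle region", {
    mt <- materialTable(fiber = 0.06, blood = 0.06)
    ph <- buildPhantom(materials = mt, n = 96, voxel = 0.2)
    dev <- ph@device
    x <- (seq_len(96) - 0.5) * 0.2 - 9.6
    r <- sqrt(outer(x^2, x^2, "+"))
    inBundle <- r > dev@bundleInnerRadius + 0.3 &
        r < dev@bundleOuterRadius - 0.3
    mid <- ph@mu[, , 48][inBundle]
    expect_equal(max(mid) - min(mid), 0)
})

test_that("too-coarse grids are rejected unless the bundle is homogenized", {
    expect_error(buildPhantom(n = 32, voxel = 0.6),
                 "resolution too coarse")
    expect_s4_class(buildPhantom(n = 32, voxel = 0.6,
                                 homogenizeBundle = TRUE),
                    "AttenuationPhantom")
})

test_that("inserting no thrombi is the identity", {
    ph <- tinyPhantom()
    expect_identical(ph@labels, insertThrombi(ph, list())@labels)
    expect_identical(ph@mu, insertThrombi(ph, list())@mu)
})

test_that("ellipsoid thrombus voxelization matches the analytic volume", {
    ph <- buildPhantom(n = 96, voxel = 0.2)
    axes <- c(1.0, 0.5, 0.5)  # semi-axes, mm
    spec <- thrombusSpec("red", "ellipsoid", center = c(1.5, 180, 0),
                         axes = axes)
    ph2 <- insertThrombi(ph, spec)
    tab <- thrombusTable(ph2)
    analytic <- 4 / 3 * pi * prod(axes)
    expect_equal(tab$analytic_mm3, analytic, tolerance = 1e-12)
    ## voxel count within one surface-voxel shell of the analytic volume
    ## (Thomsen approximation of the ellipsoid surface area)
    p <- 1.6075
    area <- 4 * pi * ((axes[1]^p * axes[2]^p + axes[1]^p * axes[3]^p +
                       axes[2]^p * axes[3]^p) / 3)^(1 / p)
    shell <- area * ph@voxelSize
    expect_lt(abs(tab$voxels * ph@voxelSize^3 - analytic), shell)
    expect_equal(tab$clipped_fraction, 0)
    ## relabeled voxels carry the red-thrombus attenuation
    mu <- attenuationCoefficients(ph)
    expect_true(all(ph2@mu[ph2@labels == materialCodes()[["red_thrombus"]]] ==
                    mu[["red_thrombus"]]))
})

test_that("thrombus insertion relabels without changing the voxel count", {
    ph <- tinyPhantom()
    spec <- thrombusSpec("white", "ellipsoid", center = c(1.2, 90, 0),
                         axes = c(1.2, 1.2, 1.2))
    ph2 <- insertThrombi(ph, spec)
    expect_identical(dim(ph2@labels), dim(ph@labels))
    expect_identical(length(ph2@labels), length(ph@labels))
    changed <- sum(ph2@labels != ph@labels)
    expect_equal(changed, thrombusTable(ph2)$voxels)
})

test_that("thrombi overlapping non-blood voxels are clipped and reported", {
    ph <- buildPhantom(n = 70, voxel = 0.25)
    ## centred on the fiber bundle: part of the ellipsoid hits fibers
    spec <- thrombusSpec("red", "ellipsoid", center = c(5.2, 45, 0),
                         axes = c(1, 1, 1))
    ph2 <- insertThrombi(ph, spec)
    tab <- thrombusTable(ph2)
    expect_gt(tab$clipped_fraction, 0)
    expect_gt(tab$voxels, 0)
    ## fully outside the blood compartment -> zero volume with a warning
    specOut <- thrombusSpec("red", "ellipsoid", center = c(7.95, 0, 0),
                            axes = c(0.2, 0.2, 0.2))
    expect_warning(ph3 <- insertThrombi(ph, specOut), "fully clipped")
    expect_equal(thrombusTable(ph3)$voxels, 0)
})

test_that("strand thrombi hug the fiber region they are attached to", {
    ph <- buildPhantom(n = 96, voxel = 0.2)
    dev <- ph@device
    r0 <- dev@bundleInnerRadius + 0.4
    spec <- thrombusSpec("red", "strand", center = c(r0, 180, 0),
                         axes = c(0.5, 2.5, 1.5))
    ph2 <- insertThrombi(ph, spec)
    idx <- which(ph2@labels == materialCodes()[["red_thrombus"]],
                 arr.ind = TRUE)
    expect_gt(nrow(idx), 0)
    ctr <- ph2@origin
    rr <- sqrt((ctr[1] + (idx[, 1] - 0.5) * 0.2)^2 +
               (ctr[2] + (idx[, 2] - 0.5) * 0.2)^2)
    ## stays within the specified radial sheath around r0
    expect_true(all(abs(rr - r0) <= 0.5 / 2 + 0.2))
})

test_that("growth series is baseline-free, late-growing and monotone", {
    ph <- buildPhantom(n = 70, voxel = 0.25)
    spec <- thrombusSpec("red", "ellipsoid", center = c(1.2, 180, 0),
                         axes = c(1.0, 0.9, 0.9), firstScan = 2)
    series <- simulateGrowthSeries(ph, spec, nScans = 8)
    expect_length(series, 8)
    vols <- vapply(series, function(p) {
        tab <- thrombusTable(p)
        if (nrow(tab)) sum(tab$voxels) else 0L
    }, 0L)
    expect_equal(vols[1], 0L)              # baseline scan is thrombus-free
    expect_true(all(vols[2:7] < 0.2 * vols[8]))
    expect_true(all(diff(vols) >= 0))      # monotone growth
})

test_that("zero growth factors reproduce the baseline at every scan", {
    ph <- tinyPhantom()
    spec <- thrombusSpec("red", "ellipsoid", center = c(1.2, 180, 0),
                         axes = c(1, 1, 1), firstScan = 1)
    series <- simulateGrowthSeries(ph, spec, schedule = rep(0, 4), nScans = 4)
    for (p in series) expect_identical(p@labels, ph@labels)
})

test_that("a scheduled volume fraction scales the inserted volume", {
    ph <- buildPhantom(n = 96, voxel = 0.2)
    spec <- thrombusSpec("red", "ellipsoid", center = c(1.2, 180, 0),
                         axes = c(1.1, 1.0, 1.0), firstScan = 1)
    series <- simulateGrowthSeries(ph, spec,
                                   schedule = c(rep(0, 6), 0.1, 1),
                                   nScans = 8)
    v7 <- thrombusTable(series[[7]])$analytic_mm3
    v8 <- thrombusTable(series[[8]])$analytic_mm3
    expect_equal(v7 / v8, 0.1, tolerance = 1e-12)
    c7 <- thrombusTable(series[[7]])$voxels
    c8 <- thrombusTable(series[[8]])$voxels
    expect_equal(c7 / c8, 0.1, tolerance = 0.25)  # voxelization granularity
})
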