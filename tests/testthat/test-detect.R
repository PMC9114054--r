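test_that("self-alignment yields a zero shift and exact shift recovery", {
    ph <- tinyPhantom()
    mk <- function(data) new("ReconVolume", data = data, voxelSize = 0.6,
                             origin = ph@origin, scanIndex = 1,
                             greyScale = 1000 / 0.06,
                             geometry = deskGeometry(), provenance = list())
    ref <- mk(ph@mu * 1000 / 0.06)
    ## a perfectly mirror-symmetric volume trips the ambiguity guard, whose
    ## declared fallback is the (here correct) zero shift
    expect_equal(suppressWarnings(alignScans(ref, ref)$shift), c(0, 0, 0))
    for (sh in list(c(3, -2, 1), c(5, 5, -5), c(-8, 0, 7))) {
        mv <- mk(oxyCT:::shiftVolume(ref@data, sh))
        al <- alignScans(ref, mv)
        expect_lte(max(abs(al$shift - sh)), 1)  # the +/- 1 voxel contract
    }
})

test_that("alignment refuses mismatched grids and flags flat volumes", {
    ph <- tinyPhantom()
    v1 <- new("ReconVolume", data = ph@mu, voxelSize = 0.6,
              origin = ph@origin, scanIndex = 1, greyScale = 1,
              geometry = deskGeometry(), provenance = list())
    v2 <- v1
    v2@data <- ph@mu[1:16, , ]
    expect_error(alignScans(v1, v2), "grid shape")
})

test_that("baseline subtraction subtracts, clips and keeps the raw field", {
    d <- c(12, 10, 8)
    mkv <- function(x, idx) new("ReconVolume", data = x, voxelSize = 0.1,
                                origin = c(0, 0, 0), scanIndex = idx,
                                greyScale = 1, geometry = deskGeometry(),
                                provenance = list())
    set.seed(1)
    a <- array(rnorm(prod(d), 1000, 10), d)
    b <- a
    b[3, 4, 5] <- a[3, 4, 5] + 500
    b[7, 2, 3] <- a[7, 2, 3] - 600
    dv <- subtractBaseline(mkv(a, 1), mkv(b, 8))
    expect_equal(dv@data[3, 4, 5], 150)   # clipped at +150
    expect_equal(dv@data[7, 2, 3], -200)  # clipped at -200
    expect_equal(dv@raw[3, 4, 5], 500)
    expect_true(all(dv@data >= -200 & dv@data <= 150))
    ## identity and antisymmetry (pre-clip)
    expect_true(all(subtractBaseline(mkv(a, 1), mkv(a, 2))@raw == 0))
    d1 <- subtractBaseline(mkv(a, 1), mkv(b, 8))@raw
    d2 <- subtractBaseline(mkv(b, 1), mkv(a, 8))@raw
    expect_equal(d1, -d2, tolerance = 1e-12)
    expect_error(subtractBaseline(mkv(a, 1), mkv(a[1:6, , ], 8)),
                 "shapes differ")
})

test_that("an empty difference volume yields an empty segmentation", {
    dv <- diffFromArray(array(0, c(24, 24, 24)))
    seg <- segmentThrombi(dv)
    expect_equal(nrow(components(seg)), 0)
    expect_true(all(volumeData(seg) == 0))
    q <- quantifyThrombi(seg)
    expect_true(all(q$totals$volume_mm3 == 0))
    expect_true(all(q$totals$n_components == 0))
})

test_that("component size rule is strictly greater than 30 voxels", {
    for (nvox in c(30, 31)) {
        dv <- makeBlobDiff(nvox, value = 120)
        seg <- segmentThrombi(dv, presmooth = 0)
        if (nvox == 30) {
            expect_equal(nrow(components(seg)), 0)
        } else {
            expect_equal(nrow(components(seg)), 1)
            expect_equal(components(seg)$voxels, 31)
            expect_equal(components(seg)$class, "red")
        }
    }
})

test_that("thresholds must bracket zero and stay inside the clip range", {
    dv <- makeBlobDiff(40, value = 120)
    expect_error(segmentThrombi(dv, tauPos = -5, tauNeg = -20), "tauPos")
    expect_error(segmentThrombi(dv, tauPos = 200, tauNeg = -20),
                 "outside the clip range")
    expect_error(segmentThrombi(dv, tauPos = 20, tauNeg = -300),
                 "outside the clip range")
})

test_that("red and white deposits are classified by the sign of their change", {
    raw <- array(0, c(48, 48, 48))
    cc <- blobCoords(60)
    raw[cc + rep(c(14, 14, 14), each = 60)] <- 120
    raw[cc + rep(c(34, 34, 34), each = 60)] <- -120
    seg <- segmentThrombi(diffFromArray(raw), presmooth = 0)
    cmp <- components(seg)
    expect_equal(nrow(cmp), 2)
    expect_setequal(cmp$class, c("red", "white"))
    expect_true(all(cmp$voxels == 60))
    ## label volume marks exactly the blob voxels
    expect_equal(sum(volumeData(seg) > 0), 120)
})

test_that("segmentation is invariant to a global grey offset on both scans", {
    mkv <- function(x, idx) new("ReconVolume", data = x, voxelSize = 0.1,
                                origin = c(0, 0, 0), scanIndex = idx,
                                greyScale = 1, geometry = deskGeometry(),
                                provenance = list())
    set.seed(4)
    base <- array(rnorm(30^3, 1000, 2), c(30, 30, 30))
    fol <- base
    cc <- blobCoords(50)
    fol[cc + rep(c(15, 15, 15), each = 50)] <- fol[cc + rep(c(15, 15, 15),
                                                            each = 50)] + 120
    s1 <- segmentThrombi(subtractBaseline(mkv(base, 1), mkv(fol, 8)),
                         presmooth = 0)
    s2 <- segmentThrombi(subtractBaseline(mkv(base + 77, 1), mkv(fol + 77, 8)),
                         presmooth = 0)
    expect_identical(volumeData(s1), volumeData(s2))
    expect_equal(components(s1)$volume_mm3, components(s2)$volume_mm3)
})

test_that("line-like low-compactness components are rejected as fiber artifacts", {
    raw <- array(0, c(48, 48, 48))
    ## thin zig-zag line of parallel segments, 1 voxel thick
    for (k in 0:40) raw[6 + k, 24 + (k %% 2), 24] <- 120
    for (k in 0:40) raw[6 + k, 28 + (k %% 2), 24] <- 120
    segKeep <- segmentThrombi(diffFromArray(raw), presmooth = 0,
                              rejectAnisotropic = FALSE)
    segDrop <- segmentThrombi(diffFromArray(raw), presmooth = 0,
                              rejectAnisotropic = TRUE)
    expect_gt(nrow(components(segKeep)), 0)
    expect_equal(nrow(components(segDrop)), 0)
})

test_that("white components at air-level contrast are flagged ambiguous", {
    raw <- array(0, c(48, 48, 48))
    cc <- blobCoords(60)
    raw[cc + rep(c(14, 14, 14), each = 60)] <- -250   # white-thrombus level
    raw[cc + rep(c(34, 34, 34), each = 60)] <- -1000  # blood -> air level
    seg <- segmentThrombi(diffFromArray(raw), presmooth = 0)
    expect_equal(nrow(components(seg)), 2)
    seg2 <- flagAirAmbiguity(seg)
    cmp <- components(seg2)
    expect_setequal(cmp$class, c("white", "ambiguous_air"))
    expect_equal(cmp$class[cmp$core_diff < -500], "ambiguous_air")
    ## no white components -> identity
    rawR <- array(0, c(32, 32, 32))
    rawR[blobCoords(40) + rep(c(16, 16, 16), each = 40)] <- 100
    segR <- segmentThrombi(diffFromArray(rawR), presmooth = 0)
    expect_identical(components(flagAirAmbiguity(segR)),
                     components(segR))
})

test_that("quantification converts voxel counts to volumes and assigns regions", {
    raw <- array(0, c(40, 40, 40))
    cc <- blobCoords(1000)
    raw[cc + rep(c(20, 20, 20), each = 1000)] <- 120
    dv <- diffFromArray(raw, voxel = 0.1)
    seg <- segmentThrombi(dv, presmooth = 0)
    q <- quantifyThrombi(seg)
    expect_equal(q$totals$volume_mm3[q$totals$class == "red"], 1.0,
                 tolerance = 1e-12)
    expect_equal(q$components$region, "unknown")
    ## with a device descriptor the centre blob sits in the inner core /
    ## transition region geometry
    dev <- deviceDescriptor()
    q2 <- quantifyThrombi(seg, dev)
    expect_true(q2$components$region %in%
                c("inlet_transition", "bundle", "outlet"))
})

test_that("half-maximum volumetry recovers blurred blob volumes", {
    ## blurred ellipsoid: voxelize, then smooth heavily; plateau stays at the
    ## inserted contrast so the half-max count matches the sharp count
    n <- 48
    x <- seq_len(n) - 24.5
    e <- outer(outer(x^2 / 64, x^2 / 36, "+"), x^2 / 36, "+") <= 1
    sharp <- sum(e)
    raw <- array(ifelse(e, 250, 0), c(n, n, n))
    for (k in 1:2) raw <- oxyCT:::boxSmooth3(raw)
    seg <- segmentThrombi(diffFromArray(raw), presmooth = 0)
    cmp <- components(seg)
    expect_equal(nrow(cmp), 1)
    expect_gt(cmp$voxels, sharp)                 # detection mask includes skirt
    expect_lt(abs(cmp$voxels_halfmax / sharp - 1), 0.05)
})
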