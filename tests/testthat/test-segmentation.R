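test_that("random split produces complementary halves", {
    h <- splitHalves(490, seed = 1)
    expect_length(h$first, 245)
    expect_length(h$second, 245)
    expect_length(intersect(h$first, h$second), 0)
    expect_setequal(c(h$first, h$second), 1:490)

    h5 <- splitHalves(5, seed = 1)
    expect_length(h5$first, 2)
    expect_length(h5$second, 3)

    expect_identical(splitHalves(100, seed = 42), splitHalves(100, seed = 42))
    expect_error(splitHalves(3), "at least 4")
})

test_that("waveform correlation is the (N-1)-normalized Pearson coefficient", {
    a <- c(0.3, 1.2, -0.5, 2.0, 0.1)
    expect_equal(waveformCorrelation(a, a), 1)
    expect_equal(waveformCorrelation(a, -a), -1)
    expect_equal(waveformCorrelation(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
    expect_true(is.nan(waveformCorrelation(rep(1, 4), c(1, 2, 3, 4))))
    expect_error(waveformCorrelation(1:4, 1:5), "same number")
})

test_that("waveform correlation matches a brute-force oracle", {
    # independent implementation straight from the defining sum
    brute <- function(a, b) {
        n <- length(a)
        ma <- sum(a) / n; mb <- sum(b) / n
        sa <- sqrt(sum((a - ma)^2) / (n - 1))
        sb <- sqrt(sum((b - mb)^2) / (n - 1))
        s <- 0
        for (i in seq_len(n))
            s <- s + ((a[i] - ma) / sa) * ((b[i] - mb) / sb)
        s / (n - 1)
    }
    set.seed(13)
    for (i in 1:200) {
        n <- sample(5:40, 1)
        a <- rnorm(n); b <- rnorm(n)
        expect_equal(waveformCorrelation(a, b), brute(a, b),
                     tolerance = 1e-12)
    }
})

test_that("split-half map separates pulsatile vessels from noise", {
    prep <- smallPrepared()
    ph <- prep$phantom
    searchMask <- Mask3D((maskData(ph@brainMask) |
                          maskData(ph@generalArteryRoi) |
                          maskData(ph@generalSssRoi)) * 1, "brain")
    m <- splitHalfCorrMap(prep$bold, prep$phases, searchMask,
                          nRepeats = 100, seed = 21)
    v <- mapValues(m)
    vessel <- v[maskData(ph@truthArtery) != 0]
    expect_true(all(is.finite(vessel)))
    expect_gt(mean(vessel), 0.6)

    bg <- v[maskData(ph@brainMask) != 0 &
            maskData(ph@generalArteryRoi) == 0 &
            maskData(ph@generalSssRoi) == 0]
    bg <- bg[is.finite(bg)]
    # zero-pulsatility voxels scatter symmetrically about 0
    expect_lt(abs(mean(bg)), 3 * sd(bg) / sqrt(length(bg)))
    expect_lt(abs(mean(bg)), 0.1)
})

test_that("averaging splits shrinks the split-sampling variance", {
    # the voxel-conditional component of the map does not average out, so
    # compare the variance of the difference of two independently seeded
    # maps: that isolates the split-sampling noise, which shrinks with the
    # number of repeats
    b <- makeNoiseBold(c(8, 8, 4), nt = 400, seed = 22)
    pk <- makePeaks(n = 260, seed = 22)
    phs <- boldPhases(b, pk)
    msk <- allOnesMask(c(8, 8, 4))
    d1 <- mapValues(splitHalfCorrMap(b, phs, msk, 1, seed = 1)) -
          mapValues(splitHalfCorrMap(b, phs, msk, 1, seed = 2))
    d100 <- mapValues(splitHalfCorrMap(b, phs, msk, 100, seed = 3)) -
            mapValues(splitHalfCorrMap(b, phs, msk, 100, seed = 4))
    expect_gt(var(as.numeric(d1)) / var(as.numeric(d100)), 10)
})

test_that("preliminary threshold is mean + 3 sd over defined brain voxels", {
    shape <- c(10, 10, 5)
    brain <- allOnesMask(shape)
    flat <- new("CorrelationMap", values = array(0.2, shape),
                kind = "split_half_mean", nRepeats = 1L)
    expect_equal(preliminaryThreshold(flat, brain), 0.2)

    set.seed(23)
    vals <- array(rnorm(prod(shape), 0, 0.1), shape)
    mp <- new("CorrelationMap", values = vals, kind = "split_half_mean",
              nRepeats = 1L)
    expect_equal(preliminaryThreshold(mp, brain),
                 mean(vals) + 3 * sd(vals), tolerance = 1e-12)

    # NaN voxels are excluded from the statistics
    vals2 <- vals; vals2[1:250] <- NaN
    mp2 <- new("CorrelationMap", values = vals2, kind = "split_half_mean",
               nRepeats = 1L)
    def <- vals2[is.finite(vals2)]
    expect_equal(preliminaryThreshold(mp2, brain),
                 mean(def) + 3 * sd(def), tolerance = 1e-12)

    tiny <- new("CorrelationMap",
                values = array(c(rep(0.1, 50), rep(NaN, 450)), shape),
                kind = "split_half_mean", nRepeats = 1L)
    expect_error(preliminaryThreshold(tiny, brain), "too few")
})

test_that("preliminary region intersects the ROI with the threshold rule", {
    shape <- c(6, 6, 2)
    set.seed(24)
    vals <- array(runif(prod(shape), -0.2, 0.5), shape)
    mp <- new("CorrelationMap", values = vals, kind = "split_half_mean",
              nRepeats = 1L)
    roi <- allOnesMask(shape, "general_artery")
    expect_error(preliminaryRegion(mp, roi, max(vals) + 0.1),
                 "empty preliminary region")
    all_in <- preliminaryRegion(mp, roi, -2)
    expect_equal(nVoxels(all_in), prod(shape))
    # strict inequality at the threshold
    vals[] <- 0.3; vals[1] <- 0.4
    mp2 <- new("CorrelationMap", values = vals, kind = "split_half_mean",
               nRepeats = 1L)
    expect_equal(nVoxels(preliminaryRegion(mp2, roi, 0.3)), 1)
})

test_that("phantom preliminary region stays near the true vessels", {
    prep <- smallPrepared()
    ph <- prep$phantom
    searchMask <- Mask3D((maskData(ph@brainMask) |
                          maskData(ph@generalArteryRoi)) * 1, "brain")
    m <- splitHalfCorrMap(prep$bold, prep$phases, searchMask,
                          nRepeats = 100, seed = 25)
    thr <- preliminaryThreshold(m, ph@brainMask)
    reg <- preliminaryRegion(m, ph@generalArteryRoi, thr)
    dilTruth <- dilateMask(ph@truthArtery, 3)   # truth dilated by 1 voxel
    expect_true(all(maskData(reg) <= maskData(dilTruth)))
})

test_that("regional mean waveform degenerates correctly", {
    prep <- smallPrepared()
    ph <- prep$phantom
    lin <- which(maskData(ph@truthArtery) != 0)[1]
    idx <- arrayInd(lin, dim(maskData(ph@truthArtery)))
    one <- array(0, dim(maskData(ph@truthArtery))); one[lin] <- 1
    wf1 <- regionMeanWaveform(prep$bold, prep$phases, Mask3D(one), 20)
    series <- prep$bold@data[idx[1], idx[2], idx[3], ]
    k <- min(idx[3], ncol(phaseMatrix(prep$phases)))
    phv <- phaseMatrix(prep$phases)[, k]
    phv[!validTimepoints(prep$phases)[, k]] <- NA
    wfd <- binWaveform(series - mean(series), phv, 20)
    expect_equal(binMeans(wf1), binMeans(wfd), tolerance = 1e-12)

    # duplicating identical voxels leaves the waveform unchanged
    set.seed(28)
    s <- rnorm(300)
    arr <- array(0, c(2, 1, 1, 300))
    arr[1, 1, 1, ] <- s; arr[2, 1, 1, ] <- s
    b2 <- Bold4D(arr, c(2, 2, 2), 0.5)
    pk2 <- makePeaks(n = 200, seed = 28)
    phs2 <- boldPhases(b2, pk2)
    oneA <- array(c(1, 0), c(2, 1, 1))
    both <- array(1, c(2, 1, 1))
    wfA <- regionMeanWaveform(b2, phs2, Mask3D(oneA), 20)
    wf2 <- regionMeanWaveform(b2, phs2, Mask3D(both), 20)
    expect_equal(binMeans(wf2), binMeans(wfA), tolerance = 1e-10)
})

test_that("truth-region waveform recovers the generating waveform", {
    prep <- smallPrepared()
    ph <- prep$phantom
    wf <- regionMeanWaveform(prep$bold, prep$phases, ph@truthArtery, 20)
    # recovery up to the constant phase rotation introduced by placing the
    # phase origin at the detected (band-passed) pulse maximum
    expect_gt(bestShiftCor(binMeans(wf)), 0.98)
    expect_gt(cor(binMeans(wf), binMeans(ph@generatorWaveform)), 0.85)
})

test_that("template map is the waveform correlation against the template", {
    prep <- smallPrepared()
    ph <- prep$phantom
    wf <- regionMeanWaveform(prep$bold, prep$phases, ph@truthArtery, 20)
    searchMask <- Mask3D((maskData(ph@brainMask) |
                          maskData(ph@generalArteryRoi)) * 1, "brain")
    tm <- templateCorrMap(prep$bold, prep$phases, wf, searchMask)
    expect_identical(mapKind(tm), "template")
    v <- mapValues(tm)

    # vessel voxels exceed the background 99th percentile often enough
    bgv <- v[maskData(ph@brainMask) != 0 &
             maskData(ph@generalArteryRoi) == 0 &
             maskData(ph@generalSssRoi) == 0]
    q99 <- quantile(bgv[is.finite(bgv)], 0.99, type = 7)
    vess <- v[maskData(ph@truthArtery) != 0]
    expect_gt(mean(vess > q99), 0.8)

    # a voxel whose waveform IS the template correlates to 1; anti-phase to -1
    expect_equal(waveformCorrelation(wf, wf), 1)
    flip <- new("CardiacWaveform", nBins = wf@nBins,
                binMeans = -binMeans(wf), binCounts = binCounts(wf),
                interpolated = interpolatedBins(wf))
    expect_equal(waveformCorrelation(flip, wf), -1)

    bad <- new("CardiacWaveform", nBins = 20L, binMeans = rnorm(20),
               binCounts = rep(0L, 20), interpolated = rep(TRUE, 20))
    expect_error(templateCorrMap(prep$bold, prep$phases, bad, searchMask),
                 "invalid template")
})

test_that("background quantile uses type-7 interpolation over eligible voxels", {
    shape <- c(10, 10, 10)
    set.seed(26)
    u <- array(runif(prod(shape)), shape)
    mp <- new("CorrelationMap", values = u, kind = "template", nRepeats = 0L)
    brain <- allOnesMask(shape)
    q <- backgroundQuantile(mp, brain, list(), 0.99)
    expect_equal(q, quantile(as.numeric(u), 0.99, type = 7, names = FALSE))
    expect_equal(q, 0.99, tolerance = 0.02)

    # q = 0.5 of {1,2,3} is 2 (values scaled into [-1,1] as correlations)
    v3 <- array(NaN, shape); v3[1:3] <- c(0.1, 0.2, 0.3)
    # too few defined -> error
    mp3 <- new("CorrelationMap", values = v3, kind = "template",
               nRepeats = 0L)
    expect_error(backgroundQuantile(mp3, brain, list(), 0.5), "too few")
    expect_equal(as.numeric(quantile(c(1, 2, 3), 0.5, type = 7)), 2)

    # excluding a high-valued ROI leaves the background statistics
    hi <- u; hi[1:200] <- 0.999
    roi <- array(0, shape); roi[1:200] <- 1
    mph <- new("CorrelationMap", values = hi, kind = "template",
               nRepeats = 0L)
    qx <- backgroundQuantile(mph, brain, list(Mask3D(roi)), 0.99)
    expect_equal(qx, quantile(as.numeric(u[-(1:200)]), 0.99, type = 7,
                              names = FALSE))
})

test_that("refinement converges on the phantom and respects its ROIs", {
    res <- cached("smallRun", {
        ph <- smallPhantom()
        segmentVessels(ph@bold, ph@physio, ph@brainMask,
                       ph@generalArteryRoi, ph@generalSssRoi,
                       seed = 31, physioStart = "scan")
    })
    ph <- smallPhantom()
    for (tg in c("artery", "sss")) {
        sr <- res[[tg]]
        expect_true(converged(sr))
        expect_lte(nrow(iterationTrace(sr)), 20)
        roi <- if (tg == "artery") ph@generalArteryRoi else ph@generalSssRoi
        expect_true(all(maskData(segmentationMask(sr)) <= maskData(roi)))
        it <- iterationTrace(sr)
        expect_equal(it$volume_cm3,
                     it$n_voxels * prod(voxelDims(ph@bold)) / 1000)
    }
    # SSS candidates are additionally restricted to the brain
    expect_true(all(maskData(segmentationMask(res$sss)) <=
                    maskData(ph@brainMask)))
    # both targets recover their vessels well at pulsatility/noise = 2
    expect_gt(diceCoefficient(segmentationMask(res$artery),
                              ph@truthArtery), 0.7)
    expect_gt(diceCoefficient(segmentationMask(res$sss), ph@truthSss), 0.7)
})

test_that("a candidate region without pulsatile voxels errors out", {
    # constant series inside the ROI -> zero-variance waveforms -> no voxel
    # can exceed the threshold
    b <- makeNoiseBold(c(8, 8, 4), nt = 400, seed = 27)
    roiArr <- array(0, c(8, 8, 4)); roiArr[3:4, 3:4, 2] <- 1
    b@data[3:4, 3:4, 2, ] <- 5
    pk <- makePeaks(n = 260, seed = 27)
    phs <- boldPhases(b, pk)
    phv <- runif(500)
    wf <- binWaveform(generatorWaveform(phv), phv, 20)
    expect_error(
        refineSegmentation(b, phs, "artery",
                           Mask3D(roiArr, "general_artery"), NULL,
                           allOnesMask(c(8, 8, 4)), wf),
        "empty segmentation")
})

test_that("identical seeds reproduce the segmentation bit for bit", {
    ph <- smallPhantom()
    run <- function() segmentVessels(ph@bold, ph@physio, ph@brainMask,
                                     ph@generalArteryRoi, ph@generalSssRoi,
                                     seed = 99, physioStart = "scan")
    r1 <- run(); r2 <- run()
    expect_identical(maskData(segmentationMask(r1$artery)),
                     maskData(segmentationMask(r2$artery)))
    expect_identical(iterationTrace(r1$sss), iterationTrace(r2$sss))
    expect_identical(mapValues(r1$splitHalfMap), mapValues(r2$splitHalfMap))
})

test_that("split-half correlation rises monotonically with pulsatility", {
    amps <- c(0, 0.5, 1, 2, 4)
    means <- vapply(amps, function(a) {
        ph <- generatePhantom(smallPhantomConfig(
            pulsatilityAmplitude = a, seed = 55))
        trimmed <- trimInitialVolumes(ph@bold, 10)
        filt <- highpassFilter(trimmed, mask = ph@brainMask)
        physio <- PhysioTrace(physioSamples(ph@physio),
                              samplingRate(ph@physio), -10 * 0.5)
        pk <- detectPeaks(physio)
        phs <- boldPhases(filt, pk)
        m <- splitHalfCorrMap(filt, phs, ph@truthArtery,
                              nRepeats = 30, seed = 56)
        mean(mapValues(m)[maskData(ph@truthArtery) != 0])
    }, numeric(1))
    expect_true(all(diff(means) > 0))
    expect_lt(abs(means[1]), 0.1)   # amplitude 0: indistinguishable from noise
    expect_gt(means[5], means[2])
})

test_that("artery-only runs succeed with a warning; strict QC gates refuse", {
    ph <- smallPhantom()
    expect_warning(
        res <- segmentVessels(ph@bold, ph@physio, ph@brainMask,
                              ph@generalArteryRoi, generalSssRoi = NULL,
                              seed = 31, physioStart = "scan"),
        "artery-only")
    expect_null(res$sss)
    expect_s4_class(res$artery, "SegmentationResult")

    set.seed(60)
    noisePhysio <- PhysioTrace(rnorm(3000), fs = 100)
    expect_error(
        segmentVessels(ph@bold, noisePhysio, ph@brainMask,
                       ph@generalArteryRoi, ph@generalSssRoi,
                       seed = 31, strict = TRUE),
        "QC gate failed")
})

test_that("geometrically inconsistent masks are rejected up front", {
    ph <- smallPhantom()
    wrong <- Mask3D(array(1, c(8, 8, 4)), "brain")
    expect_error(
        segmentVessels(ph@bold, ph@physio, wrong, ph@generalArteryRoi,
                       ph@generalSssRoi, seed = 1),
        "geometric inconsistency")
})
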