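test_that("the default phantom bundle satisfies its geometric contract", {
    ph <- defaultPhantom()
    expect_true(validObject(ph))
    expect_equal(dim(boldData(ph@bold)), c(32, 32, 32, 450))
    expect_equal(repetitionTime(ph@bold), 0.5)
    # truth inside general ROIs, ROIs disjoint (validity), truth in brain
    expect_true(all(maskData(ph@truthArtery) <= maskData(ph@brainMask)))
    expect_true(all(maskData(ph@truthSss) <= maskData(ph@brainMask)))
    expect_gt(nVoxels(ph@generalArteryRoi), nVoxels(ph@truthArtery))
    expect_gt(nVoxels(ph@generalSssRoi), nVoxels(ph@truthSss))
})

test_that("the same seed reproduces the bundle bit for bit", {
    a <- generatePhantom(smallPhantomConfig(seed = 3))
    b <- generatePhantom(smallPhantomConfig(seed = 3))
    expect_identical(boldData(a@bold), boldData(b@bold))
    expect_identical(physioSamples(a@physio), physioSamples(b@physio))
    expect_identical(a@beatTimes, b@beatTimes)
    c_ <- generatePhantom(smallPhantomConfig(seed = 4))
    expect_false(identical(boldData(a@bold), boldData(c_@bold)))
})

test_that("configured heart rate is recovered from the synthetic PPG", {
    ph <- generatePhantom(smallPhantomConfig(meanHr = 67, seed = 6))
    pk <- detectPeaks(ph@physio)
    expect_lt(abs(meanHeartRate(pk) - 67), 1)
    # and against the generator's own beats
    expect_lt(abs(60 / mean(diff(ph@beatTimes)) - 67), 1)
})

test_that("zero-amplitude vessels are indistinguishable from background", {
    # thicker tube than the standard small fixture: the |mean| bound needs
    # enough vessel voxels to average over
    ph <- generatePhantom(smallPhantomConfig(
        pulsatilityAmplitude = 0, seed = 9,
        arterySegments = list(
            list(from = c(4, 8, 5), to = c(12, 8, 5), radius = 1.6))))
    trimmed <- trimInitialVolumes(ph@bold, 10)
    filt <- highpassFilter(trimmed, mask = ph@brainMask)
    physio <- PhysioTrace(physioSamples(ph@physio),
                          samplingRate(ph@physio), -10 * 0.5)
    pk <- detectPeaks(physio)
    phs <- boldPhases(filt, pk)
    m <- splitHalfCorrMap(filt, phs, ph@truthArtery, nRepeats = 50,
                          seed = 10)
    vessel <- mapValues(m)[maskData(ph@truthArtery) != 0]
    expect_lt(abs(mean(vessel)), 0.1)
})

test_that("the generator waveform is standardized and non-sinusoidal", {
    phi <- (seq_len(4096) - 0.5) / 4096
    w <- generatorWaveform(phi)
    expect_lt(abs(mean(w)), 1e-6)
    expect_equal(sd(w), 1, tolerance = 1e-3)
    # systolic peak near phase 0.15; the shape is not a sinusoid, so phase
    # binning is exercised by an asymmetric waveform
    expect_equal(phi[which.max(w)], 0.15, tolerance = 0.02)
    bestSine <- max(abs(sapply(seq(0, 1, by = 0.01), function(s)
        cor(w, sin(2 * pi * (phi - s))))))
    expect_lt(bestSine, 0.9)
})

test_that("cubic dilation grows masks like an imdilate kernel", {
    shape <- c(7, 7, 7)
    center <- array(0, shape); center[4, 4, 4] <- 1
    d <- dilateMask(Mask3D(center), 3)
    expect_equal(nVoxels(d), 27)
    expect_true(all(maskData(d)[3:5, 3:5, 3:5] == 1))

    corner <- array(0, shape); corner[1, 1, 1] <- 1
    expect_equal(nVoxels(dilateMask(Mask3D(corner), 3)), 8)

    empty <- Mask3D(array(0, shape))
    expect_equal(nVoxels(dilateMask(empty, 3)), 0)

    m <- Mask3D(array(rbinom(prod(shape), 1, 0.2), shape))
    expect_true(all(maskData(dilateMask(m, 3)) >= maskData(m)))
    expect_error(dilateMask(m, 2), "odd")
    expect_error(dilateMask(m, 0), "odd")
})

test_that("probability binarization is strictly greater-than", {
    p <- array(0, c(3, 3, 1))
    p[1, 1, 1] <- 0.005   # exactly at threshold: excluded
    p[2, 1, 1] <- 0.006   # just above: included
    m <- binarizeProbability(p, 0.005)
    expect_equal(maskData(m)[1, 1, 1], 0)
    expect_equal(maskData(m)[2, 1, 1], 1)
    expect_equal(nVoxels(binarizeProbability(array(0, c(3, 3, 1)))), 0)
    expect_error(binarizeProbability(array(1.5, c(2, 2, 1))), "\\[0, 1\\]")
})

test_that("slice-timed phantoms record interleaved slice offsets", {
    ph <- generatePhantom(smallPhantomConfig(sliceTiming = TRUE, seed = 12))
    off <- sliceOffsets(ph@bold)
    expect_length(off, 12)
    expect_true(all(off >= 0 & off < repetitionTime(ph@bold)))
    expect_false(is.unsorted(sort(off)))
    # analysis with matching offsets still recovers the vessels
    trimmed <- trimInitialVolumes(ph@bold, 10)
    filt <- highpassFilter(trimmed, mask = ph@brainMask)
    physio <- PhysioTrace(physioSamples(ph@physio),
                          samplingRate(ph@physio), -10 * 0.5)
    pk <- detectPeaks(physio)
    phs <- boldPhases(filt, pk)
    expect_equal(ncol(phaseMatrix(phs)), 12)
    wf <- regionMeanWaveform(filt, phs, ph@truthArtery, 20)
    expect_gt(bestShiftCor(binMeans(wf)), 0.95)
})

test_that("partial-volume shells carry half-amplitude pulsatility", {
    ph <- generatePhantom(smallPhantomConfig(partialVolumeShell = TRUE,
                                             seed = 13))
    shell <- maskData(dilateMask(ph@truthArtery, 3)) == 1 &
        maskData(ph@truthArtery) == 0 & maskData(ph@brainMask) == 1
    lin <- which(shell)[1]
    idx <- arrayInd(lin, dim(maskData(ph@truthArtery)))
    s <- boldData(ph@bold)[idx[1], idx[2], idx[3], ]
    # pulsatile variance beyond the noise floor, but less than a vessel voxel
    linV <- which(maskData(ph@truthArtery) == 1)[1]
    idxV <- arrayInd(linV, dim(maskData(ph@truthArtery)))
    sV <- boldData(ph@bold)[idxV[1], idxV[2], idxV[3], ]
    expect_gt(sd(sV), sd(s))
    expect_gt(sd(s), ph@config$noiseSd)
})
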