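# Shared fixtures, built in code and cached for the duration of the run.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
    if (!exists(key, envir = .fixtureCache))
        assign(key, force(expr), envir = .fixtureCache)
    get(key, envir = .fixtureCache)
}

# jittered peak series: RR ~ N(rr0, jitter) clipped to [0.3, 2] s
makePeaks <- function(n = 260, rr0 = 0.9, jitter = 0.03, seed = 5,
                      start = 0.05) {
    set.seed(seed)
    rr <- pmin(pmax(stats::rnorm(n, rr0, jitter), 0.3), 2)
    new("PeakSeries", peakTimes = c(start, start + cumsum(rr)),
        meanHr = 60 / mean(rr))
}

# small white-noise BOLD cube
makeNoiseBold <- function(shape = c(10, 10, 10), nt = 450, tr = 0.5,
                          sd = 1, seed = 11) {
    set.seed(seed)
    Bold4D(array(stats::rnorm(prod(shape) * nt, 0, sd), c(shape, nt)),
           voxelDims = c(2, 2, 2), tr = tr)
}

allOnesMask <- function(shape, label = "brain") {
    Mask3D(array(1, shape), label)
}

# correlation between a binned waveform and the generator waveform,
# maximized over a circular phase shift: peak detection places the phase
# origin at the band-passed pulse maximum, a constant ~0.03-cycle rotation
# of the generator's beat-onset convention
bestShiftCor <- function(wfMeans, nBins = length(wfMeans)) {
    centers <- (seq_len(nBins) - 0.5) / nBins
    max(vapply(seq(0, 1, by = 0.0025), function(s)
        stats::cor(wfMeans, generatorWaveform((centers - s) %% 1)),
        numeric(1)))
}

# compact phantom used by unit tests (the default config is reserved for
# the acceptance checks)
smallPhantomConfig <- function(...,
        arterySegments = list(
            list(from = c(4, 8, 5), to = c(12, 8, 5), radius = 0.8)),
        sssSegments = list(
            list(from = c(8, 4, 11), to = c(8, 12, 11), radius = 0.8))) {
    phantomConfig(
        shape = c(16, 16, 12), voxelDims = c(2.5, 2.5, 2.5),
        nVolumes = 350, roiDilation = 1,
        arterySegments = arterySegments, sssSegments = sssSegments,
        ...)
}

defaultPhantom <- function() {
    cached("defaultPhantom", generatePhantom(phantomConfig()))
}

# one full-pipeline run on the default phantom, shared across tests
defaultRun <- function() {
    cached("defaultRun", {
        ph <- defaultPhantom()
        segmentVessels(ph@bold, ph@physio, ph@brainMask,
                       ph@generalArteryRoi, ph@generalSssRoi,
                       seed = 11, physioStart = "scan")
    })
}

smallPhantom <- function() {
    cached("smallPhantom", generatePhantom(smallPhantomConfig()))
}

# phases + filtered bold for the small phantom, shared
smallPrepared <- function() {
    cached("smallPrepared", {
        ph <- smallPhantom()
        trimmed <- trimInitialVolumes(ph@bold, 10)
        physio <- PhysioTrace(physioSamples(ph@physio),
                              samplingRate(ph@physio),
                              traceStart(ph@physio) - 10 * repetitionTime(ph@bold))
        filt <- highpassFilter(trimmed)
        pk <- detectPeaks(physio)
        list(phantom = ph, bold = filt, peaks = pk,
             phases = boldPhases(filt, pk))
    })
}
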