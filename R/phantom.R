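# Synthetic pulsatile phantom: 4D BOLD with cardiac-locked vessel voxels,
# a matching PPG trace, ground-truth vessel masks and overly inclusive
# general ROIs — every stage of the pipeline is testable without real data.

# Pulsatile driving waveform: sharp systolic peak near phase 0.15 and a
# dicrotic bump near 0.5, wrapped circularly, standardized to mean 0 / sd 1
# over the cycle. Non-sinusoidal and phase-asymmetric on purpose, so phase
# binning and correlation are exercised by an asymmetric shape.
.generatorWaveformRaw <- function(phi) {
    out <- 0
    for (k in -1:1) {
        p <- phi + k
        out <- out + exp(-0.5 * ((p - 0.15) / 0.05)^2) +
            0.45 * exp(-0.5 * ((p - 0.50) / 0.12)^2)
    }
    out
}

.generatorWaveformConstants <- function() {
    g <- .generatorWaveformRaw((seq_len(4096) - 0.5) / 4096)
    c(mean = mean(g), sd = stats::sd(g))
}

#' Evaluate the phantom's driving waveform
#'
#' The standardized (mean 0, unit sd over the cycle) pulsatile waveform that
#' drives vessel voxels in \code{\link{generatePhantom}}: a sharp systolic
#' peak at phase ~0.15 with a dicrotic bump at ~0.5.
#'
#' @param phi cardiac phases in [0, 1).
#' @return waveform values.
#' @export
generatorWaveform <- function(phi) {
    k <- .generatorWaveformConstants()
    as.numeric((.generatorWaveformRaw(phi) - k[["mean"]]) / k[["sd"]])
}

#' Morphological dilation with a cubic structuring element
#'
#' Binary 3D dilation with a size x size x size cube (size odd, e.g. the
#' reference pipeline's kernel size 3), implemented as the union of all
#' integer shifts within the cube; the grid boundary clips the kernel. The
#' output always contains the input.
#'
#' @param mask a \linkS4class{Mask3D} (or 3D 0/1 array).
#' @param size odd kernel edge length >= 1, voxels.
#' @return A \linkS4class{Mask3D}.
#' @export
dilateMask <- function(mask, size = 3) {
    if (size < 1 || size %% 2 == 0)
        stop("kernel size must be an odd positive integer")
    a <- .maskArr(mask) != 0
    d <- dim(a)
    r <- (size - 1) / 2
    out <- a
    for (dx in -r:r) for (dy in -r:r) for (dz in -r:r) {
        if (dx == 0 && dy == 0 && dz == 0) next
        xs <- pmax(1, 1 - dx):pmin(d[1], d[1] - dx)
        ys <- pmax(1, 1 - dy):pmin(d[2], d[2] - dy)
        zs <- pmax(1, 1 - dz):pmin(d[3], d[3] - dz)
        out[xs + dx, ys + dy, zs + dz] <-
            out[xs + dx, ys + dy, zs + dz] | a[xs, ys, zs]
    }
    lb <- if (is(mask, "Mask3D")) mask@label else "segmentation"
    Mask3D(out * 1, label = lb)
}

#' Binarize a probability map
#'
#' Strictly-greater-than thresholding of a probability map (default 0.5\%,
#' the cutoff used to build overly inclusive vessel ROIs from atlas
#' probability maps).
#'
#' @param probMap 3D array with values in [0, 1].
#' @param threshold probability cutoff; voxels with values strictly greater
#'   are included.
#' @return A \linkS4class{Mask3D}.
#' @export
binarizeProbability <- function(probMap, threshold = 0.005) {
    if (any(probMap < 0 | probMap > 1))
        stop("probability map values must lie in [0, 1]")
    Mask3D((probMap > threshold) * 1, label = "segmentation")
}

# voxels within `radius` of the segment from a to b (voxel coordinates)
.tubeMask <- function(shape, a, b, radius) {
    idx <- arrayInd(seq_len(prod(shape)), shape)
    ab <- b - a
    len2 <- sum(ab^2)
    P <- sweep(idx, 2, a)
    tpar <- if (len2 == 0) rep(0, nrow(idx)) else
        pmin(pmax(as.numeric(P %*% ab) / len2, 0), 1)
    closest <- outer(tpar, ab) + rep(a, each = nrow(idx))
    d2 <- rowSums((idx - closest)^2)
    array(d2 <= radius^2, shape)
}

#' Phantom configuration
#'
#' Defaults describe the study conditions the package is validated under: a
#' 32^3 grid of 2.5 mm voxels, 450 volumes at TR 0.5 s, heart rate 66 bpm
#' with 2 bpm beat-to-beat jitter, pulsatility amplitude twice the noise
#' standard deviation, low-frequency background drift at half the noise sd,
#' and general ROIs built by dilating the truth tubes with a cubic kernel of
#' half-width \code{roiDilation}.
#'
#' @param shape spatial grid dimensions.
#' @param voxelDims voxel dimensions, mm.
#' @param tr repetition time, s.
#' @param nVolumes number of volumes.
#' @param meanHr mean heart rate, bpm.
#' @param hrJitterSd beat-to-beat heart-rate jitter sd, bpm.
#' @param pulsatilityAmplitude vessel waveform amplitude (signal units; the
#'   waveform has unit sd, so this is the pulsatile signal sd).
#' @param noiseSd white-noise sd (> 0).
#' @param lowfreqDriftAmplitude background drift amplitude.
#' @param roiDilation half-width (voxels) of the cubic dilation producing
#'   the overly inclusive general ROIs from the truth tubes (>= 1).
#' @param partialVolumeShell add a 1-voxel shell of half-amplitude voxels
#'   around each vessel tube (emulating partial-volume voxels); the shell is
#'   not part of the ground truth.
#' @param sssPhaseDelay phase lag of the SSS (venous) waveform relative to
#'   the arterial waveform, fraction of the cycle.
#' @param sliceTiming when TRUE, generate (and record) interleaved per-slice
#'   acquisition offsets; otherwise all slices share volume onset + tr/2.
#' @param ppgFs PPG sampling rate, Hz.
#' @param seed integer seed; the bundle is a deterministic function of the
#'   config.
#' @param arterySegments,sssSegments lists of tube segments
#'   (list(from =, to =, radius =) in voxel coordinates) overriding the
#'   built-in schematic geometry (an arterial ring near the grid centre and
#'   an SSS tube running anterior-posterior near the top of the brain).
#' @return config list (class "phantomConfig").
#' @export
phantomConfig <- function(shape = c(32, 32, 32),
                          voxelDims = c(2.5, 2.5, 2.5),
                          tr = 0.5,
                          nVolumes = 450,
                          meanHr = 66,
                          hrJitterSd = 2,
                          pulsatilityAmplitude = 2,
                          noiseSd = 1,
                          lowfreqDriftAmplitude = 0.5,
                          roiDilation = 2,
                          partialVolumeShell = FALSE,
                          sssPhaseDelay = 0.05,
                          sliceTiming = FALSE,
                          ppgFs = 100,
                          seed = 7,
                          arterySegments = NULL,
                          sssSegments = NULL) {
    if (is.null(arterySegments)) {
        c0 <- (shape + 1) / 2
        z0 <- round(shape[3] * 0.45)
        ring <- list(
            list(from = c(c0[1] - 5, c0[2] - 4, z0),
                 to = c(c0[1] + 5, c0[2] - 4, z0), radius = 1.3),
            list(from = c(c0[1] - 5, c0[2] + 4, z0),
                 to = c(c0[1] + 5, c0[2] + 4, z0), radius = 1.3),
            list(from = c(c0[1] - 5, c0[2] - 4, z0),
                 to = c(c0[1] - 5, c0[2] + 4, z0), radius = 1.3),
            list(from = c(c0[1] + 5, c0[2] - 4, z0),
                 to = c(c0[1] + 5, c0[2] + 4, z0), radius = 1.3),
            list(from = c(c0[1], c0[2], z0),
                 to = c(c0[1], c0[2], z0 + 4), radius = 1.3))
        arterySegments <- ring
    }
    if (is.null(sssSegments)) {
        c0 <- (shape + 1) / 2
        zt <- round(shape[3] * 0.84)
        sssSegments <- list(
            list(from = c(c0[1], round(shape[2] * 0.32), zt),
                 to = c(c0[1], round(shape[2] * 0.72), zt), radius = 1.5))
    }
    cfg <- list(shape = shape, voxelDims = voxelDims, tr = tr,
                nVolumes = nVolumes, meanHr = meanHr,
                hrJitterSd = hrJitterSd,
                pulsatilityAmplitude = pulsatilityAmplitude,
                noiseSd = noiseSd,
                lowfreqDriftAmplitude = lowfreqDriftAmplitude,
                roiDilation = roiDilation,
                partialVolumeShell = partialVolumeShell,
                sssPhaseDelay = sssPhaseDelay,
                sliceTiming = sliceTiming,
                ppgFs = ppgFs, seed = seed,
                arterySegments = arterySegments,
                sssSegments = sssSegments)
    class(cfg) <- c("phantomConfig", "list")
    cfg
}

.segmentsToMask <- function(shape, segments) {
    out <- array(FALSE, shape)
    for (s in segments)
        out <- out | .tubeMask(shape, s$from, s$to, s$radius)
    out
}

#' Generate a synthetic pulsatile phantom
#'
#' Builds a complete test dataset from a \code{\link{phantomConfig}}:
#' (i) beat times from jittered RR intervals 60 / (meanHr + jitter), jitter
#' ~ N(0, hrJitterSd) with RR clipped to [0.3, 2] s; (ii) a PPG trace as a
#' stereotyped fast-rise/slow-decay pulse placed at each beat; (iii) vessel
#' voxels carrying pulsatilityAmplitude x the driving waveform evaluated at
#' the voxel's slice-corrected acquisition phase, plus white noise; brain
#' background carrying noise plus a slow sinusoidal drift; (iv) general ROIs
#' as cubic dilations of the truth tubes. Deterministic given the seed.
#'
#' @param config a \code{\link{phantomConfig}} list.
#' @return A \linkS4class{PhantomBundle}. The physio trace starts at the
#'   scan start (use \code{physioStart = "scan"} in
#'   \code{\link{segmentVessels}}).
#' @export
generatePhantom <- function(config = phantomConfig()) {
    cfg <- config
    set.seed(cfg$seed)
    shape <- cfg$shape
    nt <- cfg$nVolumes
    scanDur <- nt * cfg$tr

    truthA <- .segmentsToMask(shape, cfg$arterySegments)
    truthS <- .segmentsToMask(shape, cfg$sssSegments)
    if (any(truthA & truthS))
        stop("artery and SSS tubes overlap")
    dil <- 2 * cfg$roiDilation + 1
    roiA <- dilateMask(Mask3D(truthA * 1, "general_artery"), dil)@data != 0
    roiS <- dilateMask(Mask3D(truthS * 1, "general_sss"), dil)@data != 0
    if (any(roiA & roiS))
        stop("general artery and SSS ROIs overlap; increase tube separation")

    # ellipsoidal brain covering both vessel systems
    c0 <- (shape + 1) / 2
    idx <- arrayInd(seq_len(prod(shape)), shape)
    zc <- c0[3] + shape[3] * 0.06
    rad <- c(shape[1] * 0.44, shape[2] * 0.44, shape[3] * 0.42)
    brain <- array(((idx[, 1] - c0[1]) / rad[1])^2 +
                   ((idx[, 2] - c0[2]) / rad[2])^2 +
                   ((idx[, 3] - zc) / rad[3])^2 <= 1, shape)
    brain <- brain | truthA | truthS

    # ---- beats and PPG -----------------------------------------------------
    beats <- -2
    tcur <- -2
    while (tcur < scanDur + 2) {
        rr <- 60 / (cfg$meanHr + stats::rnorm(1, 0, cfg$hrJitterSd))
        rr <- min(max(rr, 0.3), 2)
        tcur <- tcur + rr
        beats <- c(beats, tcur)
    }
    fs <- cfg$ppgFs
    tt <- seq(0, scanDur, by = 1 / fs)
    ppg <- numeric(length(tt))
    # gamma-shaped pulse (fast rise, slow decay) whose maximum falls exactly
    # on the beat time, so detected systolic peaks coincide with the beats
    # that drive the vessel phases
    for (b in beats) {
        rel <- tt - b + 0.16
        w <- rel >= 0 & rel < 1.2
        if (any(w))
            ppg[w] <- ppg[w] + (rel[w] / 0.08)^2 * exp(-rel[w] / 0.08)
    }
    ppg <- ppg + stats::rnorm(length(ppg), 0, 0.02 * max(ppg))
    physio <- PhysioTrace(ppg, fs = fs, t0 = 0)

    # ---- acquisition phases -------------------------------------------------
    nz <- shape[3]
    sliceOff <- NULL
    if (cfg$sliceTiming) {
        ord <- order(c(seq(1, nz, by = 2), seq(2, nz, by = 2)))
        sliceOff <- ((ord - 1) / nz) * cfg$tr
    }
    off <- if (is.null(sliceOff)) rep(cfg$tr / 2, nz) else sliceOff
    acq <- outer((seq_len(nt) - 1) * cfg$tr, off, `+`)   # t x nz
    k <- findInterval(acq, beats)
    phase <- (acq - beats[k]) / (beats[k + 1] - beats[k])
    dim(phase) <- dim(acq)

    # ---- voxel time series --------------------------------------------------
    nvox <- prod(shape)
    X <- matrix(stats::rnorm(nvox * nt, 0, cfg$noiseSd), nvox, nt)
    outside <- which(!brain)
    X[outside, ] <- X[outside, ] * 0.2

    inBrainBg <- which(brain & !truthA & !truthS)
    if (cfg$lowfreqDriftAmplitude > 0 && length(inBrainBg)) {
        fD <- stats::runif(length(inBrainBg), 0.01, 0.05)
        th <- stats::runif(length(inBrainBg), 0, 2 * pi)
        tcenters <- (seq_len(nt) - 0.5) * cfg$tr
        X[inBrainBg, ] <- X[inBrainBg, ] + cfg$lowfreqDriftAmplitude *
            sin(outer(2 * pi * fD, tcenters) + th)
    }

    zOf <- ((seq_len(nvox) - 1L) %/% (shape[1] * shape[2])) + 1L
    addPulse <- function(lin, amp, delay) {
        for (zz in unique(zOf[lin])) {
            v <- lin[zOf[lin] == zz]
            w <- generatorWaveform((phase[, zz] - delay) %% 1)
            X[v, ] <<- X[v, ] + rep(amp * w, each = length(v))
        }
    }
    addPulse(which(truthA), cfg$pulsatilityAmplitude, 0)
    addPulse(which(truthS), cfg$pulsatilityAmplitude, cfg$sssPhaseDelay)
    if (cfg$partialVolumeShell) {
        shellA <- dilateMask(Mask3D(truthA * 1), 3)@data != 0 & !truthA
        shellS <- dilateMask(Mask3D(truthS * 1), 3)@data != 0 & !truthS
        addPulse(which(shellA & !truthS), cfg$pulsatilityAmplitude / 2, 0)
        addPulse(which(shellS & !truthA & !shellA),
                 cfg$pulsatilityAmplitude / 2, cfg$sssPhaseDelay)
    }
    X <- X + 100   # scanner-like DC offset, removed by the high-pass

    bold <- Bold4D(array(X, c(shape, nt)), cfg$voxelDims, cfg$tr,
                   sliceOffsets = sliceOff)

    gw <- binWaveform(generatorWaveform((seq_len(2000) - 0.5) / 2000),
                      (seq_len(2000) - 0.5) / 2000, nBins = 20)

    new("PhantomBundle", bold = bold, physio = physio,
        brainMask = Mask3D(brain * 1, "brain"),
        truthArtery = Mask3D(truthA * 1, "ground_truth"),
        truthSss = Mask3D(truthS * 1, "ground_truth"),
        generalArteryRoi = Mask3D(roiA * 1, "general_artery"),
        generalSssRoi = Mask3D(roiS * 1, "general_sss"),
        generatorWaveform = gw,
        config = unclass(cfg), beatTimes = beats)
}
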