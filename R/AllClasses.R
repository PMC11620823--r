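#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Bold4D: a 4D BOLD fMRI series
#'
#' Container for a 4D voxel array (x, y, z, t) together with the acquisition
#' geometry needed by the segmentation pipeline: voxel dimensions in mm, the
#' repetition time (TR) in seconds, optional per-slice acquisition offsets
#' within a volume, and the voxel-to-world affine (carried through unchanged,
#' never interpreted).
#'
#' @slot data 4D numeric array, scanner units.
#' @slot voxelDims numeric(3), voxel edge lengths in mm, all > 0.
#' @slot tr numeric(1), repetition time in seconds, > 0.
#' @slot sliceOffsets numeric of length \code{dim(data)[3]} with per-slice
#'   acquisition times within a volume (seconds, in [0, tr)), or NULL when
#'   unknown; in that case every slice is taken to be acquired at volume
#'   onset + tr/2.
#' @slot affine 4x4 voxel-to-world matrix.
#' @exportClass Bold4D
setClass("Bold4D",
    representation(
        data = "array",
        voxelDims = "numeric",
        tr = "numeric",
        sliceOffsets = "numericOrNULL",
        affine = "matrix"
    )
)

setValidity("Bold4D", function(object) {
    msg <- character()
    if (length(dim(object@data)) != 4L)
        msg <- c(msg, "data must be a 4D array (x, y, z, t)")
    if (length(object@tr) != 1L || !is.finite(object@tr) || object@tr <= 0)
        msg <- c(msg, "tr must be a single positive number (seconds)")
    if (length(object@voxelDims) != 3L || any(object@voxelDims <= 0))
        msg <- c(msg, "voxelDims must be 3 positive numbers (mm)")
    if (length(dim(object@data)) == 4L && dim(object@data)[4] < 2L)
        msg <- c(msg, "series must have at least 2 timepoints")
    if (!is.null(object@sliceOffsets)) {
        nz <- dim(object@data)[3]
        if (length(object@sliceOffsets) != nz)
            msg <- c(msg, "sliceOffsets must have one entry per slice")
        else if (any(object@sliceOffsets < 0 | object@sliceOffsets >= object@tr))
            msg <- c(msg, "sliceOffsets must lie in [0, tr)")
    }
    if (!all(dim(object@affine) == c(4L, 4L)))
        msg <- c(msg, "affine must be a 4x4 matrix")
    if (length(msg)) msg else TRUE
})

#' Construct a Bold4D object
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param voxelDims voxel dimensions in mm (length 3).
#' @param tr repetition time in seconds.
#' @param sliceOffsets optional per-slice acquisition offsets (s) in [0, tr).
#' @param affine optional 4x4 voxel-to-world matrix; defaults to a diagonal
#'   scaling by \code{voxelDims}.
#' @return A \linkS4class{Bold4D} object.
#' @export
#' @examples
#' b <- Bold4D(array(rnorm(4 * 4 * 2 * 10), c(4, 4, 2, 10)),
#'             voxelDims = c(2.5, 2.5, 2.5), tr = 0.5)
#' dim(boldData(b))
Bold4D <- function(data, voxelDims, tr, sliceOffsets = NULL, affine = NULL) {
    if (is.null(affine))
        affine <- diag(c(voxelDims, 1))
    new("Bold4D", data = data, voxelDims = as.numeric(voxelDims),
        tr = as.numeric(tr), sliceOffsets = sliceOffsets, affine = affine)
}

#' Mask3D: a binary mask on an fMRI grid
#'
#' @slot data 3D array with values in {0, 1} (stored as integer-ish numeric).
#' @slot label role tag: one of "brain", "general_artery", "general_sss",
#'   "segmentation", "ground_truth".
#' @exportClass Mask3D
setClass("Mask3D",
    representation(data = "array", label = "character")
)

.maskLabels <- c("brain", "general_artery", "general_sss",
                 "segmentation", "ground_truth")

setValidity("Mask3D", function(object) {
    msg <- character()
    if (length(dim(object@data)) != 3L)
        msg <- c(msg, "mask data must be a 3D array")
    if (!all(object@data %in% c(0, 1)))
        msg <- c(msg, "mask values must be 0 or 1")
    if (length(object@label) != 1L || !(object@label %in% .maskLabels))
        msg <- c(msg, sprintf("label must be one of: %s",
                              paste(.maskLabels, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Construct a Mask3D object
#'
#' @param data 3D logical or 0/1 numeric array.
#' @param label role tag (see \linkS4class{Mask3D}).
#' @return A \linkS4class{Mask3D}.
#' @export
Mask3D <- function(data, label = "segmentation") {
    storage.mode(data) <- "double"
    new("Mask3D", data = (data != 0) * 1, label = label)
}

#' PhysioTrace: a finger-plethysmography recording
#'
#' @slot samples numeric vector of PPG samples.
#' @slot fs sampling rate, Hz.
#' @slot t0 time of the first sample relative to the first retained fMRI
#'   volume, seconds (0 = trace starts with the retained series).
#' @exportClass PhysioTrace
setClass("PhysioTrace",
    representation(samples = "numeric", fs = "numeric", t0 = "numeric")
)

setValidity("PhysioTrace", function(object) {
    msg <- character()
    if (length(object@fs) != 1L || object@fs <= 0)
        msg <- c(msg, "fs must be a single positive sampling rate (Hz)")
    else if (length(object@samples) < 2 * object@fs)
        msg <- c(msg, "trace too short: need at least 2 s of samples")
    if (length(object@t0) != 1L || !is.finite(object@t0))
        msg <- c(msg, "t0 must be a single finite number (s)")
    if (length(msg)) msg else TRUE
})

#' Construct a PhysioTrace
#'
#' @param samples numeric PPG samples.
#' @param fs sampling rate in Hz.
#' @param t0 offset of the first sample relative to the first retained fMRI
#'   volume (s). Default 0.
#' @return A \linkS4class{PhysioTrace}.
#' @export
PhysioTrace <- function(samples, fs, t0 = 0) {
    new("PhysioTrace", samples = as.numeric(samples), fs = as.numeric(fs),
        t0 = as.numeric(t0))
}

#' MotionTable: rigid-motion parameters per volume
#'
#' Six columns in FSL MCFLIRT order: three rotations (radians) then three
#' translations (mm), one row per volume.
#'
#' @slot params numeric matrix, n x 6.
#' @slot frames which series the rows refer to: "retained" or "original".
#' @exportClass MotionTable
setClass("MotionTable",
    representation(params = "matrix", frames = "character")
)

setValidity("MotionTable", function(object) {
    msg <- character()
    if (ncol(object@params) != 6L)
        msg <- c(msg, "motion table must have 6 columns (3 rotations rad, 3 translations mm)")
    if (nrow(object@params) < 1L)
        msg <- c(msg, "motion table must have at least one row")
    if (!(object@frames %in% c("retained", "original")))
        msg <- c(msg, "frames must be 'retained' or 'original'")
    if (length(msg)) msg else TRUE
})

#' Construct a MotionTable
#'
#' @param params n x 6 matrix (3 rotations rad, then 3 translations mm).
#' @param frames "retained" (rows match the trimmed series) or "original".
#' @return A \linkS4class{MotionTable}.
#' @export
MotionTable <- function(params, frames = "original") {
    params <- as.matrix(params)
    colnames(params) <- c("rx", "ry", "rz", "tx", "ty", "tz")
    new("MotionTable", params = params, frames = frames)
}

#' PeakSeries: detected systolic peak times
#'
#' @slot peakTimes strictly increasing peak times in seconds.
#' @slot meanHr mean heart rate, beats per minute (60 / mean RR interval).
#' @exportClass PeakSeries
setClass("PeakSeries",
    representation(peakTimes = "numeric", meanHr = "numeric")
)

setValidity("PeakSeries", function(object) {
    msg <- character()
    if (length(object@peakTimes) < 3L)
        msg <- c(msg, "need at least 3 peaks")
    else {
        rr <- diff(object@peakTimes)
        if (any(rr <= 0))
            msg <- c(msg, "peak times must be strictly increasing")
        else if (any(rr < 0.3 - 1e-9 | rr > 2.0 + 1e-9))
            msg <- c(msg, "inter-peak intervals must lie in [0.3, 2.0] s after cleaning")
    }
    if (length(msg)) msg else TRUE
})

#' PhaseAssignment: cardiac phase of every fMRI timepoint
#'
#' Phases are the linear fraction of the beat-to-beat (RR) interval in
#' [0, 1). When per-slice acquisition offsets are present each slice has its
#' own column; otherwise a single column applies to all slices.
#'
#' @slot phases t x nSlices matrix of phases in [0, 1) (NA where invalid).
#' @slot valid t x nSlices logical matrix; FALSE before the first or after
#'   the last detected peak. Invalid timepoints are excluded from all
#'   downstream statistics.
#' @exportClass PhaseAssignment
setClass("PhaseAssignment",
    representation(phases = "matrix", valid = "matrix")
)

setValidity("PhaseAssignment", function(object) {
    msg <- character()
    if (!all(dim(object@phases) == dim(object@valid)))
        msg <- c(msg, "phases and valid must have identical dimensions")
    ph <- object@phases[object@valid]
    if (length(ph) && (any(!is.finite(ph)) || any(ph < 0 | ph >= 1)))
        msg <- c(msg, "valid phases must lie in [0, 1)")
    if (length(msg)) msg else TRUE
})

#' CardiacWaveform: a phase-binned mean signal over one cardiac cycle
#'
#' The unit interval of cardiac phase is partitioned into \code{nBins} equal
#' half-open bins; \code{binMeans[j]} is the mean signal over valid samples
#' with phase in [(j-1)/n, j/n). Empty bins are filled by circular linear
#' interpolation from the nearest non-empty bins and flagged.
#'
#' @slot nBins number of phase bins.
#' @slot binMeans numeric(nBins), mean signal per bin (signal units).
#' @slot binCounts integer(nBins), samples per bin (0 for interpolated bins).
#' @slot interpolated logical(nBins), TRUE where the value was interpolated.
#' @exportClass CardiacWaveform
setClass("CardiacWaveform",
    representation(nBins = "integer", binMeans = "numeric",
                   binCounts = "integer", interpolated = "logical")
)

setValidity("CardiacWaveform", function(object) {
    msg <- character()
    n <- object@nBins
    if (length(n) != 1L || n < 2L)
        msg <- c(msg, "nBins must be a single integer >= 2")
    if (length(object@binMeans) != n || length(object@binCounts) != n ||
        length(object@interpolated) != n)
        msg <- c(msg, "binMeans, binCounts and interpolated must all have length nBins")
    if (any(object@binCounts < 0))
        msg <- c(msg, "binCounts must be non-negative")
    if (length(msg)) msg else TRUE
})

#' CorrelationMap: voxel-wise correlation coefficients
#'
#' @slot values 3D array of correlation coefficients in [-1, 1]; NaN/NA where
#'   undefined (zero-variance waveforms or rejected bin coverage).
#' @slot kind provenance: "split_half_mean" or "template".
#' @slot nRepeats number of random splits averaged (split-half maps only).
#' @exportClass CorrelationMap
setClass("CorrelationMap",
    representation(values = "array", kind = "character", nRepeats = "integer")
)

setValidity("CorrelationMap", function(object) {
    msg <- character()
    if (length(dim(object@values)) != 3L)
        msg <- c(msg, "values must be a 3D array")
    v <- object@values[is.finite(object@values)]
    if (length(v) && any(v < -1 - 1e-9 | v > 1 + 1e-9))
        msg <- c(msg, "defined correlations must lie in [-1, 1]")
    if (!(object@kind %in% c("split_half_mean", "template")))
        msg <- c(msg, "kind must be 'split_half_mean' or 'template'")
    if (length(msg)) msg else TRUE
})

#' SegmentationResult: a final vessel mask and its refinement trace
#'
#' @slot mask final binary \linkS4class{Mask3D}.
#' @slot target "artery" or "sss".
#' @slot iterations data.frame with one row per refinement iteration:
#'   \code{volume_cm3}, \code{threshold}, \code{n_voxels}.
#' @slot converged TRUE when the segmentation volume stabilized to within 1\%
#'   of the previous iteration's volume.
#' @slot templateWaveform the \linkS4class{CardiacWaveform} used for the final
#'   correlation map.
#' @slot seed integer seed that governed the randomized split step.
#' @exportClass SegmentationResult
setClass("SegmentationResult",
    representation(mask = "Mask3D", target = "character",
                   iterations = "data.frame", converged = "logical",
                   templateWaveform = "CardiacWaveform", seed = "integer")
)

setValidity("SegmentationResult", function(object) {
    msg <- character()
    if (!(object@target %in% c("artery", "sss")))
        msg <- c(msg, "target must be 'artery' or 'sss'")
    need <- c("volume_cm3", "threshold", "n_voxels")
    if (!all(need %in% names(object@iterations)))
        msg <- c(msg, "iterations must have columns volume_cm3, threshold, n_voxels")
    if (length(msg)) msg else TRUE
})

#' QcReport: photoplethysmography and motion quality gates
#'
#' @slot ppgQuality fraction of PPG power in the cardiac band, in [0, 1].
#' @slot ppgPass TRUE when ppgQuality meets the configured threshold.
#' @slot maxTranslationMm maximum absolute translation over volumes (mm);
#'   NA when no motion table was supplied.
#' @slot motionPass TRUE iff maxTranslationMm <= min(voxelDims); NA without
#'   a motion table.
#' @slot nVolumesRetained number of volumes after trimming.
#' @exportClass QcReport
setClass("QcReport",
    representation(ppgQuality = "numeric", ppgPass = "logical",
                   maxTranslationMm = "numeric", motionPass = "logical",
                   nVolumesRetained = "integer")
)

setValidity("QcReport", function(object) {
    msg <- character()
    q <- object@ppgQuality
    if (length(q) != 1L || (is.finite(q) && (q < 0 || q > 1)))
        msg <- c(msg, "ppgQuality must be a single value in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' SpectrumReport: amplitude spectrum of an ROI-mean signal
#'
#' @slot freqs frequency grid in Hz, from 0 up to the Nyquist frequency.
#' @slot amplitude one-sided amplitude spectrum (signal units).
#' @slot cardiacFreq cardiac frequency in Hz (mean heart rate / 60), folded
#'   to below Nyquist when it aliases.
#' @slot cardiacAmplitude maximum amplitude within 0.1 Hz of cardiacFreq.
#' @slot nyquist Nyquist frequency 1/(2 tr), Hz.
#' @slot aliased TRUE when the cardiac frequency exceeded Nyquist and the
#'   folded alias frequency was used.
#' @exportClass SpectrumReport
setClass("SpectrumReport",
    representation(freqs = "numeric", amplitude = "numeric",
                   cardiacFreq = "numeric", cardiacAmplitude = "numeric",
                   nyquist = "numeric", aliased = "logical")
)

setValidity("SpectrumReport", function(object) {
    msg <- character()
    if (length(object@freqs) != length(object@amplitude))
        msg <- c(msg, "freqs and amplitude must have equal length")
    if (length(object@freqs) &&
        (min(object@freqs) < 0 || max(object@freqs) > object@nyquist + 1e-9))
        msg <- c(msg, "freqs must lie in [0, nyquist]")
    if (length(msg)) msg else TRUE
})

#' PhantomBundle: a complete synthetic test dataset
#'
#' @slot bold pulsatile \linkS4class{Bold4D} phantom.
#' @slot physio synthetic \linkS4class{PhysioTrace} (t0 relative to the scan
#'   start; see \code{\link{segmentVessels}} argument \code{physioStart}).
#' @slot brainMask,truthArtery,truthSss,generalArteryRoi,generalSssRoi
#'   \linkS4class{Mask3D} objects on the bold grid.
#' @slot generatorWaveform the pulsatile waveform used to drive vessel
#'   voxels, sampled at phase-bin centers (\linkS4class{CardiacWaveform}).
#' @slot config the \code{\link{phantomConfig}} list used.
#' @slot beatTimes true beat onset times (s, scan clock) — ground truth for
#'   peak-detection checks.
#' @exportClass PhantomBundle
setClass("PhantomBundle",
    representation(bold = "Bold4D", physio = "PhysioTrace",
                   brainMask = "Mask3D", truthArtery = "Mask3D",
                   truthSss = "Mask3D", generalArteryRoi = "Mask3D",
                   generalSssRoi = "Mask3D",
                   generatorWaveform = "CardiacWaveform",
                   config = "list", beatTimes = "numeric")
)

setValidity("PhantomBundle", function(object) {
    msg <- character()
    sp <- dim(object@bold@data)[1:3]
    for (nm in c("brainMask", "truthArtery", "truthSss",
                 "generalArteryRoi", "generalSssRoi")) {
        if (!all(dim(slot(object, nm)@data) == sp))
            msg <- c(msg, sprintf("%s is not on the bold grid", nm))
    }
    if (any(object@truthArtery@data > object@generalArteryRoi@data))
        msg <- c(msg, "truthArtery must be a subset of generalArteryRoi")
    if (any(object@truthSss@data > object@generalSssRoi@data))
        msg <- c(msg, "truthSss must be a subset of generalSssRoi")
    if (any(object@generalArteryRoi@data * object@generalSssRoi@data > 0))
        msg <- c(msg, "general artery and SSS ROIs must be disjoint")
    if (length(msg)) msg else TRUE
})
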