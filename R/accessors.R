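#' Accessors for pulsevessel classes
#'
#' Slot access for the package's S4 containers. \code{boldData} returns the
#' 4D array, \code{maskData} the 3D 0/1 array, \code{mapValues} the 3D
#' correlation array, \code{binMeans}/\code{binCounts} the waveform vectors,
#' and so on.
#'
#' @param object a pulsevessel S4 object.
#' @return The slot value (see the class documentation for types).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("boldData", function(object) standardGeneric("boldData"))
#' @rdname accessors
#' @export
setMethod("boldData", "Bold4D", function(object) object@data)

#' @rdname accessors
#' @export
setGeneric("voxelDims", function(object) standardGeneric("voxelDims"))
#' @rdname accessors
#' @export
setMethod("voxelDims", "Bold4D", function(object) object@voxelDims)

#' @rdname accessors
#' @export
setGeneric("repetitionTime", function(object) standardGeneric("repetitionTime"))
#' @rdname accessors
#' @export
setMethod("repetitionTime", "Bold4D", function(object) object@tr)

#' @rdname accessors
#' @export
setGeneric("sliceOffsets", function(object) standardGeneric("sliceOffsets"))
#' @rdname accessors
#' @export
setMethod("sliceOffsets", "Bold4D", function(object) object@sliceOffsets)

#' @rdname accessors
#' @export
setGeneric("nTimepoints", function(object) standardGeneric("nTimepoints"))
#' @rdname accessors
#' @export
setMethod("nTimepoints", "Bold4D", function(object) dim(object@data)[4])

#' @rdname accessors
#' @export
setGeneric("maskData", function(object) standardGeneric("maskData"))
#' @rdname accessors
#' @export
setMethod("maskData", "Mask3D", function(object) object@data)

#' @rdname accessors
#' @export
setGeneric("maskLabel", function(object) standardGeneric("maskLabel"))
#' @rdname accessors
#' @export
setMethod("maskLabel", "Mask3D", function(object) object@label)

#' @rdname accessors
#' @export
setGeneric("nVoxels", function(object) standardGeneric("nVoxels"))
#' @rdname accessors
#' @export
setMethod("nVoxels", "Mask3D", function(object) sum(object@data))

#' @rdname accessors
#' @export
setGeneric("physioSamples", function(object) standardGeneric("physioSamples"))
#' @rdname accessors
#' @export
setMethod("physioSamples", "PhysioTrace", function(object) object@samples)

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setMethod("samplingRate", "PhysioTrace", function(object) object@fs)

#' @rdname accessors
#' @export
setGeneric("traceStart", function(object) standardGeneric("traceStart"))
#' @rdname accessors
#' @export
setMethod("traceStart", "PhysioTrace", function(object) object@t0)

#' @rdname accessors
#' @export
setGeneric("peakTimes", function(object) standardGeneric("peakTimes"))
#' @rdname accessors
#' @export
setMethod("peakTimes", "PeakSeries", function(object) object@peakTimes)

#' @rdname accessors
#' @export
setGeneric("meanHeartRate", function(object) standardGeneric("meanHeartRate"))
#' @rdname accessors
#' @export
setMethod("meanHeartRate", "PeakSeries", function(object) object@meanHr)

#' @rdname accessors
#' @export
setGeneric("phaseMatrix", function(object) standardGeneric("phaseMatrix"))
#' @rdname accessors
#' @export
setMethod("phaseMatrix", "PhaseAssignment", function(object) object@phases)

#' @rdname accessors
#' @export
setGeneric("validTimepoints", function(object) standardGeneric("validTimepoints"))
#' @rdname accessors
#' @export
setMethod("validTimepoints", "PhaseAssignment", function(object) object@valid)

#' @rdname accessors
#' @export
setGeneric("nBins", function(object) standardGeneric("nBins"))
#' @rdname accessors
#' @export
setMethod("nBins", "CardiacWaveform", function(object) object@nBins)

#' @rdname accessors
#' @export
setGeneric("binMeans", function(object) standardGeneric("binMeans"))
#' @rdname accessors
#' @export
setMethod("binMeans", "CardiacWaveform", function(object) object@binMeans)

#' @rdname accessors
#' @export
setGeneric("binCounts", function(object) standardGeneric("binCounts"))
#' @rdname accessors
#' @export
setMethod("binCounts", "CardiacWaveform", function(object) object@binCounts)

#' @rdname accessors
#' @export
setGeneric("interpolatedBins", function(object) standardGeneric("interpolatedBins"))
#' @rdname accessors
#' @export
setMethod("interpolatedBins", "CardiacWaveform", function(object) object@interpolated)

#' @rdname accessors
#' @export
setGeneric("mapValues", function(object) standardGeneric("mapValues"))
#' @rdname accessors
#' @export
setMethod("mapValues", "CorrelationMap", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("mapKind", function(object) standardGeneric("mapKind"))
#' @rdname accessors
#' @export
setMethod("mapKind", "CorrelationMap", function(object) object@kind)

#' @rdname accessors
#' @export
setGeneric("segmentationMask", function(object) standardGeneric("segmentationMask"))
#' @rdname accessors
#' @export
setMethod("segmentationMask", "SegmentationResult", function(object) object@mask)

#' @rdname accessors
#' @export
setGeneric("iterationTrace", function(object) standardGeneric("iterationTrace"))
#' @rdname accessors
#' @export
setMethod("iterationTrace", "SegmentationResult", function(object) object@iterations)

#' @rdname accessors
#' @export
setGeneric("converged", function(object) standardGeneric("converged"))
#' @rdname accessors
#' @export
setMethod("converged", "SegmentationResult", function(object) object@converged)

#' @rdname accessors
#' @export
setGeneric("templateWaveform", function(object) standardGeneric("templateWaveform"))
#' @rdname accessors
#' @export
setMethod("templateWaveform", "SegmentationResult",
          function(object) object@templateWaveform)

setMethod("show", "Bold4D", function(object) {
    d <- dim(object@data)
    cat("Bold4D:", paste(d[1:3], collapse = " x "), "voxels,",
        d[4], "volumes\n")
    cat("  voxel size:", paste(format(object@voxelDims), collapse = " x "),
        "mm; TR:", object@tr, "s\n")
    cat("  slice timing:",
        if (is.null(object@sliceOffsets)) "unknown (volume onset + TR/2)"
        else "per-slice offsets present", "\n")
})

setMethod("show", "Mask3D", function(object) {
    cat("Mask3D [", object@label, "]: ",
        paste(dim(object@data), collapse = " x "), " grid, ",
        sum(object@data), " voxels set\n", sep = "")
})

setMethod("show", "PhysioTrace", function(object) {
    cat("PhysioTrace:", length(object@samples), "samples at",
        object@fs, "Hz (", round(length(object@samples) / object@fs, 2),
        "s ), t0 =", object@t0, "s\n")
})

setMethod("show", "PeakSeries", function(object) {
    cat("PeakSeries:", length(object@peakTimes), "peaks, mean HR",
        round(object@meanHr, 1), "bpm\n")
})

setMethod("show", "CardiacWaveform", function(object) {
    cat("CardiacWaveform:", object@nBins, "phase bins,",
        sum(object@binCounts), "samples,",
        sum(object@interpolated), "interpolated bin(s)\n")
})

setMethod("show", "CorrelationMap", function(object) {
    v <- object@values[is.finite(object@values)]
    cat("CorrelationMap [", object@kind, "]: ",
        paste(dim(object@values), collapse = " x "), " grid, ",
        length(v), " defined voxels", sep = "")
    if (length(v))
        cat(", range ", sprintf("%.3f .. %.3f", min(v), max(v)), sep = "")
    cat("\n")
})

setMethod("show", "SegmentationResult", function(object) {
    it <- object@iterations
    cat("SegmentationResult [", object@target, "]: ",
        sum(object@mask@data), " voxels (",
        sprintf("%.2f", it$volume_cm3[nrow(it)]), " cm^3), ",
        nrow(it), " iteration(s), ",
        if (object@converged) "converged" else "NOT converged", "\n", sep = "")
})

setMethod("show", "QcReport", function(object) {
    cat("QcReport:\n")
    cat(sprintf("  PPG quality: %.3f (%s)\n", object@ppgQuality,
                if (isTRUE(object@ppgPass)) "pass" else "FAIL"))
    if (is.na(object@maxTranslationMm)) {
        cat("  motion: no table supplied\n")
    } else {
        cat(sprintf("  max translation: %.2f mm (%s)\n", object@maxTranslationMm,
                    if (isTRUE(object@motionPass)) "pass" else "FAIL"))
    }
    cat("  volumes retained:", object@nVolumesRetained, "\n")
})

setMethod("show", "SpectrumReport", function(object) {
    cat("SpectrumReport:", length(object@freqs), "frequencies up to",
        round(object@nyquist, 3), "Hz (Nyquist)\n")
    cat(sprintf("  cardiac frequency: %.3f Hz%s, amplitude %.4g\n",
                object@cardiacFreq,
                if (object@aliased) " (aliased)" else "",
                object@cardiacAmplitude))
})

setMethod("show", "PhantomBundle", function(object) {
    cat("PhantomBundle:\n  ")
    show(object@bold)
    cat("  truth artery:", sum(object@truthArtery@data), "voxels; truth SSS:",
        sum(object@truthSss@data), "voxels\n")
    cat("  general ROIs:", sum(object@generalArteryRoi@data), "(artery) /",
        sum(object@generalSssRoi@data), "(SSS) voxels\n")
})
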