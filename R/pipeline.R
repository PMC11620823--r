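#' End-to-end data-driven vessel segmentation
#'
#' Orchestrates the full pipeline: trim the initial volumes, high-pass
#' filter, quality control, PPG peak detection and cardiac phase assignment,
#' randomized split-half correlation mapping (Step 1), preliminary artery
#' region and waveform (Step 2), and iterative template-correlation
#' refinement of the artery and (optionally) SSS segmentations (Step 3).
#' Identical inputs and seed produce bit-identical results.
#'
#' @param bold a \linkS4class{Bold4D} (untrimmed).
#' @param physio a \linkS4class{PhysioTrace}.
#' @param brainMask brain \linkS4class{Mask3D}.
#' @param generalArteryRoi general artery \linkS4class{Mask3D}.
#' @param generalSssRoi general SSS \linkS4class{Mask3D}, or NULL for an
#'   artery-only run (a warning is emitted).
#' @param motion optional \linkS4class{MotionTable} for the motion gate.
#' @param nTrim leading volumes to discard.
#' @param cutoff high-pass cutoff, Hz.
#' @param filterOrder Butterworth order.
#' @param nBins phase bins per cardiac waveform.
#' @param nRepeats random splits in Step 1.
#' @param seed integer seed for the randomized split step.
#' @param maxIter refinement iteration cap.
#' @param ppgThreshold minimum PPG quality score.
#' @param strict when TRUE, a failing QC gate aborts the run; otherwise it
#'   warns and continues.
#' @param physioStart clock of \code{physio@t0}: "retained" (default; trace
#'   offset is relative to the first retained volume) or "scan" (relative to
#'   the first acquired volume; the trim shift \code{nTrim * tr} is applied
#'   internally).
#' @return list with elements \code{artery} and \code{sss}
#'   (\linkS4class{SegmentationResult}; \code{sss} is NULL when no SSS ROI
#'   was supplied), \code{splitHalfMap} (\linkS4class{CorrelationMap}),
#'   \code{qc} (\linkS4class{QcReport}), \code{peaks}
#'   (\linkS4class{PeakSeries}), \code{preliminaryMask},
#'   \code{preliminaryWaveform} and \code{preliminaryThreshold}.
#' @export
segmentVessels <- function(bold, physio, brainMask, generalArteryRoi,
                           generalSssRoi = NULL, motion = NULL,
                           nTrim = 10, cutoff = 0.005, filterOrder = 2,
                           nBins = 20, nRepeats = 100, seed = 1L,
                           maxIter = 20, ppgThreshold = 0.30,
                           strict = FALSE,
                           physioStart = c("retained", "scan")) {
    physioStart <- match.arg(physioStart)
    .stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("[", name, "] ", conditionMessage(e), call. = FALSE))
    }
    sp <- dim(bold@data)[1:3]
    for (nm in c("brainMask", "generalArteryRoi", "generalSssRoi")) {
        m <- get(nm)
        if (!is.null(m) && !all(dim(m@data) == sp))
            stop("geometric inconsistency: ", nm, " grid ",
                 paste(dim(m@data), collapse = "x"),
                 " does not match BOLD grid ", paste(sp, collapse = "x"))
    }
    if (is.null(generalSssRoi))
        warning("no SSS ROI supplied: running artery-only segmentation")

    trimmed <- .stage("trim", trimInitialVolumes(bold, nTrim))
    if (physioStart == "scan")
        physio <- PhysioTrace(physio@samples, physio@fs,
                              physio@t0 - nTrim * bold@tr)

    qc <- .stage("qc", qcReport(physio, motion, bold@voxelDims,
                                nVolumesRetained = dim(trimmed@data)[4],
                                ppgThreshold = ppgThreshold))
    if (!isTRUE(qc@ppgPass) || isFALSE(qc@motionPass)) {
        msg <- sprintf("QC gate failed (PPG quality %.3f, max translation %s mm)",
                       qc@ppgQuality,
                       if (is.na(qc@maxTranslationMm)) "NA"
                       else sprintf("%.2f", qc@maxTranslationMm))
        if (strict) stop("[qc] ", msg, call. = FALSE) else warning(msg)
    }

    unionArr <- brainMask@data != 0 | generalArteryRoi@data != 0
    if (!is.null(generalSssRoi))
        unionArr <- unionArr | generalSssRoi@data != 0
    unionMask <- Mask3D(unionArr * 1, "segmentation")

    filtered <- .stage("highpass",
                       highpassFilter(trimmed, cutoff, filterOrder,
                                      mask = unionMask))
    peaks <- .stage("peaks", detectPeaks(physio))
    phases <- .stage("phase", boldPhases(filtered, peaks))

    shMap <- .stage("split_half",
                    splitHalfCorrMap(filtered, phases, unionMask,
                                     nRepeats = nRepeats, nBins = nBins,
                                     seed = seed))
    thr <- .stage("preliminary_threshold",
                  preliminaryThreshold(shMap, brainMask))
    prelim <- .stage("preliminary_region",
                     preliminaryRegion(shMap, generalArteryRoi, thr))
    prelimWf <- .stage("preliminary_waveform",
                       regionMeanWaveform(filtered, phases, prelim, nBins))

    artery <- .stage("refine_artery",
                     refineSegmentation(filtered, phases, "artery",
                                        generalArteryRoi, generalSssRoi,
                                        brainMask, prelimWf,
                                        maxIter = maxIter, seed = seed))
    sss <- NULL
    if (!is.null(generalSssRoi))
        sss <- .stage("refine_sss",
                      refineSegmentation(filtered, phases, "sss",
                                         generalArteryRoi, generalSssRoi,
                                         brainMask, prelimWf,
                                         maxIter = maxIter, seed = seed))

    list(artery = artery, sss = sss, splitHalfMap = shMap, qc = qc,
         peaks = peaks, preliminaryMask = prelim,
         preliminaryWaveform = prelimWf, preliminaryThreshold = thr)
}
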