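# Retrospective cardiac alignment: peak detection on the PPG, phase
# assignment of fMRI timepoints, and phase-binned cardiac waveforms.

#' Detect systolic peaks in a plethysmography trace
#'
#' The trace is band-pass filtered to 0.5-3 Hz (order-2 Butterworth, zero
#' phase), local maxima separated by at least \code{minSeparation} seconds
#' are located, and peaks below \code{prominenceFrac} times the median
#' positive peak amplitude are discarded. Remaining implausible inter-peak
#' intervals (< 0.3 s) are merged (the smaller peak dropped); intervals
#' longer than 2 s are bridged by inserting evenly spaced surrogate peak
#' times so the surviving RR intervals are physiological.
#'
#' @param trace a \linkS4class{PhysioTrace}.
#' @param minSeparation minimum peak separation, s.
#' @param prominenceFrac minimum peak amplitude relative to the median
#'   detected pulse amplitude.
#' @return A \linkS4class{PeakSeries}; peak times are on the trace's clock
#'   (first sample at \code{t0}).
#' @export
detectPeaks <- function(trace, minSeparation = 0.3, prominenceFrac = 0.5) {
    fs <- trace@fs
    x <- trace@samples - mean(trace@samples)
    if (stats::sd(x) == 0)
        stop("insufficient peaks: flat-line trace")
    nyq <- fs / 2
    hi <- min(3 / nyq, 0.99)
    filt <- signal::butter(2, c(0.5 / nyq, hi), type = "pass")
    xf <- signal::filtfilt(filt, x)
    minDist <- max(1L, round(minSeparation * fs))
    pk <- pracma::findpeaks(xf, minpeakdistance = minDist, sortstr = FALSE)
    if (is.null(pk) || nrow(pk) < 3L)
        stop("insufficient peaks detected in the trace")
    ord <- order(pk[, 2])
    locs <- pk[ord, 2]
    heights <- pk[ord, 1]
    keep <- heights >= prominenceFrac * stats::median(heights[heights > 0])
    locs <- locs[keep]
    heights <- heights[keep]
    if (length(locs) < 3L)
        stop("insufficient peaks after amplitude screening")
    # merge implausibly close peaks: drop the smaller of any pair < 0.3 s apart
    repeat {
        rr <- diff(locs) / fs
        bad <- which(rr < 0.3)
        if (!length(bad)) break
        i <- bad[1]
        drop <- if (heights[i] < heights[i + 1]) i else i + 1
        locs <- locs[-drop]; heights <- heights[-drop]
        if (length(locs) < 3L)
            stop("insufficient peaks after interval cleaning")
    }
    times <- trace@t0 + (locs - 1) / fs
    # bridge implausibly long gaps with evenly spaced surrogate beats
    rr <- diff(times)
    if (any(rr > 2.0)) {
        out <- times[1]
        for (i in seq_along(rr)) {
            if (rr[i] > 2.0) {
                k <- ceiling(rr[i] / 2.0)
                out <- c(out, times[i] + rr[i] * seq_len(k - 1) / k)
            }
            out <- c(out, times[i + 1])
        }
        times <- out
    }
    new("PeakSeries", peakTimes = times,
        meanHr = 60 / mean(diff(times)))
}

# Acquisition time of every (timepoint, slice) pair, seconds on the retained
# series clock: volume onset + slice offset, or + tr/2 when timing unknown.
.acquisitionTimes <- function(bold) {
    nt <- dim(bold@data)[4]
    nz <- dim(bold@data)[3]
    onset <- (seq_len(nt) - 1) * bold@tr
    off <- if (is.null(bold@sliceOffsets)) rep(bold@tr / 2, nz)
           else bold@sliceOffsets
    outer(onset, off, `+`)          # t x nz
}

#' Assign a cardiac phase to each acquisition time
#'
#' For an acquisition time t between consecutive peaks p_k and p_(k+1), the
#' phase is the linear fraction (t - p_k) / (p_(k+1) - p_k) of the RR
#' interval, in [0, 1). Timepoints before the first or after the last peak
#' are marked invalid and excluded from all downstream statistics.
#'
#' @param acqTimes numeric vector or t x nSlices matrix of acquisition times
#'   (s, same clock as the peak times).
#' @param peaks a \linkS4class{PeakSeries}.
#' @return A \linkS4class{PhaseAssignment} with one column per slice (a
#'   vector input yields one column).
#' @export
assignPhase <- function(acqTimes, peaks) {
    tm <- as.matrix(acqTimes)
    p <- peaks@peakTimes
    idx <- findInterval(tm, p)   # p[idx] <= t < p[idx + 1]
    valid <- idx >= 1L & idx < length(p)
    ph <- matrix(NA_real_, nrow(tm), ncol(tm))
    ii <- which(valid)
    k <- idx[ii]
    v <- (tm[ii] - p[k]) / (p[k + 1] - p[k])
    v[v >= 1] <- 0   # guard against floating-point landing exactly on 1
    ph[ii] <- v
    dim(valid) <- dim(tm)
    new("PhaseAssignment", phases = ph, valid = valid)
}

#' Cardiac phases for a BOLD series
#'
#' Convenience wrapper: computes per-slice acquisition times for the retained
#' series and assigns phases against the detected peaks.
#'
#' @param bold a (trimmed, filtered) \linkS4class{Bold4D}.
#' @param peaks a \linkS4class{PeakSeries} on the retained-series clock.
#' @return A \linkS4class{PhaseAssignment} with one column per slice.
#' @export
boldPhases <- function(bold, peaks) {
    assignPhase(.acquisitionTimes(bold), peaks)
}

# circular linear interpolation of empty bins, operating on an
# nBins x nVox matrix of bin means with a shared count vector.
.interpolateEmptyBins <- function(M, counts) {
    n <- length(counts)
    empty <- which(counts == 0)
    if (!length(empty)) return(M)
    filled <- which(counts > 0)
    if (!length(filled))
        stop("all phase bins are empty")
    for (j in empty) {
        dPrev <- (j - filled) %% n   # circular distance to previous filled
        dNext <- (filled - j) %% n
        pj <- filled[which.min(dPrev)]
        nj <- filled[which.min(dNext)]
        dp <- min(dPrev); dn <- min(dNext)
        if (pj == nj) {
            M[j, ] <- M[pj, ]
        } else {
            M[j, ] <- (dn * M[pj, ] + dp * M[nj, ]) / (dp + dn)
        }
    }
    M
}

# Bin a t x nVox signal matrix by phase. `phase` and `valid` are per-timepoint
# (one slice). Returns nBins x nVox means (empty bins interpolated),
# shared counts, and the interpolated flag.
.binMatrix <- function(X, phase, valid, nBins) {
    use <- which(valid & is.finite(phase))
    if (!length(use))
        stop("no valid samples to bin")
    b <- pmin(floor(phase[use] * nBins) + 1L, nBins)
    counts <- tabulate(b, nBins)
    S <- rowsum(X[use, , drop = FALSE], group = b, reorder = TRUE)
    M <- matrix(NA_real_, nBins, ncol(X))
    M[as.integer(rownames(S)), ] <- S / counts[as.integer(rownames(S))]
    M <- .interpolateEmptyBins(M, counts)
    list(means = M, counts = counts, interpolated = counts == 0)
}

#' Bin a signal into a phase-locked cardiac waveform
#'
#' Averages the signal over valid timepoints falling in each of \code{nBins}
#' equal phase bins. Empty bins are filled by circular linear interpolation
#' from the nearest non-empty bins and flagged.
#'
#' @param signal numeric vector, one value per timepoint.
#' @param phases a \linkS4class{PhaseAssignment} (its first column is used)
#'   or a numeric vector of phases in [0, 1) with NA marking invalid
#'   timepoints.
#' @param nBins number of phase bins.
#' @return A \linkS4class{CardiacWaveform}.
#' @export
binWaveform <- function(signal, phases, nBins = 20) {
    if (is(phases, "PhaseAssignment")) {
        ph <- phases@phases[, 1]
        valid <- phases@valid[, 1]
    } else {
        ph <- as.numeric(phases)
        valid <- is.finite(ph)
    }
    if (length(signal) != length(ph))
        stop("signal and phases must have equal length")
    r <- .binMatrix(matrix(signal, ncol = 1), ph, valid, nBins)
    new("CardiacWaveform", nBins = as.integer(nBins),
        binMeans = as.numeric(r$means),
        binCounts = as.integer(r$counts),
        interpolated = r$interpolated)
}
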