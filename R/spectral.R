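# Spectral verification: amplitude spectrum of ROI-mean signals and the
# cardiac-band amplification from general ROI to final segmentation.

#' Temporal Nyquist frequency of an fMRI series
#'
#' @param tr repetition time, s.
#' @return 1 / (2 tr), Hz.
#' @export
nyquistFreq <- function(tr) {
    if (any(tr <= 0)) stop("tr must be positive")
    1 / (2 * tr)
}

#' Cardiac frequency from heart rate
#'
#' @param meanHr heart rate in beats per minute.
#' @return frequency in Hz (beats per second).
#' @export
cardiacFreq <- function(meanHr) {
    if (any(meanHr <= 0)) stop("heart rate must be positive")
    meanHr / 60
}

#' Fold a frequency below Nyquist
#'
#' Alias frequency of \code{f} for a sampling process with the given Nyquist
#' frequency: |f - 2 k nyquist| for the integer k bringing the result into
#' [0, nyquist].
#'
#' @param f frequency, Hz.
#' @param nyquist Nyquist frequency, Hz.
#' @return folded frequency in [0, nyquist].
#' @export
aliasFrequency <- function(f, nyquist) {
    fs <- 2 * nyquist
    fm <- f %% fs
    ifelse(fm > nyquist, fs - fm, fm)
}

#' Amplitude spectrum of an ROI-mean fMRI signal
#'
#' Averages the time series over the mask, removes a linear trend, and
#' computes the one-sided amplitude spectrum. The cardiac-band amplitude is
#' the maximum amplitude within 0.1 Hz of the cardiac frequency (mean heart
#' rate / 60, folded below Nyquist and flagged when it aliases).
#'
#' @param bold a \linkS4class{Bold4D}.
#' @param mask non-empty \linkS4class{Mask3D}.
#' @param peaks \linkS4class{PeakSeries} supplying the mean heart rate.
#' @param bandHalfWidth half-width of the cardiac search band, Hz.
#' @return A \linkS4class{SpectrumReport}.
#' @export
roiSpectrum <- function(bold, mask, peaks, bandHalfWidth = 0.1) {
    lin <- which(mask@data != 0)
    if (!length(lin)) stop("empty mask")
    sp <- dim(bold@data)[1:3]
    nt <- dim(bold@data)[4]
    X <- matrix(bold@data, prod(sp), nt)
    s <- colMeans(X[lin, , drop = FALSE])
    tt <- seq_len(nt)
    s <- as.numeric(stats::residuals(stats::lm(s ~ tt)))
    nyq <- nyquistFreq(bold@tr)
    m <- floor(nt / 2)
    amp <- Mod(stats::fft(s))[1:(m + 1)] / nt
    amp[-1] <- 2 * amp[-1]
    if (nt %% 2 == 0)
        amp[m + 1] <- amp[m + 1] / 2   # Nyquist bin is not doubled
    freqs <- (0:m) / (nt * bold@tr)
    fc <- cardiacFreq(peaks@meanHr)
    aliased <- fc > nyq + 1e-12
    fcFold <- aliasFrequency(fc, nyq)
    inBand <- abs(freqs - fcFold) <= bandHalfWidth
    if (!any(inBand))
        inBand <- which.min(abs(freqs - fcFold))
    new("SpectrumReport", freqs = freqs, amplitude = amp,
        cardiacFreq = fcFold, cardiacAmplitude = max(amp[inBand]),
        nyquist = nyq, aliased = aliased)
}
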