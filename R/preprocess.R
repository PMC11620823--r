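#' Discard initial fMRI volumes
#'
#' Removes the first \code{n} volumes of the series (default 10) to reduce
#' T1-relaxation (non-steady-state) effects. The time origin of the retained
#' series shifts by \code{n * tr}; physio offsets are interpreted relative to
#' the retained series (see \code{\link{segmentVessels}}).
#'
#' @param bold a \linkS4class{Bold4D}.
#' @param n number of leading volumes to discard.
#' @return A \linkS4class{Bold4D} with \code{t - n} volumes.
#' @export
trimInitialVolumes <- function(bold, n = 10) {
    stopifnot(is(bold, "Bold4D"))
    nt <- dim(bold@data)[4]
    if (n < 0) stop("n must be non-negative")
    if (n == 0) return(bold)
    if (nt <= n)
        stop(sprintf("cannot trim %d volumes from a series of length %d", n, nt))
    Bold4D(bold@data[, , , (n + 1):nt, drop = FALSE], bold@voxelDims,
           bold@tr, bold@sliceOffsets, bold@affine)
}

.designHighpass <- function(cutoff, tr, order = 2) {
    nyq <- 1 / (2 * tr)
    if (cutoff >= nyq)
        stop(sprintf("cutoff %.4g Hz must be below the Nyquist frequency %.4g Hz",
                     cutoff, nyq))
    signal::butter(order, cutoff / nyq, type = "high")
}

#' Voxel-wise zero-phase Butterworth high-pass filter
#'
#' Applies an order-\code{order} Butterworth high-pass at \code{cutoff} Hz
#' forward and backward (zero phase, so the cardiac phase of the signal is
#' not shifted relative to the PPG), voxel by voxel. Each series is demeaned
#' before filtering and any residual mean is removed afterwards, so the DC
#' offset of every voxel is eliminated exactly. The operation is linear.
#'
#' @param bold a \linkS4class{Bold4D} with at least 8 timepoints.
#' @param cutoff high-pass cutoff frequency, Hz.
#' @param order Butterworth order (applied twice via forward-backward, so
#'   the effective attenuation is squared).
#' @param mask optional \linkS4class{Mask3D}; when supplied only in-mask
#'   voxels are filtered (identical results for those voxels, out-of-mask
#'   voxels are set to 0).
#' @return A filtered \linkS4class{Bold4D}.
#' @export
highpassFilter <- function(bold, cutoff = 0.005, order = 2, mask = NULL) {
    stopifnot(is(bold, "Bold4D"))
    nt <- dim(bold@data)[4]
    if (nt < 8)
        stop("series too short to filter meaningfully (need >= 8 timepoints)")
    filt <- .designHighpass(cutoff, bold@tr, order)
    d <- dim(bold@data)
    X <- matrix(bold@data, prod(d[1:3]), d[4])
    keep <- if (is.null(mask)) seq_len(nrow(X)) else which(mask@data != 0)
    Y <- matrix(0, nrow(X), ncol(X))
    sub <- X[keep, , drop = FALSE]
    mu <- rowMeans(sub)
    sub <- sub - mu
    out <- t(apply(sub, 1, function(x) signal::filtfilt(filt, x)))
    out <- out - rowMeans(out)
    Y[keep, ] <- out
    Bold4D(array(Y, d), bold@voxelDims, bold@tr, bold@sliceOffsets,
           bold@affine)
}

#' Frequency response of the pipeline high-pass filter
#'
#' Magnitude of the effective (forward-backward, i.e. squared) transfer
#' function of the designed Butterworth high-pass at the requested
#' frequencies. Useful for verifying pass-band flatness.
#'
#' @param freqs frequencies at which to evaluate, Hz.
#' @param tr repetition time, s.
#' @param cutoff cutoff frequency, Hz.
#' @param order Butterworth order.
#' @return numeric vector of gains in [0, 1].
#' @export
highpassGain <- function(freqs, tr, cutoff = 0.005, order = 2) {
    filt <- .designHighpass(cutoff, tr, order)
    w <- 2 * pi * freqs * tr
    z <- exp(1i * w)
    num <- vapply(z, function(zz)
        sum(filt$b * zz^(-(seq_along(filt$b) - 1))), complex(1))
    den <- vapply(z, function(zz)
        sum(filt$a * zz^(-(seq_along(filt$a) - 1))), complex(1))
    Mod(num / den)^2
}

#' Photoplethysmography signal-quality score
#'
#' Fraction of PPG spectral power concentrated at the cardiac frequency: the
#' spectral peak f_c is located in the 0.6-2.0 Hz heart-rate band, and the
#' score is the power inside [f_c - 0.15, f_c + 0.15] and the first-harmonic
#' band [2 f_c - 0.15, 2 f_c + 0.15] Hz divided by the total power in
#' 0.5-3 Hz. Invariant to amplitude scaling of the trace. Returns 0 with a
#' warning when no spectral power exists in the search band.
#'
#' @param trace a \linkS4class{PhysioTrace}.
#' @param delta half-width of the cardiac bands, Hz.
#' @return quality fraction in [0, 1].
#' @export
ppgQuality <- function(trace, delta = 0.15) {
    x <- trace@samples - mean(trace@samples)
    n <- length(x)
    P <- Mod(stats::fft(x))^2
    m <- floor(n / 2)
    freqs <- (0:m) * trace@fs / n
    P <- P[1:(m + 1)]
    band <- freqs >= 0.5 & freqs <= 3
    search <- freqs >= 0.6 & freqs <= 2.0
    if (!any(search) || max(P[search]) <= 0 || sum(P[band]) <= 0) {
        warning("no spectral peak in the cardiac search band (0.6-2.0 Hz)")
        return(0)
    }
    fc <- freqs[search][which.max(P[search])]
    inBands <- band & ((abs(freqs - fc) <= delta) |
                       (abs(freqs - 2 * fc) <= delta))
    sum(P[inBands]) / sum(P[band])
}

#' Motion-exclusion check on rigid-motion parameters
#'
#' Evaluates the exclusion rule "maximum translation greater than one voxel
#' dimension" on a table of motion parameters. By default the maximum
#' absolute per-axis translation relative to the reference volume is used;
#' \code{method = "euclidean"} uses the translation vector magnitude, and
#' \code{relative = "frame"} differences consecutive volumes first.
#'
#' @param motion a \linkS4class{MotionTable}.
#' @param voxelDims voxel dimensions, mm; the pass threshold is their minimum.
#' @param method "per-axis" (default) or "euclidean".
#' @param relative "reference" (default; translations as stored, relative to
#'   the realignment reference) or "frame" (frame-to-frame differences).
#' @return list with \code{maxTranslationMm} and \code{pass}.
#' @export
motionCheck <- function(motion, voxelDims,
                        method = c("per-axis", "euclidean"),
                        relative = c("reference", "frame")) {
    method <- match.arg(method)
    relative <- match.arg(relative)
    tr3 <- motion@params[, 4:6, drop = FALSE]
    if (nrow(tr3) == 0) stop("empty motion table")
    if (relative == "frame")
        tr3 <- diff(rbind(0, tr3))
    maxT <- if (method == "per-axis") max(abs(tr3))
            else max(sqrt(rowSums(tr3^2)))
    list(maxTranslationMm = maxT, pass = maxT <= min(voxelDims))
}

#' Assemble a quality-control report
#'
#' @param trace a \linkS4class{PhysioTrace}.
#' @param motion optional \linkS4class{MotionTable}.
#' @param voxelDims voxel dimensions, mm (needed when \code{motion} given).
#' @param nVolumesRetained number of volumes after trimming.
#' @param ppgThreshold minimum acceptable PPG quality score.
#' @param ... passed to \code{\link{motionCheck}}.
#' @return A \linkS4class{QcReport}.
#' @export
qcReport <- function(trace, motion = NULL, voxelDims = NULL,
                     nVolumesRetained = NA_integer_, ppgThreshold = 0.30,
                     ...) {
    q <- ppgQuality(trace)
    if (is.null(motion)) {
        mt <- NA_real_; mp <- NA
    } else {
        if (is.null(voxelDims))
            stop("voxelDims required for the motion check")
        mc <- motionCheck(motion, voxelDims, ...)
        mt <- mc$maxTranslationMm; mp <- mc$pass
    }
    new("QcReport", ppgQuality = q, ppgPass = q >= ppgThreshold,
        maxTranslationMm = mt, motionPass = mp,
        nVolumesRetained = as.integer(nVolumesRetained))
}
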