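#' Load a 4D BOLD series from a NIfTI file
#'
#' Reads a NIfTI-1/2 file and wraps it as a \linkS4class{Bold4D}. The
#' repetition time is taken from header \code{pixdim[4]} unless overridden;
#' an explicit \code{tr} always wins, and a mismatch of more than 1 ms
#' between the two triggers a warning.
#'
#' @param path path to a 4D NIfTI file.
#' @param tr optional repetition time override, seconds.
#' @param sliceOffsets optional per-slice acquisition offsets (s, in
#'   [0, tr)); NIfTI headers rarely carry usable slice timing, so these are
#'   supplied explicitly when known.
#' @return A \linkS4class{Bold4D}.
#' @export
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' b0 <- Bold4D(array(rnorm(64 * 5), c(4, 4, 4, 5)), c(2, 2, 2), tr = 0.5)
#' saveBold(b0, f)
#' b <- loadBold(f)
#' repetitionTime(b)
loadBold <- function(path, tr = NULL, sliceOffsets = NULL) {
    if (!file.exists(path))
        stop("file not found: ", path)
    img <- RNifti::readNifti(path)
    if (length(dim(img)) != 4L)
        stop("not a 4D series: '", path, "' has ",
             length(dim(img)), " dimensions")
    hdr <- RNifti::niftiHeader(img)
    headerTr <- hdr$pixdim[5]
    if (is.null(tr)) {
        if (!is.finite(headerTr) || headerTr <= 0)
            stop("non-positive TR in NIfTI header and no override supplied")
        tr <- headerTr
    } else if (is.finite(headerTr) && headerTr > 0 &&
               abs(headerTr - tr) > 1e-3) {
        warning(sprintf(
            "TR override %.4f s differs from header pixdim[4] = %.4f s",
            tr, headerTr))
    }
    vd <- abs(hdr$pixdim[2:4])
    aff <- tryCatch(unclass(RNifti::xform(img))[, , drop = FALSE],
                    error = function(e) diag(c(vd, 1)))
    aff <- matrix(as.numeric(aff), 4, 4)
    Bold4D(data = array(as.numeric(img), dim(img)), voxelDims = vd, tr = tr,
           sliceOffsets = sliceOffsets, affine = aff)
}

#' Load a 3D mask and check it against a reference grid
#'
#' Values greater than 0.5 map to 1, all others to 0, so probabilistic maps
#' are binarized at 0.5 on load. The file's spatial shape must equal the
#' reference's; no resampling is performed (registration is out of scope).
#'
#' @param path path to a 3D NIfTI file (a 4D file with a single volume is
#'   accepted).
#' @param reference a \linkS4class{Bold4D} (or \linkS4class{Mask3D}) defining
#'   the expected grid.
#' @param label role tag for the mask.
#' @return A \linkS4class{Mask3D}.
#' @export
loadMask <- function(path, reference, label = "segmentation") {
    if (!file.exists(path))
        stop("file not found: ", path)
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) == 4L && d[4] == 1L) {
        img <- array(img, d[1:3]); d <- d[1:3]
    }
    if (length(d) != 3L)
        stop("mask must be a 3D image: '", path, "'")
    refShape <- if (is(reference, "Bold4D")) dim(reference@data)[1:3]
                else dim(reference@data)
    if (!all(d == refShape))
        stop(sprintf(
            "geometric inconsistency: mask grid %s does not match reference grid %s",
            paste(d, collapse = "x"), paste(refShape, collapse = "x")))
    Mask3D((array(as.numeric(img), d) > 0.5) * 1, label = label)
}

#' Load a plethysmography trace from a text/TSV file
#'
#' Accepts a single-column file of samples (requires \code{fs}) or a
#' two-column file (time in seconds, value), from which the sampling rate is
#' inferred as the reciprocal of the median time step; timing jitter above
#' 1\% of that step triggers a warning.
#'
#' @param path path to a whitespace/tab-delimited text file.
#' @param fs sampling rate, Hz (required for single-column input).
#' @param t0 offset of the first sample relative to the first retained fMRI
#'   volume, seconds.
#' @return A \linkS4class{PhysioTrace}.
#' @export
loadPhysio <- function(path, fs = NULL, t0 = 0) {
    if (!file.exists(path))
        stop("file not found: ", path)
    tab <- utils::read.table(path, header = FALSE)
    if (ncol(tab) == 1L) {
        if (is.null(fs))
            stop("single-column physio input requires an explicit fs")
        samples <- tab[[1]]
    } else if (ncol(tab) >= 2L) {
        tt <- tab[[1]]
        dt <- diff(tt)
        if (any(dt <= 0))
            stop("non-monotone time column in physio file")
        step <- stats::median(dt)
        if (max(abs(dt - step)) > 0.01 * step)
            warning("physio time column jitter exceeds 1% of the median step")
        inferred <- 1 / step
        if (!is.null(fs) && abs(inferred - fs) > 0.01 * fs)
            warning(sprintf("declared fs %.3f Hz differs from inferred %.3f Hz",
                            fs, inferred))
        fs <- inferred
        samples <- tab[[2]]
    }
    if (length(samples) < 2 * fs)
        stop("trace too short: need at least 2 s of samples")
    PhysioTrace(samples, fs = fs, t0 = t0)
}

#' Load a rigid-motion parameter table
#'
#' Expects six whitespace-delimited columns in FSL MCFLIRT order: three
#' rotations (radians) followed by three translations (mm), one row per
#' volume.
#'
#' @param path path to the parameter file.
#' @param frames whether rows correspond to the "original" or "retained"
#'   (trimmed) series.
#' @return A \linkS4class{MotionTable}.
#' @export
loadMotion <- function(path, frames = "original") {
    if (!file.exists(path))
        stop("file not found: ", path)
    tab <- as.matrix(utils::read.table(path, header = FALSE))
    if (ncol(tab) != 6L)
        stop("motion table must have exactly 6 columns, found ", ncol(tab))
    MotionTable(tab, frames = frames)
}

.writeNiftiWithGeometry <- function(arr, path, voxelDims, tr = NULL,
                                    datatype = "double") {
    img <- RNifti::asNifti(arr)
    pd <- if (is.null(tr)) voxelDims else c(voxelDims, tr)
    RNifti::pixdim(img) <- pd
    RNifti::writeNifti(img, path, datatype = datatype)
}

#' Write masks, maps and BOLD series as NIfTI
#'
#' \code{saveMask} writes a binary mask (uint8, bit-exact round-trip),
#' \code{saveMap} a real-valued 3D map (float64), and \code{saveBold} a 4D
#' series (float64) with TR recorded in \code{pixdim[4]}.
#'
#' @param mask a \linkS4class{Mask3D}.
#' @param map a 3D numeric array or \linkS4class{CorrelationMap}.
#' @param bold a \linkS4class{Bold4D}.
#' @param path output path (directory must exist).
#' @param voxelDims voxel dimensions recorded in the header (mm).
#' @return The path, invisibly.
#' @export
saveMask <- function(mask, path, voxelDims = c(1, 1, 1)) {
    if (!dir.exists(dirname(path)))
        stop("cannot write '", path, "': directory does not exist")
    .writeNiftiWithGeometry(mask@data, path, voxelDims, datatype = "uint8")
    invisible(path)
}

#' @rdname saveMask
#' @export
saveMap <- function(map, path, voxelDims = c(1, 1, 1)) {
    if (!dir.exists(dirname(path)))
        stop("cannot write '", path, "': directory does not exist")
    arr <- if (is(map, "CorrelationMap")) map@values else map
    if (length(dim(arr)) != 3L)
        stop("map must be a 3D array")
    .writeNiftiWithGeometry(arr, path, voxelDims, datatype = "double")
    invisible(path)
}

#' @rdname saveMask
#' @export
saveBold <- function(bold, path) {
    if (!dir.exists(dirname(path)))
        stop("cannot write '", path, "': directory does not exist")
    .writeNiftiWithGeometry(bold@data, path, bold@voxelDims, tr = bold@tr,
                            datatype = "double")
    invisible(path)
}

#' Export a cardiac waveform as TSV
#'
#' Columns: phase bin center in [0, 1), mean signal, sample count,
#' interpolated flag.
#'
#' @param waveform a \linkS4class{CardiacWaveform}.
#' @param path output path.
#' @return The path, invisibly.
#' @export
saveWaveform <- function(waveform, path) {
    n <- waveform@nBins
    df <- data.frame(
        phase_bin_center = (seq_len(n) - 0.5) / n,
        mean = waveform@binMeans,
        count = waveform@binCounts,
        interpolated = as.integer(waveform@interpolated))
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    invisible(path)
}
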