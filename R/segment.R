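# Split-half correlation mapping, preliminary artery region, and iterative
# template-correlation refinement of artery and SSS segmentations.

# ---- internal helpers -------------------------------------------------------

# phase column for slice z (phase matrix has 1 column when slice timing is
# unknown, otherwise one per slice)
.sliceCol <- function(phases, z) min(z, ncol(phases@phases))

# Stack the time series of the requested voxels into a t x nVox matrix with
# slice bookkeeping. `lin` are 3D linear indices into the spatial grid.
.stackVoxels <- function(bold, lin) {
    sp <- dim(bold@data)[1:3]
    nt <- dim(bold@data)[4]
    Xall <- matrix(bold@data, prod(sp), nt)
    z <- ((lin - 1L) %/% (sp[1] * sp[2])) + 1L
    list(X = t(Xall[lin, , drop = FALSE]), lin = lin, z = z, shape = sp)
}

# raw per-bin sums and counts (no interpolation); X is t x v
.binSums <- function(X, phase, valid, nBins) {
    use <- which(valid & is.finite(phase))
    counts <- integer(nBins)
    S <- matrix(0, nBins, ncol(X))
    if (length(use)) {
        b <- pmin(floor(phase[use] * nBins) + 1L, nBins)
        counts <- tabulate(b, nBins)
        R <- rowsum(X[use, , drop = FALSE], group = b, reorder = TRUE)
        S[as.integer(rownames(R)), ] <- R
    }
    list(S = S, counts = counts)
}

# column-wise Pearson correlation of two nBins x v matrices, Eq-2.1 style
# ((N-1)-normalized standardized cross product); NaN for zero variance.
.corrColumns <- function(A, B) {
    n <- nrow(A)
    A0 <- A - rep(colMeans(A), each = n)
    B0 <- B - rep(colMeans(B), each = n)
    sa <- sqrt(colSums(A0^2))
    sb <- sqrt(colSums(B0^2))
    r <- colSums(A0 * B0) / (sa * sb)
    r[sa == 0 | sb == 0] <- NaN
    r
}

# full-series phase-binned waveform of every stacked voxel.
# Returns nBins x nv matrix and a per-voxel rejection flag (slice had > 25%
# empty/interpolated bins).
.voxelWaveforms <- function(stack, phases, nBins,
                            maxInterpFrac = 0.25) {
    nv <- ncol(stack$X)
    W <- matrix(NA_real_, nBins, nv)
    rejected <- logical(nv)
    for (zz in unique(stack$z)) {
        cols <- which(stack$z == zz)
        k <- .sliceCol(phases, zz)
        r <- .binMatrix(stack$X[, cols, drop = FALSE],
                        phases@phases[, k], phases@valid[, k], nBins)
        W[, cols] <- r$means
        if (mean(r$interpolated) > maxInterpFrac)
            rejected[cols] <- TRUE
    }
    list(W = W, rejected = rejected)
}

# ---- exported operations ----------------------------------------------------

#' Randomly split timepoints into two halves
#'
#' Draws floor(n/2) distinct timepoint indices uniformly at random as the
#' first temporal subset; the second subset is its complement (all
#' timepoints not used in the first).
#'
#' @param nTimepoints number of timepoints (>= 4).
#' @param seed optional integer seed (set for a reproducible split; when
#'   NULL the current RNG state is used).
#' @return list with integer vectors \code{first} and \code{second}.
#' @export
splitHalves <- function(nTimepoints, seed = NULL) {
    if (nTimepoints < 4)
        stop("need at least 4 timepoints to split")
    if (!is.null(seed)) set.seed(seed)
    first <- sort(sample.int(nTimepoints, floor(nTimepoints / 2)))
    list(first = first, second = setdiff(seq_len(nTimepoints), first))
}

#' Correlation between two cardiac waveforms
#'
#' Pearson product-moment correlation over the N phase bins, computed as the
#' (N-1)-normalized sum of the standardized bin values of the two waveforms
#' (sample standard deviations). Undefined (NaN) when either waveform has
#' zero variance.
#'
#' @param a,b \linkS4class{CardiacWaveform} objects (or plain numeric
#'   vectors) with the same number of bins.
#' @return correlation coefficient in [-1, 1], or NaN.
#' @export
waveformCorrelation <- function(a, b) {
    va <- if (is(a, "CardiacWaveform")) a@binMeans else as.numeric(a)
    vb <- if (is(b, "CardiacWaveform")) b@binMeans else as.numeric(b)
    if (length(va) != length(vb))
        stop("waveforms must have the same number of phase bins")
    n <- length(va)
    sa <- stats::sd(va)
    sb <- stats::sd(vb)
    if (sa == 0 || sb == 0) return(NaN)
    sum(((va - mean(va)) / sa) * ((vb - mean(vb)) / sb)) / (n - 1)
}

#' Split-half cardiac correlation map
#'
#' For each voxel in the search mask, the retained timepoints are split into
#' two random halves, each half is phase-binned into a cardiac waveform, and
#' the two waveforms are correlated; the procedure is repeated
#' \code{nRepeats} times (100 in the reference pipeline) and the mean
#' correlation is returned per voxel. Reproducible pulsatility yields high
#' mean correlations; noise voxels scatter around zero.
#'
#' @param bold trimmed, high-passed \linkS4class{Bold4D}.
#' @param phases \linkS4class{PhaseAssignment} for the retained series.
#' @param searchMask \linkS4class{Mask3D} of voxels to map (typically brain
#'   plus the general vessel ROIs).
#' @param nRepeats number of random splits.
#' @param nBins phase bins per waveform.
#' @param seed optional integer seed governing all splits.
#' @param maxInterpFrac waveforms with more than this fraction of
#'   interpolated (empty) bins are rejected for that repeat.
#' @return A \linkS4class{CorrelationMap} (kind "split_half_mean"); NaN at
#'   voxels with no defined repeat.
#' @export
splitHalfCorrMap <- function(bold, phases, searchMask, nRepeats = 100,
                             nBins = 20, seed = NULL,
                             maxInterpFrac = 0.25) {
    if (!is.null(seed)) set.seed(seed)
    nt <- dim(bold@data)[4]
    if (nt < 4) stop("need at least 4 timepoints")
    lin <- which(searchMask@data != 0)
    if (!length(lin)) stop("empty search mask")
    stack <- .stackVoxels(bold, lin)
    zs <- sort(unique(stack$z))
    colsByZ <- lapply(zs, function(zz) which(stack$z == zz))
    acc <- numeric(length(lin))
    cnt <- integer(length(lin))
    for (r in seq_len(nRepeats)) {
        halves <- splitHalves(nt)
        in1 <- logical(nt); in1[halves$first] <- TRUE
        for (iz in seq_along(zs)) {
            zz <- zs[iz]; cols <- colsByZ[[iz]]
            k <- .sliceCol(phases, zz)
            ph <- phases@phases[, k]; vl <- phases@valid[, k]
            X <- stack$X[, cols, drop = FALSE]
            wA <- tryCatch(.binMatrix(X, ph, vl & in1, nBins),
                           error = function(e) NULL)
            wB <- tryCatch(.binMatrix(X, ph, vl & !in1, nBins),
                           error = function(e) NULL)
            if (is.null(wA) || is.null(wB) ||
                mean(wA$interpolated) > maxInterpFrac ||
                mean(wB$interpolated) > maxInterpFrac)
                next
            rho <- .corrColumns(wA$means, wB$means)
            ok <- is.finite(rho)
            acc[cols[ok]] <- acc[cols[ok]] + rho[ok]
            cnt[cols[ok]] <- cnt[cols[ok]] + 1L
        }
    }
    vals <- array(NA_real_, dim(searchMask@data))
    m <- acc / cnt        # NaN where cnt == 0
    m[cnt == 0] <- NaN
    vals[lin] <- m
    new("CorrelationMap", values = vals, kind = "split_half_mean",
        nRepeats = as.integer(nRepeats))
}

#' Data-driven preliminary threshold
#'
#' Mean plus three standard deviations of the defined correlation values
#' over all brain voxels (the participant-specific T_preliminary).
#'
#' @param map a \linkS4class{CorrelationMap}.
#' @param brainMask brain \linkS4class{Mask3D}.
#' @param nSd number of standard deviations above the mean.
#' @return threshold scalar.
#' @export
preliminaryThreshold <- function(map, brainMask, nSd = 3) {
    v <- map@values[brainMask@data != 0]
    v <- v[is.finite(v)]
    if (length(v) < 100)
        stop("too few defined brain voxels (", length(v),
             ") for a stable threshold")
    mean(v) + nSd * stats::sd(v)
}

#' Preliminary artery region
#'
#' All voxels of the general cerebral artery ROI whose mean split-half
#' correlation strictly exceeds the preliminary threshold.
#'
#' @param map split-half \linkS4class{CorrelationMap}.
#' @param generalArteryRoi general artery \linkS4class{Mask3D}.
#' @param threshold scalar from \code{\link{preliminaryThreshold}}.
#' @return A \linkS4class{Mask3D}.
#' @export
preliminaryRegion <- function(map, generalArteryRoi, threshold) {
    v <- map@values
    sel <- is.finite(v) & v > threshold & generalArteryRoi@data != 0
    if (!any(sel))
        stop("empty preliminary region: no pulsatile arterial voxels found")
    Mask3D(sel * 1, label = "segmentation")
}

#' Mean cardiac waveform of a region
#'
#' Pools the demeaned samples of every voxel in the mask (each sample
#' carrying its own slice's cardiac phase) and bins the pooled samples into
#' a single regional waveform. Without per-slice acquisition offsets this
#' equals phase-binning the demeaned regional mean time series.
#'
#' @param bold trimmed, high-passed \linkS4class{Bold4D}.
#' @param phases \linkS4class{PhaseAssignment}.
#' @param mask region \linkS4class{Mask3D} (non-empty).
#' @param nBins phase bins.
#' @return A \linkS4class{CardiacWaveform}.
#' @export
regionMeanWaveform <- function(bold, phases, mask, nBins = 20) {
    lin <- which(mask@data != 0)
    if (!length(lin)) stop("empty mask")
    stack <- .stackVoxels(bold, lin)
    X <- stack$X
    X <- X - rep(colMeans(X), each = nrow(X))
    totS <- numeric(nBins)
    totN <- numeric(nBins)
    for (zz in unique(stack$z)) {
        cols <- which(stack$z == zz)
        k <- .sliceCol(phases, zz)
        bs <- .binSums(X[, cols, drop = FALSE],
                       phases@phases[, k], phases@valid[, k], nBins)
        totS <- totS + rowSums(bs$S)
        totN <- totN + bs$counts * length(cols)
    }
    if (all(totN == 0)) stop("no valid samples in the region")
    means <- totS / totN
    means[totN == 0] <- NA_real_
    M <- .interpolateEmptyBins(matrix(means, ncol = 1), totN)
    new("CardiacWaveform", nBins = as.integer(nBins),
        binMeans = as.numeric(M),
        binCounts = as.integer(round(totN)),
        interpolated = totN == 0)
}

#' Template correlation map
#'
#' Correlates every search-mask voxel's full-series cardiac waveform with a
#' template waveform (Eq-2.1-style Pearson correlation over the phase bins).
#'
#' @param bold trimmed, high-passed \linkS4class{Bold4D}.
#' @param phases \linkS4class{PhaseAssignment}.
#' @param template \linkS4class{CardiacWaveform} with at most 25\%
#'   interpolated bins.
#' @param searchMask voxels to map.
#' @param maxInterpFrac rejection threshold for template and voxel waveform
#'   bin coverage.
#' @return A \linkS4class{CorrelationMap} (kind "template").
#' @export
templateCorrMap <- function(bold, phases, template, searchMask,
                            maxInterpFrac = 0.25) {
    if (mean(template@interpolated) > maxInterpFrac)
        stop("invalid template: more than ",
             round(100 * maxInterpFrac), "% interpolated bins")
    lin <- which(searchMask@data != 0)
    if (!length(lin)) stop("empty search mask")
    stack <- .stackVoxels(bold, lin)
    vw <- .voxelWaveforms(stack, phases, template@nBins, maxInterpFrac)
    rho <- .corrColumns(vw$W, matrix(template@binMeans, template@nBins,
                                     ncol(vw$W)))
    rho[vw$rejected] <- NaN
    vals <- array(NA_real_, dim(searchMask@data))
    vals[lin] <- rho
    new("CorrelationMap", values = vals, kind = "template",
        nRepeats = 0L)
}

#' Background quantile threshold
#'
#' q-quantile (linear interpolation between order statistics, type 7) of the
#' defined correlation values within the brain but outside every excluded
#' ROI — the data-driven cutoff of the refinement loop (q = 0.99 for the
#' artery target, 0.95 for the SSS).
#'
#' @param map a \linkS4class{CorrelationMap}.
#' @param brainMask brain \linkS4class{Mask3D}.
#' @param excludeMasks list of \linkS4class{Mask3D} to exclude (the general
#'   artery and SSS ROIs).
#' @param q quantile in (0, 1).
#' @return threshold scalar.
#' @export
backgroundQuantile <- function(map, brainMask, excludeMasks, q) {
    elig <- brainMask@data != 0
    for (m in excludeMasks)
        elig <- elig & m@data == 0
    v <- map@values[elig]
    v <- v[is.finite(v)]
    if (length(v) < 100)
        stop("too few eligible background voxels (", length(v), ")")
    as.numeric(stats::quantile(v, q, type = 7, names = FALSE))
}

#' Iterative template-correlation refinement
#'
#' Starting from the preliminary-artery mean waveform, repeats: (i) template
#' correlation map over the candidate region and brain; (ii) background
#' quantile threshold (99th for artery, 95th for SSS) over brain voxels
#' outside both general ROIs; (iii) candidate voxels strictly above the
#' threshold become the current segmentation (artery candidates: general
#' artery ROI; SSS candidates: general SSS ROI restricted to brain);
#' (iv) the mean waveform of the current segmentation becomes the next
#' template. Stops when the segmentation volume changes by less than 1\%
#' relative to the previous iteration, or after \code{maxIter} iterations
#' (\code{converged(x)} is then FALSE; an oscillating volume is reported the
#' same way, with the last mask returned).
#'
#' @param bold trimmed, high-passed \linkS4class{Bold4D}.
#' @param phases \linkS4class{PhaseAssignment}.
#' @param target "artery" or "sss".
#' @param generalArteryRoi,generalSssRoi general \linkS4class{Mask3D} ROIs.
#'   Both are excluded from the background population; the SSS ROI may be
#'   NULL for an artery-only run.
#' @param brainMask brain \linkS4class{Mask3D}.
#' @param initialWaveform \linkS4class{CardiacWaveform} from the preliminary
#'   artery region (used for both targets).
#' @param maxIter iteration cap.
#' @param volTol relative volume-change convergence tolerance.
#' @param seed integer recorded in the result (the randomized step happened
#'   upstream).
#' @return A \linkS4class{SegmentationResult}.
#' @export
refineSegmentation <- function(bold, phases, target = c("artery", "sss"),
                               generalArteryRoi, generalSssRoi, brainMask,
                               initialWaveform, maxIter = 20,
                               volTol = 0.01, seed = NA_integer_) {
    target <- match.arg(target)
    nBinsW <- initialWaveform@nBins
    candArr <- if (target == "artery") generalArteryRoi@data != 0
               else (generalSssRoi@data != 0) & (brainMask@data != 0)
    if (!any(candArr)) stop("empty candidate region for target ", target)
    exclude <- Filter(Negate(is.null),
                      list(generalArteryRoi, generalSssRoi))
    searchArr <- candArr | brainMask@data != 0
    searchMask <- Mask3D(searchArr * 1, "segmentation")
    lin <- which(searchArr)
    stack <- .stackVoxels(bold, lin)
    vw <- .voxelWaveforms(stack, phases, nBinsW)
    candHere <- candArr[lin]
    voxVolCm3 <- prod(bold@voxelDims) / 1000
    tmpl <- initialWaveform
    iters <- data.frame(volume_cm3 = numeric(), threshold = numeric(),
                        n_voxels = integer())
    conv <- FALSE
    prevVol <- NA_real_
    maskLin <- integer()
    for (it in seq_len(maxIter)) {
        if (mean(tmpl@interpolated) > 0.25)
            stop("template waveform rejected: > 25% interpolated bins")
        rho <- .corrColumns(vw$W, matrix(tmpl@binMeans, nBinsW,
                                         ncol(vw$W)))
        rho[vw$rejected] <- NaN
        vals <- array(NA_real_, dim(brainMask@data))
        vals[lin] <- rho
        cmap <- new("CorrelationMap", values = vals, kind = "template",
                    nRepeats = 0L)
        thr <- backgroundQuantile(cmap, brainMask, exclude,
                                  if (target == "artery") 0.99 else 0.95)
        sel <- candHere & is.finite(rho) & rho > thr
        if (!any(sel))
            stop("empty segmentation at iteration ", it,
                 " for target ", target)
        maskLin <- lin[sel]
        nv <- length(maskLin)
        vol <- nv * voxVolCm3
        iters <- rbind(iters, data.frame(volume_cm3 = vol, threshold = thr,
                                         n_voxels = nv))
        if (!is.na(prevVol) && abs(vol - prevVol) / prevVol < volTol) {
            conv <- TRUE
            break
        }
        prevVol <- vol
        if (it < maxIter) {
            arr <- array(0, dim(brainMask@data)); arr[maskLin] <- 1
            tmpl <- regionMeanWaveform(bold, phases,
                                       Mask3D(arr, "segmentation"), nBinsW)
        }
    }
    arr <- array(0, dim(brainMask@data)); arr[maskLin] <- 1
    new("SegmentationResult", mask = Mask3D(arr, "segmentation"),
        target = target, iterations = iters, converged = conv,
        templateWaveform = tmpl, seed = as.integer(seed))
}
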