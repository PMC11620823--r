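# Segmentation performance and reproducibility statistics.

.maskArr <- function(x) if (is(x, "Mask3D")) x@data else x

#' Dice similarity of two binary masks
#'
#' Dice = 2 |X intersect Y| / (|X| + |Y|), in [0, 1].
#'
#' @param x,y \linkS4class{Mask3D} objects (or 0/1 arrays) on the same grid.
#' @return Dice score.
#' @export
diceCoefficient <- function(x, y) {
    a <- .maskArr(x); b <- .maskArr(y)
    if (!all(dim(a) == dim(b)))
        stop("masks are not on the same grid")
    sa <- sum(a); sb <- sum(b)
    if (sa + sb == 0) stop("both masks are empty")
    2 * sum(a * b) / (sa + sb)
}

#' Percent overlap with a reference segmentation
#'
#' Default ("intersection") semantics: the number of test voxels overlapping
#' the reference divided by the reference size, |X intersect Y| / |Y| * 100.
#' The size-ratio variant |X| / |Y| * 100 is available via
#' \code{method = "size-ratio"}. Computed for whichever ordering is supplied;
#' call twice with swapped arguments to let each segmentation serve as the
#' reference.
#'
#' @param seg tested segmentation (\linkS4class{Mask3D} or array).
#' @param ref reference segmentation (non-empty).
#' @param method "intersection" (default) or "size-ratio".
#' @return overlap percentage.
#' @export
percentOverlap <- function(seg, ref, method = c("intersection", "size-ratio")) {
    method <- match.arg(method)
    a <- .maskArr(seg); b <- .maskArr(ref)
    if (!all(dim(a) == dim(b)))
        stop("masks are not on the same grid")
    rv <- sum(b)
    if (rv == 0) stop("empty reference segmentation")
    if (method == "intersection") 100 * sum(a * b) / rv
    else 100 * sum(a) / rv
}

#' Segmentation volume in cubic centimetres
#'
#' @param mask a \linkS4class{Mask3D} (or 0/1 array).
#' @param voxelDims voxel dimensions, mm.
#' @return volume in cm^3 (voxel count x voxel volume / 1000).
#' @export
volumeCm3 <- function(mask, voxelDims) {
    sum(.maskArr(mask)) * prod(voxelDims) / 1000
}

# two-way ANOVA mean squares of an n x k complete table
.twoWayMeanSquares <- function(tab) {
    n <- nrow(tab); k <- ncol(tab)
    gm <- mean(tab)
    rm_ <- rowMeans(tab); cm <- colMeans(tab)
    ssr <- k * sum((rm_ - gm)^2)
    ssc <- n * sum((cm - gm)^2)
    sst <- sum((tab - gm)^2)
    sse <- sst - ssr - ssc
    list(MSR = ssr / (n - 1), MSC = ssc / (k - 1),
         MSE = sse / ((n - 1) * (k - 1)), n = n, k = k)
}

#' Intraclass correlation, two-way model, single rater, absolute agreement
#'
#' ICC(A,1) of McGraw & Wong computed from the two-way ANOVA mean squares:
#' (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE)), where rows are
#' subjects (participants) and columns are repeated measurements (scans).
#' The 95\% confidence interval uses the F-based interval with
#' Satterthwaite degrees of freedom; the p-value tests ICC = 0 via
#' F = MSR/MSE on (n-1, (n-1)(k-1)) degrees of freedom.
#'
#' @param table numeric matrix or data frame, participants x scans, no
#'   missing cells, at least 2 of each.
#' @param conf confidence level.
#' @return list with \code{icc}, \code{ciLow}, \code{ciHigh}, \code{p},
#'   \code{n}, \code{k}.
#' @export
iccAbsoluteAgreement <- function(table, conf = 0.95) {
    tab <- as.matrix(table)
    if (anyNA(tab)) stop("ICC requires a complete table (no missing cells)")
    if (nrow(tab) < 2 || ncol(tab) < 2)
        stop("need at least 2 participants and 2 scans")
    ms <- .twoWayMeanSquares(tab)
    n <- ms$n; k <- ms$k
    icc <- (ms$MSR - ms$MSE) /
        (ms$MSR + (k - 1) * ms$MSE + (k / n) * (ms$MSC - ms$MSE))
    alpha <- 1 - conf
    r <- icc
    a <- (k * r) / (n * (1 - r))
    b <- 1 + (k * r * (n - 1)) / (n * (1 - r))
    v <- (a * ms$MSC + b * ms$MSE)^2 /
        ((a * ms$MSC)^2 / (k - 1) + (b * ms$MSE)^2 / ((n - 1) * (k - 1)))
    fL <- stats::qf(1 - alpha / 2, n - 1, v)
    fU <- stats::qf(1 - alpha / 2, v, n - 1)
    ciLow <- n * (ms$MSR - fL * ms$MSE) /
        (fL * (k * ms$MSC + (k * n - k - n) * ms$MSE) + n * ms$MSR)
    ciHigh <- n * (fU * ms$MSR - ms$MSE) /
        (k * ms$MSC + (k * n - k - n) * ms$MSE + n * fU * ms$MSR)
    fStat <- ms$MSR / ms$MSE
    p <- stats::pf(fStat, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
    list(icc = icc, ciLow = ciLow, ciHigh = ciHigh, p = p, n = n, k = k)
}

#' Total least squares (orthogonal) regression
#'
#' Fits y = slope * x + intercept by minimizing orthogonal distances
#' (Deming regression with error-variance ratio 1): the slope follows the
#' principal eigenvector of the centered covariance matrix of (x, y), with
#' the sign chosen to match the covariance of x and y.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with \code{slope} and \code{intercept}.
#' @export
tlsRegression <- function(x, y) {
    if (length(x) != length(y)) stop("x and y must have equal length")
    if (length(x) < 3) stop("need at least 3 points")
    cv <- stats::cov(cbind(x, y))
    if (sum(diag(cv)) == 0) stop("all points identical")
    ev <- eigen(cv, symmetric = TRUE)$vectors[, 1]
    if (abs(ev[1]) < .Machine$double.eps)
        stop("vertical principal axis: slope undefined")
    slope <- ev[2] / ev[1]
    list(slope = slope, intercept = mean(y) - slope * mean(x))
}

#' Bland-Altman agreement battery for paired volumes
#'
#' Differences are computed as x minus y (the first argument minus the
#' second, matching a scatter plot's x-axis minus y-axis). Reports the
#' Pearson correlation, total-least-squares fit of y on x, mean difference
#' and its 1.96-standard-deviation limits of agreement, and the paired
#' two-tailed t-test of x against y. When the paired differences have zero
#' variance the t statistic is undefined; p is reported as 1 for x = y
#' exactly and 0 for a nonzero constant shift.
#'
#' @param x,y paired measurement vectors (e.g. segmentation volumes of two
#'   repeated scans), equal length >= 2.
#' @return list with \code{pearson_r}, \code{tls_slope}, \code{tls_intercept},
#'   \code{mean_diff}, \code{diff_sd}, \code{loa_low}, \code{loa_high},
#'   \code{paired_t_p}, \code{n}.
#' @export
blandAltman <- function(x, y) {
    if (length(x) != length(y)) stop("x and y must have equal length")
    if (length(x) < 2) stop("need at least 2 pairs")
    d <- x - y
    md <- mean(d)
    sdd <- stats::sd(d)
    if (sdd == 0) {
        p <- if (md == 0) 1 else 0
    } else {
        p <- stats::t.test(x, y, paired = TRUE)$p.value
    }
    r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_
         else stats::cor(x, y)
    tls <- tryCatch(tlsRegression(x, y),
                    error = function(e) list(slope = NA_real_,
                                             intercept = NA_real_))
    list(pearson_r = r, tls_slope = tls$slope, tls_intercept = tls$intercept,
         mean_diff = md, diff_sd = sdd,
         loa_low = md - 1.96 * sdd, loa_high = md + 1.96 * sdd,
         paired_t_p = p, n = length(x))
}

#' Reproducibility report for a table of repeated segmentation volumes
#'
#' Computes the ICC(A,1) over the full table and the Bland-Altman/TLS
#' agreement battery for every unordered pair of scan columns (four repeated
#' scans yield six comparisons).
#'
#' @param table participants x scans volume matrix (cm^3), complete.
#' @return list with \code{icc} (see \code{\link{iccAbsoluteAgreement}}) and
#'   \code{pairs}, a named list of \code{\link{blandAltman}} results, one
#'   per column pair ("A_vs_B" uses A as x and B as y).
#' @export
volumeReproducibility <- function(table) {
    tab <- as.matrix(table)
    if (is.null(colnames(tab)))
        colnames(tab) <- paste0("scan", seq_len(ncol(tab)))
    cmb <- utils::combn(ncol(tab), 2)
    pairs <- list()
    for (j in seq_len(ncol(cmb))) {
        i1 <- cmb[1, j]; i2 <- cmb[2, j]
        pairs[[paste0(colnames(tab)[i1], "_vs_", colnames(tab)[i2])]] <-
            blandAltman(tab[, i1], tab[, i2])
    }
    list(icc = iccAbsoluteAgreement(tab), pairs = pairs)
}
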