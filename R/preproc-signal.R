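#' Nuisance regression of ROI time series
#'
#' Regresses each ROI signal on a nuisance design (typically an intercept,
#' the WM-CSF mean signal, and the six rigid motion parameters) by ordinary
#' least squares over retained volumes only, and returns the residuals.
#' Censored volumes are left in place unchanged (they stay excluded by the
#' censor mask).
#'
#' @param scan a [scan_ts()].
#' @param regressors numeric matrix with one row per retained volume (or per
#'   volume, in which case censored rows are dropped internally). An
#'   intercept column is added when absent.
#' @return The input `scan_ts` with residualized data on retained volumes.
#' @export
nuisance_regress <- function(scan, regressors) {
  stopifnot(inherits(scan, "scan_ts"))
  keep <- scan$censor_mask
  X <- as.matrix(regressors)
  if (nrow(X) == ncol(scan$data)) X <- X[keep, , drop = FALSE]
  if (nrow(X) != sum(keep))
    stop("regressor rows must match the retained (or total) volume count")
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%d", seq_len(ncol(X)))
  if (!any(apply(X, 2, function(c) max(c) - min(c) < 1e-12)))
    X <- cbind(`(intercept)` = 1, X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient nuisance design; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  Y <- t(scan$data[, keep, drop = FALSE])
  res <- qr.resid(qrX, Y)
  out <- scan
  out$data[, keep] <- t(res)
  out
}

#' In-plane Gaussian smoothing
#'
#' Convolves each frame of an x-by-y-by-time array with a normalized 3 x 3
#' Gaussian kernel (sigma = 0.7 pixels). Mask-aware: the kernel is
#' renormalized by the in-mask kernel mass, so constant images are preserved
#' at borders and next to masked-out voxels.
#'
#' @param volume_series numeric array, x by y by time (a single frame may be
#'   passed as a matrix).
#' @param mask optional logical x-by-y matrix (TRUE = in mask).
#' @param sigma Gaussian SD in pixels.
#' @return Array of the same shape.
#' @export
spatial_smooth <- function(volume_series, mask = NULL, sigma = 0.7) {
  is_mat <- is.matrix(volume_series)
  if (is_mat) volume_series <- array(volume_series, c(dim(volume_series), 1))
  d <- dim(volume_series)
  stopifnot(length(d) == 3)
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  stopifnot(all(dim(mask) == d[1:2]))
  g <- outer(exp(-(-1:1)^2 / (2 * sigma^2)), exp(-(-1:1)^2 / (2 * sigma^2)))
  g <- g / sum(g)
  out <- volume_series
  mnum <- matrix(as.numeric(mask), d[1], d[2])
  norm <- conv3x3(mnum, g)         # in-mask kernel mass per pixel
  for (t in seq_len(d[3])) {
    fr <- volume_series[, , t] * mnum
    sm <- conv3x3(fr, g) / pmax(norm, .Machine$double.eps)
    sm[!mask] <- volume_series[, , t][!mask]
    out[, , t] <- sm
  }
  if (is_mat) out[, , 1] else out
}

# 3x3 convolution with zero padding outside the image.
conv3x3 <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    w <- k[di + 2, dj + 2]
    if (w == 0) next
    si <- max(1, 1 - di):min(nr, nr - di)
    sj <- max(1, 1 - dj):min(nc, nc - dj)
    out[si + di, sj + dj] <- out[si + di, sj + dj] + w * m[si, sj]
  }
  out
}

#' Temporal band-pass filter
#'
#' Zero-phase 4th-order Butterworth band-pass (default 0.01--0.1 Hz,
#' matching the low-frequency BOLD band). Censored volumes are linearly
#' interpolated before filtering to avoid ringing across gaps, then
#' re-excluded (they remain censored in the output mask).
#'
#' @param scan a [scan_ts()].
#' @param lo,hi cutoff frequencies in Hz; requires 0 < lo < hi < Nyquist.
#' @return The filtered `scan_ts`.
#' @export
bandpass <- function(scan, lo = 0.01, hi = 0.1) {
  stopifnot(inherits(scan, "scan_ts"))
  fs <- 1 / scan$tr
  nyq <- fs / 2
  if (!(lo > 0 && lo < hi)) stop("need 0 < lo < hi")
  if (hi >= nyq) stop(sprintf("hi = %g Hz is at or above Nyquist (%g Hz)", hi, nyq))
  bf <- signal::butter(2, c(lo, hi) / nyq, type = "pass")
  n <- ncol(scan$data)
  keep <- scan$censor_mask
  out <- scan
  idx <- seq_len(n)
  pad <- min(n - 1, 3 * ceiling(fs / lo))   # reflection padding length
  for (i in seq_len(nrow(scan$data))) {
    y <- scan$data[i, ]
    if (!all(keep)) {
      if (sum(keep) < 2) stop("too few retained volumes to interpolate")
      y <- approx(idx[keep], y[keep], xout = idx, rule = 2)$y
    }
    # demean and reflect-pad to suppress start/end transients of the
    # zero-phase filter
    mu <- mean(y)
    yp <- c(rev(y[2:(pad + 1)]), y, rev(y[(n - pad):(n - 1)])) - mu
    f <- signal::filtfilt(bf, yp)
    out$data[i, ] <- f[(pad + 1):(pad + n)]
  }
  out
}

#' Pairwise ROI correlation matrix
#'
#' Pearson correlation between all ROI pairs over retained volumes.
#' Zero-variance ROIs get NA rows/columns (with a warning) and are excluded
#' pairwise downstream rather than failing the scan.
#'
#' @param scan a [scan_ts()] with at least 30 retained volumes.
#' @param min_volumes minimum retained volumes required.
#' @return A [conn_matrix()] carrying the scan's metadata plus
#'   `retained_fraction`.
#' @export
roi_correlation <- function(scan, min_volumes = 30) {
  stopifnot(inherits(scan, "scan_ts"))
  keep <- scan$censor_mask
  if (sum(keep) < min_volumes)
    stop(sprintf("only %d retained volumes (< %d)", sum(keep), min_volumes))
  x <- t(scan$data[, keep, drop = FALSE])
  sds <- apply(x, 2, sd)
  degen <- sds < 1e-12
  r <- suppressWarnings(cor(x))
  if (any(degen)) {
    warning("zero-variance ROI(s): ",
            paste(scan$roi_names[degen], collapse = ", "))
    r[degen, ] <- NA_real_
    r[, degen] <- NA_real_
  }
  diag(r) <- 1
  conn_matrix(r, scan$roi_names,
              metadata = list(subject = scan$subject_id,
                              genotype = scan$genotype,
                              age_months = scan$age_months,
                              scan_id = scan$scan_id,
                              retained_fraction = mean(keep)))
}
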