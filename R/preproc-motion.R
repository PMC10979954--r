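#' Per-volume motion parameter from rigid-body affines
#'
#' Converts per-volume 4 x 4 rigid transforms (relative to the reference
#' volume) into a scalar displacement per volume,
#' \deqn{|T_x|+|T_y|+|T_z| + |\theta_x| r_z + |\theta_y| r_z + |\theta_z| r_x,}
#' using Euler angles back-computed from the rotation block. Absolute values
#' are summed so the displacement is non-negative. Angles are extracted with
#' the intrinsic Z-Y-X convention (R = Rz Ry Rx).
#'
#' The paper-facing radii are not standardized; the default 5 mm matches an
#' effective mouse-brain radius and is configurable. Note the asymmetric
#' pairing of angles and radii (both in-plane rotations scale with `rz`),
#' retained as published.
#'
#' @param affines list of 4 x 4 matrices, or a 4 x 4 x n array.
#' @param radii effective radii (rx, ry, rz) in mm.
#' @return A [motion_trace()].
#' @examples
#' aff <- diag(4); aff[1:3, 4] <- c(0.05, 0.03, 0.02)
#' compute_motion_parameter(list(diag(4), aff))$displacement
#' @export
compute_motion_parameter <- function(affines, radii = c(5, 5, 5)) {
  if (is.array(affines) && length(dim(affines)) == 3)
    affines <- lapply(seq_len(dim(affines)[3]), function(i) affines[, , i])
  stopifnot(length(affines) >= 1, length(radii) == 3, all(radii > 0))
  tr <- matrix(0, length(affines), 3)
  ro <- matrix(0, length(affines), 3)
  for (i in seq_along(affines)) {
    a <- as.matrix(affines[[i]])
    if (!all(dim(a) == c(4, 4))) stop("each affine must be 4 x 4")
    R <- a[1:3, 1:3]
    if (max(abs(crossprod(R) - diag(3))) > 1e-6 || abs(det(R) - 1) > 1e-6)
      stop(sprintf("volume %d: transform is not rigid (non-orthonormal rotation)", i))
    tr[i, ] <- a[1:3, 4]
    ro[i, ] <- euler_zyx(R)
  }
  motion_trace(tr, ro, radii)
}

# Intrinsic Z-Y-X Euler angles from a rotation matrix R = Rz(c) Ry(b) Rx(a).
# Returns c(theta_x, theta_y, theta_z). Gimbal lock (|R31| = 1) resolved by
# fixing theta_z = 0.
euler_zyx <- function(R) {
  sy <- -R[3, 1]
  if (abs(sy) < 1 - 1e-10) {
    b <- asin(sy)
    a <- atan2(R[3, 2], R[3, 3])
    c <- atan2(R[2, 1], R[1, 1])
  } else {
    b <- if (sy > 0) pi / 2 else -pi / 2
    a <- atan2(-R[1, 2], R[2, 2])
    c <- 0
  }
  c(a, b, c)
}

# Rotation matrix for intrinsic Z-Y-X angles (used in round-trip tests).
rot_zyx <- function(theta) {
  a <- theta[1]; b <- theta[2]; cc <- theta[3]
  Rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  Rz <- rbind(c(cos(cc), -sin(cc), 0), c(sin(cc), cos(cc), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Motion scrubbing: censor high-motion volumes
#'
#' Volumes whose displacement exceeds the threshold (half an in-plane voxel,
#' 0.125 mm, by default) are discarded together with one volume before and
#' one after. A scan is kept only if at least 90% of its volumes survive.
#' Volumes already censored (`prior_mask` FALSE) are not re-detected as
#' offenders, so scrubbing an already-scrubbed trace discards nothing new.
#'
#' @param trace a [motion_trace()] or a numeric displacement vector (mm).
#' @param threshold displacement threshold in mm.
#' @param prior_mask optional logical per volume (TRUE = currently kept).
#' @return A `scrub_result` list: `displacement`, `discarded` (integer
#'   indices), `retained_fraction`, `scan_kept`, `censor_mask`.
#' @examples
#' d <- rep(0.01, 10); d[5] <- 0.3
#' scrub_volumes(d)
#' @export
scrub_volumes <- function(trace, threshold = 0.125, prior_mask = NULL) {
  disp <- if (inherits(trace, "motion_trace")) trace$displacement
          else as.numeric(trace)
  n <- length(disp)
  if (n == 0) stop("empty motion trace")
  stopifnot(threshold > 0)
  if (is.null(prior_mask)) prior_mask <- rep(TRUE, n)
  stopifnot(length(prior_mask) == n)
  offenders <- which(disp > threshold & prior_mask)
  discarded <- sort(unique(pmin(pmax(
    rep(offenders, each = 3) + c(-1L, 0L, 1L), 1L), n)))
  mask <- prior_mask
  mask[discarded] <- FALSE
  retained <- 1 - length(discarded) / n
  structure(list(displacement = disp, discarded = discarded,
                 retained_fraction = retained,
                 scan_kept = retained >= 0.9, censor_mask = mask),
            class = "scrub_result")
}

#' @export
print.scrub_result <- function(x, ...) {
  cat(sprintf("Scrub: %d/%d volumes discarded (retained %.1f%%) -> scan %s\n",
              length(x$discarded), length(x$displacement),
              100 * x$retained_fraction,
              if (x$scan_kept) "kept" else "discarded"))
  invisible(x)
}
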