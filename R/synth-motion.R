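#' Motion trace container
#'
#' Per-volume rigid-body motion relative to the reference volume:
#' translations (mm), rotations (radians), the effective radii used to
#' convert rotations to displacement, and the derived per-volume scalar
#' displacement in mm.
#'
#' @param translations n x 3 matrix (Tx, Ty, Tz) in mm.
#' @param rotations n x 3 matrix (theta_x, theta_y, theta_z) in radians.
#' @param radii length-3 effective radii (rx, ry, rz) in mm.
#' @return A `motion_trace` with the displacement computed as
#'   |Tx|+|Ty|+|Tz| + |theta_x| rz + |theta_y| rz + |theta_z| rx.
#' @export
motion_trace <- function(translations, rotations, radii = c(5, 5, 5)) {
  translations <- as.matrix(translations)
  rotations <- as.matrix(rotations)
  stopifnot(ncol(translations) == 3, ncol(rotations) == 3,
            nrow(translations) == nrow(rotations), length(radii) == 3,
            all(radii > 0))
  disp <- rowSums(abs(translations)) +
    abs(rotations[, 1]) * radii[3] +
    abs(rotations[, 2]) * radii[3] +
    abs(rotations[, 3]) * radii[1]
  structure(list(translations = translations, rotations = rotations,
                 radii = as.numeric(radii), displacement = as.numeric(disp)),
            class = "motion_trace")
}

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf("Motion trace: %d volumes, displacement %.3g-%.3g mm (radii %s mm)\n",
              length(x$displacement), min(x$displacement),
              max(x$displacement), paste(x$radii, collapse = "/")))
  invisible(x)
}

#' Generate a synthetic motion trace
#'
#' Baseline jitter is drawn well below the 0.125 mm scrub threshold;
#' spikes exceeding it are inserted at Bernoulli(`spike_rate`) volumes.
#' Ground-truth spike indices are recorded in the `spikes` attribute.
#'
#' @param config a [synth_config()].
#' @param n_volumes number of volumes (default: the configured scan length).
#' @return A [motion_trace()] with attribute `spikes` (integer indices).
#' @export
gen_motion_trace <- function(config, n_volumes = config$n_timepoints_per_scan) {
  stopifnot(inherits(config, "synth_config"), n_volumes >= 1)
  with_seed(child_seed(config$seed, "motion"), {
    tr <- matrix(runif(n_volumes * 3, -0.01, 0.01), n_volumes, 3)
    ro <- matrix(runif(n_volumes * 3, -0.002, 0.002), n_volumes, 3)
    spikes <- which(as.logical(rbinom(n_volumes, 1, config$spike_rate)))
    # a 0.2 mm x-translation guarantees displacement > 0.125 mm
    tr[spikes, 1] <- tr[spikes, 1] + 0.2
    out <- motion_trace(tr, ro)
    attr(out, "spikes") <- spikes
    out
  })
}
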