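#' ROI time-series container
#'
#' Constructs a `scan_ts`: an ROI x time matrix of BOLD-like signal with
#' acquisition and design metadata plus a per-volume censor mask
#' (TRUE = keep).
#'
#' @param data numeric ROI x time matrix.
#' @param roi_names unique ROI labels (one per row).
#' @param tr repetition time in seconds.
#' @param subject_id subject label.
#' @param genotype "5xFAD" or "WT".
#' @param age_months age in months.
#' @param scan_id scan label.
#' @param censor_mask logical per volume; defaults to all TRUE.
#' @return A `scan_ts` object.
#' @export
scan_ts <- function(data, roi_names, tr, subject_id = NA_character_,
                    genotype = NA_character_, age_months = NA_real_,
                    scan_id = NA_character_, censor_mask = NULL) {
  data <- as.matrix(data)
  if (is.null(censor_mask)) censor_mask <- rep(TRUE, ncol(data))
  if (length(roi_names) != nrow(data)) stop("one roi name per row required")
  if (anyDuplicated(roi_names)) stop("roi_names must be unique")
  if (length(censor_mask) != ncol(data))
    stop("censor_mask length must equal the number of volumes")
  if (!is.numeric(tr) || tr <= 0) stop("tr must be positive")
  rownames(data) <- roi_names
  structure(list(data = data, roi_names = as.character(roi_names), tr = tr,
                 subject_id = subject_id, genotype = genotype,
                 age_months = age_months, scan_id = scan_id,
                 censor_mask = as.logical(censor_mask)),
            class = "scan_ts")
}

#' @export
print.scan_ts <- function(x, ...) {
  cat(sprintf("ROI time series: %d ROIs x %d volumes (TR %.2g s), %d retained\n",
              nrow(x$data), ncol(x$data), x$tr, sum(x$censor_mask)))
  cat(sprintf("  subject %s, genotype %s, age %s months, scan %s\n",
              x$subject_id, x$genotype, x$age_months, x$scan_id))
  invisible(x)
}

# Target block correlation matrix in r-space for one scan. Effects are
# additive in z-space (arctanh), then back-transformed, so entries always
# stay in (-1, 1).
block_correlation <- function(config, genotype, age, subject_z,
                              max_neg = Inf) {
  n <- config$n_rois
  assign <- as.integer(system_assignment(n, config$n_systems))
  same <- outer(assign, assign, "==")
  z <- matrix(atanh(config$between_system_r), n, n)
  z[same] <- atanh(config$within_system_r)
  if (genotype == "5xFAD" && config$genotype_effect != 0 &&
      age %in% config$effect_ages) {
    for (b in config$effect_blocks) {
      sel_i <- assign == b[1]
      sel_j <- assign == b[2]
      z[sel_i, sel_j] <- z[sel_i, sel_j] + config$genotype_effect
      if (b[1] != b[2])
        z[sel_j, sel_i] <- z[sel_j, sel_i] + config$genotype_effect
    }
  }
  z <- z + subject_z
  r <- tanh(z)
  diag(r) <- 1
  nearest_correlation(r, max_neg = max_neg)
}

# Eigenvalue clipping at 1e-8 followed by re-scaling to unit diagonal.
# Rejects targets whose indefiniteness is too severe to be a plausible
# block construction (repair would distort the requested structure).
nearest_correlation <- function(r, clip = 1e-8, max_neg = 0.05) {
  e <- eigen(r, symmetric = TRUE)
  if (min(e$values) >= clip) return(r)
  if (min(e$values) < -max_neg * max(e$values))
    stop("implied block correlation matrix is far from positive definite; ",
         "lower |within_system_r| / |between_system_r| or the effect size")
  vals <- pmax(e$values, clip)
  m <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(m))
  m <- m / tcrossprod(d)
  diag(m) <- 1
  (m + t(m)) / 2
}

#' Generate a synthetic scan set
#'
#' Draws, for every subject x age x scan, an ROI x time matrix from a
#' multivariate normal whose correlation matrix has the configured
#' within/between-system block values, shifted in Fisher-z space by the
#' genotype effect (on the designated blocks and ages) and by a
#' subject-level random intercept, then back-transformed. Subjects are
#' cross-sectional: each subject belongs to one genotype x age cell.
#'
#' @param config a [synth_config()].
#' @return A list of [scan_ts()] objects with a `manifest` attribute
#'   (data.frame: subject, genotype, age_months, scan_id, tr).
#' @examples
#' scans <- gen_scan_set(synth_config(n_subjects_per_group = 2, n_rois = 8,
#'                                    n_timepoints_per_scan = 60,
#'                                    scans_per_subject = 2, seed = 7))
#' length(scans)
#' @export
gen_scan_set <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  # validate the configured (noise-free) block targets up front: a config
  # whose implied correlation matrix is severely indefinite is rejected;
  # per-subject random perturbations are later repaired by clipping only
  for (gt in c("5xFAD", "WT")) for (age in config$ages)
    block_correlation(config, gt, age, 0, max_neg = 0.05)
  with_seed(child_seed(config$seed, "scans"), {
    rois <- names(system_assignment(config$n_rois, config$n_systems))
    scans <- list()
    manifest <- list()
    for (gt in c("5xFAD", "WT")) for (age in config$ages) {
      for (s in seq_len(config$n_subjects_per_group)) {
        subj <- sprintf("%s_m%g_%02d", gt, age, s)
        u <- if (config$subject_sd > 0) rnorm(1, 0, config$subject_sd) else 0
        r_target <- block_correlation(config, gt, age, u)
        cd <- chol(r_target)
        for (k in seq_len(config$scans_per_subject)) {
          x <- matrix(rnorm(config$n_timepoints_per_scan * config$n_rois),
                      config$n_timepoints_per_scan, config$n_rois) %*% cd
          sid <- sprintf("%s_scan%d", subj, k)
          scans[[sid]] <- scan_ts(t(x), rois, config$tr_seconds,
                                  subject_id = subj, genotype = gt,
                                  age_months = age, scan_id = sid)
          manifest[[sid]] <- data.frame(subject = subj, genotype = gt,
                                        age_months = age, scan_id = sid,
                                        tr = config$tr_seconds)
        }
      }
    }
    manifest <- do.call(rbind, manifest)
    rownames(manifest) <- NULL
    attr(scans, "manifest") <- manifest
    scans
  })
}
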