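#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the synthetic data generators into one validated
#' list. Defaults emulate the study design the pipeline targets: two
#' genotypes (5xFAD, WT) at four cross-sectional ages (1.5, 2, 4, 6 months),
#' 4 echo-planar scans per imaging session at TR = 1.5 s, a block-community
#' ROI correlation structure organised into seven anatomical systems, and a
#' 23-analyte lognormal cytokine panel with three planted age-covarying
#' analytes in the disease genotype.
#'
#' Genotype and subject effects are applied additively in Fisher-z space and
#' back-transformed, so generated matrices are always valid correlation
#' matrices. The genotype effect is applied to the system-pair blocks in
#' `effect_blocks` at the ages in `effect_ages` only (default: the
#' intra-hippocampus block at 4 and 6 months, mimicking late-stage
#' suppression of intra-hippocampal connectivity).
#'
#' @param n_subjects_per_group subjects per genotype x age cell.
#' @param ages numeric vector of ages in months.
#' @param n_rois number of ROIs (divided evenly over systems as far as
#'   possible).
#' @param n_systems number of anatomical systems (default 7).
#' @param n_timepoints_per_scan volumes per scan.
#' @param scans_per_subject EPI scans per imaging session.
#' @param tr_seconds repetition time in seconds.
#' @param within_system_r,between_system_r target Pearson correlations for
#'   within- and between-system ROI pairs, each in (-1, 1).
#' @param genotype_effect additive change in z-space applied to
#'   `effect_blocks` at `effect_ages` in the 5xFAD group. Negative values
#'   model connectivity suppression.
#' @param effect_blocks list of length-2 integer vectors naming system-pair
#'   blocks (by system index) that receive the genotype effect.
#' @param effect_ages ages (months) at which the genotype effect applies.
#' @param subject_sd SD of the subject-level random intercept in z-space.
#' @param n_cytokines number of analytes in the panel (default 23).
#' @param planted_age_slopes numeric vector (recycled/padded to
#'   `n_cytokines`) of per-analyte log-concentration slopes vs age, in units
#'   of the lognormal noise SD per month, applied in `planted_genotype`.
#' @param planted_genotype genotype receiving the planted slopes.
#' @param cytokine_sdlog SD of log-concentration noise.
#' @param detection_floor,detection_ceiling assay detection limits in pg/mL.
#' @param spike_rate per-volume probability of a motion spike.
#' @param seed integer seed; every generator derives its randomness from it.
#'
#' @return An object of class `synth_config` (a validated named list).
#' @examples
#' cfg <- synth_config(n_subjects_per_group = 4, n_rois = 14,
#'                     n_timepoints_per_scan = 120, seed = 1)
#' @export
synth_config <- function(n_subjects_per_group = 16,
                         ages = c(1.5, 2, 4, 6),
                         n_rois = 28,
                         n_systems = 7,
                         n_timepoints_per_scan = 300,
                         scans_per_subject = 4,
                         tr_seconds = 1.5,
                         within_system_r = 0.6,
                         between_system_r = 0.2,
                         genotype_effect = -0.3,
                         effect_blocks = NULL,
                         effect_ages = c(4, 6),
                         subject_sd = 0.1,
                         n_cytokines = 23,
                         planted_age_slopes = c(0.5, 0.5, 0.5),
                         planted_genotype = "5xFAD",
                         cytokine_sdlog = 0.5,
                         detection_floor = 2,
                         detection_ceiling = 20000,
                         spike_rate = 0.01,
                         seed = 1L) {
  stopifnot(n_subjects_per_group >= 1, n_rois >= 1, n_systems >= 1,
            n_timepoints_per_scan >= 2, scans_per_subject >= 1,
            tr_seconds > 0, n_cytokines >= 1, length(ages) >= 1)
  if (abs(within_system_r) >= 1 || abs(between_system_r) >= 1)
    stop("within_system_r and between_system_r must lie in (-1, 1)")
  if (detection_floor >= detection_ceiling)
    stop("detection_floor must be below detection_ceiling")
  if (spike_rate < 0 || spike_rate > 1)
    stop("spike_rate must lie in [0, 1]")
  if (n_systems > n_rois)
    stop("n_systems cannot exceed n_rois")
  slopes <- rep(0, n_cytokines)
  slopes[seq_len(min(length(planted_age_slopes), n_cytokines))] <-
    planted_age_slopes[seq_len(min(length(planted_age_slopes), n_cytokines))]
  # default perturbed block: the hippocampus system when present (system 4
  # of the default seven), else the last system's intra block
  if (is.null(effect_blocks))
    effect_blocks <- list(rep(min(4L, n_systems), 2))
  bad <- vapply(effect_blocks, function(b)
    length(b) != 2 || any(b < 1) || any(b > n_systems), logical(1))
  if (any(bad)) stop("effect_blocks must be pairs of system indices")
  cfg <- list(
    n_subjects_per_group = as.integer(n_subjects_per_group),
    ages = as.numeric(ages),
    n_rois = as.integer(n_rois),
    n_systems = as.integer(n_systems),
    n_timepoints_per_scan = as.integer(n_timepoints_per_scan),
    scans_per_subject = as.integer(scans_per_subject),
    tr_seconds = tr_seconds,
    within_system_r = within_system_r,
    between_system_r = between_system_r,
    genotype_effect = genotype_effect,
    effect_blocks = lapply(effect_blocks, as.integer),
    effect_ages = as.numeric(effect_ages),
    subject_sd = subject_sd,
    n_cytokines = as.integer(n_cytokines),
    planted_age_slopes = slopes,
    planted_genotype = planted_genotype,
    cytokine_sdlog = cytokine_sdlog,
    detection_floor = detection_floor,
    detection_ceiling = detection_ceiling,
    spike_rate = spike_rate,
    seed = as.integer(seed)
  )
  class(cfg) <- "synth_config"
  cfg
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  %d subjects/genotype/age; ages: %s months\n",
              x$n_subjects_per_group, paste(x$ages, collapse = ", ")))
  cat(sprintf("  %d ROIs in %d systems; %d scans x %d volumes, TR %.2g s\n",
              x$n_rois, x$n_systems, x$scans_per_subject,
              x$n_timepoints_per_scan, x$tr_seconds))
  cat(sprintf("  within/between-system r: %.2f / %.2f; genotype effect %.2f z\n",
              x$within_system_r, x$between_system_r, x$genotype_effect))
  cat(sprintf("  %d cytokines (%d planted); seed %d\n",
              x$n_cytokines, sum(x$planted_age_slopes != 0), x$seed))
  invisible(x)
}

# ROI -> system assignment: splits 1:n_rois into n_systems contiguous groups.
# Returns a factor of system names; names() are ROI labels.
system_assignment <- function(n_rois, n_systems) {
  sys_names <- default_system_names(n_systems)
  idx <- sort(rep_len(seq_len(n_systems), n_rois))
  rois <- sprintf("ROI%02d", seq_len(n_rois))
  out <- factor(sys_names[idx], levels = sys_names)
  names(out) <- rois
  out
}

default_system_names <- function(n_systems) {
  base <- c("SensorimotorCortex", "HeteromodalCortex", "OlfactoryCortex",
            "Hippocampus", "StriatumPallidum", "Thalamus", "Hypothalamus")
  if (n_systems <= length(base)) base[seq_len(n_systems)]
  else c(base, sprintf("System%02d", seq_len(n_systems - length(base))))
}

#' System definition for a configuration
#'
#' @param config a `synth_config`.
#' @return Named list mapping system name to the ROI names it contains.
#' @export
system_definition <- function(config) {
  a <- system_assignment(config$n_rois, config$n_systems)
  split(names(a), a)
}

# Run code under a seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Derive a child seed from a base seed and a stream label; keeps results
# reproducible while decoupling the generators from one another.
child_seed <- function(seed, stream) {
  offs <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 1009 + offs) %% .Machine$integer.max)
}
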