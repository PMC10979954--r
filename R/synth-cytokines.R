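#' Generate a synthetic cytokine panel
#'
#' Long-format lognormal concentrations (pg/mL) for every subject x region x
#' analyte. Planted analytes carry a log-concentration slope vs age (months)
#' in the designated genotype: slope `s` in `planted_age_slopes` means the
#' log-concentration rises by `s * cytokine_sdlog` per month, i.e. `s` noise
#' SDs per month. Values outside the detection limits are flagged
#' (`below_limit`, `above_limit`) but not censored; see [censor_panel()].
#'
#' @param config a [synth_config()].
#' @param regions region names to simulate (default: the nine dissected
#'   regions of the study design).
#' @return A `cytokine_panel`: data.frame with columns subject, genotype,
#'   age_months, region, analyte, concentration_pg_per_ml, below_limit,
#'   above_limit. Attributes: `planted` (analyte names with nonzero planted
#'   slope) and `limits` (per-analyte standard-curve min/max).
#' @examples
#' panel <- gen_cytokine_panel(synth_config(n_subjects_per_group = 3, seed = 2),
#'                             regions = "Parietal")
#' head(panel)
#' @export
gen_cytokine_panel <- function(config,
                               regions = c("Frontal", "Parietal", "Temporal",
                                           "Occipital", "Hippocampus",
                                           "Striatum", "Thalamus",
                                           "Hypothalamus", "Cerebellum")) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(child_seed(config$seed, "cytokines"), {
    analytes <- sprintf("CYT%02d", seq_len(config$n_cytokines))
    base_meanlog <- runif(config$n_cytokines, log(20), log(200))
    slopes <- config$planted_age_slopes * config$cytokine_sdlog
    rows <- list()
    for (gt in c("5xFAD", "WT")) for (age in config$ages) {
      for (s in seq_len(config$n_subjects_per_group)) {
        subj <- sprintf("%s_m%g_%02d", gt, age, s)
        for (rg in regions) {
          mu <- base_meanlog
          if (gt == config$planted_genotype) mu <- mu + slopes * age
          conc <- exp(rnorm(config$n_cytokines, mu, config$cytokine_sdlog))
          rows[[length(rows) + 1]] <- data.frame(
            subject = subj, genotype = gt, age_months = age, region = rg,
            analyte = analytes, concentration_pg_per_ml = conc,
            below_limit = conc < config$detection_floor,
            above_limit = conc > config$detection_ceiling)
        }
      }
    }
    panel <- do.call(rbind, rows)
    rownames(panel) <- NULL
    class(panel) <- c("cytokine_panel", "data.frame")
    attr(panel, "planted") <- analytes[config$planted_age_slopes != 0]
    attr(panel, "limits") <- data.frame(
      analyte = analytes,
      lower_pg_ml = config$detection_floor,
      upper_pg_ml = config$detection_ceiling)
    panel
  })
}
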