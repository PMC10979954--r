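#' Censor concentrations at the standard-curve limits
#'
#' Values below an analyte's lower curve limit are set to 0 pg/mL; values
#' above the upper limit are set to the curve maximum. Idempotent.
#'
#' @param panel long-format cytokine data.frame (columns analyte and
#'   concentration_pg_per_ml, plus any metadata), e.g. from
#'   [gen_cytokine_panel()].
#' @param limits data.frame with columns analyte, lower_pg_ml, upper_pg_ml;
#'   defaults to the panel's `limits` attribute.
#' @return The panel with censored concentrations and updated
#'   `below_limit` / `above_limit` flags.
#' @export
censor_panel <- function(panel, limits = attr(panel, "limits")) {
  stopifnot(all(c("analyte", "concentration_pg_per_ml") %in% names(panel)))
  if (is.null(limits))
    stop("no curve limits supplied and none attached to the panel")
  stopifnot(all(c("analyte", "lower_pg_ml", "upper_pg_ml") %in% names(limits)))
  miss <- setdiff(unique(panel$analyte), limits$analyte)
  if (length(miss))
    stop("missing curve limits for analyte(s): ", paste(miss, collapse = ", "))
  i <- match(panel$analyte, limits$analyte)
  lower <- limits$lower_pg_ml[i]
  upper <- limits$upper_pg_ml[i]
  conc <- panel$concentration_pg_per_ml
  below <- conc < lower
  above <- conc > upper
  conc[below] <- 0
  conc[above] <- upper[above]
  panel$concentration_pg_per_ml <- conc
  panel$below_limit <- below & !above
  panel$above_limit <- above
  attr(panel, "limits") <- limits
  panel
}

#' Analyte retention with a group-bias exception
#'
#' Within each region stratum, an analyte is retained if it is nonzero
#' (above background after censoring) in at least half of the subjects, OR
#' if its nonzero values are biased toward one genotype (one-sided Fisher
#' exact test on the genotype x nonzero 2 x 2 table, p < `bias_p`).
#'
#' @param panel censored long-format panel (see [censor_panel()]).
#' @param groups column name holding the group labels for the bias test.
#' @param bias_p Fisher-exact threshold for the bias exception.
#' @return list with `panel` (records of retained analytes only) and
#'   `audit` (data.frame: region, analyte, n_subjects, n_nonzero,
#'   frac_nonzero, bias_p, retained, rule — "half", "bias" or "dropped").
#' @export
retain_analytes <- function(panel, groups = "genotype", bias_p = 0.10) {
  stopifnot(all(c("subject", "region", "analyte",
                  "concentration_pg_per_ml", groups) %in% names(panel)))
  audit <- list()
  for (rg in unique(panel$region)) {
    sub <- panel[panel$region == rg, ]
    subjects <- unique(sub[, c("subject", groups)])
    if (any(table(subjects[[groups]]) < 2))
      stop("need >= 2 subjects per group in region ", rg)
    for (an in unique(sub$analyte)) {
      rec <- sub[sub$analyte == an, ]
      nz_subj <- unique(rec$subject[rec$concentration_pg_per_ml > 0])
      n <- nrow(subjects)
      k <- length(nz_subj)
      pbias <- NA_real_
      rule <- "dropped"
      if (k >= n / 2) {
        rule <- "half"
      } else if (k > 0) {
        nz <- factor(subjects$subject %in% nz_subj, levels = c(TRUE, FALSE))
        tab <- table(factor(subjects[[groups]]), nz)
        # one-sided in each direction; bias toward either group counts
        p1 <- fisher.test(tab, alternative = "greater")$p.value
        p2 <- fisher.test(tab, alternative = "less")$p.value
        pbias <- min(p1, p2)
        if (pbias < bias_p) rule <- "bias"
      }
      audit[[length(audit) + 1]] <- data.frame(
        region = rg, analyte = an, n_subjects = n, n_nonzero = k,
        frac_nonzero = k / n, bias_p = pbias,
        retained = rule != "dropped", rule = rule)
    }
  }
  audit <- do.call(rbind, audit)
  rownames(audit) <- NULL
  keep_key <- paste(audit$region, audit$analyte)[audit$retained]
  kept <- panel[paste(panel$region, panel$analyte) %in% keep_key, ]
  list(panel = kept, audit = audit)
}

#' Wide subjects-by-analytes matrix for one modelling stratum
#'
#' Extracts the cleaned concentrations for one region and genotype group as
#' a numeric matrix (rows = subjects, columns = analytes) together with the
#' age response, ready for [pls_fit()] / [cross_validate()].
#'
#' @param panel cleaned long-format panel.
#' @param region region to extract.
#' @param genotype genotype group to extract.
#' @return list with `X` (subjects x analytes), `y` (age in months),
#'   `subjects`.
#' @export
panel_to_design <- function(panel, region, genotype) {
  sub <- panel[panel$region == region & panel$genotype == genotype, ]
  if (!nrow(sub)) stop("no records for that region/genotype")
  analytes <- sort(unique(sub$analyte))
  subjects <- unique(sub$subject)
  X <- matrix(NA_real_, length(subjects), length(analytes),
              dimnames = list(subjects, analytes))
  X[cbind(match(sub$subject, subjects), match(sub$analyte, analytes))] <-
    sub$concentration_pg_per_ml
  if (anyNA(X)) stop("panel is not complete for that stratum")
  age <- sub$age_months[match(subjects, sub$subject)]
  list(X = X, y = age, subjects = subjects)
}
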