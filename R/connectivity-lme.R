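#' Long edge table from connectivity matrices
#'
#' Stacks the upper triangles of per-scan connectivity matrices into a long
#' data frame with Fisher-z connectivity as the response, ready for
#' [fit_edgewise_lme()].
#'
#' @param matrices list of [conn_matrix()] with subject/genotype/age
#'   metadata (as produced by [roi_correlation()]).
#' @return data.frame: roi_i, roi_j, z, subject, genotype, age_months,
#'   scan_id.
#' @export
edge_table <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  rois <- matrices[[1]]$roi_names
  ut <- upper.tri(matrices[[1]]$r)
  ii <- row(matrices[[1]]$r)[ut]
  jj <- col(matrices[[1]]$r)[ut]
  do.call(rbind, lapply(matrices, function(m) {
    if (!identical(m$roi_names, rois)) stop("matrices must share one ROI set")
    data.frame(roi_i = rois[ii], roi_j = rois[jj],
               z = fisher_z(m$r[ut]),
               subject = m$metadata$subject %||% NA_character_,
               genotype = m$metadata$genotype %||% NA_character_,
               age_months = m$metadata$age_months %||% NA_real_,
               scan_id = m$metadata$scan_id %||% NA_character_)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Edgewise mixed-effects genotype contrast
#'
#' Fits, per edge, a linear mixed model of Fisher-z connectivity with a
#' subject random intercept (REML), so repeated scans per subject enter as
#' repeated rows. Per-timepoint analyses use genotype as the sole fixed
#' effect (`z ~ genotype + (1 | subject)`); longitudinal analyses add age
#' and the genotype x age interaction. The coefficient of interest is
#' tested with a two-tailed Wald t-test on residual degrees of freedom.
#' Singular fits fall back to OLS with a flag.
#'
#' @param edges long edge table (see [edge_table()]), typically restricted
#'   to one age for per-timepoint contrasts.
#' @param design "genotype" (per-timepoint) or "genotype_by_age"
#'   (longitudinal: genotype * age fixed effects).
#' @param coef_of_interest fixed-effect name to test; defaults to the
#'   genotype main effect ("genotype5xFAD"; WT is the reference level).
#' @param alpha significance level for the FDR mask.
#' @return An `edge_stats` data.frame: roi_i, roi_j, beta, se, t, df, p, q,
#'   sig, ols_fallback.
#' @export
fit_edgewise_lme <- function(edges, design = c("genotype", "genotype_by_age"),
                             coef_of_interest = "genotype5xFAD",
                             alpha = 0.05) {
  design <- match.arg(design)
  stopifnot(all(c("roi_i", "roi_j", "z", "subject", "genotype") %in%
                  names(edges)))
  edges$genotype <- factor(edges$genotype, levels = c("WT", "5xFAD"))
  if (any(table(unique(edges[c("subject", "genotype")])$genotype) < 2))
    stop("need >= 2 subjects per genotype")
  if (design == "genotype_by_age" && !"age_months" %in% names(edges))
    stop("longitudinal design requires age_months")
  fml <- if (design == "genotype") z ~ genotype + (1 | subject)
         else z ~ genotype * age_months + (1 | subject)
  key <- paste(edges$roi_i, edges$roi_j, sep = "\r")
  parts <- split(edges, factor(key, levels = unique(key)))
  rows <- lapply(parts, function(d) {
    fit_one_edge(d, fml, coef_of_interest)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- fdr_correct(out$p)
  out$sig <- binarize(out$p, alpha)
  class(out) <- c("edge_stats", "data.frame")
  attr(out, "alpha") <- alpha
  attr(out, "design") <- design
  out
}

fit_one_edge <- function(d, fml, coef_name) {
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  fit <- tryCatch(suppressMessages(suppressWarnings(
    lme4::lmer(fml, data = d, REML = TRUE, control = ctrl))),
    error = function(e) NULL)   # e.g. one scan per subject
  fallback <- is.null(fit) || lme4::isSingular(fit, tol = 1e-5)
  if (fallback) {
    ols <- lm(lme4::nobars(fml), data = d)
    cf <- summary(ols)$coefficients
    if (!coef_name %in% rownames(cf)) stop("unknown coefficient: ", coef_name)
    beta <- cf[coef_name, 1]; se <- cf[coef_name, 2]
    nfix <- nrow(cf)
  } else {
    cf <- lme4::fixef(fit)
    if (!coef_name %in% names(cf)) stop("unknown coefficient: ", coef_name)
    vc <- as.matrix(vcov(fit))
    beta <- cf[[coef_name]]
    se <- sqrt(vc[coef_name, coef_name])
    nfix <- length(cf)
  }
  # residual df at the subject stratum: genotype (and age, in this
  # cross-sectional design) vary between subjects, so the correct error
  # stratum for the Wald t is subjects, not scan rows
  dfres <- max(length(unique(d$subject)) - nfix, 1)
  tval <- beta / se
  data.frame(roi_i = d$roi_i[1], roi_j = d$roi_j[1], beta = beta, se = se,
             t = tval, df = dfres, p = 2 * pt(-abs(tval), dfres),
             ols_fallback = fallback)
}

#' @export
print.edge_stats <- function(x, ...) {
  cat(sprintf("Edgewise contrast (%s): %d edges, %d with p < %.3g (%d FDR), %d OLS fallbacks\n",
              attr(x, "design") %||% "genotype", nrow(x), sum(x$sig),
              attr(x, "alpha") %||% 0.05,
              sum(x$q < (attr(x, "alpha") %||% 0.05)), sum(x$ols_fallback)))
  NextMethod()
  invisible(x)
}

#' Symmetric matrix view of edge statistics
#'
#' @param stats an `edge_stats` data.frame.
#' @param value column to spread ("p", "q", "beta", "sig").
#' @param roi_names ROI ordering; defaults to order of appearance.
#' @return Symmetric matrix (diagonal NA for p/q, 0 otherwise).
#' @export
edge_stats_matrix <- function(stats, value = "p", roi_names = NULL) {
  stopifnot(value %in% names(stats))
  if (is.null(roi_names)) roi_names <- unique(c(stats$roi_i, stats$roi_j))
  n <- length(roi_names)
  m <- matrix(if (value %in% c("p", "q")) NA_real_ else 0, n, n,
              dimnames = list(roi_names, roi_names))
  i <- match(stats$roi_i, roi_names)
  j <- match(stats$roi_j, roi_names)
  m[cbind(i, j)] <- m[cbind(j, i)] <- as.numeric(stats[[value]])
  m
}

#' Two-way ANOVA on subject-mean values
#'
#' Fixed-effects genotype x timepoint ANOVA on subject means (used for
#' global graph metrics and other per-subject summaries), plus a two-tailed
#' Welch t-test between any two requested cells.
#'
#' @param df data.frame with columns `value`, `genotype`, `age_months`,
#'   `subject` (one or more rows per subject; rows are averaged by subject
#'   first).
#' @return list with `anova` (the genotype x age table) and `cell_means`.
#' @export
metric_anova <- function(df) {
  stopifnot(all(c("value", "genotype", "age_months", "subject") %in% names(df)))
  agg <- stats::aggregate(value ~ subject + genotype + age_months, df, mean)
  agg$genotype <- factor(agg$genotype)
  agg$age <- factor(agg$age_months)
  fit <- aov(value ~ genotype * age, data = agg)
  tab <- summary(fit)[[1]]
  rownames(tab) <- trimws(rownames(tab))
  list(anova = tab,
       cell_means = stats::aggregate(value ~ genotype + age, agg, mean),
       subject_means = agg)
}
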