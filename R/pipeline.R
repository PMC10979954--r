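#' Preprocess one scan to a connectivity matrix
#'
#' The fixed preprocessing order: motion scrubbing (0.125 mm rule with
#' neighbour censoring and the 90% retention verdict), nuisance GLM
#' (WM-CSF signal + six motion parameters + intercept), band-pass
#' 0.01--0.1 Hz (censored gaps interpolated, then re-excluded), pairwise
#' ROI correlation over retained volumes. Spatial smoothing operates on
#' image planes and is not part of the ROI-series path.
#'
#' @param scan a [scan_ts()].
#' @param trace a [motion_trace()] for the scan (same volume count).
#' @param wmcsf optional numeric WM-CSF mean-signal regressor per volume;
#'   defaults to zero-mean noise-free absence (dropped).
#' @param threshold scrub threshold in mm.
#' @param band band-pass cutoffs in Hz.
#' @return A [conn_matrix()], or NULL when the scan fails the 90% retention
#'   rule.
#' @export
preprocess_scan <- function(scan, trace, wmcsf = NULL, threshold = 0.125,
                            band = c(0.01, 0.1)) {
  stopifnot(inherits(scan, "scan_ts"), inherits(trace, "motion_trace"))
  if (length(trace$displacement) != ncol(scan$data))
    stop("motion trace length must equal the scan volume count")
  sc <- scrub_volumes(trace, threshold, prior_mask = scan$censor_mask)
  if (!sc$scan_kept) return(NULL)
  scan$censor_mask <- sc$censor_mask
  reg <- cbind(trace$translations, trace$rotations)
  colnames(reg) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  if (!is.null(wmcsf)) reg <- cbind(wmcsf = wmcsf, reg)
  # synthetic motion regressors can be (near-)constant; keep only columns
  # with usable variance so the GLM design stays full rank
  keepcol <- apply(reg[scan$censor_mask, , drop = FALSE], 2,
                   function(c) max(c) - min(c) > 1e-10)
  scan <- nuisance_regress(scan, reg[, keepcol, drop = FALSE])
  scan <- bandpass(scan, band[1], band[2])
  roi_correlation(scan)
}

#' Run the full synthetic-study pipeline
#'
#' Generates a synthetic study from `config`, then runs every analysis
#' stage: per-scan preprocessing to connectivity matrices; group means,
#' system aggregation and z-space difference matrices per age; edgewise
#' mixed-effects genotype contrasts with BH-FDR per age; per-scan graph
#' metrics with subject-then-group averaging, a two-way genotype x age
#' ANOVA on the global metrics, and hub scores on group-mean graphs;
#' cytokine censoring, retention and, per region x genotype, an
#' orthogonalized PLSR of the panel against age with cross-validated LV
#' selection, permutation significance and a VIP > 1 signature.
#'
#' @param config a [synth_config()].
#' @param out_dir optional directory: when given, all artifacts are written
#'   as TSV/CSV/JSON files.
#' @param pls_regions regions to model (default "Parietal", "Frontal",
#'   "Temporal").
#' @param cv_repeats,n_perm,perm_cv_repeats sizes of the cross-validation
#'   and permutation computations.
#' @param alpha edgewise significance level.
#' @return list with `manifest`, `conn` (per-scan matrices), `group_means`,
#'   `system_matrices`, `difference` (per age, z units), `edge_stats` (per
#'   age), `metrics` (per-scan global metric table), `metric_anova` (per
#'   metric), `hubs` (per genotype x age), `audit` (cytokine retention),
#'   `pls` (per region x genotype: cv, permutation, signature).
#' @export
run_pipeline <- function(config = synth_config(), out_dir = NULL,
                         pls_regions = c("Parietal", "Frontal", "Temporal"),
                         cv_repeats = 100, n_perm = 1000,
                         perm_cv_repeats = 10, alpha = 0.05) {
  stopifnot(inherits(config, "synth_config"))
  scans <- gen_scan_set(config)
  manifest <- attr(scans, "manifest")
  systems <- system_definition(config)

  # --- preprocessing: one motion trace per scan, derived reproducibly ----
  conn <- list()
  for (sid in names(scans)) {
    cfg_i <- config
    cfg_i$seed <- child_seed(config$seed, paste0("trace_", sid))
    trace <- gen_motion_trace(cfg_i)
    cm <- preprocess_scan(scans[[sid]], trace)
    if (!is.null(cm)) conn[[sid]] <- cm
  }
  manifest <- manifest[manifest$scan_id %in% names(conn), ]

  # --- connectivity: group means, systems, differences, edgewise LME -----
  meta <- function(cm, f) cm$metadata[[f]]
  group_means <- list(); system_mats <- list(); diffs <- list()
  stats_by_age <- list()
  for (age in config$ages) {
    sel <- vapply(conn, function(cm) meta(cm, "age_months") == age, logical(1))
    by_gt <- split(conn[sel], vapply(conn[sel], meta, "", f = "genotype"))
    gm <- lapply(by_gt, group_mean_matrix)
    for (gt in names(gm)) {
      gm[[gt]]$metadata$age_months <- age
      key <- sprintf("%s_m%g", gt, age)
      group_means[[key]] <- gm[[gt]]
      system_mats[[key]] <- aggregate_system(gm[[gt]], systems)
    }
    diffs[[sprintf("m%g", age)]] <-
      difference_matrix(gm[["5xFAD"]], gm[["WT"]])
    stats_by_age[[sprintf("m%g", age)]] <-
      fit_edgewise_lme(edge_table(conn[sel]), design = "genotype",
                       alpha = alpha)
  }

  # --- graph metrics: per scan -> subject -> group; hubs on group means --
  met_rows <- lapply(conn, function(cm) {
    g <- graph_metrics(to_weighted_graph(cm))$global
    data.frame(subject = meta(cm, "subject"), genotype = meta(cm, "genotype"),
               age_months = meta(cm, "age_months"),
               scan_id = meta(cm, "scan_id"), strength = g$mean_s,
               clustering = g$mean_C, char_path = g$L_w_finite,
               efficiency = g$E_w, assortativity = g$r_w)
  })
  metrics <- do.call(rbind, met_rows)
  rownames(metrics) <- NULL
  manova <- lapply(c("strength", "clustering", "char_path", "efficiency",
                     "assortativity"), function(m) {
    df <- metrics[, c("subject", "genotype", "age_months")]
    df$value <- metrics[[m]]
    metric_anova(df[complete.cases(df), ])
  })
  names(manova) <- c("strength", "clustering", "char_path", "efficiency",
                     "assortativity")
  hubs <- lapply(group_means, function(gm) hub_scores(to_weighted_graph(gm)))

  # --- cytokines: clean then model per region x genotype -----------------
  panel <- gen_cytokine_panel(config)
  panel <- censor_panel(panel)
  ret <- retain_analytes(panel[panel$region %in% pls_regions, ])
  pls <- list()
  for (rg in pls_regions) for (gt in c("5xFAD", "WT")) {
    des <- panel_to_design(ret$panel, rg, gt)
    cv <- cross_validate(des$X, des$y, repeats = cv_repeats,
                         seed = child_seed(config$seed,
                                           paste0("cv_", rg, gt)))
    model <- orthogonalize(pls_fit(des$X, des$y, ncomp = cv$chosen_A))
    perm <- permutation_test(des$X, des$y, cv$chosen_A, n_perm = n_perm,
                             cv_repeats = perm_cv_repeats,
                             seed = child_seed(config$seed,
                                               paste0("perm_", rg, gt)))
    pls[[paste(rg, gt, sep = "_")]] <-
      list(region = rg, genotype = gt, n = nrow(des$X), cv = cv,
           model = model, permutation = perm,
           signature = signature_report(model))
  }

  out <- list(manifest = manifest, conn = conn, group_means = group_means,
              system_matrices = system_mats, difference = diffs,
              edge_stats = stats_by_age, metrics = metrics,
              metric_anova = manova, hubs = hubs, audit = ret$audit,
              pls = pls, systems = systems, config = config)
  if (!is.null(out_dir)) write_pipeline(out, out_dir)
  invisible(out)
}

# Serialize every pipeline artifact as deterministic plain text.
write_pipeline <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(res$manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  write_systems(res$systems, file.path(dir, "systems.json"))
  cdir <- file.path(dir, "connectivity")
  dir.create(cdir, showWarnings = FALSE)
  for (nm in names(res$conn))
    write_conn_matrix(res$conn[[nm]], file.path(cdir, paste0(nm, ".tsv")))
  for (nm in names(res$group_means))
    write_conn_matrix(res$group_means[[nm]],
                      file.path(dir, paste0("groupmean_", nm, ".tsv")))
  for (nm in names(res$system_matrices))
    write_conn_matrix(res$system_matrices[[nm]],
                      file.path(dir, paste0("systems_", nm, ".tsv")))
  for (nm in names(res$difference))
    write.table(format(res$difference[[nm]], digits = 17, trim = TRUE),
                file.path(dir, paste0("difference_", nm, ".tsv")),
                sep = "\t", quote = FALSE)
  for (nm in names(res$edge_stats))
    write.csv(res$edge_stats[[nm]],
              file.path(dir, paste0("edgestats_", nm, ".csv")),
              row.names = FALSE)
  write.csv(res$metrics, file.path(dir, "graph_metrics.csv"),
            row.names = FALSE)
  for (nm in names(res$hubs))
    write.csv(res$hubs[[nm]], file.path(dir, paste0("hubs_", nm, ".csv")),
              row.names = FALSE)
  write.csv(res$audit, file.path(dir, "cytokine_audit.csv"),
            row.names = FALSE)
  for (nm in names(res$pls)) {
    p <- res$pls[[nm]]
    jsonlite::write_json(
      list(region = p$region, genotype = p$genotype, n = p$n,
           chosen_A = p$cv$chosen_A, k = p$cv$k,
           mean_cv = as.list(setNames(p$cv$mean,
                                      paste0("A", p$cv$candidates))),
           rmsecv = p$permutation$x_model, Z = p$permutation$Z,
           p = p$permutation$p,
           vip = as.list(setNames(p$model$vip, p$model$var_names))),
      file.path(dir, paste0("pls_", nm, ".json")),
      auto_unbox = TRUE, digits = NA)
    write.csv(p$signature, file.path(dir, paste0("signature_", nm, ".csv")),
              row.names = FALSE)
  }
  invisible(dir)
}
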