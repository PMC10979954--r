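test_that("scan generator reproduces the configured block correlations", {
  cfg <- synth_config(n_subjects_per_group = 2, n_rois = 8, n_systems = 4,
                      ages = 4, scans_per_subject = 1,
                      n_timepoints_per_scan = 300,
                      within_system_r = 0.6, between_system_r = 0.2,
                      genotype_effect = 0, subject_sd = 0, seed = 10)
  scans <- gen_scan_set(cfg)
  assign <- rep(1:4, each = 2)
  same <- outer(assign, assign, "==")
  within <- c(); between <- c()
  for (s in scans) {
    r <- cor(t(s$data))
    within <- c(within, r[same & upper.tri(r)])
    between <- c(between, r[!same & upper.tri(r)])
  }
  # Monte-Carlo check against the generating values (300 timepoints,
  # 16 within / 96 between values: SE of the mean ~ 0.01)
  expect_equal(mean(within), 0.6, tolerance = 0.05)
  expect_equal(mean(between), 0.2, tolerance = 0.05)
  expect_gt(mean(within) - mean(between), 0)
})

test_that("single-ROI scans degenerate to a 1x1 unit correlation", {
  cfg <- synth_config(n_subjects_per_group = 1, n_rois = 1, n_systems = 1,
                      ages = 4, scans_per_subject = 1,
                      n_timepoints_per_scan = 50, seed = 1)
  scans <- gen_scan_set(cfg)
  expect_equal(nrow(scans[[1]]$data), 1)
  cm <- roi_correlation(scans[[1]])
  expect_equal(unname(cm$r), matrix(1, 1, 1))
})

test_that("all generators are bit-reproducible under a fixed seed", {
  cfg <- synth_config(n_subjects_per_group = 2, n_rois = 6, n_systems = 3,
                      ages = c(2, 4), scans_per_subject = 2,
                      n_timepoints_per_scan = 40, seed = 99)
  expect_identical(gen_scan_set(cfg), gen_scan_set(cfg))
  expect_identical(gen_motion_trace(cfg), gen_motion_trace(cfg))
  expect_identical(gen_cytokine_panel(cfg), gen_cytokine_panel(cfg))
})

test_that("within-block minus between-block correlation keeps its sign", {
  for (seed in 1:5) {
    cfg <- synth_config(n_subjects_per_group = 1, n_rois = 8, n_systems = 4,
                        ages = 4, scans_per_subject = 1,
                        n_timepoints_per_scan = 300, seed = seed)
    s <- gen_scan_set(cfg)[[1]]
    r <- cor(t(s$data))
    assign <- rep(1:4, each = 2)
    same <- outer(assign, assign, "==")
    expect_gt(mean(r[same & upper.tri(r)]), mean(r[!same & upper.tri(r)]))
  }
})

test_that("severely indefinite block targets are rejected with a diagnostic", {
  cfg <- synth_config(n_subjects_per_group = 1, n_rois = 9, n_systems = 3,
                      ages = 4, scans_per_subject = 1,
                      n_timepoints_per_scan = 40,
                      within_system_r = 0.05, between_system_r = -0.45,
                      seed = 1)
  expect_error(gen_scan_set(cfg), "positive definite")
})

test_that("motion trace spikes respect the 0.125 mm threshold contract", {
  cfg0 <- synth_config(spike_rate = 0, seed = 4)
  tr0 <- gen_motion_trace(cfg0, 200)
  expect_true(all(tr0$displacement < 0.125))
  expect_length(attr(tr0, "spikes"), 0)

  cfg1 <- synth_config(spike_rate = 1, seed = 4)
  tr1 <- gen_motion_trace(cfg1, 10)
  expect_identical(attr(tr1, "spikes"), 1:10)
  expect_true(all(tr1$displacement[attr(tr1, "spikes")] > 0.125))

  cfg <- synth_config(spike_rate = 0.1, seed = 21)
  tr <- gen_motion_trace(cfg, 1000)
  k <- length(attr(tr, "spikes"))
  # binomial 99% interval around 100 of 1000
  expect_true(k >= qbinom(0.005, 1000, 0.1) && k <= qbinom(0.995, 1000, 0.1))
})

test_that("cytokine panel plants slopes and flags censoring correctly", {
  cfg <- synth_config(n_subjects_per_group = 8,
                      planted_age_slopes = c(1, 1, 1), seed = 6)
  panel <- gen_cytokine_panel(cfg, regions = "Parietal")
  expect_setequal(attr(panel, "planted"), c("CYT01", "CYT02", "CYT03"))
  # regression slope of log-concentration on age in the planted genotype
  sub <- panel[panel$genotype == "5xFAD", ]
  sl <- sapply(split(sub, sub$analyte), function(d)
    coef(lm(log(concentration_pg_per_ml) ~ age_months, d))[2])
  planted <- names(sl) %in% paste0(attr(panel, "planted"), ".age_months")
  expect_true(all(abs(sl[planted] - 1 * cfg$cytokine_sdlog) < 0.15))
  expect_true(all(abs(sl[!planted]) < 0.15))

  # null panel: no analyte slope differs from 0 beyond sampling error
  cfg0 <- synth_config(n_subjects_per_group = 8, planted_age_slopes = 0,
                       seed = 7)
  p0 <- gen_cytokine_panel(cfg0, regions = "Parietal")
  ps <- sapply(split(p0, p0$analyte), function(d)
    summary(lm(log(concentration_pg_per_ml) ~ age_months, d))$coefficients[2, 4])
  expect_gt(min(p.adjust(ps, "BH")), 0.05)

  # total censoring flags
  cfgc <- synth_config(n_subjects_per_group = 2, detection_floor = 1e9,
                       detection_ceiling = 2e9, seed = 8)
  pc <- gen_cytokine_panel(cfgc, regions = "Parietal")
  expect_true(all(pc$below_limit))
  # flag definition is exactly value < floor / value > ceiling
  expect_identical(pc$below_limit,
                   pc$concentration_pg_per_ml < cfgc$detection_floor)
})

test_that("toy graph fixtures match their documented definitions", {
  tg <- gen_toy_graph("triangle_unit")
  expect_equal(dim(tg$r), c(3, 3))
  expect_true(all(tg$r == 1))
  st <- gen_toy_graph("star5")
  expect_equal(unname(st$r[1, 2:5]), rep(0.5, 4))
  expect_equal(unname(st$r[2:5, 2:5][upper.tri(diag(4))]), rep(0, 6))
  r5 <- gen_toy_graph("random5_seeded")
  expect_identical(r5$r, gen_toy_graph("random5_seeded")$r)
  off <- r5$r[upper.tri(r5$r)]
  expect_true(all(off > 0 & off < 1))
  expect_error(gen_toy_graph("nope"))
})
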