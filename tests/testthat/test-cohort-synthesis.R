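test_that("synthetic atlas meets the region contract and is deterministic", {
  cfg <- synthesis_config(grid_shape = c(24L, 24L, 24L), n_regions = 4L,
                          seed = 5L)
  atl <- synthesize_atlas(cfg)
  codes <- sort(unique(atl$labels[atl$labels > 0L]))
  expect_identical(codes, 1:4)
  sizes <- tabulate(atl$labels[atl$labels > 0L], nbins = 4L)
  expect_true(all(sizes >= 200L))
  expect_true(any(atl$labels == 0L))  # background present
  atl2 <- synthesize_atlas(cfg)
  expect_identical(atl$labels, atl2$labels)
  # regions are spatially contiguous under 6-connectivity
  for (code in codes) {
    comp <- label_components(atl$labels == code, 6L)
    expect_identical(max(comp), 1L)
  }
})

test_that("an atlas-sized parcellation (90 regions) fits a 48^3 grid", {
  cfg <- synthesis_config(grid_shape = c(48L, 48L, 48L), n_regions = 90L,
                          seed = 2L)
  atl <- synthesize_atlas(cfg)
  expect_identical(sort(unique(atl$labels[atl$labels > 0L])), 1:90)
})

test_that("a too-small grid for the requested regions is an error", {
  cfg <- synthesis_config(grid_shape = c(10L, 10L, 10L), n_regions = 12L)
  expect_error(synthesize_atlas(cfg), "too small")
})

test_that("planted effect shifts regional group means by d * noise_sd", {
  cfg <- synthesis_config(grid_shape = c(20L, 20L, 20L), n_regions = 4L,
                          n_responders = 200L, n_nonresponders = 200L,
                          effect_regions = 3L, effect_size = 2,
                          noise_sd = 0.08, seed = 9L)
  coh <- synthesize_cohort(cfg)
  in_region <- coh$atlas$labels == 3L
  grp <- coh$clinical$group
  mean_in <- vapply(coh$maps, function(m) mean(m$values[in_region]), numeric(1L))
  gap <- mean(mean_in[grp == "responder"]) - mean(mean_in[grp == "nonresponder"])
  # planted offset is 2 * 0.08 = 0.16; regional averaging leaves it intact
  expect_lt(abs(gap - 0.16), 0.01)
})

test_that("null cohorts give a nominal voxelwise false-positive rate", {
  rates <- vapply(1:50, function(s) {
    cfg <- synthesis_config(grid_shape = c(16L, 16L, 16L), n_regions = 2L,
                            n_responders = 10L, n_nonresponders = 10L,
                            effect_size = 0, seed = 1000L + s)
    coh <- synthesize_cohort(cfg)
    tm <- voxelwise_t_map(coh$maps, coh$labels)
    tv <- tm$t_values[tm$analysis_mask]
    mean(2 * pt(-abs(tv), df = tm$df) < 0.05)
  }, numeric(1L))
  expect_gt(mean(rates), 0.03)
  expect_lt(mean(rates), 0.07)
})

test_that("clinical generator recovers the target group means at large n", {
  set.seed(77)
  tab <- ectradiomics:::synth_clinical_group(
    10000L, "responder", ectradiomics:::default_clinical_params(), 0L)
  expect_equal(mean(tab$panss_total_baseline), 94.1, tolerance = 0.01 * 94.1)
  expect_equal(mean(tab$panss_negative_baseline), 19.5, tolerance = 0.02 * 19.5)
  expect_equal(mean(tab$dose_ddd), 17.5, tolerance = 0.02 * 17.5)
  # responder percentage reductions all sit at or above the 70% criterion
  pct <- 100 * (tab$panss_total_baseline - tab$panss_total_post) /
    tab$panss_total_baseline
  expect_true(all(pct >= 70 - 0.5))
})

test_that("response labelling applies the inclusive 70% criterion", {
  coh <- data.frame(subject_id = c("a", "b", "c"),
                    panss_total_baseline = c(100, 94, 100),
                    panss_total_post = c(30, 40, 100))
  lab <- label_response(coh)
  expect_identical(lab$label, c("responder", "nonresponder", "nonresponder"))
  expect_equal(lab$pct_reduction, c(70, 100 * 54 / 94, 0))
  expect_error(label_response(data.frame(subject_id = "z",
                                         panss_total_baseline = 0,
                                         panss_total_post = 0)),
               "positive")
})

test_that("every synthesized subject's label matches its intended group", {
  cfg <- synthesis_config(grid_shape = c(16L, 16L, 16L), n_regions = 2L,
                          n_responders = 15L, n_nonresponders = 17L, seed = 4L)
  coh <- synthesize_cohort(cfg)
  expect_identical(coh$labels$label == "responder",
                   coh$clinical$group == "responder")
})

test_that("cohort splitting honors explicit counts, ratios and the seed", {
  lab <- data.frame(subject_id = sprintf("S%03d", 1:57),
                    pct_reduction = c(rep(80, 28), rep(40, 29)),
                    label = rep(c("responder", "nonresponder"), c(28, 29)))
  sp <- split_cohort(lab, seed = 3L)  # study default: 22 + 22 training
  expect_length(sp$train_ids, 44L)
  expect_length(sp$validation_ids, 13L)
  tr_lab <- lab$label[lab$subject_id %in% sp$train_ids]
  expect_identical(sum(tr_lab == "responder"), 22L)
  expect_identical(sum(tr_lab == "nonresponder"), 22L)
  expect_length(intersect(sp$train_ids, sp$validation_ids), 0L)
  expect_setequal(c(sp$train_ids, sp$validation_ids), lab$subject_id)
  expect_identical(split_cohort(lab, seed = 3L), sp)  # deterministic

  lab10 <- lab[c(1:5, 29:33), ]
  sp2 <- split_cohort(lab10, train_counts = NULL, ratio = 1, seed = 1L)
  expect_length(sp2$train_ids, 5L)
  expect_length(sp2$validation_ids, 5L)

  expect_error(split_cohort(lab10, train_counts = c(responder = 9L,
                                                    nonresponder = 2L)),
               "exceed")
})
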