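test_that("endmember spectra place peaks and valleys where requested", {
  g <- hsi_grid()
  flat <- make_endmember_spectrum(g, baseline = 0.4)
  expect_equal(flat$values, rep(0.4, length(g)))

  em <- make_endmember_spectrum(
    g,
    peaks = list(c(705, 15, 0.10), c(800, 25, 0.12)),
    valleys = list(c(750, 12, 0.06), c(985, 10, 0.15)),
    baseline = 0.45)
  win <- g >= 690 & g <= 720
  expect_equal(as.numeric(g[win][which.max(em$values[win])]), 705)
  win2 <- g >= 970 & g <= 1000
  expect_equal(as.numeric(g[win2][which.min(em$values[win2])]), 985)

  # a coincident peak and valley of equal shape cancel exactly
  cancel <- make_endmember_spectrum(g,
    peaks = list(c(800, 20, 0.1)), valleys = list(c(800, 20, 0.1)),
    baseline = 0.45)
  expect_equal(cancel$values, rep(0.45, length(g)))

  expect_error(make_endmember_spectrum(g, peaks = list(c(1100, 10, 0.1))),
               "peak.*outside the grid")
  expect_error(make_endmember_spectrum(g, valleys = list(c(700, -1, 0.1))),
               "widths")
})

test_that("tissue layout builds concentric zones inside a disc", {
  cfg <- scene_config(image_height = 64, image_width = 64,
                      slice_radius_fraction = 0.9,
                      zone_radii = c(0.3, 0.6, 0.7, 1.0), seed = 1)
  lay <- make_tissue_layout(cfg)
  expect_setequal(unique(lay$zone_labels[lay$foreground_mask]), 1:4)
  expect_true(all(lay$zone_labels[!lay$foreground_mask] == 0L))

  # full-radius disc covers pi/4 of a square frame within 2%
  for (n in c(64, 96)) {
    cfg2 <- scene_config(image_height = n, image_width = n,
                         slice_radius_fraction = 1.0, seed = 1)
    lay2 <- make_tissue_layout(cfg2)
    expect_lt(abs(mean(lay2$foreground_mask) / (pi / 4) - 1), 0.02)
  }

  expect_error(scene_config(zone_radii = c(0.5, 0.5, 0.7, 1.0)),
               "strictly increasing")
  expect_error(scene_config(zone_radii = c(0.3, 0.6, 0.8, 1.2)),
               "must not exceed 1")
})

test_that("concentration fields follow first-order PPO inactivation", {
  cfg0 <- noiseless_cfg(blanch_time_min = 0)
  tr0 <- assign_concentrations(make_tissue_layout(cfg0), cfg0)
  fg <- tr0$foreground_mask
  zl <- tr0$zone_labels
  for (z in 1:4) {
    expect_equal(unique(tr0$ppo_field[fg & zl == z]),
                 unname(cfg0$ppo_profile[z]))
    expect_equal(unique(tr0$tpc_field[fg & zl == z]),
                 unname(cfg0$tpc_profile[z]))
  }
  expect_true(all(tr0$ppo_field[!fg] == 0))
  expect_equal(tr0$bulk_ppo, mean(tr0$ppo_field[fg]))

  cfg2 <- noiseless_cfg(blanch_time_min = 2, ppo_decay_rate = 0.5)
  tr2 <- assign_concentrations(make_tissue_layout(cfg2), cfg2)
  expect_equal(tr2$ppo_field[fg], tr0$ppo_field[fg] * exp(-1), tolerance = 1e-12)

  expect_error(scene_config(ppo_decay_rate = -0.1), "non-negative")
})

test_that("PPO is monotone in blanching time under heterogeneity", {
  bulks <- sapply(c(0, 2, 4, 6, 10), function(t) {
    cfg <- scene_config(blanch_time_min = t, seed = 17)
    assign_concentrations(make_tissue_layout(cfg), cfg)$bulk_ppo
  })
  expect_true(all(diff(bulks) < 0))

  # pointwise: same seed, later time never exceeds earlier time
  cfg_a <- scene_config(blanch_time_min = 2, seed = 5)
  cfg_b <- scene_config(blanch_time_min = 6, seed = 5)
  tr_a <- assign_concentrations(make_tissue_layout(cfg_a), cfg_a)
  tr_b <- assign_concentrations(make_tissue_layout(cfg_b), cfg_b)
  expect_true(all(tr_b$ppo_field <= tr_a$ppo_field + 1e-12))
})

test_that("rendering is deterministic and respects the forward model", {
  cfg <- scene_config(seed = 9)
  s1 <- simulate_scene(cfg)
  s2 <- simulate_scene(cfg)
  expect_identical(s1$frames$raw, s2$frames$raw)
  expect_identical(s1$frames$white, s2$frames$white)
  expect_identical(s1$truth$ppo_field, s2$truth$ppo_field)

  # zero concentrations: foreground reflectance equals the matrix spectrum
  cfg0 <- noiseless_cfg(ppo_profile = rep(0, 4), tpc_profile = rep(0, 4))
  sc <- simulate_scene(cfg0)
  cube <- calibrate_reflectance(sc$frames)
  fg <- sc$truth$foreground_mask
  for (bnd in c(1, 40, 81)) {
    plane <- cube$data[, , bnd]
    expect_equal(unique(round(plane[fg], 12)),
                 round(sc$endmembers$matrix$values[bnd], 12))
  }

  em <- sc$endmembers$ppo_chromophore
  bad <- list(matrix = sc$endmembers$matrix,
              ppo_chromophore = make_endmember_spectrum(hmi_grid(), baseline = 0.1),
              tpc_chromophore = sc$endmembers$tpc_chromophore)
  expect_error(render_frames(sc$truth, sc$grid, bad, cfg0), "mismatched")
})

test_that("HMI mode renders full-frame tissue with a ridge lattice", {
  cfg <- scene_config(mode = "HMI", seed = 3)
  sc <- simulate_scene(cfg)
  expect_length(sc$grid, 101)
  expect_true(all(sc$truth$foreground_mask))
  expect_true(!is.null(sc$truth$lattice))
  expect_gte(min(sc$truth$lattice), 0)
  expect_lte(max(sc$truth$lattice), 1)
})

test_that("reference assays reproduce the stated error model", {
  cfg <- noiseless_cfg()
  tr <- assign_concentrations(make_tissue_layout(cfg), cfg)
  exact <- sample_reference_assays(tr, assay_cv = 0, seed = 1)
  expect_equal(unname(exact), c(tr$bulk_ppo, tr$bulk_tpc))

  draws <- t(sapply(seq_len(1000), function(i) {
    sample_reference_assays(tr, assay_cv = 0.05, seed = 10000 + i)
  }))
  rel_sd <- apply(draws, 2, sd) / apply(draws, 2, mean)
  expect_true(all(rel_sd >= 0.04 & rel_sd <= 0.06))

  cfg0 <- noiseless_cfg(ppo_profile = rep(0, 4), tpc_profile = rep(0, 4))
  tr0 <- assign_concentrations(make_tissue_layout(cfg0), cfg0)
  expect_equal(unname(sample_reference_assays(tr0, 0.05, seed = 2)), c(0, 0))
  expect_error(sample_reference_assays(tr, assay_cv = -0.1), "non-negative")
})
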