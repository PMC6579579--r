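# Generators: deterministic under a fixed seed, correct in the
# noiseless limit, and carrying a ground-truth record sufficient to
# predict every downstream estimate.

test_that("generators are bit-identical under a fixed seed", {
  gens <- list(
    function(s) gen_gel_lanes(218000, 2, noise_cv = 0.1, seed = s),
    function(s) gen_fcm_events(
      data.frame(cell_line = "a", true_abundance = 1e5,
                 au_per_molecule = 0.05),
      n_events = 500, seed = s),
    function(s) gen_fcs_curve(5, 0.7, 1e-4, 1e-2, noise_sd = 0.01, seed = s),
    function(s) gen_coip(0.1, noise_cv = 0.1, seed = s),
    function(s) gen_cell_cycle(n_events = 2000, seed = s),
    function(s) gen_image_stack(field_um = c(6, 9.6, 9.6),
                                nucleus_axes_um = c(2, 3, 3),
                                cell_axes_um = c(2.6, 4.4, 4.4),
                                photons_per_au = 20, seed = s)
  )
  for (g in gens) {
    expect_identical(serialize(g(42), NULL), serialize(g(42), NULL))
    expect_false(identical(serialize(g(42), NULL), serialize(g(43), NULL)))
  }
})

test_that("noiseless gel lanes are exactly linear", {
  sim <- gen_gel_lanes(true_abundance = 100, fpm = 2,
                       standard_amounts = c(10, 20, 40),
                       cells_per_lane = 1000, noise_cv = 0, seed = 1)
  std <- sim$lanes[sim$lanes$kind == "standard", ]
  expect_equal(std$band_intensity[std$amount == 10], 20)
  expect_equal(std$band_intensity, 2 * std$amount)
  lys <- sim$lanes[sim$lanes$kind == "lysate", ]
  expect_equal(lys$band_intensity, 200000)
  expect_error(gen_gel_lanes(-1, 2), class = "invalid_parameter")
  expect_error(gen_gel_lanes(100, 0), class = "invalid_parameter")
})

test_that("noisy gel data recover truth within the MC sampling spread", {
  # sampling sd of the 5-replicate estimator at noise_cv = 0.1 frozen
  # from a 10,000-rep Monte-Carlo run of this generator/estimator pair
  # (mean 218385, sd 6898)
  sd_mc <- 6898
  sim <- gen_gel_lanes(218000, 2, n_replicates = 5, noise_cv = 0.1,
                       seed = 1234)
  est <- gel_abundance(sim$lanes)
  expect_lt(abs(est$mean - 218000), 3 * sd_mc)
})

test_that("FCM events: zero abundance matches the unlabeled control", {
  lines <- data.frame(cell_line = "null", true_abundance = 0,
                      au_per_molecule = 0.05)
  sim <- gen_fcm_events(lines, n_events = 1000, seed = 9)
  lab <- sim$events[sim$events$labeled, "intensity_au"]
  unl <- sim$events[!sim$events$labeled, "intensity_au"]
  expect_identical(lab, unl)
  expect_error(gen_fcm_events(data.frame()), class = "invalid_parameter")
})

test_that("FCM noiseless limit: mean intensity = au_per_molecule * abundance", {
  lines <- data.frame(cell_line = "a", true_abundance = 1e5,
                      au_per_molecule = 0.05)
  sim <- gen_fcm_events(lines, sigma = 1e-12, background_meanlog = -30,
                        background_sdlog = 1e-12, n_events = 100, seed = 2)
  lab <- sim$events[sim$events$labeled, "intensity_au"]
  expect_equal(mean(lab), 0.05 * 1e5, tolerance = 1e-9)
})

test_that("FCM 2:1 abundance ratio is recovered within MC error", {
  # ratio-estimator sd 0.0121 frozen from a 2,000-rep Monte-Carlo run
  lines <- data.frame(cell_line = c("std", "target"),
                      true_abundance = c(1e5, 2e5),
                      au_per_molecule = c(0.05, 0.05))
  sim <- gen_fcm_events(lines, sigma = 0.4, n_events = 10000, seed = 77)
  est <- fcm_abundance(sim$events, "std", 1e5)
  ratio <- est$n_X[est$cell_line == "target"] / 1e5
  expect_lt(abs(ratio - 2), 3 * 0.0121)
})

test_that("FCS curve generator obeys the model limits", {
  lags <- c(1e-9, 10^seq(-6, 2, length.out = 50))
  sim <- gen_fcs_curve(N_mean = 4, f1 = 0.5, tau1_s = 1e-4, tau2_s = 1e-2,
                       kappa = 5, offset = 0.01, lags_s = lags,
                       noise_sd = 0)
  expect_equal(sim$curve$g[1], 0.01 + 1 / 4, tolerance = 1e-4)
  expect_equal(tail(sim$curve$g, 1), 0.01, tolerance = 1e-3)
  expect_error(gen_fcs_curve(4, 0.5, 1e-4, 1e-2, kappa = 0),
               class = "invalid_parameter")
  expect_error(
    gen_fcs_curve(4, 0.5, 1e-4, 1e-2, lags_s = c(2, 1)),
    class = "invalid_parameter"
  )
})

test_that("image stack: noiseless zero-concentration field is flat background", {
  sim <- gen_image_stack(conc_nuc_nM = 0, conc_cyt_nM = 0,
                         background_AU = 3,
                         field_um = c(6, 9.6, 9.6),
                         nucleus_axes_um = c(2, 3, 3),
                         cell_axes_um = c(2.6, 4.4, 4.4))
  expect_true(all(sim$stack$channels$protein == 3))
})

test_that("voxelised sphere volume matches the analytic value within 2%", {
  sim <- gen_image_stack(nucleus_axes_um = c(5, 5, 5),
                         cell_axes_um = c(7, 7, 7),
                         field_um = c(16, 16, 16),
                         voxel_size_um = c(0.5, 0.5, 0.5))
  expect_equal(sim$truth$volume_nucleus_um3, 4 / 3 * pi * 125,
               tolerance = 0.02)
})

test_that("ground-truth molecule count is conc * volume * NA", {
  sim <- gen_image_stack(conc_nuc_nM = 144.3,
                         field_um = c(6, 9.6, 9.6),
                         nucleus_axes_um = c(2, 3, 3),
                         cell_axes_um = c(2.6, 4.4, 4.4))
  expect_equal(sim$truth$count_nucleus,
               144.3 * sim$truth$volume_nucleus_um3 * AVOGADRO_UM3_NM)
})

test_that("a nucleus outside the cell is a geometry error", {
  expect_error(
    gen_image_stack(nucleus_axes_um = c(3, 4, 4),
                    cell_axes_um = c(2, 3, 3),
                    field_um = c(6, 9.6, 9.6)),
    class = "geometry_error"
  )
})

test_that("CoIP generator: degenerate dimer fractions", {
  none <- gen_coip(0, noise_cv = 0)
  expect_true(all(none$experiments$I_CoIP == 0))
  all_d <- gen_coip(1, noise_cv = 0)
  est <- coip_stoichiometry(all_d$experiments)
  expect_equal(est$per_experiment$dimer_pct, rep(100, 4))
  expect_error(gen_coip(0.5, loading = c(input = 0, ip = 0.1, coip = 0.9)),
               class = "invalid_parameter")
})

test_that("cell-cycle generator: degenerate inputs", {
  pure_g1 <- gen_cell_cycle(fractions = c(1, 0, 0), n_events = 500, seed = 3)
  expect_true(all(pure_g1$events$phase == "G1"))
  expect_true(all(abs(pure_g1$events$dapi_au - 100) < 100 * 0.08 * 6))
  empty <- gen_cell_cycle(n_events = 0, seed = 1)
  expect_identical(nrow(empty$events), 0L)
  expect_identical(nrow(empty$control), 0L)
  expect_error(gen_cell_cycle(fractions = c(0.5, 0.2, 0.2)),
               class = "invalid_parameter")
  expect_error(gen_cell_cycle(n_events = -1), class = "invalid_parameter")
})
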