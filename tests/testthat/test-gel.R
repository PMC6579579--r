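# In-gel fluorescence quantification.

test_that("standard curve through the origin recovers exact linear data", {
  lanes <- data.frame(kind = "standard", amount = c(10, 20, 40),
                      band_intensity = c(20, 40, 80))
  curve <- fit_standard_curve(lanes)
  expect_equal(curve$fluorescence_per_molecule, 2.0)
  expect_equal(curve$residual_rms, 0)
  expect_error(fit_standard_curve(lanes[1, ]),
               class = "insufficient_standard")
  expect_error(
    fit_standard_curve(data.frame(kind = "standard", amount = c(10, 10),
                                  band_intensity = c(20, 22))),
    class = "insufficient_standard"
  )
})

test_that("noisy standard curves land within 5% of truth in >=95% of seeds", {
  n_ok <- sum(vapply(1:1000, function(s) {
    sim <- gen_gel_lanes(1e5, fpm = 3,
                         standard_amounts = c(1, 2, 4, 8, 16, 32) * 1e8,
                         noise_cv = 0.05, seed = s)
    fpm <- fit_standard_curve(sim$lanes)$fluorescence_per_molecule
    abs(fpm - 3) / 3 < 0.05
  }, logical(1)))
  expect_gte(n_ok, 950)
})

test_that("molecules_per_cell divides by fpm and cell number", {
  curve <- fit_standard_curve(data.frame(
    kind = "standard", amount = c(1e5, 2e5), band_intensity = c(2e5, 4e5)))
  lane <- list(band_intensity = 200000, n_cells = 1000)
  expect_equal(as.numeric(molecules_per_cell(lane, curve)), 100)
  expect_equal(as.numeric(molecules_per_cell(
    list(band_intensity = 0, n_cells = 1000), curve)), 0)
  expect_error(molecules_per_cell(list(band_intensity = 1, n_cells = 0),
                                  curve), class = "invalid_lane")
  # homogeneity: degree 1 in intensity, degree -1 in cells
  expect_equal(
    as.numeric(molecules_per_cell(list(band_intensity = 7 * 200000,
                                       n_cells = 1000), curve)),
    700
  )
  expect_equal(
    as.numeric(molecules_per_cell(list(band_intensity = 200000,
                                       n_cells = 7000), curve)),
    100 / 7
  )
})

test_that("lanes above the standard range are flagged, not dropped", {
  curve <- fit_standard_curve(data.frame(
    kind = "standard", amount = c(10, 20), band_intensity = c(20, 40)))
  v <- molecules_per_cell(list(band_intensity = 1e6, n_cells = 10), curve)
  expect_true(attr(v, "extrapolated"))
})

test_that("noiseless synthetic replicate set round-trips the truth", {
  sim <- gen_gel_lanes(218000, fpm = 2, n_replicates = 4, noise_cv = 0,
                       seed = 5)
  est <- gel_abundance(sim$lanes)
  expect_equal(est$mean, 218000, tolerance = 1e-9)
  expect_equal(est$std, 0)
})

test_that("labeling efficiency follows the saturation model", {
  conc <- c(10, 30, 100, 300, 1000, 5000)
  titr <- data.frame(dye_concentration = conc,
                     background_corrected_intensity = 100 * conc / (50 + conc))
  eff <- labeling_efficiency(titr, 500)
  expect_equal(as.numeric(eff), 500 / 550, tolerance = 1e-6)
  expect_equal(as.numeric(labeling_efficiency(titr, 1e12)), 1,
               tolerance = 1e-6)
  # saturated data: efficiency 1 at any positive concentration
  flat <- data.frame(dye_concentration = c(10, 100, 1000),
                     background_corrected_intensity = c(50, 50, 50))
  expect_equal(as.numeric(labeling_efficiency(flat, 30)), 1)
  # monotone in the query concentration
  effs <- vapply(c(5, 50, 500, 5000), function(cq) {
    as.numeric(labeling_efficiency(titr, cq))
  }, numeric(1))
  expect_true(all(diff(effs) >= 0))
})

test_that("replicate aggregation reproduces the published dimer summary", {
  est <- aggregate_replicates(c(11.23, 7.60, 5.19, 6.47))
  expect_equal(round(est$mean, 2), 7.62)
  expect_equal(round(est$std, 1), 2.6)
  single <- aggregate_replicates(5)
  expect_equal(single$mean, 5)
  expect_equal(single$std, 0)
  expect_true(single$single_replicate)
  expect_equal(aggregate_replicates(c(3, 3))$std, 0)
  expect_error(aggregate_replicates(numeric(0)), class = "invalid_parameter")
})
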