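# Cell-cycle classification and genome-model constraint arithmetic.

test_that("pure-G1 data classify as all G1", {
  sim <- gen_cell_cycle(fractions = c(1, 0, 0), n_events = 5000, seed = 1)
  cls <- classify_cell_cycle(sim$events, sim$control)
  expect_gte(unname(cls$fractions["G1"]), 0.99)
  expect_true("unimodal_pool" %in% cls$flags)
})

test_that("all-EdU-positive data classify as all S", {
  ev <- data.frame(dapi_au = runif(100, 100, 200), edu_au = rep(1e5, 100))
  ctrl <- data.frame(dapi_au = runif(100, 100, 200),
                     edu_au = rlnorm(100, log(10), 0.5))
  cls <- classify_cell_cycle(ev, ctrl)
  expect_equal(unname(cls$fractions["S"]), 1)
  expect_error(classify_cell_cycle(ev[0, ], ctrl),
               class = "invalid_parameter")
})

test_that("realistic mixture is recovered within +/-0.02", {
  sim <- gen_cell_cycle(n_events = 50000, seed = 10)
  truth <- prop.table(table(factor(sim$events$phase,
                                   c("G1", "S", "G2"))))
  cls <- classify_cell_cycle(sim$events, sim$control)
  expect_lt(max(abs(cls$fractions[c("G1", "S", "G2")] - truth)), 0.02)
})

test_that("expected genome copies follow 2/3/4 weighting", {
  expect_equal(mean_genome_copies(c(1, 0, 0)), 2)
  expect_equal(mean_genome_copies(c(0, 0, 1)), 4)
  expect_equal(mean_genome_copies(c(0.102, 0.739, 0.159)), 3.057)
  expect_equal(round(mean_genome_copies(c(0.102, 0.739, 0.159))), 3)
  # monotone in fG2 at fixed fG1
  f <- function(g2) mean_genome_copies(c(0.2, 0.8 - g2, g2))
  vals <- vapply(seq(0, 0.8, by = 0.1), f, numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_error(mean_genome_copies(c(0.5, 0.5, 0.5)),
               class = "invalid_parameter")
})

test_that("fractional occupancy matches the published worked example", {
  occ <- fractional_occupancy(0.491, 217200, 71200, 3)
  expect_equal(round(as.numeric(occ), 3), 0.499)
  expect_equal(as.numeric(fractional_occupancy(0, 1000, 100, 2)), 0)
  expect_equal(as.numeric(fractional_occupancy(1, 71200 * 3, 71200, 3)), 1)
  over <- fractional_occupancy(1, 1e7, 100, 2)
  expect_true("over_occupancy" %in% attr(over, "flags"))
  expect_error(fractional_occupancy(0.5, 1000, 0, 2),
               class = "invalid_parameter")
  # homogeneity: linear in f_bound and n, inverse in sites and copies
  base <- as.numeric(fractional_occupancy(0.4, 1e5, 5e4, 2))
  expect_equal(as.numeric(fractional_occupancy(0.4, 3e5, 5e4, 2)), 3 * base)
  expect_equal(as.numeric(fractional_occupancy(0.4, 1e5, 1e5, 2)), base / 2)
})

test_that("extrusion density matches the published worked example", {
  d1 <- extrusion_density(0.398, 109400, 2716, 3, stoichiometry = 1)
  expect_equal(round(d1$density_molecules_per_Mb, 2), 5.34)
  d2 <- extrusion_density(0.398, 109400, 2716, 3, stoichiometry = 2)
  expect_equal(round(d2$density_units_per_Mb, 2), 2.67)
  # spacing * density = 1000 exactly
  expect_equal(d1$spacing_kb * d1$density_units_per_Mb, 1000)
  expect_equal(d2$spacing_kb * d2$density_units_per_Mb, 1000)
  z <- extrusion_density(0, 109400, 2716, 3)
  expect_equal(z$density_molecules_per_Mb, 0)
  expect_true(is.na(z$spacing_kb))
  expect_true("zero_density" %in% z$flags)
  expect_error(extrusion_density(0.4, 1e5, 0, 3),
               class = "invalid_parameter")
  expect_error(extrusion_density(0.4, 1e5, 2716, 3, stoichiometry = 3),
               class = "invalid_parameter")
})

test_that("combine_estimates reproduces all three final averages", {
  expect_equal(combine_estimates(c(215200, 219200)), 217200)
  expect_equal(combine_estimates(c(104900, 114600)), 109800)
  expect_equal(combine_estimates(c(86900, 131800)), 109400)
  expect_equal(combine_estimates(c(68077, 74374)), 71200)
  expect_error(combine_estimates(numeric(0)), class = "invalid_parameter")
})

test_that("round_half_up rounds halves away from zero", {
  expect_equal(round_half_up(109750), 109800)
  expect_equal(round_half_up(109350), 109400)
  expect_equal(round_half_up(149, 100), 100)
  expect_equal(round_half_up(150, 100), 200)
})
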