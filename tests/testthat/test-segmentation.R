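# 3D segmentation and compartment quantification.

test_that("Otsu threshold separates a bimodal sample", {
  x <- c(rnorm(500, 10, 1), rnorm(500, 100, 5))
  thr <- otsu_threshold(x)
  expect_gt(thr, 20)
  expect_lt(thr, 90)
  expect_equal(otsu_threshold(rep(3, 10)), 3)
})

test_that("isotropic interpolation preserves extent and values", {
  a <- array(seq_len(4 * 6 * 6), c(4, 6, 6))
  out <- interpolate_isotropic(a, c(0.6, 0.2, 0.2))
  expect_equal(dim(out$array), c(12, 6, 6))
  expect_equal(out$voxel_size_um, 0.2)
  expect_equal(range(out$array), range(a))
  # already isotropic: untouched
  same <- interpolate_isotropic(a, c(0.2, 0.2, 0.2))
  expect_identical(same$array, a)
  # nearest-neighbour keeps original values only
  nn <- interpolate_isotropic(a, c(0.6, 0.2, 0.2), method = "nearest")
  expect_true(all(nn$array %in% a))
})

test_that("noiseless phantom segments with Dice >= 0.98", {
  sim <- make_phantom(seed = 1)
  seg <- segment_stack(sim$stack)
  vs <- sim$stack$voxel_size_um
  expect_gte(dice_coefficient(seg$nuclear_mask,
                              iso_truth_mask(sim$truth$nucleus_mask, vs)),
             0.98)
  expect_gte(dice_coefficient(seg$cell_mask,
                              iso_truth_mask(sim$truth$cell_mask, vs)),
             0.98)
  expect_true(all(seg$cell_mask[seg$nuclear_mask]))
})

test_that("of two equal nuclei the centred one is selected", {
  # two identical nuclei inside one wide cell: selection must fall back
  # to distance from the image centre
  vox <- c(0.2, 0.2, 0.2)
  dims <- c(48, 150, 70)  # field 9.6 x 30 x 14 um
  em <- haloquant:::ellipsoid_mask
  n_off <- em(dims, vox, c(4.8, 5.5, 7), c(2.8, 4, 4))
  n_ctr <- em(dims, vox, c(4.8, 15, 7), c(2.8, 4, 4))
  cell <- em(dims, vox, c(4.8, 11, 7), c(4.4, 14, 6.2))
  sim <- gen_image_stack(nucleus_mask = n_off | n_ctr, cell_mask = cell,
                         field_um = c(9.6, 30, 14), voxel_size_um = vox)
  seg <- segment_stack(sim$stack)
  picked <- seg$nucleus_table[seg$nucleus_table$label == seg$target_label, ]
  ctr <- (dim(seg$nuclear_mask) + 1) / 2
  # centred nucleus: centroid y at the image centre
  expect_lt(abs(picked$cy - ctr[2]), 5)
  expect_equal(nrow(seg$nucleus_table), 2L)
})

test_that("segmentation fails loudly when no nucleus is plausible", {
  sim <- make_phantom(seed = 2)
  expect_error(
    segment_stack(sim$stack, nucleus_volume_range_um3 = c(3000, 4000)),
    class = "segmentation_failure"
  )
})

test_that("compartment quantification: arithmetic and additivity", {
  seg <- list(compartments = data.frame(
    compartment = c("nucleus", "cytoplasm", "cell"),
    Vp = c(100, 100, 200), V_um3 = c(100, 100, 200),
    It = c(100 * 7, 100 * 2, 100 * 7 + 100 * 2)
  ))
  calib <- structure(list(k_nM = 2, background_Ib = 2),
                     class = "calibration_factor")
  q <- compartment_quant(seg, calib)
  # mean - background = 5 AU, k = 2 -> 10 nM; 10 nM * 100 um^3 * NA
  expect_equal(q$table$Ca_nM[1], 10)
  expect_equal(q$table$Nt[1], 10 * 100 * 0.602214086)
  expect_equal(q$table$Nt[1] + q$table$Nt[2], q$table$Nt[3],
               tolerance = 1e-12)
  # pure background: zero everywhere
  seg0 <- list(compartments = data.frame(
    compartment = "cell", Vp = 10, V_um3 = 10, It = 20))
  q0 <- compartment_quant(seg0, calib)
  expect_equal(q0$table$Ca_nM, 0)
  expect_equal(q0$table$Nt, 0)
})

test_that("Nt additivity holds on a real segmented phantom", {
  sim <- make_phantom(seed = 3, noisy = TRUE)
  seg <- segment_stack(sim$stack)
  q <- compartment_quant(seg, truth_calibration(sim$truth))
  tab <- q$table
  expect_equal(tab$Nt[tab$compartment == "nucleus"] +
                 tab$Nt[tab$compartment == "cytoplasm"],
               tab$Nt[tab$compartment == "cell"], tolerance = 1e-6)
})

test_that("nuclear fraction matches the analytic compartment ratio", {
  # concentration ratio 20:1, volume ratio 1:2 -> 20 / (20 + 2)
  seg <- list(compartments = data.frame(
    compartment = c("nucleus", "cytoplasm", "cell"),
    Vp = c(100, 200, 300), V_um3 = c(100, 200, 300),
    It = c(100 * 20, 200 * 1, 100 * 20 + 200 * 1)
  ))
  calib <- structure(list(k_nM = 1, background_Ib = 0),
                     class = "calibration_factor")
  q <- compartment_quant(seg, calib)
  expect_equal(nuclear_fraction(q), 20 / 22, tolerance = 1e-12)
  expect_equal(q$nuclear_fraction, 20 / 22, tolerance = 1e-12)
  # all-nuclear and zero-nuclear limits
  seg$compartments$It <- c(2000, 0, 2000)
  expect_equal(nuclear_fraction(compartment_quant(seg, calib)), 1)
  seg$compartments$It <- c(0, 200, 200)
  expect_equal(nuclear_fraction(compartment_quant(seg, calib)), 0)
})

test_that("molecule number is stable under voxel resampling", {
  common <- list(nucleus_axes_um = c(3, 4, 4), cell_axes_um = c(4, 6, 6),
                 field_um = c(10.8, 14.4, 14.4))
  s1 <- do.call(gen_image_stack, c(common,
                                   list(voxel_size_um = c(0.6, 0.2, 0.2))))
  s2 <- do.call(gen_image_stack, c(common,
                                   list(voxel_size_um = c(0.3, 0.3, 0.3))))
  n1 <- compartment_quant(segment_stack(s1$stack),
                          truth_calibration(s1$truth))
  n2 <- compartment_quant(segment_stack(s2$stack),
                          truth_calibration(s2$truth))
  cell1 <- n1$table$Nt[n1$table$compartment == "cell"]
  cell2 <- n2$table$Nt[n2$table$compartment == "cell"]
  expect_equal(cell1, cell2, tolerance = 0.02)
})
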