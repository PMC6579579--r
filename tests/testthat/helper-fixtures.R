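# Shared helpers for the test suite.

# Resample a truth mask (anisotropic grid) to the isotropic grid used
# by segment_stack, for Dice comparisons.
iso_truth_mask <- function(mask, voxel_size_um) {
  interpolate_isotropic(array(as.numeric(mask), dim(mask)),
                        voxel_size_um)$array > 0.5
}

# Small phantom parameters reused across imaging tests: full-resolution
# voxels (0.6 um z, 0.2 um xy) on a reduced field of view.
phantom_field <- c(12.6, 19.2, 19.2)

make_phantom <- function(seed = 1, noisy = FALSE, ...) {
  gen_image_stack(
    field_um = phantom_field,
    photons_per_au = if (noisy) 20 else NULL,
    read_noise_sd = if (noisy) 1 else 0,
    seed = seed, ...
  )
}

truth_calibration <- function(truth) {
  structure(list(k_nM = truth$k_nM, background_Ib = truth$background_AU),
            class = "calibration_factor")
}
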