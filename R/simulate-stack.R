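# Synthetic 3D confocal stacks: ellipsoid nucleus inside a convex cell,
# three channels (DNA, cell boundary, protein), anisotropic voxels.

#' Multi-channel 3D image stack container
#'
#' @param dna,boundary,protein numeric 3D arrays of identical dimension,
#'   indexed `[z, y, x]`.
#' @param voxel_size_um voxel edge lengths in micrometres, `(z, y, x)`.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(dna, boundary, protein, voxel_size_um) {
  dims <- dim(dna)
  if (length(dims) != 3 || !identical(dims, dim(boundary)) ||
      !identical(dims, dim(protein))) {
    stop_haloquant("all three channels must be 3D arrays of identical shape",
                   "invalid_parameter")
  }
  if (length(voxel_size_um) != 3 || any(voxel_size_um <= 0)) {
    stop_haloquant("`voxel_size_um` must be 3 positive values (z, y, x)",
                   "invalid_parameter")
  }
  structure(
    list(channels = list(dna = dna, boundary = boundary, protein = protein),
         voxel_size_um = as.numeric(voxel_size_um)),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels$dna)
  cat(sprintf(
    "<image_stack: %d planes of %d x %d, voxel %.3g x %.3g x %.3g um (z,y,x)>\n",
    d[1], d[2], d[3], x$voxel_size_um[1], x$voxel_size_um[2],
    x$voxel_size_um[3]))
  invisible(x)
}

# Logical ellipsoid mask on the voxel grid of extent `dims` (z,y,x)
# voxels; centre and semi-axes in micrometres.
ellipsoid_mask <- function(dims, voxel_size_um, center_um, semi_axes_um) {
  zc <- (seq_len(dims[1]) - 0.5) * voxel_size_um[1]
  yc <- (seq_len(dims[2]) - 0.5) * voxel_size_um[2]
  xc <- (seq_len(dims[3]) - 0.5) * voxel_size_um[3]
  dz2 <- ((zc - center_um[1]) / semi_axes_um[1])^2
  dy2 <- ((yc - center_um[2]) / semi_axes_um[2])^2
  dx2 <- ((xc - center_um[3]) / semi_axes_um[3])^2
  # outer sums over the three axes, kept as an array
  m <- outer(outer(dz2, dy2, `+`), dx2, `+`)
  m <= 1
}

#' Simulate an FCS-calibrated confocal z-stack with known ground truth
#'
#' Builds an ellipsoidal nucleus strictly inside a larger convex
#' (default ellipsoidal) cell on an anisotropic voxel grid mimicking the
#' acquisition geometry (21 planes, 600 nm z interval, 200 nm xy
#' pixels). The protein channel carries
#' `background_AU + concentration / k_nM` per compartment; the DNA
#' channel marks the nucleus and the boundary channel is a
#' dextran-exclusion stain, bright outside the cell. Optional
#' Poisson photon noise (via `photons_per_au`) and Gaussian read noise.
#'
#' @param nucleus_axes_um,nucleus_center_um ellipsoid semi-axes and
#'   centre (z, y, x) in um; centre defaults to the field centre.
#' @param cell_axes_um,cell_center_um cell ellipsoid geometry; ignored
#'   when `cell_mask` is given.
#' @param nucleus_mask,cell_mask optional explicit logical masks
#'   overriding the ellipsoids (any convex region).
#' @param conc_nuc_nM,conc_cyt_nM true compartment concentrations (nM).
#' @param k_nM imaging calibration factor (nM per AU).
#' @param background_AU additive background in every channel.
#' @param dna_signal_AU,boundary_signal_AU channel contrasts.
#' @param field_um physical field of view (z, y, x) in um.
#' @param voxel_size_um voxel size (z, y, x) in um.
#' @param photons_per_au Poisson gain; `NULL` disables photon noise.
#' @param read_noise_sd additive Gaussian read noise s.d. (AU).
#' @param seed RNG seed.
#' @return list with `stack` ([image_stack]) and `truth` carrying the
#'   masks, voxelised compartment volumes (um^3) and molecule counts
#'   (`N = C * V * AVOGADRO_UM3_NM`).
#' @export
gen_image_stack <- function(nucleus_axes_um = c(4, 6, 6),
                            nucleus_center_um = NULL,
                            cell_axes_um = c(5.5, 9, 9),
                            cell_center_um = NULL,
                            nucleus_mask = NULL, cell_mask = NULL,
                            conc_nuc_nM = 144.3, conc_cyt_nM = 7,
                            k_nM = 2, background_AU = 5,
                            dna_signal_AU = 100, boundary_signal_AU = 100,
                            field_um = c(12.6, 25.6, 25.6),
                            voxel_size_um = c(0.6, 0.2, 0.2),
                            photons_per_au = NULL, read_noise_sd = 0,
                            seed = 1) {
  check_number(conc_nuc_nM, "conc_nuc_nM", lower = 0)
  check_number(conc_cyt_nM, "conc_cyt_nM", lower = 0)
  check_number(k_nM, "k_nM", lower = 0, strict_lower = TRUE)
  check_number(read_noise_sd, "read_noise_sd", lower = 0)
  dims <- as.integer(round(field_um / voxel_size_um))
  centre <- field_um / 2
  if (is.null(nucleus_mask)) {
    nucleus_mask <- ellipsoid_mask(dims, voxel_size_um,
                                   nucleus_center_um %||% centre,
                                   nucleus_axes_um)
  }
  if (is.null(cell_mask)) {
    cell_mask <- ellipsoid_mask(dims, voxel_size_um,
                                cell_center_um %||% centre, cell_axes_um)
  }
  if (any(nucleus_mask & !cell_mask)) {
    stop_haloquant("nucleus is not contained in the cell", "geometry_error")
  }
  vox_vol <- prod(voxel_size_um)
  cyt_mask <- cell_mask & !nucleus_mask
  v_nuc <- sum(nucleus_mask) * vox_vol
  v_cyt <- sum(cyt_mask) * vox_vol

  protein <- array(background_AU, dims)
  protein[cyt_mask] <- background_AU + conc_cyt_nM / k_nM
  protein[nucleus_mask] <- background_AU + conc_nuc_nM / k_nM
  dna <- array(background_AU, dims)
  dna[nucleus_mask] <- background_AU + dna_signal_AU
  boundary <- array(background_AU + boundary_signal_AU, dims)
  boundary[cell_mask] <- background_AU

  noisy <- with_seed(seed, {
    lapply(list(dna = dna, boundary = boundary, protein = protein), function(ch) {
      if (!is.null(photons_per_au)) {
        ch <- array(rpois(length(ch), ch * photons_per_au) / photons_per_au,
                    dims)
      }
      if (read_noise_sd > 0) {
        ch <- ch + array(rnorm(length(ch), 0, read_noise_sd), dims)
      }
      ch
    })
  })
  stack <- image_stack(noisy$dna, noisy$boundary, noisy$protein, voxel_size_um)
  truth <- new_truth(
    "image_stack",
    nucleus_mask = nucleus_mask, cell_mask = cell_mask,
    conc_nuc_nM = conc_nuc_nM, conc_cyt_nM = conc_cyt_nM,
    k_nM = k_nM, background_AU = background_AU,
    volume_nucleus_um3 = v_nuc, volume_cytoplasm_um3 = v_cyt,
    volume_cell_um3 = v_nuc + v_cyt,
    count_nucleus = conc_nuc_nM * v_nuc * AVOGADRO_UM3_NM,
    count_cytoplasm = conc_cyt_nM * v_cyt * AVOGADRO_UM3_NM,
    count_cell = conc_nuc_nM * v_nuc * AVOGADRO_UM3_NM +
      conc_cyt_nM * v_cyt * AVOGADRO_UM3_NM,
    seed = seed
  )
  list(stack = stack, truth = truth)
}
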