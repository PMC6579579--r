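# 3D nucleus/cell segmentation of confocal z-stacks:
# crop -> isotropic z interpolation -> Gaussian smoothing -> Otsu
# nucleus detection (per-plane AND whole-stack) with iterative
# re-thresholding -> small-mass removal -> marker-based watershed for
# the cell region -> target selection by volume and centrality.

#' Otsu threshold of a numeric sample
#'
#' Classic histogram-based threshold maximising between-class variance.
#'
#' @param x numeric vector (or array) of intensities.
#' @param nbins number of histogram bins.
#' @return threshold value; voxels strictly above it are foreground.
#' @export
otsu_threshold <- function(x, nbins = 256) {
  x <- x[is.finite(x)]
  r <- range(x)
  if (diff(r) <= 0) return(r[1])
  h <- tabulate(pmin(pmax(
    as.integer((x - r[1]) / diff(r) * nbins) + 1L, 1L), nbins), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- r[1] + (seq_len(nbins) - 0.5) * diff(r) / nbins
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  # the criterion is flat across an empty gap between modes: take the
  # midpoint of the maximising plateau, not its left edge
  peak <- sigma_b >= max(sigma_b) * (1 - 1e-12)
  mean(mids[peak])
}

gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- dnorm(seq(-r, r), sd = sigma_vox)
  k / sum(k)
}

# Separable Gaussian smoothing of a 3D array; sigma given per dimension
# in voxels.
smooth_gaussian_3d <- function(a, sigma_vox) {
  dims <- dim(a)
  perms <- list(c(1, 2, 3), c(2, 1, 3), c(3, 2, 1))
  for (d in 1:3) {
    k <- gaussian_kernel_1d(sigma_vox[d])
    if (length(k) == 1) next
    ap <- aperm(a, perms[[d]])
    ap <- array(.conv_dim1(as.numeric(ap), dim(ap), k), dim(ap))
    a <- aperm(ap, order(perms[[d]]))
  }
  a
}

#' Interpolate a z-stack to isotropic voxels
#'
#' Resamples along z so that the z spacing matches the xy pixel size
#' (plane centres are aligned; edge planes are clamped). Linear
#' interpolation suits channels used for boundary detection;
#' `method = "nearest"` preserves voxel values and avoids partial-volume
#' mixing in channels that are averaged over compartments.
#'
#' @param a 3D array indexed `[z, y, x]`.
#' @param voxel_size_um voxel size `(z, y, x)`; x and y must match.
#' @param method `"linear"` (default) or `"nearest"`.
#' @return list with the resampled `array` and the isotropic
#'   `voxel_size_um` scalar.
#' @export
interpolate_isotropic <- function(a, voxel_size_um,
                                  method = c("linear", "nearest")) {
  method <- match.arg(method)
  dz <- voxel_size_um[1]; dxy <- voxel_size_um[2]
  if (abs(voxel_size_um[2] - voxel_size_um[3]) > 1e-9 * dxy) {
    stop_haloquant("xy pixel sizes must be equal", "invalid_parameter")
  }
  d <- dim(a)
  if (abs(dz - dxy) < 1e-9 * dxy) {
    return(list(array = a, voxel_size_um = dxy))
  }
  nz_new <- max(2L, as.integer(round(d[1] * dz / dxy)))
  # source plane centres at (i - 0.5) dz, targets at (j - 0.5) dxy
  zt <- (seq_len(nz_new) - 0.5) * dxy
  zs <- (seq_len(d[1]) - 0.5) * dz
  out <- array(0, c(nz_new, d[2], d[3]))
  for (j in seq_len(nz_new)) {
    k <- findInterval(zt[j], zs)
    if (k < 1) {
      out[j, , ] <- a[1, , ]
    } else if (k >= d[1]) {
      out[j, , ] <- a[d[1], , ]
    } else {
      w <- (zt[j] - zs[k]) / (zs[k + 1] - zs[k])
      if (method == "nearest") w <- round(w)
      out[j, , ] <- (1 - w) * a[k, , ] + w * a[k + 1, , ]
    }
  }
  list(array = out, voxel_size_um = dxy)
}

# Nucleus foreground mask: whole-stack Otsu AND per-plane Otsu (planes
# whose dynamic range is negligible contribute no foreground).
nucleus_mask_otsu <- function(dna) {
  thr_global <- otsu_threshold(dna)
  mask <- dna > thr_global
  global_spread <- diff(range(dna))
  for (z in seq_len(dim(dna)[1])) {
    plane <- dna[z, , ]
    if (diff(range(plane)) < 0.1 * global_spread) {
      # plane without real signal: per-plane Otsu would split noise
      mask[z, , ] <- FALSE
    } else {
      mask[z, , ] <- mask[z, , ] & (plane > otsu_threshold(plane))
    }
  }
  mask
}

label_components <- function(mask) {
  lab <- .cc_label_3d(as.logical(mask), dim(mask))
  array(lab, dim(mask))
}

component_stats <- function(labels, vox_vol, dims) {
  n <- max(labels)
  if (n == 0) return(data.frame())
  idx <- which(labels > 0)
  lab <- labels[idx]
  ai <- arrayInd(idx, dims)
  data.frame(
    label = seq_len(n),
    volume_um3 = as.numeric(tabulate(lab, n)) * vox_vol,
    cz = tapply(ai[, 1], lab, mean)[as.character(seq_len(n))],
    cy = tapply(ai[, 2], lab, mean)[as.character(seq_len(n))],
    cx = tapply(ai[, 3], lab, mean)[as.character(seq_len(n))]
  )
}

#' Segment nucleus and cell from a 3-channel confocal stack
#'
#' Runs the full pipeline described above. Nucleus detection accepts a
#' threshold only if the resulting masses pass plausibility checks on
#' volume and count; otherwise the brightest intensities are clipped at
#' `clip_quantile` and thresholding repeats (at most `max_iterations`
#' times). The cell region is recovered from the boundary channel
#' (bright outside the cell) by marker-based watershed seeded with the
#' nuclear masses and an image-border background marker. The reported
#' nucleus/cell is the largest in-range nucleus, ties broken by
#' proximity to the image centre.
#'
#' @param stack an [image_stack].
#' @param crop_um optional xy crop: side length (um) of the centred
#'   square region retained (default `NULL`, full frame).
#' @param sigma_um Gaussian smoothing s.d. in um.
#' @param nucleus_volume_range_um3 plausible nuclear volume range.
#' @param max_nuclei plausible upper bound on nucleus count.
#' @param min_volume_um3 masses smaller than this are discarded.
#' @param clip_quantile intensity quantile clipped per re-threshold
#'   iteration.
#' @param max_iterations maximum re-threshold iterations.
#' @param border_tolerance fraction of the selected cell's surface
#'   voxels allowed on the xy frame border before a leakage warning.
#' @return a `segmentation_result`: logical `nuclear_mask` and
#'   `cell_mask` (isotropic grid), `voxel_size_um` (scalar),
#'   `compartments` (data.frame with `compartment`, `Vp`, `V_um3`, `It`;
#'   measured on the original un-resampled grid so protein intensities
#'   carry no interpolation artefacts), `nucleus_table` of all detected
#'   nuclei (isotropic-grid volumes), and `diagnostics`.
#' @export
segment_stack <- function(stack,
                          crop_um = NULL,
                          sigma_um = 0.3,
                          nucleus_volume_range_um3 = c(150, 4000),
                          max_nuclei = 20,
                          min_volume_um3 = 30,
                          clip_quantile = 0.99,
                          max_iterations = 5,
                          border_tolerance = 0.02) {
  if (!inherits(stack, "image_stack")) {
    stop_haloquant("`stack` must be an image_stack", "invalid_parameter")
  }
  chans <- stack$channels
  vs <- stack$voxel_size_um
  # (1) optional central crop
  if (!is.null(crop_um)) {
    d <- dim(chans$dna)
    nkeep <- pmin(d[2:3], as.integer(round(crop_um / vs[2:3])))
    from <- pmax(1L, (d[2:3] - nkeep) %/% 2L + 1L)
    sel_y <- from[1]:(from[1] + nkeep[1] - 1L)
    sel_x <- from[2]:(from[2] + nkeep[2] - 1L)
    chans <- lapply(chans, function(a) a[, sel_y, sel_x, drop = FALSE])
  }
  # (2) isotropic interpolation, (3) smoothing. The protein channel is
  # never resampled: compartment sums are taken on the original voxel
  # grid (masks mapped back, below) so intensities carry no
  # partial-volume mixing from interpolation.
  iso <- lapply(chans[c("dna", "boundary")], interpolate_isotropic,
                voxel_size_um = vs)
  vox <- iso$dna$voxel_size_um
  sig_vox <- rep(sigma_um / vox, 3)
  dna <- smooth_gaussian_3d(iso$dna$array, sig_vox)
  boundary <- smooth_gaussian_3d(iso$boundary$array, sig_vox)
  protein <- chans$protein
  dims <- dim(dna)
  vox_vol <- vox^3

  # (4)-(6) nucleus detection with iterative re-thresholding
  work <- dna
  stats <- NULL
  labels <- NULL
  iter <- 0L
  repeat {
    iter <- iter + 1L
    mask <- nucleus_mask_otsu(work)
    labels <- label_components(mask)
    st <- component_stats(labels, vox_vol, dims)
    if (nrow(st) > 0) {
      st <- st[st$volume_um3 >= min_volume_um3, , drop = FALSE]
    }
    in_range <- if (nrow(st) > 0) {
      st$volume_um3 >= nucleus_volume_range_um3[1] &
        st$volume_um3 <= nucleus_volume_range_um3[2]
    } else {
      logical(0)
    }
    ok <- nrow(st) >= 1 && nrow(st) <= max_nuclei && any(in_range)
    if (ok || iter >= max_iterations) break
    # suppress the brightest intensities and re-threshold
    work <- pmin(work, quantile(work, clip_quantile))
  }
  if (!(nrow(st %||% data.frame()) >= 1 && any(in_range))) {
    stop_haloquant(sprintf(
      paste0("no nucleus within the plausible volume range ",
             "[%g, %g] um^3 after %d iterations (found %d masses)"),
      nucleus_volume_range_um3[1], nucleus_volume_range_um3[2],
      iter, nrow(st %||% data.frame())), "segmentation_failure")
  }
  # keep only retained components in the label array
  keep <- st$label
  relab <- integer(max(labels) + 1L)
  relab[keep + 1L] <- seq_along(keep)
  labels <- array(relab[labels + 1L], dims)
  st$label <- seq_len(nrow(st))
  in_range <- st$volume_um3 >= nucleus_volume_range_um3[1] &
    st$volume_um3 <= nucleus_volume_range_um3[2]

  # (8) target nucleus: largest in-range volume, near-ties (within 1%)
  # broken by centroid distance to the image centre
  cand <- st[in_range, , drop = FALSE]
  ctr <- (dims + 1) / 2
  cand$dist <- sqrt((cand$cz - ctr[1])^2 + (cand$cy - ctr[2])^2 +
                      (cand$cx - ctr[3])^2)
  near_max <- cand$volume_um3 >= max(cand$volume_um3) * 0.99
  pick <- cand[near_max, , drop = FALSE]
  target <- pick$label[which.min(pick$dist)]

  # (7) cell regions by marker-based watershed on the boundary channel:
  # the exclusion stain is bright outside cells, so the intracellular
  # foreground is the below-Otsu region; the watershed floods it from
  # the nuclear markers, splitting touching cells along intensity ridges
  fg <- boundary < otsu_threshold(boundary)
  ws <- array(
    .watershed_3d(as.numeric(boundary), as.integer(labels), dims,
                  fg | labels > 0L),
    dims
  )
  nuclear_mask <- labels == target
  cell_mask <- ws == target
  border <- array(FALSE, dims)
  border[, c(1L, dims[2]), ] <- TRUE
  border[, , c(1L, dims[3])] <- TRUE

  # leakage check: how much of the selected cell touches the xy border
  frac_border <- sum(cell_mask & border) / max(sum(border), 1L)
  if (frac_border > border_tolerance) {
    warning(sprintf(
      "cell region touches the frame border (%.1f%% of border voxels); possible watershed leakage",
      100 * frac_border))
  }

  # map masks back to the original anisotropic grid (nearest source
  # plane per original plane centre) and sum the raw protein channel
  d0 <- dim(protein)
  zs <- (seq_len(d0[1]) - 0.5) * vs[1]
  j_near <- pmin(pmax(as.integer(round(zs / vox + 0.5)), 1L), dims[1])
  to_aniso <- function(m) {
    a <- m[j_near, , , drop = FALSE]
    dim(a) <- d0
    a
  }
  vox_vol0 <- prod(vs)
  comp_masks <- list(nucleus = to_aniso(nuclear_mask),
                     cell = to_aniso(cell_mask))
  comp_masks$cell <- comp_masks$cell | comp_masks$nucleus
  comp_masks <- list(nucleus = comp_masks$nucleus,
                     cytoplasm = comp_masks$cell & !comp_masks$nucleus,
                     cell = comp_masks$cell)
  compartments <- do.call(rbind, lapply(names(comp_masks), function(nm) {
    m <- comp_masks[[nm]]
    data.frame(compartment = nm, Vp = sum(m), V_um3 = sum(m) * vox_vol0,
               It = sum(protein[m]))
  }))
  structure(
    list(
      nuclear_mask = nuclear_mask, cell_mask = cell_mask,
      voxel_size_um = vox, compartments = compartments,
      nucleus_table = st, target_label = target,
      protein = protein,
      diagnostics = list(iterations = iter, n_masses = nrow(st),
                         border_fraction = frac_border)
    ),
    class = "segmentation_result"
  )
}

#' @export
print.segmentation_result <- function(x, ...) {
  v <- x$compartments
  cat(sprintf(
    "<segmentation_result: nucleus %.0f um^3, cell %.0f um^3 (%d nuclei found)>\n",
    v$V_um3[v$compartment == "nucleus"], v$V_um3[v$compartment == "cell"],
    nrow(x$nucleus_table)))
  invisible(x)
}

#' Dice similarity of two masks
#'
#' @param a,b logical arrays of identical dimension.
#' @return `2|a & b| / (|a| + |b|)`.
#' @export
dice_coefficient <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop_haloquant("masks must have identical dimensions", "invalid_parameter")
  }
  2 * sum(a & b) / (sum(a) + sum(b))
}
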