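# In-gel fluorescence quantification: molecules per cell from lysate
# band intensities normalised by a purified-protein standard curve.

#' Fit the fluorescence-per-molecule standard curve
#'
#' Least-squares line of band intensity against loaded molecule number
#' over the standard lanes, through the origin by default (zero
#' molecules give zero specific signal); an intercept can be allowed
#' with `intercept = TRUE`, in which case the slope is still reported as
#' the fluorescence per molecule. Because band noise scales with band
#' intensity (multiplicative), the default weighting is
#' `1/amount^2` — for the origin fit this is the mean of the per-lane
#' intensity/amount ratios, the maximum-likelihood slope under
#' constant-CV noise. `weighting = "none"` gives the ordinary fit, which
#' is dominated by the brightest lane.
#'
#' @param lanes gel-lane data.frame (see [gen_gel_lanes()]); only rows
#'   with `kind == "standard"` are used.
#' @param intercept fit an intercept instead of forcing the origin.
#' @param weighting `"inverse_amount_sq"` (default) or `"none"`.
#' @return an object of class `standard_curve` with elements
#'   `fluorescence_per_molecule`, `intercept`, `n_points`,
#'   `residual_rms` and `max_standard_intensity`.
#' @export
fit_standard_curve <- function(lanes, intercept = FALSE,
                               weighting = c("inverse_amount_sq", "none")) {
  weighting <- match.arg(weighting)
  std <- lanes[lanes$kind == "standard", , drop = FALSE]
  std <- std[is.finite(std$amount) & std$amount > 0, , drop = FALSE]
  if (nrow(std) < 2 || length(unique(std$amount)) < 2) {
    stop_haloquant(
      "need at least 2 standard lanes with distinct positive amounts",
      "insufficient_standard"
    )
  }
  w <- if (weighting == "inverse_amount_sq") 1 / std$amount^2 else NULL
  fit <- if (intercept) {
    stats::lm(band_intensity ~ amount, data = std, weights = w)
  } else {
    stats::lm(band_intensity ~ 0 + amount, data = std, weights = w)
  }
  slope <- unname(coef(fit)[["amount"]])
  if (!is.finite(slope) || slope <= 0) {
    stop_haloquant("fitted fluorescence per molecule is not positive",
                   "degenerate_standard")
  }
  structure(
    list(
      fluorescence_per_molecule = slope,
      intercept = if (intercept) unname(coef(fit)[[1]]) else 0,
      n_points = nrow(std),
      residual_rms = sqrt(mean(resid(fit)^2)),
      max_standard_intensity = max(std$band_intensity)
    ),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve: %.4g AU/molecule, %d points, residual RMS %.3g AU>\n",
    x$fluorescence_per_molecule, x$n_points, x$residual_rms))
  invisible(x)
}

#' Molecules per cell from one lysate lane
#'
#' `band_intensity / (fluorescence_per_molecule * n_cells)`. Lanes whose
#' intensity exceeds the top of the standard range are still converted
#' but flagged (`extrapolated` attribute) rather than dropped.
#'
#' @param lysate_lane a one-row gel-lane data.frame with `kind ==
#'   "lysate"`, or a list with `band_intensity` and `n_cells`.
#' @param curve a [fit_standard_curve()] result.
#' @return molecules per cell (numeric scalar); attribute
#'   `extrapolated` is `TRUE` when the lane lies above the standards.
#' @export
molecules_per_cell <- function(lysate_lane, curve) {
  intensity <- lysate_lane$band_intensity
  n_cells <- lysate_lane$n_cells
  check_number(intensity, "band_intensity", lower = 0)
  if (!is.finite(n_cells) || n_cells <= 0) {
    stop_haloquant("lysate lane must carry a positive cell count",
                   "invalid_lane")
  }
  value <- intensity / (curve$fluorescence_per_molecule * n_cells)
  attr(value, "extrapolated") <- intensity > curve$max_standard_intensity
  value
}

#' Labeling efficiency from a dye-titration experiment
#'
#' Fits the hyperbolic saturation model `I(c) = Imax * c / (K + c)` to
#' background-corrected fluorescence versus dye concentration and
#' returns the occupied fraction `I(c*) / Imax = c* / (K + c*)` at the
#' queried labeling concentration. Efficiency is relative to the fitted
#' plateau, not to the highest measured point.
#'
#' @param titration data.frame with columns `dye_concentration` (nM) and
#'   `background_corrected_intensity` (AU).
#' @param at_concentration concentration (nM) at which to evaluate.
#' @return labeling efficiency in `[0, 1]`, with attributes `Imax`, `K`.
#' @export
labeling_efficiency <- function(titration, at_concentration) {
  check_number(at_concentration, "at_concentration", lower = 0)
  conc <- titration$dye_concentration
  ints <- titration$background_corrected_intensity
  keep <- is.finite(conc) & is.finite(ints) & conc > 0
  conc <- conc[keep]; ints <- ints[keep]
  if (length(conc) < 3) {
    stop_haloquant("need at least 3 titration points with positive dye",
                   "invalid_parameter")
  }
  if (max(ints) <= 0) {
    stop_haloquant("titration carries no positive intensity", "fit_failure")
  }
  rel_spread <- (max(ints) - min(ints)) / max(ints)
  if (rel_spread < 1e-9) {
    # already saturated everywhere: K -> 0, efficiency 1 at any c > 0
    out <- if (at_concentration > 0) 1 else 0
    attr(out, "Imax") <- max(ints); attr(out, "K") <- 0
    return(out)
  }
  df <- data.frame(c = conc, I = ints)
  half <- max(ints) / 2
  k0 <- max(min(conc[which.min(abs(ints - half))], max(conc)), min(conc) / 10)
  fit <- tryCatch(
    nls(I ~ Imax * c / (K + c), data = df,
        start = list(Imax = max(ints), K = k0),
        lower = c(Imax = 0, K = 0), algorithm = "port",
        control = nls.control(maxiter = 200, scaleOffset = 1)),
    error = function(e) {
      stop_haloquant(paste0("saturation fit did not converge: ",
                            conditionMessage(e)), "fit_failure")
    }
  )
  K <- coef(fit)[["K"]]
  out <- min(max(at_concentration / (K + at_concentration), 0), 1)
  attr(out, "Imax") <- coef(fit)[["Imax"]]
  attr(out, "K") <- K
  out
}

#' Combine replicate abundance estimates
#'
#' Arithmetic mean and sample (n - 1) standard deviation over
#' independent biological replicates. A single replicate reports a
#' standard deviation of 0 together with `single_replicate = TRUE`.
#'
#' @param values replicate estimates (molecules per cell or percent).
#' @param cell_line,method labels carried into the result.
#' @return an `abundance_estimate`: list with `cell_line`, `method`,
#'   `replicate_values`, `mean`, `std`, `n`, `single_replicate`.
#' @export
aggregate_replicates <- function(values, cell_line = NA_character_,
                                 method = NA_character_) {
  values <- as.numeric(values)
  if (length(values) == 0 || any(!is.finite(values))) {
    stop_haloquant("`values` must be a non-empty finite numeric vector",
                   "invalid_parameter")
  }
  structure(
    list(cell_line = cell_line, method = method,
         replicate_values = values,
         mean = mean(values), std = sample_sd0(values),
         n = length(values), single_replicate = length(values) == 1L),
    class = "abundance_estimate"
  )
}

#' @export
print.abundance_estimate <- function(x, ...) {
  cat(sprintf("<abundance_estimate %s [%s]: %.4g +/- %.3g (n = %d)>\n",
              x$cell_line, x$method, x$mean, x$std, x$n))
  invisible(x)
}

#' Molecules per cell for a whole gel-lane table
#'
#' Convenience wrapper: fits the standard curve per replicate gel and
#' converts every lysate lane, then combines per-replicate values
#' (lysate lanes of one replicate are averaged first).
#'
#' @param lanes gel-lane data.frame with both standard and lysate rows.
#' @param per_replicate_standard fit one curve per replicate (default)
#'   or a single pooled curve.
#' @param intercept passed to [fit_standard_curve()].
#' @return an `abundance_estimate` for the lysate cell line.
#' @export
gel_abundance <- function(lanes, per_replicate_standard = TRUE,
                          intercept = FALSE) {
  lys <- lanes[lanes$kind == "lysate", , drop = FALSE]
  if (nrow(lys) == 0) {
    stop_haloquant("no lysate lanes in table", "invalid_parameter")
  }
  reps <- sort(unique(lys$replicate))
  pooled <- if (!per_replicate_standard) {
    fit_standard_curve(lanes, intercept = intercept)
  }
  per_rep <- vapply(reps, function(r) {
    curve <- if (per_replicate_standard) {
      fit_standard_curve(lanes[lanes$replicate == r, , drop = FALSE],
                         intercept = intercept)
    } else {
      pooled
    }
    rl <- lys[lys$replicate == r, , drop = FALSE]
    mean(vapply(seq_len(nrow(rl)), function(i) {
      as.numeric(molecules_per_cell(rl[i, , drop = FALSE], curve))
    }, numeric(1)))
  }, numeric(1))
  aggregate_replicates(per_rep, cell_line = lys$cell_line[1], method = "gel")
}
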