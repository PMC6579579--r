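# Flow-cytometry cross-calibration: absolute abundance of any tagged
# line from its mean fluorescence relative to a quantified standard
# line, with line-matched unlabeled-background subtraction.

#' Mean fluorescence intensity of one sample
#'
#' @param sample numeric vector of per-event intensities, or a
#'   data.frame with an `intensity_au` column.
#' @return arithmetic mean intensity (AU).
#' @export
sample_mean_intensity <- function(sample) {
  x <- if (is.data.frame(sample)) sample$intensity_au else sample
  if (length(x) == 0) {
    stop_haloquant("sample has no events", "invalid_parameter")
  }
  if (any(!is.finite(x))) {
    stop_haloquant("sample intensities must be finite", "invalid_parameter")
  }
  mean(x)
}

#' Rescale sample means so the standard line reads 10,000 AU
#'
#' Reproduces the reporting convention in which the labeled standard
#' line's mean is scaled to exactly 10,000 arbitrary units and all other
#' samples are rescaled by the same factor. The abundance ratio is
#' invariant under this common factor; scaling affects reported
#' intermediate numbers only.
#'
#' @param events event table with columns `cell_line`, `labeled`,
#'   `intensity_au` (see [gen_fcm_events()]).
#' @param standard_line cell-line label of the labeled standard.
#' @param target scaled value of the standard mean (default 10,000).
#' @return data.frame with `cell_line`, `labeled`, `mean_au`,
#'   `mean_scaled`.
#' @export
scale_to_standard <- function(events, standard_line, target = 10000) {
  groups <- split(events, interaction(events$cell_line, events$labeled,
                                      drop = TRUE))
  means <- do.call(rbind, lapply(groups, function(g) {
    data.frame(cell_line = g$cell_line[1], labeled = g$labeled[1],
               mean_au = mean(g$intensity_au))
  }))
  row.names(means) <- NULL
  std <- means$mean_au[means$cell_line == standard_line & means$labeled]
  if (length(std) != 1 || std <= 0) {
    stop_haloquant("labeled standard sample missing or non-positive",
                   "calibration_error")
  }
  means$mean_scaled <- means$mean_au * target / std
  means
}

#' Absolute abundance from background-subtracted intensity ratio
#'
#' `n_X = (I_X - I_bg_X) / (I_std - I_bg_std) * n_std`, where the
#' backgrounds are unlabeled cells of the matching line. A negative
#' numerator is clamped to zero and flagged; a non-positive denominator
#' is a calibration error.
#'
#' @param I_X,I_bg_X mean intensities of the labeled / unlabeled target.
#' @param I_std,I_bg_std mean intensities of the labeled / unlabeled
#'   standard line.
#' @param standard_abundance molecules per cell of the standard line.
#' @return molecules per cell, with attribute `flags` (character vector,
#'   possibly empty; see [dynamic_range_flags()]).
#' @export
abundance_from_intensities <- function(I_X, I_bg_X, I_std, I_bg_std,
                                       standard_abundance) {
  check_number(standard_abundance, "standard_abundance",
               lower = 0, strict_lower = TRUE)
  denom <- I_std - I_bg_std
  if (!is.finite(denom) || denom <= 0) {
    stop_haloquant("standard intensity does not exceed its background",
                   "calibration_error")
  }
  numer <- I_X - I_bg_X
  flags <- character(0)
  if (numer < 0) {
    warning("background exceeds labeled intensity; abundance clamped to 0")
    flags <- "negative_clamped"
    numer <- 0
  }
  n_X <- numer / denom * standard_abundance
  attr(n_X, "flags") <- c(flags, dynamic_range_flags(n_X))
  n_X
}

#' Validity flags for the FCM dynamic range
#'
#' The ratio method is unreliable for very lowly expressed proteins
#' (below ~10,000 molecules per cell, where background dominates) and
#' for extremely highly expressed ones (above ~10 million, where
#' labeling and detection saturate).
#'
#' @param n_X estimated molecules per cell.
#' @param low,high warning thresholds.
#' @return character vector of zero or more of `"low_abundance"`,
#'   `"high_abundance"`.
#' @export
dynamic_range_flags <- function(n_X, low = 1e4, high = 1e7) {
  check_number(n_X, "n_X", lower = 0)
  c(character(0),
    if (n_X < low) "low_abundance",
    if (n_X > high) "high_abundance")
}

#' Absolute abundances for every line in an FCM event table
#'
#' Computes per-line mean intensities, subtracts the line-matched
#' unlabeled background (or a shared fallback background if a line has
#' no control), and converts to molecules per cell against the standard.
#'
#' @param events event table (`cell_line`, `labeled`, `intensity_au`).
#' @param standard_line label of the quantified standard cell line.
#' @param standard_abundance its molecules per cell.
#' @param shared_background_line optional line whose unlabeled sample
#'   serves as background for lines lacking their own control.
#' @return data.frame with `cell_line`, `n_X`, `flags` (comma-joined).
#' @export
fcm_abundance <- function(events, standard_line, standard_abundance,
                          shared_background_line = NULL) {
  means <- scale_to_standard(events, standard_line)
  get_mean <- function(line, labeled) {
    v <- means$mean_au[means$cell_line == line & means$labeled == labeled]
    if (length(v) == 1) v else NA_real_
  }
  bg_of <- function(line) {
    v <- get_mean(line, FALSE)
    if (is.na(v) && !is.null(shared_background_line)) {
      v <- get_mean(shared_background_line, FALSE)
    }
    if (is.na(v)) {
      stop_haloquant(sprintf("no unlabeled background for line '%s'", line),
                     "calibration_error")
    }
    v
  }
  I_std <- get_mean(standard_line, TRUE)
  I_bg_std <- bg_of(standard_line)
  lines <- setdiff(unique(means$cell_line[means$labeled]), standard_line)
  out <- lapply(lines, function(line) {
    n <- abundance_from_intensities(get_mean(line, TRUE), bg_of(line),
                                    I_std, I_bg_std, standard_abundance)
    data.frame(cell_line = line, n_X = as.numeric(n),
               flags = paste(attr(n, "flags"), collapse = ","))
  })
  do.call(rbind, out)
}
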