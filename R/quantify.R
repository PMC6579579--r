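# Per-compartment concentration and molecule number from a segmented
# stack and the FCS imaging calibration.

#' Concentrations and molecule numbers per compartment
#'
#' Applies the calibrated-imaging equations per compartment:
#' `Ca = (It/Vp - Ib) * k_nM` (mean background-subtracted intensity times
#' the calibration factor) and `Nt = Ca * V_um3 * NA` with NA the
#' molecules-per-um^3-per-nM constant [AVOGADRO_UM3_NM]. With the total
#' compartment volume in um^3 this form conserves molecule number:
#' nucleus + cytoplasm = cell exactly. The literal variant
#' `Nt = (It - Vp*Ib) * k_nM * V_um3 * NA` (total rather than mean
#' intensity) is available behind `literal = TRUE` for comparison with
#' legacy outputs; it is not dimensionally consistent with `Ca`.
#'
#' @param seg a [segment_stack()] result (or any list with a
#'   `compartments` data.frame of `compartment`, `Vp`, `V_um3`, `It`).
#' @param calib a [calibration_factor()] (fields `k_nM`,
#'   `background_Ib`).
#' @param literal use the literal total-intensity variant of the
#'   molecule-number equation.
#' @return a `compartment_quant`: data.frame `table` with `compartment`,
#'   `Ca_nM`, `Nt`, plus `nuclear_fraction` and `flags`.
#' @export
compartment_quant <- function(seg, calib, literal = FALSE) {
  comp <- seg$compartments
  if (is.null(comp) || nrow(comp) == 0 || any(comp$Vp <= 0)) {
    stop_haloquant("segmentation has an empty compartment", "invalid_parameter")
  }
  k <- calib$k_nM
  Ib <- calib$background_Ib
  flags <- character(0)
  Ca <- (comp$It / comp$Vp - Ib) * k
  if (any(Ca < 0)) {
    flags <- c(flags, "negative_concentration_clamped")
    Ca <- pmax(Ca, 0)
  }
  Nt <- if (literal) {
    pmax((comp$It - comp$Vp * Ib) * k * comp$V_um3 * AVOGADRO_UM3_NM, 0)
  } else {
    Ca * comp$V_um3 * AVOGADRO_UM3_NM
  }
  tab <- data.frame(compartment = comp$compartment, Vp = comp$Vp,
                    V_um3 = comp$V_um3, Ca_nM = Ca, Nt = Nt)
  n_nuc <- tab$Nt[tab$compartment == "nucleus"]
  n_cell <- tab$Nt[tab$compartment == "cell"]
  structure(
    list(table = tab,
         nuclear_fraction = if (length(n_cell) && n_cell > 0) {
           n_nuc / n_cell
         } else {
           NA_real_
         },
         flags = flags),
    class = "compartment_quant"
  )
}

#' @export
print.compartment_quant <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("nuclear fraction: %.3f\n", x$nuclear_fraction))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Nuclear fraction of total cellular molecules
#'
#' @param quant a [compartment_quant()] result.
#' @return `Nt(nucleus) / Nt(cell)`, in `[0, 1]`.
#' @export
nuclear_fraction <- function(quant) {
  tab <- quant$table
  n_cell <- tab$Nt[tab$compartment == "cell"]
  if (length(n_cell) != 1 || n_cell <= 0) {
    stop_haloquant("cell compartment has no molecules", "invalid_parameter")
  }
  tab$Nt[tab$compartment == "nucleus"] / n_cell
}
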