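# Cohesin dimer-fraction inference from reciprocal-tag IP/CoIP band
# intensities.

#' IP and CoIP efficiencies from band intensities
#'
#' Loading-corrected pull-down efficiencies:
#' `%IP = input_fraction * I_IP / (ip_load_fraction * I_IN)` and
#' `%CoIP = input_fraction * I_CoIP / (coip_load_fraction * I_IN)`,
#' where `input_fraction` (default 1.5%) is how much of the input went
#' on the gel and the load fractions (default 10% / 90%) how much of the
#' pull-down material was loaded for the IP and CoIP blots.
#'
#' @param exp one experiment: list/one-row data.frame with `I_IN`,
#'   `I_IP`, `I_CoIP` and optionally the three loading fractions.
#' @return named numeric `c(pct_ip, pct_coip)` (fractions, not percent).
#' @export
coip_efficiencies <- function(exp) {
  input_fraction <- exp$input_fraction %||% 0.015
  ip_load <- exp$ip_load_fraction %||% 0.1
  coip_load <- exp$coip_load_fraction %||% 0.9
  for (f in c(input_fraction, ip_load, coip_load)) {
    if (!is.finite(f) || f <= 0 || f > 1) {
      stop_haloquant("loading fractions must be in (0, 1]",
                     "invalid_parameter")
    }
  }
  if (!is.finite(exp$I_IN) || exp$I_IN <= 0) {
    stop_haloquant("input band intensity must be > 0", "invalid_parameter")
  }
  c(pct_ip = input_fraction * exp$I_IP / (ip_load * exp$I_IN),
    pct_coip = input_fraction * exp$I_CoIP / (coip_load * exp$I_IN))
}

#' Dimer fraction from IP/CoIP efficiencies
#'
#' Under the equal-likelihood pairing assumption (bait:bait dimers as
#' frequent as bait:prey dimers, with the two tagged alleles expressed
#' at the same level), the bait monomer signal is
#' `M = %IP - 3 * %CoIP`, the monomer fraction `M / %IP`, and hence
#' `dimer_fraction = 3 * %CoIP / %IP`. If `%CoIP > %IP / 3` the algebra
#' leaves `[0, 1]`; the result is clamped and flagged
#' (`out_of_model`) rather than silently accepted. The alternative
#' random-pairing model (bait:bait : bait:prey : prey:prey = 1:2:1,
#' giving `dimer_fraction = 2 * %CoIP / %IP`) is provided for
#' sensitivity analysis only.
#'
#' @param pct_ip,pct_coip efficiencies from [coip_efficiencies()].
#' @param pairing `"equal"` (default) or `"random"`.
#' @return a `dimer_estimate`: list with `pct_ip`, `pct_coip`,
#'   `monomer_fraction`, `dimer_fraction`, `flags`.
#' @export
dimer_fraction <- function(pct_ip, pct_coip, pairing = c("equal", "random")) {
  pairing <- match.arg(pairing)
  check_number(pct_coip, "pct_coip", lower = 0)
  if (!is.finite(pct_ip) || pct_ip <= 0) {
    stop_haloquant("pct_ip must be > 0", "invalid_parameter")
  }
  mult <- if (pairing == "equal") 3 else 2
  d <- mult * pct_coip / pct_ip
  flags <- character(0)
  if (d > 1 + 1e-9) {
    flags <- "out_of_model"
    warning("CoIP efficiency exceeds the model bound (pct_coip > pct_ip/",
            mult, "); dimer fraction clamped to 1")
  }
  d <- min(d, 1)
  structure(
    list(pct_ip = unname(pct_ip), pct_coip = unname(pct_coip),
         monomer_fraction = 1 - d, dimer_fraction = d,
         pairing = pairing, flags = flags),
    class = "dimer_estimate"
  )
}

#' @export
print.dimer_estimate <- function(x, ...) {
  cat(sprintf("<dimer_estimate: %.2f%% dimeric (%%IP %.3g, %%CoIP %.3g)%s>\n",
              100 * x$dimer_fraction, x$pct_ip, x$pct_coip,
              if (length(x$flags)) paste0(" [", x$flags, "]") else ""))
  invisible(x)
}

#' Dimer fraction for a table of CoIP experiments
#'
#' Runs [coip_efficiencies()] and [dimer_fraction()] per row and
#' aggregates the dimer percentages (mean, sample std over experiments).
#'
#' @param experiments data.frame with `I_IN`, `I_IP`, `I_CoIP` and
#'   optionally `antibody`, `benzonase` and loading columns.
#' @param pairing passed to [dimer_fraction()].
#' @return list with `per_experiment` (data.frame) and `aggregate`
#'   (an `abundance_estimate` of dimer percentages).
#' @export
coip_stoichiometry <- function(experiments, pairing = "equal") {
  if (!is.data.frame(experiments) || nrow(experiments) == 0) {
    stop_haloquant("`experiments` must be a non-empty data.frame",
                   "invalid_parameter")
  }
  rows <- lapply(seq_len(nrow(experiments)), function(i) {
    e <- experiments[i, , drop = FALSE]
    eff <- coip_efficiencies(e)
    est <- dimer_fraction(eff[["pct_ip"]], eff[["pct_coip"]],
                          pairing = pairing)
    data.frame(
      antibody = e$antibody %||% NA_character_,
      benzonase = e$benzonase %||% NA,
      pct_ip = est$pct_ip, pct_coip = est$pct_coip,
      dimer_pct = 100 * est$dimer_fraction,
      flags = paste(est$flags, collapse = ",")
    )
  })
  per_experiment <- do.call(rbind, rows)
  list(
    per_experiment = per_experiment,
    aggregate = aggregate_replicates(per_experiment$dimer_pct,
                                     cell_line = "coip", method = "coip")
  )
}
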