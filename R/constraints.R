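# Cell-cycle classification and the genome-model constraint arithmetic:
# CTCF site occupancy, extruding-cohesin density/spacing, cross-method
# estimate combination.

# Two-component 1D Gaussian mixture EM. Returns NULL on failure.
gmm2_em <- function(x, max_iter = 200, tol = 1e-8) {
  q <- quantile(x, c(0.25, 0.75), names = FALSE)
  if (diff(q) <= 0) return(NULL)
  mu <- q
  s <- rep(max(stats::sd(x) / 2, 1e-12), 2)
  w <- c(0.5, 0.5)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * dnorm(x, mu[1], s[1])
    d2 <- w[2] * dnorm(x, mu[2], s[2])
    tot <- d1 + d2
    if (any(!is.finite(tot)) || any(tot <= 0)) return(NULL)
    r <- d1 / tot
    w <- c(mean(r), 1 - mean(r))
    if (any(w < 1e-12)) return(NULL)
    mu <- c(sum(r * x) / sum(r), sum((1 - r) * x) / sum(1 - r))
    s <- sqrt(c(sum(r * (x - mu[1])^2) / sum(r),
                sum((1 - r) * (x - mu[2])^2) / sum(1 - r)))
    s <- pmax(s, 1e-12)
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  if (mu[1] > mu[2]) {
    mu <- rev(mu); s <- rev(s); w <- rev(w); r <- 1 - r
  }
  list(mu = mu, sigma = s, weight = w, resp_low = r)
}

#' Classify cell-cycle phases from DAPI/EdU bivariate events
#'
#' S-phase cells are those whose EdU signal exceeds a quantile (default
#' 99.5%) of the EdU-negative control. The EdU-negative remainder is
#' split into G1 and G2 by a two-component Gaussian mixture on DAPI
#' (lower-mean component = G1, 2C DNA content). When the mixture does
#' not converge, a midpoint threshold between the DAPI quartiles is used
#' and flagged. When the EdU-negative pool is effectively unimodal (the
#' component means differ by less than `unimodal_ratio`-fold, so the
#' 2C/4C doubling is absent), the whole pool is assigned to one phase:
#' G1 if its mean lies below 1.5x the inferred 2C level (taken from
#' `dapi_2c`, or from 2/3 of the median DAPI of S-phase events), G2
#' otherwise, defaulting to G1 when no reference exists.
#'
#' @param events data.frame with `dapi_au` and `edu_au`.
#' @param negative_control data.frame with `edu_au` of an unpulsed
#'   sample.
#' @param edu_quantile control quantile defining the EdU gate.
#' @param edu_gate `"quantile"` (default: threshold at `edu_quantile` of
#'   the control) or `"otsu"` (threshold in the gap of the log-EdU
#'   histogram of the pulsed sample; exact when the S and background
#'   populations are fully separated).
#' @param unimodal_ratio minimum 4C/2C component-mean ratio to accept a
#'   bimodal split (the true ratio is 2).
#' @param dapi_2c optional known 2C DAPI level.
#' @return a `cell_cycle_fractions`: list with `fractions`
#'   (named `G1`, `S`, `G2`), `edu_threshold`, `flags`.
#' @export
classify_cell_cycle <- function(events, negative_control,
                                edu_quantile = 0.995,
                                edu_gate = c("quantile", "otsu"),
                                unimodal_ratio = 1.35,
                                dapi_2c = NULL) {
  edu_gate <- match.arg(edu_gate)
  if (!nrow(events) || !nrow(negative_control)) {
    stop_haloquant("events and control must both be non-empty",
                   "invalid_parameter")
  }
  thr <- if (edu_gate == "quantile") {
    quantile(negative_control$edu_au, edu_quantile, names = FALSE)
  } else {
    exp(otsu_threshold(log(pmax(events$edu_au, .Machine$double.xmin))))
  }
  s_pos <- events$edu_au > thr
  n <- nrow(events)
  flags <- character(0)
  dapi_neg <- events$dapi_au[!s_pos]
  if (length(dapi_neg) == 0) {
    fr <- c(G1 = 0, S = 1, G2 = 0)
    return(structure(list(fractions = fr, edu_threshold = thr,
                          flags = flags), class = "cell_cycle_fractions"))
  }
  fit <- gmm2_em(dapi_neg)
  if (is.null(fit)) {
    flags <- c(flags, "gmm_fallback")
    mid <- mean(quantile(dapi_neg, c(0.25, 0.75), names = FALSE))
    n_g1 <- sum(dapi_neg <= mid)
    n_g2 <- length(dapi_neg) - n_g1
  } else if (fit$mu[2] / fit$mu[1] < unimodal_ratio) {
    # no 2C/4C separation: the pool is one phase
    # a 2C reference from S-phase DAPI (~3C at mid-S) is only trusted
    # when a real S population exists, not a handful of gate outliers
    ref_2c <- dapi_2c %||% if (mean(s_pos) >= 0.05) {
      (2 / 3) * median(events$dapi_au[s_pos])
    } else {
      NULL
    }
    pool_is_g1 <- is.null(ref_2c) || mean(dapi_neg) < 1.5 * ref_2c
    flags <- c(flags, "unimodal_pool")
    n_g1 <- if (pool_is_g1) length(dapi_neg) else 0L
    n_g2 <- length(dapi_neg) - n_g1
  } else {
    assign_g1 <- fit$resp_low > 0.5
    n_g1 <- sum(assign_g1)
    n_g2 <- length(dapi_neg) - n_g1
  }
  fr <- c(G1 = n_g1 / n, S = sum(s_pos) / n, G2 = n_g2 / n)
  structure(list(fractions = fr, edu_threshold = thr, flags = flags),
            class = "cell_cycle_fractions")
}

#' @export
print.cell_cycle_fractions <- function(x, ...) {
  f <- x$fractions
  cat(sprintf("<cell cycle: G1 %.1f%%, S %.1f%%, G2 %.1f%%>\n",
              100 * f["G1"], 100 * f["S"], 100 * f["G2"]))
  invisible(x)
}

#' Expected genome copies per cell from cell-cycle fractions
#'
#' `2 fG1 + 3 fS + 4 fG2`: G1 cells carry 2 genome copies, G2 cells 4,
#' and a mid-S cell is assigned 3 (half-replicated). Rounding to an
#' integer copy number is left to the caller.
#'
#' @param fractions numeric `(fG1, fS, fG2)` summing to 1, or a
#'   `cell_cycle_fractions` object.
#' @param copies copies per phase, default `c(2, 3, 4)`.
#' @return expected genome copies per cell.
#' @export
mean_genome_copies <- function(fractions, copies = c(2, 3, 4)) {
  if (inherits(fractions, "cell_cycle_fractions")) {
    fractions <- fractions$fractions
  }
  fractions <- as.numeric(fractions)
  if (length(fractions) != 3 || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    stop_haloquant("`fractions` must be 3 non-negative values summing to 1",
                   "invalid_parameter")
  }
  sum(fractions * copies)
}

#' Average fractional occupancy per binding site
#'
#' `f = f_bound * n_protein / (genome_copies * n_sites_haploid)`: the
#' number of specifically bound molecules divided by the total number of
#' sites in the cell, i.e. the time-averaged probability that a site is
#' occupied, assuming all sites are equally likely to be bound. Values
#' above 1 are returned as-is with an `over_occupancy` flag.
#'
#' @param f_bound fraction of molecules bound to specific sites.
#' @param n_protein molecules per cell.
#' @param n_sites_haploid binding sites per haploid genome.
#' @param genome_copies genome copies per cell.
#' @return occupancy fraction, attribute `flags`.
#' @export
fractional_occupancy <- function(f_bound, n_protein, n_sites_haploid,
                                 genome_copies) {
  check_number(f_bound, "f_bound", 0, 1)
  check_number(n_protein, "n_protein", lower = 0, strict_lower = TRUE)
  check_number(genome_copies, "genome_copies", lower = 0, strict_lower = TRUE)
  if (!is.finite(n_sites_haploid) || n_sites_haploid <= 0) {
    stop_haloquant("`n_sites_haploid` must be > 0", "invalid_parameter")
  }
  f <- f_bound * n_protein / (genome_copies * n_sites_haploid)
  attr(f, "flags") <- if (f > 1) "over_occupancy" else character(0)
  f
}

#' Density and spacing of extruding cohesin complexes
#'
#' `density_molecules = f_engaged * n_cohesin / (genome_copies *
#' genome_size_Mb)` molecules per Mb; with `stoichiometry` rings per
#' extruding unit (1 for single rings, 2 for paired rings) the unit
#' density is `density_molecules / stoichiometry` and the mean genomic
#' spacing `1000 / density_units` kb.
#'
#' @param f_engaged fraction of cohesin topologically engaged in
#'   extrusion.
#' @param n_cohesin cohesin complexes (Rad21 molecules) per cell.
#' @param genome_size_Mb haploid genome size in Mb.
#' @param genome_copies genome copies per cell.
#' @param stoichiometry rings per extruding unit, 1 or 2.
#' @return a `constraint_results`: list with `density_molecules_per_Mb`,
#'   `density_units_per_Mb`, `spacing_kb`, `flags`.
#' @export
extrusion_density <- function(f_engaged, n_cohesin, genome_size_Mb,
                              genome_copies, stoichiometry = 1) {
  check_number(f_engaged, "f_engaged", 0, 1)
  check_number(n_cohesin, "n_cohesin", lower = 0, strict_lower = TRUE)
  check_number(genome_copies, "genome_copies", lower = 0, strict_lower = TRUE)
  if (!is.finite(genome_size_Mb) || genome_size_Mb <= 0) {
    stop_haloquant("`genome_size_Mb` must be > 0", "invalid_parameter")
  }
  if (!stoichiometry %in% c(1, 2)) {
    stop_haloquant("`stoichiometry` must be 1 or 2", "invalid_parameter")
  }
  dm <- f_engaged * n_cohesin / (genome_copies * genome_size_Mb)
  du <- dm / stoichiometry
  flags <- character(0)
  spacing <- if (du > 0) {
    1000 / du
  } else {
    flags <- "zero_density"
    NA_real_
  }
  structure(
    list(density_molecules_per_Mb = dm, density_units_per_Mb = du,
         spacing_kb = spacing, stoichiometry = stoichiometry,
         flags = flags),
    class = "constraint_results"
  )
}

#' @export
print.constraint_results <- function(x, ...) {
  cat(sprintf(
    "<extrusion density: %.3g molecules/Mb, %.3g units/Mb (stoichiometry %d), spacing %.3g kb>\n",
    x$density_molecules_per_Mb, x$density_units_per_Mb, x$stoichiometry,
    x$spacing_kb))
  invisible(x)
}

#' Combine method-level abundance estimates into a final average
#'
#' Arithmetic mean across methods, then rounded to the nearest hundred
#' with halves rounded up — the convention that reproduces the published
#' final averages from their method-level inputs.
#'
#' @param values method-level estimates (molecules per cell).
#' @param round_to rounding multiple (default 100); `NA` disables
#'   rounding.
#' @return combined estimate (molecules per cell).
#' @export
combine_estimates <- function(values, round_to = 100) {
  values <- as.numeric(values)
  if (length(values) == 0 || any(!is.finite(values))) {
    stop_haloquant("`values` must be a non-empty finite numeric vector",
                   "invalid_parameter")
  }
  m <- mean(values)
  if (is.na(round_to)) m else round_half_up(m, round_to)
}
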