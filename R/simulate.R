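# Synthetic-data generators. Each generator returns a list with the
# simulated dataset plus a `truth` record (class "halo_truth") holding
# every parameter needed to predict the downstream noiseless estimate.
# Identical seed + parameters give bit-identical output.

new_truth <- function(generator, ...) {
  structure(c(list(generator = generator), list(...)), class = "halo_truth")
}

#' @export
print.halo_truth <- function(x, ...) {
  cat("<ground truth:", x$generator, ">\n")
  for (nm in setdiff(names(x), "generator")) {
    v <- x[[nm]]
    if (is.numeric(v) && length(v) <= 6) {
      cat(" ", nm, "=", paste(signif(v, 6), collapse = ", "), "\n")
    } else {
      cat(" ", nm, ": <", class(v)[1], ">\n", sep = "")
    }
  }
  invisible(x)
}

#' Simulate an in-gel fluorescence titration experiment
#'
#' Generates one gel per replicate: standard lanes with known amounts of
#' purified labeled protein, and lysate lanes with known cell counts.
#' Band intensity is linear in molecule number with multiplicative
#' zero-mean Gaussian noise of coefficient of variation `noise_cv`.
#'
#' @param true_abundance molecules per cell of the tagged protein.
#' @param fpm fluorescence per molecule (AU/molecule) of the gel scanner.
#' @param standard_amounts vector of standard-lane amounts (molecules).
#' @param cells_per_lane vector of lysate-lane cell counts; one lysate
#'   lane per entry and per replicate.
#' @param n_replicates number of biological replicates (gels).
#' @param noise_cv multiplicative noise CV (0 = noiseless).
#' @param cell_line label carried through to the output table.
#' @param seed RNG seed.
#' @return list with `lanes` (a data.frame with columns `lane_id`,
#'   `kind`, `band_intensity`, `amount`, `n_cells`, `replicate`,
#'   `cell_line`) and `truth`.
#' @export
gen_gel_lanes <- function(true_abundance, fpm,
                          standard_amounts = c(0.5, 1, 2, 4, 8, 16) * 1e9,
                          cells_per_lane = c(5e4, 1e5, 1.5e5),
                          n_replicates = 1,
                          noise_cv = 0.05,
                          cell_line = "simulated",
                          seed = 1) {
  check_number(true_abundance, "true_abundance", lower = 0, strict_lower = TRUE)
  check_number(fpm, "fpm", lower = 0, strict_lower = TRUE)
  check_number(noise_cv, "noise_cv", lower = 0)
  if (any(standard_amounts <= 0) || any(cells_per_lane <= 0)) {
    stop_haloquant("amounts and cell counts must be > 0", "invalid_parameter")
  }
  with_seed(seed, {
    rows <- list()
    for (r in seq_len(n_replicates)) {
      for (i in seq_along(standard_amounts)) {
        mu <- fpm * standard_amounts[i]
        rows[[length(rows) + 1L]] <- data.frame(
          lane_id = sprintf("rep%d_std%d", r, i), kind = "standard",
          band_intensity = mu * (1 + rnorm(1, 0, noise_cv)),
          amount = standard_amounts[i], n_cells = NA_real_,
          replicate = r, cell_line = cell_line
        )
      }
      for (i in seq_along(cells_per_lane)) {
        mu <- fpm * true_abundance * cells_per_lane[i]
        rows[[length(rows) + 1L]] <- data.frame(
          lane_id = sprintf("rep%d_lys%d", r, i), kind = "lysate",
          band_intensity = mu * (1 + rnorm(1, 0, noise_cv)),
          amount = NA_real_, n_cells = cells_per_lane[i],
          replicate = r, cell_line = cell_line
        )
      }
    }
    lanes <- do.call(rbind, rows)
    lanes$band_intensity <- pmax(lanes$band_intensity, 0)
    list(
      lanes = lanes,
      truth = new_truth("gel", abundance = true_abundance, fpm = fpm,
                        noise_cv = noise_cv, seed = seed)
    )
  })
}

#' Simulate per-cell flow-cytometry fluorescence events
#'
#' For each cell line, draws a labeled and an unlabeled sample. Per-cell
#' tag signal is lognormal with arithmetic mean
#' `au_per_molecule * abundance` and shape `sigma`; autofluorescence
#' background is an additive (linear-space) lognormal draw shared
#' event-wise between the labeled/unlabeled pair of a line, so an
#' abundance-zero labeled sample is event-identical to its control.
#'
#' @param lines data.frame with columns `cell_line`, `true_abundance`
#'   (molecules/cell) and `au_per_molecule` (AU per molecule).
#' @param sigma lognormal shape (sdlog) of the per-cell signal.
#' @param background_meanlog,background_sdlog log-space parameters of
#'   the additive autofluorescence background.
#' @param n_events events per sample.
#' @param seed RNG seed.
#' @return list with `events` (data.frame: `cell_line`, `labeled`,
#'   `event_id`, `intensity_au`) and `truth`.
#' @export
gen_fcm_events <- function(lines, sigma = 0.4,
                           background_meanlog = log(200),
                           background_sdlog = 0.3,
                           n_events = 10000, seed = 1) {
  if (!is.data.frame(lines) || nrow(lines) == 0) {
    stop_haloquant("`lines` must be a non-empty data.frame", "invalid_parameter")
  }
  check_number(n_events, "n_events", lower = 1)
  with_seed(seed, {
    per_line_seeds <- sample.int(.Machine$integer.max, nrow(lines))
    out <- vector("list", 2L * nrow(lines))
    for (i in seq_len(nrow(lines))) {
      ab <- lines$true_abundance[i]
      au <- lines$au_per_molecule[i]
      # derived per-line seed: the labeled and unlabeled sample of a
      # line share the same background event stream
      set.seed(per_line_seeds[i])
      bg <- rlnorm(n_events, background_meanlog, background_sdlog)
      signal <- if (ab > 0) {
        m <- au * ab
        rlnorm(n_events, log(m) - sigma^2 / 2, sigma)
      } else {
        rep(0, n_events)
      }
      out[[2 * i - 1L]] <- data.frame(
        cell_line = lines$cell_line[i], labeled = TRUE,
        event_id = seq_len(n_events), intensity_au = bg + signal
      )
      out[[2 * i]] <- data.frame(
        cell_line = lines$cell_line[i], labeled = FALSE,
        event_id = seq_len(n_events), intensity_au = bg
      )
    }
    list(
      events = do.call(rbind, out),
      truth = new_truth("fcm", lines = lines, sigma = sigma,
                        background_mean = exp(background_meanlog +
                                                background_sdlog^2 / 2),
                        n_events = n_events, seed = seed)
    )
  })
}

#' Simulate an FCS autocorrelation curve
#'
#' Evaluates the two-component 3D free-diffusion autocorrelation model
#' (see [two_component_model()]) on a lag grid and adds heteroscedastic
#' Gaussian noise: the noise s.d. at lag tau is
#' `noise_sd * sqrt(Gn(tau))` where `Gn` is the model decay normalised
#' to 1 at zero lag, so short lags (large amplitude) are noisier — the
#' empirical pattern of measured correlation curves.
#'
#' @param N_mean mean number of molecules in the focal volume.
#' @param f1 fraction of the fast component, in `[0, 1]`.
#' @param tau1_s,tau2_s diffusion times of the two components (seconds).
#' @param kappa structure parameter (axial/lateral focal extent ratio).
#' @param offset additive baseline of the correlation curve.
#' @param lags_s strictly increasing positive lag grid (seconds).
#' @param noise_sd noise scale at zero lag (0 = noiseless).
#' @param seed RNG seed.
#' @return list with `curve` (data.frame: `lag_s`, `g`) and `truth`.
#' @export
gen_fcs_curve <- function(N_mean, f1, tau1_s, tau2_s, kappa = 5,
                          offset = 0,
                          lags_s = 10^seq(-6, 0, length.out = 120),
                          noise_sd = 0, seed = 1) {
  check_number(N_mean, "N_mean", lower = 0, strict_lower = TRUE)
  check_number(f1, "f1", lower = 0, upper = 1)
  check_number(kappa, "kappa", lower = 0, strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  if (any(lags_s <= 0) || any(diff(lags_s) <= 0)) {
    stop_haloquant("`lags_s` must be strictly increasing and positive",
                   "invalid_parameter")
  }
  g <- two_component_model(lags_s, N_mean = N_mean, f1 = f1,
                           tau1 = tau1_s, tau2 = tau2_s,
                           kappa = kappa, offset = offset)
  if (noise_sd > 0) {
    gn <- (g - offset) * N_mean  # decay normalised to 1 at lag -> 0
    g <- with_seed(seed, g + rnorm(length(g), 0, noise_sd * sqrt(pmax(gn, 0))))
  }
  list(
    curve = data.frame(lag_s = lags_s, g = g),
    truth = new_truth("fcs", N_mean = N_mean, f1 = f1, tau1 = tau1_s,
                      tau2 = tau2_s, kappa = kappa, offset = offset,
                      noise_sd = noise_sd, seed = seed)
  )
}

#' Simulate reciprocal-tag IP/CoIP band intensities
#'
#' Forward model of the dual-tag co-immunoprecipitation assay under the
#' equal-likelihood pairing assumption (as many bait:bait dimers as
#' bait:prey dimers). With dimer fraction `d` and pull-down efficiency
#' `e`, the loading-corrected efficiencies are `%IP = e` and
#' `%CoIP = d * e / 3`, and band intensities are laid out on the gel at
#' the stated loading fractions so that [coip_stoichiometry()] inverts
#' them back to `d` exactly in the noiseless case.
#'
#' @param true_dimer_fraction fraction of molecules in dimers, `[0, 1]`.
#' @param ip_efficiency pull-down efficiency, `(0, 1]`.
#' @param input_total_AU input band intensity before loading correction.
#' @param loading named vector of gel-loading fractions
#'   (`input`, `ip`, `coip`); the published defaults are 1.5%, 10%, 90%.
#' @param antibodies bait tag of each experiment.
#' @param benzonase nuclease-treatment flag of each experiment.
#' @param noise_cv multiplicative band-intensity noise CV.
#' @param seed RNG seed.
#' @return list with `experiments` (data.frame: `antibody`, `benzonase`,
#'   `I_IN`, `I_IP`, `I_CoIP`, loading columns) and `truth`.
#' @export
gen_coip <- function(true_dimer_fraction, ip_efficiency = 0.3,
                     input_total_AU = 1e5,
                     loading = c(input = 0.015, ip = 0.1, coip = 0.9),
                     antibodies = c("V5", "V5", "FLAG", "FLAG"),
                     benzonase = c(FALSE, TRUE, FALSE, TRUE),
                     noise_cv = 0, seed = 1) {
  check_number(true_dimer_fraction, "true_dimer_fraction", 0, 1)
  check_number(ip_efficiency, "ip_efficiency", lower = 0, upper = 1,
               strict_lower = TRUE)
  if (any(loading <= 0) || any(loading > 1)) {
    stop_haloquant("loading fractions must be in (0, 1]", "invalid_parameter")
  }
  check_number(noise_cv, "noise_cv", lower = 0)
  n <- length(antibodies)
  pct_ip <- ip_efficiency
  pct_coip <- true_dimer_fraction * ip_efficiency / 3
  with_seed(seed, {
    eps <- function() 1 + rnorm(n, 0, noise_cv)
    I_IN <- input_total_AU * loading[["input"]] / 0.015 * eps()
    # band = efficiency * input-equivalent * (load / input-load ratio)
    I_IP <- pct_ip * I_IN * loading[["ip"]] / loading[["input"]] * eps()
    I_CoIP <- pct_coip * I_IN * loading[["coip"]] / loading[["input"]] * eps()
    experiments <- data.frame(
      antibody = antibodies, benzonase = benzonase,
      I_IN = I_IN, I_IP = I_IP, I_CoIP = I_CoIP,
      input_fraction = loading[["input"]],
      ip_load_fraction = loading[["ip"]],
      coip_load_fraction = loading[["coip"]]
    )
    list(
      experiments = experiments,
      truth = new_truth("coip", dimer_fraction = true_dimer_fraction,
                        ip_efficiency = ip_efficiency,
                        noise_cv = noise_cv, seed = seed)
    )
  })
}

#' Simulate a bivariate DAPI/EdU cell-cycle dataset
#'
#' Draws G1, S and G2 events at the given fractions. DNA content (DAPI)
#' is Gaussian about the 2C mean for G1 and the 4C mean for G2 with CV
#' `dapi_cv`; S-phase DNA content is uniform between 2C and 4C (simplest
#' replication model) with the same multiplicative measurement noise.
#' EdU is lognormal autofluorescence for G1/G2 and shifted up by
#' `edu_pos_shift`-fold for S. A matching EdU-negative control table
#' (no EdU pulse: background only) is generated alongside.
#'
#' @param fractions numeric `(fG1, fS, fG2)` summing to 1; the default
#'   is the published mESC interphase distribution.
#' @param dapi_means DAPI means `(2C, 4C)`; 4C must exceed 2C.
#' @param dapi_cv DAPI coefficient of variation.
#' @param edu_pos_shift fold-increase of EdU signal in S-phase cells.
#' @param edu_meanlog,edu_sdlog log-space EdU background parameters.
#' @param n_events total events (0 gives empty tables).
#' @param seed RNG seed.
#' @return list with `events` and `control` (data.frames: `dapi_au`,
#'   `edu_au`, and for `events` the true `phase`) and `truth`.
#' @export
gen_cell_cycle <- function(fractions = c(0.102, 0.739, 0.159),
                           dapi_means = c(100, 200), dapi_cv = 0.08,
                           edu_pos_shift = 30,
                           edu_meanlog = log(10), edu_sdlog = 0.5,
                           n_events = 50000, seed = 1) {
  if (length(fractions) != 3 || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    stop_haloquant("`fractions` must be 3 non-negative values summing to 1",
                   "invalid_parameter")
  }
  if (dapi_means[2] <= dapi_means[1]) {
    stop_haloquant("4C DAPI mean must exceed the 2C mean", "invalid_parameter")
  }
  check_number(n_events, "n_events", lower = 0)
  with_seed(seed, {
    n <- as.integer(n_events)
    phase <- if (n > 0) {
      sample(c("G1", "S", "G2"), n, replace = TRUE, prob = fractions)
    } else {
      character(0)
    }
    dapi <- numeric(n)
    edu <- numeric(n)
    g1 <- phase == "G1"; s <- phase == "S"; g2 <- phase == "G2"
    dapi[g1] <- dapi_means[1] * (1 + rnorm(sum(g1), 0, dapi_cv))
    dapi[g2] <- dapi_means[2] * (1 + rnorm(sum(g2), 0, dapi_cv))
    dapi[s] <- runif(sum(s), dapi_means[1], dapi_means[2]) *
      (1 + rnorm(sum(s), 0, dapi_cv))
    edu[!s] <- rlnorm(sum(!s), edu_meanlog, edu_sdlog)
    edu[s] <- rlnorm(sum(s), edu_meanlog + log(edu_pos_shift), edu_sdlog)
    ctrl_phase <- if (n > 0) {
      sample(c("G1", "S", "G2"), n, replace = TRUE, prob = fractions)
    } else {
      character(0)
    }
    cdapi <- numeric(n)
    cg1 <- ctrl_phase == "G1"; cs <- ctrl_phase == "S"; cg2 <- ctrl_phase == "G2"
    cdapi[cg1] <- dapi_means[1] * (1 + rnorm(sum(cg1), 0, dapi_cv))
    cdapi[cg2] <- dapi_means[2] * (1 + rnorm(sum(cg2), 0, dapi_cv))
    cdapi[cs] <- runif(sum(cs), dapi_means[1], dapi_means[2]) *
      (1 + rnorm(sum(cs), 0, dapi_cv))
    cedu <- rlnorm(n, edu_meanlog, edu_sdlog)
    list(
      events = data.frame(dapi_au = dapi, edu_au = edu, phase = phase),
      control = data.frame(dapi_au = cdapi, edu_au = cedu),
      truth = new_truth("cell_cycle", fractions = fractions,
                        dapi_means = dapi_means, dapi_cv = dapi_cv,
                        edu_pos_shift = edu_pos_shift, seed = seed)
    )
  })
}
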