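# Fluorescence correlation spectroscopy: two-component free-diffusion
# model, curve fitting, effective-volume calibration and the
# intensity -> concentration calibration factor.

#' Two-component 3D free-diffusion autocorrelation model
#'
#' `G(tau) = offset + (1/N) * (f1 * g(tau; tau1) + (1 - f1) * g(tau; tau2))`
#' with the 3D Gaussian focal-volume decay
#' `g(tau; taud) = (1 + tau/taud)^-1 * (1 + tau/(kappa^2 taud))^-1/2`.
#' No triplet/blinking term. At `tau -> 0` the curve approaches
#' `offset + 1/N`; at `tau -> Inf` it decays to `offset`.
#'
#' @param lag lag time(s) in seconds, > 0 (vectorised).
#' @param N_mean mean molecule number in the focal volume.
#' @param f1 fraction of the fast component.
#' @param tau1,tau2 diffusion times (s) of the fast / slow component.
#' @param kappa structure parameter (axial-to-lateral focal ratio).
#' @param offset baseline.
#' @return G values, same length as `lag`.
#' @export
two_component_model <- function(lag, N_mean, f1, tau1, tau2,
                                kappa = 5, offset = 0) {
  g1 <- 1 / ((1 + lag / tau1) * sqrt(1 + lag / (kappa^2 * tau1)))
  g2 <- 1 / ((1 + lag / tau2) * sqrt(1 + lag / (kappa^2 * tau2)))
  offset + (f1 * g1 + (1 - f1) * g2) / N_mean
}

# data-driven starting values: baseline from the curve tail, amplitude
# from the head, diffusion times from the lags where the normalised
# decay crosses 0.7 and 0.2.
fcs_start_values <- function(lags, g) {
  offset0 <- mean(tail(g, max(3L, length(g) %/% 10)))
  amp <- max(g[1] - offset0, .Machine$double.eps)
  gn <- (g - offset0) / amp
  lag_at <- function(level) {
    i <- which(gn <= level)[1]
    if (is.na(i)) tail(lags, 1) else lags[max(i, 2L)]
  }
  list(N_mean = 1 / amp, f1 = 0.6,
       tau1 = lag_at(0.7) / 2, tau2 = lag_at(0.2) * 2, offset = offset0)
}

#' Fit the two-component diffusion model to an autocorrelation curve
#'
#' Weighted nonlinear least squares (port algorithm, bounded). The two
#' components are re-ordered afterwards so that `tau1 < tau2`.
#' Parameters that end up pinned at a bound (e.g. `f1` = 1 for
#' effectively single-component data) are flagged. `kappa` is fixed by
#' default — in practice it is determined once from the dye calibration
#' and reused for cell measurements — but can be fitted.
#'
#' @param curve data.frame with `lag_s` and `g` (and optionally
#'   `weight`), or the `curve` element of [gen_fcs_curve()] output.
#' @param kappa structure parameter (fixed unless `fit_kappa`).
#' @param fit_kappa also fit `kappa`.
#' @param init optional named list of starting values
#'   (`N_mean`, `f1`, `tau1`, `tau2`, `offset`).
#' @param weights optional per-point weights (default equal).
#' @param v_eff_um3 optional effective confocal volume; when supplied
#'   the fit also reports `concentration_nM = N / (V_eff * NA)`.
#' @return an `fcs_fit`: list with the fitted parameters, `residual_rms`,
#'   `flags` and optionally `concentration_nM`.
#' @export
fit_autocorrelation <- function(curve, kappa = 5, fit_kappa = FALSE,
                                init = NULL, weights = NULL,
                                v_eff_um3 = NULL) {
  lags <- curve$lag_s
  g <- curve$g
  if (length(lags) < 8) {
    stop_haloquant("need at least 8 lag points to fit", "invalid_parameter")
  }
  s <- fcs_start_values(lags, g)
  if (!is.null(init)) s[names(init)] <- init
  w <- weights %||% rep(1, length(g))
  df <- data.frame(lag = lags, g = g, w = w)

  lower <- c(N_mean = 1e-6, f1 = 0, tau1 = min(lags) / 10,
             tau2 = min(lags) / 10, offset = -1)
  upper <- c(N_mean = 1e9, f1 = 1, tau1 = max(lags) * 10,
             tau2 = max(lags) * 10, offset = 1)
  start <- list(N_mean = s$N_mean, f1 = s$f1, tau1 = s$tau1,
                tau2 = s$tau2, offset = s$offset)
  if (fit_kappa) {
    start$kappa <- kappa
    lower <- c(lower, kappa = 0.5)
    upper <- c(upper, kappa = 100)
    form <- g ~ two_component_model(lag, N_mean, f1, tau1, tau2, kappa, offset)
  } else {
    form <- substitute(
      g ~ two_component_model(lag, N_mean, f1, tau1, tau2, K, offset),
      list(K = kappa)
    )
  }
  fit <- withCallingHandlers(
    tryCatch(
      nls(form, data = df, start = start, weights = w,
          lower = lower[names(start)], upper = upper[names(start)],
          algorithm = "port",
          control = nls.control(maxiter = 500, scaleOffset = 1,
                                warnOnly = TRUE)),
      error = function(e) {
        stop_haloquant(paste0("autocorrelation fit failed: ",
                              conditionMessage(e)), "fit_failure")
      }
    ),
    warning = function(w) invokeRestart("muffleWarning")
  )
  conv_flag <- character(0)
  ci <- fit$convInfo
  if (!is.null(ci) && !isTRUE(ci$isConv)) {
    # port's "false convergence" reports a usable local optimum; keep
    # the fit but flag it so downstream users can discount it
    conv_flag <- "questionable_convergence"
  }
  p <- as.list(coef(fit))
  if (!fit_kappa) p$kappa <- kappa
  # order components so tau1 < tau2
  if (p$tau1 > p$tau2) {
    tmp <- p$tau1; p$tau1 <- p$tau2; p$tau2 <- tmp
    p$f1 <- 1 - p$f1
  }
  flags <- conv_flag
  tol <- 1e-6
  # effectively single-component data: the two diffusion times collapse
  # and f1 becomes unidentifiable; canonicalise to f1 = 1 and flag
  if (p$tau2 / p$tau1 < 1.2) {
    p$tau1 <- p$tau2 <- p$f1 * p$tau1 + (1 - p$f1) * p$tau2
    p$f1 <- 1
    flags <- c(flags, "single_component")
  }
  if (p$f1 <= tol || p$f1 >= 1 - tol) flags <- c(flags, "f1_at_bound")
  if (p$N_mean <= lower[["N_mean"]] * (1 + 1e-6)) {
    flags <- c(flags, "N_at_bound")
  }
  out <- list(
    N_mean = p$N_mean, f1 = p$f1, tau1 = p$tau1, tau2 = p$tau2,
    kappa = p$kappa, offset = p$offset,
    residual_rms = sqrt(mean(resid(fit)^2)), flags = flags
  )
  if (!is.null(v_eff_um3)) {
    out$concentration_nM <- p$N_mean / (v_eff_um3 * AVOGADRO_UM3_NM)
  }
  structure(out, class = "fcs_fit")
}

#' @export
print.fcs_fit <- function(x, ...) {
  cat(sprintf(
    "<fcs_fit: N = %.4g, f1 = %.3f, tau1 = %.3g s, tau2 = %.3g s, kappa = %.3g>\n",
    x$N_mean, x$f1, x$tau1, x$tau2, x$kappa))
  if (!is.null(x$concentration_nM)) {
    cat(sprintf("  concentration: %.4g nM\n", x$concentration_nM))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Effective confocal volume from a dye measurement
#'
#' A solution of known concentration C containing N molecules in the
#' focal volume gives `V_eff = N / (C * NA)` with NA the
#' molecules-per-um^3-per-nM constant [AVOGADRO_UM3_NM]; the result is
#' in um^3 (= fL).
#'
#' @param dye_fit an `fcs_fit` of the dye measurement (or any list with
#'   an `N_mean` element).
#' @param known_concentration_nM dye concentration (nM), > 0.
#' @return effective volume in um^3, class `effective_volume`.
#' @export
effective_volume_from_dye <- function(dye_fit, known_concentration_nM) {
  check_number(known_concentration_nM, "known_concentration_nM",
               lower = 0, strict_lower = TRUE)
  N <- dye_fit$N_mean
  if (!is.finite(N) || N <= 0) {
    stop_haloquant("dye fit has non-positive N_mean", "invalid_parameter")
  }
  structure(N / (known_concentration_nM * AVOGADRO_UM3_NM),
            class = "effective_volume")
}

#' Concentration from an FCS fit and effective volume
#'
#' @param fit an `fcs_fit` (or list with `N_mean`).
#' @param v_eff_um3 effective confocal volume (um^3).
#' @return concentration in nM.
#' @export
fcs_concentration <- function(fit, v_eff_um3) {
  check_number(as.numeric(v_eff_um3), "v_eff_um3",
               lower = 0, strict_lower = TRUE)
  fit$N_mean / (as.numeric(v_eff_um3) * AVOGADRO_UM3_NM)
}

#' Imaging calibration factor from paired FCS/image measurements
#'
#' Least-squares line through the origin of FCS concentration against
#' background-subtracted image intensity at the same spots:
#' `C = k_nM * (I - I_b)`. A single point gives the exact ratio.
#'
#' @param points data.frame with `intensity_au` (image intensity at the
#'   FCS spot) and `concentration_nM` (FCS-derived concentration).
#' @param background_Ib image background intensity (AU).
#' @return a `calibration_factor`: list with `k_nM`, `background_Ib`,
#'   `n_points`, `residual_rms`.
#' @export
calibration_factor <- function(points, background_Ib = 0) {
  check_number(background_Ib, "background_Ib", lower = 0)
  x <- points$intensity_au - background_Ib
  y <- points$concentration_nM
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 1 || all(x <= 0)) {
    stop_haloquant("no calibration point above background",
                   "calibration_error")
  }
  k <- sum(y * x) / sum(x^2)
  if (!is.finite(k) || k <= 0) {
    stop_haloquant("calibration slope is not positive", "calibration_error")
  }
  structure(
    list(k_nM = k, background_Ib = background_Ib, n_points = length(x),
         residual_rms = sqrt(mean((y - k * x)^2))),
    class = "calibration_factor"
  )
}

#' @export
print.calibration_factor <- function(x, ...) {
  cat(sprintf(
    "<calibration_factor: k = %.4g nM/AU, Ib = %.3g AU, %d points>\n",
    x$k_nM, x$background_Ib, x$n_points))
  invisible(x)
}
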