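#' Construct an ITC titration series
#'
#' @param heats_ucal integrated heats per injection (microcalories).
#' @param injection_volumes_uL injection volumes (uL), one per heat.
#' @param cell_volume_uL calorimeter cell volume (uL).
#' @param cell_conc_uM macromolecule concentration in the cell (uM).
#' @param syringe_conc_uM ligand concentration in the syringe (uM).
#' @param temperature_K temperature; default 298.15 K (25 C).
#' @return object of class `titration_series`.
#' @export
titration_series <- function(heats_ucal, injection_volumes_uL,
                             cell_volume_uL = 200, cell_conc_uM,
                             syringe_conc_uM, temperature_K = 298.15) {
  if (length(heats_ucal) != length(injection_volumes_uL))
    stop("one injection volume per heat required")
  if (length(heats_ucal) < 10) stop("at least 10 injections required")
  if (any(c(cell_volume_uL, cell_conc_uM, syringe_conc_uM) <= 0))
    stop("volumes and concentrations must be positive")
  if (any(!is.finite(heats_ucal))) stop("heats must be finite")
  structure(list(heats_ucal = heats_ucal,
                 injection_volumes_uL = injection_volumes_uL,
                 cell_volume_uL = cell_volume_uL,
                 cell_conc_uM = cell_conc_uM,
                 syringe_conc_uM = syringe_conc_uM,
                 temperature_K = temperature_K),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("ITC titration: %d injections, cell %g uM (%g uL), syringe %g uM, %g K\n",
              length(x$heats_ucal), x$cell_conc_uM, x$cell_volume_uL,
              x$syringe_conc_uM, x$temperature_K))
  invisible(x)
}

#' One-site Wiseman model heats
#'
#' Closed-form integrated heats for a single-site binding titration. After
#' injection i (cumulative injected volume dV), total concentrations in the
#' cell are corrected for the displaced volume as
#' `Mt = M0*(1 - dV/(2*V0))/(1 + dV/(2*V0))` and
#' `Xt = X0*(dV/V0)*(1 - dV/(2*V0))`. The cumulative heat is
#' `Q = (n*Mt*dH*V0/2) * (1 + Xt/(n*Mt) + Kd/(n*Mt) -
#'   sqrt((1 + Xt/(n*Mt) + Kd/(n*Mt))^2 - 4*Xt/(n*Mt)))`
#' and the per-injection heat is obtained by differencing with the standard
#' displaced-volume term `dQ_i = Q_i - Q_{i-1} + (v_i/V0)*(Q_i + Q_{i-1})/2`,
#' plus a constant dilution offset per mole of injectant.
#'
#' @param Kd dissociation constant (uM).
#' @param dH binding enthalpy (kcal/mol).
#' @param n stoichiometry.
#' @param cell_conc,syringe_conc concentrations (uM).
#' @param injection_volumes per-injection volumes (uL).
#' @param cell_volume cell volume (uL).
#' @param dilution_offset dilution heat (kcal per mol injectant).
#' @return per-injection heats in microcalories.
#' @export
wiseman_heats <- function(Kd, dH, n, cell_conc, syringe_conc,
                          injection_volumes, cell_volume = 200,
                          dilution_offset = 0) {
  V0 <- cell_volume
  dV <- cumsum(injection_volumes)
  Mt <- cell_conc * (1 - dV / (2 * V0)) / (1 + dV / (2 * V0))
  Xt <- syringe_conc * (dV / V0) * (1 - dV / (2 * V0))
  a <- 1 + Xt / (n * Mt) + Kd / (n * Mt)
  Q <- (n * Mt * dH * V0 / 2) * (a - sqrt(a^2 - 4 * Xt / (n * Mt)))
  Q <- Q * 1e-3  # uM * uL * kcal/mol -> ucal
  Qprev <- c(0, Q[-length(Q)])
  dQ <- Q - Qprev + (injection_volumes / V0) * (Q + Qprev) / 2
  # dilution heat: offset per mole injected
  dQ + dilution_offset * syringe_conc * injection_volumes * 1e-3
}

#' Fit a one-site binding model to ITC heats
#'
#' Nonlinear least squares (Levenberg-Marquardt) of the Wiseman one-site
#' closed form ([wiseman_heats()]) against integrated per-injection heats,
#' co-fitting Kd, the binding enthalpy, the stoichiometry and a constant
#' per-injection dilution offset. Kd is fitted on the log scale (positivity);
#' its standard error is delta-method transformed back.
#'
#' Heats that carry no resolvable binding signal -- a flat series, or a fitted
#' enthalpy smaller than 3x its standard error -- are reported as
#' `binding = "not measurable"` rather than as parameter estimates, matching
#' how weak binders are reported experimentally.
#'
#' @param series a [titration_series()].
#' @return object of class `itc_fit` with `Kd`, `dH`, `n`, `dilution_offset`
#'   (each `_se` where applicable), `converged`, `binding`
#'   (`"measurable"`/`"not measurable"`), `residual_sd`, and the input series.
#' @examples
#' cfg <- scenario_config(seed = 1, noise_cv = 0)
#' ser <- gen_itc_titration(Kd = 6.1, dH = -5.02, n = 0.6, cell_conc = 70,
#'                          syringe_conc = 1000, config = cfg)
#' fit <- fit_one_site(ser)
#' coef(fit)
#' @export
fit_one_site <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  h <- series$heats_ucal
  v <- series$injection_volumes_uL

  not_measurable <- function() {
    structure(list(converged = FALSE, binding = "not measurable",
                   series = series),
              class = "itc_fit")
  }
  if (diff(range(h)) == 0) return(not_measurable())

  model <- function(p) {
    wiseman_heats(exp(p[1]), p[2], p[3], series$cell_conc_uM,
                  series$syringe_conc_uM, v, series$cell_volume_uL, p[4])
  }
  resid_fn <- function(p) h - model(p)

  # molar ratio at the steepest heat change approximates the equivalence point
  ratio <- series$syringe_conc_uM * cumsum(v) /
    (series$cell_conc_uM * series$cell_volume_uL)
  n0 <- ratio[which.max(abs(diff(h)))]
  if (!is.finite(n0) || n0 <= 0) n0 <- 1
  dh0 <- h[1] / (series$syringe_conc_uM * v[1] * 1e-3)
  if (!is.finite(dh0) || dh0 == 0) dh0 <- -1

  best <- NULL
  for (kd0 in series$cell_conc_uM * c(0.01, 0.1, 1, 10)) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = c(log(kd0), dh0, n0, 0), fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 1000, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$deviance < best$deviance))
      best <- res
  }
  if (is.null(best)) stop("one-site fit did not converge; residuals unavailable")

  p <- best$par
  np <- length(h) - length(p)
  sigma2 <- best$deviance / max(1, np)
  covm <- tryCatch(sigma2 * solve(best$hessian), error = function(e)
    matrix(NA_real_, 4, 4))
  se <- suppressWarnings(sqrt(pmax(diag(covm), 0)))
  Kd <- exp(p[1])
  Kd_se <- Kd * se[1]
  dH <- p[2]; dH_se <- se[2]

  if (is.finite(dH_se) && dH_se > 0 && abs(dH) < 3 * dH_se)
    return(not_measurable())

  structure(list(Kd = Kd, Kd_se = Kd_se, dH = dH, dH_se = dH_se,
                 n = p[3], n_se = se[3],
                 dilution_offset = p[4], dilution_offset_se = se[4],
                 converged = TRUE, binding = "measurable",
                 residual_sd = sqrt(sigma2), series = series,
                 fitted_heats = model(p)),
            class = "itc_fit")
}

#' @export
print.itc_fit <- function(x, ...) {
  if (x$binding == "not measurable") {
    cat("One-site ITC fit: binding not measurable under these conditions\n")
    return(invisible(x))
  }
  cat("One-site ITC fit (Wiseman isotherm)\n")
  cat(sprintf("  Kd = %.4g +/- %.3g uM\n", x$Kd, x$Kd_se))
  cat(sprintf("  dH = %.4g +/- %.3g kcal/mol\n", x$dH, x$dH_se))
  cat(sprintf("  n  = %.4g +/- %.3g\n", x$n, x$n_se))
  cat(sprintf("  dilution offset = %.3g kcal/mol injectant\n",
              x$dilution_offset))
  invisible(x)
}

#' @export
coef.itc_fit <- function(object, ...) {
  if (object$binding == "not measurable")
    return(c(Kd = NA_real_, dH = NA_real_, n = NA_real_))
  c(Kd = object$Kd, dH = object$dH, n = object$n)
}

#' @export
summary.itc_fit <- function(object, ...) {
  if (object$binding == "not measurable") {
    cat("Binding not measurable under these conditions.\n")
    return(invisible(object))
  }
  tab <- data.frame(
    estimate = c(object$Kd, object$dH, object$n, object$dilution_offset),
    se = c(object$Kd_se, object$dH_se, object$n_se, object$dilution_offset_se),
    row.names = c("Kd (uM)", "dH (kcal/mol)", "n", "offset"))
  print(tab)
  cat(sprintf("residual sd %.4g ucal over %d injections\n",
              object$residual_sd, length(object$series$heats_ucal)))
  invisible(object)
}

#' @export
predict.itc_fit <- function(object, ...) {
  if (object$binding == "not measurable") stop("no parameters")
  object$fitted_heats
}

#' @export
plot.itc_fit <- function(x, ...) {
  ser <- x$series
  ratio <- ser$syringe_conc_uM * cumsum(ser$injection_volumes_uL) /
    (ser$cell_conc_uM * ser$cell_volume_uL)
  plot(ratio, ser$heats_ucal, xlab = "molar ratio",
       ylab = "heat per injection (ucal)", ...)
  if (x$binding == "measurable") graphics::lines(ratio, x$fitted_heats)
  invisible(x)
}

#' Thermodynamic dissection of a binding constant
#'
#' Splits the binding free energy into enthalpic and entropic parts:
#' `dG = R*T*ln(Kd)` with Kd in molar (R = 1.9872e-3 kcal mol^-1 K^-1) and
#' `-T*dS = dG - dH`, so that `dG = dH + (-T*dS)` holds by construction. The
#' driving force is labelled `entropy-driven` when the entropic term dominates
#' and is favorable (`|-TdS| > |dH|`, `-TdS < 0`), `enthalpy-driven` when the
#' enthalpic term dominates and is favorable, and `mixed` otherwise.
#'
#' @param Kd dissociation constant (uM).
#' @param dH binding enthalpy (kcal/mol).
#' @param temperature temperature in K; default 298.15 (25 C).
#' @return object of class `thermo_profile`: `dG`, `dH`, `minusTdS` (kcal/mol),
#'   `temperature`, `driving_force`.
#' @examples
#' thermo_dissection(Kd = 6.1, dH = -5.02)
#' @export
thermo_dissection <- function(Kd, dH, temperature = 298.15) {
  if (!is.finite(Kd) || Kd <= 0) stop("Kd must be positive")
  if (temperature <= 0) stop("temperature must be positive")
  dG <- .R_KCAL * temperature * log(Kd * 1e-6)
  mTdS <- dG - dH
  driving <- if (abs(mTdS) > abs(dH) && mTdS < 0) "entropy-driven"
  else if (abs(dH) > abs(mTdS) && dH < 0) "enthalpy-driven"
  else "mixed"
  structure(list(dG = dG, dH = dH, minusTdS = mTdS,
                 temperature = temperature, driving_force = driving,
                 Kd = Kd),
            class = "thermo_profile")
}

#' @export
print.thermo_profile <- function(x, ...) {
  cat(sprintf("Kd %.4g uM at %g K: dG = %.3f, dH = %.3f, -TdS = %.3f kcal/mol (%s)\n",
              x$Kd, x$temperature, x$dG, x$dH, x$minusTdS, x$driving_force))
  invisible(x)
}

#' Fold change in binding affinity
#'
#' Ratio of two dissociation constants, `Kd_a / Kd_b`: how many fold tighter
#' condition b binds than condition a.
#'
#' @param Kd_a,Kd_b dissociation constants (same units), both positive.
#' @return the fold change.
#' @examples
#' fold_affinity_change(318, 8)  # ~40-fold better with GDP bound
#' @export
fold_affinity_change <- function(Kd_a, Kd_b) {
  if (Kd_a <= 0 || Kd_b <= 0) stop("dissociation constants must be positive")
  Kd_a / Kd_b
}
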