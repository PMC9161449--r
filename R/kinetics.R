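#' Fit a GDP standard curve
#'
#' Ordinary least-squares line relating luminescence to the amount of GDP, used
#' to calibrate GDP-release assay signals into pmol of product.
#'
#' @param gdp_amounts known GDP amounts (pmol), at least 3 monotone levels.
#' @param luminescence measured luminescence at each amount.
#' @return object of class `calibration_curve` with `slope` (luminescence per
#'   pmol), `intercept`, `r_squared` and the underlying `lm` fit.
#' @examples
#' cal <- fit_standard_curve(c(0, 10, 20), c(5, 25, 45))  # y = 2x + 5
#' gdp_from_luminescence(cal, 45)  # 20 pmol
#' @export
fit_standard_curve <- function(gdp_amounts, luminescence) {
  stopifnot(length(gdp_amounts) == length(luminescence))
  if (length(unique(gdp_amounts)) < 3)
    stop("at least 3 distinct GDP amounts required")
  if (is.unsorted(gdp_amounts) && is.unsorted(rev(gdp_amounts)))
    stop("gdp_amounts must be monotone")
  if (any(luminescence < 0)) stop("negative luminescence")
  fit <- lm(luminescence ~ gdp_amounts)
  sl <- unname(coef(fit)[2])
  if (!is.finite(sl) || sl <= 0) stop("calibration slope must be positive")
  sm <- suppressWarnings(summary(fit))  # perfect fits are legitimate here
  structure(list(slope = sl, intercept = unname(coef(fit)[1]),
                 slope_se = sm$coefficients[2, 2],
                 r_squared = sm$r.squared, fit = fit),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("GDP standard curve: luminescence = %.4g * pmol + %.4g (R^2 = %.4f)\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Invert a standard curve: luminescence to pmol GDP
#'
#' @param cal a [fit_standard_curve()] result.
#' @param luminescence luminescence values.
#' @return pmol GDP.
#' @export
gdp_from_luminescence <- function(cal, luminescence) {
  stopifnot(inherits(cal, "calibration_curve"))
  (luminescence - cal$intercept) / cal$slope
}

#' Assemble a kinetics dataset from its raw components
#'
#' @param data data frame with columns `substrate_id`, `acceptor_conc_uM`,
#'   `replicate`, `luminescence`, `is_blank`. Blank (no-acceptor) rows carry
#'   `acceptor_conc_uM = 0` and `is_blank = TRUE` and are required.
#' @param enzyme_conc_nM,reaction_volume_uL,incubation_time_min,enzyme_molar_mass
#'   assay geometry (defaults 100 nM, 10 uL, 30 min, 58 kg/mol).
#' @return list of class `kinetics_dataset`.
#' @export
kinetics_dataset <- function(data, enzyme_conc_nM = 100,
                             reaction_volume_uL = 10,
                             incubation_time_min = 30,
                             enzyme_molar_mass = 58000) {
  need <- c("substrate_id", "acceptor_conc_uM", "replicate", "luminescence",
            "is_blank")
  if (!all(need %in% names(data)))
    stop("missing columns: ", paste(setdiff(need, names(data)), collapse = ", "))
  if (!any(data$is_blank)) stop("no blank (no-acceptor) rows present")
  structure(list(data = data, standard_curve = NULL,
                 enzyme_conc_nM = enzyme_conc_nM,
                 reaction_volume_uL = reaction_volume_uL,
                 incubation_time_min = incubation_time_min,
                 enzyme_molar_mass = enzyme_molar_mass,
                 ground_truth = NULL),
            class = "kinetics_dataset")
}

# Enzyme mass in the reaction, mg.
enzyme_mass_mg <- function(ds) {
  ds$enzyme_conc_nM * ds$reaction_volume_uL * ds$enzyme_molar_mass * 1e-12
}

#' Calibrate and blank-correct a kinetics dataset into velocities
#'
#' Converts luminescence to pmol GDP through the standard curve, subtracts the
#' mean no-acceptor (hydrolysis) blank, and normalizes by incubation time and
#' enzyme mass to velocities in nmol min^-1 mg^-1. Negative corrected values
#' are clipped to zero with a warning.
#'
#' @param dataset a [kinetics_dataset()] (or generator output).
#' @param cal a [fit_standard_curve()] calibration.
#' @return data frame with columns `substrate_id`, `acceptor_conc_uM`,
#'   `replicate`, `velocity` (nmol min^-1 mg^-1).
#' @export
correct_and_convert <- function(dataset, cal) {
  stopifnot(inherits(dataset, "kinetics_dataset"),
            inherits(cal, "calibration_curve"))
  df <- dataset$data
  if (!any(df$is_blank)) stop("no blank (no-acceptor) rows present")
  pmol <- gdp_from_luminescence(cal, df$luminescence)
  blank_pmol <- mean(pmol[df$is_blank])
  sig <- df[!df$is_blank, ]
  corrected <- pmol[!df$is_blank] - blank_pmol
  if (any(corrected < 0)) {
    warning("negative blank-corrected values clipped to 0")
    corrected <- pmax(corrected, 0)
  }
  v <- corrected / 1000 / (dataset$incubation_time_min * enzyme_mass_mg(dataset))
  if (all(v == 0)) warning("all velocities are zero after blank correction")
  data.frame(substrate_id = sig$substrate_id,
             acceptor_conc_uM = sig$acceptor_conc_uM,
             replicate = sig$replicate, velocity = v)
}

#' Fit the Michaelis-Menten equation to velocity data
#'
#' Nonlinear least squares of `v = Vmax*S/(Km+S)` (Levenberg-Marquardt) on
#' pooled replicate velocities, with standard errors from the fit covariance.
#' The turnover number is derived as `kcat = Vmax * enzyme_molar_mass * 1e-6`
#' (nmol min^-1 mg^-1 into min^-1) and the catalytic efficiency as `kcat/Km`.
#'
#' A substrate that does not saturate the enzyme over the tested range cannot
#' be described by the hyperbola: when the fitted `Km` exceeds 5x the largest
#' tested concentration, or its 95% confidence interval is unbounded, the fit
#' is returned with `saturable = FALSE` and no kinetic parameters, mirroring
#' the experimental "linear increase in activity" outcome.
#'
#' Starting values are `Vmax0 = max(v)` and `Km0` interpolated as the
#' concentration at half of `Vmax0`.
#'
#' @param velocities data frame with columns `acceptor_conc_uM` and `velocity`
#'   (e.g. from [correct_and_convert()]); at least 4 distinct concentrations.
#' @param enzyme_molar_mass enzyme molar mass (g/mol) for the kcat conversion;
#'   default 58000 (the value consistent with the reference kinetic table).
#' @return object of class `mm_fit`: `Km`, `Vmax`, `kcat` (each `_se`),
#'   `efficiency`, `saturable`, `residual_sd`, plus the data and `nls` fit.
#' @examples
#' S <- c(5, 10, 25, 50, 100, 250, 500, 1000)
#' v <- 282.1 * S / (113.1 + S)
#' fit <- fit_michaelis_menten(data.frame(acceptor_conc_uM = S, velocity = v))
#' coef(fit)
#' @export
fit_michaelis_menten <- function(velocities, enzyme_molar_mass = 58000) {
  stopifnot(is.data.frame(velocities),
            all(c("acceptor_conc_uM", "velocity") %in% names(velocities)))
  S <- velocities$acceptor_conc_uM
  v <- velocities$velocity
  if (length(unique(S)) < 4)
    stop("at least 4 distinct concentration levels required")
  if (any(S <= 0)) stop("acceptor concentrations must be positive")

  vmax0 <- max(v)
  km0 <- tryCatch({
    agg <- tapply(v, S, mean)
    s_lev <- as.numeric(names(agg))
    approx(agg, s_lev, xout = vmax0 / 2, rule = 2, ties = mean)$y
  }, error = function(e) median(S))
  if (!is.finite(km0) || km0 <= 0) km0 <- median(S)

  nonsat <- function(reason) {
    structure(list(saturable = FALSE, reason = reason,
                   data = velocities, enzyme_molar_mass = enzyme_molar_mass),
              class = "mm_fit")
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(velocity ~ Vmax * acceptor_conc_uM /
                        (Km + acceptor_conc_uM),
                      data = velocities,
                      start = list(Vmax = vmax0, Km = km0),
                      lower = c(Vmax = 0, Km = 1e-12),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
    error = function(e) NULL)
  if (is.null(fit)) return(nonsat("fit did not converge"))

  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, 2], error = function(e)
    rep(NA_real_, 2))
  km <- unname(est["Km"]); vmax <- unname(est["Vmax"])
  km_se <- unname(se["Km"]); vmax_se <- unname(se["Vmax"])
  if (km > 5 * max(S))
    return(nonsat("fitted Km exceeds 5x the maximal tested concentration"))
  if (!is.finite(km_se))
    return(nonsat("unbounded Km confidence interval"))

  conv <- vmax * enzyme_molar_mass * 1e-6
  kcat <- conv
  kcat_se <- if (is.finite(vmax_se)) vmax_se * enzyme_molar_mass * 1e-6 else NA_real_
  structure(list(Km = km, Km_se = km_se, Vmax = vmax, Vmax_se = vmax_se,
                 kcat = kcat, kcat_se = kcat_se,
                 efficiency = kcat / km, saturable = TRUE,
                 residual_sd = sqrt(sum(residuals(fit)^2) /
                                      max(1, length(v) - 2)),
                 enzyme_molar_mass = enzyme_molar_mass,
                 data = velocities, fit = fit),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  if (!x$saturable) {
    cat("Michaelis-Menten fit: NOT saturable (", x$reason, ")\n", sep = "")
    cat("Kinetic parameters not determined.\n")
    return(invisible(x))
  }
  cat("Michaelis-Menten fit\n")
  cat(sprintf("  Km   = %.4g +/- %.3g uM\n", x$Km, x$Km_se))
  cat(sprintf("  Vmax = %.4g +/- %.3g nmol min^-1 mg^-1\n", x$Vmax, x$Vmax_se))
  cat(sprintf("  kcat = %.4g +/- %.3g min^-1  (M = %g g/mol)\n",
              x$kcat, x$kcat_se, x$enzyme_molar_mass))
  cat(sprintf("  kcat/Km = %.3g min^-1 uM^-1\n", x$efficiency))
  invisible(x)
}

#' @export
coef.mm_fit <- function(object, ...) {
  if (!object$saturable) return(c(Km = NA_real_, Vmax = NA_real_,
                                  kcat = NA_real_))
  c(Km = object$Km, Vmax = object$Vmax, kcat = object$kcat)
}

#' @export
summary.mm_fit <- function(object, ...) {
  if (object$saturable) {
    tab <- data.frame(estimate = c(object$Km, object$Vmax, object$kcat,
                                   object$efficiency),
                      se = c(object$Km_se, object$Vmax_se, object$kcat_se, NA),
                      row.names = c("Km", "Vmax", "kcat", "kcat/Km"))
  } else tab <- NULL
  structure(list(saturable = object$saturable, table = tab,
                 residual_sd = object$residual_sd %||% NA_real_,
                 n = nrow(object$data)),
            class = "summary.mm_fit")
}

#' @export
print.summary.mm_fit <- function(x, ...) {
  if (!x$saturable) cat("Non-saturable substrate; no parameters.\n")
  else {
    print(x$table)
    cat(sprintf("residual sd %.4g over %d points\n", x$residual_sd, x$n))
  }
  invisible(x)
}

#' @export
predict.mm_fit <- function(object, newdata = NULL, ...) {
  if (!object$saturable) stop("no parameters: non-saturable fit")
  S <- if (is.null(newdata)) object$data$acceptor_conc_uM
       else newdata$acceptor_conc_uM
  object$Vmax * S / (object$Km + S)
}

#' @export
residuals.mm_fit <- function(object, ...) {
  if (!object$saturable) stop("no parameters: non-saturable fit")
  object$data$velocity - predict(object)
}

#' @export
plot.mm_fit <- function(x, ...) {
  plot(x$data$acceptor_conc_uM, x$data$velocity,
       xlab = "acceptor (uM)", ylab = "v (nmol min^-1 mg^-1)", ...)
  if (x$saturable) {
    S <- seq(0, max(x$data$acceptor_conc_uM), length.out = 200)
    graphics::lines(S, x$Vmax * S / (x$Km + S))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Catalytic efficiency kcat/Km
#'
#' @param fit an `mm_fit` (must be saturable) or a list/vector with `kcat` and
#'   `Km` elements.
#' @param digits decimal places for the reported value (the reference tables
#'   print 2); use `NULL` for no rounding.
#' @return efficiency in min^-1 uM^-1.
#' @examples
#' catalytic_efficiency(list(kcat = 14.17, Km = 14.56))  # 0.97
#' @export
catalytic_efficiency <- function(fit, digits = 2) {
  if (inherits(fit, "mm_fit") && !fit$saturable)
    stop("non-saturable fit: catalytic efficiency undefined")
  eff <- fit[["kcat"]] / fit[["Km"]]
  if (!is.null(digits)) eff <- round(eff, digits)
  eff
}

#' Fold differences of initial velocities between substrates
#'
#' Compares velocities measured at the same acceptor concentration across
#' substrates, reporting how many fold *worse* each substrate is than a named
#' reference (`fold = v_reference / v_substrate`; 1 for the reference itself).
#'
#' @param velocities named numeric vector of velocities at a common acceptor
#'   concentration, or a data frame with `substrate_id` and `velocity`.
#' @param reference name of the reference substrate.
#' @return data frame with `substrate_id`, `velocity`, `fold_worse`.
#' @export
compare_initial_velocities <- function(velocities, reference) {
  if (is.data.frame(velocities))
    v <- setNames(velocities$velocity, velocities$substrate_id)
  else v <- velocities
  if (!reference %in% names(v)) stop("reference substrate not found")
  if (any(v == 0)) stop("zero velocity: fold difference undefined")
  data.frame(substrate_id = names(v), velocity = unname(v),
             fold_worse = unname(v[reference] / v))
}
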