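#' Construct an STD build-up series
#'
#' @param proton_id proton label (e.g. `"GlcNAc-A H1"`).
#' @param condition `"apo"` or `"plus_GDP"`.
#' @param sat_times saturation times (s), strictly increasing.
#' @param std_amplitude STD amplitudes (fractions), non-negative.
#' @param merged_group optional proton ids summed into this series.
#' @return object of class `buildup_series`.
#' @export
buildup_series <- function(proton_id, condition = "apo", sat_times,
                           std_amplitude, merged_group = NULL) {
  if (is.unsorted(sat_times, strictly = TRUE))
    stop("sat_times must be strictly increasing")
  if (length(sat_times) != length(std_amplitude))
    stop("one amplitude per saturation time required")
  if (any(std_amplitude < 0)) stop("amplitudes must be non-negative")
  structure(list(proton_id = proton_id, condition = condition,
                 sat_times = sat_times, std_amplitude = std_amplitude,
                 merged_group = merged_group),
            class = "buildup_series")
}

#' @export
as.data.frame.buildup_series <- function(x, ...) {
  data.frame(proton_id = x$proton_id, condition = x$condition,
             sat_time_s = x$sat_times, std_amplitude = x$std_amplitude)
}

#' Fit a mono-exponential STD build-up curve
#'
#' Least-squares fit of `STD(t) = STDmax*(1 - exp(-ksat*t))`. The build-up
#' rate -- the initial slope `STDmax*ksat` -- is the quantity carried into the
#' epitope map, because it is free of the T1-relaxation bias that affects STD
#' values at any single saturation time. Starting values: `STDmax0` = largest
#' amplitude, `ksat0` = reciprocal of the time at half of `STDmax0`.
#'
#' A series with no overall build-up (regression slope of amplitude on time
#' <= 0, e.g. constant zero amplitudes) is returned as a null fit
#' (`null = TRUE`, rate 0) rather than an error: such protons contribute no
#' epitope entry.
#'
#' @param series a [buildup_series()] (at least 4 time points).
#' @return object of class `std_fit`: `STDmax`, `ksat`, `buildup_rate` (each
#'   with `_se`; the rate SE by the delta method from the fit covariance),
#'   `null` flag and the input series.
#' @examples
#' s <- buildup_series("H1", sat_times = c(0.5, 1, 2, 3, 4, 5),
#'                     std_amplitude = 0.08 * (1 - exp(-0.9 * c(0.5, 1, 2, 3, 4, 5))))
#' fit_buildup(s)
#' @export
fit_buildup <- function(series) {
  stopifnot(inherits(series, "buildup_series"))
  t <- series$sat_times; y <- series$std_amplitude
  if (length(t) < 4) stop("at least 4 saturation times required")

  null_fit <- function() {
    structure(list(STDmax = 0, ksat = NA_real_, buildup_rate = 0,
                   STDmax_se = NA_real_, ksat_se = NA_real_,
                   buildup_rate_se = NA_real_, null = TRUE, series = series),
              class = "std_fit")
  }
  if (all(y == 0)) return(null_fit())
  if (unname(coef(lm(y ~ t))[2]) <= 0) return(null_fit())

  max0 <- max(y)
  thalf <- tryCatch(approx(y, t, xout = max0 / 2, rule = 2, ties = mean)$y,
                    error = function(e) t[2])
  k0 <- if (is.finite(thalf) && thalf > 0) 1 / thalf else 1
  fit <- minpack.lm::nlsLM(
    y ~ STDmax * (1 - exp(-ksat * t)),
    data = data.frame(t = t, y = y),
    start = list(STDmax = max0, ksat = k0),
    lower = c(STDmax = 0, ksat = 1e-9),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14))
  est <- coef(fit)
  cv <- tryCatch(vcov(fit), error = function(e) matrix(NA_real_, 2, 2))
  se <- suppressWarnings(sqrt(diag(cv)))
  stdmax <- unname(est["STDmax"]); ksat <- unname(est["ksat"])
  rate <- stdmax * ksat
  rate_var <- ksat^2 * cv[1, 1] + stdmax^2 * cv[2, 2] +
    2 * stdmax * ksat * cv[1, 2]
  structure(list(STDmax = stdmax, ksat = ksat, buildup_rate = rate,
                 STDmax_se = unname(se[1]), ksat_se = unname(se[2]),
                 buildup_rate_se = suppressWarnings(sqrt(max(rate_var, 0))),
                 null = FALSE, series = series, fit = fit),
            class = "std_fit")
}

#' @export
print.std_fit <- function(x, ...) {
  if (x$null) {
    cat("STD build-up fit:", x$series$proton_id, "- no build-up (null)\n")
    return(invisible(x))
  }
  cat(sprintf("STD build-up fit: %s  STDmax = %.4g, ksat = %.4g s^-1, rate = %.4g s^-1\n",
              x$series$proton_id, x$STDmax, x$ksat, x$buildup_rate))
  invisible(x)
}

#' @export
coef.std_fit <- function(object, ...) {
  c(STDmax = object$STDmax, ksat = object$ksat,
    buildup_rate = object$buildup_rate)
}

#' @export
predict.std_fit <- function(object, newdata = NULL, ...) {
  if (object$null) stop("null fit: no parameters")
  t <- if (is.null(newdata)) object$series$sat_times else newdata$sat_times
  object$STDmax * (1 - exp(-object$ksat * t))
}

#' Merge overlapping STD signals into a pseudo-proton series
#'
#' Spectrally overlapping protons cannot be integrated separately; their STD
#' amplitudes are summed pointwise into one pseudo-proton series (or averaged,
#' via `method = "mean"`). All members must share condition and time grid.
#'
#' @param series_list list of [buildup_series()].
#' @param group proton ids to merge (names into `series_list`).
#' @param method `"sum"` (default) or `"mean"`.
#' @return a merged [buildup_series()] with `merged_group` populated.
#' @export
merge_overlapping <- function(series_list, group, method = c("sum", "mean")) {
  method <- match.arg(method)
  members <- series_list[group]
  if (any(vapply(members, is.null, logical(1))))
    stop("group members missing from series_list")
  t0 <- members[[1]]$sat_times
  cond <- members[[1]]$condition
  for (m in members) {
    if (!identical(m$sat_times, t0)) stop("mismatched saturation time grids")
    if (!identical(m$condition, cond)) stop("mismatched conditions")
  }
  amp <- Reduce(`+`, lapply(members, `[[`, "std_amplitude"))
  if (method == "mean") amp <- amp / length(members)
  buildup_series(proton_id = paste(group, collapse = "+"),
                 condition = cond, sat_times = t0, std_amplitude = amp,
                 merged_group = group)
}

#' Build a normalized binding-epitope map from STD build-up fits
#'
#' Normalizes per-proton build-up rates so that the largest equals exactly
#' 100%; the proton carrying it is recorded as the reference. Relative STD
#' build-up rates report the proximity of each ligand proton to the protein
#' surface.
#'
#' @param fits named list of [fit_buildup()] results (names = proton ids), or
#'   a named numeric vector of build-up rates.
#' @param condition condition label stored on the map.
#' @return object of class `epitope_map`: data frame `map` (`proton_id`,
#'   `STDmax`, `ksat`, `buildup_rate`, `normalized_pct`), `reference_proton`,
#'   `condition`. Null fits are dropped; all null is an error.
#' @export
build_epitope_map <- function(fits, condition = "apo") {
  if (is.numeric(fits)) {
    rates <- fits[fits > 0]   # zero-rate protons carry no epitope entry
    if (length(rates) == 0) stop("no positive build-up rates")
    stdmax <- ksat <- rep(NA_real_, length(rates))
  } else {
    keep <- !vapply(fits, `[[`, logical(1), "null")
    fits <- fits[keep]
    if (length(fits) == 0) stop("all fits are null: no epitope to map")
    rates <- vapply(fits, `[[`, numeric(1), "buildup_rate")
    stdmax <- vapply(fits, `[[`, numeric(1), "STDmax")
    ksat <- vapply(fits, `[[`, numeric(1), "ksat")
  }
  if (is.null(names(rates)) || any(!nzchar(names(rates))))
    stop("fits must be named by proton id")
  if (all(rates <= 0)) stop("no positive build-up rates")
  ref <- names(rates)[which.max(rates)]
  map <- data.frame(proton_id = names(rates), STDmax = unname(stdmax),
                    ksat = unname(ksat), buildup_rate = unname(rates),
                    normalized_pct = 100 * unname(rates) / max(rates),
                    row.names = NULL)
  structure(list(map = map, reference_proton = ref, condition = condition),
            class = "epitope_map")
}

#' @export
print.epitope_map <- function(x, ...) {
  cat("STD epitope map (", x$condition, "), reference proton ",
      x$reference_proton, " = 100%\n", sep = "")
  print(x$map[order(-x$map$normalized_pct),
              c("proton_id", "buildup_rate", "normalized_pct")],
        row.names = FALSE)
  invisible(x)
}

#' Compare epitope maps between conditions
#'
#' Per-proton comparison of two epitope maps (e.g. without and with bound
#' GDP): differences and ratios of the un-normalized build-up rates plus
#' deltas of the normalized percentages, with a summary flag raised when every
#' shared proton's rate increased.
#'
#' @param map_apo,map_gdp [build_epitope_map()] results.
#' @return list of class `epitope_comparison`: `table` (per shared proton:
#'   rates, `rate_ratio`, `rate_delta`, `normalized_delta`), `all_increase`
#'   flag, `only_in_apo`, `only_in_gdp`.
#' @export
compare_conditions <- function(map_apo, map_gdp) {
  stopifnot(inherits(map_apo, "epitope_map"), inherits(map_gdp, "epitope_map"))
  a <- map_apo$map; g <- map_gdp$map
  shared <- intersect(a$proton_id, g$proton_id)
  if (length(shared) == 0) stop("no shared protons between conditions")
  ia <- match(shared, a$proton_id); ig <- match(shared, g$proton_id)
  tab <- data.frame(proton_id = shared,
                    rate_apo = a$buildup_rate[ia],
                    rate_gdp = g$buildup_rate[ig])
  tab$rate_ratio <- tab$rate_gdp / tab$rate_apo
  tab$rate_delta <- tab$rate_gdp - tab$rate_apo
  tab$normalized_delta <- g$normalized_pct[ig] - a$normalized_pct[ia]
  structure(list(table = tab, all_increase = all(tab$rate_ratio > 1),
                 only_in_apo = setdiff(a$proton_id, shared),
                 only_in_gdp = setdiff(g$proton_id, shared)),
            class = "epitope_comparison")
}

#' @export
print.epitope_comparison <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(if (x$all_increase) "All shared protons increased.\n"
      else "Not all shared protons increased.\n")
  if (length(x$only_in_apo) || length(x$only_in_gdp))
    cat("Excluded (single-condition):",
        paste(c(x$only_in_apo, x$only_in_gdp), collapse = ", "), "\n")
  invisible(x)
}
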