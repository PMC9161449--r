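#' Construct a NOESY build-up curve
#'
#' @param pair_id proton-pair label (e.g. `"H1B-H4A"`).
#' @param mixing_times mixing times (ms), strictly increasing, >= 4 points.
#' @param integrals cross-peak integrals (arbitrary units).
#' @return object of class `noe_buildup`.
#' @export
noe_buildup <- function(pair_id, mixing_times, integrals) {
  if (is.unsorted(mixing_times, strictly = TRUE))
    stop("mixing_times must be strictly increasing")
  if (length(mixing_times) < 4) stop("at least 4 mixing times required")
  if (length(mixing_times) != length(integrals))
    stop("one integral per mixing time required")
  structure(list(pair_id = pair_id, mixing_times = mixing_times,
                 integrals = integrals),
            class = "noe_buildup")
}

#' @export
as.data.frame.noe_buildup <- function(x, ...) {
  data.frame(pair_id = x$pair_id, mixing_time_ms = x$mixing_times,
             integral = x$integrals)
}

# R^2 of an OLS line; a perfect fit of constant data counts as 1.
line_r2 <- function(t, y) {
  f <- lm(y ~ t)
  ss_res <- sum(residuals(f)^2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(if (ss_res <= 1e-24) 1 else 0)
  1 - ss_res / ss_tot
}

#' Initial slope of a NOESY build-up curve
#'
#' OLS slope of cross-peak integral versus mixing time over the linear initial
#' part of the curve. With `window = "auto"` the linear window is found by
#' growing the prefix of points (starting from the minimum of 3) while the
#' prefix's linear-fit R^2 stays at or above `r2_threshold`; growth stops at
#' the first prefix that drops below, so the window never extends into the
#' curved (saturating) regime. A numeric `window = c(lo, hi)` selects points
#' inside that mixing-time range instead.
#'
#' @param buildup a [noe_buildup()].
#' @param window `"auto"` or a numeric range in ms (>= 3 points inside).
#' @param r2_threshold linearity threshold for the auto window (default 0.99).
#' @return object of class `noe_slope`: `slope` (units/ms), `se`,
#'   `window_ms`, `n_points`, `r_squared`, `flagged` (TRUE for slope <= 0),
#'   `pair_id`.
#' @examples
#' b <- noe_buildup("H1B-H4A", c(100, 150, 200, 250), 0.5 * c(100, 150, 200, 250))
#' initial_slope(b)$slope  # 0.5
#' @export
initial_slope <- function(buildup, window = "auto", r2_threshold = 0.99) {
  stopifnot(inherits(buildup, "noe_buildup"))
  t <- buildup$mixing_times; y <- buildup$integrals
  if (identical(window, "auto")) {
    k <- 3
    if (length(t) > 3)
      for (j in 4:length(t)) {
        if (line_r2(t[1:j], y[1:j]) < r2_threshold) break
        k <- j
      }
    idx <- 1:k
  } else {
    idx <- which(t >= window[1] & t <= window[2])
    if (length(idx) < 3) stop("fewer than 3 points inside the window")
  }
  f <- lm(y[idx] ~ t[idx])
  slope <- unname(coef(f)[2])
  se <- suppressWarnings(summary(f))$coefficients[2, 2]
  structure(list(pair_id = buildup$pair_id, slope = slope, se = se,
                 window_ms = range(t[idx]), n_points = length(idx),
                 r_squared = line_r2(t[idx], y[idx]),
                 flagged = (slope <= 0)),
            class = "noe_slope")
}

#' @export
print.noe_slope <- function(x, ...) {
  cat(sprintf("NOE initial slope %s: %.4g units/ms over [%g, %g] ms (%d pts, R^2 = %.4f)%s\n",
              x$pair_id, x$slope, x$window_ms[1], x$window_ms[2], x$n_points,
              x$r_squared, if (x$flagged) " [flagged: non-positive]" else ""))
  invisible(x)
}

#' Inter-proton distance by the isolated spin pair approximation
#'
#' Converts an NOE initial slope (cross-relaxation rate) to a distance by
#' referencing against a pair of known separation:
#' `r = ref_distance * (ref_slope / slope)^(1/6)`.
#'
#' @param slope initial slope of the pair of interest (or a `noe_slope`).
#' @param ref_slope initial slope of the reference pair (or a `noe_slope`).
#' @param ref_distance known reference distance (Angstrom).
#' @return distance in Angstrom.
#' @examples
#' ispa_distance(1, 64, 2.58)  # 64^(1/6) = 2 => 5.16 A
#' @export
ispa_distance <- function(slope, ref_slope, ref_distance) {
  if (inherits(slope, "noe_slope")) slope <- slope$slope
  if (inherits(ref_slope, "noe_slope")) ref_slope <- ref_slope$slope
  if (slope <= 0 || ref_slope <= 0) stop("slopes must be positive")
  if (ref_distance <= 0) stop("ref_distance must be positive")
  ref_distance * (ref_slope / slope)^(1 / 6)
}

#' ISPA distances for a set of NOESY build-up curves
#'
#' Runs [initial_slope()] on every curve and converts each slope to a distance
#' with [ispa_distance()] against the named reference pair.
#'
#' @param buildups named list of [noe_buildup()] objects.
#' @param ref_pair name of the reference pair within `buildups`.
#' @param ref_distance reference distance (Angstrom).
#' @param window,r2_threshold passed to [initial_slope()].
#' @return data frame: `pair_id`, `slope`, `slope_se`, `window_lo_ms`,
#'   `window_hi_ms`, `reference_pair`, `reference_distance`, `distance`.
#' @export
estimate_distances <- function(buildups, ref_pair, ref_distance,
                               window = "auto", r2_threshold = 0.99) {
  if (!ref_pair %in% names(buildups))
    stop("reference pair not among the build-up curves")
  slopes <- lapply(buildups, initial_slope, window = window,
                   r2_threshold = r2_threshold)
  ref <- slopes[[ref_pair]]
  if (ref$flagged) stop("reference pair has a non-positive slope")
  do.call(rbind, lapply(slopes, function(s) {
    data.frame(pair_id = s$pair_id, slope = s$slope, slope_se = s$se,
               window_lo_ms = s$window_ms[1], window_hi_ms = s$window_ms[2],
               reference_pair = ref_pair, reference_distance = ref_distance,
               distance = if (s$flagged) NA_real_
                          else ispa_distance(s$slope, ref$slope, ref_distance),
               row.names = NULL)
  }))
}

#' Call the glycosidic conformer from ISPA distances
#'
#' Votes each proton pair for the conformer (syn or anti about the glycosidic
#' psi dihedral) whose expected distance it lies nearest; a unanimous vote
#' yields that conformer, a split vote -- or any pair farther than `tolerance`
#' from both expectations -- yields `ambiguous`. Expected distances come from
#' an independently supplied idealized geometry; none are built in.
#'
#' @param distances data frame with `pair_id` and `distance` (e.g. from
#'   [estimate_distances()]).
#' @param reference_geometry data frame with `pair_id`, `expected_syn`,
#'   `expected_anti` (Angstrom). Every evaluated pair needs both expectations.
#' @param tolerance maximal accepted deviation from the nearest expectation
#'   (Angstrom, default 0.3).
#' @param linkage linkage label carried into the result.
#' @return object of class `conformer_call`: `call` in
#'   `{"syn", "anti", "ambiguous"}` and an `evidence` table.
#' @export
call_conformer <- function(distances, reference_geometry, tolerance = 0.3,
                           linkage = "GlcNAc-b1,4-GlcNAc") {
  stopifnot(all(c("pair_id", "distance") %in% names(distances)),
            all(c("pair_id", "expected_syn", "expected_anti") %in%
                  names(reference_geometry)))
  m <- match(distances$pair_id, reference_geometry$pair_id)
  keep <- !is.na(m) & !is.na(distances$distance)
  if (!any(keep)) stop("no pair has both measured distance and reference geometry")
  d <- distances$distance[keep]
  syn <- reference_geometry$expected_syn[m[keep]]
  anti <- reference_geometry$expected_anti[m[keep]]
  if (any(is.na(syn) | is.na(anti))) stop("missing reference geometry")
  dev_syn <- abs(d - syn); dev_anti <- abs(d - anti)
  vote <- ifelse(dev_syn <= dev_anti, "syn", "anti")
  out_of_tol <- pmin(dev_syn, dev_anti) > tolerance
  call <- if (any(out_of_tol) || length(unique(vote)) > 1) "ambiguous"
          else unique(vote)
  structure(list(linkage = linkage, call = call,
                 evidence = data.frame(pair_id = distances$pair_id[keep],
                                       distance = d, expected_syn = syn,
                                       expected_anti = anti, vote = vote,
                                       within_tolerance = !out_of_tol,
                                       row.names = NULL),
                 tolerance = tolerance),
            class = "conformer_call")
}

#' @export
print.conformer_call <- function(x, ...) {
  cat("Conformer call for ", x$linkage, ": ", x$call,
      " (tolerance ", x$tolerance, " A)\n", sep = "")
  print(x$evidence, row.names = FALSE)
  invisible(x)
}
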