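#' Assay constants for the WST-8 absorbance readout
#'
#' The formazan product of WST-8 reduction absorbs at 460 nm with molar
#' absorption coefficient 3.07e4 M^-1 cm^-1.  The optical path length of a
#' plate well depends on fill volume and plate format and is therefore
#' configurable; the 1 cm default should be overridden whenever the true path
#' is known, and every fit report echoes the value used.
#'
#' @param epsilon molar absorption coefficient, M^-1 cm^-1 (default 3.07e4).
#' @param path_cm optical path length in cm (default 1).
#' @return List of class `assay_constants`.
#' @export
assay_constants <- function(epsilon = 3.07e4, path_cm = 1) {
  stopifnot(epsilon > 0, path_cm > 0)
  structure(list(epsilon = epsilon, path_cm = path_cm),
            class = "assay_constants")
}

#' Convert absorbance to product concentration
#'
#' Beer-Lambert: `c = A / (epsilon * l)`, reported in micromolar.  Negative
#' absorbances (blank noise) are clipped at zero; values below `-tol` trigger
#' a warning since they indicate a blanking problem rather than noise.
#'
#' @param a460 absorbance value(s) at 460 nm.
#' @param constants an [assay_constants()] object.
#' @param tol blank tolerance in absorbance units (default 0.02).
#' @return Concentration(s) in uM.
#' @export
absorbance_to_concentration <- function(a460, constants = assay_constants(),
                                        tol = 0.02) {
  if (any(a460 < -tol, na.rm = TRUE))
    warning("absorbance below -", tol, ": check blank subtraction; clipping at 0")
  pmax(a460, 0) / (constants$epsilon * constants$path_cm) * 1e6
}

prefix_r2_slope <- function(t, y) {
  # slope and R^2 of OLS y ~ t; R^2 defined as 1 for a zero-variance response
  n <- length(t)
  sxx <- sum((t - mean(t))^2)
  sxy <- sum((t - mean(t)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  slope <- sxy / sxx
  r2 <- if (syy < 1e-18) 1 else sxy^2 / (sxx * syy)
  c(slope = slope, r2 = r2)
}

#' Initial velocity from an absorbance time course
#'
#' Blank-subtracts the trace (first-timepoint blank), converts absorbance to
#' product concentration, and takes the slope of ordinary least squares over
#' the longest early-linear prefix window: the largest window of at least
#' `min_points` leading timepoints whose linear fit has R^2 >= `r2_min`.
#' Saturating portions of the trace fail the linearity screen and are
#' excluded.
#'
#' @param trace data frame with columns `time_min`, `a460`, `substrate_uM`
#'   (constant within a trace) and optionally `replicate`.
#' @param constants an [assay_constants()] object.
#' @param min_points minimum window size (default 5).
#' @param r2_min linearity threshold (default 0.99).
#' @return Data frame of class `rate_record`: `substrate_uM`, `v0`
#'   (uM min^-1), `t_start`, `t_end`, `n_points`, `r2`, `replicate`.
#' @export
initial_velocity <- function(trace, constants = assay_constants(),
                             min_points = 5, r2_min = 0.99) {
  t <- trace$time_min
  if (length(t) < min_points) stop("trace has fewer than ", min_points, " timepoints")
  if (any(diff(t) <= 0)) stop("timepoints must be strictly increasing")
  conc <- absorbance_to_concentration(trace$a460 - trace$a460[1], constants)
  ks <- min_points:length(t)
  stats <- vapply(ks, function(k) prefix_r2_slope(t[1:k], conc[1:k]), numeric(2))
  ok <- which(stats["r2", ] >= r2_min)
  if (!length(ok))
    stop("no prefix window of >= ", min_points,
         " points reaches R^2 >= ", r2_min, ": trace not linear at early times")
  k <- ks[max(ok)]
  out <- data.frame(substrate_uM = trace$substrate_uM[1],
                    v0 = unname(stats["slope", max(ok)]),
                    t_start = t[1], t_end = t[k], n_points = k,
                    r2 = unname(stats["r2", max(ok)]),
                    replicate = if ("replicate" %in% names(trace))
                      trace$replicate[1] else NA_character_)
  class(out) <- c("rate_record", class(out))
  out
}

#' Michaelis constant by asymptotic double-reciprocal regression
#'
#' Under substrate-excess inhibition the Lineweaver-Burk plot (1/v against
#' 1/\[S\]) bends away from the Michaelis-Menten line at high substrate, so the
#' regression is restricted to the asymptotic low-concentration subset: the
#' `k` points of highest 1/\[S\] (default `max(3, floor(n/2))`).  The Michaelis
#' constant is read off the abscissa intersection, `KM = -1 / x-intercept =
#' slope / intercept`, and `Vmax = 1 / intercept`.
#'
#' @param rates data frame with `substrate_uM` and `v0` columns (one row per
#'   concentration; >= 3 distinct concentrations with positive velocity).
#' @param k number of low-concentration points used; `NULL` for the default
#'   policy.
#' @return Object of class `km_fit`: `km` (uM), `vmax` (uM min^-1), `slope`,
#'   `intercept`, `points_used` (the subset), `n_used`.
#' @export
lineweaver_burk_km <- function(rates, k = NULL) {
  r <- rates[!is.na(rates$v0) & rates$v0 > 0, , drop = FALSE]
  r <- r[order(r$substrate_uM), , drop = FALSE]
  if (length(unique(r$substrate_uM)) < 3)
    stop("need at least 3 distinct substrate concentrations with positive velocity")
  if (is.null(k)) k <- max(3L, floor(nrow(r) / 2))
  k <- min(k, nrow(r))
  sub <- r[seq_len(k), , drop = FALSE]       # lowest [S] = highest 1/[S]
  inv_s <- 1 / sub$substrate_uM
  inv_v <- 1 / sub$v0
  fit <- stats::lm(inv_v ~ inv_s)
  intercept <- unname(stats::coef(fit)[1])
  slope <- unname(stats::coef(fit)[2])
  if (intercept <= 0 || slope <= 0)
    stop("non-positive double-reciprocal intercept/slope: ",
         "data dominated by substrate inhibition; no abscissa crossing at negative 1/[S]")
  structure(list(km = slope / intercept, vmax = 1 / intercept,
                 slope = slope, intercept = intercept,
                 points_used = sub, n_used = k),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("<km_fit> KM = %.2f uM, Vmax = %.3f uM/min (asymptotic subset of %d points)\n",
              x$km, x$vmax, x$n_used))
  invisible(x)
}

#' Normalise velocities to the 0-1 range
#'
#' Divides every initial velocity by the maximum, preserving ordering —
#' the scaling used when comparing titration or temperature series.
#'
#' @param rates data frame with a `v0` column.
#' @return `rates` with a `v_norm` column added.
#' @export
normalize_velocities <- function(rates) {
  m <- max(rates$v0, na.rm = TRUE)
  if (!is.finite(m) || m <= 0) stop("all velocities zero or missing: cannot normalise")
  rates$v_norm <- rates$v0 / m
  rates
}

#' Double-reciprocal plot
#'
#' @param fit a [lineweaver_burk_km()] result.
#' @param rates optional full rate table to show excluded (inhibited) points.
#' @return A ggplot object.
#' @export
plot_lineweaver_burk <- function(fit, rates = NULL) {
  used <- data.frame(inv_s = 1 / fit$points_used$substrate_uM,
                     inv_v = 1 / fit$points_used$v0, used = TRUE)
  pts <- used
  if (!is.null(rates)) {
    all_pts <- data.frame(inv_s = 1 / rates$substrate_uM, inv_v = 1 / rates$v0)
    pts <- rbind(used, cbind(all_pts[!all_pts$inv_s %in% used$inv_s, ],
                             used = FALSE))
  }
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$inv_s, y = .data$inv_v,
                                    shape = .data$used)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept,
                         colour = "red") +
    ggplot2::labs(x = "1/[S] (1/uM)", y = "1/v (min/uM)",
                  shape = "in asymptotic fit")
}
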