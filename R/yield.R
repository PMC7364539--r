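# Experiment-side calculations: optical density to dry weight, biomass
# yield from growth curves, and conversion between model fluxes and
# enzyme specific activities.

#' Optical density to dry weight
#'
#' Uses the conversion factor 1 OD ml = 0.25 mg dry weight (OD at
#' 540 nm).
#'
#' @param od Optical density (>= 0).
#' @param volume_ml Culture volume in ml (> 0).
#' @param factor mg dry weight per OD ml unit.
#' @return Dry weight in mg.
#' @export
od_to_dry_weight <- function(od, volume_ml, factor = 0.25) {
  if (any(od < 0)) stop("optical density must be non-negative", call. = FALSE)
  if (any(volume_ml <= 0)) stop("volume must be positive", call. = FALSE)
  od * volume_ml * factor
}

#' Estimate biomass yield from a growth time series
#'
#' The yield is the slope of produced biomass (g dry weight) versus
#' consumed substrate (mol), fitted by ordinary least squares with a free
#' intercept over the chosen window — the intercept absorbs baseline OD
#' offsets.  Points past the onset of nutrient limitation bias the slope
#' and should be excluded via `window`; `window = "auto"` picks the
#' prefix of at least 3 points with maximal R-squared.
#'
#' @param series Data frame with columns `time_h`, `substrate_mmol`,
#'   `od`, `volume_ml` (see [simulate_growth_series()]).
#' @param window Integer index range into the series (default: all
#'   points), or `"auto"`.
#' @return A `yield_estimate`: list with `slope` (g-DW per mol),
#'   `se`, `window`, `r_squared`.
#' @export
estimate_yield <- function(series, window = seq_len(nrow(series))) {
  stopifnot(all(c("time_h", "substrate_mmol", "od", "volume_ml") %in%
                  names(series)))
  if (identical(window, "auto")) {
    window <- auto_linear_window(series)
  }
  if (length(window) < 3)
    stop("fit window needs at least 3 points", call. = FALSE)
  s <- series[window, ]
  x <- (s$substrate_mmol[1] - s$substrate_mmol) / 1000          # mol consumed
  y <- od_to_dry_weight(s$od, s$volume_ml) / 1000               # g produced
  if (stats::sd(x) == 0)
    stop("no substrate consumption in the window; slope undefined",
         call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 se = sm$coefficients[2, 2],
                 window = range(window),
                 r_squared = sm$r.squared),
            class = "yield_estimate")
}

auto_linear_window <- function(series) {
  n <- nrow(series)
  best <- seq_len(min(3, n)); best_r2 <- -Inf
  for (end in 3:n) {
    w <- seq_len(end)
    x <- series$substrate_mmol[1] - series$substrate_mmol[w]
    y <- series$od[w]
    if (stats::sd(x) == 0) next
    r2 <- summary(stats::lm(y ~ x))$r.squared
    if (r2 > best_r2) { best_r2 <- r2; best <- w }
  }
  best
}

#' @export
print.yield_estimate <- function(x, ...) {
  cat("Biomass yield: ", format(x$slope, digits = 4), " +/- ",
      format(x$se, digits = 2), " g-DW mol-1 (points ", x$window[1], "..",
      x$window[2], ", R2 = ", format(x$r_squared, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' Convert a metabolic flux to an enzyme specific activity
#'
#' A flux in mmol h\eqn{^{-1}} g-DW\eqn{^{-1}} is the minimal in-vivo
#' activity of the catalysing enzyme; assuming a protein fraction of the
#' dry biomass (default one half) it converts to
#' nmol min\eqn{^{-1}} mg-protein\eqn{^{-1}} as
#' `flux * 1e6 / 60 / (1000 * protein_fraction)`.
#'
#' @param flux Flux in mmol h\eqn{^{-1}} g-DW\eqn{^{-1}} (>= 0).
#' @param protein_fraction Protein mass fraction of dry biomass, in
#'   (0, 1].
#' @return Specific activity in nmol min\eqn{^{-1}} mg-protein\eqn{^{-1}}.
#' @export
flux_to_specific_activity <- function(flux, protein_fraction = 0.5) {
  if (any(flux < 0)) stop("flux must be non-negative", call. = FALSE)
  if (protein_fraction <= 0 || protein_fraction > 1)
    stop("protein_fraction must be in (0, 1]", call. = FALSE)
  flux * 1e6 / 60 / (1000 * protein_fraction)
}

#' @rdname flux_to_specific_activity
#' @param activity Specific activity in nmol min\eqn{^{-1}}
#'   mg-protein\eqn{^{-1}}.
#' @export
specific_activity_to_flux <- function(activity, protein_fraction = 0.5) {
  if (any(activity < 0)) stop("activity must be non-negative", call. = FALSE)
  if (protein_fraction <= 0 || protein_fraction > 1)
    stop("protein_fraction must be in (0, 1]", call. = FALSE)
  activity * 60 * 1000 * protein_fraction / 1e6
}

#' Headspace gas amount from volume fraction
#'
#' Ideal-gas helper for serum-vial cultures: converts a headspace volume
#' fraction to mmol of gas.
#'
#' @param fraction Volume fraction of the gas (e.g. 0.1 for 10% v/v).
#' @param headspace_ml Headspace volume in ml.
#' @param temp_c Temperature in Celsius.
#' @param pressure_atm Total pressure in atm.
#' @return Amount of gas in mmol.
#' @export
headspace_to_mmol <- function(fraction, headspace_ml, temp_c = 25,
                              pressure_atm = 1) {
  stopifnot(fraction >= 0, fraction <= 1, headspace_ml >= 0)
  r_l_atm <- 0.082057                      # L atm mol-1 K-1
  pressure_atm * fraction * (headspace_ml / 1000) /
    (r_l_atm * (temp_c + 273.15)) * 1000
}
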