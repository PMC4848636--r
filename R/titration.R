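# Active-site titration and reversibility assessment for tight-binding
# protease inhibitors.

#' Active inhibitor concentration from a stoichiometric titration
#'
#' Under conditions where the enzyme concentration exceeds Ki a hundred-fold,
#' an inhibitor titrates the enzyme stoichiometrically: residual activity
#' declines linearly with added inhibitor and reaches zero at the equivalence
#' point where total inhibitor equals total enzyme. The active inhibitor
#' concentration is read off as the x-intercept of a least-squares line through
#' the linearly descending region, assuming a 1:1 complex.
#'
#' @param data Data frame with columns `conc` (added inhibitor, M, as nominal
#'   concentration) and `activity` (fractional residual activity vi/v0).
#' @param e0_over_ki Ratio of enzyme concentration to Ki for the assay. Values
#'   below 100 do not abort the analysis but attach a validity warning, because
#'   the stoichiometric (sharp-kink) regime is then not guaranteed.
#' @param window Fractional-activity window defining the linear region used
#'   for the regression (default points with vi/v0 in \[0.15, 0.85\]).
#' @return A `titration_fit` with `active_conc` (M), the regression
#'   coefficients, and any validity warnings. Supports [tidy()] and
#'   [glance()].
#' @examples
#' tt <- gen_titration(active_conc = 100e-9, e_total = 100e-9,
#'                     noise_sd = 0, seed = 1)
#' fit_titration(tt, e0_over_ki = 150)
#' @export
fit_titration <- function(data, e0_over_ki = NA_real_, window = c(0.15, 0.85)) {
  check_columns(data, c("conc", "activity"))
  d <- tibble(conc = as.numeric(data$conc), activity = as.numeric(data$activity))
  if (anyNA(d)) abort("`data` contains missing values.")
  if (nrow(d) < 3L) abort("titration underdetermined: fewer than 3 points.")
  d <- arrange(d, conc)
  if (min(d$activity) > 0.9 || suppressWarnings(cor(d$conc, d$activity)) >= 0) {
    abort("no titration signal: activities do not decline with added inhibitor.")
  }
  warnings <- character()
  if (!is.na(e0_over_ki) && e0_over_ki < 100) {
    msg <- sprintf("[E0]/Ki = %.3g < 100: titration may not be stoichiometric; active concentration is approximate.", e0_over_ki)
    warn(msg)
    warnings <- c(warnings, msg)
  }
  lin <- filter(d, .data$activity >= window[1], .data$activity <= window[2])
  if (nrow(lin) < 3L) {
    abort(sprintf("titration underdetermined: only %d point(s) in the linear region [%.2f, %.2f].",
                  nrow(lin), window[1], window[2]))
  }
  fit <- lm(activity ~ conc, data = lin)
  b <- coef(fit)
  if (!is.finite(b[[2]]) || b[[2]] >= 0) abort("no titration signal: non-descending linear region.")
  active <- -b[[1]] / b[[2]]
  new_fit("titration_fit",
          active_conc = active,
          intercept = unname(b[[1]]), slope = unname(b[[2]]),
          r_squared = suppressWarnings(summary(fit)$r.squared),
          n_linear = nrow(lin), n_points = nrow(d),
          e0_over_ki = e0_over_ki, data = d, region = lin,
          warnings = warnings)
}

#' Assess reversibility via substrate competition and preincubation stability
#'
#' Two qualitative diagnostics of a reversible, substrate-competitive
#' inhibitor: (i) fractional activity at fixed enzyme/inhibitor increases with
#' substrate concentration (substrate displaces inhibitor from the complex);
#' (ii) fractional activity is stable across preincubation times (equilibrium
#' is reached before the measurement).
#'
#' @param substrate Data frame with columns `s0_over_km` (substrate level as a
#'   multiple of KM, typically 0.5, 1, 2) and `activity` (vi/v0). Optional
#'   columns `e0` and `i0` are checked for constancy across levels. Replicate
#'   rows per level are averaged.
#' @param preincubation Data frame with columns `minutes` and `activity`
#'   (at least two times).
#' @param s0_tol Minimum increase in vi/v0 (fractional units) between
#'   consecutive substrate levels to call the trend real; default 0.02
#'   (2 percentage points).
#' @param time_tol Maximum spread of vi/v0 across preincubation times
#'   compatible with equilibrium; default 0.05 (5 percentage points).
#' @return A `reversibility_assessment` list with the per-level tables and a
#'   `verdict`: `"reversible_substrate_competitive"`,
#'   `"equilibrium_not_reached"`, or `"inconsistent"`.
#' @examples
#' assess_reversibility(
#'   substrate = data.frame(s0_over_km = c(0.5, 1, 2),
#'                          activity = c(0.55, 0.63, 0.72)),
#'   preincubation = data.frame(minutes = c(1, 5, 10, 20),
#'                              activity = c(0.63, 0.63, 0.64, 0.63)))
#' @export
assess_reversibility <- function(substrate, preincubation,
                                 s0_tol = 0.02, time_tol = 0.05) {
  check_columns(substrate, c("s0_over_km", "activity"), "substrate")
  check_columns(preincubation, c("minutes", "activity"), "preincubation")
  for (cond in intersect(c("e0", "i0"), names(substrate))) {
    if (length(unique(substrate[[cond]])) > 1L) {
      abort(sprintf("substrate-level curves were recorded under different `%s`; levels are not comparable.", cond))
    }
  }
  sub <- substrate |>
    group_by(.data$s0_over_km) |>
    summarise(activity = mean(.data$activity), .groups = "drop") |>
    arrange(.data$s0_over_km)
  if (nrow(sub) < 2L) abort("at least two substrate levels are required.")
  pre <- preincubation |>
    group_by(.data$minutes) |>
    summarise(activity = mean(.data$activity), .groups = "drop") |>
    arrange(.data$minutes)
  if (nrow(pre) < 2L) abort("at least two preincubation times are required.")

  time_spread <- max(pre$activity) - min(pre$activity)
  time_falling <- suppressWarnings(cor(pre$minutes, pre$activity)) < 0
  time_stable <- time_spread <= time_tol
  substrate_relief <- all(diff(sub$activity) > s0_tol)

  verdict <- if (!time_stable && isTRUE(time_falling)) {
    "equilibrium_not_reached"
  } else if (time_stable && substrate_relief) {
    "reversible_substrate_competitive"
  } else {
    "inconsistent"
  }
  structure(list(substrate = sub, preincubation = pre,
                 substrate_relief = substrate_relief,
                 time_stable = time_stable, time_spread = time_spread,
                 s0_tol = s0_tol, time_tol = time_tol, verdict = verdict),
            class = "reversibility_assessment")
}

#' @export
print.reversibility_assessment <- function(x, ...) {
  cat("<reversibility_assessment>\n")
  cat("verdict:", x$verdict, "\n")
  cat(sprintf("substrate relief beyond %.0f pp: %s; time spread %.3f (tol %.2f)\n",
              100 * x$s0_tol, x$substrate_relief, x$time_spread, x$time_tol))
  invisible(x)
}
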