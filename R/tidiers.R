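# broom-style tidiers for the fitted objects.

#' @method tidy morrison_fit
#' @export
tidy.morrison_fit <- function(x, ...) {
  tibble(term = "ki_app", estimate = x$ki_app, std.error = x$ki_app_se)
}

#' @method glance morrison_fit
#' @export
glance.morrison_fit <- function(x, ...) {
  tibble(ki_app = x$ki_app, ki_app_se = x$ki_app_se, rss = x$rss,
         e0 = x$e0, n_points = x$n_points, converged = x$converged)
}

#' @method tidy hill_fit
#' @export
tidy.hill_fit <- function(x, ...) {
  tibble(term = c("ic50", "h"),
         estimate = c(x$ic50, x$h),
         std.error = c(x$ic50_se, x$h_se))
}

#' @method glance hill_fit
#' @export
glance.hill_fit <- function(x, ...) {
  tibble(ic50 = x$ic50, ic50_se = x$ic50_se, h = x$h, h_se = x$h_se,
         extrapolated = x$extrapolated, n_points = x$n_points,
         converged = x$converged)
}

#' @method tidy boltzmann_fit
#' @export
tidy.boltzmann_fit <- function(x, ...) {
  tibble(term = c("v_half", "slope_k", "gmax"),
         estimate = c(x$v_half, x$slope_k, x$gmax),
         std.error = c(x$v_half_se, x$slope_k_se, NA_real_))
}

#' @method glance boltzmann_fit
#' @export
glance.boltzmann_fit <- function(x, ...) {
  tibble(v_half = x$v_half, v_half_se = x$v_half_se, slope_k = x$slope_k,
         slope_k_se = x$slope_k_se, gmax = x$gmax, n_points = x$n_points,
         converged = x$converged)
}

#' @method tidy titration_fit
#' @export
tidy.titration_fit <- function(x, ...) {
  tibble(term = c("active_conc", "slope", "intercept"),
         estimate = c(x$active_conc, x$slope, x$intercept),
         std.error = NA_real_)
}

#' @method glance titration_fit
#' @export
glance.titration_fit <- function(x, ...) {
  tibble(active_conc = x$active_conc, r_squared = x$r_squared,
         n_linear = x$n_linear, n_points = x$n_points,
         e0_over_ki = x$e0_over_ki,
         converged = TRUE)
}

#' @method tidy specificity_grouping
#' @export
tidy.specificity_grouping <- function(x, ...) x$groups

#' @method tidy vdep_assessment
#' @export
tidy.vdep_assessment <- function(x, ...) x$table

#' @method tidy compensation_report
#' @export
tidy.compensation_report <- function(x, ...) x$substitutions
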