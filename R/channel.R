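# Kv-channel block analysis: percent block, Hill concentration-response fits,
# conductance-voltage transformation, Boltzmann activation fits and tests for
# shifts in gating or voltage dependence of block.

#' Percent block from paired steady-state currents
#'
#' `100 * (1 - i_toxin / i_control)`, the standard summary of channel block by
#' a toxin at a fixed test potential. Values outside \[0, 100\] (noise
#' overshoot or current run-up) are clamped with a warning.
#'
#' @param i_control,i_toxin Steady-state currents (same units, same sign)
#'   before and after toxin application.
#' @return Percent block in \[0, 100\], vectorized.
#' @examples
#' percent_block(2, 1)
#' @export
percent_block <- function(i_control, i_toxin) {
  n <- max(length(i_control), length(i_toxin))
  ic <- rep_len(as.numeric(i_control), n)
  it <- rep_len(as.numeric(i_toxin), n)
  if (anyNA(ic) || anyNA(it) || !all(is.finite(ic), is.finite(it))) {
    abort("currents must be finite.")
  }
  if (any(ic == 0)) abort("undefined block: control current is zero.")
  if (any(ic * it < 0)) abort("control and toxin currents must have the same sign.")
  pb <- 100 * (1 - it / ic)
  if (any(pb < 0 | pb > 100)) {
    warn("percent block outside [0, 100] clamped.")
    pb <- pmin(pmax(pb, 0), 100)
  }
  pb
}

#' Fit the Hill equation to a concentration-response curve
#'
#' Fits `y = 100 / (1 + (ic50 / conc)^h)` to percent block as a function of
#' toxin concentration by nonlinear least squares. By construction the fitted
#' curve passes through 50% block at `conc = ic50` for any Hill coefficient.
#'
#' @param data Data frame with columns `conc` (M) and `block` (percent,
#'   0-100).
#' @param fix_h Optional fixed Hill coefficient (e.g. `fix_h = 1` for a
#'   one-site fit); by default `h` is estimated.
#' @return A `hill_fit` with `ic50`, `h`, standard errors, a `converged` flag
#'   and an `extrapolated` flag set when the observed plateau never reaches
#'   50% block. Supports [tidy()], [glance()], [predict()], [autoplot()].
#' @examples
#' dr <- gen_dose_response(ic50 = 9e-9, h = 1, noise_sd = 0, seed = 1)
#' fit_hill(dr)
#' @export
fit_hill <- function(data, fix_h = NULL) {
  check_columns(data, c("conc", "block"))
  d <- tibble(conc = as.numeric(data$conc), block = as.numeric(data$block))
  if (anyNA(d)) abort("`data` contains missing values.")
  check_positive_finite(d$conc, "conc")
  if (any(d$block < 0 | d$block > 100)) abort("`block` must lie in [0, 100].")
  if (length(unique(d$conc)) < 4L) abort("at least 4 concentrations are required.")
  d <- arrange(d, conc)
  warnings <- character()
  if (!any(d$block < 50) || !any(d$block > 50)) {
    warn("50% block is not bracketed by the data; IC50 is partly extrapolated.")
    warnings <- c(warnings, "50% block not bracketed")
  }
  extrapolated <- max(d$block) < 50
  if (extrapolated) warnings <- c(warnings, "IC50 extrapolated: plateau below 50% block")
  steps <- diff(d$block)
  if (any(steps < -10)) {
    warn("response is non-monotonic beyond tolerance (10 percentage points).")
    warnings <- c(warnings, "non-monotonic response")
  }
  start_ic50 <- 10^interp_crossing(log10(d$conc), d$block, 50)
  if (!is.finite(start_ic50) || start_ic50 <= 0) start_ic50 <- exp(mean(log(d$conc)))
  fit <- tryCatch({
    if (is.null(fix_h)) {
      minpack.lm::nlsLM(block ~ 100 / (1 + (ic50 / conc)^h), data = d,
                        start = list(ic50 = start_ic50, h = 1),
                        lower = c(ic50 = 1e-15, h = 1e-3),
                        control = nls.control(maxiter = 500))
    } else {
      check_positive_finite(fix_h, "fix_h")
      minpack.lm::nlsLM(block ~ 100 / (1 + (ic50 / conc)^fix_h), data = d,
                        start = list(ic50 = start_ic50),
                        lower = c(ic50 = 1e-15),
                        control = nls.control(maxiter = 500))
    }
  }, error = function(e) e)
  if (inherits(fit, "error")) {
    warn(paste0("Hill fit did not converge: ", conditionMessage(fit)))
    return(new_fit("hill_fit", ic50 = NA_real_, h = fix_h %||% NA_real_,
                   ic50_se = NA_real_, h_se = NA_real_, converged = FALSE,
                   extrapolated = extrapolated, n_points = nrow(d),
                   fix_h = fix_h, data = d, fit = NULL,
                   warnings = c(warnings, "non-convergence")))
  }
  sm <- summary(fit)$coefficients
  est <- coef(fit)
  new_fit("hill_fit",
          ic50 = unname(est[["ic50"]]),
          h = if (is.null(fix_h)) unname(est[["h"]]) else fix_h,
          ic50_se = unname(sm["ic50", "Std. Error"]),
          h_se = if (is.null(fix_h)) unname(sm["h", "Std. Error"]) else NA_real_,
          converged = isTRUE(fit$convInfo$isConv),
          extrapolated = extrapolated, n_points = nrow(d), fix_h = fix_h,
          data = d, fit = fit, warnings = warnings)
}

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$conc else newdata$conc
  100 / (1 + (object$ic50 / conc)^object$h)
}

#' Normalized conductance from a current-voltage series
#'
#' Transforms steady-state currents into conductances via the ohmic driving
#' force, `G = I / (V - Erev)`, excludes points too close to the reversal
#' potential (where the ratio is ill-conditioned), and normalizes to the
#' maximum.
#'
#' @param data Data frame with columns `v` (mV) and `i` (current).
#' @param erev Reversal potential (mV). When `NULL` it is estimated as the
#'   zero-crossing of the IV relation by linear interpolation.
#' @param exclusion_mv Half-width of the exclusion band around `erev`
#'   (default 5 mV).
#' @return Tibble with `v`, `i`, `g`, `g_norm`, with `erev` as an attribute.
#' @export
conductance_from_iv <- function(data, erev = NULL, exclusion_mv = 5) {
  check_columns(data, c("v", "i"))
  d <- tibble(v = as.numeric(data$v), i = as.numeric(data$i)) |> arrange(v)
  if (anyNA(d)) abort("`data` contains missing values.")
  if (is.null(erev)) {
    erev <- interp_crossing(d$v, d$i, 0)
    if (!is.finite(erev)) {
      abort("cannot estimate the reversal potential: the IV relation does not cross zero; supply `erev`.")
    }
  }
  keep <- abs(d$v - erev) >= exclusion_mv
  if (!any(keep)) {
    abort(sprintf("all voltages lie within %.1f mV of Erev = %.1f mV.", exclusion_mv, erev))
  }
  d <- d[keep, ]
  g <- d$i / (d$v - erev)
  if (all(g == 0)) abort("zero conductance at every voltage.")
  if (sum(g) < 0) g <- -g  # sign convention: conductance is positive
  if (any(g < 0)) {
    if (min(g) < -1e-6 * max(abs(g))) warn("negative conductances clamped to zero.")
    g <- pmax(g, 0)
  }
  out <- mutate(d, g = g, g_norm = g / max(g))
  attr(out, "erev") <- erev
  out
}

#' Fit a Boltzmann activation curve
#'
#' Fits `G(V) = Gmax / (1 + exp((v_half - v) / k))` to a (normalized)
#' conductance-voltage series, yielding the midpoint of activation `v_half`
#' and slope factor `k` in mV. `G(v_half)` equals `Gmax / 2` by construction.
#'
#' @param data Data frame with columns `v` (mV) and `g` (conductance,
#'   normalized or raw).
#' @return A `boltzmann_fit` with `v_half`, `slope_k`, `gmax`, standard errors
#'   and a `converged` flag. Supports [tidy()], [glance()], [predict()],
#'   [autoplot()].
#' @examples
#' iv <- gen_gv_family(v_half = 14, slope_k = 8, noise_sd = 0, seed = 1)
#' gv <- conductance_from_iv(data.frame(v = iv$v, i = iv$i_control), erev = -90)
#' fit_boltzmann(data.frame(v = gv$v, g = gv$g_norm))
#' @export
fit_boltzmann <- function(data) {
  check_columns(data, c("v", "g"))
  d <- tibble(v = as.numeric(data$v), g = as.numeric(data$g)) |> arrange(v)
  if (anyNA(d)) abort("`data` contains missing values.")
  if (nrow(d) < 4L) abort("at least 4 voltages are required.")
  warnings <- character()
  gmax0 <- max(d$g)
  if (diff(range(d$g)) < 1e-12) {
    warn("degenerate flat conductance series; fit not attempted.")
    return(new_fit("boltzmann_fit", v_half = NA_real_, slope_k = NA_real_,
                   gmax = NA_real_, v_half_se = NA_real_, slope_k_se = NA_real_,
                   converged = FALSE, n_points = nrow(d), data = d, fit = NULL,
                   warnings = "degenerate flat series"))
  }
  if (min(d$g) > 0.3 * gmax0) {
    warn("activation transition poorly spanned (min G > 0.3 max G); estimates may be unstable.")
    warnings <- c(warnings, "transition poorly spanned")
  }
  vh0 <- interp_crossing(d$v, d$g, gmax0 / 2)
  if (!is.finite(vh0)) vh0 <- mean(range(d$v))
  fit <- tryCatch(
    minpack.lm::nlsLM(g ~ gmax / (1 + exp((v_half - v) / k)), data = d,
                      start = list(gmax = gmax0, v_half = vh0, k = 8),
                      lower = c(gmax = 1e-12, v_half = -Inf, k = 1e-6),
                      control = nls.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    warn(paste0("Boltzmann fit did not converge: ", conditionMessage(fit)))
    return(new_fit("boltzmann_fit", v_half = NA_real_, slope_k = NA_real_,
                   gmax = NA_real_, v_half_se = NA_real_, slope_k_se = NA_real_,
                   converged = FALSE, n_points = nrow(d), data = d, fit = NULL,
                   warnings = c(warnings, "non-convergence")))
  }
  sm <- summary(fit)$coefficients
  est <- coef(fit)
  new_fit("boltzmann_fit",
          v_half = unname(est[["v_half"]]), slope_k = unname(est[["k"]]),
          gmax = unname(est[["gmax"]]),
          v_half_se = unname(sm["v_half", "Std. Error"]),
          slope_k_se = unname(sm["k", "Std. Error"]),
          converged = isTRUE(fit$convInfo$isConv),
          n_points = nrow(d), data = d, fit = fit, warnings = warnings)
}

#' @export
predict.boltzmann_fit <- function(object, newdata = NULL, ...) {
  v <- if (is.null(newdata)) object$data$v else newdata$v
  object$gmax / (1 + exp((object$v_half - v) / object$slope_k))
}

#' Paired comparison of activation midpoints
#'
#' Paired two-sided Student's t test on replicate `v_half` estimates under
#' control and toxin conditions. The verdict is `"no_shift"` when the p-value
#' is at or above `alpha`, i.e. when toxin application does not significantly
#' move the midpoint of activation (pore block rather than gating
#' modification).
#'
#' @param v_half_control,v_half_toxin Numeric vectors of paired midpoints
#'   (mV), one pair per oocyte/replicate.
#' @param alpha Significance level (default 0.05).
#' @return One-row tibble with means, the t statistic, p-value and verdict.
#' @examples
#' compare_v_half(c(14, 13, 15), c(15, 14, 16))
#' @export
compare_v_half <- function(v_half_control, v_half_toxin, alpha = 0.05) {
  a <- as.numeric(v_half_control)
  b <- as.numeric(v_half_toxin)
  if (length(a) != length(b)) abort("control and toxin vectors must be paired (equal length).")
  if (length(a) < 2L) abort("at least 2 paired replicates are required.")
  if (length(a) < 3L) warn("fewer than 3 pairs: the paired t test has very low power.")
  ddiff <- b - a
  if (isTRUE(all.equal(stats::sd(ddiff), 0)) || stats::sd(ddiff) == 0) {
    statistic <- if (mean(ddiff) == 0) 0 else Inf * sign(mean(ddiff))
    p <- if (mean(ddiff) == 0) 1 else 0
  } else {
    tt <- t.test(b, a, paired = TRUE)
    statistic <- unname(tt$statistic)
    p <- tt$p.value
  }
  tibble(n = length(a),
         mean_control = mean(a), mean_toxin = mean(b),
         mean_shift = mean(ddiff),
         statistic = statistic, p_value = p, alpha = alpha,
         verdict = if (p >= alpha) "no_shift" else "shift_detected")
}

#' Test whether channel block is voltage dependent
#'
#' Summarises percent block per test potential and calls the block voltage
#' independent when the spread of mean block across the voltage grid does not
#' exceed `tol` percentage points, or when a linear trend test of block
#' against voltage is non-significant.
#'
#' @param data Data frame with column `v` (mV) and either a `block` column
#'   (percent) or the current pair `i_control`, `i_toxin` from which block is
#'   computed. Replicates per voltage are averaged.
#' @param tol Tolerance on max - min mean block, percentage points
#'   (default 5).
#' @param alpha Significance level for the fallback trend test.
#' @return A `vdep_assessment` with the per-voltage table, the spread, the
#'   trend p-value and the verdict.
#' @export
voltage_dependence_of_block <- function(data, tol = 5, alpha = 0.05) {
  check_columns(data, "v")
  d <- as_tibble(data)
  if (!"block" %in% names(d)) {
    check_columns(d, c("i_control", "i_toxin"))
    d$block <- percent_block(d$i_control, d$i_toxin)
  }
  voltages <- unique(d$v)
  if (length(voltages) < 3L || diff(range(voltages)) < 40) {
    abort("at least 3 test potentials spanning >= 40 mV are required.")
  }
  tab <- d |>
    group_by(v = .data$v) |>
    summarise(block = mean(.data$block), n = dplyr::n(), .groups = "drop") |>
    arrange(v)
  spread <- max(tab$block) - min(tab$block)
  fit <- lm(block ~ v, data = tab)
  # noise-free block tables give a perfect linear fit; that is expected here
  p_trend <- suppressWarnings(summary(fit)$coefficients["v", "Pr(>|t|)"])
  verdict <- if (spread <= tol || p_trend >= alpha) "voltage_independent" else "voltage_dependent"
  structure(list(table = tab, spread = spread, p_trend = p_trend,
                 tol = tol, alpha = alpha, verdict = verdict),
            class = "vdep_assessment")
}

#' @export
print.vdep_assessment <- function(x, ...) {
  cat("<vdep_assessment>\n")
  cat(sprintf("verdict: %s (spread %.2f pp, tol %.1f; trend p = %.3g)\n",
              x$verdict, x$spread, x$tol, x$p_trend))
  print(as.data.frame(x$table), row.names = FALSE)
  invisible(x)
}
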