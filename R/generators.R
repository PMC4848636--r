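# Synthetic-data generators. Every generator is a deterministic function of
# (parameters, seed) and emits data satisfying the exact input contract of the
# analysis function that consumes it, plus a ground-truth attribute, so
# parameter-recovery can be tested end to end without laboratory data.
#
# Noise is multiplicative Gaussian (sd as a fraction of the signal):
# spectrophotometric rates and voltage-clamp currents both have errors that
# scale with the signal.

#' Generate a Morrison inhibition curve
#'
#' Inhibitor grid log-spaced up to `i_max_over_e0` times the enzyme
#' concentration (with the uninhibited point at 0 included), fractional
#' activities from [morrison_fraction()] with multiplicative Gaussian noise.
#' The default design mirrors a tight-binding assay run at an enzyme-to-Ki
#' ratio near 10 with 12 points.
#'
#' @param e0 Total enzyme concentration (M).
#' @param ki_app Generating apparent dissociation constant (M).
#' @param n_points Number of points including the zero-inhibitor point.
#' @param i_max_over_e0 Top of the inhibitor grid as a multiple of `e0`.
#' @param noise_sd Multiplicative noise sd (fraction of signal).
#' @param seed Mandatory RNG seed.
#' @return Tibble `conc`, `activity` with the generating parameters in
#'   `attr(, "truth")`.
#' @examples
#' gen_morrison_curve(e0 = 27e-9, ki_app = 5.4e-9, noise_sd = 0, seed = 1)
#' @export
gen_morrison_curve <- function(e0, ki_app, n_points = 12, i_max_over_e0 = 5,
                               noise_sd = 0.02, seed) {
  check_positive_finite(e0, "e0")
  check_positive_finite(ki_app, "ki_app")
  check_positive_finite(noise_sd, "noise_sd", allow_zero = TRUE)
  if (n_points < 5L) abort("`n_points` must be at least 5.")
  i_max <- i_max_over_e0 * e0
  grid <- c(0, 10^seq(log10(i_max / 30), log10(i_max), length.out = n_points - 1L))
  with_seed(seed, {
    act <- morrison_fraction(e0, grid, ki_app) * (1 + rnorm(n_points, 0, noise_sd))
    act <- pmin(pmax(act, 0), 1.05)
    out <- tibble(conc = grid, activity = act)
    attr(out, "truth") <- list(e0 = e0, ki_app = ki_app, noise_sd = noise_sd,
                               seed = seed)
    out
  })
}

#' Generate a stoichiometric active-site titration series
#'
#' Residual activity declines piecewise-linearly with added inhibitor,
#' reaching zero exactly at the equivalence point where the active inhibitor
#' added equals the enzyme present, then stays at zero. `active_conc` is the
#' nominal added concentration at the equivalence point, i.e. the quantity
#' [fit_titration()] recovers.
#'
#' @param active_conc Nominal added concentration at the equivalence point (M).
#' @param e_total Total enzyme concentration (M), metadata for the validity
#'   check.
#' @param n_points Number of points, spanning 0 to twice the equivalence
#'   point.
#' @param noise_sd Multiplicative noise sd.
#' @param seed Mandatory RNG seed.
#' @return Tibble `conc`, `activity`; truth in `attr(, "truth")`.
#' @export
gen_titration <- function(active_conc, e_total, n_points = 10, noise_sd = 0.01,
                          seed) {
  check_positive_finite(active_conc, "active_conc")
  check_positive_finite(e_total, "e_total")
  check_positive_finite(noise_sd, "noise_sd", allow_zero = TRUE)
  if (n_points < 6L) abort("`n_points` must be at least 6 (the grid must span the equivalence point).")
  grid <- seq(0, 2 * active_conc, length.out = n_points)
  with_seed(seed, {
    act <- pmax(0, 1 - grid / active_conc) * (1 + rnorm(n_points, 0, noise_sd))
    out <- tibble(conc = grid, activity = pmax(act, 0))
    attr(out, "truth") <- list(active_conc = active_conc, e_total = e_total,
                               noise_sd = noise_sd, seed = seed)
    out
  })
}

#' Generate a Hill concentration-response curve
#'
#' Log-spaced concentrations centred on the generating IC50, percent block
#' from `100 / (1 + (ic50/conc)^h)` with multiplicative noise, clipped to
#' \[0, 100\].
#'
#' @param ic50 Generating half-maximal concentration (M).
#' @param h Generating Hill coefficient.
#' @param n_conc Number of concentrations.
#' @param decades Width of the grid in log10 units, centred on `ic50`
#'   (at least 2).
#' @param noise_sd Multiplicative noise sd.
#' @param seed Mandatory RNG seed.
#' @return Tibble `conc`, `block`; truth in `attr(, "truth")`.
#' @export
gen_dose_response <- function(ic50, h = 1, n_conc = 8, decades = 2,
                              noise_sd = 0.05, seed) {
  check_positive_finite(ic50, "ic50")
  check_positive_finite(h, "h")
  check_positive_finite(noise_sd, "noise_sd", allow_zero = TRUE)
  if (decades < 2) abort("`decades` must be at least 2 so the curve brackets the IC50.")
  if (n_conc < 4L) abort("`n_conc` must be at least 4.")
  conc <- 10^seq(log10(ic50) - decades / 2, log10(ic50) + decades / 2,
                 length.out = n_conc)
  with_seed(seed, {
    y <- 100 / (1 + (ic50 / conc)^h) * (1 + rnorm(n_conc, 0, noise_sd))
    out <- tibble(conc = conc, block = pmin(pmax(y, 0), 100))
    attr(out, "truth") <- list(ic50 = ic50, h = h, noise_sd = noise_sd,
                               seed = seed)
    out
  })
}

#' Generate a paired control/toxin IV family with Boltzmann gating
#'
#' Currents follow an ohmic driving force gated by a Boltzmann open
#' probability, `I(V) = gmax * Po(V) * (V - erev)`; the toxin series is the
#' control scaled by `1 - block_fraction` uniformly in voltage, so the
#' generated block is voltage independent by construction.
#'
#' @param v_half,slope_k Midpoint (mV) and slope factor (mV) of activation.
#' @param erev Reversal potential (mV); the default -90 mV is the potassium
#'   equilibrium potential in a standard low-K bath.
#' @param v_grid Test potentials (mV).
#' @param block_fraction Fraction of current blocked by the toxin.
#' @param gmax Maximal conductance (uA/mV).
#' @param noise_sd Multiplicative noise sd applied independently to both
#'   series.
#' @param seed Mandatory RNG seed.
#' @return Tibble `v`, `i_control`, `i_toxin`; truth in `attr(, "truth")`.
#' @export
gen_gv_family <- function(v_half = 14, slope_k = 8, erev = -90,
                          v_grid = seq(-40, 40, by = 10), block_fraction = 0.5,
                          gmax = 0.05, noise_sd = 0.05, seed) {
  check_positive_finite(slope_k, "slope_k")
  check_positive_finite(gmax, "gmax")
  check_positive_finite(noise_sd, "noise_sd", allow_zero = TRUE)
  if (block_fraction < 0 || block_fraction > 1) abort("`block_fraction` must lie in [0, 1].")
  po <- 1 / (1 + exp((v_half - v_grid) / slope_k))
  ideal <- gmax * po * (v_grid - erev)
  with_seed(seed, {
    out <- tibble(
      v = v_grid,
      i_control = ideal * (1 + rnorm(length(v_grid), 0, noise_sd)),
      i_toxin = (1 - block_fraction) * ideal * (1 + rnorm(length(v_grid), 0, noise_sd))
    )
    attr(out, "truth") <- list(v_half = v_half, slope_k = slope_k, erev = erev,
                               block_fraction = block_fraction, gmax = gmax,
                               noise_sd = noise_sd, seed = seed)
    out
  })
}

#' Generate a synthetic Kunitz alignment with planted specificity groups
#'
#' Builds an ungapped alignment of sequences sharing a six-cysteine framework
#' (Cys VI = Cys V + 4), with residues at the five exposed window positions
#' drawn from planted physicochemical classes. Sequences fall into: a base
#' group; `n_compensated` variants carrying the intra-window class swap at
#' (Xa+1, Xa+3), which preserves the N-window class multiset; and
#' `n_noncompensated` variants carrying a single class change at Xb+1, which
#' does not. Non-window positions are drawn uniformly from the 19 non-Cys
#' residues per sequence; buried window positions are held constant. An ASA
#' table marks the canonical exposed set as >50% exposed and everything else
#' below. The truth record lists the intended strict- and compensated-mode
#' groupings.
#'
#' @param n_seqs Total number of sequences.
#' @param scaffold_length Ungapped sequence length.
#' @param cys_positions The six framework cysteine positions (increasing;
#'   positions 5 and 6 exactly 4 apart; Cys I at position 3 or later).
#' @param window_classes Named classes for the exposed slots `Xa-2`, `Xa+1`,
#'   `Xa+3`, `Xb+1`, `Xb+2`. The defaults place a positive charge at Xa-2 and
#'   the C-window positions and a hydrophobic/positive contrast at Xa+1/Xa+3,
#'   the configuration in which the intra-window swap is well defined.
#' @param n_compensated Number of swap variants.
#' @param n_noncompensated Number of single-change variants (at most 3, so
#'   each carries a distinct replacement class).
#' @param seed Mandatory RNG seed.
#' @return List with `alignment` (a [kunitz_alignment()]), `asa` (tibble
#'   `id`, `pos_published`, `rel_asa`) and `truth` (planted classes and
#'   intended groupings).
#' @export
gen_kunitz_msa <- function(n_seqs = 8, scaffold_length = 58,
                           cys_positions = c(5, 14, 30, 38, 51, 55),
                           window_classes = c("Xa-2" = "positive",
                                              "Xa+1" = "hydrophobic",
                                              "Xa+3" = "positive",
                                              "Xb+1" = "positive",
                                              "Xb+2" = "positive"),
                           n_compensated = 2, n_noncompensated = 2, seed) {
  cys_positions <- as.integer(cys_positions)
  if (length(cys_positions) != 6L || is.unsorted(cys_positions, strictly = TRUE)) {
    abort("`cys_positions` must be six strictly increasing positions.")
  }
  if (cys_positions[6] - cys_positions[5] != 4L) {
    abort("inconsistent plant spec: Cys VI must sit exactly 4 residues after Cys V.")
  }
  if (cys_positions[1] < 3L) abort("inconsistent plant spec: Cys I must be at position 3 or later.")
  if (max(cys_positions) + 0L > scaffold_length) abort("cysteines exceed the scaffold length.")
  if (!setequal(names(window_classes), DEFAULT_EXPOSED_SLOTS)) {
    abort(sprintf("`window_classes` must name exactly: %s.",
                  paste(DEFAULT_EXPOSED_SLOTS, collapse = ", ")))
  }
  valid_classes <- unique(unname(RESIDUE_CLASSES))
  if (!all(window_classes %in% valid_classes)) {
    abort("inconsistent plant spec: unknown residue class in `window_classes`.")
  }
  n_base <- n_seqs - n_compensated - n_noncompensated
  if (n_base < 1L) abort("inconsistent plant spec: no sequences left for the base group.")
  if (n_compensated > 0L && window_classes[["Xa+1"]] == window_classes[["Xa+3"]]) {
    abort("inconsistent plant spec: the (Xa+1, Xa+3) swap requires different classes at those slots.")
  }
  if (n_noncompensated > 3L) {
    abort("inconsistent plant spec: at most 3 non-compensated variants (distinct replacement classes).")
  }

  cI <- cys_positions[1]; cV <- cys_positions[5]; cVI <- cys_positions[6]
  slot_pos <- c("Xa-2" = cI - 2L, "Xa-1" = cI - 1L, "CysI" = cI,
                "Xa+1" = cI + 1L, "Xa+2" = cI + 2L, "Xa+3" = cI + 3L,
                "CysV" = cV, "Xb+1" = cV + 1L, "Xb+2" = cV + 2L,
                "Xb+3" = cV + 3L, "CysVI" = cVI)
  if (any(slot_pos[c("Xa+1", "Xa+2", "Xa+3")] >= cys_positions[2])) {
    abort("inconsistent plant spec: the N-window overlaps Cys II.")
  }
  exposed_pos <- slot_pos[DEFAULT_EXPOSED_SLOTS]
  buried_window_pos <- slot_pos[c("Xa-1", "Xa+2", "Xb+3")]

  # residue pools per class; Cys excluded everywhere so exactly the six
  # framework columns are cysteine-conserved
  pools <- split(names(RESIDUE_CLASSES), unname(RESIDUE_CLASSES))
  pools <- map(pools, setdiff, "C")
  aa19 <- setdiff(names(RESIDUE_CLASSES), "C")

  # planted class vectors per sequence
  base_classes <- window_classes
  comp_classes <- base_classes
  comp_classes[c("Xa+1", "Xa+3")] <- base_classes[c("Xa+3", "Xa+1")]
  other <- setdiff(valid_classes, base_classes[["Xb+1"]])
  seq_classes <- c(rep(list(base_classes), n_base),
                   rep(list(comp_classes), n_compensated),
                   map(seq_len(n_noncompensated), function(k) {
                     v <- base_classes
                     v[["Xb+1"]] <- other[k]
                     v
                   }))
  role <- c(rep("base", n_base), rep("compensated", n_compensated),
            if (n_noncompensated) paste0("noncompensated_", seq_len(n_noncompensated)))
  ids <- sprintf("syn%02d", seq_len(n_seqs))

  with_seed(seed, {
    scaffold <- sample(aa19, scaffold_length, replace = TRUE)
    scaffold[buried_window_pos] <- sample(aa19, 3, replace = TRUE)
    seqs <- map_chr(seq_len(n_seqs), function(s) {
      chars <- sample(aa19, scaffold_length, replace = TRUE)
      chars[cys_positions] <- "C"
      chars[buried_window_pos] <- scaffold[buried_window_pos]
      for (slot in DEFAULT_EXPOSED_SLOTS) {
        pool <- pools[[seq_classes[[s]][[slot]]]]
        chars[slot_pos[[slot]]] <- sample(pool, 1)
      }
      paste(chars, collapse = "")
    })
    aln <- kunitz_alignment(ids, seqs, offset = 0L)
    asa <- tidyr::expand_grid(id = ids, slot = names(slot_pos)) |>
      mutate(pos_published = unname(slot_pos[.data$slot]),
             rel_asa = ifelse(.data$slot %in% DEFAULT_EXPOSED_SLOTS,
                              runif(dplyr::n(), 55, 95),
                              runif(dplyr::n(), 5, 45))) |>
      select("id", "pos_published", "rel_asa")
    strict_key <- map_chr(seq_classes, paste, collapse = "|")
    comp_key <- role
    comp_key[comp_key %in% c("base", "compensated")] <- "base"
    truth <- list(
      ids = ids, role = role,
      classes = seq_classes,
      strict_groups = tibble(id = ids, group = match(strict_key, unique(strict_key))),
      compensated_groups = tibble(id = ids, group = match(comp_key, unique(comp_key))),
      cys_positions = cys_positions, slot_pos = slot_pos, seed = seed
    )
    list(alignment = aln, asa = asa, truth = truth)
  })
}
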