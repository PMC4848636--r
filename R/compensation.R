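# Physicochemical class profiles at the exposed window positions,
# compensated-substitution detection and specificity grouping.

#' Residue physicochemical class table
#'
#' Total mapping of the 20 standard residues onto four physicochemical
#' classes. His counts as positive and Pro and Gly as hydrophobic; Cys and
#' Tyr sit with the polar uncharged residues. Pass a modified copy as the
#' `classes` argument of [classify_residue()] / [class_profiles()] to change
#' the convention.
#'
#' @format Named character vector of length 20.
#' @export
RESIDUE_CLASSES <- c(
  D = "negative", E = "negative",
  K = "positive", R = "positive", H = "positive",
  S = "polar_uncharged", T = "polar_uncharged", N = "polar_uncharged",
  Q = "polar_uncharged", C = "polar_uncharged", Y = "polar_uncharged",
  G = "hydrophobic", A = "hydrophobic", V = "hydrophobic", L = "hydrophobic",
  I = "hydrophobic", P = "hydrophobic", F = "hydrophobic", M = "hydrophobic",
  W = "hydrophobic"
)

#' Physicochemical class of amino-acid residues
#'
#' Maps one-letter codes onto `negative` (D, E), `positive` (K, R, H),
#' `polar_uncharged` (S, T, N, Q, C, Y) or `hydrophobic`
#' (G, A, V, L, I, P, F, M, W). Unknown letters (including X) yield the
#' explicit marker `"unclassifiable"`, which downstream comparisons treat as
#' never matching, so an ambiguous residue can not silently support a
#' grouping.
#'
#' @param aa Character vector of one-letter residue codes.
#' @param classes Named class table; override to change the mapping.
#' @return Character vector of class labels.
#' @examples
#' classify_residue(c("H", "P", "E", "X"))
#' @export
classify_residue <- function(aa, classes = RESIDUE_CLASSES) {
  aa <- toupper(as.character(aa))
  out <- unname(classes[aa])
  out[is.na(out)] <- "unclassifiable"
  out
}

#' Filter window positions by solvent exposure
#'
#' Retains window positions whose relative accessible surface area exceeds
#' `threshold` percent (strictly). Without an ASA table the canonical exposed
#' set of the Kunitz fold, `{Xa-2, Xa+1, Xa+3, Xb+1, Xb+2}`, is used and the
#' provenance column records that the default was applied; positions missing
#' from a supplied table are marked `exposure_unknown`.
#'
#' @param mw A `motif_windows` object from [extract_windows()].
#' @param asa Optional tibble with columns `id`, `pos_published`,
#'   `rel_asa` (percent; the relative scale may exceed 100).
#' @param threshold Exposure threshold in percent (default 50, strict
#'   inequality).
#' @return Tibble `id`, `window`, `slot`, `pos_published`, `rel_asa`,
#'   `exposed`, `provenance`.
#' @export
exposure_filter <- function(mw, asa = NULL, threshold = 50) {
  check_columns(mw, c("id", "window", "slot", "pos_published"), "mw")
  base <- as_tibble(mw)[, c("id", "window", "slot", "pos_published")]
  if (is.null(asa)) {
    return(mutate(base,
                  rel_asa = NA_real_,
                  exposed = as.character(.data$slot) %in% DEFAULT_EXPOSED_SLOTS,
                  provenance = "default_exposed_set"))
  }
  check_columns(asa, c("id", "pos_published", "rel_asa"), "asa")
  if (any(asa$rel_asa < 0, na.rm = TRUE)) abort("`rel_asa` must be non-negative.")
  out <- left_join(base, as_tibble(asa)[, c("id", "pos_published", "rel_asa")],
                   by = c("id", "pos_published"))
  mutate(out,
         exposed = .data$rel_asa > threshold,
         provenance = ifelse(is.na(.data$rel_asa), "exposure_unknown", "asa_table"))
}

#' Build per-toxin physicochemical class profiles
#'
#' Restricts the extracted windows to exposed positions and attaches the
#' residue class at each. Buried or partially exposed positions (the
#' framework cysteines, Xa-1, Xa+2, Xb+3) never enter profiles.
#'
#' @param mw A `motif_windows` object.
#' @param exposure Optional result of [exposure_filter()]; by default the
#'   canonical exposed set is used.
#' @param classes Residue-class table, see [classify_residue()].
#' @return A `class_profile` tibble: `id`, `window`, `slot`, `residue`,
#'   `class`.
#' @export
class_profiles <- function(mw, exposure = NULL, classes = RESIDUE_CLASSES) {
  if (is.null(exposure)) exposure <- exposure_filter(mw)
  keep <- filter(exposure, !is.na(.data$exposed) & .data$exposed)
  out <- inner_join(as_tibble(mw)[, c("id", "window", "slot", "residue")],
                    keep[, c("id", "slot")], by = c("id", "slot"))
  out <- mutate(out, class = classify_residue(.data$residue, classes)) |>
    arrange(.data$id, .data$slot)
  class(out) <- c("class_profile", class(out))
  out
}

verdict_levels <- c("identical", "compensated", "non_compensated")

# per-window comparison of two class vectors; returns the verdict and the
# decomposition of differences into class-swap pairs when one exists
compare_window_classes <- function(slots, class_a, class_b) {
  differ <- which(class_a != class_b |
                    class_a == "unclassifiable" | class_b == "unclassifiable")
  if (!length(differ)) {
    return(list(verdict = "identical",
                swaps = tibble(slot_1 = character(), slot_2 = character())))
  }
  from <- class_a[differ]
  to <- class_b[differ]
  if (any(from == "unclassifiable" | to == "unclassifiable")) {
    return(list(verdict = "non_compensated",
                swaps = tibble(slot_1 = character(), slot_2 = character())))
  }
  # the differences decompose into swaps iff every x->y change is matched by
  # a y->x change; pair them up greedily
  swaps <- list()
  unmatched <- seq_along(differ)
  while (length(unmatched)) {
    i <- unmatched[1]
    j <- unmatched[unmatched != i][
      from[unmatched[unmatched != i]] == to[i] &
        to[unmatched[unmatched != i]] == from[i]]
    if (!length(j)) {
      return(list(verdict = "non_compensated",
                  swaps = tibble(slot_1 = character(), slot_2 = character())))
    }
    j <- j[1]
    swaps[[length(swaps) + 1L]] <- c(slots[differ[i]], slots[differ[j]])
    unmatched <- setdiff(unmatched, c(i, j))
  }
  list(verdict = "compensated",
       swaps = tibble(slot_1 = map_chr(swaps, 1), slot_2 = map_chr(swaps, 2)))
}

#' Compare two class profiles for compensated substitutions
#'
#' Within each window the exposed-position class vectors of toxins `a` and `b`
#' are compared. The window verdict is `identical` when the vectors agree
#' position-wise; `compensated` when they differ but every class change is
#' matched by the reciprocal change at another position of the same window
#' (the differences decompose into class swaps, preserving the window's class
#' multiset); `non_compensated` otherwise. The overall verdict is the worse of
#' the two windows. Substitution pairs that preserve the class multiset only
#' across windows are reported separately and do not soften the verdict.
#'
#' @param profiles A `class_profile` tibble covering both toxins.
#' @param a,b The two toxin ids to compare.
#' @return A `compensation_report` with the substitution table, the swap
#'   pairs, per-window verdicts and the overall verdict.
#' @export
detect_compensation <- function(profiles, a, b) {
  check_columns(profiles, c("id", "window", "slot", "class"), "profiles")
  pa <- filter(as_tibble(profiles), .data$id == a) |> arrange(.data$slot)
  pb <- filter(as_tibble(profiles), .data$id == b) |> arrange(.data$slot)
  if (!nrow(pa) || !nrow(pb)) abort("both ids must be present in `profiles`.")
  if (!identical(paste(pa$window, pa$slot), paste(pb$window, pb$slot))) {
    abort("profiles cover different position sets; rebuild them with a common exposure filter.")
  }
  per_window <- map(c(N = "N", C = "C"), function(w) {
    ia <- pa$window == w
    if (!any(ia)) return(list(verdict = "identical",
                              swaps = tibble(slot_1 = character(), slot_2 = character())))
    compare_window_classes(as.character(pa$slot[ia]), pa$class[ia], pb$class[ia])
  })
  verdicts <- map_chr(per_window, "verdict")
  overall <- verdict_levels[max(match(verdicts, verdict_levels))]
  subs <- tibble(window = pa$window, slot = as.character(pa$slot),
                 class_a = pa$class, class_b = pb$class) |>
    filter(.data$class_a != .data$class_b)
  cross_multiset <- overall == "non_compensated" &&
    identical(sort(pa$class), sort(pb$class))
  structure(list(pair = c(a = a, b = b),
                 substitutions = subs,
                 compensated_pairs = bind_rows(
                   mutate(per_window$N$swaps, window = "N"),
                   mutate(per_window$C$swaps, window = "C")),
                 verdict_by_window = verdicts,
                 cross_window_multiset_preserved = cross_multiset,
                 verdict = overall),
            class = "compensation_report")
}

#' @export
print.compensation_report <- function(x, ...) {
  cat(sprintf("<compensation_report> %s vs %s: %s\n",
              x$pair[["a"]], x$pair[["b"]], x$verdict))
  if (nrow(x$substitutions)) print(as.data.frame(x$substitutions), row.names = FALSE)
  if (nrow(x$compensated_pairs)) {
    cat("swap pairs:",
        paste(sprintf("(%s, %s)", x$compensated_pairs$slot_1,
                      x$compensated_pairs$slot_2), collapse = " "), "\n")
  }
  if (x$cross_window_multiset_preserved) {
    cat("note: class multiset preserved across windows only.\n")
  }
  invisible(x)
}

#' Partition toxins into predicted specificity groups
#'
#' In `strict` mode two toxins share a group iff their exposed-position class
#' vectors are identical in both windows. In `compensated` mode (the default)
#' they share a group iff [detect_compensation()] returns `identical` or
#' `compensated`; because that relation need not be transitive, groups are its
#' transitive closure, and a closure that merges a non-compensated pair is
#' flagged.
#'
#' @param profiles A `class_profile` tibble.
#' @param mode `"compensated"` or `"strict"`.
#' @return A `specificity_grouping` with a `groups` tibble (`id`, `group`),
#'   the pairwise verdict table, and a `nontransitive` flag.
#' @export
group_specificities <- function(profiles, mode = c("compensated", "strict")) {
  mode <- match.arg(mode)
  check_columns(profiles, c("id", "window", "slot", "class"), "profiles")
  ids <- unique(profiles$id)
  n <- length(ids)
  pairs <- if (n > 1L) as_tibble(t(combn(ids, 2L)), .name_repair = ~c("a", "b")) else
    tibble(a = character(), b = character())
  if (nrow(pairs)) {
    pairs$verdict <- map_chr(seq_len(nrow(pairs)), function(k) {
      detect_compensation(profiles, pairs$a[k], pairs$b[k])$verdict
    })
  } else {
    pairs$verdict <- character()
  }
  linked <- if (mode == "strict") pairs$verdict == "identical" else
    pairs$verdict %in% c("identical", "compensated")
  # union-find transitive closure
  parent <- setNames(seq_len(n), ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (k in which(linked)) {
    ra <- find(match(pairs$a[k], ids))
    rb <- find(match(pairs$b[k], ids))
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(seq_len(n), find, integer(1))
  groups <- tibble(id = ids, group = match(roots, unique(roots)))
  nontransitive <- FALSE
  if (mode == "compensated" && nrow(pairs)) {
    ga <- groups$group[match(pairs$a, groups$id)]
    gb <- groups$group[match(pairs$b, groups$id)]
    nontransitive <- any(ga == gb & pairs$verdict == "non_compensated")
    if (nontransitive) {
      warn("compensation relation is not transitive on this set: the closure merged at least one non-compensated pair.")
    }
  }
  structure(list(groups = groups, pairs = pairs, mode = mode,
                 nontransitive = nontransitive),
            class = "specificity_grouping")
}

#' @export
print.specificity_grouping <- function(x, ...) {
  cat(sprintf("<specificity_grouping> mode = %s, %d group(s)%s\n",
              x$mode, max(x$groups$group),
              if (x$nontransitive) " [non-transitive closure]" else ""))
  for (g in sort(unique(x$groups$group))) {
    cat(sprintf("  %d: %s\n", g, paste(x$groups$id[x$groups$group == g], collapse = ", ")))
  }
  invisible(x)
}

#' Locate annotated key residues relative to the two windows
#'
#' Labels each annotated residue (published numbering) as lying inside the
#' N-window, inside the C-window, or outside both; positions beyond the
#' record's sequence range are reported as `out_of_range`.
#'
#' @param mw A `motif_windows` object.
#' @param annotations Tibble with columns `id`, `pos_published` and optional
#'   `note`.
#' @param aln Optional alignment used to determine each record's sequence
#'   range for out-of-range checks.
#' @return Tibble `id`, `pos_published`, `note`, `location`, `slot`.
#' @export
map_key_residues <- function(mw, annotations, aln = NULL) {
  check_columns(annotations, c("id", "pos_published"), "annotations")
  ann <- as_tibble(annotations)
  if (!"note" %in% names(ann)) ann$note <- NA_character_
  w <- as_tibble(mw)[, c("id", "window", "slot", "pos_published")]
  out <- left_join(ann, w, by = c("id", "pos_published"))
  out$location <- ifelse(is.na(out$window), "outside",
                         ifelse(out$window == "N", "N_window", "C_window"))
  if (!is.null(aln)) {
    rng <- tibble(id = aln$id,
                  lo = aln$offset + 1L,
                  hi = aln$offset + nchar(gsub("-", "", aln$aligned)))
    out <- left_join(out, rng, by = "id")
    oor <- !is.na(out$lo) & (out$pos_published < out$lo | out$pos_published > out$hi)
    out$location[oor] <- "out_of_range"
    out$lo <- out$hi <- NULL
  }
  out$slot <- as.character(out$slot)
  out[, c("id", "pos_published", "note", "location", "slot")]
}
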