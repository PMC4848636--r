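# Solvent accessibility from coordinates (Shrake-Rupley sphere sampling),
# relative accessibility against an isolated-residue reference, and
# distance-cutoff interatomic contacts.

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Built-in van der Waals radius table
#'
#' Element-to-radius map (Angstrom) used by [shrake_rupley()]. Override or
#' extend by passing a modified copy as `radii`.
#'
#' @return Named numeric vector.
#' @export
vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80,
    SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
    ZN = 1.39, CA = 1.74, MG = 1.73, FE = 1.80, "NA" = 2.27, K = 2.75)
}

# n approximately evenly distributed points on the unit sphere
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-atom solvent accessible surface area (Shrake-Rupley)
#'
#' Rolls a spherical probe over every atom: each atom is expanded to radius
#' `r_atom + probe_radius` and sampled with `n_points` quasi-uniform sphere
#' points (golden-spiral set); a point is accessible when it lies outside the
#' expanded spheres of all neighbouring atoms, and the atom's ASA is the
#' accessible fraction times the expanded sphere area. The result is
#' deterministic for a fixed point count.
#'
#' @param atoms Tibble of atoms with columns `element`, `x`, `y`, `z` (and,
#'   for per-residue summaries, `chain`, `resno`, `resid`), e.g. from
#'   [read_structure()]. Hydrogens are typically excluded upstream.
#' @param probe_radius Probe radius in Angstrom (default 1.4, water).
#' @param n_points Sphere sample points per atom (default 960).
#' @param radii Element radius table, see [vdw_radii()].
#' @return The input tibble with columns `radius` and `asa` (Angstrom^2)
#'   added; `probe_radius` and `n_points` are stored as attributes.
#' @examples
#' one <- data.frame(element = "C", x = 0, y = 0, z = 0)
#' shrake_rupley(one)$asa # ~ 4*pi*(1.7 + 1.4)^2
#' @export
shrake_rupley <- function(atoms, probe_radius = 1.4, n_points = 960,
                          radii = vdw_radii()) {
  check_columns(atoms, c("element", "x", "y", "z"), "atoms")
  check_positive_finite(probe_radius, "probe_radius")
  el <- toupper(atoms$element)
  unknown <- setdiff(unique(el), names(radii))
  if (length(unknown)) {
    abort(sprintf("no van der Waals radius for element(s): %s.",
                  paste(unknown, collapse = ", ")))
  }
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  if (anyNA(xyz) || !all(is.finite(xyz))) abort("coordinates must be finite.")
  n <- nrow(xyz)
  r <- unname(radii[el]) + probe_radius
  sp <- golden_spiral_points(n_points)
  d2 <- as.matrix(stats::dist(xyz))^2
  asa <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (r[i] + r)^2 & seq_len(n) != i)
    if (!length(nb)) {
      asa[i] <- 4 * pi * r[i]^2
      next
    }
    pts <- sweep(sp * r[i], 2, xyz[i, ], `+`)
    accessible <- rep(TRUE, n_points)
    for (j in nb) {
      dd <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      accessible <- accessible & dd > r[j]^2
      if (!any(accessible)) break
    }
    asa[i] <- 4 * pi * r[i]^2 * mean(accessible)
  }
  out <- as_tibble(atoms)
  out$radius <- r - probe_radius
  out$asa <- asa
  attr(out, "probe_radius") <- probe_radius
  attr(out, "n_points") <- n_points
  out
}

#' Per-residue ASA from per-atom values
#'
#' @param atom_asa Result of [shrake_rupley()].
#' @return Tibble `chain`, `resno`, `resid`, `asa` (sum over the residue's
#'   atoms).
#' @export
residue_asa <- function(atom_asa) {
  check_columns(atom_asa, c("chain", "resno", "resid", "asa"), "atom_asa")
  atom_asa |>
    group_by(.data$chain, .data$resno, .data$resid) |>
    summarise(asa = sum(.data$asa), .groups = "drop")
}

#' Relative solvent accessibility against the isolated residue
#'
#' For every residue, the ASA computed in the full structure is divided by the
#' ASA of the same residue extracted alone in its observed conformation (its
#' area "in a vacuum") and expressed in percent. A residue is called fully
#' exposed when its relative ASA strictly exceeds 50%. The isolated-residue
#' reference convention is recorded in the result's attributes so that tables
#' produced under other normalizations can be substituted knowingly.
#'
#' @inheritParams shrake_rupley
#' @return Tibble `chain`, `resno`, `resid`, `asa`, `asa_ref`, `rel_asa`,
#'   `exposed`.
#' @export
relative_asa <- function(atoms, probe_radius = 1.4, n_points = 960,
                         radii = vdw_radii()) {
  check_columns(atoms, c("chain", "resno", "resid", "element", "x", "y", "z"),
                "atoms")
  full <- shrake_rupley(atoms, probe_radius, n_points, radii)
  per_res <- residue_asa(full)
  key <- paste(atoms$chain, atoms$resno, sep = "\r")
  ref <- map_dbl(paste(per_res$chain, per_res$resno, sep = "\r"), function(k) {
    iso <- shrake_rupley(atoms[key == k, , drop = FALSE],
                         probe_radius, n_points, radii)
    sum(iso$asa)
  })
  if (any(ref <= 0)) abort("zero reference ASA for at least one residue.")
  out <- mutate(per_res, asa_ref = ref,
                rel_asa = 100 * .data$asa / .data$asa_ref,
                exposed = .data$rel_asa > 50)
  attr(out, "probe_radius") <- probe_radius
  attr(out, "n_points") <- n_points
  attr(out, "reference") <- "isolated residue, observed conformation"
  out
}

#' Interatomic contacts within a distance cutoff
#'
#' Lists all unordered atom pairs from different residues whose distance does
#' not exceed `cutoff`, labelled by backbone membership (N, CA, C, O are
#' backbone) as backbone-backbone, backbone-side chain or side chain-side
#' chain.
#'
#' @param atoms Atom tibble with `chain`, `resno`, `resid`, `elety`, `x`,
#'   `y`, `z`.
#' @param cutoff Distance cutoff in Angstrom (default 4.0).
#' @return Tibble with one row per contact: both atoms' identifiers, the
#'   distance and the contact `type`.
#' @export
interatomic_contacts <- function(atoms, cutoff = 4.0) {
  check_columns(atoms, c("chain", "resno", "resid", "elety", "x", "y", "z"),
                "atoms")
  check_positive_finite(cutoff, "cutoff")
  n <- nrow(atoms)
  if (n < 2L) {
    return(tibble(i = integer(), j = integer(), chain_i = character(),
                  resno_i = integer(), resid_i = character(), elety_i = character(),
                  chain_j = character(), resno_j = integer(), resid_j = character(),
                  elety_j = character(), distance = numeric(), type = character()))
  }
  d <- as.matrix(stats::dist(cbind(atoms$x, atoms$y, atoms$z)))
  idx <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  same_res <- atoms$chain[idx[, 1]] == atoms$chain[idx[, 2]] &
    atoms$resno[idx[, 1]] == atoms$resno[idx[, 2]]
  idx <- idx[!same_res, , drop = FALSE]
  bb <- function(k) atoms$elety[k] %in% BACKBONE_ATOMS
  type <- dplyr::case_when(
    bb(idx[, 1]) & bb(idx[, 2]) ~ "backbone-backbone",
    !bb(idx[, 1]) & !bb(idx[, 2]) ~ "sidechain-sidechain",
    TRUE ~ "backbone-sidechain"
  )
  tibble(i = idx[, 1], j = idx[, 2],
         chain_i = atoms$chain[idx[, 1]], resno_i = atoms$resno[idx[, 1]],
         resid_i = atoms$resid[idx[, 1]], elety_i = atoms$elety[idx[, 1]],
         chain_j = atoms$chain[idx[, 2]], resno_j = atoms$resno[idx[, 2]],
         resid_j = atoms$resid[idx[, 2]], elety_j = atoms$elety[idx[, 2]],
         distance = d[idx], type = type) |>
    arrange(.data$i, .data$j)
}

#' Read a PDB coordinate file into an atom tibble
#'
#' Thin wrapper around `bio3d::read.pdb` that applies the package's
#' conventions: heavy atoms only by default, alternate location A retained,
#' HETATM records (including waters) excluded unless requested.
#'
#' @param path Path to a PDB file.
#' @param keep_hetatm Keep HETATM records (default FALSE).
#' @param keep_hydrogens Keep hydrogen atoms (default FALSE).
#' @param altloc Alternate-location indicator to retain alongside blank
#'   (default `"A"`).
#' @return Tibble `chain`, `resno`, `resid`, `elety`, `element`, `x`, `y`,
#'   `z`.
#' @export
read_structure <- function(path, keep_hetatm = FALSE, keep_hydrogens = FALSE,
                           altloc = "A") {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    abort("reading PDB files requires the bio3d package.")
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  if (!keep_hetatm) a <- a[a$type == "ATOM", , drop = FALSE]
  if (nrow(a) == 0L) abort("no ATOM records found.")
  a <- a[is.na(a$alt) | a$alt == "" | a$alt == altloc, , drop = FALSE]
  el <- a$elesy
  blank <- is.na(el) | el == ""
  if (any(blank)) el[blank] <- bio3d::atom2ele(a$elety[blank])
  if (!keep_hydrogens) {
    keep <- toupper(el) != "H"
    a <- a[keep, , drop = FALSE]
    el <- el[keep]
  }
  if (nrow(a) == 0L) abort("no atoms left after filtering.")
  tibble(chain = as.character(a$chain), resno = as.integer(a$resno),
         resid = as.character(a$resid), elety = as.character(a$elety),
         element = toupper(as.character(el)),
         x = a$x, y = a$y, z = a$z)
}
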