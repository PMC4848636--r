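# Detection of the six-cysteine Kunitz framework in an alignment and
# extraction of the two cysteine-flanking sequence windows.

N_SLOTS <- c("Xa-2", "Xa-1", "CysI", "Xa+1", "Xa+2", "Xa+3")
C_SLOTS <- c("CysV", "Xb+1", "Xb+2", "Xb+3", "CysVI")
ALL_SLOTS <- c(N_SLOTS, C_SLOTS)

# the five fully-exposed window positions used for class profiles when no
# per-structure accessibility table is supplied
DEFAULT_EXPOSED_SLOTS <- c("Xa-2", "Xa+1", "Xa+3", "Xb+1", "Xb+2")

#' Locate the six conserved cysteine columns of the Kunitz framework
#'
#' The Kunitz/BPTI fold is cross-linked by three disulfide bridges formed by
#' six framework cysteines, labelled Cys I-VI from the N-terminus. This
#' function finds the alignment columns whose cysteine conservation reaches
#' `threshold` and requires exactly six of them; individual records lacking a
#' Cys at a framework column are flagged, not fatal.
#'
#' @param aln A [kunitz_alignment()].
#' @param threshold Minimum fraction of records with Cys in a column for the
#'   column to qualify (default 0.9; must exceed 0.5).
#' @return A `cysteine_framework` with the six column indices (named I-VI),
#'   a per-record position table in ungapped and published numbering, and the
#'   ids of flagged (non-canonical) records.
#' @export
find_cysteine_framework <- function(aln, threshold = 0.9) {
  check_columns(aln, c("id", "aligned", "offset"), "aln")
  if (nrow(aln) < 1L) abort("the alignment has no records.")
  if (!is.numeric(threshold) || threshold <= 0.5 || threshold > 1) {
    abort("`threshold` must lie in (0.5, 1].")
  }
  m <- aln_matrix(aln)
  cons <- colMeans(m == "C")
  qual <- which(cons >= threshold)
  if (length(qual) != 6L) {
    abort(sprintf(
      "non-canonical cysteine framework: %d column(s) reach Cys conservation >= %.2f (columns %s); exactly 6 are required.",
      length(qual), threshold,
      if (length(qual)) paste(qual, collapse = ", ") else "none"))
  }
  labels <- c("I", "II", "III", "IV", "V", "VI")
  positions <- map_dfr(seq_len(nrow(aln)), function(r) {
    chars <- m[r, ]
    pos <- aln_pos_of_col(chars)
    tibble(id = aln$id[r], label = labels, column = qual,
           residue = chars[qual],
           pos = pos[qual],
           pos_published = pos[qual] + aln$offset[r],
           is_cys = chars[qual] == "C")
  })
  flagged <- unique(positions$id[!positions$is_cys])
  structure(list(columns = setNames(qual, labels),
                 conservation = setNames(unname(cons[qual]), labels),
                 positions = positions, flagged = flagged,
                 threshold = threshold),
            class = "cysteine_framework")
}

#' @export
print.cysteine_framework <- function(x, ...) {
  cat("<cysteine_framework> columns:",
      paste(sprintf("%s=%d", names(x$columns), x$columns), collapse = " "), "\n")
  if (length(x$flagged)) cat("flagged records:", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

#' Extract the N- and C-terminal cysteine-flanking windows
#'
#' For each record the two windows are taken in that record's own ungapped
#' coordinates, anchored on its framework cysteines: the N-window
#' `[Xa-2 Xa-1 CysI Xa+1 Xa+2 Xa+3]` around Cys I, and the C-window
#' `[CysV Xb+1 Xb+2 Xb+3 CysVI]` spanning Cys V to Cys VI. Anchoring on each
#' sequence rather than on alignment columns means an insertion between Cys V
#' and Cys VI surfaces as an explicit per-record `non_canonical_c` flag
#' instead of silently shifting residues.
#'
#' @param fw A [find_cysteine_framework()] result.
#' @param aln The same alignment.
#' @return A `motif_windows` tibble (one row per record and slot) with
#'   columns `id`, `window` ("N"/"C"), `slot`, `residue`, `pos`,
#'   `pos_published`, `gap_flag`; the per-record flag table is in
#'   `attr(, "flags")`.
#' @export
extract_windows <- function(fw, aln) {
  stopifnot(inherits(fw, "cysteine_framework"))
  check_columns(aln, c("id", "aligned", "offset"), "aln")
  m <- aln_matrix(aln)
  res <- map(seq_len(nrow(aln)), function(r) {
    rec <- aln$id[r]
    chars <- m[r, ]
    seq_chars <- chars[chars != "-"]
    len <- length(seq_chars)
    posrec <- filter(fw$positions, .data$id == rec)
    anchor_ok <- all(posrec$is_cys[posrec$label %in% c("I", "V", "VI")])
    cys1 <- posrec$pos[posrec$label == "I"]
    cys5 <- posrec$pos[posrec$label == "V"]
    cys6 <- posrec$pos[posrec$label == "VI"]
    non_canonical_c <- anchor_ok && (cys6 - cys5 != 4L)
    if (non_canonical_c) {
      warn(sprintf("record %s: non-canonical C-window (CysVI - CysV = %d, expected 4).",
                   rec, cys6 - cys5))
    }
    truncated <- anchor_ok && (cys1 <= 2L)
    n_pos <- if (anchor_ok) cys1 + (-2):3 else rep(NA_integer_, 6)
    c_pos <- if (anchor_ok && !non_canonical_c) cys5 + 0:4 else rep(NA_integer_, 5)
    grab <- function(p) ifelse(!is.na(p) & p >= 1 & p <= len, seq_chars[pmax(p, 1)], NA_character_)
    gap_in_window <- function(p) {
      p <- p[!is.na(p) & p >= 1 & p <= len]
      if (length(p) < 2L) return(FALSE)
      cols <- which(!is.na(aln_pos_of_col(chars)) & aln_pos_of_col(chars) %in% p)
      (max(cols) - min(cols) + 1L) > length(p)
    }
    rows <- tibble(
      id = rec,
      window = c(rep("N", 6), rep("C", 5)),
      slot = ALL_SLOTS,
      residue = c(grab(n_pos), grab(c_pos)),
      pos = c(n_pos, c_pos),
      pos_published = c(n_pos, c_pos) + aln$offset[r],
      gap_flag = c(rep(gap_in_window(n_pos), 6), rep(gap_in_window(c_pos), 5))
    )
    flags <- tibble(id = rec,
                    non_cys_anchor = !anchor_ok,
                    truncated = isTRUE(truncated),
                    non_canonical_c = isTRUE(non_canonical_c))
    list(rows = rows, flags = flags)
  })
  out <- bind_rows(map(res, "rows"))
  out$slot <- factor(out$slot, levels = ALL_SLOTS)
  attr(out, "flags") <- bind_rows(map(res, "flags"))
  class(out) <- c("motif_windows", class(out))
  out
}

#' Per-record flags of a window extraction
#'
#' @param mw A `motif_windows` object.
#' @return Tibble with logical columns `non_cys_anchor`, `truncated`,
#'   `non_canonical_c`.
#' @export
window_flags <- function(mw) {
  attr(mw, "flags")
}
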