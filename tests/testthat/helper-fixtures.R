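# Synthetic stand-in alignment for the dendrotoxin-family window checks.
#
# These are NOT the real toxin sequences: they are synthetic scaffolds that
# carry the published key residues at the published residue numbers (via
# per-record numbering offsets), which is all the window-extraction and
# compensation logic sees. Layout (alignment columns, width 60):
#   Cys I-VI at columns 7, 18, 30, 42, 53, 57 for every row.
#   "alpha"  (alpha-DTX-like, offset 0):  K5, I8, L9, H10; K54, R55.
#   "dtxk"   (DTX-K-like, offset 24, 4 leading gaps): K25 K26 C27 K28 A29 P30;
#            K46; C73 R74 R75 Y76 C77.
#   "hg1"    (Hg1-like, offset 24, 2 leading gaps): K77 at Xb+2.
#   "alpha_mut": alpha with the single class change K5 -> D5 (positive ->
#            negative at Xa-2), an uncompensated substitution.
dtx_fixture_alignment <- function() {
  width <- 60
  cys_cols <- c(7, 18, 30, 42, 53, 57)
  base_row <- function(filler) {
    chars <- rep(filler, width)
    chars[cys_cols] <- "C"
    chars
  }
  alpha <- base_row("A")
  alpha[5] <- "K"; alpha[6] <- "T"; alpha[8] <- "I"; alpha[9] <- "L"; alpha[10] <- "H"
  alpha[54] <- "K"; alpha[55] <- "R"; alpha[56] <- "G"

  dtxk <- base_row("G")
  dtxk[1:4] <- "-"
  dtxk[5] <- "K"; dtxk[6] <- "K"; dtxk[8] <- "K"; dtxk[9] <- "A"; dtxk[10] <- "P"
  dtxk[26] <- "K"                      # published K46, outside both windows
  dtxk[54] <- "R"; dtxk[55] <- "R"; dtxk[56] <- "Y"

  hg1 <- base_row("S")
  hg1[1:2] <- "-"
  hg1[5] <- "K"; hg1[8] <- "I"; hg1[10] <- "H"
  hg1[54] <- "K"; hg1[55] <- "K"; hg1[56] <- "N"   # K77 at Xb+2 (offset 24)

  alpha_mut <- alpha
  alpha_mut[5] <- "D"

  kunitz_alignment(
    id = c("alpha", "dtxk", "hg1", "alpha_mut"),
    aligned = vapply(list(alpha, dtxk, hg1, alpha_mut), paste,
                     character(1), collapse = ""),
    offset = c(0L, 24L, 24L, 0L)
  )
}

dtx_fixture_windows <- function() {
  aln <- dtx_fixture_alignment()
  fw <- find_cysteine_framework(aln)
  extract_windows(fw, aln)
}
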