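# Kunitz framework detection, window extraction, residue classes,
# exposure filtering, compensation and grouping.

test_that("framework detection finds exactly six conserved Cys columns", {
  aln <- dtx_fixture_alignment()
  fw <- find_cysteine_framework(aln)
  expect_identical(names(fw$columns), c("I", "II", "III", "IV", "V", "VI"))
  expect_identical(unname(fw$columns), c(7L, 18L, 30L, 42L, 53L, 57L))
  expect_length(fw$flagged, 0)
  # invariant to appended non-Cys columns and to record order
  aln2 <- kunitz_alignment(aln$id, paste0(aln$aligned, "AAAA"), aln$offset)
  expect_identical(unname(find_cysteine_framework(aln2)$columns),
                   unname(fw$columns))
  aln3 <- aln[rev(seq_len(nrow(aln))), ]
  expect_identical(unname(find_cysteine_framework(aln3)$columns),
                   unname(fw$columns))
})

test_that("framework detection flags records and applies the threshold", {
  aln <- dtx_fixture_alignment()
  # knock out one cysteine in one record: per-record flag, not global failure
  broken <- sub("C", "S", aln$aligned[1])
  aln_b <- kunitz_alignment(aln$id, c(broken, aln$aligned[-1]), aln$offset)
  fw <- find_cysteine_framework(aln_b, threshold = 0.7)
  expect_identical(fw$flagged, "alpha")
  # a 50%-conserved Cys column does not qualify at threshold 0.9
  extra <- ifelse(seq_len(nrow(aln)) <= 2, "C", "A")
  aln_c <- kunitz_alignment(aln$id, paste0(aln$aligned, extra), aln$offset)
  expect_identical(unname(find_cysteine_framework(aln_c, 0.9)$columns),
                   c(7L, 18L, 30L, 42L, 53L, 57L))
  # seven fully conserved Cys columns: non-canonical framework
  aln_d <- kunitz_alignment(aln$id, paste0(aln$aligned, "C"), aln$offset)
  expect_error(find_cysteine_framework(aln_d), "non-canonical cysteine framework")
})

test_that("windows carry the published key residues at the pattern slots", {
  mw <- dtx_fixture_windows()
  slot_of <- function(rec, s) {
    row <- mw[mw$id == rec & mw$slot == s, ]
    c(residue = row$residue, pos = row$pos_published)
  }
  expect_identical(slot_of("dtxk", "Xa-2"), c(residue = "K", pos = "25"))
  expect_identical(slot_of("dtxk", "Xa+1"), c(residue = "K", pos = "28"))
  expect_identical(slot_of("dtxk", "Xa+3"), c(residue = "P", pos = "30"))
  expect_identical(slot_of("dtxk", "Xb+1"), c(residue = "R", pos = "74"))
  expect_identical(slot_of("dtxk", "Xb+2"), c(residue = "R", pos = "75"))
  expect_identical(slot_of("alpha", "Xa-2"), c(residue = "K", pos = "5"))
  expect_identical(slot_of("alpha", "Xa+1"), c(residue = "I", pos = "8"))
  expect_true(all(mw$residue[mw$slot %in% c("CysI", "CysV", "CysVI")] == "C"))
  expect_false(any(window_flags(mw)$non_canonical_c))
})

test_that("a C-window insertion is a per-record error, not a silent shift", {
  aln <- dtx_fixture_alignment()
  # insert one residue between CysV and CysVI of the first record only
  rows <- aln$aligned
  rows[1] <- paste0(substr(rows[1], 1, 54), "W", substr(rows[1], 55, 60))
  rows[-1] <- paste0(substr(rows[-1], 1, 54), "-", substr(rows[-1], 55, 60))
  aln_i <- kunitz_alignment(aln$id, rows, aln$offset)
  fw <- find_cysteine_framework(aln_i)
  expect_warning(mw <- extract_windows(fw, aln_i), "non-canonical C-window")
  fl <- window_flags(mw)
  expect_true(fl$non_canonical_c[fl$id == "alpha"])
  expect_false(any(fl$non_canonical_c[fl$id != "alpha"]))
})

test_that("residue classes partition the 20-letter alphabet 2/3/6/9", {
  aa <- names(toxkit::RESIDUE_CLASSES)
  expect_length(aa, 20)
  cls <- classify_residue(aa)
  expect_identical(as.integer(table(cls)[c("negative", "positive", "polar_uncharged", "hydrophobic")]),
                   c(2L, 3L, 6L, 9L))
  expect_identical(classify_residue(c("H", "P", "E")),
                   c("positive", "hydrophobic", "negative"))
  expect_identical(classify_residue("X"), "unclassifiable")
})

test_that("exposure filtering applies the strict >50% rule and the default set", {
  mw <- dtx_fixture_windows()
  no_table <- exposure_filter(mw)
  exp_slots <- no_table$slot[no_table$exposed & no_table$id == "alpha"]
  expect_setequal(as.character(exp_slots), c("Xa-2", "Xa+1", "Xa+3", "Xb+1", "Xb+2"))
  expect_true(all(no_table$provenance == "default_exposed_set"))
  asa <- data.frame(id = "alpha", pos_published = c(5, 6),
                    rel_asa = c(60, 30))
  with_table <- exposure_filter(mw, asa)
  a5 <- with_table[with_table$id == "alpha" & with_table$pos_published == 5, ]
  a6 <- with_table[with_table$id == "alpha" & with_table$pos_published == 6, ]
  expect_true(a5$exposed)
  expect_false(a6$exposed)
  expect_identical(unique(with_table$provenance[is.na(with_table$rel_asa)]),
                   "exposure_unknown")
  # boundary: exactly 50% is buried
  asa50 <- data.frame(id = "alpha", pos_published = 5, rel_asa = 50)
  t50 <- exposure_filter(mw, asa50)
  expect_false(t50$exposed[t50$id == "alpha" & t50$pos_published == 5])
})

test_that("compensation verdicts: identical, swap-compensated, non-compensated", {
  mw <- dtx_fixture_windows()
  pr <- class_profiles(mw)
  comp <- detect_compensation(pr, "alpha", "dtxk")
  expect_identical(comp$verdict, "compensated")
  expect_identical(unname(comp$verdict_by_window["N"]), "compensated")
  expect_identical(unname(comp$verdict_by_window["C"]), "identical")
  expect_true(nrow(comp$compensated_pairs) == 1)
  expect_setequal(unlist(comp$compensated_pairs[1, c("slot_1", "slot_2")]),
                  c("Xa+1", "Xa+3"))
  ident <- detect_compensation(pr, "alpha", "hg1")
  expect_identical(ident$verdict, "identical")
  non <- detect_compensation(pr, "alpha", "alpha_mut")
  expect_identical(non$verdict, "non_compensated")
  # symmetry
  expect_identical(detect_compensation(pr, "dtxk", "alpha")$verdict, "compensated")
})

test_that("grouping modes partition as expected and strict refines compensated", {
  mw <- dtx_fixture_windows()
  pr <- class_profiles(mw)
  comp <- group_specificities(pr, mode = "compensated")
  strict <- group_specificities(pr, mode = "strict")
  gc <- comp$groups
  gs <- strict$groups
  # alpha, dtxk, hg1 together in compensated mode; the mutant alone
  expect_equal(gc$group[gc$id == "alpha"], gc$group[gc$id == "dtxk"])
  expect_equal(gc$group[gc$id == "alpha"], gc$group[gc$id == "hg1"])
  expect_false(gc$group[gc$id == "alpha_mut"] == gc$group[gc$id == "alpha"])
  # strict splits alpha/hg1 (identical classes) from dtxk (swapped)
  expect_equal(gs$group[gs$id == "alpha"], gs$group[gs$id == "hg1"])
  expect_false(gs$group[gs$id == "alpha"] == gs$group[gs$id == "dtxk"])
  # refinement: ids sharing a strict group always share a compensated group
  merged <- merge(gs, gc, by = "id", suffixes = c("_s", "_c"))
  for (g in unique(merged$group_s)) {
    expect_length(unique(merged$group_c[merged$group_s == g]), 1)
  }
})

test_that("non-transitive compensation chains are merged with a warning", {
  # A<->B swaps slots 1-2, B<->C swaps slots 2-3; A<->C then carries a
  # 3-cycle of class changes with no reciprocal pairs, which is not a swap
  # decomposition
  prof <- tibble::tibble(
    id = rep(c("A", "B", "C"), each = 3),
    window = "N",
    slot = rep(c("Xa-2", "Xa+1", "Xa+3"), 3),
    residue = "A",
    class = c("positive", "negative", "hydrophobic",
              "negative", "positive", "hydrophobic",
              "negative", "hydrophobic", "positive")
  )
  class(prof) <- c("class_profile", class(prof))
  expect_identical(detect_compensation(prof, "A", "B")$verdict, "compensated")
  expect_identical(detect_compensation(prof, "B", "C")$verdict, "compensated")
  expect_identical(detect_compensation(prof, "A", "C")$verdict, "non_compensated")
  expect_warning(g <- group_specificities(prof, mode = "compensated"),
                 "not transitive")
  expect_length(unique(g$groups$group), 1)
  expect_true(g$nontransitive)
})

test_that("key residues are located relative to the windows", {
  aln <- dtx_fixture_alignment()
  mw <- dtx_fixture_windows()
  ann <- data.frame(id = c("dtxk", "hg1", "dtxk", "dtxk"),
                    pos_published = c(28, 77, 46, 500),
                    note = c("K28", "K77", "K46", "bogus"))
  out <- map_key_residues(mw, ann, aln)
  expect_identical(out$location, c("N_window", "C_window", "outside", "out_of_range"))
  expect_identical(out$slot[1:2], c("Xa+1", "Xb+2"))
})
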