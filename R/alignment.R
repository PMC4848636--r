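# Alignment container for Kunitz-domain toxins. Rows are gapped sequences of
# equal width; each record carries a numbering offset mapping its ungapped
# positions onto the published (UniProt-style) residue numbers.

#' Construct a Kunitz alignment
#'
#' @param id Character vector of unique record labels.
#' @param aligned Equal-length gapped sequences (gaps `-`; `.` is accepted and
#'   converted).
#' @param offset Integer numbering offset per record: published residue number
#'   = ungapped position + offset. Defaults to 0 (published numbering starts
#'   at 1 at the first residue).
#' @param uniprot Optional accession per record.
#' @return A `kunitz_alignment` tibble with columns `id`, `aligned`,
#'   `offset`, `uniprot`.
#' @examples
#' kunitz_alignment(c("a", "b"), c("KKCKAP", "RKC-AP"))
#' @export
kunitz_alignment <- function(id, aligned, offset = 0L, uniprot = NA_character_) {
  id <- as.character(id)
  aligned <- toupper(gsub(".", "-", as.character(aligned), fixed = TRUE))
  if (length(id) != length(aligned)) abort("`id` and `aligned` must have equal length.")
  if (anyDuplicated(id)) abort("duplicate record ids are not allowed.")
  w <- nchar(aligned)
  if (length(unique(w)) > 1L) {
    abort(paste0("ragged alignment: row widths ",
                 paste(sprintf("%s=%d", id, w), collapse = ", "), "."))
  }
  bad <- grepl("[^A-Z*-]", aligned)
  if (any(bad)) abort(sprintf("invalid characters in record(s): %s.",
                              paste(id[bad], collapse = ", ")))
  out <- tibble(id = id, aligned = aligned,
                offset = as.integer(rep_len(offset, length(id))),
                uniprot = as.character(rep_len(uniprot, length(id))))
  class(out) <- c("kunitz_alignment", class(out))
  out
}

# character matrix view, rows = records
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$aligned, "", fixed = TRUE))
  rownames(m) <- aln$id
  m
}

# ungapped position of each column for one gapped row (NA at gap columns)
aln_pos_of_col <- function(row_chars) {
  p <- cumsum(row_chars != "-")
  p[row_chars == "-"] <- NA_integer_
  p
}

#' Read a multiple sequence alignment (aligned FASTA or Clustal)
#'
#' The dialect is auto-detected from the first non-empty line (`>` for FASTA,
#' a `CLUSTAL` header otherwise). Clustal conservation lines are ignored.
#' Parsing is delegated to Biostrings.
#'
#' @param path Path to the alignment file.
#' @param format `"auto"`, `"fasta"` or `"clustal"`.
#' @param offset Numbering offset(s) applied to the records (recycled).
#' @return A [kunitz_alignment()] tibble.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "clustal"), offset = 0L) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("reading alignments requires the Biostrings package.")
  }
  if (format == "auto") {
    first <- head(grep(".", readLines(path, warn = FALSE), value = TRUE), 1)
    format <- if (length(first) && startsWith(first, ">")) "fasta" else "clustal"
  }
  if (format == "fasta") {
    seqs <- Biostrings::readBStringSet(path, format = "fasta")
    ids <- sub("\\s.*$", "", names(seqs))
    aligned <- as.character(seqs)
    w <- nchar(aligned)
    if (length(unique(w)) > 1L) {
      abort(paste0("ragged alignment: row widths ",
                   paste(sprintf("%s=%d", ids, w), collapse = ", "), "."))
    }
    kunitz_alignment(ids, aligned, offset = offset)
  } else {
    msa <- Biostrings::readAAMultipleAlignment(path, format = "clustal")
    rows <- as.character(msa)
    kunitz_alignment(names(rows), unname(rows), offset = offset)
  }
}

#' Write an alignment as aligned FASTA
#'
#' @param aln A [kunitz_alignment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  check_columns(aln, c("id", "aligned"), "aln")
  writeLines(paste0(">", aln$id, "\n", aln$aligned), path)
  invisible(path)
}
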