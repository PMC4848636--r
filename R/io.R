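# Delimited-text readers for the exchanged assay formats and report writers.
# Canonical internal units: molar for concentrations, mV for potentials,
# percent for block, fractional (0-1) for vi/v0.

ASSAY_SCHEMAS <- list(
  inhibition = list(required = c(inhibitor_conc_M = "conc",
                                 fractional_activity = "activity"),
                    optional = c(replicate = "replicate"),
                    molar = "conc"),
  titration = list(required = c(inhibitor_conc_M = "conc",
                                fractional_activity = "activity"),
                   optional = c(replicate = "replicate"),
                   molar = "conc"),
  dose_response = list(required = c(conc_M = "conc", percent_block = "block"),
                       optional = c(replicate = "replicate"),
                       molar = "conc"),
  iv = list(required = c(V_mV = "v", I_control_uA = "i_control",
                         I_toxin_uA = "i_toxin"),
            optional = c(toxin_conc_M = "toxin_conc", replicate = "replicate"),
            molar = "toxin_conc")
)

#' Read an assay table (CSV or TSV)
#'
#' Reads one of the documented delimited-text schemas and returns a tibble
#' with canonical column names and units. Concentration columns accept either
#' bare molar numbers or strings with SI suffixes (`"1 nM"`); the delimiter
#' is sniffed from the header line.
#'
#' Schemas (by `schema`): `inhibition` and `titration` require
#' `inhibitor_conc_M`, `fractional_activity`; `dose_response` requires
#' `conc_M`, `percent_block`; `iv` requires `V_mV`, `I_control_uA`,
#' `I_toxin_uA`. A `replicate` column is optional everywhere.
#'
#' @param path File path.
#' @param schema One of `"inhibition"`, `"titration"`, `"dose_response"`,
#'   `"iv"`.
#' @return Tibble with canonical names (`conc`/`activity`, `conc`/`block`, or
#'   `v`/`i_control`/`i_toxin`).
#' @export
read_assay_table <- function(path, schema = names(ASSAY_SCHEMAS)) {
  schema <- match.arg(schema)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  sc <- ASSAY_SCHEMAS[[schema]]
  header <- readLines(path, n = 1L, warn = FALSE)
  delim <- if (grepl("\t", header)) "\t" else ","
  d <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         progress = FALSE)
  known <- c(names(sc$required), names(sc$optional))
  extra <- setdiff(names(d), known)
  if (length(extra)) {
    abort(sprintf("unknown column(s) %s for schema %s; expected: %s.",
                  paste0("`", extra, "`", collapse = ", "), dQuote(schema),
                  paste(known, collapse = ", ")))
  }
  missing <- setdiff(names(sc$required), names(d))
  if (length(missing)) {
    abort(sprintf("schema %s requires column(s): %s.", dQuote(schema),
                  paste0("`", missing, "`", collapse = ", ")))
  }
  ren <- c(sc$required, sc$optional)
  names(d) <- unname(ren[names(d)])
  if (!is.na(sc$molar) && sc$molar %in% names(d)) {
    d[[sc$molar]] <- parse_molar(d[[sc$molar]])
    if (any(d[[sc$molar]] < 0)) abort("negative concentrations are not allowed.")
  }
  d
}

#' Write an assay table (CSV or TSV)
#'
#' Inverse of [read_assay_table()]: writes canonical columns back under the
#' documented schema headers so a write-read round trip is lossless.
#'
#' @param data Tibble with canonical column names.
#' @param path Output path; a `.tsv` extension selects tab delimiting.
#' @param schema Schema name, see [read_assay_table()].
#' @return `path`, invisibly.
#' @export
write_assay_table <- function(data, path, schema = names(ASSAY_SCHEMAS)) {
  schema <- match.arg(schema)
  sc <- ASSAY_SCHEMAS[[schema]]
  ren <- c(sc$required, sc$optional)
  inv <- setNames(names(ren), unname(ren))
  out <- data[, intersect(unname(ren), names(data)), drop = FALSE]
  names(out) <- unname(inv[names(out)])
  if (grepl("\\.tsv$", path)) readr::write_tsv(out, path) else readr::write_csv(out, path)
  invisible(path)
}

report_payload <- function(x) {
  if (inherits(x, "toxkit_fit")) return(as.list(glance(x)))
  if (inherits(x, "specificity_grouping")) {
    return(list(mode = x$mode, nontransitive = x$nontransitive,
                groups = split(x$groups$id, x$groups$group)))
  }
  if (inherits(x, "compensation_report")) {
    return(list(pair = as.list(x$pair), verdict = x$verdict,
                verdict_by_window = as.list(x$verdict_by_window),
                substitutions = x$substitutions,
                compensated_pairs = x$compensated_pairs))
  }
  if (inherits(x, "reversibility_assessment")) {
    return(list(verdict = x$verdict, substrate = x$substrate,
                preincubation = x$preincubation))
  }
  if (inherits(x, "vdep_assessment")) {
    return(list(verdict = x$verdict, spread = x$spread, p_trend = x$p_trend,
                table = x$table))
  }
  if (is.data.frame(x)) return(x)
  x
}

#' Write an analysis result as JSON or TSV
#'
#' Fitted objects are flattened via their [glance()] summaries; verdict
#' objects carry their tables. Numeric values are written at 6 significant
#' digits with stable field ordering, so re-running an analysis on identical
#' inputs reproduces the report byte for byte.
#'
#' @param x A toxkit result object or data frame.
#' @param path Output path.
#' @param format `"json"` or `"tsv"` (TSV requires a tabular result).
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  payload <- report_payload(x)
  if (format == "json") {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(6),
                         pretty = TRUE, na = "null", dataframe = "rows")
  } else {
    if (!is.data.frame(payload)) {
      payload <- as_tibble(payload[vapply(payload, function(v)
        is.atomic(v) && length(v) == 1L, logical(1))])
    }
    num <- vapply(payload, is.numeric, logical(1))
    payload[num] <- lapply(payload[num], signif, digits = 6)
    readr::write_tsv(payload, path)
  }
  invisible(path)
}
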