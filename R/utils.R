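# Internal helpers shared across modules.

# Evaluate `code` with a temporary RNG state seeded at `seed`, restoring the
# caller's stream afterwards. All generators funnel through this so identical
# (parameters, seed) always yield identical data.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number.")
  }
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv) else if (exists(".Random.seed", envir = genv, inherits = FALSE)) rm(".Random.seed", envir = genv)
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# First x where the piecewise-linear interpolant of (x, y) crosses `level`.
# Returns NA_real_ when no crossing exists.
interp_crossing <- function(x, y, level) {
  ord <- order(x)
  x <- x[ord]
  y <- y[ord]
  s <- y - level
  hit <- which(s == 0)
  if (length(hit)) return(x[hit[1L]])
  k <- which(s[-length(s)] * s[-1L] < 0)
  if (!length(k)) return(NA_real_)
  k <- k[1L]
  x[k] + (level - y[k]) * (x[k + 1L] - x[k]) / (y[k + 1L] - y[k])
}

check_columns <- function(data, cols, what = "data") {
  if (!is.data.frame(data)) abort(sprintf("`%s` must be a data frame.", what))
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    abort(sprintf("`%s` is missing required column(s): %s.", what,
                  paste0("`", missing, "`", collapse = ", ")))
  }
  invisible(data)
}

check_positive_finite <- function(x, name, allow_zero = FALSE) {
  if (!is.numeric(x) || anyNA(x) || !all(is.finite(x))) {
    abort(sprintf("`%s` must be finite and numeric.", name))
  }
  bad <- if (allow_zero) any(x < 0) else any(x <= 0)
  if (bad) {
    abort(sprintf("`%s` must be %s.", name,
                  if (allow_zero) "non-negative" else "strictly positive"))
  }
  invisible(x)
}

#' Parse concentrations with SI suffixes into molar
#'
#' Accepts bare numbers (already molar) or strings such as `"1 nM"`,
#' `"0.5 uM"`, `"2mM"`. The canonical internal unit everywhere in toxkit is
#' molar (M).
#'
#' @param x Numeric vector, or character vector of number-unit strings.
#' @return Numeric vector of molar concentrations.
#' @examples
#' parse_molar(c("1 nM", "0.5 uM", "2e-9"))
#' @export
parse_molar <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  if (!is.character(x)) abort("`x` must be numeric or character.")
  mult <- c(M = 1, mM = 1e-3, uM = 1e-6, "µM" = 1e-6, nM = 1e-9, pM = 1e-12)
  m <- regmatches(x, regexec("^\\s*([-+0-9.eE]+)\\s*([munµp]?M)?\\s*$", x))
  vapply(seq_along(x), function(i) {
    g <- m[[i]]
    if (length(g) == 0L) {
      abort(sprintf("cannot parse concentration %s.", dQuote(x[i])))
    }
    val <- suppressWarnings(as.numeric(g[2]))
    if (is.na(val)) abort(sprintf("cannot parse concentration %s.", dQuote(x[i])))
    unit <- g[3]
    if (!is.na(unit) && nzchar(unit)) val <- val * mult[[unit]]
    val
  }, numeric(1))
}

new_fit <- function(class, ...) {
  structure(list(...), class = c(class, "toxkit_fit"))
}

#' @export
print.toxkit_fit <- function(x, ...) {
  cat("<", class(x)[1], ">\n", sep = "")
  g <- glance(x)
  print(as.data.frame(g), row.names = FALSE)
  if (length(x$warnings)) cat("warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}
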