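#' Round half away from zero
#'
#' Rounding used for all reported counts and percentages. Unlike [round()],
#' which rounds half to even, ties are rounded away from zero so that e.g.
#' `round_half_up(0.5) == 1` and `round_half_up(-0.5) == -1`.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector of the same length as `x`.
#' @export
#' @examples
#' round_half_up(c(2.5, 3.5, -2.5))
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Format a proportion as a percentage label
#'
#' Percentages are printed to the nearest integer, except values strictly
#' below 1 percent (and above 0), which are shown with one decimal so that
#' small module fractions remain visible (e.g. "0.4\%" rather than "0\%").
#'
#' @param pct numeric vector of percentages (on the 0--100 scale).
#' @return character vector of labels such as "28\%" or "0.4\%".
#' @export
format_percent <- function(pct) {
  out <- character(length(pct))
  for (i in seq_along(pct)) {
    p <- pct[[i]]
    if (is.na(p)) {
      out[[i]] <- NA_character_
    } else if (p > 0 && p < 1) {
      out[[i]] <- sprintf("%.1f%%", round_half_up(p, 1))
    } else {
      out[[i]] <- sprintf("%d%%", as.integer(round_half_up(p)))
    }
  }
  out
}

#' Format a score delta as a signed two-decimal label
#'
#' @param delta numeric vector of score differences.
#' @return character labels such as "+0.04" or "-0.01".
#' @export
format_delta <- function(delta) {
  ifelse(is.na(delta), NA_character_,
         sprintf("%+.2f", round_half_up(delta, 2)))
}

# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
# All synthetic-data generators route randomness through this so that they
# are pure functions of (config, seed).
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Internal: stable composite key for a set of (source, target) pairs.
pair_key <- function(source_iri, target_iri) {
  paste(source_iri, target_iri, sep = "\r")
}

# Internal: split pipe-separated TSV cells into character vectors.
split_pipe <- function(x) {
  out <- strsplit(as.character(x), "|", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

collapse_pipe <- function(x) {
  vapply(x, function(v) paste(v, collapse = "|"), character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
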