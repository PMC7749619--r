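# shared internal helpers

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Normalize gene symbols to a canonical matching key
#'
#' Symbol matching throughout the package is done on a case-folded key so
#' that e.g. mouse title-case (`"Lrrk2"`) and human upper-case (`"LRRK2"`)
#' symbols refer to the same gene. Original case is preserved everywhere in
#' output; the key is only used for joins, set operations and lookups.
#'
#' @param symbols Character vector of gene symbols.
#' @return Character vector of canonical keys, same length as `symbols`.
#'   Normalization is idempotent: `gene_key(gene_key(x)) == gene_key(x)`.
#' @examples
#' gene_key(c("Lrrk2", "LRRK2"))
#' @export
gene_key <- function(symbols) {
  s <- trimws(as.character(symbols))
  bad <- is.na(s) | !nzchar(s) | grepl("\\s", s)
  if (any(bad)) {
    abort(paste0(
      "invalid gene symbol(s): ",
      paste(utils::head(unique(symbols[bad]), 5L), collapse = ", ")
    ))
  }
  toupper(s)
}

#' Parse numbers written with either decimal mark and typographic minus
#'
#' Published supplementary tables frequently print scientific notation with a
#' decimal comma and a Unicode minus sign (e.g. `"2,29E−04"`). This parser
#' accepts both `"."` and `","` decimal marks and maps U+2212 (minus),
#' U+2010 (hyphen) and U+2013 (en dash) to ASCII `-` before conversion.
#'
#' @param x Character vector of numeric cells.
#' @param dialect `"auto"` (default) converts a comma to a decimal point only
#'   when no period is present; `"comma"` always treats the first comma as the
#'   decimal mark; `"point"` leaves commas alone.
#' @return Numeric vector; unparseable cells become `NA` without warning so
#'   callers can report row positions.
#' @export
parse_flex_number <- function(x, dialect = c("auto", "comma", "point")) {
  dialect <- match.arg(dialect)
  s <- trimws(as.character(x))
  s <- gsub("−|‐|–", "-", s)
  to_dot <- switch(dialect,
    auto  = grepl(",", s, fixed = TRUE) & !grepl(".", s, fixed = TRUE),
    comma = grepl(",", s, fixed = TRUE),
    point = rep(FALSE, length(s))
  )
  s[to_dot] <- sub(",", ".", s[to_dot], fixed = TRUE)
  suppressWarnings(as.numeric(s))
}

# Deterministic per-stage seed derivation: a single master seed plus a stage
# label yields an independent, reproducible sub-seed (< 2^31).
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  cp <- utf8ToInt(stage)
  h <- sum(cp * seq_along(cp))
  as.integer((abs(as.numeric(seed)) + h * 10007) %% (.Machine$integer.max - 1L)) + 1L
}

# strict scalar checks used by several entry points
check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(paste0("`", name, "` must be a single probability in [0, 1]"))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(paste0("`", name, "` must be a single integer >= ", min))
  }
  invisible(as.integer(x))
}
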