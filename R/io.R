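# Readers and writers for the plain-text formats the workflow consumes:
# DEG tables (TSV/CSV), GMT gene sets, interaction edge lists (TSV/SIF),
# TF-target edge tables, plus the bundled prioritized-gene example tables.

.col_alias <- list(
  gene = c("gene", "genes", "symbol", "gene_symbol", "gene symbol", "genesymbol", "gene_name"),
  fold_change = c("fold_change", "foldchange", "fold change", "fc", "log_fc", "ratio"),
  p_value = c("p_value", "pvalue", "p.value", "p value", "p", "pval")
)

.match_col <- function(nms, what) {
  hit <- which(tolower(trimws(nms)) %in% .col_alias[[what]])
  if (length(hit) == 0L) {
    abort(paste0("DEG table format error: no column matching `", what, "` ",
                 "(have: ", paste(nms, collapse = ", "), ")"))
  }
  hit[1L]
}

.read_delim_chr <- function(path) {
  first <- readLines(path, n = 10L, encoding = "UTF-8")
  first <- first[!startsWith(first, "#")]
  header <- if (length(first)) first[[1L]] else ""
  delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    comment = "#", progress = FALSE, show_col_types = FALSE,
    locale = readr::locale(encoding = "UTF-8")
  )
}

#' Read a differential-expression (DEG) table
#'
#' Expects a delimited text file with a header naming gene, fold-change and
#' p-value columns (synonyms such as `symbol`, `FC`, `pval` are recognized).
#' Numeric cells may use either decimal mark and a typographic minus, as
#' printed in many supplementary tables (see [parse_flex_number()]).
#'
#' Rows whose fold change or p-value cannot be parsed, whose fold change is
#' zero, or whose p-value falls outside \[0, 1\] are rejected with a warning
#' reporting their row indices. Duplicate gene symbols (on the case-folded
#' key) are an error.
#'
#' @param path Path to a TSV or CSV file.
#' @param dialect Numeric dialect passed to [parse_flex_number()].
#' @return A tibble with columns `gene`, `fold_change`, `p_value`.
#' @export
read_deg_table <- function(path, dialect = c("auto", "comma", "point")) {
  dialect <- match.arg(dialect)
  df <- .read_delim_chr(path)
  gi <- .match_col(names(df), "gene")
  fi <- .match_col(names(df), "fold_change")
  pi <- .match_col(names(df), "p_value")

  out <- tibble::tibble(
    gene = trimws(df[[gi]]),
    fold_change = parse_flex_number(df[[fi]], dialect),
    p_value = parse_flex_number(df[[pi]], dialect)
  )
  bad <- is.na(out$fold_change) | is.na(out$p_value) | out$fold_change == 0 |
    out$p_value < 0 | out$p_value > 1 | is.na(out$gene) | !nzchar(out$gene)
  if (any(bad)) {
    warn(paste0("rejecting ", sum(bad), " DEG row(s) with invalid values at row(s): ",
                paste(which(bad), collapse = ", ")))
    out <- out[!bad, , drop = FALSE]
  }
  key <- gene_key(out$gene)
  if (anyDuplicated(key)) {
    dups <- unique(out$gene[duplicated(key)])
    abort(paste0("duplicate gene symbol(s) in DEG table: ", paste(dups, collapse = ", ")))
  }
  out
}

#' Write a DEG table as TSV
#'
#' @param deg Tibble with columns `gene`, `fold_change`, `p_value`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_deg_table <- function(deg, path) {
  readr::write_tsv(deg[, c("gene", "fold_change", "p_value")], path, progress = FALSE)
  invisible(path)
}

#' Read one annotation category from a GMT file
#'
#' Standard GMT: one term per line, `term-id TAB description TAB gene...`.
#' Genes are deduplicated within a line on the case-folded key; lines sharing
#' a term id are unioned with a warning; terms left with no genes are dropped
#' with a warning.
#'
#' @param path Path to a GMT file.
#' @param category Category name to assign to every term (defaults to the
#'   file name without extension).
#' @return An [annotation_corpus()] fragment (single category).
#' @export
read_gmt <- function(path, category = NULL) {
  category <- category %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 2L
  if (any(short)) {
    abort(paste0("GMT format error: fewer than 2 fields at line(s) ",
                 paste(which(short), collapse = ", ")))
  }
  df <- tibble::tibble(
    category = category,
    term = purrr::map_chr(fields, 1L),
    label = purrr::map_chr(fields, 2L),
    genes = purrr::map(fields, function(f) {
      g <- trimws(f[-(1:2)])
      g[nzchar(g)]
    })
  )
  if (anyDuplicated(df$term)) {
    warn(paste0("GMT: duplicated term id(s) unioned: ",
                paste(unique(df$term[duplicated(df$term)]), collapse = ", ")))
  }
  annotation_corpus(df)
}

#' Write one annotation category to a GMT file
#'
#' @param corpus An [annotation_corpus()]; must contain a single category.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(corpus, path) {
  if (length(unique(corpus$category)) > 1L) {
    abort("write_gmt() writes one category per file; filter the corpus first")
  }
  lines <- purrr::pmap_chr(
    list(corpus$term, corpus$label, corpus$genes),
    function(term, label, genes) paste(c(term, label, genes), collapse = "\t")
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read an undirected interaction edge list
#'
#' Accepts 2-column TSV (`from TAB to`), 3-column TSV (middle column
#' ignored), or SIF (`from relation to`, whitespace-delimited).
#'
#' @param path Path to the edge file.
#' @return Tibble with columns `from`, `to` (self-loops removed).
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "[\t ]+")
  n <- lengths(fields)
  if (any(n < 2L)) {
    abort(paste0("edge list: fewer than 2 fields at line(s) ",
                 paste(which(n < 2L), collapse = ", ")))
  }
  from <- purrr::map_chr(fields, 1L)
  to <- purrr::map_chr(fields, ~ .x[[length(.x)]])
  if (tolower(from[1]) %in% c("from", "source") ) {
    from <- from[-1]; to <- to[-1]
  }
  out <- tibble::tibble(from = from, to = to)
  out[gene_key(out$from) != gene_key(out$to), , drop = FALSE]
}

#' Read a TF-to-target edge table
#'
#' Expects TSV columns `tf`, `target`, `peak_intensity`,
#' `regulatory_potential` (ChIP peak signal and a regulatory-potential score
#' as produced by target-prediction tools).
#'
#' @param path Path to the TSV file.
#' @return Tibble with the four columns, numerics parsed flexibly.
#' @export
read_tf_edges <- function(path) {
  df <- .read_delim_chr(path)
  need <- c("tf", "target", "peak_intensity", "regulatory_potential")
  miss <- setdiff(need, tolower(names(df)))
  if (length(miss)) abort(paste0("TF edge table: missing column(s) ", paste(miss, collapse = ", ")))
  names(df) <- tolower(names(df))
  tibble::tibble(
    tf = trimws(df$tf),
    target = trimws(df$target),
    peak_intensity = parse_flex_number(df$peak_intensity),
    regulatory_potential = parse_flex_number(df$regulatory_potential)
  )
}

#' Bundled prioritized-gene tables for prefrontal cortex and striatum
#'
#' Loads the two example tables shipped with the package: prioritized genes
#' in mouse prefrontal cortex (44 genes) and striatum (26 genes) from a
#' chronic ethanol-intake transcriptome study, with the p-values as printed
#' (comma-decimal scientific notation, parsed on load). The `shared` flag
#' marks genes annotated in the source tables as prioritized in both tissues
#' by direct trained-list overlap.
#'
#' @return Named list of two tibbles (`pfc`, `striatum`) with columns
#'   `tissue`, `gene`, `gene_id`, `description`, `p_value`, `shared`.
#' @export
load_prioritized_tables <- function() {
  read_one <- function(file, tissue) {
    path <- system.file("extdata", file, package = "gbanet", mustWork = TRUE)
    df <- .read_delim_chr(path)
    out <- tibble::tibble(
      tissue = tissue,
      gene = df$gene,
      gene_id = as.integer(df$gene_id),
      description = df$description,
      p_value = parse_flex_number(df$p_value),
      shared = as.logical(df$shared)
    )
    if (anyDuplicated(gene_key(out$gene))) abort("fixture table has duplicate genes")
    if (any(out$p_value <= 0)) abort("fixture p-values must be strictly positive")
    out
  }
  list(
    pfc = read_one("prioritized_pfc.tsv", "pfc"),
    striatum = read_one("prioritized_striatum.tsv", "striatum")
  )
}

#' Keep records passing a significance cutoff
#'
#' The final selection step applied to prioritized-gene tables: retain rows
#' with `p_value <= p_cutoff` (default 1e-3, the cutoff implied by an FDR-5%
#' selection on these lists).
#'
#' @param records Tibble with a `p_value` column.
#' @param p_cutoff Inclusive upper bound on `p_value`.
#' @return Filtered tibble.
#' @export
filter_significant <- function(records, p_cutoff = 1e-3) {
  check_prob(p_cutoff, "p_cutoff")
  records[records$p_value <= p_cutoff, , drop = FALSE]
}
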