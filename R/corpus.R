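#' Build an annotation corpus
#'
#' The annotation corpus is the shared substrate of seed selection,
#' annotation-similarity prioritization and over-representation analysis: a
#' tidy table with one row per (category, term), where `genes` is a list
#' column of member gene symbols. Categories play the role of annotation
#' sources (GO biological process / molecular function / cellular component,
#' pathways, phenotypes, diseases, literature, coexpression).
#'
#' @param df A data frame with columns `category`, `term`, `label`, `genes`
#'   (list of character vectors). `label` may be missing; it defaults to the
#'   term id.
#' @return A tibble of class `annotation_corpus`. Gene sets are deduplicated
#'   on the case-folded symbol key; empty gene sets are dropped with a
#'   warning; duplicated (category, term) rows are unioned.
#' @seealso [read_gmt()] to load one category from a GMT file.
#' @export
annotation_corpus <- function(df) {
  df <- tibble::as_tibble(df)
  if (!all(c("category", "term", "genes") %in% names(df))) {
    abort("corpus needs columns `category`, `term`, `genes`")
  }
  if (!"label" %in% names(df)) df$label <- df$term
  df$label <- dplyr::coalesce(as.character(df$label), as.character(df$term))
  if (!is.list(df$genes)) df$genes <- as.list(df$genes)
  df$genes <- purrr::map(df$genes, function(g) {
    g <- as.character(g)
    g[!duplicated(gene_key(g))]
  })

  # union rows sharing (category, term)
  if (anyDuplicated(paste(df$category, df$term, sep = "\r"))) {
    df <- df |>
      dplyr::group_by(.data$category, .data$term) |>
      dplyr::summarise(
        label = dplyr::first(.data$label),
        genes = {
          g <- unlist(genes)
          list(g[!duplicated(gene_key(g))])
        },
        .groups = "drop"
      )
  }

  empty <- lengths(df$genes) == 0L
  if (any(empty)) {
    warn(paste0("dropping ", sum(empty), " term(s) with empty gene sets"))
    df <- df[!empty, , drop = FALSE]
  }
  df <- df[, c("category", "term", "label", "genes")]
  class(df) <- c("annotation_corpus", class(df))
  df
}

#' All genes annotated in a corpus (optionally one category)
#'
#' @param corpus An [annotation_corpus()].
#' @param category Optional category name to restrict to.
#' @return Character vector of unique gene symbols (original case, first
#'   occurrence wins).
#' @export
corpus_genes <- function(corpus, category = NULL) {
  if (!is.null(category)) {
    if (!category %in% corpus$category) abort(paste0("unknown category: ", category))
    corpus <- corpus[corpus$category == category, , drop = FALSE]
  }
  g <- unlist(corpus$genes, use.names = FALSE)
  g[!duplicated(gene_key(g))]
}

# Sparse gene x term membership matrix for one category; rows are keyed by
# the case-folded symbol. Used by the vectorized similarity kernels.
category_membership <- function(corpus, category) {
  if (!category %in% corpus$category) abort(paste0("unknown category: ", category))
  sub <- corpus[corpus$category == category, , drop = FALSE]
  terms <- sub$term
  keys <- purrr::map(sub$genes, gene_key)
  all_keys <- unique(unlist(keys, use.names = FALSE))
  i <- unlist(purrr::map(keys, ~ match(.x, all_keys)), use.names = FALSE)
  j <- rep.int(seq_along(terms), lengths(keys))
  Matrix::sparseMatrix(
    i = i, j = j, x = 1,
    dims = c(length(all_keys), length(terms)),
    dimnames = list(all_keys, terms)
  )
}
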