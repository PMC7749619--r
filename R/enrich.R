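# Over-representation analysis of prioritized gene lists with per-category
# Benjamini-Hochberg control, plus the signed up/down z-score summarizing
# the fold-change profile of a term's overlap genes.

#' Over-representation enrichment analysis
#'
#' Tests, per annotation term, whether the gene list overlaps the term more
#' than expected under hypergeometric sampling from the background
#' (upper-tail p for an overlap of at least `k`). Terms with zero overlap
#' are excluded before testing; q-values are Benjamini-Hochberg adjusted
#' within each category (mirroring per-category reporting conventions).
#' A term is `enriched` iff `p < alpha` and `q <= fdr`.
#'
#' Supplying `fold_changes` adds the up/down split of the overlap genes and
#' the signed z-score of [term_zscore()].
#'
#' @param genes Character vector: the gene list (must lie in the
#'   background).
#' @param corpus An [annotation_corpus()].
#' @param background Character vector of background genes; default: all
#'   genes annotated in the corpus category under test.
#' @param alpha Nominal p-value threshold (default 0.05).
#' @param fdr FDR threshold (default 0.05).
#' @param fold_changes Optional named numeric vector (names = gene symbols)
#'   of signed fold changes used for the z-score columns.
#' @param z_denominator `"sqrt"` (default; `(up - down)/sqrt(count)`) or
#'   `"count"` (`(up - down)/count`).
#' @param keep_all Return all tested terms (default) or only enriched ones.
#' @return Tibble of class `gba_enrichment`: `category`, `term`, `label`,
#'   `k` (overlap), `K` (list size in background), `n` (term size in
#'   background), `N` (background size), `p_value`, `q_value`, `enriched`,
#'   `up`, `down`, `count`, `z_score`, `genes` (overlap list column);
#'   ordered by category then p-value.
#' @export
ora <- function(genes, corpus, background = NULL, alpha = 0.05, fdr = 0.05,
                fold_changes = NULL, z_denominator = c("sqrt", "count"),
                keep_all = TRUE) {
  z_denominator <- match.arg(z_denominator)
  check_prob(alpha, "alpha")
  check_prob(fdr, "fdr")
  gkey <- unique(gene_key(genes))
  genes <- genes[!duplicated(gene_key(genes))]
  fc_key <- if (!is.null(fold_changes)) {
    stats::setNames(as.numeric(fold_changes), gene_key(names(fold_changes)))
  }

  res <- purrr::map_dfr(unique(corpus$category), function(cat_) {
    sub <- corpus[corpus$category == cat_, , drop = FALSE]
    bg <- if (is.null(background)) corpus_genes(sub) else background
    bkey <- unique(gene_key(bg))
    missing <- setdiff(gkey, bkey)
    if (length(missing)) {
      abort(paste0("gene(s) not in the ", cat_, " background: ",
                   paste(utils::head(genes[gene_key(genes) %in% missing], 5L),
                         collapse = ", ")))
    }
    N <- length(bkey)
    K <- length(gkey)
    rows <- purrr::pmap_dfr(
      list(sub$term, sub$label, sub$genes),
      function(term, label, tg) {
        tkey <- intersect(gene_key(tg), bkey)
        ov <- intersect(tkey, gkey)
        k <- length(ov)
        if (k == 0L) return(NULL)
        n_t <- length(tkey)
        p <- phyper(k - 1L, n_t, N - n_t, K, lower.tail = FALSE)
        ov_genes <- genes[gene_key(genes) %in% ov]
        up <- down <- NA_integer_; z <- NA_real_
        if (!is.null(fc_key)) {
          signs <- sign(fc_key[ov])
          if (!anyNA(signs) && all(signs != 0)) {
            up <- sum(signs > 0); down <- sum(signs < 0)
            z <- term_zscore(signs, denominator = z_denominator)
          }
        }
        tibble::tibble(category = cat_, term = term, label = label,
                       k = k, K = K, n = n_t, N = N, p_value = p,
                       up = up, down = down, count = k, z_score = z,
                       genes = list(ov_genes))
      }
    )
    if (nrow(rows) == 0L) return(rows)
    rows$q_value <- p.adjust(rows$p_value, method = "BH")
    rows
  })
  if (nrow(res) == 0L) {
    res <- tibble::tibble(category = character(), term = character(),
                          label = character(), k = integer(), K = integer(),
                          n = integer(), N = integer(), p_value = numeric(),
                          q_value = numeric(), enriched = logical(),
                          up = integer(), down = integer(), count = integer(),
                          z_score = numeric(), genes = list())
  } else {
    res$enriched <- res$p_value < alpha & res$q_value <= fdr
    res <- res[order(res$category, res$p_value, res$term),
               c("category", "term", "label", "k", "K", "n", "N", "p_value",
                 "q_value", "enriched", "up", "down", "count", "z_score",
                 "genes")]
  }
  if (!keep_all) res <- res[res$enriched, , drop = FALSE]
  class(res) <- c("gba_enrichment", class(res))
  res
}

#' Signed up/down z-score of a term's overlap genes
#'
#' `(up - down) / sqrt(count)` where `up`/`down` count overlap genes with
#' positive/negative fold change and `count = up + down`. A positive score
#' means the term's genes are predominantly up-regulated. The `"count"`
#' denominator variant (`(up - down)/count`, i.e. the signed fraction) is
#' provided because the formula is printed ambiguously in parts of the
#' literature.
#'
#' @param signs Vector of fold-change signs (any numeric; only the sign is
#'   used; zeros are not allowed).
#' @param denominator `"sqrt"` (default) or `"count"`.
#' @return Signed scalar; `|z| <= sqrt(count)` for the default denominator.
#' @export
term_zscore <- function(signs, denominator = c("sqrt", "count")) {
  denominator <- match.arg(denominator)
  s <- sign(as.numeric(signs))
  if (length(s) == 0L) abort("empty overlap: z-score undefined")
  if (any(is.na(s) | s == 0)) abort("fold-change signs must be non-zero")
  up <- sum(s > 0); down <- sum(s < 0); count <- up + down
  (up - down) / switch(denominator, sqrt = sqrt(count), count = count)
}

#' Tissue-level z-score of a whole gene list
#'
#' The same statistic as [term_zscore()] applied to all fold-change signs of
#' a gene list (e.g. all DEGs, or all prioritized genes, of one tissue);
#' summarizes whether the list is predominantly up- or down-regulated.
#'
#' @inheritParams term_zscore
#' @return Signed scalar.
#' @export
list_zscore <- function(signs, denominator = c("sqrt", "count")) {
  term_zscore(signs, denominator = denominator)
}

#' @rdname ora
#' @param object A `gba_enrichment`.
#' @param top Terms per category to display (by p-value).
#' @param ... Unused.
#' @method autoplot gba_enrichment
#' @export
autoplot.gba_enrichment <- function(object, top = 10, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::group_by(.data$category) |>
    dplyr::slice_min(.data$p_value, n = top, with_ties = FALSE) |>
    dplyr::ungroup()
  has_z <- !all(is.na(df$z_score))
  df$term <- stats::reorder(df$term, -df$p_value)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$p_value), y = .data$term))
  p <- if (has_z) {
    p + ggplot2::geom_col(ggplot2::aes(fill = .data$z_score)) +
      ggplot2::scale_fill_gradient2(low = "steelblue", mid = "grey90",
                                    high = "firebrick", midpoint = 0)
  } else {
    p + ggplot2::geom_col(fill = "steelblue")
  }
  p + ggplot2::facet_wrap(ggplot2::vars(.data$category), scales = "free_y") +
    ggplot2::labs(x = expression(-log[10](p)), y = NULL, fill = "z-score") +
    ggplot2::theme_minimal()
}
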