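# Candidate-gene prioritization by annotation similarity to a trained list:
# fold-change filtering, per-category similarity scores with genome-sampling
# null distributions, Fisher combination across informative categories,
# Benjamini-Hochberg control across candidates, and the auto-inclusion rule
# for candidates already present in the trained list.

#' Filter DEG records by absolute fold change
#'
#' Retains records with `|fold_change|` strictly greater than `cutoff`
#' (default 1.3, i.e. at least a 30% expression difference in either
#' direction); the sign is preserved.
#'
#' @param deg Tibble with columns `gene`, `fold_change` (and typically
#'   `p_value`).
#' @param cutoff Ratio-scale fold-change cutoff, must exceed 1.
#' @param source_tissue Optional tissue label attached as an attribute.
#' @return Filtered tibble (a candidate list).
#' @export
filter_by_fold_change <- function(deg, cutoff = 1.3, source_tissue = NULL) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 1) {
    abort("`cutoff` must be a single ratio > 1")
  }
  out <- deg[abs(deg$fold_change) > cutoff, , drop = FALSE]
  attr(out, "fc_cutoff") <- cutoff
  attr(out, "source_tissue") <- source_tissue
  out
}

# training genes carried as symbols or a trained_list tibble
.training_genes <- function(training) {
  g <- if (is.data.frame(training)) training$gene else as.character(training)
  if (length(g) == 0L) abort("training list is empty")
  g
}

# Vectorized gene-to-training-set similarity for one category.
#
# Set-valued categories: pairwise similarity is the Jaccard index of the two
# genes' term sets; vector-valued (coexpression) categories: Pearson
# correlation of the two genes' profiles mapped to [0, 1]. The gene-level
# score is the mean of the k highest pairwise similarities against the
# training genes (k = |training| by default, i.e. the plain mean, counting
# unannotated training genes as similarity 0). Genes without annotation in
# the category get similarity 0 and are flagged uninformative.
#
# Returns list(sim = numeric named by `genes`, informative = logical).
.sim_to_training <- function(genes, training, corpus, category,
                             coexpression = NULL, k = NULL) {
  train_genes <- .training_genes(training)
  tkeys <- unique(gene_key(train_genes))
  qkeys <- gene_key(genes)
  n_train <- length(tkeys)

  if (!is.null(coexpression) && category == "coexpression") {
    rk <- gene_key(rownames(coexpression))
    qi <- match(qkeys, rk)
    ti <- match(tkeys, rk)
    informative <- !is.na(qi)
    sims <- matrix(0, nrow = length(qkeys), ncol = n_train)
    ti_ok <- which(!is.na(ti))
    if (length(ti_ok) && any(informative)) {
      cc <- suppressWarnings(
        cor(t(coexpression[qi[informative], , drop = FALSE]),
            t(coexpression[ti[ti_ok], , drop = FALSE]))
      )
      cc[is.na(cc)] <- 0
      sims[informative, ti_ok] <- (cc + 1) / 2
    }
  } else {
    M <- category_membership(corpus, category)
    qi <- match(qkeys, rownames(M))
    ti <- match(tkeys, rownames(M))
    informative <- !is.na(qi)
    sims <- matrix(0, nrow = length(qkeys), ncol = n_train)
    ti_ok <- which(!is.na(ti))
    if (length(ti_ok) && any(informative)) {
      MQ <- M[qi[informative], , drop = FALSE]
      MT <- M[ti[ti_ok], , drop = FALSE]
      inter <- as.matrix(Matrix::tcrossprod(MQ, MT))
      uni <- outer(Matrix::rowSums(MQ), Matrix::rowSums(MT), "+") - inter
      J <- ifelse(uni > 0, inter / uni, 0)
      sims[informative, ti_ok] <- J
    }
  }

  k <- k %||% n_train
  k <- min(k, n_train)
  sim <- if (k == n_train) {
    rowSums(sims) / n_train
  } else {
    apply(sims, 1L, function(row) mean(sort(row, decreasing = TRUE)[seq_len(k)]))
  }
  sim[!informative] <- 0
  names(sim) <- genes
  list(sim = sim, informative = informative)
}

#' Similarity of one gene to a training set within an annotation category
#'
#' @param gene A gene symbol.
#' @param training A trained list (tibble from [threshold_trained_list()])
#'   or character vector of gene symbols.
#' @param corpus An [annotation_corpus()].
#' @param category Category name present in the corpus, or `"coexpression"`
#'   with a `coexpression` matrix supplied.
#' @param coexpression Optional numeric matrix (genes in rows, named by
#'   symbol) used when `category = "coexpression"`; pairwise similarity is
#'   then the Pearson correlation mapped to \[0, 1\].
#' @param k Use the mean of the `k` highest pairwise similarities (defaults
#'   to the training-set size, i.e. the plain mean).
#' @return A single similarity in \[0, 1\]; 0 (with attribute
#'   `informative = FALSE`) when the gene has no annotation in the category.
#' @export
feature_similarity <- function(gene, training, corpus, category,
                               coexpression = NULL, k = NULL) {
  stopifnot(length(gene) == 1L)
  if (!(category %in% corpus$category) &&
      !(category == "coexpression" && !is.null(coexpression))) {
    abort(paste0("unknown category: ", category))
  }
  r <- .sim_to_training(gene, training, corpus, category, coexpression, k)
  structure(unname(r$sim), informative = r$informative)
}

#' Permutation p-value for an observed similarity score
#'
#' The null distribution is built by sampling `n_samples` genes uniformly
#' with replacement from the gene universe and computing their similarity to
#' the training set; the p-value uses the add-one estimator
#' `p = (1 + #(null >= observed)) / (n_samples + 1)`, which can never reach
#' zero (so downstream meta-analytic combination stays finite).
#'
#' @param observed Observed similarity score.
#' @param gene_universe Character vector of genome symbols to sample from.
#' @param training,corpus,category,coexpression,k See [feature_similarity()].
#' @param n_samples Number of null draws (default 5000).
#' @param seed Integer seed; the result is deterministic given the seed.
#' @return A single p-value in (0, 1\].
#' @export
sampling_pvalue <- function(observed, gene_universe, training, corpus,
                            category, n_samples = 5000, seed = 1L,
                            coexpression = NULL, k = NULL) {
  check_count(n_samples, "n_samples")
  if (length(gene_universe) == 0L) abort("gene universe is empty")
  null <- .null_sims(gene_universe, training, corpus, category, n_samples,
                     seed, coexpression, k)
  (1 + sum(null >= observed)) / (n_samples + 1)
}

# shared null machinery: sample with replacement, score unique keys once
.null_sims <- function(gene_universe, training, corpus, category, n_samples,
                       seed, coexpression = NULL, k = NULL) {
  withr::with_seed(as.integer(seed), {
    draws <- sample(gene_universe, n_samples, replace = TRUE)
  })
  uniq <- unique(draws)
  r <- .sim_to_training(uniq, training, corpus, category, coexpression, k)
  unname(r$sim[match(draws, uniq)])
}

#' Combine per-category p-values by Fisher's method
#'
#' `-2 * sum(log(p))` referred to a chi-square distribution with `2m`
#' degrees of freedom, where `m` is the number of informative categories.
#'
#' @param per_feature_p Numeric vector of p-values in (0, 1\] from
#'   informative categories only.
#' @return Combined p-value; with zero categories, 1 with a warning.
#' @export
combine_pvalues <- function(per_feature_p) {
  p <- as.numeric(per_feature_p)
  p <- p[!is.na(p)]
  if (length(p) == 0L) {
    warn("no informative categories; combined p-value set to 1")
    return(1)
  }
  if (any(p <= 0 | p > 1)) abort("p-values must lie in (0, 1]")
  stat <- -2 * sum(log(p))
  pchisq(stat, df = 2 * length(p), lower.tail = FALSE)
}

#' Prioritize fold-change-filtered candidates against a trained list
#'
#' For every candidate gene, computes per-category similarities to the
#' trained list, permutation p-values against genome-sampling nulls (one
#' shared null per category, seeded deterministically from `seed`), a
#' Fisher-combined p-value over informative categories, and
#' Benjamini-Hochberg q-values across all candidates. A candidate is
#' `selected` iff `q_value <= alpha_fdr` and `combined_p <= p_cutoff`;
#' candidates that are themselves members of the trained list are
#' auto-included (selected regardless of their p-values).
#'
#' @param candidates Candidate list from [filter_by_fold_change()] (tibble
#'   with a `gene` column) or a character vector of symbols.
#' @param training Trained list ([threshold_trained_list()]) or character
#'   vector.
#' @param corpus An [annotation_corpus()].
#' @param universe Character vector of genome symbols for null sampling.
#' @param alpha_fdr FDR level for selection (default 0.05).
#' @param p_cutoff Combined p-value cutoff for selection (default 1e-3).
#' @param n_samples Null draws per category (default 5000).
#' @param seed Master seed; per-category seeds are derived deterministically.
#' @param categories Categories to use (default: all in the corpus).
#' @param coexpression Optional coexpression matrix (see
#'   [feature_similarity()]); adds a `"coexpression"` category.
#' @param k Top-k pairwise similarities averaged per gene (default: all).
#' @return Tibble of class `gba_prioritization`, ordered by `combined_p`
#'   (ties broken lexicographically): columns `gene`, `combined_p`,
#'   `q_value`, `auto_included`, `selected`, `n_informative`, plus list
#'   columns `similarity` and `feature_p` (named per category).
#' @export
prioritize <- function(candidates, training, corpus, universe,
                       alpha_fdr = 0.05, p_cutoff = 1e-3, n_samples = 5000,
                       seed = 1L, categories = NULL, coexpression = NULL,
                       k = NULL) {
  check_prob(alpha_fdr, "alpha_fdr")
  check_prob(p_cutoff, "p_cutoff")
  genes <- if (is.data.frame(candidates)) candidates$gene else as.character(candidates)
  if (length(genes) == 0L) abort("candidate list is empty")
  train_genes <- .training_genes(training)
  categories <- categories %||% unique(corpus$category)
  if (!is.null(coexpression)) categories <- union(categories, "coexpression")

  ## canonical processing order: sorted unique genes, so input order cannot
  ## influence any score or the shared nulls
  ord_genes <- genes[order(gene_key(genes))]
  n <- length(ord_genes)

  sim_mat <- matrix(NA_real_, n, length(categories),
                    dimnames = list(ord_genes, categories))
  p_mat <- matrix(NA_real_, n, length(categories),
                  dimnames = list(ord_genes, categories))
  for (ci in seq_along(categories)) {
    cat_ <- categories[ci]
    obs <- .sim_to_training(ord_genes, training, corpus, cat_, coexpression, k)
    null <- .null_sims(universe, training, corpus, cat_, n_samples,
                       derive_seed(seed, paste0("null:", cat_)), coexpression, k)
    sim_mat[, ci] <- obs$sim
    sn <- sort(null)
    n_ge <- n_samples - findInterval(obs$sim, sn, left.open = TRUE)
    pv <- (1 + n_ge) / (n_samples + 1)
    pv[!obs$informative] <- NA_real_
    p_mat[, ci] <- pv
  }

  combined <- apply(p_mat, 1L, function(p) {
    p <- p[!is.na(p)]
    if (length(p) == 0L) 1 else pchisq(-2 * sum(log(p)), df = 2 * length(p),
                                       lower.tail = FALSE)
  })
  combined <- pmax(combined, .Machine$double.xmin)  # keep strictly positive
  q <- p.adjust(combined, method = "BH")
  auto <- gene_key(ord_genes) %in% gene_key(train_genes)
  selected <- auto | (q <= alpha_fdr & combined <= p_cutoff)

  out <- tibble::tibble(
    gene = ord_genes,
    combined_p = unname(combined),
    q_value = unname(q),
    auto_included = auto,
    selected = selected,
    n_informative = apply(p_mat, 1L, function(p) sum(!is.na(p))),
    similarity = purrr::map(seq_len(n), ~ sim_mat[.x, ]),
    feature_p = purrr::map(seq_len(n), ~ p_mat[.x, ])
  )
  out <- out[order(out$combined_p, gene_key(out$gene)), , drop = FALSE]
  attr(out, "params") <- list(alpha_fdr = alpha_fdr, p_cutoff = p_cutoff,
                              n_samples = n_samples, seed = seed,
                              categories = categories)
  class(out) <- c("gba_prioritization", class(out))
  out
}

#' @rdname prioritize
#' @param object A `gba_prioritization`.
#' @param ... Unused.
#' @method autoplot gba_prioritization
#' @export
autoplot.gba_prioritization <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$rank <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = -log10(.data$combined_p),
                                   color = .data$selected)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "candidate rank", y = expression(-log[10](combined~p)),
                  color = "selected") +
    ggplot2::theme_minimal()
}
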