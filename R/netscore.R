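# Trained-list construction: keyword-driven seed selection on the annotation
# corpus, topology-global propagation scoring of the interaction network, and
# score thresholding. The propagation scheme is this package's concrete
# contract for a seed-dominated, [0,1]-scaled network prioritization score.

#' Select seed genes by keyword match against annotation terms
#'
#' A gene is a seed iff it is annotated to at least one term whose id or
#' free-text label contains at least one keyword as a case-insensitive
#' substring (no stemming; multiword phrases match literally). Seeds absent
#' from the network node set are dropped with a warning listing them.
#'
#' @param corpus An [annotation_corpus()].
#' @param keywords Non-empty character vector of keywords.
#' @param network_nodes Character vector of network node names; seeds must
#'   exist in the network (matching on the case-folded key).
#' @return Tibble of class `seed_set` with columns `gene` and
#'   `matched_keywords` (semicolon-joined provenance).
#' @export
select_seeds <- function(corpus, keywords, network_nodes) {
  keywords <- as.character(keywords)
  if (length(keywords) == 0L || any(!nzchar(trimws(keywords)))) {
    abort("`keywords` must be non-empty")
  }
  hay <- tolower(paste(corpus$term, corpus$label))
  prov <- list()
  for (kw in keywords) {
    hit <- stringr::str_detect(hay, stringr::fixed(tolower(kw)))
    genes <- unique(unlist(corpus$genes[hit], use.names = FALSE))
    if (length(genes)) prov[[kw]] <- genes
  }
  if (length(prov) == 0L) {
    abort("no seeds matched any keyword; revise the keyword list")
  }
  long <- tibble::tibble(
    keyword = rep(names(prov), lengths(prov)),
    gene = unlist(prov, use.names = FALSE)
  )
  seeds <- long |>
    dplyr::mutate(key = gene_key(.data$gene)) |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(
      gene = dplyr::first(.data$gene),
      matched_keywords = paste(unique(.data$keyword), collapse = ";"),
      .groups = "drop"
    )
  in_net <- seeds$key %in% gene_key(network_nodes)
  if (any(!in_net)) {
    warn(paste0("dropping ", sum(!in_net), " seed(s) absent from the network: ",
                paste(seeds$gene[!in_net], collapse = ", ")))
    seeds <- seeds[in_net, , drop = FALSE]
  }
  if (nrow(seeds) == 0L) {
    abort("no seeds remain after network filtering; revise the keyword list")
  }
  out <- seeds[order(seeds$key), c("gene", "matched_keywords")]
  class(out) <- c("seed_set", class(out))
  out
}

#' Propagation scoring of a network from seed genes
#'
#' Assigns every network node a phenotype-association score in \[0, 1\] by
#' repeated local averaging from seed nodes. Seeds start at score 1, all
#' other nodes at 0. Each of `repetitions` repetitions performs `iterations`
#' synchronous rounds in which a node's incoming value is the mean of its
#' neighbors' previous-round values; the repetition then updates each node's
#' score to `max(own score, decay * max over rounds of incoming value)` with
#' `decay = 0.5`. Keeping the running maximum over rounds (rather than the
#' final round only) makes the score monotone in connectivity to scored
#' nodes regardless of path-length parity. Final scores are rescaled by the
#' maximum; isolated non-seed nodes score exactly 0. The procedure is fully
#' deterministic.
#'
#' @param network An igraph object, or an edge tibble/data frame with two
#'   columns, taken as an undirected graph.
#' @param seeds A `seed_set` from [select_seeds()], or a character vector of
#'   gene symbols.
#' @param repetitions Number of score-merging repetitions (default 3).
#' @param iterations Propagation rounds per repetition (default 2).
#' @param decay Per-repetition damping of the propagated value (default 0.5).
#' @return Object of class `netscore_result`: list with `scores` (tibble
#'   `gene`, `score`, `seed`) and `params`.
#' @export
netscore <- function(network, seeds, repetitions = 3, iterations = 2,
                     decay = 0.5) {
  g <- .as_graph(network)
  repetitions <- check_count(repetitions, "repetitions")
  iterations <- check_count(iterations, "iterations")
  seed_genes <- if (is.data.frame(seeds)) seeds$gene else as.character(seeds)
  if (length(seed_genes) == 0L) abort("seed set is empty")

  nodes <- igraph::V(g)$name
  keys <- gene_key(nodes)
  is_seed <- keys %in% gene_key(seed_genes)
  if (!any(is_seed)) abort("no seed maps onto the network")

  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  deg <- Matrix::rowSums(A)
  inv_deg <- ifelse(deg > 0, 1 / deg, 0)

  s <- as.numeric(is_seed)
  for (r in seq_len(repetitions)) {
    v <- s
    vmax <- rep(0, length(s))
    for (i in seq_len(iterations)) {
      v <- as.numeric(A %*% v) * inv_deg
      vmax <- pmax(vmax, v)
    }
    s <- pmax(s, decay * vmax)
  }
  if (max(s) > 0) s <- s / max(s)

  structure(
    list(
      scores = tibble::tibble(gene = nodes, score = s, seed = is_seed),
      params = list(repetitions = repetitions, iterations = iterations,
                    decay = decay, n_seeds = sum(is_seed))
    ),
    class = "netscore_result"
  )
}

.as_graph <- function(network) {
  if (inherits(network, "igraph")) {
    g <- igraph::as_undirected(network, mode = "collapse")
  } else if (is.data.frame(network)) {
    g <- igraph::graph_from_data_frame(network[, 1:2], directed = FALSE)
    g <- igraph::simplify(g)
  } else {
    abort("`network` must be an igraph object or an edge data frame")
  }
  if (is.null(igraph::V(g)$name)) igraph::V(g)$name <- as.character(seq_len(igraph::gorder(g)))
  g
}

#' @export
print.netscore_result <- function(x, ...) {
  cat("<netscore_result>", nrow(x$scores), "nodes,", x$params$n_seeds, "seeds",
      sprintf("(R=%d, I=%d, decay=%g)\n", x$params$repetitions,
              x$params$iterations, x$params$decay))
  print(head(dplyr::arrange(x$scores, dplyr::desc(.data$score)), 5))
  invisible(x)
}

#' @rdname netscore
#' @param x A `netscore_result`.
#' @param ... Unused.
#' @method tidy netscore_result
#' @export
tidy.netscore_result <- function(x, ...) {
  dplyr::arrange(x$scores, dplyr::desc(.data$score), .data$gene)
}

#' @rdname netscore
#' @method glance netscore_result
#' @export
glance.netscore_result <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$scores),
    n_seeds = x$params$n_seeds,
    repetitions = x$params$repetitions,
    iterations = x$params$iterations,
    max_nonseed_score = max(c(0, x$scores$score[!x$scores$seed]))
  )
}

#' @rdname netscore
#' @param object A `netscore_result`.
#' @param cutoff Threshold drawn on the score histogram.
#' @method autoplot netscore_result
#' @export
autoplot.netscore_result <- function(object, cutoff = 0.1, ...) {
  ggplot2::ggplot(object$scores, ggplot2::aes(x = .data$score, fill = .data$seed)) +
    ggplot2::geom_histogram(bins = 40, alpha = 0.8, position = "identity") +
    ggplot2::geom_vline(xintercept = cutoff, linetype = "dashed") +
    ggplot2::scale_y_sqrt() +
    ggplot2::labs(x = "propagation score", y = "genes (sqrt scale)",
                  fill = "seed") +
    ggplot2::theme_minimal()
}

#' Threshold propagation scores into a trained list
#'
#' Retains genes with score strictly greater than `cutoff`, ordered by
#' descending score with lexicographic tie-break for reproducible output.
#'
#' @param result A [netscore()] result.
#' @param cutoff Score threshold in \[0, 1); strict inequality.
#' @return Tibble of class `trained_list` with columns `gene`, `score`,
#'   `seed`; the cutoff is stored in `attr(, "cutoff")`.
#' @export
threshold_trained_list <- function(result, cutoff = 0.1) {
  stopifnot(inherits(result, "netscore_result"))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff < 0 || cutoff >= 1) {
    abort("`cutoff` must be a single value in [0, 1)")
  }
  kept <- result$scores[result$scores$score > cutoff, , drop = FALSE]
  kept <- kept[order(-kept$score, kept$gene), , drop = FALSE]
  out <- tibble::as_tibble(kept)
  attr(out, "cutoff") <- cutoff
  class(out) <- c("trained_list", class(out))
  out
}
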