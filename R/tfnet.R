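# TF-target regulatory network: ChIP-derived edge filtering on peak
# intensity and regulatory potential, network construction restricted to
# prioritized target genes, degree/betweenness centrality, and top-TF
# ranking.

#' Filter TF-target edges on peak intensity and regulatory potential
#'
#' Retains edges with `peak_intensity < peak_cutoff` and
#' `regulatory_potential < rp_cutoff`, both strict. Duplicate (tf, target)
#' pairs are collapsed keeping the lowest regulatory potential.
#'
#' @param edges Tibble with columns `tf`, `target`, `peak_intensity`,
#'   `regulatory_potential`.
#' @param peak_cutoff Strict upper bound on peak intensity (default 500).
#' @param rp_cutoff Strict upper bound on regulatory potential (default 1).
#' @return Filtered, deduplicated tibble.
#' @export
filter_tf_edges <- function(edges, peak_cutoff = 500, rp_cutoff = 1) {
  neg <- which(edges$peak_intensity < 0 | edges$regulatory_potential < 0)
  if (length(neg)) {
    abort(paste0("negative peak intensity or regulatory potential at row(s): ",
                 paste(utils::head(neg, 5L), collapse = ", ")))
  }
  out <- edges[edges$peak_intensity < peak_cutoff &
                 edges$regulatory_potential < rp_cutoff, , drop = FALSE]
  out |>
    dplyr::mutate(.tfk = gene_key(.data$tf), .tgk = gene_key(.data$target)) |>
    dplyr::group_by(.data$.tfk, .data$.tgk) |>
    dplyr::slice_min(.data$regulatory_potential, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select(-".tfk", -".tgk")
}

#' Build the TF-target regulatory network over prioritized genes
#'
#' Undirected simple graph restricted to (filtered) edges whose target is a
#' prioritized gene; isolated prioritized genes are retained as nodes. Each
#' node carries a `kind` attribute (`"TF"` or `"gene"`) and each gene node a
#' `tf_count` attribute (number of distinct TFs targeting it).
#'
#' @param edges Filtered edge tibble from [filter_tf_edges()].
#' @param prioritized Character vector of prioritized gene symbols.
#' @return An igraph object.
#' @export
build_regulatory_network <- function(edges, prioritized) {
  prioritized <- as.character(prioritized)
  if (length(prioritized) == 0L) abort("prioritized gene list is empty")
  pkey <- gene_key(prioritized)
  keep <- gene_key(edges$target) %in% pkey
  e <- edges[keep, , drop = FALSE]
  tf_nodes <- unique(e$tf)
  gene_nodes <- prioritized[!duplicated(pkey)]
  ## a prioritized gene that also appears as TF keeps its TF role
  gene_nodes <- gene_nodes[!gene_key(gene_nodes) %in% gene_key(tf_nodes)]
  verts <- tibble::tibble(
    name = c(tf_nodes, gene_nodes),
    kind = c(rep("TF", length(tf_nodes)), rep("gene", length(gene_nodes)))
  )
  g <- igraph::graph_from_data_frame(
    e[, c("tf", "target")], directed = FALSE, vertices = verts
  )
  g <- igraph::simplify(g)
  tfc <- purrr::map_int(igraph::V(g)$name, function(v) {
    if (verts$kind[match(v, verts$name)] == "TF") return(NA_integer_)
    length(unique(e$tf[gene_key(e$target) == gene_key(v)]))
  })
  igraph::V(g)$tf_count <- tfc
  g
}

#' Degree and betweenness centrality of every network node
#'
#' Degree is the incident-edge count; betweenness is unnormalized
#' shortest-path betweenness with equal edge weights and even splitting
#' across equally short paths (Brandes' algorithm).
#'
#' @param network An igraph object, e.g. from [build_regulatory_network()].
#' @return Tibble with columns `node`, `node_kind` (`"TF"`/`"gene"` when the
#'   graph carries a `kind` attribute, `NA` otherwise), `degree`,
#'   `betweenness`.
#' @export
centrality <- function(network) {
  if (!inherits(network, "igraph")) network <- .as_graph(network)
  if (igraph::gorder(network) == 0L) abort("empty network")
  kind <- igraph::vertex_attr(network, "kind") %||% rep(NA_character_, igraph::gorder(network))
  tibble::tibble(
    node = igraph::V(network)$name,
    node_kind = kind,
    degree = as.integer(igraph::degree(network)),
    betweenness = unname(igraph::betweenness(network, directed = FALSE,
                                             normalized = FALSE))
  )
}

#' Rank transcription factors by centrality
#'
#' TF nodes sorted by degree (descending), ties broken by betweenness
#' (descending) then lexicographically, truncated to `k`.
#'
#' @param records Centrality tibble from [centrality()].
#' @param k Number of TFs to return (default 10).
#' @return Tibble of at most `k` TF rows with a `rank` column.
#' @export
top_tfs <- function(records, k = 10) {
  check_count(k, "k")
  tf <- records[!is.na(records$node_kind) & records$node_kind == "TF", , drop = FALSE]
  tf <- tf[order(-tf$degree, -tf$betweenness, gene_key(tf$node)), , drop = FALSE]
  tf <- utils::head(tf, k)
  tf$rank <- seq_len(nrow(tf))
  tf[, c("rank", "node", "degree", "betweenness")]
}
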