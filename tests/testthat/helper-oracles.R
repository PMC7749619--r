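# Independent oracles and small fixture builders used across the suite.
# Every oracle is a deliberately naive implementation that shares no code
# with the package internals.

# Round-by-round propagation oracle over an adjacency list. Mirrors the
# documented contract: per repetition, `iterations` synchronous
# mean-of-neighbors rounds; merge max(own, decay * max over rounds);
# rescale by the maximum at the end.
netscore_oracle <- function(edges, seeds, repetitions = 3, iterations = 2,
                            decay = 0.5) {
  nodes <- sort(unique(c(edges$from, edges$to, seeds)))
  nbr <- lapply(nodes, function(v) {
    unique(c(edges$to[edges$from == v], edges$from[edges$to == v]))
  })
  names(nbr) <- nodes
  s <- stats::setNames(as.numeric(nodes %in% seeds), nodes)
  for (r in seq_len(repetitions)) {
    v <- s
    vmax <- stats::setNames(rep(0, length(s)), nodes)
    for (i in seq_len(iterations)) {
      v_new <- vapply(nodes, function(nd) {
        nb <- nbr[[nd]]
        if (length(nb) == 0) 0 else mean(v[nb])
      }, numeric(1))
      v <- v_new
      vmax <- pmax(vmax, v)
    }
    s <- pmax(s, decay * vmax)
  }
  if (max(s) > 0) s <- s / max(s)
  s
}

# Brute-force betweenness: enumerate every simple path between every node
# pair, keep the shortest ones, split credit evenly. Exponential; fine for
# the <= 8-node graphs it is used on.
betweenness_oracle <- function(adj) {
  nodes <- names(adj)
  bc <- stats::setNames(rep(0, length(nodes)), nodes)
  all_paths <- function(from, to, visited) {
    if (from == to) return(list(visited))
    out <- list()
    for (nb in adj[[from]]) {
      if (!(nb %in% visited)) {
        out <- c(out, all_paths(nb, to, c(visited, nb)))
      }
    }
    out
  }
  for (i in seq_along(nodes)) {
    for (j in seq_along(nodes)) {
      if (i >= j) next
      paths <- all_paths(nodes[i], nodes[j], nodes[i])
      if (length(paths) == 0) next
      lens <- vapply(paths, length, integer(1))
      shortest <- paths[lens == min(lens)]
      for (p in shortest) {
        inner <- setdiff(p, c(nodes[i], nodes[j]))
        bc[inner] <- bc[inner] + 1 / length(shortest)
      }
    }
  }
  bc
}

# Classical-scaling oracle: explicit Torgerson double centering and
# eigendecomposition, independent of stats::cmdscale.
torgerson_oracle <- function(D, k = 2) {
  D <- as.matrix(D)
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- which(e$values > 1e-12)
  kk <- min(k, length(pos))
  pts <- e$vectors[, pos[seq_len(kk)], drop = FALSE] %*%
    diag(sqrt(e$values[pos[seq_len(kk)]]), kk)
  list(points = pts, eigenvalues = e$values,
       variance_explained = e$values / sum(e$values[pos]))
}

# Upper-tail hypergeometric probability by direct summation over overlap
# counts (independent of stats::phyper).
hyper_tail_oracle <- function(k, n_term, N, K) {
  js <- k:min(n_term, K)
  sum(choose(n_term, js) * choose(N - n_term, K - js)) / choose(N, K)
}

# Rank-based AUROC (Mann-Whitney form): P(score_pos > score_neg).
auroc <- function(score, positive) {
  r <- rank(score)
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# small deterministic corpus used by several unit tests
tiny_corpus <- function() {
  annotation_corpus(tibble::tibble(
    category = c("GO_BP", "GO_BP", "GO_BP", "pathway", "pathway"),
    term = c("bp1", "bp2", "bp3", "kg1", "kg2"),
    label = c("dopamine receptor signaling", "axon guidance",
              "synaptic vesicle cycle", "calcium signaling pathway",
              "long-term potentiation"),
    genes = list(c("Drd2", "Th"), c("Nrp1", "Plcb1", "Drd2"),
                 c("Stx1a", "Dnm1", "Syn1"), c("Plcb1", "Camk2a"),
                 c("Gria1", "Camk2a", "Drd2"))
  ))
}

write_tmp <- function(lines, ext = ".tsv") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path, useBytes = TRUE)
  path
}
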