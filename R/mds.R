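# Functional-similarity clustering: binary gene x term incidence matrix over
# enriched terms, Hamming distances between genes, a Euclidean
# transformation, classical (Torgerson) multidimensional scaling with
# per-component variance explained, and Venn-style sharing partitions of
# prioritized gene sets.

#' Build a binary gene-by-term incidence matrix
#'
#' `cell(g, t) = 1` iff gene `g` is annotated to term `t` in the corpus.
#' Terms annotating none of the listed genes are dropped with a warning;
#' genes with no annotations keep an all-zero row (their distance
#' contributions are well defined).
#'
#' @param genes Character vector of gene symbols (rows).
#' @param terms Term ids (character), or a [ora()] result whose `term`
#'   column is used.
#' @param corpus An [annotation_corpus()].
#' @return Binary matrix with gene rows and term columns.
#' @export
build_incidence <- function(genes, terms, corpus) {
  if (is.data.frame(terms)) terms <- terms$term
  terms <- unique(as.character(terms))
  if (length(terms) == 0L) abort("empty term list")
  miss <- setdiff(terms, corpus$term)
  if (length(miss)) {
    abort(paste0("term(s) not in corpus: ", paste(utils::head(miss, 5L), collapse = ", ")))
  }
  gkeys <- gene_key(genes)
  inc <- matrix(0L, nrow = length(genes), ncol = length(terms),
                dimnames = list(genes, terms))
  for (j in seq_along(terms)) {
    tg <- gene_key(corpus$genes[[match(terms[j], corpus$term)]])
    inc[, j] <- as.integer(gkeys %in% tg)
  }
  empty <- colSums(inc) == 0L
  if (any(empty)) {
    warn(paste0("dropping ", sum(empty), " term(s) annotating none of the listed genes: ",
                paste(terms[empty], collapse = ", ")))
    inc <- inc[, !empty, drop = FALSE]
  }
  inc
}

#' Pairwise Hamming distances between incidence rows
#'
#' `entry(i, j)` is the number of terms on which genes `i` and `j` disagree
#' (unnormalized count of differing columns).
#'
#' @param inc Binary incidence matrix from [build_incidence()].
#' @return Symmetric matrix of counts with zero diagonal.
#' @export
hamming_matrix <- function(inc) {
  if (nrow(inc) < 2L) abort("need at least 2 genes")
  ## for binary rows the Manhattan distance equals the Hamming count
  h <- as.matrix(dist(inc, method = "manhattan"))
  dimnames(h) <- list(rownames(inc), rownames(inc))
  h
}

#' Euclidean distances derived from a Hamming distance matrix
#'
#' Two readings of "Euclidean distance computed from the Hamming matrix" are
#' supported. `"hamming-rows"` (default) treats each gene's row of the
#' Hamming matrix as its coordinate vector and returns Euclidean distances
#' between those rows — the literal reading of deriving a second distance
#' from the first. `"incidence-sqrt"` returns `sqrt(Hamming)`, which is
#' exactly the Euclidean distance between the original binary incidence rows
#' (the geometrically standard reading, and a metric satisfying the triangle
#' inequality).
#'
#' @param hmat Hamming distance matrix from [hamming_matrix()].
#' @param mode `"hamming-rows"` or `"incidence-sqrt"`.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
euclidean_from_hamming <- function(hmat, mode = c("hamming-rows", "incidence-sqrt")) {
  mode <- match.arg(mode)
  hmat <- as.matrix(hmat)
  if (!isSymmetric(unname(hmat)) || any(diag(hmat) != 0) || any(hmat < 0)) {
    abort("`hmat` must be a symmetric non-negative matrix with zero diagonal")
  }
  out <- switch(mode,
    "hamming-rows" = as.matrix(dist(hmat, method = "euclidean")),
    "incidence-sqrt" = sqrt(hmat)
  )
  dimnames(out) <- dimnames(hmat)
  out
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared distances, eigendecomposes, and builds
#' coordinates from the top-`k` positive eigenvalues. The variance explained
#' by component `i` is `lambda_i / sum(positive lambdas)`; negative
#' eigenvalues (possible for non-Euclidean input) are excluded from both
#' coordinates and the denominator. Axes are canonicalized so the first
#' nonzero coordinate of each axis is positive, making output reproducible
#' up to machine precision.
#'
#' @param d Distance matrix (symmetric, zero diagonal) or `dist` object.
#' @param k Number of components (default 2; must be `< n` points).
#' @return Object of class `gba_mds`: list with `points` (n x k coordinate
#'   matrix), `eigenvalues` (all, non-increasing), `variance_explained`
#'   (fractions over positive eigenvalues).
#' @export
classical_mds <- function(d, k = 2) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  check_count(k, "k")
  if (k >= n) abort("`k` must be smaller than the number of points")
  fit <- suppressWarnings(cmdscale(as.dist(dm), k = k, eig = TRUE))
  pts <- fit$points
  if (ncol(pts) < k) {  # degenerate configurations embed in fewer dimensions
    pts <- cbind(pts, matrix(0, n, k - ncol(pts)))
  }
  pts[is.na(pts)] <- 0
  ## axis sign canonicalization
  for (j in seq_len(ncol(pts))) {
    nz <- which(abs(pts[, j]) > 1e-12)
    if (length(nz) && pts[nz[1L], j] < 0) pts[, j] <- -pts[, j]
  }
  rownames(pts) <- rownames(dm)
  colnames(pts) <- paste0("MDS", seq_len(ncol(pts)))
  eig <- fit$eig
  pos <- eig[eig > 1e-12]
  ve <- if (length(pos)) eig[seq_along(eig)] / sum(pos) else rep(0, length(eig))
  ve <- pmax(ve, 0)
  ve[eig <= 1e-12] <- 0
  structure(
    list(points = pts, eigenvalues = eig,
         variance_explained = ve[seq_len(min(length(ve), n))]),
    class = "gba_mds"
  )
}

#' @export
print.gba_mds <- function(x, ...) {
  ve <- x$variance_explained
  cat("<gba_mds>", nrow(x$points), "points,", ncol(x$points), "components\n")
  cat("  variance explained:",
      paste(sprintf("%.2f%%", 100 * ve[seq_len(ncol(x$points))]), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname classical_mds
#' @param x A `gba_mds`.
#' @param ... Unused.
#' @method tidy gba_mds
#' @export
tidy.gba_mds <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(gene = rownames(x$points) %||% as.character(seq_len(nrow(x$points)))),
    tibble::as_tibble(x$points)
  )
}

#' @rdname classical_mds
#' @method glance gba_mds
#' @export
glance.gba_mds <- function(x, ...) {
  kk <- ncol(x$points)
  tibble::tibble(
    n = nrow(x$points),
    k = kk,
    var_explained_1 = x$variance_explained[1L],
    var_explained_2 = if (kk >= 2L) x$variance_explained[2L] else NA_real_,
    cum_var_explained = sum(x$variance_explained[seq_len(kk)])
  )
}

#' @rdname classical_mds
#' @param object A `gba_mds`.
#' @param groups Optional named group assignment (names = gene symbols) used
#'   to color points.
#' @method autoplot gba_mds
#' @export
autoplot.gba_mds <- function(object, groups = NULL, ...) {
  df <- tidy(object)
  ve <- object$variance_explained
  lab <- function(i) sprintf("MDS%d (%.1f%%)", i, 100 * ve[i])
  if (!is.null(groups)) df$group <- unname(groups[df$gene])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$MDS1, y = .data$MDS2))
  p <- if (is.null(groups)) p + ggplot2::geom_point() else
    p + ggplot2::geom_point(ggplot2::aes(color = .data$group))
  p + ggplot2::labs(x = lab(1), y = lab(2), color = NULL) +
    ggplot2::theme_minimal()
}

#' Venn-region partition of up to four named gene sets
#'
#' Computes the cardinality and membership of every intersection region
#' (genes in all sets of a combination and in none of the others); region
#' sizes sum to the size of the union.
#'
#' @param sets Named list of 2 to 4 character vectors of gene symbols.
#' @return Tibble with columns `region` (e.g. `"A&B"`), `n_sets`, `size`,
#'   `genes` (list column).
#' @export
sharing_partition <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L || length(sets) > 4L ||
      is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort("`sets` must be a named list of 2-4 gene sets")
  }
  keys <- purrr::map(sets, gene_key)
  symbols <- purrr::map2(sets, keys, ~ stats::setNames(.x, .y))
  all_sym <- unlist(unname(symbols))
  all_sym <- all_sym[!duplicated(names(all_sym))]
  nm <- names(sets)
  member <- purrr::map(keys, ~ names(all_sym) %in% .x)
  combos <- purrr::map(seq_along(nm), ~ utils::combn(nm, .x, simplify = FALSE))
  combos <- purrr::flatten(combos)
  purrr::map_dfr(combos, function(cmb) {
    inside <- Reduce(`&`, member[cmb])
    outside <- Reduce(`|`, member[setdiff(nm, cmb)], init = rep(FALSE, length(all_sym)))
    sel <- inside & !outside
    tibble::tibble(
      region = paste(cmb, collapse = "&"),
      n_sets = length(cmb),
      size = sum(sel),
      genes = list(sort(unname(all_sym[sel])))
    )
  })
}
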