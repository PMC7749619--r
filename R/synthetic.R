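# Synthetic-world generator: networks, annotation corpora, DEG tables and
# TF edge tables with planted, recoverable structure, so that every
# downstream stage of the workflow can be validated against ground truth.

#' Generate a synthetic world with a planted phenotype module
#'
#' Emulates the inputs of a two-tissue guilt-by-association study: a
#' scale-free protein-interaction network containing a planted, densely
#' interconnected "phenotype module"; an annotation corpus whose phenotype
#' and functional terms are enriched for module genes; two tissue DEG tables
#' with opposite fold-change sign bias (one mostly up-regulated, one mostly
#' down-regulated) and a signal-dependent excess of module genes; and a
#' TF-to-target edge table containing one planted hub TF.
#'
#' `signal` interpolates between a pure null world (`signal = 0`: module
#' genes are statistically indistinguishable from the background in network
#' degree, annotation and differential expression) and a strongly structured
#' world (`signal = 1`).
#'
#' @param n_genes Genome size.
#' @param module_size Number of planted phenotype-module genes
#'   (`< n_genes`).
#' @param signal Planted-structure strength in \[0, 1\].
#' @param up_bias Fraction of positive fold changes in the up-biased tissue
#'   table; the down-biased table uses `1 - up_bias`.
#' @param seed Integer seed; identical seeds give bit-identical worlds.
#' @param n_deg_up,n_deg_down Number of DEG records per tissue table
#'   (defaults: 12% and 6.5% of the genome, the proportions of the motivating
#'   study scaled to `n_genes`).
#' @param fc_pass_frac Fraction of fold-change magnitudes exceeding the 1.3
#'   candidate cutoff (default 0.92, matching the published screen's
#'   pass rate).
#' @param pa_edges Edges attached per node in the preferential-attachment
#'   backbone.
#' @param term_size Genes drawn per annotation term (default 15; larger
#'   values give denser annotation coverage per gene).
#' @return An object of class `gba_world`: a list with elements `genome`,
#'   `network` (igraph), `module_genes`, `corpus`, `deg_tissue_up`,
#'   `deg_tissue_down`, `tf_edges`, `seed`, `params`.
#' @export
generate_world <- function(n_genes = 2000, module_size = 50, signal = 0.7,
                           up_bias = 0.8, seed = 1L,
                           n_deg_up = round(0.12 * n_genes),
                           n_deg_down = round(0.065 * n_genes),
                           fc_pass_frac = 0.92, pa_edges = 3,
                           term_size = 15L) {
  check_count(n_genes, "n_genes", 10L)
  check_count(module_size, "module_size", 2L)
  if (module_size >= n_genes) abort("`module_size` must be smaller than `n_genes`")
  check_prob(signal, "signal")
  check_prob(up_bias, "up_bias")
  check_prob(fc_pass_frac, "fc_pass_frac")

  withr::with_seed(as.integer(seed), {
    genome <- sprintf("g%05d", seq_len(n_genes))
    module_genes <- sort(sample(genome, module_size))

    ## scale-free backbone; vertex labels randomly permuted so module genes
    ## land anywhere in the attachment order
    g <- igraph::sample_pa(n_genes, power = 1, m = pa_edges, directed = FALSE)
    igraph::V(g)$name <- sample(genome)
    extra <- .module_pairs(module_genes, prob = 0.08 * signal)
    if (nrow(extra)) {
      g <- igraph::add_edges(g, as.vector(t(as.matrix(extra))))
    }
    g <- igraph::simplify(g)

    corpus <- .synthetic_corpus(genome, module_genes, signal,
                                term_size = as.integer(term_size))
    deg_up <- .synthetic_deg(genome, module_genes, signal, n_deg_up,
                             up_frac = up_bias, fc_pass_frac = fc_pass_frac)
    deg_down <- .synthetic_deg(genome, module_genes, signal, n_deg_down,
                               up_frac = 1 - up_bias, fc_pass_frac = fc_pass_frac)
    tf_edges <- .synthetic_tf_edges(genome, unique(c(deg_up$gene, deg_down$gene)))

    world <- list(
      genome = genome, network = g, module_genes = module_genes,
      corpus = corpus, deg_tissue_up = deg_up, deg_tissue_down = deg_down,
      tf_edges = tf_edges, seed = as.integer(seed),
      params = list(
        n_genes = n_genes, module_size = module_size, signal = signal,
        up_bias = up_bias, n_deg_up = n_deg_up, n_deg_down = n_deg_down,
        fc_pass_frac = fc_pass_frac, pa_edges = pa_edges,
        term_size = term_size
      )
    )
    class(world) <- "gba_world"
    world
  })
}

# unordered module pairs kept with probability `prob`
.module_pairs <- function(module_genes, prob) {
  if (prob <= 0 || length(module_genes) < 2L) {
    return(data.frame(a = character(), b = character()))
  }
  pairs <- utils::combn(module_genes, 2L)
  keep <- runif(ncol(pairs)) < prob
  data.frame(a = pairs[1L, keep], b = pairs[2L, keep])
}

# Terms draw members from the module with probability `signal`, otherwise
# uniformly from the genome; at signal = 0 every term is a uniform draw.
.signal_term <- function(genome, module_genes, signal, size) {
  from_module <- runif(size) < signal
  g <- character(size)
  g[from_module] <- sample(module_genes, sum(from_module), replace = TRUE)
  g[!from_module] <- sample(genome, sum(!from_module), replace = TRUE)
  unique(g)
}

.synthetic_corpus <- function(genome, module_genes, signal,
                              term_size = 15L, n_signal = 8L, n_noise = 30L,
                              n_pheno = 10L) {
  one_cat <- function(cat, n_sig, n_bg, prefix) {
    sig <- tibble::tibble(
      category = cat,
      term = sprintf("%s_S%02d", prefix, seq_len(n_sig)),
      label = sprintf("synthetic %s signal term %d", cat, seq_len(n_sig)),
      genes = purrr::map(seq_len(n_sig),
                         ~ .signal_term(genome, module_genes, signal, term_size))
    )
    bg <- tibble::tibble(
      category = cat,
      term = sprintf("%s_B%02d", prefix, seq_len(n_bg)),
      label = sprintf("synthetic %s background term %d", cat, seq_len(n_bg)),
      genes = purrr::map(seq_len(n_bg), ~ unique(sample(genome, term_size, replace = TRUE)))
    )
    dplyr::bind_rows(sig, bg)
  }
  annotation_corpus(dplyr::bind_rows(
    one_cat("phenotype", n_pheno, 5L, "PH"),
    one_cat("GO_BP", n_signal, n_noise, "BP"),
    one_cat("GO_MF", n_signal, n_noise, "MF"),
    one_cat("pathway", n_signal, n_noise, "KG")
  ))
}

.synthetic_deg <- function(genome, module_genes, signal, n_deg, up_frac,
                           fc_pass_frac) {
  n_deg <- min(n_deg, length(genome))
  w <- ifelse(genome %in% module_genes, 1 + 9 * signal, 1)
  genes <- sample(genome, n_deg, prob = w)
  above <- runif(n_deg) < fc_pass_frac
  mag <- ifelse(above, 1.3 * exp(rexp(n_deg, rate = 3)), runif(n_deg, 1.01, 1.3))
  sign <- ifelse(runif(n_deg) < up_frac, 1, -1)
  tibble::tibble(
    gene = genes,
    fold_change = sign * mag,
    p_value = 10^runif(n_deg, -6, -2)
  )
}

.synthetic_tf_edges <- function(genome, deg_genes, n_tf = 25L) {
  tfs <- sprintf("Tf%02d", seq_len(n_tf))
  hub_targets <- sample(deg_genes, min(20L, length(deg_genes)))
  hub <- tibble::tibble(
    tf = tfs[1L], target = hub_targets,
    peak_intensity = runif(length(hub_targets), 50, 450),
    regulatory_potential = runif(length(hub_targets), 0.05, 0.9)
  )
  others <- purrr::map_dfr(tfs[-1L], function(tf) {
    k <- sample(1:4, 1L)
    tibble::tibble(
      tf = tf,
      target = sample(c(deg_genes, genome), k),
      peak_intensity = rexp(k, rate = 1 / 300),
      regulatory_potential = runif(k, 0, 2)
    )
  })
  dplyr::bind_rows(hub, others)
}

#' @export
print.gba_world <- function(x, ...) {
  cat("<gba_world> seed", x$seed, "\n")
  cat("  genome:", length(x$genome), "genes; planted module:",
      length(x$module_genes), "genes\n")
  cat("  network:", igraph::gorder(x$network), "nodes /",
      igraph::gsize(x$network), "edges\n")
  cat("  corpus:", nrow(x$corpus), "terms in",
      length(unique(x$corpus$category)), "categories\n")
  cat("  DEG tables:", nrow(x$deg_tissue_up), "up-biased /",
      nrow(x$deg_tissue_down), "down-biased records\n")
  cat("  TF edges:", nrow(x$tf_edges), "\n")
  invisible(x)
}

#' Attach keyword-matchable descriptions to phenotype terms
#'
#' Emulates keyword-driven seeding against curated databases: free-text
#' descriptions are attached to the world's phenotype terms so that each
#' supplied keyword matches (case-insensitive substring) at least one term
#' whose gene set intersects the planted module. With
#' `match_guarantee = FALSE` descriptions are left as generated and keywords
#' may legitimately match nothing.
#'
#' @param world A [generate_world()] object.
#' @param keywords Non-empty character vector of non-empty keywords.
#' @param match_guarantee Rewrite term labels so every keyword has a
#'   module-overlapping match (default `TRUE`).
#' @return List with `world` (corpus updated) and `mapping`, a tibble of the
#'   keyword-to-term assignments used (empty when nothing matched).
#' @export
keyword_annotations <- function(world, keywords, match_guarantee = TRUE) {
  stopifnot(inherits(world, "gba_world"))
  keywords <- as.character(keywords)
  if (length(keywords) == 0L || any(is.na(keywords)) || any(!nzchar(trimws(keywords)))) {
    abort("`keywords` must be non-empty strings")
  }
  corpus <- world$corpus
  pheno <- which(corpus$category == "phenotype")
  overlap <- purrr::map_int(corpus$genes[pheno],
                            ~ length(intersect(gene_key(.x), gene_key(world$module_genes))))
  mapping <- tibble::tibble(keyword = character(), term = character())
  for (i in seq_along(keywords)) {
    kw <- keywords[i]
    hit <- pheno[overlap > 0 &
                   stringr::str_detect(tolower(corpus$label[pheno]), stringr::fixed(tolower(kw)))]
    if (length(hit) == 0L && match_guarantee) {
      cand <- pheno[overlap > 0]
      if (length(cand) == 0L) cand <- pheno
      hit <- cand[((i - 1L) %% length(cand)) + 1L]
      corpus$label[hit] <- paste0(corpus$label[hit], "; associated with ", kw)
    }
    if (length(hit)) {
      mapping <- dplyr::bind_rows(mapping,
                                  tibble::tibble(keyword = kw, term = corpus$term[hit]))
    }
  }
  world$corpus <- corpus
  list(world = world, mapping = mapping)
}

#' Write a synthetic world to standard plain-text formats
#'
#' Emits the formats the rest of the workflow consumes: an interaction edge
#' list, one GMT per annotation category, two DEG tables and a TF edge
#' table. Every file carries the generating seed in a `#` header comment.
#'
#' @param world A [generate_world()] object.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "gba_world"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- paste0("# gbanet synthetic world, seed ", world$seed)
  out <- c()

  write_commented <- function(df, path) {
    writeLines(hdr, path)
    readr::write_tsv(df, path, append = TRUE, col_names = TRUE, progress = FALSE)
    path
  }

  edges <- igraph::as_data_frame(world$network, what = "edges")
  out["network"] <- write_commented(tibble::as_tibble(edges), file.path(dir, "network.tsv"))
  out["deg_up"] <- write_commented(world$deg_tissue_up, file.path(dir, "deg_tissue_up.tsv"))
  out["deg_down"] <- write_commented(world$deg_tissue_down, file.path(dir, "deg_tissue_down.tsv"))
  out["tf_edges"] <- write_commented(world$tf_edges, file.path(dir, "tf_edges.tsv"))
  for (cat in unique(world$corpus$category)) {
    p <- file.path(dir, paste0("corpus_", cat, ".gmt"))
    write_gmt(world$corpus[world$corpus$category == cat, ], p)
    out[paste0("gmt_", cat)] <- p
  }
  invisible(out)
}
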