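# End-to-end orchestration: a single validated configuration drives
# fold-change filtering, trained-list construction, prioritization,
# enrichment, functional clustering, TF-network centrality and cross-tissue
# sharing, writing per-stage TSVs, a JSON manifest and a log.

#' Build a validated run configuration
#'
#' Collects every input path and numeric knob of the workflow. All cutoffs
#' are validated against their documented ranges; the configuration is
#' serialized verbatim into the run manifest.
#'
#' @param network Path to an interaction edge list (TSV/SIF).
#' @param gmt Character vector of GMT paths, one annotation category each
#'   (named by category; unnamed entries use the file name).
#' @param deg Named character vector of DEG table paths, one per tissue.
#' @param tf_edges Path to the TF-target edge table (or `NULL` to skip the
#'   TF stage).
#' @param keywords Character vector of seeding keywords, or the path of a
#'   plain-text file with one keyword per line.
#' @param fc_cutoff Fold-change cutoff (> 1; default 1.3).
#' @param score_cutoff Trained-list score cutoff in \[0, 1) (default 0.1).
#' @param repetitions,iterations Propagation parameters (defaults 3, 2).
#' @param n_samples Null draws per category (default 5000).
#' @param alpha_fdr,p_cutoff Prioritization selection thresholds (defaults
#'   0.05, 1e-3).
#' @param enrich_alpha,enrich_fdr Enrichment thresholds (defaults 0.05, 0.05).
#' @param peak_cutoff,rp_cutoff TF edge filters (defaults 500, 1).
#' @param mds_mode Euclidean mode, `"hamming-rows"` or `"incidence-sqrt"`.
#' @param z_denominator `"sqrt"` or `"count"` for the z-score.
#' @param seed Master seed; per-stage seeds are derived deterministically
#'   from it and the stage name.
#' @return List of class `gba_config`.
#' @export
run_config <- function(network, gmt, deg, tf_edges = NULL, keywords,
                       fc_cutoff = 1.3, score_cutoff = 0.1,
                       repetitions = 3, iterations = 2, n_samples = 5000,
                       alpha_fdr = 0.05, p_cutoff = 1e-3,
                       enrich_alpha = 0.05, enrich_fdr = 0.05,
                       peak_cutoff = 500, rp_cutoff = 1,
                       mds_mode = c("hamming-rows", "incidence-sqrt"),
                       z_denominator = c("sqrt", "count"), seed = 1L) {
  mds_mode <- match.arg(mds_mode)
  z_denominator <- match.arg(z_denominator)
  if (!is.numeric(fc_cutoff) || fc_cutoff <= 1) abort("`fc_cutoff` must exceed 1")
  if (!is.numeric(score_cutoff) || score_cutoff < 0 || score_cutoff >= 1) {
    abort("`score_cutoff` must lie in [0, 1)")
  }
  check_prob(alpha_fdr, "alpha_fdr"); check_prob(p_cutoff, "p_cutoff")
  check_prob(enrich_alpha, "enrich_alpha"); check_prob(enrich_fdr, "enrich_fdr")
  if (peak_cutoff <= 0 || rp_cutoff <= 0) abort("TF cutoffs must be positive")
  check_count(n_samples, "n_samples")
  if (is.null(names(deg)) || any(!nzchar(names(deg)))) {
    abort("`deg` must be a named vector (tissue = path)")
  }
  cfg <- list(
    network = network, gmt = gmt, deg = as.list(deg), tf_edges = tf_edges,
    keywords = keywords, fc_cutoff = fc_cutoff, score_cutoff = score_cutoff,
    repetitions = repetitions, iterations = iterations, n_samples = n_samples,
    alpha_fdr = alpha_fdr, p_cutoff = p_cutoff,
    enrich_alpha = enrich_alpha, enrich_fdr = enrich_fdr,
    peak_cutoff = peak_cutoff, rp_cutoff = rp_cutoff,
    mds_mode = mds_mode, z_denominator = z_denominator,
    seed = as.integer(seed)
  )
  class(cfg) <- "gba_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of [run_config()].
#' @return A validated `gba_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$deg <- unlist(y$deg)
  do.call(run_config, y)
}

# flatten list columns for TSV output
.flatten_for_tsv <- function(df) {
  df <- tibble::as_tibble(df)
  for (nm in names(df)) {
    col <- df[[nm]]
    if (is.list(col)) {
      if (!is.null(names(col[[1]]))) {
        wide <- purrr::map_dfr(col, ~ tibble::as_tibble(as.list(.x)))
        names(wide) <- paste0(nm, "_", names(wide))
        df[[nm]] <- NULL
        df <- dplyr::bind_cols(df, wide)
      } else {
        df[[nm]] <- purrr::map_chr(col, ~ paste(.x, collapse = ";"))
      }
    }
  }
  df
}

#' Run the whole prioritization workflow
#'
#' Executes, for each tissue: fold-change filter, trained-list construction
#' (shared across tissues), annotation-similarity prioritization,
#' over-representation enrichment with z-scores, functional-similarity MDS
#' clustering, TF-network centrality, and finally the cross-tissue sharing
#' partition. Writes one TSV per stage, a JSON manifest (configuration,
#' seed, package version, per-stage record counts) and a human-readable
#' log. Identical configuration and seed give byte-identical tables.
#'
#' @param config A [run_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the manifest and the per-tissue results.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "gba_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  say <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " INFO ", paste0(...))
    log_lines <<- c(log_lines, line)
  }
  counts <- list()
  emit <- function(df, name) {
    path <- file.path(outdir, paste0(name, ".tsv"))
    readr::write_tsv(.flatten_for_tsv(df), path, progress = FALSE)
    counts[[name]] <<- nrow(df)
    path
  }

  ## ingest
  edges <- read_edge_list(config$network)
  graph <- .as_graph(edges)
  gmt_names <- names(config$gmt) %||% rep("", length(config$gmt))
  corpus <- annotation_corpus(dplyr::bind_rows(purrr::map2(
    config$gmt, gmt_names,
    ~ read_gmt(.x, category = if (nzchar(.y)) .y else NULL)
  )))
  keywords <- config$keywords
  if (length(keywords) == 1L && file.exists(keywords)) {
    keywords <- readLines(keywords, encoding = "UTF-8")
    keywords <- keywords[nzchar(trimws(keywords))]
  }
  deg_tables <- purrr::map(config$deg, read_deg_table)
  universe <- union(igraph::V(graph)$name, corpus_genes(corpus))
  say("inputs: ", igraph::gorder(graph), " network nodes, ", nrow(corpus),
      " corpus terms, ", length(deg_tables), " tissue(s)")

  ## trained list (shared across tissues)
  seeds <- select_seeds(corpus, keywords, igraph::V(graph)$name)
  say("seed selection: ", nrow(seeds), " seeds from ", length(keywords), " keywords")
  ns <- netscore(graph, seeds, repetitions = config$repetitions,
                 iterations = config$iterations)
  trained <- threshold_trained_list(ns, cutoff = config$score_cutoff)
  say("trained list: score > ", config$score_cutoff, " retains ", nrow(trained),
      " of ", nrow(ns$scores), " genes")
  emit(trained, "trained_list")

  tf_filtered <- NULL
  if (!is.null(config$tf_edges)) {
    tf_raw <- read_tf_edges(config$tf_edges)
    tf_filtered <- filter_tf_edges(tf_raw, config$peak_cutoff, config$rp_cutoff)
    say("TF edges: peak < ", config$peak_cutoff, " & RP < ", config$rp_cutoff,
        " keeps ", nrow(tf_filtered), " of ", nrow(tf_raw))
  }

  tissues <- names(deg_tables)
  results <- list()
  for (tissue in tissues) {
    deg <- deg_tables[[tissue]]
    cand <- filter_by_fold_change(deg, config$fc_cutoff, source_tissue = tissue)
    say(tissue, ": |FC| > ", config$fc_cutoff, " keeps ", nrow(cand),
        " of ", nrow(deg), " DEGs")
    emit(cand, paste0(tissue, "_candidates"))

    prio <- prioritize(
      cand, trained, corpus, universe,
      alpha_fdr = config$alpha_fdr, p_cutoff = config$p_cutoff,
      n_samples = config$n_samples,
      seed = derive_seed(config$seed, paste0("prioritize:", tissue))
    )
    sel <- prio[prio$selected, , drop = FALSE]
    say(tissue, ": ", nrow(sel), " prioritized (",
        sum(sel$auto_included), " auto-included)")
    emit(prio, paste0(tissue, "_prioritized"))

    fc <- stats::setNames(deg$fold_change, deg$gene)
    enr <- ora(sel$gene, corpus, background = universe,
               alpha = config$enrich_alpha,
               fdr = config$enrich_fdr, fold_changes = fc,
               z_denominator = config$z_denominator)
    say(tissue, ": ", sum(enr$enriched), " enriched of ", nrow(enr),
        " tested terms")
    emit(enr, paste0(tissue, "_enriched"))

    terms <- if (any(enr$enriched)) enr$term[enr$enriched] else enr$term
    cl_genes <- if (nrow(sel) >= 3L) sel$gene else cand$gene
    mds <- NULL
    if (length(terms) >= 1L && length(cl_genes) >= 3L) {
      inc <- suppressWarnings(build_incidence(cl_genes, terms, corpus))
      if (ncol(inc) >= 1L) {
        h <- hamming_matrix(inc)
        eu <- euclidean_from_hamming(h, mode = config$mds_mode)
        mds <- classical_mds(eu, k = 2)
        emit(tidy(mds), paste0(tissue, "_mds"))
        say(tissue, ": MDS variance explained ",
            sprintf("%.2f%% / %.2f%%", 100 * mds$variance_explained[1],
                    100 * mds$variance_explained[2]))
      }
    }
    if (is.null(mds)) {
      emit(tibble::tibble(gene = character(), MDS1 = numeric(), MDS2 = numeric()),
           paste0(tissue, "_mds"))
      say(tissue, ": too few genes/terms for MDS clustering")
    }

    cent <- top <- NULL
    if (!is.null(tf_filtered)) {
      net <- build_regulatory_network(tf_filtered, sel$gene)
      cent <- centrality(net)
      top <- top_tfs(cent, k = 10)
      emit(cent, paste0(tissue, "_centrality"))
      emit(top, paste0(tissue, "_top_tfs"))
      say(tissue, ": TF network ", igraph::gorder(net), " nodes / ",
          igraph::gsize(net), " edges")
    }
    results[[tissue]] <- list(candidates = cand, prioritized = prio,
                              enriched = enr, mds = mds, centrality = cent,
                              top_tfs = top)
  }

  sharing <- NULL
  if (length(tissues) >= 2L) {
    sets <- purrr::map(results, ~ .x$prioritized$gene[.x$prioritized$selected])
    sharing <- sharing_partition(sets)
    emit(sharing, "sharing")
  }

  manifest <- list(
    package = "gbanet",
    version = as.character(utils::packageVersion("gbanet")),
    seed = config$seed,
    config = unclass(config),
    counts = counts
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(outdir, "run.log"))
  invisible(list(manifest = manifest, results = results, sharing = sharing,
                 trained = trained))
}
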