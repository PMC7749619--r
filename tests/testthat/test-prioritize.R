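test_that("fold-change filtering is strict on the modulus", {
  deg <- tibble::tibble(gene = c("A", "B", "C", "D"),
                        fold_change = c(-1.5, 1.3, 1.31, -1.29),
                        p_value = rep(0.001, 4))
  out <- filter_by_fold_change(deg)
  expect_setequal(out$gene, c("A", "C"))        # -1.5 kept, 1.3 dropped
  expect_equal(out$fold_change[out$gene == "A"], -1.5)  # sign preserved
  expect_error(filter_by_fold_change(deg, cutoff = 0.9), "cutoff")

  # constructed table mirroring a realistic screen: 1,674 records of which
  # exactly 1,550 have |FC| > 1.3
  set.seed(11)
  n <- 1674
  pass <- sample(c(rep(TRUE, 1550), rep(FALSE, 124)))
  mag <- ifelse(pass, runif(n, 1.301, 8), runif(n, 1.0, 1.3))
  big <- tibble::tibble(gene = sprintf("G%04d", 1:n),
                        fold_change = sample(c(-1, 1), n, TRUE) * mag,
                        p_value = runif(n, 0, 0.01))
  expect_equal(nrow(filter_by_fold_change(big)), 1550L)
})

test_that("pairwise annotation similarity is the Jaccard index", {
  corpus <- annotation_corpus(tibble::tibble(
    category = "GO_BP",
    term = c("t1", "t2", "t3"),
    label = c("t1", "t2", "t3"),
    genes = list(c("A", "B"), c("A", "B", "C"), c("B", "C"))
  ))
  # A: {t1,t2}; B: {t1,t2,t3}; C: {t2,t3}
  expect_equal(as.numeric(feature_similarity("A", "A", corpus, "GO_BP")),
               1)                                                      # identical sets
  expect_equal(as.numeric(feature_similarity("A", "C", corpus, "GO_BP")),
               1 / 3)                                                  # {t1,t2} vs {t2,t3}
  lone <- annotation_corpus(tibble::tibble(
    category = "GO_BP", term = c("u1", "u2"), label = c("u1", "u2"),
    genes = list("A", "C")
  ))
  expect_equal(as.numeric(feature_similarity("A", "C", lone, "GO_BP")), 0)  # disjoint

  # unannotated gene: similarity 0, flagged uninformative
  s <- feature_similarity("Zzz", "A", corpus, "GO_BP")
  expect_equal(as.numeric(s), 0)
  expect_false(attr(s, "informative"))
  expect_error(feature_similarity("A", "A", corpus, "nope"), "category")
})

test_that("coexpression similarity maps Pearson correlation onto [0, 1]", {
  coex <- rbind(A = c(1, 2, 3, 4), B = c(2, 4, 6, 8), C = c(4, 3, 2, 1))
  corpus <- tiny_corpus()
  expect_equal(as.numeric(
    feature_similarity("A", "B", corpus, "coexpression", coexpression = coex)
  ), 1)   # r = 1
  expect_equal(as.numeric(
    feature_similarity("A", "C", corpus, "coexpression", coexpression = coex)
  ), 0)   # r = -1
})

test_that("sampling p-values use the add-one estimator and a fixed seed", {
  w <- generate_world(n_genes = 150, module_size = 10, signal = 0.9, seed = 8)
  training <- w$module_genes
  n_s <- 200
  # an observed score above every possible similarity gets the floor p
  p_min <- sampling_pvalue(2, w$genome, training, w$corpus, "GO_BP",
                           n_samples = n_s, seed = 42)
  expect_equal(p_min, 1 / (n_s + 1))
  # similarity 0 is never exceeded: p = 1 exactly (all nulls >= 0)
  p_max <- sampling_pvalue(0, w$genome, training, w$corpus, "GO_BP",
                           n_samples = n_s, seed = 42)
  expect_equal(p_max, 1)
  # determinism given the seed
  p1 <- sampling_pvalue(0.05, w$genome, training, w$corpus, "GO_BP",
                        n_samples = n_s, seed = 7)
  p2 <- sampling_pvalue(0.05, w$genome, training, w$corpus, "GO_BP",
                        n_samples = n_s, seed = 7)
  expect_identical(p1, p2)
  expect_error(sampling_pvalue(0.1, character(), training, w$corpus, "GO_BP"),
               "universe")
})

test_that("Fisher combination matches the chi-square closed form", {
  expect_equal(combine_pvalues(0.05), 0.05)
  expect_equal(combine_pvalues(c(1, 1)), 1)
  expect_equal(combine_pvalues(c(0.5, 0.5)),
               pchisq(-2 * (log(0.5) + log(0.5)), df = 4, lower.tail = FALSE))
  for (p in list(c(0.01, 0.2), c(0.9, 0.4, 0.03), rep(0.1, 5))) {
    expect_equal(combine_pvalues(p),
                 pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE))
  }
  expect_warning(p0 <- combine_pvalues(numeric()), "informative")
  expect_equal(p0, 1)
  expect_error(combine_pvalues(c(0.5, 0)), "0, 1")
})

test_that("prioritization applies auto-inclusion and FDR selection", {
  w <- generate_world(n_genes = 200, module_size = 15, signal = 0.9, seed = 12)
  training <- w$module_genes
  cand <- filter_by_fold_change(w$deg_tissue_up)
  pr <- prioritize(cand, training, w$corpus, w$genome, n_samples = 200, seed = 3)

  expect_true(all(pr$combined_p > 0 & pr$combined_p <= 1))
  expect_true(all(pr$q_value >= pr$combined_p - 1e-12))
  # auto-included implies selected
  expect_true(all(pr$selected[pr$auto_included]))
  # every candidate present in the training list is auto-included
  in_train <- gene_key(pr$gene) %in% gene_key(training)
  expect_identical(pr$auto_included, in_train)
  # ordered by combined p
  expect_true(!is.unsorted(pr$combined_p))
  # BH q-values are non-decreasing in p-rank
  expect_true(!is.unsorted(pr$q_value))

  # candidate order must not matter
  cand_shuf <- cand[rev(seq_len(nrow(cand))), ]
  pr2 <- prioritize(cand_shuf, training, w$corpus, w$genome,
                    n_samples = 200, seed = 3)
  expect_equal(tibble::as_tibble(pr), tibble::as_tibble(pr2))
})

test_that("a trained-list member is selected even with hopeless p-values", {
  # candidate gene X is in the training list but shares no annotation
  corpus <- annotation_corpus(tibble::tibble(
    category = "GO_BP", term = c("t1", "t2"), label = c("t1", "t2"),
    genes = list(c("A", "B"), c("C", "D"))
  ))
  universe <- c("A", "B", "C", "D", "X", "Y")
  pr <- prioritize(c("X", "Y"), c("X", "A"), corpus, universe,
                   n_samples = 50, seed = 1)
  x <- pr[pr$gene == "X", ]
  expect_true(x$auto_included)
  expect_true(x$selected)
  expect_equal(x$combined_p, 1)      # unannotated: uninformative everywhere
  # Y shares nothing either and is not in training: not selected
  expect_false(pr$selected[pr$gene == "Y"])
  expect_error(prioritize(c("X"), character(), corpus, universe), "empty")
})

test_that("null-world sampling p-values are uniform and FDR is controlled", {
  # calibration world: no planted structure, dense annotation
  w <- generate_world(n_genes = 400, module_size = 20, signal = 0,
                      seed = 21, term_size = 40)
  training <- w$genome[1:40]
  test_genes <- w$genome[41:240]
  ps <- vapply(test_genes, function(g) {
    obs <- feature_similarity(g, training, w$corpus, "GO_BP")
    sampling_pvalue(obs, w$genome, training, w$corpus, "GO_BP",
                    n_samples = 500, seed = 99)
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)

  # type-I control across independent null worlds
  fp <- total <- 0
  for (s in 1:20) {
    ws <- generate_world(n_genes = 150, module_size = 10, signal = 0,
                         seed = 500 + s, term_size = 30)
    cand <- filter_by_fold_change(ws$deg_tissue_up)
    pr <- prioritize(cand, ws$genome[1:12], ws$corpus, ws$genome,
                     n_samples = 100, seed = s)
    non_mod <- !pr$auto_included
    fp <- fp + sum(pr$selected & non_mod)
    total <- total + sum(non_mod)
  }
  rate <- fp / total
  mc_err <- sqrt(0.05 * 0.95 / total)
  expect_lte(rate, 0.05 + 2 * mc_err)
})

test_that("ranking by combined p recovers planted module genes (AUROC)", {
  w <- generate_world(n_genes = 2000, module_size = 50, signal = 0.9, seed = 101)
  kw <- c("dopamine", "long-term potentiation", "addiction")
  w <- keyword_annotations(w, kw)$world
  seeds <- select_seeds(w$corpus, kw, igraph::V(w$network)$name)
  trained <- threshold_trained_list(netscore(w$network, seeds))
  cand <- filter_by_fold_change(w$deg_tissue_up)
  pr <- prioritize(cand, trained, w$corpus, w$genome, n_samples = 1000, seed = 5)
  is_mod <- gene_key(pr$gene) %in% gene_key(w$module_genes)
  expect_gte(auroc(-pr$combined_p, is_mod), 0.9)
})
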