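test_that("seed selection is constructive keyword-to-gene matching", {
  corpus <- tiny_corpus()
  seeds <- select_seeds(corpus, "dopamine", c("Drd2", "Th", "Gria1"))
  expect_setequal(seeds$gene, c("Drd2", "Th"))

  expect_error(select_seeds(corpus, "no-such-keyword", c("Drd2")), "revise")
  expect_error(select_seeds(corpus, character(), c("Drd2")), "non-empty")

  # a gene hit by two keywords appears once with both in its provenance
  two <- select_seeds(corpus, c("dopamine", "long-term potentiation"),
                      c("Drd2", "Th", "Gria1", "Camk2a"))
  drd2 <- two[two$gene == "Drd2", ]
  expect_equal(nrow(drd2), 1L)
  expect_match(drd2$matched_keywords, "dopamine")
  expect_match(drd2$matched_keywords, "long-term potentiation")

  # seeds not in the network are dropped with a warning naming them
  expect_warning(kept <- select_seeds(corpus, "dopamine", "Drd2"), "Th")
  expect_identical(kept$gene, "Drd2")
})

test_that("propagation scores match a hand-simulated oracle exactly", {
  cases <- list(
    list(edges = tibble::tibble(from = c("A", "B"), to = c("B", "C")),
         seeds = "A", R = 1, I = 2),
    list(edges = tibble::tibble(from = c("A", "B"), to = c("B", "C")),
         seeds = "A", R = 3, I = 2),
    list(edges = tibble::tibble(from = c("c", "c", "c", "c"),
                                to = c("l1", "l2", "l3", "l4")),
         seeds = "c", R = 1, I = 1),
    list(edges = tibble::tibble(from = c("A", "B", "C", "D"),
                                to = c("B", "C", "D", "A")),
         seeds = c("A", "C"), R = 2, I = 3)
  )
  for (cs in cases) {
    got <- netscore(cs$edges, cs$seeds, repetitions = cs$R, iterations = cs$I)
    want <- netscore_oracle(cs$edges, cs$seeds, cs$R, cs$I)
    sc <- stats::setNames(got$scores$score, got$scores$gene)
    expect_equal(sc[names(want)], want, tolerance = 1e-12)
  }
})

test_that("propagation boundary behavior: stars, components, all-seeds", {
  # star: center seed reaches every leaf in one round
  star <- tibble::tibble(from = rep("c", 4), to = paste0("l", 1:4))
  r <- netscore(star, "c", repetitions = 1, iterations = 1)
  leaf <- r$scores$score[r$scores$gene != "c"]
  expect_true(all(leaf > 0))

  # disconnected component without seeds scores exactly 0
  two_comp <- tibble::tibble(from = c("A", "X"), to = c("B", "Y"))
  r2 <- netscore(two_comp, "A", repetitions = 2, iterations = 2)
  expect_equal(r2$scores$score[r2$scores$gene %in% c("X", "Y")], c(0, 0))

  # every node a seed: normalization fixed point, all scores 1
  r3 <- netscore(two_comp, c("A", "B", "X", "Y"))
  expect_true(all(r3$scores$score == 1))

  expect_error(netscore(star, character()), "empty")
  expect_error(netscore(star, "not-present"), "seed")
})

test_that("seeds dominate and connectivity strictly helps", {
  w <- generate_world(n_genes = 150, module_size = 10, signal = 0.5, seed = 4)
  seeds <- w$genome[1:5]
  r <- netscore(w$network, seeds)
  sc <- stats::setNames(r$scores$score, r$scores$gene)
  expect_true(all(sc[seeds] == 1))
  # a non-seed can never exceed decay * (max neighbor score) = 0.5
  expect_lte(max(sc[setdiff(names(sc), seeds)]), 0.5)

  # adding an edge from a seed to a zero-score node raises that node's score
  g <- igraph::graph_from_data_frame(
    tibble::tibble(from = c("S", "X"), to = c("A", "Y")), directed = FALSE
  )
  before <- netscore(g, "S", repetitions = 1, iterations = 2)
  x_before <- before$scores$score[before$scores$gene == "X"]
  expect_equal(x_before, 0)
  g2 <- igraph::add_edges(g, c("S", "X"))
  after <- netscore(g2, "S", repetitions = 1, iterations = 2)
  x_after <- after$scores$score[after$scores$gene == "X"]
  expect_gt(x_after, x_before)

  # determinism: no randomness anywhere in propagation
  expect_identical(netscore(w$network, seeds), netscore(w$network, seeds))
})

test_that("trained-list thresholding is strict and deterministically ordered", {
  r <- structure(list(
    scores = tibble::tibble(gene = c("A", "B", "C", "D"),
                            score = c(0.5, 0.1, 0.05, 0.5),
                            seed = c(TRUE, FALSE, FALSE, FALSE)),
    params = list(repetitions = 3, iterations = 2, decay = 0.5, n_seeds = 1)
  ), class = "netscore_result")
  tl <- threshold_trained_list(r, cutoff = 0.1)
  expect_identical(tl$gene, c("A", "D"))  # 0.1 excluded (strict), ties a-z
  expect_identical(threshold_trained_list(r, cutoff = 0)$gene,
                   c("A", "D", "B", "C"))
  expect_error(threshold_trained_list(r, cutoff = 1), "cutoff")
})

test_that("trained list recovers the planted module well above base rate", {
  w <- generate_world(n_genes = 2000, module_size = 50, signal = 0.9, seed = 101)
  kw <- c("dopamine", "long-term potentiation", "addiction")
  w <- keyword_annotations(w, kw)$world
  seeds <- select_seeds(w$corpus, kw, igraph::V(w$network)$name)
  trained <- threshold_trained_list(netscore(w$network, seeds), cutoff = 0.1)
  frac_trained <- mean(gene_key(trained$gene) %in% gene_key(w$module_genes))
  base_rate <- length(w$module_genes) / length(w$genome)
  expect_gte(frac_trained / base_rate, 5)
})
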