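test_that("incidence matrices encode annotation membership", {
  corpus <- annotation_corpus(tibble::tibble(
    category = "GO_BP", term = c("T", "U", "V"), label = c("T", "U", "V"),
    genes = list("A", c("A", "B"), "Z")
  ))
  expect_warning(inc <- build_incidence(c("A", "B"), c("T", "U", "V"), corpus),
                 "annotating none")
  expect_identical(colnames(inc), c("T", "U"))   # V annotates neither gene
  expect_equal(unname(inc[, "T"]), c(1L, 0L))

  # gene with no annotations keeps an all-zero row
  inc2 <- build_incidence(c("A", "B", "Q"), c("T", "U"), corpus)
  expect_equal(unname(inc2["Q", ]), c(0L, 0L))

  expect_error(build_incidence(c("A"), character(), corpus), "empty")
})

test_that("Hamming distances count differing terms", {
  inc <- rbind(A = c(1, 0, 1), B = c(0, 0, 1), C = c(0, 1, 0))
  h <- hamming_matrix(inc)
  expect_equal(h["A", "A"], 0)         # identical rows
  expect_equal(h["A", "B"], 1)         # (1,0,1) vs (0,0,1)
  expect_equal(h["A", "C"], 3)         # complementary rows of length 3
  expect_true(isSymmetric(h))
})

test_that("Euclidean transformation supports both documented modes", {
  h <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(euclidean_from_hamming(matrix(c(0, 4, 4, 0), 2),
                                      mode = "incidence-sqrt")[1, 2], 2)
  eu <- euclidean_from_hamming(h, mode = "hamming-rows")
  # rows a=(0,1,2), c=(2,1,0): sqrt(4+0+4)
  expect_equal(eu["a", "c"], sqrt(8))
  expect_equal(diag(eu), c(a = 0, b = 0, c = 0))
  expect_error(euclidean_from_hamming(matrix(c(0, 1, 2, 0), 2)), "symmetric")

  # incidence-sqrt distances between binary rows are a metric: triangle
  # inequality holds exhaustively on random binary matrices up to 8x8
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(3:8, 1); m <- sample(2:8, 1)
    inc <- matrix(rbinom(n * m, 1, 0.5), n)
    rownames(inc) <- paste0("g", 1:n)
    d <- euclidean_from_hamming(hamming_matrix(inc), mode = "incidence-sqrt")
    for (i in 1:n) for (j in 1:n) for (l in 1:n) {
      expect_lte(d[i, j], d[i, l] + d[l, j] + 1e-12)
    }
  }
})

test_that("classical MDS embeds exact configurations and reports variance", {
  # collinear points at 0, 1, 3: one dimension carries all the variance
  d3 <- as.matrix(dist(c(0, 1, 3)))
  m <- classical_mds(d3, k = 2)
  expect_equal(m$variance_explained[1], 1, tolerance = 1e-9)
  expect_equal(as.matrix(dist(m$points[, 1])), d3, tolerance = 1e-9,
               ignore_attr = TRUE)

  # equilateral triangle: two equal components, variance split 0.5 / 0.5
  tri <- matrix(1, 3, 3) - diag(3)
  mt <- classical_mds(tri, k = 2)
  expect_equal(mt$variance_explained[1:2], c(0.5, 0.5), tolerance = 1e-9)

  # random planar configurations are reconstructed to numerical precision
  set.seed(8)
  for (rep in 1:5) {
    pts <- matrix(rnorm(12), 6, 2)
    d <- as.matrix(dist(pts))
    fit <- classical_mds(d, k = 2)
    expect_equal(as.matrix(dist(fit$points)), d, tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_true(all(diff(fit$eigenvalues) <= 1e-9))
    # no meaningful negative eigenvalues for exact Euclidean input
    expect_gt(min(fit$eigenvalues), -1e-9)
    # agreement with an independent double-centering oracle
    want <- torgerson_oracle(d, 2)
    expect_equal(abs(fit$points), abs(want$points), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(fit$variance_explained[1:2], want$variance_explained[1:2],
                 tolerance = 1e-10)
  }

  expect_error(classical_mds(tri, k = 3), "smaller")
})

test_that("identical incidence rows collapse to identical coordinates", {
  inc <- rbind(A = c(1, 0, 1, 1), B = c(1, 0, 1, 1), C = c(0, 1, 0, 0),
               D = c(1, 1, 0, 1))
  d <- euclidean_from_hamming(hamming_matrix(inc), mode = "incidence-sqrt")
  m <- classical_mds(d, k = 2)
  expect_equal(m$points["A", ], m$points["B", ], tolerance = 1e-9)
  # cumulative variance over all positive components is 1
  pos <- m$variance_explained[m$variance_explained > 0]
  expect_equal(sum(pos), 1, tolerance = 1e-9)
  # tidy/glance expose the standard summaries
  expect_identical(tidy(m)$gene, rownames(inc))
  expect_equal(glance(m)$n, 4L)
})

test_that("sharing partitions enumerate Venn regions", {
  tabs <- load_prioritized_tables()
  part <- sharing_partition(list(pfc = tabs$pfc$gene,
                                 striatum = tabs$striatum$gene))
  both <- part[part$region == "pfc&striatum", ]
  expect_equal(both$size, 7L)
  expect_setequal(both$genes[[1]],
                  c("Atp1a3", "Camk2a", "Dnm1", "Drd2", "Gabrb3", "Gria1",
                    "Mef2c"))
  # regions partition the union
  expect_equal(sum(part$size), length(union(tabs$pfc$gene, tabs$striatum$gene)))

  dis <- sharing_partition(list(x = c("A", "B"), y = c("C")))
  expect_equal(dis$size[dis$region == "x&y"], 0L)
  sub <- sharing_partition(list(a = c("A"), b = c("A", "B")))
  expect_equal(sub$size[sub$region == "a"], 0L)   # A only in a&b region
  expect_error(sharing_partition(list(c("A"), c("B"))), "named")
})
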