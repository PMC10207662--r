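B <- example_inclusion_matrix()
Bgenes <- c("g1", "g2", "g3")

test_that("worked-example matrix reproduces all printed pairwise distances", {
  expect_equal(rhd_pair(B, "g1", "g2"), 0)
  expect_equal(rhd_pair(B, "g2", "g1"), 7 / 9)
  expect_equal(rhd_pair(B, "g1", "g3"), 1)
  expect_equal(rhd_pair(B, "g3", "g1"), 1)
  expect_equal(rhd_pair(B, "g2", "g3"), 7 / 9)
  expect_equal(rhd_pair(B, "g3", "g2"), 0)
  expect_equal(rhd_set(B, "g1", Bgenes), 1 / 2)
  expect_equal(rhd_set(B, "g2", Bgenes), 7 / 9)
  expect_equal(rhd_set(B, "g3", Bgenes), 1 / 2)
  expect_equal(mutual_exclusivity(B, Bgenes), 16 / 27)
  expect_identical(mwsm_weight(B, Bgenes), 5L)
  expect_equal(coverage(B, Bgenes), 1)  # union = support(g2) = dataset max
})

test_that("coverage is normalized by the dataset-wide maximum support", {
  # two disjoint genes of supports 3 and 4; dataset max support is 4
  A <- mm(a = 1:3, b = 4:7)
  expect_equal(coverage(A, c("a", "b")), 7 / 4)  # may exceed 1
  expect_equal(coverage(A, "b"), 1)
  expect_error(coverage(A, character(0)), "at least 1")
})

test_that("RHD characterizes inclusion and disjointness (property)", {
  withr::with_seed(23, {
    for (rep in 1:30) {
      A <- random_mutation_matrix(15, 6, prob = 0.35)
      sup <- supports_of(A)
      pair <- sample(colnames(A), 2)
      r <- rhd_pair(A, pair[1], pair[2])
      expect_gte(r, 0); expect_lte(r, 1)
      expect_equal(r, rhd_oracle(sup, pair[1], pair[2]))
      expect_identical(r == 0,
                       all(sup[[pair[1]]] %in% sup[[pair[2]]]))
      expect_identical(r == 1,
                       length(intersect(sup[[pair[1]]],
                                        sup[[pair[2]]])) == 0L)
    }
  })
  expect_error(rhd_pair(mm(a = 1, b = 2, samples = 3), "c", "a"),
               "not in matrix")
  A0 <- as_mutation_matrix(matrix(c(0L, 1L), 1, 2,
          dimnames = list("s1", c("a", "b"))))
  expect_error(rhd_pair(A0, "a", "b"), "empty support")
})

test_that("mutual exclusivity attains its boundary values", {
  expect_equal(mutual_exclusivity(mm(a = 1:2, b = 3:4, c = 5:6),
                                  c("a", "b", "c")), 1)
  expect_equal(mutual_exclusivity(mm(a = 1:3, b = 1:3), c("a", "b")), 0)
  # K = 2 reduces rhd_set to rhd_pair
  A <- mm(a = 1:4, b = 3:6)
  expect_equal(rhd_set(A, "a", c("a", "b")), rhd_pair(A, "a", "b"))
  expect_error(mutual_exclusivity(A, "a"), "at least 2")
})

test_that("mutual exclusivity is invariant under sample permutation,
           gene relabeling and all-zero samples", {
  withr::with_seed(31, {
    A <- random_mutation_matrix(20, 5, prob = 0.3)
    genes <- colnames(A)
    me <- mutual_exclusivity(A, genes)
    m <- unclass(A)
    # permute samples
    mp <- m[sample(nrow(m)), , drop = FALSE]
    expect_equal(mutual_exclusivity(as_mutation_matrix(mp), genes), me)
    # relabel genes (reverse columns and rename)
    mr <- m[, rev(seq_len(ncol(m))), drop = FALSE]
    colnames(mr) <- paste0("x", seq_len(ncol(mr)))
    expect_equal(mutual_exclusivity(as_mutation_matrix(mr), colnames(mr)),
                 me)
    # add all-zero samples
    mz <- rbind(m, matrix(0L, 7, ncol(m),
                          dimnames = list(paste0("z", 1:7), colnames(m))))
    expect_equal(mutual_exclusivity(as_mutation_matrix(mz), genes), me)
  })
})

test_that("network score equals the mean unordered pairwise weight", {
  genes <- c("a", "b", "c")
  W <- sym_w(genes, list(list("a", "b", 0.6), list("a", "c", 0.3)))
  expect_equal(network_score(W, genes), (2 * 0.6 + 2 * 0.3 + 0) / 6)
  expect_equal(network_score(sym_w(genes, default = 1), genes), 1)
  expect_equal(network_score(sym_w(genes), genes), 0)
  # oracle: direct enumeration of the C(k,2) pairs on random symmetric W
  withr::with_seed(17, {
    for (rep in 1:20) {
      ids <- sprintf("g%d", 1:7)
      W <- random_correlation_matrix(ids)
      sub <- sample(ids, 4)
      pairs <- utils::combn(sub, 2)
      expect_equal(network_score(W, sub),
                   mean(apply(pairs, 2, function(p) W[p[1], p[2]])))
    }
  })
  expect_error(network_score(sym_w(c("a", "b", "c")), "a"), "at least 2")
})

test_that("gene-set score decomposes exactly into its three components", {
  Wz <- sym_w(Bgenes)
  sc <- score_gene_set(B, Wz, Bgenes)
  expect_equal(sc$total, 1 + 16 / 27 + 0, tolerance = 1e-12)
  expect_equal(sc$total, sc$coverage + sc$mutual_exclusivity + sc$network,
               tolerance = 1e-12)
  expect_identical(sort(sc$covered_samples), sort(paste0("s", 1:9)))
  # network term switched off
  sc2 <- score_gene_set(B, genes = Bgenes, use_network = FALSE)
  expect_equal(sc2$total, 1 + 16 / 27, tolerance = 1e-12)
  expect_identical(sc2$network, 0)
  g <- glance(sc)
  expect_identical(g$n_covered, 9L)
  expect_equal(g$total, sc$total)
})

test_that("baseline maximum-weight-submatrix score matches set algebra", {
  expect_identical(mwsm_weight(B, "g2"), 9L)                # single gene
  expect_identical(mwsm_weight(mm(a = 1:3, b = 4:5), c("a", "b")), 5L)
  withr::with_seed(41, {
    for (rep in 1:200) {
      A <- random_mutation_matrix(12, 6, prob = 0.3)
      sup <- supports_of(A)
      genes <- sample(colnames(A), sample(2:4, 1))
      expect_identical(mwsm_weight(A, genes),
                       as.integer(mwsm_oracle(sup, genes)))
    }
  })
})

test_that("inclusion relationships are the zero-RHD ordered pairs", {
  inc <- detect_inclusions(B)
  expect_identical(nrow(inc), 2L)
  expect_setequal(paste(inc$gene, inc$included_in),
                  c("g1 g2", "g3 g2"))
  expect_identical(nrow(detect_inclusions(mm(a = 1, b = 2, c = 3))), 0L)
  ident <- detect_inclusions(mm(a = 1:2, b = 1:2))
  expect_identical(nrow(ident), 2L)  # both orientations
})

test_that("scoring refuses genes with empty support instead of silently
           returning zero", {
  A0 <- as_mutation_matrix(matrix(c(1L, 0L, 1L, 0L, 0L, 0L), 2, 3,
          dimnames = list(c("s1", "s2"), c("a", "b", "c"))))
  expect_error(mutual_exclusivity(A0, c("a", "c")), "empty mutation support")
  expect_error(score_gene_set(A0, genes = c("a", "c"), use_network = FALSE),
               "empty mutation support")
})
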