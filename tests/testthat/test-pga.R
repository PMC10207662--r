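# Toy with exactly one feasible K=3 chromosome: genes a,b,c are mutually
# exclusive and strongly connected; d is connected to nobody, so any
# chromosome touching d dies at the connectivity constraint.
single_chain_toy <- function() {
  A <- mm(a = 1:2, b = 3:4, c = 5:6, d = 7:8)
  W <- sym_w(colnames(A), list(list("a", "b", 0.9), list("a", "c", 0.9),
                               list("b", "c", 0.9)))
  list(A = A, W = W,
       index = gene_cluster_index(A, W, mu = 0.7, nu = 0.5),
       control = pga_control(K = 3, pop_size = 2, seed = 1))
}

test_that("initialization returns the unique feasible chromosome", {
  toy <- single_chain_toy()
  # brute force: {a,b,c} is the only K=3 subset whose members are pairwise
  # eligible under mu = 0.7, nu = 0.5
  feasible <- apply(utils::combn(colnames(toy$A), 3), 2, function(g) {
    all(utils::combn(g, 2, function(p) toy$W[p[1], p[2]] >= 0.5))
  })
  expect_identical(sum(feasible), 1L)
  withr::with_seed(4, {
    for (rep in 1:10) {
      pop <- init_population(toy$A, toy$W, toy$index, toy$control)
      for (X in pop) expect_setequal(X, c("a", "b", "c"))
    }
  })
})

test_that("initialization signals failure instead of raising", {
  # identical supports: all RHD = 0, c1 empty at mu = 0.7 -> empty pool
  A <- mm(a = 1:3, b = 1:3, c = 1:3)
  W <- sym_w(colnames(A), default = 0.9)
  index <- gene_cluster_index(A, W, mu = 0.7, nu = 0.5)
  control <- pga_control(K = 3, pop_size = 2, seed = 1)
  withr::with_seed(1, {
    expect_null(init_chromosome(A, W, index, control))
    expect_error(init_population(A, W, index, control, max_retries = 5),
                 "lower mu/nu or K")
  })
})

test_that("population contract: N chromosomes of K distinct known genes", {
  withr::with_seed(8, {
    inst <- simulate_driver_instance(n_samples = 80, n_genes = 20, seed = 5)
    A <- filter_low_frequency_genes(inst$A)
    W <- inst$W[colnames(A), colnames(A)]
    control <- pga_control(K = 3, pop_size = 50, mu = 0.2, nu = 0.1,
                           seed = 1)
    index <- gene_cluster_index(A, W, mu = 0.2, nu = 0.1)
    pop <- init_population(A, W, index, control)
    expect_length(pop, 50)
    for (X in pop) {
      expect_length(X, 3)
      expect_false(anyDuplicated(X) > 0)
      expect_true(all(X %in% colnames(A)))
    }
  })
})

test_that("fitness is the gene-set objective and is a pure function", {
  B <- example_inclusion_matrix()
  expect_equal(fitness(B, genes = c("g1", "g2", "g3"), use_network = FALSE),
               1 + 16 / 27)
  W <- sym_w(colnames(B), default = 0.4)
  f1 <- fitness(B, W, c("g1", "g2", "g3"))
  expect_equal(f1, 1 + 16 / 27 + 0.4)
  expect_identical(f1, fitness(B, W, c("g3", "g2", "g1")))
})

test_that("roulette selection draws proportionally to fitness,
           elitism always keeps the best", {
  pop <- list(c("a", "b"), c("c", "d"))
  fit <- c(3, 1)
  counts <- c(0L, 0L)
  withr::with_seed(99, {
    for (i in 1:5000) {
      sel <- select_population(pop, fit, best = pop[[1]], best_fitness = 3)
      # slot 1 is the elite; slot 2 is a free roulette draw
      expect_setequal(sel$population[[1]], c("a", "b"))
      j <- if (setequal(sel$population[[2]], c("a", "b"))) 1L else 2L
      counts[j] <- counts[j] + 1L
    }
  })
  # expected 3:1; chi-squared GOF should not reject
  p <- stats::chisq.test(counts, p = c(0.75, 0.25))$p.value
  expect_gt(p, 0.001)
  # identical individuals: selection leaves the multiset unchanged
  same <- list(c("a", "b"), c("a", "b"))
  sel <- select_population(same, c(2, 2), same[[1]], 2)
  expect_identical(sel$population, same)
})

test_that("recombination is a no-op when no candidate is eligible", {
  toy <- single_chain_toy()
  X <- c("a", "b", "c")
  # with d unconnected, dropping any member leaves no eligible addition
  # except the dropped gene itself or nothing
  withr::with_seed(2, {
    for (rep in 1:20) {
      Y <- recombine(X, toy$A, toy$W, toy$index, toy$control)
      expect_setequal(Y, X)  # only {a,b,c} is feasible: unchanged
      expect_length(Y, 3)
    }
  })
  # all-zero network at nu > 0: never any eligible candidate
  Wz <- sym_w(colnames(toy$A))
  idx0 <- gene_cluster_index(toy$A, Wz, mu = 0, nu = 0.5)
  ctl <- pga_control(K = 3, pop_size = 2, nu = 0.5, mu = 0, seed = 1)
  withr::with_seed(3, {
    expect_identical(recombine(X, toy$A, Wz, idx0, ctl), X)
  })
})

test_that("greedy recombination swaps in the largest eligible support", {
  # e has the largest support and is eligible once the weak gene a leaves
  A <- mm(a = 1, b = 2:4, c = 5:7, e = 8:11)
  W <- sym_w(colnames(A), list(list("b", "c", 0.9), list("b", "e", 0.9),
                               list("c", "e", 0.9)))
  index <- gene_cluster_index(A, W, mu = 0.7, nu = 0.5)
  ctl <- pga_control(K = 3, pop_size = 2, seed = 1)
  X <- c("a", "b", "c")
  outcomes <- character(0)
  withr::with_seed(12, {
    for (rep in 1:50) {
      Y <- recombine(X, A, W, index, ctl)
      expect_length(Y, 3)
      expect_false(anyDuplicated(Y) > 0)
      outcomes <- c(outcomes, paste(sort(Y), collapse = "+"))
    }
  })
  # min-support drop (a) admits exactly e; random drop of b or c leaves the
  # pool infeasible (the remaining pair's intersection lacks an eligible
  # gene reachable at nu) or re-adds the dropped gene: X unchanged
  expect_setequal(unique(outcomes), c("b+c+e", "a+b+c"))
  expect_true(sum(outcomes == "b+c+e") > 0)
})

test_that("evolution is deterministic given a seed and monotone by elitism", {
  inst <- simulate_driver_instance(n_samples = 80, n_genes = 20, seed = 2)
  A <- filter_low_frequency_genes(inst$A)
  f1 <- find_driver_set(A, inst$W, pga_control(K = 3, seed = 42))
  f2 <- find_driver_set(A, inst$W, pga_control(K = 3, seed = 42))
  expect_identical(f1$genes, f2$genes)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$generations_run, f2$generations_run)
  expect_true(all(diff(f1$history) >= 0))
  expect_equal(f1$fitness, f1$history[length(f1$history)])
  expect_equal(f1$fitness, f1$score$total, tolerance = 1e-12)
})

test_that("maxg = 0 returns the best of the initial population", {
  inst <- simulate_driver_instance(n_samples = 80, n_genes = 20, seed = 2)
  A <- filter_low_frequency_genes(inst$A)
  f0 <- find_driver_set(A, inst$W, pga_control(K = 3, maxg = 0, seed = 7))
  expect_identical(f0$generations_run, 0L)
  expect_length(f0$history, 1)
  expect_false(f0$converged)
})

test_that("the search attains the exhaustive optimum on a small instance", {
  inst <- simulate_driver_instance(n_samples = 60, n_genes = 12, seed = 3)
  A <- filter_low_frequency_genes(inst$A)
  ex <- exhaustive_best(A, inst$W[colnames(A), colnames(A)], 3)
  hits <- sum(vapply(1:5, function(s) {
    fit <- find_driver_set(A, inst$W, pga_control(K = 3, seed = s))
    abs(fit$fitness - ex$total) < 1e-9
  }, logical(1)))
  expect_gte(hits, 4)
})

test_that("tidiers expose the trajectory and the summary row", {
  inst <- simulate_driver_instance(n_samples = 60, n_genes = 12, seed = 3)
  A <- filter_low_frequency_genes(inst$A)
  fit <- find_driver_set(A, inst$W, pga_control(K = 3, seed = 1))
  tr <- tidy(fit)
  expect_identical(tr$generation[1], 0L)
  expect_identical(nrow(tr), length(fit$history))
  g <- glance(fit)
  expect_identical(g$seed, 1L)
  expect_equal(g$total, fit$fitness)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
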