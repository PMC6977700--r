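test_that("tail transform is finite, clamped at zero, and strictly increasing", {
  expect_equal(tail_transform(0), qnorm(1e-15))
  expect_equal(tail_transform(0, clamp_eps = 1e-6), qnorm(1e-6))
  expect_true(is.finite(tail_transform(100)))
  # strictly increasing below the clamp boundary (two-sided tail > clamp_eps),
  # non-decreasing beyond it where the transform is deliberately flat
  grid <- c(0, 10^seq(-4, log10(7.5), length.out = 60))
  expect_true(all(diff(tail_transform(grid)) > 0))
  wide <- c(grid, 8.5, 10, 20)
  expect_true(all(diff(tail_transform(wide)) >= 0))
  expect_error(tail_transform(-0.1), "non-negative")
})

test_that("tail transform matches the quadrature oracle at reference points", {
  # d from p = 0.05, |log2FC| = 1 and from the worked edge example
  for (d in c(1.30103, 3.8055)) {
    expect_equal(tail_transform(d), oracle_tail_transform(d), tolerance = 1e-9)
  }
  expect_equal(tail_transform(1.30103), 0.86599, tolerance = 1e-4)
  expect_equal(tail_transform(3.8055), 3.63035, tolerance = 1e-4)
})

test_that("node score follows D = (-log10 p) * |log2FC| with monotone behavior", {
  expect_equal(node_score(0.01, 2), oracle_node_score(0.01, 2), tolerance = 1e-9)
  expect_equal(node_score(0.01, 2), 3.83282, tolerance = 1e-4)  # D = 4
  expect_equal(node_score(0.37, 0), tail_transform(0))          # D = 0
  expect_lt(node_score(0.01, 1), node_score(0.001, 1))
  expect_lt(node_score(0.01, 1), node_score(0.01, 2))
  expect_error(node_score(1.2, 1), "in \\(0, 1\\]")
  expect_error(node_score(0, 1), "in \\(0, 1\\]")
  # extreme p is floored, not infinite
  expect_true(is.finite(node_score(1e-320, 3)))
})

test_that("fisher_z equals atanh and is odd", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.549306, tolerance = 1e-6)
  expect_equal(fisher_z(-0.3), -fisher_z(0.3))
  r <- seq(-0.99, 0.99, by = 0.01)
  expect_equal(fisher_z(r), atanh(r), tolerance = 1e-12)
  expect_true(all(is.finite(fisher_z(c(-1, 1)))))
})

test_that("edge score measures co-expression change symmetrically in |xi|", {
  same <- edge_score(0.6, 0.001, 30, 0.6, 0.001, 30)
  expect_equal(same$xi, 0)
  expect_equal(same$score, tail_transform(0))

  e <- edge_score(0.5, 0.01, 28, 0.1, 0.6, 28)
  expect_equal(e$xi, -3.80548, tolerance = 1e-4)
  expect_equal(e$score, 3.63033, tolerance = 1e-4)
  ref <- oracle_edge(0.5, 0.01, 28, 0.1, 0.6, 28)
  expect_equal(e$xi, ref$xi, tolerance = 1e-10)
  expect_equal(e$score, ref$score, tolerance = 1e-9)

  swapped <- edge_score(0.1, 0.6, 28, 0.5, 0.01, 28)
  expect_equal(swapped$xi, -e$xi)
  expect_equal(swapped$score, e$score)
  expect_error(edge_score(0.5, 0.01, 3, 0.1, 0.6, 28), "more than 3")
})

test_that("combined score averages nodes and edges with weight omega", {
  expect_equal(triplet_score(c(1, 1, 1), c(2, 2, 2), omega = 0.5), 1.5)
  expect_equal(triplet_score(c(1, 2, 3), c(9, 9, 9), omega = 1), 2)
  expect_equal(triplet_score(c(1, 2, 3), c(4, 5, 6), omega = 0), 5)
  expect_error(triplet_score(c(1, 2), c(1, 2, 3)), "exactly 3")
})

test_that("a triplet with identical behavior in both states scores at the clamped floor", {
  # state2 duplicates state1's values under new sample ids: zero log2fc,
  # identical correlations, so all six components sit at tail_transform(0)
  set.seed(8)
  n <- 10L
  mk <- function(ng, prefix, cls) {
    half <- matrix(rnorm(ng * n), ng)
    m <- cbind(half, half)
    dimnames(m) <- list(paste0(prefix, seq_len(ng)),
                        c(paste0("c", 1:n), paste0("k", 1:n)))
    expression_matrix(m, cls)
  }
  expr <- list(mrna = mk(6L, "g", "mRNA"), lncrna = mk(4L, "l", "lncRNA"),
               mirna = mk(3L, "m", "miRNA"))
  cand <- data.frame(lncrna = "l1", mirna = "m1", mrna = "g1")
  sc <- score_candidates(cand, expr, paste0("c", 1:n), paste0("k", 1:n),
                         config = scoring_config(de_method = "welch"))
  expect_equal(sc$score, tail_transform(0), tolerance = 1e-8)
})

test_that("planted dysregulated triplets outrank intact ones and get small empirical p", {
  co <- tiny_cohort()
  ctrl <- group_samples(co, "control")
  case <- group_samples(co, "case")
  sc <- score_candidates(co$truth, co$expr, ctrl, case,
                         config = scoring_config(n_permutations = 500L, seed = 5L))
  sc <- permutation_pvalues(sc)
  dys <- co$truth$is_dysregulated[match(triplet_key(sc), triplet_key(co$truth))]
  expect_true(min(sc$score[dys]) > max(sc$score[!dys]))
  expect_true(all(sc$dysregulated[dys]))

  # empirical p is the strict-exceedance fraction over the shared null
  null <- attr(sc, "null_scores")
  expect_length(null, 500L)
  manual <- vapply(sc$score, function(s) mean(null > s), numeric(1L))
  expect_equal(sc$empirical_p, manual)
  expect_true(all(sc$empirical_p * 500L == round(sc$empirical_p * 500L)))

  # same seed reproduces identical p-values; flags follow perm_alpha
  sc2 <- permutation_pvalues(sc)
  expect_identical(sc2$empirical_p, sc$empirical_p)
  expect_equal(sc$dysregulated, sc$empirical_p < 0.05)
})

test_that("scoring fails loudly when a triplet gene is missing from a matrix", {
  co <- tiny_cohort()
  bad <- data.frame(lncrna = "LNC001", mirna = "MIR001", mrna = "NOT_A_GENE")
  expect_error(
    score_candidates(bad, co$expr, group_samples(co, "control"),
                     group_samples(co, "case")),
    "NOT_A_GENE"
  )
})

test_that("the traditional comparator applies SDE and correlation-loss criteria", {
  co <- tiny_cohort()  # 3 dysregulated (delta = 1), 3 intact planted triplets
  ctrl <- group_samples(co, "control")
  case <- group_samples(co, "case")
  trad <- traditional_method(co$expr, ctrl, case, co$interactions)
  dys_keys <- triplet_key(co$truth[co$truth$is_dysregulated, ])
  intact_keys <- triplet_key(co$truth[!co$truth$is_dysregulated, ])
  expect_true(all(dys_keys %in% triplet_key(trad)))
  # intact triplets keep their positive lncRNA-mRNA correlation in cases
  expect_false(any(intact_keys %in% triplet_key(trad)))

  # decoupled but unshifted members are not SDE, so criterion 1 excludes them
  co0 <- generate_cohort(n_control = 30L, n_case = 30L, n_mrna = 80L,
                         n_lncrna = 40L, n_mirna = 40L, n_triplets = 6L,
                         n_dysregulated = 3L, rho = 0.9, delta = 0,
                         sigma = 0.3, n_decoy = 150L, seed = 11L)
  trad0 <- traditional_method(co0$expr, group_samples(co0, "control"),
                              group_samples(co0, "case"), co0$interactions)
  expect_false(any(triplet_key(co0$truth) %in% triplet_key(trad0)))
})
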