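test_that("shared-miRNA hypergeometric p matches exhaustive enumeration values", {
  # universe of 10 miRNAs, 5 target each transcript, all 5 shared: 1/C(10,5)
  ints <- interaction_set(
    stats::setNames(rep(list("g1"), 5L), paste0("m", 1:5)),
    stats::setNames(rep(list("l1"), 5L), paste0("m", 1:5))
  )
  res <- shared_mirna_test("g1", "l1", ints, universe = paste0("m", 1:10))
  expect_equal(res$shared_count, 5L)
  expect_equal(res$hypergeom_p, 1 / 252, tolerance = 1e-12)

  # universe of 4, K = n = 2, one shared: 5 of the C(4,2) = 6 draws overlap
  ints2 <- interaction_set(
    list(m1 = "g1", m2 = "g1"),
    list(m2 = "l1", m3 = "l1")
  )
  res2 <- shared_mirna_test("g1", "l1", ints2, universe = paste0("m", 1:4))
  expect_equal(res2$shared_count, 1L)
  expect_equal(res2$hypergeom_p, 5 / 6, tolerance = 1e-12)

  # no shared miRNA: P(X >= 0) = 1
  ints3 <- interaction_set(list(m1 = "g1"), list(m2 = "l1"))
  res3 <- shared_mirna_test("g1", "l1", ints3, universe = paste0("m", 1:6))
  expect_equal(res3$shared_count, 0L)
  expect_equal(res3$hypergeom_p, 1)

  expect_error(shared_mirna_test("nope", "l1", ints3), "absent")
})

test_that("correlation p-values follow the t-transform and match cor.test", {
  res <- correlation_with_p(1:5, c(2, 1, 4, 3, 5))
  expect_equal(res$r, 0.8, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(0.8 * sqrt(3) / sqrt(1 - 0.64), df = 3, lower.tail = FALSE),
               tolerance = 1e-12)

  expect_equal(correlation_with_p(1:6, 2 * (1:6) + 1)$r, 1)
  expect_equal(correlation_with_p(1:6, -(1:6))$r, -1)
  expect_error(correlation_with_p(1:6, rep(2, 6)), "constant")
  expect_error(correlation_with_p(1:3, 3:1), "at least 4")

  # dual route against cor.test on random draws
  set.seed(9)
  for (i in 1:20) {
    x <- rnorm(12)
    y <- rnorm(12)
    mine <- correlation_with_p(x, y)
    ref <- cor.test(x, y)
    expect_equal(mine$r, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("a single planted triplet among noise is recovered exactly", {
  co <- generate_cohort(n_control = 30L, n_case = 10L, n_mrna = 80L,
                        n_lncrna = 40L, n_mirna = 40L, n_triplets = 1L,
                        rho = 0.9, sigma = 0.3, n_decoy = 120L, seed = 21L)
  ctrl <- group_samples(co, "control")
  cands <- find_candidates(lapply(co$expr, subset_samples, samples = ctrl),
                           co$interactions)
  expect_equal(triplet_key(cands), triplet_key(co$truth))
})

test_that("emitted candidates satisfy all sign, significance and support invariants", {
  co <- tiny_cohort()
  ctrl <- group_samples(co, "control")
  cfg <- candidate_config()
  cands <- find_candidates(lapply(co$expr, subset_samples, samples = ctrl),
                           co$interactions, cfg)
  expect_gt(nrow(cands), 0L)
  expect_true(all(cands$r_mi_m < 0 & cands$r_mi_l < 0 & cands$r_l_m > 0))
  expect_true(all(cands$p_mi_m < cfg$corr_alpha & cands$p_mi_l < cfg$corr_alpha &
                    cands$p_l_m < cfg$corr_alpha))
  expect_true(all(cands$hypergeom_p < cfg$hyper_alpha))
  expect_true(all(cands$shared_mirna_count >= 1L))
  supported <- mapply(function(mi, g, l) {
    g %in% co$interactions$mirna_to_mrna[[mi]] &&
      l %in% co$interactions$mirna_to_lncrna[[mi]]
  }, cands$mirna, cands$mrna, cands$lncrna)
  expect_true(all(supported))
})

test_that("a triplet with a negative lncRNA-mRNA correlation is rejected", {
  set.seed(5)
  n <- 24L
  L <- rnorm(n)
  samples <- paste0("s", seq_len(n))
  mk <- function(rows, cls) {
    expression_matrix(do.call(rbind, lapply(rows, function(v) {
      stats::setNames(v, samples)
    })) , cls)
  }
  noise <- function() rnorm(n, 0, 0.2)
  # second miRNA/mRNA/lncRNA give the hypergeometric test a 2-miRNA universe
  # (with a single miRNA the shared-miRNA p is identically 1)
  expr_neg <- list(
    mrna = mk(list(g1 = L + noise(), g2 = rnorm(n)), "mRNA"),
    lncrna = mk(list(l1 = -L + noise(), l2 = rnorm(n)), "lncRNA"), # anti-correlated sponge
    mirna = mk(list(m1 = -L + noise(), m2 = rnorm(n)), "miRNA")
  )
  ints <- interaction_set(list(m1 = "g1", m2 = "g2"), list(m1 = "l1", m2 = "l2"))
  # hypergeometric filter disarmed: this test isolates the sign constraints
  cfg <- candidate_config(percentile_cut = 0, hyper_alpha = 0.9999)
  expect_equal(nrow(find_candidates(expr_neg, ints, cfg)), 0L)
  # flipping the lncRNA back to the ceRNA sign pattern admits the triplet
  expr_pos <- expr_neg
  expr_pos$lncrna <- mk(list(l1 = L + noise(), l2 = rnorm(n)), "lncRNA")
  found <- find_candidates(expr_pos, ints, cfg)
  expect_equal(triplet_key(found), "l1 m1 g1")
})

test_that("raising the percentile cut never adds candidates", {
  co <- tiny_cohort()
  ctrl <- group_samples(co, "control")
  control <- lapply(co$expr, subset_samples, samples = ctrl)
  keys <- lapply(c(0, 50, 90, 99), function(pc) {
    triplet_key(find_candidates(control, co$interactions,
                                candidate_config(percentile_cut = pc)))
  })
  for (i in 2:4) expect_true(all(keys[[i]] %in% keys[[i - 1L]]))
  counts <- lengths(keys)
  expect_true(all(diff(counts) <= 0))
})
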