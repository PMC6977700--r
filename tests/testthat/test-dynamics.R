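test_that("profile standardization centers and scales rows, is idempotent", {
  m <- rbind(a = c(1, 2, 3), b = c(10, 30, 20))
  z <- standardize_profiles(m)
  expect_equal(unname(rowMeans(z)), c(0, 0))
  expect_equal(unname(apply(z, 1L, sd)), c(1, 1))
  expect_equal(z["a", ], c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(standardize_profiles(z), z)
  expect_error(standardize_profiles(rbind(a = c(1, 1, 1), b = 1:3)), "a")
  expect_error(standardize_profiles(m[, 1L, drop = FALSE]), "at least 2")
})

test_that("fuzzy c-means recovers planted trend families with valid memberships", {
  st <- tiny_staged()
  prof <- stage_means(st$expr$lncrna, st$metadata,
                      stages = c("control", paste0("S", 1:4)))
  planted <- prof[st$truth$lncrna, ]
  cl <- fuzzy_cmeans(standardize_profiles(planted), k = 2L, seed = 4L)

  expect_equal(unname(rowSums(cl$membership)), rep(1, nrow(planted)), tolerance = 1e-9)
  expect_true(all(cl$membership >= 0 & cl$membership <= 1))
  # hard labels reproduce the two planted families exactly (up to label swap)
  fam <- st$truth$family
  agreement <- max(mean(cl$hard_labels == fam), mean(cl$hard_labels == 3L - fam))
  expect_equal(agreement, 1)
  # alternating centroid/membership updates never increase the objective
  expect_true(all(diff(cl$objective) <= 1e-10))
  expect_error(fuzzy_cmeans(standardize_profiles(planted), k = 1L), "at least 2")
  expect_error(fuzzy_cmeans(standardize_profiles(planted), k = nrow(planted)),
               "more genes than clusters")
})

test_that("fuzzy c-means agrees with the e1071 reference on separated data", {
  set.seed(12)
  up <- matrix(rep(c(-1, 0, 1), each = 15L), 15L) + rnorm(45, 0, 0.05)
  down <- matrix(rep(c(1, 0, -1), each = 15L), 15L) + rnorm(45, 0, 0.05)
  m <- rbind(up, down)
  rownames(m) <- paste0("g", 1:30)
  mine <- fuzzy_cmeans(m, k = 2L, seed = 1L)
  ref <- e1071::cmeans(m, centers = 2L, m = 2)
  agreement <- max(mean(mine$hard_labels == ref$cluster),
                   mean(mine$hard_labels == 3L - ref$cluster))
  expect_equal(agreement, 1)
})

test_that("co-expression partners obey the |r| and p thresholds", {
  set.seed(6)
  n <- 40L
  samples <- paste0("s", seq_len(n))
  driver <- rnorm(n)
  vals <- rbind(
    partner1 = driver + rnorm(n, 0, 0.2),
    partner2 = -driver + rnorm(n, 0, 0.2),
    weak = 0.5 * driver + rnorm(n, 0, 1.2),
    noise1 = rnorm(n), noise2 = rnorm(n)
  )
  colnames(vals) <- samples
  mrna <- expression_matrix(vals, "mRNA")
  prof <- stats::setNames(driver, samples)
  hits <- coexpressed_partners(prof, mrna, r_cut = 0.7, p_cut = 0.01)
  expect_setequal(hits, c("partner1", "partner2"))
  # identical profile is always included (r = 1)
  vals2 <- rbind(vals, self = driver)
  colnames(vals2) <- samples
  expect_true("self" %in% coexpressed_partners(prof, expression_matrix(vals2, "mRNA")))
  expect_error(coexpressed_partners(prof[1:3], mrna), "shared samples")
})

test_that("gene-set enrichment matches exhaustive enumeration on small universes", {
  universe <- paste0("u", 1:12)
  sets <- list(setA = paste0("u", 1:5), setB = paste0("u", 9:12))
  query <- paste0("u", c(1:4, 6))
  res <- geneset_enrichment(query, sets, universe, retain_best_per_parent = FALSE)

  enum_p <- function(set, query, universe, k_obs) {
    draws <- combn(length(universe), length(query))
    hits <- apply(draws, 2L, function(ix) length(intersect(universe[ix], set)))
    mean(hits >= k_obs)
  }
  for (s in names(sets)) {
    row <- res[res$set == s, ]
    expect_equal(row$p, enum_p(sets[[s]], query, universe, row$k), tolerance = 1e-12)
  }
  # disjoint query: k = 0, upper tail is 1
  expect_equal(res$p[res$set == "setB"], 1)
  expect_equal(res$k[res$set == "setB"], 0L)
})

test_that("enrichment retains only the lowest-p sub-pathway per parent", {
  universe <- paste0("u", 1:100)
  coll <- structure(list(
    sets = list(pw1_a = paste0("u", 1:10), pw1_b = paste0("u", 1:20),
                pw2_a = paste0("u", 90:100)),
    parent = c(pw1_a = "pw1", pw1_b = "pw1", pw2_a = "pw2")
  ), class = "gene_set_collection")
  query <- paste0("u", 1:10)
  res <- geneset_enrichment(query, coll, universe)
  expect_equal(sum(res$parent == "pw1"), 1L)
  expect_equal(res$set[res$parent == "pw1"], "pw1_a")  # the tighter, lower-p subset
  expect_error(geneset_enrichment(character(), coll, universe), "empty query")
  expect_error(geneset_enrichment("zz", coll, universe), "outside the universe")
})

test_that("GMT round trip preserves sets and parent labels", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("s1\tpathwayX\tg1\tg2\tg3", "s2\t\tg2\tg4"), path)
  coll <- read_gmt(path)
  expect_equal(coll$sets$s1, c("g1", "g2", "g3"))
  expect_equal(unname(coll$parent["s1"]), "pathwayX")
  expect_equal(unname(coll$parent["s2"]), "s2")  # empty description falls back
})
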