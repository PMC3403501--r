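test_that("hypergeometric p-values match direct enumeration", {
  expect_equal(hypergeometric_pvalue(0, 5, 5, 10), 1)
  expect_equal(hypergeometric_pvalue(5, 5, 5, 10), 1 / choose(10, 5))
  expect_equal(hypergeometric_pvalue(1, 2, 2, 4), 5 / 6)

  # exhaustive agreement for every consistent configuration up to universe 12
  for (N in 2:12) for (K in 1:N) for (n in 1:N) {
    for (ov in 0:min(K, n)) {
      expect_equal(hypergeometric_pvalue(ov, K, n, N),
                   hyper_tail_enum(ov, K, n, N), tolerance = 1e-12)
    }
  }
  expect_error(hypergeometric_pvalue(3, 2, 5, 10), "inconsistent")
})

test_that("p-value decreases as the observed overlap grows", {
  p <- vapply(0:5, function(ov) hypergeometric_pvalue(ov, 8, 5, 30), 0)
  expect_true(all(diff(p) < 0))
})

make_collection <- function(n_universe = 1000, p_threshold = 1e-4,
                            max_term_size = NULL) {
  universe <- sprintf("g%04d", seq_len(n_universe))
  terms <- list(tight = universe[1:5],
                broad = universe[1:301],
                medium = universe[300:330])
  annotation_collection("functional", terms, universe,
                        p_threshold = p_threshold,
                        max_term_size = max_term_size)
}

test_that("cluster enrichment collapses exons to genes and applies the term filter", {
  coll <- make_collection(max_term_size = 300)
  # two exons of the same gene count once
  map <- c(e1 = "g0001", e2 = "g0002", e3 = "g0003", e4 = "g0004",
           e5 = "g0005", e5b = "g0005")
  cl <- fs_cluster(names(map), c("d1", "d2", "d3"), 0.5)
  res <- enrich_clusters(list(cl), map, coll)
  expect_false("broad" %in% res$term_id)         # 301 genes, filtered out
  tight <- res[res$term_id == "tight", ]
  expect_equal(tight$overlap, 5L)
  expect_equal(tight$cluster_genes, 5L)
  expect_equal(tight$p_value, 1 / choose(1000, 5))
  expect_true(tight$enriched)
  expect_true(homogeneous_clusters(res, 1))

  # unmapped exons are dropped with a warning; all-unmapped gives no result
  cl2 <- fs_cluster(c("zz1", "zz2", "zz3", "zz4", "zz5"), "d1", 0.5)
  expect_warning(res2 <- enrich_clusters(list(cl2), map, coll),
                 "without gene mapping")
  expect_equal(nrow(res2), 0)
  expect_false(homogeneous_clusters(res2, 1))
})

test_that("fold ratio reproduces the real/random percentage division", {
  expect_equal(fold_ratio(23.3, 6.0), 3.9)
  expect_equal(fold_ratio(10, 10), 1.0)
  expect_true(is.na(fold_ratio(10, 0)))

  # full baseline: tight real clusters versus random size-matched draws
  universe200 <- sprintf("g%04d", 1:200)
  coll <- annotation_collection("functional",
                                list(tight = universe200[1:5],
                                     medium = universe200[100:130]),
                                universe200, p_threshold = 1e-4)
  real_sets <- list(coll$terms$tight, coll$terms$medium[1:5])
  set.seed(99)
  out <- baseline_fold_ratio(real_sets, coll, reps = 50, seed = 2)
  expect_equal(out$pct_real, 100)
  expect_true(out$fold_defined || out$pct_random == 0)

  # clusters drawn from the random generator behave like the baseline
  universe <- coll$universe
  set.seed(11)
  rand_sets <- replicate(40, sample(universe, 5), simplify = FALSE)
  out2 <- baseline_fold_ratio(rand_sets, coll, reps = 50, seed = 3)
  if (out2$fold_defined) {
    p_hat <- out2$pct_random / 100
    se <- sqrt(p_hat * (1 - p_hat) / (40 * 50)) * 100
    expect_lt(abs(out2$pct_real - out2$pct_random),
              3 * (se + sqrt(p_hat * (1 - p_hat) / 40) * 100))
  }
  expect_error(baseline_fold_ratio(real_sets,
                                   annotation_collection("x", list(),
                                                         character(0))),
               "empty gene universe")
})

test_that("mean pairwise correlation flags co-splicing without co-expression", {
  expr <- rbind(gA = c(1, 2, 3), gB = c(1, 2, 4), gC = c(2, 4, 6))
  r <- mean_pairwise_profile_correlation(c("gA", "gB"), expr)
  expect_equal(r$mean_correlation, 0.98198, tolerance = 1e-5)
  expect_false(r$low_correlation)

  r2 <- mean_pairwise_profile_correlation(c("gA", "gC"), expr)
  expect_equal(r2$mean_correlation, 1)

  set.seed(13)
  noisy <- matrix(rnorm(5 * 30), nrow = 5,
                  dimnames = list(paste0("n", 1:5), NULL))
  r3 <- mean_pairwise_profile_correlation(rownames(noisy), noisy)
  expect_true(r3$mean_correlation <= 0.2)
  expect_true(r3$low_correlation)

  expect_error(mean_pairwise_profile_correlation("gA", expr), "at least 2")
})

test_that("multi-membership fraction requires distinct enriched-term sets", {
  cl1 <- fs_cluster(c("A", "B", "C"), c("d1", "d2", "d3"), 0.5)
  cl2 <- fs_cluster(c("A", "D", "E"), c("d1", "d2", "d3"), 0.5)
  enr_diff <- data.frame(cluster_id = c(1L, 2L),
                         term_id = c("t1", "t2"),
                         overlap = 1L, cluster_genes = 3L, term_genes = 5L,
                         universe = 100L, p_value = 1e-6,
                         enriched = TRUE)
  expect_equal(multi_membership_fraction(list(cl1, cl2), enr_diff, 3), 0.2)

  enr_same <- enr_diff
  enr_same$term_id <- "t1"
  expect_equal(multi_membership_fraction(list(cl1, cl2), enr_same, 3), 0)

  expect_equal(multi_membership_fraction(list(cl1), enr_diff, 3), 0)
  # clusters below the recurrence filter are ignored
  cl3 <- fs_cluster(c("A", "F"), c("d1"), 0.5)
  expect_equal(multi_membership_fraction(list(cl1, cl3), enr_diff, 3), 0)
})

test_that("GMT collections round-trip and validate their universe", {
  dir <- withr::local_tempdir()
  gmt <- file.path(dir, "sets.gmt")
  writeLines(c("t1\tdesc one\tg1\tg2\tg3",
               "t2\tdesc two\tg2\tg4"), gmt)
  terms <- read_gmt(gmt)
  expect_equal(names(terms), c("t1", "t2"))
  expect_equal(terms$t2, c("g2", "g4"))
  expect_error(annotation_collection("x", terms, c("g1", "g2", "g3")),
               "outside the universe")
  coll <- annotation_collection("x", terms, paste0("g", 1:5))
  expect_equal(length(coll$terms), 2)
})
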