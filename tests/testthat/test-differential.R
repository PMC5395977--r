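test_that("paired signed-rank test: exact small-sample cases", {
  # 6 pairs, all tumor higher: two-sided exact p = 2/2^6
  out <- paired_wilcoxon(rep(0, 6), c(1, 2, 3, 4, 5, 6))
  expect_equal(out$p_value, 0.03125)
  expect_equal(out$direction, "tumor-higher")
  expect_equal(out$n_pairs, 6L)
  # identical vectors: all differences zero
  same <- paired_wilcoxon(1:5, 1:5)
  expect_equal(same$p_value, 1)
  expect_true(is.na(same$direction))
  expect_equal(same$n_pairs, 0L)
  # direction from the median paired difference
  expect_equal(paired_wilcoxon(c(1, 1, 1), c(0.5, 0.2, 0.1))$direction,
               "tumor-lower")
})

test_that("paired signed-rank test agrees with the reference implementation", {
  set.seed(11)
  for (rep in 1:8) {
    n <- sample(6:40, 1)
    x <- rnorm(n)
    y <- x + rnorm(n, 0.3)
    ours <- paired_wilcoxon(x, y)$p_value
    ref <- suppressWarnings(stats::wilcox.test(
      y, x, paired = TRUE, exact = (n <= 25), correct = TRUE)$p.value)
    expect_equal(ours, ref, tolerance = 1e-12, label = paste("n =", n))
  }
  # tied data forces the corrected normal approximation on both sides
  x <- round(rnorm(30), 1)
  y <- round(x + rnorm(30, 0.2), 1)
  expect_equal(paired_wilcoxon(x, y)$p_value,
               suppressWarnings(stats::wilcox.test(
                 y, x, paired = TRUE, exact = FALSE, correct = TRUE)$p.value),
               tolerance = 1e-12)
})

test_that("Bonferroni thresholds reproduce the analytic constants", {
  expect_equal(signif(bonferroni_threshold(0.05, 11), 2), 0.0045)
  expect_equal(signif(bonferroni_threshold(0.05, 16736), 1), 3e-6)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_error(bonferroni_threshold(0.05, 0), "m must be")
})

test_that("differential scan bookkeeping and flag consistency", {
  cfg <- sim_config(n_patients = 36L, seed = 21L)   # 3 pairs x 12 cancers
  co <- simulate_cohort(cfg)
  ids <- c(co$manifest$normal_sample_id, co$manifest$tumor_sample_id)
  counts <- simulate_allele_counts(cfg, rbind(co$truth_normal, co$truth_tumor),
                                   ids)
  meth <- methylation_level(counts, cfg$sites)
  res <- differential_scan(meth, co$manifest, cfg$sites)
  expect_equal(nrow(res), 11L * 12L)
  # monotone significance
  expect_true(all(res$nominal_significant[res$bonferroni_significant]))
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
})

test_that("cross-cancer pooled test reduces to the per-cancer test for one cancer", {
  cfg <- sim_config(n_patients = 15L, cancer_labels = "ONLY", seed = 33L)
  co <- simulate_cohort(cfg)
  ids <- c(co$manifest$normal_sample_id, co$manifest$tumor_sample_id)
  counts <- simulate_allele_counts(cfg, rbind(co$truth_normal, co$truth_tumor),
                                   ids)
  meth <- methylation_level(counts, cfg$sites)
  mstd <- standardize_methylation(meth, co$manifest)
  pooled <- cross_cancer_test(mstd, co$manifest, cfg$sites)
  single <- differential_scan(mstd, co$manifest, cfg$sites,
                              level_col = "level_std")
  expect_equal(pooled$p_value, single$p_value)
  expect_equal(pooled$n_pairs, single$n_pairs)
})

test_that("Ward clustering: identical rows merge first; cophenetic matches brute force", {
  m <- rbind(a = c(0, 0, 0), b = c(0, 0, 0.001), c = c(5, 5, 5))
  cl <- cluster_groups(m)
  merge1 <- cl$row_hclust$merge[1, ]
  expect_setequal(abs(merge1), c(1, 2))
  # 5 x 3 oracle comparison on the full cophenetic matrix
  set.seed(44)
  m2 <- matrix(rnorm(15), 5, 3)
  rownames(m2) <- letters[1:5]
  colnames(m2) <- LETTERS[1:3]
  cl2 <- cluster_groups(m2)
  got <- as.matrix(stats::cophenetic(cl2$row_hclust))
  want <- brute_ward_cophenetic(m2)
  dimnames(want) <- dimnames(got)
  expect_equal(got, want, tolerance = 1e-10)
  # missing cells imputed and reported
  m3 <- m2
  m3[2, 3] <- NA
  cl3 <- cluster_groups(m3)
  expect_equal(unname(cl3$imputed[, "col"]), 3L)
  expect_error(cluster_groups(m2[1, , drop = FALSE]), "at least 2")
})

test_that("DE scan: F equals squared t for two groups; planted shift detected", {
  set.seed(55)
  labels <- rep(c("normal", "tumor"), each = 25)
  expr <- matrix(rnorm(20 * 50), 20, 50,
                 dimnames = list(sprintf("g%02d", 1:20), NULL))
  expr[1, labels == "tumor"] <- expr[1, labels == "tumor"] + 2
  de <- de_scan(expr, labels)
  tt <- vapply(1:20, function(g) {
    unname(stats::t.test(expr[g, labels == "tumor"],
                         expr[g, labels == "normal"],
                         var.equal = TRUE)$statistic^2)
  }, numeric(1))
  expect_equal(de$F, tt, tolerance = 1e-10)
  expect_true(de$bonferroni_significant[1])
  expect_equal(sign(de$delta_log2[1]), 1)
  # equal group means: F = 0, p = 1
  de0 <- de_scan(matrix(rep(1:25, 2), 1, 50,
                        dimnames = list("g", NULL)), labels)
  expect_lt(de0$F, 1e-20)
  expect_equal(de0$p_value, 1)
  expect_error(de_scan(expr[, 1:26], labels[1:26]), ">= 2 samples")
})
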