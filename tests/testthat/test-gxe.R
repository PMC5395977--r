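test_that("exact HWE test: analytic cases and permutation oracle", {
  expect_equal(hwe_exact_p(25, 50, 25), 1)
  expect_lt(hwe_exact_p(50, 0, 50), 1e-20)
  expect_true(hwe_filter(25, 50, 25))
  expect_false(hwe_filter(50, 0, 50))
  expect_error(hwe_exact_p(0, 0, 0), "all-missing")
  # independent Monte-Carlo oracle on n = 30: permute the 2n alleles into
  # pairs and use the heterozygote-count null distribution
  counts <- c(hom_major = 18L, het = 7L, hom_minor = 5L)
  n_minor <- 2L * counts[[3]] + counts[[2]]
  alleles <- c(rep(1L, n_minor), rep(0L, 60L - n_minor))
  set.seed(71)
  reps <- 20000L
  hets <- vapply(seq_len(reps), function(i) {
    a <- sample(alleles)
    sum(a[seq(1, 59, 2)] != a[seq(2, 60, 2)])
  }, integer(1))
  null_tab <- table(hets) / reps
  p_obs <- null_tab[as.character(counts[[2]])]
  mc_p <- sum(null_tab[null_tab <= p_obs * (1 + 1e-9)])
  exact <- hwe_exact_p(counts[[1]], counts[[2]], counts[[3]])
  expect_lt(abs(exact - mc_p), 4 * sqrt(mc_p * (1 - mc_p) / reps) + 0.005)
})

test_that("dominant recode pools minor homozygotes with heterozygotes", {
  expect_equal(dominant_recode(c(0L, 1L, 2L, NA)), c(0L, 1L, 1L, NA))
  expect_equal(dominant_recode(rep(0L, 4)), rep(0L, 4))
  # idempotent
  x <- c(0L, 1L, 2L, NA, 2L)
  expect_equal(dominant_recode(dominant_recode(x)), dominant_recode(x))
  expect_error(dominant_recode(c(0L, 3L)), "0, 1, 2 or missing")
})

test_that("eligibility gates: MAF, completeness, carrier count", {
  calls60 <- c(rep(0L, 52), rep(1L, 7), 2L)   # MAF = 9/120 = 0.075
  ok <- snp_eligibility(calls60, rep(TRUE, 60))
  expect_true(ok$keep)
  # 39 complete individuals
  few <- snp_eligibility(calls60[1:39], rep(TRUE, 39))
  expect_false(few$keep)
  expect_equal(few$reason, "min_n")
  # 4 carriers
  carriers4 <- snp_eligibility(c(rep(0L, 56), rep(1L, 4)), rep(TRUE, 60))
  expect_false(carriers4$keep)
  expect_true(carriers4$reason %in% c("carriers", "maf"))
  low_maf <- snp_eligibility(c(rep(0L, 55), rep(1L, 5)), rep(TRUE, 60))
  expect_false(low_maf$keep)
  expect_equal(low_maf$reason, "maf")
})

test_that("interaction z: worked example and degenerate cases", {
  wz <- gxe_z(0, 0.5, 1, 0.5)
  expect_equal(wz$z, 1 / sqrt(0.5), tolerance = 1e-4)
  expect_equal(round(wz$z, 4), 1.4142)
  expect_equal(wz$p_value, 2 * pnorm(-1 / sqrt(0.5)), tolerance = 1e-12)
  expect_equal(round(wz$p_value, 3), 0.157)
  # identical per-state data: z = 0, p = 1
  set.seed(72)
  y <- rnorm(50)
  g <- rbinom(50, 1L, 0.3)
  same <- gxe_test(y, y, g)
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)
  # zero genotype variance: NA, not a crash
  degen <- gxe_test(y, y + 1, rep(0L, 50))
  expect_true(is.na(degen$z))
})

test_that("per-state OLS matches lm, and planted effects are recovered", {
  set.seed(73)
  n <- 100L
  g <- rbinom(n, 1L, 0.4)
  yn <- rnorm(n, 0, 0.05)
  yt <- 0.1 + 0.15 * g + rnorm(n, 0, 0.05)
  gt <- gxe_test(yn, yt, g)
  fit <- stats::lm(yt ~ g)
  expect_equal(gt$beta_tumor, unname(coef(fit)[2]), tolerance = 1e-10)
  expect_equal(gt$se_tumor,
               unname(summary(fit)$coefficients[2, 2]), tolerance = 1e-10)
  expect_lt(gt$p_value, 1e-8)
  expect_gt(gt$z, 0)
})

test_that("quality masking, HWE and MAF filters commute on the scan path", {
  set.seed(74)
  cfg <- sim_config(n_patients = 120L, cancer_labels = "A", n_snps = 40L,
                    seed = 74L)
  geno <- simulate_genotypes(cfg)
  masked <- apply_quality_filter(geno$calls, geno$quality, 0.1)
  trait_ok <- rep(TRUE, ncol(masked))
  elig_then_hwe <- vapply(seq_len(nrow(masked)), function(s) {
    cs <- masked[s, ]
    el <- snp_eligibility(cs, trait_ok)
    cs <- cs[!is.na(cs)]
    el$keep && hwe_filter(sum(cs == 0), sum(cs == 1), sum(cs == 2))
  }, logical(1))
  hwe_then_elig <- vapply(seq_len(nrow(masked)), function(s) {
    cs <- masked[s, ]
    csc <- cs[!is.na(cs)]
    hwe_filter(sum(csc == 0), sum(csc == 1), sum(csc == 2)) &&
      snp_eligibility(cs, trait_ok)$keep
  }, logical(1))
  expect_identical(elig_then_hwe, hwe_then_elig)
})

test_that("replication table: planted shared effects replicate, empty hits give empty output", {
  cfg <- sim_config(n_patients = 160L, cancer_labels = c("CA", "CB"),
                    n_snps = 60L, theta_sd = 0.03,
                    planted_gxe = data.frame(snp_index = 1L,
                                             site_id = "p9_10413",
                                             beta_tumor = 0.2),
                    seed = 75L)
  co <- simulate_cohort(cfg)
  scan <- gxe_scan(co$genotype_calls, co$genotype_quality, co$truth_normal,
                   co$truth_tumor, co$manifest$cancer_type)
  hits <- scan[scan$genomewide_significant, , drop = FALSE]
  expect_true(any(hits$snp_id == "snp00001"))
  rep_tab <- replicate_hits(hits[hits$snp_id == "snp00001", ][1, ], scan)
  # effect planted in both synthetic cancers: replicates in the other one
  other <- rep_tab[rep_tab$site_id == "p9_10413", ]
  expect_true(any(other$replicated))
  # empty hit list
  empty <- replicate_hits(hits[0, ], scan)
  expect_equal(nrow(empty), 0L)
  expect_true("replicated" %in% names(empty))
})
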