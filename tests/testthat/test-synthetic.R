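test_that("configuration validation rejects impossible rates", {
  expect_error(sim_config(theta_normal = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(theta_normal = 0.99, delta_tumor = 0.05),
               "theta_normal \\+ delta_tumor")
  expect_error(sim_config(maf_range = c(0, 0.5)), "\\(0, 0.5\\]")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "\\(0, 0.5\\]")
  expect_error(sim_config(censor_months = -5), "non-negative")
  expect_error(simulate_reads(sim_config(), "s", "neither"))
  expect_error(simulate_reads(sim_config(), "s", "tumor", theta = rep(2, 11)),
               "\\[0, 1\\]")
})

test_that("identical config and seed reproduce outputs exactly", {
  cfg <- sim_config(n_patients = 4L, cancer_labels = "A", n_snps = 12L,
                    seed = 91L)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  expect_identical(simulate_reads(cfg, "S1", "tumor"),
                   simulate_reads(cfg, "S1", "tumor"))
  co <- simulate_cohort(cfg)
  expect_identical(
    simulate_allele_counts(cfg, co$truth_normal, co$manifest$patient_id),
    simulate_allele_counts(cfg, co$truth_normal, co$manifest$patient_id))
  # substreams are independent: a different sample's reads differ
  expect_false(identical(simulate_reads(cfg, "S1", "tumor"),
                         simulate_reads(cfg, "S2", "tumor")))
})

test_that("observed mismatch fraction matches the binomial expectation", {
  # theta = 0.3, seq error 1e-3, deep fixed-ish coverage
  cfg <- sim_config(n_patients = 1L, cancer_labels = "A",
                    sites = p9_sites()[1, , drop = FALSE],
                    theta_normal = 0.3, delta_tumor = 0,
                    coverage_mean = 1000, coverage_dispersion = 1e6,
                    seed = 92L)
  aln <- simulate_reads(cfg, "S1", "normal")
  kept <- filter_reads(aln)$kept
  cnt <- count_alleles(kept, cfg$sites, "S1")
  lev <- methylation_level(cnt, cfg$sites)$level
  expected <- 0.3 + (1 - 0.3) * 1e-3
  expect_lt(abs(lev - expected),
            3 * sqrt(expected * (1 - expected) / cnt$depth))
  # zero case: theta = 0, seq_error = 0 -> exactly 0
  cfg0 <- sim_config(n_patients = 1L, cancer_labels = "A",
                     sites = p9_sites()[1, , drop = FALSE],
                     theta_normal = 0, delta_tumor = 0, seq_error = 0,
                     coverage_mean = 500, seed = 93L)
  aln0 <- simulate_reads(cfg0, "S1", "normal")
  cnt0 <- count_alleles(filter_reads(aln0)$kept, cfg0$sites, "S1")
  expect_equal(methylation_level(cnt0, cfg0$sites)$level, 0)
})

test_that("decoy reads violate exactly the intended ingest filters", {
  cfg <- sim_config(n_patients = 1L, cancer_labels = "A", seed = 94L)
  aln <- simulate_reads(cfg, "S1", "normal")
  reasons <- filter_read(aln)
  expect_true(all(c("pairing", "mapq") %in% reasons))
  rej <- table(reasons[reasons != "keep"])
  # one decoy class per filter, approximately decoy_fraction each
  expect_equal(unname(rej["pairing"]), unname(rej["mapq"]))
})

test_that("genotypes follow HWE proportions and planted effects are tumor-only", {
  cfg <- sim_config(n_patients = 10000L, cancer_labels = "A", n_snps = 1L,
                    maf_range = c(0.2, 0.2), seed = 95L)
  geno <- simulate_genotypes(cfg)
  freq <- as.vector(table(factor(geno$calls[1, ], levels = 0:2))) / 10000
  hwe <- c(0.64, 0.32, 0.04)
  se <- sqrt(hwe * (1 - hwe) / 10000)
  expect_true(all(abs(freq - hwe) < 3 * se))
  expect_error(sim_config(maf_range = c(0, 0)), "\\(0, 0.5\\]")
  # planted dominant effect: tumor-only mean shift for carriers
  cfg2 <- sim_config(n_patients = 400L, cancer_labels = "A", n_snps = 10L,
                     theta_sd = 0.02,
                     planted_gxe = data.frame(snp_index = 3L,
                                              site_id = "p9_1610",
                                              beta_tumor = 0.05),
                     seed = 96L)
  co <- simulate_cohort(cfg2)
  carrier <- co$genotype_calls[3L, ] >= 1L
  dt <- mean(co$truth_tumor[carrier, "p9_1610"]) -
    mean(co$truth_tumor[!carrier, "p9_1610"])
  dn <- mean(co$truth_normal[carrier, "p9_1610"]) -
    mean(co$truth_normal[!carrier, "p9_1610"])
  expect_lt(abs(dt - 0.05), 0.01)
  expect_lt(abs(dn), 0.01)
})

test_that("expression coupling exists in normal samples and vanishes in tumors", {
  cfg <- sim_config(n_patients = 200L, cancer_labels = "A", n_genes = 6L,
                    expr_coupling = c(0.9, 0, 0, 0, 0, 0), seed = 97L)
  meth <- with_seed(1L, runif(400, 0.1, 0.7))
  state <- rep(c("normal", "tumor"), each = 200L)
  ex <- simulate_expression(cfg, meth, state, paste0("x", 1:400))
  norm_cols <- state == "normal"
  rho_n <- cor(meth[norm_cols], ex$counts[1, norm_cols], method = "spearman")
  rho_t <- cor(meth[!norm_cols], ex$counts[1, !norm_cols], method = "spearman")
  expect_gt(rho_n, 0.6)
  expect_lt(abs(rho_t), 0.2)
  # uncoupled gene: null in both states
  rho0 <- cor(meth[norm_cols], ex$counts[2, norm_cols], method = "spearman")
  expect_lt(abs(rho0), 0.2)
  # counts and lengths emitted for the TPM stage
  expect_true(all(ex$counts >= 0))
  expect_true(all(ex$gene_models$length > 0))
  expect_setequal(unique(ex$gene_models$compartment), c("nuclear", "mito"))
})

test_that("survival generator recovers the planted log-hazard", {
  # parameter recovery across replicates (scaled-down version; the
  # acceptance suite runs 200 replicates at n = 500)
  hits <- vapply(1:40, function(r) {
    cfg <- sim_config(n_patients = 250L, cancer_labels = "A",
                      survival_gamma = log(2), seed = 1000L + r)
    delta <- with_seed(2000L + r, rnorm(250, 0, 0.5))
    rec <- simulate_survival(cfg, delta, sprintf("P%04d", 1:250))
    fit <- cox_continuous(rec)
    abs(fit$coef - log(2)) <= 1.96 * fit$se
  }, logical(1))
  expect_gte(mean(hits), 0.85)
})
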