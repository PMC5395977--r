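sites <- p9_sites()

test_that("cleavage rate is exact on constructed terminus tables", {
  s <- sites[1, ]                      # heavy strand, p9 585, boundary 576
  cpos <- cleavage_position(s)
  tt <- data.frame(sample_id = "x",
                   position = c(cpos, cpos + 1L),
                   n_start = c(0L, 5L), n_end = c(25L, 0L),
                   n_cover = c(100L, 99L), stringsAsFactors = FALSE)
  expect_equal(cleavage_rate(tt, s), 0.30)
  # no termini near the boundary
  tt0 <- data.frame(sample_id = "x", position = cpos, n_start = 0L,
                    n_end = 0L, n_cover = 50L)
  expect_equal(cleavage_rate(tt0, s), 0)
  # zero coverage: undefined
  ttna <- data.frame(sample_id = "x", position = cpos, n_start = 0L,
                     n_end = 0L, n_cover = 0L)
  expect_true(is.na(cleavage_rate(ttna, s)))
  # control is the same computation 9 bases further upstream
  c2 <- cleavage_position(s, control = TRUE)
  tt$position <- c(c2, c2 + 1L)
  expect_equal(cleavage_control(tt, s), 0.30)
})

test_that("light-strand cleavage mirrors a reflected heavy-strand construction", {
  heavy <- sites[sites$strand == "+", ][1, ]
  light <- sites[sites$strand == "-", ][1, ]
  # 30 reads ending at the heavy boundary, 10 starting just 3' of it,
  # 60 spanning reads covering the boundary without terminating there
  ch <- cleavage_position(heavy)
  aln_h <- rbind(make_aln(rep(ch - 19L, 30L)),               # end at ch
                 make_aln(rep(ch + 1L, 10L)),                # start at ch+1
                 make_aln(rep(ch - 10L, 60L)))
  th <- count_termini(aln_h, c(ch, ch + 1L), "h")
  # mirrored: reads starting at the light boundary, ending just 3' of it
  cl <- cleavage_position(light)
  aln_l <- rbind(make_aln(rep(cl, 30L)),                     # start at cl
                 make_aln(rep(cl - 1L - 19L, 10L)),          # end at cl-1
                 make_aln(rep(cl - 10L, 60L)))
  tl <- count_termini(aln_l, c(cl, cl - 1L), "l")
  rh <- cleavage_rate(th, heavy)
  rl <- cleavage_rate(tl, light)
  expect_equal(rh, rl)
  expect_gt(rh, 0)
})

test_that("tRNA expression is the span mean of mito-normalized coverage", {
  expect_equal(trna_expression(rep(600, 69), 1:69, 1e6), 6e-4)
  # scale invariance
  expect_equal(trna_expression(rep(1200, 69), 1:69, 2e6), 6e-4)
  # naive per-position oracle
  set.seed(31)
  cov <- sample(100:900, 200, replace = TRUE)
  span <- 41:110
  expect_equal(trna_expression(cov, span, 5e5),
               mean(vapply(span, function(p) cov[p] / 5e5, numeric(1))))
  expect_error(trna_expression(cov, integer(), 1e6), "empty")
  expect_error(trna_expression(cov, span, 0), "positive")
})

test_that("TPM uses the compartment-specific library term", {
  counts <- rbind(nuc1 = c(100, 100), nuc2 = c(900, 900),
                  mt1 = c(500, 500), mt2 = c(500, 1500))
  models <- data.frame(gene_id = rownames(counts),
                       length = c(1000, 2000, 1000, 1000),
                       compartment = c("nuclear", "nuclear", "mito", "mito"))
  tp <- tpm(counts, models)
  lib <- colSums(counts)
  mito_lib <- colSums(counts[3:4, ])
  expect_equal(tp["nuc1", 1], 1e6 * (100 / 1000) / lib[1], ignore_attr = TRUE)
  expect_equal(tp["mt1", 1], 1e6 * (500 / 1000) / mito_lib[1],
               ignore_attr = TRUE)
  # worked example: count 100, length 1 kb, L = 1e6 -> 0.1
  one <- tpm(matrix(c(100, 1e6 - 100), 2, 1),
             data.frame(gene_id = c("g", "rest"), length = c(1000, 1000),
                        compartment = "nuclear"))
  expect_equal(one[1, 1], 0.1)
  # zero count -> 0
  expect_equal(tpm(matrix(c(0, 10), 2, 1),
                   data.frame(gene_id = c("a", "b"), length = c(1000, 1000),
                              compartment = "nuclear"))[1, 1], 0)
  # mito TPM invariant to nuclear library depth
  counts2 <- counts
  counts2[1, ] <- counts2[1, ] * 10
  tp2 <- tpm(counts2, models)
  expect_equal(tp2[3:4, ], tp[3:4, ])
  expect_false(isTRUE(all.equal(tp2[2, ], tp[2, ])))
  expect_error(tpm(counts * 0, models), "zero library")
})

test_that("log-median normalization zeroes sample medians and is idempotent", {
  m <- cbind(s1 = c(1, 10, 100))
  out <- log_median_normalize(m, pseudocount = 0)
  expect_equal(as.vector(out), c(-1, 0, 1))
  # all-equal sample
  expect_true(all(log_median_normalize(cbind(rep(7, 5))) == 0))
  set.seed(5)
  m2 <- matrix(rexp(60, 0.1), 12, 5)
  n1 <- log_median_normalize(m2)
  expect_true(all(abs(apply(n1, 2, median)) < 1e-12))
  # reapplying the median step changes nothing
  n2 <- sweep(n1, 2, apply(n1, 2, median), "-")
  expect_equal(n1, n2)
})

test_that("PCA outlier filter removes planted outliers and their pair-mates", {
  set.seed(17)
  man <- tiny_manifest(5L)           # 10 patients, 20 samples
  ids <- c(man$normal_sample_id, man$tumor_sample_id)
  m <- matrix(rnorm(50 * 20), 50, 20, dimnames = list(NULL, ids))
  # no outliers: identity
  res0 <- pca_outlier_filter(m, man)
  expect_setequal(res0$retained, ids)
  # plant an extreme sample far out on the leading component
  m2 <- m
  m2[, "P03_T"] <- m2[, "P03_T"] + 30
  res <- pca_outlier_filter(m2, man)
  expect_true(all(c("P03_T", "P03_N") %in% res$removed$sample_id))
  expect_false("P03_T" %in% res$retained)
  expect_false("P03_N" %in% res$retained)
  expect_identical(
    res$removed$reason[res$removed$sample_id == "P03_N"],
    "paired_with_outlier")
  expect_error(pca_outlier_filter(m[, 1:3], man), "at least 4")
})
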