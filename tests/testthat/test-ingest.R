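test_that("read filter keeps proper high-MAPQ reads and codes rejections", {
  base <- make_aln(rep(100L, 6))
  base$flag <- c(99L, 99L + 256L, 65L, 99L + 1024L, 99L + 2048L, 99L + 4L)
  base$mapq <- c(60L, 60L, 60L, 60L, 60L, 60L)
  expect_identical(filter_read(base),
                   c("keep", "secondary", "pairing", "duplicate",
                     "supplementary", "unmapped"))
  low <- make_aln(100L, mapq = 10L)
  expect_identical(filter_read(low), "mapq")
  expect_identical(filter_read(low, min_mapq = 5L), "keep")
  # flag precedence and option toggles
  dup <- make_aln(100L, flag = 99L + 1024L)
  expect_identical(filter_read(dup, drop_duplicates = FALSE), "keep")
  improper <- make_aln(100L, flag = 65L)
  expect_identical(filter_read(improper, require_proper_pair = FALSE), "keep")
  # malformed record rejected, never a crash
  bad <- make_aln(100L)
  bad$mapq <- NA_integer_
  expect_identical(filter_read(bad), "malformed")
})

test_that("allele counting is exact on constructed reads", {
  s <- p9_sites()[1, ]  # position 585
  p <- s$position
  aln <- make_aln(rep(p - 5L, 4))
  tmp <- aln$seq
  substr(tmp[1:3], 6L, 6L) <- "G"
  substr(tmp[4], 6L, 6L) <- "A"
  aln$seq <- tmp
  cnt <- count_alleles(aln, s, "x")
  expect_equal(cnt$count_G, 3L)
  expect_equal(cnt$count_A, 1L)
  expect_equal(cnt$depth, 4L)
  # base below quality threshold is excluded
  q <- aln$qual
  substr(q[1], 6L, 6L) <- "#"
  aln$qual <- q
  cnt2 <- count_alleles(aln, s, "x")
  expect_equal(cnt2$count_G, 2L)
  expect_equal(cnt2$depth, 3L)
  # empty input
  cnt0 <- count_alleles(aln[0, ], s, "x")
  expect_equal(cnt0$depth, 0L)
})

test_that("allele counting equals the naive per-read oracle on random reads", {
  set.seed(401)
  s <- p9_sites()[3, ]
  p <- s$position
  n <- 100L
  starts <- p - sample(0:29, n, replace = TRUE)
  cig <- sample(c("30M", "5S25M", "10M3D20M", "12M2I16M"), n, replace = TRUE)
  qlen <- ifelse(cig == "30M", 30L, ifelse(cig == "5S25M", 30L,
                 ifelse(cig == "10M3D20M", 30L, 30L)))
  refstr <- mt_reference(as_string = TRUE)
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), qlen[i], replace = TRUE),
          collapse = "")
  }, character(1))
  quals <- vapply(seq_len(n), function(i) {
    paste(sample(c("#", "5", "I"), qlen[i], replace = TRUE,
                 prob = c(0.1, 0.2, 0.7)), collapse = "")
  }, character(1))
  aln <- make_aln(starts, cigar = cig, seq = seqs, qual = quals)
  got <- count_alleles(aln, s, "x", min_base_quality = 13L)
  want <- naive_count_oracle(aln, p, min_baseq = 13L)
  expect_equal(c(A = got$count_A, C = got$count_C, G = got$count_G,
                 T = got$count_T), want)
  expect_equal(got$depth, sum(want))
})

test_that("filters are monotone: stricter thresholds never raise counts", {
  set.seed(402)
  cfg <- sim_config(n_patients = 2L, cancer_labels = "A", seed = 9L)
  aln <- simulate_reads(cfg, "S1", "tumor")
  tot <- function(min_mapq, min_bq) {
    kept <- filter_reads(aln, min_mapq = min_mapq)$kept
    sum(count_alleles(kept, cfg$sites, "S1", min_base_quality = min_bq)$depth)
  }
  d0 <- tot(0L, 0L)
  d1 <- tot(30L, 0L)
  d2 <- tot(30L, 13L)
  d3 <- tot(61L, 13L)
  expect_true(d0 >= d1 && d1 >= d2 && d2 >= d3)
  expect_equal(d3, 0L)  # nothing exceeds MAPQ 60
})

test_that("terminus counting matches naive enumeration", {
  p <- 1000L
  aln <- make_aln(rep(p, 10L), len = 20L)
  tt <- count_termini(aln, c(p, p + 5L), "x")
  expect_equal(tt$n_start, c(10L, 0L))
  expect_equal(tt$n_cover, c(10L, 10L))
  # spanning read covers but contributes no terminus at interior positions
  span <- make_aln(p - 5L, len = 11L)  # [p-5, p+5]
  tt2 <- count_termini(span, p, "x")
  expect_equal(tt2$n_start, 0L)
  expect_equal(tt2$n_end, 0L)
  expect_equal(tt2$n_cover, 1L)
  # soft clips do not count as aligned termini
  sc <- make_aln(p, cigar = "5S15M", seq = strrep("A", 20L))
  tt3 <- count_termini(sc, c(p, p + 14L), "x")
  expect_equal(tt3$n_start, c(1L, 0L))
  expect_equal(tt3$n_end, c(0L, 1L))
  # brute force on random reads
  set.seed(403)
  starts <- sample(900:1100, 100L, replace = TRUE)
  lens <- sample(10:40, 100L, replace = TRUE)
  rnd <- make_aln(starts, cigar = paste0(lens, "M"),
                  seq = vapply(lens, function(l) strrep("A", l), character(1)))
  pos <- 950:1050
  got <- count_termini(rnd, pos, "x")
  ends <- starts + lens - 1L
  expect_equal(got$n_start, vapply(pos, function(q) sum(starts == q), integer(1)))
  expect_equal(got$n_end, vapply(pos, function(q) sum(ends == q), integer(1)))
  expect_equal(got$n_cover,
               vapply(pos, function(q) sum(starts <= q & ends >= q), integer(1)))
  expect_error(count_termini(rnd, 10^7), "beyond contig")
})
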