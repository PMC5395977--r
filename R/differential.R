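# Paired tumor-normal differential testing, multiplicity control, Ward
# clustering of group means, and the mtRNA-binding-protein DE scan.

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test of tumor versus normal levels. Zero paired
#' differences are dropped before ranking (the signed-rank convention);
#' with `n <= exact_max` untied differences the exact null distribution is
#' used, otherwise the normal approximation with tie correction and
#' continuity correction. Direction is the sign of the median paired
#' difference.
#'
#' @param normal,tumor equal-length paired vectors; pairs with a missing
#'   member are dropped.
#' @param exact_max largest n for the exact distribution (default 25).
#' @return list `p_value`, `direction` ("tumor-higher"/"tumor-lower"/NA),
#'   `n_pairs` (after zero-difference removal), `statistic` (V, the
#'   positive-rank sum).
#' @export
paired_wilcoxon <- function(normal, tumor, exact_max = 25L) {
  stopifnot(length(normal) == length(tumor))
  ok <- stats::complete.cases(normal, tumor)
  d <- tumor[ok] - normal[ok]
  med <- stats::median(d)
  direction <- if (length(d) == 0L || med == 0) NA_character_
               else if (med > 0) "tumor-higher" else "tumor-lower"
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(p_value = 1, direction = NA_character_, n_pairs = 0L,
                statistic = NA_real_))
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- anyDuplicated(r) > 0L
  if (n <= exact_max && !ties) {
    p <- 2 * min(stats::psignrank(V, n),
                 stats::psignrank(V - 1, n, lower.tail = FALSE))
    p <- min(1, p)
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(p_value = p, direction = direction, n_pairs = n, statistic = V)
}

#' Bonferroni threshold
#'
#' @param alpha family-wise error rate.
#' @param m number of tests.
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (m < 1L) stop("m must be >= 1")
  alpha / m
}

#' Per-(site, cancer) paired differential scan
#'
#' One paired Wilcoxon signed-rank test per site within each cancer type,
#' pairing each patient's normal and tumor levels; pairs missing either
#' member (e.g. below-coverage records) are dropped at that site. The
#' Bonferroni flag is at `alpha / (sites tested within the cancer)`.
#'
#' @param meth methylation data.frame (`sample_id`, `site_id`, `level`).
#' @param manifest pairing manifest.
#' @param sites site table (defines the per-cancer family size).
#' @param alpha significance level (default 0.05).
#' @param level_col column of `meth` holding the level to test.
#' @return data.frame, one row per site x cancer: `n_pairs`, `direction`,
#'   `p_value`, `nominal_significant`, `bonferroni_significant`.
#' @export
differential_scan <- function(meth, manifest, sites = p9_sites(),
                              alpha = 0.05, level_col = "level") {
  sites <- validate_sites(sites)
  m_sites <- nrow(sites)
  rows <- list()
  for (cancer in unique(manifest$cancer_type)) {
    man <- manifest[manifest$cancer_type == cancer, , drop = FALSE]
    for (i in seq_len(m_sites)) {
      sid <- sites$site_id[i]
      ms <- meth[meth$site_id == sid, , drop = FALSE]
      lev <- stats::setNames(ms[[level_col]], ms$sample_id)
      nl <- lev[man$normal_sample_id]
      tl <- lev[man$tumor_sample_id]
      w <- paired_wilcoxon(nl, tl)
      rows[[length(rows) + 1L]] <- data.frame(
        site_id = sid, cancer_type = cancer, n_pairs = w$n_pairs,
        direction = if (is.na(w$direction)) NA_character_ else w$direction,
        p_value = w$p_value, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$nominal_significant <- out$p_value < alpha
  out$bonferroni_significant <- out$p_value < bonferroni_threshold(alpha, m_sites)
  out
}

#' Cross-cancer combined paired test on standardized levels
#'
#' After per-(site, cancer) standardization, pools pairs from all cancers
#' and runs a single paired Wilcoxon per site, Bonferroni-corrected over
#' the number of sites.
#'
#' @param meth_std standardized methylation table
#'   ([standardize_methylation()] output, `level_std` column).
#' @param manifest pairing manifest.
#' @param sites site table.
#' @param alpha significance level.
#' @return data.frame, one row per site.
#' @export
cross_cancer_test <- function(meth_std, manifest, sites = p9_sites(),
                              alpha = 0.05) {
  sites <- validate_sites(sites)
  pooled <- manifest
  pooled$cancer_type <- "ALL"
  out <- differential_scan(meth_std, pooled, sites, alpha,
                           level_col = "level_std")
  out$cancer_type <- NULL
  out
}

#' Two-way Ward clustering of group-mean methylation
#'
#' Agglomerative clustering (Ward linkage on Euclidean distance,
#' `hclust(method = "ward.D2")`) of rows and columns independently.
#' Missing cells are imputed as the column mean and reported. `hclust`'s
#' deterministic merge order (lowest index first among ties) fixes the
#' dendrogram.
#'
#' @param mat groups x sites numeric matrix (e.g. mean standardized level
#'   per cancer-state group).
#' @return list `row_hclust`, `col_hclust`, `row_order`, `col_order`,
#'   `imputed` (row/column indices of imputed cells).
#' @export
cluster_groups <- function(mat) {
  if (nrow(mat) < 2L) stop("need at least 2 rows to cluster")
  imputed <- which(is.na(mat), arr.ind = TRUE)
  if (nrow(imputed)) {
    cm <- colMeans(mat, na.rm = TRUE)
    mat[imputed] <- cm[imputed[, 2L]]
  }
  rh <- stats::hclust(stats::dist(mat), method = "ward.D2")
  ch <- stats::hclust(stats::dist(t(mat)), method = "ward.D2")
  list(row_hclust = rh, col_hclust = ch,
       row_order = rownames(mat)[rh$order],
       col_order = colnames(mat)[ch$order],
       imputed = imputed)
}

#' Differential-expression scan by one-way ANOVA
#'
#' Per gene, a one-way ANOVA of (normalized, log-scale) expression on
#' sample-type labels, with the mean difference on the input scale
#' rescaled to log2 units for volcano-plot coordinates. Genes with zero
#' within-group variance are reported with NA p rather than crashing.
#'
#' @param expr gene x sample matrix (log10-scale normalized expression).
#' @param labels per-sample group labels (2+ groups, 2+ samples each).
#' @param alpha significance level for the Bonferroni flag (over genes).
#' @return data.frame `gene_id`, `delta_log2` (group 2 minus group 1 mean,
#'   log2 units, for 2 groups), `F`, `p_value`, `bonferroni_significant`.
#' @export
de_scan <- function(expr, labels, alpha = 0.05) {
  labels <- as.factor(labels)
  if (nlevels(labels) < 2L || any(table(labels) < 2L)) {
    stop("need >= 2 samples per group")
  }
  k <- nlevels(labels)
  n <- ncol(expr)
  gm <- vapply(levels(labels), function(l)
    rowMeans(expr[, labels == l, drop = FALSE]), numeric(nrow(expr)))
  gm <- matrix(gm, nrow(expr), k)   # guard the single-gene case
  ng <- as.integer(table(labels))
  grand <- rowMeans(expr)
  ssb <- as.vector((gm - grand)^2 %*% ng)
  ssw <- numeric(nrow(expr))
  for (l in seq_len(k)) {
    dev <- expr[, labels == levels(labels)[l], drop = FALSE] - gm[, l]
    ssw <- ssw + rowSums(dev^2)
  }
  Fv <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- stats::pf(Fv, k - 1, n - k, lower.tail = FALSE)
  p[ssw == 0] <- NA_real_
  delta <- if (k == 2L) (gm[, 2L] - gm[, 1L]) * log2(10) else NA_real_
  data.frame(gene_id = rownames(expr), delta_log2 = delta, F = Fv,
             p_value = p,
             bonferroni_significant = !is.na(p) &
               p < bonferroni_threshold(alpha, nrow(expr)),
             stringsAsFactors = FALSE)
}
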