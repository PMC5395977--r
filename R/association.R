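# Spearman correlation scans and Fisher-exact gene-set enrichment.

#' Spearman rank correlation with a t-approximation p-value
#'
#' Tie-corrected rank correlation (Pearson correlation of mid-ranks) with
#' a two-sided p-value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`. Constant inputs give NA.
#'
#' @param x,y numeric vectors; incomplete pairs are dropped.
#' @return list `rho`, `p_value`, `n`.
#' @export
spearman_test <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3L || length(unique(x)) < 2L || length(unique(y)) < 2L) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

#' Methylation-expression Spearman scan
#'
#' Rank correlation of each p9 site's methylation against each gene's
#' expression, normal and tumor samples scanned separately. The Bonferroni
#' flag divides `alpha` by the number of attempted tests per scan (one
#' scan = one state); NA results (constant inputs) stay in the
#' denominator, conservatively.
#'
#' @param meth site x sample methylation matrix (NA allowed).
#' @param expr gene x sample matrix, columns matching `meth`.
#' @param state per-sample "normal"/"tumor" labels.
#' @param alpha family-wise error rate.
#' @return data.frame per (site, gene, state): `rho`, `p_value`, `n`,
#'   `m_tests`, `bonferroni_significant`.
#' @export
spearman_scan <- function(meth, expr, state, alpha = 0.05) {
  stopifnot(ncol(meth) == ncol(expr), ncol(expr) == length(state))
  if (!all(state %in% c("normal", "tumor"))) stop("invalid state label")
  out <- list()
  for (st in c("normal", "tumor")) {
    cols <- state == st
    if (!any(cols)) next
    m_tests <- nrow(meth) * nrow(expr)
    thr <- bonferroni_threshold(alpha, m_tests)
    for (i in seq_len(nrow(meth))) {
      mv <- meth[i, cols]
      res <- vapply(seq_len(nrow(expr)), function(g) {
        r <- spearman_test(mv, expr[g, cols])
        c(r$rho, r$p_value, r$n)
      }, numeric(3))
      out[[length(out) + 1L]] <- data.frame(
        site_id = rownames(meth)[i], gene_id = rownames(expr),
        state = st, rho = res[1, ], p_value = res[2, ], n = as.integer(res[3, ]),
        m_tests = m_tests,
        bonferroni_significant = !is.na(res[2, ]) & res[2, ] < thr,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Methylation versus cleavage (and control) correlation
#'
#' Per site and cancer, Spearman correlation of methylation with the 5'
#' cleavage rate and, separately, with the control rate 9 bases further
#' upstream, over pooled normal and tumor samples. Only (site, cancer)
#' cells with at least `min_individuals` samples having both measures are
#' tested.
#'
#' @param meth methylation data.frame with `sample_id`, `site_id`, `level`,
#'   `cancer_type`.
#' @param cleav cleavage table ([cleavage_table()] shape) with cancer
#'   resolved by the caller or via `sample_id` join on `meth`.
#' @param alpha family-wise error rate (over tested comparisons, per
#'   metric).
#' @param min_individuals cohort filter (default 20).
#' @return data.frame per (site, cancer, metric in cleavage/control).
#' @export
methylation_vs_cleavage <- function(meth, cleav, alpha = 0.05,
                                    min_individuals = 20L) {
  key <- paste(meth$sample_id, meth$site_id)
  ckey <- paste(cleav$sample_id, cleav$site_id)
  i <- match(key, ckey)
  meth$cleavage <- cleav$cleavage[i]
  meth$control <- cleav$control[i]
  groups <- split(meth, interaction(meth$site_id, meth$cancer_type,
                                    drop = TRUE))
  rows <- list()
  for (g in groups) {
    for (metric in c("cleavage", "control")) {
      ok <- stats::complete.cases(g$level, g[[metric]])
      if (sum(ok) < min_individuals) next
      st <- spearman_test(g$level[ok], g[[metric]][ok])
      rows[[length(rows) + 1L]] <- data.frame(
        site_id = g$site_id[1], cancer_type = g$cancer_type[1],
        metric = metric, rho = st$rho, p_value = st$p_value, n = st$n,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  for (metric in c("cleavage", "control")) {
    sel <- out$metric == metric
    m <- sum(sel)
    out$bonferroni_significant[sel] <- !is.na(out$p_value[sel]) &
      out$p_value[sel] < bonferroni_threshold(alpha, max(1L, m))
  }
  rownames(out) <- NULL
  out
}

#' Right-tailed Fisher exact (hypergeometric) gene-set enrichment
#'
#' Probability of observing at least the given overlap between the focus
#' genes and the gene set by chance from the reference, plus fold
#' enrichment.
#'
#' @param n_focus number of focus genes (e.g. genes associated with a p9
#'   site).
#' @param n_set number of genes annotated to the process.
#' @param n_overlap focus genes inside the set.
#' @param n_reference size of the reference gene universe.
#' @return list `p_value`, `fold_enrichment`, counts echoed back.
#' @export
fisher_enrichment <- function(n_focus, n_set, n_overlap, n_reference) {
  if (n_focus < 1L || n_set < 1L) stop("empty focus or gene set")
  if (n_set > n_reference || n_focus > n_reference ||
      n_overlap > min(n_focus, n_set)) {
    stop("inconsistent counts: sets must be subsets of the reference")
  }
  p <- stats::phyper(n_overlap - 1L, n_set, n_reference - n_set, n_focus,
                     lower.tail = FALSE)
  fold <- (n_overlap / n_focus) / (n_set / n_reference)
  list(p_value = p, fold_enrichment = fold, n_focus = n_focus,
       n_set = n_set, n_overlap = n_overlap, n_reference = n_reference)
}

#' Enrichment of focus genes across a gene-set collection
#'
#' @param focus_genes character vector of focus gene ids.
#' @param gene_sets named list of character vectors.
#' @param reference character vector: the gene universe.
#' @return data.frame per set: overlap, p, fold enrichment.
#' @export
enrichment_scan <- function(focus_genes, gene_sets, reference) {
  focus_genes <- intersect(focus_genes, reference)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], reference)
    k <- length(intersect(focus_genes, set))
    fe <- fisher_enrichment(length(focus_genes), length(set), k,
                            length(reference))
    data.frame(gene_set = nm, n_set = fe$n_set, n_overlap = fe$n_overlap,
               p_value = fe$p_value, fold_enrichment = fe$fold_enrichment,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
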