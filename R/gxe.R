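# Genotype-by-disease-state interaction testing on p9 methylation.

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact two-sided HWE p-value: the probability, conditional on the allele
#' counts, of heterozygote counts no more likely than the observed one
#' (the standard SNP exact test). Probabilities are computed directly from
#' the log-factorial formula for every admissible heterozygote count.
#'
#' @param n_hom_major,n_het,n_hom_minor genotype counts.
#' @return p-value.
#' @export
hwe_exact_p <- function(n_hom_major, n_het, n_hom_minor) {
  n <- n_hom_major + n_het + n_hom_minor
  if (n == 0L) stop("all-missing SNP: no genotype calls")
  n_minor <- 2L * n_hom_minor + n_het
  hets <- seq(n_minor %% 2L, min(n_minor, 2L * n - n_minor), by = 2L)
  logp <- vapply(hets, function(h) {
    a <- (n_minor - h) / 2L   # minor homozygotes
    b <- n - (h + a)          # major homozygotes
    lgamma(n + 1) - lgamma(a + 1) - lgamma(h + 1) - lgamma(b + 1) +
      h * log(2) + lgamma(n_minor + 1) + lgamma(2 * n - n_minor + 1) -
      lgamma(2 * n + 1)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_het, hets)]
  sum(pr[pr <= p_obs * (1 + 1e-12)])
}

#' Hardy-Weinberg filter
#'
#' @param n_hom_major,n_het,n_hom_minor genotype counts (pre dominant
#'   recode; the recode destroys the het/hom distinction).
#' @param p_cut drop SNPs with exact HWE p at or below this (default 0.001).
#' @return TRUE to keep, FALSE to drop.
#' @export
hwe_filter <- function(n_hom_major, n_het, n_hom_minor, p_cut = 0.001) {
  hwe_exact_p(n_hom_major, n_het, n_hom_minor) > p_cut
}

#' Dominant-model recode
#'
#' Pools minor-allele homozygotes with heterozygotes: 0 -> 0, 1 -> 1,
#' 2 -> 1, missing stays missing. Idempotent.
#'
#' @param calls integer vector in \{0, 1, 2, NA\}.
#' @return carrier indicator in \{0, 1, NA\}.
#' @export
dominant_recode <- function(calls) {
  if (any(!is.na(calls) & !(calls %in% 0:2))) {
    stop("genotype calls must be 0, 1, 2 or missing")
  }
  pmin(calls, 1L)
}

#' SNP eligibility gates
#'
#' A SNP enters the interaction scan iff its minor allele frequency is at
#' least `min_maf`, at least `min_n` individuals have both genotype and
#' trait data, and at least `min_carriers` of them carry a minor allele.
#'
#' @param calls original calls (0/1/2/NA) for one SNP.
#' @param trait_available logical: individual has methylation data.
#' @param min_maf,min_n,min_carriers thresholds (defaults 0.05, 40, 5).
#' @return list `keep` (logical) and `reason` ("ok", "maf", "min_n",
#'   "carriers").
#' @export
snp_eligibility <- function(calls, trait_available, min_maf = 0.05,
                            min_n = 40L, min_carriers = 5L) {
  ok <- !is.na(calls) & trait_available
  n <- sum(ok)
  if (n < min_n) return(list(keep = FALSE, reason = "min_n"))
  maf <- sum(calls[ok]) / (2 * n)
  maf <- min(maf, 1 - maf)
  if (maf < min_maf) return(list(keep = FALSE, reason = "maf"))
  carriers <- sum(dominant_recode(calls[ok]) == 1L)
  if (carriers < min_carriers) return(list(keep = FALSE, reason = "carriers"))
  list(keep = TRUE, reason = "ok")
}

#' Interaction z from per-state regression coefficients
#'
#' `z = (beta_tumor - beta_normal) / sqrt(se_tumor^2 + se_normal^2)` with a
#' two-sided standard-normal p.
#'
#' @param beta_normal,se_normal,beta_tumor,se_tumor per-state OLS slope and
#'   standard error.
#' @return list `z`, `p_value`.
#' @export
gxe_z <- function(beta_normal, se_normal, beta_tumor, se_tumor) {
  z <- (beta_tumor - beta_normal) / sqrt(se_tumor^2 + se_normal^2)
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

# OLS of y on x (simple regression), closed form.
ols_fit <- function(y, x) {
  ok <- stats::complete.cases(y, x)
  y <- y[ok]
  x <- x[ok]
  n <- length(y)
  vx <- sum((x - mean(x))^2)
  if (n < 3L || vx == 0) {
    return(list(beta = NA_real_, se = NA_real_, n = n))
  }
  beta <- sum((x - mean(x)) * (y - mean(y))) / vx
  res <- (y - mean(y)) - beta * (x - mean(x))
  s2 <- sum(res^2) / (n - 2)
  list(beta = beta, se = sqrt(s2 / vx), n = n)
}

#' Genotype-by-disease-state interaction test for one SNP and one site
#'
#' Ordinary least squares of the methylation level on carrier status,
#' separately in normal and in tumor samples of the same individuals; the
#' two slopes are compared with [gxe_z()].
#'
#' @param trait_normal,trait_tumor per-individual methylation levels.
#' @param carrier dominant-model carrier indicator per individual.
#' @return list `beta_normal`, `se_normal`, `beta_tumor`, `se_tumor`, `n`,
#'   `z`, `p_value`. Zero trait or genotype variance in a state yields NA.
#' @export
gxe_test <- function(trait_normal, trait_tumor, carrier) {
  stopifnot(length(trait_normal) == length(carrier),
            length(trait_tumor) == length(carrier))
  fn <- ols_fit(trait_normal, carrier)
  ft <- ols_fit(trait_tumor, carrier)
  n <- min(fn$n, ft$n)
  if (is.na(fn$beta) || is.na(ft$beta) ||
      (fn$se == 0 && ft$se == 0)) {
    if (!is.na(fn$beta) && !is.na(ft$beta) && fn$beta == ft$beta) {
      return(list(beta_normal = fn$beta, se_normal = fn$se,
                  beta_tumor = ft$beta, se_tumor = ft$se, n = n,
                  z = 0, p_value = 1))
    }
    return(list(beta_normal = fn$beta, se_normal = fn$se,
                beta_tumor = ft$beta, se_tumor = ft$se, n = n,
                z = NA_real_, p_value = NA_real_))
  }
  gz <- gxe_z(fn$beta, fn$se, ft$beta, ft$se)
  list(beta_normal = fn$beta, se_normal = fn$se,
       beta_tumor = ft$beta, se_tumor = ft$se, n = n,
       z = gz$z, p_value = gz$p_value)
}

# Quality mask: calls with quality below the threshold become missing.
apply_quality_filter <- function(calls, quality, min_quality = 0.1) {
  calls[quality < min_quality] <- NA_integer_
  calls
}

#' Genome-wide interaction scan
#'
#' For each cancer type, each p9 site and each SNP: mask low-quality
#' calls, drop SNPs out of HWE, recode to the dominant model, apply the
#' eligibility gates, then run [gxe_test()]. The genome-wide significance
#' threshold defaults to `alpha` Bonferroni-corrected by the number of
#' tests actually run.
#'
#' @param calls SNP x patient genotype matrix (0/1/2/NA).
#' @param quality SNP x patient call-quality matrix.
#' @param meth_normal,meth_tumor patient x site methylation matrices (NA
#'   where undefined).
#' @param cancer per-patient cancer label.
#' @param alpha family-wise error rate.
#' @param min_quality,hwe_p,min_maf,min_n,min_carriers filter thresholds.
#' @return data.frame sorted by p: one row per tested (snp, site, cancer)
#'   with per-state betas/SEs, z, p and `genomewide_significant`.
#' @export
gxe_scan <- function(calls, quality, meth_normal, meth_tumor, cancer,
                     alpha = 0.05, min_quality = 0.1, hwe_p = 0.001,
                     min_maf = 0.05, min_n = 40L, min_carriers = 5L) {
  stopifnot(ncol(calls) == nrow(meth_normal),
            nrow(meth_normal) == nrow(meth_tumor),
            length(cancer) == ncol(calls))
  calls <- apply_quality_filter(calls, quality, min_quality)
  rows <- list()
  for (ca in unique(cancer)) {
    sel <- cancer == ca
    sub <- calls[, sel, drop = FALSE]
    mn <- meth_normal[sel, , drop = FALSE]
    mt <- meth_tumor[sel, , drop = FALSE]
    hwe_keep <- vapply(seq_len(nrow(sub)), function(s) {
      cs <- sub[s, ]
      cs <- cs[!is.na(cs)]
      if (!length(cs)) return(FALSE)
      hwe_filter(sum(cs == 0L), sum(cs == 1L), sum(cs == 2L), hwe_p)
    }, logical(1))
    for (j in seq_len(ncol(mn))) {
      trait_ok <- !is.na(mn[, j]) & !is.na(mt[, j])
      for (s in which(hwe_keep)) {
        el <- snp_eligibility(sub[s, ], trait_ok, min_maf, min_n, min_carriers)
        if (!el$keep) next
        carrier <- dominant_recode(sub[s, ])
        carrier[!trait_ok] <- NA_integer_
        gt <- gxe_test(mn[, j], mt[, j], carrier)
        rows[[length(rows) + 1L]] <- data.frame(
          snp_id = rownames(calls)[s], site_id = colnames(mn)[j],
          cancer_type = ca, n = gt$n,
          beta_normal = gt$beta_normal, se_normal = gt$se_normal,
          beta_tumor = gt$beta_tumor, se_tumor = gt$se_tumor,
          z = gt$z, p_value = gt$p_value, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(snp_id = character(), site_id = character(),
                      cancer_type = character(), n = integer(),
                      beta_normal = numeric(), se_normal = numeric(),
                      beta_tumor = numeric(), se_tumor = numeric(),
                      z = numeric(), p_value = numeric(),
                      genomewide_significant = logical(),
                      stringsAsFactors = FALSE))
  }
  m <- sum(!is.na(out$p_value))
  thr <- bonferroni_threshold(alpha, max(1L, m))
  out$genomewide_significant <- !is.na(out$p_value) & out$p_value < thr
  out[order(out$p_value), , drop = FALSE]
}

#' Replication of interaction hits in other cancers and sites
#'
#' Reruns [gxe_test()] for each discovery SNP against every other
#' (cancer, site) combination that meets the same eligibility criteria,
#' flagging replications at `alpha_rep` (default 0.001).
#'
#' @param hits data.frame of discovery rows (`snp_id`, `site_id`,
#'   `cancer_type`).
#' @param scan full [gxe_scan()] output to search for replication rows.
#' @param alpha_rep replication threshold.
#' @return data.frame of replication attempts with `replicated` flag;
#'   empty hits give an empty table.
#' @export
replicate_hits <- function(hits, scan, alpha_rep = 0.001) {
  out <- list()
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    cand <- scan[scan$snp_id == h$snp_id &
                   !(scan$cancer_type == h$cancer_type &
                       scan$site_id == h$site_id), , drop = FALSE]
    if (!nrow(cand)) next
    cand$discovery_cancer <- h$cancer_type
    cand$discovery_site <- h$site_id
    cand$replicated <- !is.na(cand$p_value) & cand$p_value < alpha_rep
    out[[length(out) + 1L]] <- cand
  }
  if (!length(out)) {
    out <- scan[0, , drop = FALSE]
    out$discovery_cancer <- character(0)
    out$discovery_site <- character(0)
    out$replicated <- logical(0)
    return(out)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Leave-one-out fragility check for an interaction hit
#'
#' Automated stand-in for visual outlier inspection: a hit is fragile if
#' removing any single individual drops its -log10 p by more than half.
#'
#' @param trait_normal,trait_tumor,carrier as in [gxe_test()].
#' @return list `fragile` (logical), `worst_p` (largest leave-one-out p),
#'   `p_full`.
#' @export
gxe_fragility <- function(trait_normal, trait_tumor, carrier) {
  full <- gxe_test(trait_normal, trait_tumor, carrier)
  if (is.na(full$p_value)) return(list(fragile = NA, worst_p = NA_real_,
                                       p_full = NA_real_))
  lp_full <- -log10(full$p_value)
  worst <- full$p_value
  for (i in seq_along(carrier)) {
    g <- gxe_test(trait_normal[-i], trait_tumor[-i], carrier[-i])
    if (!is.na(g$p_value) && g$p_value > worst) worst <- g$p_value
  }
  list(fragile = (-log10(worst)) < lp_full / 2, worst_p = worst,
       p_full = full$p_value)
}
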