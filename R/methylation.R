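# p9 methylation levels: non-reference proportion, coverage gating,
# coverage-matched resampling, per-(site, cancer) standardization, and
# confounder scans.

#' Methylation levels from allele counts
#'
#' The p9 methylation level is the proportion of non-reference alleles,
#' `1 - count_ref / depth`, defined only where depth is at least
#' `min_coverage` (default 20x). Low-coverage records are dropped, not
#' zeroed: a pair missing either member is excluded from paired
#' comparisons at that site.
#'
#' @param counts allele-count data.frame ([count_alleles()] shape).
#' @param sites site table providing each site's reference allele.
#' @param min_coverage minimum depth for a defined level.
#' @return data.frame `sample_id`, `site_id`, `level`, `depth`; rows below
#'   coverage are omitted.
#' @export
methylation_level <- function(counts, sites, min_coverage = 20L) {
  sites <- validate_sites(sites)
  if (min_coverage < 1L) stop("min_coverage must be >= 1")
  i <- match(counts$site_id, sites$site_id)
  if (any(is.na(i))) stop("unknown site_id in counts")
  refcol <- paste0("count_", sites$ref_allele[i])
  ref_n <- as.integer(counts[cbind(seq_len(nrow(counts)),
                                   match(refcol, names(counts)))])
  depth <- counts$depth
  keep <- depth >= min_coverage
  data.frame(sample_id = counts$sample_id[keep],
             site_id = counts$site_id[keep],
             level = 1 - ref_n[keep] / depth[keep],
             depth = depth[keep], stringsAsFactors = FALSE)
}

# Multivariate hypergeometric draw: sample `size` items without
# replacement from categories with counts `k`.
rmultihyper <- function(k, size) {
  out <- integer(length(k))
  remaining <- sum(k)
  for (i in seq_along(k)) {
    if (size == 0L) break
    if (i == length(k)) {
      out[i] <- size
      break
    }
    out[i] <- stats::rhyper(1L, k[i], remaining - k[i], size)
    size <- size - out[i]
    remaining <- remaining - k[i]
  }
  out
}

#' Coverage-matched resampling of a normal/tumor record pair
#'
#' Downsamples the deeper record's base multiset without replacement
#' (multivariate hypergeometric) to the lower of the two depths, so paired
#' comparisons are free of coverage bias. The shallower record is returned
#' unchanged; equal depths are an identity.
#'
#' @param rec_normal,rec_tumor single-row allele-count data.frames.
#' @param seed seed for the hypergeometric draw.
#' @return list with `normal` and `tumor` resampled records.
#' @export
resample_matched <- function(rec_normal, rec_tumor, seed = 1L) {
  cols <- paste0("count_", c("A", "C", "G", "T"))
  dN <- rec_normal$depth
  dT <- rec_tumor$depth
  if (dN == 0L || dT == 0L) stop("cannot resample a zero-depth record")
  d <- min(dN, dT)
  shrink <- function(rec) {
    if (rec$depth == d) return(rec)
    k <- as.integer(rec[1, cols])
    nk <- rmultihyper(k, d)
    rec[1, cols] <- as.list(nk)
    rec$depth <- sum(nk)
    rec
  }
  with_seed(seed, list(normal = shrink(rec_normal), tumor = shrink(rec_tumor)))
}

#' Standardize levels by the pooled per-site maximum
#'
#' Divides each value by the maximum observed across the pooled normal and
#' tumor samples (per site, per cancer), putting sites and cancers on a
#' common \[0,1\] scale while preserving within-group variation. The
#' maximum maps to exactly 1.
#'
#' @param values numeric vector of levels for one site within one cancer,
#'   normal and tumor pooled.
#' @return standardized values.
#' @export
standardize <- function(values) {
  m <- max(values, na.rm = TRUE)
  if (!is.finite(m) || m <= 0) stop("standardization undefined: no positive value")
  values / m
}

#' Standardize a methylation table per (site, cancer)
#'
#' @param meth methylation data.frame ([methylation_level()] shape).
#' @param manifest sample-pairing manifest with `normal_sample_id`,
#'   `tumor_sample_id`, `cancer_type`.
#' @return `meth` with an added `level_std` column and a `cancer_type`
#'   column resolved from the manifest.
#' @export
standardize_methylation <- function(meth, manifest) {
  map <- sample_state_map(manifest)
  i <- match(meth$sample_id, map$sample_id)
  if (any(is.na(i))) stop("sample not in manifest: ",
                          paste(unique(meth$sample_id[is.na(i)])[1], "..."))
  meth$cancer_type <- map$cancer_type[i]
  meth$state <- map$state[i]
  key <- interaction(meth$site_id, meth$cancer_type, drop = TRUE)
  meth$level_std <- unsplit(lapply(split(meth$level, key), standardize), key)
  meth
}

# Long sample -> (patient, cancer, state) map from a pairing manifest.
sample_state_map <- function(manifest) {
  data.frame(
    sample_id = c(manifest$normal_sample_id, manifest$tumor_sample_id),
    patient_id = rep(manifest$patient_id, 2L),
    cancer_type = rep(manifest$cancer_type, 2L),
    state = rep(c("normal", "tumor"), each = nrow(manifest)),
    stringsAsFactors = FALSE)
}

#' Scan candidate confounders against methylation change
#'
#' Spearman rank correlation of per-patient tumor-normal methylation change
#' against a covariate (tumor purity, stromal or lymphocyte fraction, age,
#' sex, ...), per site and cancer, with a Bonferroni flag over the whole
#' family of comparisons. Constant covariates give NA rho (reported, and
#' counted in the family size).
#'
#' @param delta data.frame `patient_id`, `site_id`, `cancer_type`, `delta`.
#' @param covariate data.frame `patient_id`, `value`.
#' @param covariate_name label for the output.
#' @param alpha family-wise error rate.
#' @return data.frame per (site, cancer): `rho`, `p_value`, `n`,
#'   `bonferroni_significant`.
#' @export
confound_scan <- function(delta, covariate, covariate_name = "covariate",
                          alpha = 0.05) {
  delta$value <- covariate$value[match(delta$patient_id, covariate$patient_id)]
  groups <- split(delta, interaction(delta$site_id, delta$cancer_type,
                                     drop = TRUE))
  rows <- lapply(groups, function(g) {
    ok <- stats::complete.cases(g$delta, g$value)
    n <- sum(ok)
    if (n < 3L || length(unique(g$value[ok])) < 2L ||
        length(unique(g$delta[ok])) < 2L) {
      return(data.frame(site_id = g$site_id[1], cancer_type = g$cancer_type[1],
                        covariate = covariate_name, rho = NA_real_,
                        p_value = NA_real_, n = n, stringsAsFactors = FALSE))
    }
    st <- spearman_test(g$delta[ok], g$value[ok])
    data.frame(site_id = g$site_id[1], cancer_type = g$cancer_type[1],
               covariate = covariate_name, rho = st$rho, p_value = st$p_value,
               n = n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  m <- nrow(out)
  out$bonferroni_significant <- !is.na(out$p_value) & out$p_value < alpha / m
  out
}
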