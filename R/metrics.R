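# RNA metrics: tRNA 5' cleavage rates, tRNA expression, mitochondria-aware
# TPM, log/median normalization, PCA outlier removal.

#' tRNA 5' cleavage rate at a p9 site
#'
#' The cleavage boundary sits 9 bases upstream (in tRNA orientation) of the
#' p9 site, between position `c` and the base immediately 3' of it. The
#' rate is the number of reads terminating on either side of that boundary
#' (ending at `c` plus starting at the abutting base, both in tRNA
#' orientation) over the number of reads covering `c`. All "upstream"
#' arithmetic uses the site's strand: for heavy-strand (+) sites
#' `c = position - 9`, for light-strand (-) sites `c = position + 9` with
#' mirrored terminus roles.
#'
#' @param termini terminus data.frame ([count_termini()] shape) for one
#'   sample.
#' @param site single-row site table entry.
#' @param control use the control boundary a further 9 bases upstream.
#' @return proportion, or NA when the boundary position has no coverage.
#' @export
cleavage_rate <- function(termini, site, control = FALSE) {
  cpos <- cleavage_position(site, control = control)
  at <- function(p, col) {
    v <- termini[[col]][termini$position == p]
    if (length(v)) v[1] else 0L
  }
  cover <- at(cpos, "n_cover")
  if (cover == 0L) return(NA_real_)
  num <- if (site$strand == "+") {
    at(cpos, "n_end") + at(cpos + 1L, "n_start")
  } else {
    at(cpos, "n_start") + at(cpos - 1L, "n_end")
  }
  num / cover
}

#' Control cleavage rate 9 bases further upstream
#'
#' Identical computation at the boundary shifted a further 9 bases upstream
#' in tRNA orientation; used as the null comparison for the cleavage
#' statistic.
#'
#' @inheritParams cleavage_rate
#' @return proportion or NA.
#' @export
cleavage_control <- function(termini, site) {
  cleavage_rate(termini, site, control = TRUE)
}

#' Cleavage and control rates for all samples and sites
#'
#' @param termini terminus table for many samples (`sample_id` column).
#' @param sites site table.
#' @return data.frame `sample_id`, `site_id`, `cleavage`, `control`.
#' @export
cleavage_table <- function(termini, sites) {
  sites <- validate_sites(sites)
  per_sample <- split(termini, termini$sample_id)
  rows <- lapply(names(per_sample), function(sid) {
    tt <- per_sample[[sid]]
    data.frame(sample_id = sid, site_id = sites$site_id,
               cleavage = vapply(seq_len(nrow(sites)), function(i)
                 cleavage_rate(tt, sites[i, ]), numeric(1)),
               control = vapply(seq_len(nrow(sites)), function(i)
                 cleavage_control(tt, sites[i, ]), numeric(1)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' tRNA expression from per-position coverage
#'
#' Per-position coverage divided by the total number of reads mapping to
#' the mitochondria, averaged over the tRNA's span.
#'
#' @param coverage numeric vector of per-position coverage indexed by
#'   genomic position (i.e. `coverage[p]` is depth at position p), or a
#'   vector covering exactly the span.
#' @param span integer positions of the tRNA (e.g. `start:end`).
#' @param mito_total_reads total reads mapping to the mitochondria.
#' @return mean normalized coverage.
#' @export
trna_expression <- function(coverage, span, mito_total_reads) {
  if (!length(span)) stop("empty tRNA span")
  if (mito_total_reads <= 0) stop("mito_total_reads must be positive")
  cov <- if (length(coverage) >= max(span)) coverage[span] else coverage
  if (length(cov) != length(span)) stop("coverage does not cover the span")
  mean(cov / mito_total_reads)
}

#' Transcripts per million with a mitochondria-specific library term
#'
#' `tpm_g = 1e6 * (count_g / length_g) / L_g`, where `L_g` is the total
#' number of fragments mapping to the mitochondrial transcriptome for
#' mitochondrial genes and the total library size for nuclear genes. Using
#' the mitochondrial total for mito genes removes copy-number and
#' polycistronic transcription-rate differences, so mito values are
#' invariant to nuclear library depth. `classic = TRUE` instead rescales
#' length-normalized rates to sum to 1e6 within each compartment.
#'
#' @param counts gene x sample count matrix.
#' @param gene_models data.frame `gene_id`, `length`, `compartment`
#'   ("mito"/"nuclear"), rows matching `counts`.
#' @param classic use the classic sum-to-a-million TPM within compartment.
#' @return gene x sample TPM matrix.
#' @export
tpm <- function(counts, gene_models, classic = FALSE) {
  stopifnot(nrow(counts) == nrow(gene_models))
  if (any(gene_models$length <= 0)) stop("gene lengths must be positive")
  if (any(counts < 0)) stop("negative counts")
  mito <- gene_models$compartment == "mito"
  rate <- counts / gene_models$length
  if (classic) {
    out <- counts * 0
    for (cmp in list(mito, !mito)) {
      if (!any(cmp)) next
      denom <- colSums(rate[cmp, , drop = FALSE])
      if (any(denom == 0)) stop("zero library size")
      out[cmp, ] <- sweep(rate[cmp, , drop = FALSE], 2L, denom, "/") * 1e6
    }
    return(out)
  }
  lib_total <- colSums(counts)
  lib_mito <- colSums(counts[mito, , drop = FALSE])
  if (any(lib_total == 0) || (any(mito) && any(lib_mito == 0))) {
    stop("zero library size")
  }
  L <- ifelse(mito, 1, 0) %o% lib_mito + ifelse(mito, 0, 1) %o% lib_total
  1e6 * rate / L
}

#' log10 transform and per-sample median normalization
#'
#' Entries become `log10(x + pseudocount)`; each sample's median is then
#' subtracted, so every sample median is exactly 0. The median step is
#' idempotent.
#'
#' @param mat gene x sample matrix of non-negative values.
#' @param pseudocount added before the log (default 1).
#' @return normalized matrix.
#' @export
log_median_normalize <- function(mat, pseudocount = 1) {
  if (any(mat < 0)) stop("negative values")
  lg <- log10(mat + pseudocount)
  sweep(lg, 2L, apply(lg, 2L, stats::median), "-")
}

#' PCA-based outlier removal with paired propagation
#'
#' PCA on samples (centered, unscaled); any sample whose score is more
#' than `sd_cut` standard deviations from the mean on any of the first
#' `n_pc` components is flagged, and the flagged sample's pair-mate is
#' removed with it.
#'
#' @param mat gene x sample matrix (normalized expression).
#' @param manifest pairing manifest (normal/tumor sample ids).
#' @param n_pc number of leading components to inspect (default 3).
#' @param sd_cut flagging threshold in SDs (default 3).
#' @return list with `retained` (sample ids), `removed` data.frame
#'   (`sample_id`, `reason`).
#' @export
pca_outlier_filter <- function(mat, manifest, n_pc = 3L, sd_cut = 3) {
  n <- ncol(mat)
  if (n < 4L) stop("need at least 4 samples for PCA outlier screening")
  n_pc <- min(n_pc, n - 1L)
  pc <- stats::prcomp(t(mat), center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(n_pc), drop = FALSE]
  zs <- sweep(sweep(scores, 2L, colMeans(scores), "-"), 2L,
              apply(scores, 2L, stats::sd), "/")
  flagged <- colnames(mat)[apply(abs(zs) > sd_cut, 1L, any)]
  map <- sample_state_map(manifest)
  mates <- vapply(flagged, function(s) {
    p <- map$patient_id[map$sample_id == s]
    if (!length(p)) return(NA_character_)
    other <- map$sample_id[map$patient_id == p & map$sample_id != s]
    if (length(other)) other[1] else NA_character_
  }, character(1))
  mates <- mates[!is.na(mates) & mates %in% colnames(mat) &
                   !(mates %in% flagged)]
  removed <- rbind(
    data.frame(sample_id = flagged,
               reason = rep("pca_outlier", length(flagged)),
               stringsAsFactors = FALSE),
    data.frame(sample_id = unname(mates),
               reason = rep("paired_with_outlier", length(mates)),
               stringsAsFactors = FALSE))
  list(retained = setdiff(colnames(mat), removed$sample_id),
       removed = removed)
}
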