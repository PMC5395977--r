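# Synthetic-data generator: the stated world for the whole pipeline.
#
# Every downstream stage is exercised against data drawn from the model the
# analysis assumes: binomially sampled mismatches at the 11 p9 sites with a
# tumor shift, read termini enriched at the 5' cleavage boundary in
# proportion to methylation, HWE genotypes with planted tumor-only effects,
# expression coupled to methylation in normal tissue only, and exponential
# survival whose log-hazard is linear in the tumor-normal methylation
# change. One global seed is expanded into named substreams so adding a
# stream never perturbs the others.

#' Simulation configuration
#'
#' Defaults describe the cohort the analysis was designed around: 613
#' patients (1226 paired samples) split across 12 cancer types, 11 p9
#' sites, ~600x negative-binomial coverage at p9 sites, and 60-month
#' administrative censoring. Rates the source data do not pin down
#' (per-site baseline methylation, between-patient spread, coupling sizes)
#' are fixed, documented choices, not tuning knobs.
#'
#' @param n_patients number of patients (each contributes a normal and a
#'   tumor sample).
#' @param cancer_labels cancer-type labels; patients are split evenly.
#' @param sites p9 site annotation table.
#' @param theta_normal per-site true mismatch-generating methylation rate in
#'   normal tissue.
#' @param delta_tumor per-site additive tumor shift (recycled to one value).
#' @param theta_sd between-patient SD of the true rate.
#' @param seq_error per-base sequencing error rate.
#' @param coverage_mean,coverage_dispersion negative-binomial law of
#'   per-sample per-site depth (mean ~600x).
#' @param read_length simulated read length.
#' @param cleavage_base baseline fraction of reads with a 5' terminus at
#'   the cleavage boundary.
#' @param cleavage_coupling slope linking methylation to that fraction.
#' @param decoy_fraction fraction of extra reads per filter class
#'   (improper pair, low MAPQ, low base quality) that ingest must reject.
#' @param n_snps number of simulated SNPs.
#' @param maf_range range of minor allele frequencies, within (0, 0.5].
#' @param planted_gxe data.frame (`snp_index`, `site_id`, `beta_tumor`)
#'   of SNPs whose carriers shift tumor methylation; normal effect is 0.
#' @param low_quality_fraction fraction of genotype calls whose quality
#'   score falls below the 0.1 analysis threshold.
#' @param n_genes number of nuclear genes in the expression panel.
#' @param expr_coupling per-gene correlation with methylation in normal
#'   samples (0 in tumors). Default: the first 30% of genes coupled at
#'   alternating-sign magnitudes 0.3-0.7, the rest 0.
#' @param expr_site site whose methylation drives expression coupling.
#' @param survival_gamma log-hazard per unit tumor-normal methylation change.
#' @param base_hazard baseline exponential hazard per month (default:
#'   median raw survival 30 months).
#' @param censor_months administrative censoring horizon.
#' @param seed global seed; fully determines all outputs.
#' @return list of class `mtp9_config`.
#' @export
sim_config <- function(n_patients = 613L,
                       cancer_labels = c("BRCA", "COAD", "HNSC", "KICH",
                                         "KIRC", "KIRP", "LIHC", "LUAD",
                                         "LUSC", "PRAD", "STAD", "THCA"),
                       sites = p9_sites(),
                       theta_normal = c(0.45, 0.35, 0.15, 0.25, 0.40, 0.10,
                                        0.30, 0.50, 0.20, 0.35, 0.25),
                       delta_tumor = 0.05,
                       theta_sd = 0.05,
                       seq_error = 1e-3,
                       coverage_mean = 600,
                       coverage_dispersion = 5,
                       read_length = 50L,
                       cleavage_base = 0.05,
                       cleavage_coupling = 0.3,
                       decoy_fraction = 0.05,
                       n_snps = 500L,
                       maf_range = c(0.05, 0.5),
                       planted_gxe = data.frame(
                         snp_index = c(1L, 2L),
                         site_id = c("p9_10413", "p9_7526"),
                         beta_tumor = c(0.15, 0.15),
                         stringsAsFactors = FALSE),
                       low_quality_fraction = 0.02,
                       n_genes = 99L,
                       expr_coupling = NULL,
                       expr_site = "p9_10413",
                       survival_gamma = log(2),
                       base_hazard = log(2) / 30,
                       censor_months = 60,
                       seed = 1L) {
  sites <- validate_sites(sites)
  ns <- nrow(sites)
  theta_normal <- rep_len(theta_normal, ns)
  delta_tumor <- rep_len(delta_tumor, ns)
  stop_if_not_prob(theta_normal, "theta_normal")
  stop_if_not_prob(theta_normal + delta_tumor, "theta_normal + delta_tumor")
  stop_if_not_prob(seq_error, "seq_error")
  stop_if_not_prob(cleavage_base, "cleavage_base")
  if (censor_months < 0) stop("censor horizon must be non-negative")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    stop("MAF range must lie within (0, 0.5]")
  }
  if (is.null(expr_coupling)) {
    k <- ceiling(0.3 * n_genes)
    expr_coupling <- numeric(n_genes)
    expr_coupling[seq_len(k)] <-
      rep_len(c(1, -1), k) * seq(0.3, 0.7, length.out = k)
  }
  expr_coupling <- rep_len(expr_coupling, n_genes)
  if (any(abs(expr_coupling) > 1)) stop("expr_coupling must lie in [-1, 1]")
  cfg <- list(n_patients = as.integer(n_patients),
              cancer_labels = cancer_labels, sites = sites,
              theta_normal = theta_normal, delta_tumor = delta_tumor,
              theta_sd = theta_sd, seq_error = seq_error,
              coverage_mean = coverage_mean,
              coverage_dispersion = coverage_dispersion,
              read_length = as.integer(read_length),
              cleavage_base = cleavage_base,
              cleavage_coupling = cleavage_coupling,
              decoy_fraction = decoy_fraction,
              n_snps = as.integer(n_snps), maf_range = maf_range,
              planted_gxe = planted_gxe,
              low_quality_fraction = low_quality_fraction,
              n_genes = as.integer(n_genes), expr_coupling = expr_coupling,
              expr_site = expr_site,
              survival_gamma = survival_gamma, base_hazard = base_hazard,
              censor_months = censor_months, seed = as.integer(seed))
  class(cfg) <- "mtp9_config"
  cfg
}

#' Simulate a full cohort: manifest, genotypes, true methylation, clinical
#'
#' True per-sample methylation rates are the per-site baseline plus a
#' patient-level Gaussian deviation (truncated to \[0,1\]); tumor samples add
#' the per-site shift and, for carriers of planted interaction SNPs, the
#' planted `beta_tumor`. These rates are the mismatch-generating truth the
#' read and count generators consume.
#'
#' @param config [sim_config()] output.
#' @return list with `config`, `manifest`, `snp_info`, `genotype_calls`
#'   (SNP x patient, copies of minor allele), `genotype_quality`,
#'   `truth_normal` / `truth_tumor` (patient x site matrices),
#'   `delta_truth`, `clinical`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "mtp9_config"))
  n <- config$n_patients
  patient_id <- sprintf("P%04d", seq_len(n))
  cancer <- sort(rep_len(config$cancer_labels, n))
  manifest <- data.frame(patient_id = patient_id, cancer_type = cancer,
                         normal_sample_id = paste0(patient_id, "_N"),
                         tumor_sample_id = paste0(patient_id, "_T"),
                         stringsAsFactors = FALSE)
  geno <- simulate_genotypes(config)
  ns <- nrow(config$sites)
  truth <- with_seed(substream_seed(config$seed, "methylation"), {
    base_n <- matrix(rep(config$theta_normal, each = n), n, ns)
    base_t <- matrix(rep(config$theta_normal + config$delta_tumor, each = n),
                     n, ns)
    tn <- clip01(base_n + matrix(stats::rnorm(n * ns, 0, config$theta_sd), n, ns))
    tt <- base_t + matrix(stats::rnorm(n * ns, 0, config$theta_sd), n, ns)
    if (nrow(config$planted_gxe)) {
      for (i in seq_len(nrow(config$planted_gxe))) {
        pl <- config$planted_gxe[i, ]
        j <- match(pl$site_id, config$sites$site_id)
        if (is.na(j)) stop("planted_gxe site not in site table: ", pl$site_id)
        carrier <- geno$calls[pl$snp_index, ] >= 1L
        tt[, j] <- tt[, j] + pl$beta_tumor * carrier
      }
    }
    list(normal = tn, tumor = clip01(tt))
  })
  dimnames(truth$normal) <- dimnames(truth$tumor) <-
    list(patient_id, config$sites$site_id)
  clinical <- with_seed(substream_seed(config$seed, "clinical"), {
    data.frame(patient_id = patient_id,
               age = round(stats::rnorm(n, 60, 10), 1),
               sex = sample(c("F", "M"), n, replace = TRUE),
               ethnicity = sample(c("GRP1", "GRP2", "GRP3"), n,
                                  replace = TRUE, prob = c(0.6, 0.25, 0.15)),
               stringsAsFactors = FALSE)
  })
  list(config = config, manifest = manifest,
       snp_info = geno$snp_info, genotype_calls = geno$calls,
       genotype_quality = geno$quality,
       truth_normal = truth$normal, truth_tumor = truth$tumor,
       delta_truth = truth$tumor - truth$normal,
       clinical = clinical)
}

#' Simulate SNP genotypes in Hardy-Weinberg equilibrium
#'
#' Minor allele frequencies are uniform over `maf_range`; per-individual
#' calls are binomial(2, MAF) (HWE proportions p^2, 2pq, q^2). A stated
#' fraction of call quality scores falls below the 0.1 analysis threshold.
#'
#' @param config [sim_config()] output.
#' @return list with `calls` (SNP x patient integer matrix), `quality`
#'   (same shape, in \[0,1\]), `snp_info` data.frame.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "mtp9_config"))
  if (config$maf_range[1] <= 0) stop("MAF must be positive")
  with_seed(substream_seed(config$seed, "genotypes"), {
    m <- config$n_snps
    n <- config$n_patients
    maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    calls <- matrix(stats::rbinom(m * n, 2L, rep(maf, n)), m, n)
    low <- stats::runif(m * n) < config$low_quality_fraction
    quality <- ifelse(low, stats::runif(m * n, 0, 0.1),
                      stats::runif(m * n, 0.1, 1))
    quality <- matrix(quality, m, n)
    snp_id <- sprintf("snp%05d", seq_len(m))
    rownames(calls) <- rownames(quality) <- snp_id
    info <- data.frame(snp_id = snp_id,
                       chromosome = rep_len(1:22, m),
                       position = 1e6L + 1000L * seq_len(m),
                       minor_allele = "B", major_allele = "A",
                       maf_true = maf, stringsAsFactors = FALSE)
    list(calls = calls, quality = quality, snp_info = info)
  })
}

#' Simulate aligned reads for one sample
#'
#' Per site, depth is negative binomial; each read carries a non-reference
#' base at the p9 site with probability `theta + (1 - theta) * seq_error`;
#' a fraction `min(1, cleavage_base + cleavage_coupling * theta)` of reads
#' has its 5' terminus (in tRNA orientation) at the cleavage boundary 9
#' bases upstream of the site. Decoy reads violating each ingest filter
#' class (pairing flag, MAPQ, base quality) are added at `decoy_fraction`
#' per class and always carry a non-reference base, so their leakage
#' through a broken filter is visible.
#'
#' @param config [sim_config()] output.
#' @param sample_id sample label (also seeds the per-sample read stream).
#' @param state `"normal"` or `"tumor"`.
#' @param theta per-site true rates for this sample; defaults to the
#'   config baselines for the requested state.
#' @return alignment data.frame ([read_sam()] shape).
#' @export
simulate_reads <- function(config, sample_id, state = c("normal", "tumor"),
                           theta = NULL) {
  stopifnot(inherits(config, "mtp9_config"))
  state <- match.arg(state)
  sites <- config$sites
  if (is.null(theta)) {
    theta <- if (state == "normal") config$theta_normal
             else clip01(config$theta_normal + config$delta_tumor)
  }
  theta <- rep_len(theta, nrow(sites))
  stop_if_not_prob(theta, "theta")
  L <- config$read_length
  refstr <- mt_reference(as_string = TRUE)
  bases <- c("A", "C", "G", "T")
  with_seed(substream_seed(config$seed, paste0("reads:", sample_id)), {
    per_site <- lapply(seq_len(nrow(sites)), function(i) {
      s <- sites[i, ]
      th <- theta[i]
      d <- max(1L, stats::rnbinom(1L, size = config$coverage_dispersion,
                                  mu = config$coverage_mean))
      n_decoy <- round(config$decoy_fraction * d)
      decoy_class <- rep(c("pairing", "mapq", "baseq"), each = n_decoy)
      n_all <- d + length(decoy_class)
      is_decoy <- c(rep(NA_character_, d), decoy_class)

      f_cleave <- min(1, config$cleavage_base + config$cleavage_coupling * th)
      cleaved <- stats::runif(n_all) < f_cleave
      cleaved[!is.na(is_decoy)] <- FALSE
      cpos <- cleavage_position(s)
      if (s$strand == "+") {
        start <- pmax(1L, s$position - sample.int(L, n_all, replace = TRUE) + 1L)
        start[cleaved] <- cpos + 1L
      } else {
        start <- pmax(1L, s$position - sample.int(L, n_all, replace = TRUE) + 1L)
        start[cleaved] <- cpos - 1L - L + 1L
      }
      mm_rate <- th + (1 - th) * config$seq_error
      mism <- stats::runif(n_all) < mm_rate
      mism[!is.na(is_decoy)] <- TRUE
      seq <- substr(rep(refstr, n_all), start, start + L - 1L)
      off <- s$position - start + 1L
      alt <- sample(3L, n_all, replace = TRUE)
      ref_b <- s$ref_allele
      alt_b <- vapply(alt, function(a) setdiff(bases, ref_b)[a], character(1))
      idx <- which(mism)
      if (length(idx)) {
        tmp <- seq[idx]
        substr(tmp, off[idx], off[idx]) <- alt_b[idx]
        seq[idx] <- tmp
      }
      qual <- rep(strrep("I", L), n_all)
      bq_decoy <- which(!is.na(is_decoy) & is_decoy == "baseq")
      if (length(bq_decoy)) {
        tmp <- qual[bq_decoy]
        substr(tmp, off[bq_decoy], off[bq_decoy]) <- "#"
        qual[bq_decoy] <- tmp
      }
      flag <- rep(99L, n_all)
      flag[!is.na(is_decoy) & is_decoy == "pairing"] <- 65L
      mapq <- rep(60L, n_all)
      mapq[!is.na(is_decoy) & is_decoy == "mapq"] <- 10L
      data.frame(
        qname = sprintf("%s_%s_r%05d", sample_id, s$site_id, seq_len(n_all)),
        flag = flag, rname = mt_contig()$name, pos = as.integer(start),
        mapq = mapq, cigar = paste0(L, "M"), rnext = "=",
        pnext = as.integer(start), tlen = 0L, seq = seq, qual = qual,
        stringsAsFactors = FALSE)
    })
    do.call(rbind, per_site)
  })
}

#' Simulate allele counts directly (count-level shortcut)
#'
#' Draws per-sample, per-site depth and non-reference counts from the same
#' law the read simulator induces (negative-binomial depth, binomial
#' mismatches at rate `theta + (1 - theta) * seq_error`), skipping read
#' construction. Used where read-level detail is irrelevant and scale
#' matters.
#'
#' @param config [sim_config()] output.
#' @param truth patient x site matrix of true rates.
#' @param sample_ids one label per row of `truth`.
#' @return allele-count data.frame ([count_alleles()] shape).
#' @export
simulate_allele_counts <- function(config, truth, sample_ids) {
  stopifnot(inherits(config, "mtp9_config"), nrow(truth) == length(sample_ids))
  sites <- config$sites
  ns <- nrow(sites)
  n <- nrow(truth)
  with_seed(substream_seed(config$seed, "counts"), {
    depth <- matrix(pmax(1L, stats::rnbinom(n * ns,
                                            size = config$coverage_dispersion,
                                            mu = config$coverage_mean)), n, ns)
    rate <- truth + (1 - truth) * config$seq_error
    nonref <- matrix(stats::rbinom(n * ns, as.vector(depth), as.vector(rate)),
                     n, ns)
    out <- data.frame(
      sample_id = rep(sample_ids, ns),
      site_id = rep(sites$site_id, each = n),
      count_A = 0L, count_C = 0L, count_G = 0L, count_T = 0L,
      depth = as.vector(depth), stringsAsFactors = FALSE)
    ref_count <- as.vector(depth - nonref)
    alts <- vapply(rep(sites$ref_allele, each = n),
                   function(r) setdiff(c("A", "C", "G", "T"), r)[1], character(1))
    cols <- paste0("count_", c("A", "C", "G", "T"))
    refcol <- match(paste0("count_", rep(sites$ref_allele, each = n)), cols)
    altcol <- match(paste0("count_", alts), cols)
    m <- matrix(0L, nrow(out), 4L)
    m[cbind(seq_len(nrow(out)), refcol)] <- ref_count
    m[cbind(seq_len(nrow(out)), altcol)] <-
      m[cbind(seq_len(nrow(out)), altcol)] + as.vector(nonref)
    out[cols] <- m
    out
  })
}

#' Simulate gene expression counts coupled to methylation in normal tissue
#'
#' For normal samples the latent log-expression of gene g is
#' `rho_g * z(m) + sqrt(1 - rho_g^2) * eps`, where `z(m)` is the
#' standardized methylation of the focal site; in tumor samples the
#' coupling is forced to 0. Latents map to true TPM on a log10 scale and
#' counts are Poisson at depth proportional to gene length and a
#' log-normal per-sample library factor, so the TPM and normalization
#' stages are exercised end to end. Thirteen mitochondrial genes with no
#' coupling are appended so the mito-specific TPM rule has substrate.
#'
#' @param config [sim_config()] output.
#' @param methylation per-sample methylation at the focal site.
#' @param state per-sample `"normal"`/`"tumor"` labels.
#' @param sample_ids sample labels.
#' @return list with `counts` (gene x sample integer matrix) and
#'   `gene_models` data.frame (`gene_id`, `length`, `compartment`).
#' @export
simulate_expression <- function(config, methylation, state, sample_ids) {
  stopifnot(inherits(config, "mtp9_config"),
            length(methylation) == length(state),
            length(state) == length(sample_ids))
  if (!all(state %in% c("normal", "tumor"))) stop("invalid state label")
  ng <- config$n_genes
  n <- length(sample_ids)
  rho <- config$expr_coupling
  with_seed(substream_seed(config$seed, "expression"), {
    mz <- as.vector(scale(methylation))
    if (any(!is.finite(mz))) mz <- rep(0, n)
    eps <- matrix(stats::rnorm(ng * n), ng, n)
    rho_eff <- outer(rho, ifelse(state == "normal", 1, 0))
    z <- rho_eff * matrix(mz, ng, n, byrow = TRUE) +
      sqrt(1 - rho_eff^2) * eps
    base <- rep_len(seq(1.2, 2.8, length.out = 7L), ng)
    tpm_true <- 10^(base + 0.35 * z)
    len <- rep_len(c(1000L, 1500L, 2000L, 2500L, 3000L), ng)
    lib <- exp(stats::rnorm(n, 0, 0.2))
    lambda <- tpm_true * (len / 1000) * matrix(lib * 30, ng, n, byrow = TRUE)
    counts <- matrix(stats::rpois(ng * n, as.vector(lambda)), ng, n)
    # mito panel: high constant expression, no coupling
    nm <- 13L
    mito_tpm <- 10^(rep_len(seq(3.0, 4.2, length.out = nm), nm))
    mito_len <- rep_len(c(950L, 1600L, 1100L), nm)
    mito_lambda <- mito_tpm %o% lib * (mito_len / 1000) * 2
    mito_counts <- matrix(stats::rpois(nm * n, as.vector(mito_lambda)), nm, n)
    counts <- rbind(counts, mito_counts)
    gene_id <- c(sprintf("GENE%03d", seq_len(ng)), sprintf("MTG%02d", seq_len(nm)))
    dimnames(counts) <- list(gene_id, sample_ids)
    models <- data.frame(gene_id = gene_id,
                         length = c(len, mito_len),
                         compartment = c(rep("nuclear", ng), rep("mito", nm)),
                         stringsAsFactors = FALSE)
    list(counts = counts, gene_models = models)
  })
}

#' Simulate survival records from methylation change
#'
#' Event times are exponential with hazard
#' `base_hazard * exp(survival_gamma * delta_methylation)`; administrative
#' censoring is applied at `censor_months`.
#'
#' @param config [sim_config()] output.
#' @param delta_methylation one tumor-normal methylation change per patient.
#' @param patient_ids patient labels.
#' @return data.frame with `patient_id`, `time` (months), `event` (1 death,
#'   0 censored), `delta_methylation`.
#' @export
simulate_survival <- function(config, delta_methylation, patient_ids) {
  stopifnot(inherits(config, "mtp9_config"),
            length(delta_methylation) == length(patient_ids))
  if (config$censor_months < 0) stop("censor horizon must be non-negative")
  with_seed(substream_seed(config$seed, "survival"), {
    rate <- config$base_hazard * exp(config$survival_gamma * delta_methylation)
    t_raw <- stats::rexp(length(rate), rate)
    event <- as.integer(t_raw <= config$censor_months)
    time <- pmin(t_raw, config$censor_months)
    data.frame(patient_id = patient_ids, time = time, event = event,
               delta_methylation = delta_methylation,
               stringsAsFactors = FALSE)
  })
}
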