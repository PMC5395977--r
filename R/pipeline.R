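# End-to-end orchestration: simulate -> ingest -> quantify -> metrics ->
# difftest -> associate -> gxe -> survival, over plain-TSV interchange
# files so every stage is independently testable and reruns are
# byte-identical under a fixed seed.

#' Pipeline thresholds
#'
#' Defaults follow the analysis conventions: 20x minimum coverage, MAPQ 30,
#' base quality 13, MAF 0.05, HWE exact p 0.001, genotype quality 0.1,
#' 40 individuals and 5 carriers for interaction tests, 50 individuals and
#' 25% death rate for survival, 60-month censoring, alpha 0.05.
#'
#' @param min_coverage,min_mapq,min_baseq ingest/quantify thresholds.
#' @param resample coverage-match pairs by hypergeometric downsampling.
#' @param maf,hwe_p,quality,min_n,min_carriers interaction-scan gates.
#' @param surv_min_n,surv_death_rate,censor_months survival gates.
#' @param alpha family-wise error rate used throughout.
#' @return named list of thresholds.
#' @export
pipeline_options <- function(min_coverage = 20L, min_mapq = 30L,
                             min_baseq = 13L, resample = TRUE,
                             maf = 0.05, hwe_p = 0.001, quality = 0.1,
                             min_n = 40L, min_carriers = 5L,
                             surv_min_n = 50L, surv_death_rate = 0.25,
                             censor_months = 60, alpha = 0.05) {
  as.list(environment())
}

#' Demo configuration: 40 synthetic patients, two cancer types
#'
#' A scaled-down stated world for the one-command demo: 40 patients split
#' over two synthetic cancer labels, 150 SNPs, the 99-gene panel, full
#' ~600x coverage. Interaction and survival cohort gates are relaxed to
#' match the 20-pairs-per-cancer size (the full-scale defaults would
#' simply empty those stages).
#'
#' @param n_patients number of patients (default 40).
#' @param seed global seed.
#' @return list with `config` ([sim_config()]) and `options`
#'   ([pipeline_options()]).
#' @export
demo_config <- function(n_patients = 40L, seed = 1L) {
  list(config = sim_config(n_patients = n_patients,
                           cancer_labels = c("CAN_A", "CAN_B"),
                           n_snps = 150L, seed = seed),
       options = pipeline_options(min_n = 15L, min_carriers = 3L,
                                  surv_min_n = 15L))
}

log_stage <- function(stage, ...) {
  message(sprintf("[mtp9:%s] %s", stage, paste0(...)))
}

stage_done <- function(outdir, files) {
  all(file.exists(file.path(outdir, files)))
}

record_outputs <- function(manifest_rows, stage, outdir, files) {
  for (f in files) {
    path <- file.path(outdir, f)
    n <- if (file.exists(path)) length(readLines(path)) - 1L else NA_integer_
    manifest_rows[[length(manifest_rows) + 1L]] <-
      data.frame(stage = stage, file = f, rows = n, stringsAsFactors = FALSE)
  }
  manifest_rows
}

#' Run the full pipeline
#'
#' Executes every stage from a single simulation config, writing all
#' intermediate and final tables under `outdir` and a `run_manifest.tsv`
#' listing each output with its row count. With `resume = TRUE`, stages
#' whose outputs already exist are skipped.
#'
#' @param config [sim_config()] output.
#' @param outdir output directory (created if needed).
#' @param options [pipeline_options()] output.
#' @param resume skip stages whose outputs exist.
#' @return invisibly, the run manifest data.frame.
#' @export
run_all <- function(config, outdir, options = pipeline_options(),
                    resume = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  mrows <- list()

  ## --- simulate -------------------------------------------------------
  sim_files <- c("manifest.tsv", "clinical.tsv", "genotypes.tsv",
                 "genotype_quality.tsv", "snp_info.tsv", "counts.tsv",
                 "gene_models.tsv", "gene_sets.tsv", "sites.tsv")
  cohort <- simulate_cohort(config)
  man <- cohort$manifest
  sample_ids <- c(man$normal_sample_id, man$tumor_sample_id)
  state <- rep(c("normal", "tumor"), each = nrow(man))
  if (!(resume && stage_done(outdir, sim_files) &&
        stage_done(outdir, "sam/.done"))) {
    log_stage("simulate", "writing synthetic inputs for ",
              config$n_patients, " patients")
    write_tsv(man, file.path(outdir, "manifest.tsv"))
    write_tsv(cohort$config$sites, file.path(outdir, "sites.tsv"))
    j <- match(config$expr_site, config$sites$site_id)
    surv <- simulate_survival(config, cohort$delta_truth[, j],
                              man$patient_id)
    clin <- merge(cohort$clinical, surv[, c("patient_id", "time", "event")],
                  by = "patient_id", sort = TRUE)
    write_tsv(clin, file.path(outdir, "clinical.tsv"))
    gcalls <- data.frame(snp_id = rownames(cohort$genotype_calls),
                         cohort$genotype_calls, check.names = FALSE,
                         stringsAsFactors = FALSE)
    names(gcalls)[-1] <- man$patient_id
    write_tsv(gcalls, file.path(outdir, "genotypes.tsv"))
    gq <- data.frame(snp_id = rownames(cohort$genotype_quality),
                     round(cohort$genotype_quality, 6), check.names = FALSE)
    names(gq)[-1] <- man$patient_id
    write_tsv(gq, file.path(outdir, "genotype_quality.tsv"))
    write_tsv(cohort$snp_info, file.path(outdir, "snp_info.tsv"))
    meth_focal <- c(cohort$truth_normal[, j], cohort$truth_tumor[, j])
    ex <- simulate_expression(config, meth_focal, state, sample_ids)
    cnt <- data.frame(gene_id = rownames(ex$counts), ex$counts,
                      check.names = FALSE)
    write_tsv(cnt, file.path(outdir, "counts.tsv"))
    write_tsv(ex$gene_models, file.path(outdir, "gene_models.tsv"))
    coupled <- ex$gene_models$gene_id[seq_len(config$n_genes)][
      config$expr_coupling != 0]
    write_tsv(data.frame(set = "COUPLED",
                         genes = paste(coupled, collapse = ","),
                         stringsAsFactors = FALSE),
              file.path(outdir, "gene_sets.tsv"))
    samdir <- file.path(outdir, "sam")
    dir.create(samdir, showWarnings = FALSE)
    for (i in seq_len(nrow(man))) {
      aln <- simulate_reads(config, man$normal_sample_id[i], "normal",
                            theta = cohort$truth_normal[i, ])
      write_sam(aln, file.path(samdir, paste0(man$normal_sample_id[i], ".sam")))
      aln <- simulate_reads(config, man$tumor_sample_id[i], "tumor",
                            theta = cohort$truth_tumor[i, ])
      write_sam(aln, file.path(samdir, paste0(man$tumor_sample_id[i], ".sam")))
    }
    writeLines("done", file.path(samdir, ".done"))
  } else log_stage("simulate", "resume: outputs exist, skipping")
  mrows <- record_outputs(mrows, "simulate", outdir, sim_files)

  sites <- validate_sites(read_tsv(file.path(outdir, "sites.tsv")))
  man <- read_tsv(file.path(outdir, "manifest.tsv"))
  sample_ids <- c(man$normal_sample_id, man$tumor_sample_id)

  ## --- ingest ---------------------------------------------------------
  ingest_files <- c("allele_counts.tsv", "termini.tsv", "coverage.tsv",
                    "ingest_rejects.tsv")
  if (!(resume && stage_done(outdir, ingest_files))) {
    log_stage("ingest", "filtering and counting ", length(sample_ids),
              " SAM files")
    tpos <- terminus_positions(sites)
    span_pos <- sort(unique(unlist(
      lapply(seq_len(nrow(sites)),
             function(i) sites$trna_start[i]:sites$trna_end[i]))))
    ac <- list(); tm <- list(); cv <- list(); rj <- list()
    for (sid in sample_ids) {
      aln <- read_sam(file.path(outdir, "sam", paste0(sid, ".sam")))
      fl <- filter_reads(aln, min_mapq = options$min_mapq)
      ac[[sid]] <- count_alleles(fl$kept, sites, sid, options$min_baseq)
      tm[[sid]] <- count_termini(fl$kept, tpos, sid)
      width <- cigar_ref_width(fl$kept$cigar)
      cov <- coverage_at(fl$kept$pos, fl$kept$pos + width - 1L, span_pos)
      cv[[sid]] <- data.frame(sample_id = sid, position = span_pos,
                              n_cover = cov,
                              mito_total = nrow(fl$kept),
                              stringsAsFactors = FALSE)
      rj[[sid]] <- cbind(sample_id = sid, fl$rejected)
    }
    write_tsv(do.call(rbind, ac), file.path(outdir, "allele_counts.tsv"))
    write_tsv(do.call(rbind, tm), file.path(outdir, "termini.tsv"))
    write_tsv(do.call(rbind, cv), file.path(outdir, "coverage.tsv"))
    write_tsv(do.call(rbind, rj), file.path(outdir, "ingest_rejects.tsv"))
  } else log_stage("ingest", "resume: outputs exist, skipping")
  mrows <- record_outputs(mrows, "ingest", outdir, ingest_files)

  ## --- quantify -------------------------------------------------------
  quant_files <- c("methylation.tsv", "methylation_std.tsv")
  if (!(resume && stage_done(outdir, quant_files))) {
    log_stage("quantify", "methylation levels at ", nrow(sites), " sites")
    counts <- read_tsv(file.path(outdir, "allele_counts.tsv"))
    if (isTRUE(options$resample)) {
      counts <- resample_pairs(counts, man, sites, options$min_coverage,
                               seed = config$seed)
    }
    meth <- methylation_level(counts, sites, options$min_coverage)
    write_tsv(meth, file.path(outdir, "methylation.tsv"))
    mstd <- standardize_methylation(meth, man)
    write_tsv(mstd, file.path(outdir, "methylation_std.tsv"))
  } else log_stage("quantify", "resume: outputs exist, skipping")
  mrows <- record_outputs(mrows, "quantify", outdir, quant_files)

  meth <- read_tsv(file.path(outdir, "methylation.tsv"))
  mstd <- read_tsv(file.path(outdir, "methylation_std.tsv"))
  map <- sample_state_map(man)

  ## --- metrics --------------------------------------------------------
  metric_files <- c("expression_norm.tsv", "qc_removed.tsv", "cleavage.tsv",
                    "trna_expression.tsv")
  if (!(resume && stage_done(outdir, metric_files))) {
    log_stage("metrics", "TPM, normalization, cleavage, tRNA expression")
    cnt <- read_tsv(file.path(outdir, "counts.tsv"))
    counts_mat <- as.matrix(cnt[, -1, drop = FALSE])
    rownames(counts_mat) <- cnt$gene_id
    models <- read_tsv(file.path(outdir, "gene_models.tsv"))
    tpmat <- tpm(counts_mat, models)
    lnorm <- log_median_normalize(tpmat)
    flt <- pca_outlier_filter(lnorm, man)
    write_tsv(flt$removed, file.path(outdir, "qc_removed.tsv"))
    keep <- lnorm[, flt$retained, drop = FALSE]
    out <- data.frame(gene_id = rownames(keep), round(keep, 6),
                      check.names = FALSE)
    write_tsv(out, file.path(outdir, "expression_norm.tsv"))
    term <- read_tsv(file.path(outdir, "termini.tsv"))
    write_tsv(cleavage_table(term, sites), file.path(outdir, "cleavage.tsv"))
    cov <- read_tsv(file.path(outdir, "coverage.tsv"))
    tex <- lapply(split(cov, cov$sample_id), function(cc) {
      data.frame(sample_id = cc$sample_id[1], trna_name = sites$trna_name,
                 expression = vapply(seq_len(nrow(sites)), function(i) {
                   span <- sites$trna_start[i]:sites$trna_end[i]
                   trna_expression(
                     stats::setNames(cc$n_cover, cc$position)[as.character(span)],
                     seq_along(span), cc$mito_total[1])
                 }, numeric(1)), stringsAsFactors = FALSE)
    })
    tex <- do.call(rbind, tex)
    tex$expression <- signif(tex$expression, 8)
    write_tsv(tex, file.path(outdir, "trna_expression.tsv"))
  } else log_stage("metrics", "resume: outputs exist, skipping")
  mrows <- record_outputs(mrows, "metrics", outdir, metric_files)

  ## --- difftest -------------------------------------------------------
  diff_files <- c("differential.tsv", "cross_cancer.tsv", "clusters.tsv",
                  "de_genes.tsv")
  if (!(resume && stage_done(outdir, diff_files))) {
    log_stage("difftest", "paired tests per site and cancer")
    dres <- differential_scan(meth, man, sites, options$alpha)
    write_tsv(dres, file.path(outdir, "differential.tsv"))
    cres <- cross_cancer_test(mstd, man, sites, options$alpha)
    write_tsv(cres, file.path(outdir, "cross_cancer.tsv"))
    grp <- group_mean_matrix(mstd)
    cl <- cluster_groups(grp)
    write_tsv(data.frame(axis = c(rep("group", length(cl$row_order)),
                                  rep("site", length(cl$col_order))),
                         order = c(seq_along(cl$row_order),
                                   seq_along(cl$col_order)),
                         label = c(cl$row_order, cl$col_order),
                         stringsAsFactors = FALSE),
              file.path(outdir, "clusters.tsv"))
    expr <- read_expression(file.path(outdir, "expression_norm.tsv"))
    models <- read_tsv(file.path(outdir, "gene_models.tsv"))
    nuc <- expr[models$gene_id[models$compartment == "nuclear"], ,
                drop = FALSE]
    labels <- map$state[match(colnames(nuc), map$sample_id)]
    de <- de_scan(nuc, labels, options$alpha)
    write_tsv(de, file.path(outdir, "de_genes.tsv"))
  } else log_stage("difftest", "resume: outputs exist, skipping")
  mrows <- record_outputs(mrows, "difftest", outdir, diff_files)

  ## --- associate ------------------------------------------------------
  assoc_files <- c("associations.tsv", "meth_cleavage.tsv", "enrichment.tsv")
  if (!(resume && stage_done(outdir, assoc_files))) {
    log_stage("associate", "Spearman scans and enrichment")
    expr <- read_expression(file.path(outdir, "expression_norm.tsv"))
    models <- read_tsv(file.path(outdir, "gene_models.tsv"))
    nuc <- expr[models$gene_id[models$compartment == "nuclear"], ,
                drop = FALSE]
    mm <- meth_matrix(meth, sites, colnames(nuc))
    st <- map$state[match(colnames(nuc), map$sample_id)]
    assoc <- spearman_scan(mm, nuc, st, options$alpha)
    write_tsv(assoc, file.path(outdir, "associations.tsv"))
    meth2 <- meth
    meth2$cancer_type <- map$cancer_type[match(meth2$sample_id, map$sample_id)]
    cle <- read_tsv(file.path(outdir, "cleavage.tsv"))
    mc <- methylation_vs_cleavage(meth2, cle, options$alpha,
                                  min_individuals = 20L)
    if (is.null(mc)) {
      mc <- data.frame(site_id = character(), cancer_type = character(),
                       metric = character(), rho = numeric(),
                       p_value = numeric(), n = integer(),
                       bonferroni_significant = logical())
    }
    write_tsv(mc, file.path(outdir, "meth_cleavage.tsv"))
    gs <- read_tsv(file.path(outdir, "gene_sets.tsv"))
    gene_sets <- stats::setNames(
      lapply(strsplit(gs$genes, ",", fixed = TRUE), trimws), gs$set)
    focal <- assoc[assoc$state == "normal" &
                     assoc$site_id == config$expr_site, , drop = FALSE]
    focus <- focal$gene_id[focal$bonferroni_significant]
    if (!length(focus)) {
      # underpowered cohorts: fall back to nominal significance so the
      # enrichment stage still has substrate (flagged in run_params)
      focus <- focal$gene_id[!is.na(focal$p_value) &
                               focal$p_value < options$alpha]
    }
    if (length(focus)) {
      enr <- enrichment_scan(focus, gene_sets, rownames(nuc))
    } else {
      enr <- data.frame(gene_set = character(), n_set = integer(),
                        n_overlap = integer(), p_value = numeric(),
                        fold_enrichment = numeric())
    }
    write_tsv(enr, file.path(outdir, "enrichment.tsv"))
  } else log_stage("associate", "resume: outputs exist, skipping")
  mrows <- record_outputs(mrows, "associate", outdir, assoc_files)

  ## --- gxe ------------------------------------------------------------
  gxe_files <- c("gxe.tsv", "gxe_replication.tsv", "gxe_qq.tsv")
  if (!(resume && stage_done(outdir, gxe_files))) {
    log_stage("gxe", "interaction scan")
    gcalls <- read_tsv(file.path(outdir, "genotypes.tsv"))
    calls <- as.matrix(gcalls[, -1, drop = FALSE])
    rownames(calls) <- gcalls$snp_id
    gq <- read_tsv(file.path(outdir, "genotype_quality.tsv"))
    qual <- as.matrix(gq[, -1, drop = FALSE])
    mn <- patient_site_matrix(meth, man, sites, "normal")
    mt <- patient_site_matrix(meth, man, sites, "tumor")
    scan <- gxe_scan(calls, qual, mn, mt, man$cancer_type,
                     alpha = options$alpha, min_quality = options$quality,
                     hwe_p = options$hwe_p, min_maf = options$maf,
                     min_n = options$min_n,
                     min_carriers = options$min_carriers)
    write_tsv(scan, file.path(outdir, "gxe.tsv"))
    hits <- scan[scan$genomewide_significant %in% TRUE, , drop = FALSE]
    rep_tab <- replicate_hits(hits, scan)
    write_tsv(rep_tab, file.path(outdir, "gxe_replication.tsv"))
    pv <- sort(scan$p_value[!is.na(scan$p_value)])
    qq <- data.frame(expected = -log10(stats::ppoints(length(pv))),
                     observed = -log10(pv))
    write_tsv(qq, file.path(outdir, "gxe_qq.tsv"))
  } else log_stage("gxe", "resume: outputs exist, skipping")
  mrows <- record_outputs(mrows, "gxe", outdir, gxe_files)

  ## --- survival -------------------------------------------------------
  surv_files <- c("survival.tsv", "km_curves.tsv")
  if (!(resume && stage_done(outdir, surv_files))) {
    log_stage("survival", "Cox models on methylation change")
    clin <- read_tsv(file.path(outdir, "clinical.tsv"))
    mn <- patient_site_matrix(meth, man, sites, "normal")
    mt <- patient_site_matrix(meth, man, sites, "tumor")
    delta <- mt - mn
    srows <- list(); km_rows <- list()
    for (ca in unique(man$cancer_type)) {
      pids <- man$patient_id[man$cancer_type == ca]
      cl <- clin[match(pids, clin$patient_id), , drop = FALSE]
      gate <- cohort_gate(cl, options$surv_min_n, options$surv_death_rate,
                          options$censor_months)
      if (!gate$eligible) next
      sc <- survival_scan(delta[pids, , drop = FALSE], cl,
                          alpha = options$alpha,
                          censor_months = options$censor_months)
      if (is.null(sc)) next
      sc$cancer_type <- ca
      srows[[ca]] <- sc
      best <- sc$site_id[which.min(sc$p_value)]
      rec <- cl
      rec$delta_methylation <- delta[pids, best]
      rec <- rec[stats::complete.cases(rec$delta_methylation), , drop = FALSE]
      cb <- cox_binned(rec, options$censor_months)
      km <- cb$km
      km$cancer_type <- ca
      km$site_id <- best
      km_rows[[ca]] <- km
    }
    surv_out <- if (length(srows)) do.call(rbind, srows) else
      data.frame(site_id = character(), n = integer(), n_events = integer(),
                 coef = numeric(), se = numeric(), p_value = numeric(),
                 ph_p = numeric(), hr = numeric(), ci_lower = numeric(),
                 ci_upper = numeric(), hr_p = numeric(),
                 bonferroni_significant = logical(),
                 cancer_type = character())
    write_tsv(surv_out, file.path(outdir, "survival.tsv"))
    km_out <- if (length(km_rows)) do.call(rbind, km_rows) else
      data.frame(time = numeric(), survival = numeric(), group = character(),
                 cancer_type = character(), site_id = character())
    write_tsv(km_out, file.path(outdir, "km_curves.tsv"))
  } else log_stage("survival", "resume: outputs exist, skipping")
  mrows <- record_outputs(mrows, "survival", outdir, surv_files)

  manifest <- do.call(rbind, mrows)
  params <- data.frame(parameter = names(options),
                       value = vapply(options, function(v)
                         paste(format(v), collapse = ","), character(1)),
                       stringsAsFactors = FALSE)
  params <- rbind(params, data.frame(parameter = "seed",
                                     value = as.character(config$seed)))
  write_tsv(params, file.path(outdir, "run_params.tsv"))
  write_tsv(manifest, file.path(outdir, "run_manifest.tsv"))
  invisible(manifest)
}

#' One-command synthetic demo
#'
#' @param outdir output directory.
#' @param n_patients demo cohort size (default 40).
#' @param seed global seed.
#' @param resume skip completed stages.
#' @return invisibly, the run manifest.
#' @export
run_demo <- function(outdir, n_patients = 40L, seed = 1L, resume = FALSE) {
  dc <- demo_config(n_patients = n_patients, seed = seed)
  run_all(dc$config, outdir, dc$options, resume = resume)
}

# --- pipeline helpers -------------------------------------------------------

# Coverage (number of intervals [start, end] containing each position).
coverage_at <- function(starts, ends, positions) {
  ss <- sort(starts)
  es <- sort(ends)
  findInterval(positions, ss) - findInterval(positions - 1L, es)
}

# Resample every complete pair at every site to matched coverage.
resample_pairs <- function(counts, manifest, sites, min_coverage, seed) {
  key <- paste(counts$sample_id, counts$site_id)
  out <- counts
  for (i in seq_len(nrow(manifest))) {
    for (s in sites$site_id) {
      iN <- match(paste(manifest$normal_sample_id[i], s), key)
      iT <- match(paste(manifest$tumor_sample_id[i], s), key)
      if (is.na(iN) || is.na(iT)) next
      if (counts$depth[iN] < min_coverage || counts$depth[iT] < min_coverage)
        next
      rs <- resample_matched(counts[iN, , drop = FALSE],
                             counts[iT, , drop = FALSE],
                             seed = substream_seed(seed, paste0("rs:", i, ":", s)))
      out[iN, ] <- rs$normal
      out[iT, ] <- rs$tumor
    }
  }
  out
}

# site x sample methylation matrix (NA where undefined).
meth_matrix <- function(meth, sites, sample_ids) {
  m <- matrix(NA_real_, nrow(sites), length(sample_ids),
              dimnames = list(sites$site_id, sample_ids))
  i <- cbind(match(meth$site_id, sites$site_id),
             match(meth$sample_id, sample_ids))
  ok <- stats::complete.cases(i)
  m[i[ok, , drop = FALSE]] <- meth$level[ok]
  m
}

# patient x site level matrix for one state.
patient_site_matrix <- function(meth, manifest, sites, state) {
  sid <- if (state == "normal") manifest$normal_sample_id
         else manifest$tumor_sample_id
  m <- matrix(NA_real_, nrow(manifest), nrow(sites),
              dimnames = list(manifest$patient_id, sites$site_id))
  i <- cbind(match(meth$sample_id, sid), match(meth$site_id, sites$site_id))
  ok <- stats::complete.cases(i)
  m[i[ok, , drop = FALSE]] <- meth$level[ok]
  m
}

# (cancer x state) group-mean matrix of standardized levels.
group_mean_matrix <- function(meth_std) {
  grp <- paste(meth_std$cancer_type, meth_std$state, sep = "_")
  agg <- stats::aggregate(meth_std$level_std,
                          by = list(group = grp, site = meth_std$site_id),
                          FUN = mean)
  groups <- sort(unique(agg$group))
  sites <- sort(unique(agg$site))
  m <- matrix(NA_real_, length(groups), length(sites),
              dimnames = list(groups, sites))
  m[cbind(match(agg$group, groups), match(agg$site, sites))] <- agg$x
  m
}

# Expression matrix reader (gene_id first column).
read_expression <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  m
}
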