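# Survival linkage: cohort gating, Cox models on methylation change.

#' Apply the 60-month administrative censoring window
#'
#' @param records data.frame with `time` (months) and `event` (1/0).
#' @param censor_months horizon (default 60).
#' @return records with no risk time beyond the horizon.
#' @export
apply_censoring <- function(records, censor_months = 60) {
  if (censor_months < 0) stop("censor horizon must be non-negative")
  beyond <- records$time > censor_months
  records$event[beyond] <- 0L
  records$time[beyond] <- censor_months
  records
}

#' Cohort eligibility gate for survival analysis
#'
#' Eligible iff at least `min_n` individuals and an event (death) fraction
#' of at least `min_death_rate` within the censoring window.
#'
#' @param records survival records (post-censoring or raw; censoring is
#'   applied first).
#' @param min_n minimum cohort size (default 50).
#' @param min_death_rate minimum event fraction (default 0.25).
#' @param censor_months censoring horizon.
#' @return list `eligible`, `n`, `death_rate`.
#' @export
cohort_gate <- function(records, min_n = 50L, min_death_rate = 0.25,
                        censor_months = 60) {
  records <- apply_censoring(records, censor_months)
  n <- nrow(records)
  dr <- if (n) mean(records$event == 1L) else 0
  list(eligible = n >= min_n && dr >= min_death_rate, n = n, death_rate = dr)
}

#' Cox model of survival on continuous methylation change
#'
#' Proportional-hazards partial-likelihood fit (Efron ties) of survival on
#' the tumor-normal methylation change, optionally adjusted for
#' covariates. The Schoenfeld-residual test of the proportional-hazards
#' assumption is reported; `ph_ok` is a flag, not an automatic rejection.
#'
#' @param records data.frame `time`, `event`, `delta_methylation`, plus any
#'   covariate columns.
#' @param covariates character vector of covariate column names to adjust
#'   for (e.g. age, sex, ethnicity).
#' @param censor_months censoring horizon applied before fitting.
#' @return list `coef`, `se`, `p_value`, `ph_p`, `ph_ok`, `n`, `n_events`.
#' @export
cox_continuous <- function(records, covariates = character(),
                           censor_months = 60) {
  records <- apply_censoring(records, censor_months)
  if (!sum(records$event)) stop("no events: Cox model undefined")
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~ delta_methylation",
    if (length(covariates)) paste("+", paste(covariates, collapse = " + "))
    else ""))
  fit <- survival::coxph(fml, data = records, ties = "efron")
  sm <- summary(fit)
  ph <- tryCatch(survival::cox.zph(fit), error = function(e) NULL)
  ph_p <- if (is.null(ph)) NA_real_ else
    ph$table["delta_methylation", "p"]
  list(coef = unname(sm$coefficients["delta_methylation", "coef"]),
       se = unname(sm$coefficients["delta_methylation", "se(coef)"]),
       p_value = unname(sm$coefficients["delta_methylation", "Pr(>|z|)"]),
       ph_p = ph_p, ph_ok = is.na(ph_p) || ph_p > 0.05,
       n = nrow(records), n_events = sum(records$event))
}

# Median split into two equal-sized groups: the lower ceiling(n/2) values
# by rank go to the low group (ties and the odd middle value to the lower
# group, by stable order).
median_split <- function(x) {
  n <- length(x)
  lower <- order(x)[seq_len(ceiling(n / 2))]
  grp <- rep("high", n)
  grp[lower] <- "low"
  factor(grp, levels = c("low", "high"))
}

#' Cox model on binned methylation change (hazard ratio)
#'
#' Splits the methylation change at the median into two equal-sized groups
#' (odd middle value to the lower group) and fits a Cox model on the group
#' indicator, giving an interpretable hazard ratio with a Wald confidence
#' interval, plus Kaplan-Meier coordinates for plotting.
#'
#' @inheritParams cox_continuous
#' @param conf_level Wald CI level (default 0.95).
#' @return list `hr`, `ci_lower`, `ci_upper`, `p_value`, `group_sizes`,
#'   `km` (data.frame of time, survival, group).
#' @export
cox_binned <- function(records, censor_months = 60, conf_level = 0.95) {
  records <- apply_censoring(records, censor_months)
  if (!sum(records$event)) stop("no events: Cox model undefined")
  records$meth_group <- median_split(records$delta_methylation)
  fit <- survival::coxph(survival::Surv(time, event) ~ meth_group,
                         data = records, ties = "efron")
  sm <- summary(fit, conf.int = conf_level)
  km <- survival::survfit(survival::Surv(time, event) ~ meth_group,
                          data = records)
  km_df <- data.frame(time = km$time, survival = km$surv,
                      group = rep(sub("meth_group=", "", names(km$strata)),
                                  km$strata), stringsAsFactors = FALSE)
  list(hr = unname(sm$conf.int[1, "exp(coef)"]),
       ci_lower = unname(sm$conf.int[1, 3]),
       ci_upper = unname(sm$conf.int[1, 4]),
       p_value = unname(sm$coefficients[1, "Pr(>|z|)"]),
       group_sizes = as.integer(table(records$meth_group)),
       km = km_df)
}

#' Per-site survival scan
#'
#' Runs the continuous and binned Cox models for each p9 site's
#' methylation change, with Bonferroni control over tested sites.
#'
#' @param delta patient x site matrix of tumor-normal methylation change.
#' @param clinical data.frame `patient_id`, `time`, `event` and optional
#'   covariates, rows matching `delta` rows.
#' @param covariates covariate names to adjust for.
#' @param alpha family-wise error rate.
#' @param censor_months censoring horizon.
#' @return data.frame per site: coef, se, p, PH p, HR, CI, flags.
#' @export
survival_scan <- function(delta, clinical, covariates = character(),
                          alpha = 0.05, censor_months = 60) {
  stopifnot(nrow(delta) == nrow(clinical))
  rows <- list()
  for (j in seq_len(ncol(delta))) {
    rec <- clinical
    rec$delta_methylation <- delta[, j]
    rec <- rec[stats::complete.cases(rec$delta_methylation, rec$time,
                                     rec$event), , drop = FALSE]
    if (!nrow(rec) || !sum(apply_censoring(rec, censor_months)$event)) next
    cc <- cox_continuous(rec, covariates, censor_months)
    cb <- cox_binned(rec, censor_months)
    rows[[length(rows) + 1L]] <- data.frame(
      site_id = colnames(delta)[j], n = cc$n, n_events = cc$n_events,
      coef = cc$coef, se = cc$se, p_value = cc$p_value, ph_p = cc$ph_p,
      hr = cb$hr, ci_lower = cb$ci_lower, ci_upper = cb$ci_upper,
      hr_p = cb$p_value, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$bonferroni_significant <-
    out$p_value < bonferroni_threshold(alpha, nrow(out))
  rownames(out) <- NULL
  out
}
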