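# The three-step inferential procedure on the prepared data:
#   1. childhood adversity / recent stress -> promoter methylation
#      (linear models; adversity models restricted to the MDD group
#      because adversity is rare among controls);
#   2. binding potential ~ stress or adversity x genotype (weighted
#      mixed model over regions, then region-wise WLS per group when
#      region interactions are significant);
#   3. binding potential ~ methylation at the three promoter sites
#      (GG carriers excluded because -1019 is in the model).
# Methylation and BP_F enter on the natural-log scale, censored at 1.5
# IQR to the nearest retained value; binding observations carry
# inverse-variance weights from the bootstrap SEs.

meth_sites <- function() c("1019", "1007", "681")

#' Prepare the cohort table for modelling
#'
#' Maps categorical fields to factors (control / CC / female reference
#' levels), collapses gender cells with fewer than 2 observations to the
#' modal level (recorded in the `"notes"` attribute), adds the G-allele
#' count, and adds natural-log, outlier-censored methylation columns
#' `log_meth_1019/1007/681`.  Censoring reports are stored in the
#' `"censoring"` attribute.
#'
#' @param cohort a [cohort_table()]
#' @return data.frame ready for the step models
#' @export
prepare_cohort <- function(cohort) {
  d <- as.data.frame(cohort)
  d$diagnosis <- factor(d$diagnosis, levels = c("control", "MDD"))
  d$genotype <- factor(d$genotype, levels = c("CC", "CG", "GG"))
  d$g_alleles <- code_genotype(as.character(d$genotype), "allele_count")$g_alleles
  d$adversity <- factor(d$adversity, levels = c("no", "yes"))
  notes <- character(0)
  tab <- table(d$gender)
  small <- names(tab)[tab < 2L & tab > 0L]
  if (length(small)) {
    modal <- names(tab)[which.max(tab)]
    notes <- c(notes, paste0("gender level(s) ", paste(small, collapse = ", "),
                             " collapsed to modal level '", modal, "'"))
    d$gender[d$gender %in% small] <- modal
  }
  d$gender <- factor(d$gender)
  reports <- list()
  for (site in meth_sites()) {
    raw <- d[[paste0("meth_", site)]]
    cen <- censor_outliers(log(raw), variable = paste0("log_meth_", site))
    d[[paste0("log_meth_", site)]] <- cen$values
    reports[[site]] <- cen$report
  }
  attr(d, "censoring") <- do.call(rbind, reports)
  attr(d, "notes") <- notes
  d
}

#' Convert one subject's quantification table to binding observations
#'
#' Keeps the 13 ROI rows, log-transforms BP_F (non-positive estimates
#' become missing with a warning) and maps the bootstrap SE to the log
#' scale by the delta method (`se / BP_F`).
#'
#' @param quant data.frame from [quantify_subject()]
#' @param subject_id subject identifier
#' @return data.frame `subject_id`, `region`, `log_bpf`, `se_bpf`
#'   (log-scale SE)
#' @export
make_binding_observations <- function(quant, subject_id) {
  rois <- quant[quant$region != reference_region(), , drop = FALSE]
  log_bpf <- log_transform(rois$bpf)
  se_log <- ifelse(is.na(log_bpf), NA_real_, rois$se_bpf / rois$bpf)
  data.frame(subject_id = subject_id, region = rois$region,
             log_bpf = log_bpf, se_bpf = se_log)
}

#' Merge binding observations with covariates and finalize weights
#'
#' Censors `log_bpf` at 1.5 IQR within each region (each region's
#' binding is one variable), converts the log-scale SEs to
#' inverse-variance weights normalized to mean 1 across the modelling
#' set, and joins the prepared cohort covariates.
#'
#' @param binding data.frame with `subject_id`, `region`, `log_bpf`,
#'   `se_bpf` (log scale)
#' @param cohort a [cohort_table()] or prepared cohort
#' @return merged data.frame with a `weight` column; censoring reports
#'   in the `"censoring"` attribute
#' @export
prepare_binding <- function(binding, cohort) {
  prep <- if (is.null(attr(cohort, "censoring"))) prepare_cohort(cohort) else cohort
  b <- binding[!is.na(binding$log_bpf) & !is.na(binding$se_bpf), , drop = FALSE]
  reports <- list()
  for (r in unique(b$region)) {
    idx <- b$region == r
    cen <- censor_outliers(b$log_bpf[idx], variable = paste0("log_bpf:", r))
    b$log_bpf[idx] <- cen$values
    reports[[r]] <- cen$report
  }
  b$weight <- weights_from_se(b$se_bpf)
  b$region <- factor(b$region, levels = roi_regions())
  out <- merge(b, prep, by = "subject_id", sort = TRUE)
  out <- out[order(out$subject_id, out$region), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "censoring") <- do.call(rbind, reports)
  out
}

geno_term <- function(config) {
  if (config$genotype_coding == "factor") "genotype" else "g_alleles"
}

exposure_var <- function(exposure) {
  switch(exposure, stress = "rlcq_lcu", adversity = "adversity",
         abort_validation("exposure must be 'stress' or 'adversity'"))
}

#' Step 1: childhood adversity / recent stress and promoter methylation
#'
#' Linear model of log methylation at one CpG site on the exposure,
#' genotype, their interaction, age and gender; recent-stress models add
#' diagnostic group.  Adversity models are run in the MDD group only
#' (adversity is rare among controls); models of the -1019 site exclude
#' GG carriers.  Non-significant interactions are pruned.
#'
#' @param cohort a [cohort_table()] or prepared cohort
#' @param exposure `"stress"` or `"adversity"`
#' @param site `"1019"`, `"1007"` or `"681"`
#' @param config a [run_config()]
#' @return a `model_result` with attributes `"prune_log"` and
#'   `"excluded_ids"` (GG exclusions, when they apply)
#' @export
step1_methylation <- function(cohort, exposure, site, config = run_config()) {
  site <- match.arg(site, meth_sites())
  d <- if (is.null(attr(cohort, "censoring"))) prepare_cohort(cohort) else cohort
  excluded <- NULL
  if (exposure == "adversity") d <- d[d$diagnosis == "MDD", , drop = FALSE]
  if (site == "1019") {
    d <- exclude_gg_for_1019(d)
    excluded <- attr(d, "excluded_ids")
  }
  ev <- exposure_var(exposure)
  g <- geno_term(config)
  fixed <- c(ev, g, paste0(ev, ":", g), "age", "gender")
  if (exposure == "stress") fixed <- c(fixed, "diagnosis")
  spec <- model_spec(paste0("log_meth_", site), fixed)
  pr <- prune_interactions(d, spec, config$prune_threshold, config$df_method)
  res <- pr$result
  attr(res, "prune_log") <- pr$log
  attr(res, "excluded_ids") <- excluded
  res
}

# region-wise WLS table for one group: one row per ROI for the focal term
.regionwise_table <- function(data, fixed, focal, group_label, config) {
  rows <- lapply(roi_regions(), function(r) {
    sub <- data[data$region == r, , drop = FALSE]
    spec <- model_spec("log_bpf", fixed, weights = "weight")
    res <- tryCatch(regionwise_wls(sub, spec, focal, config$df_method),
                    error = function(e) NULL)
    if (is.null(res)) {
      return(data.frame(group = group_label, region = r, term = focal,
                        estimate = NA_real_, se = NA_real_, t = NA_real_,
                        df = NA_real_, p = NA_real_,
                        std_estimate = NA_real_, n = 0L))
    }
    row <- res$coef[res$coef$term == focal, , drop = FALSE]
    if (nrow(row) != 1L) {          # factor exposure: use its single dummy
      row <- res$coef[startsWith(res$coef$term, focal), , drop = FALSE][1L, ]
    }
    data.frame(group = group_label, region = r, term = focal,
               estimate = row$estimate, se = row$se, t = row$t,
               df = row$df, p = row$p, std_estimate = row$std_estimate,
               n = res$n)
  })
  do.call(rbind, rows)
}

#' Step 2: binding potential, stress/adversity and genotype
#'
#' Weighted mixed model of log BP_F over all regions with a subject
#' random intercept: region enters as a main effect and in interaction
#' with the exposure and genotype; for recent stress, diagnostic group
#' is included as a main effect and in interaction with stress and
#' region.  Non-significant interactions are pruned.  Region-wise WLS
#' follow-ups are then run per diagnostic group, giving one row per
#' region for the exposure effect with raw and standardized estimates
#' (the shape of the published region-wise stress table).
#'
#' @param merged output of [prepare_binding()] (PET subset)
#' @param exposure `"stress"` or `"adversity"`
#' @param config a [run_config()]
#' @return list with `mixed` (`model_result`), `regionwise`
#'   (data.frame), `prune_log`
#' @export
step2_bpf_exposure <- function(merged, exposure, config = run_config()) {
  ev <- exposure_var(exposure)
  g <- geno_term(config)
  d <- merged
  if (exposure == "adversity") d <- d[d$diagnosis == "MDD", , drop = FALSE]
  fixed <- c("region", ev, g, "age", "gender",
             paste0("region:", ev), paste0("region:", g),
             paste0(ev, ":", g), paste0("region:", ev, ":", g))
  if (exposure == "stress") {
    fixed <- c(fixed, "diagnosis", paste0(ev, ":diagnosis"),
               "region:diagnosis", paste0("region:", ev, ":diagnosis"))
  }
  spec <- model_spec("log_bpf", fixed, random = "subject_id",
                     weights = "weight")
  pr <- prune_interactions(d, spec, config$prune_threshold, config$df_method)
  groups <- if (exposure == "adversity") "MDD" else c("MDD", "control")
  rw_fixed <- c(ev, g, "age", "gender")
  regionwise <- do.call(rbind, lapply(groups, function(gl) {
    .regionwise_table(d[d$diagnosis == gl, , drop = FALSE],
                      rw_fixed, ev, gl, config)
  }))
  rownames(regionwise) <- NULL
  list(mixed = pr$result, regionwise = regionwise, prune_log = pr$log)
}

#' Step 3: binding potential and promoter methylation
#'
#' Weighted mixed model of log BP_F on log methylation at the three
#' promoter sites jointly, with diagnostic group as a main effect and in
#' interactions (site x group, site x region, and the three-way site x
#' region x group), adjusted for genotype, age and gender.  GG carriers
#' are excluded because the -1019 site is in the model.  Region-wise WLS
#' follow-ups per group give one row per site x region x group with
#' standardized estimates (the shape of the published methylation
#' effect-size table).
#'
#' @param merged output of [prepare_binding()] (PET subset)
#' @param config a [run_config()]
#' @return list with `mixed`, `regionwise` (78 rows: 3 sites x 13
#'   regions x 2 groups), `prune_log`, `excluded_ids`
#' @export
step3_bpf_methylation <- function(merged, config = run_config()) {
  d <- exclude_gg_for_1019(merged)
  excluded <- attr(d, "excluded_ids")
  g <- geno_term(config)
  sites <- paste0("log_meth_", meth_sites())
  fixed <- c("region", "diagnosis", sites, g, "age", "gender",
             "region:diagnosis",
             paste0("region:", sites), paste0("diagnosis:", sites),
             paste0("region:diagnosis:", sites))
  spec <- model_spec("log_bpf", fixed, random = "subject_id",
                     weights = "weight")
  pr <- prune_interactions(d, spec, config$prune_threshold, config$df_method)
  rw_fixed <- c(sites, g, "age", "gender")
  regionwise <- do.call(rbind, lapply(c("MDD", "control"), function(gl) {
    sub <- d[d$diagnosis == gl, , drop = FALSE]
    do.call(rbind, lapply(sites, function(s) {
      tab <- .regionwise_table(sub, rw_fixed, s, gl, config)
      tab$site <- sub("log_meth_", "-", s)
      tab
    }))
  }))
  rownames(regionwise) <- NULL
  list(mixed = pr$result, regionwise = regionwise, prune_log = pr$log,
       excluded_ids = excluded)
}

#' Preliminary covariate models
#'
#' Logistic regression of childhood adversity on genotype, age and
#' gender (MDD group only), and multiple linear regression of recent
#' stress on genotype, diagnostic group, age and gender.
#'
#' @param cohort a [cohort_table()] or prepared cohort
#' @param config a [run_config()]
#' @return list with `adversity_model` and `stress_model`
#'   (`model_result` objects)
#' @export
preliminary_models <- function(cohort, config = run_config()) {
  d <- if (is.null(attr(cohort, "censoring"))) prepare_cohort(cohort) else cohort
  g <- geno_term(config)
  mdd <- d[d$diagnosis == "MDD", , drop = FALSE]
  adv <- fit_model(mdd,
                   model_spec("adversity", c(g, "age", "gender"),
                              family = stats::binomial()),
                   config$df_method)
  stress <- fit_model(d,
                      model_spec("rlcq_lcu",
                                 c(g, "diagnosis", "age", "gender")),
                      config$df_method)
  list(adversity_model = adv, stress_model = stress)
}
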