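# Calibrated synthetic study generator.
#
# The generator emulates the statistical structure the analysis assumes:
# MDD/control sizes 192/88 with a 69/50 PET subset; rs6295 genotypes in
# Hardy-Weinberg proportions; childhood adversity prevalences 0.33 (MDD)
# vs 0.06 (controls); recent-stress LCU totals with a between-group
# shift of d = 0.46; trivariate promoter methylation with a -1019/-1007
# rank correlation of 0.28 and a stress->-681 slope; and log BP_F built
# from region baselines, a diagnosis effect of 0.23, MDD-only stress
# slopes in three regions and MDD-only -1007 methylation slopes in seven
# regions, over a subject random intercept and inverse-variance noise.
# Every dataset is fully determined by (config, seed).

#' Configuration of the synthetic study generator
#'
#' Defaults reproduce the study conditions the analysis is designed for;
# see the methods vignette for the reasoning behind values the study
#' does not pin down.
#'
#' @param n_mdd,n_control cohort sizes
#' @param pet_n_mdd,pet_n_control PET subset sizes
#' @param g_allele_freq rs6295 G-allele frequency (genotypes drawn under
#'   Hardy-Weinberg equilibrium)
#' @param adversity_prev named prevalences for `MDD` and `control`
#' @param stress_shape,stress_scale gamma parameters of the control
#'   LCU total distribution
#' @param stress_d standardized MDD-control mean shift in LCU totals
#' @param adversity_missing,rlcq_missing,meth_1019_extra_missing,meth_681_missing
#'   missingness rates
#' @param meth_mean methylation fractions at -1019/-1007/-681 (means on
#'   the fraction scale; values are generated by a logistic transform of
#'   a latent trivariate normal so they stay in (0, 1))
#' @param meth_latent_sd latent logit-scale SDs
#' @param meth_cor_1019_1007 target rank correlation between -1019 and
#'   -1007 methylation (other pairs uncorrelated)
#' @param stress_meth681_slope latent-logit units of -681 methylation
#'   per LCU (centered stress)
#' @param diagnosis_effect MDD shift of log BP_F, all regions
#' @param stress_bpf_slope log BP_F per LCU in [stress_effect_regions()],
#'   MDD only
#' @param meth1007_bpf_slope log BP_F per unit centered log -1007
#'   methylation in [methylation_effect_regions()], MDD only
#' @param region_baseline named numeric: baseline log BP_F per ROI
#' @param subject_sd SD of the subject random intercept (log scale)
#' @param se_log_mean,se_log_sd lognormal parameters of the per-
#'   observation BP_F standard errors (log scale); the observation noise
#'   SD equals the drawn SE, so weights are correctly specified
#' @param vnd reference-region non-displaceable volume of distribution
#'   (K1'/k2')
#' @param ref_K1 reference-region K1'
#' @param fp_range plasma free-fraction range (uniform draw)
#' @param tac_noise_pct TAC noise as a fraction of activity (SD =
#'   `pct * activity / sqrt(duration)`)
#' @param n_frames,scan_minutes framing of the synthetic acquisition
#'   (geometrically lengthening frames)
#' @return list of class `generator_config`
#' @export
generator_config <- function(
    n_mdd = 192L, n_control = 88L,
    pet_n_mdd = 69L, pet_n_control = 50L,
    g_allele_freq = 0.5,
    adversity_prev = c(MDD = 0.33, control = 0.06),
    stress_shape = 2, stress_scale = 75, stress_d = 0.46,
    adversity_missing = 0.07, rlcq_missing = 0.21,
    meth_1019_extra_missing = 5 / 280, meth_681_missing = 1 / 280,
    meth_mean = c(0.30, 0.05, 0.02),
    meth_latent_sd = c(0.5, 0.5, 0.5),
    meth_cor_1019_1007 = 0.28,
    stress_meth681_slope = 0.001,
    diagnosis_effect = 0.23,
    stress_bpf_slope = 0.001,
    meth1007_bpf_slope = 0.3,
    region_baseline = NULL,
    subject_sd = 0.1,
    se_log_mean = log(0.25), se_log_sd = 0.3,
    vnd = 0.5, ref_K1 = 0.08,
    fp_range = c(0.05, 0.15),
    tac_noise_pct = 0.05,
    n_frames = 20L, scan_minutes = 110) {
  if (g_allele_freq <= 0 || g_allele_freq >= 1) {
    abort_validation("g_allele_freq must lie in (0, 1)")
  }
  if (any(adversity_prev < 0 | adversity_prev > 1)) {
    abort_validation("prevalences must lie in [0, 1]")
  }
  if (abs(meth_cor_1019_1007) >= 1) {
    abort_validation("methylation correlation must lie in (-1, 1)")
  }
  if (is.null(region_baseline)) {
    region_baseline <- log(c(
      "raphe nuclei" = 3.5, "anterior cingulate" = 5.5, "cingulate" = 5.0,
      "dorsal prefrontal cortex" = 4.5, "hippocampus" = 6.5, "insula" = 5.5,
      "medial prefrontal cortex" = 5.0, "parietal cortex" = 4.0,
      "parahippocampal gyrus" = 6.0, "occipital cortex" = 3.0,
      "orbital cortex" = 5.5, "temporal cortex" = 5.0, "amygdala" = 5.5
    ))
  }
  if (!all(roi_regions() %in% names(region_baseline))) {
    abort_validation("region_baseline must cover all 13 ROIs")
  }
  structure(as.list(environment()), class = "generator_config")
}

# latent Pearson correlation giving a target Spearman correlation for
# bivariate normal latents (monotone transforms preserve rank correlation)
.pearson_for_spearman <- function(rs) 2 * sin(pi * rs / 6)

#' Generate a synthetic cohort table
#'
#' Genotypes are drawn under Hardy-Weinberg equilibrium; adversity is
#' Bernoulli by group; LCU totals are gamma with a constant MDD shift
#' calibrated to the configured Cohen's d; methylation is a logistic
#' transform of a latent trivariate normal with the configured
#' correlation plus the stress->-681 term; GG carriers get missing
#' -1019 values by construction.  The complete (pre-missingness) stress
#' and methylation values are kept in the `"latent"` attribute so the
#' binding generator and recovery tests can use the ground truth.
#'
#' @param config a [generator_config()]
#' @param seed integer seed
#' @return a [cohort_table()] with an extra logical `pet` column and
#'   attributes `"latent"` and `"truth"`
#' @export
generate_cohort <- function(config = generator_config(), seed = 1L) {
  set.seed(seed)
  n <- config$n_mdd + config$n_control
  diagnosis <- rep(c("MDD", "control"), c(config$n_mdd, config$n_control))
  subject_id <- sprintf("S%03d", seq_len(n))
  age <- round(pmin(pmax(stats::rnorm(n, 40, 12), 18), 70), 1)
  gender <- ifelse(diagnosis == "MDD",
                   sample(c("female", "male", "other"), n, TRUE,
                          prob = c(0.573, 0.422, 0.005)),
                   sample(c("female", "male"), n, TRUE,
                          prob = c(48, 40) / 88))
  f <- config$g_allele_freq
  genotype <- sample(c("CC", "CG", "GG"), n, TRUE,
                     prob = c((1 - f)^2, 2 * f * (1 - f), f^2))
  prev <- config$adversity_prev[diagnosis]
  adversity <- ifelse(stats::rbinom(n, 1, prev) == 1, "yes", "no")

  # gamma(shape, scale) has SD scale * sqrt(shape); equal SDs in the two
  # groups make the pooled SD the same, so a constant shift of d * SD
  # realizes the target standardized difference
  shift <- config$stress_d * config$stress_scale * sqrt(config$stress_shape)
  stress <- stats::rgamma(n, config$stress_shape, scale = config$stress_scale) +
    ifelse(diagnosis == "MDD", shift, 0)

  rho <- .pearson_for_spearman(config$meth_cor_1019_1007)
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- rho
  L <- tryCatch(chol(R), error = function(e) {
    abort_validation("infeasible methylation correlation matrix")
  })
  Z <- matrix(stats::rnorm(3 * n), ncol = 3) %*% L
  mu <- stats::qlogis(config$meth_mean)
  latent <- sweep(Z %*% diag(config$meth_latent_sd), 2, mu, `+`)
  latent[, 3] <- latent[, 3] +
    config$stress_meth681_slope * (stress - mean(stress))
  meth <- stats::plogis(latent)

  hrsd <- ifelse(
    diagnosis == "MDD",
    pmax(0, round(20 + 2 * scale(latent[, 3])[, 1] + stats::rnorm(n, 0, 5))),
    stats::rpois(n, 1.5)
  )

  pet <- rep(FALSE, n)
  pet[sample(which(diagnosis == "MDD"), config$pet_n_mdd)] <- TRUE
  pet[sample(which(diagnosis == "control"), config$pet_n_control)] <- TRUE

  df <- data.frame(
    subject_id = subject_id, diagnosis = diagnosis, age = age,
    gender = gender, genotype = genotype, adversity = adversity,
    rlcq_lcu = round(stress, 1),
    meth_1019 = round(meth[, 1], 4), meth_1007 = round(meth[, 2], 4),
    meth_681 = round(meth[, 3], 4), hrsd = hrsd, pet = pet
  )
  # missingness (missing completely at random, as the analysis assumes)
  df$adversity[stats::runif(n) < config$adversity_missing] <- NA
  df$rlcq_lcu[stats::runif(n) < config$rlcq_missing] <- NA
  df$meth_1019[genotype == "GG"] <- NA
  df$meth_1019[stats::runif(n) < config$meth_1019_extra_missing] <- NA
  df$meth_681[stats::runif(n) < config$meth_681_missing] <- NA

  out <- cohort_table(df)
  attr(out, "latent") <- data.frame(
    subject_id = subject_id, stress = stress,
    log_meth_1007 = log(meth[, 2])
  )
  attr(out, "truth") <- list(
    stress_d = config$stress_d, adversity_prev = config$adversity_prev,
    meth_cor_1019_1007 = config$meth_cor_1019_1007,
    stress_meth681_slope = config$stress_meth681_slope
  )
  out
}

#' Generate binding observations for the PET subset
#'
#' `log BP_F = baseline(region) + diagnosis_effect x I(MDD) +
#' stress_bpf_slope x centered LCU x I(MDD, stress region) +
#' meth1007_bpf_slope x centered log -1007 methylation x I(MDD, meth
#' region) + subject intercept + noise`, with per-observation noise SD
#' equal to the drawn standard error (so the inverse-variance weights
#' are correctly specified).  Centering uses the MDD PET subset means,
#' so the injected slopes do not shift the marginal diagnosis effect.
#'
#' @param cohort a cohort from [generate_cohort()] (its `"latent"`
#'   attribute supplies complete stress / methylation values)
#' @param config a [generator_config()]
#' @param seed integer seed
#' @return data.frame of binding observations (`subject_id`, `region`,
#'   `log_bpf`, `se_bpf`) with a `"truth"` attribute recording every
#'   generated effect
#' @export
generate_binding <- function(cohort, config = generator_config(), seed = 1L) {
  set.seed(seed + 1000L)
  lat <- attr(cohort, "latent")
  stopifnot(!is.null(lat))
  pet <- cohort[cohort$pet, , drop = FALSE]
  lat <- lat[match(pet$subject_id, lat$subject_id), , drop = FALSE]
  n <- nrow(pet)
  regions <- roi_regions()
  mdd <- pet$diagnosis == "MDD"
  stress_c <- lat$stress - mean(lat$stress[mdd])
  meth_c <- lat$log_meth_1007 - mean(lat$log_meth_1007[mdd])
  b_subj <- stats::rnorm(n, 0, config$subject_sd)

  rows <- lapply(seq_along(regions), function(ri) {
    r <- regions[ri]
    mu <- config$region_baseline[[r]] +
      config$diagnosis_effect * mdd +
      (r %in% stress_effect_regions()) *
        config$stress_bpf_slope * stress_c * mdd +
      (r %in% methylation_effect_regions()) *
        config$meth1007_bpf_slope * meth_c * mdd
    se <- stats::rlnorm(n, config$se_log_mean, config$se_log_sd)
    data.frame(subject_id = pet$subject_id, region = r,
               log_bpf = mu + b_subj + stats::rnorm(n, 0, se),
               se_bpf = se)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$subject_id, out$region), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "truth") <- list(
    diagnosis_effect = config$diagnosis_effect,
    stress_bpf_slope = config$stress_bpf_slope,
    stress_regions = stress_effect_regions(),
    meth1007_bpf_slope = config$meth1007_bpf_slope,
    meth_regions = methylation_effect_regions(),
    region_baseline = config$region_baseline,
    subject_sd = config$subject_sd
  )
  out
}

# geometric frame schedule: durations d1 * r^(0:(k-1)) summing to the
# scan length, first frame 0.25 min
.frame_schedule <- function(n_frames, scan_minutes, d1 = 0.25) {
  f <- function(r) d1 * sum(r^(0:(n_frames - 1L))) - scan_minutes
  r <- stats::uniroot(f, c(1.0001, 3), tol = 1e-12)$root
  durations <- d1 * r^(0:(n_frames - 1L))
  starts <- cumsum(c(0, durations[-n_frames]))
  list(start = starts, duration = durations)
}

# template arterial input function: sharp early peak, slow tail
.template_aif <- function() aif_model(tp = 1.5, A = c(200, 50, 10),
                                      lambda = c(2.0, 0.3, 0.01))

# template Hill metabolite curve
.template_hill <- function() {
  structure(list(t50 = 20, h = 2, floor = 0.05, rss = 0, converged = TRUE),
            class = "hill_fit")
}

#' Generate raw PET inputs (plasma + TACs) for one synthetic subject
#'
#' Draws f_P and uses the configured V_ND; each ROI's total volume of
#' distribution is `V_T = V_ND + f_P x BP_F`, realized by a two-tissue
#' parameter set with `k2 = K1 / V_ND` and `k3 = k4 (V_T / V_ND - 1)`.
#' The reference region is a pure one-tissue curve (BP_F = 0 by
#' construction).  Plasma samples follow the template piecewise AIF and
#' Hill parent-fraction curve exactly (total activity = AIF / parent
#' fraction); TACs are framed on a geometrically lengthening schedule
#' with Gaussian noise of SD `noise_pct x activity / sqrt(duration)`.
#'
#' @param target_bpf named vector of target BP_F for the 13 ROIs, >= 0
#' @param config a [generator_config()]
#' @param seed integer seed
#' @param noise_pct TAC noise level (defaults to `config$tac_noise_pct`;
#'   0 gives noiseless curves)
#' @return list with `plasma` ([plasma_series()]), `tacs` (named list of
#'   [tac()]), and `truth` (f_P, V_ND, per-region parameters and V_T)
#' @export
generate_pet_subject <- function(target_bpf, config = generator_config(),
                                 seed = 1L, noise_pct = NULL) {
  if (is.null(names(target_bpf))) names(target_bpf) <- roi_regions()
  if (!all(roi_regions() %in% names(target_bpf))) {
    abort_validation("target_bpf must name all 13 ROIs")
  }
  if (any(target_bpf < 0)) {
    abort_validation("target BP_F must be >= 0 (would imply k3/k4 < 0)")
  }
  noise_pct <- noise_pct %||% config$tac_noise_pct
  set.seed(seed + 2000L)
  fp <- stats::runif(1, config$fp_range[1L], config$fp_range[2L])
  vnd <- config$vnd
  aif <- .template_aif()
  hill <- .template_hill()

  # arterial sampling: dense around the peak, sparse late; includes the
  # template peak time so the piecewise model is exactly recoverable
  times <- c(0.25, 0.5, 0.75, 1, 1.25, 1.5, 2, 2.5, 3, 4, 5, 7, 10, 15,
             20, 30, 45, 60, 80, 100)
  pf <- predict_parent_fraction(hill, times)
  total <- evaluate_aif(aif, times) / pf
  pf_meas <- ifelse(seq_along(times) %% 2 == 1L, pf, NA_real_)
  plasma <- plasma_series(times, total, pf_meas, fp)

  sched <- .frame_schedule(config$n_frames, config$scan_minutes)
  k4 <- 0.02
  K1 <- 0.1
  truth_rows <- list()
  make_region_tac <- function(region, params) {
    clean <- predict_tac(params, aif, sched$start, sched$duration, "midpoint")
    noisy <- if (noise_pct > 0) {
      clean + stats::rnorm(length(clean),
                           0, noise_pct * abs(clean) / sqrt(sched$duration))
    } else {
      clean
    }
    tac(region, sched$start, sched$duration, noisy)
  }
  tacs <- list()
  for (r in roi_regions()) {
    vt <- vnd + fp * target_bpf[[r]]
    params <- kinetic_params(K1, K1 / vnd, k4 * (vt / vnd - 1), k4)
    tacs[[r]] <- make_region_tac(r, params)
    truth_rows[[r]] <- data.frame(region = r, K1 = params$K1,
                                  k2 = params$k2, k3 = params$k3,
                                  k4 = params$k4, vt = vt,
                                  bpf = target_bpf[[r]])
  }
  ref_params <- kinetic_params(config$ref_K1, config$ref_K1 / vnd)
  tacs[[reference_region()]] <- make_region_tac(reference_region(), ref_params)
  truth_rows[[reference_region()]] <- data.frame(
    region = reference_region(), K1 = ref_params$K1, k2 = ref_params$k2,
    k3 = NA_real_, k4 = NA_real_, vt = vnd, bpf = 0
  )
  list(
    plasma = plasma, tacs = tacs,
    truth = list(fp = fp, vnd = vnd, aif = aif, hill = hill,
                 params = do.call(rbind, truth_rows))
  )
}
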