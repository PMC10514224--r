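# construct a small multi-region data set with known structure; centering
# the noise within subject forces the REML random-intercept variance to
# its zero boundary, which is the regime where the mixed fit must agree
# with ordinary least squares
make_zero_variance_data <- function(seed = 1, n_subj = 30, n_region = 4) {
  set.seed(seed)
  d <- expand.grid(subject_id = sprintf("P%02d", 1:n_subj),
                   region = factor(paste0("r", 1:n_region)))
  d$x <- rnorm(nrow(d))
  eps <- rnorm(nrow(d))
  eps <- eps - ave(eps, d$subject_id)        # no between-subject variance
  d$y <- 1 + 0.5 * d$x + 0.3 * (d$region == "r2") + eps
  d$w <- 1
  d
}

test_that("mixed model with zero random variance equals the normal equations", {
  d <- make_zero_variance_data()
  spec <- model_spec("y", c("region", "x"), random = "subject_id",
                     weights = "w")
  res <- fit_weighted_lmm(d, spec)
  expect_true(res$singular)
  expect_identical(res$random_sd, 0)
  X <- model.matrix(~ region + x, d)
  beta <- wls_oracle(X, d$y, d$w)
  expect_equal(res$coef$estimate, as.numeric(beta), tolerance = 1e-6)
})

test_that("region-wise WLS with equal weights equals OLS", {
  set.seed(2)
  d <- data.frame(x = rnorm(40), g = factor(rbinom(40, 1, 0.4)))
  d$y <- 2 - 0.7 * d$x + rnorm(40)
  d$weight <- 1
  spec <- model_spec("y", c("x", "g"), weights = "weight")
  res <- regionwise_wls(d, spec, focal = "x")
  ols <- lm(y ~ x + g, data = d)
  expect_equal(res$coef$estimate, unname(coef(ols)), tolerance = 1e-10)
  expect_equal(res$coef$se, unname(sqrt(diag(vcov(ols)))), tolerance = 1e-10)
  # standardized estimate definition
  xrow <- res$coef[res$coef$term == "x", ]
  expect_equal(xrow$std_estimate, xrow$estimate * sd(d$x))
})

test_that("estimates are invariant to rescaling all weights", {
  d <- make_zero_variance_data(seed = 3)
  d$w2 <- 2 * d$w
  spec1 <- model_spec("y", c("region", "x"), random = "subject_id",
                      weights = "w")
  spec2 <- model_spec("y", c("region", "x"), random = "subject_id",
                      weights = "w2")
  r1 <- fit_weighted_lmm(d, spec1)
  r2 <- fit_weighted_lmm(d, spec2)
  expect_equal(r1$coef$estimate, r2$coef$estimate, tolerance = 1e-8)
})

test_that("joint Wald F reduces to t^2 for single-coefficient terms", {
  d <- make_zero_variance_data(seed = 4)
  spec <- model_spec("y", c("region", "x"), random = "subject_id",
                     weights = "w")
  res <- fit_weighted_lmm(d, spec)
  tx <- res$coef$t[res$coef$term == "x"]
  ft <- test_interaction(res, "x")
  expect_equal(ft$F, tx^2, tolerance = 1e-10)
  expect_identical(ft$df1, 1L)
})

test_that("F statistics are invariant to region level reordering", {
  d <- make_merged(seed = 11)
  spec <- model_spec("log_bpf", c("region", "rlcq_lcu", "region:rlcq_lcu"),
                     random = "subject_id", weights = "weight")
  r1 <- fit_weighted_lmm(d, spec)
  d2 <- d
  d2$region <- factor(d2$region, levels = rev(levels(d$region)))
  r2 <- fit_weighted_lmm(d2, spec)
  f1 <- test_interaction(r1, "region:rlcq_lcu")
  f2 <- test_interaction(r2, "region:rlcq_lcu")
  expect_equal(f1$F, f2$F, tolerance = 1e-6)
  expect_identical(f1$df1, f2$df1)
})

test_that("interaction pruning drops null terms, keeps strong ones, logs order", {
  set.seed(7)
  n <- 300
  d <- data.frame(x = rnorm(n), z = rnorm(n), u = rnorm(n))
  d$y <- 1 + d$x + d$z + 1.5 * d$x * d$z + rnorm(n)   # x:z real, x:u null
  spec <- model_spec("y", c("x", "z", "u", "x:z", "x:u"))
  pr <- prune_interactions(d, spec, threshold = 0.05)
  expect_true("x:z" %in% pr$spec$fixed)
  expect_false("x:u" %in% pr$spec$fixed)
  expect_equal(pr$log$removed, "x:u")
  # main effects are never dropped
  expect_true(all(c("x", "z", "u") %in% pr$spec$fixed))
})

test_that("pruning respects marginality for three-way interactions", {
  set.seed(8)
  n <- 400
  d <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  d$y <- d$a + d$b + d$c + rnorm(n)      # all interactions null
  spec <- model_spec("y", c("a", "b", "c", "a:b", "a:b:c"))
  pr <- prune_interactions(d, spec, threshold = 0.05)
  expect_false(any(grepl(":", pr$spec$fixed)))
  # the three-way must have been removed before its nested two-way
  expect_equal(pr$log$removed[1], "a:b:c")
})

test_that("no multiplicity adjustment appears in any output table", {
  d <- make_merged(seed = 12)
  s2 <- step2_bpf_exposure(d, "stress")
  expect_false(any(grepl("adjust|fdr|bonferroni|p_adj",
                         names(s2$regionwise), ignore.case = TRUE)))
  expect_false(any(grepl("adjust|fdr|bonferroni|p_adj",
                         names(s2$mixed$coef), ignore.case = TRUE)))
})

test_that("step 1 applies the MDD restriction and the GG exclusion", {
  ch <- generate_cohort(seed = 13)
  res_adv <- step1_methylation(ch, "adversity", "681")
  n_mdd_avail <- with(as.data.frame(ch),
                      sum(diagnosis == "MDD" & !is.na(adversity) &
                            !is.na(meth_681)))
  expect_equal(res_adv$n, n_mdd_avail)

  res_1019 <- step1_methylation(ch, "stress", "1019")
  expect_true(length(attr(res_1019, "excluded_ids")) > 0)
  expect_false(any(grepl("GG", res_1019$coef$term)))
  # stress models keep both groups and include diagnosis
  expect_true(any(res_1019$coef$term == "diagnosisMDD"))
})

test_that("step 2 emits a 13-row region-wise table per group", {
  d <- make_merged(seed = 14)
  s2 <- step2_bpf_exposure(d, "stress")
  expect_equal(nrow(s2$regionwise), 26L)
  expect_setequal(unique(s2$regionwise$group), c("control", "MDD"))
  expect_setequal(unique(s2$regionwise$region), roi_regions())
  expect_true(all(c("estimate", "se", "t", "p", "std_estimate", "n") %in%
                    names(s2$regionwise)))
  s2a <- step2_bpf_exposure(d, "adversity")
  expect_equal(unique(s2a$regionwise$group), "MDD")
  expect_equal(nrow(s2a$regionwise), 13L)
})

test_that("step 3 emits 3 sites x 13 regions x 2 groups and excludes GG", {
  d <- make_merged(seed = 15)
  s3 <- step3_bpf_methylation(d)
  expect_equal(nrow(s3$regionwise), 78L)
  expect_setequal(unique(s3$regionwise$site), c("-1019", "-1007", "-681"))
  expect_true(length(s3$excluded_ids) > 0)
  expect_false(any(s3$excluded_ids %in%
                     d$subject_id[d$genotype != "GG"]))
})

test_that("region-wise significance shows the expected group contrast", {
  # controls carry no generated stress or methylation slopes: their
  # per-region rejection rate stays near the nominal 5% level, while in
  # the MDD group significance concentrates in the generated regions
  rw_stress <- c("rlcq_lcu", "genotype", "age", "gender")
  sites <- paste0("log_meth_", c("1019", "1007", "681"))
  rw_meth <- c(sites, "genotype", "age", "gender")
  slope_p <- function(data, fixed, focal) {
    rw <- regionwise_wls(data, model_spec("log_bpf", fixed,
                                          weights = "weight"), focal)
    row <- rw$coef[rw$coef$term == focal, ]
    c(row$p, row$estimate)
  }
  n_sim <- 50
  ctrl_rej <- 0; mdd_true_hit <- 0; mdd_null_rej <- 0
  meth_true_hit <- 0; meth_null_rej <- 0
  other_stress <- setdiff(roi_regions(), stress_effect_regions())
  other_meth <- setdiff(roi_regions(), methylation_effect_regions())
  for (s in 1:n_sim) {
    m <- make_merged(seed = 3000 + s)
    ctrl <- m[m$diagnosis == "control", ]
    mdd <- m[m$diagnosis == "MDD", ]
    nogg <- mdd[mdd$genotype != "GG", ]
    for (r in roi_regions()) {
      pr <- slope_p(ctrl[ctrl$region == r, ], rw_stress, "rlcq_lcu")
      ctrl_rej <- ctrl_rej + (pr[1] < 0.05)
    }
    for (r in stress_effect_regions()) {
      pr <- slope_p(mdd[mdd$region == r, ], rw_stress, "rlcq_lcu")
      mdd_true_hit <- mdd_true_hit + (pr[1] < 0.05 && pr[2] > 0)
    }
    for (r in other_stress[1:3]) {
      pr <- slope_p(mdd[mdd$region == r, ], rw_stress, "rlcq_lcu")
      mdd_null_rej <- mdd_null_rej + (pr[1] < 0.05)
    }
    for (r in methylation_effect_regions()) {
      pr <- slope_p(nogg[nogg$region == r, ], rw_meth, "log_meth_1007")
      meth_true_hit <- meth_true_hit + (pr[1] < 0.05 && pr[2] > 0)
    }
    for (r in other_meth[1:3]) {
      pr <- slope_p(nogg[nogg$region == r, ], rw_meth, "log_meth_1007")
      meth_null_rej <- meth_null_rej + (pr[1] < 0.05)
    }
  }
  ctrl_rate <- ctrl_rej / (13 * n_sim)
  expect_lte(ctrl_rate, 0.10)              # near nominal, no spurious signal
  # generated regions dominate the significant set in the MDD group
  expect_gt(mdd_true_hit / (3 * n_sim), 3 * mdd_null_rej / (3 * n_sim))
  expect_gt(mdd_true_hit / (3 * n_sim), 0.4)
  expect_gt(meth_true_hit / (7 * n_sim), 3 * meth_null_rej / (3 * n_sim))
  expect_gt(meth_true_hit / (7 * n_sim), 0.5)
})

test_that("preliminary models fit, and separation raises a clear error", {
  ch <- generate_cohort(seed = 16)
  pm <- preliminary_models(ch)
  expect_s3_class(pm$adversity_model, "model_result")
  expect_true("diagnosisMDD" %in% pm$stress_model$coef$term)

  tiny <- data.frame(
    subject_id = paste0("T", 1:8),
    diagnosis = "MDD",
    age = c(20, 21, 22, 23, 50, 51, 52, 53),
    gender = rep(c("female", "male"), 4),
    genotype = rep("CC", 8),
    adversity = factor(rep(c("no", "yes"), each = 4), c("no", "yes")),
    rlcq_lcu = 1:8, hrsd = 1:8,
    meth_1019 = 0.3, meth_1007 = 0.05, meth_681 = 0.02
  )
  expect_error(
    fit_model(tiny, model_spec("adversity", c("age"), family = binomial())),
    "separation"
  )
})
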