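test_that("two-tissue model nests the one-tissue model at k3 = 0", {
  aif <- template_aif()
  sched <- template_schedule()
  p2 <- kinetic_params(0.1, 0.2, 0, 0.02)
  p1 <- kinetic_params(0.1, 0.2)
  expect_equal(
    predict_tac(p2, aif, sched$start, sched$duration),
    predict_tac(p1, aif, sched$start, sched$duration)
  )
  # one-tissue curve is K1 * (C_p conv exp(-k2 t)) by definition
  mid <- sched$start + sched$duration / 2
  expect_equal(predict_tac(p1, aif, sched$start, sched$duration),
               0.1 * convolve_exp(aif, 0.2, mid))
})

test_that("V_T equals the integrated impulse response (quadrature oracle)", {
  # independently coded impulse response, integrated numerically
  impulse <- function(K1, k2, k3, k4) {
    s <- k2 + k3 + k4
    r <- sqrt(s^2 - 4 * k2 * k4)
    a1 <- (s - r) / 2
    a2 <- (s + r) / 2
    function(t) K1 / (a2 - a1) *
      ((k3 + k4 - a1) * exp(-a1 * t) + (a2 - k3 - k4) * exp(-a2 * t))
  }
  p <- kinetic_params(0.1, 0.05, 0.03, 0.01)
  expect_identical(vt_from_params(p), 8)
  num <- integrate(impulse(0.1, 0.05, 0.03, 0.01), 0, 1e4,
                   rel.tol = 1e-10)$value
  expect_equal(vt_from_params(p), num, tolerance = 1e-4)

  set.seed(31)
  for (i in 1:20) {
    K1 <- runif(1, 0.02, 0.4); k2 <- runif(1, 0.02, 0.5)
    k3 <- runif(1, 0.005, 0.2); k4 <- runif(1, 0.005, 0.2)
    pp <- kinetic_params(K1, k2, k3, k4)
    num <- integrate(impulse(K1, k2, k3, k4), 0, Inf, rel.tol = 1e-10)$value
    expect_equal(vt_from_params(pp), num, tolerance = 1e-6)
  }
})

test_that("zero-amplitude input gives an all-zero tissue curve", {
  flat <- aif_model(tp = 1.5, A = c(0, 0, 0), lambda = c(2, 0.3, 0.01))
  sched <- template_schedule()
  pred <- predict_tac(kinetic_params(0.1, 0.2, 0.06, 0.02), flat,
                      sched$start, sched$duration)
  expect_equal(pred, rep(0, length(sched$start)))
})

test_that("reference fit recovers truth and is scale-equivariant in the AIF", {
  aif <- template_aif()
  ref <- make_roi_tac(reference_region(), K1 = 0.08, k2 = 0.16, k3 = NA)
  fit <- fit_reference(ref, aif)
  expect_equal(fit$params$K1, 0.08, tolerance = 1e-4)
  expect_equal(fit$params$k2, 0.16, tolerance = 1e-4)
  expect_equal(fit$vnd, 0.5, tolerance = 1e-4)
  expect_identical(fit$bpf, 0)

  expect_error(fit_reference(make_roi_tac("insula", k3 = NA), aif),
               "cerebellar white matter")

  # doubling the AIF amplitude doubles K1', leaves k2' unchanged
  aif2 <- aif_model(aif$tp, 2 * aif$A, aif$lambda)
  fit2 <- fit_reference(ref, aif2)
  expect_equal(fit2$params$K1, fit$params$K1 / 2, tolerance = 1e-6)
  expect_equal(fit2$params$k2, fit$params$k2, tolerance = 1e-6)
})

test_that("constrained ROI fit recovers V_T and honours the constraint", {
  aif <- template_aif()
  roi <- make_roi_tac("amygdala", K1 = 0.1, k2 = 0.2, k3 = 0.06, k4 = 0.02)
  fit <- fit_roi_2tcc(roi, aif, vnd_ref = 0.5)
  expect_identical(fit$params$K1 / fit$params$k2, 0.5)  # exact by construction
  expect_equal(fit$vt, 2.0, tolerance = 1e-3)
  expect_equal(fit$params$k3, 0.06, tolerance = 1e-3)
  expect_error(fit_roi_2tcc(make_roi_tac(reference_region()), aif, 0.5),
               "ROI")
  expect_error(fit_roi_2tcc(roi, aif, -1), "positive")
})

test_that("BP_F formula and its degenerate cases", {
  expect_equal(compute_bpf(2.0, 0.5, 0.1), 15)
  expect_equal(compute_bpf(0.5, 0.5, 0.1), 0)
  expect_equal(compute_bpf(0.4, 0.5, 0.1), -1)   # negative allowed
  expect_error(compute_bpf(2, 0.5, 0), "fp")
})

test_that("single-subject quantification recovers generator truth end to end", {
  gen <- generator_config()
  subj <- generate_pet_subject(exp(gen$region_baseline), gen, seed = 7,
                               noise_pct = 0)
  cfg <- run_config(boot_B = 0)
  q <- quantify_subject(subj$plasma, subj$tacs, cfg)
  expect_equal(nrow(q), 14L)
  ref_row <- q[q$region == reference_region(), ]
  expect_identical(ref_row$bpf, 0)
  truth <- subj$truth$params
  m <- merge(q[q$region != reference_region(), ], truth, by = "region",
             suffixes = c("", ".true"))
  expect_true(all(abs(m$bpf - m$bpf.true) / m$bpf.true < 0.05))
  # constraint holds in every ROI row
  expect_true(all(abs(m$K1 / m$k2 - subj$truth$vnd) < 1e-12))
  expect_error(
    quantify_subject(subj$plasma,
                     subj$tacs[setdiff(all_regions(), reference_region())],
                     cfg),
    "cerebellar white matter"
  )
})

test_that("quantification is deterministic under a fixed seed", {
  gen <- generator_config(tac_noise_pct = 0.05)
  subj <- generate_pet_subject(exp(gen$region_baseline), gen, seed = 9)
  cfg <- run_config(boot_B = 10, seed = 42)
  q1 <- suppressWarnings(quantify_subject(subj$plasma, subj$tacs, cfg))
  q2 <- suppressWarnings(quantify_subject(subj$plasma, subj$tacs, cfg))
  expect_identical(q1, q2)
  expect_true(all(q1$se_bpf[q1$region != reference_region()] > 0))
})

test_that("BP_F is invariant to joint rescaling of plasma and TAC units", {
  gen <- generator_config()
  subj <- generate_pet_subject(exp(gen$region_baseline), gen, seed = 13,
                               noise_pct = 0)
  cfg <- run_config(boot_B = 0)
  q1 <- quantify_subject(subj$plasma, subj$tacs, cfg)
  c_scale <- 37           # e.g. kBq -> nCi
  plasma2 <- plasma_series(subj$plasma$sample_times,
                           subj$plasma$total_activity * c_scale,
                           subj$plasma$parent_fraction, subj$plasma$fp)
  tacs2 <- lapply(subj$tacs, function(x)
    tac(x$region, x$frame_start, x$frame_duration, x$activity * c_scale))
  q2 <- quantify_subject(plasma2, tacs2, cfg)
  expect_equal(q2$bpf, q1$bpf, tolerance = 1e-6)
})
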