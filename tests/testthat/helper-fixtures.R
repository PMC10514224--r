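# shared fixtures, built in code at test time

template_aif <- function() aif_model(tp = 1.5, A = c(200, 50, 10),
                                     lambda = c(2.0, 0.3, 0.01))

template_schedule <- function() petbpf:::.frame_schedule(20, 110)

# noiseless tissue curve for given rates on the template schedule
make_roi_tac <- function(region = "amygdala", K1 = 0.1, k2 = 0.2,
                         k3 = 0.06, k4 = 0.02, aif = template_aif(),
                         noise_sd = NULL, seed = NULL) {
  sched <- template_schedule()
  p <- if (is.na(k3) || is.null(k3)) kinetic_params(K1, k2) else
    kinetic_params(K1, k2, k3, k4)
  y <- predict_tac(p, aif, sched$start, sched$duration)
  if (!is.null(noise_sd)) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + rnorm(length(y), 0, noise_sd)
  }
  tac(region, sched$start, sched$duration, y)
}

# duration-scaled PET noise SD for a clean curve at a fractional level
pet_noise_sd <- function(clean, pct = 0.05) {
  sched <- template_schedule()
  pct * abs(clean) / sqrt(sched$duration)
}

make_plasma <- function(fp = 0.1, hill = list(t50 = 20, h = 2, floor = 0.05),
                        aif = template_aif()) {
  times <- c(0.25, 0.5, 0.75, 1, 1.25, 1.5, 2, 2.5, 3, 4, 5, 7, 10, 15,
             20, 30, 45, 60, 80, 100)
  pf <- predict_parent_fraction(hill, times)
  total <- evaluate_aif(aif, times) / pf
  pf_meas <- ifelse(seq_along(times) %% 2 == 1L, pf, NA_real_)
  plasma_series(times, total, pf_meas, fp)
}

# small cohort + binding pair for the statistics tests
make_merged <- function(seed = 1, gen = generator_config(), quiet = TRUE) {
  ch <- generate_cohort(gen, seed = seed)
  b <- generate_binding(ch, gen, seed = seed)
  if (quiet) suppressWarnings(prepare_binding(b, ch)) else prepare_binding(b, ch)
}

# direct normal-equations weighted least squares (independent oracle)
wls_oracle <- function(X, y, w) {
  solve(crossprod(X, w * X), crossprod(X, w * y))
}
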