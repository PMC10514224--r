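test_that("Hill parent-fraction model has the required boundary behaviour", {
  # pf(0) = 1 exactly for any admissible parameters, and with floor = 0
  # the half-time definition pf(t50) = 0.5 holds
  set.seed(11)
  for (i in 1:50) {
    fit <- list(t50 = runif(1, 1, 80), h = runif(1, 0.3, 6),
                floor = runif(1, 0, 0.9))
    expect_equal(predict_parent_fraction(fit, 0), 1)
    # monotone non-increasing over a dense grid
    pf <- predict_parent_fraction(fit, seq(0, 200, by = 0.5))
    expect_true(all(diff(pf) <= 1e-12))
    expect_gte(min(pf), fit$floor)
  }
  expect_equal(predict_parent_fraction(list(t50 = 20, h = 2, floor = 0), 20),
               0.5)
})

test_that("Hill fit recovers noiseless parameters and beats a grid oracle", {
  truth <- list(t50 = 20, h = 2, floor = 0.05)
  t8 <- c(0.5, 2, 5, 10, 20, 40, 60, 90)
  pf <- predict_parent_fraction(truth, t8)
  series <- plasma_series(t8, rep(10, 8), pf, 0.1)
  fit <- fit_parent_fraction(series)
  expect_equal(fit$t50, truth$t50, tolerance = 1e-6)
  expect_equal(fit$h, truth$h, tolerance = 1e-6)
  expect_equal(fit$floor, truth$floor, tolerance = 1e-6)
  expect_equal(predict_parent_fraction(fit, 0), 1)

  # independent grid-search oracle on the same objective: the converged
  # fit must be at least as good as every grid point
  rss <- function(p) sum((predict_parent_fraction(p, t8) - pf)^2)
  grid <- expand.grid(t50 = seq(5, 60, by = 2.5), h = seq(0.5, 5, by = 0.25),
                      floor = seq(0, 0.3, by = 0.05))
  grid_best <- min(apply(grid, 1, function(g)
    rss(list(t50 = g[1], h = g[2], floor = g[3]))))
  expect_lte(fit$rss, grid_best + 1e-12)

  flat <- plasma_series(t8, rep(10, 8), rep(0.5, 8), 0.1)
  expect_error(fit_parent_fraction(flat), "degenerate")
})

test_that("metabolite correction multiplies totals by the parent fraction", {
  pl <- make_plasma()
  hill <- structure(list(t50 = 20, h = 2, floor = 0.05), class = "hill_fit")
  corr <- correct_metabolites(pl, hill)
  expect_identical(corr$time, pl$sample_times)
  expect_equal(corr$activity,
               pl$total_activity * predict_parent_fraction(hill, pl$sample_times))
  expect_true(all(corr$activity <= pl$total_activity + 1e-12))
  # floor -> 1 limit: correction is the identity
  unity <- structure(list(t50 = 20, h = 2, floor = 1), class = "hill_fit")
  expect_equal(correct_metabolites(pl, unity)$activity, pl$total_activity)
  # point product example: total 10 at a time where pf = 0.4
  t04 <- 20 * ((1 - 0.4) / (0.4 - 0))^(1 / 2)   # invert floor = 0 Hill curve
  hill0 <- structure(list(t50 = 20, h = 2, floor = 0), class = "hill_fit")
  pl2 <- plasma_series(c(0.5, 1, t04, 100), rep(10, 4),
                       c(0.99, 0.95, 0.4, 0.1), 0.1)
  expect_equal(correct_metabolites(pl2, hill0)$activity[3], 4)
})

test_that("piecewise AIF fit recovers a known model from noiseless samples", {
  truth <- template_aif()
  pl <- make_plasma()
  hill <- structure(list(t50 = 20, h = 2, floor = 0.05), class = "hill_fit")
  corr <- correct_metabolites(pl, hill)
  fit <- fit_aif(corr)
  expect_equal(fit$tp, truth$tp)
  expect_equal(fit$A, truth$A, tolerance = 1e-4)
  expect_equal(fit$lambda, truth$lambda, tolerance = 1e-4)
  # rss at least as low as at the truth (multi-start oracle on the
  # same objective)
  post <- corr$time >= truth$tp
  rss_truth <- sum((evaluate_aif(truth, corr$time[post]) -
                      corr$activity[post])^2)
  expect_lte(attr(fit, "rss"), rss_truth + 1e-10)

  # structural properties: zero at origin, continuity at the peak
  expect_identical(evaluate_aif(fit, 0), 0)
  peak <- evaluate_aif(fit, fit$tp)
  eps <- 1e-9
  expect_lt(abs(evaluate_aif(fit, fit$tp - eps) -
                  evaluate_aif(fit, fit$tp + eps)), 1e-10 * peak)
  expect_error(evaluate_aif(fit, -1), "t >= 0")
  expect_error(fit_aif(data.frame(time = c(0.5, 1, 1.5, 2),
                                  activity = c(1, 5, 2, 1))),
               "post-peak")
})

test_that("closed-form exponential convolution matches quadrature oracles", {
  aif <- template_aif()
  # a = 0: running integral against adaptive quadrature
  for (t in c(0.5, 1.5, 4, 30, 100)) {
    num <- integrate(function(u) evaluate_aif(aif, u), 0, t,
                     rel.tol = 1e-10)$value
    expect_equal(convolve_exp(aif, 0, t), num, tolerance = 1e-6)
  }
  expect_identical(convolve_exp(aif, 0.3, 0), 0)
  expect_error(convolve_exp(aif, -0.1, 1), ">= 0")

  # general a against a trapezoidal discrete convolution on a fine grid
  for (a in c(0.02, 0.3, 2.5)) {
    for (t in c(2, 25, 80)) {
      u <- seq(0, t, by = 1e-3)
      f <- evaluate_aif(aif, u) * exp(-a * (t - u))
      disc <- sum((f[-1] + f[-length(f)]) / 2) * 1e-3
      expect_equal(convolve_exp(aif, a, t), disc, tolerance = 1e-4)
    }
  }

  # linearity in the AIF amplitudes
  aif2 <- aif_model(aif$tp, aif$A * 3, aif$lambda)
  tt <- c(0.7, 5, 40)
  expect_equal(convolve_exp(aif2, 0.1, tt), 3 * convolve_exp(aif, 0.1, tt))

  # analytic total integral equals quadrature
  expect_equal(integrate_aif(aif),
               integrate(function(u) evaluate_aif(aif, u), 0, Inf,
                         rel.tol = 1e-10)$value,
               tolerance = 1e-8)
})

test_that("AIF is continuous and nonnegative for random admissible models", {
  set.seed(21)
  for (i in 1:25) {
    m <- aif_model(tp = runif(1, 0.5, 3),
                   A = runif(3, 1, 300),
                   lambda = sort(10^runif(3, -2.2, 0.8), decreasing = TRUE))
    tt <- seq(0, 120, by = 0.05)
    v <- evaluate_aif(m, tt)
    expect_true(all(v >= 0))
    expect_lt(abs(evaluate_aif(m, m$tp - 1e-10) -
                    evaluate_aif(m, m$tp + 1e-10)),
              1e-8 * max(v))
    expect_equal(integrate_aif(m),
                 m$line_slope * m$tp^2 / 2 +
                   sum(m$A * exp(-m$lambda * m$tp) / m$lambda))
  }
})

test_that("AIF models serialize to a text record and back", {
  m <- template_aif()
  path <- withr::local_tempfile(fileext = ".txt")
  write_aif(m, path)
  back <- read_aif(path)
  expect_equal(back$A, m$A)
  expect_equal(back$lambda, m$lambda)
  expect_equal(back$tp, m$tp)
})
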