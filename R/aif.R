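# Metabolite-corrected arterial input function:
#   1. the unmetabolised parent fraction over time is fit with a Hill
#      function and multiplied into the total plasma activity;
#   2. the corrected samples are modelled as a straight line from the
#      origin to the curve peak and a sum of three decreasing
#      exponentials after the peak.
# The piecewise model admits a closed-form convolution with exp(-a t),
# which is what the compartment model needs.

# ---- Hill parent-fraction model ------------------------------------------

#' Predict the unmetabolised parent fraction
#'
#' Decreasing Hill curve
#' `pf(t) = floor + (1 - floor) * t50^h / (t50^h + t^h)`,
#' which equals 1 at injection, decays with half-time `t50` (when
#' `floor = 0`, `pf(t50) = 0.5`) and flattens to an asymptotic parent
#' fraction `floor`.
#'
#' @param fit a `hill_fit` (or a list with `t50`, `h`, `floor`)
#' @param t minutes post-injection (vector)
#' @return predicted parent fractions
#' @export
predict_parent_fraction <- function(fit, t) {
  stopifnot(all(t >= 0))
  a <- fit$t50^fit$h
  fit$floor + (1 - fit$floor) * a / (a + t^fit$h)
}

#' Fit a Hill function to measured parent fractions
#'
#' Least-squares fit of the decreasing Hill curve to the plasma samples
#' with a measured parent fraction.  Multi-start bounded
#' Levenberg-Marquardt; the fit is deterministic (the start grid is
#' fixed).
#'
#' @param series a [plasma_series()] with >= 3 parent-fraction samples
#' @param config a [run_config()] supplying optimizer tolerances
#' @return object of class `hill_fit` with fields `t50` (minutes), `h`
#'   (Hill coefficient), `floor` (asymptotic parent fraction), `rss` and
#'   `converged`
#' @export
fit_parent_fraction <- function(series, config = run_config()) {
  stopifnot(inherits(series, "plasma_series"))
  keep <- !is.na(series$parent_fraction)
  t <- series$sample_times[keep]
  pf <- series$parent_fraction[keep]
  if (length(unique(pf)) == 1L) {
    abort_validation("degenerate parent-fraction data: all measurements identical")
  }
  resid_fun <- function(p) {
    predict_parent_fraction(list(t50 = p[1L], h = p[2L], floor = p[3L]), t) - pf
  }
  lower <- c(1e-3, 0.1, 0)
  upper <- c(1e3, 12, 0.999)
  starts <- expand.grid(t50 = c(5, 20, 60), h = c(1, 2.5), floor = 0.05)
  best <- multistart_lm(resid_fun, starts, lower, upper, config)
  if (is.null(best)) {
    abort_validation("Hill fit failed to converge from any start")
  }
  structure(list(t50 = best$par[1L], h = best$par[2L], floor = best$par[3L],
                 rss = best$rss, converged = TRUE),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> t50 = %.3g min, h = %.3g, floor = %.3g (rss %.3g)\n",
              x$t50, x$h, x$floor, x$rss))
  invisible(x)
}

#' Apply the metabolite correction to total plasma activity
#'
#' Multiplies each total-activity sample by the fitted parent fraction at
#' its draw time; times are unchanged.
#'
#' @param series a [plasma_series()]
#' @param hill a `hill_fit` from [fit_parent_fraction()]
#' @return data.frame with columns `time` and `activity` (corrected)
#' @export
correct_metabolites <- function(series, hill) {
  stopifnot(inherits(series, "plasma_series"))
  pf <- predict_parent_fraction(hill, series$sample_times)
  data.frame(time = series$sample_times,
             activity = series$total_activity * pf)
}

# ---- piecewise AIF model --------------------------------------------------

#' Construct a piecewise arterial input function model
#'
#' `C_p(t)` is a straight line from the origin to the curve peak at
#' `tp`, then a sum of three decreasing exponentials
#' `sum(A_i * exp(-lambda_i * t))` for `t >= tp`.  The line is anchored
#' so the function is continuous at `tp` by construction.
#'
#' @param tp peak time, minutes > 0
#' @param A amplitudes, kBq/mL, length 3, >= 0
#' @param lambda rates, 1/min, length 3, > 0, strictly decreasing order
#'   is enforced (components are sorted)
#' @return object of class `aif_model` with the derived `line_slope`
#' @export
aif_model <- function(tp, A, lambda) {
  stopifnot(is_number(tp), tp > 0, length(A) == 3L, length(lambda) == 3L)
  if (any(A < 0)) abort_validation("AIF amplitudes must be >= 0")
  if (any(lambda <= 0)) abort_validation("AIF rates must be > 0")
  ord <- order(lambda, decreasing = TRUE)
  A <- as.numeric(A[ord])
  lambda <- as.numeric(lambda[ord])
  # strict ordering invariant: separate numerically tied rates
  for (i in 2:3) {
    if (lambda[i] >= lambda[i - 1L]) lambda[i] <- lambda[i - 1L] * (1 - 1e-9)
  }
  peak_value <- sum(A * exp(-lambda * tp))
  structure(list(tp = tp, A = A, lambda = lambda,
                 line_slope = peak_value / tp),
            class = "aif_model")
}

#' @export
print.aif_model <- function(x, ...) {
  cat(sprintf("<aif_model> tp = %.3g min, A = (%s) kBq/mL, lambda = (%s) /min\n",
              x$tp, paste(signif(x$A, 4), collapse = ", "),
              paste(signif(x$lambda, 4), collapse = ", ")))
  invisible(x)
}

#' Serialize an AIF model to / from a small text record
#' @param model an [aif_model()]
#' @param path file path
#' @return `read_aif()` returns an [aif_model()]
#' @export
write_aif <- function(model, path) {
  writeLines(c(
    paste("tp", as.character(model$tp)),
    paste("A", paste(as.character(model$A), collapse = " ")),
    paste("lambda", paste(as.character(model$lambda), collapse = " "))
  ), path)
  invisible(path)
}

#' @rdname write_aif
#' @export
read_aif <- function(path) {
  kv <- strsplit(readLines(path), " ")
  get <- function(key) {
    row <- kv[[which(vapply(kv, `[[`, character(1), 1L) == key)]]
    as.numeric(row[-1L])
  }
  aif_model(get("tp"), get("A"), get("lambda"))
}

#' Evaluate the arterial input function
#'
#' @param model an [aif_model()]
#' @param t minutes, >= 0 (vectorized)
#' @return plasma activity, kBq/mL
#' @export
evaluate_aif <- function(model, t) {
  if (any(t < 0)) abort_validation("AIF is defined for t >= 0")
  pre <- t <= model$tp
  out <- numeric(length(t))
  out[pre] <- model$line_slope * t[pre]
  if (any(!pre)) {
    tt <- t[!pre]
    out[!pre] <- colSums(model$A * exp(-outer(model$lambda, tt)))
  }
  out
}

#' Total integral of the AIF over `[0, Inf)`
#' @param model an [aif_model()]
#' @return `slope*tp^2/2 + sum(A_i exp(-lambda_i tp)/lambda_i)`
#' @export
integrate_aif <- function(model) {
  model$line_slope * model$tp^2 / 2 +
    sum(model$A * exp(-model$lambda * model$tp) / model$lambda)
}

# (exp(-x) - 1 + x)/a^2, computed stably for small x = a*t
.expm1_quad <- function(a, x) {
  small <- x < 1e-4
  out <- numeric(length(x))
  if (any(small)) {
    xs <- x[small]
    out[small] <- (xs^2 / 2 - xs^3 / 6 + xs^4 / 24) / a^2
  }
  if (any(!small)) out[!small] <- (expm1(-x[!small]) + x[!small]) / a^2
  out
}

# convolution of the pre-peak line slope*u on [0, min(t, tp)] with
# exp(-a (t - u)), evaluated at a vector t
.conv_line <- function(slope, tp, a, t) {
  te <- pmin(t, tp)                       # line active on [0, te]
  if (a == 0) {
    return(slope * te^2 / 2)
  }
  # integral over [0, te] of slope*u*exp(-a(te-u)) du, then decayed by
  # exp(-a (t - te)) for t beyond the line segment
  base <- slope * (te / a - 1 / a^2 + exp(-a * te) / a^2)
  # stable form for small a*te
  small <- a * te < 1e-4
  if (any(small)) {
    base[small] <- slope * (te[small]^2 / 2 - a * te[small]^3 / 6 +
                              a^2 * te[small]^4 / 24)
  }
  base * exp(-a * pmax(t - tp, 0))
}

# convolution of A*exp(-lambda u) on [tp, t] with exp(-a (t - u))
.conv_exp_tail <- function(A, lambda, tp, a, t) {
  dt <- pmax(t - tp, 0)
  d <- a - lambda
  x <- d * dt
  fac <- numeric(length(t))
  small <- abs(x) < 1e-8
  fac[small] <- dt[small] * (1 + x[small] / 2)
  if (any(!small)) fac[!small] <- expm1(x[!small]) / d
  A * exp(-a * dt) * exp(-lambda * tp) * fac
}

#' Closed-form convolution of the AIF with a decaying exponential
#'
#' Returns `(C_p (*) exp(-a .))(t) = integral_0^t C_p(u) exp(-a (t-u)) du`
#' in closed form, piecewise over the pre-peak line and the post-peak
#' exponential components.  With `a = 0` this is the running integral of
#' the AIF.
#'
#' @param model an [aif_model()]
#' @param a convolution rate, 1/min, >= 0
#' @param t minutes, >= 0 (vectorized)
#' @return activity (kBq/mL x min weighting folded into the kinetics)
#' @export
convolve_exp <- function(model, a, t) {
  if (!is_number(a) || a < 0) abort_validation("convolution rate must be >= 0")
  if (any(t < 0)) abort_validation("convolution is defined for t >= 0")
  out <- .conv_line(model$line_slope, model$tp, a, t)
  tail_idx <- t > model$tp
  if (any(tail_idx)) {
    tt <- t[tail_idx]
    add <- numeric(length(tt))
    for (i in 1:3) {
      add <- add + .conv_exp_tail(model$A[i], model$lambda[i], model$tp, a, tt)
    }
    out[tail_idx] <- out[tail_idx] + add
  }
  out
}

# running time-average of convolve_exp over frames, in closed form:
# integral_0^T conv(a, t) dt = (conv(0, T) - conv(a, T)) / a   (a > 0)
.conv_exp_frame_avg <- function(model, a, start, duration) {
  ends <- start + duration
  if (a == 0) {
    # integrate the running integral numerically (rarely used path)
    vapply(seq_along(start), function(i) {
      stats::integrate(function(u) convolve_exp(model, 0, u),
                       start[i], ends[i],
                       rel.tol = 1e-9)$value / duration[i]
    }, numeric(1))
  } else {
    int_at <- function(T) (convolve_exp(model, 0, T) - convolve_exp(model, a, T)) / a
    (int_at(ends) - int_at(start)) / duration
  }
}

# ---- tri-exponential fit --------------------------------------------------

#' Fit the piecewise AIF model to metabolite-corrected samples
#'
#' The peak is located at the maximum corrected sample (earliest in case
#' of ties); a sum of three decreasing exponentials is fit by bounded
#' multi-start least squares to all samples at `t >= tp`; and the
#' pre-peak straight line is drawn from the origin to the fitted value at
#' the peak so the model is continuous by construction.
#'
#' @param corrected data.frame with columns `time`, `activity` as
#'   returned by [correct_metabolites()]
#' @param config a [run_config()]
#' @return an [aif_model()] with attributes `rss` and `n_fit`
#' @export
fit_aif <- function(corrected, config = run_config()) {
  stopifnot(all(c("time", "activity") %in% names(corrected)))
  t <- corrected$time
  y <- corrected$activity
  ipk <- which.max(y)          # which.max returns the earliest maximum
  tp <- t[ipk]
  if (tp <= 0) abort_validation("peak at t = 0: no pre-peak rise in the data")
  post <- t >= tp
  if (sum(post) < 4L) {
    abort_validation(paste0("too few post-peak samples (", sum(post),
                            "); need >= 4 to fit three exponentials"))
  }
  tf <- t[post]
  yf <- y[post]
  peak <- y[ipk]
  resid_fun <- function(p) {
    A <- p[1:3]
    lam <- p[4:6]
    colSums(A * exp(-outer(lam, tf))) - yf
  }
  lower <- c(0, 0, 0, 1e-5, 1e-5, 1e-5)
  upper <- c(rep(peak * 20, 3), 50, 50, 50)
  starts <- rbind(
    c(peak * 0.8, peak * 0.2, peak * 0.05, 2.0, 0.3, 0.01),
    c(peak * 0.8, peak * 0.2, peak * 0.05, 4.0, 0.5, 0.02),
    c(peak * 0.6, peak * 0.3, peak * 0.10, 1.0, 0.1, 0.005),
    c(peak * 0.9, peak * 0.1, peak * 0.02, 8.0, 1.0, 0.05),
    c(peak * 0.5, peak * 0.4, peak * 0.10, 3.0, 0.2, 0.02)
  )
  best <- multistart_lm(resid_fun, starts, lower, upper, config)
  if (is.null(best)) abort_validation("tri-exponential AIF fit did not converge")
  model <- aif_model(tp, best$par[1:3], best$par[4:6])
  attr(model, "rss") <- best$rss
  attr(model, "n_fit") <- length(tf)
  model
}

#' Build the metabolite-corrected AIF from a plasma series
#'
#' Convenience wrapper: Hill fit, metabolite correction, piecewise AIF fit.
#'
#' @param series a [plasma_series()]
#' @param config a [run_config()]
#' @return list with `hill`, `corrected`, `aif`
#' @export
build_aif <- function(series, config = run_config()) {
  hill <- fit_parent_fraction(series, config)
  corrected <- correct_metabolites(series, hill)
  list(hill = hill, corrected = corrected,
       aif = fit_aif(corrected, config))
}
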