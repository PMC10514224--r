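# Compartmental quantification of [11C]WAY100635 binding.
#
# The reference region (cerebellar white matter, no specific binding) is
# fit with a one-tissue model whose K1'/k2' supplies the non-displaceable
# volume of distribution V_ND.  Each ROI is then fit with a two-tissue
# compartment model constrained so that its K1/k2 equals V_ND (the 2TCC
# model); the total volume of distribution is V_T = (K1/k2)(1 + k3/k4)
# and the outcome measure is BP_F = (V_T(ROI) - V_T(REF)) / f_P.

#' Kinetic rate-constant set
#'
#' @param K1 plasma-to-tissue transfer, mL cm^-3 min^-1, > 0
#' @param k2 tissue-to-plasma rate, min^-1, > 0
#' @param k3 binding rate, min^-1, >= 0 (`NA` for one-tissue fits)
#' @param k4 dissociation rate, min^-1, > 0 (`NA` for one-tissue fits)
#' @return list of class `kinetic_params`
#' @export
kinetic_params <- function(K1, k2, k3 = NA_real_, k4 = NA_real_) {
  stopifnot(K1 > 0, k2 > 0)
  if (!is.na(k3)) stopifnot(k3 >= 0, k4 > 0)
  structure(list(K1 = K1, k2 = k2, k3 = k3, k4 = k4),
            class = "kinetic_params")
}

#' Total volume of distribution implied by rate constants
#' @param params a [kinetic_params()]
#' @return `K1/k2 * (1 + k3/k4)` (two-tissue) or `K1/k2` (one-tissue)
#' @export
vt_from_params <- function(params) {
  vnd <- params$K1 / params$k2
  if (is.na(params$k3)) vnd else vnd * (1 + params$k3 / params$k4)
}

#' Predict a tissue time-activity curve from the compartment model
#'
#' The two-tissue impulse response is
#' `h(t) = K1/(a2 - a1) * ((k3 + k4 - a1) exp(-a1 t) + (a2 - k3 - k4) exp(-a2 t))`
#' with `a1, a2 = ((k2+k3+k4) -/+ sqrt((k2+k3+k4)^2 - 4 k2 k4)) / 2`;
#' the tissue curve is its convolution with the AIF, evaluated in closed
#' form through [convolve_exp()].  With `k3 = 0` this reduces exactly to
#' the one-tissue curve `K1 * (C_p (*) exp(-k2 .))`.
#'
#' @param params a [kinetic_params()]
#' @param aif an [aif_model()]
#' @param frame_start,frame_duration PET frame definition, minutes
#' @param frame_mode `"midpoint"` or `"average"` (see [run_config()])
#' @return predicted frame activities, kBq/mL
#' @export
predict_tac <- function(params, aif, frame_start, frame_duration,
                        frame_mode = "midpoint") {
  K1 <- params$K1; k2 <- params$k2; k3 <- params$k3; k4 <- params$k4
  conv <- function(a) {
    if (frame_mode == "midpoint") {
      convolve_exp(aif, a, frame_start + frame_duration / 2)
    } else {
      .conv_exp_frame_avg(aif, a, frame_start, frame_duration)
    }
  }
  if (is.na(k3) || k3 == 0) {
    return(K1 * conv(k2))
  }
  s <- k2 + k3 + k4
  disc <- s^2 - 4 * k2 * k4
  if (disc < 0) stop("internal: negative discriminant with positive rates")
  r <- sqrt(disc)
  a1 <- (s - r) / 2
  a2 <- (s + r) / 2
  if (a2 - a1 < 1e-12) {          # coincident roots: perturb infinitesimally
    a1 <- a1 * (1 - 1e-9)
    a2 <- a2 * (1 + 1e-9)
  }
  (K1 / (a2 - a1)) * ((k3 + k4 - a1) * conv(a1) + (a2 - k3 - k4) * conv(a2))
}

# shared TAC fit machinery: least squares of predict_tac against observed
# frame activities over a free-parameter vector mapped by `make_params`
.fit_tac <- function(tac_obj, aif, make_params, starts, lower, upper, config) {
  y <- tac_obj$activity
  w <- switch(config$tac_weighting,
              uniform = NULL,
              duration = tac_obj$frame_duration / mean(tac_obj$frame_duration))
  resid_fun <- function(p) {
    predict_tac(make_params(p), aif, tac_obj$frame_start,
                tac_obj$frame_duration, config$frame_mode) - y
  }
  # ties (identical rss) resolved toward the lower k4 where it exists
  tie <- function(cand, best) {
    length(cand$par) >= 3L && cand$par[3L] < best$par[3L]
  }
  best <- multistart_lm(resid_fun, starts, lower, upper, config,
                        weights = w, tie_break = tie)
  if (is.null(best)) {
    abort_validation(paste0("kinetic fit did not converge for region '",
                            tac_obj$region, "'"))
  }
  best
}

#' Fit the reference region
#'
#' One-tissue (default) or two-tissue least-squares fit of the cerebellar
#' white matter curve; either way the returned `vt` estimates the
#' non-displaceable volume of distribution V_ND = K1'/k2' used to
#' constrain the ROI fits (for the two-tissue option V_ND is still
#' reported as K1'/k2').
#'
#' @param tac_obj a [tac()] for the reference region
#' @param aif an [aif_model()]
#' @param config a [run_config()]
#' @return object of class `kinetic_fit`
#' @export
fit_reference <- function(tac_obj, aif, config = run_config()) {
  if (tac_obj$region != reference_region()) {
    abort_validation(paste0("fit_reference expects the '", reference_region(),
                            "' curve, got '", tac_obj$region, "'"))
  }
  if (config$reference_model == "one_tissue") {
    make_params <- function(p) kinetic_params(p[1L], p[2L])
    starts <- expand.grid(K1 = c(0.02, 0.08, 0.3), k2 = c(0.05, 0.16, 0.5))
    lower <- c(1e-4, 1e-4)
    upper <- c(5, 5)
  } else {
    make_params <- function(p) kinetic_params(p[1L], p[2L], p[3L], p[4L])
    starts <- expand.grid(K1 = c(0.05, 0.2), k2 = c(0.1, 0.3),
                          k3 = 0.01, k4 = 0.02)
    lower <- c(1e-4, 1e-4, 0, 1e-4)
    upper <- c(5, 5, 1, 1)
  }
  best <- .fit_tac(tac_obj, aif, make_params, starts, lower, upper, config)
  params <- make_params(best$par)
  vnd <- params$K1 / params$k2
  structure(list(region = tac_obj$region, params = params,
                 vt = vt_from_params(params), vnd = vnd, bpf = 0,
                 rss = best$rss, converged = TRUE, info = best$info),
            class = "kinetic_fit")
}

#' Fit the constrained two-tissue compartment (2TCC) model to an ROI
#'
#' Least squares over the free parameters `(K1, k3, k4)` with
#' `k2 := K1 / vnd_ref`, so that the fitted `K1/k2` equals the reference
#' region's non-displaceable volume of distribution exactly.
#'
#' @param tac_obj a [tac()] for one of the 13 ROIs
#' @param aif an [aif_model()]
#' @param vnd_ref reference V_ND = K1'/k2', > 0
#' @param config a [run_config()]
#' @param start optional single start (numeric `c(K1, k3, k4)`) used
#'   alone, e.g. to warm-start bootstrap refits
#' @return object of class `kinetic_fit` (its `bpf` field is filled by
#'   [quantify_subject()], which knows f_P)
#' @export
fit_roi_2tcc <- function(tac_obj, aif, vnd_ref, config = run_config(),
                         start = NULL) {
  if (!is_number(vnd_ref) || vnd_ref <= 0) {
    abort_validation("vnd_ref must be a positive number")
  }
  if (tac_obj$region == reference_region()) {
    abort_validation("fit_roi_2tcc expects an ROI, not the reference region")
  }
  make_params <- function(p) kinetic_params(p[1L], p[1L] / vnd_ref, p[2L], p[3L])
  lower <- c(1e-4, 0, 1e-4)
  upper <- c(5, 2, 2)
  starts <- if (!is.null(start)) matrix(start, nrow = 1L) else rbind(
    c(0.05, 0.02, 0.01),
    c(0.10, 0.06, 0.02),
    c(0.20, 0.15, 0.05),
    c(0.10, 0.30, 0.10),
    c(0.30, 0.05, 0.005)
  )
  best <- .fit_tac(tac_obj, aif, make_params, starts, lower, upper, config)
  params <- make_params(best$par)
  if (params$k4 <= lower[3L] * (1 + 1e-8)) {
    warning("k4 reached its lower bound in region '", tac_obj$region,
            "'; V_T may be unstable", call. = FALSE)
  }
  structure(list(region = tac_obj$region, params = params,
                 vt = vt_from_params(params), vnd = vnd_ref, bpf = NA_real_,
                 rss = best$rss, converged = TRUE, info = best$info),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit> %s: K1 = %.4g, k2 = %.4g, k3 = %s, k4 = %s, V_T = %.4g\n",
              x$region, x$params$K1, x$params$k2,
              ifelse(is.na(x$params$k3), "-", signif(x$params$k3, 4)),
              ifelse(is.na(x$params$k4), "-", signif(x$params$k4, 4)),
              x$vt))
  invisible(x)
}

#' Binding potential referenced to free plasma ligand
#'
#' `BP_F = (V_T(ROI) - V_T(REF)) / f_P`.  Noise can push an ROI's V_T
#' below the reference value, so negative BP_F is allowed and returned
#' (flagged downstream, not floored).
#'
#' @param vt_roi,vt_ref total volumes of distribution, mL cm^-3
#' @param fp plasma free fraction, > 0
#' @return BP_F (mL cm^-3 per unit f_P)
#' @export
compute_bpf <- function(vt_roi, vt_ref, fp) {
  if (any(fp <= 0)) abort_validation("fp must be > 0")
  (vt_roi - vt_ref) / fp
}

#' Quantify one subject: plasma + TACs -> per-region kinetic fits
#'
#' Runs the full single-subject pipeline: Hill parent-fraction fit,
#' metabolite correction, piecewise AIF fit, one-tissue reference fit,
#' constrained two-tissue fits for the 13 ROIs, and BP_F computation.
#' When `config$boot_B >= 2`, residual-bootstrap standard errors of BP_F
#' are appended (see [bootstrap_bpf()]).
#'
#' @param plasma a [plasma_series()]
#' @param tacs named list of [tac()] including the reference region
#' @param config a [run_config()]
#' @return data.frame with one row per region: `region`, `K1`, `k2`,
#'   `k3`, `k4`, `vt`, `bpf`, `se_bpf`, `rss`, `negative_bpf` flag.
#'   The reference row has `bpf = 0`.  Attribute `"aif"` carries the
#'   fitted input function, `"vnd_ref"` the constraint value.
#' @export
quantify_subject <- function(plasma, tacs, config = run_config()) {
  regions <- vapply(tacs, `[[`, character(1), "region")
  names(tacs) <- regions
  if (!reference_region() %in% regions) {
    abort_validation(paste0("quantify pipeline requires a '",
                            reference_region(), "' curve"))
  }
  built <- build_aif(plasma, config)
  aif <- built$aif
  ref_fit <- fit_reference(tacs[[reference_region()]], aif, config)
  vnd <- ref_fit$vnd
  vt_ref <- ref_fit$vt
  roi_names <- setdiff(regions, reference_region())
  fits <- lapply(roi_names, function(r) fit_roi_2tcc(tacs[[r]], aif, vnd, config))
  names(fits) <- roi_names

  row_of <- function(fit, bpf, se) {
    data.frame(region = fit$region, K1 = fit$params$K1, k2 = fit$params$k2,
               k3 = fit$params$k3, k4 = fit$params$k4, vt = fit$vt,
               bpf = bpf, se_bpf = se, rss = fit$rss,
               negative_bpf = !is.na(bpf) & bpf < 0)
  }
  rows <- vector("list", length(roi_names) + 1L)
  for (i in seq_along(roi_names)) {
    fit <- fits[[i]]
    bpf <- compute_bpf(fit$vt, vt_ref, plasma$fp)
    se <- NA_real_
    if (config$boot_B >= 2L) {
      se <- bootstrap_bpf(tacs[[fit$region]], aif, fit, vnd, plasma$fp,
                          B = config$boot_B,
                          seed = config$seed + i, config = config,
                          vt_ref = vt_ref)
    }
    rows[[i]] <- row_of(fit, bpf, se)
  }
  rows[[length(rows)]] <- row_of(ref_fit, 0, if (config$boot_B >= 2L) 0 else NA_real_)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "aif") <- aif
  attr(out, "hill") <- built$hill
  attr(out, "vnd_ref") <- vnd
  attr(out, "fp") <- plasma$fp
  out
}
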