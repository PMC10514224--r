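# Residual-bootstrap precision of BP_F and inverse-variance weights.
# The fitted TAC residuals are standardized by the frame noise shape
# (PET frame variance scales with activity and inversely with frame
# duration, so sigma_i is proportional to activity_i / sqrt(duration_i)),
# resampled with replacement, rescaled onto the predicted frames, and
# the constrained fit is repeated.  The AIF and the reference fit are
# treated as fixed, so the replicate spread reflects the TAC fit alone
# (a hook for AIF-inclusive resampling would extend it).  Standardizing
# keeps the scheme calibrated under count-statistics heteroscedasticity;
# with homoscedastic noise it reduces to the plain residual bootstrap.

#' Residual-bootstrap standard error of BP_F for one region
#'
#' @param tac_obj the observed [tac()]
#' @param aif the fitted [aif_model()] (held fixed)
#' @param fit the converged [fit_roi_2tcc()] result for this region
#' @param vnd_ref the reference V_ND constraint used in the fit
#' @param fp plasma free fraction
#' @param B number of bootstrap replicates, >= 2
#' @param seed integer seed (replicates are reproducible)
#' @param config a [run_config()]
#' @param vt_ref reference-region V_T used in BP_F (defaults to
#'   `vnd_ref`, exact for a one-tissue reference)
#' @return standard error of BP_F (standard deviation of the replicate
#'   BP_F values); 0 when the fit is exact (all residuals zero)
#' @export
bootstrap_bpf <- function(tac_obj, aif, fit, vnd_ref, fp, B = 200L,
                          seed = 1L, config = run_config(),
                          vt_ref = vnd_ref) {
  stopifnot(B >= 2L)
  pred <- predict_tac(fit$params, aif, tac_obj$frame_start,
                      tac_obj$frame_duration, config$frame_mode)
  resid <- tac_obj$activity - pred
  if (all(abs(resid) < 1e-12)) return(0)
  # frame noise shape: sd_i proportional to activity_i / sqrt(duration_i)
  sigma <- pmax(abs(pred), 1e-6 * max(abs(pred))) /
    sqrt(tac_obj$frame_duration)
  z <- resid / sigma
  start <- c(fit$params$K1, fit$params$k3, fit$params$k4)
  vt_b <- rep(NA_real_, B)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  for (b in seq_len(B)) {
    y_b <- pred + sigma * sample(z, length(z), replace = TRUE)
    tac_b <- tac_obj
    tac_b$activity <- y_b
    fit_b <- tryCatch(
      suppressWarnings(
        fit_roi_2tcc(tac_b, aif, vnd_ref, config, start = start)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit_b)) vt_b[b] <- fit_b$vt
  }
  fail <- mean(is.na(vt_b))
  if (fail > 0.2) {
    abort_validation(sprintf(
      "bootstrap unstable for region '%s': %.0f%% of %d replicates failed to converge",
      tac_obj$region, 100 * fail, B
    ))
  }
  bpf_b <- compute_bpf(vt_b[!is.na(vt_b)], vt_ref, fp)
  stats::sd(bpf_b)
}

#' Inverse-variance observation weights from standard errors
#'
#' `w_i = se_i^-2`, then normalized to mean 1 across the modelling data
#' set so variance components stay on an interpretable scale (the
#' normalization leaves weighted-least-squares point estimates
#' unchanged).  A zero standard error (an exact fit) is replaced by the
#' smallest positive standard error in the batch, with a warning.
#'
#' @param se standard errors, >= 0, no missing values
#' @return weights with mean 1
#' @export
weights_from_se <- function(se) {
  if (anyNA(se) || any(se < 0)) {
    abort_validation("standard errors must be non-negative and non-missing")
  }
  if (all(se == 0)) abort_validation("all standard errors are zero")
  if (any(se == 0)) {
    warning(sum(se == 0), " zero standard error(s) replaced by the smallest ",
            "positive value in the batch", call. = FALSE)
    se[se == 0] <- min(se[se > 0])
  }
  w <- se^-2
  w / mean(w)
}
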