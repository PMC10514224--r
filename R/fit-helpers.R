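# bounded Levenberg-Marquardt with a deterministic multi-start grid.
# `starts` is a matrix or data.frame, one start per row.  Returns the
# converged solution with the lowest residual sum of squares, breaking
# ties by the tie_break function (default: first found), or NULL when no
# start converges.
multistart_lm <- function(resid_fun, starts, lower, upper,
                          config = run_config(), weights = NULL,
                          tie_break = NULL) {
  starts <- as.matrix(starts)
  wfun <- if (is.null(weights)) resid_fun else {
    sw <- sqrt(weights)
    function(p) sw * resid_fun(p)
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- pmin(pmax(as.numeric(starts[i, ]), lower), upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = p0, lower = lower, upper = upper, fn = wfun,
        control = minpack.lm::nls.lm.control(
          ftol = config$ftol, ptol = config$ptol, maxiter = config$maxiter
        )
      ),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$info %in% 1:4) next
    rss <- sum(fit$fvec^2)
    cand <- list(par = fit$par, rss = rss, info = fit$info,
                 message = fit$message)
    if (is.null(best) || rss < best$rss * (1 - 1e-10) ||
        (!is.null(tie_break) && abs(rss - best$rss) <= best$rss * 1e-10 &&
           tie_break(cand, best))) {
      best <- cand
    }
  }
  best
}
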