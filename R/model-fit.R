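# Weighted model fitting used by the three analysis steps.
#
# Binding outcomes are analysed on the log scale with inverse-variance
# observation weights; models over all regions include brain region as a
# main effect and in interactions, plus a subject-specific random
# intercept (lme4).  When the random-intercept variance is estimated as
# singular the fit falls back to weighted least squares with the
# variance reported as zero.  Fixed effects are summarised with Wald
# t/F statistics; no multiplicity adjustment is applied anywhere, by
# design.

#' Describe a model to be fitted
#'
#' @param outcome outcome column name (already on its modelling scale)
#' @param fixed character vector of fixed-effect terms; interactions are
#'   written `"a:b"` and every interaction's constituent main effects
#'   must be present
#' @param random optional grouping column for a random intercept
#' @param weights optional column of observation weights
#' @param family optional [stats::glm()] family (e.g. `binomial()`) for
#'   non-Gaussian outcomes; incompatible with `random`
#' @return list of class `model_spec`
#' @export
model_spec <- function(outcome, fixed, random = NULL, weights = NULL,
                       family = NULL) {
  inter <- fixed[grepl(":", fixed, fixed = TRUE)]
  for (tm in inter) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1L]]
    if (!all(parts %in% fixed)) {
      abort_validation(paste0("interaction '", tm,
                              "' lacks a constituent main effect"))
    }
  }
  structure(list(outcome = outcome, fixed = fixed, random = random,
                 weights = weights, family = family),
            class = "model_spec")
}

spec_formula <- function(spec) {
  rhs <- paste(spec$fixed, collapse = " + ")
  if (!is.null(spec$random)) rhs <- paste0(rhs, " + (1 | ", spec$random, ")")
  stats::as.formula(paste(spec$outcome, "~", rhs))
}

# classify fixed-design columns as between- or within-subject for the
# containment-style df option
.bw_classify <- function(X, subject) {
  vapply(seq_len(ncol(X)), function(j) {
    all(tapply(X[, j], subject, function(v) max(v) - min(v)) < 1e-12)
  }, logical(1))
}

#' Fit a model described by a [model_spec()]
#'
#' Dispatches to [lme4::lmer()] (random intercept present),
#' [stats::glm()] (family present) or [stats::lm()], always with the
#' spec's observation weights, and returns a uniform `model_result`
#' holding a coefficient table (estimate, SE, t, df, p) and a Wald
#' F-test table with one row per model term (joint across a term's
#' coefficients).
#'
#' @param data data.frame
#' @param spec a [model_spec()]
#' @param df_method `"residual"` (denominator df = n observations minus
#'   fixed-effect rank) or `"between_within"` (containment split by
#'   whether a column varies within subject); see [run_config()]
#' @return object of class `model_result`
#' @export
fit_model <- function(data, spec, df_method = "residual") {
  used <- unique(c(spec$outcome,
                   unlist(strsplit(spec$fixed, ":", fixed = TRUE)),
                   spec$random, spec$weights))
  used <- intersect(used, names(data))
  dat <- data[stats::complete.cases(data[used]), used, drop = FALSE]
  w <- if (!is.null(spec$weights)) dat[[spec$weights]] else NULL
  note <- character(0)
  singular <- FALSE
  random_sd <- NA_real_

  if (!is.null(spec$family)) {
    f <- spec_formula(spec)
    environment(f) <- environment()
    fit <- stats::glm(f, data = dat, family = spec$family, weights = w)
    se <- sqrt(diag(stats::vcov(fit)))
    if (!fit$converged || any(se > 50, na.rm = TRUE) ||
        any(abs(stats::coef(fit)) > 15, na.rm = TRUE)) {
      abort_validation(paste0(
        "generalized linear model unstable (possible complete separation) for ",
        deparse(spec_formula(spec))))
    }
    X <- stats::model.matrix(fit)
    beta <- stats::coef(fit)
    V <- stats::vcov(fit)
    df2 <- Inf
  } else if (!is.null(spec$random)) {
    f <- spec_formula(spec)
    environment(f) <- environment()
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(f, data = dat, weights = w, REML = TRUE)
    ))
    if (lme4::isSingular(fit, tol = 1e-6)) {
      singular <- TRUE
      random_sd <- 0
      note <- c(note, "singular random-intercept variance; refit as weighted least squares")
      spec_wls <- spec
      spec_wls$random <- NULL
      return(.finish_lm(dat, spec_wls, w, df_method, note, singular,
                        random_sd, spec))
    }
    random_sd <- sqrt(unname(lme4::VarCorr(fit)[[spec$random]][1L, 1L]))
    X <- lme4::getME(fit, "X")
    beta <- lme4::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
    df2 <- NULL   # resolved below
  } else {
    return(.finish_lm(dat, spec, w, df_method, note, singular, random_sd, spec))
  }

  .summarize_fit(fit, spec, X, beta, V, dat, df_method, df2, note,
                 singular, random_sd)
}

# lm/WLS path, also the singular-lmm fallback (orig_spec keeps the
# originally requested structure for the record)
.finish_lm <- function(dat, spec, w, df_method, note, singular, random_sd,
                       orig_spec = spec) {
  f <- spec_formula(spec)
  environment(f) <- environment()
  fit <- stats::lm(f, data = dat, weights = w)
  keep <- !is.na(stats::coef(fit))
  X <- stats::model.matrix(fit)[, keep, drop = FALSE]
  beta <- stats::coef(fit)[keep]
  V <- stats::vcov(fit)    # already drops aliased coefficients
  .summarize_fit(fit, orig_spec, X, beta, V, dat, df_method,
                 df2 = stats::df.residual(fit), note = note,
                 singular = singular, random_sd = random_sd)
}

.summarize_fit <- function(fit, spec, X, beta, V, dat, df_method, df2,
                           note, singular, random_sd) {
  n <- nrow(X)
  rank_X <- qr(X)$rank
  tl <- attr(stats::terms(spec_formula_fixed(spec)), "term.labels")
  # map coefficients to terms through a freshly built full design, so
  # columns dropped for rank deficiency (lm aliasing, lmer column drops)
  # cannot misalign the assignment
  full <- stats::model.matrix(spec_formula_fixed(spec), dat)
  asg <- attr(full, "assign")[match(names(beta), colnames(full))]

  n_subj <- if (!is.null(spec$random) && spec$random %in% names(dat)) {
    length(unique(dat[[spec$random]]))
  } else {
    NA_integer_
  }

  if (is.null(df2)) df2 <- n - rank_X
  coef_df <- rep(df2, length(beta))
  if (identical(df_method, "between_within") && !is.na(n_subj)) {
    bw <- .bw_classify(X, dat[[spec$random]])
    df_b <- max(n_subj - sum(bw), 1L)
    df_w <- max(n - n_subj - sum(!bw), 1L)
    coef_df <- ifelse(bw, df_b, df_w)
  }

  se <- sqrt(diag(V))
  tval <- beta / se
  pval <- if (is.infinite(df2[1L])) {
    2 * stats::pnorm(-abs(tval))
  } else {
    2 * stats::pt(-abs(tval), coef_df)
  }
  coef_tab <- data.frame(term = names(beta), estimate = unname(beta),
                         se = unname(se), t = unname(tval),
                         df = unname(coef_df), p = unname(pval))

  frows <- lapply(seq_along(tl), function(k) {
    idx <- which(asg == k)
    if (!length(idx)) return(NULL)
    b <- beta[idx]
    Vs <- V[idx, idx, drop = FALSE]
    Fstat <- tryCatch(
      drop(t(b) %*% solve(Vs, b)) / length(idx),
      error = function(e) NA_real_
    )
    dfe <- if (identical(df_method, "between_within") && !is.na(n_subj)) {
      min(coef_df[idx])
    } else {
      df2
    }
    p <- if (is.na(Fstat)) NA_real_ else if (is.infinite(dfe)) {
      stats::pchisq(length(idx) * Fstat, df = length(idx), lower.tail = FALSE)
    } else {
      stats::pf(Fstat, length(idx), dfe, lower.tail = FALSE)
    }
    data.frame(term = tl[k], F = Fstat, df1 = length(idx), df2 = dfe, p = p)
  })
  ftests <- do.call(rbind, frows)

  structure(list(
    coef = coef_tab, ftests = ftests, n = n, n_subjects = n_subj,
    df_method = df_method, singular = singular, random_sd = random_sd,
    sigma = tryCatch(stats::sigma(fit), error = function(e) NA_real_),
    spec = spec, fit = fit, note = note
  ), class = "model_result")
}

# fixed-effects-only formula (terms() cannot parse the lmer bar)
spec_formula_fixed <- function(spec) {
  stats::as.formula(paste(spec$outcome, "~",
                          paste(spec$fixed, collapse = " + ")))
}

#' @export
print.model_result <- function(x, ...) {
  cat("<model_result> n =", x$n,
      if (!is.na(x$n_subjects)) paste0("(", x$n_subjects, " subjects)"), "\n")
  if (!is.na(x$random_sd)) {
    cat("  random-intercept SD:", signif(x$random_sd, 4), "\n")
  }
  print(transform(x$coef, estimate = signif(estimate, 4),
                  se = signif(se, 4), t = signif(t, 3),
                  p = signif(p, 3)), row.names = FALSE)
  if (length(x$note)) cat("  note:", paste(x$note, collapse = "; "), "\n")
  invisible(x)
}

#' Weighted linear mixed model with a subject random intercept
#'
#' Thin, explicit entry point for the all-regions binding models:
#' requires a random grouping factor in the model spec.
#'
#' @inheritParams fit_model
#' @return a `model_result`
#' @export
fit_weighted_lmm <- function(data, spec, df_method = "residual") {
  if (is.null(spec$random)) {
    abort_validation("fit_weighted_lmm requires a random grouping factor")
  }
  fit_model(data, spec, df_method)
}

# canonical form of a term label: interaction components sorted, so that
# "a:b" and "b:a" (terms() may reorder) compare equal
.canon_term <- function(x) {
  vapply(strsplit(x, ":", fixed = TRUE),
         function(p) paste(sort(p), collapse = ":"), character(1))
}

#' Joint Wald F-test for one model term
#'
#' For a single-coefficient term the statistic reduces to `t^2`.
#'
#' @param result a `model_result`
#' @param term term label as it appears in the model spec
#' @return list with `F`, `df1`, `df2`, `p`
#' @export
test_interaction <- function(result, term) {
  row <- result$ftests[.canon_term(result$ftests$term) == .canon_term(term), ]
  if (nrow(row) != 1L) {
    abort_validation(paste0("term '", term, "' not in the fitted model"))
  }
  list(F = row$F, df1 = row$df1, df2 = row$df2, p = row$p)
}

#' Backward pruning of non-significant interactions
#'
#' Repeatedly refits the model, removing the interaction with the
#' highest Wald-F p-value at or above the threshold, until every
#' remaining interaction is below it.  Main effects are never dropped.
#' The removal order is recorded for audit.
#'
#' @param data data.frame
#' @param spec a [model_spec()] containing removable interactions
#' @param threshold removal p-value threshold (default 0.05)
#' @param df_method see [fit_model()]
#' @return list with `spec` (final), `result` (final fit), `log`
#'   (data.frame of removed terms and their p-values)
#' @export
prune_interactions <- function(data, spec, threshold = 0.05,
                               df_method = "residual") {
  log_rows <- list()
  repeat {
    result <- fit_model(data, spec, df_method)
    inter <- spec$fixed[grepl(":", spec$fixed, fixed = TRUE)]
    if (!length(inter)) break
    # respect marginality: a lower-order interaction is only removable
    # once no remaining higher-order interaction contains it
    removable <- Filter(function(tm) {
      p <- strsplit(tm, ":", fixed = TRUE)[[1L]]
      !any(vapply(setdiff(inter, tm), function(other) {
        q <- strsplit(other, ":", fixed = TRUE)[[1L]]
        all(p %in% q)
      }, logical(1)))
    }, inter)
    ptab <- result$ftests[.canon_term(result$ftests$term) %in%
                            .canon_term(removable), ]
    ptab <- ptab[!is.na(ptab$p), ]
    if (!nrow(ptab) || all(ptab$p < threshold)) break
    worst <- ptab$term[which.max(ptab$p)]
    log_rows[[length(log_rows) + 1L]] <-
      data.frame(removed = worst, p = max(ptab$p))
    spec$fixed <- spec$fixed[.canon_term(spec$fixed) != .canon_term(worst)]
  }
  list(spec = spec, result = result,
       log = if (length(log_rows)) do.call(rbind, log_rows) else
         data.frame(removed = character(0), p = numeric(0)))
}

#' Region-level weighted least squares
#'
#' Fits one region's observations by WLS and reports, alongside the raw
#' coefficient table, the standardized estimate for the focal predictor:
#' its raw estimate multiplied by the predictor's standard deviation
#' (i.e. the change in log binding per SD of the predictor).
#'
#' @param data observations for a single region
#' @param spec a [model_spec()] without a random term
#' @param focal name of the continuous focal predictor to standardize
#' @param df_method see [fit_model()]
#' @return a `model_result` with an extra `std_estimate` column on the
#'   focal row(s) of `coef`
#' @export
regionwise_wls <- function(data, spec, focal, df_method = "residual") {
  if (!is.null(spec$random)) {
    abort_validation("regionwise_wls expects a fixed-effects spec")
  }
  result <- fit_model(data, spec, df_method)
  sd_focal <- stats::sd(data[[focal]], na.rm = TRUE)
  result$coef$std_estimate <- ifelse(result$coef$term == focal,
                                     result$coef$estimate * sd_focal,
                                     NA_real_)
  result
}
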