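# Variable preparation and small descriptive statistics used around the
# modelling steps: natural-log transforms, 1.5-IQR outlier censoring to
# the nearest retained value, genotype design coding, the GG exclusion
# rule for -1019 methylation models, a Hardy-Weinberg goodness-of-fit
# test, Cohen's d and Spearman correlation.

#' Natural-log transform with domain guarding
#'
#' Non-positive values (BP_F can drop below zero from noise) are returned
#' as `NA` with a warning rather than producing `-Inf`/`NaN`.
#'
#' @param values numeric vector
#' @return `log(values)` with non-positive entries as `NA`
#' @export
log_transform <- function(values) {
  bad <- !is.na(values) & values <= 0
  if (any(bad)) {
    warning(sum(bad), " non-positive value(s) set to NA before log transform",
            call. = FALSE)
    values[bad] <- NA_real_
  }
  log(values)
}

#' Censor outliers to the nearest retained observation
#'
#' Outliers are values more than 1.5 interquartile ranges below the first
#' or above the third quartile (quartiles by linear interpolation,
#' [stats::quantile()] type 7).  Each outlier is replaced by the nearest
#' observed non-outlier value -- i.e. winsorized to the most extreme
#' retained observation, not to the fence itself.  Missing values are
#' preserved.
#'
#' @param values numeric vector with >= 4 non-missing values
#' @param k fence multiplier (1.5 by default)
#' @param variable label recorded in the report
#' @return list with `values` (censored) and `report`, a one-row
#'   data.frame (`variable`, `lower_fence`, `upper_fence`, `n_censored`,
#'   `fraction_censored`)
#' @export
censor_outliers <- function(values, k = 1.5, variable = "value") {
  obs <- values[!is.na(values)]
  if (length(obs) < 4L) {
    abort_validation("censoring needs at least 4 non-missing values",
                     where = variable)
  }
  q <- stats::quantile(obs, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2L] - q[1L]
  lo <- q[1L] - k * iqr
  hi <- q[2L] + k * iqr
  inside <- obs[obs >= lo & obs <= hi]
  out <- values
  low_out <- !is.na(values) & values < lo
  high_out <- !is.na(values) & values > hi
  if (any(low_out)) out[low_out] <- min(inside)
  if (any(high_out)) out[high_out] <- max(inside)
  n_cens <- sum(low_out) + sum(high_out)
  list(
    values = out,
    report = data.frame(
      variable = variable, lower_fence = lo, upper_fence = hi,
      n_censored = n_cens, fraction_censored = n_cens / length(obs)
    )
  )
}

#' Code rs6295 genotype for regression design matrices
#'
#' Factor mode yields two indicator columns with CC as reference
#' (`geno_CG`, `geno_GG`); allele mode yields the G-allele count 0/1/2.
#'
#' @param genotypes character vector in {CC, CG, GG}
#' @param mode `"factor"` or `"allele_count"`
#' @return data.frame of design columns
#' @export
code_genotype <- function(genotypes, mode = c("factor", "allele_count")) {
  mode <- match.arg(mode)
  bad <- !is.na(genotypes) & !genotypes %in% c("CC", "CG", "GG")
  if (any(bad)) {
    abort_validation(paste0("unknown genotype '", genotypes[which(bad)[1L]],
                            "' (allowed: CC, CG, GG)"),
                     where = paste0("row ", which(bad)[1L]))
  }
  if (mode == "factor") {
    data.frame(geno_CG = as.numeric(genotypes == "CG"),
               geno_GG = as.numeric(genotypes == "GG"))
  } else {
    data.frame(g_alleles = ifelse(is.na(genotypes), NA_real_,
                                  (genotypes == "CG") + 2 * (genotypes == "GG")))
  }
}

#' Exclude GG carriers for -1019 methylation models
#'
#' The G allele abolishes the -1019 CpG site, so GG carriers cannot be
#' methylated there and are removed from any model involving -1019
#' methylation.  Removed subject ids are recorded in the
#' `"excluded_ids"` attribute.
#'
#' @param table a [cohort_table()] or any data.frame with `genotype`
#' @return the table without GG rows
#' @export
exclude_gg_for_1019 <- function(table) {
  stopifnot("genotype" %in% names(table))
  drop <- table$genotype == "GG"
  out <- table[!drop, , drop = FALSE]
  attr(out, "excluded_ids") <-
    if ("subject_id" %in% names(table)) table$subject_id[drop] else which(drop)
  out
}

#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' One-degree-of-freedom chi-square test of observed genotype counts
#' against the proportions expected from the estimated G-allele
#' frequency under random mating.
#'
#' @param n_CC,n_CG,n_GG genotype counts
#' @return list with `chi2`, `p`, `allele_freq` (G), `expected` counts
#' @export
hwe_test <- function(n_CC, n_CG, n_GG) {
  n <- n_CC + n_CG + n_GG
  if (n <= 0) abort_validation("hwe_test needs a positive total count")
  pG <- (2 * n_GG + n_CG) / (2 * n)
  expected <- n * c(CC = (1 - pG)^2, CG = 2 * pG * (1 - pG), GG = pG^2)
  observed <- c(CC = n_CC, CG = n_CG, GG = n_GG)
  nz <- expected > 0
  chi2 <- sum((observed[nz] - expected[nz])^2 / expected[nz])
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       allele_freq = pG, expected = expected)
}

#' Cohen's d (pooled-SD standardized mean difference)
#'
#' @param group_a,group_b numeric vectors, each with >= 2 non-missing
#'   values
#' @return `(mean(a) - mean(b)) / pooled SD`
#' @export
cohens_d <- function(group_a, group_b) {
  a <- group_a[!is.na(group_a)]
  b <- group_b[!is.na(group_b)]
  if (length(a) < 2L || length(b) < 2L) {
    abort_validation("cohens_d needs >= 2 values per group")
  }
  sp <- sqrt(((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
               (length(a) + length(b) - 2))
  (mean(a) - mean(b)) / sp
}

#' Spearman rank correlation with large-sample p-value
#'
#' Mid-ranks for ties, pairwise-complete observations, asymptotic
#' t-approximation for the p-value.
#'
#' @param x,y numeric vectors
#' @return list with `rho`, `p`, `n` (pairs used)
#' @export
spearman <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  if (sum(keep) < 4L) abort_validation("spearman needs >= 4 complete pairs")
  ct <- suppressWarnings(
    stats::cor.test(x[keep], y[keep], method = "spearman", exact = FALSE)
  )
  list(rho = unname(ct$estimate), p = ct$p.value, n = sum(keep))
}
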