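#' Run configuration for quantification and analysis
#'
#' Bundles the tunables of the kinetic and statistical stages.
#'
#' @param frame_mode how the model prediction is matched to PET frames:
#'   `"midpoint"` evaluates the tissue curve at the frame mid-time,
#'   `"average"` integrates it over the frame and divides by the duration.
#' @param tac_weighting `"uniform"` (default) or `"duration"` (weights
#'   proportional to frame duration) for the TAC least-squares fits.
#' @param boot_B residual-bootstrap replicates for BP_F standard errors;
#'   0 disables the bootstrap, otherwise must be >= 2.
#' @param seed integer seed controlling every stochastic step of a run.
#' @param prune_threshold p-value at or above which a non-significant
#'   interaction is removed from a model (backward, one at a time).
#' @param df_method denominator degrees of freedom for Wald tests in
#'   mixed models: `"residual"` (n observations minus fixed-effect rank)
#'   or `"between_within"` (containment-style split).
#' @param genotype_coding `"factor"` (three-level, CC reference) or
#'   `"allele_count"` (number of G alleles).
#' @param reference_model `"one_tissue"` (default) or `"two_tissue"` for
#'   the reference-region fit supplying V_ND.
#' @param ftol,ptol,maxiter optimizer tolerances for the bounded
#'   Levenberg-Marquardt fits.
#' @return list of class `run_config`
#' @export
run_config <- function(frame_mode = c("midpoint", "average"),
                       tac_weighting = c("uniform", "duration"),
                       boot_B = 200L,
                       seed = 1L,
                       prune_threshold = 0.05,
                       df_method = c("residual", "between_within"),
                       genotype_coding = c("factor", "allele_count"),
                       reference_model = c("one_tissue", "two_tissue"),
                       ftol = 1e-12, ptol = 1e-12, maxiter = 500L) {
  boot_B <- as.integer(boot_B)
  if (boot_B != 0L && boot_B < 2L) {
    abort_validation("boot_B must be 0 (off) or >= 2")
  }
  if (!is_number(prune_threshold) || prune_threshold <= 0 ||
      prune_threshold >= 1) {
    abort_validation("prune_threshold must lie in (0, 1)")
  }
  structure(list(
    frame_mode = match.arg(frame_mode),
    tac_weighting = match.arg(tac_weighting),
    boot_B = boot_B,
    seed = as.integer(seed),
    prune_threshold = prune_threshold,
    df_method = match.arg(df_method),
    genotype_coding = match.arg(genotype_coding),
    reference_model = match.arg(reference_model),
    ftol = ftol, ptol = ptol, maxiter = as.integer(maxiter)
  ), class = "run_config")
}

#' Read / write a flat key-value configuration file
#'
#' One `key value` pair per line; `#` comments allowed.  Values are kept
#' as strings except where [run_config()] expects numbers.
#'
#' @param path file path
#' @return `read_config()` returns a [run_config()]
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "\\s+")
  args <- stats::setNames(
    lapply(kv, function(x) paste(x[-1L], collapse = " ")),
    vapply(kv, `[[`, character(1), 1L)
  )
  numeric_keys <- c("boot_B", "seed", "prune_threshold", "ftol", "ptol",
                    "maxiter")
  for (k in intersect(names(args), numeric_keys)) {
    args[[k]] <- as.numeric(args[[k]])
  }
  do.call(run_config, args)
}

#' @param config a [run_config()]
#' @rdname read_config
#' @export
write_config <- function(config, path) {
  writeLines(paste(names(config),
                   vapply(config, as.character, character(1))), path)
  invisible(path)
}
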