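cohort_schema <- function() {
  c("subject_id", "diagnosis", "age", "gender", "genotype", "adversity",
    "rlcq_lcu", "meth_1019", "meth_1007", "meth_681", "hrsd")
}

#' Validate a cohort covariate table
#'
#' Checks the per-subject covariate table against its controlled
#' vocabularies: diagnosis in {MDD, control}, rs6295 genotype in
#' {CC, CG, GG}, gender in {female, male, other}, adversity in
#' {yes, no} or missing, methylation fractions in (0, 1].  Because the
#' G allele destroys the -1019 CpG site, GG carriers cannot carry a
#' -1019 methylation value: such entries are coerced to missing with a
#' warning (treated as a data error).
#'
#' @param df data.frame with the cohort schema (extra columns are kept)
#' @return validated data.frame of class `cohort_table`
#' @export
cohort_table <- function(df) {
  miss <- setdiff(cohort_schema(), names(df))
  if (length(miss)) {
    abort_validation(paste("cohort table missing columns:",
                           paste(miss, collapse = ", ")))
  }
  chk_level <- function(col, levels, allow_na = FALSE) {
    v <- df[[col]]
    bad <- !(v %in% levels) & !(allow_na & (is.na(v) | v == ""))
    if (any(bad)) {
      i <- which(bad)[1L]
      abort_validation(
        paste0("invalid value '", v[i], "' (allowed: ",
               paste(levels, collapse = ", "), ")"),
        where = paste0("row ", i, ", column ", col)
      )
    }
  }
  chk_level("diagnosis", c("MDD", "control"))
  chk_level("genotype", c("CC", "CG", "GG"))
  chk_level("gender", c("female", "male", "other"))
  chk_level("adversity", c("yes", "no"), allow_na = TRUE)
  df$adversity[df$adversity == ""] <- NA_character_
  for (col in c("age", "rlcq_lcu", "meth_1019", "meth_1007", "meth_681", "hrsd")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  for (col in c("meth_1019", "meth_1007", "meth_681")) {
    v <- df[[col]]
    bad <- !is.na(v) & (v <= 0 | v > 1)
    if (any(bad)) {
      i <- which(bad)[1L]
      abort_validation("methylation fraction must lie in (0, 1]",
                       where = paste0("row ", i, ", column ", col))
    }
  }
  if (any(!is.na(df$rlcq_lcu) & df$rlcq_lcu < 0)) {
    abort_validation("rlcq_lcu must be non-negative", where = "column rlcq_lcu")
  }
  gg_meas <- df$genotype == "GG" & !is.na(df$meth_1019)
  if (any(gg_meas)) {
    warning(sum(gg_meas),
            " GG row(s) carried a -1019 methylation value; coerced to missing",
            " (GG cannot be methylated at -1019)", call. = FALSE)
    df$meth_1019[gg_meas] <- NA_real_
  }
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Read / write the cohort covariate table
#'
#' Comma-separated file with columns `subject_id`, `diagnosis`, `age`,
#' `gender`, `genotype` (rs6295), `adversity` (childhood physical or
#' sexual abuse, yes/no, blank = missing), `rlcq_lcu` (Recent Life
#' Changes Questionnaire life-change-unit total over 2 years),
#' `meth_1019`, `meth_1007`, `meth_681` (promoter CpG methylation
#' fractions) and `hrsd` (Hamilton depression severity).
#'
#' @param path file path
#' @return `read_cohort()` returns a [cohort_table()]
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  cohort_table(df)
}

#' @param cohort a [cohort_table()]
#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)
  for (col in names(out)) {
    if (is.numeric(out[[col]])) out[[col]] <- fmt_num(out[[col]])
    if (is.logical(out[[col]])) out[[col]] <- as.character(out[[col]])
    out[[col]][is.na(out[[col]])] <- ""
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
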