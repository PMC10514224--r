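#' Construct an arterial plasma sampling series
#'
#' Holds timed arterial samples for one PET measurement: total plasma
#' radioactivity at each draw, the subset of draws with a measured
#' unmetabolised parent fraction, and the plasma free fraction f_P
#' (fraction of tracer not bound to plasma proteins).
#'
#' @param sample_times minutes post-injection, strictly ascending, >= 0
#' @param total_activity total plasma radioactivity, kBq/mL, >= 0
#' @param parent_fraction parent fraction in `[0, 1]` at each sample time;
#'   `NA` where no metabolite subsample was drawn.  At least 3 non-missing
#'   values are required.
#' @param fp plasma free fraction, in (0, 1]
#' @return an object of class `plasma_series`
#' @export
plasma_series <- function(sample_times, total_activity, parent_fraction, fp) {
  n <- length(sample_times)
  if (n < 4L) {
    abort_validation("too few samples: need at least 4 total-activity samples",
                     where = "column time_min")
  }
  if (length(total_activity) != n || length(parent_fraction) != n) {
    abort_validation("sample_times, total_activity and parent_fraction must align")
  }
  if (anyNA(sample_times) || any(sample_times < 0)) {
    abort_validation("sample times must be non-negative and non-missing",
                     where = "column time_min")
  }
  if (any(diff(sample_times) <= 0)) {
    i <- which(diff(sample_times) <= 0)[1L] + 1L
    abort_validation("sample times must be strictly ascending",
                     where = paste0("row ", i, ", column time_min"))
  }
  if (anyNA(total_activity) || any(total_activity < 0)) {
    i <- which(is.na(total_activity) | total_activity < 0)[1L]
    abort_validation("total activity must be non-negative",
                     where = paste0("row ", i, ", column total_kbq_ml"))
  }
  pf_ok <- is.na(parent_fraction) |
    (parent_fraction >= 0 & parent_fraction <= 1)
  if (!all(pf_ok)) {
    i <- which(!pf_ok)[1L]
    abort_validation("parent fraction must lie in [0, 1]",
                     where = paste0("row ", i, ", column parent_fraction"))
  }
  if (sum(!is.na(parent_fraction)) < 3L) {
    abort_validation("too few samples: need at least 3 parent-fraction samples",
                     where = "column parent_fraction")
  }
  if (!is_number(fp) || fp <= 0 || fp > 1) {
    abort_validation("free fraction fp must lie in (0, 1]", where = "fp")
  }
  structure(
    list(
      sample_times = as.numeric(sample_times),
      total_activity = as.numeric(total_activity),
      parent_fraction = as.numeric(parent_fraction),
      fp = as.numeric(fp)
    ),
    class = "plasma_series"
  )
}

#' @export
print.plasma_series <- function(x, ...) {
  cat("<plasma_series>", length(x$sample_times), "samples,",
      sum(!is.na(x$parent_fraction)), "parent-fraction subsamples,",
      "f_P =", x$fp, "\n")
  invisible(x)
}

#' Read / write arterial plasma data
#'
#' Tab-separated file with `#`-prefixed metadata lines (one of which must
#' be `# fp <value>`) followed by a header `time_min`, `total_kbq_ml`,
#' `parent_fraction`.  Parent fraction is blank where not measured.
#' Times are minutes post-injection, activities kBq/mL.
#'
#' @param path file path
#' @return `read_plasma()` returns a [plasma_series()]
#' @export
read_plasma <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  fp_line <- grep("^#\\s*fp\\s", meta, value = TRUE)
  if (length(fp_line) != 1L) {
    abort_validation("plasma file must carry exactly one '# fp <value>' metadata line",
                     where = path)
  }
  fp <- suppressWarnings(as.numeric(sub("^#\\s*fp\\s+", "", fp_line)))
  if (is.na(fp)) abort_validation("could not parse fp metadata", where = fp_line)
  header <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
  need <- c("time_min", "total_kbq_ml", "parent_fraction")
  if (!identical(header, need)) {
    abort_validation(
      paste0("plasma header must be '", paste(need, collapse = "\\t"), "'"),
      where = path
    )
  }
  df <- utils::read.table(
    text = paste(body[-1L], collapse = "\n"), sep = "\t",
    col.names = need, colClasses = "character", fill = TRUE
  )
  num <- function(col) suppressWarnings(ifelse(df[[col]] == "", NA_real_,
                                               as.numeric(df[[col]])))
  plasma_series(num("time_min"), num("total_kbq_ml"),
                num("parent_fraction"), fp)
}

#' @param series a [plasma_series()]
#' @rdname read_plasma
#' @export
write_plasma <- function(series, path) {
  stopifnot(inherits(series, "plasma_series"))
  lines <- c(
    "# units: minutes post-injection, kBq/mL",
    paste("# fp", as.character(series$fp)),
    "time_min\ttotal_kbq_ml\tparent_fraction",
    paste(fmt_num(series$sample_times), fmt_num(series$total_activity),
          fmt_num(series$parent_fraction), sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}
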