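#' Construct a regional time-activity curve
#'
#' Framed PET radioactivity measurements for one region: frame start times
#' and durations in minutes, frame-mean activity in kBq/mL.  Frames must be
#' ascending and non-overlapping, and the region label must belong to the
#' controlled 14-region vocabulary ([all_regions()]).
#'
#' @param region region label
#' @param frame_start frame start times, minutes
#' @param frame_duration frame durations, minutes, > 0
#' @param activity frame-mean activity, kBq/mL
#' @return an object of class `tac`
#' @export
tac <- function(region, frame_start, frame_duration, activity) {
  if (!region %in% all_regions()) {
    abort_validation(
      paste0("unknown region '", region, "'; must be one of: ",
             paste(all_regions(), collapse = ", ")),
      where = "column region"
    )
  }
  n <- length(frame_start)
  if (length(frame_duration) != n || length(activity) != n) {
    abort_validation("frame columns must align", where = region)
  }
  if (n < 4L) abort_validation("too few frames (need >= 4)", where = region)
  if (anyNA(frame_start) || anyNA(frame_duration) || anyNA(activity)) {
    abort_validation("frames must be complete", where = region)
  }
  if (any(frame_duration <= 0)) {
    i <- which(frame_duration <= 0)[1L]
    abort_validation("frame durations must be positive",
                     where = paste0(region, " row ", i, ", column frame_duration"))
  }
  ends <- frame_start + frame_duration
  if (any(diff(frame_start) <= 0) ||
      any(frame_start[-1L] < ends[-n] - 1e-9)) {
    abort_validation("frames must be ascending and non-overlapping",
                     where = paste0(region, ", column frame_start"))
  }
  structure(
    list(region = region, frame_start = as.numeric(frame_start),
         frame_duration = as.numeric(frame_duration),
         activity = as.numeric(activity)),
    class = "tac"
  )
}

#' @export
print.tac <- function(x, ...) {
  cat("<tac>", x$region, "-", length(x$frame_start), "frames,",
      sprintf("%.1f-%.1f min\n", x$frame_start[1L],
              max(x$frame_start + x$frame_duration)))
  invisible(x)
}

frame_midpoints <- function(tac) tac$frame_start + tac$frame_duration / 2

#' Read / write regional time-activity curves
#'
#' Long-format tab-separated file with header
#' `region`, `frame_start`, `frame_duration`, `activity`
#' (minutes and kBq/mL).  One [tac()] is returned per region; unknown
#' region labels are rejected with the controlled vocabulary in the
#' error message.
#'
#' @param path file path
#' @return `read_tacs()` returns a named list of [tac()] objects
#' @export
read_tacs <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", rep("numeric", 3)),
                          comment.char = "#")
  need <- c("region", "frame_start", "frame_duration", "activity")
  if (!identical(names(df), need)) {
    abort_validation(paste0("TAC header must be '",
                            paste(need, collapse = "\\t"), "'"), where = path)
  }
  regions <- unique(df$region)
  out <- lapply(regions, function(r) {
    sub <- df[df$region == r, , drop = FALSE]
    sub <- sub[order(sub$frame_start), , drop = FALSE]
    tac(r, sub$frame_start, sub$frame_duration, sub$activity)
  })
  names(out) <- regions
  out
}

#' @param tacs a list of [tac()] objects
#' @rdname read_tacs
#' @export
write_tacs <- function(tacs, path) {
  if (inherits(tacs, "tac")) tacs <- list(tacs)
  rows <- unlist(lapply(tacs, function(x) {
    paste(x$region, fmt_num(x$frame_start), fmt_num(x$frame_duration),
          fmt_num(x$activity), sep = "\t")
  }))
  writeLines(c("region\tframe_start\tframe_duration\tactivity", rows), path)
  invisible(path)
}
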