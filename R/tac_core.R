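#' Frame schedules for 30-min dynamic acquisitions
#'
#' Builds one of the two temporal sampling protocols used for 30-minute
#' dynamic brain PET acquisitions: a variable protocol with short early
#' frames for analyses that need an arterial input function (12 x 5 s,
#' 6 x 10 s, 6 x 30 s, 5 x 60 s, 4 x 300 s; 33 frames), or a uniform
#' protocol of 30 x 60 s frames for analyses that do not. Both span
#' exactly 1800 s from injection.
#'
#' @param protocol `"input_function"` or `"uniform"`.
#' @return A `frame_schedule` object: a data frame with columns
#'   `frame_start_s` and `frame_duration_s` (seconds from injection).
#' @examples
#' sched <- make_schedule("uniform")
#' nrow(sched)                       # 30
#' sum(sched$frame_duration_s)      # 1800
#' @export
make_schedule <- function(protocol = c("input_function", "uniform")) {
  protocol <- match.arg(protocol)
  dur <- switch(protocol,
    input_function = c(rep(5, 12), rep(10, 6), rep(30, 6), rep(60, 5), rep(300, 4)),
    uniform = rep(60, 30)
  )
  frame_schedule(frame_start_s = cumsum(c(0, dur[-length(dur)])),
                 frame_duration_s = dur)
}

#' Construct and validate a frame schedule
#'
#' @param frame_start_s Frame start times in seconds from injection.
#' @param frame_duration_s Frame durations in seconds.
#' @return A `frame_schedule` data frame.
#' @export
frame_schedule <- function(frame_start_s, frame_duration_s) {
  stopifnot(length(frame_start_s) == length(frame_duration_s),
            length(frame_start_s) >= 1L)
  if (any(frame_duration_s <= 0)) stop("frame durations must be > 0")
  if (is.unsorted(frame_start_s, strictly = TRUE))
    stop("frame starts must be strictly increasing")
  ends <- frame_start_s + frame_duration_s
  if (any(abs(frame_start_s[-1] - ends[-length(ends)]) > 1e-9))
    stop("frames must be contiguous and non-overlapping")
  structure(data.frame(frame_start_s = as.numeric(frame_start_s),
                       frame_duration_s = as.numeric(frame_duration_s)),
            class = c("frame_schedule", "data.frame"))
}

#' Frame midpoints in minutes
#'
#' @param schedule A `frame_schedule`.
#' @return Numeric vector of frame midpoints in minutes post-injection,
#'   strictly increasing.
#' @export
frame_midpoints <- function(schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  (schedule$frame_start_s + schedule$frame_duration_s / 2) / 60
}

#' Time-activity curve (TAC)
#'
#' A region-level dynamic PET curve: one mean SUV per frame of a schedule.
#' Negative values (possible in noisy early frames) are preserved, not
#' clipped, since clipping biases late-slope estimates.
#'
#' @param schedule A `frame_schedule`.
#' @param values Numeric SUV values, one per frame; must be finite.
#' @param region One of `"tumor"`, `"brain_reference"`, `"blood"`.
#' @param protocol Which built-in protocol the schedule corresponds to
#'   (`"uniform"` or `"input_function"`); informational.
#' @return A `tac` object.
#' @export
tac <- function(schedule, values, region = c("tumor", "brain_reference", "blood"),
                protocol = NULL) {
  region <- match.arg(region)
  stopifnot(inherits(schedule, "frame_schedule"))
  values <- as.numeric(values)
  if (length(values) != nrow(schedule))
    stop("need exactly one SUV value per frame")
  if (any(!is.finite(values))) stop("TAC values must be finite")
  structure(list(schedule = schedule, values = values, region = region,
                 protocol = protocol %||% guess_protocol(schedule)),
            class = "tac")
}

guess_protocol <- function(schedule) {
  if (nrow(schedule) == 30 && all(schedule$frame_duration_s == 60)) return("uniform")
  if (nrow(schedule) == 33 && schedule$frame_duration_s[1] == 5) return("input_function")
  "custom"
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("TAC: region %s, %d frames (%s protocol), span %.0f s\n",
              x$region, nrow(x$schedule), x$protocol,
              sum(x$schedule$frame_duration_s)))
  cat(sprintf("  SUV range [%.3f, %.3f]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.tac <- function(x, ...) {
  plot(frame_midpoints(x$schedule), x$values, xlab = "time (min)",
       ylab = "SUV", main = sprintf("%s TAC", x$region), ...)
  invisible(x)
}

#' Pointwise ratio of two fitted curves
#'
#' Evaluates the tumor-to-reference ratio on a dense time grid, the curve
#' from which reference-normalised semiquantitative parameters (TTP ratio,
#' slope ratio) are extracted.
#'
#' @param tumor,reference Continuous curves: functions of time in minutes.
#' @param times_min Evaluation grid in minutes (default 1-s resolution over
#'   the full acquisition).
#' @return A data frame with columns `time_min` and `value`.
#' @export
tac_ratio <- function(tumor, reference, times_min = dense_grid_min()) {
  tv <- eval_curve(tumor, times_min)
  rv <- eval_curve(reference, times_min)
  if (any(rv <= 0))
    stop(sprintf("reference curve non-positive at t = %.3f min",
                 times_min[which(rv <= 0)[1]]))
  data.frame(time_min = times_min, value = tv / rv)
}

#' Subject record
#'
#' Bundles a subject's TACs with its binary IDH label. A subject may hold
#' the tumor TAC under both temporal protocols (the uniform curve feeds the
#' semiquantitative and graphical models, the short-early-frame curve feeds
#' the compartmental model).
#'
#' @param subject_id Character id.
#' @param idh_mutant Logical IDH mutation status (may be `NA` if unknown).
#' @param tacs A list of `tac` objects.
#' @return A `subject_record`.
#' @export
subject_record <- function(subject_id, idh_mutant, tacs) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L,
            is.logical(idh_mutant), length(idh_mutant) == 1L,
            is.list(tacs), all(vapply(tacs, inherits, logical(1), "tac")))
  regions <- vapply(tacs, `[[`, character(1), "region")
  if (!"tumor" %in% regions)
    stop(sprintf("subject %s: tumor TAC is required", subject_id))
  names(tacs) <- paste(regions, vapply(tacs, `[[`, character(1), "protocol"),
                       sep = ".")
  if (anyDuplicated(names(tacs)))
    stop(sprintf("subject %s: duplicate region/protocol TAC", subject_id))
  structure(list(subject_id = subject_id, idh_mutant = idh_mutant, tacs = tacs),
            class = "subject_record")
}

#' Retrieve a subject's TAC for a region (and optionally a protocol)
#'
#' @param subject A `subject_record`.
#' @param region Region label.
#' @param protocol Optional protocol; if `NULL`, the unique TAC for the
#'   region is returned (error if the region is present under several
#'   protocols).
#' @return A `tac`, or `NULL` if absent.
#' @export
get_tac <- function(subject, region, protocol = NULL) {
  hits <- Filter(function(x) x$region == region &&
                   (is.null(protocol) || x$protocol == protocol),
                 subject$tacs)
  if (length(hits) == 0L) return(NULL)
  if (length(hits) > 1L)
    stop(sprintf("subject %s: region %s present under several protocols; specify one",
                 subject$subject_id, region))
  hits[[1]]
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("Subject %s (IDH %s): %s\n", x$subject_id,
              if (isTRUE(x$idh_mutant)) "mutant" else if (isFALSE(x$idh_mutant)) "wild-type" else "unknown",
              paste(names(x$tacs), collapse = ", ")))
  invisible(x)
}

cohort_columns <- c("subject_id", "region", "protocol", "frame_start_s",
                    "frame_duration_s", "suv_mean")

#' Write a cohort of subject records to delimited text
#'
#' Produces two comma-separated files: one row per (subject, region,
#' protocol, frame) with the frame timing and mean SUV, plus a label file
#' mapping `subject_id` to `idh_mutant` (0/1).
#'
#' @param subjects A list of `subject_record` objects.
#' @param tac_path,label_path Output file paths.
#' @return Invisibly, the list of subjects.
#' @export
write_cohort <- function(subjects, tac_path, label_path) {
  stopifnot(all(vapply(subjects, inherits, logical(1), "subject_record")))
  rows <- do.call(rbind, lapply(subjects, function(s) {
    do.call(rbind, lapply(s$tacs, function(x) {
      data.frame(subject_id = s$subject_id, region = x$region,
                 protocol = x$protocol,
                 frame_start_s = x$schedule$frame_start_s,
                 frame_duration_s = x$schedule$frame_duration_s,
                 suv_mean = x$values)
    }))
  }))
  rownames(rows) <- NULL
  utils::write.csv(format(rows, digits = 17, scientific = FALSE, trim = TRUE),
                   tac_path, row.names = FALSE, quote = FALSE)
  labels <- data.frame(
    subject_id = vapply(subjects, `[[`, character(1), "subject_id"),
    idh_mutant = as.integer(vapply(subjects, `[[`, logical(1), "idh_mutant")))
  utils::write.csv(labels, label_path, row.names = FALSE, quote = FALSE)
  invisible(subjects)
}

#' Read a cohort from delimited text
#'
#' Reads the files written by [write_cohort()]. Frame rows may appear in any
#' order on disk: they are sorted by `frame_start_s` within each (subject,
#' region, protocol) group, then checked for contiguity and duplicates. The
#' `protocol` column is optional; if absent, each region is assumed to carry
#' a single schedule whose protocol is inferred from the frame grid.
#'
#' @param tac_path Path to the TAC file.
#' @param label_path Optional path to the label file; if omitted, labels are
#'   `NA`.
#' @return A list of `subject_record` objects, ordered as in the label file
#'   (or by first appearance in the TAC file).
#' @export
read_cohort <- function(tac_path, label_path = NULL) {
  df <- utils::read.csv(tac_path, stringsAsFactors = FALSE)
  if (!"protocol" %in% names(df)) df$protocol <- NA_character_
  missing <- setdiff(setdiff(cohort_columns, "protocol"), names(df))
  if (length(missing))
    stop("cohort file missing column(s): ", paste(missing, collapse = ", "))
  labels <- NULL
  if (!is.null(label_path)) {
    labels <- utils::read.csv(label_path, stringsAsFactors = FALSE)
    if (!all(c("subject_id", "idh_mutant") %in% names(labels)))
      stop("label file must have columns subject_id, idh_mutant")
  }
  ids <- if (!is.null(labels)) as.character(labels$subject_id) else unique(df$subject_id)
  subjects <- lapply(ids, function(id) {
    sub <- df[df$subject_id == id, , drop = FALSE]
    if (nrow(sub) == 0L) stop(sprintf("subject %s has no TAC rows", id))
    groups <- split(sub, paste(sub$region, sub$protocol, sep = "."))
    tacs <- lapply(groups, function(g) {
      g <- g[order(g$frame_start_s), , drop = FALSE]
      if (anyDuplicated(g$frame_start_s)) {
        dup <- g$frame_start_s[duplicated(g$frame_start_s)][1]
        stop(sprintf("subject %s region %s: duplicate frame at %g s",
                     id, g$region[1], dup))
      }
      sched <- tryCatch(frame_schedule(g$frame_start_s, g$frame_duration_s),
        error = function(e) stop(sprintf("subject %s region %s: %s",
                                         id, g$region[1], conditionMessage(e))))
      tac(sched, g$suv_mean, region = g$region[1],
          protocol = if (is.na(g$protocol[1])) NULL else g$protocol[1])
    })
    mut <- if (!is.null(labels)) {
      as.logical(labels$idh_mutant[labels$subject_id == id][1])
    } else NA
    subject_record(id, mut, unname(tacs))
  })
  subjects
}
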