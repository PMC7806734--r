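#' Construct a single maze session
#'
#' A session is one mouse exploring the maze under one condition for a fixed
#' duration (5 minutes by default). It holds the ordered arm-entry events
#' (arm label, entry time, exit time, in seconds on a session clock starting
#' at animal placement) plus animal metadata. Distance travelled and average
#' speed are optional pass-through values produced by the video-tracking
#' software, never computed here.
#'
#' @param mouse_id Character scalar identifying the animal.
#' @param events Data frame with columns `arm`, `t_enter`, `t_exit`
#'   (seconds). Events must be ordered by `t_enter`, non-overlapping, with
#'   `t_exit >= t_enter`, and lie within `[0, duration_s]`.
#' @param genotype `"WT"` or `"AD+"`.
#' @param sex `"M"` or `"F"`.
#' @param age_months Positive number.
#' @param condition One of `"NC"`, `"L"`, `"M"`, `"H"`, `"RH"`, `"E"`,
#'   `"CONTRAST"`.
#' @param duration_s Session length in seconds (default 300).
#' @param mode Arm-label vocabulary, see [arm_labels()].
#' @param distance_m,speed_mps Optional pass-through tracking summaries.
#' @return An object of class `vis4m_session`.
#' @examples
#' ev <- data.frame(arm = c("R", "G", "B", "W"),
#'                  t_enter = c(0, 20, 40, 60), t_exit = c(10, 30, 50, 70))
#' s <- session("m1", ev)
#' arm_sequence(s)
#' @export
session <- function(mouse_id, events,
                    genotype = c("WT", "AD+"), sex = c("M", "F"),
                    age_months = NA_real_,
                    condition = c("E", "NC", "L", "M", "H", "RH", "CONTRAST"),
                    duration_s = 300, mode = c("color", "contrast", "generic"),
                    distance_m = NA_real_, speed_mps = NA_real_) {
  genotype <- match.arg(genotype)
  sex <- match.arg(sex)
  condition <- match.arg(condition)
  mode <- match.arg(mode)
  stopifnot(is.character(mouse_id), length(mouse_id) == 1L,
            is.numeric(duration_s), duration_s > 0)
  events <- as.data.frame(events)
  req <- c("arm", "t_enter", "t_exit")
  missing_cols <- setdiff(req, names(events))
  if (length(missing_cols) > 0L) {
    stop("events is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  events$arm <- as.character(events$arm)
  check_arm_sequence(events$arm, arm_labels(mode))
  if (nrow(events) > 0L) {
    if (any(events$t_exit < events$t_enter)) {
      stop("event with t_exit < t_enter")
    }
    if (any(events$t_enter < 0) || any(events$t_exit > duration_s + 1e-9)) {
      stop("event times outside [0, duration_s]")
    }
    if (is.unsorted(events$t_enter)) stop("events not ordered by t_enter")
    n <- nrow(events)
    if (n > 1L && any(events$t_enter[-1L] < events$t_exit[-n] - 1e-9)) {
      stop("overlapping events")
    }
  }
  structure(
    list(mouse_id = mouse_id, genotype = genotype, sex = sex,
         age_months = age_months, condition = condition,
         duration_s = duration_s, mode = mode,
         events = events[, req, drop = FALSE],
         distance_m = distance_m, speed_mps = speed_mps),
    class = "vis4m_session"
  )
}

#' Extract the ordered arm-entry sequence of a session
#'
#' @param x A `vis4m_session` or a plain character vector (returned as is).
#' @param collapse If `TRUE` (default), consecutive same-arm re-entries are
#'   collapsed with [collapse_reentries()] before returning.
#' @return Character vector of arm labels.
#' @export
arm_sequence <- function(x, collapse = TRUE) {
  seq <- if (inherits(x, "vis4m_session")) x$events$arm else as.character(x)
  if (collapse) collapse_reentries(seq)$sequence else seq
}

#' @export
print.vis4m_session <- function(x, ...) {
  cat(sprintf("<vis4m_session> %s | %s %s %.1f mo | condition %s | %d entries / %.0f s\n",
              x$mouse_id, x$genotype, x$sex, x$age_months, x$condition,
              nrow(x$events), x$duration_s))
  invisible(x)
}
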