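#' Read arm-entry event logs into sessions
#'
#' The event-log dialect is a UTF-8, comma-delimited file with a mandatory
#' header and columns `mouse_id, genotype, sex, age_months, condition, arm,
#' t_enter_s, t_exit_s` (optional `distance_m`, `speed_mps`, `duration_s`
#' pass-throughs). One session is formed per `(mouse_id, condition)` group,
#' with events ordered by entry time. Validation failures (unknown arm
#' label, negative or reversed times, overlapping events, missing columns)
#' raise errors citing the offending file line.
#'
#' @param path CSV file path.
#' @param mode Arm vocabulary the labels must come from (see
#'   [arm_labels()]).
#' @param duration_s Session duration when the file carries none.
#' @return List of [session()] objects.
#' @export
read_sessions <- function(path, mode = c("color", "contrast", "generic"),
                          duration_s = 300) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("mouse_id", "genotype", "sex", "age_months", "condition",
           "arm", "t_enter_s", "t_exit_s")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols) > 0L) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  raw$.line <- seq_len(nrow(raw)) + 1L   # header is line 1
  labels <- arm_labels(mode)
  bad <- which(!(raw$arm %in% labels))
  if (length(bad) > 0L) {
    stop(sprintf("unknown arm label '%s' on line %d of %s",
                 raw$arm[bad[1L]], raw$.line[bad[1L]], path))
  }
  if (any(!is.finite(raw$t_enter_s)) || any(!is.finite(raw$t_exit_s))) {
    stop("non-numeric entry/exit times in ", path)
  }
  rev_t <- which(raw$t_exit_s < raw$t_enter_s)
  if (length(rev_t) > 0L) {
    stop(sprintf("t_exit_s < t_enter_s on line %d of %s",
                 raw$.line[rev_t[1L]], path))
  }
  groups <- split(raw, list(raw$mouse_id, raw$condition), drop = TRUE)
  sessions <- lapply(groups, function(g) {
    g <- g[order(g$t_enter_s), , drop = FALSE]
    n <- nrow(g)
    if (n > 1L) {
      ov <- which(g$t_enter_s[-1L] < g$t_exit_s[-n] - 1e-9)
      if (length(ov) > 0L) {
        stop(sprintf("overlapping events for mouse %s (%s), line %d of %s",
                     g$mouse_id[1L], g$condition[1L], g$.line[ov[1L] + 1L],
                     path))
      }
    }
    dur <- if ("duration_s" %in% names(g)) g$duration_s[1L] else duration_s
    session(
      mouse_id = as.character(g$mouse_id[1L]),
      events = data.frame(arm = g$arm, t_enter = g$t_enter_s,
                          t_exit = g$t_exit_s),
      genotype = g$genotype[1L], sex = g$sex[1L],
      age_months = as.numeric(g$age_months[1L]),
      condition = g$condition[1L], duration_s = dur, mode = mode,
      distance_m = if ("distance_m" %in% names(g)) g$distance_m[1L] else NA_real_,
      speed_mps = if ("speed_mps" %in% names(g)) g$speed_mps[1L] else NA_real_
    )
  })
  unname(sessions)
}

#' Write sessions to the event-log CSV dialect
#'
#' Inverse of [read_sessions()]; the round trip is lossless for the event
#' table and metadata.
#'
#' @param sessions List of [session()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sessions <- function(sessions, path) {
  if (inherits(sessions, "vis4m_session")) sessions <- list(sessions)
  rows <- lapply(sessions, function(s) {
    if (nrow(s$events) == 0L) return(NULL)
    data.frame(
      mouse_id = s$mouse_id, genotype = s$genotype, sex = s$sex,
      age_months = s$age_months, condition = s$condition,
      arm = s$events$arm, t_enter_s = s$events$t_enter,
      t_exit_s = s$events$t_exit, duration_s = s$duration_s,
      distance_m = s$distance_m, speed_mps = s$speed_mps
    )
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a transition-count table in Circos tableviewer format
#'
#' Emits the tab-delimited 4x4 count matrix consumed by the Circos online
#' tableviewer: a first row of segment labels, then one row per origin arm
#' with integer counts of transitions to each destination arm. The diagonal
#' is zero (self-transitions do not exist after collapsing re-entries) and
#' the matrix sums to the session's total transitions. For chord diagrams
#' restricted to the most or least frequent quartile, pass `quartile` so that
#' counts outside the selected quartile are zeroed.
#'
#' @param profile A [transition_profile()].
#' @param path Output TSV path.
#' @param quartile Optional: `"Q4_most_frequent"` or `"Q1_least_frequent"`,
#'   see [select_quartile_transitions()].
#' @return The written matrix, invisibly.
#' @export
write_circos_table <- function(profile, path, quartile = NULL) {
  stopifnot(inherits(profile, "transition_profile"))
  labels <- profile$labels
  m <- matrix(0L, 4L, 4L, dimnames = list(labels, labels))
  keep <- names(profile$uni_counts)
  if (!is.null(quartile)) {
    keep <- select_quartile_transitions(profile, quartile)
  }
  for (key in keep) {
    ft <- strsplit(key, ">", fixed = TRUE)[[1L]]
    m[ft[1L], ft[2L]] <- profile$uni_counts[[key]]
  }
  lines <- c(
    paste(c("labels", labels), collapse = "\t"),
    vapply(labels, function(fr) {
      paste(c(fr, m[fr, ]), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(m)
}

#' Summarize a cohort of sessions into a tidy metric table
#'
#' One row per session and metric: `total_entries` (raw, before collapsing
#' re-entries), `n_collapsed`, `percent_alternation`, per-arm
#' `pct_entries_<arm>` and `pct_time_<arm>`, the 12 unidirectional
#' `pct_uni_<from>_<to>` and 6 bidirectional `pct_bi_<a>_<b>` transition
#' percentages, plus pass-through `distance_m` / `speed_mps` when present.
#' Sessions too short to score (fewer than 4 collapsed entries) keep their
#' rows with `NA` alternation and a `flag` instead of being dropped.
#'
#' @param sessions List of [session()] objects.
#' @return Tibble with columns `mouse_id`, `genotype`, `sex`, `age_months`,
#'   `condition`, `metric`, `value`, `flag`.
#' @export
summarize_cohort <- function(sessions) {
  if (inherits(sessions, "vis4m_session")) sessions <- list(sessions)
  stopifnot(length(sessions) >= 1L)
  per_session <- lapply(sessions, function(s) {
    raw_seq <- s$events$arm
    col <- collapse_reentries(raw_seq)
    seq <- col$sequence
    metrics <- c(total_entries = length(raw_seq),
                 n_collapsed = col$n_collapsed)
    flag <- ""
    if (length(seq) >= 4L) {
      metrics <- c(metrics,
                   percent_alternation = percent_alternation(seq)$percent)
    } else {
      metrics <- c(metrics, percent_alternation = NA_real_)
      flag <- "too_few_entries"
    }
    labels <- arm_labels(s$mode)
    pe <- percent_entries(raw_seq, labels)
    names(pe) <- paste0("pct_entries_", labels)
    pt <- tryCatch(percent_time(s, labels), error = function(e) {
      stats::setNames(rep(NA_real_, 4L), labels)
    })
    names(pt) <- paste0("pct_time_", labels)
    metrics <- c(metrics, pe, pt)
    if (length(seq) >= 2L) {
      prof <- transition_profile(seq, labels)
      uni <- prof$uni_percent
      names(uni) <- paste0("pct_uni_", gsub(">", "_", names(uni), fixed = TRUE))
      bi <- prof$bi_percent
      names(bi) <- paste0("pct_bi_", gsub(":", "_", names(bi), fixed = TRUE))
      metrics <- c(metrics, uni, bi)
    }
    if (!is.na(s$distance_m)) metrics <- c(metrics, distance_m = s$distance_m)
    if (!is.na(s$speed_mps)) metrics <- c(metrics, speed_mps = s$speed_mps)
    tibble::tibble(
      mouse_id = s$mouse_id, genotype = s$genotype, sex = s$sex,
      age_months = s$age_months, condition = s$condition,
      metric = names(metrics), value = unname(metrics), flag = flag
    )
  })
  do.call(rbind, per_session)
}

#' Load an illumination-condition configuration
#'
#' Reads a YAML or JSON file describing one or more illumination conditions:
#' per condition, per arm, either an exposure value (`ev`), an illuminance
#' (`lux`) or a luminance (`cd_m2`), plus optional LED spectral parameters
#' (`peak_nm`, `fwhm_nm`, `weights` per arm under `spectra`). Every derived
#' photometric quantity is filled in via [light_condition()]. An unlit
#' condition (all arms 0 lux) models the no-color configuration.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @param lens_correction Passed to [light_condition()].
#' @return Named list of `light_condition` objects.
#' @export
load_condition_config <- function(path, lens_correction = TRUE) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$conditions)) {
    stop("malformed config ", path, ": top-level 'conditions' missing")
  }
  spectra <- vis4m_led_set()
  if (!is.null(cfg$spectra)) {
    spectra <- lapply(cfg$spectra, function(sp) {
      led_spectrum(unlist(sp$peak_nm), unlist(sp$fwhm_nm),
                   weights = if (!is.null(sp$weights)) unlist(sp$weights))
    })
  }
  out <- lapply(names(cfg$conditions), function(cname) {
    arms <- cfg$conditions[[cname]]
    if (!is.list(arms) || is.null(names(arms))) {
      stop("malformed config ", path, ": condition '", cname,
           "' must map arm labels to intensities")
    }
    missing_arms <- setdiff(names(spectra), names(arms))
    if (length(missing_arms) > 0L) {
      stop("condition '", cname, "' in ", path, " is missing arm(s): ",
           paste(missing_arms, collapse = ", "))
    }
    light_condition(cname, arms, spectra = spectra,
                    lens_correction = lens_correction)
  })
  stats::setNames(out, names(cfg$conditions))
}
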