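#' Trial dataset container for alternating sojourn histories
#'
#' A `trial_dataset` holds one clinical trial's event histories in the
#' two-state representation: a `subjects` table (one row per subject with
#' covariates, study length and dropout outcome) and a `sojourns` table (one
#' row per observed interval in a state, with its duration in days and a flag
#' saying whether the transition out of the state was observed or the
#' interval was right-censored at end of follow-up).
#'
#' Validity rules enforced on construction:
#' \itemize{
#'   \item states strictly alternate within each subject, starting in
#'     state 1 (asymptomatic) at episode 1;
#'   \item only the final sojourn of a subject may be censored
#'     (\code{event = FALSE});
#'   \item durations are at least 0.5 days (the package's resolution floor:
#'     the log-hazard diverges as \eqn{t \to 0} for some families, and the
#'     source trials record events at day resolution);
#'   \item per-subject total time does not exceed the subject's study length
#'     (tolerance 1e-6);
#'   \item \code{dropout_flag} is \code{TRUE} exactly when follow-up ends
#'     more than \code{dropout_window} days before the nominal study end.
#' }
#'
#' @param subjects Data frame with columns \code{subject_id},
#'   \code{treatment}, \code{disease_stage}, \code{smoke}, \code{pack_years},
#'   \code{season}, \code{study_length}, \code{dropout_time} (\code{NA} when
#'   the subject was followed to study end), \code{dropout_flag}.
#' @param sojourns Data frame with columns \code{subject_id}, \code{episode},
#'   \code{state}, \code{duration}, \code{event}.
#' @param dropout_window Grace period in days before nominal study end within
#'   which an early last visit does not count as dropout (30 by default; 14
#'   for short-study analyses).
#'
#' @return An object of class \code{"trial_dataset"}.
#' @seealso [read_trial()], [episodes_to_sojourns()], [simulate_trial()]
#' @export
trial_dataset <- function(subjects, sojourns, dropout_window = 30) {
  subjects <- as.data.frame(subjects)
  sojourns <- as.data.frame(sojourns)
  need_subj <- c("subject_id", "treatment", "disease_stage", "smoke",
                 "pack_years", "season", "study_length", "dropout_time",
                 "dropout_flag")
  miss <- setdiff(need_subj, names(subjects))
  if (length(miss))
    stop("`subjects` is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  need_soj <- c("subject_id", "episode", "state", "duration", "event")
  miss <- setdiff(need_soj, names(sojourns))
  if (length(miss))
    stop("`sojourns` is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  subjects$subject_id <- as.character(subjects$subject_id)
  sojourns$subject_id <- as.character(sojourns$subject_id)
  sojourns$event <- as.logical(sojourns$event)
  subjects$dropout_flag <- as.logical(subjects$dropout_flag)
  if (anyDuplicated(subjects$subject_id))
    stop("duplicated subject_id in `subjects`", call. = FALSE)
  x <- structure(list(subjects = subjects,
                      sojourns = sojourns[order(sojourns$subject_id,
                                                sojourns$episode), ,
                                          drop = FALSE],
                      dropout_window = dropout_window),
                 class = "trial_dataset")
  validate_trial_dataset(x)
  x
}

validate_trial_dataset <- function(x, tol = 1e-6) {
  sub <- x$subjects
  soj <- x$sojourns
  for (nm in c("treatment", "disease_stage", "smoke", "season")) {
    v <- sub[[nm]]
    if (any(!v %in% c(0, 1)))
      stop("subject covariate '", nm, "' must be 0/1", call. = FALSE)
  }
  if (any(!is.finite(sub$study_length)) || any(sub$study_length <= 0))
    stop("`study_length` must be finite and > 0", call. = FALSE)
  if (any(sub$pack_years < 0, na.rm = TRUE))
    stop("`pack_years` must be >= 0", call. = FALSE)
  unknown <- setdiff(soj$subject_id, sub$subject_id)
  if (length(unknown))
    stop("sojourns refer to unknown subject(s): ",
         paste(utils::head(unknown, 3), collapse = ", "), call. = FALSE)
  if (any(!soj$state %in% c(1, 2)))
    stop("`state` must be 1 or 2", call. = FALSE)
  if (any(!is.finite(soj$duration)) || any(soj$duration < 0.5 - tol))
    stop("sojourn durations must be >= 0.5 days (row ",
         which(soj$duration < 0.5 - tol)[1], ")", call. = FALSE)
  split_idx <- split(seq_len(nrow(soj)), soj$subject_id)
  fu <- setNames(numeric(nrow(sub)), sub$subject_id)
  for (id in names(split_idx)) {
    i <- split_idx[[id]]
    ep <- soj$episode[i]
    if (!identical(as.integer(ep), seq_along(i)))
      stop("subject ", id, ": episodes must be 1, 2, ... without gaps",
           call. = FALSE)
    expected_state <- 2 - (ep %% 2)  # 1, 2, 1, 2, ...
    if (any(soj$state[i] != expected_state))
      stop("subject ", id, ": states must alternate starting in state 1",
           call. = FALSE)
    ev <- soj$event[i]
    if (any(!ev[-length(ev)]))
      stop("subject ", id, ": only the final sojourn may be censored",
           call. = FALSE)
    fu[id] <- sum(soj$duration[i])
    T_j <- sub$study_length[sub$subject_id == id]
    if (fu[id] > T_j + tol)
      stop("subject ", id, ": total sojourn time ", fu[id],
           " exceeds study length ", T_j, call. = FALSE)
  }
  # dropout window rule
  has_rows <- sub$subject_id %in% names(split_idx)
  end <- ifelse(has_rows, fu[sub$subject_id], sub$study_length)
  expected_flag <- end < sub$study_length - x$dropout_window - tol
  bad <- which(expected_flag != sub$dropout_flag)
  if (length(bad))
    stop("subject ", sub$subject_id[bad[1]],
         ": dropout_flag inconsistent with the ", x$dropout_window,
         "-day dropout window rule", call. = FALSE)
  invisible(x)
}

#' @export
print.trial_dataset <- function(x, ...) {
  n <- nrow(x$subjects)
  cat("Two-state trial dataset:", n, "subjects,", nrow(x$sojourns),
      "sojourns\n")
  cat("  arms:", sum(x$subjects$treatment == 1), "active /",
      sum(x$subjects$treatment == 0), "placebo;",
      sum(x$subjects$dropout_flag), "dropouts (window",
      x$dropout_window, "days)\n")
  cat("  exacerbations observed:",
      sum(x$sojourns$state == 2 & x$sojourns$event), "completed,",
      sum(x$sojourns$state == 2 & !x$sojourns$event), "ongoing at censoring\n")
  invisible(x)
}

#' Number of subjects / person-time helpers
#' @param x A \code{trial_dataset}.
#' @return \code{n_subjects}: integer count; \code{person_time}: total
#'   observed days summed over subjects.
#' @export
n_subjects <- function(x) nrow(x$subjects)

#' @rdname n_subjects
#' @export
person_time <- function(x) sum(x$sojourns$duration)

#' Convert exacerbation intervals to alternating sojourn records
#'
#' Trials often record exacerbations as (onset, resolution) day pairs. This
#' converts one subject's interval list into the alternating two-state
#' representation: the gap before the first onset is an asymptomatic (state 1)
#' sojourn, each exacerbation is a symptomatic (state 2) sojourn, and the
#' final interval is right-censored at end of follow-up when no transition
#' closes it. An exacerbation still ongoing at end of follow-up yields a
#' censored state-2 record; a resolution at exactly end of follow-up counts
#' as observed.
#'
#' @param intervals Data frame (or matrix) with columns \code{onset},
#'   \code{resolution}, sorted, non-overlapping, contained in
#'   \code{[0, study_length]}; \code{resolution = NA} marks an exacerbation
#'   ongoing at end of follow-up.
#' @param study_length Follow-up end in days (study length, or the dropout
#'   time if the subject left early).
#' @param subject_id Identifier stamped on the returned records.
#' @return Data frame of sojourn records (columns \code{subject_id},
#'   \code{episode}, \code{state}, \code{duration}, \code{event}).
#' @examples
#' episodes_to_sojourns(data.frame(onset = 100, resolution = 110), 364)
#' @export
episodes_to_sojourns <- function(intervals, study_length, subject_id = "s1") {
  intervals <- as.data.frame(intervals)
  if (nrow(intervals) > 0) {
    on <- intervals$onset
    res <- intervals$resolution
    res_chk <- ifelse(is.na(res), study_length, res)
    if (any(on < 0) || any(res_chk > study_length + 1e-9))
      stop("intervals must lie within [0, study_length]", call. = FALSE)
    if (any(res_chk < on))
      stop("interval resolution precedes onset", call. = FALSE)
    if (is.unsorted(on, strictly = TRUE) ||
        any(on[-1] < res_chk[-nrow(intervals)]))
      stop("intervals must be sorted and non-overlapping", call. = FALSE)
    if (any(is.na(res[-nrow(intervals)])))
      stop("only the final interval may have missing resolution",
           call. = FALSE)
  }
  state <- integer(0); duration <- numeric(0); event <- logical(0)
  t0 <- 0
  if (nrow(intervals) > 0) {
    for (i in seq_len(nrow(intervals))) {
      on <- intervals$onset[i]
      res <- intervals$resolution[i]
      state <- c(state, 1L); duration <- c(duration, on - t0)
      event <- c(event, TRUE)
      if (is.na(res) || res >= study_length) {
        # ongoing (or closing exactly) at end of follow-up
        state <- c(state, 2L)
        duration <- c(duration, study_length - on)
        event <- c(event, !is.na(res) && res <= study_length)
        t0 <- study_length
      } else {
        state <- c(state, 2L); duration <- c(duration, res - on)
        event <- c(event, TRUE)
        t0 <- res
      }
    }
  }
  if (t0 < study_length) {
    state <- c(state, 1L); duration <- c(duration, study_length - t0)
    event <- c(event, FALSE)
  }
  data.frame(subject_id = subject_id, episode = seq_along(state),
             state = state, duration = duration, event = event,
             stringsAsFactors = FALSE)
}

#' Read / write a trial dataset in the flat CSV dialect
#'
#' The on-disk layout is one comma-delimited file with a header and one row
#' per sojourn, the subject-level fields repeated on each row:
#' \code{subject_id,episode,state,duration,event,treatment,disease_stage,}
#' \code{smoke,pack_years,season,study_length,dropout_time,dropout_flag}.
#' A missing \code{dropout_time} is an empty field. A second accepted layout
#' (\code{format = "interval"}) has columns
#' \code{subject_id,onset,resolution,study_length} plus the covariate columns,
#' one row per exacerbation, and is converted through
#' [episodes_to_sojourns()].
#'
#' @param path File path.
#' @param format \code{"sojourn"} (default) or \code{"interval"}.
#' @param dropout_window Passed to [trial_dataset()].
#' @return \code{read_trial}: a \code{trial_dataset}. \code{write_trial}:
#'   the path, invisibly.
#' @export
read_trial <- function(path, format = c("sojourn", "interval"),
                       dropout_window = 30) {
  format <- match.arg(format)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  cov_cols <- c("treatment", "disease_stage", "smoke", "pack_years", "season",
                "study_length", "dropout_time", "dropout_flag")
  if (format == "interval") {
    need <- c("subject_id", "onset", "resolution")
    miss <- setdiff(need, names(raw))
    if (length(miss))
      stop("missing column(s) in ", path, ": ",
           paste(miss, collapse = ", "), call. = FALSE)
    raw$subject_id <- as.character(raw$subject_id)
    soj <- do.call(rbind, lapply(split(raw, raw$subject_id), function(d) {
      ival <- d[!is.na(d$onset), c("onset", "resolution"), drop = FALSE]
      fu <- d$study_length[1]
      if (!is.na(d$dropout_time[1])) fu <- min(fu, d$dropout_time[1])
      episodes_to_sojourns(ival, fu, d$subject_id[1])
    }))
    sub <- raw[!duplicated(raw$subject_id), c("subject_id", cov_cols)]
  } else {
    need <- c("subject_id", "episode", "state", "duration", "event", cov_cols)
    miss <- setdiff(need, names(raw))
    if (length(miss))
      stop("missing column(s) in ", path, ": ",
           paste(miss, collapse = ", "), call. = FALSE)
    soj <- raw[, c("subject_id", "episode", "state", "duration", "event")]
    sub <- raw[!duplicated(raw$subject_id), c("subject_id", cov_cols)]
  }
  rownames(sub) <- rownames(soj) <- NULL
  trial_dataset(sub, soj, dropout_window = dropout_window)
}

#' @rdname read_trial
#' @param x A \code{trial_dataset}.
#' @export
write_trial <- function(x, path) {
  stopifnot(inherits(x, "trial_dataset"))
  flat <- merge(x$sojourns, x$subjects, by = "subject_id", sort = FALSE)
  flat <- flat[order(flat$subject_id, flat$episode), ]
  utils::write.csv(flat, path, row.names = FALSE, na = "")
  invisible(path)
}
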