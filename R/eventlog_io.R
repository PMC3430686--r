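# Event-log data model, validation and CSV I/O.
#
# Two plain-text files describe a study:
#   events CSV:   pair_id,session,time_s,from_state,to_state   (one row/event)
#   sessions CSV: pair_id,session,duration_s,initial_state,focal_boldness,
#                 partner_boldness,focal_satiated,category     (one row/session)
# Times are seconds from session start on the half-open interval
# [0, duration); the final sojourn is right-censored at the session end.

SESSIONS <- c("control", "satiated")
CATEGORIES <- c("SM", "SL", "BM", "BL")

#' Construct a pair-session trajectory
#'
#' A `pair_trajectory` is the ordered, validated list of state-transition
#' events observed for one pair during one session, together with the
#' session duration and the state occupied at time 0.  It is the unit of
#' all downstream inference.
#'
#' @param pair_id Character identifier of the pair.
#' @param session Session label, `"control"` or `"satiated"`.
#' @param duration Session duration in seconds (> 0).
#' @param initial_state State occupied at time 0 (integer 1..4).
#' @param events Data frame with columns `time` (seconds, strictly
#'   increasing, in `(0, duration)`), `from` and `to` (states).  May have
#'   zero rows for a session in which the pair never changed state.
#' @param validate If `TRUE` (default) the invariants are enforced and the
#'   constructor stops on the first violation.
#' @return An object of class `pair_trajectory`.
#' @seealso [validate_trajectory()], [read_event_log()]
#' @export
pair_trajectory <- function(pair_id, session, duration, initial_state,
                            events = empty_events(), validate = TRUE) {
  events <- as.data.frame(events)
  if (nrow(events) == 0L) events <- empty_events()
  stopifnot(all(c("time", "from", "to") %in% names(events)))
  events <- data.frame(time = as.numeric(events$time),
                       from = as.integer(events$from),
                       to = as.integer(events$to))
  obj <- structure(
    list(pair_id = as.character(pair_id),
         session = as.character(session),
         duration = as.numeric(duration),
         initial_state = as.integer(initial_state),
         events = events),
    class = "pair_trajectory")
  if (validate) {
    v <- validate_trajectory(obj)
    if (length(v)) {
      stop(sprintf("invalid trajectory %s/%s: %s",
                   pair_id, session, paste(v, collapse = "; ")),
           call. = FALSE)
    }
  }
  obj
}

empty_events <- function() {
  data.frame(time = numeric(0), from = integer(0), to = integer(0))
}

#' @export
print.pair_trajectory <- function(x, ...) {
  cat(sprintf("<pair_trajectory %s/%s: %d events over %.0f s, start state %d>\n",
              x$pair_id, x$session, nrow(x$events), x$duration,
              x$initial_state))
  invisible(x)
}

#' Validate a trajectory, reporting violations instead of throwing
#'
#' Checks every structural invariant of a [pair_trajectory()]: positive
#' duration, valid states, strictly increasing event times inside
#' `(0, duration)`, permitted edges only (one fish moves per event), and
#' chain consistency (each event departs from the state the previous event
#' produced).
#'
#' @param t A `pair_trajectory` (possibly built with `validate = FALSE`).
#' @return Character vector of violation descriptions, empty if the
#'   trajectory is valid.  Each violation names the invariant and the
#'   offending event index.
#' @export
validate_trajectory <- function(t) {
  out <- character(0)
  if (!is.finite(t$duration) || t$duration <= 0) {
    out <- c(out, "duration must be a positive finite number")
  }
  if (!t$initial_state %in% STATES) {
    out <- c(out, "initial_state must be in 1..4")
  }
  ev <- t$events
  n <- nrow(ev)
  if (n == 0L) return(out)
  bad_state <- which(!(ev$from %in% STATES) | !(ev$to %in% STATES))
  for (k in bad_state) {
    out <- c(out, sprintf("state out of range at index %d", k))
  }
  if (length(bad_state)) return(out)

  if (any(ev$time <= 0) || any(ev$time >= t$duration)) {
    k <- which(ev$time <= 0 | ev$time >= t$duration)[1]
    out <- c(out, sprintf("event time outside (0, duration) at index %d", k))
  }
  if (n > 1L && any(diff(ev$time) <= 0)) {
    k <- which(diff(ev$time) <= 0)[1] + 1L
    out <- c(out, sprintf("non-increasing time at index %d", k))
  }
  self <- which(ev$from == ev$to)
  for (k in self) out <- c(out, sprintf("self-transition at index %d", k))
  forb <- which(!is_permitted_edge(ev$from, ev$to) & ev$from != ev$to)
  for (k in forb) {
    out <- c(out, sprintf(
      "forbidden edge %d->%d (both fish moving) at index %d",
      ev$from[k], ev$to[k], k))
  }
  prev <- c(t$initial_state, ev$to[-n])
  inc <- which(ev$from != prev)
  for (k in inc) {
    out <- c(out, sprintf("chain inconsistency at index %d (from %d, expected %d)",
                          k, ev$from[k], prev[k]))
  }
  out
}

#' Read session metadata CSV
#'
#' @param path Path to a sessions CSV with header
#'   `pair_id,session,duration_s,initial_state,focal_boldness,partner_boldness,focal_satiated,category`.
#' @return Data frame with those columns, types coerced and checked.
#' @export
read_sessions <- function(path) {
  meta <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pair_id", "session", "duration_s", "initial_state",
            "focal_boldness", "partner_boldness", "focal_satiated", "category")
  missing <- setdiff(need, names(meta))
  if (length(missing)) {
    stop(sprintf("sessions file %s is missing columns: %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  meta$pair_id <- as.character(meta$pair_id)
  meta$session <- as.character(meta$session)
  if (any(duplicated(meta[c("pair_id", "session")]))) {
    stop("duplicate (pair_id, session) rows in sessions file", call. = FALSE)
  }
  bad <- which(!meta$session %in% SESSIONS)
  if (length(bad)) {
    stop(sprintf("row %d: unknown session label '%s'", bad[1] + 1L,
                 meta$session[bad[1]]), call. = FALSE)
  }
  if (any(meta$duration_s <= 0)) stop("non-positive duration_s", call. = FALSE)
  if (any(!meta$initial_state %in% STATES)) {
    stop("initial_state outside 1..4 in sessions file", call. = FALSE)
  }
  b <- c(meta$focal_boldness, meta$partner_boldness)
  if (any(!is.na(b) & (b < 0 | b > 1))) {
    stop("boldness values must lie in [0, 1]", call. = FALSE)
  }
  if (any(!meta$focal_satiated %in% c(0L, 1L))) {
    stop("focal_satiated must be 0 or 1", call. = FALSE)
  }
  if (any(meta$focal_satiated == 1L & meta$session != "satiated")) {
    stop("focal_satiated = 1 is only allowed in the satiated session",
         call. = FALSE)
  }
  if (any(!meta$category %in% c(CATEGORIES, "none"))) {
    stop("category must be one of SM, SL, BM, BL, none", call. = FALSE)
  }
  meta
}

#' Read a pair-session event log
#'
#' Parses the events CSV, groups rows by `(pair_id, session)`, attaches
#' duration and initial state from the sessions CSV, and validates every
#' trajectory.  A session listed in the metadata with no event rows yields
#' a valid zero-event trajectory (the pair stayed in its initial state).
#'
#' @param events_path Path to the events CSV (header
#'   `pair_id,session,time_s,from_state,to_state`).
#' @param sessions_path Path to the sessions CSV (see [read_sessions()]).
#' @return A named list of [pair_trajectory()] objects (names
#'   `"<pair_id>/<session>"`, in sessions-file order), with the sessions
#'   data frame attached as attribute `"meta"`.
#' @export
read_event_log <- function(events_path, sessions_path) {
  meta <- read_sessions(sessions_path)
  ev <- utils::read.csv(events_path, stringsAsFactors = FALSE)
  need <- c("pair_id", "session", "time_s", "from_state", "to_state")
  missing <- setdiff(need, names(ev))
  if (length(missing)) {
    stop(sprintf("events file %s is missing columns: %s", events_path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  ev$pair_id <- as.character(ev$pair_id)
  ev$.row <- seq_len(nrow(ev)) + 1L  # +1: header line, for error messages
  if (nrow(ev)) {
    if (any(!is.finite(ev$time_s))) {
      stop(sprintf("row %d: malformed time_s", ev$.row[which(!is.finite(ev$time_s))[1]]),
           call. = FALSE)
    }
    bad <- which(!ev$from_state %in% STATES | !ev$to_state %in% STATES)
    if (length(bad)) {
      stop(sprintf("row %d: state outside 1..4", ev$.row[bad[1]]), call. = FALSE)
    }
    forb <- which(!is_permitted_edge(ev$from_state, ev$to_state))
    if (length(forb)) {
      k <- forb[1]
      stop(sprintf("row %d: forbidden transition %d->%d", ev$.row[k],
                   ev$from_state[k], ev$to_state[k]), call. = FALSE)
    }
    key <- paste(ev$pair_id, ev$session, sep = "/")
    mkey <- paste(meta$pair_id, meta$session, sep = "/")
    orphan <- which(!key %in% mkey)
    if (length(orphan)) {
      stop(sprintf("row %d: (%s) has no sessions-file entry", ev$.row[orphan[1]],
                   key[orphan[1]]), call. = FALSE)
    }
  }

  out <- vector("list", nrow(meta))
  names(out) <- paste(meta$pair_id, meta$session, sep = "/")
  for (i in seq_len(nrow(meta))) {
    rows <- ev[ev$pair_id == meta$pair_id[i] & ev$session == meta$session[i], ,
               drop = FALSE]
    rows <- rows[order(rows$time_s), , drop = FALSE]
    tr <- pair_trajectory(meta$pair_id[i], meta$session[i],
                          duration = meta$duration_s[i],
                          initial_state = meta$initial_state[i],
                          events = data.frame(time = rows$time_s,
                                              from = rows$from_state,
                                              to = rows$to_state),
                          validate = FALSE)
    v <- validate_trajectory(tr)
    if (length(v)) {
      # map the first violation back to a file row where possible
      idx <- regmatches(v[1], regexpr("[0-9]+$", v[1]))
      rowno <- if (length(idx) && nrow(rows)) rows$.row[as.integer(idx)] else NA
      stop(sprintf("invalid trajectory %s/%s%s: %s",
                   meta$pair_id[i], meta$session[i],
                   if (!is.na(rowno)) sprintf(" (events row %d)", rowno) else "",
                   paste(v, collapse = "; ")), call. = FALSE)
    }
    out[[i]] <- tr
  }
  attr(out, "meta") <- meta
  out
}

#' Write trajectories (and optional metadata) back to CSV
#'
#' Times are written with six decimal places, so a write/read round trip
#' reproduces states exactly and times to 1e-6 s.
#'
#' @param trajectories List of [pair_trajectory()] objects.
#' @param events_path Output path for the events CSV.
#' @param sessions_path Output path for the sessions CSV.
#' @param meta Optional sessions data frame (as from [read_sessions()]);
#'   if omitted, a minimal one is reconstructed from the trajectories with
#'   `NA` boldness, `focal_satiated` inferred from the session label and
#'   category `"none"`.
#' @return Invisibly, the two paths.
#' @export
write_event_log <- function(trajectories, events_path, sessions_path,
                            meta = NULL) {
  if (is.null(meta)) {
    meta <- do.call(rbind, lapply(trajectories, function(t) {
      data.frame(pair_id = t$pair_id, session = t$session,
                 duration_s = t$duration, initial_state = t$initial_state,
                 focal_boldness = NA_real_, partner_boldness = NA_real_,
                 focal_satiated = as.integer(t$session == "satiated"),
                 category = "none")
    }))
  }
  ev <- do.call(rbind, lapply(trajectories, function(t) {
    if (nrow(t$events) == 0L) return(NULL)
    data.frame(pair_id = t$pair_id, session = t$session,
               time_s = sprintf("%.6f", t$events$time),
               from_state = t$events$from, to_state = t$events$to)
  }))
  if (is.null(ev)) {
    ev <- data.frame(pair_id = character(0), session = character(0),
                     time_s = character(0), from_state = integer(0),
                     to_state = integer(0))
  }
  utils::write.csv(ev, events_path, row.names = FALSE, quote = FALSE)
  meta_out <- meta
  meta_out$duration_s <- sprintf("%.6f", meta$duration_s)
  for (col in c("focal_boldness", "partner_boldness")) {
    meta_out[[col]] <- ifelse(is.na(meta[[col]]), "",
                              sprintf("%.6f", meta[[col]]))
  }
  utils::write.csv(meta_out, sessions_path, row.names = FALSE, quote = FALSE)
  invisible(c(events = events_path, sessions = sessions_path))
}
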