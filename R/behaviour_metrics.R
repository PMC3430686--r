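# Behavioural summaries derived from trajectories: boldness scores,
# sufficient statistics of the chain, the trip taxonomy (attempted
# initiations / joint trips / follows) and per-fish session summaries.

#' Boldness score: proportion of time out of cover
#'
#' Temperament is scored as the fraction of an observation period an
#' isolated fish spends out of cover.  Intervals must be disjoint, ordered
#' and contained in `[0, duration)`; an interval still open at the end of
#' the observation is given as `(start, duration)`.
#'
#' @param out_intervals List (or 2-column matrix) of `(start, end)` times in
#'   seconds during which the fish was out of cover.
#' @param duration Observation duration in seconds (> 0).
#' @return A single number in `[0, 1]`.
#' @export
boldness_score <- function(out_intervals, duration) {
  stopifnot(is.finite(duration), duration > 0)
  if (length(out_intervals) == 0L) return(0)
  m <- if (is.matrix(out_intervals)) out_intervals else
    do.call(rbind, lapply(out_intervals, function(x) x[1:2]))
  if (any(m[, 2] <= m[, 1])) stop("empty or reversed interval", call. = FALSE)
  if (any(m[, 1] < 0) || any(m[, 2] > duration)) {
    stop("interval outside [0, duration]", call. = FALSE)
  }
  m <- m[order(m[, 1]), , drop = FALSE]
  if (nrow(m) > 1L && any(m[-1, 1] < m[-nrow(m), 2])) {
    stop("overlapping intervals", call. = FALSE)
  }
  sum(m[, 2] - m[, 1]) / duration
}

#' Merge per-fish leave/return streams into a joint trajectory
#'
#' Each fish contributes an alternating stream of event times: leave cover,
#' return to cover, leave, ...  Both fish start under cover, so the merged
#' trajectory starts in state 1 and every merged event moves exactly one
#' fish.  Simultaneous events across fish are rejected: the chain assigns
#' them probability zero, and silently shifting them would mask logging
#' faults (pass `break_ties = "shift"` to move the second event +0.01 s).
#'
#' @param focal_times,partner_times Numeric vectors of alternating
#'   leave/return times for each fish, strictly increasing, in
#'   `(0, duration)`.
#' @param duration Session duration in seconds.
#' @param pair_id,session Labels for the resulting trajectory.
#' @param break_ties `"error"` (default) or `"shift"`.
#' @return A [pair_trajectory()] starting in state 1.
#' @export
derive_states <- function(focal_times, partner_times, duration,
                          pair_id = "pair", session = "control",
                          break_ties = c("error", "shift")) {
  break_ties <- match.arg(break_ties)
  for (ts in list(focal_times, partner_times)) {
    if (length(ts) > 1L && any(diff(ts) <= 0)) {
      stop("per-fish event times must be strictly increasing", call. = FALSE)
    }
  }
  times <- c(focal_times, partner_times)
  who <- c(rep("focal", length(focal_times)), rep("partner", length(partner_times)))
  o <- order(times)
  times <- times[o]; who <- who[o]
  dup <- which(diff(times) == 0)
  if (length(dup)) {
    if (break_ties == "error") {
      stop(sprintf("simultaneous events across fish at t = %g", times[dup[1]]),
           call. = FALSE)
    }
    while (length(dup <- which(diff(times) <= 0))) {
      times[dup + 1L] <- times[dup] + 0.01
    }
  }
  if (length(times) == 0L) {
    return(pair_trajectory(pair_id, session, duration, initial_state = 1L))
  }
  state <- 1L
  ev <- data.frame(time = times, from = NA_integer_, to = NA_integer_)
  f_out <- FALSE; p_out <- FALSE
  for (k in seq_along(times)) {
    if (who[k] == "focal") f_out <- !f_out else p_out <- !p_out
    new_state <- 1L + 1L * f_out + 2L * p_out
    ev$from[k] <- state; ev$to[k] <- new_state
    state <- new_state
  }
  pair_trajectory(pair_id, session, duration, initial_state = 1L, events = ev)
}

#' Sufficient statistics of a trajectory
#'
#' For the fully observed chain the likelihood depends on the data only
#' through the transition counts and state sojourn totals.  The final
#' sojourn, right-censored at the session end, is included in the sojourn
#' time of the last state, so the sojourns always sum exactly to the
#' session duration.
#'
#' @param t A [pair_trajectory()].
#' @return List with `counts` (named integer vector over [EDGES]) and
#'   `sojourn` (named numeric vector over states `"1".."4"`, seconds),
#'   of class `sufficient_stats`.
#' @export
sufficient_statistics <- function(t) {
  ev <- t$events
  states <- c(t$initial_state, ev$to)
  times <- c(0, ev$time, t$duration)
  counts <- table(factor(edge_key(ev$from, ev$to), levels = EDGES))
  counts <- stats::setNames(as.integer(counts), EDGES)
  lens <- diff(times)
  sojourn <- vapply(split(lens, factor(states, levels = STATES)), sum,
                    numeric(1))
  names(sojourn) <- as.character(STATES)
  structure(list(counts = counts, sojourn = sojourn), class = "sufficient_stats")
}

#' Classify trips into attempted initiations, joint-trip initiations and follows
#'
#' Walks the event sequence applying the taxonomy:
#' * an event `1->2` (`1->3`) opens an attempted initiation by the focal
#'   (partner) fish — it left cover while the other was still under cover;
#' * if the next event from the resulting state is the other fish joining
#'   (`2->4`, resp. `3->4`), the attempt becomes a `joint_trip_initiation`
#'   and the joining fish is credited a `follow` at the join time;
#' * if instead the initiator returns to cover, the attempt is an
#'   `attempted_initiation_failed`;
#' * an attempt still unresolved at session end is recorded as failed with
#'   `censored = TRUE`.
#'
#' Follows pair one-to-one with joint initiations: after a joint trip has
#' formed, a partner that returns to cover and re-joins the still-out
#' initiator (`...2->4->2->4...`) is rejoining the same joint trip, not
#' recording a new follow (each leave still counts in `n_trips`).
#'
#' A trip record's `end_time` is the time its actor next returned to cover
#' (`NA` with `censored = TRUE` if still out at session end).
#'
#' @param t A [pair_trajectory()].
#' @return Data frame with columns `actor` (`"focal"`/`"partner"`), `kind`,
#'   `start_time`, `end_time`, `censored`; zero rows if no trips opened
#'   from state 1.
#' @export
classify_trips <- function(t) {
  ev <- t$events
  n <- nrow(ev)
  rec <- list()
  add <- function(actor, kind, start, end, censored = FALSE) {
    rec[[length(rec) + 1L]] <<- data.frame(
      actor = actor, kind = kind, start_time = start,
      end_time = end, censored = censored)
  }
  # return time of `actor` after event index k (NA if never returns)
  return_after <- function(actor, k) {
    if (k > n) return(NA_real_)
    ret_edges <- if (actor == "focal") c("21", "43") else c("31", "42")
    for (j in k:n) {
      if (edge_key(ev$from[j], ev$to[j]) %in% ret_edges) return(ev$time[j])
    }
    NA_real_
  }
  k <- 1L
  while (k <= n) {
    e <- edge_key(ev$from[k], ev$to[k])
    if (e %in% c("12", "13")) {
      actor <- if (e == "12") "focal" else "partner"
      other <- if (e == "12") "partner" else "focal"
      join_edge <- if (e == "12") "24" else "34"
      t0 <- ev$time[k]
      if (k + 1L <= n) {
        nxt <- edge_key(ev$from[k + 1L], ev$to[k + 1L])
        if (nxt == join_edge) {
          add(actor, "joint_trip_initiation", t0, return_after(actor, k + 1L),
              censored = is.na(return_after(actor, k + 1L)))
          add(other, "follow", ev$time[k + 1L], return_after(other, k + 2L),
              censored = is.na(return_after(other, k + 2L)))
        } else {
          # initiator returned to cover: failed attempt
          add(actor, "attempted_initiation_failed", t0, ev$time[k + 1L])
        }
      } else {
        add(actor, "attempted_initiation_failed", t0, NA_real_, censored = TRUE)
      }
    }
    k <- k + 1L
  }
  if (!length(rec)) {
    return(data.frame(actor = character(0), kind = character(0),
                      start_time = numeric(0), end_time = numeric(0),
                      censored = logical(0)))
  }
  out <- do.call(rbind, rec)
  out[order(out$start_time), , drop = FALSE]
}

#' Per-fish behavioural summary of one session
#'
#' @param t A [pair_trajectory()].
#' @return Data frame with one row per fish (`focal`, `partner`) and
#'   columns `prop_time_out`, `n_trips`, `n_attempted_initiations`,
#'   `n_joint_initiations`, `n_follows`, `n_failed_initiations`.
#'   `n_trips` counts every exit from cover;
#'   `prop_time_out` is `(T2 + T4)/duration` for the focal fish and
#'   `(T3 + T4)/duration` for the partner.
#' @export
session_summary <- function(t) {
  ss <- sufficient_statistics(t)
  trips <- classify_trips(t)
  one <- function(fish) {
    leave <- if (fish == "focal") c("12", "34") else c("13", "24")
    out_states <- if (fish == "focal") c("2", "4") else c("3", "4")
    mine <- trips[trips$actor == fish, , drop = FALSE]
    n_joint <- sum(mine$kind == "joint_trip_initiation")
    n_fail <- sum(mine$kind == "attempted_initiation_failed")
    data.frame(
      fish = fish,
      prop_time_out = sum(ss$sojourn[out_states]) / t$duration,
      n_trips = sum(ss$counts[leave]),
      n_attempted_initiations = n_joint + n_fail,
      n_joint_initiations = n_joint,
      n_follows = sum(mine$kind == "follow"),
      n_failed_initiations = n_fail)
  }
  rbind(one("focal"), one("partner"))
}

#' Tidy summary table for a set of trajectories
#'
#' One row per (pair, session, fish), joining behavioural summaries to
#' session metadata; the layout written by the `summarize` pipeline stage.
#'
#' @param trajectories Named list as returned by [read_event_log()].
#' @param meta Sessions data frame; defaults to `attr(trajectories, "meta")`.
#' @return Data frame with columns `pair_id`, `session`, `category`,
#'   `focal_boldness`, `partner_boldness`, `fish`, `boldness`, plus the
#'   [session_summary()] columns.
#' @export
summaries_table <- function(trajectories, meta = attr(trajectories, "meta")) {
  if (is.null(meta)) stop("sessions metadata required", call. = FALSE)
  rows <- lapply(trajectories, function(t) {
    m <- meta[meta$pair_id == t$pair_id & meta$session == t$session, , drop = FALSE]
    s <- session_summary(t)
    s$pair_id <- t$pair_id
    s$session <- t$session
    s$category <- m$category[1]
    s$focal_boldness <- m$focal_boldness[1]
    s$partner_boldness <- m$partner_boldness[1]
    s$boldness <- ifelse(s$fish == "focal", m$focal_boldness[1],
                         m$partner_boldness[1])
    s
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  front <- c("pair_id", "session", "category", "fish", "boldness",
             "focal_boldness", "partner_boldness")
  out[c(front, setdiff(names(out), front))]
}

#' Categorize a pair by the ratio of focal to partner boldness
#'
#' Pairing categories are defined by `r = focal / partner`:
#' `SM` (focal moderately shyer) for `0.70 <= r <= 0.85`, `SL` (much
#' shyer) for `r < 0.50`, `BM` (moderately bolder) for
#' `1.15 <= r <= 1.40`, `BL` (much bolder) for `r > 2.00`; anything else
#' is `"none"`.  Band endpoints are inclusive as printed; the 50% and
#' 200% cuts are strict.
#'
#' @param focal_boldness,partner_boldness Boldness scores in `[0, 1]`;
#'   `partner_boldness` must be positive.
#' @return One of `"SM"`, `"SL"`, `"BM"`, `"BL"`, `"none"`.
#' @export
categorize_pair <- function(focal_boldness, partner_boldness) {
  if (partner_boldness <= 0) stop("partner boldness must be > 0", call. = FALSE)
  r <- focal_boldness / partner_boldness
  if (r < 0.50) "SL"
  else if (r >= 0.70 && r <= 0.85) "SM"
  else if (r >= 1.15 && r <= 1.40) "BM"
  else if (r > 2.00) "BL"
  else "none"
}
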