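# Shared fixtures and independent oracles used across test files.

# Build a trajectory from an initial state and a vector of event times plus
# destination states (chain-consistent by construction of the caller).
make_traj <- function(initial, times, to, duration,
                      pair_id = "p1", session = "control") {
  from <- c(initial, to[-length(to)])
  if (length(times) == 0L) from <- integer(0)
  pair_trajectory(pair_id, session, duration, initial,
                  events = data.frame(time = times, from = from, to = to))
}

# A moderately busy reference intensity model used in several tests.
ref_model <- function() {
  intensity_model(c("12" = 0.005, "21" = 0.011, "13" = 0.003, "31" = 0.012,
                    "24" = 0.004, "42" = 0.010, "34" = 0.006, "43" = 0.009))
}

# ---- independent trip-classification oracle ---------------------------------
# Walks the verbal rules over per-fish bout intervals (a different code path
# from classify_trips, which scans the event sequence):
#   * a bout of fish F that starts with F leaving from state 1 (the other
#     fish under cover) is an attempted initiation;
#   * if the other fish's first exit from cover falls inside that bout, the
#     attempt is a joint-trip initiation and that exit is the other's follow;
#   * otherwise the attempt failed (censored if the bout is still open at
#     session end).
oracle_trips <- function(t) {
  ev <- t$events
  states <- c(t$initial_state, ev$to)
  times <- c(0, ev$time)
  bouts <- function(fish) {
    out_fun <- if (fish == "focal") focal_is_out else partner_is_out
    out <- out_fun(states)
    res <- list()
    k <- 1L
    while (k <= length(states)) {
      if (out[k] && (k == 1L || !out[k - 1L])) {
        j <- k
        while (j <= length(states) && out[j]) j <- j + 1L
        res[[length(res) + 1L]] <- list(
          start = times[k],
          end = if (j <= length(states)) times[j] else NA_real_,
          from_state = if (k > 1L) states[k - 1L] else NA_integer_,
          starts_at_zero = k == 1L)
        k <- j
      } else k <- k + 1L
    }
    res
  }
  rec <- list()
  for (fish in c("focal", "partner")) {
    other <- setdiff(c("focal", "partner"), fish)
    other_bouts <- bouts(other)
    for (b in bouts(fish)) {
      if (b$starts_at_zero) next            # no leave event opened this bout
      if (!identical(b$from_state, 1L)) next # other fish was already out
      bout_end <- if (is.na(b$end)) t$duration else b$end
      joins <- Filter(function(ob) !ob$starts_at_zero &&
                        ob$start > b$start && ob$start < bout_end,
                      other_bouts)
      if (length(joins)) {
        jb <- joins[[1]]
        rec[[length(rec) + 1L]] <- data.frame(
          actor = fish, kind = "joint_trip_initiation",
          start_time = b$start, end_time = b$end, censored = is.na(b$end))
        rec[[length(rec) + 1L]] <- data.frame(
          actor = other, kind = "follow",
          start_time = jb$start, end_time = jb$end, censored = is.na(jb$end))
      } else {
        rec[[length(rec) + 1L]] <- data.frame(
          actor = fish, kind = "attempted_initiation_failed",
          start_time = b$start, end_time = b$end, censored = is.na(b$end))
      }
    }
  }
  if (!length(rec)) {
    return(data.frame(actor = character(0), kind = character(0),
                      start_time = numeric(0), end_time = numeric(0),
                      censored = logical(0)))
  }
  out <- do.call(rbind, rec)
  out <- out[order(out$start_time, out$actor), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exhaustively enumerate every chain-consistent state sequence of up to
# `max_events` events over the permitted edges, from every initial state.
# Event k occurs at time k; duration places all events strictly inside.
enumerate_trajectories <- function(max_events = 6L) {
  succ <- lapply(1:4, function(s) {
    e <- EDGES[vapply(EDGES, function(x) edge_from(x) == s, logical(1))]
    vapply(e, edge_to, integer(1), USE.NAMES = FALSE)
  })
  out <- list()
  recurse <- function(path) {
    k <- length(path) - 1L
    out[[length(out) + 1L]] <<- path
    if (k >= max_events) return()
    for (nxt in succ[[path[length(path)]]]) recurse(c(path, nxt))
  }
  for (s in 1:4) recurse(s)
  lapply(out, function(path) {
    k <- length(path) - 1L
    make_traj(path[1], times = seq_len(k), to = path[-1],
              duration = k + 1)
  })
}

# random trajectory generator for property tests (uniform over the stated
# rate box, seeded by the caller)
random_trajectory <- function(seed, duration = 2000) {
  set.seed(seed)
  q <- stats::setNames(stats::runif(8, 0.0005, 0.02), EDGES)
  m <- intensity_model(q)
  simulate_trajectory(m, list(), duration = duration,
                      initial_state = sample(1:4, 1), seed = seed + 13L)
}
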