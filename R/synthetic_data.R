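# Ground-truth-known synthetic studies: a boldness population, pairs
# assembled into the four temperament-ratio categories, and exact
# (Gillespie) simulation of control and satiated sessions from the same
# log-linear CTMC the inference assumes, so that fitting the generated
# data is a well-specified parameter-recovery problem by construction.

#' Default study configuration
#'
#' Returns the configuration of the emulated study, every field
#' overridable.  Defaults encode the stated world:
#' * category quotas SM 14, SL 11, BM 25, BL 10 (60 pairs);
#' * two sessions of 7200 s per pair (control, then focal satiated);
#' * boldness ~ Beta(1.25, 2.782): mean 0.31, central 95% range
#'   approximately 0.02-0.77;
#' * rate link `log q_leave = a_leave + b_leave * boldness`,
#'   `log q_return = a_return - b_return * boldness`, with defaults chosen
#'   so a boldness-0.31 fish alone spends ~31% of its time out of cover in
#'   ~25 trips per 2 h (`q_leave = 0.005`/s, `q_return = 0.011`/s at 0.31);
#' * satiation multiplies the satiated (focal) fish's cover-leaving
#'   intensities by `exp(-1.5)` and its return intensities by `exp(0.5)`;
#'   partner edges unaffected;
#' * `responsiveness` multiplies the follow edges 2->4 and 3->4 (default 1:
#'   off, which keeps the generative model identical to the fitted one).
#'
#' @param ... Named overrides for any top-level field.
#' @return A list of class `study_config`.
#' @export
study_config <- function(...) {
  cfg <- list(
    n_pairs_per_category = c(SM = 14L, SL = 11L, BM = 25L, BL = 10L),
    session_duration = 7200,
    boldness_distribution = c(shape1 = 1.25, shape2 = 1.25 * 0.69 / 0.31),
    rate_link = c(a_leave = log(0.005) - 3 * 0.31, b_leave = 3,
                  a_return = log(0.011) + 2 * 0.31, b_return = 2),
    satiation_effects = c("12" = -1.5, "34" = -1.5, "21" = 0.5, "43" = 0.5,
                          "13" = 0, "31" = 0, "24" = 0, "42" = 0),
    responsiveness = 1,
    population_size = 2000L,
    seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  for (nm in names(dots)) {
    v <- dots[[nm]]
    if (nm %in% c("n_pairs_per_category", "boldness_distribution",
                  "rate_link", "satiation_effects")) {
      tmpl <- cfg[[nm]]
      if (is.null(names(v))) {
        stopifnot(length(v) == length(tmpl))
        names(v) <- names(tmpl)
      }
      tmpl[names(v)] <- unlist(v)
      cfg[[nm]] <- tmpl
    } else {
      cfg[[nm]] <- v
    }
  }
  if (cfg$session_duration <= 0) stop("session_duration must be > 0", call. = FALSE)
  if (any(cfg$boldness_distribution <= 0)) {
    stop("boldness distribution shapes must be > 0", call. = FALSE)
  }
  if (cfg$responsiveness <= 0) stop("responsiveness must be > 0", call. = FALSE)
  structure(cfg, class = "study_config")
}

#' Load a study configuration from a JSON file
#'
#' Every field has a default ([study_config()]); the file may set any
#' subset.
#'
#' @param path Path to a JSON config file.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(study_config, raw)
}

# Deterministic child seed from a root seed and a stream counter
# (independent of generation order).  Two rounds of Lehmer-style mixing so
# that nested derivations (replicate root -> trajectory seed) do not fall
# on a common arithmetic progression and reuse RNG streams across
# replicates.  All arithmetic stays below 2^53, exact in doubles.
child_seed <- function(root_seed, counter) {
  m <- 2147483647
  s <- ((as.numeric(root_seed) %% m) * 48271) %% m
  s <- (s + as.numeric(counter) * 69621) %% m
  s <- (s * 16807) %% m
  as.integer(if (s == 0) 1 else s)
}

#' Draw a boldness population
#'
#' @param n Number of fish.
#' @param config A [study_config()] (supplies the Beta shapes).
#' @param seed Seed (default: the config's).
#' @return Numeric vector of `n` boldness scores in (0, 1).
#' @export
generate_boldness_population <- function(n, config = study_config(),
                                         seed = config$seed) {
  stopifnot(n >= 1L)
  set.seed(seed)
  sh <- config$boldness_distribution
  b <- stats::rbeta(n, sh[["shape1"]], sh[["shape2"]])
  # open interval: the link functions require boldness in (0, 1]
  pmin(pmax(b, 1e-6), 1 - 1e-6)
}

#' Assemble pairs into the four temperament-ratio categories
#'
#' Greedy deterministic matching: fish are scanned in order and the first
#' unused (focal, partner) assignment whose boldness ratio falls in a
#' category band fills that category's quota.
#'
#' @param population Numeric vector of boldness scores.
#' @param config A [study_config()] (supplies the quotas).
#' @return Data frame with columns `pair_id`, `category`, `focal_boldness`,
#'   `partner_boldness`; every row satisfies
#'   `categorize_pair(focal, partner) == category` and quotas are met
#'   exactly.
#' @export
assemble_pairs <- function(population, config = study_config()) {
  quotas <- config$n_pairs_per_category
  used <- logical(length(population))
  rows <- list()
  for (cat in names(quotas)) {
    need <- quotas[[cat]]
    got <- 0L
    i <- 1L
    while (got < need && i <= length(population)) {
      if (!used[i]) {
        j <- i + 1L
        while (got < need && j <= length(population)) {
          if (!used[j]) {
            hit <- NULL
            if (categorize_pair(population[i], population[j]) == cat) {
              hit <- c(i, j)
            } else if (categorize_pair(population[j], population[i]) == cat) {
              hit <- c(j, i)
            }
            if (!is.null(hit)) {
              used[hit] <- TRUE
              got <- got + 1L
              rows[[length(rows) + 1L]] <- data.frame(
                category = cat,
                focal_boldness = population[hit[1]],
                partner_boldness = population[hit[2]])
              break  # fish i consumed; move on
            }
          }
          j <- j + 1L
        }
      }
      i <- i + 1L
    }
    if (got < need) {
      stop(sprintf("cannot fill quota for category %s: %d of %d pairs found",
                   cat, got, need), call. = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$pair_id <- sprintf("%s%02d", out$category,
                         stats::ave(seq_len(nrow(out)), out$category,
                                    FUN = seq_along))
  out[c("pair_id", "category", "focal_boldness", "partner_boldness")]
}

#' Build the true intensity model for one pair
#'
#' Each fish's cover-leaving rate rises log-linearly with its own boldness
#' and its return rate falls log-linearly, independent of the joint state;
#' the focal fish owns edges 1->2, 3->4 (leave) and 2->1, 4->3 (return),
#' the partner edges 1->3, 2->4 and 3->1, 4->2.  The `responsiveness`
#' multiplier (if not 1) scales the two follow edges 2->4 and 3->4.
#' Satiation effects from the config are attached as the `satiated`
#' covariate of the model.
#'
#' @param focal_boldness,partner_boldness Boldness scores in (0, 1].
#' @param config A [study_config()].
#' @return An [intensity_model()] with a `satiated` effect vector.
#' @export
build_pair_model <- function(focal_boldness, partner_boldness,
                             config = study_config()) {
  stopifnot(focal_boldness > 0, focal_boldness <= 1,
            partner_boldness > 0, partner_boldness <= 1)
  rl <- config$rate_link
  q_leave <- function(b) exp(rl[["a_leave"]] + rl[["b_leave"]] * b)
  q_return <- function(b) exp(rl[["a_return"]] - rl[["b_return"]] * b)
  base <- c("12" = q_leave(focal_boldness),
            "34" = q_leave(focal_boldness) * config$responsiveness,
            "21" = q_return(focal_boldness),
            "43" = q_return(focal_boldness),
            "13" = q_leave(partner_boldness),
            "24" = q_leave(partner_boldness) * config$responsiveness,
            "31" = q_return(partner_boldness),
            "42" = q_return(partner_boldness))
  if (any(!is.finite(base)) || any(base <= 0)) {
    stop("rate link implies a non-positive or non-finite intensity",
         call. = FALSE)
  }
  intensity_model(base, effects = list(satiated = config$satiation_effects))
}

#' Exact stochastic simulation of one session
#'
#' Gillespie's algorithm for the finite-state chain: from state `i`, the
#' holding time is Exponential with rate `Lambda_i(z) = sum_j q_ij(z)` and
#' the next state is drawn proportional to `q_ij(z)`; the realization is
#' truncated at the session end (the final sojourn is right-censored).
#'
#' @param model An [intensity_model()].
#' @param covariates Named covariate values for the session (e.g.
#'   `list(satiated = 1)`).
#' @param duration Session length in seconds.
#' @param initial_state Starting state (default 1, both fish under cover).
#' @param seed Integer seed; the same seed reproduces the event list
#'   bit for bit.
#' @param pair_id,session Labels for the trajectory.
#' @return A valid [pair_trajectory()].
#' @export
simulate_trajectory <- function(model, covariates = list(satiated = 0),
                                duration, initial_state = 1L, seed,
                                pair_id = "sim", session = "control") {
  q <- edge_intensities(model, covariates)
  # per-state exit rates and destination tables
  dest <- lapply(STATES, function(s) {
    ee <- EDGES[edge_from(EDGES) == s]
    list(to = edge_to(ee), rate = unname(q[ee]), total = sum(q[ee]))
  })
  set.seed(seed)
  state <- as.integer(initial_state)
  t_now <- 0
  cap <- 256L
  times <- numeric(cap); from <- integer(cap); to <- integer(cap)
  n <- 0L
  repeat {
    d <- dest[[state]]
    if (d$total <= 0) break
    t_now <- t_now + stats::rexp(1, d$total)
    if (t_now >= duration) break
    nxt <- d$to[sample.int(length(d$to), 1L, prob = d$rate)]
    n <- n + 1L
    if (n > cap) {
      cap <- cap * 2L
      length(times) <- cap; length(from) <- cap; length(to) <- cap
    }
    times[n] <- t_now; from[n] <- state; to[n] <- nxt
    state <- nxt
  }
  idx <- seq_len(n)
  pair_trajectory(pair_id, session, duration, initial_state,
                  events = data.frame(time = times[idx], from = from[idx],
                                      to = to[idx]))
}

#' Generate a complete synthetic study with ground truth
#'
#' Draws a boldness population, assembles the configured pair quotas, and
#' simulates for every pair one control session (`satiated = 0`) and one
#' satiated session (`satiated = 1`, satiation effects applied to the
#' configured edges).  Per-trajectory seeds are derived from the root seed
#' by a fixed counter scheme, so output is reproducible and independent of
#' generation order.
#'
#' @param config A [study_config()].
#' @param seed Root seed (default: the config's).
#' @return List with `trajectories` (named list with `"meta"` attribute as
#'   from [read_event_log()]), `meta` (sessions data frame) and `truth`
#'   (config echo plus the per-pair table and the true per-edge satiation
#'   effects).
#' @export
generate_study <- function(config = study_config(), seed = config$seed) {
  population <- generate_boldness_population(config$population_size, config,
                                             seed = seed)
  pairs <- assemble_pairs(population, config)
  trajectories <- vector("list", 2L * nrow(pairs))
  meta_rows <- vector("list", 2L * nrow(pairs))
  counter <- 0L
  for (p in seq_len(nrow(pairs))) {
    model <- build_pair_model(pairs$focal_boldness[p],
                              pairs$partner_boldness[p], config)
    for (sess in SESSIONS) {
      counter <- counter + 1L
      sat <- as.integer(sess == "satiated")
      tr <- simulate_trajectory(model, covariates = list(satiated = sat),
                                duration = config$session_duration,
                                initial_state = 1L,
                                seed = child_seed(seed, counter),
                                pair_id = pairs$pair_id[p], session = sess)
      trajectories[[counter]] <- tr
      meta_rows[[counter]] <- data.frame(
        pair_id = pairs$pair_id[p], session = sess,
        duration_s = config$session_duration, initial_state = 1L,
        focal_boldness = pairs$focal_boldness[p],
        partner_boldness = pairs$partner_boldness[p],
        focal_satiated = sat, category = pairs$category[p])
    }
  }
  meta <- do.call(rbind, meta_rows)
  names(trajectories) <- paste(meta$pair_id, meta$session, sep = "/")
  attr(trajectories, "meta") <- meta
  truth <- list(
    config = unclass(config), seed = seed, pairs = pairs,
    satiation_effects = config$satiation_effects,
    rate_link = config$rate_link)
  list(trajectories = trajectories, meta = meta, truth = truth)
}

#' True working-scale parameters implied by a study's ground truth
#'
#' For a per-category fit with `satiated` on all edges and boldness
#' covariates centred at the category sample mean, the generative model is
#' exactly log-linear, so the true centred baseline for e.g. edge 1->2 is
#' `exp(a_leave + b_leave * mean(focal boldness))` and the true boldness
#' coefficients are `b_leave` / `-b_return` on the acting fish's edges and
#' 0 elsewhere.
#'
#' @param truth The `truth` element of [generate_study()] output.
#' @param category Category label.
#' @return List with `logq0` (named over [EDGES], working scale, at the
#'   category mean boldness) and `beta` (the per-edge satiation effects).
#' @export
true_parameters <- function(truth, category) {
  pr <- truth$pairs[truth$pairs$category == category, , drop = FALSE]
  rl <- truth$rate_link
  resp <- truth$config$responsiveness
  mf <- mean(pr$focal_boldness)
  mp <- mean(pr$partner_boldness)
  logq0 <- c(
    "12" = rl[["a_leave"]] + rl[["b_leave"]] * mf,
    "34" = rl[["a_leave"]] + rl[["b_leave"]] * mf + log(resp),
    "21" = rl[["a_return"]] - rl[["b_return"]] * mf,
    "43" = rl[["a_return"]] - rl[["b_return"]] * mf,
    "13" = rl[["a_leave"]] + rl[["b_leave"]] * mp,
    "24" = rl[["a_leave"]] + rl[["b_leave"]] * mp + log(resp),
    "31" = rl[["a_return"]] - rl[["b_return"]] * mp,
    "42" = rl[["a_return"]] - rl[["b_return"]] * mp)
  list(logq0 = logq0[EDGES], beta = truth$satiation_effects[EDGES],
       boldness_coef = list(
         focal_boldness = c("12" = rl[["b_leave"]], "34" = rl[["b_leave"]],
                            "21" = -rl[["b_return"]], "43" = -rl[["b_return"]],
                            "13" = 0, "31" = 0, "24" = 0, "42" = 0)[EDGES],
         partner_boldness = c("13" = rl[["b_leave"]], "24" = rl[["b_leave"]],
                              "31" = -rl[["b_return"]], "42" = -rl[["b_return"]],
                              "12" = 0, "21" = 0, "34" = 0, "43" = 0)[EDGES]))
}
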