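# Simulation-based validation studies: closed-form oracle agreement,
# parameter recovery with CI coverage, null calibration of the test
# battery, qualitative emulation of the leadership pattern, and long-run
# simulator fidelity.  These power the acceptance checks and are exported
# so users can rerun them at any scale.

#' Closed-form oracle check for the covariate-free MLE
#'
#' Simulates covariate-free trajectories and compares the numerical MLE to
#' the crude-rate estimator `N_ij / T_i` edge by edge.
#'
#' @param n_trajectories Number of independent trajectories (each fitted
#'   alone).
#' @param duration Session length per trajectory (seconds).
#' @param seed Root seed.
#' @return List with `max_rel_err` (worst relative disagreement over all
#'   observed edges) and `n_edges_checked`.
#' @export
mle_oracle_check <- function(n_trajectories = 20L, duration = 7200,
                             seed = 1L) {
  set.seed(seed)
  worst <- 0
  n_edges <- 0L
  for (r in seq_len(n_trajectories)) {
    q <- stats::setNames(stats::runif(8, 0.001, 0.02), EDGES)
    t <- simulate_trajectory(intensity_model(q), list(), duration = duration,
                             seed = child_seed(seed, r))
    ss <- sufficient_statistics(t)
    crude <- closed_form_intensities(ss)
    fit <- fit_mle(list(t))
    q_hat <- fitted_intensities(fit)
    obs <- names(which(ss$counts > 0))
    if (!length(obs)) next
    worst <- max(worst, abs(q_hat[obs] / crude[obs] - 1))
    n_edges <- n_edges + length(obs)
  }
  list(max_rel_err = worst, n_edges_checked = n_edges)
}

#' Monte Carlo parameter-recovery study
#'
#' Repeatedly generates a full synthetic study from `config`, fits the
#' per-category covariate model, and measures (a) the absolute error of
#' every identifiable satiation coefficient against its generative truth
#' and (b) empirical coverage of the 95% intervals for the baseline
#' intensities (at the category-mean boldness) and the satiation
#' coefficients.
#'
#' @param n_replicates Number of studies.
#' @param config A [study_config()].
#' @param seed Root seed.
#' @return List: `beta_mae` (median absolute error of satiation
#'   coefficients), `coverage` (data frame per category/edge/type with
#'   `covered`, `checked`, `coverage`), `coverage_range` (min, max over
#'   parameters), `n_replicates`.
#' @export
recovery_study <- function(n_replicates = 200L, config = study_config(),
                           seed = 1L) {
  beta_err <- numeric(0)
  keys <- character(0)
  covered <- integer(0)
  checked <- integer(0)
  bump <- function(key, hit) {
    i <- match(key, keys)
    if (is.na(i)) {
      keys <<- c(keys, key)
      covered <<- c(covered, 0L)
      checked <<- c(checked, 0L)
      i <- length(keys)
    }
    checked[i] <<- checked[i] + 1L
    covered[i] <<- covered[i] + as.integer(hit)
  }
  for (r in seq_len(n_replicates)) {
    st <- generate_study(config, seed = child_seed(seed, r))
    fits <- fit_by_category(st$trajectories)
    for (cat in names(fits)) {
      tp <- true_parameters(st$truth, cat)
      p <- fits[[cat]]$params
      for (e in EDGES) {
        q_row <- p[p$parameter == "logq0" & p$edge == e, ]
        if (nrow(q_row) == 1L && q_row$identifiable && is.finite(q_row$se)) {
          truth <- exp(tp$logq0[[e]])
          bump(paste(cat, e, "q0", sep = ":"),
               q_row$ci_lo <= truth && truth <= q_row$ci_hi)
        }
        b_row <- p[p$parameter == "coef" & !is.na(p$covariate) &
                     p$covariate == "satiated" & p$edge == e, ]
        if (nrow(b_row) == 1L && b_row$identifiable && is.finite(b_row$se)) {
          truth <- tp$beta[[e]]
          beta_err <- c(beta_err, abs(b_row$estimate - truth))
          bump(paste(cat, e, "beta", sep = ":"),
               b_row$ci_lo <= truth && truth <= b_row$ci_hi)
        }
      }
    }
  }
  cov <- data.frame(parameter = keys, covered = covered, checked = checked,
                    coverage = covered / checked)
  list(beta_mae = stats::median(beta_err),
       coverage = cov,
       coverage_range = range(cov$coverage),
       n_replicates = n_replicates)
}

#' Null calibration of the test battery
#'
#' Simulates the generator's null world — symmetric pairs (equal boldness)
#' and no satiation effect — and measures the rejection rate at
#' `alpha = 0.05` of (a) the Wald test of the satiation coefficient on
#' edge 1->2, (b) the Wald contrast of baselines q_12 vs q_13 (equal by
#' symmetry), and (c) the paired t-test of focal trip counts before vs
#' after (sham) satiation.
#'
#' @param n_replicates Number of simulated studies.
#' @param n_pairs Pairs per study.
#' @param duration Session length (seconds).
#' @param boldness Common boldness of every fish.
#' @param seed Root seed.
#' @return List of rejection rates `wald_coefficient`, `intensity_contrast`,
#'   `paired_t`, plus `n_replicates`.
#' @export
calibration_study <- function(n_replicates = 500L, n_pairs = 12L,
                              duration = 7200, boldness = 0.31, seed = 1L) {
  cfg <- study_config(satiation_effects = stats::setNames(rep(0, 8), EDGES))
  model <- build_pair_model(boldness, boldness, cfg)
  rej <- c(wald_coefficient = 0L, intensity_contrast = 0L, paired_t = 0L)
  n_ok <- c(wald_coefficient = 0L, intensity_contrast = 0L, paired_t = 0L)
  counter <- 0L
  for (r in seq_len(n_replicates)) {
    trajs <- vector("list", 2L * n_pairs)
    sat <- integer(2L * n_pairs)
    k <- 0L
    for (pr in seq_len(n_pairs)) {
      for (s in c(0L, 1L)) {
        k <- k + 1L; counter <- counter + 1L
        trajs[[k]] <- simulate_trajectory(
          model, list(satiated = s), duration = duration,
          seed = child_seed(seed, counter),
          pair_id = sprintf("p%02d", pr),
          session = if (s == 1L) "satiated" else "control")
        sat[k] <- s
      }
    }
    fit <- fit_mle(trajs, covariates = data.frame(satiated = sat))
    w <- tryCatch(wald_test_coefficient(fit, "satiated", "12"),
                  error = function(e) NULL)
    if (!is.null(w)) {
      n_ok["wald_coefficient"] <- n_ok["wald_coefficient"] + 1L
      rej["wald_coefficient"] <- rej["wald_coefficient"] +
        as.integer(w$p < 0.05)
    }
    ct <- tryCatch(wald_test_intensity_contrast(fit, "12", "13"),
                   error = function(e) NULL)
    if (!is.null(ct)) {
      n_ok["intensity_contrast"] <- n_ok["intensity_contrast"] + 1L
      rej["intensity_contrast"] <- rej["intensity_contrast"] +
        as.integer(ct$p < 0.05)
    }
    n_trips <- vapply(trajs, function(t) {
      cs <- sufficient_statistics(t)$counts
      cs[["12"]] + cs[["34"]]
    }, numeric(1))
    tt <- paired_t_test(n_trips[sat == 0L], n_trips[sat == 1L])
    n_ok["paired_t"] <- n_ok["paired_t"] + 1L
    rej["paired_t"] <- rej["paired_t"] + as.integer(tt$p < 0.05)
  }
  as.list(c(rej / n_ok, n_replicates = n_replicates))
}

#' Qualitative emulation of the leadership pattern
#'
#' Generates studies under boldness-monotone leaving rates and negative
#' satiation effects on the satiated fish's leaving edges, and checks the
#' directional pattern per replicate: (a) the bolder pair member initiates
#' the majority of joint trips before satiation, (b) focal time out of
#' cover drops after satiation, and (c) focal trip counts drop after
#' satiation.
#'
#' @param n_replicates Number of studies.
#' @param config A [study_config()]; the default here scales the category
#'   quotas down to SM 4, SL 3, BM 6, BL 3 to keep runtime modest while
#'   preserving the category mix.
#' @param seed Root seed.
#' @return List with the per-check success rates, `all_rate` (all three
#'   jointly), and `n_replicates`.
#' @export
qualitative_emulation <- function(n_replicates = 100L,
                                  config = study_config(
                                    n_pairs_per_category =
                                      c(SM = 4, SL = 3, BM = 6, BL = 3)),
                                  seed = 1L) {
  hits <- matrix(FALSE, n_replicates, 3,
                 dimnames = list(NULL, c("bolder_leads", "time_out_drops",
                                         "trips_drop")))
  for (r in seq_len(n_replicates)) {
    st <- generate_study(config, seed = child_seed(seed, r))
    s <- summaries_table(st$trajectories)
    ctrl <- s[s$session == "control", ]
    bolder <- ifelse(ctrl$fish == "focal",
                     ctrl$focal_boldness >= ctrl$partner_boldness,
                     ctrl$partner_boldness > ctrl$focal_boldness)
    hits[r, "bolder_leads"] <-
      sum(ctrl$n_joint_initiations[bolder]) >
      sum(ctrl$n_joint_initiations[!bolder])
    f <- s[s$fish == "focal", ]
    hits[r, "time_out_drops"] <-
      mean(f$prop_time_out[f$session == "satiated"]) <
      mean(f$prop_time_out[f$session == "control"])
    hits[r, "trips_drop"] <-
      mean(f$n_trips[f$session == "satiated"]) <
      mean(f$n_trips[f$session == "control"])
  }
  out <- as.list(colMeans(hits))
  out$all_rate <- mean(apply(hits, 1, all))
  out$n_replicates <- n_replicates
  out
}

#' Long-run simulator fidelity check
#'
#' Simulates one long trajectory at known intensities and compares the
#' crude rates `N_ij / T_i` to the truth on every edge.
#'
#' @param duration Trajectory length in seconds (default 1e6).
#' @param q Named vector of true intensities over [EDGES] (default 0.02/s
#'   everywhere, which keeps every state well-occupied).
#' @param seed Seed.
#' @return List with `max_rel_err` and the per-edge relative errors.
#' @export
simulator_fidelity <- function(duration = 1e6,
                               q = stats::setNames(rep(0.02, 8), EDGES),
                               seed = 1L) {
  t <- simulate_trajectory(intensity_model(q), list(), duration = duration,
                           seed = seed)
  crude <- closed_form_intensities(sufficient_statistics(t))
  rel <- abs(crude[EDGES] / q[EDGES] - 1)
  list(max_rel_err = max(rel), rel_err = rel, n_events = nrow(t$events))
}
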