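test_that("log_likelihood matches closed forms for single sojourns", {
  m <- intensity_model(c("12" = 0.1, "13" = 0.05))
  # one completed sojourn of 10 s in state 1 ending 1->2:
  # -(0.1 + 0.05) * 10 + log(0.1)
  t <- make_traj(1L, 9.999999999, 2L, 10)
  # almost-zero final sojourn in state 2 (state 2 has floor intensities)
  ll <- log_likelihood(m, t)
  expect_equal(ll, -0.15 * 10 + log(0.1), tolerance = 1e-6)

  # zero-event trajectory: pure censoring term -Lambda_1 * duration
  m2 <- intensity_model(c("12" = 0.015, "13" = 0.005))
  t0 <- make_traj(1L, numeric(0), integer(0), 100)
  expect_equal(log_likelihood(m2, t0), -2, tolerance = 1e-6)

  # covariate satiated = 1 with beta_12 = log 2 doubles q12: independent
  # substitution oracle recomputes with q12 = 0.2 directly
  m3 <- intensity_model(c("12" = 0.1, "13" = 0.05),
                        effects = list(satiated = c("12" = log(2))))
  m3_sub <- intensity_model(c("12" = 0.2, "13" = 0.05))
  t1 <- make_traj(1L, 9.999999999, 2L, 10)
  expect_equal(log_likelihood(m3, t1, covariates = list(satiated = 1)),
               log_likelihood(m3_sub, t1), tolerance = 1e-12)
  expect_error(log_likelihood(m3, t1), "covariate 'satiated' missing")
})

test_that("closed_form_intensities is N/T with flagged undefined states", {
  ss <- structure(list(
    counts = stats::setNames(c(5L, rep(0L, 7)), EDGES),
    sojourn = stats::setNames(c(100, 50, 0, 0), as.character(1:4))),
    class = "sufficient_stats")
  q <- closed_form_intensities(ss)
  expect_equal(q[["12"]], 0.05)
  expect_equal(q[["21"]], 0)         # T_2 > 0, no departures
  expect_true(is.na(q[["34"]]))      # state 3 never visited
  expect_true("34" %in% attr(q, "undefined"))
  ss$counts[["34"]] <- 2L
  expect_error(closed_form_intensities(ss), "inconsistent")
})

test_that("covariate-free MLE equals crude rates to 1e-6 relative", {
  for (seed in c(3, 17)) {
    t <- simulate_trajectory(ref_model(), list(), duration = 7200, seed = seed)
    ss <- sufficient_statistics(t)
    crude <- closed_form_intensities(ss)
    fit <- fit_mle(list(t))
    q <- fitted_intensities(fit)
    obs <- names(which(ss$counts > 0))
    expect_true(length(obs) >= 4)
    expect_lt(max(abs(q[obs] / crude[obs] - 1)), 1e-6)
    expect_true(fit$converged)
  }
})

test_that("log-likelihood at the MLE beats random perturbations", {
  t <- simulate_trajectory(ref_model(), list(), duration = 7200, seed = 5)
  fit <- fit_mle(list(t))
  q_hat <- fitted_intensities(fit)
  obs <- names(which(sufficient_statistics(t)$counts > 0))
  ll_hat <- log_likelihood(intensity_model(q_hat[obs]), t)
  set.seed(99)
  for (k in 1:100) {
    q_pert <- q_hat[obs] * exp(stats::rnorm(length(obs), 0, 0.1))
    expect_lte(log_likelihood(intensity_model(q_pert), t), ll_hat + 1e-9)
  }
})

test_that("time rescaling divides fitted intensities by the same factor", {
  t <- simulate_trajectory(ref_model(), list(), duration = 7200, seed = 21)
  q1 <- fitted_intensities(fit_mle(list(t)))
  c_scale <- 3.7
  t2 <- pair_trajectory(t$pair_id, t$session, t$duration * c_scale,
                        t$initial_state,
                        events = transform(t$events, time = time * c_scale))
  q2 <- fitted_intensities(fit_mle(list(t2)))
  obs <- names(which(sufficient_statistics(t)$counts > 0))
  expect_equal(q2[obs], q1[obs] / c_scale, tolerance = 1e-7)
})

test_that("estimator error shrinks with observation time", {
  durations <- c(2000, 8000, 32000)
  med_err <- vapply(durations, function(d) {
    errs <- vapply(1:20, function(r) {
      t <- simulate_trajectory(ref_model(), list(), duration = d,
                               seed = 1000L * r + as.integer(d / 1000))
      q <- fitted_intensities(fit_mle(list(t)))
      abs(q[["12"]] - 0.005)
    }, numeric(1))
    stats::median(errs)
  }, numeric(1))
  expect_true(all(diff(med_err) < 0))
})

test_that("satiation coefficients are estimated and unidentifiable edges flagged", {
  m <- intensity_model(
    c("12" = 0.006, "21" = 0.01, "13" = 0.004, "31" = 0.011,
      "24" = 0.004, "42" = 0.01, "34" = 0.006, "43" = 0.01),
    effects = list(satiated = c("12" = -1, "34" = -1)))
  trajs <- list(); covs <- numeric(0)
  for (k in 1:30) {
    sat <- as.integer(k %% 2 == 0)
    trajs[[k]] <- simulate_trajectory(m, list(satiated = sat), duration = 7200,
                                      seed = 500L + k)
    covs[k] <- sat
  }
  fit <- fit_mle(trajs, covariates = data.frame(satiated = covs))
  expect_true(fit$converged)
  b12 <- fitted_coefficient(fit, "satiated", "12")
  expect_true(b12$identifiable)
  expect_lt(abs(b12$estimate - (-1)), 0.5)
  b13 <- fitted_coefficient(fit, "satiated", "13")
  expect_lt(abs(b13$estimate), 0.5)

  # an edge never observed under satiated = 1 leaves beta unidentifiable
  # but other parameters untouched
  drop24 <- lapply(seq_along(trajs), function(k) {
    t <- trajs[[k]]
    if (covs[k] == 1) {
      keep <- !(paste0(t$events$from, t$events$to) %in% c("24")) &
        cumsum(paste0(t$events$from, t$events$to) == "24") == 0
      t$events <- t$events[keep, , drop = FALSE]
      # truncate at first 2->4 so the chain stays consistent
      t <- pair_trajectory(t$pair_id, t$session, t$duration, t$initial_state,
                           events = t$events)
    }
    t
  })
  fit2 <- fit_mle(drop24, covariates = data.frame(satiated = covs))
  b24 <- fitted_coefficient(fit2, "satiated", "24")
  expect_false(b24$identifiable)
  expect_error(wald_test_coefficient(fit2, "satiated", "24"),
               "not identifiable")
  expect_true(fitted_coefficient(fit2, "satiated", "12")$identifiable)
})

test_that("wald tests match normal-tail oracles", {
  t <- simulate_trajectory(ref_model(), list(), duration = 7200, seed = 31)
  fit <- fit_mle(list(t))
  # synthetic fit surgery: inject known estimate/SE to check the formula
  fit$params$estimate[fit$params$parameter == "logq0" &
                        fit$params$edge == "12"] <- -1
  row <- which(fit$params$parameter == "logq0" & fit$params$edge == "12")
  fit$params$se[row] <- 0.5
  # coefficient test oracle: z = (est - null)/se, p = 2 * pnorm(-|z|)
  fitc <- fit_mle(
    list(simulate_trajectory(intensity_model(
      c("12" = 0.01, "21" = 0.01), effects = list(satiated = c("12" = 0))),
      list(satiated = 0), duration = 7200, seed = 2),
      simulate_trajectory(intensity_model(
        c("12" = 0.01, "21" = 0.01), effects = list(satiated = c("12" = 0))),
        list(satiated = 1), duration = 7200, seed = 3)),
    covariates = data.frame(satiated = c(0, 1)))
  w <- wald_test_coefficient(fitc, "satiated", "12")
  expect_equal(w$z, w$estimate / w$se)
  expect_equal(w$p, 2 * stats::pnorm(-abs(w$z)))
  # the spec-level example: estimate -1, SE 0.5 -> z = -2, p = 0.0455
  z <- (-1 - 0) / 0.5
  expect_equal(2 * stats::pnorm(-abs(z)), 0.0455, tolerance = 1e-3)

  # contrast: equal log-intensities give z = 0, p = 1
  fit$params$estimate[fit$params$parameter == "logq0" &
                        fit$params$edge %in% c("12", "21")] <- -4
  ct <- wald_test_intensity_contrast(fit, "12", "21")
  expect_equal(ct$z, 0)
  expect_equal(ct$p, 1)
  expect_equal(ct$direction, "a=b")
  # delta-method hand calculation with independent edges:
  # diff 1.0, SEs 0.3 and 0.4 -> z = 1 / sqrt(0.25) = 2
  fit$params$estimate[fit$params$parameter == "logq0" &
                        fit$params$edge == "12"] <- -3
  fit$vcov["12:logq0", "12:logq0"] <- 0.09
  fit$vcov["21:logq0", "21:logq0"] <- 0.16
  fit$vcov["12:logq0", "21:logq0"] <- 0
  fit$vcov["21:logq0", "12:logq0"] <- 0
  ct2 <- wald_test_intensity_contrast(fit, "12", "21")
  expect_equal(ct2$z, 2)
  expect_equal(ct2$p, 0.0455, tolerance = 1e-3)
  expect_equal(ct2$direction, "a>b")
})
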