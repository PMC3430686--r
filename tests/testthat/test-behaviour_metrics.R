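test_that("boldness_score sums disjoint out-of-cover intervals", {
  expect_equal(boldness_score(list(c(0, 1800)), 3600), 0.5)
  expect_equal(boldness_score(list(), 3600), 0)
  # hand-sum: (600 + 300) / 3600
  expect_equal(boldness_score(list(c(0, 600), c(1200, 1500)), 3600), 0.25)
  expect_error(boldness_score(list(c(0, 600), c(500, 700)), 3600), "overlap")
  expect_error(boldness_score(list(c(3500, 3700)), 3600), "outside")
})

test_that("derive_states merges per-fish streams into a joint trajectory", {
  # hand-merge: focal leaves 5, partner leaves 10, partner returns 50,
  # focal returns 60
  t <- derive_states(c(5, 60), c(10, 50), duration = 100)
  expect_equal(t$events$time, c(5, 10, 50, 60))
  expect_equal(t$events$from, c(1L, 2L, 4L, 2L))
  expect_equal(t$events$to, c(2L, 4L, 2L, 1L))
  expect_identical(validate_trajectory(t), character(0))

  t0 <- derive_states(numeric(0), numeric(0), duration = 100)
  expect_equal(nrow(t0$events), 0L)
  expect_equal(t0$initial_state, 1L)

  expect_error(derive_states(c(10), c(10), duration = 100), "simultaneous")
  shifted <- derive_states(c(10), c(10), duration = 100, break_ties = "shift")
  expect_equal(shifted$events$time, c(10, 10.01))
  expect_error(derive_states(c(5, 4), c(10), duration = 100),
               "strictly increasing")
})

test_that("derive_states inverts per-fish projection on random trajectories", {
  for (seed in 1:25) {
    t <- random_trajectory(seed)
    if (t$initial_state != 1L) next  # projection starts-under-cover premise
    ek <- paste0(t$events$from, t$events$to)
    focal <- t$events$time[ek %in% c("12", "21", "34", "43")]
    partner <- t$events$time[ek %in% c("13", "31", "24", "42")]
    back <- derive_states(focal, partner, t$duration)
    expect_equal(back$events$time, t$events$time)
    expect_identical(back$events$to, t$events$to)
  }
})

test_that("sufficient statistics count transitions and conserve time", {
  t <- make_traj(1L, c(5, 10), c(2L, 1L), 100)
  ss <- sufficient_statistics(t)
  expect_equal(ss$counts[["12"]], 1L)
  expect_equal(ss$counts[["21"]], 1L)
  expect_equal(sum(ss$counts), 2L)
  expect_equal(ss$sojourn[["1"]], 95)
  expect_equal(ss$sojourn[["2"]], 5)

  t0 <- make_traj(1L, numeric(0), integer(0), 100)
  ss0 <- sufficient_statistics(t0)
  expect_equal(sum(ss0$counts), 0L)
  expect_equal(ss0$sojourn[["1"]], 100)

  for (seed in 1:20) {
    t <- random_trajectory(seed)
    ss <- sufficient_statistics(t)
    expect_equal(sum(ss$sojourn), t$duration)
    # departures from each state match counts by row
    dep <- table(factor(t$events$from, levels = 1:4))
    for (s in 1:4) {
      expect_equal(sum(ss$counts[substr(EDGES, 1, 1) == s]),
                   unname(dep[as.character(s)]))
    }
  }
})

test_that("classify_trips follows the taxonomy on hand-traced sequences", {
  # 1 ->(5) 2 ->(10) 4 ->(50) 3 ->(60) 1: focal joint initiation at 5,
  # partner follow at 10
  t <- make_traj(1L, c(5, 10, 50, 60), c(2L, 4L, 3L, 1L), 100)
  tr <- classify_trips(t)
  expect_equal(nrow(tr), 2L)
  joint <- tr[tr$kind == "joint_trip_initiation", ]
  expect_equal(joint$actor, "focal")
  expect_equal(joint$start_time, 5)
  expect_equal(joint$end_time, 50)  # focal returned via 4->3 at 50
  fol <- tr[tr$kind == "follow", ]
  expect_equal(fol$actor, "partner")
  expect_equal(fol$start_time, 10)
  expect_equal(fol$end_time, 60)

  # 1 ->(5) 3 ->(20) 1: partner failed attempt
  t2 <- make_traj(1L, c(5, 20), c(3L, 1L), 100)
  tr2 <- classify_trips(t2)
  expect_equal(tr2$actor, "partner")
  expect_equal(tr2$kind, "attempted_initiation_failed")
  expect_equal(tr2$end_time, 20)

  expect_equal(nrow(classify_trips(make_traj(1L, numeric(0), integer(0), 10))),
               0L)

  # attempt open at session end is failed + censored
  t3 <- make_traj(1L, 5, 2L, 100)
  tr3 <- classify_trips(t3)
  expect_equal(tr3$kind, "attempted_initiation_failed")
  expect_true(tr3$censored)

  # re-join of an existing joint trip adds no new follow:
  # 1 ->2 ->4 ->2 ->4 (partner rejoins the same focal-initiated trip)
  t4 <- make_traj(1L, c(5, 10, 20, 30), c(2L, 4L, 2L, 4L), 100)
  tr4 <- classify_trips(t4)
  expect_equal(sum(tr4$kind == "joint_trip_initiation"), 1L)
  expect_equal(sum(tr4$kind == "follow"), 1L)
})

test_that("session_summary matches hand-computed sojourns and counts", {
  # events at 5, 10, 50, 60 over duration 100:
  # T1 = 5 + 40 = 45, T2 = 5, T4 = 40, T3 = 10
  t <- make_traj(1L, c(5, 10, 50, 60), c(2L, 4L, 3L, 1L), 100)
  s <- session_summary(t)
  focal <- s[s$fish == "focal", ]
  partner <- s[s$fish == "partner", ]
  expect_equal(focal$prop_time_out, 0.45)
  expect_equal(partner$prop_time_out, 0.50)
  expect_equal(focal$n_trips, 1L)
  expect_equal(partner$n_trips, 1L)
  expect_equal(focal$n_joint_initiations, 1L)
  expect_equal(partner$n_follows, 1L)

  s0 <- session_summary(make_traj(1L, numeric(0), integer(0), 100))
  expect_true(all(s0$prop_time_out == 0))
  expect_true(all(s0[, c("n_trips", "n_attempted_initiations",
                         "n_follows")] == 0L))
})

test_that("ledger and decomposition identities hold on random trajectories", {
  for (seed in 1:40) {
    t <- random_trajectory(seed)
    s <- session_summary(t)
    focal <- s[s$fish == "focal", ]
    partner <- s[s$fish == "partner", ]
    expect_equal(focal$n_joint_initiations, partner$n_follows)
    expect_equal(partner$n_joint_initiations, focal$n_follows)
    expect_equal(focal$n_attempted_initiations,
                 focal$n_joint_initiations + focal$n_failed_initiations)
    expect_equal(partner$n_attempted_initiations,
                 partner$n_joint_initiations + partner$n_failed_initiations)
  }
})

test_that("categorize_pair applies the ratio bands with printed endpoints", {
  expect_equal(categorize_pair(0.30, 0.40), "SM")  # r = 0.75
  expect_equal(categorize_pair(0.60, 0.25), "BL")  # r = 2.4
  expect_equal(categorize_pair(0.30, 0.30), "none")
  # inclusive band endpoints, strict 50%/200% cuts
  expect_equal(categorize_pair(0.70, 1.00), "SM")
  expect_equal(categorize_pair(0.85, 1.00), "SM")
  expect_equal(categorize_pair(0.50, 1.00), "none")
  expect_equal(categorize_pair(0.499, 1.00), "SL")
  expect_equal(categorize_pair(1.15 * 0.5, 0.5), "BM")
  expect_equal(categorize_pair(1.40 * 0.5, 0.5), "BM")
  expect_equal(categorize_pair(2.00 * 0.4, 0.4), "none")
  expect_equal(categorize_pair(2.01 * 0.4, 0.4), "BL")
  expect_error(categorize_pair(0.3, 0), "> 0")
})
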