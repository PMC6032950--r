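test_that("invalid configurations are rejected with the offending fields", {
  expect_error(cohort_config(p_augmentation = 1.4), "p_augmentation")
  expect_error(cohort_config(n_women = 0), "n_women")
  err <- tryCatch(cohort_config(p_caesarean = -0.1, frailty_shape = 0),
                  error = conditionMessage)
  expect_match(err, "p_caesarean")
  expect_match(err, "frailty_shape")
  rt <- default_rate_table()
  rt[2, 3] <- -1
  expect_error(cohort_config(subgroup_rate_table = rt),
               "subgroup_rate_table")
})

test_that("identical config and seed give a bit-identical cohort", {
  cfg <- cohort_config(n_women = 100, seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$women, b$women)
  expect_identical(a$exams, b$exams)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  g1 <- tempfile(fileext = ".csv"); g2 <- tempfile(fileext = ".csv")
  write_cohort(a, f1, g1)
  write_cohort(b, f2, g2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(g1), readLines(g2))
  # and a different seed gives a different cohort
  c_ <- simulate_cohort(cohort_config(n_women = 100, seed = 43))
  expect_false(identical(a$exams, c_$exams))
})

test_that("latent trajectories are progressive with exponential sojourns", {
  rates <- rep(1, 9); names(rates) <- 2:10
  set.seed(8)
  path <- simulate_trajectory(rates, 4L)
  expect_equal(path$state, c(4:10, 11))
  expect_true(all(diff(path$entry_time) > 0))
  expect_equal(path$entry_time[1], 0)
  # start at 10 cm: single transition to birth
  p10 <- simulate_trajectory(rates, 10L)
  expect_equal(p10$state, c(10L, 11L))
  # sojourn mean equals 1/rate (9 cm -> 10 cm at 1/h)
  soj <- replicate(4000, {
    p <- simulate_trajectory(rates, 9L)
    p$entry_time[2]
  })
  expect_lt(abs(mean(soj) - 1), 3 / sqrt(4000) + 0.02)
  # mean 4 -> 10 cm at 0.5/h is the sum of six exponential means = 12 h
  tot <- replicate(4000, {
    p <- simulate_trajectory(rep(0.5, 9) |> stats::setNames(2:10), 4L)
    p$entry_time[p$state == 10L]
  })
  expect_lt(abs(mean(tot) - 12), 3 * sqrt(6 * 4) / sqrt(4000) + 0.05)
  expect_error(simulate_trajectory(c(`9` = 1), 4L), "state")
})

test_that("panel observation records the latent state at the exam time", {
  path <- data.frame(state = c(4:10, 11L),
                     entry_time = c(0, 1, 2.5, 3, 5, 6, 8, 9))
  # fixed schedule samples the latent step function; times past birth drop
  obs <- observe_panel(path, times = c(0, 4, 8, 12))
  expect_equal(obs$time_hours, c(0, 4, 8))
  expect_equal(obs$dilatation_cm, c(4L, 7L, 10L))
  # zero extra exams: admission only
  expect_equal(nrow(observe_panel(path)), 1L)
  # random window exams stay in the 4-10 window and match the latent state
  set.seed(14)
  for (i in 1:50) {
    rates <- stats::setNames(runif(9, 0.4, 2), 2:10)
    p <- simulate_trajectory(rates, sample(2:6, 1))
    obs <- observe_panel(p, n_window_exams = 3)
    expect_equal(obs$time_hours[1], 0)
    expect_false(is.unsorted(obs$time_hours))
    win <- obs[-1, ]
    expect_true(all(win$dilatation_cm >= 4 & win$dilatation_cm <= 9))
    for (j in seq_len(nrow(obs))) {
      k <- findInterval(obs$time_hours[j], p$entry_time)
      expect_equal(obs$dilatation_cm[j], p$state[k])
    }
  }
})

test_that("exam counts in the active-phase window hit the configured mean", {
  coh <- small_cohort()
  ex <- coh$exams
  reach4 <- tapply(ex$dilatation_cm >= 4 & ex$dilatation_cm <= 10, ex$id, any)
  cnt <- tapply(ex$dilatation_cm >= 4 & ex$dilatation_cm < 10, ex$id, sum)
  m <- mean(cnt[reach4])
  se <- stats::sd(cnt[reach4]) / sqrt(sum(reach4))
  expect_lt(abs(m - 2.22), 3 * se + 0.01)
})

test_that("cohort marginals match the configured probabilities", {
  coh <- small_cohort()
  w <- coh$women
  n <- nrow(w)
  check <- function(obs, p) {
    expect_lt(abs(mean(obs) - p), 3 * sqrt(p * (1 - p) / n) + 1e-9)
  }
  check(w$augmentation, 0.351)
  check(w$caesarean, 0.132)
  check(w$onset == "spontaneous", 0.899)
  check(w$parity == 0, 0.408)
  check(w$presentation == "cephalic", 0.986)
  expect_true(all(w$previous_caesarean[w$parity == 0] == 0))
  expect_true(all(w$birth_time > 0))
  # exam validity: non-decreasing dilatation, strictly increasing times
  ex <- coh$exams
  expect_true(all(ex$dilatation_cm >= 2 & ex$dilatation_cm <= 10))
  by_id <- split(ex, ex$id)
  ok <- vapply(by_id, function(e) {
    all(diff(e$time_hours) > 0) && all(diff(e$dilatation_cm) >= 0)
  }, logical(1))
  expect_true(all(ok))
})

test_that("a unit odds multiplier makes outcomes independent of speed", {
  cfg <- cohort_config(n_women = 4000, seed = 17,
                       slow_labour_odds_multiplier = 1)
  coh <- simulate_cohort(cfg)
  w <- coh$women
  # outcome rate at the configured baseline
  expect_lt(abs(mean(w$severe_adverse_outcome) - 0.022),
            3 * sqrt(0.022 * 0.978 / 4000))
  # alert-line crossing carries no information about the outcome
  exl <- split(coh$exams[, c("time_hours", "dilatation_cm")], coh$exams$id)
  n_act <- vapply(exl, function(e)
    sum(e$dilatation_cm >= 4 & e$dilatation_cm <= 10), integer(1))
  crossed <- rep(NA, nrow(w))
  for (i in which(n_act >= 2)) {
    crossed[i] <- crossed_alert_line(exl[[as.character(i)]])$crossed
  }
  r <- accuracy_stats(tabulate_2x2(crossed, w$severe_adverse_outcome))
  se_logdor <- sqrt(sum(1 / r$counts))
  expect_lt(abs(log(r$dor[["estimate"]])), 3 * se_logdor)
})

test_that("cohort CSV round-trip preserves the tables", {
  coh <- simulate_cohort(cohort_config(n_women = 60, seed = 5))
  wf <- tempfile(fileext = ".csv"); ef <- tempfile(fileext = ".csv")
  write_cohort(coh, wf, ef)
  expect_equal(readLines(wf, n = 1),
               paste("id,parity,previous_caesarean,onset,gestational_weeks,",
                     "presentation,augmentation,caesarean,",
                     "severe_adverse_outcome,birth_time", sep = ""))
  back <- read_cohort(wf, ef)
  expect_equal(back$women$parity, coh$women$parity)
  expect_equal(back$exams$dilatation_cm, coh$exams$dilatation_cm)
  expect_equal(back$women$birth_time, coh$women$birth_time,
               tolerance = 1e-12)
  expect_error(read_cohort(ef, ef), "missing column")
})
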