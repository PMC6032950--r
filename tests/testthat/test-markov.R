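test_that("generator matrix is bidiagonal, conservative and validated", {
  Q <- build_generator(c(`9` = 2))
  expect_equal(unname(Q), matrix(c(-2, 2, 0, 0), 2, 2, byrow = TRUE))
  Q2 <- build_generator(c(`8` = 1, `9` = 1))
  expect_equal(unname(Q2[cbind(1:2, 2:3)]), c(1, 1))
  for (rates in list(c(1, 2, 3), runif(9, 0.2, 3))) {
    expect_equal(rowSums(build_generator(rates)), rep(0, length(rates) + 1),
                 ignore_attr = TRUE)
  }
  expect_error(build_generator(c(1, 0, 2)), "positive")
  expect_error(build_generator(c(1, -1)), "positive")
})

test_that("transition matrix matches closed forms and is row-stochastic", {
  Q <- build_generator(c(`9` = 1))
  expect_equal(transition_matrix(Q, 0), diag(2), ignore_attr = TRUE)
  expect_equal(transition_matrix(Q, 1)[1, 1], exp(-1), tolerance = 1e-12)
  expect_error(transition_matrix(Q, -0.5), "non-negative")

  # hypoexponential CDF oracle vs matrix exponential, distinct rates
  rates <- c(0.7, 1.1, 0.9, 1.4, 2.0, 1.7, 1.2)
  Q <- build_generator(rates)
  for (t in c(0.1, 0.5, 1, 2.5, 6, 15)) {
    P <- transition_matrix(Q, t)
    expect_true(all(P >= 0 & P <= 1))
    expect_equal(rowSums(P), rep(1, 8), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_true(all(P[lower.tri(P)] == 0))
    expect_lt(abs(P[1, 8] - hypoexp_cdf_oracle(rates, t)), 1e-8)
    # two transient states with distinct rates: explicit closed form
    expect_equal(transition_matrix(build_generator(rates[1:2]), t)[1, 3],
                 1 - (rates[2] * exp(-rates[1] * t) -
                        rates[1] * exp(-rates[2] * t)) /
                   (rates[2] - rates[1]),
                 tolerance = 1e-10)
  }
})

test_that("Chapman-Kolmogorov holds on small models", {
  set.seed(42)
  for (rep in 1:5) {
    rates <- runif(sample(2:6, 1), 0.3, 2.5)
    Q <- build_generator(rates)
    s <- runif(1, 0.1, 3); t <- runif(1, 0.1, 3)
    expect_equal(transition_matrix(Q, s + t),
                 transition_matrix(Q, s) %*% transition_matrix(Q, t),
                 tolerance = 1e-10)
  }
})

test_that("panel log-likelihood matches hand-computed and additive forms", {
  m <- progressive_model(c(`9` = 1, `10` = 1))
  one <- data.frame(id = 1, time_hours = c(0, 1), dilatation_cm = c(9, 9))
  expect_equal(panel_log_likelihood(m, one), -1)

  set.seed(7)
  s1 <- data.frame(id = 1, time_hours = c(0, 0.7, 2.1),
                   dilatation_cm = c(9, 10, 11))
  s2 <- data.frame(id = 2, time_hours = c(0, 1.4),
                   dilatation_cm = c(9, 11))
  both <- rbind(s1, s2)
  expect_equal(panel_log_likelihood(m, both),
               panel_log_likelihood(m, s1) + panel_log_likelihood(m, s2),
               tolerance = 1e-12)

  # grouped fast path agrees with direct matrix-exponential evaluation
  mod <- progressive_model(c(`6` = 0.8, `7` = 1.3, `8` = 0.9, `9` = 1.7,
                             `10` = 1.1))
  ex <- data.frame(id = rep(1:4, each = 3),
                   time_hours = rep(c(0, 1.3, 3.9), 4),
                   dilatation_cm = c(6, 7, 9, 6, 6, 11, 7, 9, 10, 8, 10, 11))
  Q <- build_generator(mod$rates)
  direct <- 0
  for (i in 1:4) {
    e <- ex[ex$id == i, ]
    for (j in 1:2) {
      a <- match(e$dilatation_cm[j], 6:11)
      b <- match(e$dilatation_cm[j + 1], 6:11)
      direct <- direct +
        log(transition_matrix(Q, e$time_hours[j + 1] - e$time_hours[j])[a, b])
    }
  }
  expect_equal(panel_log_likelihood(mod, ex), direct, tolerance = 1e-8)

  bad <- data.frame(id = 5, time_hours = c(0, 2), dilatation_cm = c(8, 6))
  expect_error(panel_log_likelihood(mod, bad), "regresses.*5")
})

test_that("panel MLE approaches transitions / time-at-risk for near-exactly
          observed single-state sojourns", {
  # each woman is watched in state 10 until just before her exactly-known
  # transition to birth; as the final interval shrinks the panel MLE tends
  # to the exponential MLE n / sum(t)
  set.seed(11)
  n <- 150
  t_obs <- rexp(n, 1.3)
  eps <- 1e-4
  ex <- data.frame(id = rep(seq_len(n), each = 3),
                   time_hours = as.vector(rbind(0, pmax(t_obs - eps, 0),
                                                t_obs)),
                   dilatation_cm = rep(c(10, 10, 11), n))
  fit <- fit_rates(ex, min_transitions = 1)
  expect_true(fit$converged)
  expect_equal(unname(fit$model$rates["10"]), n / sum(t_obs),
               tolerance = 1e-2)
})

test_that("fitting recovers simulated rates and is stationary at the optimum", {
  set.seed(21)
  true <- c(`4` = 0.9, `5` = 1.1, `6` = 1.3, `7` = 1.6, `8` = 1.9,
            `9` = 2.1, `10` = 1.4)
  n <- 300
  exl <- lapply(seq_len(n), function(i) {
    path <- simulate_trajectory(true, 4L)
    obs <- observe_panel(path, times = seq(0, 24, by = 0.25))
    birth <- path$entry_time[path$state == 11L]
    rbind(cbind(id = i, obs),
          data.frame(id = i, time_hours = birth, dilatation_cm = 11L))
  })
  ex <- do.call(rbind, exl)
  fit <- fit_rates(ex)
  expect_true(fit$converged)
  expect_true(all(abs(fit$model$rates / true - 1) < 0.25))

  # restarting at the fitted optimum does not move the optimum
  fit2 <- fit_rates(ex, init_rates = fit$model$rates, n_starts = 1)
  expect_equal(fit2$log_likelihood, fit$log_likelihood, tolerance = 1e-6)
  # and the likelihood at truth is no better than at the MLE
  expect_lte(panel_log_likelihood(progressive_model(true), ex),
             fit$log_likelihood + 1e-6)
})

test_that("insufficient per-state transitions raise an informative error", {
  ex <- data.frame(id = rep(1:3, each = 2),
                   time_hours = rep(c(0, 5), 3),
                   dilatation_cm = rep(c(9, 11), 3))
  expect_error(fit_rates(ex, min_transitions = 5), "state")
})

test_that("first-passage quantiles invert Erlang and hypoexponential CDFs", {
  m <- progressive_model(rep(1, 9))
  expect_equal(first_passage_quantile(m, 4, 5, 0.5), log(2),
               tolerance = 1e-6)
  # Erlang(k, 1) quantile oracle for k = 1..6
  for (d in 5:10) {
    k <- d - 4
    expect_equal(first_passage_quantile(m, 4, d, 0.5),
                 qgamma(0.5, shape = k, rate = 1), tolerance = 1e-6)
    expect_equal(first_passage_quantile(m, 4, d, 0.95),
                 qgamma(0.95, shape = k, rate = 1), tolerance = 1e-6)
  }
  expect_error(first_passage_quantile(m, 4, 8, 1.2), "between 0 and 1")
  expect_error(first_passage_quantile(m, 8, 4, 0.5), "below")
})

test_that("percentile curves are monotone and scale with the rates", {
  set.seed(3)
  rates <- runif(9, 0.4, 2.5)
  names(rates) <- 2:10
  m <- progressive_model(rates)
  c50 <- percentile_curve(m, 50)
  c95 <- percentile_curve(m, 95)
  expect_true(all(diff(c50$hours_from_4cm) > 0))
  expect_true(all(c95$hours_from_4cm[-1] > c50$hours_from_4cm[-1]))
  # doubling all intensities halves every quantile
  m2 <- progressive_model(rates * 2)
  expect_equal(percentile_curve(m2, 50)$hours_from_4cm,
               c50$hours_from_4cm / 2, tolerance = 1e-5)
  # equal-rate model reproduces Erlang medians
  erlang <- percentile_curve(progressive_model(rep(1, 9)), 50)
  expect_equal(erlang$hours_from_4cm[-1], qgamma(0.5, 1:6, 1),
               tolerance = 1e-6)
})

test_that("curve crossing respects boundaries and percentile nesting", {
  m <- progressive_model(rep(1, 9))
  c50 <- percentile_curve(m, 50)
  q8 <- c50$hours_from_4cm[c50$dilatation_cm == 8]
  on_line <- data.frame(time_hours = c(0, q8), dilatation_cm = c(4, 8))
  expect_false(crossed_percentile_curve(on_line, c50)$crossed)
  late <- data.frame(time_hours = c(0, q8 + 0.1), dilatation_cm = c(4, 8))
  expect_true(crossed_percentile_curve(late, c50)$crossed)

  # anchored above 4 cm: offset by the curve's own quantile to the anchor
  q6 <- c50$hours_from_4cm[c50$dilatation_cm == 6]
  anchored <- data.frame(time_hours = c(0, q8 - q6 + 0.05),
                         dilatation_cm = c(6, 8))
  expect_true(crossed_percentile_curve(anchored, c50)$crossed)

  no_anchor <- data.frame(time_hours = c(0, 2), dilatation_cm = c(2, 3))
  expect_true(is.na(crossed_percentile_curve(no_anchor, c50)$crossed))

  # crossing the 95th percentile implies crossing the 50th
  c95 <- percentile_curve(m, 95)
  set.seed(12)
  for (i in 1:200) {
    ex <- random_exam_series()
    r95 <- crossed_percentile_curve(ex, c95)$crossed
    r50 <- crossed_percentile_curve(ex, c50)$crossed
    if (!is.na(r95) && isTRUE(r95)) expect_true(r50)
  }
})
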