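#' Progressive multi-state model of cervical dilatation
#'
#' Constructs a continuous-time Markov model in which each centimetre of
#' cervical dilatation from `first_state` cm to 10 cm is a transient state and
#' childbirth is the final absorbing state. The process is progressive and
#' unidirectional: from state \eqn{d} the only possible move is to \eqn{d + 1}
#' (or from 10 cm to birth), governed by the transition intensity
#' \eqn{\lambda_d} (per hour).
#'
#' @param rates Numeric vector of positive transition intensities (1/hours),
#'   one per transient state, ordered from the lowest modelled dilatation up
#'   to 10 cm. Names, if present, must be the dilatations in centimetres.
#' @param first_state Dilatation (cm) of the first transient state. Ignored
#'   when `rates` is named.
#' @return An object of class `progressive_model` with elements `rates`
#'   (named by dilatation) and `states` (the transient dilatations, in cm).
#' @examples
#' m <- progressive_model(rep(1, 9))            # states 2..10 cm
#' m4 <- progressive_model(rep(0.8, 7), first_state = 4)
#' @export
progressive_model <- function(rates, first_state = 2L) {
  if (!is.numeric(rates) || length(rates) < 1L) {
    stop("'rates' must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(rates)) || any(rates <= 0)) {
    stop("all transition intensities must be strictly positive and finite",
         call. = FALSE)
  }
  if (!is.null(names(rates))) {
    states <- as.integer(names(rates))
    if (anyNA(states) || any(diff(states) != 1L)) {
      stop("names of 'rates' must be consecutive integer dilatations",
           call. = FALSE)
    }
  } else {
    states <- seq.int(as.integer(first_state), length.out = length(rates))
  }
  if (states[length(states)] != 10L) {
    stop("the last transient state must be 10 cm (followed by birth)",
         call. = FALSE)
  }
  rates <- as.numeric(rates)
  names(rates) <- states
  structure(list(rates = rates, states = states),
            class = "progressive_model")
}

#' @export
print.progressive_model <- function(x, ...) {
  cat("Progressive labour model:", length(x$states),
      "transient states (", x$states[1], "cm ... 10 cm ) + birth\n")
  cat("Transition intensities (1/h):\n")
  print(round(x$rates, 4))
  invisible(x)
}

#' Generator matrix of a progressive labour model
#'
#' Builds the (bidiagonal) intensity matrix Q of the progressive chain:
#' `Q[i, i] = -rate[i]`, `Q[i, i + 1] = rate[i]`, absorbing row all zero.
#'
#' @param rates Positive transition intensities, one per transient state
#'   (lowest dilatation first). A `progressive_model` is also accepted.
#' @return A square numeric matrix of dimension `length(rates) + 1`, with the
#'   absorbing childbirth state last. Rows sum to zero.
#' @examples
#' build_generator(c(`9` = 2))    # [[-2, 2], [0, 0]]
#' @export
build_generator <- function(rates) {
  if (inherits(rates, "progressive_model")) rates <- rates$rates
  if (!is.numeric(rates) || length(rates) < 1L) {
    stop("'rates' must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(rates)) || any(rates <= 0)) {
    stop("all transition intensities must be strictly positive and finite",
         call. = FALSE)
  }
  m <- length(rates)
  Q <- matrix(0, m + 1L, m + 1L)
  Q[cbind(seq_len(m), seq_len(m))] <- -rates
  Q[cbind(seq_len(m), seq_len(m) + 1L)] <- rates
  lab <- c(if (is.null(names(rates))) as.character(seq_len(m)) else
    names(rates), "birth")
  dimnames(Q) <- list(lab, lab)
  Q
}

#' Transition probability matrix over an interval
#'
#' Computes \eqn{P(\Delta t) = \exp(Q \Delta t)} by matrix exponentiation.
#'
#' @param Q Generator matrix as returned by [build_generator()].
#' @param dt Non-negative interval length in hours.
#' @return Row-stochastic matrix of transition probabilities; entries below
#'   the diagonal are zero for a progressive generator.
#' @export
transition_matrix <- function(Q, dt) {
  if (!is.matrix(Q) || nrow(Q) != ncol(Q)) {
    stop("'Q' must be a square matrix", call. = FALSE)
  }
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt < 0) {
    stop("'dt' must be a single non-negative number", call. = FALSE)
  }
  if (dt == 0) {
    P <- diag(nrow(Q))
    dimnames(P) <- dimnames(Q)
    return(P)
  }
  P <- as.matrix(Matrix::expm(Q * dt))
  # clip tiny negative round-off and renormalise rows
  P[P < 0] <- 0
  P[P > 1] <- 1
  dimnames(P) <- dimnames(Q)
  P
}

# Closed-form transition probabilities for the progressive chain, vectorised
# over interval lengths. Positions are 1-based indices into `rates` with
# position m + 1 the absorbing state. Requires pairwise-distinct rates over
# the straddled span; callers must check `.rates_distinct()` first.
.hypoexp_P_pair <- function(rates, a, b, dt) {
  m <- length(rates)
  if (b == a) return(exp(-rates[a] * dt))
  if (b <= m) {
    lam <- rates[a:b]
    k <- length(lam)
    coef <- vapply(seq_len(k), function(i) {
      prod(lam[-k][1:(k - 1)]) / prod(lam[-i] - lam[i])
    }, numeric(1))
    return(pmin(1, pmax(0, as.vector(exp(-outer(dt, lam)) %*% coef))))
  }
  # absorbing: 1 - sum of probabilities of still being transient
  p <- rep(1, length(dt))
  for (j in a:m) p <- p - .hypoexp_P_pair(rates, a, j, dt)
  pmin(1, pmax(0, p))
}

.rates_distinct <- function(rates, tol = 1e-6) {
  s <- sort(rates)
  length(s) < 2L || min(diff(s)) > tol * max(s)
}

# Convert a collection of exam series into panel intervals.
# `exams`: data.frame with id, time_hours, dilatation_cm (11 = birth).
# Returns data.frame(from, to, dt) in cm / hours.
panel_intervals <- function(exams) {
  stopifnot(is.data.frame(exams),
            all(c("id", "time_hours", "dilatation_cm") %in% names(exams)))
  o <- order(exams$id, exams$time_hours)
  id <- exams$id[o]
  t <- exams$time_hours[o]
  d <- exams$dilatation_cm[o]
  same <- id[-1] == id[-length(id)]
  from <- d[-length(d)][same]
  to <- d[-1][same]
  dt <- (t[-1] - t[-length(t)])[same]
  if (any(to < from)) {
    bad <- unique(id[-1][same][to < from])
    stop("dilatation regresses within series for id(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  if (any(dt < 0)) stop("exam times must be non-decreasing within a series",
                        call. = FALSE)
  data.frame(from = from, to = to, dt = dt)
}

#' Panel log-likelihood of a progressive labour model
#'
#' Log-likelihood of panel-observed dilatation series under a progressive
#' model: each consecutive pair of observations \eqn{(s_a, t_a) \to
#' (s_b, t_b)} within a woman contributes \eqn{\log P_{s_a s_b}(t_b - t_a)}.
#' Observations at full dilatation followed by childbirth enter as a
#' transition into the absorbing state over that interval (code the birth
#' observation as dilatation 11).
#'
#' @param model A [progressive_model()].
#' @param exams Long-format exam table with columns `id`, `time_hours` and
#'   `dilatation_cm` (integer cm; 11 denotes the childbirth observation).
#'   Series with a dilatation regression raise an error naming the woman.
#' @return The log-likelihood (scalar; `-Inf` if any observed pair is
#'   impossible under the model).
#' @export
panel_log_likelihood <- function(model, exams) {
  stopifnot(inherits(model, "progressive_model"))
  iv <- if (is.data.frame(exams) && all(c("from", "to", "dt") %in%
                                          names(exams))) {
    exams
  } else {
    panel_intervals(exams)
  }
  .panel_loglik(model$rates, model$states, iv)
}

# Group panel intervals by (from, to) position pair for repeated likelihood
# evaluation. states = transient dilatations of the model.
.group_intervals <- function(states, iv) {
  m <- length(states)
  abs_cm <- states[m] + 1L           # 11 = birth
  a <- match(iv$from, states)
  b <- ifelse(iv$to == abs_cm, m + 1L, match(iv$to, states))
  if (anyNA(a) || anyNA(b)) {
    stop("observed dilatation outside the model's state space", call. = FALSE)
  }
  key <- a * 100L + b
  lapply(split(seq_along(key), key), function(idx)
    list(a = a[idx[1]], b = b[idx[1]], dt = iv$dt[idx]))
}

# Closed-form transition probabilities for one grouped (a, b) pair with a
# round-off reliability estimate; falls back to the matrix exponential for
# the interval lengths where alternating-sign cancellation dominates.
.pair_prob <- function(rates, a, b, dt, Q = NULL) {
  m <- length(rates)
  if (b == a) return(pmax(exp(-rates[a] * dt), 1e-300))
  if (b <= m) {
    lam <- rates[a:b]
    k <- length(lam)
    coef <- vapply(seq_len(k), function(i)
      prod(lam[-k]) / prod(lam[-i] - lam[i]), numeric(1))
    terms <- sweep(exp(-outer(dt, lam)), 2, coef, `*`)
    p <- rowSums(terms)
    mag <- rowSums(abs(terms))
    bad <- !is.finite(p) | p <= mag * 1e-9 | p > 1
  } else {
    p <- rep(1, length(dt))
    mag <- rep(0, length(dt))
    for (j in a:m) {
      pj <- .pair_prob(rates, a, j, dt, Q)
      p <- p - pj
      mag <- mag + abs(pj)
    }
    bad <- !is.finite(p) | p <= mag * 1e-9 | p > 1
  }
  if (any(bad)) {
    if (is.null(Q)) Q <- build_generator(rates)
    p[bad] <- vapply(dt[bad], function(h)
      as.matrix(Matrix::expm(Q * h))[a, b], numeric(1))
  }
  pmin(1, pmax(p, 1e-300))
}

# rates per transient state; grp = .group_intervals() output (or raw
# intervals together with states)
.panel_loglik <- function(rates, states, iv = NULL, grp = NULL) {
  if (is.null(grp)) grp <- .group_intervals(states, iv)
  if (any(!is.finite(rates)) || any(rates <= 0)) return(-Inf)
  Q <- if (.rates_distinct(rates, 1e-4)) NULL else build_generator(rates)
  ll <- 0
  for (g in grp) {
    ll <- ll + sum(log(.pair_prob(rates, g$a, g$b, g$dt, Q)))
  }
  ll
}

# number of observation pairs informative about each state's intensity:
# intervals with from <= s < to straddle state s
.transitions_per_state <- function(states, iv) {
  vapply(states, function(s) sum(iv$from <= s & iv$to > s), integer(1))
}

#' Fit transition intensities to panel-observed exam series
#'
#' Maximum-likelihood estimation of the per-centimetre transition intensities
#' of a progressive labour model from sparse panel data, by quasi-Newton
#' (BFGS) optimisation over log-intensities. Several starting points are used
#' to guard against flat likelihoods on sparse panels.
#'
#' @param exams Long-format exam table (`id`, `time_hours`, `dilatation_cm`;
#'   11 = childbirth observation). All observed dilatations below 11 must lie
#'   between 2 and 10 cm.
#' @param init_rates Optional named vector of starting intensities. Default:
#'   a crude overall progression-rate estimate for every state.
#' @param min_transitions Minimum number of observation pairs straddling each
#'   state; states with fewer raise an error naming them.
#' @param n_starts Number of starting points (the default start plus
#'   deterministic multiplicative offsets).
#' @return An object of class `labour_fit`: list with `model`
#'   (a [progressive_model()]), `log_likelihood`, `converged`,
#'   `n_transitions_used`.
#' @export
fit_rates <- function(exams, init_rates = NULL, min_transitions = 5L,
                      n_starts = 3L) {
  iv <- if (is.data.frame(exams) && all(c("from", "to", "dt") %in%
                                          names(exams))) exams else
    panel_intervals(exams)
  if (nrow(iv) == 0L) stop("no observation pairs to fit", call. = FALSE)
  lo <- min(iv$from)
  if (lo < 2L) stop("dilatations below 2 cm are outside the modelled range",
                    call. = FALSE)
  states <- seq.int(lo, 10L)
  ntr <- .transitions_per_state(states, iv)
  if (any(ntr < min_transitions)) {
    stop("insufficient observed transitions (< ", min_transitions,
         ") for state(s): ",
         paste(states[ntr < min_transitions], collapse = ", "),
         call. = FALSE)
  }
  if (is.null(init_rates)) {
    prog <- pmin(iv$to, 10L + 1L) - iv$from
    crude <- sum(prog) / max(sum(iv$dt), 1e-8)
    init_rates <- rep(max(crude, 1e-3), length(states))
  } else {
    if (!is.null(names(init_rates))) init_rates <- init_rates[as.character(states)]
    if (length(init_rates) != length(states) || anyNA(init_rates)) {
      stop("'init_rates' must supply one positive rate per state ",
           states[1], "..10", call. = FALSE)
    }
  }
  grp <- .group_intervals(states, iv)
  negll <- function(logr) -.panel_loglik(exp(logr), states, grp = grp)
  offsets <- c(1, 0.5, 2, 0.75, 1.5)[seq_len(max(1L, n_starts))]
  best <- NULL
  for (f in offsets) {
    opt <- stats::optim(log(init_rates * f), negll, method = "L-BFGS-B",
                        lower = -7, upper = 7,
                        control = list(maxit = 150, factr = 1e8))
    if (is.null(best) || opt$value < best$value - 1e-9) best <- opt
  }
  rates <- exp(best$par)
  names(rates) <- states
  structure(list(model = progressive_model(rates),
                 log_likelihood = -best$value,
                 converged = best$convergence == 0L,
                 n_transitions_used = nrow(iv)),
            class = "labour_fit")
}

#' @export
print.labour_fit <- function(x, ...) {
  cat("Progressive labour model fit\n")
  cat("  log-likelihood:", format(x$log_likelihood, digits = 8),
      " converged:", x$converged,
      " observation pairs:", x$n_transitions_used, "\n")
  print(round(x$model$rates, 4))
  invisible(x)
}

#' First-passage-time quantile between two dilatations
#'
#' The p-th quantile (in hours) of the time to progress from `from` cm to
#' `to` cm under a progressive model. The first-passage time is
#' hypoexponential (a sum of independent exponential sojourns); its CDF is
#' evaluated through the absorbing entry of the matrix-exponential transition
#' matrix of the sub-chain and inverted numerically.
#'
#' @param model A [progressive_model()].
#' @param from,to Dilatations in cm, `from < to`, both within the model's
#'   states (`to` may be at most 10).
#' @param p Probability in (0, 1).
#' @param tol Absolute tolerance of the root search, in hours.
#' @return Time in hours.
#' @examples
#' m <- progressive_model(rep(1, 9))
#' first_passage_quantile(m, 4, 5, 0.5)   # log(2)
#' @export
first_passage_quantile <- function(model, from = 4L, to, p, tol = 1e-6) {
  stopifnot(inherits(model, "progressive_model"))
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1) {
    stop("'p' must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!(from %in% model$states) || !(to %in% c(model$states))) {
    stop("'from' and 'to' must be modelled dilatations", call. = FALSE)
  }
  if (from >= to) stop("'from' must be below 'to'", call. = FALSE)
  lam <- model$rates[as.character(seq.int(from, to - 1L))]
  Q <- build_generator(lam)
  k <- length(lam) + 1L
  cdf <- function(t) transition_matrix(Q, t)[1L, k]
  upper <- sum(1 / lam) * 2 + 1
  while (cdf(upper) < p) upper <- upper * 2
  stats::uniroot(function(t) cdf(t) - p, lower = 0, upper = upper,
                 tol = tol)$root
}

#' Customised percentile labour curve
#'
#' Builds the labour curve for one obstetric subgroup and percentile: for
#' each dilatation d in 5..10 cm, the p-th percentile of the first-passage
#' time from 4 cm to d cm under the subgroup's fitted progressive model.
#' Times are anchored at 4 cm (hour zero).
#'
#' @param model A converged [progressive_model()] covering states 4..10 cm.
#' @param percentile One of 50, 60, 70, 80, 90, 95 (any value in (0, 100)
#'   is accepted).
#' @param subgroup Optional subgroup label carried in the result.
#' @return An object of class `percentile_curve`: data frame with columns
#'   `dilatation_cm` (4..10; 4 cm at 0 hours) and `hours_from_4cm`, with
#'   attributes `subgroup` and `percentile`.
#' @export
percentile_curve <- function(model, percentile, subgroup = NULL) {
  stopifnot(inherits(model, "progressive_model"))
  if (percentile <= 0 || percentile >= 100) {
    stop("'percentile' must lie strictly between 0 and 100", call. = FALSE)
  }
  if (model$states[1] > 4L) {
    stop("model must include state 4 cm to anchor curves", call. = FALSE)
  }
  d <- 5:10
  q <- vapply(d, function(dd)
    first_passage_quantile(model, 4L, dd, percentile / 100), numeric(1))
  out <- data.frame(dilatation_cm = c(4L, d), hours_from_4cm = c(0, q))
  attr(out, "subgroup") <- subgroup
  attr(out, "percentile") <- percentile
  class(out) <- c("percentile_curve", "data.frame")
  out
}

# quantile lookup q_p(4 -> d) from a percentile_curve; d = 4 gives 0
.curve_q <- function(curve, d) {
  idx <- match(d, curve$dilatation_cm)
  if (anyNA(idx)) stop("dilatation outside curve range", call. = FALSE)
  curve$hours_from_4cm[idx]
}

#' Classify an exam series against a percentile labour curve
#'
#' A woman crosses the percentile curve if, at any examination after her
#' active-phase anchor (first exam at >= 4 cm), she took longer to reach the
#' observed dilatation than the curve's percentile time. Women anchored above
#' 4 cm are offset by the curve's own quantile to the anchor dilatation, so
#' that time is measured on the curve's 4-cm clock. Boundary equality counts
#' as not crossed; crossing is evaluated only at observed exam points.
#'
#' @param exams Data frame with columns `time_hours`, `dilatation_cm` for one
#'   woman, sorted by time (dilatations above 10 are ignored).
#' @param curve A [percentile_curve()].
#' @return An object of class `crossing_result`: list with `crossed`
#'   (TRUE/FALSE, or NA when no anchor exists) and
#'   `first_crossing_exam_index` (index into `exams`, or NA).
#' @export
crossed_percentile_curve <- function(exams, curve) {
  stopifnot(inherits(curve, "percentile_curve"))
  anchor <- anchor_active_phase(exams)
  if (is.null(anchor)) {
    return(structure(list(crossed = NA, first_crossing_exam_index = NA_integer_),
                     class = "crossing_result"))
  }
  offset <- .curve_q(curve, anchor$anchor_dilatation)
  idx <- which(exams$time_hours > anchor$anchor_time &
                 exams$dilatation_cm >= 4 & exams$dilatation_cm <= 10)
  crossed_at <- NA_integer_
  for (i in idx) {
    tau <- exams$time_hours[i] - anchor$anchor_time
    if (tau + offset > .curve_q(curve, exams$dilatation_cm[i]) + 1e-9) {
      crossed_at <- i
      break
    }
  }
  structure(list(crossed = !is.na(crossed_at),
                 first_crossing_exam_index = crossed_at),
            class = "crossing_result")
}

#' @export
print.crossing_result <- function(x, ...) {
  if (is.na(x$crossed)) {
    cat("not evaluable (no active-phase anchor)\n")
  } else if (x$crossed) {
    cat("crossed at exam index", x$first_crossing_exam_index, "\n")
  } else cat("not crossed\n")
  invisible(x)
}
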