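#' Default per-subgroup transition-intensity table
#'
#' Per-centimetre transition intensities (1/hours) for each of the twelve
#' modelled obstetric subgroups (Robson groups 1-5 and 10, split by
#' augmentation; `"3N"` = group 3, not augmented). The default table encodes
#' the qualitative structure of facility-based labour cohorts: dilatation
#' accelerates towards full dilatation, multiparous groups progress faster
#' than nulliparous ones, and augmented labours progress slightly faster
#' than unaugmented ones within a group. Values are configuration, not
#' constants: pass your own table via [cohort_config()].
#'
#' @return Numeric matrix, rows = subgroup labels ([analysis_subgroups()]),
#'   columns = states `"2"`..`"10"`.
#' @export
default_rate_table <- function() {
  base <- c(`2` = 0.50, `3` = 0.60, `4` = 0.70, `5` = 0.85, `6` = 1.00,
            `7` = 1.20, `8` = 1.40, `9` = 1.60, `10` = 1.20)
  grp_mult <- c(`1` = 1.00, `2` = 0.95, `3` = 1.45, `4` = 1.35,
                `5` = 1.15, `10` = 1.30)
  aug_mult <- c(A = 1.05, N = 1.00)
  sg <- analysis_subgroups()
  tab <- t(vapply(sg, function(s) {
    g <- sub("[AN]$", "", s)
    a <- substr(s, nchar(s), nchar(s))
    base * grp_mult[[g]] * aug_mult[[a]]
  }, numeric(length(base))))
  colnames(tab) <- names(base)
  tab
}

#' Configuration of the synthetic labour cohort generator
#'
#' Assembles and validates the parameters of the synthetic cohort generator.
#' The defaults reproduce the statistical structure of a large multicentre
#' intrapartum cohort from high-burden facility settings: a 2.2% severe
#' adverse birth outcome rate, 35.1% labour augmentation, 13.2% intrapartum
#' caesarean section, 89.9% spontaneous onset, 40.8% nulliparity, 5.4%
#' previous caesarean among parous women, 98.6% cephalic presentation,
#' admission at no more than 6 cm of dilatation, and a mean of 2.22 cervical
#' assessments between 4 and 10 cm.
#'
#' Inter-woman variability in labour speed is modelled by a gamma frailty
#' (mean 1) multiplying all of a woman's transition intensities; the
#' standardized log-frailty is the latent "slowness" score through which a
#' weak association between slow labour and adverse outcome is induced
#' (`slow_labour_odds_multiplier` is the odds ratio per standard deviation
#' of slowness).
#'
#' @param n_women Number of women (>= 1).
#' @param seed Integer seed; identical config + seed gives an identical
#'   cohort.
#' @param p_adverse_baseline Baseline probability of a severe adverse birth
#'   outcome.
#' @param slow_labour_odds_multiplier Odds ratio of adverse outcome per SD
#'   of the latent slowness score (1 = no association).
#' @param p_augmentation,p_caesarean,p_spontaneous_onset,p_nulliparous
#'   Marginal probabilities.
#' @param p_prev_caesarean_given_parous,p_cephalic,p_preterm Marginal
#'   probabilities (preterm = birth before 37 completed weeks).
#' @param admission_probs_spontaneous Named probabilities over admission
#'   dilatations 2..6 cm for spontaneous labour.
#' @param admission_probs_induced Named probabilities over entry dilatations
#'   for induced labour.
#' @param exam_count_mean Target mean number of cervical assessments while
#'   dilatation is in [4, 10) cm, among women reaching 4 cm.
#' @param exam_count_sd Nominal dispersion of that count (descriptive; the
#'   generator uses a zero-truncated Poisson calibrated to the mean).
#' @param subgroup_rate_table Matrix of per-state intensities per modelled
#'   subgroup; see [default_rate_table()].
#' @param frailty_shape Shape of the gamma frailty (rate = shape, so the
#'   frailty has mean 1); smaller values give more heterogeneous labours.
#' @param cs_decision_frac Range (length 2, within (0, 1]) of the uniform
#'   fraction of the latent labour duration at which an intrapartum
#'   caesarean is decided.
#' @param cs_delivery_delay_hours Decision-to-delivery interval for
#'   caesarean births.
#' @return Validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_women = 10000L,
                          seed = 1L,
                          p_adverse_baseline = 0.022,
                          slow_labour_odds_multiplier = 1.4,
                          p_augmentation = 0.351,
                          p_caesarean = 0.132,
                          p_spontaneous_onset = 0.899,
                          p_nulliparous = 0.408,
                          p_prev_caesarean_given_parous = 0.054,
                          p_cephalic = 0.986,
                          p_preterm = 0.045,
                          admission_probs_spontaneous =
                            c(`2` = 0.08, `3` = 0.17, `4` = 0.25,
                              `5` = 0.30, `6` = 0.20),
                          admission_probs_induced = c(`2` = 0.6, `3` = 0.4),
                          exam_count_mean = 2.22,
                          exam_count_sd = 1.02,
                          subgroup_rate_table = default_rate_table(),
                          frailty_shape = 4,
                          cs_decision_frac = c(0.2, 1),
                          cs_delivery_delay_hours = 0.75) {
  cfg <- list(n_women = as.integer(n_women), seed = as.integer(seed),
              p_adverse_baseline = p_adverse_baseline,
              slow_labour_odds_multiplier = slow_labour_odds_multiplier,
              p_augmentation = p_augmentation, p_caesarean = p_caesarean,
              p_spontaneous_onset = p_spontaneous_onset,
              p_nulliparous = p_nulliparous,
              p_prev_caesarean_given_parous = p_prev_caesarean_given_parous,
              p_cephalic = p_cephalic, p_preterm = p_preterm,
              admission_probs_spontaneous = admission_probs_spontaneous,
              admission_probs_induced = admission_probs_induced,
              exam_count_mean = exam_count_mean,
              exam_count_sd = exam_count_sd,
              subgroup_rate_table = subgroup_rate_table,
              frailty_shape = frailty_shape,
              cs_decision_frac = cs_decision_frac,
              cs_delivery_delay_hours = cs_delivery_delay_hours)
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

#' Validate a cohort configuration
#'
#' @param cfg A list of generator parameters (see [cohort_config()]).
#' @return The configuration, invisibly; invalid configurations raise an
#'   error listing every offending field.
#' @export
validate_cohort_config <- function(cfg) {
  bad <- character(0)
  probs <- c("p_adverse_baseline", "p_augmentation", "p_caesarean",
             "p_spontaneous_onset", "p_nulliparous",
             "p_prev_caesarean_given_parous", "p_cephalic", "p_preterm")
  for (nm in probs) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      bad <- c(bad, nm)
    }
  }
  if (!is.numeric(cfg$n_women) || cfg$n_women < 1) bad <- c(bad, "n_women")
  if (!is.numeric(cfg$slow_labour_odds_multiplier) ||
      cfg$slow_labour_odds_multiplier <= 0) {
    bad <- c(bad, "slow_labour_odds_multiplier")
  }
  for (nm in c("admission_probs_spontaneous", "admission_probs_induced")) {
    v <- cfg[[nm]]
    if (is.null(names(v)) || any(v < 0) ||
        abs(sum(v) - 1) > 1e-8 ||
        any(!as.integer(names(v)) %in% 2:6)) {
      bad <- c(bad, nm)
    }
  }
  if (!is.numeric(cfg$exam_count_mean) || cfg$exam_count_mean <= 1) {
    bad <- c(bad, "exam_count_mean")
  }
  rt <- cfg$subgroup_rate_table
  if (!is.matrix(rt) || !all(analysis_subgroups() %in% rownames(rt)) ||
      !identical(colnames(rt), as.character(2:10)) ||
      any(!is.finite(rt)) || any(rt <= 0)) {
    bad <- c(bad, "subgroup_rate_table")
  }
  if (!is.numeric(cfg$frailty_shape) || cfg$frailty_shape <= 0) {
    bad <- c(bad, "frailty_shape")
  }
  if (length(cfg$cs_decision_frac) != 2L ||
      any(cfg$cs_decision_frac <= 0) || any(cfg$cs_decision_frac > 1) ||
      cfg$cs_decision_frac[1] > cfg$cs_decision_frac[2]) {
    bad <- c(bad, "cs_decision_frac")
  }
  if (length(bad)) {
    stop("invalid cohort configuration field(s): ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  invisible(cfg)
}

# mean of a zero-truncated Poisson is mu / (1 - exp(-mu)); invert for mu
.ztpois_mu <- function(target_mean) {
  stats::uniroot(function(mu) mu / (1 - exp(-mu)) - target_mean,
                 lower = 1e-8, upper = 4 * target_mean, tol = 1e-10)$root
}

.rztpois <- function(n, mu) {
  # inverse-CDF draw restricted to k >= 1
  u <- stats::runif(n, stats::dpois(0, mu), 1)
  stats::qpois(u, mu)
}

#' Simulate a latent labour trajectory
#'
#' Forward-simulates the progressive labour model: starting from the
#' admission dilatation, the sojourn in each centimetre state is exponential
#' with that state's transition intensity, each intermediate centimetre is
#' visited exactly once, and the path ends in the absorbing childbirth
#' state (coded 11).
#'
#' @param rates Named vector of transition intensities covering at least
#'   states `start_state`..10.
#' @param start_state Admission dilatation in cm (2..10).
#' @return Data frame with columns `state` (cm; 11 = birth) and `entry_time`
#'   (hours since admission).
#' @export
simulate_trajectory <- function(rates, start_state) {
  states <- seq.int(start_state, 10L)
  lam <- rates[as.character(states)]
  if (anyNA(lam) || any(lam <= 0)) {
    stop("missing or non-positive rate for reachable state(s): ",
         paste(states[is.na(lam) | lam <= 0], collapse = ", "),
         call. = FALSE)
  }
  sojourn <- stats::rexp(length(lam), rate = lam)
  data.frame(state = c(states, 11L),
             entry_time = c(0, cumsum(sojourn)))
}

# latent state of a path at time t (step function; right-continuous)
.state_at <- function(path, t) {
  path$state[findInterval(t, path$entry_time)]
}

#' Observe a latent trajectory as a sparse exam series
#'
#' Turns a full latent path into the panel data a partograph records: an
#' admission exam at time zero, plus examinations at either a fixed schedule
#' or at random times while dilatation is in the active-phase window
#' [4, 10) cm. Recorded dilatations equal the latent state at the exam time.
#'
#' @param path Latent path from [simulate_trajectory()].
#' @param times Optional explicit exam times (hours); times at or past birth
#'   (or `truncate_time`) are dropped.
#' @param n_window_exams Number of random exams to place uniformly in the
#'   active-phase window (ignored when `times` is given).
#' @param truncate_time Censoring time (e.g. a caesarean decision); no exam
#'   is recorded at or after it.
#' @return Data frame `time_hours`, `dilatation_cm`, sorted, starting with
#'   the admission exam.
#' @export
observe_panel <- function(path, times = NULL, n_window_exams = 0L,
                          truncate_time = Inf) {
  birth_time <- path$entry_time[path$state == 11L]
  end <- min(birth_time, truncate_time)
  if (!is.null(times)) {
    tt <- sort(times[times >= 0 & times < end])
  } else if (n_window_exams > 0L) {
    t4 <- if (path$state[1] >= 4L) 0 else
      path$entry_time[match(4L, path$state)]
    t10 <- path$entry_time[match(10L, path$state)]
    hi <- min(t10, end, na.rm = TRUE)
    tt <- if (is.finite(hi) && hi > t4) {
      sort(stats::runif(n_window_exams, t4, hi))
    } else numeric(0)
  } else {
    tt <- numeric(0)
  }
  tt <- unique(c(0, tt))
  data.frame(time_hours = tt, dilatation_cm = .state_at(path, tt))
}

#' Assign severe adverse birth outcomes from latent labour speed
#'
#' Bernoulli outcome with
#' `logit(p) = logit(p_adverse_baseline) + log(slow_labour_odds_multiplier) * score`,
#' where `score` is the standardized latent slowness score (positive = slower
#' labour). With a multiplier of 1 the outcome is independent of labour
#' speed and every curve-crossing classifier's diagnostic odds ratio tends
#' to 1.
#'
#' The intercept is calibrated (by quadrature over the frailty distribution)
#' so that the marginal adverse rate equals `p_adverse_baseline` under the
#' default configuration, rather than drifting upwards through
#' logistic-normal mixing.
#'
#' @param speed_score Numeric vector of standardized slowness scores.
#' @param config A [cohort_config()].
#' @return Integer 0/1 vector of outcome flags.
#' @export
assign_outcome <- function(speed_score, config) {
  stopifnot(all(is.finite(speed_score)))
  beta <- log(config$slow_labour_odds_multiplier)
  # population quantiles of the standardized slowness score
  shape <- config$frailty_shape
  qs <- -log(stats::qgamma(seq(0.0005, 0.9995, by = 0.001),
                           shape = shape, rate = shape)) /
    sqrt(trigamma(shape))
  marginal <- function(b0) mean(stats::plogis(b0 + beta * qs))
  target <- config$p_adverse_baseline
  b0 <- stats::uniroot(function(b) marginal(b) - target,
                       lower = stats::qlogis(target) - 5,
                       upper = stats::qlogis(target) + 1,
                       tol = 1e-10)$root
  stats::rbinom(length(speed_score), 1L, stats::plogis(b0 + beta * speed_score))
}

#' Simulate a synthetic labour cohort
#'
#' Generates a full cohort: obstetric covariates with the configured
#' marginals, Robson classification, per-woman latent labour trajectories
#' (subgroup intensities scaled by a gamma frailty), sparse cervical-exam
#' panels, intrapartum caesarean censoring, and severe adverse outcomes
#' weakly associated with slow labour. Bit-identical output under an
#' identical configuration and seed.
#'
#' @param config A [cohort_config()].
#' @return Object of class `labour_cohort`: list with `women` (one row per
#'   woman: covariates, flags, `birth_time`, `robson_group`,
#'   `analysis_subgroup`) and `exams` (long table `id`, `time_hours`,
#'   `dilatation_cm`).
#' @examples
#' coh <- simulate_cohort(cohort_config(n_women = 50, seed = 7))
#' head(coh$women)
#' @export
simulate_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n <- config$n_women

  nullip <- stats::rbinom(n, 1L, config$p_nulliparous)
  parity <- ifelse(nullip == 1L, 0L,
                   1L + stats::rpois(n, 1.2))
  prev_cs <- integer(n)
  parous <- which(nullip == 0L)
  prev_cs[parous] <- stats::rbinom(length(parous), 1L,
                                   config$p_prev_caesarean_given_parous)
  onset <- ifelse(stats::rbinom(n, 1L, config$p_spontaneous_onset) == 1L,
                  "spontaneous", "induced")
  preterm <- stats::rbinom(n, 1L, config$p_preterm)
  term_probs <- c(`37` = 0.08, `38` = 0.18, `39` = 0.30, `40` = 0.28,
                  `41` = 0.12, `42` = 0.04)
  gest <- integer(n)
  gest[preterm == 1L] <- sample(34:36, sum(preterm), replace = TRUE)
  gest[preterm == 0L] <- sample(as.integer(names(term_probs)),
                                sum(preterm == 0L), replace = TRUE,
                                prob = term_probs)
  cephalic <- stats::rbinom(n, 1L, config$p_cephalic)
  presentation <- ifelse(cephalic == 1L, "cephalic",
                         sample(c("breech", "transverse"), n, replace = TRUE,
                                prob = c(0.8, 0.2)))
  augmentation <- stats::rbinom(n, 1L, config$p_augmentation)
  caesarean <- stats::rbinom(n, 1L, config$p_caesarean)

  robson <- classify_robson(parity, prev_cs, onset, gest, presentation)
  subgroup <- assign_subgroup(robson, augmentation)

  adm <- integer(n)
  sp <- onset == "spontaneous"
  adm[sp] <- sample(as.integer(names(config$admission_probs_spontaneous)),
                    sum(sp), replace = TRUE,
                    prob = config$admission_probs_spontaneous)
  adm[!sp] <- sample(as.integer(names(config$admission_probs_induced)),
                     sum(!sp), replace = TRUE,
                     prob = config$admission_probs_induced)

  shape <- config$frailty_shape
  frailty <- stats::rgamma(n, shape = shape, rate = shape)
  speed_score <- -log(frailty) / sqrt(trigamma(shape))
  outcome <- assign_outcome(speed_score, config)

  # women outside the modelled subgroups labour at the average of the
  # unaugmented term-group intensities
  rt <- config$subgroup_rate_table
  pooled_rates <- colMeans(rt[c("1N", "3N"), , drop = FALSE])
  mu <- .ztpois_mu(config$exam_count_mean)
  k_window <- .rztpois(n, mu)
  cs_frac <- stats::runif(n, config$cs_decision_frac[1],
                          config$cs_decision_frac[2])

  exam_list <- vector("list", n)
  birth_time <- numeric(n)
  for (i in seq_len(n)) {
    rates_i <- if (is.na(subgroup[i])) pooled_rates else rt[subgroup[i], ]
    path <- simulate_trajectory(rates_i * frailty[i], adm[i])
    latent_birth <- path$entry_time[path$state == 11L]
    trunc <- if (caesarean[i] == 1L) cs_frac[i] * latent_birth else Inf
    n_extra <- k_window[i] - as.integer(adm[i] >= 4L)
    ex <- observe_panel(path, n_window_exams = max(0L, n_extra),
                        truncate_time = trunc)
    t10 <- path$entry_time[match(10L, path$state)]
    if (!is.na(t10) && t10 < trunc) {
      ex <- rbind(ex, data.frame(time_hours = t10, dilatation_cm = 10L))
      ex <- ex[order(ex$time_hours), ]
      ex <- ex[!duplicated(ex$time_hours), ]
    }
    birth_time[i] <- if (caesarean[i] == 1L) {
      trunc + config$cs_delivery_delay_hours
    } else latent_birth
    exam_list[[i]] <- ex
  }
  n_ex <- vapply(exam_list, nrow, integer(1))
  exams <- data.frame(id = rep(seq_len(n), n_ex),
                      time_hours = unlist(lapply(exam_list,
                                                 `[[`, "time_hours")),
                      dilatation_cm = unlist(lapply(exam_list,
                                                    `[[`, "dilatation_cm")))
  women <- data.frame(id = seq_len(n), parity = parity,
                      previous_caesarean = prev_cs, onset = onset,
                      gestational_weeks = gest, presentation = presentation,
                      augmentation = augmentation, caesarean = caesarean,
                      severe_adverse_outcome = outcome,
                      birth_time = birth_time,
                      robson_group = robson, analysis_subgroup = subgroup,
                      stringsAsFactors = FALSE)
  structure(list(women = women, exams = exams, config = config),
            class = "labour_cohort")
}

#' @export
print.labour_cohort <- function(x, ...) {
  cat("Synthetic labour cohort:", nrow(x$women), "women,",
      nrow(x$exams), "cervical exams\n")
  cat("  adverse outcomes:",
      sprintf("%.1f%%", 100 * mean(x$women$severe_adverse_outcome)),
      " augmentation:", sprintf("%.1f%%", 100 * mean(x$women$augmentation)),
      " caesarean:", sprintf("%.1f%%", 100 * mean(x$women$caesarean)), "\n")
  invisible(x)
}

#' Write a cohort to woman-level and exam-level CSV files
#'
#' @param cohort A [simulate_cohort()] result (or a compatible list with
#'   `women` and `exams` data frames).
#' @param women_csv,exams_csv Output paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, women_csv, exams_csv) {
  w <- cohort$women
  cols <- c("id", "parity", "previous_caesarean", "onset",
            "gestational_weeks", "presentation", "augmentation",
            "caesarean", "severe_adverse_outcome", "birth_time")
  utils::write.csv(w[, cols], women_csv, row.names = FALSE, quote = FALSE,
                   na = "")
  utils::write.csv(cohort$exams, exams_csv, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(c(women_csv, exams_csv))
}

#' Read a cohort from woman-level and exam-level CSV files
#'
#' @param women_csv,exams_csv Paths written by [write_cohort()] (or any files
#'   with the same schemas).
#' @return A `labour_cohort` (without a generator config).
#' @export
read_cohort <- function(women_csv, exams_csv) {
  women <- utils::read.csv(women_csv, stringsAsFactors = FALSE)
  exams <- utils::read.csv(exams_csv, stringsAsFactors = FALSE)
  need_w <- c("id", "parity", "previous_caesarean", "onset",
              "gestational_weeks", "presentation", "augmentation",
              "caesarean", "severe_adverse_outcome", "birth_time")
  need_e <- c("id", "time_hours", "dilatation_cm")
  if (!all(need_w %in% names(women))) {
    stop("woman-level CSV is missing column(s): ",
         paste(setdiff(need_w, names(women)), collapse = ", "),
         call. = FALSE)
  }
  if (!all(need_e %in% names(exams))) {
    stop("exam-level CSV is missing column(s): ",
         paste(setdiff(need_e, names(exams)), collapse = ", "),
         call. = FALSE)
  }
  structure(list(women = women, exams = exams, config = NULL),
            class = "labour_cohort")
}
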