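# Shared fixtures, built once per test run and cached across test files.

.fixtures <- new.env(parent = emptyenv())

# calibrated cohort at the study scale, for the acceptance-level checks
study_cohort <- function() {
  if (is.null(.fixtures$cohort10k)) {
    .fixtures$cohort10k <- simulate_cohort(cohort_config(n_women = 10000L,
                                                         seed = 20260925L))
  }
  .fixtures$cohort10k
}

study_report <- function() {
  if (is.null(.fixtures$report10k)) {
    .fixtures$report10k <- run_analysis(study_cohort())
  }
  .fixtures$report10k
}

# small cohort for fast structural tests
small_cohort <- function() {
  if (is.null(.fixtures$cohort_small)) {
    .fixtures$cohort_small <- simulate_cohort(cohort_config(n_women = 1200L,
                                                            seed = 99L))
  }
  .fixtures$cohort_small
}

small_report <- function() {
  if (is.null(.fixtures$report_small)) {
    .fixtures$report_small <- run_analysis(small_cohort())
  }
  .fixtures$report_small
}

# random monotone exam series for property-style tests
random_exam_series <- function(n_exams = sample(2:6, 1)) {
  t <- sort(round(cumsum(stats::rexp(n_exams, 0.4)), 2))
  d <- sort(sample(2:10, n_exams, replace = TRUE))
  data.frame(time_hours = t - t[1], dilatation_cm = d)
}

# closed-form hypoexponential CDF (sum of exponentials with distinct rates),
# independent oracle for the matrix-exponential path
hypoexp_cdf_oracle <- function(rates, t) {
  k <- length(rates)
  if (k == 1L) return(stats::pexp(t, rates))
  coefs <- vapply(seq_len(k), function(i)
    prod(rates[-i] / (rates[-i] - rates[i])), numeric(1))
  1 - as.vector(exp(-outer(t, rates)) %*% coefs)
}
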