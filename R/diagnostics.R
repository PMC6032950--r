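#' Cross-tabulate a binary classifier against outcomes
#'
#' Builds the 2x2 contingency table of a binary classifier (e.g. "crossed
#' the alert line") against the severe-adverse-outcome flag. Pairs in which
#' either entry is missing (not-evaluable women) are dropped pairwise and
#' counted.
#'
#' @param classifier Logical/0-1 vector, `NA` = not evaluable.
#' @param outcome Logical/0-1 vector of the same length.
#' @return An object of class `two_by_two`: list with integer `tp`, `fp`,
#'   `fn`, `tn` (tp = classifier positive and outcome present) and
#'   `n_dropped`.
#' @export
tabulate_2x2 <- function(classifier, outcome) {
  if (length(classifier) != length(outcome)) {
    stop("'classifier' and 'outcome' must have equal length", call. = FALSE)
  }
  keep <- !is.na(classifier) & !is.na(outcome)
  cl <- as.logical(classifier[keep])
  oc <- as.logical(outcome[keep])
  structure(list(tp = sum(cl & oc), fp = sum(cl & !oc),
                 fn = sum(!cl & oc), tn = sum(!cl & !oc),
                 n_dropped = sum(!keep)),
            class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(c("classifier +", "classifier -"),
                              c("outcome +", "outcome -")))
  print(m)
  if (x$n_dropped > 0) cat("(", x$n_dropped, "not-evaluable pairs dropped )\n")
  invisible(x)
}

# Wilson score interval for a binomial proportion (no continuity correction)
.wilson_ci <- function(x, n, conf_level = 0.95) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, centre - half), min(1, centre + half))
}

#' Diagnostic accuracy statistics from a 2x2 table
#'
#' Sensitivity, specificity, positive and negative likelihood ratios,
#' diagnostic odds ratio and Youden's J statistic, each with a 95%
#' confidence interval, plus the classifier's point in ROC space.
#'
#' Interval methods: Wilson score for the proportions (sensitivity,
#' specificity); Woolf log interval for the diagnostic odds ratio; Simel log
#' intervals for the likelihood ratios; a normal approximation with
#' `Var(J) = se(sens)^2 + se(spec)^2` for Youden's J. When any cell is zero,
#' a Haldane-Anscombe 0.5 correction is applied to all four cells for the
#' ratio statistics (and their intervals) only.
#'
#' @param counts A [tabulate_2x2()] result, or `tp` given as a count with
#'   `fp`, `fn`, `tn`.
#' @param tp,fp,fn,tn Cell counts (used when `counts` is missing).
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `accuracy_result`: list of length-3 numeric
#'   vectors `(estimate, lower, upper)` for `sensitivity`, `specificity`,
#'   `plr`, `nlr`, `dor`, `youden_j`, plus `roc_point = c(fpr, tpr)` and the
#'   `counts`.
#' @examples
#' accuracy_stats(tp = 110, fp = 4053, fn = 84, tn = 4242)
#' @export
accuracy_stats <- function(counts = NULL, tp, fp, fn, tn,
                           conf_level = 0.95) {
  if (!is.null(counts)) {
    if (inherits(counts, "two_by_two")) {
      tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
    } else if (is.numeric(counts) && length(counts) == 1L) {
      tp <- counts   # called as accuracy_stats(tp, fp, fn, tn)
    } else stop("'counts' must be a two_by_two object", call. = FALSE)
  }
  cells <- c(tp, fp, fn, tn)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  if (tp + fn < 1 || fp + tn < 1) {
    stop("both outcome margins must be non-empty", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  sens <- tp / (tp + fn)
  spec <- tn / (fp + tn)
  sens_ci <- .wilson_ci(tp, tp + fn, conf_level)
  spec_ci <- .wilson_ci(tn, fp + tn, conf_level)

  # ratio statistics on (possibly) corrected cells
  cc <- if (any(cells == 0)) cells + 0.5 else cells
  a <- cc[1]; b <- cc[2]; c_ <- cc[3]; d <- cc[4]
  sens_c <- a / (a + c_); spec_c <- d / (b + d)
  plr <- sens_c / (1 - spec_c)
  nlr <- (1 - sens_c) / spec_c
  dor <- (a * d) / (b * c_)
  se_lnplr <- sqrt(1 / a - 1 / (a + c_) + 1 / b - 1 / (b + d))
  se_lnnlr <- sqrt(1 / c_ - 1 / (a + c_) + 1 / d - 1 / (b + d))
  se_lndor <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  plr_ci <- plr * exp(c(-1, 1) * z * se_lnplr)
  nlr_ci <- nlr * exp(c(-1, 1) * z * se_lnnlr)
  dor_ci <- dor * exp(c(-1, 1) * z * se_lndor)

  j <- sens + spec - 1
  se_j <- sqrt(sens * (1 - sens) / (tp + fn) + spec * (1 - spec) / (fp + tn))
  j_ci <- j + c(-1, 1) * z * se_j

  structure(list(
    sensitivity = c(estimate = sens, lower = sens_ci[1], upper = sens_ci[2]),
    specificity = c(estimate = spec, lower = spec_ci[1], upper = spec_ci[2]),
    plr = c(estimate = plr, lower = plr_ci[1], upper = plr_ci[2]),
    nlr = c(estimate = nlr, lower = nlr_ci[1], upper = nlr_ci[2]),
    dor = c(estimate = dor, lower = dor_ci[1], upper = dor_ci[2]),
    youden_j = c(estimate = j, lower = j_ci[1], upper = j_ci[2]),
    roc_point = c(fpr = 1 - spec, tpr = sens),
    counts = c(tp = tp, fp = fp, fn = fn, tn = tn),
    conf_level = conf_level), class = "accuracy_result")
}

.fmt_pct <- function(v) sprintf("%.1f%% (%.1f-%.1f)",
                                100 * v[1], 100 * v[2], 100 * v[3])
.fmt_ratio <- function(v) sprintf("%.2f (%.2f-%.2f)", v[1], v[2], v[3])

#' @export
print.accuracy_result <- function(x, ...) {
  cat("Diagnostic accuracy (", round(100 * x$conf_level), "% CI )\n",
      sep = "")
  cat("  counts tp/fp/fn/tn:", paste(x$counts, collapse = "/"), "\n")
  cat("  sensitivity:", .fmt_pct(x$sensitivity), "\n")
  cat("  specificity:", .fmt_pct(x$specificity), "\n")
  cat("  +LR:", .fmt_ratio(x$plr), "  -LR:", .fmt_ratio(x$nlr), "\n")
  cat("  DOR:", .fmt_ratio(x$dor), "\n")
  cat("  Youden J:", .fmt_pct(x$youden_j), "\n")
  invisible(x)
}

#' ROC-space table for a set of binary classifiers
#'
#' Each binary classifier occupies one point in ROC space: the unit square of
#' (false-positive rate, true-positive rate). Youden's J is the vertical
#' distance of the point above the chance diagonal.
#'
#' @param results Named list of [accuracy_stats()] results.
#' @return Data frame with columns `classifier`, `fpr`, `tpr`, `j`.
#' @export
roc_space_table <- function(results) {
  if (length(results) < 1L) stop("need at least one result", call. = FALSE)
  if (is.null(names(results))) names(results) <- seq_along(results)
  data.frame(
    classifier = names(results),
    fpr = vapply(results, function(r) unname(r$roc_point["fpr"]), numeric(1)),
    tpr = vapply(results, function(r) unname(r$roc_point["tpr"]), numeric(1)),
    j = vapply(results, function(r) unname(r$youden_j["estimate"]),
               numeric(1)),
    row.names = NULL)
}

#' Flat accuracy table for a set of classifiers
#'
#' @param results Named list of [accuracy_stats()] results.
#' @return Data frame with one row per classifier and columns for the cell
#'   counts and every statistic with its confidence bounds, suitable for CSV
#'   export.
#' @export
accuracy_table <- function(results) {
  if (is.null(names(results))) names(results) <- seq_along(results)
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(classifier = nm,
               tp = r$counts["tp"], fp = r$counts["fp"],
               fn = r$counts["fn"], tn = r$counts["tn"],
               sens = r$sensitivity[1], sens_lo = r$sensitivity[2],
               sens_hi = r$sensitivity[3],
               spec = r$specificity[1], spec_lo = r$specificity[2],
               spec_hi = r$specificity[3],
               plr = r$plr[1], plr_lo = r$plr[2], plr_hi = r$plr[3],
               nlr = r$nlr[1], nlr_lo = r$nlr[2], nlr_hi = r$nlr[3],
               dor = r$dor[1], dor_lo = r$dor[2], dor_hi = r$dor[3],
               j = r$youden_j[1], j_lo = r$youden_j[2],
               j_hi = r$youden_j[3], row.names = NULL)
  })
  do.call(rbind, rows)
}
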