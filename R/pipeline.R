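#' Configuration of the end-to-end accuracy analysis
#'
#' @param percentiles Percentile labour curves to evaluate (subset of
#'   50, 60, 70, 80, 90, 95).
#' @param min_exams_active_phase Minimum number of cervical assessments at
#'   4-10 cm for a woman to enter the reference-line analyses (default 2).
#' @param fit_on_outcome_free_only Fit subgroup models only on women without
#'   a severe adverse outcome (default TRUE), so the curves describe labour
#'   that ended well.
#' @param min_transitions Minimum observed transitions per state required to
#'   fit a subgroup model; subgroups below it are skipped and their women
#'   marked not evaluable for the curve classifiers.
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(percentiles = c(50, 60, 70, 80, 90, 95),
                            min_exams_active_phase = 2L,
                            fit_on_outcome_free_only = TRUE,
                            min_transitions = 5L) {
  if (length(percentiles) < 1L || any(percentiles <= 0 | percentiles >= 100)) {
    stop("'percentiles' must be a non-empty set within (0, 100)",
         call. = FALSE)
  }
  if (min_exams_active_phase < 2L) {
    stop("'min_exams_active_phase' must be at least 2", call. = FALSE)
  }
  structure(list(percentiles = sort(unique(percentiles)),
                 min_exams_active_phase = as.integer(min_exams_active_phase),
                 fit_on_outcome_free_only = isTRUE(fit_on_outcome_free_only),
                 min_transitions = as.integer(min_transitions)),
            class = "analysis_config")
}

# split a long exam table into per-woman sorted data frames, keyed by id
.split_exams <- function(exams, ids) {
  exams <- exams[order(exams$id, exams$time_hours), ]
  out <- split(exams[, c("time_hours", "dilatation_cm")], exams$id)
  out[as.character(ids)]
}

#' Run the full labour-progression accuracy analysis
#'
#' End-to-end pipeline: Robson/subgroup classification, WHO alert- and
#' action-line crossing on women with enough active-phase assessments,
#' per-subgroup progressive Markov model fitting on outcome-free women,
#' customised percentile curves, per-woman curve-crossing classification,
#' and diagnostic accuracy of every classifier against severe adverse birth
#' outcomes, with a ROC-space table.
#'
#' @param cohort A `labour_cohort` (from [simulate_cohort()] or
#'   [read_cohort()]), or a woman-level data frame.
#' @param exams Exam-level data frame (only when `cohort` is a data frame).
#' @param config An [analysis_config()].
#' @param verbose Log per-stage counts to stderr.
#' @return Object of class `labour_report`: list with `flow` (named filter
#'   counts), `classification` (woman-level flags), `fits`, `curves` (long
#'   data frame), `accuracy` (list of [accuracy_stats()] results),
#'   `accuracy_table`, `roc_table`, `skipped_subgroups`.
#' @export
run_analysis <- function(cohort, exams = NULL,
                         config = analysis_config(), verbose = FALSE) {
  if (inherits(cohort, "labour_cohort")) {
    women <- cohort$women
    exams <- cohort$exams
  } else {
    women <- cohort
    if (is.null(exams)) stop("'exams' required when 'cohort' is a data frame",
                             call. = FALSE)
  }
  stopifnot(is.data.frame(women), is.data.frame(exams))
  if (!all(c("robson_group", "analysis_subgroup") %in% names(women))) {
    women <- add_robson(women)
  }
  log_ <- function(...) if (verbose) message(...)
  n_input <- nrow(women)
  exl <- .split_exams(exams, women$id)
  n_active <- vapply(exl, function(e) {
    if (is.null(e)) 0L else
      sum(e$dilatation_cm >= 4 & e$dilatation_cm <= 10)
  }, integer(1))
  eligible <- n_active >= config$min_exams_active_phase
  log_("input women: ", n_input, "; with >= ",
       config$min_exams_active_phase, " active-phase exams: ",
       sum(eligible))

  alert <- rep(NA, n_input)
  action <- rep(NA, n_input)
  for (i in which(eligible)) {
    alert[i] <- crossed_alert_line(exl[[i]])$crossed
    action[i] <- crossed_action_line(exl[[i]])$crossed
  }

  # per-subgroup model fitting on (by default) outcome-free women; vaginal
  # births contribute a panel transition into the absorbing state
  fits <- list()
  skipped <- character(0)
  for (sg in analysis_subgroups()) {
    in_sg <- !is.na(women$analysis_subgroup) & women$analysis_subgroup == sg
    fit_on <- in_sg
    if (config$fit_on_outcome_free_only) {
      fit_on <- fit_on & women$severe_adverse_outcome == 0
    }
    ids <- women$id[fit_on]
    if (length(ids) == 0L) {
      skipped <- c(skipped, sg)
      next
    }
    ex_sg <- exams[exams$id %in% ids, ]
    vaginal <- women$id[fit_on & women$caesarean == 0 &
                          !is.na(women$birth_time)]
    if (length(vaginal)) {
      ex_sg <- rbind(ex_sg,
                     data.frame(id = vaginal,
                                time_hours =
                                  women$birth_time[match(vaginal, women$id)],
                                dilatation_cm = 11L))
    }
    fit <- tryCatch(fit_rates(ex_sg, min_transitions = config$min_transitions),
                    error = function(e) {
                      log_("subgroup ", sg, " skipped: ", conditionMessage(e))
                      NULL
                    })
    if (is.null(fit)) skipped <- c(skipped, sg) else fits[[sg]] <- fit
  }
  log_("fitted subgroups: ", length(fits), "; skipped: ",
       if (length(skipped)) paste(skipped, collapse = ", ") else "none")

  curves <- list()
  for (sg in names(fits)) {
    for (p in config$percentiles) {
      curves[[paste(sg, p, sep = "_")]] <-
        percentile_curve(fits[[sg]]$model, p, subgroup = sg)
    }
  }

  # vectorised curve-crossing classification: for every post-anchor exam of
  # every evaluable woman in a fitted subgroup, compare elapsed time on the
  # curve's 4-cm clock with the percentile quantile of the observed
  # dilatation (boundary equality = not crossed)
  pcols <- paste0("p", config$percentiles)
  crossed_p <- matrix(NA, n_input, length(pcols),
                      dimnames = list(NULL, pcols))
  ex <- exams[order(exams$id, exams$time_hours), ]
  sg_of <- women$analysis_subgroup[match(ex$id, women$id)]
  evaluable_w <- eligible & !is.na(women$analysis_subgroup) &
    women$analysis_subgroup %in% names(fits)
  use <- women$id[evaluable_w]
  act <- ex$dilatation_cm >= 4 & ex$dilatation_cm <= 10 & ex$id %in% use
  idx_act <- which(act)
  first_act <- idx_act[!duplicated(ex$id[idx_act])]
  anchor_time <- ex$time_hours[first_act]
  anchor_dil <- ex$dilatation_cm[first_act]
  names(anchor_time) <- names(anchor_dil) <- ex$id[first_act]
  at <- anchor_time[as.character(ex$id)]
  post <- act & !is.na(at) & ex$time_hours > at
  if (any(post)) {
    wid <- ex$id[post]
    tau <- ex$time_hours[post] - at[post]
    d <- ex$dilatation_cm[post]
    d0 <- anchor_dil[as.character(wid)]
    sgp <- sg_of[post]
    for (k in seq_along(config$percentiles)) {
      qm <- t(vapply(names(fits), function(sg)
        curves[[paste(sg, config$percentiles[k],
                      sep = "_")]]$hours_from_4cm, numeric(7)))
      colnames(qm) <- as.character(4:10)
      hit <- tau + qm[cbind(sgp, as.character(d0))] >
        qm[cbind(sgp, as.character(d))] + 1e-9
      n_hit <- rowsum(as.integer(hit), wid)
      crossed_row <- match(women$id, rownames(n_hit))
      crossed_p[, k] <- ifelse(is.na(crossed_row), NA,
                               n_hit[crossed_row] > 0)
    }
  }
  # evaluable women whose series has no post-anchor exam did not cross
  crossed_p[evaluable_w & is.na(crossed_p[, 1]), ] <- FALSE
  crossed_p[!evaluable_w, ] <- NA

  outcome <- women$severe_adverse_outcome
  results <- list(alert_line = accuracy_stats(tabulate_2x2(alert, outcome)),
                  action_line = accuracy_stats(tabulate_2x2(action, outcome)))
  for (k in seq_along(pcols)) {
    tab <- tabulate_2x2(crossed_p[, k], outcome)
    if (tab$tp + tab$fn >= 1 && tab$fp + tab$tn >= 1) {
      results[[paste0("percentile_", config$percentiles[k])]] <-
        accuracy_stats(tab)
    }
  }

  curves_df <- do.call(rbind, lapply(names(curves), function(nm) {
    cv <- curves[[nm]]
    data.frame(subgroup = attr(cv, "subgroup"),
               percentile = attr(cv, "percentile"),
               dilatation_cm = cv$dilatation_cm,
               hours_from_4cm = cv$hours_from_4cm)
  }))
  classification <- data.frame(id = women$id,
                               robson_group = women$robson_group,
                               analysis_subgroup = women$analysis_subgroup,
                               n_active_exams = n_active,
                               line_evaluable = eligible,
                               alert_crossed = as.integer(alert),
                               action_crossed = as.integer(action))
  classification <- cbind(classification,
                          as.data.frame(crossed_p * 1L))
  flow <- c(n_input = n_input,
            n_too_few_active_exams = sum(!eligible),
            n_line_evaluable = sum(eligible),
            n_modelled_subgroup = sum(eligible &
                                        !is.na(women$analysis_subgroup)),
            n_curve_evaluable = sum(!is.na(crossed_p[, 1])))
  structure(list(flow = flow,
                 classification = classification,
                 fits = fits,
                 curves = curves_df,
                 accuracy = results,
                 accuracy_table = accuracy_table(results),
                 roc_table = roc_space_table(results),
                 skipped_subgroups = skipped,
                 config = config),
            class = "labour_report")
}

#' @export
print.labour_report <- function(x, ...) {
  cat("Labour progression accuracy analysis\n")
  cat("  flow:", paste(names(x$flow), x$flow, sep = " = ",
                       collapse = "; "), "\n")
  cat("  fitted subgroups:", length(x$fits), "\n")
  tab <- x$roc_table
  tab$fpr <- round(tab$fpr, 3); tab$tpr <- round(tab$tpr, 3)
  tab$j <- round(tab$j, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Write pipeline outputs to CSV and JSON
#'
#' Emits `accuracy_table.csv`, `roc_space.csv`, `curves.csv`, `models.csv`,
#' `classification.csv` and a machine-readable `run_summary.json`.
#'
#' @param report A [run_analysis()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$accuracy_table,
                   file.path(dir, "accuracy_table.csv"), row.names = FALSE)
  utils::write.csv(report$roc_table, file.path(dir, "roc_space.csv"),
                   row.names = FALSE)
  if (!is.null(report$curves)) {
    utils::write.csv(report$curves, file.path(dir, "curves.csv"),
                     row.names = FALSE)
  }
  models <- do.call(rbind, lapply(names(report$fits), function(sg) {
    f <- report$fits[[sg]]
    r <- f$model$rates
    out <- as.data.frame(as.list(r))
    names(out) <- paste0("lambda_", names(r))
    cbind(data.frame(subgroup = sg,
                     log_likelihood = f$log_likelihood,
                     converged = f$converged), out)
  }))
  if (!is.null(models)) {
    utils::write.csv(models, file.path(dir, "models.csv"), row.names = FALSE)
  }
  utils::write.csv(report$classification,
                   file.path(dir, "classification.csv"), row.names = FALSE)
  summary <- list(flow = as.list(report$flow),
                  skipped_subgroups = report$skipped_subgroups,
                  max_youden_j = max(vapply(report$accuracy, function(r)
                    unname(r$youden_j["estimate"]), numeric(1))))
  jsonlite::write_json(summary, file.path(dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Diagnostic plots for a pipeline run
#'
#' Writes three figures: a spaghetti plot of cervical dilatation over time
#' (adverse-outcome labours highlighted), the fitted 95th-percentile curves
#' by subgroup, and the ROC-space scatter of every classifier against the
#' chance diagonal.
#'
#' @param report A [run_analysis()] result.
#' @param cohort The cohort that was analysed.
#' @param dir Output directory.
#' @param max_series Cap on the number of plotted labour series (plotting
#'   only; sampled deterministically).
#' @return Invisibly, the paths written.
#' @export
plot_outputs <- function(report, cohort, dir, max_series = 500L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  women <- if (inherits(cohort, "labour_cohort")) cohort$women else cohort
  exams <- cohort$exams
  cls <- report$classification
  keep_ids <- cls$id[cls$line_evaluable]
  if (length(keep_ids) > max_series) {
    keep_ids <- keep_ids[round(seq(1, length(keep_ids),
                                   length.out = max_series))]
  }
  ex <- exams[exams$id %in% keep_ids & exams$dilatation_cm <= 10, ]
  ex$adverse <- women$severe_adverse_outcome[match(ex$id, women$id)] == 1
  paths <- character(0)

  p1 <- ggplot2::ggplot(ex, ggplot2::aes(x = time_hours, y = dilatation_cm,
                                         group = id, colour = adverse)) +
    ggplot2::geom_line(data = ex[!ex$adverse, ], alpha = 0.25,
                       linewidth = 0.2) +
    ggplot2::geom_line(data = ex[ex$adverse, ], alpha = 0.9,
                       linewidth = 0.4) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::labs(x = "Hours since admission", y = "Cervical dilatation (cm)",
                  title = "Cervical dilatation over time") +
    ggplot2::theme_minimal()
  f1 <- file.path(dir, "spaghetti.png")
  ggplot2::ggsave(f1, p1, width = 7, height = 5, dpi = 150)
  paths <- c(paths, f1)

  cv <- report$curves
  if (!is.null(cv) && nrow(cv)) {
    cv95 <- cv[cv$percentile == max(cv$percentile), ]
    p2 <- ggplot2::ggplot(cv95, ggplot2::aes(x = hours_from_4cm,
                                             y = dilatation_cm,
                                             colour = subgroup)) +
      ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
      ggplot2::labs(x = "Hours from 4 cm", y = "Cervical dilatation (cm)",
                    title = paste0(max(cv$percentile),
                                   "th percentile labour curves")) +
      ggplot2::theme_minimal()
    f2 <- file.path(dir, "percentile_curves.png")
    ggplot2::ggsave(f2, p2, width = 7, height = 5, dpi = 150)
    paths <- c(paths, f2)
  }

  rt <- report$roc_table
  p3 <- ggplot2::ggplot(rt, ggplot2::aes(x = fpr, y = tpr,
                                         label = classifier)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(colour = "steelblue", size = 2) +
    ggplot2::geom_text(nudge_y = 0.03, size = 2.8) +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "False-positive rate (1 - specificity)",
                  y = "True-positive rate (sensitivity)",
                  title = "ROC space") +
    ggplot2::theme_minimal()
  f3 <- file.path(dir, "roc_space.png")
  ggplot2::ggsave(f3, p3, width = 6, height = 6, dpi = 150)
  invisible(c(paths, f3))
}

#' Accuracy statistics from a table of published 2x2 counts
#'
#' Recomputes the full accuracy panel from a data frame of printed
#' contingency-table counts (columns `classifier`, `tp`, `fp`, `fn`, `tn`),
#' such as the alert/action-line counts shipped in
#' `system.file("extdata", "alert_action_counts.csv", package = "labourdx")`.
#'
#' @param counts Data frame or path to a CSV with those columns.
#' @return Named list of [accuracy_stats()] results.
#' @export
accuracy_from_counts <- function(counts) {
  if (is.character(counts)) counts <- utils::read.csv(counts)
  stopifnot(all(c("classifier", "tp", "fp", "fn", "tn") %in% names(counts)))
  out <- lapply(seq_len(nrow(counts)), function(i)
    accuracy_stats(tp = counts$tp[i], fp = counts$fp[i],
                   fn = counts$fn[i], tn = counts$tn[i]))
  names(out) <- counts$classifier
  out
}
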