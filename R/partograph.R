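#' Active-phase anchor of an exam series
#'
#' The WHO partograph reference lines are drawn from the first observation in
#' the active phase of labour: the first examination at a cervical dilatation
#' of at least 4 cm. Admissions already in the active phase anchor at the
#' admission exam, even when above 4 cm.
#'
#' @param exams Data frame with columns `time_hours` and `dilatation_cm`,
#'   sorted by time.
#' @return A list with `anchor_time` (hours) and `anchor_dilatation` (cm), or
#'   `NULL` if the series never reaches 4 cm.
#' @export
anchor_active_phase <- function(exams) {
  if (!is.data.frame(exams) ||
      !all(c("time_hours", "dilatation_cm") %in% names(exams))) {
    stop("'exams' must have columns time_hours and dilatation_cm",
         call. = FALSE)
  }
  if (nrow(exams) == 0L) stop("empty exam series", call. = FALSE)
  if (is.unsorted(exams$time_hours)) {
    stop("exam times must be sorted", call. = FALSE)
  }
  i <- which(exams$dilatation_cm >= 4 & exams$dilatation_cm <= 10)
  if (length(i) == 0L) return(NULL)
  list(anchor_time = exams$time_hours[i[1]],
       anchor_dilatation = exams$dilatation_cm[i[1]])
}

#' Alert-line expected dilatation
#'
#' The partograph alert line rises at one centimetre per hour from the
#' active-phase anchor, capped at full dilatation (10 cm).
#'
#' @param anchor Anchor as returned by [anchor_active_phase()].
#' @param t Time(s) in hours, at or after the anchor time.
#' @return Expected dilatation in cm, `min(10, anchor + (t - t0))`.
#' @export
alert_line_value <- function(anchor, t) {
  if (any(t < anchor$anchor_time)) {
    stop("'t' must not precede the anchor time", call. = FALSE)
  }
  pmin(10, anchor$anchor_dilatation + (t - anchor$anchor_time))
}

#' Action-line expected dilatation
#'
#' The action line runs parallel to the alert line, four hours to its right:
#' before four hours have elapsed past the anchor it imposes no requirement.
#'
#' @inheritParams alert_line_value
#' @return Expected dilatation in cm (can be below the anchor dilatation
#'   while the action line has not yet started).
#' @export
action_line_value <- function(anchor, t) {
  if (any(t < anchor$anchor_time)) {
    stop("'t' must not precede the anchor time", call. = FALSE)
  }
  pmin(10, anchor$anchor_dilatation + (t - anchor$anchor_time - 4))
}

.crossed_line <- function(exams, line_value_fun) {
  anchor <- anchor_active_phase(exams)
  if (is.null(anchor)) {
    return(structure(list(crossed = NA,
                          first_crossing_exam_index = NA_integer_),
                     class = "crossing_result"))
  }
  idx <- which(exams$time_hours > anchor$anchor_time &
                 exams$dilatation_cm <= 10)
  crossed_at <- NA_integer_
  for (i in idx) {
    expect <- line_value_fun(anchor, exams$time_hours[i])
    if (exams$dilatation_cm[i] < expect - 1e-9) {
      crossed_at <- i
      break
    }
  }
  structure(list(crossed = !is.na(crossed_at),
                 first_crossing_exam_index = crossed_at),
            class = "crossing_result")
}

#' Alert-line crossing classification
#'
#' A woman crosses the alert line if any examination after her active-phase
#' anchor records a dilatation strictly below the alert-line value at that
#' time (observations exactly on the line count as not crossed). Crossing is
#' evaluated only at observed exam points, matching how the partograph is
#' read on sparse panel data.
#'
#' @param exams Data frame with `time_hours`, `dilatation_cm`, sorted.
#' @return A `crossing_result`: `crossed` is `NA` when the series has no
#'   active-phase anchor (not evaluable, distinct from not crossed).
#' @examples
#' crossed_alert_line(data.frame(time_hours = c(0, 5),
#'                               dilatation_cm = c(4, 8)))  # crossed: 8 < 9
#' @export
crossed_alert_line <- function(exams) .crossed_line(exams, alert_line_value)

#' Action-line crossing classification
#'
#' As [crossed_alert_line()], against the action line four hours to the right
#' of the alert line. Action-line crossing implies alert-line crossing.
#'
#' @inheritParams crossed_alert_line
#' @return A `crossing_result`.
#' @export
crossed_action_line <- function(exams) .crossed_line(exams, action_line_value)
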