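#' Robson 10-group classification (study-eligible population)
#'
#' Classifies women into the Robson obstetric groups reachable in a cohort of
#' singleton pregnancies admitted in labour: groups 1-5 and 10, with the
#' non-cephalic groups (6, 7 and 9) pooled. Group 8 (multiple pregnancy) and
#' pre-labour caesarean sections are excluded by eligibility, so the
#' classifier refuses non-singleton input rather than guessing.
#'
#' Rules, applied in order: non-cephalic presentation pools into
#' `pooled_679`; cephalic births before 37 completed weeks form group 10;
#' cephalic term women with a previous caesarean form group 5 regardless of
#' onset; the remainder split by parity and onset into groups 1-4.
#'
#' @param parity Integer count of previous births (vectorised).
#' @param previous_caesarean Logical/0-1 flag; must be 0 for nulliparous
#'   women.
#' @param onset `"spontaneous"` or `"induced"`.
#' @param gestational_weeks Completed weeks of gestation at childbirth.
#' @param presentation `"cephalic"`, `"breech"` or `"transverse"`.
#' @param plurality Number of fetuses; anything other than 1 is an error.
#' @return Character vector with values `"1"`..`"5"`, `"10"` or
#'   `"pooled_679"`.
#' @export
classify_robson <- function(parity, previous_caesarean, onset,
                            gestational_weeks, presentation,
                            plurality = 1L) {
  args <- list(parity = parity, previous_caesarean = previous_caesarean,
               onset = onset, gestational_weeks = gestational_weeks,
               presentation = presentation)
  for (nm in names(args)) {
    if (anyNA(args[[nm]])) {
      stop("missing covariate '", nm, "' prevents Robson classification",
           call. = FALSE)
    }
  }
  if (any(plurality != 1L)) {
    stop("non-singleton pregnancies are outside the eligible population",
         call. = FALSE)
  }
  n <- length(parity)
  previous_caesarean <- as.logical(previous_caesarean)
  if (!all(onset %in% c("spontaneous", "induced"))) {
    stop("onset must be 'spontaneous' or 'induced'", call. = FALSE)
  }
  if (!all(presentation %in% c("cephalic", "breech", "transverse"))) {
    stop("presentation must be cephalic, breech or transverse", call. = FALSE)
  }
  if (any(previous_caesarean & parity < 1)) {
    stop("previous caesarean recorded for a nulliparous woman", call. = FALSE)
  }
  g <- character(n)
  noncep <- presentation != "cephalic"
  preterm <- gestational_weeks < 37
  g[noncep] <- "pooled_679"
  g[!noncep & preterm] <- "10"
  term_cep <- !noncep & !preterm
  g[term_cep & previous_caesarean] <- "5"
  null_ <- term_cep & !previous_caesarean & parity == 0
  multi <- term_cep & !previous_caesarean & parity >= 1
  g[null_ & onset == "spontaneous"] <- "1"
  g[null_ & onset == "induced"] <- "2"
  g[multi & onset == "spontaneous"] <- "3"
  g[multi & onset == "induced"] <- "4"
  g
}

#' Analysis subgroup from Robson group and augmentation
#'
#' The modelled obstetric subgroups split Robson groups 1-5 and 10 by the use
#' of labour augmentation, giving twelve subgroups (e.g. `"3A"` for group 3
#' with augmentation, `"10N"` without). The pooled non-cephalic groups are
#' never modelled: they return `NA`, marking the woman as excluded from
#' curve fitting (she still takes part in the alert/action-line analyses).
#'
#' @param robson_group Character vector as returned by [classify_robson()].
#' @param augmentation Logical/0-1 flag of labour augmentation.
#' @return Character vector of subgroup labels, `NA` for excluded women.
#' @export
assign_subgroup <- function(robson_group, augmentation) {
  modelled <- c("1", "2", "3", "4", "5", "10")
  ok <- robson_group %in% c(modelled, "pooled_679")
  if (!all(ok)) {
    stop("unknown Robson group: ",
         paste(unique(robson_group[!ok]), collapse = ", "), call. = FALSE)
  }
  out <- ifelse(robson_group %in% modelled,
                paste0(robson_group, ifelse(as.logical(augmentation),
                                            "A", "N")),
                NA_character_)
  out
}

#' All modelled analysis subgroup labels
#' @return Character vector of the twelve subgroup labels.
#' @export
analysis_subgroups <- function() {
  as.vector(outer(c("1", "2", "3", "4", "5", "10"), c("A", "N"), paste0))
}

#' Add Robson classification columns to a woman-level table
#'
#' @param women Woman-level data frame with columns `parity`,
#'   `previous_caesarean`, `onset`, `gestational_weeks`, `presentation`,
#'   `augmentation`.
#' @return The input with columns `robson_group` and `analysis_subgroup`
#'   appended.
#' @export
add_robson <- function(women) {
  women$robson_group <- classify_robson(
    women$parity, women$previous_caesarean, women$onset,
    women$gestational_weeks, women$presentation)
  women$analysis_subgroup <- assign_subgroup(women$robson_group,
                                             women$augmentation)
  women
}
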