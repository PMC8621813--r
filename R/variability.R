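# Coefficient-of-variation gait variability.
#
# Two levels: the within-participant CV (SD of a participant's per-cycle
# parameter values over their mean — stride-to-stride variability) and the
# cohort-level CV (SD of participant means over their mean). Group tables
# present the mean +/- SD of the within-participant CVs, which is how
# published gait-variability tables are laid out; the cohort-level CV is
# exposed separately. Sample (n-1) SDs are used throughout, the convention
# of the gait-variability literature. CVs are reported in percent.

#' Within-participant coefficient of variation
#'
#' `100 * sd(x) / mean(x)` over one participant's per-cycle values of a
#' cyclogram parameter.
#'
#' @param per_cycle_values Numeric vector (>= 2 values, positive mean).
#' @return CV in percent (0 iff the values are constant).
#' @export
#' @examples
#' participant_cv(c(1, 2, 3))  # 50
participant_cv <- function(per_cycle_values) {
  x <- as.numeric(per_cycle_values)
  if (length(x) < 2) stop("participant_cv() needs >= 2 values", call. = FALSE)
  m <- mean(x)
  if (m <= 0) {
    warning("nonpositive mean; CV undefined (parameters should be positive)",
            call. = FALSE)
    return(NA_real_)
  }
  100 * stats::sd(x) / m
}

#' Cohort-level coefficient of variation
#'
#' `100 * sd(participant_means) / mean(participant_means)` — the dispersion
#' of a parameter across participants, a cohort-level gait-variability
#' summary.
#'
#' @param participant_means Numeric vector (>= 2 participants).
#' @return CV in percent.
#' @export
#' @examples
#' group_cv(c(40, 60))  # 28.28
group_cv <- function(participant_means) {
  x <- as.numeric(participant_means)
  if (length(x) < 2) stop("group_cv() needs >= 2 participants", call. = FALSE)
  m <- mean(x)
  if (m <= 0) {
    warning("nonpositive mean; CV undefined", call. = FALSE)
    return(NA_real_)
  }
  100 * stats::sd(x) / m
}

#' Per-participant CV table and group summaries
#'
#' @param per_cycle A `data.frame` with columns `participant_id`, `group`,
#'   and the eight cyclogram parameters (one row per cycle), as assembled by
#'   the pipeline from [participant_params()]`$per_cycle`.
#' @param parameters Parameter columns to summarize (default all eight).
#' @return List with `cv` (long `data.frame`: `participant_id`, `group`,
#'   `parameter`, `cv_percent`) and `summary` (`group`, `parameter`,
#'   `cv_mean`, `cv_sd`, `n`; `cv_sd` is `NA` for single-participant
#'   groups). Participants with a single cycle are excluded with a warning.
#' @export
cv_table <- function(per_cycle, parameters = cyclogram_param_names()) {
  stopifnot(all(c("participant_id", "group", parameters) %in% names(per_cycle)))
  counts <- table(per_cycle$participant_id)
  singles <- names(counts)[counts < 2]
  if (length(singles) > 0) {
    warning("excluding participant(s) with a single cycle: ",
            paste(singles, collapse = ", "), call. = FALSE)
    per_cycle <- per_cycle[!(per_cycle$participant_id %in% singles), ,
                           drop = FALSE]
  }
  if (nrow(per_cycle) == 0) stop("no participants with >= 2 cycles", call. = FALSE)

  ids <- unique(per_cycle$participant_id)
  cv <- do.call(rbind, lapply(ids, function(pid) {
    sub <- per_cycle[per_cycle$participant_id == pid, , drop = FALSE]
    data.frame(
      participant_id = pid,
      group = sub$group[1],
      parameter = parameters,
      cv_percent = vapply(parameters,
                          function(p) participant_cv(sub[[p]]), numeric(1)),
      row.names = NULL, stringsAsFactors = FALSE
    )
  }))

  summary <- do.call(rbind, lapply(split(cv, cv[c("group", "parameter")],
                                         drop = TRUE), function(s) {
    data.frame(
      group = s$group[1], parameter = s$parameter[1],
      cv_mean = mean(s$cv_percent),
      cv_sd = if (nrow(s) > 1) stats::sd(s$cv_percent) else NA_real_,
      n = nrow(s), row.names = NULL, stringsAsFactors = FALSE
    )
  }))
  summary <- summary[order(summary$group,
                           match(summary$parameter, parameters)), ]
  rownames(summary) <- NULL
  list(cv = cv, summary = summary)
}
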