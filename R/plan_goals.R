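#' Clinical dose-volume goal
#'
#' A single planning objective on one structure: a dose-volume metric, a
#' comparator and a threshold. Supported metrics:
#' \describe{
#'   \item{`D_percent`}{dose to the hottest `metric_arg` percent of the
#'     volume (Gy); `metric_arg = 100` is the near-minimum dose D_100%.}
#'   \item{`V_gray`}{volume fraction receiving at least `metric_arg` Gy.}
#'   \item{`D_max`, `D_min`}{extreme occupied doses (Gy). `D_min` is
#'     implemented as D_100%, the dose covering the whole volume, which
#'     is how minimum-dose goals are stated for hippocampal avoidance.}
#' }
#' Volume thresholds are stored as fractions internally and rendered as
#' percent at the interface.
#'
#' @param structure_label structure the goal applies to.
#' @param metric one of `"D_percent"`, `"V_gray"`, `"D_max"`, `"D_min"`.
#' @param comparator `"<="` or `">="`.
#' @param threshold Gy for dose metrics, fraction in (0, 1\] for `V_gray`.
#' @param metric_arg the `x` of D_x% (in percent) or V_xGy (in Gy); `NA`
#'   for `D_max`/`D_min`.
#' @param priority `"primary"` or `"secondary"`.
#' @return An object of class `clinical_goal`.
#' @export
clinical_goal <- function(structure_label, metric, comparator, threshold,
                          metric_arg = NA_real_, priority = "primary") {
  metric <- match.arg(metric, c("D_percent", "V_gray", "D_max", "D_min"))
  comparator <- match.arg(comparator, c("<=", ">="))
  priority <- match.arg(priority, c("primary", "secondary"))
  if (!is.numeric(threshold) || threshold <= 0)
    stop("threshold must be > 0", call. = FALSE)
  if (metric == "V_gray" && threshold > 1)
    stop("V_xGy thresholds are volume fractions in (0, 1]", call. = FALSE)
  if (metric %in% c("D_percent", "V_gray") && !is.finite(metric_arg))
    stop("metric '", metric, "' needs a metric_arg", call. = FALSE)
  structure(list(structure_label = structure_label, metric = metric,
                 comparator = comparator, threshold = threshold,
                 metric_arg = metric_arg, priority = priority),
            class = "clinical_goal")
}

goal_label <- function(g) {
  m <- switch(g$metric,
              D_percent = sprintf("D_%g%%", g$metric_arg),
              V_gray = sprintf("V_%gGy", g$metric_arg),
              D_max = "D_max", D_min = "D_min")
  thr <- if (g$metric == "V_gray") sprintf("%g%%", 100 * g$threshold)
         else sprintf("%g Gy", g$threshold)
  sprintf("%s %s %s %s", g$structure_label, m, g$comparator, thr)
}

#' Default whole-brain IMRT planning goal set
#'
#' The ten standard objectives for hippocampal-avoidance whole-brain
#' plans at a 30 Gy prescription: PTV D_2% <= 37.5 Gy, D_98% >= 25 Gy and
#' V_30Gy >= 90% (with a secondary >= 95% tier); bilateral hippocampi
#' D_min <= 9 Gy and D_max <= 16 Gy; bilateral lacrimal glands
#' V_15Gy <= 80% with secondary D_max <= 15 Gy; bilateral parotid glands
#' V_20Gy <= 50% with secondary D_max <= 20 Gy.
#'
#' @return A list of ten [clinical_goal()] objects (class `goal_set`).
#' @export
default_goals <- function() {
  g <- list(
    clinical_goal("ptv", "D_percent", "<=", 37.5, metric_arg = 2),
    clinical_goal("ptv", "D_percent", ">=", 25, metric_arg = 98),
    clinical_goal("ptv", "V_gray", ">=", 0.90, metric_arg = 30),
    clinical_goal("ptv", "V_gray", ">=", 0.95, metric_arg = 30,
                  priority = "secondary"),
    clinical_goal("hippocampi", "D_min", "<=", 9),
    clinical_goal("hippocampi", "D_max", "<=", 16),
    clinical_goal("lacrimal", "V_gray", "<=", 0.80, metric_arg = 15),
    clinical_goal("lacrimal", "D_max", "<=", 15, priority = "secondary"),
    clinical_goal("parotid", "V_gray", "<=", 0.50, metric_arg = 20),
    clinical_goal("parotid", "D_max", "<=", 20, priority = "secondary"))
  class(g) <- c("goal_set", "list")
  g
}

#' Evaluate one clinical goal against a DVH
#'
#' @param dvh a `dvh_cum` (or `dvh_diff`, converted) whose
#'   `structure_label` matches the goal's.
#' @param g a [clinical_goal()].
#' @return A list with `achieved` (the measured metric value) and `pass`.
#' @export
evaluate_goal <- function(dvh, g) {
  stopifnot(inherits(g, "clinical_goal"))
  cdvh <- as_cumulative(dvh)
  if (!identical(cdvh$structure_label, g$structure_label))
    stop(sprintf("DVH structure '%s' does not match goal structure '%s'",
                 cdvh$structure_label, g$structure_label), call. = FALSE)
  achieved <- switch(
    g$metric,
    D_percent = dose_at_volume(cdvh, g$metric_arg / 100),
    V_gray = volume_at_dose(cdvh, g$metric_arg),
    # highest dose any volume reaches: where the cumulative curve hits 0,
    # or the end of the grid if it never does
    D_max = {
      z <- which(cdvh$volume_fraction <= 0)
      if (length(z)) cdvh$dose_grid[z[1]] else max(cdvh$dose_grid)
    },
    D_min = dose_at_volume(cdvh, 1))
  pass <- if (g$comparator == "<=") achieved <= g$threshold
          else achieved >= g$threshold
  list(achieved = achieved, pass = pass)
}

#' Evaluate a plan's DVH set against a goal set
#'
#' Every goal whose structure has a DVH in `dvhs` is evaluated; missing
#' organ-at-risk DVHs produce a warning and `NA` rows. Overall clinical
#' acceptability is the target-coverage rule: at least 90% of the PTV
#' must receive the 30 Gy prescription (`V_30Gy >= 0.90`). Without a PTV
#' DVH, acceptability is indeterminate (`NA`), not `FALSE`.
#'
#' @param dvhs named list of DVHs keyed by structure label.
#' @param goals a goal set from [default_goals()] or a list of
#'   [clinical_goal()]s.
#' @param prescription prescription dose in Gy (default 30).
#' @param coverage_fraction required PTV coverage at prescription
#'   (default 0.90).
#' @return An object of class `plan_report`: a data frame of per-goal rows
#'   (`structure`, `goal`, `priority`, `achieved`, `threshold`, `pass`)
#'   with attribute `overall_acceptable`.
#' @export
evaluate_plan <- function(dvhs, goals = default_goals(), prescription = 30,
                          coverage_fraction = 0.90) {
  stopifnot(is.list(dvhs))
  rows <- lapply(goals, function(g) {
    if (!g$structure_label %in% names(dvhs)) {
      warning("no DVH supplied for structure '", g$structure_label,
              "'; goal skipped", call. = FALSE)
      res <- list(achieved = NA_real_, pass = NA)
    } else {
      res <- evaluate_goal(dvhs[[g$structure_label]], g)
    }
    data.frame(structure = g$structure_label, goal = goal_label(g),
               priority = g$priority, achieved = res$achieved,
               threshold = g$threshold, pass = res$pass,
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  acceptable <- if (!"ptv" %in% names(dvhs)) NA else {
    volume_at_dose(as_cumulative(dvhs[["ptv"]]), prescription) >=
      coverage_fraction
  }
  attr(report, "overall_acceptable") <- acceptable
  class(report) <- c("plan_report", "data.frame")
  report
}

#' @export
print.plan_report <- function(x, ...) {
  df <- x
  df$achieved <- ifelse(grepl("V_", df$goal), sprintf("%.1f%%", 100 * df$achieved),
                        sprintf("%.2f Gy", df$achieved))
  print.data.frame(df, row.names = FALSE)
  acc <- attr(x, "overall_acceptable")
  cat("overall acceptable (PTV coverage):",
      if (is.na(acc)) "indeterminate (no PTV DVH)" else acc, "\n")
  invisible(x)
}
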