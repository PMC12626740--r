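#' Paired t-test on two matched samples
#'
#' Computes the paired t statistic `t = mean(d) / (sd(d)/sqrt(n))` on the
#' per-pair differences `d_i = x_i - y_i`, with `df = n - 1` and a
#' two-sided p-value from the t distribution. Zero-variance differences
#' are an error (the t statistic is undefined), as is `n < 2`.
#'
#' @param x,y numeric vectors of equal length `n >= 2`.
#' @return A list with `t`, `df`, `p_two_sided`, `mean_diff`, `sd_diff`.
#' @examples
#' paired_t(c(0.3, 0.4, 0.5), c(0.2, 0.25, 0.45))
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  n <- length(x)
  if (n < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- x - y
  sdd <- stats::sd(d)
  if (!is.finite(sdd) || sdd == 0)
    stop("zero-variance differences: paired t statistic is undefined ",
         "(all pairs shifted identically)", call. = FALSE)
  tval <- mean(d) / (sdd / sqrt(n))
  list(t = tval, df = n - 1,
       p_two_sided = 2 * stats::pt(-abs(tval), df = n - 1),
       mean_diff = mean(d), sd_diff = sdd)
}

#' Bonferroni-adjusted per-test significance level
#'
#' @param alpha_family familywise level in (0, 1).
#' @param k number of comparisons, `>= 1`.
#' @return `alpha_family / k`.
#' @examples
#' bonferroni(0.05, 2) # 0.025
#' @export
bonferroni <- function(alpha_family, k) {
  if (!is.numeric(alpha_family) || alpha_family <= 0 || alpha_family >= 1)
    stop("alpha_family must be in (0, 1)", call. = FALSE)
  if (!is.numeric(k) || k < 1 || k != round(k))
    stop("k must be a positive integer", call. = FALSE)
  alpha_family / k
}

#' Mean and SD of per-pair differences
#'
#' Summary of the per-patient risk difference `x_i - y_i` (sample SD,
#' `n - 1` denominator). With `x` the re-plan risk and `y` the original,
#' a risk reduction appears as a negative mean.
#'
#' @param x,y numeric vectors of equal length.
#' @return A list with `mean_delta` and `sd_delta`.
#' @export
delta_summary <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  d <- x - y
  if (length(d) < 2) stop("need at least 2 pairs for an SD", call. = FALSE)
  list(mean_delta = mean(d), sd_delta = stats::sd(d))
}

#' Power of the two-sided paired t-test
#'
#' Exact power via the noncentral t distribution: with `df = n - 1`,
#' noncentrality `effect_size * sqrt(n)` and critical value
#' `t_crit = qt(1 - alpha/2, df)`, power is
#' `P(|T_ncp| > t_crit)`. At a standardized effect of 1.1 and n = 11
#' patients this gives about 82% power at two-sided alpha = 0.025.
#'
#' @param n number of pairs, `>= 2`.
#' @param effect_size standardized effect `mean(d)/sd(d)`, `>= 0`.
#' @param alpha two-sided significance level in (0, 1).
#' @return Power in (0, 1).
#' @examples
#' paired_power(11, 1.1, 0.025)
#' @export
paired_power <- function(n, effect_size, alpha) {
  if (!is.numeric(n) || n < 2 || n != round(n))
    stop("n must be an integer >= 2", call. = FALSE)
  if (!is.numeric(effect_size) || effect_size < 0)
    stop("effect_size must be >= 0", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)", call. = FALSE)
  df <- n - 1
  tc <- stats::qt(1 - alpha / 2, df)
  ncp <- effect_size * sqrt(n)
  (1 - stats::pt(tc, df, ncp)) + stats::pt(-tc, df, ncp)
}

#' Standardized effect size of a risk difference
#'
#' @param delta mean risk difference (probability scale).
#' @param sd standard deviation of the risk (probability scale), > 0.
#' @return `delta / sd`, dimensionless.
#' @examples
#' standardized_effect(0.07, 0.062) # ~1.13
#' @export
standardized_effect <- function(delta, sd) {
  if (!is.numeric(sd) || sd <= 0) stop("sd must be > 0", call. = FALSE)
  delta / sd
}

#' Assemble a per-patient NTCP cohort table
#'
#' Validates a long-format cohort of per-patient, per-plan, per-endpoint
#' NTCP values and returns it as a `cohort_ntcp` data frame. Every
#' patient must carry all plans for each endpoint it appears under, so
#' that downstream paired tests are well defined.
#'
#' @param df data frame with columns `patient_id`, `plan`, `endpoint`,
#'   `ntcp` (fractions in \[0, 1\]).
#' @param plans expected plan labels (default original / 3D re-plan /
#'   IMRT re-plan).
#' @return The validated data frame, class `cohort_ntcp`.
#' @export
cohort_ntcp <- function(df, plans = c("original", "replan_3d", "replan_imrt")) {
  need <- c("patient_id", "plan", "endpoint", "ntcp")
  if (!all(need %in% names(df)))
    stop("cohort table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(df$ntcp)) || any(df$ntcp < 0 | df$ntcp > 1))
    stop("ntcp values must be in [0, 1]", call. = FALSE)
  if (any(!df$plan %in% plans))
    stop("unknown plan label(s): ",
         paste(setdiff(unique(df$plan), plans), collapse = ", "),
         call. = FALSE)
  for (ep in unique(df$endpoint)) {
    sub <- df[df$endpoint == ep, ]
    tab <- table(sub$patient_id, factor(sub$plan, levels = plans))
    if (any(tab != 1))
      stop("endpoint '", ep, "': every patient needs exactly one NTCP ",
           "per plan for paired testing", call. = FALSE)
  }
  df <- df[order(df$endpoint, df$plan, df$patient_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("cohort_ntcp", "data.frame")
  df
}

#' Paired plan comparison of cohort NTCP
#'
#' For each endpoint, reports the cohort mean and SD of NTCP under each
#' plan and the per-patient risk difference of each re-plan against the
#' original (mean, SD, paired t, two-sided p). The two original-vs-re-plan
#' tests form the Bonferroni family (per-test level
#' `alpha_family / comparisons`); the 3D-vs-IMRT contrast is reported for
#' completeness but is outside the family and is flagged at the same
#' per-test level without counting toward it.
#'
#' @param cohort a [cohort_ntcp()] table (a plain data frame is validated).
#' @param alpha_family familywise level (default 0.05).
#' @param comparisons size of the Bonferroni family (default 2).
#' @return An object of class `comparison_table`: one row per endpoint x
#'   plan with columns `endpoint`, `plan`, `mean_pct`, `sd_pct`,
#'   `delta_mean_pct`, `delta_sd_pct`, `t`, `p`, `significant`,
#'   `in_family`; attribute `alpha_per_test`.
#' @export
compare_cohort <- function(cohort, alpha_family = 0.05, comparisons = 2) {
  cohort <- cohort_ntcp(as.data.frame(cohort))
  alpha <- bonferroni(alpha_family, comparisons)
  plans <- c("original", "replan_3d", "replan_imrt")
  rows <- list()
  for (ep in sort(unique(cohort$endpoint))) {
    sub <- cohort[cohort$endpoint == ep, ]
    vals <- lapply(plans, function(pl) {
      s <- sub[sub$plan == pl, ]
      s$ntcp[order(s$patient_id)]
    })
    names(vals) <- plans
    for (pl in plans) {
      v <- vals[[pl]]
      row <- data.frame(endpoint = ep, plan = pl,
                        mean_pct = 100 * mean(v), sd_pct = 100 * stats::sd(v),
                        delta_mean_pct = NA_real_, delta_sd_pct = NA_real_,
                        t = NA_real_, p = NA_real_, significant = NA,
                        in_family = FALSE, stringsAsFactors = FALSE)
      if (pl != "original") {
        ds <- delta_summary(v, vals$original)
        tt <- paired_t(v, vals$original)
        row$delta_mean_pct <- 100 * ds$mean_delta
        row$delta_sd_pct <- 100 * ds$sd_delta
        row$t <- tt$t
        row$p <- tt$p_two_sided
        row$significant <- tt$p_two_sided < alpha
        row$in_family <- TRUE
      }
      rows[[length(rows) + 1L]] <- row
    }
    # supplementary 3D-vs-IMRT contrast, outside the Bonferroni family
    tt <- paired_t(vals$replan_imrt, vals$replan_3d)
    ds <- delta_summary(vals$replan_imrt, vals$replan_3d)
    rows[[length(rows) + 1L]] <- data.frame(
      endpoint = ep, plan = "imrt_vs_3d",
      mean_pct = NA_real_, sd_pct = NA_real_,
      delta_mean_pct = 100 * ds$mean_delta,
      delta_sd_pct = 100 * ds$sd_delta,
      t = tt$t, p = tt$p_two_sided,
      significant = tt$p_two_sided < alpha, in_family = FALSE,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "alpha_per_test") <- alpha
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' @export
print.comparison_table <- function(x, ...) {
  df <- as.data.frame(x)
  num <- c("mean_pct", "sd_pct", "delta_mean_pct", "delta_sd_pct")
  df[num] <- lapply(df[num], function(v) ifelse(is.na(v), NA, round(v, 1)))
  df$t <- round(df$t, 2)
  df$p <- signif(df$p, 3)
  cat(sprintf("Cohort NTCP comparison (per-test alpha = %.4g)\n",
              attr(x, "alpha_per_test")))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
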