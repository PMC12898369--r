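# Regeneration percentage per case and cohort summaries.

#' Regeneration report for one case
#'
#' Applies the continuity criterion inside the defect interval and computes
#' the headline statistic at both density thresholds:
#' `Regeneration (%) = length of regenerated canal / defect length x 100`.
#' The regenerated length is the summed passing-station length of the runs
#' returned by [find_runs()], restricted to stations inside the defect
#' interval; the defect length is the straight-line apex-to-apex distance.
#' On a curved axis the arc can exceed the chord, so the percentage is
#' clipped at 100 with the `clipped` flag set (and a warning).
#'
#' @param verdicts a `section_verdicts` data.frame covering the centerline.
#' @param di a [defect_interval()].
#' @param p the [scoring_params()] used for scoring.
#' @param step_mm station spacing override (defaults to the value recorded
#'   on `verdicts`).
#' @return An object of class `regen_report`: `defect_length`,
#'   `regen_length_800`, `regen_length_400`, `regen_pct_800`,
#'   `regen_pct_400`, the run tables `runs_800`/`runs_400`, `clipped`,
#'   `n_stations`, `step_mm` and `params`.
#' @export
regeneration_report <- function(verdicts, di, p = scoring_params(),
                                step_mm = NULL) {
  if (!inherits(di, "defect_interval"))
    stop_input("di must be a defect_interval")
  step_mm <- step_mm %||% attr(verdicts, "step_mm") %||%
    (if (nrow(verdicts) > 1L) stats::median(diff(verdicts$station_s)) else 0)
  eps <- 1e-9
  inside <- verdicts$station_s >= di$s_start - eps &
    verdicts$station_s <= di$s_end + eps
  vd <- verdicts[inside, , drop = FALSE]
  if (nrow(vd) < 2L)
    stop_input("defect interval contains fewer than 2 stations")
  attr(vd, "step_mm") <- step_mm
  class(vd) <- class(verdicts)

  runs_800 <- find_runs(vd, "mature", p, step_mm)
  runs_400 <- find_runs(vd, "early", p, step_mm)
  # Each station stands for a step-wide slab of canal centred on it; runs
  # crossing a defect boundary are truncated there, so a fully passing
  # straight-axis defect measures exactly its own length.
  truncated_len <- function(runs) {
    if (nrow(runs) == 0L) return(0)
    over_lo <- pmax(0, di$s_start - (runs$s_start - step_mm / 2))
    over_hi <- pmax(0, (runs$s_end + step_mm / 2) - di$s_end)
    sum(pmax(0, runs$length_mm - over_lo - over_hi))
  }
  len_800 <- truncated_len(runs_800)
  len_400 <- truncated_len(runs_400)
  pct <- function(len) min(100, 100 * len / di$defect_length)
  tol <- 1e-6  # floating-point slack, percent
  clipped <- 100 * max(len_800, len_400) / di$defect_length > 100 + tol
  if (clipped)
    warning("regenerated arc length exceeds the linear defect length; percentage clipped at 100")
  p800 <- pct(len_800); p400 <- pct(len_400)
  structure(list(defect_length = di$defect_length,
                 regen_length_800 = len_800, regen_length_400 = len_400,
                 regen_pct_800 = p800, regen_pct_400 = p400,
                 runs_800 = runs_800, runs_400 = runs_400,
                 clipped = clipped,
                 n_stations = nrow(vd), step_mm = step_mm,
                 params = p),
            class = "regen_report")
}

#' @export
print.regen_report <- function(x, ...) {
  cat("Mandibular canal regeneration\n")
  cat(sprintf("  defect length: %.2f mm (%d stations at %.2f mm)\n",
              x$defect_length, x$n_stations, x$step_mm))
  cat(sprintf("  > 800 HU (mature bone):   %.2f mm regenerated = %.1f%%%s\n",
              x$regen_length_800, x$regen_pct_800,
              if (x$clipped) " [clipped]" else ""))
  cat(sprintf("  > 400 HU (early + mature): %.2f mm regenerated = %.1f%%\n",
              x$regen_length_400, x$regen_pct_400))
  invisible(x)
}

#' Cohort-level summary of regeneration reports
#'
#' Mean and standard deviation (n - 1 denominator) of the regeneration
#' percentage at both thresholds, Shapiro-Wilk normality p-values (reported,
#' no decision made), and the clinical count cutoffs: cases above 70%
#' (substantial regeneration) and below 50% / below 40% (partial
#' regeneration), all at the mature threshold.
#'
#' @param reports a list of `regen_report` objects (n >= 1). With a single
#'   report only the means are available; Shapiro-Wilk needs n >= 3.
#' @return An object of class `cohort_summary`.
#' @export
summarize_cohort <- function(reports) {
  if (inherits(reports, "regen_report")) reports <- list(reports)
  if (!length(reports) || !all(vapply(reports, inherits, TRUE, "regen_report")))
    stop_input("reports must be a non-empty list of regen_report objects")
  p800 <- vapply(reports, `[[`, 0, "regen_pct_800")
  p400 <- vapply(reports, `[[`, 0, "regen_pct_400")
  n <- length(reports)
  sw <- function(x) {
    if (n >= 3L && stats::sd(x) > 0) stats::shapiro.test(x)$p.value
    else NA_real_
  }
  structure(list(
    n = n,
    mean_800 = mean(p800), sd_800 = if (n >= 2L) stats::sd(p800) else NA_real_,
    mean_400 = mean(p400), sd_400 = if (n >= 2L) stats::sd(p400) else NA_real_,
    shapiro_p_800 = sw(p800), shapiro_p_400 = sw(p400),
    count_above_70_800 = sum(p800 > 70),
    count_below_50_800 = sum(p800 < 50),
    count_below_40_800 = sum(p800 < 40),
    pct_800 = p800, pct_400 = p400),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  fmt <- function(m, s) if (is.na(s)) sprintf("%.1f%%", m)
    else sprintf("%.1f%% ± %.1f%%", m, s)
  cat(sprintf("Cohort of %d case%s\n", x$n, if (x$n == 1) "" else "s"))
  cat("  regeneration, > 800 HU:", fmt(x$mean_800, x$sd_800), "\n")
  cat("  regeneration, > 400 HU:", fmt(x$mean_400, x$sd_400), "\n")
  if (!is.na(x$shapiro_p_800))
    cat(sprintf("  Shapiro-Wilk p: %.3f (800 HU), %.3f (400 HU)\n",
                x$shapiro_p_800, x$shapiro_p_400))
  cat(sprintf("  cases > 70%%: %d; < 50%%: %d; < 40%%: %d (at 800 HU)\n",
              x$count_above_70_800, x$count_below_50_800,
              x$count_below_40_800))
  invisible(x)
}

#' @export
as.data.frame.cohort_summary <- function(x, ...) {
  data.frame(case = seq_along(x$pct_800),
             regen_pct_800 = x$pct_800,
             regen_pct_400 = x$pct_400)
}
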