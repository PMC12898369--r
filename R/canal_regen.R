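# Front-end estimator: volume + centerline + landmarks -> regeneration.

#' Quantify mandibular canal regeneration
#'
#' The package's main entry point. Resamples cross-sections perpendicular
#' to the canal centerline, scores each against the four canal criteria
#' (continuity, wall density at > 800 / > 400 HU, >= 270 degree enclosure,
#' tubular morphology) and measures what fraction of the implant-bounded
#' defect segment carries a regenerated canal.
#'
#' @param volume an [hu_volume()] (see [read_volume()]).
#' @param centerline a [centerline()] tracing the nerve/canal axis.
#' @param landmarks a [landmark_pair()]: mesial and distal implant apices.
#' @param params a [scoring_params()].
#' @param step_mm section spacing along the axis; default 0.3 mm.
#' @param patch_mm section patch side; default twice the wall-search band
#'   plus 1 mm.
#' @param in_plane_mm in-plane sample spacing; default the smallest voxel
#'   dimension.
#' @return An object of class `canal_regen` with the per-case
#'   `report` (a `regen_report`), the per-section `verdicts`, the defect
#'   `interval`, `params` and the matched call. Methods: `print`,
#'   `summary`, `plot`, `as.data.frame`.
#' @examples
#' ph <- build_phantom(phantom_spec(shape = c(40, 40, 50)))
#' fit <- canal_regen(ph$volume, ph$truth$centerline, ph$truth$landmarks)
#' fit
#' @export
canal_regen <- function(volume, centerline, landmarks,
                        params = scoring_params(), step_mm = 0.3,
                        patch_mm = NULL, in_plane_mm = NULL) {
  patch_mm <- patch_mm %||% (2 * params$band_outer_mm + 1)
  sections <- resample_sections(volume, centerline, step_mm = step_mm,
                                patch_mm = patch_mm,
                                in_plane_mm = in_plane_mm)
  verdicts <- score_sections(sections, params)
  interval <- defect_interval(centerline, landmarks)
  report <- regeneration_report(verdicts, interval, params,
                                step_mm = step_mm)
  structure(list(report = report, verdicts = verdicts,
                 interval = interval, params = params,
                 step_mm = step_mm, n_sections = nrow(verdicts),
                 call = match.call()),
            class = "canal_regen")
}

#' @export
print.canal_regen <- function(x, ...) {
  cat("Canal regeneration analysis\n")
  cat("Call: ", deparse(x$call), "\n\n", sep = "")
  print(x$report)
  invisible(x)
}

#' @export
summary.canal_regen <- function(object, ...) {
  structure(list(fit = object), class = "summary.canal_regen")
}

#' @export
print.summary.canal_regen <- function(x, ...) {
  f <- x$fit
  print(f)
  v <- f$verdicts
  cat(sprintf("\nSections: %d scored, %d inside the defect interval\n",
              nrow(v), f$report$n_stations))
  cat(sprintf("  passing: %d (mature), %d (early)\n",
              sum(v$pass_mature), sum(v$pass_early)))
  if (any(v$low_confidence))
    cat(sprintf("  %d section(s) flagged low-confidence (metal occlusion > %.0f%% of rays)\n",
                sum(v$low_confidence), 100 * f$params$occlusion_max_frac))
  pr <- function(runs, lab) {
    if (nrow(runs) == 0) cat("  no runs at", lab, "\n")
    else for (i in seq_len(nrow(runs)))
      cat(sprintf("  run [%s]: s %.2f .. %.2f mm, %.2f mm canal\n",
                  lab, runs$s_start[i], runs$s_end[i], runs$length_mm[i]))
  }
  cat("\nContinuity runs inside the defect:\n")
  pr(f$report$runs_800, "> 800 HU")
  pr(f$report$runs_400, "> 400 HU")
  invisible(x)
}

#' @export
as.data.frame.canal_regen <- function(x, ...) {
  as.data.frame(unclass(x$verdicts), ...)
}

#' Plot the per-station enclosure trace
#'
#' Enclosure angle against arc-length station at both thresholds, with the
#' 270 degree acceptance bound, the defect interval, and the accepted
#' mature-threshold runs shaded.
#'
#' @param x a `canal_regen` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.canal_regen <- function(x, ...) {
  v <- x$verdicts
  graphics::plot(v$station_s, v$enclosure_early, type = "l", col = "grey50",
                 ylim = c(0, 370), xlab = "station s (mm)",
                 ylab = "enclosure angle (deg)", ...)
  graphics::lines(v$station_s, v$enclosure_mature, col = "black")
  r <- x$report$runs_800
  if (nrow(r)) graphics::rect(r$s_start, 0, r$s_end, 370,
                              col = grDevices::adjustcolor("steelblue", 0.15),
                              border = NA)
  graphics::abline(h = x$params$enclosure_min_deg, lty = 2)
  graphics::abline(v = c(x$interval$s_start, x$interval$s_end), lty = 3)
  graphics::legend("bottomleft",
                   legend = c("> 400 HU", "> 800 HU", "enclosure bound",
                              "defect limits"),
                   col = c("grey50", "black", "black", "black"),
                   lty = c(1, 1, 2, 3), bty = "n", cex = 0.8)
  invisible(x)
}
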