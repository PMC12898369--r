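# Cross-section resampling along the centerline and the defect interval.

#' Resample cross-sections perpendicular to the centerline
#'
#' Sections are the unit of analysis for the canal criteria: square HU
#' patches sampled by trilinear interpolation on the plane orthogonal to the
#' local centerline tangent, at stations `0, step, 2*step, ...` along the
#' arc. Tangents are central differences of the station positions (one-sided
#' at the endpoints) and the in-plane (u, v) frame is transported along the
#' axis with minimal rotation, so it is continuous from section to section;
#' enclosure angles are rotation-invariant, so only continuity matters.
#'
#' @param v an [hu_volume()].
#' @param c a [centerline()]; every point must lie inside the volume's
#'   world bounding box.
#' @param step_mm station spacing, mm; default 0.3 (one native voxel of the
#'   default imaging protocol, i.e. "sequential sections" at scanner
#'   resolution).
#' @param patch_mm side length of the square patch, mm. Must cover twice the
#'   wall-search annulus of the scoring step.
#' @param in_plane_mm in-plane sample spacing; default `min(v$spacing)`.
#' @return A list of `cross_section` objects (fields `station_s`, `center`,
#'   `normal`, `u`, `v`, `grid`, `offsets`, `in_plane_spacing`, `oob_count`),
#'   with the station step attached as attribute `step_mm`. Patch samples
#'   falling outside the volume are filled with -1024 HU and counted in
#'   `oob_count`; a section with no in-bounds sample is an error.
#' @export
resample_sections <- function(v, c, step_mm = 0.3, patch_mm = 10,
                              in_plane_mm = NULL) {
  if (!inherits(v, "hu_volume")) stop_input("v must be an hu_volume")
  if (!inherits(c, "centerline")) stop_input("c must be a centerline")
  if (step_mm <= 0) stop_input("step_mm must be > 0")
  in_plane_mm <- in_plane_mm %||% min(v$spacing)
  bb <- world_bbox(v)
  eps <- 1e-9
  inside <- c$points[, 1] >= bb[1, 1] - eps & c$points[, 1] <= bb[2, 1] + eps &
            c$points[, 2] >= bb[1, 2] - eps & c$points[, 2] <= bb[2, 2] + eps &
            c$points[, 3] >= bb[1, 3] - eps & c$points[, 3] <= bb[2, 3] + eps
  if (!all(inside))
    stop_geometry("centerline extends outside the volume bounding box")

  L <- total_arc_length(c)
  stations <- (0:floor(L / step_mm + 1e-9)) * step_mm
  P <- point_at_arc(c, stations)
  n <- length(stations)

  # central-difference tangents, one-sided at the ends
  tangents <- matrix(0, n, 3L)
  if (n >= 2L) {
    tangents[1L, ] <- P[2L, ] - P[1L, ]
    tangents[n, ] <- P[n, ] - P[n - 1L, ]
    if (n > 2L)
      tangents[2:(n - 1L), ] <- P[3:n, ] - P[1:(n - 2L), ]
  } else {
    tangents[1L, ] <- c$points[2L, ] - c$points[1L, ]
  }
  tangents <- tangents / sqrt(rowSums(tangents^2))

  # minimal-rotation frame transport
  t0 <- tangents[1L, ]
  seed_axis <- diag(3)[, which.min(abs(t0))]
  u <- seed_axis - sum(seed_axis * t0) * t0
  u <- u / vnorm(u)

  half <- floor((patch_mm / 2) / in_plane_mm + 1e-9)
  off <- (-half:half) * in_plane_mm
  m <- length(off)
  A <- as.vector(matrix(off, m, m))            # u-offsets vary along rows
  B <- as.vector(matrix(off, m, m, byrow = TRUE))

  sections <- vector("list", n)
  for (k in seq_len(n)) {
    tk <- tangents[k, ]
    u <- u - sum(u * tk) * tk
    u <- u / vnorm(u)
    w <- c(tk[2] * u[3] - tk[3] * u[2],
           tk[3] * u[1] - tk[1] * u[3],
           tk[1] * u[2] - tk[2] * u[1])
    pts <- cbind(P[k, 1] + A * u[1] + B * w[1],
                 P[k, 2] + A * u[2] + B * w[2],
                 P[k, 3] + A * u[3] + B * w[3])
    smp <- trilinear_sample(v, pts)
    if (all(smp$oob))
      stop_geometry(sprintf("section at s = %.3f mm lies fully outside the volume",
                            stations[k]))
    sections[[k]] <- structure(
      list(station_s = stations[k], center = P[k, ], normal = tk,
           u = u, v = w, grid = matrix(smp$values, m, m),
           offsets = off, in_plane_spacing = in_plane_mm,
           oob_count = sum(smp$oob)),
      class = "cross_section")
  }
  attr(sections, "step_mm") <- step_mm
  sections
}

#' Locate the defect interval on the centerline
#'
#' Maps the two implant apices onto the centerline: `s_start` and `s_end`
#' are the arc-length coordinates of the centerline points nearest the
#' mesial and distal apex (ties resolved toward smaller arc length). The
#' defect length is the straight-line Euclidean distance between the apices
#' — on a curved axis this chord is shorter than the arc, which is why the
#' regeneration percentage is clipped at 100 downstream.
#'
#' @param c a [centerline()].
#' @param lm a [landmark_pair()].
#' @return An object of class `defect_interval` with `s_start`, `s_end`
#'   (mm, `s_start < s_end`) and `defect_length` (mm).
#' @export
defect_interval <- function(c, lm) {
  if (!inherits(c, "centerline")) stop_input("c must be a centerline")
  if (!inherits(lm, "landmark_pair")) stop_input("lm must be a landmark_pair")
  nearest_s <- function(p) {
    d2 <- (c$points[, 1] - p[1])^2 + (c$points[, 2] - p[2])^2 +
      (c$points[, 3] - p[3])^2
    c$arc_length[which.min(d2)]   # which.min takes the first (smaller s) tie
  }
  sa <- nearest_s(lm$mesial_apex)
  sb <- nearest_s(lm$distal_apex)
  if (sa == sb)
    stop_geometry("both apices map to the same centerline point (degenerate defect)")
  structure(list(s_start = min(sa, sb), s_end = max(sa, sb),
                 defect_length = lm$defect_length),
            class = "defect_interval")
}

#' @export
print.defect_interval <- function(x, ...) {
  cat(sprintf("Defect: s in [%.2f, %.2f] mm, linear defect length %.2f mm\n",
              x$s_start, x$s_end, x$defect_length))
  invisible(x)
}
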