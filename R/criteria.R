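# The four canal-identification criteria, per section and per run.
#
# Criterion 2 (wall density) is embodied in the HU threshold in use
# (> 800 HU mature bone, > 400 HU early mineralizing bone, upper bone bound
# 3071 HU). Criterion 3 (>= 270 deg circumferential enclosure) is measured
# by radial ray casting. Criterion 4 (tubular/circular morphology) is a
# radial-uniformity score. Criterion 1 (continuity across sequential
# sections) is applied across sections by find_runs().

#' Scoring parameters
#'
#' Collects every tunable of the criteria with its default. Thresholds and
#' the 270 degree enclosure bound follow the clinical criteria; the
#' circularity formula with its 0.6 default and the 0.9 mm (three sections
#' at 0.3 mm) minimum run are this package's operationalization of the
#' qualitative morphology and continuity criteria, and are deliberately
#' configurable.
#'
#' @param hu_mature HU threshold for mature bone walls; default 800.
#' @param hu_early HU threshold for early/partially mineralized walls;
#'   default 400.
#' @param hu_bone_upper upper bone bound; values at or above it are treated
#'   as clamped metal, default 3071.
#' @param enclosure_min_deg minimum circumferential enclosure; default 270.
#' @param ray_count rays per section; default 360 (1 degree resolution).
#' @param canal_radius_mm nominal lumen radius used to derive the default
#'   wall-search annulus; default 1.5.
#' @param band_inner_mm,band_outer_mm radial annulus searched for wall bone;
#'   defaults `0.8 * canal_radius_mm` and `canal_radius_mm + 3` (tolerates
#'   modest centerline error while excluding distant cortex).
#' @param min_wall_mm minimal contiguous supra-threshold radial chord for a
#'   ray to count as walled; default `NULL` = one in-plane sample.
#' @param circularity_min morphology acceptance bound; default 0.6.
#' @param min_run_mm minimal contiguous passing span kept by the continuity
#'   criterion; default 0.9 (shorter spans are isolated areas, not canal).
#' @param max_gap_sections failing sections tolerated inside a run;
#'   default 0.
#' @param occlusion_max_frac fraction of metal-occluded rays above which a
#'   section is flagged low-confidence; default 0.1.
#' @return An object of class `scoring_params`.
#' @export
scoring_params <- function(hu_mature = 800, hu_early = 400,
                           hu_bone_upper = 3071,
                           enclosure_min_deg = 270, ray_count = 360L,
                           canal_radius_mm = 1.5,
                           band_inner_mm = NULL, band_outer_mm = NULL,
                           min_wall_mm = NULL,
                           circularity_min = 0.6,
                           min_run_mm = 0.9, max_gap_sections = 0L,
                           occlusion_max_frac = 0.1) {
  band_inner_mm <- band_inner_mm %||% (0.8 * canal_radius_mm)
  band_outer_mm <- band_outer_mm %||% (canal_radius_mm + 3)
  if (!(hu_early > 0 && hu_early < hu_mature && hu_mature <= hu_bone_upper))
    stop_input("need 0 < hu_early < hu_mature <= hu_bone_upper")
  if (enclosure_min_deg <= 0 || enclosure_min_deg > 360)
    stop_input("enclosure_min_deg must lie in (0, 360]")
  if (band_inner_mm <= 0 || band_inner_mm >= band_outer_mm)
    stop_input("need 0 < band_inner_mm < band_outer_mm")
  if (ray_count < 8) stop_input("ray_count must be >= 8")
  if (circularity_min < 0 || circularity_min > 1)
    stop_input("circularity_min must lie in [0, 1]")
  if (min_run_mm < 0) stop_input("min_run_mm must be >= 0")
  if (max_gap_sections < 0) stop_input("max_gap_sections must be >= 0")
  structure(list(hu_mature = hu_mature, hu_early = hu_early,
                 hu_bone_upper = hu_bone_upper,
                 enclosure_min_deg = enclosure_min_deg,
                 ray_count = as.integer(ray_count),
                 canal_radius_mm = canal_radius_mm,
                 band_inner_mm = band_inner_mm, band_outer_mm = band_outer_mm,
                 min_wall_mm = min_wall_mm,
                 circularity_min = circularity_min,
                 min_run_mm = min_run_mm,
                 max_gap_sections = as.integer(max_gap_sections),
                 occlusion_max_frac = occlusion_max_frac),
            class = "scoring_params")
}

# Bilinear interpolation on a section grid at in-plane coordinates (a, b)
# relative to the section centre. a along u (rows), b along v (columns).
section_bilinear <- function(cs, a, b) {
  off <- cs$offsets
  dl <- cs$in_plane_spacing
  m <- length(off)
  ia <- (a - off[1]) / dl
  ib <- (b - off[1]) / dl
  if (any(ia < -1e-9 | ia > m - 1 + 1e-9 | ib < -1e-9 | ib > m - 1 + 1e-9))
    stop_geometry("sample outside the section patch")
  ia <- pmin(pmax(ia, 0), m - 1); ib <- pmin(pmax(ib, 0), m - 1)
  i0 <- pmin(floor(ia), m - 2); fa <- ia - i0
  j0 <- pmin(floor(ib), m - 2); fb <- ib - j0
  g <- cs$grid
  base <- 1 + i0 + m * j0
  c00 <- g[base]; c10 <- g[base + 1]
  c01 <- g[base + m]; c11 <- g[base + m + 1]
  (c00 * (1 - fa) + c10 * fa) * (1 - fb) + (c01 * (1 - fa) + c11 * fa) * fb
}

# HU profile along p$ray_count equally spaced rays from the section centre:
# matrix [ray, radial sample] over the wall-search annulus.
ray_profile <- function(cs, p) {
  half_extent <- max(cs$offsets)
  if (p$band_outer_mm > half_extent + 1e-9)
    stop_geometry(sprintf(
      "wall-search annulus (outer %.2f mm) exceeds the section patch (half-extent %.2f mm)",
      p$band_outer_mm, half_extent))
  dr <- cs$in_plane_spacing
  radii <- seq(p$band_inner_mm, p$band_outer_mm, by = dr)
  theta <- (seq_len(p$ray_count) - 1L) * 2 * pi / p$ray_count
  a <- outer(cos(theta), radii)
  b <- outer(sin(theta), radii)
  V <- matrix(section_bilinear(cs, as.vector(a), as.vector(b)),
              nrow = p$ray_count)
  list(V = V, radii = radii, dr = dr)
}

# Per-ray wall detection at one threshold. A ray is "walled" when, inside
# the annulus and before any clamped-metal sample, it crosses a contiguous
# supra-threshold chord of at least min_wall_mm. Rays blocked by metal
# before qualifying bone are "occluded" and leave the denominator.
ray_metrics <- function(prof, hu_thresh, p) {
  V <- prof$V
  nr <- nrow(V); nc <- ncol(V)
  min_wall <- p$min_wall_mm %||% prof$dr
  need <- max(1L, ceiling(min_wall / prof$dr - 1e-9))
  metal <- V >= p$hu_bone_upper
  # partial-volume guard: interpolated samples radially adjacent to metal
  # blend metal with soft tissue and can land in the bone range; they are
  # metal fringe, not wall bone
  metal_adj <- metal
  if (nc > 1L) {
    metal_adj[, -1L] <- metal_adj[, -1L] | metal[, -nc]
    metal_adj[, -nc] <- metal_adj[, -nc] | metal[, -1L]
  }
  bone <- V > hu_thresh & V < p$hu_bone_upper & !metal_adj
  run <- integer(nr); best <- integer(nr)
  alive <- rep(TRUE, nr); hit_metal <- rep(FALSE, nr)
  first_idx <- rep(NA_integer_, nr)
  for (j in seq_len(nc)) {
    m <- metal[, j] & alive
    hit_metal <- hit_metal | m
    alive <- alive & !metal[, j]
    bj <- bone[, j] & alive
    run <- ifelse(bj, run + 1L, 0L)
    best <- pmax(best, run)
    new_first <- is.na(first_idx) & bj
    first_idx[new_first] <- j
  }
  walled <- best >= need
  occluded <- hit_metal & !walled
  denom <- nr - sum(occluded)
  enclosure <- if (denom > 0) 360 * sum(walled) / denom else 0
  # longest contiguous walled arc (circular), recorded for sensitivity use
  contiguous <- if (all(walled)) 360 else if (!any(walled)) 0 else {
    r <- rle(c(walled, walled))
    maxrun <- max(r$lengths[r$values])
    360 * min(maxrun, nr) / nr
  }
  list(walled = walled, occluded = occluded,
       first_r = prof$radii[first_idx],
       enclosure = enclosure, contiguous = contiguous,
       occluded_frac = sum(occluded) / nr)
}

circ_from_radii <- function(r) {
  if (length(r) < 3L) return(0)
  rcv <- stats::mad(r) / stats::median(r)
  max(0, 1 - min(rcv, 1))
}

#' Circumferential enclosure angle of a cross-section
#'
#' Casts equally spaced rays from the section centre and measures the total
#' angular coverage (degrees) of rays that encounter supra-threshold wall
#' bone inside the wall-search annulus. Coverage is the union of walled
#' rays, not necessarily one contiguous arc; the longest contiguous arc is
#' attached as attribute `contiguous_deg` for sensitivity analyses. Rays
#' occluded by clamped metal before reaching bone are excluded from the
#' denominator (`occluded_frac` attribute).
#'
#' @param cs a `cross_section` from [resample_sections()].
#' @param hu_thresh wall density threshold (e.g. 800 or 400 HU).
#' @param p a [scoring_params()].
#' @return Enclosure angle in degrees \[0, 360\].
#' @export
enclosure_angle <- function(cs, hu_thresh, p = scoring_params()) {
  m <- ray_metrics(ray_profile(cs, p), hu_thresh, p)
  structure(m$enclosure, contiguous_deg = m$contiguous,
            occluded_frac = m$occluded_frac)
}

#' Tubularity/circularity score of a cross-section
#'
#' Among walled rays, takes the radial distance to the first supra-threshold
#' sample and scores the section as `1 - robust CV` of those radii (MAD /
#' median, clipped to \[0, 1\]). A circular canal wall keeps a near-constant
#' inner radius and scores near 1; fragmented or sheet-like bone scores low.
#' Sections with fewer than 3 walled rays score 0.
#'
#' @inheritParams enclosure_angle
#' @return Score in \[0, 1\].
#' @export
circularity <- function(cs, hu_thresh, p = scoring_params()) {
  m <- ray_metrics(ray_profile(cs, p), hu_thresh, p)
  circ_from_radii(m$first_r[m$walled])
}

#' Score every cross-section against the canal criteria
#'
#' Evaluates the density (thresholds), enclosure and morphology criteria at
#' both HU thresholds for each section. Morphology is assessed once per
#' section over the full bone range (> `hu_early`): the same `circularity`
#' value gates both thresholds. The continuity criterion across sections is
#' applied afterwards by [find_runs()].
#'
#' @param sections list of `cross_section`s ordered by station.
#' @param p a [scoring_params()].
#' @return A data.frame of class `section_verdicts` with one row per
#'   section: `station_s`, `enclosure_mature`, `enclosure_early`,
#'   `contiguous_mature`, `contiguous_early`, `circularity`,
#'   `occluded_frac`, `low_confidence`, `pass_mature`, `pass_early`.
#' @export
score_sections <- function(sections, p = scoring_params()) {
  if (length(sections) == 0L)
    stop_input("no sections to score")
  rows <- lapply(sections, function(cs) {
    prof <- ray_profile(cs, p)
    mm <- ray_metrics(prof, p$hu_mature, p)
    me <- ray_metrics(prof, p$hu_early, p)
    circ <- circ_from_radii(me$first_r[me$walled])
    data.frame(
      station_s = cs$station_s,
      enclosure_mature = mm$enclosure,
      enclosure_early = me$enclosure,
      contiguous_mature = mm$contiguous,
      contiguous_early = me$contiguous,
      circularity = circ,
      occluded_frac = me$occluded_frac,
      low_confidence = me$occluded_frac > p$occlusion_max_frac,
      pass_mature = mm$enclosure >= p$enclosure_min_deg &
        circ >= p$circularity_min,
      pass_early = me$enclosure >= p$enclosure_min_deg &
        circ >= p$circularity_min)
  })
  out <- do.call(rbind, rows)
  if (is.unsorted(out$station_s))
    stop_input("sections must be ordered by station_s")
  attr(out, "step_mm") <- attr(sections, "step_mm")
  class(out) <- c("section_verdicts", "data.frame")
  out
}

#' Continuity runs of passing sections
#'
#' The continuity criterion: maximal runs of criterion-passing sections,
#' tolerating at most `max_gap_sections` consecutive failures inside a run.
#' Runs whose passing span is shorter than `min_run_mm` are discarded as
#' isolated areas rather than true linear canal. A run's length is the
#' number of passing stations times the station step, so tolerated gaps do
#' not inflate the measured canal length.
#'
#' @param verdicts a `section_verdicts` data.frame from [score_sections()].
#' @param threshold_kind `"mature"` (> 800 HU) or `"early"` (> 400 HU).
#' @param p a [scoring_params()].
#' @param step_mm station spacing; defaults to the value recorded on
#'   `verdicts` (or the median station difference).
#' @return data.frame with columns `s_start`, `s_end` (stations of the
#'   first/last passing section of each run), `n_pass` and `length_mm`.
#' @export
find_runs <- function(verdicts, threshold_kind = c("mature", "early"),
                      p = scoring_params(), step_mm = NULL) {
  threshold_kind <- match.arg(threshold_kind)
  pass <- verdicts[[paste0("pass_", threshold_kind)]]
  s <- verdicts$station_s
  step_mm <- step_mm %||% attr(verdicts, "step_mm") %||%
    (if (length(s) > 1L) stats::median(diff(s)) else 0)
  empty <- data.frame(s_start = numeric(0), s_end = numeric(0),
                      n_pass = integer(0), length_mm = numeric(0))
  if (!any(pass)) return(empty)
  r <- rle(pass)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  pb <- which(r$values)          # indices of passing blocks
  groups <- list()
  cur <- pb[1L]
  if (length(pb) > 1L) for (i in 2:length(pb)) {
    gap_len <- starts[pb[i]] - ends[cur[length(cur)]] - 1L
    if (gap_len <= p$max_gap_sections) cur <- c(cur, pb[i])
    else { groups[[length(groups) + 1L]] <- cur; cur <- pb[i] }
  }
  groups[[length(groups) + 1L]] <- cur
  out <- lapply(groups, function(g) {
    i0 <- starts[g[1L]]; i1 <- ends[g[length(g)]]
    n_pass <- sum(r$lengths[g])
    data.frame(s_start = s[i0], s_end = s[i1], n_pass = n_pass,
               length_mm = n_pass * step_mm)
  })
  out <- do.call(rbind, out)
  out <- out[out$length_mm >= p$min_run_mm - 1e-9, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) empty else out
}

#' Angular-histogram enclosure oracle
#'
#' Independent voxel-space measurement of the enclosure angle, used to
#' validate the ray-casting path: every voxel of the slab within
#' `slab_halfwidth` of the plane through `center` orthogonal to `normal`,
#' inside the wall-search annulus and above the threshold, is classified by
#' its polar angle into 1 degree bins; the enclosure is the number of
#' occupied bins. Operates directly on the voxel grid — no resampling, no
#' interpolation, no rays.
#'
#' @param v an [hu_volume()].
#' @param center world-mm point on the canal axis.
#' @param normal unit canal-axis direction at `center`.
#' @param hu_thresh wall density threshold.
#' @param p a [scoring_params()] (annulus and upper bone bound are used).
#' @param slab_halfwidth half-thickness of the voxel slab, mm; default half
#'   the largest voxel dimension.
#' @return Occupied-bin enclosure angle in degrees.
#' @export
enclosure_oracle <- function(v, center, normal, hu_thresh,
                             p = scoring_params(), slab_halfwidth = NULL) {
  center <- as_point3(center, "center")
  normal <- as_point3(normal, "normal")
  normal <- normal / vnorm(normal)
  slab_halfwidth <- slab_halfwidth %||% (max(v$spacing) / 2)
  d <- dim(v$data)
  ii <- (seq_len(d[1]) - 1) * v$spacing[1] + v$origin[1]
  jj <- (seq_len(d[2]) - 1) * v$spacing[2] + v$origin[2]
  kk <- (seq_len(d[3]) - 1) * v$spacing[3] + v$origin[3]
  # restrict to voxels within band_outer of the centre on each axis
  sel <- function(w, c0) which(abs(w - c0) <= p$band_outer_mm + slab_halfwidth + 1e-9)
  si <- sel(ii, center[1]); sj <- sel(jj, center[2]); sk <- sel(kk, center[3])
  if (!length(si) || !length(sj) || !length(sk)) return(0)
  G <- expand.grid(x = ii[si], y = jj[sj], z = kk[sk])
  vals <- v$data[si, sj, sk]
  rel <- cbind(G$x - center[1], G$y - center[2], G$z - center[3])
  axial <- rel %*% normal
  keep <- abs(axial) <= slab_halfwidth + 1e-9
  rel_in <- rel[keep, , drop = FALSE] - as.vector(axial[keep]) %o% normal
  r <- sqrt(rowSums(rel_in^2))
  hu <- as.vector(vals)[keep]
  wall <- r >= p$band_inner_mm & r <= p$band_outer_mm &
    hu > hu_thresh & hu < p$hu_bone_upper
  if (!any(wall)) return(0)
  # polar angle in a fixed in-plane frame
  seed_axis <- diag(3)[, which.min(abs(normal))]
  u <- seed_axis - sum(seed_axis * normal) * normal
  u <- u / vnorm(u)
  w <- c(normal[2] * u[3] - normal[3] * u[2],
         normal[3] * u[1] - normal[1] * u[3],
         normal[1] * u[2] - normal[2] * u[1])
  ang <- atan2(rel_in[wall, , drop = FALSE] %*% w,
               rel_in[wall, , drop = FALSE] %*% u) * 180 / pi
  length(unique(floor((ang %% 360))))
}
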