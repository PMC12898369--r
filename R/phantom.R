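# Synthetic CT phantoms with analytic ground truth.
#
# A phantom is a block of trabecular-density background containing a tubular
# canal: a low-density lumen (the neurovascular bundle) surrounded by a
# partial annular wall whose angular coverage and HU vary along the canal
# axis according to a station table. This reproduces, with known truth, the
# radiographic situation scored by the pipeline: mature walls (> 800 HU),
# early mineralizing walls (400-800 HU), and wall-free gaps. Optional
# high-HU implant cylinders and additive Gaussian noise complete the scene.
#
# Voxel membership is decided by the voxel centre against the analytic
# surfaces (no anti-aliasing), so the per-station truth table is exact at
# voxel-centre resolution.

#' Specify a synthetic canal phantom
#'
#' The canal axis runs along z through the centre of the grid (optionally a
#' gentle sinusoid in x). The `stations` table assigns each arc-length
#' interval of the axis a wall coverage (degrees, a single contiguous arc
#' centred on the +x reference direction) and a wall HU. Ground truth for
#' the regeneration statistic is computed analytically from this table, not
#' from the rendered voxels.
#'
#' @param shape voxel counts per axis (length 3).
#' @param spacing voxel size mm (scalar or length 3); default 0.3, a typical
#'   CBCT protocol resolution.
#' @param canal_radius lumen radius, mm.
#' @param wall_thickness radial wall thickness, mm; must be at least one
#'   voxel diagonal so the rendered wall is watertight.
#' @param axis `list(kind = "straight")` or
#'   `list(kind = "sinusoid", amplitude =, period =)` (mm, x-deflection).
#' @param stations data.frame with columns `s0`, `s1` (arc-length interval,
#'   mm), `arc_deg` in \[0, 360\] and `hu`; intervals must be disjoint and
#'   cover \[0, total arc length\].
#' @param background_hu trabecular/graft background; default 150.
#' @param lumen_hu soft-tissue lumen value; default 40.
#' @param implants optional data.frame with columns `x`, `y`, `z` (cylinder
#'   centre, mm), `radius`, `length`, `hu`; cylinders are parallel to the
#'   x axis (buccolingual), emulating fixtures beside the canal.
#' @param noise_sd additive Gaussian HU noise (applied after rendering).
#' @param defect arc-length interval `c(s0, s1)` bounded by the landmarks;
#'   default: 2.1 mm in from either end of the axis. Ignored when implants
#'   are given (their apices define the landmarks).
#' @param seed RNG seed used for the noise draw.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(50, 50, 64),
                         spacing = 0.3,
                         canal_radius = 1.5,
                         wall_thickness = 1.0,
                         axis = list(kind = "straight"),
                         stations = NULL,
                         background_hu = 150,
                         lumen_hu = 40,
                         implants = NULL,
                         noise_sd = 0,
                         defect = NULL,
                         seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 2L))
    stop_spec("shape must give at least 2 voxels per axis")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (any(spacing <= 0)) stop_spec("spacing must be positive")
  if (canal_radius <= 0) stop_spec("canal_radius must be > 0")
  voxel_diag <- sqrt(sum(spacing^2))
  if (wall_thickness < voxel_diag)
    stop_spec(sprintf("wall_thickness (%.3g mm) must be >= one voxel diagonal (%.3g mm)",
                      wall_thickness, voxel_diag))
  if (noise_sd < 0) stop_spec("noise_sd must be >= 0")
  axis$kind <- match.arg(axis$kind %||% "straight", c("straight", "sinusoid"))
  if (axis$kind == "sinusoid") {
    if (is.null(axis$amplitude) || is.null(axis$period) || axis$period <= 0)
      stop_spec("sinusoid axis needs amplitude and period (> 0)")
  }

  L <- phantom_axis_length(shape, spacing, axis)

  if (is.null(stations))
    stations <- data.frame(s0 = 0, s1 = L, arc_deg = 360, hu = 1200)
  stations <- as.data.frame(stations)
  if (!all(c("s0", "s1", "arc_deg", "hu") %in% names(stations)))
    stop_spec("stations must have columns s0, s1, arc_deg, hu")
  stations <- stations[order(stations$s0), , drop = FALSE]
  tol <- 1e-6
  if (any(stations$s1 <= stations$s0))
    stop_spec("station intervals must have s1 > s0")
  if (abs(stations$s0[1]) > tol ||
      stations$s1[nrow(stations)] < L - tol ||
      (nrow(stations) > 1 &&
       any(abs(stations$s0[-1] - stations$s1[-nrow(stations)]) > tol)))
    stop_spec("station intervals must be disjoint and cover [0, axis length]")
  if (any(stations$arc_deg < 0 | stations$arc_deg > 360))
    stop_spec("station arc_deg must lie in [0, 360]")
  if (any(stations$hu < HU_MIN | stations$hu > HU_MAX))
    stop_spec("station hu must lie in [-1024, 3071]")

  if (!is.null(implants)) {
    implants <- as.data.frame(implants)
    if (!all(c("x", "y", "z", "radius", "length", "hu") %in% names(implants)))
      stop_spec("implants must have columns x, y, z, radius, length, hu")
  }

  if (is.null(defect)) {
    if (is.null(implants)) {
      margin <- 2.1
      if (L <= 2 * margin)
        stop_spec("axis too short for the default 2.1 mm defect margins")
      defect <- c(margin, L - margin)
    }
  } else {
    defect <- as.numeric(defect)
    if (length(defect) != 2L || defect[1] < 0 || defect[2] > L + tol ||
        defect[1] >= defect[2])
      stop_spec("defect must be an increasing interval within [0, axis length]")
  }

  structure(list(shape = shape, spacing = spacing,
                 canal_radius = canal_radius, wall_thickness = wall_thickness,
                 axis = axis, stations = stations,
                 background_hu = background_hu, lumen_hu = lumen_hu,
                 implants = implants, noise_sd = noise_sd,
                 defect = defect, seed = as.integer(seed),
                 axis_length = L),
            class = "phantom_spec")
}

# Arc length of the phantom axis over the grid's z extent.
phantom_axis_length <- function(shape, spacing, axis) {
  zext <- (shape[3] - 1) * spacing[3]
  if (axis$kind == "straight") return(zext)
  # numeric quadrature of sqrt(1 + x'(z)^2)
  z <- seq(0, zext, length.out = 4096L)
  dx <- axis$amplitude * 2 * pi / axis$period * cos(2 * pi * z / axis$period)
  sum(sqrt(1 + dx^2)) * (z[2] - z[1]) -
    0.5 * (sqrt(1 + dx[1]^2) + sqrt(1 + dx[length(z)]^2)) * (z[2] - z[1])
}

# Axis centre (x, y) and arc-length coordinate for each z slice.
phantom_axis_table <- function(spec) {
  sp <- spec$spacing; sh <- spec$shape
  z <- (seq_len(sh[3]) - 1) * sp[3]
  cx0 <- (sh[1] - 1) * sp[1] / 2
  cy0 <- (sh[2] - 1) * sp[2] / 2
  if (spec$axis$kind == "straight") {
    data.frame(z = z, cx = cx0, cy = cy0, s = z)
  } else {
    cx <- cx0 + spec$axis$amplitude * sin(2 * pi * z / spec$axis$period)
    dz <- diff(z)
    seg <- sqrt(dz^2 + diff(cx)^2)
    data.frame(z = z, cx = cx, cy = cy0, s = c(0, cumsum(seg)))
  }
}

#' Render a phantom volume and its ground truth
#'
#' Renders the scene described by a [phantom_spec()] and computes the truth
#' twin of the regeneration statistic analytically from the station table:
#' the fraction of the defect interval (by arc length) whose stations have
#' wall coverage >= 270 degrees and wall HU above each density threshold.
#' Truth is therefore exact and independent of rendering noise or implants.
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `phantom` with elements `volume` (an
#'   [hu_volume()]) and `truth` (centerline, landmarks, defect arc interval,
#'   the station table, `true_regen_fraction_800`, `true_regen_fraction_400`).
#' @examples
#' ph <- build_phantom(phantom_spec(shape = c(40, 40, 40)))
#' ph$truth$true_regen_fraction_800
#' @export
build_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop_spec("spec must be a phantom_spec")
  sh <- spec$shape; sp <- spec$spacing
  ax <- phantom_axis_table(spec)
  x <- (seq_len(sh[1]) - 1) * sp[1]
  y <- (seq_len(sh[2]) - 1) * sp[2]
  X <- matrix(x, sh[1], sh[2])
  Y <- matrix(y, sh[1], sh[2], byrow = TRUE)

  vol <- array(spec$background_hu, dim = sh)
  r_out <- spec$canal_radius + spec$wall_thickness
  # station row per slice (last interval closed on the right)
  srow <- findInterval(pmin(ax$s, spec$axis_length - 1e-9),
                       spec$stations$s0)
  srow <- pmin(pmax(srow, 1L), nrow(spec$stations))

  straight <- spec$axis$kind == "straight"
  if (straight) {
    dxm <- X - ax$cx[1]; dym <- Y - ax$cy[1]
    r2 <- dxm^2 + dym^2
    theta <- abs(atan2(dym, dxm)) * 180 / pi  # |angle| from +x reference
    lumen <- r2 < spec$canal_radius^2
    band <- !lumen & r2 < r_out^2
  }
  for (k in seq_len(sh[3])) {
    if (!straight) {
      dxm <- X - ax$cx[k]; dym <- Y - ax$cy[k]
      r2 <- dxm^2 + dym^2
      theta <- abs(atan2(dym, dxm)) * 180 / pi
      lumen <- r2 < spec$canal_radius^2
      band <- !lumen & r2 < r_out^2
    }
    slab <- matrix(spec$background_hu, sh[1], sh[2])
    st <- spec$stations[srow[k], ]
    if (st$arc_deg > 0) {
      wall <- band & theta <= st$arc_deg / 2
      slab[wall] <- st$hu
    }
    slab[lumen] <- spec$lumen_hu
    vol[, , k] <- slab
  }

  # implants: cylinders parallel to x
  if (!is.null(spec$implants)) {
    zc <- (seq_len(sh[3]) - 1) * sp[3]
    for (i in seq_len(nrow(spec$implants))) {
      im <- spec$implants[i, ]
      # lumen overlap check against the axis polyline
      dyz <- sqrt((ax$cy - im$y)^2 + (ax$z - im$z)^2)
      dx <- pmax(0, abs(ax$cx - im$x) - im$length / 2)
      gap <- sqrt(dx^2 + pmax(0, dyz - im$radius)^2)
      if (any(gap <= spec$canal_radius))
        stop_spec(sprintf("implant %d overlaps the canal lumen", i))
      inx <- abs(x - im$x) <= im$length / 2
      for (k in which(abs(zc - im$z) <= im$radius)) {
        iny <- (y - im$y)^2 + (zc[k] - im$z)^2 <= im$radius^2
        if (any(inx) && any(iny))
          vol[inx, iny, k] <- im$hu
      }
    }
  }

  if (spec$noise_sd > 0) {
    vol <- vol + with_seed(spec$seed,
                           array(stats::rnorm(length(vol), 0, spec$noise_sd),
                                 dim = sh))
  }
  volume <- hu_volume(vol, spacing = sp, origin = c(0, 0, 0))

  truth <- phantom_truth(spec, ax)
  structure(list(volume = volume, truth = truth, spec = spec),
            class = "phantom")
}

# Ground-truth centerline, landmarks and analytic regeneration fractions.
phantom_truth <- function(spec, ax = phantom_axis_table(spec)) {
  # dense polyline (~0.1 mm) along the axis
  s_fine <- seq(0, spec$axis_length, by = 0.1)
  if (spec$axis$kind == "straight") {
    pts <- cbind(ax$cx[1], ax$cy[1], s_fine)
  } else {
    z_fine <- stats::approx(ax$s, ax$z, xout = s_fine, rule = 2)$y
    pts <- cbind(ax$cx[1] + spec$axis$amplitude *
                   sin(2 * pi * z_fine / spec$axis$period),
                 ax$cy[1], z_fine)
  }
  cl <- centerline(pts)

  if (!is.null(spec$implants)) {
    apices <- t(apply(spec$implants, 1L, function(im) {
      ends <- rbind(c(im[["x"]] - im[["length"]] / 2, im[["y"]], im[["z"]]),
                    c(im[["x"]] + im[["length"]] / 2, im[["y"]], im[["z"]]))
      d <- apply(ends, 1L, function(e)
        min(sqrt((cl$points[, 1] - e[1])^2 + (cl$points[, 2] - e[2])^2 +
                   (cl$points[, 3] - e[3])^2)))
      ends[which.min(d), ]
    }))
    ord <- order(spec$implants$z)
    lm <- landmark_pair(apices[ord[1], ], apices[ord[length(ord)], ])
  } else {
    lm <- landmark_pair(point_at_arc(cl, spec$defect[1]),
                        point_at_arc(cl, spec$defect[2]))
  }
  di <- defect_interval(cl, lm)

  frac <- function(hu_min) {
    st <- spec$stations
    ok <- st$arc_deg >= 270 & st$hu > hu_min
    if (!any(ok)) return(0)
    lo <- pmax(st$s0[ok], di$s_start)
    hi <- pmin(st$s1[ok], di$s_end)
    sum(pmax(0, hi - lo)) / (di$s_end - di$s_start)
  }
  list(centerline = cl, landmarks = lm, defect_interval = di,
       per_station = spec$stations,
       true_regen_fraction_800 = frac(800),
       true_regen_fraction_400 = frac(400))
}

#' Draw a cohort of phantom specifications
#'
#' Generates `n` phantoms whose true mature-bone regeneration fractions are
#' drawn from a normal distribution truncated to \[0, 1\] (rejection
#' sampling), the demo regime used to emulate a patient cohort. Each phantom
#' places a fully enclosed high-density wall (330 deg, 1200 HU) over the
#' regenerated part of the defect and an under-enclosed wall (120 deg) over
#' the rest, plus 30 HU Gaussian noise.
#'
#' @param n number of cases (>= 1).
#' @param regen_mean,regen_sd mean and sd of the truncated normal for the
#'   true regeneration fraction at the mature (> 800 HU) threshold; defaults
#'   0.727 and 0.13.
#' @param seed integer seed; the draw (and each phantom's noise seed) is
#'   deterministic given `seed`.
#' @return A list of [phantom_spec()] objects; the drawn fractions are
#'   attached as attribute `target_fractions`.
#' @export
sample_cohort <- function(n, regen_mean = 0.727, regen_sd = 0.13, seed = 1L) {
  if (n < 1) stop_spec("n must be >= 1")
  if (regen_mean < 0 || regen_mean > 1)
    stop_spec("regen_mean must lie in [0, 1]")
  if (regen_sd < 0) stop_spec("regen_sd must be >= 0")
  draws <- with_seed(seed, {
    f <- if (regen_sd == 0) rep(regen_mean, n) else {
      out <- numeric(0)
      while (length(out) < n) {
        cand <- stats::rnorm(2L * n, regen_mean, regen_sd)
        out <- c(out, cand[cand >= 0 & cand <= 1])
      }
      out[seq_len(n)]
    }
    list(f = f, case_seeds = sample.int(.Machine$integer.max - 1L, n))
  })

  specs <- vector("list", n)
  shape <- c(50, 50, 64); spacing <- 0.3
  L <- (shape[3] - 1) * spacing
  d0 <- 2.1; d1 <- L - 2.1
  for (i in seq_len(n)) {
    f <- draws$f[i]
    cut <- d0 + f * (d1 - d0)
    st <- data.frame(
      s0      = c(0,  d0,  cut, d1),
      s1      = c(d0, cut, d1,  L),
      arc_deg = c(0,  330, 120, 0),
      hu      = c(0, 1200, 1200, 0))
    st <- st[st$s1 - st$s0 > 1e-9, , drop = FALSE]
    specs[[i]] <- phantom_spec(shape = shape, spacing = spacing,
                               stations = st, noise_sd = 30,
                               defect = c(d0, d1),
                               seed = draws$case_seeds[i])
  }
  attr(specs, "target_fractions") <- draws$f
  specs
}
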