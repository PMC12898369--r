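# Shared phantom builders for the test suite. Everything is generated in
# code; nothing is read from fixtures on disk.

# Standard cohort-style geometry: straight axis, 18.9 mm long, defect
# between 2.1 and 16.8 mm; a passing wall (arc/hu) over the leading
# fraction `frac` of the defect and an under-enclosed wall over the rest.
station_table <- function(frac, arc = 330, hu = 1200, fail_arc = 120,
                          fail_hu = 1200, L = 18.9, d0 = 2.1, d1 = 16.8) {
  cut <- d0 + frac * (d1 - d0)
  st <- data.frame(s0 = c(0, d0, cut, d1), s1 = c(d0, cut, d1, L),
                   arc_deg = c(0, arc, fail_arc, 0),
                   hu = c(0, hu, fail_hu, 0))
  st[st$s1 - st$s0 > 1e-9, , drop = FALSE]
}

simple_phantom <- function(frac = 1, arc = 330, hu = 1200, noise_sd = 0,
                           seed = 1, fail_arc = 120, shape = c(50, 50, 64)) {
  L <- (shape[3] - 1) * 0.3
  build_phantom(phantom_spec(
    shape = shape,
    stations = station_table(frac, arc = arc, hu = hu, fail_arc = fail_arc,
                             L = L, d1 = L - 2.1),
    noise_sd = noise_sd, defect = c(2.1, L - 2.1), seed = seed))
}

# Fine-grid validation geometry for the enclosure oracle: 0.1 mm voxels and
# an 8 mm lumen so each voxel subtends well under one angular degree in the
# wall band; six axial segments carry the six analytic arcs. Cached: built
# once per test run.
.oracle_env <- new.env(parent = emptyenv())
oracle_phantom <- function() {
  if (!is.null(.oracle_env$ph)) return(.oracle_env$ph)
  arcs <- c(90, 180, 269, 271, 275, 360)
  sp <- 0.1; seg <- 0.9
  shape <- c(236, 236, round(length(arcs) * seg / sp) + 1)
  L <- (shape[3] - 1) * sp
  st <- data.frame(s0 = (seq_along(arcs) - 1) * seg,
                   s1 = seq_along(arcs) * seg, arc_deg = arcs, hu = 1000)
  st$s1[length(arcs)] <- L
  ph <- build_phantom(phantom_spec(
    shape = shape, spacing = sp, canal_radius = 8, wall_thickness = 1.5,
    stations = st, defect = c(0.3, L - 0.3)))
  params <- scoring_params(canal_radius_mm = 8)
  sections <- resample_sections(ph$volume, ph$truth$centerline,
                                step_mm = 0.45,
                                patch_mm = 2 * params$band_outer_mm + 1,
                                in_plane_mm = 0.1)
  ss <- vapply(sections, `[[`, 0, "station_s")
  mid <- (st$s0 + st$s1) / 2
  .oracle_env$ph <- list(
    phantom = ph, arcs = arcs, params = params,
    sections = lapply(mid, function(m) sections[[which.min(abs(ss - m))]]))
  .oracle_env$ph
}

# Synthetic cross-section built directly from an analytic HU field
# hu_fun(a, b) (vectorized over in-plane mm coordinates).
make_section <- function(hu_fun, patch = 10, dl = 0.1) {
  half <- floor((patch / 2) / dl)
  off <- (-half:half) * dl
  m <- length(off)
  A <- matrix(off, m, m)
  B <- matrix(off, m, m, byrow = TRUE)
  structure(list(station_s = 0, center = c(0, 0, 0), normal = c(0, 0, 1),
                 u = c(1, 0, 0), v = c(0, 1, 0),
                 grid = matrix(hu_fun(as.vector(A), as.vector(B)), m, m),
                 offsets = off, in_plane_spacing = dl, oob_count = 0L),
            class = "cross_section")
}

# Hand-built verdict table for run/report tests.
make_verdicts <- function(pass_mature, pass_early = pass_mature,
                          step = 0.3, s0 = 0) {
  n <- length(pass_mature)
  v <- data.frame(station_s = s0 + (0:(n - 1)) * step,
                  enclosure_mature = ifelse(pass_mature, 360, 0),
                  enclosure_early = ifelse(pass_early, 360, 0),
                  contiguous_mature = 0, contiguous_early = 0,
                  circularity = 1, occluded_frac = 0,
                  low_confidence = FALSE,
                  pass_mature = pass_mature, pass_early = pass_early)
  attr(v, "step_mm") <- step
  class(v) <- c("section_verdicts", "data.frame")
  v
}

# Independent brute-force reference for the continuity/gap rule: greedy
# maximal runs over the pass vector, run length = passing stations * step.
bf_runs <- function(pass, max_gap, min_run, step) {
  n <- length(pass)
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (!pass[i]) { i <- i + 1L; next }
    last_pass <- i; k <- i + 1L; fails <- 0L
    while (k <= n) {
      if (pass[k]) { last_pass <- k; fails <- 0L }
      else { fails <- fails + 1L; if (fails > max_gap) break }
      k <- k + 1L
    }
    n_pass <- sum(pass[i:last_pass])
    if (n_pass * step >= min_run - 1e-9)
      runs[[length(runs) + 1L]] <- c(i, last_pass, n_pass)
    i <- last_pass + 1L
    while (i <= n && !pass[i]) i <- i + 1L
  }
  runs
}

# Straight-axis fit helper.
fit_phantom <- function(ph, ...) {
  canal_regen(ph$volume, ph$truth$centerline, ph$truth$landmarks, ...)
}
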