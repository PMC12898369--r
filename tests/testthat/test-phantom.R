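test_that("analytic truth fractions follow the station table", {
  # fully walled, dense canal
  ph <- simple_phantom(frac = 1, arc = 360, hu = 1200)
  expect_equal(ph$truth$true_regen_fraction_800, 1.0)
  expect_equal(ph$truth$true_regen_fraction_400, 1.0)

  # no wall anywhere
  L <- 18.9
  ph0 <- build_phantom(phantom_spec(
    stations = data.frame(s0 = 0, s1 = L, arc_deg = 0, hu = 0)))
  expect_equal(ph0$truth$true_regen_fraction_800, 0)
  expect_equal(ph0$truth$true_regen_fraction_400, 0)

  # 70% of the defect at 300 deg, 30% at 90 deg: only the first counts
  ph70 <- simple_phantom(frac = 0.7, arc = 300, hu = 1000, fail_arc = 90)
  # independent oracle: integrate passing interval lengths over the defect
  st <- ph70$spec$stations
  di <- ph70$truth$defect_interval
  ok <- st$arc_deg >= 270 & st$hu > 800
  expected <- sum(pmax(0, pmin(st$s1[ok], di$s_end) -
                          pmax(st$s0[ok], di$s_start))) /
    (di$s_end - di$s_start)
  expect_equal(expected, 0.7, tolerance = 1e-12)
  expect_equal(ph70$truth$true_regen_fraction_800, 0.7, tolerance = 1e-12)

  # early-but-not-mature bone counts only at the 400 HU threshold
  ph600 <- simple_phantom(frac = 0.5, arc = 330, hu = 600)
  expect_equal(ph600$truth$true_regen_fraction_800, 0)
  expect_equal(ph600$truth$true_regen_fraction_400, 0.5, tolerance = 1e-12)
  expect_lte(ph600$truth$true_regen_fraction_800,
             ph600$truth$true_regen_fraction_400)
})

test_that("noiseless rendering puts exact HU at voxel centres", {
  sp <- 0.3
  ph <- simple_phantom(frac = 1, arc = 330, hu = 1000)
  spec <- ph$spec
  d <- dim(ph$volume$data)
  cx <- (d[1] - 1) * sp / 2
  cy <- (d[2] - 1) * sp / 2
  # independent membership recomputation at voxel centres
  x <- (seq_len(d[1]) - 1) * sp
  y <- (seq_len(d[2]) - 1) * sp
  X <- matrix(x, d[1], d[2]); Y <- matrix(y, d[1], d[2], byrow = TRUE)
  r <- sqrt((X - cx)^2 + (Y - cy)^2)
  th <- abs(atan2(Y - cy, X - cx)) * 180 / pi
  k <- 20L  # a slice inside the walled station (s = 5.7 mm)
  st <- spec$stations[findInterval((k - 1) * sp, spec$stations$s0), ]
  lumen <- r < spec$canal_radius
  wall <- !lumen & r < spec$canal_radius + spec$wall_thickness &
    th <= st$arc_deg / 2
  slab <- ph$volume$data[, , k]
  expect_true(all(slab[lumen] == spec$lumen_hu))
  expect_true(all(slab[wall] == st$hu))
  expect_true(all(slab[!lumen & !wall] == spec$background_hu))
})

test_that("truth is invariant to noise and implants", {
  a <- simple_phantom(frac = 0.6, noise_sd = 0)
  b <- simple_phantom(frac = 0.6, noise_sd = 80, seed = 99)
  expect_equal(a$truth$true_regen_fraction_800,
               b$truth$true_regen_fraction_800)
  L <- 18.9
  imp <- data.frame(x = 12, y = 7.35, z = c(2.1, 16.8),
                    radius = 1.2, length = 6, hu = 3071)
  ph <- build_phantom(phantom_spec(
    stations = station_table(0.6), implants = imp))
  expect_equal(ph$truth$true_regen_fraction_800, 0.6, tolerance = 0.02)
  # apices sit at the implant end-caps nearest the canal
  expect_equal(ph$truth$landmarks$mesial_apex[3], 2.1)
  expect_equal(ph$truth$landmarks$mesial_apex[1], 9)
})

test_that("invalid phantom specifications are rejected", {
  expect_error(phantom_spec(stations = data.frame(
    s0 = 0, s1 = 5, arc_deg = 360, hu = 1200)),
    class = "canalregen_spec_error")          # does not cover the axis
  expect_error(phantom_spec(stations = data.frame(
    s0 = c(0, 8), s1 = c(10, 18.9), arc_deg = 360, hu = 1200)),
    class = "canalregen_spec_error")          # overlapping intervals
  expect_error(phantom_spec(wall_thickness = 0.1),
               class = "canalregen_spec_error")
  expect_error(phantom_spec(stations = data.frame(
    s0 = 0, s1 = 18.9, arc_deg = 400, hu = 1200)),
    class = "canalregen_spec_error")
  # implant through the lumen
  imp <- data.frame(x = 7.35, y = 7.35, z = 9, radius = 1, length = 6,
                    hu = 3071)
  expect_error(build_phantom(phantom_spec(implants = imp)),
               class = "canalregen_spec_error")
})

test_that("cohort draws are seeded, truncated and reproducible", {
  s1 <- sample_cohort(22, seed = 5)
  s2 <- sample_cohort(22, seed = 5)
  expect_identical(attr(s1, "target_fractions"), attr(s2, "target_fractions"))
  expect_identical(s1[[7]]$stations, s2[[7]]$stations)
  expect_length(s1, 22)

  # degenerate draw
  s0 <- sample_cohort(5, regen_mean = 0.5, regen_sd = 0, seed = 1)
  f0 <- vapply(s0, function(sp) build_phantom(sp)$truth$true_regen_fraction_800, 0)
  expect_equal(f0, rep(0.5, 5), tolerance = 1e-9)

  # law of large numbers against a direct Monte-Carlo truncation oracle
  f <- attr(sample_cohort(500, 0.727, 0.13, seed = 11), "target_fractions")
  expect_true(all(f >= 0 & f <= 1))
  set.seed(2024)
  mc <- rnorm(2e5, 0.727, 0.13)
  mc <- mc[mc >= 0 & mc <= 1]
  expect_equal(mean(f), mean(mc), tolerance = 0.02)
  expect_equal(mean(f), 0.727, tolerance = 0.02)
})

test_that("phantom artifacts on disk reproduce the in-memory phantom", {
  out <- file.path(tempdir(), "ph-io")
  spec <- phantom_spec(shape = c(40, 40, 48),
                       stations = station_table(0.5, L = 14.1, d1 = 12),
                       defect = c(2.1, 12), noise_sd = 10, seed = 3)
  cmd_phantom(spec, out)
  v <- read_volume(file.path(out, "volume.nii.gz"))
  ph <- build_phantom(spec)
  expect_equal(v$data, ph$volume$data, tolerance = 1e-12)
  cl <- read_centerline(file.path(out, "centerline.csv"))
  expect_equal(nrow(cl$points), nrow(ph$truth$centerline$points))
  truth <- jsonlite::read_json(file.path(out, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$true_regen_fraction_800,
               ph$truth$true_regen_fraction_800, tolerance = 1e-9)
})
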