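# Ideal annular wall field: lumen 40 HU, background 150 HU, wall `hu`
# between r0 and r1 over a contiguous arc (degrees, centred on +x).
annulus_field <- function(arc, hu = 1000, r0 = 1.5, r1 = 2.5,
                          lumen = 40, bg = 150) {
  function(a, b) {
    r <- sqrt(a^2 + b^2)
    th <- abs(atan2(b, a)) * 180 / pi
    out <- rep(bg, length(a))
    out[r < r0] <- lumen
    out[r >= r0 & r < r1 & th <= arc / 2] <- hu
    out
  }
}

test_that("enclosure angle recovers analytic arcs on ideal sections", {
  p <- scoring_params()
  cs_full <- make_section(annulus_field(360))
  expect_lt(abs(enclosure_angle(cs_full, 800, p) - 360), 1)  # one ray step
  cs_half <- make_section(annulus_field(180))
  e_half <- enclosure_angle(cs_half, 800, p)
  expect_lt(abs(e_half - 180), 1 + 1e-9)
  expect_lt(e_half, p$enclosure_min_deg)       # fails the 270-degree bound
  cs_275 <- make_section(annulus_field(275))
  expect_lt(abs(enclosure_angle(cs_275, 800, p) - 275), 2)
})

test_that("enclosure is monotone in the threshold and converges in rays", {
  p <- scoring_params()
  set.seed(31)
  for (i in 1:8) {
    arc <- runif(1, 30, 360)
    hu <- runif(1, 450, 1400)
    cs <- make_section(annulus_field(arc, hu = hu))
    e400 <- enclosure_angle(cs, 400, p)
    e800 <- enclosure_angle(cs, 800, p)
    expect_lte(e800, e400 + 1e-9)
  }
  # doubling the ray count changes the angle by < 1 degree (noiseless)
  cs <- make_section(annulus_field(275))
  p720 <- scoring_params(ray_count = 720L)
  expect_lt(abs(enclosure_angle(cs, 800, p720) -
                  enclosure_angle(cs, 800, p)), 1)
})

test_that("enclosure is invariant to in-plane rotation of the section", {
  cs <- make_section(annulus_field(200))
  m <- length(cs$offsets)
  rot <- cs
  rot$grid <- t(cs$grid)[m:1, ]   # 90-degree in-plane rotation
  p <- scoring_params()
  expect_lte(abs(enclosure_angle(rot, 800, p) - enclosure_angle(cs, 800, p)),
             360 / p$ray_count + 1e-9)
})

test_that("metal-occluded rays leave the enclosure denominator", {
  # wall ring everywhere except a 90-degree sector where clamped metal
  # replaces it: those rays hit metal before any bone
  f <- function(a, b) {
    r <- sqrt(a^2 + b^2)
    th <- abs(atan2(b, a)) * 180 / pi
    out <- rep(150, length(a))
    out[r < 1.5] <- 40
    out[r >= 1.5 & r < 2.5] <- ifelse(th[r >= 1.5 & r < 2.5] <= 45,
                                      3071, 1000)
    out
  }
  cs <- make_section(f)
  p <- scoring_params()
  e <- enclosure_angle(cs, 800, p)
  expect_gt(attr(e, "occluded_frac"), 0.15)      # ~90/360 rays occluded
  expect_lt(attr(e, "occluded_frac"), 0.30)
  expect_gt(as.numeric(e), 330)                  # remaining rays all walled
  v <- score_sections(structure(list(cs), step_mm = 0.3), p)
  expect_true(v$low_confidence)
})

test_that("circularity scores annuli high, ellipses by formula, voids zero", {
  p <- scoring_params()
  expect_gte(circularity(make_section(annulus_field(360)), 800, p), 0.95)
  expect_identical(circularity(make_section(function(a, b)
    rep(150, length(a))), 800, p), 0)

  # 2:1 elliptical wall; oracle = the same robust-CV score evaluated on the
  # closed-form polar radius of the ellipse
  ea <- 3; eb <- 1.5
  f <- function(a, b) {
    q <- sqrt((a / ea)^2 + (b / eb)^2)
    ifelse(q >= 1 & q < 1.25, 1000, ifelse(q < 1, 40, 150))
  }
  cs <- make_section(f, patch = 10, dl = 0.1)
  pfine <- scoring_params(band_inner_mm = 1.0, band_outer_mm = 4.0)
  got <- circularity(cs, 800, pfine)
  th <- (0:359) * pi / 180
  r_analytic <- 1 / sqrt((cos(th) / ea)^2 + (sin(th) / eb)^2)
  oracle <- 1 - min(1, stats::mad(r_analytic) / stats::median(r_analytic))
  expect_equal(got, oracle, tolerance = 0.05)
  expect_lt(got, 0.95)   # visibly less circular than a ring
})

test_that("section verdicts follow the phantom's station table", {
  L <- 10.2
  st <- data.frame(s0 = c(0, 7), s1 = c(7, L), arc_deg = c(300, 90),
                   hu = 1000)
  ph <- build_phantom(phantom_spec(shape = c(40, 40, 35), stations = st,
                                   defect = c(1, 9)))
  secs <- resample_sections(ph$volume, ph$truth$centerline, step_mm = 0.3,
                            patch_mm = 10)
  v <- score_sections(secs, scoring_params())
  inner <- v$station_s > 0.5 & v$station_s < 6.5   # clear of the transition
  outer <- v$station_s > 7.5
  expect_true(all(v$pass_mature[inner]))
  expect_true(all(v$pass_early[inner]))
  expect_false(any(v$pass_mature[outer]))
  expect_false(any(v$pass_early[outer]))
  expect_true(all(v$enclosure_early >= v$enclosure_mature - 1e-9))
})

test_that("a 600 HU wall passes only the early threshold", {
  ph <- simple_phantom(frac = 1, arc = 360, hu = 600)
  v <- score_sections(resample_sections(ph$volume, ph$truth$centerline,
                                        step_mm = 0.3, patch_mm = 10),
                      scoring_params())
  mid <- v$station_s > 2.2 & v$station_s < 16.7   # the walled interval
  expect_true(all(v$pass_early[mid]))
  expect_false(any(v$pass_mature[mid]))
})

test_that("an all-air volume passes nothing", {
  v <- hu_volume(array(-1000, dim = c(40, 40, 20)), spacing = 0.3)
  cl <- centerline(rbind(c(5.85, 5.85, 1), c(5.85, 5.85, 4.5)))
  verd <- score_sections(resample_sections(v, cl, step_mm = 0.3,
                                           patch_mm = 10),
                         scoring_params())
  expect_false(any(verd$pass_mature))
  expect_false(any(verd$pass_early))
  expect_true(all(verd$enclosure_early == 0))
  expect_error(score_sections(list(), scoring_params()),
               class = "canalregen_input_error")
})

test_that("continuity runs follow the gap and minimum-span rules", {
  p <- scoring_params()    # min_run 0.9 mm, max_gap 0, step 0.3
  v <- make_verdicts(c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))
  r <- find_runs(v, "mature", p)
  expect_equal(nrow(r), 2)
  expect_equal(r$length_mm, c(0.9, 0.9))
  expect_equal(r$s_start, c(0, 1.2))

  # a single passing section is an isolated area, not canal
  expect_equal(nrow(find_runs(make_verdicts(c(FALSE, TRUE, FALSE)),
                              "mature", p)), 0)

  # one tolerated gap merges the two runs across all seven stations
  p1 <- scoring_params(max_gap_sections = 1L)
  r1 <- find_runs(v, "mature", p1)
  expect_equal(nrow(r1), 1)
  expect_equal(c(r1$s_start, r1$s_end), c(0, 1.8))
  expect_equal(r1$n_pass, 6)              # gaps don't inflate the length
  expect_equal(r1$length_mm, 1.8)
})

test_that("runs agree with a brute-force reference on random patterns", {
  set.seed(77)
  for (i in 1:40) {
    n <- sample(5:30, 1)
    pass <- runif(n) < 0.55
    g <- sample(0:2, 1)
    min_run <- sample(c(0.3, 0.9, 1.5), 1)
    p <- scoring_params(max_gap_sections = g, min_run_mm = min_run)
    v <- make_verdicts(pass)
    got <- find_runs(v, "mature", p)
    ref <- bf_runs(pass, g, min_run, 0.3)
    expect_equal(nrow(got), length(ref))
    if (length(ref)) {
      ref_m <- do.call(rbind, ref)
      expect_equal(got$s_start, (ref_m[, 1] - 1) * 0.3)
      expect_equal(got$s_end, (ref_m[, 2] - 1) * 0.3)
      expect_equal(got$n_pass, ref_m[, 3])
    }
  }
})
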