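test_that("rate model evaluates 1/Tc + 2 rho/r and its limits", {
  p <- fixture_params_t2()
  expect_equal(rate_from_radius(0.7, p), 1 / 126.97 + 2 * 0.00116 / 0.7)
  expect_equal(rate_from_radius(0.7, p), 0.011190, tolerance = 1e-4)

  # zero relaxivity: rate is the cytoplasmic rate for any radius
  p0 <- surface_params("T2", Tc = 100, rho = 0)
  expect_equal(rate_from_radius(c(0.3, 1, 10), p0), rep(0.01, 3))

  # large-radius limit approaches 1/Tc
  expect_lt(abs(rate_from_radius(1e6, p) - 1 / p$Tc), 1e-8)

  # strictly decreasing in r
  r <- seq(0.2, 3, by = 0.1)
  expect_true(all(diff(rate_from_radius(r, p)) < 0))
  expect_error(rate_from_radius(-1, p), "positive")
})

test_that("radius inversion is the exact inverse of the rate model", {
  p <- fixture_params_t2()
  for (r in c(0.3, 0.7, 2.0)) {
    expect_equal(radius_from_relaxation(1 / rate_from_radius(r, p), p), r)
  }
  # worked inverse of the rate example
  expect_equal(radius_from_relaxation(89.4, p), 0.70, tolerance = 0.01)
  # no finite radius when Ta >= Tc
  expect_true(is.na(radius_from_relaxation(p$Tc, p)))
  expect_true(is.na(radius_from_relaxation(p$Tc + 10, p)))
  expect_error(radius_from_relaxation(-5, p), "positive")
})

test_that("effective radius is the r^2-to-r moment ratio", {
  expect_equal(effective_radius(rep(0.8, 25)), 0.8)
  expect_equal(effective_radius(c(0.5, 1.0)), 1.25 / 1.5)
  # per-ROI summary route assumes circular cross-sections
  expect_equal(effective_radius(mean_radius = 0.5, mean_area = pi * 0.25),
               0.5)
  expect_error(effective_radius(c(0.5, -1)), "positive")
  expect_error(effective_radius(), "Provide")
})

test_that("effective radius dominates the arithmetic mean (Cauchy-Schwarz)", {
  for (s in 1:20) {
    r <- sample_radii(50, "gamma", seed = s, shape = 3, scale = 0.2)
    expect_gte(effective_radius(r), mean(r) - 1e-12)
  }
  r <- sample_radii(50, "gamma", seed = 3, shape = 3, scale = 0.2)
  expect_gt(effective_radius(r), mean(r))  # strict for unequal radii
})

test_that("calibration recovers parameters from collinear points", {
  r <- c(0.5, 0.7, 0.9, 1.1)
  gen <- surface_params("T2", Tc = 120, rho = 0.0012)
  d <- tibble::tibble(r_eff = r, Ta = 1 / rate_from_radius(r, gen))
  cal <- calibrate(d, r_eff, Ta)
  expect_equal(cal$params$Tc, 120, tolerance = 1e-10)
  expect_equal(cal$params$rho, 0.0012, tolerance = 1e-10)
  expect_equal(cal$pearson_r, 1, tolerance = 1e-12)
  # prediction reproduces the calibration radii exactly on-line
  pred <- radius_from_relaxation(d$Ta, cal$params)
  expect_equal(pred, r, tolerance = 1e-9)
})

test_that("regression coefficients map to Tc = 1/intercept, rho = slope", {
  # intercept 0.0079 1/ms and slope 0.00116 um/ms imply
  # Tc ~ 126.6 ms and rho = 1.16 nm/ms
  expect_equal(1 / 0.0079, 126.6, tolerance = 1e-3)
  d <- tibble::tibble(r_eff = c(0.6, 0.8, 1.0, 1.2),
                      Ta = 1 / (0.0079 + 0.00116 * 2 / c(0.6, 0.8, 1.0, 1.2)))
  cal <- calibrate(d, r_eff, Ta)
  expect_equal(cal$intercept, 0.0079, tolerance = 1e-9)
  expect_equal(cal$slope, 0.00116, tolerance = 1e-9)
  expect_equal(cal$params$rho * 1000, 1.16, tolerance = 1e-6)  # nm/ms
})

test_that("two-point calibrations interpolate with undefined p", {
  d <- tibble::tibble(r_eff = c(0.5, 1.0), Ta = c(85, 105))
  cal <- calibrate(d, r_eff, Ta)
  expect_equal(cal$n_points, 2)
  expect_true(is.na(cal$slope_p))
  pred <- radius_from_relaxation(d$Ta, cal$params)
  expect_equal(pred, d$r_eff, tolerance = 1e-9)
})

test_that("invalid calibrations raise or warn", {
  # steep rate increase extrapolates to a negative intercept at x = 0,
  # i.e. a nonpositive cytoplasmic time
  d <- tibble::tibble(r_eff = c(1.0, 0.5), Ta = c(1000, 50))
  expect_error(calibrate(d, r_eff, Ta), "intercept")
  # rate decreasing with 2/r gives a negative relaxivity: warned, clamped
  d2 <- tibble::tibble(r_eff = c(0.5, 1.0), Ta = c(200, 100))
  expect_warning(cal <- calibrate(d2, r_eff, Ta), "negative")
  expect_equal(cal$params$rho, 0)
  expect_error(calibrate(tibble::tibble(r = 1, t = 100), r, t),
               "at least 2")
})

test_that("calibrations round-trip through the JSON file format", {
  r <- c(0.5, 0.7, 0.9, 1.1)
  gen <- surface_params("T2", Tc = 120, rho = 0.0012)
  d <- tibble::tibble(r_eff = r, Ta = 1 / rate_from_radius(r, gen))
  cal <- calibrate(d, r_eff, Ta)
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration(cal, path)
  back <- read_calibration(path)
  expect_equal(back$Tc, cal$params$Tc)
  expect_equal(back$rho, cal$params$rho)
  expect_equal(back$channel, "T2")
})

test_that("histology tables reduce to per-ROI effective radii", {
  dir <- withr::local_tempdir()
  # per-axon layout
  axons <- data.frame(roi_id = rep(c("ROI2", "ROI5"), each = 3),
                      radius_um = c(0.5, 1.0, 0.75, 0.6, 0.8, 1.0))
  write.csv(axons, file.path(dir, "axons.csv"), row.names = FALSE)
  h <- read_histology(file.path(dir, "axons.csv"))
  expect_equal(nrow(h), 2)
  expect_equal(h$r_eff_um[h$roi == "ROI2"],
               effective_radius(c(0.5, 1.0, 0.75)))
  expect_equal(h$n_axons, c(3, 3))

  # per-ROI summary layout with circular-geometry fallback
  summ <- data.frame(roi_id = "ROI8", mean_radius_um = 0.5,
                     mean_area_um2 = pi * 0.25, n_axons = 100)
  write.csv(summ, file.path(dir, "summ.csv"), row.names = FALSE)
  h2 <- read_histology(file.path(dir, "summ.csv"))
  expect_equal(h2$r_eff_um, 0.5)

  # shrinkage scales radii up (measured = true * factor)
  h3 <- read_histology(file.path(dir, "axons.csv"), shrinkage_factor = 0.8)
  expect_equal(h3$r_eff_um, h$r_eff_um / 0.8)
  expect_error(read_histology(file.path(dir, "axons.csv"),
                              shrinkage_factor = 1.5), "shrinkage")
  bad <- data.frame(x = 1)
  write.csv(bad, file.path(dir, "bad.csv"), row.names = FALSE)
  expect_error(read_histology(file.path(dir, "bad.csv")), "columns")
})

test_that("tidy/glance/autoplot methods work on calibrations", {
  d <- tibble::tibble(r_eff = c(0.5, 0.7, 0.9, 1.1),
                      Ta = c(80, 90, 97, 102))
  cal <- calibrate(d, r_eff, Ta)
  expect_setequal(tidy(cal)$term, c("rho", "Tc"))
  expect_named(glance(cal),
               c("slope", "intercept", "pearson_r", "slope_p", "n"))
  expect_s3_class(autoplot(cal), "ggplot")
})
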