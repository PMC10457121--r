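test_that("radius sampler is reproducible and respects its family", {
  r1 <- sample_radii(10, "discrete", seed = 3,
                     radii = c(0.5, 1.0), weights = c(0.2, 0.8))
  r2 <- sample_radii(10, "discrete", seed = 3,
                     radii = c(0.5, 1.0), weights = c(0.2, 0.8))
  expect_identical(r1, r2)
  expect_true(all(r1 %in% c(0.5, 1.0)))

  # gamma(3, 0.2): mean 0.6, sd 0.2*sqrt(3); sample mean within 3 SE
  g <- sample_radii(1e4, "gamma", seed = 5, shape = 3, scale = 0.2)
  se <- 0.2 * sqrt(3) / sqrt(1e4)
  expect_lt(abs(mean(g) - 0.6), 3 * se)
  expect_true(all(g > 0))

  expect_error(sample_radii(0, "gamma", seed = 1), "positive")
  expect_error(sample_radii(5, "discrete", seed = 1, radii = 1,
                            weights = c(0.5, 0.5)), "matching")
  expect_error(sample_radii(5, "gamma"), "seed")
})

test_that("T2 mixtures use spin-count (r^2) weights", {
  p <- fixture_params_t2()
  # weights for radii {0.5, 1.0} are 0.25/1.25 and 1/1.25
  m <- mixture_signal_t2(c(0.5, 1.0), p, K = 1, TEs = 80)
  w <- c(0.25, 1) / 1.25
  rates <- rate_from_radius(c(0.5, 1.0), p)
  expect_equal(as.numeric(m), sum(w * exp(-80 * rates)))

  # single radius reduces to the mono-exponential forward model
  m1 <- mixture_signal_t2(0.7, p, K = 1, TEs = 80)
  expect_equal(as.numeric(m1), exp(-80 * rate_from_radius(0.7, p)))
  expect_equal(as.numeric(m1), 0.4086, tolerance = 1e-3)

  # zero relaxivity: mono-exponential at Tc regardless of radii
  p0 <- surface_params("T2", Tc = 110, rho = 0)
  tes <- c(73, 93, 118, 150)
  m0 <- mixture_signal_t2(c(0.3, 0.9, 2.1), p0, K = 5, TEs = tes)
  expect_equal(as.numeric(m0), 5 * exp(-tes / 110))

  expect_error(mixture_signal_t2(0.7, fixture_params_t1(), 1, 80),
               "T2 channel")
})

test_that("T1 mixtures combine magnitude inversion-recovery factors", {
  p1 <- surface_params("T1", Tc = 870, rho = 0.000087)
  prot <- new_protocol(6000, TE = 80, TI = 400, TR = 1e9)
  radii <- c(0.5, 1.0)
  t1s <- 1 / rate_from_radius(radii, p1)
  w <- radii^2 / sum(radii^2)
  byhand <- sum(w * abs(1 - 2 * exp(-400 / t1s)))
  expect_equal(as.numeric(mixture_signal_t1(radii, p1, 1, prot)),
               byhand, tolerance = 1e-12)

  # single radius reduces to the joint model's inversion-recovery factor
  p9 <- protocol_preset("t1t2-9pt")
  one <- mixture_signal_t1(0.7, p1, 3, p9)
  t1 <- 1 / rate_from_radius(0.7, p1)
  expect_equal(as.numeric(one),
               3 * abs(1 - 2 * exp(-p9$TI / t1) + exp(-p9$TR / t1)),
               tolerance = 1e-12)

  # zero inversion time with negligible TR term returns K
  prot0 <- new_protocol(6000, TE = 80, TI = 0, TR = 1e9)
  expect_equal(as.numeric(mixture_signal_t1(radii, p1, 7, prot0)), 7)

  expect_error(mixture_signal_t1(radii, fixture_params_t2(), 1, prot),
               "T1 channel")
})

test_that("joint mixtures factorise for a single radius", {
  p2 <- fixture_params_t2()
  p1 <- fixture_params_t1()
  prot <- protocol_preset("t1t2-9pt")
  m <- mixture_signal_t1t2(0.7, p2, p1, 500, prot)
  expect_equal(as.numeric(m),
               signal_t1t2(500, 1 / rate_from_radius(0.7, p2),
                           1 / rate_from_radius(0.7, p1), prot),
               tolerance = 1e-12)
})

test_that("rician noise sampler matches closed-form moments", {
  # at v = 0 the magnitude is Rayleigh with mean sigma*sqrt(pi/2)
  x <- add_rician_noise(rep(0, 1e5), 1, seed = 9)
  se <- sqrt((2 - pi / 2)) / sqrt(1e5)
  expect_lt(abs(mean(x) - sqrt(pi / 2)), 3 * se)

  # second moment E[m^2] = v^2 + 2 sigma^2
  v <- 10
  y <- add_rician_noise(rep(v, 1e5), 2, seed = 10)
  expect_lt(abs(mean(y^2) - (v^2 + 2 * 4)) / (v^2 + 8), 0.01)

  expect_identical(add_rician_noise(c(1, 2), 0, seed = 1), c(1, 2))
  expect_identical(add_rician_noise(1:5 + 0, 0.5, seed = 2),
                   add_rician_noise(1:5 + 0, 0.5, seed = 2))
  expect_error(add_rician_noise(1, -1, seed = 1), "nonnegative")
})

test_that("mixture fits recover the effective radius in the Taylor regime", {
  p <- fixture_params_t2()
  tes <- protocol_preset("t2-4te")$TE
  # all radii >= 0.75 um keeps max(2 TE rho / r) <= 0.47 < 0.5
  radii <- sample_radii(3000, "discrete", seed = 21,
                        radii = c(0.75, 0.9, 1.1, 1.4),
                        weights = c(0.3, 0.3, 0.25, 0.15))
  expect_lte(max(2 * max(tes) * p$rho / radii), 0.5)
  m <- mixture_signal_t2(radii, p, K = 1, TEs = tes)
  fit <- fit_t2(as.numeric(m), tes)
  pred <- radius_from_relaxation(fit$T2a, p)
  reff <- effective_radius(radii)
  expect_lt(abs(pred - reff) / reff, 0.05)
})

test_that("effective-radius error grows as the Taylor condition is violated", {
  tes <- protocol_preset("t2-4te")$TE
  radii <- sample_radii(3000, "gamma", seed = 8, shape = 16, scale = 0.05)
  rmin <- min(radii)
  reff <- effective_radius(radii)
  errs <- vapply(c(0.25, 0.5, 1.0, 2.0), function(cond) {
    rho <- cond * rmin / (2 * max(tes))
    p <- surface_params("T2", Tc = 126.97, rho = rho)
    m <- mixture_signal_t2(radii, p, K = 1, TEs = tes)
    pred <- radius_from_relaxation(fit_t2(as.numeric(m), tes)$T2a, p)
    abs(pred - reff) / reff
  }, numeric(1))
  expect_true(all(diff(errs) > 0))
  expect_lt(errs[2], 0.05)  # condition 0.5 still within 5%
})

test_that("phantom voxels carry the exact mixture signal when noiseless", {
  p2 <- fixture_params_t2()
  rois <- list(roi1 = array(TRUE, c(4, 4, 1)))
  specs <- list(roi1 = list(n = 1, family = "discrete",
                            radii = 0.8, weights = 1))
  prot <- protocol_preset("t2-4te")
  ph <- make_phantom_dwi(rois, specs, p2, protocol = prot, K = 100,
                         sigma = 0, seed = 2, n_directions = 6)
  expected <- as.numeric(mixture_signal_t2(0.8, p2, 100, prot$TE))
  for (p in 1:4) {
    expect_true(all(abs(ph$blocks[[p]]$volume - expected[p]) < 1e-12))
  }
  # ground truth bookkeeping
  expect_equal(ph$truth$r_eff_um, 0.8)
  expect_equal(ph$truth$r_eff_um,
               effective_radius(ph$radii$roi1))
})

test_that("phantom rejects overlapping layouts and writes text outputs", {
  m <- array(TRUE, c(4, 4, 1))
  expect_error(
    make_phantom_dwi(list(a = m, b = m),
                     list(a = list(n = 1, family = "discrete", radii = 1,
                                   weights = 1),
                          b = list(n = 1, family = "discrete", radii = 1,
                                   weights = 1)),
                     fixture_params_t2(), protocol = protocol_preset("t2-4te"),
                     seed = 1),
    "overlap")

  dir <- withr::local_tempdir()
  rois <- list(roi1 = array(TRUE, c(4, 4, 1)))
  specs <- list(roi1 = list(n = 50, family = "gamma"))
  ph <- make_phantom_dwi(rois, specs, fixture_params_t2(),
                         protocol = protocol_preset("t2-4te"), sigma = 2,
                         seed = 4, n_directions = 6, out_dir = dir)
  expect_true(file.exists(file.path(dir, "protocol.yaml")))
  expect_true(file.exists(file.path(dir, "ground_truth.csv")))
  expect_equal(length(ph$paths), 4)
  back <- read_volume(ph$paths[1])
  expect_equal(dim(back), c(4, 4, 1, 6))
})
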