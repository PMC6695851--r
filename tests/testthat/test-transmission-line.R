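test_that("Womersley number and its correction factors evaluate exactly", {
  bp <- blood_properties()  # eta 0.035, rho 1.056
  # independent scalar evaluation: d0 = 0.5 cm, 72 bpm
  omega <- 2 * pi * 72 / 60
  W_ref <- 0.5 * sqrt(omega * 1.056 / (4 * 0.035))
  expect_equal(womersley(0.5, omega, bp), W_ref, tolerance = 1e-12)
  expect_equal(W_ref, 3.77, tolerance = 0.002)

  # linear in d0; vanishes with omega
  expect_equal(womersley(0.8, omega, bp) / womersley(0.4, omega, bp), 2)
  expect_lt(womersley(0.5, 1e-12, bp), 1e-5)
  expect_error(womersley(-0.5, omega, bp), "d0")

  expect_equal(womersley_coeffs(0), list(c1 = 0.45, c2 = 1.39))
  expect_equal(womersley_coeffs(1), list(c1 = 0.63, c2 = 1.372))
  expect_equal(womersley_coeffs(10), list(c1 = 2.25, c2 = 1.21))
})

test_that("line parameters follow the stated power laws and fixture values", {
  hemo <- fixture_hemo()
  bp <- blood_properties()
  v1 <- fixture_vessel()
  lp <- line_params(v1, hemo, bp)

  # independent scalar evaluation of every component
  W <- 0.5 * sqrt(hemo$omega * 1.056 / (4 * 0.035))
  c1 <- 0.18 * W + 0.45; c2 <- -0.018 * W + 1.39
  expect_equal(lp$W, W, tolerance = 1e-12)
  expect_equal(lp$R, c1 * 128 * 0.035 / (pi * 0.5^4), tolerance = 1e-12)
  expect_equal(lp$L, c2 * 4 * 1.056 / (pi * 0.5^2), tolerance = 1e-12)
  expect_identical(lp$G, 0)
  expect_equal(lp$C, (1 - 0.49^2) * pi * 0.5^3 / (4 * 0.05 * 4e6),
               tolerance = 1e-12)

  # halving d0 multiplies the d0^-4 resistance factor by 16 (fixed c1)
  v2 <- vessel_state(D = 0.6, d = 0.25, d0 = 0.25, h1 = 0.05, h2 = 0,
                     E = 4e6, sigma_p = 0.49)
  lp2 <- line_params(v2, hemo, bp)
  expect_equal((lp2$R / lp2$c1) / (lp$R / lp$c1), 16, tolerance = 1e-12)

  # compliance scales as d0^3, 1/h, 1/E
  v3 <- vessel_state(D = 1.2, d = 1, d0 = 1, h1 = 0.1, h2 = 0,
                     E = 8e6, sigma_p = 0.49)
  lp3 <- line_params(v3, hemo, bp)
  expect_equal(lp3$C / lp$C, (1 / 0.5)^3 * (0.05 / 0.1) * (4e6 / 8e6),
               tolerance = 1e-12)

  # printed-formula bookkeeping switch removes the pi
  lp_nopi <- line_params(v1, hemo, bp, poiseuille_pi = FALSE)
  expect_equal(lp_nopi$R / lp$R, pi, tolerance = 1e-12)
})

test_that("propagation constants are the principal telegrapher square root", {
  lossless <- structure(list(R = 0, L = 4, G = 0, C = 1e-6, omega = 7),
                        class = "line_params")
  pc <- propagation_constants(lossless)
  expect_equal(pc$alpha, 0, tolerance = 1e-12)
  expect_equal(pc$beta, 7 * sqrt(4 * 1e-6), tolerance = 1e-12)

  lp <- line_params(fixture_vessel(), fixture_hemo())
  pc <- propagation_constants(lp)
  expect_gte(pc$alpha, 0)
  expect_gte(pc$beta, 0)
  expect_equal(pc$gamma^2,
               (lp$R + 1i * lp$omega * lp$L) * (lp$G + 1i * lp$omega * lp$C),
               tolerance = 1e-12)

  # attenuation is nondecreasing in R on a grid (L, C, omega fixed)
  alphas <- vapply(seq(0, 50, length.out = 21), function(R) {
    propagation_constants(structure(list(R = R, L = 4, G = 0, C = 1e-6,
                                         omega = 7), class = "line_params"))$alpha
  }, numeric(1))
  expect_true(all(diff(alphas) >= -1e-12))
})

test_that("characteristic impedance matches its defining identity", {
  lossless <- structure(list(R = 0, L = 4, G = 0, C = 1e-6, omega = 7),
                        class = "line_params")
  z <- characteristic_impedance(lossless)
  expect_equal(Im(z), 0, tolerance = 1e-9)
  expect_equal(Re(z), sqrt(4 / 1e-6), tolerance = 1e-9)

  lp <- line_params(fixture_vessel(), fixture_hemo())
  z <- characteristic_impedance(lp)
  w <- lp$omega
  expect_equal(Mod(z)^2 * Mod(lp$G + 1i * w * lp$C), Mod(lp$R + 1i * w * lp$L),
               tolerance = 1e-12)
  # frozen complex-arithmetic evaluation for the fixture vessel
  z_ref <- sqrt((lp$R + 1i * w * lp$L) / (1i * w * lp$C))
  expect_equal(z, z_ref, tolerance = 1e-12)

  degenerate <- structure(list(R = 1, L = 1, G = 0, C = 1, omega = 0),
                          class = "line_params")
  expect_error(characteristic_impedance(degenerate), "undefined")
})

test_that("mean blood pressure is the 1/3-2/3 convex combination", {
  expect_equal(mean_bp(120, 80), 93.3333, tolerance = 1e-4)
  expect_equal(mean_bp(90, 60), 70)
  expect_error(mean_bp(80, 80), "exceed")
  for (i in 1:20) {
    sbp <- 100 + i; dbp <- 60 + i / 2
    m <- mean_bp(sbp, dbp)
    expect_true(m > dbp && m < sbp)
  }
})

test_that("average flow scales with MBP, shrinks with d0, and has a lossless limit", {
  bp <- blood_properties()
  v <- fixture_vessel()
  q1 <- average_bfv(v, hemo_state(120, 80, 72), bp)
  q2 <- average_bfv(v, hemo_state(180, 120, 72), bp)
  expect_equal(q2 / q1, mean_bp(180, 120) / mean_bp(120, 80), tolerance = 1e-9)

  # monotone decreasing as the measuring-spot diameter shrinks
  qs <- vapply(seq(0.8, 0.1, by = -0.05), function(d0) {
    vv <- vessel_state(D = 0.8, d = d0, d0 = d0, h1 = 0.05, h2 = 0,
                       E = 4e6, sigma_p = 0.49)
    average_bfv(vv, fixture_hemo(), bp)
  }, numeric(1))
  expect_true(all(diff(qs) < 0))

  # near-lossless blood: q -> MBP_cgs * sqrt(C/L) * 60 (eta small but kept
  # inside the Womersley fit's validity, where c2 stays positive)
  bp0 <- blood_properties(eta = 0.002)
  lp0 <- line_params(v, fixture_hemo(), bp0)
  q0 <- average_bfv(v, fixture_hemo(), bp0)
  expect_lt(lp0$R / (lp0$omega * lp0$L), 0.1)
  expect_equal(q0, mean_bp(120, 80) * 1333.22 * sqrt(lp0$C / lp0$L) * 60,
               tolerance = 0.005)

  # order-of-magnitude physiology guard: healthy fistula, default mechanics
  healthy <- vessel_state(D = 0.6, d = 0.6, d0 = 0.6, h1 = 0.03, h2 = 0)
  q <- average_bfv(healthy, hemo_state(120, 80, 72))
  expect_gt(q, 200); expect_lt(q, 2000)
})

test_that("compliance and wall thickness honor their defining relations", {
  expect_equal(vessel_compliance(0.3, 0.3, 120, 80), 0)
  c1 <- vessel_compliance(0.33, 0.30, 120, 80)
  c2 <- vessel_compliance(0.33, 0.30, 160, 80)
  expect_equal(c1 / c2, 2, tolerance = 1e-12)
  # circular cross-sections from the pulsatile-diameter fixture
  d_max <- 0.52; d_min <- 0.48
  expect_equal(vessel_compliance(pi * d_max^2 / 4, pi * d_min^2 / 4, 120, 80),
               pi / 4 * (d_max^2 - d_min^2) / (40 * 1333.22),
               tolerance = 1e-12)
  expect_error(vessel_compliance(0.3, 0.31, 120, 80), "a_max")

  v <- fixture_vessel()
  h <- vessel_thickness(v, hemo_state(120, 80, 72))
  v_stiff <- vessel_state(D = 0.6, d = 0.5, d0 = 0.5, h1 = 0.05, h2 = 0,
                          E = 8e6, sigma_p = 0.49, d_max = 0.52, d_min = 0.48)
  expect_equal(vessel_thickness(v_stiff, hemo_state(120, 80, 72)), h / 2,
               tolerance = 1e-12)
  expect_equal(vessel_thickness(v, hemo_state(160, 80, 72)), 2 * h,
               tolerance = 1e-12)

  # closure: the h so obtained, fed back through the line compliance,
  # reproduces the area-based compliance up to the documented pi factor
  vh <- vessel_state(D = 0.6, d = 0.5, d0 = 0.5, h1 = h, h2 = 0,
                     E = 4e6, sigma_p = 0.49, d_max = 0.52, d_min = 0.48)
  lp <- line_params(vh, hemo_state(120, 80, 72))
  c_areas <- vessel_compliance(pi * 0.52^2 / 4, pi * 0.48^2 / 4, 120, 80)
  expect_equal(lp$C * pi, c_areas, tolerance = 1e-9)
})

test_that("the two stenosis formulas agree and are monotone", {
  expect_equal(dos_from_geometry(0.6, 0.6), 0)
  expect_equal(dos_from_geometry(0.7 * 0.6, 0.6), 51, tolerance = 1e-12)
  expect_error(dos_from_geometry(0.7, 0.6), "exceed")
  dvals <- seq(0.1, 0.6, by = 0.05)
  expect_true(all(diff(dos_from_geometry(dvals, 0.6)) < 0))

  expect_equal(dos_from_thickness(0.4, 0.07, 0.07), 0)
  expect_equal(dos_from_thickness(0.3, 0.1, 0.05), 43.75, tolerance = 1e-12)
  expect_error(dos_from_thickness(0.3, 0.04, 0.05), "h1")

  # identity with the geometric form for many (d, h, h1) triples
  grid <- expand.grid(d = c(0.2, 0.35, 0.5), h = c(0.05, 0.1, 0.2),
                      h1 = c(0, 0.02, 0.05))
  for (i in seq_len(nrow(grid)))
    expect_equal(dos_from_thickness(grid$d[i], grid$h[i], grid$h1[i]),
                 dos_from_geometry(grid$d[i],
                                   grid$d[i] + 2 * (grid$h[i] - grid$h1[i])),
                 tolerance = 1e-12)
})
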