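test_that("forward intensities reproduce the closed-form channel patterns", {
  expect_equal(as.numeric(forwardIntensities(90, 0, 0, 2)),
               c(1, 0.5, 0, 0.5))
  expect_equal(as.numeric(forwardIntensities(0, 37, 0, 4)),
               c(1, 1, 1, 1))
  expect_equal(as.numeric(forwardIntensities(90, 45, 0, 4)),
               c(1, 2, 1, 0))
  ## components conserve the total intensity for arbitrary inputs
  I <- forwardIntensities(c(13, 55, 78), c(-30, 10, 80), 22, 7)
  expect_equal(rowSums(I), rep(7, 3))
  expect_true(all(I >= 0))
})

test_that("angle estimation inverts the forward model exactly", {
  a <- estimateAngles(1, 0.5, 0, 0.5, Calibration(delta = 0))
  expect_equal(a$theta, 90)
  expect_equal(a$phi, 0)
  ## degenerate axial dipole: phi undefined, reported 0 with a flag
  d <- estimateAngles(1, 1, 1, 1, Calibration())
  expect_equal(d$theta, 0)
  expect_equal(d$phi, 0)
  expect_equal(d$flag, "degenerate")
  expect_error(estimateAngles(0, 0, 0, 0, Calibration()), "undefined")
})

test_that("forward/estimate round trip is exact over theta, phi and delta", {
  set.seed(42)
  n <- 500
  th <- runif(n, 0.5, 90)
  ph <- runif(n, -89.9, 90)
  dl <- runif(n, 0, 50)
  for (i in seq_len(n)) {
    I <- forwardIntensities(th[i], ph[i], dl[i], 1e4)
    a <- estimateAngles(I[1], I[2], I[3], I[4], Calibration(delta = dl[i]))
    expect_lt(abs(a$theta - th[i]), 1e-9)
    expect_lt(abs(a$phi - ph[i]), 1e-9)
  }
})

test_that("angle estimates are invariant to uniform intensity scaling", {
  I <- forwardIntensities(63, 28, 20, 1000)
  a1 <- estimateAngles(I[1], I[2], I[3], I[4], Calibration(delta = 20))
  a2 <- estimateAngles(1e-3 * I[1], 1e-3 * I[2], 1e-3 * I[3], 1e-3 * I[4],
                       Calibration(delta = 20))
  expect_equal(a1$theta, a2$theta)
  expect_equal(a1$phi, a2$phi)
})

test_that("gain and background corrections are applied before inversion", {
  cal <- Calibration(delta = 10, gains = c(1.1, 0.9, 1.05, 0.97),
                     backgrounds = c(3, 5, 2, 4))
  I <- forwardIntensities(70, 25, 10, 2000)
  raw <- as.numeric(I) * cal@gains + cal@backgrounds
  a <- estimateAngles(raw[1], raw[2], raw[3], raw[4], cal)
  expect_equal(a$theta, 70, tolerance = 1e-9)
  expect_equal(a$phi, 25, tolerance = 1e-9)
})

test_that("the inter-state angle omega respects dipole line symmetry", {
  expect_equal(omegaAngle(41, 17, 41, 17), 0)
  expect_equal(omegaAngle(90, 0, 90, 90), 90)
  expect_equal(omegaAngle(90, 0, 0, 0), 90)
  ## folding: nearly antiparallel axes are nearly parallel as lines
  expect_lt(omegaAngle(90, 89, 90, -89), 3)
  expect_true(all(omegaAngle(runif(50, 0, 90), runif(50, -89, 90),
                             runif(50, 0, 90), runif(50, -89, 90)) <= 90))
})

test_that("the wobble order parameter is monotone with S(0) = 1", {
  expect_equal(orderParameter(0), 1)
  dl <- seq(0, 54, by = 2)
  expect_true(all(diff(orderParameter(dl)) < 0))
  expect_error(orderParameter(60), "54.7")
})

test_that("local-frame registration fixes the reference states", {
  v <- anglesToVec(polarizationAngles[, 1], polarizationAngles[, 2])
  ## reference means already satisfying the convention: identity rotation
  lf0 <- toLocalFrame(v, v[1, ], v[4, ])
  expect_equal(lf0$angles$theta, polarizationAngles[, 1], tolerance = 1e-9)
  expect_equal(lf0$angles$phi, polarizationAngles[, 2], tolerance = 1e-9)
  ## after an arbitrary rigid rotation the local-frame output is unchanged
  R <- rotationMatrix(0.7, -0.4, 1.9)
  vr <- v %*% t(R)
  lf <- toLocalFrame(vr, vr[1, ], vr[4, ])
  expect_equal(lf$angles$theta, polarizationAngles[, 1], tolerance = 1e-9)
  expect_equal(lf$angles$phi, polarizationAngles[, 2], tolerance = 1e-9)
  ## C1 maps to (90, 0) and C4 to theta = 90 by definition
  expect_equal(lf$angles$theta[c(1, 4)], c(90, 90), tolerance = 1e-9)
  expect_equal(lf$angles$phi[1], 0, tolerance = 1e-9)
  expect_gt(lf$angles$phi[4], 0)
  expect_error(toLocalFrame(v, c(1, 0, 0), c(-1, 0, 0)), "parallel")
})
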