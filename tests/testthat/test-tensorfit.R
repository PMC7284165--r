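test_that("pointwise ADC computation clamps and flags the noise floor", {
  expect_equal(as.numeric(adc_from_signal(1000, 1000, 1000)), 0)
  expect_equal(as.numeric(adc_from_signal(1000 * exp(-0.5), 1000, 1000)),
               0.5e-3, tolerance = 1e-12)
  over <- adc_from_signal(1200, 1000, 1000) # noise above the reference
  expect_equal(as.numeric(over), 0)
  expect_true(attr(over, "clamped"))
  expect_error(adc_from_signal(1, 0, 1000), "S0")
  expect_error(adc_from_signal(1, 1, 0), "b")
})

test_that("noise-free fits invert the signal model to machine precision", {
  withr::with_seed(7, {
    sc <- make_scheme(60, 1000, 6, seed = 5)
    D6 <- t(replicate(50, random_spd_tensor()))
    st <- simulate_signal(tensor_field_from_rows(D6), sc, S0 = 800)
    tf <- fit_tensor(st, mask = TRUE)
    expect_lt(max(abs(tf$D - D6)) / max(abs(D6)), 1e-10)
    expect_equal(tf$n_clamped, 0L)

    # WLS = OLS = direct inversion when #directions = 6
    sc6 <- make_scheme(6, 1000, 1, seed = 5)
    st6 <- simulate_signal(tensor_field_from_rows(D6), sc6, S0 = 800)
    tf6 <- fit_tensor(st6, mask = TRUE)
    B <- hippodwi:::design_matrix(sc6)
    y <- -log(st6$signals[, sc6$bvals > 0] / 800)
    direct <- t(solve(B, t(y)))
    expect_equal(unname(tf6$D), unname(direct), tolerance = 1e-10)

    # isotropic tensor fits to FA = 0
    iso <- tensor_field_from_rows(matrix(c(0.5e-3, 0.5e-3, 0.5e-3, 0, 0, 0), 1))
    sm <- tensor_metrics(fit_tensor(simulate_signal(iso, sc, S0 = 800), mask = TRUE))
    expect_lt(sm$fa, 1e-10)
    expect_equal(sm$md, 0.5e-3, tolerance = 1e-12)
  })
})

test_that("scalar metrics match their spectral definitions", {
  diag6 <- function(l) matrix(c(l, 0, 0, 0), 1)
  sm <- tensor_metrics(tensor_field_from_rows(diag6(c(2e-3, 2e-3, 2e-3))))
  expect_equal(sm$fa, 0)
  expect_equal(sm$md, 2e-3)
  sm1 <- tensor_metrics(tensor_field_from_rows(diag6(c(1e-3, 0, 0))))
  expect_equal(sm1$fa, 1, tolerance = 1e-12)
  sm2 <- tensor_metrics(tensor_field_from_rows(diag6(c(1.5e-3, 0.3e-3, 0.3e-3))))
  expect_equal(sm2$md, 0.7e-3, tolerance = 1e-12)
  expect_equal(sm2$fa, sqrt(1.5 * 0.96 / 2.43), tolerance = 1e-12) # 0.7698
  expect_equal(sm2$theta, 0) # principal axis along x
})

test_that("FA and MD are rotation invariant; theta is equivariant in-plane", {
  withr::with_seed(11, {
    base <- c(1.4e-3, 0.4e-3, 0.2e-3)
    for (i in 1:20) {
      # random 3D rotation via QR of a Gaussian matrix
      Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
      D <- Q %*% diag(base) %*% t(Q)
      sm <- tensor_metrics(tensor_field_from_rows(
        matrix(c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3]), 1)))
      expect_equal(sm$md, mean(base), tolerance = 1e-10)
      md <- mean(base)
      fa_expect <- sqrt(1.5 * sum((base - md)^2) / sum(base^2))
      expect_equal(sm$fa, fa_expect, tolerance = 1e-10)
    }
    # in-plane rotation by alpha shifts theta by alpha (mod 180)
    for (alpha in c(10, 45, 117, 170)) {
      a <- alpha * pi / 180
      R <- rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
      D <- R %*% diag(c(1.5e-3, 0.3e-3, 0.3e-3)) %*% t(R)
      sm <- tensor_metrics(tensor_field_from_rows(
        matrix(c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3]), 1)))
      expect_lt(min(abs(sm$theta - alpha), 180 - abs(sm$theta - alpha)), 1e-6)
    }
  })
})

test_that("tensor recovery at acquisition SNR is unbiased within tolerance", {
  # 500 replicate voxels of one FA = 0.77 tensor at SNR 15
  withr::with_seed(12, {
    sc <- make_scheme(60, 1000, 6, seed = 5)
    D6 <- matrix(rep(c(1.5e-3, 0.3e-3, 0.3e-3, 0, 0, 0), each = 500), 500)
    st <- simulate_signal(tensor_field_from_rows(D6), sc, S0 = 1000)
    stn <- add_rician_noise(st, snr = 15, seed = 8)
    sm <- tensor_metrics(fit_tensor(stn, mask = TRUE))
    fa_true <- sqrt(1.5 * 0.96 / 2.43)
    expect_lt(abs(mean(sm$fa) - fa_true), 0.05)
  })
})

test_that("default masking recovers the tissue from the b0 contrast", {
  sp <- small_spec(seed = 41)
  ph <- build_phantom(sp)
  sc <- make_scheme(30, 1000, 3, seed = 2)
  st <- add_rician_noise(simulate_signal(ph$tensors, sc, S0 = 1000, s0_map = ph$s0_map),
                         15, seed = 2)
  tf <- fit_tensor(st) # Otsu on mean b0
  tissue <- as.vector(ph$roi$labels > 0)
  expect_gt(mean((tf$mask) == tissue), 0.95)
})

test_that("phantom round trip reproduces configured orientations and metrics", {
  sp <- small_spec(seed = 51)
  ph <- build_phantom(sp)
  sc <- make_scheme(60, 1000, 6, seed = 1)
  st <- simulate_signal(ph$tensors, sc, S0 = 1000, s0_map = ph$s0_map)
  sm <- tensor_metrics(fit_tensor(st, mask = TRUE))
  truth <- tensor_metrics(ph$tensors)
  expect_equal(sm$fa, truth$fa, tolerance = 1e-9)
  expect_equal(sm$md, truth$md, tolerance = 1e-9)
  for (rn in ROIS) {
    sel <- ph$roi$labels == LAB[[rn]]
    want <- axial_mean(ph$orientations[sel])
    got <- axial_mean(sm$theta[sel][is.finite(sm$theta[sel])])
    expect_lt(min(abs(got - want), 180 - abs(got - want)), 1)
  }
})
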