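test_that("geometry partitions the grid, fills all regions, and is deterministic", {
  sp <- phantom_spec("control", seed = 4)
  roi <- generate_geometry(sp)
  counts <- vapply(LAB, function(l) sum(roi$labels == l), integer(1))
  expect_true(all(counts > 0))
  expect_equal(sum(counts) + sum(roi$labels == 0L), prod(sp$grid_shape))
  expect_identical(roi$labels, generate_geometry(sp)$labels)

  # sub-minimum grids are rejected at spec level; a grid too small to hold
  # the bands errors explicitly at geometry level
  expect_error(phantom_spec("control", grid_shape = c(24, 24)), "32")
  tiny <- phantom_spec("control")
  tiny$grid_shape <- c(16L, 16L)
  expect_error(generate_geometry(tiny), "too small")
})

test_that("granule cell layer width tracks the dispersion factor", {
  # straight synthetic band: area / principal-axis length, exact
  expect_equal(measure_gcl_width(straight_band_roiset(5)), 5 * 0.04,
               tolerance = 0.02 / 0.2)

  ctrl <- generate_geometry(phantom_spec("control", seed = 1))
  w_ctrl <- measure_gcl_width(ctrl)
  nominal <- ctrl$gcl_nominal_width_vox * 0.04
  expect_lt(abs(w_ctrl - nominal), 0.04) # within one voxel

  ipsi <- generate_geometry(phantom_spec("ipsilateral", severity = 1, seed = 1))
  expect_equal(ipsi$gcl_nominal_width_vox / ctrl$gcl_nominal_width_vox, 2)
  expect_equal(measure_gcl_width(ipsi) / w_ctrl, 2, tolerance = 0.1)
})

test_that("orientation fields follow the axial von Mises model", {
  sp <- small_spec(seed = 2)
  roi <- generate_geometry(sp)
  th <- generate_orientation_field(roi, sp)

  # region means land on the configured orientations
  for (rn in ROIS) {
    mu <- hippodwi::roi_orientation_hypotheses[[rn]]
    got <- axial_mean(th[roi$labels == LAB[[rn]]])
    expect_lt(min(abs(got - mu), 180 - abs(got - mu)), 5)
  }
  expect_true(all(is.na(th[roi$labels == 0L])))
  expect_identical(th, generate_orientation_field(roi, sp)) # determinism

  # kappa -> infinity collapses to the mean orientation
  tiss <- default_tissue_params()
  for (rn in ROIS) tiss[[rn]]$kappa <- 1e6
  spd <- small_spec(seed = 2, tissue = tiss)
  thd <- generate_orientation_field(roi, spd)
  expect_lt(max(abs(thd[roi$labels == LAB[["CA1"]]] - 90)), 0.1)

  # kappa = 0 gives uniform axial orientations (chi-square GOF)
  withr::with_seed(99, {
    u <- hippodwi:::rvonmises(1e4, 0, 0) * 180 / pi / 2
    ct <- table(cut(u, breaks = seq(0, 180, by = 10)))
    expect_gt(stats::chisq.test(ct)$p.value, 0.01)
  })
})

test_that("generated orientations pass the V-test against their own mean", {
  sp <- small_spec(seed = 5)
  roi <- generate_geometry(sp)
  th <- generate_orientation_field(roi, sp)
  for (rn in ROIS) { # all default kappas are >= 5 with n >= 50 voxels
    angles <- th[roi$labels == LAB[[rn]]]
    res <- vtest(angles, hippodwi::roi_orientation_hypotheses[[rn]])
    expect_gte(res$n, 50)
    expect_true(res$significant)
  }
})

test_that("tensor construction matches the rotated diffusion model", {
  # one region, hand-set eigenvalues, three reference angles
  mk <- function(mu) {
    tiss <- default_tissue_params()
    tiss$CA1$lambda_par <- 1.5e-3; tiss$CA1$lambda_perp <- 0.3e-3
    sp <- small_spec(seed = 3, tissue = tiss, jitter_sd = 0, coupling = list(b_MD = 0))
    roi <- generate_geometry(sp)
    th <- matrix(mu, nrow(roi$labels), ncol(roi$labels)) # exact orientation
    tf <- build_tensor_field(roi, th, sp)
    tf$D[which(roi$labels == LAB[["CA1"]])[1], ]
  }
  d0 <- mk(0)
  expect_equal(unname(d0[1:3]), c(1.5e-3, 0.3e-3, 0.3e-3), tolerance = 1e-9)
  expect_equal(unname(d0[4:6]), c(0, 0, 0), tolerance = 1e-9)
  d90 <- mk(90)
  expect_equal(unname(d90[1:2]), c(0.3e-3, 1.5e-3), tolerance = 1e-9)
  d45 <- mk(45)
  expect_equal(unname(d45[1]), 0.9e-3, tolerance = 1e-8)
  expect_equal(unname(d45[2]), 0.9e-3, tolerance = 1e-8)
  expect_equal(unname(d45[4]), 0.6e-3, tolerance = 1e-8)

  # every phantom tensor is positive definite; background is saline-like
  ph <- build_phantom(small_spec(seed = 8))
  m <- hippodwi:::cpp_tensor_metrics(ph$tensors$D, 1e-12)
  expect_gt(min(m[, 6]), 0)
  bg <- which(ph$roi$labels == 0L)[1]
  expect_equal(mean(ph$tensors$D[bg, 1:3]), 2.0e-3)
})

test_that("density maps encode condition effects and couple to diffusivity", {
  ctrl <- build_phantom(small_spec("control", seed = 21))
  ipsi <- build_phantom(small_spec("ipsilateral", seed = 22))
  dens <- function(ph, rn) ph$density$roi_means$density[ph$density$roi_means$roi == rn]
  expect_lt(dens(ipsi, "CA1"), dens(ctrl, "CA1"))
  expect_true(all(ctrl$density$map >= 0))
  expect_true(all(ctrl$density$map[ctrl$roi$labels == 0L] == 0))

  # monotone coupling: larger b_MD lowers MD in the dense granule cell layer
  md_dg <- function(b) {
    ph <- build_phantom(small_spec(seed = 3, coupling = list(a_MD = 0.7e-3, b_MD = b)))
    sm <- tensor_metrics(ph$tensors)
    mean(sm$md[ph$roi$labels == LAB[["DG"]]])
  }
  expect_lt(md_dg(0.5e-3), md_dg(0.3e-3))

  # non-physical coupling is rejected up front
  expect_error(small_spec(coupling = list(a_MD = 0.7e-3, b_MD = 2e-3)), "coupling")
})

test_that("slice severity spread makes intra-group density-FA correlations recoverable", {
  fa_ca1 <- function(ph) {
    sm <- tensor_metrics(ph$tensors)
    mean(sm$fa[ph$roi$labels == LAB[["CA1"]]])
  }
  one_cohort <- function(seed, b_MD) {
    set.seed(seed)
    sev <- runif(9, 0.5, 1)
    vals <- vapply(seq_len(9), function(i) {
      sp <- phantom_spec("ipsilateral", grid_shape = c(64L, 80L), severity = sev[i],
                         seed = seed * 100 + i,
                         coupling = list(a_MD = 0.7e-3, b_MD = b_MD))
      ph <- build_phantom(sp)
      c(dens = ph$density$roi_means$density[1], fa = fa_ca1(ph))
    }, numeric(2))
    stats::cor(vals[1, ], vals[2, ])
  }
  r_coupled <- vapply(1:100, one_cohort, numeric(1), b_MD = 0.5e-3)
  expect_gte(mean(r_coupled > 0), 0.95)
  r_null <- vapply(1:100, one_cohort, numeric(1), b_MD = 0)
  expect_lt(abs(mean(r_null)), 0.2)
})

test_that("identical spec and seed give bit-identical phantoms", {
  a <- build_phantom(small_spec("ipsilateral", seed = 77))
  b <- build_phantom(small_spec("ipsilateral", seed = 77))
  expect_identical(a$roi$labels, b$roi$labels)
  expect_identical(a$orientations, b$orientations)
  expect_identical(a$density$map, b$density$map)
  expect_identical(a$tensors$D, b$tensors$D)
})
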