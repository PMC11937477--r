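test_that("phantom spec validation enforces the geometric invariants", {
  expect_error(phantom_spec(lumen_radius_mm = c(4, 3, -1, 2)), "> 0")
  expect_error(phantom_spec(deformation = list(amplitude_mm = 30,
                                               period_mm = 48)),
               "fold-free")
  expect_error(generate_phantom(phantom_spec(grid_shape = 24)), "too small")
})

test_that("the tree is a symmetric dichotomy with 2^depth terminal branches", {
  ph <- clean_phantom()
  tr <- ph$truth$tree
  expect_equal(sum(tr$generation == 3), 8)        # 2^3 terminals
  expect_equal(nrow(tr), 1 + 2 + 4 + 8)
  expect_equal(nrow(ph$truth$lobe_map), 4)
  expect_setequal(ph$truth$lobe_map$lobe, c("RUL", "RLL", "LUL", "LLL"))
})

test_that("ground-truth areas follow the analytic annulus formulas", {
  ph <- clean_phantom()
  s <- ph$truth$sections
  # generation 3: lumen 2 mm, wall 2 mm -> WA% = 75 exactly
  g3 <- s[s$generation == 3, ]
  expect_equal(g3$LA, rep(4 * pi, 8))
  expect_equal(g3$WA, rep(12 * pi, 8))
  expect_equal(g3$WA_percent, rep(75, 8))
  # WA% from radii equals 100*WA/(WA+LA) to machine precision on all rows
  expect_equal(s$WA_percent,
               100 * (s$r_outer^2 - s$r_lumen^2) / s$r_outer^2,
               tolerance = 1e-12)
  expect_equal(s$WA_percent, 100 * s$WA / (s$WA + s$LA), tolerance = 1e-12)
})

test_that("identity deformation gives voxel-identical airway masks across modalities", {
  ph <- clean_phantom()
  root <- phantom_root(ph)
  m_ct <- segment_lumen(ph$ct, root, threshold = -500)
  m_ute <- segment_lumen(ph$ute, root, threshold = 65)  # lumen/wall midpoint
  expect_identical(unname(which(m_ct)), unname(which(m_ute)))
})

test_that("an equal seed reproduces bit-identical volumes", {
  s <- phantom_spec(seed = 31)
  a <- generate_phantom(s)
  b <- generate_phantom(s)
  expect_identical(a$ct$data, b$ct$data)
  expect_identical(a$ute$data, b$ute$data)
  expect_identical(a$t2w$data, b$t2w$data)
  expect_identical(a$truth$field, b$truth$field)
  c3 <- generate_phantom(phantom_spec(seed = 32))
  expect_false(identical(a$ct$data, c3$ct$data))
})

test_that("T2w wall voxels carry the ground-truth signal pre-noise", {
  ph <- clean_phantom()
  wall <- ph$truth$labels == 2
  expect_equal(mean(ph$t2w$data[wall]), ph$truth$wall_t2_signal)
  expect_equal(stats::sd(ph$t2w$data[wall]), 0)
})

test_that("voxelized lumen volume converges to the analytic volume", {
  # single straight tube at three resolutions: error strictly decreases
  err <- vapply(c(1.6, 0.8, 0.4), function(h) {
    n <- round(48 / h)
    sp <- phantom_spec(grid_shape = c(n, n, n), voxel_size_mm = h,
                       tree_depth = 0, lumen_radius_mm = 4,
                       wall_thickness_mm = 2, trachea_length_mm = 20,
                       deformation = list(amplitude_mm = 0, period_mm = 48),
                       noise_sigma = c(ct = 0, ute = 0, t2w = 0),
                       n_vessels = 0, seed = 1)
    ph <- generate_phantom(sp)
    vol <- sum(ph$truth$labels == 1) * h^3
    # cylinder plus the two hemispherical end caps of the rounded tube
    analytic <- pi * 16 * 20 + (4 / 3) * pi * 4^3
    abs(vol - analytic) / analytic
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 0.02)
})

test_that("the deformation field is smooth, bounded and invertible", {
  ph <- cached("deformed", function() generate_phantom(phantom_spec(seed = 3)))
  u <- ph$truth$field
  mag <- sqrt(u[, , , 1]^2 + u[, , , 2]^2 + u[, , , 3]^2)
  expect_lte(max(mag), 3 + 1e-9)        # amplitude bounds |u|
  jd <- field_jacobian_det(u)
  expect_gt(min(jd[5:92, 5:92, 5:92]), 0)
  # forward and inverse fields compose to near-identity
  v <- ph$truth$field_inv
  g <- bronchowall:::index_grid(dim(u)[1:3])
  xi <- g$xi + as.vector(v[, , , 1]); yi <- g$yi + as.vector(v[, , , 2])
  zi <- g$zi + as.vector(v[, , , 3])
  ux_at_v <- bronchowall:::interp_trilinear(u[, , , 1], xi, yi, zi, fill = 0)
  comp <- as.vector(v[, , , 1]) + ux_at_v
  interior <- g$xi > 8 & g$xi < 88 & g$yi > 8 & g$yi < 88 &
    g$zi > 8 & g$zi < 88
  expect_lt(mean(abs(comp[interior])), 0.05)
})

test_that("mucus plugging fills the proximal lumen with wall-level intensity", {
  ph <- cached("plugged", function() {
    generate_phantom(clean_spec(mucus_plug_paths = "RUL", seed = 7))
  })
  expect_equal(ph$truth$plugged_branches,
               ph$truth$lobe_map$label[ph$truth$lobe_map$lobe == "RUL"])
  plug <- ph$truth$labels == 3
  expect_gt(sum(plug), 0)
  expect_equal(unique(ph$ct$data[plug]), 0)   # wall-level HU-analog
})

test_that("phantom files round-trip through NIfTI/CSV/JSON", {
  dir <- withr::local_tempdir()
  ph <- clean_phantom()
  files <- write_phantom(ph, dir, prefix = "s1")
  expect_true(all(file.exists(files)))
  back <- read_volume(file.path(dir, "s1_t2w.nii.gz"), "T2w-like")
  expect_equal(as.vector(back$data), as.vector(ph$t2w$data),
               tolerance = 1e-6)
  expect_equal(back$spacing, ph$t2w$spacing)
  cl <- utils::read.csv(file.path(dir, "s1_centerline.csv"))
  expect_true(all(c("label", "arc_mm", "x", "y", "z") %in% names(cl)))
})
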