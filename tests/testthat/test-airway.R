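test_that("lumen segmentation recovers the analytic airway volume", {
  ph <- clean_phantom()
  root <- phantom_root(ph)
  mask <- segment_lumen(ph$ct, root)
  tr <- ph$truth$tree
  analytic <- sum(pi * tr$r_lumen^2 * tr$length_mm)
  got <- sum(mask) * prod(ph$ct$spacing)
  expect_lt(abs(got - analytic) / analytic, 0.05)
  # no leakage into the background; the boundary may graze wall voxels
  expect_true(all(ph$truth$labels[mask] != 0L))
  expect_lt(mean(ph$truth$labels[mask] == 2L), 0.05)
})

test_that("a seed in the wall raises a seed error", {
  ph <- clean_phantom()
  tr <- ph$truth$tree
  # a point 5 mm lateral of the trachea axis sits inside the wall (r 4-6 mm)
  wall_pt <- c(tr$x0[1] + 5, tr$y0[1], tr$z0[1] - 10)
  expect_error(segment_lumen(ph$ct, wall_pt), "air intensity range")
  expect_error(segment_lumen(ph$ct, c(500, 0, 0)), "outside")
})

test_that("a plugged path loses its distal lumen", {
  ph <- cached("plugged", function() {
    generate_phantom(clean_spec(mucus_plug_paths = "RUL", seed = 7))
  })
  root <- phantom_root(ph)
  mask <- segment_lumen(ph$ct, root)
  plugged_id <- ph$truth$lobe_map$branch_id[ph$truth$lobe_map$lobe == "RUL"]
  in_plugged <- ph$truth$path_id == plugged_id & ph$truth$labels == 1L
  # distal lumen of the plugged branch is not reachable from the seed
  expect_equal(sum(mask & in_plugged), 0)
})

test_that("centerline extraction recovers the dichotomous topology", {
  tree <- clean_tree()
  expect_equal(sum(tree$branches$terminal), 8)
  expect_equal(as.integer(table(tree$branches$generation)), c(1, 2, 4, 8))
  expect_error(extract_centerline(array(FALSE, c(8, 8, 8))), "empty")
})

test_that("centerline stays within a voxel of the analytic centerline", {
  ph <- clean_phantom()
  tree <- clean_tree()
  gt <- ph$truth$centerline
  nd <- tree$nodes
  err <- vapply(seq_len(nrow(nd)), function(i) {
    min(sqrt((gt$x - nd$x[i])^2 + (gt$y - nd$y[i])^2 + (gt$z - nd$z[i])^2))
  }, numeric(1))
  expect_lt(mean(err), 1)
})

test_that("a straight tube yields one branch with the tube-axis tangent", {
  sp <- phantom_spec(grid_shape = c(40, 40, 64), voxel_size_mm = 1,
                     tree_depth = 0, lumen_radius_mm = 4,
                     wall_thickness_mm = 2, trachea_length_mm = 40,
                     deformation = list(amplitude_mm = 0, period_mm = 48),
                     noise_sigma = c(ct = 0, ute = 0, t2w = 0),
                     n_vessels = 0, seed = 2)
  ph <- generate_phantom(sp)
  root <- phantom_root(ph)
  mask <- segment_lumen(ph$ct, root)
  tree <- label_generations(extract_centerline(mask, spacing = 1,
                                               root_mm = root))
  expect_equal(nrow(tree$branches), 1)
  expect_true(all(tree$branches$generation == 0))
  # tangent within 5 degrees of the tube axis (0, 0, -1)
  nd <- tree$nodes
  mid <- nd[nd$arc_mm > 5 & nd$arc_mm < max(nd$arc_mm) - 5, ]
  ang <- acos(pmin(1, abs(mid$tz))) * 180 / pi
  expect_lt(max(ang), 5)
})

test_that("pruning a short twig leaves the topology unchanged", {
  ph <- clean_phantom()
  root <- phantom_root(ph)
  mask <- segment_lumen(ph$ct, root)
  # bolt a 3-voxel spur (shorter than the prune length) onto the trachea
  idx <- which(mask, arr.ind = TRUE)
  top <- idx[idx[, 3] == max(idx[, 3]) - 4, , drop = FALSE][1, ]
  spur <- mask
  spur[top[1] + 1:3, top[2], top[3]] <- TRUE
  t1 <- label_generations(extract_centerline(mask, spacing = 1, root_mm = root))
  t2 <- label_generations(extract_centerline(spur, spacing = 1, root_mm = root))
  expect_equal(table(t2$branches$generation), table(t1$branches$generation))
})

test_that("generation labels start at the trachea and increment per bifurcation", {
  tree <- clean_tree()
  br <- tree$branches
  root <- br[is.na(br$parent_branch_id), ]
  expect_equal(root$generation, 0L)
  kids <- br[!is.na(br$parent_branch_id), ]
  parent_gen <- br$generation[match(kids$parent_branch_id, br$branch_id)]
  expect_equal(kids$generation, parent_gen + 1L)
  # idempotence
  again <- label_generations(tree)
  expect_identical(again$branches$generation, tree$branches$generation)
})

test_that("select_paths returns one generation-3 branch per lobe", {
  ph <- clean_phantom()
  tree <- clean_tree()
  sel <- select_paths(tree, ph$truth$lobe_map, ct = ph$ct)
  expect_equal(nrow(sel$paths), 4)
  expect_setequal(sel$paths$lobe, c("RUL", "RLL", "LUL", "LLL"))
  expect_equal(nrow(sel$excluded), 0)
  expect_equal(anyDuplicated(sel$paths$branch_id), 0)
})

test_that("a plugged lobe is excluded with a record, not an error", {
  ph <- cached("plugged", function() {
    generate_phantom(clean_spec(mucus_plug_paths = "RUL", seed = 7))
  })
  root <- phantom_root(ph)
  mask <- segment_lumen(ph$ct, root)
  tree <- label_generations(extract_centerline(mask, spacing = 1,
                                               root_mm = root))
  sel <- select_paths(tree, ph$truth$lobe_map, ct = ph$ct)
  expect_equal(nrow(sel$paths), 3)
  expect_equal(sel$excluded$lobe, "RUL")
  expect_match(sel$excluded$reason, "obstruction|plug")
})

test_that("a depth-2 tree triggers a selection error naming the lobes", {
  sp <- clean_spec(tree_depth = 2, seed = 9)
  ph <- generate_phantom(sp)
  root <- phantom_root(ph)
  mask <- segment_lumen(ph$ct, root)
  tree <- label_generations(extract_centerline(mask, spacing = 1,
                                               root_mm = root))
  # borrow the lobe geometry of the standard phantom for the request
  lm <- clean_phantom()$truth$lobe_map
  expect_error(select_paths(tree, lm), "no generation-3")
})

test_that("measurement sites sit at fixed arc-length fractions", {
  sp <- phantom_spec(grid_shape = c(40, 40, 56), voxel_size_mm = 1,
                     tree_depth = 0, lumen_radius_mm = 3,
                     wall_thickness_mm = 2, trachea_length_mm = 30,
                     deformation = list(amplitude_mm = 0, period_mm = 48),
                     noise_sigma = c(ct = 0, ute = 0, t2w = 0),
                     n_vessels = 0, seed = 2)
  ph <- generate_phantom(sp)
  root <- phantom_root(ph)
  mask <- segment_lumen(ph$ct, root)
  tree <- label_generations(extract_centerline(mask, spacing = 1,
                                               root_mm = root))
  b <- tree$branches$branch_id[1]
  L <- tree$branches$length_mm[1]
  s2 <- pick_measurement_sites(tree, b, n_sites = 2)
  expect_equal(s2$arc_mm, c(L / 3, 2 * L / 3))
  s1 <- pick_measurement_sites(tree, b, n_sites = 1)
  expect_equal(s1$arc_mm, L / 2)
  # a branch shorter than two local lumen diameters errors
  stub <- tree
  stub$nodes <- stub$nodes[stub$nodes$arc_mm <= 8, ]
  stub$branches$length_mm <- 8
  expect_error(pick_measurement_sites(stub, b), "too short")
})

test_that("cross-section reformatting is perpendicular and flags padding", {
  ph <- clean_phantom()
  tr <- ph$truth$tree
  ctr <- c((tr$x0[1] + tr$x1[1]) / 2, (tr$y0[1] + tr$y1[1]) / 2,
           (tr$z0[1] + tr$z1[1]) / 2)
  expect_error(reformat_cross_section(ph$ct, ctr, c(0, 0, 2)), "unit")
  sec <- reformat_cross_section(ph$ct, ctr, c(0, 0, 1), half_size_mm = 8)
  expect_false(sec$flagged)
  expect_equal(sum(sec$e1 * sec$normal), 0, tolerance = 1e-12)
  expect_equal(sum(sec$e2 * sec$normal), 0, tolerance = 1e-12)
  expect_equal(sum(sec$e1 * sec$e2), 0, tolerance = 1e-12)
  # a plane hanging over the volume edge is padded and flagged
  sec2 <- reformat_cross_section(ph$ct, c(4, 4, 50), c(0, 0, 1),
                                 half_size_mm = 10)
  expect_true(sec2$flagged)
  expect_true(anyNA(sec2$image))
})

test_that("sections of straight and oblique tubes are circular annuli", {
  ph <- clean_phantom()
  lm <- ph$truth$lobe_map
  tr <- ph$truth$tree
  # oblique generation-3 branch, sectioned along its own tangent
  b <- tr[tr$branch_id == lm$branch_id[lm$lobe == "RUL"], ]
  ctr <- c((b$x0 + b$x1) / 2, (b$y0 + b$y1) / 2, (b$z0 + b$z1) / 2)
  sec <- reformat_cross_section(ph$ct, ctr, c(b$dx, b$dy, b$dz),
                                half_size_mm = 8)
  m <- detect_wall(sec)
  expect_equal(m$status, "ok")
  ecc_in <- boundary_eccentricity(m$boundary$x_inner, m$boundary$y_inner)
  expect_lt(ecc_in, 0.2)
  # trachea sectioned along the z axis
  ctr0 <- c((tr$x0[1] + tr$x1[1]) / 2, (tr$y0[1] + tr$y1[1]) / 2,
            (tr$z0[1] + tr$z1[1]) / 2)
  sec0 <- reformat_cross_section(ph$ct, ctr0, c(0, 0, 1), half_size_mm = 10)
  m0 <- detect_wall(sec0)
  ecc0 <- boundary_eccentricity(m0$boundary$x_inner, m0$boundary$y_inner)
  expect_lt(ecc0, 0.2)
})

test_that("tree extraction is equivariant to a 90-degree volume rotation", {
  ph <- clean_phantom()
  root <- phantom_root(ph)
  # rotate about the z axis: (i, j, k) -> (j, n - i + 1, k)
  rot <- function(a) aperm(a, c(2, 1, 3))[, dim(a)[1]:1, , drop = FALSE]
  ct_r <- brw_volume(rot(ph$ct$data), ph$ct$spacing, "CT-like")
  n <- dim(ph$ct$data)[1]
  root_r <- c(root[2], (n - 1) - root[1], root[3])
  m1 <- segment_lumen(ph$ct, root)
  m2 <- segment_lumen(ct_r, root_r)
  t1 <- label_generations(extract_centerline(m1, spacing = 1, root_mm = root))
  t2 <- label_generations(extract_centerline(m2, spacing = 1, root_mm = root_r))
  expect_equal(as.integer(table(t2$branches$generation)),
               as.integer(table(t1$branches$generation)))
})
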