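test_that("wa_percent computes the normalized wall area", {
  expect_equal(wa_percent(0, 5), 0)
  expect_equal(wa_percent(12 * pi, 4 * pi), 75)
  expect_equal(wa_percent(73, 27), 73)   # scale anchor near the CT cutoff
  expect_error(wa_percent(0, 0), "> 0")
  expect_error(wa_percent(-1, 5), "non-negative")
})

test_that("LoG boundary detection recovers analytic areas on clean annuli", {
  sec <- annulus_section(r_in = 2, r_out = 4, spacing = 0.3)
  m <- detect_wall(sec)
  expect_equal(m$status, "ok")
  expect_lt(abs(m$LA - 4 * pi) / (4 * pi), 0.05)
  expect_lt(abs(m$WA - 12 * pi) / (12 * pi), 0.05)
  expect_lt(abs(m$WA_percent - 75), 3)
  # a different geometry: r 3/4.5 -> LA 9pi, WA 11.25pi, WA% 55.6
  sec2 <- annulus_section(r_in = 3, r_out = 4.5, spacing = 0.3)
  m2 <- detect_wall(sec2)
  expect_lt(abs(m2$LA - 9 * pi) / (9 * pi), 0.05)
  expect_lt(abs(m2$WA - 11.25 * pi) / (11.25 * pi), 0.05)
})

test_that("wall measurement tolerates wall-SNR-10 noise", {
  ok <- 0
  for (seed in 1:3) {
    m <- detect_wall(annulus_section(r_in = 2, r_out = 4, spacing = 0.3,
                                     snr = 10, seed = seed))
    expect_equal(m$status, "ok")
    expect_lt(abs(m$WA_percent - 75), 3)
  }
})

test_that("a uniform wall-free section fails cleanly", {
  sec <- annulus_section()
  sec$image[] <- -850
  m <- detect_wall(sec)
  expect_equal(m$status, "failed")
  expect_true(is.na(m$LA))
})

test_that("measured areas converge as section sampling is halved", {
  errs <- vapply(c(0.6, 0.3), function(sp) {
    m <- detect_wall(annulus_section(r_in = 2, r_out = 4, spacing = sp))
    abs(m$LA - 4 * pi) + abs(m$WA - 12 * pi)
  }, numeric(1))
  expect_lt(errs[2], errs[1])
})

test_that("WA% is invariant to uniform intensity rescaling", {
  sec <- annulus_section(r_in = 2, r_out = 4, spacing = 0.3, snr = 10,
                         seed = 4)
  m1 <- detect_wall(sec)
  sec10 <- sec
  sec10$image <- sec$image * 10 + 500
  m2 <- detect_wall(sec10)
  expect_lt(abs(m1$WA_percent - m2$WA_percent), 2)
})

test_that("wall masks rasterize the annulus volume and exclude the lumen", {
  ph <- clean_phantom()
  tree <- clean_tree()
  root <- phantom_root(ph)
  lumen <- segment_lumen(ph$ct, root)
  cfg <- default_config()
  res <- measure_airways(ph$ct, normalize_t2(ph$t2w)$volume, ph$ute,
                         root, ph$truth$lobe_map, cfg)
  mask <- res$mask
  expect_equal(sum(mask > 0 & lumen), 0)    # disjoint from the lumen
  # per-site mask volume vs analytic annulus slab volume (2 mm slab x WA)
  ok_sites <- res$sites[res$sites$status == "ok", ]
  vol_per_site <- vapply(ok_sites$site_id,
                         function(s) sum(mask == s) * prod(ph$ute$spacing),
                         numeric(1))
  analytic <- 2 * 12 * pi   # slab 2 mm x true WA at generation 3
  rel <- abs(vol_per_site - analytic) / analytic
  expect_lt(stats::median(rel), 0.25)
  # disjoint paths stay disjoint labels
  site_lobes <- ok_sites$lobe[match(sort(unique(mask[mask > 0])),
                                    ok_sites$site_id)]
  expect_setequal(unique(site_lobes), c("RUL", "RLL", "LUL", "LLL"))
  expect_error(wall_mask_3d(res$sites[0, ], ph$ute), "empty")
})

test_that("BrWall_T2-MIS aggregates site -> path -> patient with plain means", {
  # four constant-intensity path regions: patient value is the mean 75
  vol <- array(0, c(20, 20, 4))
  vol[1:5, 1:5, 1] <- 60; vol[6:10, 1:5, 1] <- 70
  vol[11:15, 1:5, 1] <- 80; vol[16:20, 1:5, 1] <- 90
  mask <- array(0L, c(20, 20, 4))
  mask[1:5, 1:5, 1] <- 1L; mask[6:10, 1:5, 1] <- 2L
  mask[11:15, 1:5, 1] <- 3L; mask[16:20, 1:5, 1] <- 4L
  t2 <- brw_volume(vol)
  tabl <- tibble::tibble(site_id = 1:4,
                         lobe = c("RUL", "RLL", "LUL", "LLL"))
  bio <- brwall_t2_mis(mask, t2, tabl)
  expect_equal(bio$brwall_t2_mis, 75)
  expect_equal(sort(bio$per_path$value), c(60, 70, 80, 90))
  # mean containment
  expect_gte(bio$brwall_t2_mis, min(bio$per_path$value))
  expect_lte(bio$brwall_t2_mis, max(bio$per_path$value))
  # constant region returns that constant
  one <- brwall_t2_mis(mask, brw_volume(array(42, dim(vol))),
                       tabl[1, ])
  expect_equal(one$brwall_t2_mis, 42)
  expect_error(brwall_t2_mis(array(0L, c(4, 4, 4)), t2, tabl), "empty")
})

test_that("measured BrWall_T2-MIS tracks the normalized ground-truth signal", {
  cfg <- default_config()
  vals <- vapply(c(60, 120), function(sig) {
    ph <- generate_phantom(clean_spec(wall_t2_signal = sig, seed = 7))
    norm <- normalize_t2(ph$t2w)
    res <- measure_airways(ph$ct, norm$volume, ph$ute,
                           phantom_root(ph), ph$truth$lobe_map, cfg)
    expected <- normalize_value(norm, sig)
    expect_lt(abs(res$biomarkers$brwall_t2_mis - expected) / expected, 0.05)
    res$biomarkers$brwall_t2_mis
  }, numeric(1))
  # doubling the wall signal strictly increases the measured biomarker
  expect_gt(vals[2], vals[1])
})
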