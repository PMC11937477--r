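#' Phantom specification
#'
#' Describes a synthetic subject: a symmetric dichotomous airway tree
#' (trachea = generation 0) embedded in a parenchyma background, imaged in
#' three co-registered modalities (CT-like, UTE-like, T2w-like), with a known
#' smooth inter-modality deformation and modality-appropriate noise. The
#' T2w wall intensity `wall_t2_signal` is the ground-truth inflammation
#' signal recovered by the measurement pipeline.
#'
#' @param grid_shape voxels per axis (length 3 or scalar).
#' @param voxel_size_mm isotropic voxel size in mm.
#' @param tree_depth generations beyond the trachea (depth 3 gives the four
#'   third-generation lobar paths plus their siblings).
#' @param lumen_radius_mm lumen radius per generation 0..`tree_depth`, mm.
#' @param wall_thickness_mm wall thickness per generation, mm.
#' @param wall_t2_signal mean pre-noise T2w wall intensity, arbitrary units.
#' @param intensities per-modality background levels: a list with elements
#'   `ct`, `ute`, `t2w`, each `c(lumen =, wall =, parenchyma =)`. The T2w
#'   `wall` entry is ignored in favour of `wall_t2_signal`.
#' @param branch_angle_deg half-angle between children at each bifurcation.
#' @param length_ratio child/parent branch length ratio.
#' @param trachea_length_mm trachea length, mm.
#' @param deformation list `(amplitude_mm, period_mm)` for the sinusoidal
#'   inter-modality displacement; amplitude 0 disables it. Amplitude must be
#'   below half the period so the field is fold-free.
#' @param noise_sigma per-modality noise level `c(ct =, ute =, t2w =)`;
#'   `NULL` picks defaults giving wall SNR of about 10 on the MR-like
#'   volumes; all zeros disables noise.
#' @param mucus_plug_paths character vector of lobe labels (e.g. `"RUL"`) or
#'   full branch labels whose proximal third is filled with wall-level
#'   intensity, emulating proximal mucus plugging.
#' @param n_vessels number of vessel-like parenchymal blobs. Lung
#'   parenchyma is threaded with vasculature visible in every modality, and
#'   those landmarks are what multimodal registration locks onto; a phantom
#'   with featureless parenchyma would make deformable alignment of the
#'   lung interior ill-posed in a way real images are not. Blobs are kept
#'   clear of the airway walls so wall measurement is unaffected.
#' @param seed integer; fully determines all stochastic content.
#' @return A `phantom_spec` list, validated.
#' @export
phantom_spec <- function(grid_shape = c(96, 96, 96),
                         voxel_size_mm = 1.0,
                         tree_depth = 3,
                         lumen_radius_mm = c(4, 3, 2.5, 2),
                         wall_thickness_mm = c(2, 2, 2, 2),
                         wall_t2_signal = 80,
                         intensities = NULL,
                         branch_angle_deg = 35,
                         length_ratio = 0.8,
                         trachea_length_mm = 22,
                         deformation = list(amplitude_mm = 3, period_mm = 48),
                         noise_sigma = NULL,
                         mucus_plug_paths = character(0),
                         n_vessels = 150L,
                         seed = 1L) {
  grid_shape <- rep_len(as.integer(grid_shape), 3)
  if (is.null(intensities)) {
    intensities <- list(
      ct  = c(lumen = -1000, wall = 0,   parenchyma = -850),
      ute = c(lumen = 10,    wall = 120, parenchyma = 40)
    )
  }
  intensities$t2w <- c(lumen = 5, wall = wall_t2_signal, parenchyma = 30)
  if (is.null(noise_sigma)) {
    # wall SNR about 10 per modality; floor keeps the MR noise level sane
    # for faint wall signals
    noise_sigma <- c(ct = 30, ute = 12, t2w = max(wall_t2_signal / 10, 1))
  }
  spec <- structure(list(
    grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
    tree_depth = as.integer(tree_depth),
    lumen_radius_mm = lumen_radius_mm,
    wall_thickness_mm = wall_thickness_mm,
    wall_t2_signal = wall_t2_signal, intensities = intensities,
    branch_angle_deg = branch_angle_deg, length_ratio = length_ratio,
    trachea_length_mm = trachea_length_mm, deformation = deformation,
    noise_sigma = noise_sigma, mucus_plug_paths = mucus_plug_paths,
    n_vessels = as.integer(n_vessels), seed = as.integer(seed)
  ), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  ng <- spec$tree_depth + 1
  if (length(spec$lumen_radius_mm) < ng || length(spec$wall_thickness_mm) < ng) {
    stop("lumen_radius_mm and wall_thickness_mm must cover generations 0..",
         spec$tree_depth, call. = FALSE)
  }
  if (any(spec$lumen_radius_mm <= 0) || any(spec$wall_thickness_mm <= 0)) {
    stop("all radii and wall thicknesses must be > 0", call. = FALSE)
  }
  def <- spec$deformation
  if (def$amplitude_mm < 0) stop("deformation amplitude must be >= 0", call. = FALSE)
  if (def$amplitude_mm > 0 && def$amplitude_mm >= def$period_mm / 2) {
    stop("deformation amplitude must be < half the spatial period ",
         "(fold-free displacement)", call. = FALSE)
  }
  if (spec$voxel_size_mm <= 0) stop("voxel size must be > 0", call. = FALSE)
  invisible(spec)
}

rotate_about <- function(v, axis, angle_rad) {
  a <- axis / sqrt(sum(axis^2))
  v * cos(angle_rad) +
    c(a[2] * v[3] - a[3] * v[2],
      a[3] * v[1] - a[1] * v[3],
      a[1] * v[2] - a[2] * v[1]) * sin(angle_rad) +
    a * sum(a * v) * (1 - cos(angle_rad))
}

#' Analytic airway-tree geometry for a phantom
#'
#' Builds the symmetric dichotomous branch table: each bifurcation opens the
#' branch angle symmetrically, alternating the bifurcation plane between
#' generations so the tree spreads in both lateral directions.
#'
#' @param spec a [phantom_spec()].
#' @return A tibble with one row per branch: label, parent, generation,
#'   start/end points and direction (mm, world coordinates), length and the
#'   lumen/outer radii.
#' @export
phantom_tree_geometry <- function(spec) {
  ext <- (spec$grid_shape - 1) * spec$voxel_size_mm
  r_out0 <- spec$lumen_radius_mm[1] + spec$wall_thickness_mm[1]
  start0 <- c(ext[1] / 2, ext[2] / 2, ext[3] - r_out0 - 2)
  ang <- spec$branch_angle_deg * pi / 180

  rows <- list()
  # queue entries: label, parent label, generation, start, dir
  queue <- list(list(label = "T", parent = NA_character_, gen = 0L,
                     start = start0, dir = c(0, 0, -1)))
  bid <- 0L
  while (length(queue) > 0) {
    b <- queue[[1]]; queue <- queue[-1]
    bid <- bid + 1L
    len <- spec$trachea_length_mm * spec$length_ratio^b$gen
    end <- b$start + b$dir * len
    g1 <- b$gen + 1L
    rows[[bid]] <- tibble::tibble(
      branch_id = bid, label = b$label, parent_label = b$parent,
      generation = b$gen,
      x0 = b$start[1], y0 = b$start[2], z0 = b$start[3],
      x1 = end[1], y1 = end[2], z1 = end[3],
      dx = b$dir[1], dy = b$dir[2], dz = b$dir[3],
      length_mm = len,
      r_lumen = spec$lumen_radius_mm[b$gen + 1],
      r_outer = spec$lumen_radius_mm[b$gen + 1] +
        spec$wall_thickness_mm[b$gen + 1]
    )
    if (g1 <= spec$tree_depth) {
      axis <- if (b$gen %% 2 == 0) c(0, 1, 0) else c(1, 0, 0)
      for (s in c(-1, 1)) {
        queue[[length(queue) + 1]] <- list(
          label = paste0(b$label, ".", if (s < 0) 1 else 2),
          parent = b$label, gen = g1, start = end,
          dir = rotate_about(b$dir, axis, s * ang))
      }
    }
  }
  tree <- dplyr::bind_rows(rows)
  # sizing check: every branch (outer surface + margin) must fit the grid
  marg <- 1.5 * spec$voxel_size_mm
  lo <- pmin(tree$x0 - tree$r_outer, tree$x1 - tree$r_outer,
             tree$y0 - tree$r_outer, tree$y1 - tree$r_outer,
             tree$z1 - tree$r_outer)
  if (min(lo) < marg ||
      max(tree$x1 + tree$r_outer, tree$y1 + tree$r_outer) > max(ext) - marg) {
    stop("grid too small to contain the airway tree at the requested radii",
         call. = FALSE)
  }
  tree
}

# Lobe assignment: each lobe is one generation-2 subtree (as real lobar
# bronchi are), labeled by its side (x relative to the grid centre) and by
# its mean height within that side. The designated third-generation lobar
# path is the first child (by label) of the lobe's generation-2 parent, so
# occluding one lobe's path never touches another lobe's subtree.
phantom_lobe_map <- function(tree, spec) {
  g3 <- tree[tree$generation == 3, ]
  if (nrow(g3) == 0) return(tibble::tibble())
  cx <- (spec$grid_shape[1] - 1) * spec$voxel_size_mm / 2
  g3$mx <- (g3$x0 + g3$x1) / 2
  g3$my <- (g3$y0 + g3$y1) / 2
  g3$mz <- (g3$z0 + g3$z1) / 2
  sub <- g3 |>
    dplyr::group_by(.data$parent_label) |>
    dplyr::summarise(sx = mean(.data$mx), sz = mean(.data$mz),
                     .groups = "drop")
  sub$side <- ifelse(sub$sx >= cx, "R", "L")
  sub$vert <- NA_character_
  for (s in c("L", "R")) {
    i <- which(sub$side == s)
    sub$vert[i] <- ifelse(rank(-sub$sz[i], ties.method = "first") <=
                            length(i) / 2, "U", "L")
  }
  sub$lobe <- paste0(sub$side, sub$vert, "L")
  designated <- g3 |>
    dplyr::arrange(.data$parent_label, .data$label) |>
    dplyr::distinct(.data$parent_label, .keep_all = TRUE) |>
    dplyr::left_join(sub[, c("parent_label", "lobe")], by = "parent_label")
  designated[order(designated$lobe),
             c("lobe", "label", "branch_id", "mx", "my", "mz")]
}

# Sinusoidal displacement field in mm on a grid (dims d, spacing mm).
# Each component varies along a different axis; phases from the current RNG.
# `amplitude` bounds the total displacement magnitude |u| (per-component
# amplitude is amplitude / sqrt(3)).
sinusoid_field <- function(d, spacing, amplitude, period, phases = c(0, 0, 0)) {
  field <- array(0, c(d, 3))
  if (amplitude == 0) return(field)
  g <- index_grid(d)
  w <- 2 * pi / period
  a <- amplitude / sqrt(3)
  field[, , , 1] <- array(a * sin(w * (g$yi - 1) * spacing + phases[1]), d)
  field[, , , 2] <- array(a * sin(w * (g$zi - 1) * spacing + phases[2]), d)
  field[, , , 3] <- array(a * sin(w * (g$xi - 1) * spacing + phases[3]), d)
  field
}

# Numerical inverse of a displacement field by fixed-point iteration:
# find v with v(x) = -u(x + v(x)). For large grids the iteration runs at
# half resolution and the result is upsampled — the fields of interest are
# smooth on a much coarser scale, so the downsampling error is negligible
# while the cost drops eightfold.
invert_field <- function(field, spacing, iters = 10) {
  d <- dim(field)[1:3]
  if (all(field == 0)) return(field)
  if (min(d) >= 64) {
    half <- array(0, c(floor(d / 2), 3))
    for (c3 in 1:3) half[, , , c3] <- downsample2(field[, , , c3])
    inv_half <- invert_field(half, spacing * 2, iters = iters)
    return(upsample_field(inv_half, d))
  }
  g <- index_grid(d)
  spacing <- rep_len(spacing, 3)
  vx <- numeric(prod(d)); vy <- numeric(prod(d)); vz <- numeric(prod(d))
  ux <- field[, , , 1]; uy <- field[, , , 2]; uz <- field[, , , 3]
  for (it in seq_len(iters)) {
    xi <- g$xi + vx / spacing[1]
    yi <- g$yi + vy / spacing[2]
    zi <- g$zi + vz / spacing[3]
    vx <- -interp_trilinear(ux, xi, yi, zi, fill = 0)
    vy <- -interp_trilinear(uy, xi, yi, zi, fill = 0)
    vz <- -interp_trilinear(uz, xi, yi, zi, fill = 0)
  }
  out <- array(0, c(d, 3))
  out[, , , 1] <- vx; out[, , , 2] <- vy; out[, , , 3] <- vz
  out
}

#' Generate a co-registered synthetic volume triplet with ground truth
#'
#' Rasterizes the analytic airway tree into a UTE-like reference volume and
#' CT-like / T2w-like moving volumes. The moving volumes are resampled
#' through the stored smooth displacement field (so registration back to the
#' UTE-like frame has a known answer), then degraded with additive Gaussian
#' (CT-like) or Rician (MR-like) noise. Boundary voxels are anti-aliased over
#' one voxel width; interior wall voxels in the T2w-like volume have mean
#' pre-noise intensity exactly `wall_t2_signal`.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `ct`, `ute`, `t2w` ([brw_volume()]s) and
#'   `truth`: the branch table, label volume (1 = lumen, 2 = wall,
#'   3 = mucus plug), per-branch path-id volume, analytic per-section areas
#'   (`LA`, `WA`, `WA_percent` per branch), centerline samples, the lobe map,
#'   the forward resampling field and its numerical inverse (the field a
#'   registration of the moving volumes onto the UTE-like frame should
#'   recover), and the true wall T2 signal.
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  set.seed(spec$seed)
  d <- spec$grid_shape
  h <- spec$voxel_size_mm
  tree <- phantom_tree_geometry(spec)
  lobe_map <- phantom_lobe_map(tree, spec)

  # resolve plug requests (lobe names or branch labels) to branch ids
  plug_ids <- integer(0)
  for (p in spec$mucus_plug_paths) {
    if (p %in% tree$label) {
      plug_ids <- c(plug_ids, tree$branch_id[tree$label == p])
    } else if (nrow(lobe_map) > 0 && p %in% lobe_map$lobe) {
      plug_ids <- c(plug_ids, lobe_map$branch_id[lobe_map$lobe == p])
    } else {
      stop("unknown mucus_plug_paths entry: ", p, call. = FALSE)
    }
  }

  # per-voxel nearest-branch classification over branch bounding boxes
  rho_best <- array(Inf, d)     # d / r_outer of the closest branch
  d_best <- array(Inf, d)
  rin_best <- array(0, d)
  rout_best <- array(0, d)
  path_best <- array(0L, d)
  plug_mask <- array(FALSE, d)

  for (b in seq_len(nrow(tree))) {
    p0 <- c(tree$x0[b], tree$y0[b], tree$z0[b])
    p1 <- c(tree$x1[b], tree$y1[b], tree$z1[b])
    r_out <- tree$r_outer[b]
    lo <- pmax(floor(pmin(p0, p1) - r_out - h) / h + 1, 1)
    hi <- pmin(ceiling(pmax(p0, p1) + r_out + h) / h + 1, d)
    ii <- seq(lo[1], hi[1]); jj <- seq(lo[2], hi[2]); kk <- seq(lo[3], hi[3])
    nx <- length(ii); ny <- length(jj); nz <- length(kk)
    px <- rep((ii - 1) * h, times = ny * nz)
    py <- rep(rep((jj - 1) * h, each = nx), times = nz)
    pz <- rep((kk - 1) * h, each = nx * ny)
    u <- p1 - p0; L <- sqrt(sum(u^2)); u <- u / L
    t <- (px - p0[1]) * u[1] + (py - p0[2]) * u[2] + (pz - p0[3]) * u[3]
    tc <- pmin(pmax(t, 0), L)
    dist <- sqrt((px - p0[1] - tc * u[1])^2 +
                 (py - p0[2] - tc * u[2])^2 +
                 (pz - p0[3] - tc * u[3])^2)
    rho <- dist / r_out
    sub <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
    lin <- sub[, 1] + d[1] * (sub[, 2] - 1) + d[1] * d[2] * (sub[, 3] - 1)
    upd <- rho < rho_best[lin]
    linu <- lin[upd]
    rho_best[linu] <- rho[upd]
    d_best[linu] <- dist[upd]
    rin_best[linu] <- tree$r_lumen[b]
    rout_best[linu] <- r_out
    path_best[linu] <- tree$branch_id[b]
    if (tree$branch_id[b] %in% plug_ids) {
      inplug <- t >= 0 & t <= L / 3 & dist < tree$r_lumen[b]
      plug_mask[lin[inplug]] <- TRUE
    }
  }

  labels <- array(0L, d)
  labels[d_best < rin_best] <- 1L
  labels[d_best >= rin_best & d_best < rout_best] <- 2L
  labels[plug_mask] <- 3L
  path_id <- path_best
  path_id[labels == 0L] <- 0L

  # anti-aliased intensity synthesis: smooth step over one voxel width
  sstep <- function(t) pmin(pmax(0.5 + t / h, 0), 1)
  wi <- sstep(rin_best - d_best)          # lumen weight
  wo <- sstep(rout_best - d_best)         # inside-outer weight
  ww <- wo * (1 - wi)                     # wall weight
  synth <- function(v) {
    out <- wi * v[["lumen"]] + ww * v[["wall"]] +
      (1 - wo) * v[["parenchyma"]]
    out[plug_mask] <- v[["wall"]]
    out
  }
  ct0 <- synth(spec$intensities$ct)
  ute0 <- synth(spec$intensities$ute)
  # vessel-like parenchymal texture, shared across modalities and kept
  # clear of the airway outer walls
  ves <- vessel_texture(spec, tree, d, h)
  ct0 <- ct0 + 420 * ves
  ute0 <- ute0 + 60 * ves
  # T2w is synthesized with sharp classification (no edge blending): wall
  # voxels carry exactly wall_t2_signal pre-noise, the quantity the
  # measurement pipeline must recover. Boundary detection never runs on the
  # T2w volume, so sub-voxel edges are not needed here.
  v2 <- spec$intensities$t2w
  t2w0 <- array(v2[["parenchyma"]], d)
  t2w0 <- t2w0 + 25 * ves
  t2w0[labels == 1L] <- v2[["lumen"]]
  t2w0[labels == 2L] <- v2[["wall"]]
  t2w0[plug_mask] <- v2[["wall"]]

  # inter-modality deformation: moving(x) = reference(x + u(x))
  phases <- stats::runif(3, 0, 2 * pi)
  fld <- sinusoid_field(d, h, spec$deformation$amplitude_mm,
                        spec$deformation$period_mm, phases)
  fld4 <- array(fld, c(d, 3))
  ct_mov <- warp_array(ct0, fld4, h, fill = spec$intensities$ct[["parenchyma"]])
  t2_mov <- warp_array(t2w0, fld4, h, fill = spec$intensities$t2w[["parenchyma"]])
  fld_inv <- invert_field(fld4, h)

  # noise: additive Gaussian on CT-like, Rician on MR-like
  ns <- spec$noise_sigma
  n_vox <- prod(d)
  add_rician <- function(a, s) {
    if (s <= 0) return(a)
    sqrt((a + stats::rnorm(n_vox, 0, s))^2 + stats::rnorm(n_vox, 0, s)^2)
  }
  if (ns[["ct"]] > 0) ct_mov <- ct_mov + stats::rnorm(n_vox, 0, ns[["ct"]])
  ute_n <- add_rician(ute0, ns[["ute"]])
  t2_n <- add_rician(t2_mov, ns[["t2w"]])

  sections <- tree |>
    dplyr::mutate(
      LA = pi * .data$r_lumen^2,
      WA = pi * (.data$r_outer^2 - .data$r_lumen^2),
      WA_percent = 100 * .data$WA / (.data$WA + .data$LA)
    ) |>
    dplyr::select("branch_id", "label", "generation", "r_lumen", "r_outer",
                  "LA", "WA", "WA_percent")

  centerline <- phantom_centerline_samples(tree, step_mm = 1)

  truth <- list(
    tree = tree, lobe_map = lobe_map, labels = array(labels, d),
    path_id = array(path_id, d), sections = sections,
    centerline = centerline, field = fld4, field_inv = fld_inv,
    wall_t2_signal = spec$wall_t2_signal,
    plugged_branches = tree$label[tree$branch_id %in% plug_ids],
    spec = spec
  )
  list(
    ct = brw_volume(array(ct_mov, d), h, "CT-like"),
    ute = brw_volume(array(ute_n, d), h, "UTE-like"),
    t2w = brw_volume(array(t2_n, d), h, "T2w-like"),
    truth = truth
  )
}

# Ground-truth centerline samples: points and tangents every step_mm.
phantom_centerline_samples <- function(tree, step_mm = 1) {
  purrr::map_dfr(seq_len(nrow(tree)), function(b) {
    n <- max(2, ceiling(tree$length_mm[b] / step_mm) + 1)
    t <- seq(0, tree$length_mm[b], length.out = n)
    tibble::tibble(
      branch_id = tree$branch_id[b], label = tree$label[b],
      generation = tree$generation[b], arc_mm = t,
      x = tree$x0[b] + t * tree$dx[b],
      y = tree$y0[b] + t * tree$dy[b],
      z = tree$z0[b] + t * tree$dz[b],
      tx = tree$dx[b], ty = tree$dy[b], tz = tree$dz[b]
    )
  })
}

#' Write a phantom subject to disk
#'
#' One NIfTI per modality, ground-truth centerline and per-section areas as
#' CSV, and the remaining ground truth (tree, lobe map, plug records) as JSON.
#'
#' @param phantom result of [generate_phantom()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Invisibly, the vector of files written.
#' @export
write_phantom <- function(phantom, dir, prefix = "subject") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- character(0)
  for (m in c("ct", "ute", "t2w")) {
    p <- file.path(dir, paste0(prefix, "_", m, ".nii.gz"))
    write_volume(phantom[[m]], p)
    f <- c(f, p)
  }
  cl <- file.path(dir, paste0(prefix, "_centerline.csv"))
  utils::write.csv(phantom$truth$centerline, cl, row.names = FALSE)
  ar <- file.path(dir, paste0(prefix, "_sections.csv"))
  utils::write.csv(phantom$truth$sections, ar, row.names = FALSE)
  js <- file.path(dir, paste0(prefix, "_truth.json"))
  jsonlite::write_json(list(
    tree = phantom$truth$tree, lobe_map = phantom$truth$lobe_map,
    plugged_branches = phantom$truth$plugged_branches,
    wall_t2_signal = phantom$truth$wall_t2_signal
  ), js, auto_unbox = TRUE, digits = NA)
  invisible(c(f, cl, ar, js))
}

# Vessel-like parenchymal blobs: anti-aliased spheres with random centres
# and radii, rejected within a clearance of the airway tree so the wall
# measurements never see them. Returns a [0, 1] coverage array.
vessel_texture <- function(spec, tree, d, h) {
  out <- array(0, d)
  if (spec$n_vessels <= 0) return(out)
  ext <- (d - 1) * h
  seg0 <- cbind(tree$x0, tree$y0, tree$z0)
  seg1 <- cbind(tree$x1, tree$y1, tree$z1)
  placed <- 0L
  tries <- 0L
  while (placed < spec$n_vessels && tries < spec$n_vessels * 20) {
    tries <- tries + 1L
    ctr <- stats::runif(3, 2, ext - 2)
    r <- stats::runif(1, 0.8, 2.2)
    # distance to every branch segment
    dmin <- Inf
    for (b in seq_len(nrow(tree))) {
      u <- seg1[b, ] - seg0[b, ]; L2 <- sum(u^2)
      t <- pmin(pmax(sum((ctr - seg0[b, ]) * u) / L2, 0), 1)
      dmin <- min(dmin, sqrt(sum((ctr - seg0[b, ] - t * u)^2)) -
                    tree$r_outer[b])
    }
    if (dmin < r + 2) next
    lo <- pmax(floor((ctr - r - h) / h) + 1, 1)
    hi <- pmin(ceiling((ctr + r + h) / h) + 1, d)
    ii <- seq(lo[1], hi[1]); jj <- seq(lo[2], hi[2]); kk <- seq(lo[3], hi[3])
    nx <- length(ii); ny <- length(jj); nz <- length(kk)
    px <- rep((ii - 1) * h, times = ny * nz) - ctr[1]
    py <- rep(rep((jj - 1) * h, each = nx), times = nz) - ctr[2]
    pz <- rep((kk - 1) * h, each = nx * ny) - ctr[3]
    cov <- pmin(pmax(0.5 + (r - sqrt(px^2 + py^2 + pz^2)) / h, 0), 1)
    sub <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
    lin <- sub[, 1] + d[1] * (sub[, 2] - 1) + d[1] * d[2] * (sub[, 3] - 1)
    out[lin] <- pmax(out[lin], cov)
    placed <- placed + 1L
  }
  out
}
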