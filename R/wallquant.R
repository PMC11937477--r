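# Cross-sectional wall measurement: Laplacian-of-Gaussian boundary detection
# along radial rays, lumen/wall areas by the shoelace formula, rasterization
# of wall masks back onto the 3D grid, and the per-patient bronchial wall T2
# mean intensity signal.

interp_bilinear <- function(m, xi, yi, fill = NA_real_) {
  d <- dim(m)
  inside <- xi >= 1 & xi <= d[1] & yi >= 1 & yi <= d[2]
  out <- rep(fill, length(xi))
  if (!any(inside)) return(out)
  xi <- xi[inside]; yi <- yi[inside]
  x0 <- pmin(floor(xi), d[1] - 1L); y0 <- pmin(floor(yi), d[2] - 1L)
  fx <- xi - x0; fy <- yi - y0
  li <- function(i, j) i + d[1] * (j - 1)
  v00 <- m[li(x0, y0)]; v10 <- m[li(x0 + 1, y0)]
  v01 <- m[li(x0, y0 + 1)]; v11 <- m[li(x0 + 1, y0 + 1)]
  out[inside] <- (v00 * (1 - fx) + v10 * fx) * (1 - fy) +
    (v01 * (1 - fx) + v11 * fx) * fy
  out
}

# Scale-normalized Laplacian-of-Gaussian response of a 2D section (sigma in
# mm; the section's sample spacing converts it to pixels).
log_response <- function(img, spacing, sigma_mm) {
  s <- gauss_smooth(img, sigma_mm / spacing)
  sigma_mm^2 * laplacian(s, spacing)
}

# Flood fill (4-connectivity) of `cond` from the centre pixel.
flood_from_center <- function(cond) {
  d <- dim(cond)
  m <- array(FALSE, d)
  m[ceiling(d[1] / 2), ceiling(d[2] / 2)] <- TRUE
  if (!cond[ceiling(d[1] / 2), ceiling(d[2] / 2)]) return(m & FALSE)
  repeat {
    grown <- (m | shift_array(m, 1, 1) | shift_array(m, -1, 1) |
                shift_array(m, 1, 2) | shift_array(m, -1, 2)) & cond
    if (identical(grown, m)) break
    m <- grown
  }
  m
}

# Zero crossings of a sampled profile: positions (in sample units, 1-based,
# fractional) where the sign changes, by linear interpolation.
zero_crossings <- function(v) {
  n <- length(v)
  i <- which(v[-n] * v[-1] < 0 | (v[-n] == 0 & v[-1] != 0))
  if (length(i) == 0) return(numeric(0))
  i + v[i] / (v[i] - v[i + 1])
}

shoelace_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Measure lumen and wall areas on a cross-section
#'
#' Computes the scale-normalized Laplacian-of-Gaussian response of the
#' section and, along radial rays from the lumen centroid, locates the
#' bronchial wall as the innermost strong negative LoG ridge; the inner and
#' outer wall boundaries are the zero-crossings bracketing that ridge
#' extremum, with sub-sample positions by linear interpolation. Boundary
#' polygons (one vertex per successful ray) give the lumen area LA and wall
#' area WA by the shoelace formula. A scale sweep keeps the
#' response-maximizing sigma.
#'
#' @param section a `cross_section` from [reformat_cross_section()],
#'   typically of the CT-like volume.
#' @param sigma_mm LoG scale(s) in mm to sweep; the scale with the largest
#'   mean ridge response is kept.
#' @param n_rays number of radial rays.
#' @param max_fail_frac measurement fails if more than this fraction of rays
#'   finds no zero-crossing pair (recorded in `status`, not an error).
#' @return A `wall_measurement` list: `LA`, `WA`, `WA_percent` (mm^2 / %),
#'   `status` (`"ok"`/`"failed"`), chosen `sigma_mm`, ray fail fraction,
#'   lumen centroid offset, and the boundary table (per-ray inner/outer
#'   radii and polygon vertices, mm).
#' @export
detect_wall <- function(section, sigma_mm = c(0.3, 0.5, 0.8), n_rays = 64,
                        max_fail_frac = 0.25) {
  stopifnot(inherits(section, "cross_section"))
  img <- section$image
  sp <- section$spacing
  ax <- section$axis_mm
  img[is.na(img)] <- stats::median(img, na.rm = TRUE)

  # lumen centroid: flood-fill the dark region around the centre
  vc <- img[ceiling(nrow(img) / 2), ceiling(ncol(img) / 2)]
  vhi <- stats::quantile(img, 0.95)
  lum <- flood_from_center(img < vc + 0.25 * (vhi - vc))
  if (!any(lum)) {
    return(failed_measurement("no lumen region around the section centre"))
  }
  idx <- which(lum, arr.ind = TRUE)
  c0 <- c(mean(ax[idx[, 1]]), mean(ax[idx[, 2]]))  # mm, in-plane

  r_max <- max(abs(ax)) * 0.95 - max(abs(c0))
  r_step <- sp / 2
  rr <- seq(r_step, r_max, by = r_step)
  theta <- 2 * pi * (seq_len(n_rays) - 1) / n_rays

  # scale sweep, smallest scale first: boundary bias grows like sigma^2/(2r)
  # on curved walls, so the smallest scale that yields a valid measurement
  # is kept; larger scales only serve noisy/thick-walled sections where the
  # small scales fail.
  best <- NULL
  for (s in sort(sigma_mm)) {
    S <- gauss_smooth(img, s / sp)
    rays <- measure_rays(S, s, ax, sp, c0, rr, theta)
    rays$sigma <- s
    rays$fail <- mean(is.na(rays$r_in))
    if (rays$fail <= max_fail_frac) { best <- rays; break }
    if (is.null(best) || rays$fail < best$fail) best <- rays
  }
  fail_frac <- best$fail
  if (fail_frac > max_fail_frac) {
    return(failed_measurement(
      sprintf("no zero-crossing pair on %.0f%% of rays", 100 * fail_frac),
      sigma = best$sigma, fail_frac = fail_frac))
  }
  ok <- !is.na(best$r_in)
  xi <- c0[1] + best$r_in[ok] * cos(theta[ok])
  yi <- c0[2] + best$r_in[ok] * sin(theta[ok])
  xo <- c0[1] + best$r_out[ok] * cos(theta[ok])
  yo <- c0[2] + best$r_out[ok] * sin(theta[ok])
  LA <- shoelace_area(xi, yi)
  A_out <- shoelace_area(xo, yo)
  WA <- A_out - LA
  structure(list(
    LA = LA, WA = WA, WA_percent = wa_percent(WA, LA),
    status = "ok", sigma_mm = best$sigma, fail_frac = fail_frac,
    centroid_mm = c0,
    boundary = tibble::tibble(
      ray = which(ok), theta = theta[ok],
      r_inner = best$r_in[ok], r_outer = best$r_out[ok],
      x_inner = xi, y_inner = yi, x_outer = xo, y_outer = yo
    )
  ), class = "wall_measurement")
}

failed_measurement <- function(reason, sigma = NA_real_, fail_frac = NA_real_) {
  structure(list(
    LA = NA_real_, WA = NA_real_, WA_percent = NA_real_,
    status = "failed", reason = reason, sigma_mm = sigma,
    fail_frac = fail_frac, centroid_mm = c(NA_real_, NA_real_),
    boundary = tibble::tibble()
  ), class = "wall_measurement")
}

# Per-ray boundary search at one LoG scale. The boundary criterion is the
# zero-crossing of the second *radial* derivative of the Gaussian-smoothed
# section along the ray (the 1D Laplacian-of-Gaussian of the radial
# profile): unlike the full 2D Laplacian it carries no 1/r curvature term,
# so crossings sit on the inflection points of the smoothed edge — the
# boundary — rather than being biased outward on curved walls. Returns
# inner/outer radii (mm; NA on failure) and the mean ridge response.
measure_rays <- function(S, sigma, ax, sp, c0, rr, theta) {
  n_rays <- length(theta)
  r_in <- rep(NA_real_, n_rays); r_out <- rep(NA_real_, n_rays)
  resp <- rep(NA_real_, n_rays)
  dr <- rr[2] - rr[1]
  o <- max(1L, round(sigma / (2 * dr)))   # derivative step ~ sigma/2
  for (k in seq_len(n_rays)) {
    px <- c0[1] + rr * cos(theta[k])
    py <- c0[2] + rr * sin(theta[k])
    xi <- (px - ax[1]) / sp + 1
    yi <- (py - ax[1]) / sp + 1
    sprof <- interp_bilinear(S, xi, yi, fill = NA_real_)
    sprof[is.na(sprof)] <- 0
    n <- length(sprof)
    prof <- rep(0, n)
    i <- (o + 1):(n - o)
    prof[i] <- sigma^2 * (sprof[i - o] - 2 * sprof[i] + sprof[i + o]) /
      (o * dr)^2
    # innermost significant negative ridge (bright wall -> LoG dip)
    gmin <- min(prof)
    if (gmin >= 0) next
    dips <- which(prof < 0.3 * gmin &
                    prof <= c(prof[-1], Inf) & prof <= c(Inf, prof[-length(prof)]))
    if (length(dips) == 0) next
    dip <- dips[1]   # pair nearest the lumen centroid (innermost wall)
    zc <- zero_crossings(prof)
    inner <- zc[zc < dip]
    outer <- zc[zc > dip]
    if (length(inner) == 0 || length(outer) == 0) next
    r_in[k] <- rr[1] + (max(inner) - 1) * (rr[2] - rr[1])
    r_out[k] <- rr[1] + (min(outer) - 1) * (rr[2] - rr[1])
    resp[k] <- -prof[dip]
  }
  list(r_in = r_in, r_out = r_out,
       response = if (all(is.na(resp))) -Inf else mean(resp, na.rm = TRUE))
}

#' Normalized wall area
#'
#' `WA% = 100 * WA / (WA + LA)`: the wall area as a percentage of the total
#' (lumen + wall) airway cross-sectional area.
#'
#' @param WA wall area, mm^2 (non-negative).
#' @param LA lumen area, mm^2 (non-negative).
#' @return WA% in percent.
#' @export
wa_percent <- function(WA, LA) {
  if (any(WA < 0) || any(LA < 0)) {
    stop("areas must be non-negative", call. = FALSE)
  }
  tot <- WA + LA
  if (any(tot == 0)) stop("WA + LA must be > 0", call. = FALSE)
  100 * WA / tot
}

#' Rasterize per-site wall measurements into a labeled 3D mask
#'
#' For each measured cross-section, voxels within a thin slab around the
#' section plane whose in-plane radius falls between the detected inner and
#' outer boundaries are labeled with the site id, giving a per-path,
#' per-site bronchial wall label volume on the reference grid.
#'
#' @param sites tibble of measured sites: columns `site_id`, `cx`, `cy`,
#'   `cz`, `nx`, `ny`, `nz` plus a `measurement` list-column of
#'   `wall_measurement` objects (and the section axes `e1`, `e2` stored as
#'   list-columns `e1`, `e2`).
#' @param grid a [brw_volume()] defining the output grid.
#' @param slab_half_mm half-thickness of the slab around each section plane.
#' @param lumen_mask optional binary lumen segmentation; any wall-mask voxel
#'   falling inside it is cleared, so the wall mask and the lumen mask are
#'   disjoint by construction.
#' @return Integer array labeled by `site_id` (0 = background).
#' @export
wall_mask_3d <- function(sites, grid, slab_half_mm = 1, lumen_mask = NULL) {
  stopifnot(is_volume(grid))
  ok <- vapply(sites$measurement, function(m) m$status == "ok", logical(1))
  if (!any(ok)) stop("empty measurement set: no successful sections",
                     call. = FALSE)
  d <- dim(grid$data)
  h <- grid$spacing
  out <- array(0L, d)
  for (i in which(ok)) {
    m <- sites$measurement[[i]]
    e1 <- sites$e1[[i]]; e2 <- sites$e2[[i]]
    nrm <- c(sites$nx[i], sites$ny[i], sites$nz[i])
    ctr <- c(sites$cx[i], sites$cy[i], sites$cz[i]) +
      m$centroid_mm[1] * e1 + m$centroid_mm[2] * e2
    rmax <- max(m$boundary$r_outer) + 1
    lo <- pmax(floor(world_to_voxel(grid, ctr - rmax - slab_half_mm)), 1)
    hi <- pmin(ceiling(world_to_voxel(grid, ctr + rmax + slab_half_mm)), d)
    ii <- seq(lo[1], hi[1]); jj <- seq(lo[2], hi[2]); kk <- seq(lo[3], hi[3])
    nx <- length(ii); ny <- length(jj); nz <- length(kk)
    px <- rep((ii - 1) * h[1], times = ny * nz) - ctr[1]
    py <- rep(rep((jj - 1) * h[2], each = nx), times = nz) - ctr[2]
    pz <- rep((kk - 1) * h[3], each = nx * ny) - ctr[3]
    dn <- px * nrm[1] + py * nrm[2] + pz * nrm[3]
    u <- px * e1[1] + py * e1[2] + pz * e1[3]
    v <- px * e2[1] + py * e2[2] + pz * e2[3]
    rho <- sqrt(u^2 + v^2)
    th <- atan2(v, u) %% (2 * pi)
    bt <- m$boundary[order(m$boundary$theta), ]
    thb <- c(bt$theta, bt$theta[1] + 2 * pi)
    rin <- stats::approx(thb, c(bt$r_inner, bt$r_inner[1]), xout = th,
                         rule = 2)$y
    rout <- stats::approx(thb, c(bt$r_outer, bt$r_outer[1]), xout = th,
                          rule = 2)$y
    inwall <- abs(dn) <= slab_half_mm & rho >= rin & rho <= rout
    if (!any(inwall)) next
    sub <- as.matrix(expand.grid(i = ii, j = jj, k = kk))[inwall, , drop = FALSE]
    lin <- sub[, 1] + d[1] * (sub[, 2] - 1) + d[1] * d[2] * (sub[, 3] - 1)
    out[lin] <- sites$site_id[i]
  }
  if (!is.null(lumen_mask)) out[lumen_mask != 0] <- 0L
  out
}

#' Per-patient bronchial wall T2 mean intensity signal
#'
#' Applies the per-site wall masks to the normalized T2w volume and
#' aggregates unweighted means in the order site -> path -> patient: the
#' mean intensity over each site's wall voxels, averaged over a path's
#' sites, averaged over the included paths, is the single patient value.
#'
#' @param site_mask labeled array from [wall_mask_3d()] (site ids).
#' @param t2 normalized T2w-like [brw_volume()] on the same grid.
#' @param site_table tibble mapping `site_id` to `lobe` (path label).
#' @return A `patient_biomarkers` list: `brwall_t2_mis` (patient value),
#'   `per_path`, `per_site` tibbles, `excluded` path records.
#' @export
brwall_t2_mis <- function(site_mask, t2, site_table) {
  stopifnot(is_volume(t2))
  if (!any(site_mask > 0)) stop("empty wall mask", call. = FALSE)
  per_site <- site_table |>
    dplyr::mutate(
      n_voxels = vapply(.data$site_id,
                        function(s) sum(site_mask == s), numeric(1)),
      mean_intensity = vapply(.data$site_id, function(s) {
        v <- t2$data[site_mask == s]
        if (length(v) == 0) NA_real_ else mean(v)
      }, numeric(1))
    )
  per_path <- per_site |>
    dplyr::group_by(.data$lobe) |>
    dplyr::summarise(
      n_sites = sum(!is.na(.data$mean_intensity)),
      value = mean(.data$mean_intensity, na.rm = TRUE),
      .groups = "drop"
    )
  excluded <- per_path |> dplyr::filter(.data$n_sites == 0 | is.nan(.data$value))
  included <- per_path |> dplyr::filter(.data$n_sites > 0 & !is.nan(.data$value))
  if (nrow(included) == 0) {
    stop("all paths have empty wall masks", call. = FALSE)
  }
  structure(list(
    brwall_t2_mis = mean(included$value),
    per_path = included, per_site = per_site, excluded = excluded
  ), class = "patient_biomarkers")
}

#' @export
print.patient_biomarkers <- function(x, ...) {
  cat(sprintf("<patient_biomarkers> BrWall_T2-MIS = %.2f Au over %d paths\n",
              x$brwall_t2_mis, nrow(x$per_path)))
  if (nrow(x$excluded) > 0) {
    cat("  excluded paths:", paste(x$excluded$lobe, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.wall_measurement <- function(x, ...) {
  if (x$status == "ok") {
    cat(sprintf("<wall_measurement> LA = %.2f mm^2, WA = %.2f mm^2, WA%% = %.1f (sigma %.2f mm)\n",
                x$LA, x$WA, x$WA_percent, x$sigma_mm))
  } else {
    cat(sprintf("<wall_measurement> FAILED: %s\n", x$reason))
  }
  invisible(x)
}
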