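# Shared fixtures: phantoms are expensive, so the common ones are built once
# per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# standard clean phantom: no deformation, no noise
clean_spec <- function(...) {
  phantom_spec(deformation = list(amplitude_mm = 0, period_mm = 48),
               noise_sigma = c(ct = 0, ute = 0, t2w = 0), ...)
}

clean_phantom <- function() {
  cached("clean", function() generate_phantom(clean_spec(seed = 7)))
}

noisy_phantom <- function() {
  cached("noisy", function() {
    generate_phantom(phantom_spec(
      deformation = list(amplitude_mm = 0, period_mm = 48), seed = 8))
  })
}

phantom_root <- function(ph) {
  tr <- ph$truth$tree
  c(tr$x0[1], tr$y0[1], tr$z0[1]) + 3 * c(tr$dx[1], tr$dy[1], tr$dz[1])
}

clean_tree <- function() {
  cached("clean_tree", function() {
    ph <- clean_phantom()
    lum <- segment_lumen(ph$ct, phantom_root(ph))
    label_generations(
      extract_centerline(lum, spacing = ph$ct$spacing,
                         root_mm = phantom_root(ph)))
  })
}

# an analytic annulus cross-section sampled directly at `spacing` mm, with
# optional Rician noise at the given wall SNR
annulus_section <- function(r_in = 2, r_out = 4, spacing = 0.3,
                            half_size = 8, snr = Inf,
                            levels = c(lumen = -1000, wall = 0,
                                       parenchyma = -850),
                            seed = NULL) {
  ax <- seq(-half_size, half_size, by = spacing)
  n <- length(ax)
  u <- rep(ax, times = n); v <- rep(ax, each = n)
  d <- sqrt(u^2 + v^2)
  ramp <- function(t) pmin(pmax(0.5 + t / spacing, 0), 1)
  wi <- ramp(r_in - d); wo <- ramp(r_out - d)
  img <- wi * levels[["lumen"]] + wo * (1 - wi) * levels[["wall"]] +
    (1 - wo) * levels[["parenchyma"]]
  if (is.finite(snr)) {
    # noise lives at the acquisition voxel scale (1 mm), not at the finer
    # section sampling: draw on a coarse grid and interpolate
    if (!is.null(seed)) set.seed(seed)
    contrast <- abs(levels[["wall"]] - levels[["parenchyma"]])
    cax <- seq(min(ax) - 1, max(ax) + 1, by = 1)
    cn <- matrix(stats::rnorm(length(cax)^2, 0, contrast / snr),
                 length(cax))
    xi <- (rep(ax, times = n) - cax[1]) / 1 + 1
    yi <- (rep(ax, each = n) - cax[1]) / 1 + 1
    img <- img + bronchowall:::interp_bilinear(cn, xi, yi, fill = 0)
  }
  structure(list(image = matrix(img, n, n), spacing = spacing,
                 center = c(0, 0, 0), normal = c(0, 0, 1),
                 e1 = c(1, 0, 0), e2 = c(0, 1, 0), axis_mm = ax,
                 flagged = FALSE),
            class = "cross_section")
}

# second-moment eccentricity of a closed boundary polygon
boundary_eccentricity <- function(x, y) {
  m <- cbind(x - mean(x), y - mean(y))
  ev <- eigen(stats::cov(m), symmetric = TRUE, only.values = TRUE)$values
  sqrt(1 - min(ev) / max(ev))
}
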