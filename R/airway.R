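# Airway-tree extraction: lumen segmentation by seeded region growing,
# centerline extraction by medial-weighted geodesic backtracing, generation
# labeling, lobar path selection with the mucus-plug exclusion rule, and
# oblique cross-section reformatting perpendicular to the bronchial axis.

# 26-connectivity neighbour offsets.
neighbour_offsets_26 <- function() {
  o <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  o[!(o$di == 0 & o$dj == 0 & o$dk == 0), ]
}

# Adjacency among a set of voxels (linear indices into an array of dim d):
# returns an edge list (pairs of positions within `lin`) and step lengths in
# mm. 26-connectivity.
voxel_adjacency <- function(lin, d, spacing) {
  ord <- order(lin)
  lin_s <- lin[ord]
  coords <- arrayInd(lin, d)
  offs <- neighbour_offsets_26()
  from <- integer(0); to <- integer(0); len <- numeric(0)
  for (r in seq_len(nrow(offs))) {
    di <- offs$di[r]; dj <- offs$dj[r]; dk <- offs$dk[r]
    ok <- coords[, 1] + di >= 1 & coords[, 1] + di <= d[1] &
          coords[, 2] + dj >= 1 & coords[, 2] + dj <= d[2] &
          coords[, 3] + dk >= 1 & coords[, 3] + dk <= d[3]
    nb <- lin[ok] + di + d[1] * dj + d[1] * d[2] * dk
    pos <- findInterval(nb, lin_s)
    hit <- pos > 0 & lin_s[pmax(pos, 1)] == nb
    f <- which(ok)[hit]
    t <- ord[pos[hit]]
    keep <- f < t   # undirected, dedupe
    from <- c(from, f[keep]); to <- c(to, t[keep])
    len <- c(len, rep(sqrt(sum((c(di, dj, dk) * spacing)^2)), sum(keep)))
  }
  list(from = from, to = to, step_mm = len)
}

# City-block distance-to-background (in voxels) by iterated 6-neighbour
# erosion; 0 outside the mask.
erosion_depth <- function(mask) {
  dt <- array(0L, dim(mask))
  er <- mask
  depth <- 0L
  while (any(er)) {
    depth <- depth + 1L
    dt[er] <- depth
    er <- er &
      shift_array(er, 1, 1) & shift_array(er, -1, 1) &
      shift_array(er, 1, 2) & shift_array(er, -1, 2) &
      shift_array(er, 1, 3) & shift_array(er, -1, 3)
    if (depth > 100L) break
  }
  dt
}

#' Segment the airway lumen by seeded region growing
#'
#' Thresholds the CT-like volume at an air-range cutoff and keeps the
#' 26-connected component containing the tracheal seed, so the segmentation
#' cannot leak into background air that is not connected to the airway.
#'
#' @param ct a CT-like [brw_volume()].
#' @param seed_mm world coordinates (mm) of a point inside the tracheal
#'   lumen.
#' @param threshold air-range upper cutoff in HU-analog units; voxels below
#'   it are lumen candidates. The default sits midway between the lumen and
#'   wall levels of the CT-like contrast, which puts the mask boundary on
#'   the lumen/wall partial-volume midpoint.
#' @param presmooth_vox Gaussian presmoothing (voxels) before thresholding;
#'   suppresses noise-induced pinhole leaks through the wall.
#' @return A binary array (lumen mask) with attribute `seed_lin`.
#' @export
segment_lumen <- function(ct, seed_mm, threshold = -500,
                          presmooth_vox = 0.5) {
  stopifnot(is_volume(ct))
  d <- dim(ct$data)
  sv <- round(world_to_voxel(ct, seed_mm))
  if (any(sv < 1) || any(sv > d)) {
    stop("seed point lies outside the volume", call. = FALSE)
  }
  seed_lin <- sv[1] + d[1] * (sv[2] - 1) + d[1] * d[2] * (sv[3] - 1)
  if (ct$data[seed_lin] >= threshold) {
    stop(sprintf(paste0("seed point is not in the air intensity range ",
                        "(value %.1f >= threshold %.1f)"),
                 ct$data[seed_lin], threshold), call. = FALSE)
  }
  grow <- function(presmooth, thr) {
    smoothed <- if (presmooth > 0) gauss_smooth(ct$data, presmooth)
                else ct$data
    grow_component(smoothed < thr, seed_lin, d)
  }
  # escalation ladder: if the grown component floods the background (a
  # noise or resampling pinhole through the wall), retry with heavier
  # presmoothing, then with a stricter threshold
  visited <- NULL
  for (attempt in list(c(presmooth_vox, threshold),
                       c(presmooth_vox + 0.6, threshold),
                       c(presmooth_vox + 0.6, threshold - 150),
                       c(presmooth_vox + 1.0, threshold - 200))) {
    visited <- grow(attempt[1], attempt[2])
    if (sum(visited) <= 0.2 * prod(d)) break
    visited <- NULL
  }
  if (is.null(visited)) {
    stop("lumen segmentation leaked into the background at every ",
         "presmooth/threshold escalation", call. = FALSE)
  }
  attr(visited, "seed_lin") <- seed_lin
  visited
}

# frontier BFS over the 26-neighbourhood restricted to `cand`
grow_component <- function(cand, seed_lin, d) {
  # frontier BFS (26-connectivity) touching only the grown component, so
  # the cost scales with the airway, not with all sub-threshold voxels
  offs <- neighbour_offsets_26()
  visited <- array(FALSE, d)
  visited[seed_lin] <- TRUE
  frontier <- seed_lin
  while (length(frontier) > 0) {
    fc <- arrayInd(frontier, d)
    nxt <- integer(0)
    for (r in seq_len(nrow(offs))) {
      di <- offs$di[r]; dj <- offs$dj[r]; dk <- offs$dk[r]
      ok <- fc[, 1] + di >= 1 & fc[, 1] + di <= d[1] &
            fc[, 2] + dj >= 1 & fc[, 2] + dj <= d[2] &
            fc[, 3] + dk >= 1 & fc[, 3] + dk <= d[3]
      nb <- frontier[ok] + di + d[1] * dj + d[1] * d[2] * dk
      nb <- nb[cand[nb] & !visited[nb]]
      visited[nb] <- TRUE
      nxt <- c(nxt, nb)
    }
    frontier <- unique(nxt)
  }
  visited
}

#' Extract a rooted centerline tree from a lumen mask
#'
#' Medial-axis paths are traced on the voxel graph of the lumen: edges are
#' weighted by step length divided by the squared depth-to-wall of their
#' endpoints, so geodesics from the tracheal root run along the tube centre.
#' Terminal branches are discovered iteratively (farthest-uncovered-voxel
#' backtracing), the union of backtraced paths forms the tree, spurious
#' twigs shorter than `prune_mm` are removed, and each branch polyline is
#' smoothed before tangents are taken by centred finite differences.
#'
#' @param lumen_mask binary array from [segment_lumen()] (or any non-empty
#'   connected lumen mask).
#' @param spacing voxel spacing in mm.
#' @param root_mm world coordinates (mm) of the tree root (tracheal seed).
#' @param prune_mm twigs shorter than this are pruned.
#' @param max_paths safety cap on backtraced terminals.
#' @return An object of class `airway_tree`: `nodes` (tibble: node_id,
#'   branch_id, position mm, tangent, within-branch arc length, local
#'   depth-to-wall in voxels) and `branches` (tibble: branch_id,
#'   parent_branch_id, generation — `NA` until [label_generations()] —,
#'   length_mm, terminal flag).
#' @export
extract_centerline <- function(lumen_mask, spacing = c(1, 1, 1),
                               root_mm = NULL, prune_mm = 4,
                               max_paths = 64) {
  d <- dim(lumen_mask)
  spacing <- rep_len(spacing, 3)
  lin <- which(lumen_mask)
  if (length(lin) == 0) stop("empty lumen mask", call. = FALSE)
  coords <- arrayInd(lin, d)
  pos_mm <- sweep(coords - 1, 2, spacing, `*`)
  dt <- erosion_depth(lumen_mask)[lin]

  if (is.null(root_mm)) {
    sl <- attr(lumen_mask, "seed_lin")
    if (is.null(sl)) stop("root_mm must be given when the mask carries no seed",
                          call. = FALSE)
    root_idx <- match(sl, lin)
  } else {
    dr <- colSums((t(pos_mm) - as.numeric(root_mm))^2)
    root_idx <- which.min(dr)
  }

  adj <- voxel_adjacency(lin, d, spacing)
  if (length(adj$from) == 0) stop("lumen mask is a single disconnected voxel",
                                  call. = FALSE)
  med <- (dt[adj$from] + dt[adj$to]) / 2
  w <- adj$step_mm / (med^2 + 1e-6)
  g <- igraph::make_empty_graph(n = length(lin), directed = FALSE)
  g <- igraph::add_edges(g, rbind(adj$from, adj$to))
  igraph::E(g)$weight <- w
  comp <- igraph::components(g)
  if (comp$no > 1) {
    inroot <- comp$membership == comp$membership[root_idx]
    if (mean(inroot) < 0.5) {
      stop("lumen mask is disconnected from the root", call. = FALSE)
    }
    # drop stray components not connected to the root
    keep <- which(inroot)
    remap <- match(seq_along(lin), keep)
    g <- igraph::induced_subgraph(g, keep)
    lin <- lin[keep]; coords <- coords[keep, , drop = FALSE]
    pos_mm <- pos_mm[keep, , drop = FALSE]; dt <- dt[keep]
    root_idx <- remap[root_idx]
  }

  # iterative farthest-terminal backtracing against the *growing* tree:
  # each iteration runs a Dijkstra from the current tree (via a virtual
  # zero-weight source), picks the farthest uncovered voxel, and backtraces
  # to the tree attach point, so paths through shared trunks share their
  # prefix exactly and bifurcations fall at the true carinae.
  n <- length(lin)
  covered <- rep(FALSE, n)
  in_tree <- rep(FALSE, n)
  parent <- rep(NA_integer_, n)
  in_tree[root_idx] <- TRUE
  h <- mean(spacing)
  virt <- n + 1L
  n_paths <- 0L
  mark_covered <- function(path) {
    pp <- pos_mm[path, , drop = FALSE]
    rad <- (dt[path] + 1.5) * h
    unc <- which(!covered)
    if (length(unc) == 0) return(invisible())
    dmin <- rep(Inf, length(unc))
    rsel <- rep(0, length(unc))
    for (s in seq_len(nrow(pp))) {
      dd <- sqrt((pos_mm[unc, 1] - pp[s, 1])^2 +
                 (pos_mm[unc, 2] - pp[s, 2])^2 +
                 (pos_mm[unc, 3] - pp[s, 3])^2)
      better <- dd < dmin
      dmin[better] <- dd[better]
      rsel[better] <- rad[s]
    }
    covered[unc[dmin <= rsel]] <<- TRUE
    invisible()
  }
  mark_covered(root_idx)
  while (n_paths < max_paths && !all(covered)) {
    tree_set <- which(in_tree)
    gv <- igraph::add_vertices(g, 1)
    gv <- igraph::add_edges(gv, rbind(rep(virt, length(tree_set)), tree_set),
                            weight = rep(1e-9, length(tree_set)))
    sp <- igraph::shortest_paths(gv, from = virt, to = igraph::V(gv),
                                 output = "vpath", predecessors = TRUE)
    pred <- as.integer(sp$predecessors)
    dist <- as.numeric(igraph::distances(gv, v = virt))[seq_len(n)]
    cand <- which(!covered)
    t_idx <- cand[which.max(dist[cand])]
    # backtrace from the terminal to the tree attach point
    path <- integer(0)
    v <- t_idx
    while (!is.na(v) && v != virt && !in_tree[v]) {
      path <- c(path, v)
      v <- pred[v]
    }
    attach <- if (!is.na(v) && v != virt) v else NA_integer_
    path <- rev(path)  # attach-side first
    full <- c(attach[!is.na(attach)], path)
    new_len <- if (length(full) >= 2) {
      sum(sqrt(rowSums((pos_mm[full[-1], , drop = FALSE] -
                        pos_mm[full[-length(full)], , drop = FALSE])^2)))
    } else 0
    if (n_paths > 0 && new_len < prune_mm) break
    if (length(path) > 0) {
      in_tree[path] <- TRUE
      if (length(path) >= 2) parent[path[-1]] <- path[-length(path)]
      parent[path[1]] <- attach
      mark_covered(path)
    } else {
      covered[t_idx] <- TRUE   # isolated pocket; nothing to trace
    }
    n_paths <- n_paths + 1L
  }

  build_airway_tree(which_tree = which(in_tree), parent = parent,
                    pos_mm = pos_mm, dt = dt, root_idx = root_idx,
                    prune_mm = prune_mm, spacing = spacing)
}

# Assemble the node/branch tables from the backtraced union-of-paths tree,
# prune short twigs, smooth branch polylines, compute tangents.
build_airway_tree <- function(which_tree, parent, pos_mm, dt, root_idx,
                              prune_mm, spacing) {
  ids <- which_tree
  par <- match(parent[ids], ids)
  children <- split(seq_along(ids), par)
  root_loc <- match(root_idx, ids)

  # decompose into branches (chains between root/bifurcations/terminals)
  branch_of <- integer(length(ids))
  branch_nodes <- list()
  branch_parent <- integer(0)
  bid <- 0L
  # stack entries: (start node, parent branch)
  stack <- list(list(node = root_loc, pbranch = NA_integer_))
  while (length(stack) > 0) {
    s <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    bid <- bid + 1L
    chain <- s$node
    repeat {
      v <- chain[length(chain)]
      kids <- children[[as.character(v)]]
      if (is.null(kids) || length(kids) != 1) break
      chain <- c(chain, kids)
    }
    branch_nodes[[bid]] <- chain
    branch_parent[bid] <- s$pbranch
    branch_of[chain] <- bid
    v <- chain[length(chain)]
    kids <- children[[as.character(v)]]
    if (!is.null(kids) && length(kids) > 1) {
      for (k in kids) stack[[length(stack) + 1]] <- list(node = k, pbranch = bid)
    }
  }

  arc_len <- function(p) {
    if (nrow(p) < 2) return(0)
    sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
  }

  # prune terminal twigs, then merge any branch left with a single child
  # into one chain (so bifurcations stay real). Spurious skeleton spurs
  # scale with the local tube radius (they live inside fat junction zones),
  # so a twig must exceed both prune_mm and 1.2 local diameters to count
  # as a real branch.
  h_mean <- mean(spacing)
  repeat {
    lens <- vapply(branch_nodes,
                   function(ch) arc_len(pos_mm[ids[ch], , drop = FALSE]),
                   numeric(1))
    thr <- vapply(branch_nodes, function(ch) {
      max(prune_mm, 1.2 * 2 * stats::median(dt[ids[ch]]) * h_mean)
    }, numeric(1))
    is_parent <- seq_len(bid) %in% branch_parent[!is.na(branch_parent)]
    drop <- which(!is_parent & lens < thr & !is.na(branch_parent))
    if (length(drop) == 0) break
    keep <- setdiff(seq_len(bid), drop)
    branch_nodes <- branch_nodes[keep]
    branch_parent <- match(branch_parent[keep], keep)  # NA propagates
    bid <- length(branch_nodes)
    repeat {
      counts <- tabulate(branch_parent[!is.na(branch_parent)], nbins = bid)
      p <- which(counts == 1)[1]
      if (is.na(p)) break
      child <- which(!is.na(branch_parent) & branch_parent == p)
      branch_nodes[[p]] <- c(branch_nodes[[p]], branch_nodes[[child]])
      keep2 <- setdiff(seq_len(bid), child)
      bp2 <- branch_parent
      bp2[!is.na(bp2) & bp2 == child] <- p   # grandchildren reattach
      branch_nodes <- branch_nodes[keep2]
      branch_parent <- match(bp2[keep2], keep2)
      bid <- length(branch_nodes)
    }
  }

  # smooth polylines and compute tangents per branch
  nodes <- list()
  branches <- list()
  for (b in seq_len(bid)) {
    ch <- branch_nodes[[b]]
    p <- pos_mm[ids[ch], , drop = FALSE]
    ps <- smooth_polyline(p, k = 5)
    tg <- polyline_tangents(ps)
    seglen <- if (nrow(ps) > 1) {
      c(0, cumsum(sqrt(rowSums((ps[-1, , drop = FALSE] -
                                ps[-nrow(ps), , drop = FALSE])^2))))
    } else 0
    nodes[[b]] <- tibble::tibble(
      branch_id = b, node_order = seq_along(ch),
      x = ps[, 1], y = ps[, 2], z = ps[, 3],
      tx = tg[, 1], ty = tg[, 2], tz = tg[, 3],
      arc_mm = seglen, dt_vox = dt[ids[ch]]
    )
    branches[[b]] <- tibble::tibble(
      branch_id = b, parent_branch_id = branch_parent[b],
      generation = NA_integer_, label = NA_character_,
      length_mm = seglen[length(seglen)],
      n_nodes = length(ch)
    )
  }
  nodes <- dplyr::bind_rows(nodes) |>
    dplyr::mutate(node_id = dplyr::row_number(), .before = 1)
  branches <- dplyr::bind_rows(branches)
  kid_count <- table(branches$parent_branch_id)
  branches$terminal <- !(branches$branch_id %in%
                           as.integer(names(kid_count)))
  structure(list(nodes = nodes, branches = branches, spacing = spacing),
            class = "airway_tree")
}

smooth_polyline <- function(p, k = 5) {
  n <- nrow(p)
  if (n <= 2) return(p)
  half <- k %/% 2
  out <- p
  for (i in seq_len(n)) {
    j <- max(1, i - half):min(n, i + half)
    out[i, ] <- colMeans(p[j, , drop = FALSE])
  }
  out[1, ] <- p[1, ]; out[n, ] <- p[n, ]
  out
}

polyline_tangents <- function(p) {
  n <- nrow(p)
  tg <- matrix(0, n, 3)
  if (n == 1) return(matrix(c(0, 0, 1), 1, 3))
  for (i in seq_len(n)) {
    a <- max(1, i - 1); b <- min(n, i + 1)
    v <- p[b, ] - p[a, ]
    nv <- sqrt(sum(v^2))
    tg[i, ] <- if (nv > 0) v / nv else c(0, 0, 1)
  }
  tg
}

#' @export
print.airway_tree <- function(x, ...) {
  nb <- nrow(x$branches)
  nt <- sum(x$branches$terminal)
  cat(sprintf("<airway_tree> %d branches (%d terminal), %d centerline nodes\n",
              nb, nt, nrow(x$nodes)))
  if (!all(is.na(x$branches$generation))) {
    cat("  generations:",
        paste(capture_gen_counts(x), collapse = ", "), "\n")
  }
  invisible(x)
}

capture_gen_counts <- function(tree) {
  tb <- table(tree$branches$generation)
  sprintf("g%s: %d", names(tb), as.integer(tb))
}

#' Label branch generations from the root
#'
#' Trachea (the root branch) is generation 0; every bifurcation increments
#' the index. Idempotent.
#'
#' @param tree an `airway_tree`.
#' @return The tree with `branches$generation` (and per-node generation)
#'   filled in.
#' @export
label_generations <- function(tree) {
  stopifnot(inherits(tree, "airway_tree"))
  br <- tree$branches
  root <- br$branch_id[is.na(br$parent_branch_id)]
  if (length(root) != 1) {
    stop("tree is not rooted: expected exactly one parentless branch",
         call. = FALSE)
  }
  gen <- rep(NA_integer_, nrow(br))
  gen[br$branch_id == root] <- 0L
  queue <- root
  while (length(queue) > 0) {
    b <- queue[1]; queue <- queue[-1]
    kids <- br$branch_id[!is.na(br$parent_branch_id) &
                           br$parent_branch_id == b]
    gen[match(kids, br$branch_id)] <- gen[match(b, br$branch_id)] + 1L
    queue <- c(queue, kids)
  }
  tree$branches$generation <- gen
  tree$nodes$generation <- gen[match(tree$nodes$branch_id, br$branch_id)]
  tree
}

#' Select the four third-generation lobar paths
#'
#' Matches each requested lobe (by a representative point, e.g. from the
#' phantom ground truth or user-supplied for real data) to its nearest
#' generation-3 branch, and applies the automated mucus-plug exclusion: a
#' path whose proximal-third centerline CT intensity is above the plug
#' cutoff — or for which no generation-3 branch exists near the lobe point,
#' as happens when a proximal plug disconnects the distal lumen — is
#' reported and dropped.
#'
#' @param tree a generation-labelled `airway_tree`.
#' @param lobe_map data frame with columns `lobe` and the representative
#'   point (`mx`, `my`, `mz`, mm) as produced in the phantom ground truth.
#' @param ct optional CT-like [brw_volume()] for the mucus intensity check.
#' @param match_tol_mm a lobe whose nearest generation-3 branch is farther
#'   than this is treated as obstructed/missing.
#' @param plug_hu proximal-third mean centerline intensity above this is
#'   called a mucus plug.
#' @return A list: `paths` (tibble lobe/branch_id), `excluded` (tibble
#'   lobe/reason).
#' @export
select_paths <- function(tree, lobe_map, ct = NULL, match_tol_mm = 8,
                         plug_hu = -300) {
  stopifnot(inherits(tree, "airway_tree"))
  if (all(is.na(tree$branches$generation))) tree <- label_generations(tree)
  g3 <- tree$branches$branch_id[!is.na(tree$branches$generation) &
                                  tree$branches$generation == 3]
  if (length(g3) == 0) {
    stop("selection error: no generation-3 branches in the tree (missing ",
         "lobes: ", paste(lobe_map$lobe, collapse = ", "), ")",
         call. = FALSE)
  }
  # candidates beyond generation 3 are kept as a fallback: spurious
  # proximal bifurcations (noise twigs surviving the prune) inflate the
  # nominal generation of the true segmental branches
  g3plus <- tree$branches$branch_id[!is.na(tree$branches$generation) &
                                      tree$branches$generation > 3]
  sel <- list(); exc <- list()
  used <- integer(0)
  nearest <- function(cands, pt) {
    best <- NA_integer_; bestd <- Inf
    for (b in cands) {
      nd <- tree$nodes[tree$nodes$branch_id == b, ]
      dd <- min((nd$x - pt[1])^2 + (nd$y - pt[2])^2 + (nd$z - pt[3])^2)
      if (dd < bestd) { bestd <- dd; best <- b }
    }
    list(id = best, d = sqrt(bestd))
  }
  for (i in seq_len(nrow(lobe_map))) {
    pt <- c(lobe_map$mx[i], lobe_map$my[i], lobe_map$mz[i])
    hit <- nearest(setdiff(g3, used), pt)
    if (is.na(hit$id) || hit$d > match_tol_mm) {
      hit2 <- nearest(setdiff(g3plus, used), pt)
      if (!is.na(hit2$id) && hit2$d <= match_tol_mm) hit <- hit2
    }
    best <- hit$id; bestd <- hit$d^2
    if (is.na(best) || sqrt(bestd) > match_tol_mm) {
      exc[[length(exc) + 1]] <- tibble::tibble(
        lobe = lobe_map$lobe[i], branch_id = NA_integer_,
        reason = "no generation-3 path found near lobe (proximal obstruction)")
      next
    }
    if (!is.null(ct)) {
      nd <- tree$nodes[tree$nodes$branch_id == best, ]
      prox <- nd[nd$arc_mm <= max(nd$arc_mm) / 3, ]
      vi <- world_to_voxel(ct, as.matrix(prox[, c("x", "y", "z")]))
      vals <- interp_trilinear(ct$data, vi[, 1], vi[, 2], vi[, 3],
                               fill = NA_real_)
      if (mean(vals, na.rm = TRUE) > plug_hu) {
        exc[[length(exc) + 1]] <- tibble::tibble(
          lobe = lobe_map$lobe[i], branch_id = best,
          reason = sprintf("proximal mucus plugging (mean lumen %.0f HU)",
                           mean(vals, na.rm = TRUE)))
        used <- c(used, best)
        next
      }
    }
    used <- c(used, best)
    sel[[length(sel) + 1]] <- tibble::tibble(
      lobe = lobe_map$lobe[i], branch_id = best, dist_mm = sqrt(bestd))
  }
  list(paths = dplyr::bind_rows(sel), excluded = dplyr::bind_rows(exc))
}

#' Choose measurement sites along a branch
#'
#' Sites sit at fixed arc-length fractions — 1/2 for a single site, 1/3 and
#' 2/3 for two, `(1:n)/(n+1)` in general — which keeps them away from the
#' bifurcation zones at both ends of the branch.
#'
#' @param tree an `airway_tree`.
#' @param branch_id branch to measure.
#' @param n_sites number of measurement sites.
#' @return Tibble of section requests: site index, arc position, centre (mm)
#'   and unit normal (the local tangent).
#' @export
pick_measurement_sites <- function(tree, branch_id, n_sites = 2) {
  nd <- tree$nodes[tree$nodes$branch_id == branch_id, ]
  if (nrow(nd) == 0) stop("unknown branch_id", call. = FALSE)
  L <- max(nd$arc_mm)
  spacing_mm <- mean(tree$spacing)
  diam <- 2 * stats::median(nd$dt_vox) * spacing_mm
  if (L < 2 * diam) {
    stop(sprintf("branch too short for measurement (length %.1f mm < 2 local lumen diameters %.1f mm)",
                 L, 2 * diam), call. = FALSE)
  }
  fr <- seq_len(n_sites) / (n_sites + 1)
  purrr::map_dfr(seq_along(fr), function(s) {
    target <- fr[s] * L
    i <- which.min(abs(nd$arc_mm - target))
    tibble::tibble(
      branch_id = branch_id, site = s, arc_mm = target,
      cx = stats::approx(nd$arc_mm, nd$x, target, rule = 2)$y,
      cy = stats::approx(nd$arc_mm, nd$y, target, rule = 2)$y,
      cz = stats::approx(nd$arc_mm, nd$z, target, rule = 2)$y,
      nx = nd$tx[i], ny = nd$ty[i], nz = nd$tz[i]
    )
  })
}

#' Reformat an oblique cross-section perpendicular to the bronchial axis
#'
#' Samples a 2D plane through `center_mm` with unit normal `normal` by
#' trilinear interpolation at sub-voxel spacing. In-plane axes are
#' orthonormal and orthogonal to the normal. Samples falling outside the
#' volume are padded with `NA` and the section is flagged.
#'
#' @param volume a [brw_volume()].
#' @param center_mm plane centre, world mm.
#' @param normal unit plane normal (the local bronchial tangent).
#' @param half_size_mm in-plane half-extent, mm.
#' @param spacing_mm in-plane sample spacing; default half the voxel size.
#' @return An object of class `cross_section`: `image` (matrix), `spacing`,
#'   `center`, `normal`, in-plane axes `e1`, `e2`, `flagged`.
#' @export
reformat_cross_section <- function(volume, center_mm, normal,
                                   half_size_mm = 8, spacing_mm = NULL) {
  stopifnot(is_volume(volume))
  normal <- as.numeric(normal)
  if (abs(sqrt(sum(normal^2)) - 1) > 1e-6) {
    stop("plane normal must be unit length", call. = FALSE)
  }
  d <- dim(volume$data)
  cv <- world_to_voxel(volume, center_mm)
  if (any(cv < 1) || any(cv > d)) {
    stop("section centre lies outside the volume", call. = FALSE)
  }
  if (is.null(spacing_mm)) spacing_mm <- min(volume$spacing) / 2
  ref <- diag(3)[, which.min(abs(normal))]
  e1 <- c(normal[2] * ref[3] - normal[3] * ref[2],
          normal[3] * ref[1] - normal[1] * ref[3],
          normal[1] * ref[2] - normal[2] * ref[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(normal[2] * e1[3] - normal[3] * e1[2],
          normal[3] * e1[1] - normal[1] * e1[3],
          normal[1] * e1[2] - normal[2] * e1[1])
  ax <- seq(-half_size_mm, half_size_mm, by = spacing_mm)
  n1 <- length(ax)
  u <- rep(ax, times = n1); v <- rep(ax, each = n1)
  px <- center_mm[1] + u * e1[1] + v * e2[1]
  py <- center_mm[2] + u * e1[2] + v * e2[2]
  pz <- center_mm[3] + u * e1[3] + v * e2[3]
  vi <- world_to_voxel(volume, cbind(px, py, pz))
  vals <- interp_trilinear(volume$data, vi[, 1], vi[, 2], vi[, 3],
                           fill = NA_real_)
  img <- matrix(vals, n1, n1)
  structure(list(
    image = img, spacing = spacing_mm, center = as.numeric(center_mm),
    normal = normal, e1 = e1, e2 = e2, axis_mm = ax,
    flagged = anyNA(img)
  ), class = "cross_section")
}
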