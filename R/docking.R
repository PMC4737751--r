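#' Deterministic rotation sampling
#'
#' Low-discrepancy unit quaternions from the super-Fibonacci spiral,
#' giving a deterministic, roughly uniform cover of rotation space.
#'
#' @param n number of orientations; default 576 (~15 degree spacing).
#' @return n x 4 matrix of unit quaternions (w, x, y, z).
#' @export
rotation_set <- function(n = 576) {
  i <- seq_len(n) - 0.5
  s <- i / n
  r <- sqrt(s)
  bigr <- sqrt(1 - s)
  phi <- sqrt(2)
  psi <- 1.533751168755204288118041
  alpha <- 2 * pi * i / phi
  beta <- 2 * pi * i / psi
  cbind(r * sin(alpha), r * cos(alpha), bigr * sin(beta), bigr * cos(beta))
}

#' Angular spacing of a rotation set
#'
#' The largest nearest-neighbour geodesic angle over the set, i.e. the
#' worst-case distance from a sampled rotation to its closest neighbour.
#'
#' @param quats n x 4 matrix of unit quaternions.
#' @return Spacing in degrees.
#' @export
rotation_set_spacing <- function(quats) {
  dots <- abs(tcrossprod(quats))
  diag(dots) <- 0
  nearest <- apply(dots, 1, max)
  max(2 * acos(pmin(1, nearest))) * 180 / pi
}

# geodesic angle between two rotations given as quaternions, degrees
quat_angle <- function(qa, qb) {
  2 * acos(min(1, abs(sum(qa * qb)))) * 180 / pi
}

#' FFT translation scan
#'
#' Masked cross-correlation of a rendered component against a target map
#' for every cyclic integer-voxel shift, computed with FFTs. The contract
#' is the exhaustive scan: `scan[s]` equals the masked correlation of the
#' component array cyclically shifted by `s - 1` voxels per axis.
#'
#' @param comp_vals rendered component density (array, map-shaped).
#' @param f_mt FFT of (mask * target density).
#' @param f_m FFT of the mask indicator.
#' @param den_t sqrt of the masked target power.
#' @return Array of correlation scores, one per shift; `-Inf` where the
#'   shifted component has (numerically) no density inside the mask.
#' @keywords internal
translation_scan <- function(comp_vals, f_mt, f_m, den_t) {
  npts <- length(comp_vals)
  f_c <- fft(comp_vals)
  f_c2 <- fft(comp_vals^2)
  num <- Re(fft(f_mt * Conj(f_c), inverse = TRUE)) / npts
  den_c2 <- Re(fft(f_m * Conj(f_c2), inverse = TRUE)) / npts
  den_c2[den_c2 < 0] <- 0
  score <- num / (sqrt(den_c2) * den_t)
  score[den_c2 < 1e-12] <- -Inf
  score
}

#' Rigid-body docking into a density map
#'
#' Exhaustive search over a deterministic rotation set and, for each
#' rotation, all integer-voxel translations on the map grid (via an FFT
#' correlation scan; the brute-force cyclic scan is the contract and
#' serves as the test oracle). The score is the cross-correlation with
#' the target restricted to its envelope mask at `threshold`. An optional
#' `region_mask` restricts the candidate centroid positions (emulating
#' independent localization evidence); the scoring mask is unchanged, so
#' restricting the region can only remove candidates and never improves
#' the rank-1 score. Returned placements are non-redundant: any two
#' differ in rotation or by at least `min_separation` voxels of
#' translation, ties broken lexicographically on the grid offset.
#'
#' @param component a [bead_component].
#' @param map target [density_map].
#' @param n_rotations number of sampled orientations.
#' @param resolution rendering resolution in Å; default 20.
#' @param threshold,threshold_mode envelope contour defining the scoring
#'   mask; defaults 0.7, `"max_fraction"`.
#' @param region_mask optional logical array (map-shaped) of allowed
#'   centroid voxels.
#' @param mask optional precomputed scoring `volume_mask` (e.g. the
#'   envelope of the original map when docking into a residual map).
#' @param top number of placements to return.
#' @param min_separation translation non-redundancy spacing in voxels.
#' @return List of placements, each with `transform`
#'   ([rigid_transform] mapping the component's input coordinates to the
#'   placed pose), `score`, `rank`, `rotation_index`, `quaternion`,
#'   `centroid`.
#' @export
dock_rigid <- function(component, map, n_rotations = 576, resolution = 20,
                       threshold = 0.7, threshold_mode = "max_fraction",
                       region_mask = NULL, mask = NULL, top = 20,
                       min_separation = 2) {
  if (n_rotations < 1)
    stop_denfit("n_rotations must be >= 1", "denfit_argument_error")
  xyz <- bead_coords(component)
  if (nrow(xyz) == 0)
    stop_denfit("empty component", "denfit_argument_error")
  dims <- dim(map$data)
  extent <- apply(xyz, 2, function(v) diff(range(v)))
  if (any(extent > dims * map$voxel))
    stop_denfit("component larger than the map extent",
                "denfit_geometry_error")
  if (is.null(mask)) mask <- threshold_mask(map, threshold, threshold_mode)
  mk <- as.numeric(mask$mask)
  tvals <- as.numeric(map$data) * mk
  den_t <- sqrt(sum(tvals^2))
  if (den_t == 0)
    stop_denfit("empty envelope mask", "denfit_degenerate_map_error")
  f_mt <- fft(array(tvals, dims))
  f_m <- fft(array(mk, dims))
  npts <- prod(dims)
  icenter <- floor(dims / 2)  # 0-based centre voxel
  ccoord <- map$origin + icenter * map$voxel
  ctr <- colMeans(xyz)
  quats <- rotation_set(n_rotations)
  # allowed centroid voxels per cyclic shift s: centroid voxel = icenter + s
  allowed <- NULL
  if (!is.null(region_mask)) {
    if (!identical(dim(region_mask), dims))
      stop_denfit("region_mask shape does not match map",
                  "denfit_argument_error")
    allowed <- array(FALSE, dims)
    idx <- which(region_mask, arr.ind = TRUE)
    if (nrow(idx) == 0)
      stop_denfit("region_mask is empty", "denfit_argument_error")
    # shift index (1-based array position) for centroid voxel v: s = v-1-icenter mod dims
    sidx <- sweep(idx - 1, 2, icenter)
    sidx <- sweep(sidx, 2, dims, "%%") + 1
    allowed[sidx] <- TRUE
  }
  cand <- vector("list", n_rotations)
  for (k in seq_len(n_rotations)) {
    R <- quat_to_matrix(quats[k, ])
    placed <- sweep(sweep(xyz, 2, ctr) %*% t(R), 2, -ccoord)
    cmap <- simulate_map(placed, resolution, grid = map)
    score <- translation_scan(cmap$data, f_mt, f_m, den_t)
    if (!is.null(allowed)) score[!allowed] <- -Inf
    best <- which.max(score)  # first (lexicographic) maximum
    s <- arrayInd(best, dims) - 1L
    cand[[k]] <- list(k = k, score = score[best], shift = as.integer(s))
  }
  scores <- vapply(cand, function(c) c$score, 0)
  ord <- order(-scores, seq_along(scores))
  kept <- list()
  for (o in ord) {
    c <- cand[[o]]
    if (!is.finite(c$score)) next
    dup <- FALSE
    for (p in kept) {
      if (p$k != c$k) next  # different rotation: non-redundant by set spacing
      if (sqrt(sum((p$shift - c$shift)^2)) < min_separation) {
        dup <- TRUE
        break
      }
    }
    if (!dup) kept[[length(kept) + 1]] <- c
    if (length(kept) >= top) break
  }
  lapply(seq_along(kept), function(r) {
    c <- kept[[r]]
    # wrap shifts to the nearest representative
    s <- c$shift
    s <- ifelse(s > dims / 2, s - dims, s)
    centroid <- ccoord + s * map$voxel
    R <- quat_to_matrix(quats[c$k, ])
    list(transform = rigid_transform(R, centroid - as.numeric(R %*% ctr)),
         score = c$score, rank = r, rotation_index = c$k,
         quaternion = quats[c$k, ], centroid = centroid)
  })
}

#' Seed an assembly from docking results
#'
#' For each component with docking results, picks a placement inside its
#' hint region (or among all returned placements when no hint is given);
#' components without docking results are randomized inside the
#' envelope. Because rigid docking at low resolution leaves near-tied
#' alternatives (flips of pseudo-symmetric shapes, neighbouring
#' positions), the default `select = "restraints"` mode evaluates every
#' combination of the top placements against the assembly's restraint
#' list and clash count and picks the most consistent combination —
#' mirroring how independent interaction evidence is used to choose
#' among docking solutions. `select = "rank"` simply takes each
#' component's rank-1 placement.
#'
#' @param base_assembly template [assembly] with an attached map (and,
#'   for restraint-guided selection, its restraint list).
#' @param dock_results named list (by component id) of placement lists
#'   from [dock_rigid()].
#' @param hints named list of logical arrays (map-shaped) of allowed
#'   centroid voxels; emulates localization evidence.
#' @param select `"restraints"` or `"rank"`.
#' @param max_combos cap on enumerated combinations.
#' @param seed RNG seed for the randomized components.
#' @return List with `assembly` (seeded) and `transforms` (the chosen
#'   placements).
#' @export
seed_assembly <- function(base_assembly, dock_results, hints = list(),
                          select = c("restraints", "rank"),
                          max_combos = 20000, seed = 1) {
  select <- match.arg(select)
  map <- base_assembly$map
  if (is.null(map))
    stop_denfit("assembly has no attached map", "denfit_state_error")
  cands <- list()
  for (id in names(dock_results)) {
    pls <- dock_results[[id]]
    hint <- hints[[id]]
    if (!is.null(hint)) {
      ok <- vapply(pls, function(p) {
        v <- round((p$centroid - map$origin) / map$voxel) + 1
        all(v >= 1 & v <= dim(map$data)) && hint[v[1], v[2], v[3]]
      }, TRUE)
      pls <- pls[ok]
      if (length(pls) == 0)
        stop_denfit(paste0("no docking placement inside the hint region for ",
                           id), "denfit_seeding_error")
    }
    cands[[id]] <- pls
  }
  ids <- names(cands)
  if (select == "rank" || length(base_assembly$restraints) == 0 ||
      length(ids) == 0) {
    chosen <- lapply(cands, function(pls) pls[[1]]$transform)
  } else {
    chosen <- select_combination(base_assembly, cands, max_combos)
  }
  set.seed(seed)
  out <- initial_positions(base_assembly, "from_docking",
                           transforms = chosen)
  list(assembly = out, transforms = chosen)
}

# choose one placement per component minimizing restraint penalty, with
# clash count as a tie-breaker among the most consistent combinations
select_combination <- function(base_assembly, cands, max_combos) {
  ids <- names(cands)
  # trim candidate lists so the enumeration stays bounded
  k <- vapply(cands, length, 0L)
  while (prod(k) > max_combos && any(k > 1)) {
    k[which.max(k)] <- k[which.max(k)] - 1L
  }
  cands <- Map(function(p, kk) p[seq_len(kk)], cands, k)
  # transformed coordinates per candidate placement
  coords_by <- lapply(ids, function(id)
    lapply(cands[[id]], function(p)
      apply_transform(bead_coords(base_assembly$components[[id]]),
                      p$transform)))
  names(coords_by) <- ids
  all_ids <- names(base_assembly$components)
  base_coords <- lapply(base_assembly$components, bead_coords)
  cres <- compile_restraints(base_assembly)
  radii <- lapply(base_assembly$components,
                  function(c) c$beads$radius)
  combos <- as.matrix(expand.grid(lapply(k, seq_len)))
  pen <- numeric(nrow(combos))
  coords <- base_coords
  for (r in seq_len(nrow(combos))) {
    for (j in seq_along(ids))
      coords[[ids[j]]] <- coords_by[[j]][[combos[r, j]]]
    pen[r] <- sum(vapply(cres, eval_restraint_fast, 0, coords = coords))
  }
  # clash tie-break on the most restraint-consistent combinations
  shortlist <- order(pen)[seq_len(min(20, length(pen)))]
  best <- NULL; best_val <- Inf
  w <- base_assembly$weights
  for (r in shortlist) {
    for (j in seq_along(ids))
      coords[[ids[j]]] <- coords_by[[j]][[combos[r, j]]]
    cl <- 0
    nc <- length(all_ids)
    for (a in seq_len(nc - 1)) for (b in (a + 1):nc)
      cl <- cl + cpp_clash_between(coords[[a]], radii[[a]],
                                   coords[[b]], radii[[b]],
                                   base_assembly$overlap_factor)
    val <- w$w_rest * pen[r] + w$w_clash * cl
    if (val < best_val) {
      best_val <- val
      best <- combos[r, ]
    }
  }
  chosen <- lapply(seq_along(ids), function(j)
    cands[[ids[j]]][[best[j]]]$transform)
  names(chosen) <- ids
  chosen
}
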