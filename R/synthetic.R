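#' Generate a synthetic coarse-grained component
#'
#' Builds a self-avoiding bead arrangement (one bead per residue) on a
#' jittered cubic lattice. The core is a sphere (`globular`) or an
#' elongated ellipsoid (`elongated`); a fraction of the beads is moved
#' into off-axis surface lobes so the shape is irregular, the way real
#' protein domains are — a centrosymmetric blob would carry no
#' orientation information at low resolution. The lattice spacing minus
#' the jitter guarantees a minimum inter-bead distance above the 3.8 Å
#' virtual-bond length; arrangements are deterministic per seed.
#'
#' @param n_residues number of beads (>= 2).
#' @param shape `"globular"` or `"elongated"`.
#' @param seed RNG seed for the lobe directions and jitter.
#' @param id component id.
#' @param radius bead radius (Å).
#' @param spacing lattice constant (Å); default 4.5.
#' @param jitter per-axis uniform jitter amplitude (Å); default 0.3.
#' @param aspect long-to-short axis ratio for `elongated`; default 6.
#' @param lobe_frac fraction of beads placed in surface lobes; default
#'   0.35 (two lobes). Set 0 for a plain convex shape.
#' @param start_resid residue number of the first bead.
#' @return A [bead_component], centred at the origin.
#' @export
make_component <- function(n_residues, shape = c("globular", "elongated"),
                           seed = 1, id = "comp", radius = 3.5,
                           spacing = 4.5, jitter = 0.3, aspect = 6,
                           lobe_frac = 0.35, start_resid = 1L) {
  shape <- match.arg(shape)
  if (n_residues < 2)
    stop_denfit("n_residues must be >= 2", "denfit_argument_error")
  set.seed(seed)
  ax <- if (shape == "elongated") aspect else 1
  n_lobe <- if (n_residues >= 12) round(n_residues * lobe_frac / 2) else 0L
  n_core <- n_residues - 2 * n_lobe
  # candidate lattice large enough for core plus protruding lobes
  rc <- spacing * (3 * n_core / (4 * pi * ax))^(1 / 3) * 1.3 + spacing
  mx <- ceiling((rc * ax + 3 * spacing) / spacing) + 2
  myz <- ceiling((rc + 3 * spacing) / spacing) + 2
  sites <- as.matrix(expand.grid(x = -mx:mx, y = -myz:myz, z = -myz:myz))
  metric <- sqrt((sites[, 1] / ax)^2 + sites[, 2]^2 + sites[, 3]^2) *
    spacing
  ord <- order(metric, sites[, 1], sites[, 2], sites[, 3])
  take <- ord[seq_len(n_core)]
  core_r <- metric[take[n_core]]
  chosen <- take
  if (n_lobe > 0) {
    for (l in 1:2) {
      # lobe centre on the core surface, off the long axis
      u <- rnorm(3)
      u[1] <- u[1] / ax  # bias away from the poles of elongated shapes
      u <- u / sqrt(sum(u^2))
      ctr <- u * core_r * c(ax, 1, 1)  # on the core surface, in angstrom
      d2 <- colSums((t(sites) * spacing - ctr)^2)
      d2[chosen] <- Inf
      add <- order(d2)[seq_len(n_lobe)]
      chosen <- c(chosen, add)
    }
  }
  pts <- sites[chosen, , drop = FALSE] * spacing
  pts <- pts + matrix(runif(3 * n_residues, -jitter, jitter),
                      n_residues, 3)
  pts <- sweep(pts, 2, colMeans(pts))
  # residue order follows the long axis so residue windows are spatially
  # coherent (restraint selectors pick out one face, not scattered beads)
  ordr <- order(pts[, 1], pts[, 2], pts[, 3])
  pts <- pts[ordr, , drop = FALSE]
  coarse_grain(pts, component_id = id, radius = radius,
               resid = seq(start_resid, length.out = n_residues))
}

rot_z90 <- function() rotation_about_axis(c(0, 0, 1), 90)

# shift a centred component so its bounding box starts at `from` on `axis`
place_after <- function(comp, axis, from, centre_other = c(0, 0)) {
  xyz <- bead_coords(comp)
  lo <- min(xyz[, axis])
  shift <- numeric(3)
  shift[axis] <- from - lo
  others <- setdiff(1:3, axis)
  shift[others] <- centre_other - colMeans(xyz[, others, drop = FALSE])
  set_bead_coords(comp, sweep(xyz, 2, -shift))
}

axis_extent <- function(comp, axis) {
  v <- bead_coords(comp)[, axis]
  diff(range(v))
}

# slide `comp` along `axis` until its minimum bead-centre distance to the
# already-placed beads equals d_pack (interfaces touch without clashing)
pack_slide <- function(fixed_xyz, comp, axis, d_pack) {
  xyz <- bead_coords(comp)
  mind <- function(delta) {
    shifted <- xyz
    shifted[, axis] <- shifted[, axis] + delta
    min(cdist(shifted, fixed_xyz)) - d_pack
  }
  # scan inward from the current position for the sign change closest to
  # the outside, then refine (mind is increasing near that crossing)
  hi <- 60
  lo <- hi
  while (lo > -80 && mind(lo) > 0) lo <- lo - 2
  if (mind(lo) > 0) return(comp)  # never reaches the fixed beads; keep
  delta <- stats::uniroot(mind, c(lo, lo + 2), tol = 1e-6)$root
  xyz[, axis] <- xyz[, axis] + delta
  set_bead_coords(comp, xyz)
}

#' Generate a ground-truth benchmark assembly
#'
#' Places clash-free components along the two arms of an L-shaped
#' envelope (optionally with lateral attachments and a split scaffold
#' whose halves are joined by a flexible linker), renders the map from
#' the truth beads at the given resolution, and adds optional Gaussian
#' voxel noise.
#'
#' The working contour is `threshold` in *absolute* mode. By default the
#' rendered density is rescaled so the weakest bead-position value sits
#' above the contour (with a margin of three noise standard deviations)
#' and clipped at 1 — emulating how an experimental display contour is
#' chosen to enclose the whole complex — so that every truth bead lies
#' inside the envelope mask. `envelope = "plain"` keeps the raw
#' normalized rendering.
#'
#' @param layout list of per-component entries: `id`, `n` (residues),
#'   `shape`, optional `aspect`, and one of `arm = 1`, `arm = 2`,
#'   `lateral = "<partner id>"`; at most one entry may set
#'   `split = list(n2 = , linker = )` making it a two-segment scaffold
#'   whose first half anchors arm 1 and second half arm 2. Optional
#'   `tail = k` appends a k-residue flexible tail.
#' @param resolution map resolution in Å; default 20.
#' @param voxel voxel size in Å; default 4.
#' @param noise Gaussian voxel noise s.d. as a fraction of the map
#'   maximum; default 0.05.
#' @param seed master RNG seed.
#' @param arm_targets optional `c(L1, L2)` target arm lengths in Å
#'   (bounding-box extent of each arm's beads).
#' @param envelope `"saturated"` (default) or `"plain"`.
#' @param threshold working contour; default 0.7.
#' @param gap minimum bounding-box gap between consecutive components
#'   (Å); default 6, which guarantees no inter-component clash at the
#'   default 0.8 overlap factor while leaving bead pairs within contact
#'   range.
#' @param padding map padding (Å).
#' @return An object of class `benchmark_truth`: `assembly` (truth
#'   coordinates with map and derived restraints attached), `map`,
#'   `arms` (component-to-arm map), `params`, `seed`.
#' @export
make_truth_assembly <- function(layout, resolution = 20, voxel = 4,
                                noise = 0.05, seed = 1,
                                arm_targets = NULL,
                                envelope = c("saturated", "plain"),
                                threshold = 0.7, gap = 6, padding = 18) {
  envelope <- match.arg(envelope)
  if (length(layout) < 2)
    stop_denfit("at least 2 components are required", "denfit_argument_error")
  seeds <- derive_seeds(seed, length(layout) + 2)
  comps <- list()
  arms <- list()
  split_info <- NULL
  for (i in seq_along(layout)) {
    e <- layout[[i]]
    if (!is.null(e$split)) {
      n1 <- e$n
      n2 <- e$split$n2
      nl <- e$split$linker
      segA <- make_component(n1, e$shape %||% "elongated", seed = seeds[i],
                             id = e$id, aspect = e$aspect %||% 3,
                             start_resid = 1L)
      segB <- make_component(n2, e$shape %||% "elongated",
                             seed = seeds[i] + 7L, id = e$id,
                             aspect = e$aspect %||% 3,
                             start_resid = n1 + nl + 1L)
      split_info <- list(id = e$id, segA = segA, segB = segB, nl = nl,
                         n1 = n1)
      arms[[e$id]] <- NA
      next
    }
    comps[[e$id]] <- make_component(e$n, e$shape %||% "globular",
                                    seed = seeds[i], id = e$id,
                                    aspect = e$aspect %||% 6)
    arms[[e$id]] <- if (!is.null(e$lateral)) e$lateral else e$arm
  }
  arm1_ids <- names(arms)[vapply(arms, function(a)
    identical(a, 1) || identical(a, 1L), TRUE)]
  arm2_ids <- names(arms)[vapply(arms, function(a)
    identical(a, 2) || identical(a, 2L), TRUE)]
  lateral_ids <- names(arms)[vapply(arms, is.character, TRUE)]

  placed <- list()
  # arm 1 along +x (split scaffold's first half leads the arm)
  arm1_comps <- list()
  if (!is.null(split_info)) arm1_comps[[split_info$id]] <- split_info$segA
  for (id in arm1_ids) arm1_comps[[id]] <- comps[[id]]
  ext1 <- vapply(arm1_comps, axis_extent, 0, axis = 1)
  g1 <- gap
  if (!is.null(arm_targets) && length(ext1) > 1)
    g1 <- max(gap, (arm_targets[1] - sum(ext1)) / (length(ext1) - 1))
  d_pack <- 8  # min inter-component bead-centre distance at interfaces
  cursor <- 0
  for (id in names(arm1_comps)) {
    placed[[id]] <- place_after(arm1_comps[[id]], 1, cursor)
    if (is.null(arm_targets) && length(placed) > 1) {
      fixed <- do.call(rbind, lapply(placed[names(placed) != id],
                                     bead_coords))
      placed[[id]] <- pack_slide(fixed, placed[[id]], 1, d_pack)
    }
    cursor <- max(bead_coords(placed[[id]])[, 1]) + g1
  }
  # arm 2 along +y, rotated so elongated shapes lie along the arm
  arm2_comps <- list()
  if (!is.null(split_info))
    arm2_comps[[paste0(split_info$id, "__B")]] <-
      apply_transform(split_info$segB, rigid_transform(rot_z90()))
  for (id in arm2_ids)
    arm2_comps[[id]] <- apply_transform(comps[[id]],
                                        rigid_transform(rot_z90()))
  ext2 <- vapply(arm2_comps, axis_extent, 0, axis = 2)
  g2 <- gap
  if (!is.null(arm_targets) && length(ext2) > 1)
    g2 <- max(gap, (arm_targets[2] - sum(ext2)) / (length(ext2) - 1))
  corner_id <- names(placed)[1]
  cursor <- max(bead_coords(placed[[corner_id]])[, 2]) + g2
  corner_x <- mean(bead_coords(placed[[corner_id]])[, 1])
  for (id in names(arm2_comps)) {
    placed[[id]] <- place_after(arm2_comps[[id]], 2, cursor,
                                centre_other = c(corner_x, 0))
    if (is.null(arm_targets)) {
      fixed <- do.call(rbind, lapply(placed[names(placed) != id],
                                     bead_coords))
      placed[[id]] <- pack_slide(fixed, placed[[id]], 2, d_pack)
    }
    cursor <- max(bead_coords(placed[[id]])[, 2]) + g2
  }
  # lateral attachments sit beside their partner along +z
  for (id in lateral_ids) {
    partner <- arms[[id]]
    pxyz <- bead_coords(placed[[partner]])
    ctr <- colMeans(pxyz)
    zoff <- max(pxyz[, 3]) - ctr[3] + axis_extent(comps[[id]], 3) / 2 + gap
    placed[[id]] <- set_bead_coords(comps[[id]],
      sweep(bead_coords(comps[[id]]), 2, -(ctr + c(0, 0, zoff))))
    fixed <- do.call(rbind, lapply(placed[names(placed) != id],
                                   bead_coords))
    placed[[id]] <- pack_slide(fixed, placed[[id]], 3, d_pack)
  }
  # rejoin split scaffold halves with a flexible linker
  if (!is.null(split_info)) {
    id <- split_info$id
    idB <- paste0(id, "__B")
    xa <- bead_coords(placed[[id]])
    xb <- bead_coords(placed[[idB]])
    d <- cdist(xa, xb)
    hit <- arrayInd(which.min(d), dim(d))
    a_anchor <- xa[hit[1], ]
    b_anchor <- xb[hit[2], ]
    nl <- max(split_info$nl, ceiling(sqrt(sum((b_anchor - a_anchor)^2)) /
                                       3.8) + 2)
    nl_final <- nl
    link <- build_linker(c(split_info$n1 + 1L, split_info$n1 + nl),
                         a_anchor, b_anchor)
    # merge: segA + linker + segB as one component with renumbered segB
    bb <- placed[[idB]]$beads
    bb$resid <- bb$resid - split_info$nl + nl  # keep declared ranges stable
    beads <- rbind(placed[[id]]$beads[, 1:6], link$beads[, 1:6], bb[, 1:6])
    placed[[id]] <- bead_component(id, beads)
    placed[[idB]] <- NULL
  }
  # tails
  for (i in seq_along(layout)) {
    e <- layout[[i]]
    if (is.null(e$tail) || is.null(placed[[e$id]])) next
    comp <- placed[[e$id]]
    xyz <- bead_coords(comp)
    last <- xyz[which.max(comp$beads$resid), ]
    ctr <- colMeans(xyz)
    u <- last - ctr
    u <- u / max(sqrt(sum(u^2)), 1e-9)
    tail <- build_linker(c(max(comp$beads$resid) + 1L,
                           max(comp$beads$resid) + e$tail),
                         last + u * 3.8, direction = u)
    placed[[e$id]] <- bead_component(e$id, rbind(comp$beads[, 1:6],
                                                 tail$beads[, 1:6]))
  }
  placed <- placed[!vapply(placed, is.null, TRUE)]

  # map from the truth beads
  all_xyz <- do.call(rbind, lapply(placed, bead_coords))
  raw <- simulate_map(all_xyz, resolution, voxel, padding = padding)
  if (envelope == "saturated") {
    at_beads <- raw$data[cbind(
      round((all_xyz[, 1] - raw$origin[1]) / voxel) + 1,
      round((all_xyz[, 2] - raw$origin[2]) / voxel) + 1,
      round((all_xyz[, 3] - raw$origin[3]) / voxel) + 1)]
    # gamma-stretch the normalized density so the weakest bead-position
    # value sits just above the working contour; monotone, so density
    # gradients and ranks are preserved and the contour stays snug
    sat <- min(threshold + 0.02, 0.95)
    gam <- min(1, log(sat) / log(min(at_beads)))
    raw$data <- pmax(raw$data, 0)^gam
  }
  if (noise > 0) {
    set.seed(seeds[length(seeds) - 1])
    raw$data <- raw$data + array(rnorm(length(raw$data), 0, noise),
                                 dim(raw$data))
  }
  truth_assembly <- assembly(placed, map = raw, restraints = list(),
                             threshold = threshold,
                             threshold_mode = "absolute")
  if (clash_count(truth_assembly) > 0)
    stop_denfit("could not pack components without clashes",
                "denfit_generation_error")
  # bead selections spanning each arm (the split scaffold contributes its
  # first half to arm 1 and its second half to arm 2)
  arm1_sel <- lapply(arm1_ids, function(id) list(component = id,
                                                 range = NULL))
  arm2_sel <- lapply(arm2_ids, function(id) list(component = id,
                                                 range = NULL))
  if (!is.null(split_info)) {
    arm1_sel <- c(list(list(component = split_info$id,
                            range = c(1, split_info$n1))), arm1_sel)
    segB_range <- range(placed[[split_info$id]]$beads$resid[
      placed[[split_info$id]]$beads$resid > split_info$n1 + nl_final])
    arm2_sel <- c(list(list(component = split_info$id,
                            range = segB_range)), arm2_sel)
  }
  structure(
    list(assembly = truth_assembly, map = raw,
         arms = list(arm1 = c(if (!is.null(split_info)) split_info$id,
                              arm1_ids),
                     arm2 = arm2_ids, lateral = lateral_ids,
                     arm1_sel = arm1_sel, arm2_sel = arm2_sel),
         params = list(resolution = resolution, voxel = voxel,
                       noise = noise, threshold = threshold,
                       envelope = envelope, arm_targets = arm_targets),
         seed = seed),
    class = "benchmark_truth"
  )
}

#' Derive truth-consistent restraints
#'
#' Samples true inter-component contacts from the ground-truth
#' configuration and emits contact restraints around them (plus one
#' proximity restraint per touching pair when satisfied at the default
#' cutoff, and connectivity restraints for any multi-segment component).
#' Every emitted restraint has zero penalty on the truth. When fewer true
#' contacts exist than requested, all available ones are returned with a
#' warning.
#'
#' @param truth a `benchmark_truth`.
#' @param contact_cutoff surface-to-surface contact cutoff (Å); default 5.
#' @param n_restraints total number of contact restraints to sample;
#'   default 9 (three per interface of a four-body assembly, the density
#'   of a modest crosslinking data set).
#' @param window residue half-width of the selector around each contact;
#'   default 3, so selectors are small surface patches that pin the
#'   orientation of the components they join, not broad slabs.
#' @return List of [restraint]s.
#' @export
derive_restraints <- function(truth, contact_cutoff = 5, n_restraints = 9,
                              window = 3) {
  comps <- truth$assembly$components
  ids <- names(comps)
  out <- list()
  candidates <- list()
  for (i in seq_along(ids)) for (j in seq_along(ids)) if (i < j) {
    ca <- comps[[i]]; cb <- comps[[j]]
    xa <- bead_coords(ca); xb <- bead_coords(cb)
    d <- cdist(xa, xb) - outer(ca$beads$radius, cb$beads$radius, "+")
    hits <- which(d <= contact_cutoff, arr.ind = TRUE)
    if (nrow(hits) == 0) next
    # spread sampled contacts across the interface: order by surface dist
    hits <- hits[order(d[hits]), , drop = FALSE]
    used_a <- integer(0)
    for (h in seq_len(nrow(hits))) {
      ra <- ca$beads$resid[hits[h, 1]]
      if (any(abs(used_a - ra) < window)) next
      used_a <- c(used_a, ra)
      rb <- cb$beads$resid[hits[h, 2]]
      candidates[[length(candidates) + 1]] <- list(
        i = i, j = j,
        range_a = c(max(min(ca$beads$resid), ra - window),
                    min(max(ca$beads$resid), ra + window)),
        range_b = c(max(min(cb$beads$resid), rb - window),
                    min(max(cb$beads$resid), rb + window)))
      if (length(used_a) >= 3) break
    }
    # one proximity restraint per touching pair, when satisfied
    sel_a <- candidates[[length(candidates)]]$range_a
    sel_b <- candidates[[length(candidates)]]$range_b
    ia <- resolve_selector(ca, sel_a); ib <- resolve_selector(cb, sel_b)
    dc <- sqrt(sum((colMeans(xa[ia, , drop = FALSE]) -
                      colMeans(xb[ib, , drop = FALSE]))^2))
    if (dc <= 15)
      out[[length(out) + 1]] <- restraint("proximity", ids[i], ids[j],
                                          sel_a, sel_b, cutoff = 15)
  }
  if (length(candidates) < n_restraints)
    warning(sprintf("only %d true contacts available (requested %d)",
                    length(candidates), n_restraints), call. = FALSE)
  # round-robin over pairs for coverage
  pair_key <- vapply(candidates, function(c) paste(c$i, c$j), "")
  picked <- integer(0)
  while (length(picked) < min(n_restraints, length(candidates))) {
    for (pk in unique(pair_key)) {
      avail <- setdiff(which(pair_key == pk), picked)
      if (length(avail) > 0 && length(picked) < n_restraints)
        picked <- c(picked, avail[1])
    }
  }
  for (k in picked) {
    c <- candidates[[k]]
    out[[length(out) + 1]] <- restraint("contact", ids[c$i], ids[c$j],
                                        c$range_a, c$range_b,
                                        cutoff = contact_cutoff)
  }
  # connectivity for multi-segment components
  for (id in ids) {
    if (sum(comps[[id]]$units$kind == "rigid") >= 2)
      out[[length(out) + 1]] <- restraint("connectivity", id)
  }
  out
}

#' Derive an exposure specification from the truth
#'
#' For each component, picks the residue window that is most
#' solvent-exposed in the ground truth (fewest foreign beads within the
#' neighbour cutoff) — emulating known partner-binding surfaces that an
#' acceptable model must keep accessible.
#'
#' @param truth a `benchmark_truth`.
#' @param window selection width in residues; default 11.
#' @param neighbor_cutoff,buriedness_threshold,required_fraction passed to
#'   [exposure_spec()].
#' @return An [exposure_spec].
#' @export
derive_exposure_spec <- function(truth, window = 11, neighbor_cutoff = 6,
                                 buriedness_threshold = 8,
                                 required_fraction = 0.5) {
  comps <- truth$assembly$components
  sels <- list()
  for (id in names(comps)) {
    comp <- comps[[id]]
    xyz <- bead_coords(comp)
    foreign <- do.call(rbind, lapply(comps[setdiff(names(comps), id)],
                                     bead_coords))
    buried <- rowSums(cdist(xyz, foreign) <= neighbor_cutoff)
    resids <- comp$beads$resid
    # best contiguous window by mean buriedness
    best <- NULL; best_val <- Inf
    for (s in seq_len(max(1, nrow(xyz) - window + 1))) {
      rows <- s:min(nrow(xyz), s + window - 1)
      v <- mean(buried[rows])
      if (v < best_val) {
        best_val <- v
        best <- c(resids[rows[1]], resids[rows[length(rows)]])
      }
    }
    sels[[paste0(id, "_surface")]] <- list(component = id, range = best)
  }
  exposure_spec(sels, neighbor_cutoff, buriedness_threshold,
                required_fraction)
}

benchmark_layouts <- list(
  two_body_toy = list(
    list(id = "A", n = 42, shape = "elongated", aspect = 3, arm = 1,
         tail = 8),
    list(id = "B", n = 38, shape = "globular", arm = 2)
  ),
  four_body = list(
    list(id = "A", n = 110, shape = "elongated", aspect = 3, arm = 1),
    list(id = "B", n = 80, shape = "globular", arm = 1),
    list(id = "C", n = 60, shape = "globular", arm = 2),
    list(id = "D", n = 50, shape = "globular", arm = 2)
  ),
  # the S. pombe deadenylase complex mimic: bead counts proportional to
  # subunit masses (kDa / 110 Da per residue, 5 residues per bead), the
  # Not1 scaffold split across both arms of the L envelope
  l_shape_ccr4not_mimic = list(
    list(id = "Not1", n = 216, shape = "elongated", aspect = 3,
         split = list(n2 = 215, linker = 12)),
    list(id = "Ccr4", n = 138, shape = "globular", arm = 1),
    list(id = "Caf1", n = 68, shape = "globular", arm = 1),
    list(id = "Not3", n = 133, shape = "globular", arm = 2),
    list(id = "Not4", n = 98, shape = "globular", arm = 2),
    list(id = "Not2", n = 62, shape = "globular", lateral = "Not3"),
    list(id = "Caf40", n = 58, shape = "globular", lateral = "Not4"),
    list(id = "Mmi1", n = 98, shape = "globular", lateral = "Caf1")
  )
)

benchmark_arm_targets <- list(
  two_body_toy = NULL,
  four_body = NULL,
  l_shape_ccr4not_mimic = c(150, 140)
)

#' Build a named benchmark
#'
#' Generates a preset ground-truth benchmark (`two_body_toy`,
#' `four_body`, `l_shape_ccr4not_mimic`), derives truth-consistent
#' restraints and an exposure specification, and optionally writes the
#' full bundle (MRC map, per-component PDB files, pipeline config, truth
#' coordinates) to a directory.
#'
#' @param name preset name.
#' @param seed master seed; every stochastic choice derives from it.
#' @param dir optional output directory; created if missing.
#' @param noise map noise level; default 0.05.
#' @param n_restraints contact restraints to derive; default 9.
#' @return A `benchmark_truth` with `restraints` and `exposure` attached
#'   (and `files` when `dir` is given).
#' @export
make_benchmark <- function(name, seed = 1, dir = NULL, noise = 0.05,
                           n_restraints = 9) {
  if (!name %in% names(benchmark_layouts))
    stop_denfit(paste0("unknown benchmark preset: ", name,
                       " (available: ",
                       paste(names(benchmark_layouts), collapse = ", "), ")"),
                "denfit_config_error")
  truth <- make_truth_assembly(benchmark_layouts[[name]],
                               noise = noise, seed = seed,
                               arm_targets = benchmark_arm_targets[[name]])
  truth$preset <- name
  truth$restraints <- derive_restraints(truth, n_restraints = n_restraints)
  truth$exposure <- derive_exposure_spec(truth)
  truth$assembly$restraints <- truth$restraints
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- list(map = file.path(dir, "map.mrc"),
                  truth_pdb = file.path(dir, "truth.pdb"),
                  config = file.path(dir, "config.yaml"))
    write_map(truth$map, files$map)
    write_model_pdb(truth$assembly, files$truth_pdb)
    comps_cfg <- list()
    for (id in names(truth$assembly$components)) {
      p <- file.path(dir, paste0(id, ".pdb"))
      write_model_pdb(truth$assembly$components[[id]], p)
      comp <- truth$assembly$components[[id]]
      flex <- comp$units[comp$units$kind == "chain", , drop = FALSE]
      comps_cfg[[id]] <- list(
        path = basename(p),
        flexible_ranges = unname(apply(flex[, c("start", "end"),
                                            drop = FALSE], 1, as.list)))
      files[[paste0("component_", id)]] <- p
    }
    cfg <- list(
      map = basename(files$map),
      threshold = truth$params$threshold,
      threshold_mode = "absolute",
      resolution = truth$params$resolution,
      components = comps_cfg,
      restraints = lapply(truth$restraints, function(r)
        list(kind = r$kind, component_a = r$component_a,
             component_b = r$component_b, range_a = r$range_a,
             range_b = r$range_b, cutoff = r$cutoff, weight = r$weight)),
      exposure = list(
        selections = truth$exposure$selections,
        neighbor_cutoff = truth$exposure$neighbor_cutoff,
        buriedness_threshold = truth$exposure$buriedness_threshold,
        required_fraction = truth$exposure$required_fraction),
      schedule = list(t0 = 10, decay = 0.999, steps = 100000),
      ensemble = list(n_runs = 1000, top_k = 100),
      clustering = list(rmsd_threshold = truth$params$resolution),
      truth = basename(files$truth_pdb),
      seed = seed)
    yaml::write_yaml(cfg, files$config)
    truth$files <- files
  }
  truth
}

#' Write a bead model as a C-alpha-only PDB file
#'
#' One chain per component; the B-factor column carries the per-bead
#' flexibility flag (1 = flexible linker bead).
#'
#' @param model an [assembly] or [bead_component].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_pdb <- function(model, path) {
  comps <- if (inherits(model, "assembly")) model$components else list(model)
  chains <- c(LETTERS, letters, 0:9)
  xyz <- c(); resno <- c(); chain <- c(); bfac <- c()
  for (i in seq_along(comps)) {
    comp <- comps[[i]]
    xyz <- c(xyz, as.numeric(t(bead_coords(comp))))
    resno <- c(resno, comp$beads$resid)
    chain <- c(chain, rep(chains[i], nrow(comp$beads)))
    bfac <- c(bfac, as.numeric(comp$beads$flexible))
  }
  n <- length(resno)
  bio3d::write.pdb(file = path, xyz = xyz, resno = resno, chain = chain,
                   resid = rep("ALA", n), elety = rep("CA", n),
                   o = rep(1, n), b = bfac)
  invisible(path)
}
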