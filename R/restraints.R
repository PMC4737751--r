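#' Spatial restraints
#'
#' A restraint declares a geometric requirement between residue selections
#' of components:
#' * `proximity` — the centroids of the two selections must lie within
#'   `cutoff` angstrom; penalty `max(0, d_centroid - cutoff)`.
#' * `contact` — at least one bead pair between the selections must be
#'   within `cutoff` surface-to-surface; penalty `max(0, d_min - cutoff)`
#'   with `d_min` the minimum surface distance over all pairs.
#' * `connectivity` — consecutive rigid segments of one component must
#'   stay linkable: for each adjacent segment pair, penalty
#'   `max(0, gap - bond_length * (intervening residues + 1))` on the
#'   terminal-bead distance.
#'
#' Every penalty is continuous, non-negative, and zero exactly when the
#' restraint is satisfied.
#'
#' @param kind `"proximity"`, `"contact"` or `"connectivity"`.
#' @param component_a,component_b component ids; `component_b` is ignored
#'   for connectivity.
#' @param range_a,range_b residue ranges `c(start, end)`, or `NULL` for
#'   "any residue".
#' @param cutoff distance cutoff in Å (proximity default 15, contact 5).
#' @param weight weight of this restraint in the composite score.
#' @return An object of class `restraint`.
#' @export
restraint <- function(kind, component_a, component_b = NULL,
                      range_a = NULL, range_b = NULL,
                      cutoff = if (kind == "proximity") 15 else 5,
                      weight = 1) {
  kind <- match.arg(kind, c("proximity", "contact", "connectivity"))
  if (kind != "connectivity" && (!is_scalar_number(cutoff) || cutoff <= 0))
    stop_denfit("restraint cutoff must be > 0", "denfit_argument_error")
  structure(
    list(kind = kind, component_a = component_a, component_b = component_b,
         range_a = range_a, range_b = range_b, cutoff = cutoff,
         weight = weight),
    class = "restraint"
  )
}

#' @export
print.restraint <- function(x, ...) {
  fmt <- function(comp, rg)
    paste0(comp, "[", if (is.null(rg)) "any" else paste(rg, collapse = "-"), "]")
  if (x$kind == "connectivity")
    cat(sprintf("connectivity: consecutive segments of %s\n", x$component_a))
  else
    cat(sprintf("%s: %s ~ %s within %.1f A (weight %.2g)\n", x$kind,
                fmt(x$component_a, x$range_a), fmt(x$component_b, x$range_b),
                x$cutoff, x$weight))
  invisible(x)
}

#' Build a restraint list from a preset or config
#'
#' The preset `"ccr4not_paper"` encodes the constraint set used to model
#' the fission-yeast CCR4-NOT complex: two proximity constraints tying
#' Not4 residues 16-76 and 113-200 to the Not1 C terminus (residues
#' 1326-2072), a contact between any Mmi1 and any Caf1 residue, a contact
#' between any Mmi1 residue and Not1 residues 1-1200, and connectivity
#' between consecutive Not1 segments.
#'
#' @param config preset name (`"ccr4not_paper"`), or a list of lists with
#'   fields `kind`, `component_a`, `component_b`, `range_a`, `range_b`,
#'   `cutoff`, `weight` (as read from a pipeline config).
#' @param components optional character vector of declared component ids;
#'   when given, selectors on unknown components raise a config error.
#' @return List of [restraint] objects.
#' @export
build_restraints <- function(config, components = NULL) {
  rs <- if (is.character(config) && length(config) == 1L) {
    if (config != "ccr4not_paper")
      stop_denfit(paste0("unknown restraint preset: ", config),
                  "denfit_config_error")
    list(
      restraint("proximity", "Not4", "Not1", c(16, 76), c(1326, 2072)),
      restraint("proximity", "Not4", "Not1", c(113, 200), c(1326, 2072)),
      restraint("contact", "Mmi1", "Caf1", NULL, NULL),
      restraint("contact", "Mmi1", "Not1", NULL, c(1, 1200)),
      restraint("connectivity", "Not1")
    )
  } else if (is.list(config)) {
    lapply(config, function(r) {
      if (inherits(r, "restraint")) return(r)
      restraint(r$kind, r$component_a, r$component_b,
                if (!is.null(r$range_a)) as.numeric(r$range_a),
                if (!is.null(r$range_b)) as.numeric(r$range_b),
                cutoff = r$cutoff %||%
                  (if (r$kind == "proximity") 15 else 5),
                weight = r$weight %||% 1)
    })
  } else {
    stop_denfit("`config` must be a preset name or a list",
                "denfit_config_error")
  }
  if (!is.null(components)) {
    for (r in rs) {
      comps <- c(r$component_a, r$component_b)
      bad <- setdiff(comps, components)
      if (length(bad) > 0)
        stop_denfit(paste0("restraint references undeclared component(s): ",
                           paste(bad, collapse = ", ")),
                    "denfit_config_error")
    }
  }
  rs
}

# indices of a component's beads selected by a residue range (NULL = all).
# Ranges that miss every covered residue fall back to the nearest covered
# bead, with a warning (partial models may lack the annotated stretch).
resolve_selector <- function(comp, range) {
  if (is.null(range)) return(seq_len(nrow(comp$beads)))
  idx <- which(comp$beads$resid >= range[1] & comp$beads$resid <= range[2])
  if (length(idx) == 0) {
    mid <- mean(range)
    idx <- which.min(abs(comp$beads$resid - mid))
    warning(sprintf(
      "selector %s[%d-%d] hits no modelled residue; using nearest bead (residue %d)",
      comp$id, range[1], range[2], comp$beads$resid[idx]), call. = FALSE)
  }
  idx
}

#' Penalty of one restraint on an assembly
#'
#' @param assembly an [assembly].
#' @param r a [restraint].
#' @return Non-negative penalty (0 iff satisfied), in Å.
#' @export
restraint_penalty <- function(assembly, r) {
  comps <- assembly$components
  if (r$kind == "connectivity") {
    comp <- comps[[r$component_a]]
    segs <- comp$units[comp$units$kind == "rigid", , drop = FALSE]
    if (nrow(segs) < 2) return(0)
    segs <- segs[order(segs$start), , drop = FALSE]
    pen <- 0
    for (i in seq_len(nrow(segs) - 1)) {
      a_end <- comp$beads[comp$beads$unit == segs$unit[i], ]
      b_start <- comp$beads[comp$beads$unit == segs$unit[i + 1], ]
      pa <- as.numeric(a_end[which.max(a_end$resid), c("x", "y", "z")])
      pb <- as.numeric(b_start[which.min(b_start$resid), c("x", "y", "z")])
      gap <- sqrt(sum((pa - pb)^2))
      intervening <- segs$start[i + 1] - segs$end[i] - 1L
      allowed <- segs$bond_length[i] * (intervening + 1)
      pen <- pen + max(0, gap - allowed)
    }
    return(pen)
  }
  ca <- comps[[r$component_a]]; cb <- comps[[r$component_b]]
  if (is.null(ca) || is.null(cb))
    stop_denfit(paste0("restraint references missing component: ",
                       r$component_a, " / ", r$component_b),
                "denfit_config_error")
  ia <- resolve_selector(ca, r$range_a)
  ib <- resolve_selector(cb, r$range_b)
  xa <- bead_coords(ca)[ia, , drop = FALSE]
  xb <- bead_coords(cb)[ib, , drop = FALSE]
  if (r$kind == "proximity") {
    d <- sqrt(sum((colMeans(xa) - colMeans(xb))^2))
    return(max(0, d - r$cutoff))
  }
  dmin <- cpp_min_surface_dist(xa, ca$beads$radius[ia],
                               xb, cb$beads$radius[ib])
  max(0, dmin - r$cutoff)
}

#' Inter-component clash count
#'
#' Beads are binned on a cubic grid of cell size `grid_size`; a pair of
#' beads from different components clashes when their centre distance is
#' below `(r_i + r_j) * overlap_factor`. The result equals the brute-force
#' all-pairs count exactly; the grid only accelerates the search.
#'
#' @param assembly an [assembly].
#' @param grid_size binning cell size in Å; default 1.5.
#' @param overlap_factor fraction of the radius sum below which two beads
#'   count as clashing; default 0.8 (beads of neighbouring residues may
#'   legitimately graze).
#' @return Number of clashing inter-component pairs.
#' @export
clash_count <- function(assembly, grid_size = 1.5, overlap_factor = 0.8) {
  xyz <- bead_coords(assembly)
  if (nrow(xyz) < 2) return(0)
  radii <- bead_radii(assembly)
  comp <- rep(seq_along(assembly$components),
              vapply(assembly$components, function(c) nrow(c$beads), 0L))
  cpp_clash_count_grid(xyz, radii, comp, grid_size, overlap_factor)
}

#' Default score weights
#'
#' Weights of the composite score terms, calibrated so that a typical
#' single-component move changes the total by roughly 0.1-1 relative to
#' the starting temperature of 10 (the acceptance rate neither saturates
#' nor freezes at the start of a run).
#'
#' @return Named list `w_out`, `w_clash`, `w_rest`, `w_fill`.
#' @export
default_score_weights <- function() {
  list(w_out = 10, w_clash = 1, w_rest = 10, w_fill = 10)
}

#' Assembly container
#'
#' Bundles components (in the shared frame of the target map), the target
#' map with its envelope mask, the restraint list and score weights into
#' the state object the annealer optimizes.
#'
#' @param components named list of [bead_component]s (names = ids).
#' @param map target [density_map] (may be `NULL` for geometry-only use).
#' @param restraints list of [restraint]s.
#' @param threshold envelope contour; default 0.7.
#' @param threshold_mode `"max_fraction"` or `"absolute"`.
#' @param weights score weights, see [default_score_weights()].
#' @param grid_size clash-binning cell size (Å).
#' @param overlap_factor clash overlap factor.
#' @return An object of class `assembly`.
#' @export
assembly <- function(components, map = NULL, restraints = list(),
                     threshold = 0.7,
                     threshold_mode = c("max_fraction", "absolute"),
                     weights = default_score_weights(),
                     grid_size = 1.5, overlap_factor = 0.8) {
  threshold_mode <- match.arg(threshold_mode)
  if (is.null(names(components)))
    names(components) <- vapply(components, function(c) c$id, "")
  if (anyDuplicated(names(components)))
    stop_denfit("component ids must be unique", "denfit_argument_error")
  mask <- if (!is.null(map)) threshold_mask(map, threshold, threshold_mode)
  structure(
    list(components = components, map = map, mask = mask,
         restraints = restraints, weights = weights,
         grid_size = grid_size, overlap_factor = overlap_factor,
         threshold = threshold, threshold_mode = threshold_mode),
    class = "assembly"
  )
}

#' @export
print.assembly <- function(x, ...) {
  cat(sprintf("assembly: %d components (%d beads), %d restraints%s\n",
              length(x$components),
              sum(vapply(x$components, function(c) nrow(c$beads), 0L)),
              length(x$restraints),
              if (is.null(x$map)) ", no map" else ""))
  invisible(x)
}

# logical vector: is each bead of `xyz` inside the mask volume?
beads_in_mask <- function(xyz, mask) {
  d <- dim(mask$mask)
  i <- round((xyz[, 1] - mask$origin[1]) / mask$voxel) + 1
  j <- round((xyz[, 2] - mask$origin[2]) / mask$voxel) + 1
  k <- round((xyz[, 3] - mask$origin[3]) / mask$voxel) + 1
  ok <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3]
  inside <- rep(FALSE, nrow(xyz))
  if (any(ok))
    inside[ok] <- mask$mask[cbind(i[ok], j[ok], k[ok])]
  inside
}

# density weights of the mask voxels, normalized to sum 1: occupying
# strong density is worth more than grazing the contour halo
mask_weights <- function(map, mask) {
  w <- pmax(as.numeric(map$data)[as.logical(mask$mask)], 0)
  if (sum(w) <= 0) w <- rep(1, length(w))
  w / sum(w)
}

# density-weighted fraction of the envelope occupied by beads: sum of the
# normalized density over mask voxels whose centre lies within any bead
fill_fraction <- function(assembly) {
  mask <- assembly$mask
  d <- dim(mask$mask)
  slot <- integer(prod(d))
  in_mask <- which(as.logical(mask$mask))
  slot[in_mask] <- seq_along(in_mask)
  xyz <- bead_coords(assembly)
  slots <- cpp_cover_slots(xyz, bead_radii(assembly), mask$origin,
                           mask$voxel, d, slot)
  w <- mask_weights(assembly$map, mask)
  sum(w[unique(slots)])
}

#' Composite assembly score
#'
#' The annealer's energy, a weighted sum of four terms (lower is better):
#' `outbox`, the fraction of beads outside the envelope mask; `clash`, the
#' inter-component clash count; `restraint`, the sum of weighted restraint
#' penalties; and `fill`, the density-weighted fraction of the envelope
#' occupied by beads (each mask voxel counts with its normalized density,
#' so occupying strong density is rewarded more than grazing the contour
#' halo), entering with a negative sign as a reward. "Best score" in
#' reporting corresponds to the lowest energy; the breakdown also carries
#' the negated total (`score`) for the highest-is-best convention.
#'
#' @param assembly an [assembly] with an attached map.
#' @return An object of class `score_breakdown`.
#' @export
composite_score <- function(assembly) {
  if (is.null(assembly$map))
    stop_denfit("assembly has no attached density map", "denfit_state_error")
  xyz <- bead_coords(assembly)
  outbox <- 1 - mean(beads_in_mask(xyz, assembly$mask))
  clash <- clash_count(assembly, assembly$grid_size, assembly$overlap_factor)
  rest <- 0
  for (r in assembly$restraints)
    rest <- rest + r$weight * restraint_penalty(assembly, r)
  fill <- fill_fraction(assembly)
  w <- assembly$weights
  total <- w$w_out * outbox + w$w_clash * clash + w$w_rest * rest -
    w$w_fill * fill
  structure(
    list(outbox = outbox, clash = clash, restraint = rest, fill = fill,
         weights = w, total = total, score = -total),
    class = "score_breakdown"
  )
}

#' @export
print.score_breakdown <- function(x, ...) {
  cat(sprintf(
    "score: total (energy) %.4f | outbox %.3f  clash %g  restraint %.3f  fill %.3f\n",
    x$total, x$outbox, x$clash, x$restraint, x$fill))
  invisible(x)
}
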