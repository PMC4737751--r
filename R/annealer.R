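#' Annealing schedule
#'
#' Geometric cooling: the temperature at step `n` is `t0 * decay^n` in
#' dimensionless units. Defaults are the protocol constants: starting
#' temperature 10, per-step decay 0.999, 100,000 steps.
#'
#' @param t0 starting temperature (> 0); default 10.
#' @param decay per-step geometric factor in (0, 1); default 0.999.
#' @param steps total number of Monte Carlo steps; default 100000.
#' @return An object of class `anneal_schedule`.
#' @export
anneal_schedule <- function(t0 = 10, decay = 0.999, steps = 100000) {
  if (!is_scalar_number(t0) || t0 <= 0)
    stop_denfit("t0 must be > 0", "denfit_argument_error")
  if (!is_scalar_number(decay) || decay <= 0 || decay >= 1)
    stop_denfit("decay must be in (0, 1)", "denfit_argument_error")
  if (!is_scalar_number(steps) || steps < 0)
    stop_denfit("steps must be >= 0", "denfit_argument_error")
  structure(list(t0 = t0, decay = decay, steps = as.integer(steps)),
            class = "anneal_schedule")
}

#' Temperature at a given step
#'
#' @param schedule an [anneal_schedule].
#' @param n step index (0-based; `n = 0` gives `t0`).
#' @return `t0 * decay^n`.
#' @export
schedule_temperature <- function(schedule, n) {
  if (any(n < 0))
    stop_denfit("step index must be >= 0", "denfit_argument_error")
  schedule$t0 * schedule$decay^n
}

#' Metropolis acceptance
#'
#' Accepts every downhill move (`delta_e <= 0`); an uphill move is
#' accepted with probability `exp(-delta_e / temperature)`, using one
#' uniform draw from the session RNG.
#'
#' @param delta_e energy change of the proposed move.
#' @param temperature current temperature (> 0).
#' @return `TRUE` to accept.
#' @export
metropolis_accept <- function(delta_e, temperature) {
  if (!is_scalar_number(temperature) || temperature <= 0)
    stop_denfit("temperature must be > 0", "denfit_argument_error")
  if (delta_e <= 0) return(TRUE)
  runif(1) < exp(-delta_e / temperature)
}

#' Move parameters
#'
#' @param p_rotate probability of a rigid rotation move; default 0.4.
#' @param rot_sigma rotation angle sigma in degrees; default 10.
#' @param trans_sigma translation sigma in Å; default 5.
#' @param p_linker probability of a flexible-chain pivot move; default 0.2
#'   (falls back to a rigid move when the assembly has no flexible chain).
#' @param pivot_sigma pivot angle sigma in degrees; default 30.
#' @return An object of class `move_params`.
#' @export
move_params <- function(p_rotate = 0.4, rot_sigma = 10, trans_sigma = 5,
                        p_linker = 0.2, pivot_sigma = 30) {
  if (p_rotate < 0 || p_linker < 0 || p_rotate + p_linker > 1)
    stop_denfit("need p_rotate, p_linker >= 0 and p_rotate + p_linker <= 1",
                "denfit_argument_error")
  structure(list(p_rotate = p_rotate, rot_sigma = rot_sigma,
                 trans_sigma = trans_sigma, p_linker = p_linker,
                 pivot_sigma = pivot_sigma),
            class = "move_params")
}

# uniform random rotation matrix (via a uniform unit quaternion)
random_rotation <- function() {
  q <- rnorm(4)
  quat_to_matrix(q / sqrt(sum(q^2)))
}

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

# Draw one move descriptor from the session RNG. Chains are identified by
# (component index, chain row indices within that component).
draw_move <- function(n_components, chains, params) {
  u <- runif(1)
  if (u < params$p_rotate || (u < params$p_rotate + params$p_linker &&
                              length(chains) == 0)) {
    kind <- "rotate"
  } else if (u < params$p_rotate + params$p_linker) {
    kind <- "pivot"
  } else {
    kind <- "translate"
  }
  if (kind == "pivot") {
    ch <- chains[[sample.int(length(chains), 1)]]
    pivot <- sample.int(length(ch$rows), 1)
    axis <- rnorm(3)
    list(kind = "pivot", comp = ch$comp, rows = ch$rows, pivot = pivot,
         axis = axis / sqrt(sum(axis^2)),
         angle = rnorm(1, 0, params$pivot_sigma))
  } else if (kind == "rotate") {
    axis <- rnorm(3)
    list(kind = "rotate", comp = sample.int(n_components, 1),
         axis = axis / sqrt(sum(axis^2)),
         angle = rnorm(1, 0, params$rot_sigma))
  } else {
    list(kind = "translate", comp = sample.int(n_components, 1),
         shift = rnorm(3, 0, params$trans_sigma))
  }
}

# chain units of an assembly: list of (comp index, bead row indices)
assembly_chains <- function(components) {
  out <- list()
  for (ci in seq_along(components)) {
    comp <- components[[ci]]
    for (u in comp$units$unit[comp$units$kind == "chain"]) {
      rows <- which(comp$beads$unit == u)
      if (length(rows) >= 2)
        out[[length(out) + 1]] <- list(comp = ci, rows = rows)
    }
  }
  out
}

# apply a move descriptor to one component's coordinate matrix
apply_move_xyz <- function(xyz, mv) {
  if (mv$kind == "translate")
    return(sweep(xyz, 2, -mv$shift))
  if (mv$kind == "rotate") {
    ctr <- colMeans(xyz)
    R <- rotation_about_axis(mv$axis, mv$angle)
    return(sweep(sweep(xyz, 2, ctr) %*% t(R), 2, -ctr))
  }
  # pivot: rotate the chain tail beyond the pivot bead about an axis
  # through the pivot bead; bond lengths within the chain are preserved
  rows <- mv$rows
  if (mv$pivot >= length(rows)) return(xyz)
  p <- rows[mv$pivot]
  tail_rows <- rows[(mv$pivot + 1L):length(rows)]
  R <- rotation_about_axis(mv$axis, mv$angle)
  ctr <- xyz[p, ]
  xyz[tail_rows, ] <- sweep(sweep(xyz[tail_rows, , drop = FALSE], 2, ctr) %*%
                              t(R), 2, -ctr)
  xyz
}

#' Propose a single Monte Carlo move
#'
#' Exactly one of: rigid rotation of one component about its centroid,
#' rigid translation of one component, or a pivot move on one flexible
#' chain (the tail beyond a random chain bead rotates about an axis
#' through that bead). All unmoved components are returned unchanged.
#'
#' @param assembly an [assembly].
#' @param params a [move_params].
#' @return List with `assembly` (the candidate) and `moved` (component
#'   index and move kind).
#' @export
propose_move <- function(assembly, params = move_params()) {
  chains <- assembly_chains(assembly$components)
  mv <- draw_move(length(assembly$components), chains, params)
  comp <- assembly$components[[mv$comp]]
  assembly$components[[mv$comp]] <-
    set_bead_coords(comp, apply_move_xyz(bead_coords(comp), mv))
  list(assembly = assembly, moved = list(component = mv$comp, kind = mv$kind))
}

#' Initial component placement
#'
#' Places every component with its centroid inside the thresholded map
#' volume. In `random_in_volume` mode the centroid voxel is drawn
#' uniformly over mask voxels and the orientation uniformly over
#' rotations; in `from_docking`/`given` mode components with a supplied
#' transform are placed exactly and the remainder randomized.
#'
#' @param assembly an [assembly] with an attached map.
#' @param mode placement mode.
#' @param transforms named list of [rigid_transform]s (for
#'   `from_docking` / `given`).
#' @param seed optional RNG seed for reproducible placement.
#' @return The assembly with updated component coordinates.
#' @export
initial_positions <- function(assembly,
                              mode = c("random_in_volume", "from_docking",
                                       "given"),
                              transforms = list(), seed = NULL) {
  mode <- match.arg(mode)
  if (is.null(assembly$mask))
    stop_denfit("assembly has no attached map", "denfit_state_error")
  vox_idx <- which(assembly$mask$mask, arr.ind = TRUE)
  if (nrow(vox_idx) == 0)
    stop_denfit("degenerate map: empty envelope mask",
                "denfit_degenerate_map_error")
  if (!is.null(seed)) set.seed(seed)
  for (id in names(assembly$components)) {
    comp <- assembly$components[[id]]
    if (mode != "random_in_volume" && !is.null(transforms[[id]])) {
      assembly$components[[id]] <- apply_transform(comp, transforms[[id]])
      next
    }
    if (mode == "given")
      stop_denfit(paste0("mode 'given' but no transform for component ", id),
                  "denfit_argument_error")
    v <- vox_idx[sample.int(nrow(vox_idx), 1), ]
    target <- assembly$mask$origin + (as.numeric(v) - 1) * assembly$mask$voxel
    xyz <- bead_coords(comp)
    ctr <- colMeans(xyz)
    R <- random_rotation()
    xyz <- sweep(sweep(xyz, 2, ctr) %*% t(R), 2, -target)
    assembly$components[[id]] <- set_bead_coords(comp, xyz)
  }
  assembly
}

## ---------------------------------------------------------------------------
## Fast incremental scoring state
## ---------------------------------------------------------------------------

# precompile restraints into index form for matrix-based evaluation
compile_restraints <- function(assembly) {
  ids <- names(assembly$components)
  lapply(assembly$restraints, function(r) {
    if (r$kind == "connectivity") {
      comp <- assembly$components[[r$component_a]]
      ci <- match(r$component_a, ids)
      segs <- comp$units[comp$units$kind == "rigid", , drop = FALSE]
      segs <- segs[order(segs$start), , drop = FALSE]
      links <- list()
      if (nrow(segs) >= 2) {
        for (i in seq_len(nrow(segs) - 1)) {
          rows_a <- which(comp$beads$unit == segs$unit[i])
          rows_b <- which(comp$beads$unit == segs$unit[i + 1])
          links[[i]] <- list(
            a = rows_a[which.max(comp$beads$resid[rows_a])],
            b = rows_b[which.min(comp$beads$resid[rows_b])],
            allowed = segs$bond_length[i] *
              (segs$start[i + 1] - segs$end[i] - 1L + 1L))
        }
      }
      list(kind = "connectivity", comps = ci, links = links,
           weight = r$weight)
    } else {
      ca <- assembly$components[[r$component_a]]
      cb <- assembly$components[[r$component_b]]
      ia <- resolve_selector(ca, r$range_a)
      ib <- resolve_selector(cb, r$range_b)
      list(kind = r$kind,
           comps = match(c(r$component_a, r$component_b), ids),
           ia = ia, ib = ib,
           ra = ca$beads$radius[ia], rb = cb$beads$radius[ib],
           cutoff = r$cutoff, weight = r$weight)
    }
  })
}

eval_restraint_fast <- function(cr, coords) {
  if (cr$kind == "connectivity") {
    pen <- 0
    xyz <- coords[[cr$comps[1]]]
    for (lk in cr$links) {
      gap <- sqrt(sum((xyz[lk$a, ] - xyz[lk$b, ])^2))
      pen <- pen + max(0, gap - lk$allowed)
    }
    return(pen)
  }
  xa <- coords[[cr$comps[1]]][cr$ia, , drop = FALSE]
  xb <- coords[[cr$comps[2]]][cr$ib, , drop = FALSE]
  if (cr$kind == "proximity") {
    d <- sqrt(sum((colMeans(xa) - colMeans(xb))^2))
    return(max(0, d - cr$cutoff))
  }
  max(0, cpp_min_surface_dist(xa, cr$ra, xb, cr$rb) - cr$cutoff)
}

anneal_state <- function(assembly) {
  mask <- assembly$mask
  d <- dim(mask$mask)
  in_mask <- which(as.logical(mask$mask))
  slot <- integer(prod(d))
  slot[in_mask] <- seq_along(in_mask)
  nc <- length(assembly$components)
  coords <- lapply(assembly$components, bead_coords)
  radii <- lapply(assembly$components, function(c) c$beads$radius)
  n_beads <- sum(vapply(coords, nrow, 0L))
  cover <- integer(length(in_mask))
  wt <- mask_weights(assembly$map, mask)
  slots <- vector("list", nc)
  in_count <- numeric(nc)
  cov_wt <- 0
  for (i in seq_len(nc)) {
    slots[[i]] <- cpp_cover_slots(coords[[i]], radii[[i]], mask$origin,
                                  mask$voxel, d, slot)
    cov_wt <- cov_wt + cpp_cover_update_w(cover, slots[[i]], 1L, wt)
    in_count[i] <- sum(beads_in_mask(coords[[i]], mask))
  }
  clash <- matrix(0, nc, nc)
  for (i in seq_len(nc)) for (j in seq_len(nc)) if (i < j)
    clash[i, j] <- cpp_clash_between(coords[[i]], radii[[i]],
                                     coords[[j]], radii[[j]],
                                     assembly$overlap_factor)
  cres <- compile_restraints(assembly)
  rest_val <- vapply(cres, eval_restraint_fast, 0, coords = coords)
  list(assembly = assembly, mask = mask, dims = d, slot = slot,
       n_mask = length(in_mask), wt = wt, coords = coords, radii = radii,
       n_beads = n_beads, cover = cover, slots = slots,
       in_count = in_count, cov_wt = cov_wt, clash = clash,
       cres = cres, rest_val = rest_val)
}

state_total <- function(st) {
  w <- st$assembly$weights
  w$w_out * (1 - sum(st$in_count) / st$n_beads) +
    w$w_clash * sum(st$clash) +
    w$w_rest * sum(vapply(seq_along(st$cres), function(k)
      st$cres[[k]]$weight * st$rest_val[k], 0)) -
    w$w_fill * st$cov_wt
}

# write current state coordinates back into the assembly object
state_to_assembly <- function(st) {
  a <- st$assembly
  for (i in seq_along(a$components))
    a$components[[i]] <- set_bead_coords(a$components[[i]], st$coords[[i]])
  a
}

#' Simulated annealing of an assembly
#'
#' Monte Carlo simulated annealing under the composite score with the
#' geometric cooling schedule. One component (or one flexible chain)
#' moves per step; the score is updated incrementally for the moved
#' selection and audited against a full recomputation every 1,000 steps
#' (agreement within 1e-9 is enforced). Both the final state and the
#' best-so-far state are returned; with geometric cooling the chain is
#' effectively frozen long before the last step, so the best-so-far model
#' is the robust deliverable.
#'
#' @param assembly0 starting [assembly] with map and restraints attached.
#' @param schedule an [anneal_schedule].
#' @param params a [move_params].
#' @param seed RNG seed for this run; `NULL` continues the current RNG
#'   stream.
#' @param trace_every record the score trace every this many steps.
#' @return An object of class `run_result`: `final`, `final_score`,
#'   `best`, `best_score`, `seed`, `accepted`, `trace`.
#' @export
anneal <- function(assembly0, schedule = anneal_schedule(),
                   params = move_params(), seed = NULL,
                   trace_every = max(1L, schedule$steps %/% 500L)) {
  if (is.null(assembly0$map))
    stop_denfit("assembly has no attached density map", "denfit_state_error")
  if (!is.null(seed)) set.seed(seed)
  st <- anneal_state(assembly0)
  w <- assembly0$weights
  chains <- assembly_chains(assembly0$components)
  nc <- length(st$coords)
  total <- state_total(st)
  best_total <- total
  best_coords <- st$coords
  accepted <- 0L
  trace <- data.frame(step = 0L, temperature = schedule$t0, total = total)
  steps <- schedule$steps
  mask <- st$mask
  if (steps > 0) {
    temps <- schedule_temperature(schedule, seq_len(steps) - 1)
    for (n in seq_len(steps)) {
      mv <- draw_move(nc, chains, params)
      ci <- mv$comp
      old_xyz <- st$coords[[ci]]
      new_xyz <- apply_move_xyz(old_xyz, mv)
      rad <- st$radii[[ci]]
      # incremental term updates
      new_in <- sum(beads_in_mask(new_xyz, mask))
      new_clash <- numeric(nc)
      for (j in seq_len(nc)) if (j != ci)
        new_clash[j] <- cpp_clash_between(new_xyz, rad, st$coords[[j]],
                                          st$radii[[j]],
                                          st$assembly$overlap_factor)
      old_clash_sum <- sum(st$clash[ci, ]) + sum(st$clash[, ci])
      new_slots <- cpp_cover_slots(new_xyz, rad, mask$origin, mask$voxel,
                                   st$dims, st$slot)
      dcov <- cpp_cover_update_w(st$cover, st$slots[[ci]], -1L, st$wt)
      dcov <- dcov + cpp_cover_update_w(st$cover, new_slots, 1L, st$wt)
      touched <- which(vapply(st$cres, function(cr) ci %in% cr$comps, TRUE))
      new_rest <- st$rest_val
      if (length(touched) > 0) {
        st$coords[[ci]] <- new_xyz
        for (k in touched)
          new_rest[k] <- eval_restraint_fast(st$cres[[k]], st$coords)
        st$coords[[ci]] <- old_xyz
      }
      delta <- w$w_out * ((st$in_count[ci] - new_in) / st$n_beads) +
        w$w_clash * (sum(new_clash) - old_clash_sum) +
        w$w_rest * sum(vapply(touched, function(k)
          st$cres[[k]]$weight * (new_rest[k] - st$rest_val[k]), 0)) -
        w$w_fill * dcov
      if (metropolis_accept(delta, temps[n])) {
        st$coords[[ci]] <- new_xyz
        st$in_count[ci] <- new_in
        for (j in seq_len(nc)) {
          if (j < ci) st$clash[j, ci] <- new_clash[j]
          else if (j > ci) st$clash[ci, j] <- new_clash[j]
        }
        st$slots[[ci]] <- new_slots
        st$cov_wt <- st$cov_wt + dcov
        st$rest_val <- new_rest
        total <- total + delta
        accepted <- accepted + 1L
        if (total < best_total) {
          best_total <- total
          best_coords <- st$coords
        }
      } else {
        # revert coverage bookkeeping
        cpp_cover_update_w(st$cover, new_slots, -1L, st$wt)
        cpp_cover_update_w(st$cover, st$slots[[ci]], 1L, st$wt)
      }
      if (n %% 1000L == 0L) {
        full <- state_total(anneal_state(state_to_assembly(st)))
        if (abs(full - total) > 1e-9)
          stop_denfit(sprintf(
            "incremental score drifted from full recomputation (%.3g)",
            abs(full - total)), "denfit_internal_error")
        total <- full
      }
      if (n %% trace_every == 0L)
        trace <- rbind(trace, data.frame(step = n, temperature = temps[n],
                                         total = total))
    }
  }
  if (trace$step[nrow(trace)] != steps)
    trace <- rbind(trace, data.frame(
      step = steps,
      temperature = if (steps > 0) temps[steps] else schedule$t0,
      total = total))
  final <- state_to_assembly(st)
  st$coords <- best_coords
  best <- state_to_assembly(st)
  structure(
    list(final = final, final_score = composite_score(final),
         best = best, best_score = composite_score(best),
         seed = seed, accepted = accepted, trace = trace),
    class = "run_result"
  )
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf(
    "run_result: final energy %.4f, best energy %.4f, %d accepted moves\n",
    x$final_score$total, x$best_score$total, x$accepted))
  invisible(x)
}

#' Generate a model ensemble from independent annealing runs
#'
#' Runs `n_runs` independent annealing trajectories, one per seed, each
#' from its own initialization (random inside the envelope, or
#' docking-derived transforms optionally perturbed by a per-run jitter so
#' the runs explore distinct basins).
#'
#' @param base_assembly template [assembly] (components, map, restraints).
#' @param n_runs number of runs; default 1000 at protocol scale.
#' @param schedule an [anneal_schedule].
#' @param params a [move_params].
#' @param seeds distinct integer seeds, one per run; default derived from
#'   `seed`.
#' @param seed master seed used when `seeds` is not given.
#' @param init `"random_in_volume"` or `"from_docking"`.
#' @param transforms named list of [rigid_transform]s for `from_docking`.
#' @param jitter_rot,jitter_trans per-run perturbation (degrees, Å) of
#'   docking-derived starts.
#' @return An object of class `model_ensemble`.
#' @export
run_ensemble <- function(base_assembly, n_runs = 1000,
                         schedule = anneal_schedule(),
                         params = move_params(),
                         seeds = NULL, seed = 1,
                         init = c("random_in_volume", "from_docking"),
                         transforms = list(),
                         jitter_rot = 10, jitter_trans = 4) {
  init <- match.arg(init)
  if (is.null(seeds)) seeds <- derive_seeds(seed, n_runs)
  if (length(seeds) != n_runs)
    stop_denfit("need one seed per run", "denfit_argument_error")
  if (anyDuplicated(seeds))
    stop_denfit("seeds must be distinct", "denfit_argument_error")
  results <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    set.seed(seeds[i])
    a0 <- if (init == "random_in_volume") {
      initial_positions(base_assembly, "random_in_volume")
    } else {
      tf <- transforms
      for (id in names(tf)) {
        t <- tf[[id]]
        c0 <- colMeans(bead_coords(base_assembly$components[[id]]))
        ctr <- as.numeric(t$rotation %*% c0) + t$translation
        axis <- rnorm(3)
        jr <- rotation_about_axis(axis / sqrt(sum(axis^2)),
                                  rnorm(1, 0, jitter_rot))
        # jitter rotates about the placed centroid, then shifts slightly
        jt <- rigid_transform(jr, ctr - as.numeric(jr %*% ctr) +
                                    rnorm(3, 0, jitter_trans))
        tf[[id]] <- compose_transforms(jt, t)
      }
      initial_positions(base_assembly, "from_docking", transforms = tf)
    }
    res <- anneal(a0, schedule, params, seed = NULL)
    res$seed <- seeds[i]
    results[[i]] <- res
  }
  structure(list(results = results, seeds = seeds,
                 schedule = schedule, params = params),
            class = "model_ensemble")
}

#' @export
print.model_ensemble <- function(x, ...) {
  en <- vapply(x$results, function(r) r$best_score$total, 0)
  cat(sprintf("model_ensemble: %d runs, best energy %.4f, median %.4f\n",
              length(x$results), min(en), stats::median(en)))
  invisible(x)
}
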