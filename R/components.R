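#' Coarse-grained protein components
#'
#' A `bead_component` represents one protein as a chain of beads, one per
#' residue, partitioned into rigid segments (whose internal geometry never
#' changes) and flexible chains (disordered linkers that may change
#' conformation during assembly, bond lengths preserved). Residue numbering
#' is 1-based along the full-length sequence, so restraint selectors can be
#' written directly as residue ranges. Components may cover only part of
#' the sequence (unmodelled termini are allowed).
#'
#' @param id component name, e.g. `"Not1"`.
#' @param beads data frame with columns `resid`, `x`, `y`, `z`, `radius`,
#'   `flexible`, `unit` (unit index, assigned if missing).
#' @param seq_length full sequence length (defaults to `max(resid)`).
#' @param units data frame describing rigid segments and flexible chains
#'   (`unit`, `kind`, `start`, `end`, `bond_length`); derived from the
#'   `flexible` flags when omitted.
#' @return An object of class `bead_component`.
#' @export
bead_component <- function(id, beads, seq_length = NULL, units = NULL) {
  req <- c("resid", "x", "y", "z", "radius", "flexible")
  if (!all(req %in% names(beads)))
    stop_denfit(paste("bead table must have columns:",
                      paste(req, collapse = ", ")), "denfit_argument_error")
  beads$resid <- as.integer(beads$resid)
  beads <- beads[order(beads$resid), , drop = FALSE]
  rownames(beads) <- NULL
  if (any(beads$radius <= 0) || any(beads$resid < 1))
    stop_denfit("bead radii must be > 0 and residue indices >= 1",
                "denfit_argument_error")
  if (anyDuplicated(beads$resid))
    stop_denfit("duplicated residue indices in bead table",
                "denfit_argument_error")
  seq_length <- seq_length %||% max(beads$resid)
  if (is.null(units)) {
    # contiguous runs of equal flexibility become units
    brk <- cumsum(c(1L, diff(beads$resid) != 1L |
                        diff(as.integer(beads$flexible)) != 0L))
    units <- do.call(rbind, lapply(split(seq_len(nrow(beads)), brk),
      function(ii) {
        data.frame(kind = if (beads$flexible[ii[1]]) "chain" else "rigid",
                   start = beads$resid[ii[1]],
                   end = beads$resid[ii[length(ii)]],
                   bond_length = 3.8)
      }))
    units$unit <- seq_len(nrow(units))
    rownames(units) <- NULL
  }
  beads$unit <- findInterval(beads$resid, units$start)
  structure(
    list(id = id, seq_length = as.integer(seq_length),
         beads = beads, units = units[, c("unit", "kind", "start", "end",
                                          "bond_length")]),
    class = "bead_component"
  )
}

#' @export
print.bead_component <- function(x, ...) {
  cat(sprintf("bead_component '%s': %d beads (seq length %d), %d rigid, %d flexible\n",
              x$id, nrow(x$beads), x$seq_length,
              sum(!x$beads$flexible), sum(x$beads$flexible)))
  invisible(x)
}

#' Extract bead coordinates as a matrix
#'
#' @param x a `bead_component`, `assembly`, plain matrix or data frame.
#' @return n x 3 numeric matrix of positions (Å).
#' @export
bead_coords <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 3)
    return(x)
  }
  if (inherits(x, "bead_component"))
    return(as.matrix(x$beads[, c("x", "y", "z")]))
  if (inherits(x, "assembly"))
    return(do.call(rbind, lapply(x$components, bead_coords)))
  if (is.data.frame(x) && all(c("x", "y", "z") %in% names(x)))
    return(as.matrix(x[, c("x", "y", "z")]))
  stop_denfit("cannot extract bead coordinates from this object",
              "denfit_argument_error")
}

bead_radii <- function(x) {
  if (inherits(x, "bead_component")) return(x$beads$radius)
  if (inherits(x, "assembly"))
    return(unlist(lapply(x$components, function(c) c$beads$radius),
                  use.names = FALSE))
  stop_denfit("cannot extract bead radii from this object",
              "denfit_argument_error")
}

set_bead_coords <- function(comp, xyz) {
  comp$beads$x <- xyz[, 1]
  comp$beads$y <- xyz[, 2]
  comp$beads$z <- xyz[, 3]
  comp
}

#' Load a component from a PDB file
#'
#' Reads atomic coordinates (via bio3d) and coarse-grains to one bead per
#' residue at the C-alpha position, falling back to the residue centroid
#' where no C-alpha is present. Residues inside annotated disordered
#' ranges are flagged flexible.
#'
#' @param path PDB file.
#' @param component_id name for the component.
#' @param flexible_ranges list of `c(start, end)` residue ranges treated as
#'   disordered linkers.
#' @param radius uniform bead radius in Å (default 3.5).
#' @param seq_length full-length sequence length; default `max(resid)`.
#' @return A [bead_component].
#' @export
load_structure <- function(path, component_id, flexible_ranges = list(),
                           radius = 3.5, seq_length = NULL) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e)
                    stop_denfit(paste0("cannot read PDB: ", conditionMessage(e)),
                                "denfit_input_error"))
  at <- pdb$atom
  resids <- sort(unique(at$resno))
  pos <- t(vapply(resids, function(r) {
    rows <- at[at$resno == r, , drop = FALSE]
    ca <- rows[rows$elety == "CA", , drop = FALSE]
    if (nrow(ca) >= 1) as.numeric(ca[1, c("x", "y", "z")])
    else colMeans(rows[, c("x", "y", "z")])
  }, numeric(3)))
  flex <- rep(FALSE, length(resids))
  unresolved <- character(0)
  for (rg in flexible_ranges) {
    hit <- resids >= rg[1] & resids <= rg[2]
    if (!any(hit))
      unresolved <- c(unresolved, sprintf("%d-%d", rg[1], rg[2]))
    flex[hit] <- TRUE
  }
  if (length(unresolved) > 0)
    stop_denfit(paste0("segmentation ranges not present in structure: ",
                       paste(unresolved, collapse = ", ")),
                "denfit_resolution_error")
  bead_component(component_id,
                 data.frame(resid = resids, x = pos[, 1], y = pos[, 2],
                            z = pos[, 3], radius = radius, flexible = flex),
                 seq_length = seq_length)
}

#' Coarse-grain residue positions into a bead model
#'
#' @param positions n x 3 matrix of per-residue positions (Å), in residue
#'   order.
#' @param component_id component name.
#' @param radius uniform bead radius (Å); alternatively a length-n vector.
#' @param resid residue indices (default `1:n`).
#' @param flexible logical flags per residue.
#' @return A [bead_component].
#' @export
coarse_grain <- function(positions, component_id = "comp", radius = 3.5,
                         resid = seq_len(nrow(positions)),
                         flexible = rep(FALSE, nrow(positions))) {
  if (is.null(nrow(positions)) || nrow(positions) < 1)
    stop_denfit("at least one residue is required", "denfit_argument_error")
  bead_component(component_id,
                 data.frame(resid = resid, x = positions[, 1],
                            y = positions[, 2], z = positions[, 3],
                            radius = radius, flexible = flexible))
}

## ---------------------------------------------------------------------------
## Rigid transforms
## ---------------------------------------------------------------------------

#' Construct a rigid transform
#'
#' @param rotation 3 x 3 rotation matrix (orthonormal, det +1).
#' @param translation length-3 translation (Å).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!identical(dim(rotation), c(3L, 3L)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    stop_denfit("rotation must be orthonormal with determinant +1 (tol 1e-9)",
                "denfit_argument_error")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Rotation matrix about an axis
#'
#' @param axis rotation axis (any nonzero length-3 vector).
#' @param angle angle in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Compose two rigid transforms
#'
#' `compose_transforms(t2, t1)` applies `t1` first, then `t2`.
#' @param t2,t1 [rigid_transform]s.
#' @return A [rigid_transform].
#' @export
compose_transforms <- function(t2, t1) {
  rigid_transform(t2$rotation %*% t1$rotation,
                  as.numeric(t2$rotation %*% t1$translation) + t2$translation)
}

#' Apply a rigid transform to beads
#'
#' Maps every bead position by `x -> R x + t`, preserving all internal
#' pairwise distances.
#'
#' @param x a [bead_component], `assembly`, or n x 3 coordinate matrix.
#' @param transform a [rigid_transform].
#' @return The moved copy of `x`.
#' @export
apply_transform <- function(x, transform) {
  if (!inherits(transform, "rigid_transform"))
    stop_denfit("`transform` must be a rigid_transform",
                "denfit_argument_error")
  tx <- function(xyz)
    sweep(xyz %*% t(transform$rotation), 2, -transform$translation)
  if (is.matrix(x)) return(tx(x))
  if (inherits(x, "bead_component")) return(set_bead_coords(x, tx(bead_coords(x))))
  if (inherits(x, "assembly")) {
    x$components <- lapply(x$components, apply_transform, transform)
    return(x)
  }
  stop_denfit("cannot transform this object", "denfit_argument_error")
}

## ---------------------------------------------------------------------------
## Flexible linkers
## ---------------------------------------------------------------------------

#' Build a flexible linker chain
#'
#' Places `n` beads with exact consecutive spacing `bond_length`, the first
#' bead at `start_anchor`. When `end_anchor` is given the chain is laid out
#' on a circular arc so that the last bead sits one bond length from the
#' end anchor (the attachment point of the downstream segment), i.e. the
#' anchors are bridged by exactly `n` bonds. Self-avoidance is not
#' enforced; clashes are handled by the scoring function.
#'
#' @param resid_range `c(start, end)` residue range (inclusive).
#' @param start_anchor position of the first bead (Å).
#' @param end_anchor optional downstream attachment point (Å).
#' @param bond_length bond length in Å; default 3.8 (C-alpha virtual bond).
#' @param radius bead radius (Å).
#' @param direction unit extension direction used when no end anchor is
#'   given.
#' @return A [bead_component] consisting of one flexible chain.
#' @export
build_linker <- function(resid_range, start_anchor, end_anchor = NULL,
                         bond_length = 3.8, radius = 3.5,
                         direction = c(1, 0, 0)) {
  n <- resid_range[2] - resid_range[1] + 1L
  if (n < 1) stop_denfit("empty residue range", "denfit_argument_error")
  if (is.null(end_anchor)) {
    u <- direction / sqrt(sum(direction^2))
    pos <- outer((seq_len(n) - 1) * bond_length, u) +
      matrix(start_anchor, n, 3, byrow = TRUE)
  } else {
    d <- sqrt(sum((end_anchor - start_anchor)^2))
    if (d > n * bond_length + 1e-9)
      stop_denfit(sprintf(
        "anchors %.2f A apart exceed the maximum span %d x %.2f = %.2f A",
        d, n, bond_length, n * bond_length), "denfit_geometry_error")
    pos <- arc_chain(start_anchor, end_anchor, n_bonds = n,
                     bond_length = bond_length)
  }
  bead_component("linker",
                 data.frame(resid = seq(resid_range[1], resid_range[2]),
                            x = pos[, 1], y = pos[, 2], z = pos[, 3],
                            radius = radius, flexible = TRUE))
}

# Points p_1..p_{n_bonds} on a circular arc from `a` to `b` such that
# |p_1 - a| is 0 (p_1 == a), consecutive points and the final hop to `b`
# all have length bond_length: n_bonds equal chords bridge a -> b.
arc_chain <- function(a, b, n_bonds, bond_length) {
  if (n_bonds == 1L) return(matrix(a, 1, 3))
  d <- sqrt(sum((b - a)^2))
  if (d >= n_bonds * bond_length * (1 - 1e-12)) {
    # fully extended: straight line
    u <- (b - a) / d
    return(outer((0:(n_bonds - 1)) * bond_length, u) +
             matrix(a, n_bonds, 3, byrow = TRUE))
  }
  # chord angle theta: sin(n*theta/2) / sin(theta/2) = d / bond_length
  upper <- 2 * pi / n_bonds
  if (d < 1e-9) {
    th <- upper
  } else {
    f <- function(th) sin(n_bonds * th / 2) / sin(th / 2) - d / bond_length
    th <- stats::uniroot(f, c(1e-9, upper - 1e-12), tol = 1e-14)$root
  }
  R <- bond_length / (2 * sin(th / 2))
  # arc plane: chord direction + a deterministic perpendicular
  u <- if (d > 1e-12) (b - a) / d else c(1, 0, 0)
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- ref - sum(ref * u) * u
  v <- v / sqrt(sum(v^2))
  # circle centre: on the perpendicular bisector of the chord in plane (u,v)
  h <- sqrt(max(R^2 - (d / 2)^2, 0))
  centre <- (a + b) / 2 + h * v
  ang0 <- atan2(sum((a - centre) * v), sum((a - centre) * u))
  ang1 <- atan2(sum((b - centre) * v), sum((b - centre) * u))
  # sweep from a to b through n_bonds chords of angle th each
  total <- n_bonds * th
  dir <- if (sin(ang1 - ang0) < 0) -1 else 1
  angs <- ang0 + dir * th * (0:(n_bonds - 1))
  # ensure we end next to b: recompute dir so that ang0 + dir*total == ang1 (mod 2pi)
  err1 <- abs(wrap_angle(ang0 + total - ang1))
  err2 <- abs(wrap_angle(ang0 - total - ang1))
  dir <- if (err1 <= err2) 1 else -1
  angs <- ang0 + dir * th * (0:(n_bonds - 1))
  t(vapply(angs, function(g) centre + R * (cos(g) * u + sin(g) * v),
           numeric(3)))
}

wrap_angle <- function(x) atan2(sin(x), cos(x))
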