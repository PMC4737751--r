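# Shared fixtures, built in code at test time.

# small deterministic density map with smooth structure
toy_map <- function(dims = c(16, 16, 16), voxel = 3, seed = 42) {
  set.seed(seed)
  ctrs <- matrix(runif(9, 10, dims[1] * voxel - 10), 3, 3)
  m <- simulate_map(ctrs, resolution = 4 * voxel, voxel_size = voxel,
                    padding = 0)
  # re-render on the exact requested grid
  g <- density_map(array(0, dims), voxel)
  simulate_map(ctrs, resolution = 4 * voxel, grid = g)
}

# random map with positive values
noise_map <- function(dims = c(16, 16, 16), voxel = 2, seed = 1) {
  set.seed(seed)
  density_map(array(runif(prod(dims)), dims), voxel)
}

# minimal two-component assembly in a box map, restraint-free
toy_assembly <- function(seed = 7, d = 12) {
  a <- make_component(20, "globular", seed = seed, id = "A")
  b <- make_component(16, "globular", seed = seed + 1, id = "B")
  b <- apply_transform(b, rigid_transform(diag(3), c(d, 0, 0)))
  map <- simulate_map(rbind(bead_coords(a), bead_coords(b)), 20,
                      voxel_size = 4, padding = 16)
  assembly(list(A = a, B = b), map = map)
}

# brute-force masked correlation oracle (triple loop)
cc_oracle <- function(a, b, mask = NULL, about_mean = FALSE) {
  dims <- dim(a)
  sa <- 0; sb <- 0; sab <- 0; n <- 0; ma <- 0; mb <- 0
  keep <- function(i, j, k) is.null(mask) || mask[i, j, k]
  if (about_mean) {
    for (i in 1:dims[1]) for (j in 1:dims[2]) for (k in 1:dims[3])
      if (keep(i, j, k)) {
        ma <- ma + a[i, j, k]; mb <- mb + b[i, j, k]; n <- n + 1
      }
    ma <- ma / n; mb <- mb / n
  }
  for (i in 1:dims[1]) for (j in 1:dims[2]) for (k in 1:dims[3])
    if (keep(i, j, k)) {
      x <- a[i, j, k] - ma; y <- b[i, j, k] - mb
      sa <- sa + x * x; sb <- sb + y * y; sab <- sab + x * y
    }
  sab / sqrt(sa * sb)
}

# brute-force all-pairs clash count oracle
clash_oracle <- function(assembly, overlap = 0.8) {
  xyz <- bead_coords(assembly)
  radii <- denfit:::bead_radii(assembly)
  comp <- rep(seq_along(assembly$components),
              vapply(assembly$components, function(c) nrow(c$beads), 0L))
  n <- nrow(xyz)
  count <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (comp[i] == comp[j]) next
    if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <
        (radii[i] + radii[j]) * overlap)
      count <- count + 1
  }
  count
}

# distance matrix hash for rigidity checks
dist_hash <- function(xyz) {
  d <- as.numeric(dist(xyz))
  round(sort(d), 6)
}

expect_same_coords <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(bead_coords(a) - bead_coords(b))), tol)
}

# an orientable component for pose-recovery tests: a rod with two unequal
# off-axis lumps, one at an end and one at the middle, so that no 180-degree
# flip maps the shape near-onto itself
asym_component <- function(seed = 2) {
  c1 <- make_component(70, "elongated", aspect = 4, seed = seed,
                       lobe_frac = 0, id = "X")
  x1 <- bead_coords(c1)
  c2 <- make_component(34, "globular", seed = seed + 1, lobe_frac = 0,
                       id = "Y")
  x2 <- sweep(bead_coords(c2), 2, -c(max(x1[, 1]), 12, 0))
  c3 <- make_component(16, "globular", seed = seed + 2, lobe_frac = 0,
                       id = "Z")
  x3 <- sweep(bead_coords(c3), 2, -c(0, -2, 14))
  coarse_grain(rbind(x1, x2, x3), "asym")
}

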