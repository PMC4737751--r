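# two beads on the x axis at a controllable separation
two_bead_assembly <- function(d, radius = 3.5, restraints = list()) {
  a <- coarse_grain(matrix(c(0, 0, 0), 1, 3), "A", radius = radius)
  b <- coarse_grain(matrix(c(d, 0, 0), 1, 3), "B", radius = radius)
  assembly(list(A = a, B = b), restraints = restraints)
}

test_that("the ccr4not_paper preset reproduces the published constraint set", {
  rs <- build_restraints("ccr4not_paper")
  expect_length(rs, 5)
  expect_equal(rs[[1]]$kind, "proximity")
  expect_equal(rs[[1]]$component_a, "Not4")
  expect_equal(rs[[1]]$range_a, c(16, 76))
  expect_equal(rs[[1]]$component_b, "Not1")
  expect_equal(rs[[1]]$range_b, c(1326, 2072))
  expect_equal(rs[[2]]$range_a, c(113, 200))
  expect_equal(rs[[2]]$range_b, c(1326, 2072))
  expect_equal(rs[[3]]$kind, "contact")
  expect_equal(rs[[3]]$component_a, "Mmi1")
  expect_equal(rs[[3]]$component_b, "Caf1")
  expect_null(rs[[3]]$range_a)
  expect_null(rs[[3]]$range_b)
  expect_equal(rs[[4]]$kind, "contact")
  expect_equal(rs[[4]]$component_a, "Mmi1")
  expect_equal(rs[[4]]$component_b, "Not1")
  expect_equal(rs[[4]]$range_b, c(1, 1200))
  expect_equal(rs[[5]]$kind, "connectivity")
  expect_equal(rs[[5]]$component_a, "Not1")
  # declared-component validation
  expect_error(build_restraints("ccr4not_paper",
                                components = c("Not1", "Not4")),
               "Mmi1", class = "denfit_config_error")
  expect_identical(build_restraints(list()), list())
  expect_error(build_restraints(list(list(kind = "contact",
                                          component_a = "Xyz",
                                          component_b = "Not1")),
                                components = "Not1"),
               "Xyz", class = "denfit_config_error")
  expect_error(build_restraints("no_such_preset"),
               class = "denfit_config_error")
})

test_that("restraint penalties are zero iff satisfied and grow continuously", {
  # contact: two touching beads within any positive cutoff
  r5 <- restraint("contact", "A", "B", cutoff = 5)
  expect_equal(restraint_penalty(two_bead_assembly(7), r5), 0)
  # surface distance 12 with cutoff 5 -> penalty 7
  expect_equal(restraint_penalty(two_bead_assembly(12 + 7), r5), 7)
  # proximity on centroids
  rp <- restraint("proximity", "A", "B", cutoff = 15)
  expect_equal(restraint_penalty(two_bead_assembly(10), rp), 0)
  expect_equal(restraint_penalty(two_bead_assembly(25), rp), 10)
  # sweep: non-decreasing in the violating distance, zero exactly inside
  dists <- seq(1, 40, by = 0.5)
  pen_c <- vapply(dists, function(d)
    restraint_penalty(two_bead_assembly(d), r5), 0)
  expect_true(all(diff(pen_c) >= 0))
  expect_true(all(pen_c[dists <= 12] == 0))
  expect_true(all(pen_c[dists > 12] > 0))
  pen_p <- vapply(dists, function(d)
    restraint_penalty(two_bead_assembly(d), rp), 0)
  expect_true(all(pen_p[dists <= 15] == 0))
  expect_true(all(pen_p[dists > 15] > 0))
})

test_that("connectivity penalizes segments further than the linker can span", {
  mk <- function(gap) {
    beads <- data.frame(
      resid = c(1:3, 7:9),
      x = c(0, 3.8, 7.6, 7.6 + gap, 11.4 + gap, 15.2 + gap),
      y = 0, z = 0, radius = 3.5, flexible = FALSE)
    assembly(list(N = bead_component("N", beads, seq_length = 9)),
             restraints = list(restraint("connectivity", "N")))
  }
  rc <- restraint("connectivity", "N")
  # 3 intervening residues allow 4 bonds = 15.2 A
  expect_equal(restraint_penalty(mk(10), rc), 0)
  expect_equal(restraint_penalty(mk(15.2), rc), 0)
  expect_equal(restraint_penalty(mk(20), rc), 20 - 15.2, tolerance = 1e-9)
})

test_that("grid clash count equals brute-force enumeration exactly", {
  # controlled cases
  expect_equal(clash_count(two_bead_assembly(500)), 0)
  expect_equal(clash_count(two_bead_assembly(0)), 1)  # coincident beads
  expect_equal(clash_count(two_bead_assembly(5.59)), 1)
  expect_equal(clash_count(two_bead_assembly(5.61)), 0)
  # random assemblies, several grid sizes
  set.seed(41)
  for (rep in 1:3) {
    comps <- lapply(1:4, function(i)
      coarse_grain(matrix(runif(150, 0, 40), 50, 3), paste0("c", i)))
    names(comps) <- paste0("c", 1:4)
    asm <- assembly(comps)
    oracle <- clash_oracle(asm)
    expect_identical(clash_count(asm, grid_size = 1.5), oracle)
    expect_identical(clash_count(asm, grid_size = 4), oracle)
  }
})

test_that("composite score combines terms with the documented signs", {
  tr <- make_truth_assembly(list(list(id = "A", n = 30, arm = 1),
                                 list(id = "B", n = 24, arm = 2)),
                            noise = 0, seed = 5)
  sc <- composite_score(tr$assembly)
  # truth: inside the envelope, clash-free -> only the fill reward
  expect_equal(sc$outbox, 0)
  expect_equal(sc$clash, 0)
  expect_equal(sc$restraint, 0)
  expect_lt(sc$total, 0)
  expect_equal(sc$total,
               with(sc, weights$w_out * outbox + weights$w_clash * clash +
                      weights$w_rest * restraint - weights$w_fill * fill))
  expect_equal(sc$score, -sc$total)
  # moving a component out of the map strictly worsens the total
  out <- tr$assembly
  out$components$B <- apply_transform(out$components$B,
                                      rigid_transform(diag(3), c(500, 0, 0)))
  sc_out <- composite_score(out)
  expect_gt(sc_out$total, sc$total)
  expect_equal(sc_out$outbox,
               nrow(out$components$B$beads) /
                 (nrow(out$components$A$beads) +
                    nrow(out$components$B$beads)))
  # fully outside: outbox = 1
  far <- tr$assembly
  for (id in names(far$components))
    far$components[[id]] <- apply_transform(far$components[[id]],
                                            rigid_transform(diag(3),
                                                            c(900, 0, 0)))
  expect_equal(composite_score(far)$outbox, 1)
  # no map attached -> state error
  nomap <- assembly(tr$assembly$components)
  expect_error(composite_score(nomap), class = "denfit_state_error")
})

test_that("composite score is invariant under component relabeling", {
  tr <- make_truth_assembly(list(list(id = "A", n = 30, arm = 1),
                                 list(id = "B", n = 24, arm = 2)),
                            noise = 0, seed = 5)
  asm <- tr$assembly
  flipped <- asm
  flipped$components <- rev(asm$components)
  s1 <- composite_score(asm)
  s2 <- composite_score(flipped)
  expect_equal(s1$total, s2$total, tolerance = 1e-12)
  expect_equal(s1$clash, s2$clash)
  expect_equal(s1$fill, s2$fill, tolerance = 1e-12)
})

test_that("the ground truth scores better than random placements", {
  tr <- suppressWarnings(make_benchmark("two_body_toy", seed = 2))
  truth_e <- composite_score(tr$assembly)$total
  set.seed(99)
  worse <- 0
  for (i in 1:100) {
    rnd <- initial_positions(tr$assembly, "random_in_volume")
    if (composite_score(rnd)$total > truth_e) worse <- worse + 1
  }
  expect_gte(worse, 95)
})
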