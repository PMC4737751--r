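# tiny ensemble with controllable coordinates and energies
fake_ensemble <- function(coords_list, energies, seeds = seq_along(energies)) {
  base <- toy_assembly()
  results <- lapply(seq_along(coords_list), function(i) {
    m <- base
    shift <- coords_list[[i]]
    for (id in names(m$components))
      m$components[[id]] <- apply_transform(m$components[[id]],
                                            rigid_transform(diag(3), shift))
    sc <- list(total = energies[i], score = -energies[i])
    list(final = m, final_score = sc, best = m, best_score = sc,
         seed = seeds[i], accepted = 0L,
         trace = data.frame(step = 0, temperature = 10,
                            total = energies[i]))
  })
  structure(list(results = results, seeds = seeds), class = "model_ensemble")
}

test_that("model RMSD matches its closed form and brute-force sum", {
  asm <- toy_assembly()
  expect_equal(model_rmsd(asm, asm), 0)
  # one bead displaced by 3 A -> 3 / sqrt(N)
  n <- sum(vapply(asm$components, function(c) nrow(c$beads), 0L))
  one <- asm
  xyz <- bead_coords(one$components$A)
  xyz[1, 1] <- xyz[1, 1] + 3
  one$components$A <- denfit:::set_bead_coords(one$components$A, xyz)
  expect_equal(model_rmsd(asm, one), 3 / sqrt(n), tolerance = 1e-12)
  # random displacement: direct per-bead summation oracle
  set.seed(21)
  rnd <- asm
  for (id in names(rnd$components)) {
    x <- bead_coords(rnd$components[[id]]) + matrix(rnorm(60, 0, 2), 20)[
      seq_len(nrow(rnd$components[[id]]$beads)), ]
    rnd$components[[id]] <- denfit:::set_bead_coords(rnd$components[[id]], x)
  }
  xa <- bead_coords(asm); xb <- bead_coords(rnd)
  oracle <- sqrt(sum((xa - xb)^2) / nrow(xa))
  expect_equal(model_rmsd(asm, rnd), oracle, tolerance = 1e-10)
  # roster mismatch is an error
  other <- asm
  other$components$A$beads <- other$components$A$beads[-1, ]
  expect_error(model_rmsd(asm, other), class = "denfit_argument_error")
})

test_that("pairwise RMSD matrices are metric-like", {
  set.seed(22)
  shifts <- lapply(1:6, function(i) rnorm(3, 0, 10))
  en <- rnorm(6)
  e <- fake_ensemble(shifts, en)
  models <- lapply(e$results, function(r) r$best)
  rm <- rmsd_matrix(models)
  expect_equal(rm, t(rm))
  expect_true(all(diag(rm) == 0))
  for (i in 1:6) for (j in 1:6) for (k in 1:6)
    expect_lte(rm[i, k], rm[i, j] + rm[j, k] + 1e-9)
})

test_that("select_top keeps the best energies with seed tie-breaks", {
  e <- fake_ensemble(lapply(1:3, function(i) c(i, 0, 0)), c(5, 1, 3))
  top2 <- select_top(e, 2)
  expect_equal(sort(vapply(top2$results, function(r) r$best_score$total, 0)),
               c(1, 3))
  expect_error(select_top(e, 0), class = "denfit_argument_error")
  expect_error(select_top(e, 4), class = "denfit_argument_error")
  # identity at k = n
  expect_length(select_top(e, 3)$results, 3)
  # random scores: equals a sort oracle; selected never worse than excluded
  set.seed(23)
  en <- rnorm(50)
  e50 <- fake_ensemble(lapply(1:50, function(i) rnorm(3)), en)
  top <- select_top(e50, 10)
  sel <- vapply(top$results, function(r) r$best_score$total, 0)
  expect_equal(sort(sel), sort(en)[1:10])
  expect_lte(max(sel), min(setdiff(en, sel)))
})

test_that("complete-linkage clustering separates well-separated groups", {
  # two tight groups of 3, far apart
  shifts <- c(lapply(1:3, function(i) c(0, 0, i * 0.5)),
              lapply(1:3, function(i) c(120, 0, i * 0.5)))
  e <- fake_ensemble(shifts, rnorm(6))
  cl <- cluster_models(e, rmsd_threshold = 20)
  expect_length(cl, 2)
  expect_setequal(lengths(lapply(cl, function(c) c$members)), c(3, 3))
  # every model in exactly one cluster
  expect_setequal(unlist(lapply(cl, function(c) c$members)), 1:6)
  # infinite threshold: one cluster holds everything
  cl1 <- cluster_models(e, rmsd_threshold = Inf)
  expect_length(cl1, 1)
  expect_length(cl1[[1]]$members, 6)
  # single model: one singleton
  cls <- cluster_models(fake_ensemble(list(c(0, 0, 0)), 0), 10)
  expect_length(cls, 1)
  expect_equal(cls[[1]]$members, 1L)
  expect_equal(cls[[1]]$representative, 1L)
  # representative is the best-scored member
  en <- c(3, 1, 2, 9, 8, 7)
  e2 <- fake_ensemble(shifts, en)
  cl2 <- cluster_models(e2, 20)
  g1 <- cl2[[which(vapply(cl2, function(c) 2 %in% c$members, TRUE))]]
  expect_equal(g1$representative, 2L)
  # relabeling models yields the same partition as sets
  perm <- c(4L, 1L, 5L, 2L, 6L, 3L)
  e3 <- fake_ensemble(shifts[perm], en[perm])
  cl3 <- cluster_models(e3, 20)
  part <- function(cl, key) {
    sets <- lapply(cl, function(c) sort(key[c$members]))
    sets[order(vapply(sets, function(s) s[1], 0))]
  }
  expect_identical(part(cl2, seq_along(shifts)), part(cl3, perm))
})

test_that("exposure fractions reflect foreign-bead burial", {
  # two distant components: everything exposed
  asm <- toy_assembly(d = 500)
  expect_equal(exposure_fraction(asm, list(component = "A", range = NULL)), 1)
  expect_equal(exposure_fraction(asm, list(component = "B", range = NULL)), 1)
  # a bead fully enclosed by a dense foreign shell is buried
  centre <- coarse_grain(matrix(0, 1, 3), "core")
  dirs <- expand.grid(u = seq(0, pi, length.out = 5),
                      v = seq(0, 2 * pi, length.out = 8))
  shell_pts <- unique(round(cbind(4 * sin(dirs$u) * cos(dirs$v),
                                  4 * sin(dirs$u) * sin(dirs$v),
                                  4 * cos(dirs$u)), 6))
  shell <- coarse_grain(shell_pts, "shell")
  buried <- assembly(list(core = centre, shell = shell))
  expect_equal(exposure_fraction(buried,
                                 list(component = "core", range = NULL),
                                 neighbor_cutoff = 6,
                                 buriedness_threshold = 8), 0)
})

test_that("filtering keeps clusters whose representatives stay exposed", {
  shifts <- c(lapply(1:2, function(i) c(0, 0, i * 0.2)),
              lapply(1:2, function(i) c(100, 0, i * 0.2)))
  e <- fake_ensemble(shifts, c(1, 2, 3, 4))
  cl <- cluster_models(e, 20)
  # no required selections: everything passes
  all_pass <- filter_clusters(cl, e, exposure_spec(list()))
  expect_true(all(vapply(all_pass, function(c) c$passes_filter, TRUE)))
  # required fraction 0 passes vacuously
  spec0 <- exposure_spec(list(s = list(component = "A", range = NULL)),
                         required_fraction = 0)
  expect_true(all(vapply(filter_clusters(cl, e, spec0),
                         function(c) c$passes_filter, TRUE)))
  # adversarial: bury the required A surface in one cluster's
  # representative by piling all of B onto it (same roster, new coords)
  e_bad <- e
  m <- e_bad$results[[1]]$best
  xa <- bead_coords(m$components$A)
  target <- (xa[1, ] + xa[2, ]) / 2
  set.seed(31)
  nb <- nrow(m$components$B$beads)
  pile <- sweep(matrix(rnorm(3 * nb, 0, 1.5), nb, 3), 2, -target)
  m$components$B <- denfit:::set_bead_coords(m$components$B, pile)
  sc <- list(total = -10, score = 10)
  e_bad$results[[1]] <- list(final = m, final_score = sc, best = m,
                             best_score = sc, seed = 1, accepted = 0L,
                             trace = e$results[[1]]$trace)
  sel_range <- m$components$A$beads$resid[1:2]
  spec <- exposure_spec(list(s = list(component = "A", range = sel_range)),
                        neighbor_cutoff = 6, buriedness_threshold = 8,
                        required_fraction = 0.5)
  cl_bad <- cluster_models(e_bad, 20)
  res <- filter_clusters(cl_bad, e_bad, spec)
  has1 <- vapply(res, function(c) 1 %in% c$members, TRUE)
  expect_false(res[[which(has1)]]$passes_filter)
  expect_true(all(vapply(res[!has1], function(c) c$passes_filter, TRUE)))
})

test_that("the representative is the best-scored model of the passing clusters", {
  tr <- make_truth_assembly(list(list(id = "A", n = 30, arm = 1),
                                 list(id = "B", n = 24, arm = 2)),
                            noise = 0, seed = 5)
  # self-fit: a singleton cluster holding the truth reproduces cc = 1 when
  # the map is the plain rendering of the model itself
  plain <- make_truth_assembly(list(list(id = "A", n = 30, arm = 1),
                                    list(id = "B", n = 24, arm = 2)),
                               noise = 0, seed = 5, envelope = "plain")
  e <- fake_ensemble(list(c(0, 0, 0)), 0)
  e$results[[1]]$best <- plain$assembly
  e$results[[1]]$final <- plain$assembly
  cl <- cluster_models(e, 10)
  cl[[1]]$passes_filter <- TRUE
  out <- representative_and_cc(cl, e, plain$map,
                               resolution = plain$params$resolution,
                               threshold = 0.7, threshold_mode = "absolute")
  expect_equal(out$cc, 1, tolerance = 1e-9)
  # two passing clusters: the lower-energy representative wins
  shifts <- list(c(0, 0, 0), c(60, 0, 0))
  e2 <- fake_ensemble(shifts, c(2, 1))
  cl2 <- cluster_models(e2, 10)
  cl2 <- lapply(cl2, function(c) { c$passes_filter <- TRUE; c })
  out2 <- representative_and_cc(cl2, e2, tr$map, threshold_mode = "absolute")
  expect_equal(out2$model_index,
               which(vapply(e2$results, function(r) r$best_score$total, 0) == 1))
  # no passing cluster: empty result with diagnostics, not an exception
  cl3 <- lapply(cl2, function(c) { c$passes_filter <- FALSE; c })
  out3 <- representative_and_cc(cl3, e2, tr$map)
  expect_null(out3$model)
  expect_true(is.na(out3$cc))
  expect_length(out3$diagnostics, length(cl3))
})
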