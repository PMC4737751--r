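test_that("MRC round trip reproduces grid, voxel size and origin exactly", {
  m <- density_map(array(as.numeric(0:7), c(2, 2, 2)), voxel = 3,
                   origin = c(-4, 2.5, 11))
  f <- tempfile(fileext = ".mrc")
  write_map(m, f)
  m2 <- read_map(f)
  expect_identical(dim(m2$data), dim(m$data))
  expect_identical(as.numeric(m2$data), as.numeric(m$data))
  expect_equal(m2$voxel, 3)
  expect_equal(m2$origin, c(-4, 2.5, 11))
  # values voxel by voxel, in the same axis order
  for (i in 1:2) for (j in 1:2) for (k in 1:2)
    expect_identical(m2$data[i, j, k], m$data[i, j, k])
  # second round trip is bit-exact even for non-representable doubles
  r <- noise_map(c(4, 3, 5), voxel = 1.5, seed = 3)
  f2 <- tempfile(fileext = ".mrc")
  write_map(r, f2)
  r1 <- read_map(f2)
  write_map(r1, f2)
  expect_identical(read_map(f2)$data, r1$data)
})

test_that("MRC header carries cell dimensions and an all-zero map reads back", {
  m <- density_map(array(0, c(4, 5, 6)), voxel = 3)
  f <- tempfile(fileext = ".mrc")
  write_map(m, f)
  con <- file(f, "rb")
  hdr <- readBin(con, "integer", n = 16, size = 4, endian = "little")
  seek(con, 0)
  hdrf <- readBin(con, "numeric", n = 16, size = 4, endian = "little")
  close(con)
  expect_identical(hdr[1:3], c(4L, 5L, 6L))
  expect_equal(hdrf[11:13], 3 * c(4, 5, 6))  # CELLA = voxel * shape
  m2 <- read_map(f)
  expect_identical(range(m2$data), c(0, 0))
})

test_that("malformed MRC files raise format errors naming the problem", {
  f <- tempfile(fileext = ".mrc")
  writeBin(raw(100), f)
  expect_error(read_map(f), "1024", class = "denfit_format_error")
  # truncated data block
  m <- density_map(array(1, c(8, 8, 8)), voxel = 2)
  write_map(m, f)
  sz <- file.size(f)
  con <- file(f, "rb"); full <- readBin(con, "raw", sz); close(con)
  writeBin(full[1:(sz - 100)], f)
  expect_error(read_map(f), "runcated", class = "denfit_format_error")
  # non-isotropic voxels are rejected, not resampled
  bad <- full
  con <- rawConnection(raw(0), "w")
  writeBin(as.numeric(17), con, size = 4, endian = "little")
  cell <- rawConnectionValue(con); close(con)
  bad[41:44] <- cell  # CELLA x (word 11)
  writeBin(bad, f)
  expect_error(read_map(f), "isotropic", class = "denfit_format_error")
})

test_that("a map written here is readable by an independent MRC reader", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  m <- density_map(array(as.numeric(1:24), c(2, 3, 4)), voxel = 2.5,
                   origin = c(1, 2, 3))
  f <- tempfile(fileext = ".mrc")
  write_map(m, f)
  script <- tempfile(fileext = ".py")
  writeLines(c("import gemmi",
               sprintf("m = gemmi.read_ccp4_map('%s')", f),
               "g = m.grid",
               "print(g.nu, g.nv, g.nw, round(g.spacing[0], 6),",
               "      g.get_value(1, 2, 3))"), script)
  out <- suppressWarnings(system2("python", script, stdout = TRUE,
                                  stderr = TRUE))
  skip_if(!is.null(attr(out, "status")) && attr(out, "status") != 0,
          "gemmi unavailable")
  parts <- strsplit(out[length(out)], " ")[[1]]
  expect_equal(as.integer(parts[1:3]), c(2L, 3L, 4L))
  expect_equal(as.numeric(parts[4]), 2.5)
  expect_equal(as.numeric(parts[5]), m$data[2, 3, 4])
})

test_that("simulate_map renders normalized Gaussians at the bead positions", {
  one <- matrix(c(10, 12, 14), 1, 3)
  m <- simulate_map(one, resolution = 12, voxel_size = 2, padding = 14)
  expect_equal(max(m$data), 1)
  peak <- arrayInd(which.max(m$data), dim(m$data))
  peak_pos <- m$origin + (peak - 1) * m$voxel
  expect_lt(sqrt(sum((peak_pos - one)^2)), m$voxel * sqrt(3) / 2 + 1e-9)
  # two identical beads far apart -> two equal local maxima
  two <- rbind(c(0, 0, 0), c(200, 0, 0))
  m2 <- simulate_map(two, resolution = 20, voxel_size = 5, padding = 25)
  v1 <- max(m2$data[m2$origin[1] + (seq_len(dim(m2$data)[1]) - 1) * 5 < 100, , ])
  v2 <- max(m2$data[m2$origin[1] + (seq_len(dim(m2$data)[1]) - 1) * 5 > 100, , ])
  expect_equal(v1, v2, tolerance = 1e-9)
  expect_equal(v1, 1)
  # integrated density matches the closed-form Gaussian integral
  sigma <- 12 / (2 * sqrt(2 * log(2)))
  total <- sum(m$data) * m$voxel^3
  expect_equal(total, (2 * pi)^(3 / 2) * sigma^3, tolerance = 0.01)
  expect_error(simulate_map(matrix(0, 0, 3), 12, 2),
               class = "denfit_argument_error")
})

test_that("threshold_mask matches direct enumeration and both modes work", {
  # uniform positive map: every voxel reaches any threshold <= 1
  u <- density_map(array(5, c(3, 3, 3)), 1)
  expect_true(all(threshold_mask(u, 0.7)$mask))
  # binary map at 0.7 keeps exactly the ones
  b <- density_map(array(rep(c(0, 1), 8)[1:8], c(2, 2, 2)), 1)
  expect_identical(threshold_mask(b, 0.7)$mask, b$data == 1)
  # linear ramp: count equals direct enumeration
  ramp <- density_map(array(seq(0, 1, length.out = 100), c(100, 1, 1)), 2)
  mk <- threshold_mask(ramp, 0.7)
  expect_identical(sum(mk$mask), sum(ramp$data >= 0.7))
  expect_true(sum(mk$mask) %in% c(30L, 31L))
  # absolute mode compares raw values
  half <- density_map(array(c(rep(0.4, 50), rep(2, 50)), c(100, 1, 1)), 1)
  expect_identical(sum(threshold_mask(half, 0.7, "absolute")$mask), 50L)
  expect_error(threshold_mask(density_map(array(0, c(2, 2, 2)), 1)),
               class = "denfit_degenerate_map_error")
})

test_that("threshold_mask voxel count is non-increasing in the threshold", {
  m <- noise_map(c(12, 12, 12), seed = 5)
  counts <- vapply(seq(0.1, 1, by = 0.1),
                   function(t) sum(threshold_mask(m, t)$mask), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("cross_correlation equals the brute-force oracle and is well-behaved", {
  a <- noise_map(seed = 11)
  b <- noise_map(seed = 12)
  mask <- threshold_mask(a, 0.5)
  expect_equal(cross_correlation(a, b), cc_oracle(a$data, b$data),
               tolerance = 1e-10)
  expect_equal(cross_correlation(a, b, mask),
               cc_oracle(a$data, b$data, mask$mask), tolerance = 1e-10)
  expect_equal(cross_correlation(a, b, mask, about_mean = TRUE),
               cc_oracle(a$data, b$data, mask$mask, about_mean = TRUE),
               tolerance = 1e-10)
  # identity, symmetry, positive-scale invariance
  expect_equal(cross_correlation(a, a), 1)
  expect_equal(cross_correlation(a, b), cross_correlation(b, a))
  a3 <- density_map(a$data * 3.7, a$voxel, a$origin)
  expect_equal(cross_correlation(a3, b), cross_correlation(a, b),
               tolerance = 1e-12)
  # anti-correlation after mean subtraction
  neg <- density_map(-(a$data - mean(a$data)) + 2, a$voxel, a$origin)
  expect_equal(cross_correlation(a, neg, about_mean = TRUE), -1,
               tolerance = 1e-9)
  expect_error(cross_correlation(a, noise_map(c(8, 8, 8))),
               class = "denfit_argument_error")
  zero <- density_map(array(0, dim(a$data)), a$voxel)
  expect_error(cross_correlation(a, zero),
               class = "denfit_undefined_correlation_error")
})

test_that("FSC of a map with itself is 1 and resolution flags Nyquist", {
  m <- toy_map()
  r <- fsc_resolution(m, m)
  expect_true(all(abs(r$curve$correlations - 1) < 1e-9))
  expect_true(r$never_crossed)
  expect_equal(r$resolution, 2 * m$voxel)
  expect_true(all(diff(r$curve$shell_frequencies) > 0))
})

test_that("independent white-noise maps decorrelate across shells", {
  a <- noise_map(c(64, 64, 64), voxel = 2, seed = 21)
  b <- noise_map(c(64, 64, 64), voxel = 2, seed = 22)
  r <- fsc_resolution(a, b)
  # skip the DC shell, which only sees the (correlated) positive means
  expect_lt(mean(abs(r$curve$correlations[-1])), 0.1)
  expect_true(all(r$curve$correlations >= -1 & r$curve$correlations <= 1))
})

test_that("FSC resolution of a noised phantom pair matches a shell-loop oracle", {
  ph <- toy_map(c(24, 24, 24), voxel = 4, seed = 31)
  set.seed(32)
  n1 <- density_map(ph$data + array(rnorm(length(ph$data), 0, 0.12),
                                    dim(ph$data)), ph$voxel)
  n2 <- density_map(ph$data + array(rnorm(length(ph$data), 0, 0.12),
                                    dim(ph$data)), ph$voxel)
  r <- fsc_resolution(n1, n2)
  # brute-force shell sums over explicit frequency loops
  dims <- dim(ph$data)
  fa <- fft(n1$data); fb <- fft(n2$data)
  df <- 1 / (min(dims) * ph$voxel)
  nshell <- floor(min(dims) / 2) + 1
  num <- numeric(nshell); pa <- numeric(nshell); pb <- numeric(nshell)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      kk <- c(i, j, k) - 1
      kk <- ifelse(kk > dims / 2, kk - dims, kk)
      s <- round(sqrt(sum((kk / dims / ph$voxel)^2)) / df) + 1
      if (s > nshell) next
      num[s] <- num[s] + Re(fa[i, j, k] * Conj(fb[i, j, k]))
      pa[s] <- pa[s] + Mod(fa[i, j, k])^2
      pb[s] <- pb[s] + Mod(fb[i, j, k])^2
    }
  corr <- num / sqrt(pa * pb)
  below <- which(corr < 0.5)
  i <- below[1]
  f1 <- (i - 2) * df; f2 <- (i - 1) * df
  fstar <- f1 + (corr[i - 1] - 0.5) / (corr[i - 1] - corr[i]) * (f2 - f1)
  oracle_res <- 1 / fstar
  expect_false(r$never_crossed)
  expect_lt(abs(1 / r$resolution - 1 / oracle_res), r$curve$shell_width)
})
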