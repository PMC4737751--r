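#' Construct a density map
#'
#' A `density_map` is a 3D voxel grid of density values together with the
#' physical voxel edge length and the position of voxel (1,1,1) in
#' angstroms. The grid is stored as an array indexed `[x, y, z]` with x the
#' fastest-varying axis, matching the on-disk layout of MRC/CCP4 maps
#' written with the canonical axis order.
#'
#' @param data numeric 3D array of density values.
#' @param voxel voxel edge length in angstrom (isotropic, > 0).
#' @param origin numeric length-3: position of the first voxel centre (Å).
#' @return An object of class `density_map`.
#' @export
density_map <- function(data, voxel, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_denfit("`data` must be a 3D array", "denfit_argument_error")
  if (!is_scalar_number(voxel) || voxel <= 0)
    stop_denfit("`voxel` must be a positive number", "denfit_argument_error")
  if (length(origin) != 3L || !all(is.finite(origin)))
    stop_denfit("`origin` must be 3 finite numbers", "denfit_argument_error")
  if (!all(is.finite(data)))
    stop_denfit("map values must all be finite", "denfit_argument_error")
  structure(
    list(data = data, voxel = as.numeric(voxel),
         origin = as.numeric(origin)),
    class = "density_map"
  )
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("density_map: %d x %d x %d voxels, %.3f A/voxel\n",
              d[1], d[2], d[3], x$voxel))
  cat(sprintf("  origin (A): %.2f %.2f %.2f\n",
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  density: min %.4g  max %.4g  mean %.4g\n",
              min(x$data), max(x$data), mean(x$data)))
  invisible(x)
}

# physical coordinates of voxel centres along one axis
map_axis <- function(map, axis) {
  map$origin[axis] + (seq_len(dim(map$data)[axis]) - 1) * map$voxel
}

same_grid <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    isTRUE(all.equal(a$voxel, b$voxel, tolerance = 1e-9))
}

## ---------------------------------------------------------------------------
## MRC2014 input / output
## ---------------------------------------------------------------------------

#' Read an MRC/CCP4 density map
#'
#' Reads MRC2014/CCP4 volume files (modes 0, 1 and 2). Axis-order
#' permutations declared in the header (`MAPC`/`MAPR`/`MAPS`) are
#' normalized so the returned grid is always indexed `[x, y, z]`.
#' Non-isotropic voxel spacing is rejected (relative tolerance 1e-3)
#' rather than resampled.
#'
#' @param path path to an MRC/CCP4 file.
#' @return A [density_map].
#' @export
read_map <- function(path) {
  if (!file.exists(path))
    stop_denfit(paste0("no such map file: ", path), "denfit_input_error")
  con <- file(path, "rb")
  on.exit(close(con))
  fsize <- file.size(path)
  if (fsize < 1024)
    stop_denfit("malformed MRC header: file shorter than 1024 bytes",
                "denfit_format_error")
  hdr_int <- readBin(con, "integer", n = 256, size = 4, endian = "little")
  seek(con, 0)
  hdr_dbl <- readBin(con, "numeric", n = 256, size = 4, endian = "little")
  seek(con, 208)
  magic <- readBin(con, "raw", n = 4)
  if (!identical(magic[1:3], charToRaw("MAP")))
    stop_denfit("malformed MRC header: missing 'MAP ' magic (word 53)",
                "denfit_format_error")
  nc <- hdr_int[1]; nr <- hdr_int[2]; ns <- hdr_int[3]
  mode <- hdr_int[4]
  if (any(c(nc, nr, ns) < 1))
    stop_denfit("malformed MRC header: non-positive dimensions (NX/NY/NZ)",
                "denfit_format_error")
  mxyz <- hdr_int[8:10]
  cella <- hdr_dbl[11:13]
  mapcrs <- hdr_int[17:19]
  if (!setequal(mapcrs, 1:3))
    stop_denfit("malformed MRC header: MAPC/MAPR/MAPS is not a permutation of 1,2,3",
                "denfit_format_error")
  nsymbt <- hdr_int[24]
  vox <- cella / mxyz
  if (any(!is.finite(vox)) || any(vox <= 0))
    stop_denfit("malformed MRC header: CELLA/MX give non-positive voxel size",
                "denfit_format_error")
  if (max(vox) - min(vox) > 1e-3 * mean(vox))
    stop_denfit(sprintf(
      "non-isotropic voxel spacing in CELLA: %.4f %.4f %.4f A (tolerance 1e-3 relative)",
      vox[1], vox[2], vox[3]), "denfit_format_error")
  n <- as.numeric(nc) * nr * ns
  bytes_per <- c(`0` = 1, `1` = 2, `2` = 4)[as.character(mode)]
  if (is.na(bytes_per))
    stop_denfit(sprintf("unsupported MRC MODE %d (modes 0, 1, 2 supported)", mode),
                "denfit_format_error")
  if (fsize < 1024 + nsymbt + n * bytes_per)
    stop_denfit("truncated MRC file: data block shorter than NX*NY*NZ values",
                "denfit_format_error")
  seek(con, 1024 + nsymbt)
  vals <- if (mode == 2) {
    readBin(con, "numeric", n = n, size = 4, endian = "little")
  } else {
    readBin(con, "integer", n = n, size = bytes_per, signed = TRUE,
            endian = "little")
  }
  arr <- array(as.numeric(vals), dim = c(nc, nr, ns))
  # normalize axis order: position of axis a within (mapc, mapr, maps)
  perm <- match(1:3, mapcrs)
  if (!identical(perm, 1:3)) arr <- aperm(arr, perm)
  # MRC2014 origin word (49:51 as floats) takes precedence; fall back to
  # NXSTART offsets when it is all zero (classic CCP4 convention).
  orig <- hdr_dbl[50:52]
  if (all(orig == 0)) {
    nstart <- hdr_int[5:7][perm]
    orig <- nstart * mean(vox)
  }
  density_map(arr, voxel = mean(vox), origin = orig)
}

#' Write a density map as MRC2014
#'
#' Writes mode-2 (float32) MRC2014 with canonical axis order, so that
#' `read_map(write_map(m, f))` reproduces `m` exactly and standard viewers
#' can open the file. Masks can be written by passing a `volume_mask`
#' (stored as values 0/1).
#'
#' @param map a [density_map] (or [threshold_mask] result).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  if (inherits(map, "volume_mask"))
    map <- density_map(array(as.numeric(map$mask), dim(map$mask)),
                       map$voxel, map$origin)
  if (!inherits(map, "density_map"))
    stop_denfit("`map` must be a density_map", "denfit_argument_error")
  con <- tryCatch(file(path, "wb"), condition = function(e)
    stop_denfit(paste0("cannot open for writing: ", path), "denfit_io_error"))
  on.exit(close(con))
  d <- dim(map$data)
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                          # NX NY NZ
  wi(2)                          # MODE 2: float32
  wi(c(0, 0, 0))                 # NXSTART..
  wi(d)                          # MX MY MZ
  wf(d * map$voxel)              # CELLA
  wf(c(90, 90, 90))              # CELLB
  wi(1:3)                        # MAPC MAPR MAPS
  wf(c(min(map$data), max(map$data), mean(map$data)))
  wi(1)                          # ISPG: 3D volume
  wi(0)                          # NSYMBT
  extra <- integer(25)           # EXTRA (words 25..49)
  extra[4] <- 20140L             # NVERSION (word 28)
  wi(extra)
  wf(map$origin)                 # ORIGIN (words 50..52)
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wf(sd(as.numeric(map$data)))   # RMS
  wi(1)                          # NLABL
  lab <- charToRaw(sprintf("%-80s", "denfit map"))
  writeBin(lab, con)
  writeBin(raw(800 - length(lab)), con)
  wf(as.numeric(map$data))
  invisible(path)
}

## ---------------------------------------------------------------------------
## Map simulation, thresholding, correlation
## ---------------------------------------------------------------------------

fwhm_to_sigma <- function(resolution) resolution / (2 * sqrt(2 * log(2)))

#' Simulate a density map from bead coordinates
#'
#' Every bead contributes an isotropic Gaussian whose FWHM equals the
#' nominal resolution (sigma = resolution / 2.3548); the summed map is
#' normalized to maximum 1. This is the rendering used both for
#' model-to-map correlation and for building synthetic benchmark maps.
#'
#' @param beads an n x 3 coordinate matrix (Å), or anything
#'   [bead_coords()] understands (component, assembly).
#' @param resolution nominal resolution in Å (>= 2 * voxel_size).
#' @param voxel_size voxel edge in Å.
#' @param padding padding added around the bead bounding box (Å).
#' @param grid optional [density_map] whose grid (dims, voxel, origin) the
#'   rendering should reuse; overrides `voxel_size`/`padding`.
#' @return A [density_map] with maximum exactly 1.
#' @export
simulate_map <- function(beads, resolution, voxel_size = resolution / 4,
                         padding = resolution, grid = NULL) {
  xyz <- bead_coords(beads)
  if (nrow(xyz) < 1L)
    stop_denfit("at least one bead is required", "denfit_argument_error")
  if (is.null(grid)) {
    if (resolution < 2 * voxel_size)
      stop_denfit("resolution must be >= 2 * voxel_size",
                  "denfit_argument_error")
    lo <- apply(xyz, 2, min) - padding
    hi <- apply(xyz, 2, max) + padding
    dims <- pmax(1L, as.integer(ceiling((hi - lo) / voxel_size)) + 1L)
    origin <- lo
    voxel <- voxel_size
  } else {
    dims <- dim(grid$data)
    origin <- grid$origin
    voxel <- grid$voxel
  }
  sigma <- fwhm_to_sigma(resolution)
  vals <- cpp_splat_gauss(xyz, sigma, origin, voxel, dims, cutoff = 4)
  m <- max(vals)
  if (m <= 0) vals[] <- 0 else vals <- vals / m
  density_map(array(vals, dims), voxel = voxel, origin = origin)
}

#' Threshold a map into a volume mask
#'
#' Defines the envelope ("map volume") as the voxels whose density reaches
#' a contour level. In `max_fraction` mode (the default) the map is first
#' normalized to maximum 1 and the threshold is a fraction of the maximum;
#' in `absolute` mode raw values are compared directly.
#'
#' @param map a [density_map] with a positive maximum.
#' @param threshold contour level; default 0.7.
#' @param mode `"max_fraction"` or `"absolute"`.
#' @return A `volume_mask`: logical grid congruent with `map` plus the
#'   threshold used.
#' @export
threshold_mask <- function(map, threshold = 0.7,
                           mode = c("max_fraction", "absolute")) {
  mode <- match.arg(mode)
  m <- max(map$data)
  if (m <= 0)
    stop_denfit("degenerate map: maximum density is not positive",
                "denfit_degenerate_map_error")
  vals <- if (mode == "max_fraction") map$data / m else map$data
  structure(
    list(mask = vals >= threshold, threshold_value = threshold, mode = mode,
         voxel = map$voxel, origin = map$origin),
    class = "volume_mask"
  )
}

#' @export
print.volume_mask <- function(x, ...) {
  cat(sprintf("volume_mask: %s voxels in mask (threshold %.3g, %s)\n",
              format(sum(x$mask)), x$threshold_value, x$mode))
  invisible(x)
}

#' Cross-correlation between two density maps
#'
#' The normalized inner product `sum(a*b) / sqrt(sum(a^2) * sum(b^2))`
#' over all voxels or over a mask; with `about_mean = TRUE` each map's
#' (masked) mean is subtracted first, giving the correlation-about-mean
#' variant of the fit-in-map coefficient.
#'
#' @param map_a,map_b congruent [density_map]s.
#' @param mask optional `volume_mask` congruent with both.
#' @param about_mean subtract masked means first?
#' @return A single correlation value in \[-1, 1\].
#' @export
cross_correlation <- function(map_a, map_b, mask = NULL, about_mean = FALSE) {
  if (!same_grid(map_a, map_b))
    stop_denfit("maps have different grid shape or voxel size",
                "denfit_argument_error")
  a <- as.numeric(map_a$data)
  b <- as.numeric(map_b$data)
  if (!is.null(mask)) {
    if (!identical(dim(mask$mask), dim(map_a$data)))
      stop_denfit("mask shape does not match maps", "denfit_argument_error")
    keep <- as.logical(mask$mask)
    a <- a[keep]; b <- b[keep]
  }
  if (about_mean) {
    a <- a - mean(a)
    b <- b - mean(b)
  }
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0)
    stop_denfit("zero-norm input over the evaluation region",
                "denfit_undefined_correlation_error")
  max(-1, min(1, sum(a * b) / (na * nb)))
}

## ---------------------------------------------------------------------------
## Fourier shell correlation
## ---------------------------------------------------------------------------

fsc_shell_index <- function(dims, voxel) {
  axis_freq <- function(n) {
    k <- c(0:floor(n / 2), -((ceiling(n / 2) - 1):1))
    if (n == 1) k <- 0
    k / (n * voxel)
  }
  fx <- axis_freq(dims[1]); fy <- axis_freq(dims[2]); fz <- axis_freq(dims[3])
  f2 <- outer(outer(fx^2, fy^2, "+"), fz^2, "+")
  df <- 1 / (min(dims) * voxel)
  list(shell = as.integer(round(sqrt(f2) / df)), df = df)
}

#' Fourier shell correlation and resolution estimate
#'
#' Computes the per-shell real part of the normalized complex
#' cross-spectrum of the two maps' Fourier transforms; shells are
#' integer-radius bins of width `1/(n*voxel)`. The resolution is taken at
#' the first crossing below `cutoff` (linearly interpolated between
#' shells); if the curve never drops below the cutoff, the Nyquist limit
#' `2*voxel` is returned with `never_crossed = TRUE`.
#'
#' @param map_a,map_b congruent [density_map]s with identical voxel size.
#' @param cutoff correlation threshold defining resolution; default 0.5.
#' @return A list with `curve` (class `fsc_curve`: shell frequencies in
#'   1/Å, correlations, shell width) and `resolution` in Å.
#' @export
fsc_resolution <- function(map_a, map_b, cutoff = 0.5) {
  if (!same_grid(map_a, map_b))
    stop_denfit("maps have different grid shape or voxel size",
                "denfit_argument_error")
  dims <- dim(map_a$data)
  fa <- fft(map_a$data)
  fb <- fft(map_b$data)
  sh <- fsc_shell_index(dims, map_a$voxel)
  nshell <- floor(min(dims) / 2) + 1L
  keep <- sh$shell < nshell
  idx <- sh$shell[keep] + 1L
  num <- Re(fa * Conj(fb))[keep]
  pa <- (Mod(fa)^2)[keep]
  pb <- (Mod(fb)^2)[keep]
  s_num <- vapply(split(num, idx), sum, 0)
  s_pa <- vapply(split(pa, idx), sum, 0)
  s_pb <- vapply(split(pb, idx), sum, 0)
  corr <- s_num / sqrt(s_pa * s_pb)
  corr[!is.finite(corr)] <- 0
  corr <- pmax(-1, pmin(1, corr))
  freqs <- (as.integer(names(s_num)) - 1L) * sh$df
  curve <- structure(
    list(shell_frequencies = freqs, correlations = unname(corr),
         shell_width = sh$df),
    class = "fsc_curve"
  )
  below <- which(curve$correlations < cutoff)
  if (length(below) == 0) {
    res <- 2 * map_a$voxel
    never <- TRUE
  } else {
    i <- below[1]
    never <- FALSE
    if (i == 1L) {
      res <- Inf   # even the DC shell is below the cutoff
    } else {
      c1 <- curve$correlations[i - 1]; c2 <- curve$correlations[i]
      f1 <- curve$shell_frequencies[i - 1]; f2 <- curve$shell_frequencies[i]
      fstar <- f1 + (c1 - cutoff) / (c1 - c2) * (f2 - f1)
      res <- 1 / fstar
    }
  }
  list(curve = curve, resolution = res, never_crossed = never,
       cutoff = cutoff)
}
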