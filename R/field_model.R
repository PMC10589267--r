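#' Build the cylindrical sample grid
#'
#' Discretizes the sensitive sample volume (a cylinder along z, the bore
#' axis, centred on the origin) into quadrature points with normalized
#' weights. Axial positions are equally spaced over the full length, so the
#' grid is symmetric under `z -> -z`. Radial points are placed in opposite
#' pairs alternating between the x and y axes (plus an on-axis point when
#' `n_radial` is odd), which keeps the grid symmetric under `x -> -x` and
#' `y -> -y` and makes the transverse and zonal shim profiles mutually
#' orthogonal under the weighted inner product.
#'
#' @param diameter_mm cylinder outer diameter in mm (default 1, the probe's
#'   region of interest).
#' @param length_mm cylinder length in mm (default 8).
#' @param n_radial number of radial positions per axial slice (default 4).
#' @param n_axial number of axial slices (default 64, at least 3).
#' @return object of class `sample_grid`: list with `points` (matrix n x 3,
#'   columns x/y/z in mm) and `weights` (non-negative, summing to 1).
#' @examples
#' g <- build_sample_grid(1, 8, 1, 3)   # 3 on-axis points at z = -4, 0, 4
#' @export
build_sample_grid <- function(diameter_mm = 1, length_mm = 8,
                              n_radial = 4, n_axial = 64) {
  if (diameter_mm <= 0 || length_mm <= 0)
    stop("grid dimensions must be positive")
  if (n_radial < 1) stop("n_radial must be >= 1")
  if (n_axial < 3) stop("n_axial must be >= 3")
  R <- diameter_mm / 2
  z <- seq(-length_mm / 2, length_mm / 2, length.out = n_axial)

  # transverse layout: optional centre point, then +/- pairs alternating
  # between the x and y axes at equal-area radii
  xy <- matrix(0, nrow = n_radial, ncol = 2)
  start <- 1L
  if (n_radial %% 2 == 1L) start <- 2L  # row 1 stays at the axis
  npairs <- (n_radial - (start - 1L)) %/% 2L
  if (npairs > 0) {
    for (j in seq_len(npairs)) {
      rho <- R * sqrt((j - 0.5) / npairs)
      rows <- start + 2L * (j - 1L) + c(0L, 1L)
      if (j %% 2 == 1L) {
        xy[rows, 1] <- c(rho, -rho)
      } else {
        xy[rows, 2] <- c(rho, -rho)
      }
    }
  }
  pts <- cbind(
    x = rep(xy[, 1], times = n_axial),
    y = rep(xy[, 2], times = n_axial),
    z = rep(z, each = n_radial)
  )
  structure(list(points = pts,
                 weights = rep(1 / nrow(pts), nrow(pts)),
                 diameter_mm = diameter_mm,
                 length_mm = length_mm),
            class = "sample_grid")
}

#' Shim coil names used throughout the package
#' @export
SHIM_COILS <- c("X", "Y", "Z", "Z2", "Z3", "Z4")

#' Build the spherical-harmonic shim basis over a sample grid
#'
#' Evaluates the real solid-harmonic field profiles of the six local shim
#' coils (X, Y, Z, Z2, Z3, Z4) at every grid point, per unit current.
#' Coordinates are normalized to the cylinder half-dimensions; each profile
#' is scaled so that its value at the reference coordinate (the cylinder
#' edge: `x = d/2` for X, `y = d/2` for Y, on-axis `z = l/2` for the zonal
#' terms) equals the coil's gain in Hz/mA. Profiles are linear in current by
#' construction.
#'
#' @param grid a [build_sample_grid()] object.
#' @param gains numeric vector of 6 per-coil gains (Hz/mA), named or in the
#'   order X, Y, Z, Z2, Z3, Z4.
#' @param coils character vector of coil names to include (default all 6);
#'   lets scaled-down worlds use e.g. only Z and Z2.
#' @return object of class `shim_basis`: list with `profiles` (matrix
#'   n_points x n_coils, Hz/mA), `coil_names`, `scale` (the gains).
#' @export
build_sh_basis <- function(grid, gains, coils = SHIM_COILS) {
  stopifnot(inherits(grid, "sample_grid"))
  coils <- match.arg(coils, SHIM_COILS, several.ok = TRUE)
  if (length(gains) != length(coils))
    stop("need exactly ", length(coils), " gain values, got ", length(gains))
  xs <- grid$points[, "x"] / (grid$diameter_mm / 2)
  ys <- grid$points[, "y"] / (grid$diameter_mm / 2)
  zs <- grid$points[, "z"] / (grid$length_mm / 2)
  rho2 <- xs^2 + ys^2
  all_profiles <- list(
    X  = xs,
    Y  = ys,
    Z  = zs,
    Z2 = zs^2 - rho2 / 2,
    Z3 = zs^3 - 1.5 * zs * rho2,
    Z4 = zs^4 - 3 * zs^2 * rho2 + 0.375 * rho2^2
  )
  profiles <- vapply(seq_along(coils),
                     function(i) gains[i] * all_profiles[[coils[i]]],
                     numeric(nrow(grid$points)))
  colnames(profiles) <- coils
  structure(list(profiles = profiles, coil_names = coils,
                 scale = stats::setNames(as.numeric(gains), coils)),
            class = "shim_basis")
}

#' Cross-channel shim coupling matrix
#'
#' Models the mutual non-orthogonality of the per-channel shim sets as a
#' constant linear map from commanded shim currents (all channels stacked
#' channel-major) to effective basis amplitudes. The diagonal is 1; the
#' off-diagonal entries are drawn uniformly from `[-epsilon, epsilon]`
#' under the given seed. `epsilon = 0` recovers fully decoupled channels.
#'
#' @param m number of channels, @param n coils per channel.
#' @param epsilon maximum off-diagonal magnitude (default 0.1).
#' @param seed integer seed for the off-diagonal draw.
#' @return an `(m*n) x (m*n)` matrix of class `coupling_matrix`.
#' @export
coupling_matrix <- function(m = 2, n = 6, epsilon = 0.1, seed = 1) {
  stopifnot(epsilon >= 0, epsilon < 1)
  d <- m * n
  M <- with_seed(seed, matrix(stats::runif(d * d, -epsilon, epsilon), d, d))
  diag(M) <- 1
  class(M) <- c("coupling_matrix", class(M))
  M
}

#' Sample a random intrinsic field distortion
#'
#' Draws a random low-order polynomial inhomogeneity over the sample: orders
#' 1-4 in z with random signed coefficients, rescaled so that the
#' max-minus-min of the on-axis z-profile equals `z_span_hz`, plus a random
#' linear transverse gradient rescaled so its span over the grid equals
#' `xy_span_hz` (zero when the grid has no transverse extent). Emulates the
#' susceptibility-induced field the local shims must correct: up to ~3000 Hz
#' along z and ~500 Hz linear distortion across the cross-section.
#'
#' @param grid a [build_sample_grid()] object.
#' @param z_span_hz target peak-to-peak span of the zonal part (Hz).
#' @param xy_span_hz target peak-to-peak span of the transverse part (Hz).
#' @param seed integer seed; identical seeds give bit-identical fields.
#' @return object of class `field_map`: list with `offsets` (Hz, one per
#'   grid point) and `channel_id`.
#' @export
sample_intrinsic_distortion <- function(grid, z_span_hz = 3000,
                                        xy_span_hz = 500, seed = 1) {
  stopifnot(inherits(grid, "sample_grid"), z_span_hz >= 0, xy_span_hz >= 0)
  xs <- grid$points[, "x"] / (grid$diameter_mm / 2)
  ys <- grid$points[, "y"] / (grid$diameter_mm / 2)
  zs <- grid$points[, "z"] / (grid$length_mm / 2)
  draws <- with_seed(seed, stats::runif(6, -1, 1))
  cz <- draws[1:4]
  offsets <- numeric(nrow(grid$points))
  if (z_span_hz > 0) {
    zcol <- sort(unique(zs))                         # on-axis z profile
    fz_axis <- cz[1] * zcol + cz[2] * zcol^2 + cz[3] * zcol^3 + cz[4] * zcol^4
    span <- max(fz_axis) - min(fz_axis)
    if (span > 0) {
      sc <- z_span_hz / span
      offsets <- sc * (cz[1] * zs + cz[2] * zs^2 + cz[3] * zs^3 + cz[4] * zs^4)
    }
  }
  if (xy_span_hz > 0) {
    t <- draws[5] * xs + draws[6] * ys
    tspan <- max(t) - min(t)
    if (tspan > 0) offsets <- offsets + (xy_span_hz / tspan) * t
  }
  structure(list(offsets = offsets, channel_id = NA_integer_),
            class = "field_map")
}

zero_field <- function(grid, channel_id = NA_integer_) {
  structure(list(offsets = numeric(nrow(grid$points)),
                 channel_id = channel_id),
            class = "field_map")
}

#' Combine shim currents, coupling and intrinsic fields into channel fields
#'
#' Effective basis amplitudes are `coupling %*% currents`; each channel's
#' per-point offsets are its intrinsic field plus the amplitude-weighted sum
#' of its own shim profiles. The result is affine in the currents.
#'
#' @param basis_per_channel list of `m` [build_sh_basis()] objects.
#' @param currents numeric vector of length `m*n`, channel-major (mA).
#' @param coupling an `(m*n) x (m*n)` [coupling_matrix()] (identity allowed).
#' @param intrinsic list of `m` `field_map`s (or NULL for zero fields).
#' @return list of `m` `field_map`s, one per channel.
#' @export
total_field <- function(basis_per_channel, currents, coupling,
                        intrinsic = NULL) {
  m <- length(basis_per_channel)
  n <- length(basis_per_channel[[1]]$coil_names)
  if (length(currents) != m * n)
    stop("currents must have length m*n = ", m * n, ", got ", length(currents))
  if (!all(dim(coupling) == c(m * n, m * n)))
    stop("coupling must be ", m * n, " x ", m * n)
  amps <- as.numeric(coupling %*% currents)
  out <- vector("list", m)
  for (ch in seq_len(m)) {
    idx <- (ch - 1) * n + seq_len(n)
    off <- as.numeric(basis_per_channel[[ch]]$profiles %*% amps[idx])
    if (!is.null(intrinsic) && !is.null(intrinsic[[ch]]))
      off <- off + intrinsic[[ch]]$offsets
    out[[ch]] <- structure(list(offsets = off, channel_id = ch),
                           class = "field_map")
  }
  out
}

#' Export field maps to CSV
#'
#' Writes one row per grid point and channel with columns
#' `x_mm, y_mm, z_mm, offset_hz, channel`.
#'
#' @param grid the sample grid the maps live on.
#' @param fields a single `field_map` or a list of them.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
export_field_map <- function(grid, fields, path) {
  if (inherits(fields, "field_map")) fields <- list(fields)
  tabs <- lapply(seq_along(fields), function(i) {
    data.table::data.table(
      x_mm = grid$points[, "x"], y_mm = grid$points[, "y"],
      z_mm = grid$points[, "z"], offset_hz = fields[[i]]$offsets,
      channel = if (is.na(fields[[i]]$channel_id)) i else fields[[i]]$channel_id)
  })
  data.table::fwrite(data.table::rbindlist(tabs), path)
  invisible(path)
}
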