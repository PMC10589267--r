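test_that("sample grid geometry: symmetry-forced layouts and bounds", {
  g <- build_sample_grid(1, 8, 1, 3)
  expect_equal(g$points[, "z"], c(-4, 0, 4))
  expect_equal(g$points[, "x"], rep(0, 3))
  expect_equal(g$weights, rep(1 / 3, 3))

  g2 <- build_sample_grid(1, 8, 4, 64)
  expect_equal(nrow(g2$points), 256)
  expect_equal(sum(g2$weights), 1, tolerance = 1e-12)
  expect_true(all(g2$weights >= 0))
  expect_lte(max(abs(g2$points[, "z"])), 4)
  expect_lte(max(sqrt(g2$points[, "x"]^2 + g2$points[, "y"]^2)), 0.5 + 1e-12)
  # z -> -z symmetry of the default constructor
  key <- function(p) paste(round(p[, 1], 12), round(p[, 2], 12),
                           round(p[, 3], 12))
  flipped <- g2$points; flipped[, "z"] <- -flipped[, "z"]
  expect_setequal(key(g2$points), key(flipped))

  expect_error(build_sample_grid(-1, 8), "positive")
  expect_error(build_sample_grid(1, 8, 4, 2), "n_axial")
})

test_that("solid-harmonic shim profiles have the stated parities", {
  g <- build_sample_grid(1, 8, 5, 33)   # odd counts: contains z = 0, axis
  b <- build_sh_basis(g, gains = c(2, 2, 7, 5, 3, 2))
  pts <- g$points
  at0 <- abs(pts[, "z"]) < 1e-12
  expect_true(all(abs(b$profiles[at0, "Z"]) < 1e-12))
  expect_true(all(abs(b$profiles[at0, "Z3"]) < 1e-12))
  # pair each point with its z-mirror and check odd/even parity pointwise
  key <- paste(round(pts[, "x"], 9), round(pts[, "y"], 9),
               round(pts[, "z"], 9))
  mirror <- match(paste(round(pts[, "x"], 9), round(pts[, "y"], 9),
                        round(-pts[, "z"], 9)), key)
  for (coil in c("Z", "Z3")) {
    expect_equal(b$profiles[, coil], -b$profiles[mirror, coil],
                 tolerance = 1e-12)
  }
  for (coil in c("Z2", "Z4")) {
    expect_equal(b$profiles[, coil], b$profiles[mirror, coil],
                 tolerance = 1e-12)
  }
  xmirror <- match(paste(round(-pts[, "x"], 9), round(pts[, "y"], 9),
                         round(pts[, "z"], 9)), key)
  expect_equal(b$profiles[, "X"], -b$profiles[xmirror, "X"],
               tolerance = 1e-12)
  ymirror <- match(paste(round(pts[, "x"], 9), round(-pts[, "y"], 9),
                         round(pts[, "z"], 9)), key)
  expect_equal(b$profiles[, "Y"], -b$profiles[ymirror, "Y"],
               tolerance = 1e-12)
  # even-symmetry example: Z2 equal at z = +/- 2 on the axis
  g3 <- build_sample_grid(1, 8, 1, 5)   # axis points at -4,-2,0,2,4
  b3 <- build_sh_basis(g3, gains = rep(1, 6))
  expect_equal(b3$profiles[2, "Z2"], b3$profiles[4, "Z2"])
  expect_error(build_sh_basis(g3, gains = 1:3), "gain values")
})

test_that("gain scaling and linearity of the basis", {
  g <- build_sample_grid(1, 8, 1, 9)
  b <- build_sh_basis(g, gains = c(2, 2, 7, 5, 3, 2))
  # profile at the reference coordinate (on-axis z = l/2) equals the gain
  top <- which.max(g$points[, "z"])
  expect_equal(unname(b$profiles[top, "Z"]), 7)
  expect_equal(unname(b$profiles[top, "Z2"]), 5)
  # linearity: doubling the current doubles the offsets exactly
  f1 <- total_field(list(b), c(1, 0, 0.5, 0, -2, 0), diag(6))
  f2 <- total_field(list(b), 2 * c(1, 0, 0.5, 0, -2, 0), diag(6))
  expect_equal(f2[[1]]$offsets, 2 * f1[[1]]$offsets, tolerance = 1e-12)
})

test_that("{X, Y, Z} profiles are orthogonal in the decoupled limit", {
  g <- build_sample_grid(1, 8, 4, 64)
  b <- build_sh_basis(g, gains = rep(1, 6))
  P <- b$profiles[, c("X", "Y", "Z")]
  G <- t(P) %*% (g$weights * P)
  offdiag <- G - diag(diag(G))
  expect_lt(max(abs(offdiag)), 1e-10)
})

test_that("intrinsic distortion hits the requested spans and is seeded", {
  g <- build_sample_grid(1, 8, 1, 65)       # axis-only: pure z-profile
  d <- sample_intrinsic_distortion(g, 3000, 0, seed = 3)
  expect_equal(max(d$offsets) - min(d$offsets), 3000, tolerance = 1e-6)
  expect_true(all(is.finite(d$offsets)))
  d2 <- sample_intrinsic_distortion(g, 3000, 0, seed = 3)
  expect_identical(d$offsets, d2$offsets)
  d3 <- sample_intrinsic_distortion(g, 3000, 0, seed = 4)
  expect_false(identical(d$offsets, d3$offsets))
  z0 <- sample_intrinsic_distortion(g, 0, 0, seed = 1)
  expect_equal(z0$offsets, numeric(nrow(g$points)))
  # transverse part bounded by the xy span
  g4 <- build_sample_grid(1, 8, 4, 33)
  d4 <- sample_intrinsic_distortion(g4, 0, 500, seed = 9)
  expect_lte(max(d4$offsets) - min(d4$offsets), 500 + 1e-9)
})

test_that("total_field combines coupling, currents and intrinsic fields", {
  g <- build_sample_grid(1, 8, 5, 33)
  b <- build_sh_basis(g, gains = c(2, 2, 7, 5, 3, 2))
  basis <- list(b, b)
  # zero currents, identity coupling: offsets equal intrinsic exactly
  intr <- list(sample_intrinsic_distortion(g, 100, 0, seed = 5),
               sample_intrinsic_distortion(g, 100, 0, seed = 6))
  f0 <- total_field(basis, numeric(12), diag(12), intr)
  expect_equal(f0[[1]]$offsets, intr[[1]]$offsets)
  expect_equal(f0[[2]]$offsets, intr[[2]]$offsets)
  # cross-channel coupling oracle: with entry (ch2 Z, ch1 Z) = 0.1, a unit
  # current on channel-1 Z appears on channel 2 as 0.1 x its own Z profile
  M <- diag(12)
  M[9, 3] <- 0.1           # row: channel-2 Z amplitude; col: channel-1 Z
  cur <- numeric(12); cur[3] <- 1
  f <- total_field(basis, cur, M)
  expect_equal(f[[2]]$offsets, 0.1 * b$profiles[, "Z"], tolerance = 1e-12)
  expect_equal(f[[1]]$offsets, b$profiles[, "Z"], tolerance = 1e-12)
  expect_error(total_field(basis, numeric(7), diag(12)), "length")
})

test_that("total_field is affine: superposition on random current pairs", {
  g <- build_sample_grid(1, 8, 4, 17)
  b <- build_sh_basis(g, gains = c(2, 2, 7, 5, 3, 2))
  basis <- list(b, b)
  M <- coupling_matrix(2, 6, 0.1, seed = 2)
  set.seed(42)
  for (i in 1:5) {
    u <- rnorm(12); v <- rnorm(12); a <- runif(1, -2, 2)
    fu <- total_field(basis, u, M)[[1]]$offsets
    fv <- total_field(basis, v, M)[[1]]$offsets
    fuv <- total_field(basis, u + a * v, M)[[1]]$offsets
    expect_equal(fuv, fu + a * fv, tolerance = 1e-10)
  }
})

test_that("coupling matrix has unit diagonal and bounded off-diagonals", {
  M <- coupling_matrix(2, 6, 0.1, seed = 7)
  expect_equal(diag(M), rep(1, 12))
  expect_lte(max(abs(M - diag(12))), 0.1)
  expect_identical(unclass(coupling_matrix(2, 6, 0, seed = 1))[, ],
                   diag(12)[, ])
})

test_that("field maps export to CSV with the documented columns", {
  g <- build_sample_grid(1, 8, 1, 5)
  d <- sample_intrinsic_distortion(g, 100, 0, seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  export_field_map(g, list(d), path)
  tab <- utils::read.csv(path)
  expect_named(tab, c("x_mm", "y_mm", "z_mm", "offset_hz", "channel"))
  expect_equal(tab$offset_hz, d$offsets, tolerance = 1e-9)
})
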