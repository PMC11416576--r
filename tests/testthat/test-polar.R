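test_that("coordinate conversions satisfy the closed-form cases", {
  expect_equal(polar_to_cart(5, 0), list(x = 5, y = 0))
  expect_equal(polar_to_cart(0, 1.234), list(x = 0, y = 0))
  p <- polar_to_cart(5, atan2(4, 3))          # 3-4-5 triangle
  expect_equal(c(p$x, p$y), c(3, 4), tolerance = 1e-12)
  expect_equal(cart_to_polar(0, 0), list(r = 0, theta = 0))
  cp <- cart_to_polar(-1, 0)
  expect_equal(c(cp$r, cp$theta), c(1, pi), tolerance = 1e-12)
})

test_that("point-level round trip is exact to floating tolerance", {
  set.seed(4)
  x <- runif(1000, -50, 50); y <- runif(1000, -50, 50)
  cp <- cart_to_polar(x, y)
  back <- polar_to_cart(cp$r, cp$theta)
  expect_equal(back$x, x, tolerance = 1e-12)
  expect_equal(back$y, y, tolerance = 1e-12)
})

test_that("polar sampling respects constancy, radial symmetry and membership", {
  g <- polar_grid(center = c(20, 20), radius = 18, angular_bins = 64,
                  radial_samples = 40)
  const <- matrix(3.5, 41, 41)
  pc <- to_polar(const, g)
  expect_true(all(abs(pc$data - 3.5) < 1e-12))
  # distance-from-center image: rows constant along angle, increasing radially
  X <- matrix(rep(0:40, each = 41), 41, 41); Y <- t(X)
  distimg <- sqrt((X - 20)^2 + (Y - 20)^2)
  pd <- to_polar(distimg, g)$data[, , 1]
  # rows differ only by bilinear interpolation error, largest where the
  # distance surface curves most (near the origin); check beyond r = 2
  expect_lt(max(apply(pd[, 6:40], 2, function(col) diff(range(col)))), 0.08)
  expect_true(all(diff(pd[1, ]) > 0))
  # binary disk of radius 10, r_max 20: each sample's membership equals a
  # scalar brute-force resampler evaluated at the same nominal position
  g2 <- polar_grid(c(20, 20), 20, angular_bins = 32, radial_samples = 21)
  disk <- (distimg <= 10) * 1
  pdisk <- to_polar(disk, g2, order = 0)$data[, , 1]
  for (b in 1:32) for (s in 1:21) {
    theta <- -pi / 2 + 2 * pi * (b - 1) / 32
    r <- 20 * (s - 1) / 20
    x <- round(20 + r * cos(theta)); y <- round(20 + r * sin(theta))
    want <- if (x >= 0 && x <= 40 && y >= 0 && y <= 40) disk[y + 1, x + 1] else 0
    expect_identical(pdisk[b, s], as.numeric(want))
  }
  # interior and exterior radii classify cleanly either way
  r_s <- 20 * (0:20) / 20
  expect_true(all(pdisk[, r_s <= 9] == 1))
  expect_true(all(pdisk[, r_s >= 11.5] == 0))
  expect_error(to_polar(const, polar_grid(c(100, 100), 5)), "outside")
})

test_that("inverse transform reconstructs a disk with Jaccard >= 0.98 at 400 bins", {
  H <- 101
  X <- matrix(rep(0:(H - 1), each = H), H, H); Y <- t(X)
  disk <- ((X - 50)^2 + (Y - 50)^2 <= 30^2) * 1
  g <- polar_grid(c(50, 50), 45, angular_bins = 400, radial_samples = 400)
  rec <- from_polar(to_polar(disk, g, order = 1), c(H, H), order = 1)
  recb <- (rec >= 0.5) * 1
  inside <- ((X - 50)^2 + (Y - 50)^2) <= 45^2
  inter <- sum(recb == 1 & disk == 1 & inside)
  uni <- sum((recb == 1 | disk == 1) & inside)
  expect_gte(inter / uni, 0.98)
  # nearest-neighbour round trip of a class mask introduces no new ids
  mask <- disk * 2L + 1L
  recm <- from_polar(to_polar(mask, g, order = 0), c(H, H), order = 0, fill = 1)
  expect_true(all(recm %in% c(1, 3)))
  expect_error(from_polar(list(data = array(0, c(4, 4, 1))), c(4, 4)), "grid")
})

test_that("round-trip error decreases as the polar resolution grows", {
  H <- 81
  X <- matrix(rep(0:(H - 1), each = H), H, H); Y <- t(X)
  smooth <- sin(X / 9) + cos(Y / 7)           # smooth test surface
  err <- vapply(c(100, 400), function(nb) {
    g <- polar_grid(c(40, 40), 38, angular_bins = nb, radial_samples = nb)
    rec <- from_polar(to_polar(smooth, g), c(H, H), fill = NA)
    mean(abs(rec - smooth), na.rm = TRUE)
  }, numeric(1))
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.01)
})

test_that("image rotation corresponds to a cyclic shift of polar rows", {
  # wedge image whose value encodes the angular sector index; rotating the
  # image by k sectors (done analytically, not by resampling) must shift the
  # polar rows cyclically by k
  H <- 61; B <- 16; k <- 3
  X <- matrix(rep(0:(H - 1), each = H), H, H); Y <- t(X)
  ang <- atan2(Y - 30, X - 30) %% (2 * pi)
  # sector boundaries offset by half a bin so polar sample angles fall at
  # sector centers (pixel rounding then cannot cross a boundary for r >= 6)
  sector <- floor(ang / (2 * pi) * B + 0.5) %% B
  ang_rot <- (ang - 2 * pi * k / B) %% (2 * pi)
  sector_rot <- floor(ang_rot / (2 * pi) * B + 0.5) %% B
  g <- polar_grid(c(30, 30), 25, angular_bins = B, radial_samples = 30,
                  rotation_deg = 0)
  P <- to_polar(sector, g, order = 0)$data[, , 1]
  Prot <- to_polar(sector_rot, g, order = 0)$data[, , 1]
  shift_rows <- ((0:(B - 1)) - k) %% B + 1
  cols <- which(25 * (0:29) / 29 >= 6)
  expect_equal(Prot[, cols], P[shift_rows, cols])
})

test_that("disc-center fallback finds a bright blob", {
  H <- 64
  X <- matrix(rep(0:(H - 1), each = H), H, H); Y <- t(X)
  img <- 20 + 200 * exp(-((X - 40)^2 + (Y - 25)^2) / 50)
  ctr <- detect_disc_center(img, k = 2)
  expect_equal(ctr, c(40, 25), tolerance = 1)
})
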