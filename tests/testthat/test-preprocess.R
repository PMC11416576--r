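test_that("contour threshold uses mean + k * population sd, strictly above", {
  # hand computation: mean 25, population sd sqrt(mean((x-25)^2)) = 43.301
  m <- matrix(c(0, 0, 0, 100), 2, 2)
  expect_identical(contour_threshold(m, k = 1),
                   matrix(c(0L, 0L, 0L, 1L), 2, 2))
  # zero-variance image: threshold equals the constant, nothing is above
  expect_true(all(contour_threshold(matrix(100, 3, 3), 1) == 0L))
  # huge k empties the mask
  expect_true(all(contour_threshold(matrix(runif(25), 5, 5), 1e6) == 0L))
  expect_error(contour_threshold(matrix(numeric(0), 0, 0), 1), "non-empty")
  expect_error(contour_threshold(m, k = -1), "non-negative")
})

test_that("threshold masks shrink monotonically in k", {
  set.seed(5)
  img <- matrix(rnorm(400, 50, 20), 20, 20)
  prev <- contour_threshold(img, 0)
  for (k in c(0.5, 1, 1.5, 2, 3)) {
    cur <- contour_threshold(img, k)
    expect_true(all(cur <= prev))
    prev <- cur
  }
})

test_that("polygon filling follows the even-odd rule on pixel centers", {
  # axis-aligned square covering pixel centers (1..3, 1..3) in a 5x5 grid
  sq <- rbind(c(0.5, 0.5), c(3.5, 0.5), c(3.5, 3.5), c(0.5, 3.5))
  m <- fill_polygon(sq, c(5, 5))
  expect_equal(sum(m), 9)
  expect_true(all(m[2:4, 2:4] == 1L))
  expect_error(fill_polygon(rbind(c(0, 0), c(1, 1)), c(5, 5)), "3 vertices")
  # mirrored triangle gives the mirrored mask
  tri <- rbind(c(0.2, 0.2), c(4.6, 0.4), c(0.4, 4.4))
  W <- 6
  tri_m <- cbind((W - 1) - tri[, 1], tri[, 2])
  expect_identical(fill_polygon(tri_m, c(6, W)), fill_polygon(tri, c(6, W))[, W:1])
})

test_that("polygon rasterization matches a brute-force point-in-polygon oracle", {
  set.seed(8)
  for (rep in 1:5) {
    nv <- sample(3:6, 1)
    verts <- cbind(runif(nv, 0, 9), runif(nv, 0, 9))
    got <- fill_polygon(verts, c(10, 10))
    for (x in 0:9) for (y in 0:9)
      expect_identical(got[y + 1, x + 1] == 1L, point_in_polygon(x, y, verts))
  }
})

test_that("alpha compositing is the exact convex combination", {
  s <- matrix(200, 2, 2); d <- matrix(100, 2, 2)
  expect_equal(alpha_composite(s, d, 1), s)
  expect_equal(alpha_composite(s, d, 0), d)
  expect_equal(alpha_composite(s, d, 0.25), matrix(125, 2, 2))
  expect_error(alpha_composite(s, d, 1.5), "\\[0, 1\\]")
  # linear in alpha and bounded by the two inputs
  set.seed(2)
  s <- matrix(runif(36, 0, 255), 6, 6); d <- matrix(runif(36, 0, 255), 6, 6)
  a <- runif(1)
  half <- alpha_composite(s, d, a / 2)
  full <- alpha_composite(s, d, a)
  expect_equal(2 * half - d, full, tolerance = 1e-9)   # affine in alpha
  expect_true(all(full <= pmax(s, d) + 1e-12 & full >= pmin(s, d) - 1e-12))
  # per-pixel alpha is supported
  am <- matrix(runif(36), 6, 6)
  expect_equal(alpha_composite(s, d, am), s * am + d * (1 - am))
})

test_that("RGBA flattening blends onto the background per channel", {
  img <- array(0, c(2, 2, 4))
  img[, , 1] <- 200; img[, , 4] <- 0.5
  out <- rgba_to_rgb(img, background = c(100, 100, 100))
  expect_equal(out[1, 1, ], c(150, 50, 50))
  # opaque alpha keeps colors, zero alpha on black gives black
  img[, , 4] <- 255
  expect_equal(rgba_to_rgb(img, c(0, 0, 0))[, , 1], img[, , 1])
  img[, , 4] <- 0
  expect_true(all(rgba_to_rgb(img, c(0, 0, 0)) == 0))
  expect_error(rgba_to_rgb(array(0, c(2, 2, 3))), "H x W x 4")
})

test_that("resize maps nearest-neighbour indices as specified and preserves ids", {
  m <- matrix(c(1L, 2L, 1L, 2L), 2, 2)   # rows 1,2
  up <- resize_raster(m, c(4, 4), order = 0)
  expect_identical(up[1:2, ], matrix(1L, 2, 4))
  expect_identical(up[3:4, ], matrix(2L, 2, 4))
  expect_error(resize_raster(m, c(4, 4), order = 1), "order = 0")
  # identity at the same size for all orders
  img <- matrix(runif(64), 8, 8)
  for (ord in c(0, 1, 3))
    expect_equal(resize_raster(img, c(8, 8), order = ord), img, tolerance = 1e-12)
  # constant stays constant at any size/order
  for (ord in c(0, 1, 3))
    expect_true(all(abs(resize_raster(matrix(5, 4, 4), c(7, 9), ord) - 5) < 1e-9))
})

test_that("min-max scaling hits both endpoints and zeroes constants", {
  expect_equal(sort(unique(as.vector(minmax_normalize(matrix(c(0, 255), 2, 2))))),
               c(0, 1))
  expect_true(all(minmax_normalize(matrix(7, 3, 3)) == 0))
  expect_equal(sort(unique(as.vector(minmax_normalize(matrix(c(10, 20, 30, 10), 2))))),
               c(0, 0.5, 1))
  out <- minmax_normalize(list(matrix(c(1, 3), 1, 2), matrix(c(0, 9), 1, 2)))
  expect_equal(out[[1]], matrix(c(0, 1), 1, 2))
})

test_that("ground-truth composition follows cup > vessels > disc > beta > alpha", {
  z <- matrix(0L, 3, 3)
  # all-empty and disc-only cases
  expect_true(all(compose_ground_truth(z, z, z, z, z) == 0L))
  d <- z; d[2, 2] <- 1L
  expect_setequal(unique(as.vector(compose_ground_truth(d, z, z, z, z))), c(0L, 1L))
  # brute-force precedence on every overlap pattern of the five masks
  combos <- expand.grid(d = 0:1, c = 0:1, v = 0:1, b = 0:1, a = 0:1)
  for (i in seq_len(nrow(combos))) {
    m1 <- matrix(combos$d[i], 1, 1); m2 <- matrix(combos$c[i], 1, 1)
    m3 <- matrix(combos$v[i], 1, 1); m4 <- matrix(combos$b[i], 1, 1)
    m5 <- matrix(combos$a[i], 1, 1)
    got <- compose_ground_truth(m1, m2, m3, m4, m5)[1, 1]
    want <- if (combos$c[i]) 2L else if (combos$v[i]) 3L else if (combos$d[i]) 1L
            else if (combos$b[i]) 4L else if (combos$a[i]) 5L else 0L
    expect_identical(got, want)
  }
  expect_error(compose_ground_truth(matrix(0L, 2, 2), matrix(0L, 3, 3)), "shapes")
})

test_that("composition is idempotent on its own decomposition and conserves counts", {
  set.seed(9)
  for (rep in 1:5) {
    masks <- lapply(1:5, function(i) matrix(rbinom(100, 1, 0.3), 10, 10))
    comp <- compose_ground_truth(masks[[1]], masks[[2]], masks[[3]], masks[[4]],
                                 masks[[5]])
    redo <- compose_ground_truth(comp == 1, comp == 2, comp == 3, comp == 4,
                                 comp == 5)
    expect_identical(redo, comp)
    # composed per-class counts never exceed the input masks
    ids <- c(1L, 2L, 3L, 4L, 5L)
    ins <- c(sum(masks[[1]]), sum(masks[[2]]), sum(masks[[3]]), sum(masks[[4]]),
             sum(masks[[5]]))
    for (j in seq_along(ids)) expect_lte(sum(comp == ids[j]), ins[j])
  }
})

test_that("dataset splitting is deterministic, disjoint and exhaustive", {
  s <- split_dataset(10, 0.2, seed = 42)
  expect_length(s$test, 2); expect_length(s$train, 8)
  expect_identical(split_dataset(10, 0.2, seed = 42), s)
  expect_setequal(c(s$train, s$test), 1:10)
  s45 <- split_dataset(45, 0.2, seed = 42)    # the 45-image cohort: 36/9
  expect_length(s45$train, 36); expect_length(s45$test, 9)
  expect_error(split_dataset(1, 0.2), "at least 2")
})
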