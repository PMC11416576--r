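#' Contour thresholding by mean plus k standard deviations
#'
#' A pixel is foreground when its value strictly exceeds
#' `mean(image) + k * sd_pop(image)`, where `sd_pop` is the population
#' standard deviation over all pixels. `k` is typically between 1 and 3;
#' larger `k` shrinks the foreground monotonically.
#'
#' @param image 2-D numeric raster.
#' @param k non-negative multiplier of the standard deviation.
#' @return Integer 0/1 matrix.
#' @examples
#' contour_threshold(matrix(c(0, 0, 0, 100), 2, 2), k = 1)
#' @export
contour_threshold <- function(image, k = 2) {
  if (!is.matrix(image) || length(image) < 1) stop("image must be a non-empty 2-D raster")
  if (k < 0) stop("k must be non-negative")
  mu <- mean(image)
  sd_pop <- sqrt(mean((image - mu)^2))
  out <- (image > mu + k * sd_pop) * 1L
  storage.mode(out) <- "integer"
  out
}

#' Rasterize a polygon with the even-odd rule
#'
#' Pixel centers use 0-based (x, y) = (column, row) coordinates; a pixel is
#' foreground when its center lies inside the polygon under the even-odd
#' (ray-crossing) rule.
#'
#' @param vertices n x 2 matrix of (x, y) vertices, n >= 3.
#' @param shape (H, W) of the output mask.
#' @return Integer 0/1 matrix.
#' @export
fill_polygon <- function(vertices, shape) {
  vertices <- matrix(as.numeric(vertices), ncol = 2)
  if (nrow(vertices) < 3) stop("a polygon needs at least 3 vertices")
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  px <- rep(0:(W - 1), each = H)     # x = column index
  py <- rep(0:(H - 1), times = W)    # y = row index
  inside <- rep(FALSE, H * W)
  n <- nrow(vertices)
  j <- n
  for (i in seq_len(n)) {
    x1 <- vertices[i, 1]; y1 <- vertices[i, 2]
    x2 <- vertices[j, 1]; y2 <- vertices[j, 2]
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
    j <- i
  }
  matrix(as.integer(inside), H, W)
}

#' Alpha-composite two rasters
#'
#' Computes `source * alpha + destination * (1 - alpha)`. `alpha` may be a
#' scalar or a per-pixel matrix in \[0, 1\].
#'
#' @param source,destination rasters of a common shape.
#' @param alpha scalar or per-pixel blending weight in \[0, 1\].
#' @return Numeric raster of the common shape.
#' @export
alpha_composite <- function(source, destination, alpha) {
  if (!identical(dim(source), dim(destination)))
    stop("source and destination must share a shape")
  if (any(alpha < 0 | alpha > 1)) stop("alpha must lie in [0, 1]")
  if (length(alpha) > 1 && length(dim(source)) == 3L)
    alpha <- array(alpha, dim(source))
  source * alpha + destination * (1 - alpha)
}

#' Flatten an RGBA raster onto a background color
#'
#' Per pixel, `RGB = (1 - a) * background + a * color` where `a` is the alpha
#' channel normalized to \[0, 1\] (values above 1 are taken as 0-255 codes).
#'
#' @param image H x W x 4 raster.
#' @param background length-3 RGB triple.
#' @return H x W x 3 numeric raster.
#' @export
rgba_to_rgb <- function(image, background = c(0, 0, 0)) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 4L) stop("image must be H x W x 4")
  a <- image[, , 4]
  if (max(a) > 1) a <- a / 255
  out <- array(0, c(d[1], d[2], 3L))
  for (ch in 1:3) out[, , ch] <- (1 - a) * background[ch] + a * image[, , ch]
  out
}

#' Resize a raster by pixel-center resampling
#'
#' Interpolation orders: 0 nearest neighbour (required for class masks so ids
#' are preserved), 1 bilinear, 3 cubic (Catmull-Rom). Sample positions align
#' pixel centers: source coordinate `(d + 0.5) * scale - 0.5`, clamped to the
#' image for `mode = "edge"` or filled with `fill` for `mode = "constant"`.
#'
#' @param image 2-D matrix or H x W x C array.
#' @param target_size (H, W) of the output.
#' @param order interpolation order, one of 0, 1, 3.
#' @param mode border mode, `"edge"` (clamp) or `"constant"`.
#' @param fill extrapolation value for `mode = "constant"`.
#' @return Raster of the target size with the input's dimensionality.
#' @export
resize_raster <- function(image, target_size, order = 1, mode = "edge", fill = 0) {
  stopifnot(order %in% c(0, 1, 3))
  if (order > 0 && is.integer(image))
    stop("integer class masks must be resized with order = 0")
  d <- dim(image)
  if (is.null(d)) stop("image must have dimensions")
  H <- d[1]; W <- d[2]
  Ho <- as.integer(target_size[1]); Wo <- as.integer(target_size[2])
  if (Ho < 1 || Wo < 1) stop("target size must be positive")
  if (order == 0) {
    ri <- pmin(H, pmax(1, floor((seq_len(Ho) - 0.5) * H / Ho) + 1))
    ci <- pmin(W, pmax(1, floor((seq_len(Wo) - 0.5) * W / Wo) + 1))
    if (length(d) == 2L) return(image[ri, ci, drop = FALSE])
    return(image[ri, ci, , drop = FALSE])
  }
  ys <- (seq_len(Ho) - 0.5) * H / Ho - 0.5
  xs <- (seq_len(Wo) - 0.5) * W / Wo - 0.5
  interp1 <- function(mat) {
    sample_rc <- function(r, c) {
      if (mode == "edge") {
        r <- pmin(H - 1, pmax(0, r)); c <- pmin(W - 1, pmax(0, c))
        mat[cbind(r + 1, c + 1)]
      } else {
        ok <- r >= 0 & r < H & c >= 0 & c < W
        v <- rep(fill, length(r))
        v[ok] <- mat[cbind(r[ok] + 1, c[ok] + 1)]
        v
      }
    }
    Y <- matrix(rep(ys, Wo), Ho, Wo)
    X <- matrix(rep(xs, each = Ho), Ho, Wo)
    y0 <- floor(Y); x0 <- floor(X)
    fy <- Y - y0; fx <- X - x0
    if (order == 1) {
      v00 <- sample_rc(y0, x0);     v01 <- sample_rc(y0, x0 + 1)
      v10 <- sample_rc(y0 + 1, x0); v11 <- sample_rc(y0 + 1, x0 + 1)
      out <- (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
    } else {
      cubw <- function(t) {  # Catmull-Rom weights for offsets -1..2
        list(w0 = ((-0.5 * t + 1) * t - 0.5) * t,
             w1 = (1.5 * t - 2.5) * t * t + 1,
             w2 = ((-1.5 * t + 2) * t + 0.5) * t,
             w3 = (0.5 * t - 0.5) * t * t)
      }
      wy <- cubw(fy); wx <- cubw(fx)
      out <- 0
      wys <- list(wy$w0, wy$w1, wy$w2, wy$w3)
      wxs <- list(wx$w0, wx$w1, wx$w2, wx$w3)
      for (i in 0:3) for (j in 0:3)
        out <- out + wys[[i + 1]] * wxs[[j + 1]] * sample_rc(y0 - 1 + i, x0 - 1 + j)
    }
    matrix(out, Ho, Wo)
  }
  if (length(d) == 2L) {
    interp1(image)
  } else {
    out <- array(0, c(Ho, Wo, d[3]))
    for (ch in seq_len(d[3])) out[, , ch] <- interp1(image[, , ch])
    out
  }
}

#' Min-max normalize a batch of rasters
#'
#' Each raster is scaled independently so its minimum maps to 0 and maximum
#' to 1; a constant raster maps to all zeros by convention.
#'
#' @param images a single raster or a list of rasters.
#' @return Same structure with values in \[0, 1\].
#' @export
minmax_normalize <- function(images) {
  norm1 <- function(x) {
    rng <- range(x)
    if (rng[1] == rng[2]) return(array(0, dim(x) %||% length(x)))
    (x - rng[1]) / (rng[2] - rng[1])
  }
  if (is.list(images)) lapply(images, norm1) else norm1(images)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compose per-structure binary masks into a six-class ground truth
#'
#' Classes claim pixels in the fixed precedence cup (2) > vessels (3) >
#' disc (1) > PPA beta (4) > PPA alpha (5) > background (0); a later class
#' only fills pixels no earlier class claimed. This mirrors the anatomy: the
#' cup sits inside the disc, vessels cross the disc, the beta zone hugs the
#' disc boundary and the alpha zone lies outside the beta zone.
#'
#' @param disc,cup,vessels,beta,alpha_z binary masks of a common shape
#'   (any may be NULL for an absent structure).
#' @return Integer class-id matrix.
#' @export
compose_ground_truth <- function(disc, cup = NULL, vessels = NULL, beta = NULL,
                                 alpha_z = NULL) {
  ref <- dim(disc)
  masks <- list(cup = cup, vessels = vessels, disc = disc, beta = beta,
                alpha_z = alpha_z)
  ids <- c(cup = 2L, vessels = 3L, disc = 1L, beta = 4L, alpha_z = 5L)
  out <- matrix(0L, ref[1], ref[2])
  claimed <- matrix(FALSE, ref[1], ref[2])
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (is.null(m)) next
    if (!identical(dim(m), ref)) stop("mask shapes differ: ", nm)
    take <- (m != 0) & !claimed
    out[take] <- ids[[nm]]
    claimed <- claimed | take
  }
  out
}

#' Deterministic train/test split
#'
#' Uniform shuffle under the given seed; the test set takes
#' `round(n * test_fraction)` items.
#'
#' @param n_items number of items (>= 2).
#' @param test_fraction fraction held out (default 0.2 for an 80:20 split).
#' @param seed RNG seed (default 42).
#' @return List with sorted integer vectors `train` and `test`.
#' @export
split_dataset <- function(n_items, test_fraction = 0.2, seed = 42) {
  if (n_items < 2) stop("need at least 2 items to split")
  if (test_fraction <= 0 || test_fraction >= 1) stop("test_fraction must be in (0,1)")
  perm <- with_seed(seed, function() sample.int(n_items))
  n_test <- round(n_items * test_fraction)
  list(train = sort(perm[seq_len(n_items - n_test) + n_test]),
       test = sort(perm[seq_len(n_test)]))
}
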