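#' Disc-centered polar sampling grid
#'
#' Describes how an image is resampled about the optic disc center into
#' (angle, radius) coordinates. Angles start at the +x axis, run
#' counter-clockwise in image coordinates (x = column, y = row, 0-based,
#' pixel-center sampling), and the whole fan is rotated by `rotation_deg`
#' (default -90, so the first angular bin points "up").
#'
#' @param center (u0, v0) = (column, row) of the disc center, 0-based.
#' @param radius maximal sampled radius r_max in pixels.
#' @param angular_bins number of angular bins (default 400).
#' @param radial_samples number of radial samples (default 400, giving a
#'   square polar raster).
#' @param rotation_deg rotation applied to the angular origin, degrees.
#' @return An object of class `polar_grid`.
#' @export
polar_grid <- function(center, radius, angular_bins = 400, radial_samples = 400,
                       rotation_deg = -90) {
  if (angular_bins < 4) stop("angular_bins must be >= 4")
  if (radius <= 0) stop("radius must be positive")
  if (radial_samples < 2) stop("radial_samples must be >= 2")
  structure(list(center = as.numeric(center), radius = as.numeric(radius),
                 angular_bins = as.integer(angular_bins),
                 radial_samples = as.integer(radial_samples),
                 rotation_deg = as.numeric(rotation_deg)),
            class = "polar_grid")
}

#' Polar to Cartesian coordinates
#'
#' `x = r * cos(theta)`, `y = r * sin(theta)`.
#'
#' @param r radius (vectorized).
#' @param theta angle in radians.
#' @return List with numeric `x` and `y`.
#' @export
polar_to_cart <- function(r, theta) list(x = r * cos(theta), y = r * sin(theta))

#' Cartesian to polar coordinates
#'
#' Radius `sqrt(x^2 + y^2)` and angle `atan2(y, x)`, with theta in (-pi, pi].
#'
#' @param x,y Cartesian coordinates (vectorized).
#' @return List with numeric `r` and `theta`.
#' @export
cart_to_polar <- function(x, y) list(r = sqrt(x^2 + y^2), theta = atan2(y, x))

#' Forward polar transformation of an image about the disc center
#'
#' Row `b` (0-based), column `s` of the output samples the source image at
#' angle `theta_b = rotation + 2*pi*b/angular_bins` and radius
#' `r_s = r_max * s / (radial_samples - 1)` relative to the grid center.
#' Samples falling outside the image take `fill`.
#'
#' @param image 2-D matrix or H x W x C array.
#' @param grid a [polar_grid()]; its center must lie inside the image.
#' @param order interpolation order (0 nearest for masks, 1 bilinear).
#' @param fill value for out-of-image samples.
#' @return A `polar_image`: list with `data` (angular_bins x radial_samples
#'   x C) and the `grid` needed for inversion.
#' @export
to_polar <- function(image, grid, order = 1, fill = 0) {
  d <- dim(image)
  H <- d[1]; W <- d[2]; C <- if (length(d) == 3L) d[3] else 1L
  u0 <- grid$center[1]; v0 <- grid$center[2]
  if (u0 < 0 || u0 > W - 1 || v0 < 0 || v0 > H - 1)
    stop("grid center lies outside the image")
  B <- grid$angular_bins; S <- grid$radial_samples
  theta <- grid$rotation_deg * pi / 180 + 2 * pi * (0:(B - 1)) / B
  rr <- grid$radius * (0:(S - 1)) / (S - 1)
  X <- u0 + outer(cos(theta), rr)             # B x S, column coordinate
  Y <- v0 + outer(sin(theta), rr)             # B x S, row coordinate
  out <- array(fill, c(B, S, C))
  img <- if (length(d) == 2L) array(image, c(H, W, 1L)) else image
  for (ch in seq_len(C))
    out[, , ch] <- sample_at(img[, , ch], Y, X, order, fill)
  structure(list(data = out, grid = grid), class = "polar_image")
}

#' Inverse polar transformation back to Cartesian pixels
#'
#' Every output pixel within `r_max` of the grid center is resampled from the
#' polar raster (with angular wrap-around); pixels outside `r_max` take
#' `fill`.
#'
#' @param polar a `polar_image` produced by [to_polar()] (the carried grid is
#'   required).
#' @param out_shape (H, W) of the Cartesian output.
#' @param order interpolation order (0 or 1).
#' @param fill value for pixels outside the sampled radius.
#' @return 2-D matrix or H x W x C array.
#' @export
from_polar <- function(polar, out_shape, order = 1, fill = 0) {
  if (!inherits(polar, "polar_image") || is.null(polar$grid))
    stop("polar image must carry its sampling grid")
  grid <- polar$grid
  B <- grid$angular_bins; S <- grid$radial_samples
  H <- as.integer(out_shape[1]); W <- as.integer(out_shape[2])
  C <- dim(polar$data)[3]
  u0 <- grid$center[1]; v0 <- grid$center[2]
  X <- matrix(rep(0:(W - 1), each = H), H, W)
  Y <- matrix(rep(0:(H - 1), times = W), H, W)
  dx <- X - u0; dy <- Y - v0
  r <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx) - grid$rotation_deg * pi / 180
  bin <- (theta / (2 * pi)) %% 1 * B          # fractional angular row
  rad <- r / grid$radius * (S - 1)            # fractional radial column
  inside <- r <= grid$radius + 1e-9
  out <- array(fill, c(H, W, C))
  for (ch in seq_len(C)) {
    pol <- polar$data[, , ch]
    v <- if (order == 0) {
      b0 <- (round(bin) %% B) + 1
      s0 <- pmin(S, pmax(1, round(rad) + 1))
      pol[cbind(as.vector(b0), as.vector(s0))]
    } else {
      b0 <- floor(bin); fb <- bin - b0
      s0 <- floor(rad); fs <- rad - s0
      s0 <- pmin(S - 2, pmax(0, s0)); fs <- pmin(1, pmax(0, rad - s0))
      i00 <- cbind(as.vector(b0 %% B) + 1, as.vector(s0) + 1)
      i01 <- cbind(i00[, 1], i00[, 2] + 1)
      i10 <- cbind(as.vector((b0 + 1) %% B) + 1, i00[, 2])
      i11 <- cbind(i10[, 1], i00[, 2] + 1)
      fbv <- as.vector(fb); fsv <- as.vector(fs)
      (1 - fbv) * ((1 - fsv) * pol[i00] + fsv * pol[i01]) +
        fbv * ((1 - fsv) * pol[i10] + fsv * pol[i11])
    }
    plane <- matrix(fill, H, W)
    plane[inside] <- matrix(v, H, W)[inside]
    out[, , ch] <- plane
  }
  if (C == 1L) out[, , 1] else out
}

# Bilinear / nearest sampler at fractional (row, col) 0-based positions.
sample_at <- function(mat, Y, X, order = 1, fill = 0) {
  H <- nrow(mat); W <- ncol(mat)
  if (order == 0) {
    r <- round(Y); c <- round(X)
    ok <- r >= 0 & r < H & c >= 0 & c < W
    v <- rep(fill, length(r))
    v[ok] <- mat[cbind(r[ok] + 1, c[ok] + 1)]
    return(matrix(v, nrow(Y), ncol(Y)))
  }
  y0 <- floor(Y); x0 <- floor(X)
  fy <- Y - y0; fx <- X - x0
  g <- function(r, c) {
    ok <- r >= 0 & r < H & c >= 0 & c < W
    v <- rep(fill, length(r))
    v[ok] <- mat[cbind(r[ok] + 1, c[ok] + 1)]
    v
  }
  v <- (1 - fy) * ((1 - fx) * g(y0, x0) + fx * g(y0, x0 + 1)) +
    fy * ((1 - fx) * g(y0 + 1, x0) + fx * g(y0 + 1, x0 + 1))
  matrix(v, nrow(Y), ncol(Y))
}

#' Fallback optic disc center detector
#'
#' Brightness centroid of the pixels retained by [contour_threshold()] on the
#' image's brightest channel (fundus discs are the brightest structure). Used
#' when no explicit disc-center annotation is available.
#'
#' @param image 2-D raster or H x W x 3 color image.
#' @param k threshold multiplier passed to [contour_threshold()].
#' @return Numeric (u0, v0) = (column, row) center, 0-based.
#' @export
detect_disc_center <- function(image, k = 2) {
  gray <- if (length(dim(image)) == 3L) {
    apply(image[, , 1:3, drop = FALSE], c(1, 2), max)
  } else image
  m <- contour_threshold(gray, k)
  if (!any(m == 1L)) return(c((ncol(gray) - 1) / 2, (nrow(gray) - 1) / 2))
  w <- gray * (m == 1L)
  tot <- sum(w)
  X <- matrix(rep(0:(ncol(gray) - 1), each = nrow(gray)), nrow(gray))
  Y <- matrix(rep(0:(nrow(gray) - 1), times = ncol(gray)), nrow(gray))
  c(sum(X * w) / tot, sum(Y * w) / tot)
}
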