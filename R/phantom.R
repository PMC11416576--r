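#' Configuration for the synthetic fundus phantom generator
#'
#' Geometry defaults scale with the image size `S = min(H, W)` so the same
#' configuration works at 512 x 512 (the native working resolution) and at
#' the smaller sizes used for fast experiments. The phantom emulates the
#' anatomy the segmentation method assumes: a bright elliptical optic disc, a
#' brighter concentric-ish cup nested strictly inside it (cup-to-disc ratio
#' drawn from `cdr_range`), dark branching vessels emanating from the disc, a
#' pale peripapillary-atrophy beta annulus hugging the disc boundary, a
#' paler alpha annulus outside the beta zone, a circular field-of-view
#' aperture, radial illumination falloff and Gaussian pixel noise.
#'
#' @param image_size (H, W) in pixels (default c(512, 512)).
#' @param disc_radius_range disc semi-axis range in pixels (default
#'   0.12-0.17 of S).
#' @param cdr_range cup-to-disc ratio interval (default 0.2-0.7; ratios above
#'   about 0.3 are the glaucoma-suspect regime).
#' @param vessel_count_range integer interval of vessel branches (default 3-6).
#' @param vessel_width_range vessel thickness range in pixels.
#' @param beta_width_range,alpha_width_range annulus widths in pixels.
#' @param illumination_gradient amplitude of the radial shading in \[0, 1\].
#' @param noise_sigma Gaussian noise standard deviation on the 0-255 scale.
#' @param center_jitter maximal disc-center offset from the image center, px.
#' @param fov whether to apply a circular field-of-view aperture.
#' @param palette named list of RGB triples for background, disc, cup,
#'   vessels, beta, alpha, frame.
#' @param seed default seed used when [generate_phantom()] is not given one.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = c(512, 512),
                           disc_radius_range = NULL,
                           cdr_range = c(0.2, 0.7),
                           vessel_count_range = c(3, 6),
                           vessel_width_range = NULL,
                           beta_width_range = NULL,
                           alpha_width_range = NULL,
                           illumination_gradient = 0.25,
                           noise_sigma = 6,
                           center_jitter = NULL,
                           fov = TRUE,
                           palette = NULL,
                           seed = 42) {
  S <- min(image_size)
  cfg <- list(
    image_size = as.integer(image_size),
    disc_radius_range = disc_radius_range %||% (c(0.12, 0.17) * S),
    cdr_range = cdr_range,
    vessel_count_range = as.integer(vessel_count_range),
    vessel_width_range = vessel_width_range %||% pmax(1, c(0.008, 0.016) * S),
    beta_width_range = beta_width_range %||% (c(0.035, 0.05) * S),
    alpha_width_range = alpha_width_range %||% (c(0.035, 0.05) * S),
    illumination_gradient = illumination_gradient,
    noise_sigma = noise_sigma,
    center_jitter = center_jitter %||% (0.06 * S),
    fov = isTRUE(fov),
    palette = palette %||% list(
      background = c(150, 62, 38), disc = c(235, 178, 95),
      cup = c(252, 226, 140), vessels = c(106, 28, 22),
      beta = c(214, 196, 150), alpha = c(168, 120, 70),
      frame = c(8, 8, 8)),
    seed = as.integer(seed))
  if (cfg$cdr_range[1] <= 0 || cfg$cdr_range[2] >= 1)
    stop("cdr_range must lie strictly inside (0, 1)")
  max_extent <- max(cfg$disc_radius_range) * 1.1 + max(cfg$beta_width_range) +
    max(cfg$alpha_width_range) + cfg$center_jitter
  if (max_extent >= S / 2)
    stop("infeasible geometry: disc plus atrophy annuli exceed the image")
  structure(cfg, class = "phantom_config")
}

ellipse_mask <- function(H, W, cx, cy, a, b) {
  X <- matrix(rep(0:(W - 1), each = H), H, W)
  Y <- matrix(rep(0:(H - 1), times = W), H, W)
  ((X - cx) / a)^2 + ((Y - cy) / b)^2 <= 1
}

# Random-walk vessel tree rasterized by stamping disks along each path.
draw_vessels <- function(H, W, cx, cy, disc_r, n_vessels, width_range) {
  mask <- matrix(FALSE, H, W)
  stamp <- function(x, y, w) {
    r <- max(1L, as.integer(ceiling(w / 2)))
    xs <- max(1, round(x) + 1 - r):min(W, round(x) + 1 + r)
    ys <- max(1, round(y) + 1 - r):min(H, round(y) + 1 + r)
    for (xi in xs) for (yi in ys)
      if ((xi - 1 - x)^2 + (yi - 1 - y)^2 <= (w / 2)^2) mask[yi, xi] <<- TRUE
  }
  for (v in seq_len(n_vessels)) {
    ang <- runif(1, 0, 2 * pi)
    w <- runif(1, width_range[1], width_range[2])
    x <- cx + 0.2 * disc_r * cos(ang)
    y <- cy + 0.2 * disc_r * sin(ang)
    steps <- as.integer(0.7 * max(H, W))
    for (s in seq_len(steps)) {
      stamp(x, y, w)
      ang <- ang + rnorm(1, 0, 0.18)
      x <- x + 1.5 * cos(ang)
      y <- y + 1.5 * sin(ang)
      if (x < 1 || x > W - 2 || y < 1 || y > H - 2) break
      # occasional branch: restart a thinner walk from here later is costly;
      # instead fork by jumping the angle, which yields visible bifurcations
      if (runif(1) < 0.02) ang <- ang + sample(c(-1, 1), 1) * runif(1, 0.5, 1.0)
    }
  }
  mask
}

#' Generate one synthetic fundus phantom
#'
#' Deterministic for a fixed `(cfg, seed)` pair: the image and mask are
#' byte-identical across runs. The label mask composes the per-structure
#' masks with the same precedence as [compose_ground_truth()].
#'
#' @param cfg a [phantom_config()].
#' @param seed integer seed (defaults to `cfg$seed`).
#' @return An object of class `phantom_sample`: list with `image` (H x W x 3
#'   integer, 0-255), `mask` (H x W integer class ids), `structures`
#'   (per-class logical masks) and `meta` (center, radii, cdr, seed).
#' @examples
#' s <- generate_phantom(phantom_config(c(64, 64)), seed = 1)
#' table(s$mask)
#' @export
generate_phantom <- function(cfg = phantom_config(), seed = cfg$seed) {
  stopifnot(inherits(cfg, "phantom_config"))
  with_seed(seed, function() {
    H <- cfg$image_size[1]; W <- cfg$image_size[2]
    S <- min(H, W)
    # disc geometry
    cx <- (W - 1) / 2 + runif(1, -cfg$center_jitter, cfg$center_jitter)
    cy <- (H - 1) / 2 + runif(1, -cfg$center_jitter, cfg$center_jitter)
    r_d <- runif(1, cfg$disc_radius_range[1], cfg$disc_radius_range[2])
    ecc <- runif(2, 0.92, 1.08)
    a_d <- r_d * ecc[1]; b_d <- r_d * ecc[2]
    cdr <- runif(1, cfg$cdr_range[1], cfg$cdr_range[2])
    a_c <- cdr * a_d; b_c <- cdr * b_d
    # bounded cup-center jitter keeps the cup strictly inside the disc
    slack <- 0.6 * (min(a_d, b_d) - max(a_c, b_c))
    off_ang <- runif(1, 0, 2 * pi)
    off_mag <- runif(1, 0, max(slack, 0))
    ccx <- cx + off_mag * cos(off_ang); ccy <- cy + off_mag * sin(off_ang)
    wb <- runif(1, cfg$beta_width_range[1], cfg$beta_width_range[2])
    wa <- runif(1, cfg$alpha_width_range[1], cfg$alpha_width_range[2])

    disc <- ellipse_mask(H, W, cx, cy, a_d, b_d)
    cup <- ellipse_mask(H, W, ccx, ccy, a_c, b_c)
    beta <- ellipse_mask(H, W, cx, cy, a_d + wb, b_d + wb) & !disc
    alpha_z <- ellipse_mask(H, W, cx, cy, a_d + wb + wa, b_d + wb + wa) &
      !disc & !beta
    nv <- if (cfg$vessel_count_range[2] < 1) 0L else {
      vals <- cfg$vessel_count_range[1]:cfg$vessel_count_range[2]
      vals[sample.int(length(vals), 1)]
    }
    vessels <- if (nv > 0)
      draw_vessels(H, W, cx, cy, r_d, nv, cfg$vessel_width_range)
    else matrix(FALSE, H, W)

    fov_mask_px <- if (cfg$fov) {
      fr <- 0.48 * S * runif(1, 0.98, 1.02)
      ellipse_mask(H, W, (W - 1) / 2, (H - 1) / 2, fr, fr)
    } else matrix(TRUE, H, W)
    # anatomy is only visible inside the field of view
    disc <- disc & fov_mask_px; cup <- cup & fov_mask_px
    beta <- beta & fov_mask_px; alpha_z <- alpha_z & fov_mask_px
    vessels <- vessels & fov_mask_px

    mask <- compose_ground_truth(disc * 1L, cup * 1L, vessels * 1L,
                                 beta * 1L, alpha_z * 1L)

    pal <- cfg$palette
    img <- array(0, c(H, W, 3))
    paint <- list(list(fov_mask_px, pal$background), list(alpha_z, pal$alpha),
                  list(beta, pal$beta), list(disc, pal$disc),
                  list(vessels, pal$vessels), list(cup, pal$cup))
    for (ch in 1:3) {
      plane <- matrix(pal$frame[ch], H, W)
      for (p in paint) plane[p[[1]]] <- p[[2]][ch]
      img[, , ch] <- plane
    }
    # radial illumination falloff about the image center
    X <- matrix(rep(0:(W - 1), each = H), H, W)
    Y <- matrix(rep(0:(H - 1), times = W), H, W)
    dist2 <- ((X - (W - 1) / 2)^2 + (Y - (H - 1) / 2)^2) / (S / 2)^2
    shade <- 1 - cfg$illumination_gradient * pmin(dist2, 1)
    for (ch in 1:3) img[, , ch] <- img[, , ch] * shade
    img <- img + array(rnorm(H * W * 3, 0, cfg$noise_sigma), c(H, W, 3))
    img <- round(pmin(pmax(img, 0), 255))
    storage.mode(img) <- "integer"

    structure(list(
      image = img, mask = mask,
      structures = list(disc = disc, cup = cup, vessels = vessels,
                        beta = beta, alpha = alpha_z, fov = fov_mask_px),
      meta = list(center = c(cx, cy), disc_axes = c(a_d, b_d),
                  cup_axes = c(a_c, b_c), cup_center = c(ccx, ccy),
                  cdr = cdr, seed = as.integer(seed))),
      class = "phantom_sample")
  })
}

#' Generate a phantom cohort
#'
#' Sample `i` uses seed `seed + i - 1`. When `dir` is given, images are
#' written under `dir/images` (PNG), masks under `dir/masks` (single-channel
#' PNG plus RLE sidecar text) and the metadata manifest as
#' `dir/manifest.csv`.
#'
#' @param n number of samples (>= 1); 45 emulates a small clinical cohort.
#' @param cfg a [phantom_config()].
#' @param seed base seed.
#' @param dir optional output directory.
#' @return List with `samples` (list of `phantom_sample`) and `manifest`
#'   (data frame of per-sample metadata).
#' @export
generate_dataset <- function(n, cfg = phantom_config(), seed = cfg$seed,
                             dir = NULL) {
  if (n < 1) stop("n must be >= 1")
  samples <- lapply(seq_len(n), function(i) generate_phantom(cfg, seed + i - 1))
  manifest <- do.call(rbind, lapply(seq_along(samples), function(i) {
    m <- samples[[i]]$meta
    data.frame(id = i, seed = m$seed, center_x = m$center[1],
               center_y = m$center[2], disc_a = m$disc_axes[1],
               disc_b = m$disc_axes[2], cdr = m$cdr)
  }))
  if (!is.null(dir)) {
    dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      write_image(samples[[i]]$image,
                  file.path(dir, "images", sprintf("phantom_%03d.png", i)))
      write_image(samples[[i]]$mask,
                  file.path(dir, "masks", sprintf("phantom_%03d.png", i)))
      write_rle(rle_encode(samples[[i]]$mask),
                file.path(dir, "masks", sprintf("phantom_%03d.rle", i)))
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  list(samples = samples, manifest = manifest)
}

#' Degrade a phantom image (blur and contrast), leaving the mask untouched
#'
#' @param sample a `phantom_sample`.
#' @param blur_sigma Gaussian blur sigma in pixels (0 = none).
#' @param contrast_scale multiplicative contrast about the mean intensity
#'   (1 = unchanged, 0 = constant image at the mean).
#' @return The degraded `phantom_sample`.
#' @export
degrade <- function(sample, blur_sigma = 0, contrast_scale = 1) {
  stopifnot(inherits(sample, "phantom_sample"))
  if (blur_sigma < 0) stop("blur_sigma must be non-negative")
  img <- sample$image * 1.0
  if (blur_sigma > 0) {
    eb <- aperm(img, c(2, 1, 3)) / 255
    eb <- EBImage::gblur(EBImage::Image(eb, colormode = "Color"), sigma = blur_sigma)
    img <- aperm(EBImage::imageData(eb), c(2, 1, 3)) * 255
  }
  mu <- mean(img)
  img <- (img - mu) * contrast_scale + mu
  img <- round(pmin(pmax(img, 0), 255))
  storage.mode(img) <- "integer"
  sample$image <- img
  sample
}
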