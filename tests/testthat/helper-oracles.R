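# Independent oracles used across the suite. These deliberately use naive
# scalar arithmetic (loops, term-by-term formulas) so they stay independent of
# the vectorized implementation paths they check.

# Term-by-term evaluation of the multi-label Dice loss on plain scalars.
dice_loss_oracle <- function(p, g, w = rep(1 / ncol(p), ncol(p)), eps = 1e-7) {
  total <- 0
  for (k in seq_len(ncol(p))) {
    num <- 0; dp <- 0; dg <- 0
    for (i in seq_len(nrow(p))) {
      num <- num + p[i, k] * g[i, k]
      dp <- dp + p[i, k]^2
      dg <- dg + g[i, k]^2
    }
    total <- total + 2 * w[k] * num / (dp + dg + eps)
  }
  1 - total
}

# Central finite differences of the Dice loss with respect to each p entry.
dice_grad_fd <- function(p, g, w = rep(1 / ncol(p), ncol(p)), eps = 1e-7,
                         h = 1e-6) {
  out <- p * 0
  for (i in seq_len(nrow(p))) for (k in seq_len(ncol(p))) {
    pp <- p; pp[i, k] <- p[i, k] + h
    pm <- p; pm[i, k] <- p[i, k] - h
    out[i, k] <- (dice_loss_oracle(pp, g, w, eps) -
                  dice_loss_oracle(pm, g, w, eps)) / (2 * h)
  }
  out
}

# Brute-force even-odd point-in-polygon test for a single point.
point_in_polygon <- function(px, py, verts) {
  n <- nrow(verts)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    x1 <- verts[i, 1]; y1 <- verts[i, 2]
    x2 <- verts[j, 1]; y2 <- verts[j, 2]
    if ((y1 > py) != (y2 > py) &&
        px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
      inside <- !inside
    j <- i
  }
  inside
}

random_label_mask <- function(H, W, K = 6) {
  matrix(sample(0:(K - 1), H * W, replace = TRUE), H, W)
}

# Small phantom cohort shared by pipeline tests (memoised per session).
tiny_cohort <- local({
  cache <- NULL
  function(n = 6, size = 32) {
    if (is.null(cache)) {
      cfg <- phantom_config(c(size, size))
      ds <- generate_dataset(n, cfg, seed = 7)
      cache <<- list(images = lapply(ds$samples, function(s) s$image),
                     masks = lapply(ds$samples, function(s) s$mask),
                     samples = ds$samples)
    }
    cache
  }
})
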