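#' Training configuration
#'
#' Defaults mirror the study protocol: Adam with learning rate 1e-4, batch
#' size 1, categorical cross-entropy for the six-class model (the multi-label
#' Dice objective is used for the disc/cup networks), an 80:20 train/test
#' split with seed 42, no shuffling within epochs, and 5 folds for
#' cross-validation.
#'
#' @param learning_rate Adam step size.
#' @param batch_size training batch size (the protocol uses 1; samples are
#'   always stepped singly).
#' @param epochs number of passes over the training set.
#' @param loss `"cce"` (softmax head, class-id masks) or `"mldice"`
#'   (sigmoid head, per-class binary target stacks).
#' @param test_fraction held-out fraction when no validation set is given.
#' @param seed RNG seed controlling the split and dropout.
#' @param shuffle shuffle sample order between epochs (off by default).
#' @param folds folds for [kfold_cv()].
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 1, epochs = 100,
                         loss = c("cce", "mldice"), test_fraction = 0.2,
                         seed = 42, shuffle = FALSE, folds = 5) {
  loss <- match.arg(loss)
  stopifnot(learning_rate > 0, epochs >= 1, batch_size >= 1, folds >= 2)
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), loss = loss,
                 test_fraction = test_fraction, seed = as.integer(seed),
                 shuffle = isTRUE(shuffle), folds = as.integer(folds)),
            class = "train_config")
}

#' Patch-protocol configuration
#'
#' @param patch_size square patch side in pixels (default 48).
#' @param stride sliding-window stride for overlap-averaged prediction
#'   (default 5); must not exceed `patch_size`.
#' @param patches_per_image random training patches per image (default 9500).
#' @param val_fraction fraction of patches held out for validation (0.10).
#' @param include_outside_fov sample patches beyond the field of view too.
#' @return An object of class `patch_config`.
#' @export
patch_config <- function(patch_size = 48, stride = 5, patches_per_image = 9500,
                         val_fraction = 0.10, include_outside_fov = TRUE) {
  stopifnot(patch_size > 0, stride > 0)
  if (stride > patch_size) stop("stride must not exceed patch_size (gaps)")
  structure(list(patch_size = as.integer(patch_size), stride = as.integer(stride),
                 patches_per_image = as.integer(patches_per_image),
                 val_fraction = val_fraction,
                 include_outside_fov = isTRUE(include_outside_fov)),
            class = "patch_config")
}

as_net_input <- function(image) {
  x <- image * 1.0
  if (max(x) > 1) x <- x / 255
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  x
}

one_hot <- function(mask, K) {
  out <- array(0, c(dim(mask), K))
  for (k in 0:(K - 1)) out[, , k + 1] <- (mask == k) * 1
  out
}

#' Disc/cup multi-label targets from a six-class mask
#'
#' Channel 1 is the whole disc region (disc or cup ids, plus vessel pixels
#' inside the disc are not recoverable from the composed mask and are left
#' out), channel 2 the cup. Used as the binary target stack for the
#' multi-label networks.
#'
#' @param mask class-id matrix.
#' @return H x W x 2 binary array.
#' @export
disc_cup_targets <- function(mask) {
  out <- array(0, c(dim(mask), 2L))
  out[, , 1] <- (mask == 1 | mask == 2) * 1
  out[, , 2] <- (mask == 2) * 1
  out
}

# One optimization step on a single sample; returns the loss and per-sample
# train metrics. `g` is a class-id matrix (cce) or H x W x K stack (mldice).
train_step <- function(model, x, g, cfg, state) {
  cache <- forward_net(model, x, train = TRUE)
  p <- cache$acts[[model$head_node]]
  d <- dim(p); npix <- prod(d[1:2]); K <- d[3]
  if (cfg$loss == "cce") {
    y <- one_hot(g, K)
    L <- -sum(y * log(pmax(p, 1e-12))) / npix
    seed_pre <- setNames(list((p - y) / npix), as.character(model$logits_node))
    seed_act <- list()
  } else {
    pm <- matrix(p, npix, K); gm <- matrix(g, npix, K)
    L <- multilabel_dice_loss(pm, gm)
    gpre <- array(multilabel_dice_grad(pm, gm), d) * p * (1 - p)
    seed_pre <- setNames(list(gpre), as.character(model$logits_node))
    seed_act <- list()
    if (length(model$side)) {
      for (s in model$side) {
        ps <- cache$acts[[s$out]]
        psm <- matrix(ps, npix, K)
        L <- L + s$weight * multilabel_dice_loss(psm, gm)
        seed_act[[as.character(s$out)]] <-
          s$weight * array(multilabel_dice_grad(psm, gm), d)
      }
    }
  }
  grads <- backward_net(model, cache, seed_act = seed_act, seed_pre = seed_pre)
  state <- adam_step(model, grads, state, lr = cfg$learning_rate)
  list(loss = L, p = p, state = state)
}

sample_metrics <- function(p, g, loss_name) {
  K <- dim(p)[3]
  if (loss_name == "cce") {
    pred <- prob_to_mask(p, "argmax")
    c(acc = pixel_accuracy(pred, g), jac = mean_iou(pred, g, K))
  } else {
    pred <- (p >= 0.5) * 1
    jac <- mean(vapply(seq_len(K), function(k)
      iou(pred[, , k], g[, , k]), numeric(1)))
    c(acc = mean(pred == g), jac = jac)
  }
}

eval_loss <- function(model, x, g, loss_name) {
  p <- predict_net(model, x)
  d <- dim(p)
  if (loss_name == "cce") {
    y <- one_hot(g, d[3])
    L <- -sum(y * log(pmax(p, 1e-12))) / prod(d[1:2])
  } else {
    L <- multilabel_dice_loss(matrix(p, prod(d[1:2]), d[3]),
                              matrix(g, prod(d[1:2]), d[3]))
  }
  list(loss = L, p = p)
}

#' Train a network
#'
#' Steps every training sample once per epoch (batch size 1, fixed order
#' unless `cfg$shuffle`), recording per-epoch training and validation loss,
#' pixel accuracy and Jaccard index. When no validation set is supplied the
#' held-out split of `cfg$test_fraction` under `cfg$seed` is used. Training
#' is deterministic for a fixed configuration and seed.
#'
#' @param model a `fundus_net`.
#' @param images list of H x W x C arrays (0-255 integers or \[0, 1\] reals).
#' @param masks list of class-id matrices (`loss = "cce"`) or H x W x K
#'   binary stacks (`loss = "mldice"`).
#' @param cfg a [train_config()].
#' @param val_images,val_masks optional explicit validation set.
#' @return List with the fitted `model` and `history` (one row per epoch).
#' @export
train <- function(model, images, masks, cfg = train_config(),
                  val_images = NULL, val_masks = NULL) {
  stopifnot(inherits(model, "fundus_net"), length(images) == length(masks))
  K <- model$n_classes
  if (cfg$loss == "cce") {
    bad <- vapply(masks, function(m) any(m >= K), logical(1))
    if (any(bad)) stop("mask contains class id >= n_classes")
  }
  xs <- lapply(images, as_net_input)
  if (is.null(val_images)) {
    if (length(images) >= 2 && cfg$test_fraction > 0) {
      sp <- split_dataset(length(images), cfg$test_fraction, cfg$seed)
      vx <- xs[sp$test]; vg <- masks[sp$test]
      xs <- xs[sp$train]; gs <- masks[sp$train]
    } else { vx <- list(); vg <- list(); gs <- masks }
  } else {
    vx <- lapply(val_images, as_net_input); vg <- val_masks; gs <- masks
  }
  state <- adam_init(model)
  hist <- vector("list", cfg$epochs)
  with_seed(cfg$seed + 1L, function() {
    for (ep in seq_len(cfg$epochs)) {
      ord <- if (cfg$shuffle) sample(seq_along(xs)) else seq_along(xs)
      tl <- ta <- tj <- 0
      for (i in ord) {
        r <- train_step(model, xs[[i]], gs[[i]], cfg, state)
        state <<- r$state
        m <- sample_metrics(r$p, gs[[i]], cfg$loss)
        tl <- tl + r$loss; ta <- ta + unname(m["acc"]); tj <- tj + unname(m["jac"])
      }
      nt <- length(xs)
      row <- data.frame(epoch = ep, train_loss = tl / nt, train_acc = ta / nt,
                        train_jaccard = tj / nt, val_loss = NA_real_,
                        val_acc = NA_real_, val_jaccard = NA_real_)
      if (length(vx)) {
        vl <- va <- vj <- 0
        for (i in seq_along(vx)) {
          e <- eval_loss(model, vx[[i]], vg[[i]], cfg$loss)
          m <- sample_metrics(e$p, vg[[i]], cfg$loss)
          vl <- vl + e$loss; va <- va + unname(m["acc"]); vj <- vj + unname(m["jac"])
        }
        row$val_loss <- vl / length(vx); row$val_acc <- va / length(vx)
        row$val_jaccard <- vj / length(vx)
      }
      hist[[ep]] <<- row
    }
  })
  list(model = model, history = do.call(rbind, hist))
}

#' K-fold cross-validation
#'
#' Shuffles the cohort once under `cfg$seed`, splits it into `cfg$folds`
#' contiguous folds (each sample validated exactly once), trains a fresh
#' model per fold and evaluates it on the held-out fold.
#'
#' @param builder zero-argument function returning a fresh `fundus_net`.
#' @param images,masks as in [train()].
#' @param cfg a [train_config()].
#' @return List with `reports` (per-fold [evaluate()] output), `histories`,
#'   and `folds` (per-sample fold assignment).
#' @export
kfold_cv <- function(builder, images, masks, cfg = train_config()) {
  n <- length(images)
  if (n < cfg$folds) stop("need at least as many samples as folds")
  perm <- with_seed(cfg$seed, function() sample.int(n))
  assign_fold <- integer(n)
  bounds <- floor(seq(0, n, length.out = cfg$folds + 1))
  for (f in seq_len(cfg$folds))
    assign_fold[perm[(bounds[f] + 1):bounds[f + 1]]] <- f
  reports <- vector("list", cfg$folds)
  histories <- vector("list", cfg$folds)
  for (f in seq_len(cfg$folds)) {
    tr <- which(assign_fold != f); va <- which(assign_fold == f)
    model <- builder()
    fit <- train(model, images[tr], masks[tr], cfg,
                 val_images = images[va], val_masks = masks[va])
    histories[[f]] <- fit$history
    reports[[f]] <- evaluate(fit$model, images[va], masks[va], loss = cfg$loss)
  }
  list(reports = reports, histories = histories, folds = assign_fold)
}

#' Randomly extract square training patches
#'
#' Draws `cfg$patches_per_image` patches at uniformly random valid offsets
#' (with replacement), deterministic per seed. Patches may cover regions
#' outside the field of view.
#'
#' @param image H x W x C array.
#' @param mask class-id matrix aligned with `image`.
#' @param cfg a [patch_config()].
#' @param seed RNG seed.
#' @return List of lists with `image`, `mask` and 0-based `offset` (row, col).
#' @export
extract_patches <- function(image, mask, cfg = patch_config(), seed = 42) {
  d <- dim(image)
  ps <- cfg$patch_size
  if (d[1] < ps || d[2] < ps) stop("image smaller than the patch size")
  with_seed(seed, function() {
    r0 <- sample.int(d[1] - ps + 1L, cfg$patches_per_image, replace = TRUE) - 1L
    c0 <- sample.int(d[2] - ps + 1L, cfg$patches_per_image, replace = TRUE) - 1L
    lapply(seq_len(cfg$patches_per_image), function(i) {
      ri <- r0[i] + seq_len(ps); ci <- c0[i] + seq_len(ps)
      list(image = if (length(d) == 3L) image[ri, ci, , drop = FALSE]
                   else image[ri, ci, drop = FALSE],
           mask = mask[ri, ci, drop = FALSE],
           offset = c(r0[i], c0[i]))
    })
  })
}

window_starts <- function(extent, ps, stride) {
  s <- seq(0L, extent - ps, by = stride)
  if (s[length(s)] != extent - ps) s <- c(s, extent - ps)  # clamp final window
  s
}

#' Overlap-averaged sliding-window prediction
#'
#' Slides `patch_size` windows at `stride` (the final row/column window is
#' clamped to the border so coverage is complete), predicts per-window class
#' probabilities and averages them per pixel over all covering windows. The
#' per-pixel cover count is attached as attribute `"cover_count"`.
#'
#' @param model a `fundus_net` (accepting patch-sized inputs) or a function
#'   mapping a patch to a probability array.
#' @param image H x W x C array.
#' @param cfg a [patch_config()].
#' @return H x W x K probability array.
#' @export
predict_overlap_average <- function(model, image, cfg = patch_config()) {
  x <- as_net_input(image)
  d <- dim(x); ps <- cfg$patch_size
  if (cfg$stride > ps) stop("stride must not exceed patch_size")
  if (d[1] < ps || d[2] < ps) stop("image smaller than the patch size")
  rs <- window_starts(d[1], ps, cfg$stride)
  cs <- window_starts(d[2], ps, cfg$stride)
  acc <- NULL
  cover <- matrix(0L, d[1], d[2])
  for (r in rs) for (cc in cs) {
    ri <- r + seq_len(ps); ci <- cc + seq_len(ps)
    p <- predict_net(model, x[ri, ci, , drop = FALSE])
    if (is.null(acc)) acc <- array(0, c(d[1], d[2], dim(p)[3]))
    acc[ri, ci, ] <- acc[ri, ci, , drop = FALSE] + p
    cover[ri, ci] <- cover[ri, ci] + 1L
  }
  for (k in seq_len(dim(acc)[3])) acc[, , k] <- acc[, , k] / cover
  attr(acc, "cover_count") <- cover
  acc
}

#' Field-of-view mask by color thresholding
#'
#' Thresholds one color channel (red by default) at mean + k standard
#' deviations and keeps the largest connected component — the illuminated
#' circular field of a fundus photograph.
#'
#' @param image H x W x 3 color image.
#' @param k threshold multiplier (default 1).
#' @param channel color channel used (default 1 = red).
#' @return Integer 0/1 matrix (single connected component, possibly empty).
#' @export
fov_mask <- function(image, k = 1, channel = 1) {
  if (length(dim(image)) != 3L) stop("fov_mask expects a color image")
  m <- contour_threshold(image[, , channel] * 1.0, k)
  if (!any(m == 1L)) return(m)
  lab <- EBImage::bwlabel(m)
  tab <- tabulate(lab[lab > 0])
  out <- (lab == which.max(tab)) * 1L
  storage.mode(out) <- "integer"
  out
}

#' Convert probability maps to masks
#'
#' `"argmax"` assigns each pixel the class of highest probability (ties break
#' to the lowest class id) and returns a class-id matrix; `"threshold"`
#' returns the per-class binary stack `prob >= thr`, allowing overlapping
#' multi-label structures.
#'
#' @param prob H x W x K probability array.
#' @param mode `"argmax"` or `"threshold"`.
#' @param thr threshold for `"threshold"` mode (default 0.5).
#' @return Class-id matrix or binary H x W x K array.
#' @export
prob_to_mask <- function(prob, mode = c("argmax", "threshold"), thr = 0.5) {
  mode <- match.arg(mode)
  d <- dim(prob)
  if (min(prob) < -1e-9 || max(prob) > 1 + 1e-9) stop("probabilities must lie in [0, 1]")
  if (mode == "argmax") {
    m <- matrix(prob, prod(d[1:2]), d[3])
    matrix(max.col(m, ties.method = "first") - 1L, d[1], d[2])
  } else {
    (prob >= thr) * 1L
  }
}

#' Evaluate a model on a labelled set
#'
#' Pools pixels over the whole evaluation set and reports pixel accuracy,
#' micro-averaged IoU, Dice coefficient, macro mean IoU over all classes and
#' the mean training-objective value (`model_loss`). Results are independent
#' of sample order.
#'
#' @param model a `fundus_net` or predictor function.
#' @param images,masks evaluation set (forms as in [train()]).
#' @param loss objective reported as `model_loss` (`"cce"` or `"mldice"`).
#' @param K number of classes (defaults to the predicted channel count).
#' @return List of class `metrics_report` with fields `pixel_accuracy`,
#'   `iou`, `dice`, `mean_iou`, `model_loss`.
#' @export
evaluate <- function(model, images, masks, loss = "cce", K = NULL) {
  if (length(images) == 0) stop("empty evaluation set")
  tot_loss <- 0
  inter <- uni <- pr <- gt <- NULL
  correct <- 0; npix_tot <- 0
  for (i in seq_along(images)) {
    e <- eval_loss(model, as_net_input(images[[i]]), masks[[i]], loss)
    tot_loss <- tot_loss + e$loss
    Kp <- dim(e$p)[3]
    if (is.null(inter)) {
      K <- K %||% Kp
      inter <- uni <- pr <- gt <- numeric(K)
    }
    if (loss == "cce") {
      pred <- prob_to_mask(e$p, "argmax")
      g <- masks[[i]]
      correct <- correct + sum(pred == g); npix_tot <- npix_tot + length(g)
      for (k in 0:(K - 1)) {
        inter[k + 1] <- inter[k + 1] + sum(pred == k & g == k)
        uni[k + 1] <- uni[k + 1] + sum(pred == k | g == k)
        pr[k + 1] <- pr[k + 1] + sum(pred == k)
        gt[k + 1] <- gt[k + 1] + sum(g == k)
      }
    } else {
      pred <- (e$p >= 0.5) * 1
      g <- masks[[i]]
      correct <- correct + sum(pred == g); npix_tot <- npix_tot + length(g)
      for (k in seq_len(K)) {
        inter[k] <- inter[k] + sum(pred[, , k] == 1 & g[, , k] == 1)
        uni[k] <- uni[k] + sum(pred[, , k] == 1 | g[, , k] == 1)
        pr[k] <- pr[k] + sum(pred[, , k] == 1)
        gt[k] <- gt[k] + sum(g[, , k] == 1)
      }
    }
  }
  per_class_iou <- ifelse(uni == 0, 1, inter / uni)
  out <- list(pixel_accuracy = correct / npix_tot,
              iou = sum(inter) / max(sum(uni), 1),
              dice = if (sum(pr) + sum(gt) == 0) 1
                     else 2 * sum(inter) / (sum(pr) + sum(gt)),
              mean_iou = mean(per_class_iou),
              model_loss = tot_loss / length(images))
  class(out) <- "metrics_report"
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("pixel accuracy %.4f | IoU %.4f | Dice %.4f | mIoU %.4f | loss %.4f\n",
              x$pixel_accuracy, x$iou, x$dice, x$mean_iou, x$model_loss))
  invisible(x)
}

#' Joint optic disc and cup segmentation through the polar domain
#'
#' Runs the full inference chain: (optional) disc-center detection, forward
#' polar transformation of the region of interest, multi-label prediction in
#' the polar domain, inverse polar transformation of the per-class
#' probability maps, 0.5 thresholding, and optional cleanup (largest
#' connected component plus hole filling). The cup is clipped to the disc.
#'
#' @param image H x W x 3 fundus image.
#' @param model a `fundus_net` (input size bins x radial_samples x 3) or a
#'   function predicting on the polar raster.
#' @param center disc center (u0, v0), 0-based; detected when NULL.
#' @param grid a [polar_grid()]; defaults to 400 bins/samples at radius
#'   0.45 * min(H, W) about the center.
#' @param thr probability threshold (default 0.5).
#' @param cleanup apply largest-component and hole-fill post-processing.
#' @return List with binary `disc` and `cup` matrices and the Cartesian
#'   H x W x 2 probability array `prob`.
#' @export
segment_disc_cup <- function(image, model, center = NULL, grid = NULL,
                             thr = 0.5, cleanup = TRUE) {
  x <- as_net_input(image)
  d <- dim(x)
  if (is.null(center)) center <- detect_disc_center(image)
  if (is.null(grid))
    grid <- polar_grid(center, radius = 0.45 * min(d[1:2]))
  pol <- to_polar(x, grid, order = 1)
  pp <- predict_net(model, pol$data)
  prob <- from_polar(structure(list(data = pp, grid = grid),
                               class = "polar_image"),
                     d[1:2], order = 1, fill = 0)
  if (length(dim(prob)) == 2L) prob <- array(prob, c(d[1:2], 1L))
  clean <- function(m) {
    if (!cleanup || !any(m == 1)) return(m)
    lab <- EBImage::bwlabel(m)
    tab <- tabulate(lab[lab > 0])
    m <- (lab == which.max(tab)) * 1L
    m <- EBImage::fillHull(m)
    storage.mode(m) <- "integer"
    m
  }
  disc <- clean((prob[, , 1] >= thr) * 1L)
  cup <- if (dim(prob)[3] >= 2) clean((prob[, , 2] >= thr) * 1L)
         else matrix(0L, d[1], d[2])
  cup <- cup * disc                      # the cup cannot leave the disc
  list(disc = disc, cup = cup, prob = prob)
}
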