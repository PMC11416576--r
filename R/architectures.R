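# Network builders: the custom 6-class U-Net, the multi-scale / multi-label
# MSU-Net, the deeply supervised BU-Net, and small randomly initialized
# backbone encoders behind a registry.

# Shared encoder-decoder graph. `pyramid_scales > 0` concatenates a
# mean-pooled image pyramid level before each matching encoder block.
build_unet_graph <- function(input_size, n_classes, base_filters = 8,
                             dropout_rate = 0.1, head_activation = "softmax",
                             pyramid_scales = 0, name = "unet") {
  if (any(input_size[1:2] %% 16L != 0L))
    stop("input height and width must be divisible by 16")
  if (pyramid_scales > 4) stop("pyramid scales exceed the encoder depth")
  net <- new_net(input_size, name)
  f <- base_filters * c(1L, 2L, 4L, 8L, 16L)
  blocks <- c(paste("Down-sampling", 1:4), "Centre Block")
  cur <- add_node(net, "input", block = blocks[1])
  skips <- integer(4)
  for (j in 1:5) {
    if (j > 1) cur <- add_node(net, "maxpool", cur, block = blocks[j])
    if (j > 1 && j <= pyramid_scales + 1) {
      pyr <- add_node(net, "meanpool_input", cur, block = blocks[j],
                      factor = j - 1L)
      cur <- add_node(net, "concat", c(cur, pyr), block = blocks[j])
    }
    cur <- add_node(net, "conv", cur, block = blocks[j], kernel = c(3L, 3L),
                    filters = f[j], activation = "relu")
    cur <- add_node(net, "dropout", cur, block = blocks[j], rate = dropout_rate)
    cur <- add_node(net, "conv", cur, block = blocks[j], kernel = c(3L, 3L),
                    filters = f[j], activation = "relu")
    if (j < 5) skips[j] <- cur
  }
  decoder_stages <- integer(4)
  for (j in 1:4) {
    blk_prev <- if (j == 1) "Centre Block" else paste("Up-sampling", j - 1)
    blk <- paste("Up-sampling", j)
    up <- add_node(net, "convt", cur, block = blk_prev, kernel = c(2L, 2L),
                   filters = f[5 - j], activation = "linear")
    cur <- add_node(net, "concat", c(up, skips[5 - j]), block = blk)
    cur <- add_node(net, "conv", cur, block = blk, kernel = c(3L, 3L),
                    filters = f[5 - j], activation = "relu")
    cur <- add_node(net, "dropout", cur, block = blk, rate = dropout_rate)
    cur <- add_node(net, "conv", cur, block = blk, kernel = c(3L, 3L),
                    filters = f[5 - j], activation = "relu")
    decoder_stages[j] <- cur
  }
  head <- add_node(net, "conv", cur, block = "Output", kernel = c(1L, 1L),
                   filters = as.integer(n_classes), activation = head_activation)
  net$head_node <- head
  net$logits_node <- head     # pre-activation of this conv is the logit map
  net$n_classes <- as.integer(n_classes)
  net$decoder_stages <- decoder_stages
  net
}

#' Build the custom six-class U-Net
#'
#' A compact U-Net for whole-image six-class segmentation of the optic nerve
#' head: four down-sampling blocks (Conv-Dropout-Conv with 3x3 kernels and
#' filters 8, 16, 32, 64, each after the first preceded by 2x2 max pooling),
#' a centre block with two 128-filter convolutions, four up-sampling blocks
#' (2x2 stride-2 transposed convolution, skip concatenation, Conv-Dropout-
#' Conv with filters 64, 32, 16, 8) and a final 1x1 convolution with softmax
#' over the six classes. All convolutions use size-preserving padding, so the
#' output raster matches the input size.
#'
#' @param input_size (H, W, C); H and W must be divisible by 16. Default
#'   c(512, 512, 3).
#' @param n_classes number of output classes (default 6).
#' @param dropout_rate dropout probability inside each block (default 0.1).
#' @param base_filters first-block filter count (default 8, doubling per block).
#' @param seed RNG seed for weight initialization (default 42).
#' @return A `fundus_net` handle.
#' @examples
#' net <- build_custom_unet(c(64, 64, 3))
#' n_params(net)
#' @export
build_custom_unet <- function(input_size = c(512, 512, 3), n_classes = 6,
                              dropout_rate = 0.1, base_filters = 8, seed = 42) {
  with_seed(seed, function()
    build_unet_graph(as.integer(input_size), n_classes, base_filters,
                     dropout_rate, head_activation = "softmax",
                     pyramid_scales = 0, name = "custom_unet"))
}

#' Build the multi-scale multi-label MSU-Net
#'
#' U-Net variant for joint optic disc / cup segmentation: a mean-pooled image
#' pyramid is concatenated channel-wise before each matching encoder block
#' (multi-scale input), and the head is a 1x1 convolution with an independent
#' sigmoid per class (multi-label, K = 2 for disc and cup), so the per-pixel
#' channel probabilities are not constrained to sum to one and overlapping
#' structures can both be active.
#'
#' @param input_size (H, W, C), divisible by 16.
#' @param K number of output classes (default 2: disc, cup).
#' @param scales pyramid depth (default 3; at most 4 = encoder depth).
#' @param base_filters,dropout_rate,seed as in [build_custom_unet()].
#' @return A `fundus_net` handle.
#' @export
build_msu_net <- function(input_size = c(512, 512, 3), K = 2, scales = 3,
                          base_filters = 8, dropout_rate = 0.1, seed = 42) {
  if (scales < 1) stop("scales must be >= 1")
  with_seed(seed, function()
    build_unet_graph(as.integer(input_size), K, base_filters, dropout_rate,
                     head_activation = "sigmoid", pyramid_scales = scales,
                     name = "msu_net"))
}

#' Attach deep-supervision side-output heads (BU-Net)
#'
#' Adds `M` auxiliary classifier heads to the decoder stages of `base`
#' (deepest first): each head is a 1x1 sigmoid convolution producing a
#' K-channel local map, up-sampled to the input resolution. During training
#' the per-head multi-label Dice losses are fused with weights
#' `fusion_weights` and added to the final-layer loss, back-propagating
#' supervision into the early decoder layers.
#'
#' @param base a `fundus_net` from [build_msu_net()] (or any builder here).
#' @param M number of side outputs (default 4, one per decoder stage).
#' @param fusion_weights per-head fusion weights a_m (default all 0.25).
#' @param seed RNG seed for the new head weights.
#' @return The same handle with side heads attached (`base$side`).
#' @export
build_bu_net <- function(base, M = 4, fusion_weights = rep(0.25, M), seed = 42) {
  stopifnot(inherits(base, "fundus_net"))
  if (M < 1 || M > length(base$decoder_stages))
    stop("M must be between 1 and the number of decoder stages (",
         length(base$decoder_stages), ")")
  if (length(fusion_weights) != M) stop("need one fusion weight per head")
  K <- base$n_classes
  with_seed(seed, function() {
    for (m in seq_len(M)) {
      stage <- base$decoder_stages[m]
      head <- add_node(base, "conv", stage, block = sprintf("Side output %d", m),
                       kernel = c(1L, 1L), filters = K, activation = "sigmoid")
      fac <- base$input_size[1] %/% node_shape(base, head)[1]
      out <- if (fac > 1L)
        add_node(base, "upsample", head, block = sprintf("Side output %d", m),
                 factor = fac)
      else head
      base$side[[m]] <- list(head = head, out = out, weight = fusion_weights[m])
    }
    base$name <- "bu_net"
    base
  })
}

#' Backbone registry for encoder-swapped U-Nets
#'
#' @return Character vector of buildable backbone names.
#' @export
list_backbones <- function() c("tiny_resnet", "tiny_vgg")

#' Build a U-Net with a named backbone encoder
#'
#' Attaches the standard decoder to a small named encoder from the registry:
#' `"tiny_resnet"` (stem convolution plus one residual block per stage) or
#' `"tiny_vgg"` (plain double-convolution stages, identical to the custom
#' U-Net encoder). Weights are always randomly initialized; no pretrained
#' weights ship with the package.
#'
#' @param backbone_name a name from [list_backbones()].
#' @param input_size (H, W, C), divisible by 16.
#' @param n_classes output classes (default 6).
#' @param pretrained must be FALSE; requesting pretrained weights errors.
#' @param base_filters,dropout_rate,seed as in [build_custom_unet()].
#' @return A `fundus_net` handle.
#' @export
build_backbone_unet <- function(backbone_name, input_size = c(512, 512, 3),
                                n_classes = 6, pretrained = FALSE,
                                base_filters = 8, dropout_rate = 0.1, seed = 42) {
  if (!backbone_name %in% list_backbones())
    stop("unknown backbone '", backbone_name, "'; available: ",
         paste(list_backbones(), collapse = ", "))
  if (isTRUE(pretrained))
    stop("no pretrained weights are bundled; use pretrained = FALSE")
  if (backbone_name == "tiny_vgg")
    return(with_seed(seed, function()
      build_unet_graph(as.integer(input_size), n_classes, base_filters,
                       dropout_rate, "softmax", 0, name = "tiny_vgg_unet")))
  with_seed(seed, function() {
    input_size <- as.integer(input_size)
    if (any(input_size[1:2] %% 16L != 0L))
      stop("input height and width must be divisible by 16")
    net <- new_net(input_size, "tiny_resnet_unet")
    f <- base_filters * c(1L, 2L, 4L, 8L, 16L)
    cur <- add_node(net, "input", block = "Stem")
    skips <- integer(4)
    for (j in 1:5) {
      blk <- if (j == 5) "Centre Block" else paste("Stage", j)
      if (j > 1) cur <- add_node(net, "maxpool", cur, block = blk)
      cur <- add_node(net, "conv", cur, block = blk, kernel = c(3L, 3L),
                      filters = f[j], activation = "relu")
      r1 <- add_node(net, "conv", cur, block = blk, kernel = c(3L, 3L),
                     filters = f[j], activation = "relu")
      r2 <- add_node(net, "conv", r1, block = blk, kernel = c(3L, 3L),
                     filters = f[j], activation = "linear")
      cur <- add_node(net, "add", c(cur, r2), block = blk)
      if (j < 5) skips[j] <- cur
    }
    decoder_stages <- integer(4)
    for (j in 1:4) {
      blk <- paste("Up-sampling", j)
      up <- add_node(net, "convt", cur, block = blk, kernel = c(2L, 2L),
                     filters = f[5 - j], activation = "linear")
      cur <- add_node(net, "concat", c(up, skips[5 - j]), block = blk)
      cur <- add_node(net, "conv", cur, block = blk, kernel = c(3L, 3L),
                      filters = f[5 - j], activation = "relu")
      cur <- add_node(net, "dropout", cur, block = blk, rate = dropout_rate)
      cur <- add_node(net, "conv", cur, block = blk, kernel = c(3L, 3L),
                      filters = f[5 - j], activation = "relu")
      decoder_stages[j] <- cur
    }
    head <- add_node(net, "conv", cur, block = "Output", kernel = c(1L, 1L),
                     filters = as.integer(n_classes), activation = "softmax")
    net$head_node <- head
    net$logits_node <- head
    net$n_classes <- as.integer(n_classes)
    net$decoder_stages <- decoder_stages
    net
  })
}

#' Tabulate a network's layers
#'
#' One row per layer in forward order with the layer type, input size, kernel,
#' filter count, activation, output size and shape-formula parameter count
#' (`kh*kw*C_in*F + F` for convolutions and transposed convolutions, 0 for
#' parameter-free layers).
#'
#' @param net a `fundus_net`.
#' @return Data frame with columns `block`, `layer`, `input`, `kernel`,
#'   `filters`, `activation`, `output`, `params`.
#' @export
layer_table <- function(net) {
  stopifnot(inherits(net, "fundus_net"))
  layer_names <- c(input = "InputLayer", conv = "Conv2D", dropout = "Dropout",
                   maxpool = "MaxPooling2D", convt = "Conv2DTranspose",
                   concat = "Concatenate", meanpool_input = "MeanPooling2D",
                   upsample = "UpSampling2D", add = "Add")
  act_names <- c(relu = "ReLU", linear = "Linear", softmax = "Softmax",
                 sigmoid = "Sigmoid", none = "")
  sz <- function(s) paste(s, collapse = "*")
  rows <- lapply(net$nodes, function(nd) {
    params <- switch(nd$type,
      conv = prod(nd$kernel) * nd$in_shape[3] * nd$filters + nd$filters,
      convt = prod(nd$kernel) * nd$in_shape[3] * nd$filters + nd$filters,
      0L)
    data.frame(block = nd$block, layer = layer_names[[nd$type]],
               input = sz(nd$in_shape),
               kernel = if (is.null(nd$kernel)) "" else sz(nd$kernel),
               filters = if (is.null(nd$filters)) NA_integer_ else nd$filters,
               activation = act_names[[nd$activation]],
               output = sz(nd$out_shape), params = as.integer(params),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Load the packaged printed reference layer table
#'
#' A machine-readable transcription of the published per-layer outline of the
#' custom U-Net, as printed (including two known typographical defects: a
#' second down-sampling-1 convolution printed with 284 parameters where the
#' shape formula gives 584, and the centre-block transposed convolution's
#' output size printed without the stride-2 doubling).
#'
#' @return Data frame in [layer_table()] format.
#' @export
reference_layer_table <- function() {
  path <- system.file("extdata", "unet_reference_table.csv", package = "fundusseg")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = c(
    block = "character", layer = "character", input = "character",
    kernel = "character", filters = "integer", activation = "character",
    output = "character", params = "integer"))
  tab$kernel[is.na(tab$kernel)] <- ""
  tab$activation[is.na(tab$activation)] <- ""
  tab
}

#' Verify a layer table against a reference
#'
#' Row-by-row comparison on layer type, kernel, filter count, output size and
#' parameter count. Rows listed in `tolerate_rows` may mismatch without
#' failing the verification (used for known typographical defects in the
#' printed reference).
#'
#' @param table layer table of the freshly built network.
#' @param reference reference table (default [reference_layer_table()]).
#' @param tolerate_rows integer row indices allowed to mismatch.
#' @return Data frame with one row per layer: per-field `ok_*` flags, an
#'   overall `match` flag and a `detail` string; attribute `"ok"` is TRUE
#'   when every row outside `tolerate_rows` matches.
#' @export
verify_against_reference <- function(table, reference = reference_layer_table(),
                                     tolerate_rows = integer()) {
  if (nrow(table) != nrow(reference))
    stop("tables have different row counts (", nrow(table), " vs ",
         nrow(reference), ")")
  fields <- c("layer", "kernel", "filters", "output", "params")
  rep_rows <- lapply(seq_len(nrow(table)), function(i) {
    oks <- vapply(fields, function(f) {
      a <- table[[f]][i]; b <- reference[[f]][i]
      (is.na(a) && is.na(b)) || identical(as.character(a), as.character(b)) ||
        (is.numeric(a) && is.numeric(b) && isTRUE(a == b))
    }, logical(1))
    detail <- if (all(oks)) "" else paste(sprintf(
      "%s: %s != %s", fields[!oks],
      as.character(unlist(table[i, fields[!oks]])),
      as.character(unlist(reference[i, fields[!oks]]))), collapse = "; ")
    data.frame(row = i, block = table$block[i], layer = table$layer[i],
               t(setNames(as.list(oks), paste0("ok_", fields))),
               match = all(oks), tolerated = i %in% tolerate_rows,
               detail = detail, stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rep_rows)
  attr(report, "ok") <- all(report$match | report$tolerated)
  report
}
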