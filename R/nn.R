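# A small computational-graph engine for the encoder-decoder networks.
#
# A network is an environment of class "fundus_net" holding an ordered node
# list (the forward order), per-node parameters, and bookkeeping for the
# output head and any deep-supervision side heads. Activations are H x W x C
# arrays; the heavy kernels live in src/nn_ops.cpp.

new_net <- function(input_size, name = "net") {
  net <- new.env(parent = emptyenv())
  net$nodes <- list()
  net$params <- list()
  net$input_size <- as.integer(input_size)
  net$name <- name
  net$side <- list()
  class(net) <- "fundus_net"
  net
}

node_shape <- function(net, id) net$nodes[[id]]$out_shape

add_node <- function(net, type, inputs = integer(), block = "", kernel = NULL,
                     filters = NULL, activation = "none", rate = NULL,
                     factor = NULL, init_sd = NULL) {
  id <- length(net$nodes) + 1L
  in_shape <- if (length(inputs)) node_shape(net, inputs[1]) else net$input_size
  out_shape <- switch(type,
    input = net$input_size,
    conv = c(in_shape[1:2], filters),
    dropout = in_shape,
    maxpool = c(in_shape[1:2] %/% 2L, in_shape[3]),
    convt = c(in_shape[1:2] * 2L, filters),
    concat = c(in_shape[1:2],
               sum(vapply(inputs, function(i) node_shape(net, i)[3], integer(1)))),
    meanpool_input = c(net$input_size[1:2] %/% (2L^factor), net$input_size[3]),
    upsample = c(in_shape[1:2] * factor, in_shape[3]),
    add = in_shape,
    stop("unknown node type: ", type)
  )
  # Glorot-uniform initialization (the convolutional default in the major
  # deep-learning frameworks); biases start at zero.
  params <- NULL
  if (type == "conv") {
    fan_in <- prod(kernel) * in_shape[3]
    fan_out <- prod(kernel) * filters
    lim <- init_sd %||% sqrt(6 / (fan_in + fan_out))
    params <- list(W = matrix(runif(fan_in * filters, -lim, lim), fan_in, filters),
                   b = numeric(filters))
  } else if (type == "convt") {
    lim <- init_sd %||% sqrt(6 / (4 * in_shape[3] + 4 * filters))
    params <- list(W = matrix(runif(in_shape[3] * 4 * filters, -lim, lim),
                              in_shape[3], 4 * filters),
                   b = numeric(filters))
  }
  net$nodes[[id]] <- list(id = id, type = type, inputs = as.integer(inputs),
                          block = block, kernel = kernel, filters = filters,
                          activation = activation, rate = rate, factor = factor,
                          in_shape = in_shape, out_shape = as.integer(out_shape))
  net$params[[id]] <- params
  id
}

pixel_softmax <- function(z) {
  d <- dim(z)
  m <- matrix(z, prod(d[1:2]), d[3])
  m <- exp(m - apply(m, 1, max))
  array(m / rowSums(m), d)
}

apply_activation <- function(z, activation) {
  switch(activation,
    none = , linear = z,
    relu = pmax(z, 0),
    sigmoid = 1 / (1 + exp(-z)),
    softmax = pixel_softmax(z),
    stop("unknown activation: ", activation)
  )
}

forward_net <- function(net, x, train = FALSE) {
  if (!identical(dim(x), as.integer(net$input_size)))
    x <- array(x, net$input_size)
  n <- length(net$nodes)
  acts <- vector("list", n)
  pre <- vector("list", n)      # pre-activation (conv heads), pool indices, dropout masks
  for (nd in net$nodes) {
    id <- nd$id
    a <- switch(nd$type,
      input = x,
      conv = {
        z <- cpp_conv2d_fwd(acts[[nd$inputs]], net$params[[id]]$W,
                            net$params[[id]]$b, nd$kernel[1], nd$kernel[2])
        if (nd$activation %in% c("sigmoid", "softmax")) pre[[id]] <- z
        apply_activation(z, nd$activation)
      },
      dropout = {
        if (train && nd$rate > 0) {
          mask <- array((runif(prod(nd$in_shape)) >= nd$rate) / (1 - nd$rate),
                        nd$in_shape)
          pre[[id]] <- mask
          acts[[nd$inputs]] * mask
        } else acts[[nd$inputs]]
      },
      maxpool = {
        r <- cpp_maxpool2_fwd(acts[[nd$inputs]])
        pre[[id]] <- r$idx
        r$y
      },
      convt = cpp_convt2_fwd(acts[[nd$inputs]], net$params[[id]]$W, net$params[[id]]$b),
      concat = {
        parts <- lapply(nd$inputs, function(i) acts[[i]])
        array(unlist(parts, use.names = FALSE), nd$out_shape)
      },
      meanpool_input = {
        a0 <- x
        for (i in seq_len(nd$factor)) a0 <- cpp_meanpool2(a0)
        a0
      },
      upsample = cpp_upsample_fwd(acts[[nd$inputs]], nd$factor),
      add = acts[[nd$inputs[1]]] + acts[[nd$inputs[2]]]
    )
    acts[[id]] <- a
  }
  list(acts = acts, pre = pre, train = train)
}

# Reverse-mode sweep. `seed_act` / `seed_pre` are named lists keyed by node id
# (as character): gradients w.r.t. a node's output activation, or w.r.t. a
# conv node's pre-activation (used to shortcut softmax/sigmoid + loss).
backward_net <- function(net, cache, seed_act = list(), seed_pre = list()) {
  n <- length(net$nodes)
  gacts <- vector("list", n)
  grads <- vector("list", n)
  for (k in names(seed_act)) gacts[[as.integer(k)]] <- seed_act[[k]]
  push <- function(i, g) {
    gacts[[i]] <<- if (is.null(gacts[[i]])) g else gacts[[i]] + g
  }
  for (id in rev(seq_len(n))) {
    nd <- net$nodes[[id]]
    ga <- gacts[[id]]
    gz_seed <- seed_pre[[as.character(id)]]
    if (is.null(ga) && is.null(gz_seed)) next
    switch(nd$type,
      input = NULL,
      conv = {
        gz <- if (!is.null(gz_seed)) gz_seed
        else switch(nd$activation,
          relu = ga * (cache$acts[[id]] > 0),
          none = , linear = ga,
          sigmoid = { p <- cache$acts[[id]]; ga * p * (1 - p) },
          softmax = {
            p <- cache$acts[[id]]; d <- dim(p)
            pm <- matrix(p, prod(d[1:2]), d[3])
            gm <- matrix(ga, prod(d[1:2]), d[3])
            array(pm * (gm - rowSums(gm * pm)), d)
          })
        r <- cpp_conv2d_bwd(cache$acts[[nd$inputs]], net$params[[id]]$W, gz,
                            nd$kernel[1], nd$kernel[2])
        grads[[id]] <- list(gW = r$gW, gb = r$gb)
        push(nd$inputs, r$gx)
      },
      dropout = {
        g <- if (cache$train && nd$rate > 0) ga * cache$pre[[id]] else ga
        push(nd$inputs, g)
      },
      maxpool = push(nd$inputs, cpp_maxpool2_bwd(cache$pre[[id]], ga,
                                                 nd$in_shape[1], nd$in_shape[2])),
      convt = {
        r <- cpp_convt2_bwd(cache$acts[[nd$inputs]], net$params[[id]]$W, ga)
        grads[[id]] <- list(gW = r$gW, gb = r$gb)
        push(nd$inputs, r$gx)
      },
      concat = {
        off <- 0L
        for (i in nd$inputs) {
          ci <- node_shape(net, i)[3]
          push(i, ga[, , off + seq_len(ci), drop = FALSE])
          off <- off + ci
        }
      },
      meanpool_input = NULL,
      upsample = push(nd$inputs, cpp_upsample_bwd(ga, nd$factor)),
      add = { push(nd$inputs[1], ga); push(nd$inputs[2], ga) }
    )
  }
  grads
}

adam_init <- function(net) {
  st <- list(t = 0L, m = vector("list", length(net$params)),
             v = vector("list", length(net$params)))
  for (i in seq_along(net$params)) {
    p <- net$params[[i]]
    if (!is.null(p)) {
      st$m[[i]] <- list(W = p$W * 0, b = p$b * 0)
      st$v[[i]] <- list(W = p$W * 0, b = p$b * 0)
    }
  }
  st
}

adam_step <- function(net, grads, state, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(grads)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (nm in c("W", "b")) {
      gv <- if (nm == "W") g$gW else g$gb
      state$m[[i]][[nm]] <- beta1 * state$m[[i]][[nm]] + (1 - beta1) * gv
      state$v[[i]][[nm]] <- beta2 * state$v[[i]][[nm]] + (1 - beta2) * gv^2
      net$params[[i]][[nm]] <- net$params[[i]][[nm]] -
        lr * (state$m[[i]][[nm]] / bc1) / (sqrt(state$v[[i]][[nm]] / bc2) + eps)
    }
  }
  state
}

#' Total trainable parameter count of a network
#'
#' Counted from the allocated weight arrays themselves (the per-layer
#' shape-formula counts are reported by [layer_table()]; the two must agree).
#'
#' @param net a network built by this package.
#' @return Integer parameter count.
#' @export
n_params <- function(net) {
  stopifnot(inherits(net, "fundus_net"))
  sum(vapply(net$params, function(p)
    if (is.null(p)) 0L else length(p$W) + length(p$b), integer(1)))
}

#' Predict per-class probability maps for one image
#'
#' Runs the network in inference mode (dropout disabled, deterministic).
#' `model` may also be a plain function `image -> probability array`, which
#' lets reference/oracle predictors stand in for a trained network.
#'
#' @param model a `fundus_net` or a function.
#' @param image H x W x C array matching the network input size, values
#'   normalized to \[0, 1\].
#' @return H x W x K array of class probabilities.
#' @export
predict_net <- function(model, image) {
  if (is.function(model)) return(model(image))
  stopifnot(inherits(model, "fundus_net"))
  cache <- forward_net(model, image, train = FALSE)
  cache$acts[[model$head_node]]
}

#' @export
print.fundus_net <- function(x, ...) {
  cat(sprintf("<fundus_net '%s'> %d nodes, %s parameters, input %s\n",
              x$name, length(x$nodes), format(n_params(x), big.mark = ","),
              paste(x$input_size, collapse = "x")))
  invisible(x)
}
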