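test_that("custom U-Net reproduces the printed layer outline", {
  net <- build_custom_unet(c(512, 512, 3))
  tab <- layer_table(net)
  ref <- reference_layer_table()
  expect_equal(nrow(tab), 41)
  # two printed rows are known typographical defects: the second
  # down-sampling-1 convolution (284 vs the shape formula's 584) and the
  # centre transposed convolution's un-doubled output size
  rep <- verify_against_reference(tab, ref, tolerate_rows = c(4, 21))
  expect_true(attr(rep, "ok"))
  expect_false(rep$match[4])
  expect_equal(tab$params[4], 584)
  # spot checks straight from the printed outline
  expect_equal(tab$params[2], 224)      # first 3->8 convolution
  expect_equal(tab$params[21], 32832)   # centre 128->64 transposed conv
  expect_equal(tab$params[41], 54)      # final 1x1 8->6 softmax conv
  expect_equal(tab$params[16], 36928)   # 4th down-block second conv (64 filters)
  expect_equal(tab$filters[16], 64)
  expect_equal(tab$output[22], "64*64*128")  # first skip concatenation
  expect_true(all(tab$params[tab$layer == "Dropout"] == 0))
})

test_that("verification flags constructed mismatches and passes identity", {
  ref <- reference_layer_table()
  rep_id <- verify_against_reference(ref, ref)
  expect_true(attr(rep_id, "ok"))
  expect_true(all(rep_id$match))
  small <- build_custom_unet(c(512, 512, 3), base_filters = 4)
  rep_bad <- verify_against_reference(layer_table(small), ref)
  expect_false(attr(rep_bad, "ok"))
  expect_false(rep_bad$match[2])        # first conv filter count differs
})

test_that("shape-formula parameter counts equal the allocated weights", {
  for (net in list(build_custom_unet(c(64, 64, 3)),
                   build_msu_net(c(64, 64, 3)),
                   build_backbone_unet("tiny_resnet", c(64, 64, 3)))) {
    tab <- layer_table(net)
    expect_equal(sum(tab$params), n_params(net))
    # per-layer: every parameterized row matches its weight array exactly
    for (id in seq_along(net$params)) {
      p <- net$params[[id]]
      if (!is.null(p))
        expect_equal(tab$params[id], length(p$W) + length(p$b))
    }
  }
})

test_that("input sizes not divisible by 16 are rejected", {
  expect_error(build_custom_unet(c(100, 100, 3)), "divisible by 16")
  expect_error(build_msu_net(c(48, 50, 3)), "divisible by 16")
})

test_that("softmax head yields a probability simplex; inference is deterministic", {
  net <- build_custom_unet(c(32, 32, 3), seed = 5)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  p1 <- predict_net(net, x)
  expect_equal(dim(p1), c(32L, 32L, 6L))
  expect_lt(max(abs(apply(p1, c(1, 2), sum) - 1)), 1e-6)
  expect_identical(p1, predict_net(net, x))    # dropout off at inference
  # same seed, same weights
  net2 <- build_custom_unet(c(32, 32, 3), seed = 5)
  expect_identical(predict_net(net2, x), p1)
})

test_that("MSU-Net is multi-label: sigmoid range, K channels, no simplex", {
  net <- build_msu_net(c(32, 32, 3), K = 2, scales = 3, seed = 3)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  p <- predict_net(net, x)
  expect_equal(dim(p), c(32L, 32L, 2L))
  expect_true(all(p >= 0 & p <= 1))
  sums <- apply(p, c(1, 2), sum)
  expect_gt(max(abs(sums - 1)), 1e-3)   # channel sums are unconstrained
  expect_error(build_msu_net(c(32, 32, 3), scales = 5), "scales")
})

test_that("BU-Net side heads cover the decoder and output at full resolution", {
  base <- build_msu_net(c(32, 32, 3), K = 2, seed = 2)
  net <- build_bu_net(base, M = 4)
  expect_length(net$side, 4)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  fs <- asNamespace("fundusseg")
  cache <- fs$forward_net(net, x)
  for (s in net$side) {
    out <- cache$acts[[s$out]]
    expect_equal(dim(out)[1:2], c(32L, 32L))
    expect_equal(dim(out)[3], 2L)
    expect_true(all(out >= 0 & out <= 1))
  }
  # M = 1 attaches a single auxiliary head
  base1 <- build_msu_net(c(32, 32, 3), K = 2, seed = 2)
  net1 <- build_bu_net(base1, M = 1, fusion_weights = 0.25)
  expect_length(net1$side, 1)
  expect_error(build_bu_net(build_msu_net(c(32, 32, 3)), M = 9), "between 1")
  # with all-perfect side heads the fused extra loss vanishes (Eq. 8 at zero)
  expect_equal(side_output_loss(rep(0, 4), rep(0.25, 4)), 0)
})

test_that("backbone registry round-trips and rejects unknown names", {
  expect_error(build_backbone_unet("resnet5000", c(32, 32, 3)), "available")
  expect_error(build_backbone_unet("tiny_resnet", c(32, 32, 3), pretrained = TRUE),
               "pretrained")
  for (nm in list_backbones()) {
    net <- build_backbone_unet(nm, c(32, 32, 3), n_classes = 4, seed = 1)
    p <- predict_net(net, array(runif(32 * 32 * 3), c(32, 32, 3)))
    expect_equal(dim(p), c(32L, 32L, 4L))
  }
})

test_that("training gradients match finite differences through the graph", {
  fs <- asNamespace("fundusseg")
  net <- build_custom_unet(c(16, 16, 2), n_classes = 3, dropout_rate = 0,
                           seed = 7)
  x <- array(runif(16 * 16 * 2), c(16, 16, 2))
  g <- matrix(sample(0:2, 256, TRUE), 16, 16)
  y <- fs$one_hot(g, 3)
  loss_of <- function() {
    p <- predict_net(net, x)
    -sum(y * log(pmax(p, 1e-12))) / 256
  }
  cache <- fs$forward_net(net, x)
  p <- cache$acts[[net$head_node]]
  grads <- fs$backward_net(net, cache,
    seed_pre = setNames(list((p - y) / 256), as.character(net$logits_node)))
  set.seed(1)
  for (id in which(!vapply(grads, is.null, logical(1)))) {
    W <- net$params[[id]]$W
    i <- sample(length(W), 1)
    h <- 1e-5
    net$params[[id]]$W[i] <- W[i] + h; Lp <- loss_of()
    net$params[[id]]$W[i] <- W[i] - h; Lm <- loss_of()
    net$params[[id]]$W[i] <- W[i]
    fd <- (Lp - Lm) / (2 * h)
    expect_equal(grads[[id]]$gW[i], fd, tolerance = 1e-4)
  }
})
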