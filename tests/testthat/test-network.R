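test_that("the default channel trace reproduces the published architecture table", {
  tr <- channel_trace(architecture_config(), c(200L, 200L))
  expected <- data.frame(
    block = c("Input", "Convolution + Dropout",
              rep("Dense block + Transition down", 4), "Dense block",
              rep("Transition up + Dense block", 4), "1 x 1 Convolution",
              "Softmax"),
    channels = c(4, 48, 96, 144, 192, 240, 288, 336, 288, 240, 192, 2, 2),
    height = c(200, 200, 200, 100, 50, 25, 12, 25, 50, 100, 200, 200, 200),
    width = c(200, 200, 200, 100, 50, 25, 12, 25, 50, 100, 200, 200, 200),
    stringsAsFactors = FALSE)
  expect_equal(tr, expected)
})

test_that("the trace follows floor-halving and exact skip restoration at 64x64", {
  tr <- channel_trace(architecture_config(), c(64L, 64L))
  bott <- tr[tr$block == "Dense block", ]
  expect_equal(unlist(bott[c("channels", "height", "width")], use.names = FALSE),
               c(288, 4, 4))
  expect_equal(tr$height[tr$block == "Softmax"], 64)
  # encoder extents replay 64 -> 32 -> 16 -> 8, mirrored by the decoder
  enc <- tr$height[tr$block == "Dense block + Transition down"]
  expect_equal(enc, c(64, 32, 16, 8))
  dec <- tr$height[tr$block == "Transition up + Dense block"]
  expect_equal(dec, c(8, 16, 32, 64))
})

test_that("channel accounting holds for non-default configurations", {
  cfg <- architecture_config(stem_channels = 10L, growth_rate = 2L,
                             units_per_block = 3L, levels = 3L)
  tr <- channel_trace(cfg, c(32L, 32L))
  expect_equal(tr$channels[tr$block == "Dense block + Transition down"],
               c(16, 22, 28))        # each dense block adds units*growth = 6
  expect_equal(tr$channels[tr$block == "Dense block"], 34)
  expect_equal(tr$channels[tr$block == "Transition up + Dense block"],
               c(6 + 28 + 6, 6 + 22 + 6, 6 + 16 + 6))
})

test_that("invalid configurations and inputs are rejected", {
  expect_error(architecture_config(dropout_p = 1.0), "dropout_p")
  expect_error(architecture_config(levels = 0), ">= 1")
  expect_error(channel_trace(architecture_config(), c(10L, 200L)), "minimum")
  net <- build_network(tiny_arch(), seed = 1)
  expect_error(network_forward(net, array(0, c(16, 16, 1, 3))), "channels")
  expect_error(network_forward(net, array(0, c(2, 16, 1, 4))), "minimum")
})

test_that("forward preserves spatial extent and yields normalized probabilities", {
  net <- build_network(tiny_arch(), seed = 7)
  set.seed(1)
  x <- array(rnorm(21 * 19 * 2 * 4), c(21, 19, 2, 4))   # odd extents
  fw <- network_forward(net, x)
  expect_equal(dim(fw$probs), c(21, 19, 2, 2))
  sums <- fw$probs[, , , 1] + fw$probs[, , , 2]
  expect_lt(max(abs(sums - 1)), 1e-5)
  # evaluation mode is deterministic
  fw2 <- network_forward(net, x)
  expect_identical(fw$probs, fw2$probs)
  # 3D single-slice input is promoted
  fw3 <- network_forward(net, x[, , 1, ])
  expect_equal(dim(fw3$probs), c(21, 19, 1, 2))
  expect_equal(fw3$probs[, , 1, ], fw$probs[, , 1, ], tolerance = 1e-12)
})

test_that("parameter count is a pure function of the configuration", {
  net <- build_network(architecture_config(), seed = 1)
  expect_equal(parameter_count(net), 2390450)
  net2 <- build_network(architecture_config(), seed = 99)
  expect_equal(parameter_count(net2), 2390450)
  expect_equal(parameter_count(build_network(tiny_arch(), seed = 1)),
               parameter_count(build_network(tiny_arch(), seed = 2)))
})

test_that("analytic gradients match central differences", {
  cfg <- architecture_config(in_channels = 3L, stem_channels = 4L,
                             growth_rate = 2L, units_per_block = 2L,
                             levels = 2L, dropout_p = 0)
  net <- build_network(cfg, seed = 1)
  set.seed(3)
  X <- array(rnorm(9 * 11 * 2 * 3), c(9, 11, 2, 3))
  Tg <- array(sample(0:1, 9 * 11 * 2, TRUE), c(9, 11, 2))
  fw <- cavityseg:::network_forward(net, X, training = TRUE, keep_cache = TRUE)
  cg <- cavityseg:::ce_loss_grad(fw$logits, Tg)
  gr <- cavityseg:::network_backward(net, fw$cache, cg$dZ)
  lossfun <- function(n) {
    f <- cavityseg:::network_forward(n, X, training = TRUE, keep_cache = FALSE)
    cavityseg:::ce_loss_grad(f$logits, Tg)$loss
  }
  eps <- 1e-6
  set.seed(11)
  worst <- 0
  for (nm in names(gr)) for (f in names(gr[[nm]])) {
    i <- sample(length(gr[[nm]][[f]]), 1L)
    n1 <- net; n1$params[[nm]][[f]][i] <- n1$params[[nm]][[f]][i] + eps
    n2 <- net; n2$params[[nm]][[f]][i] <- n2$params[[nm]][[f]][i] - eps
    num <- (lossfun(n1) - lossfun(n2)) / (2 * eps)
    worst <- max(worst, abs(num - gr[[nm]][[f]][i]) /
                   max(1e-8, abs(num) + abs(gr[[nm]][[f]][i])))
  }
  expect_lt(worst, 1e-4)
})

test_that("parameter initialization is reproducible per seed", {
  n1 <- build_network(tiny_arch(), seed = 5)
  n2 <- build_network(tiny_arch(), seed = 5)
  n3 <- build_network(tiny_arch(), seed = 6)
  expect_identical(n1$params, n2$params)
  expect_false(identical(n1$params$stem.conv$W, n3$params$stem.conv$W))
})
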