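# The densely connected fully-convolutional encoder-decoder.
#
# Structure: stem convolution (+dropout); `levels` encoder stages each made
# of a dense block (units_per_block densely connected units, each adding
# growth_rate channels) followed by a channel-preserving transition-down
# (dense unit + 2x2 max-pool); a bottleneck dense block; `levels` decoder
# stages each made of a transition-up (bilinear upsampling to the stored skip
# size + convolution compressing to units_per_block*growth_rate channels),
# concatenation with the skip, and a dense block; a final 1x1 convolution to
# the class logits and a softmax. Every dense unit is batch-norm -> ReLU ->
# 3x3 convolution -> dropout.

#' Architecture hyperparameters
#'
#' With the defaults the channel/resolution trace of the network reproduces
#' the published architecture description exactly: encoder channels
#' 48, 96, 144, 192, 240, bottleneck 288, decoder 336, 288, 240, 192, output 2.
#' `growth_rate = 12` follows from each dense block adding 48 channels across
#' its four units.
#'
#' @param in_channels input channels (four MR sequences).
#' @param stem_channels channels after the stem convolution.
#' @param growth_rate channels added by each dense unit.
#' @param units_per_block dense units per dense block.
#' @param levels contraction-expansion levels.
#' @param dropout_p dropout probability in \[0, 1).
#' @param kernel spatial kernel extent of all convolutions except the final
#'   1x1 (only 3 is supported).
#' @param classes output classes (foreground/background).
#' @return an `architecture_config` list.
#' @export
architecture_config <- function(in_channels = 4L, stem_channels = 48L,
                                growth_rate = 12L, units_per_block = 4L,
                                levels = 4L, dropout_p = 0.2, kernel = 3L,
                                classes = 2L) {
  counts <- c(in_channels = in_channels, stem_channels = stem_channels,
              growth_rate = growth_rate, units_per_block = units_per_block,
              levels = levels, classes = classes)
  if (any(counts < 1))
    stop("architecture_config: all counts must be >= 1")
  if (dropout_p < 0 || dropout_p >= 1)
    stop("architecture_config: dropout_p must lie in [0, 1)")
  if (kernel != 3L)
    stop("architecture_config: only 3x3 kernels are supported")
  structure(as.list(c(as.list(counts), list(dropout_p = dropout_p,
                                            kernel = kernel))),
            class = "architecture_config")
}

# Channel bookkeeping shared by the builder, the forward pass, and the trace.
arch_channels <- function(config) {
  add <- config$units_per_block * config$growth_rate
  L <- config$levels
  enc_in <- config$stem_channels + (seq_len(L) - 1L) * add
  enc_out <- config$stem_channels + seq_len(L) * add   # also the skip widths
  bott_out <- enc_out[L] + add
  dec_in <- integer(L)   # channels entering decoder dense block at level l
  dec_out <- integer(L)
  below <- bott_out
  for (l in rev(seq_len(L))) {
    dec_in[l] <- add + enc_out[l]
    dec_out[l] <- dec_in[l] + add
    below <- dec_out[l]
  }
  tu_in <- c(if (L > 1) dec_out[seq(2L, L)] else integer(0), bott_out)
  list(add = add, enc_in = enc_in, enc_out = enc_out, bott_out = bott_out,
       dec_in = dec_in, dec_out = dec_out, tu_in = tu_in)
}

init_conv3 <- function(cin, cout) {
  list(W = matrix(rnorm(9L * cin * cout, 0, sqrt(2 / (9 * cin))), 9L * cin, cout),
       b = numeric(cout))
}

init_conv1 <- function(cin, cout) {
  list(W = matrix(rnorm(cin * cout, 0, sqrt(2 / cin)), cin, cout),
       b = numeric(cout))
}

init_bn <- function(c) list(gamma = rep(1, c), beta = rep(0, c))

#' Build a network from an architecture config
#'
#' Parameters are initialized with rectifier-scaled (He) Gaussian weights from
#' a seedable generator; batch-norm scales start at 1, biases and shifts at 0.
#'
#' @param config an [architecture_config()].
#' @param seed optional integer seed for weight initialization.
#' @return an object of class `rc_network` holding `config`, `params`, and
#'   batch-norm running statistics `bn_state`.
#' @export
build_network <- function(config, seed = NULL) {
  if (!inherits(config, "architecture_config")) config <- do.call(architecture_config, config)
  ch <- arch_channels(config)
  L <- config$levels; U <- config$units_per_block; g <- config$growth_rate
  params <- list()
  bn_state <- list()
  add_unit <- function(name, cin, cout) {
    params[[paste0(name, ".bn")]] <<- init_bn(cin)
    bn_state[[paste0(name, ".bn")]] <<- list(mean = numeric(cin), var = rep(1, cin))
    params[[paste0(name, ".conv")]] <<- init_conv3(cin, cout)
  }
  with_seed(seed, {
    params[["stem.conv"]] <- init_conv3(config$in_channels, config$stem_channels)
    for (l in seq_len(L)) {
      cin <- ch$enc_in[l]
      for (u in seq_len(U)) {
        add_unit(sprintf("enc%d.u%d", l, u), cin, g)
        cin <- cin + g
      }
      add_unit(sprintf("td%d", l), cin, cin)   # channel-preserving
    }
    cin <- ch$enc_out[L]
    for (u in seq_len(U)) {
      add_unit(sprintf("bott.u%d", u), cin, g)
      cin <- cin + g
    }
    for (l in rev(seq_len(L))) {
      params[[sprintf("tu%d.conv", l)]] <- init_conv3(ch$tu_in[l], ch$add)
      cin <- ch$dec_in[l]
      for (u in seq_len(U)) {
        add_unit(sprintf("dec%d.u%d", l, u), cin, g)
        cin <- cin + g
      }
    }
    params[["final.conv"]] <- init_conv1(ch$dec_out[1L], config$classes)
  })
  structure(list(config = config, params = params, bn_state = bn_state),
            class = "rc_network")
}

#' Total number of trainable parameters
#' @param network an `rc_network`.
#' @return integer count.
#' @export
parameter_count <- function(network) {
  sum(vapply(network$params, function(p) sum(vapply(p, length, 0L)), 0L))
}

## ---- forward / backward ----

dense_unit_fwd <- function(net, name, X, training, env) {
  p <- net$params
  bn_name <- paste0(name, ".bn")
  bnr <- bn_fwd(X, p[[bn_name]]$gamma, p[[bn_name]]$beta,
                env$bn[[bn_name]], training)
  if (training) env$bn[[bn_name]] <- bnr$state
  r <- relu_fwd(bnr$out)
  cv <- conv3_fwd(r$out, p[[paste0(name, ".conv")]]$W,
                  p[[paste0(name, ".conv")]]$b)
  dp <- dropout_fwd(cv$out, net$config$dropout_p, training)
  list(out = dp$out,
       cache = list(bn = bnr$cache, relu = r$cache, conv = cv$cache,
                    drop = dp$cache))
}

dense_unit_bwd <- function(net, name, dF, cache, acc) {
  p <- net$params
  d1 <- dropout_bwd(dF, cache$drop)
  cb <- conv3_bwd(d1, cache$conv, p[[paste0(name, ".conv")]]$W)
  acc(paste0(name, ".conv"), list(W = cb$dW, b = cb$db))
  d2 <- relu_bwd(cb$dX, cache$relu)
  bb <- bn_bwd(d2, cache$bn, p[[paste0(name, ".bn")]]$gamma)
  acc(paste0(name, ".bn"), list(gamma = bb$dgamma, beta = bb$dbeta))
  bb$dX
}

dense_block_fwd <- function(net, prefix, X, training, env) {
  caches <- vector("list", net$config$units_per_block)
  for (u in seq_len(net$config$units_per_block)) {
    r <- dense_unit_fwd(net, sprintf("%s.u%d", prefix, u), X, training, env)
    caches[[u]] <- r$cache
    X <- concat_c(X, r$out)
  }
  list(out = X, cache = caches)
}

dense_block_bwd <- function(net, prefix, dX, caches, acc) {
  g <- net$config$growth_rate
  for (u in rev(seq_len(net$config$units_per_block))) {
    sp <- split_c(dX, dim(dX)[4] - g)
    dprev <- sp$dA
    dunit <- dense_unit_bwd(net, sprintf("%s.u%d", prefix, u), sp$dB,
                            caches[[u]], acc)
    dX <- dprev + dunit
  }
  dX
}

#' Forward pass of the network
#'
#' @param network an `rc_network` from [build_network()].
#' @param x numeric array of dim (H, W, batch, channels) — channels-last, so
#'   the matrix view used by the BLAS products is copy-free; a 3D
#'   (H, W, channels) array is promoted to a single-slice batch. H and W must
#'   each be at least `2^levels`.
#' @param training logical; training mode enables dropout (consuming the R
#'   RNG stream) and batch statistics; evaluation mode is deterministic.
#' @param keep_cache keep intermediate activations for a backward pass.
#' @return list with `probs` (per-pixel class probabilities, summing to 1 over
#'   the class axis), `logits`, and when requested `cache` and the updated
#'   `bn_state`.
#' @export
network_forward <- function(network, x, training = FALSE, keep_cache = training) {
  cfg <- network$config
  d <- dim(x)
  if (length(d) == 3L) { dim(x) <- c(d[1], d[2], 1L, d[3]); d <- dim(x) }
  if (d[4] != cfg$in_channels)
    stop("network_forward: expected ", cfg$in_channels, " channels, got ", d[4])
  min_ext <- 2^cfg$levels
  if (d[1] < min_ext || d[2] < min_ext)
    stop("network_forward: spatial extent ", d[1], "x", d[2],
         " below the architecture minimum of ", min_ext, "x", min_ext)
  env <- new.env(parent = emptyenv())
  env$bn <- network$bn_state
  L <- cfg$levels
  K <- list()  # cache

  cv <- conv3_fwd(x, network$params[["stem.conv"]]$W,
                  network$params[["stem.conv"]]$b)
  dp <- dropout_fwd(cv$out, cfg$dropout_p, training)
  K$stem <- list(conv = cv$cache, drop = dp$cache)
  X <- dp$out

  skips <- vector("list", L)
  K$enc <- K$td <- vector("list", L)
  for (l in seq_len(L)) {
    db <- dense_block_fwd(net = network, prefix = sprintf("enc%d", l), X,
                          training, env)
    K$enc[[l]] <- db$cache
    skips[[l]] <- db$out
    u <- dense_unit_fwd(network, sprintf("td%d", l), db$out, training, env)
    pl <- pool2_fwd(u$out)
    K$td[[l]] <- list(unit = u$cache, pool = pl$cache)
    X <- pl$out
  }

  db <- dense_block_fwd(network, "bott", X, training, env)
  K$bott <- db$cache
  X <- db$out

  K$tu <- K$dec <- vector("list", L)
  for (l in rev(seq_len(L))) {
    tgt <- dim(skips[[l]])
    up <- upsample_fwd(X, tgt[1], tgt[2])
    cv <- conv3_fwd(up$out, network$params[[sprintf("tu%d.conv", l)]]$W,
                    network$params[[sprintf("tu%d.conv", l)]]$b)
    K$tu[[l]] <- list(up = up$cache, conv = cv$cache,
                      skip_channels = tgt[4])
    X <- concat_c(cv$out, skips[[l]])
    db <- dense_block_fwd(network, sprintf("dec%d", l), X, training, env)
    K$dec[[l]] <- db$cache
    X <- db$out
  }

  fc <- conv1_fwd(X, network$params[["final.conv"]]$W,
                  network$params[["final.conv"]]$b)
  K$final <- fc$cache
  logits <- fc$out
  out <- list(probs = softmax_c(logits), logits = logits,
              bn_state = env$bn)
  if (keep_cache) out$cache <- K
  out
}

# Backward pass: gradient of the scalar loss w.r.t. every parameter given
# d(loss)/d(logits). Returns a named list mirroring network$params.
network_backward <- function(network, cache, dlogits) {
  cfg <- network$config
  L <- cfg$levels
  add <- cfg$units_per_block * cfg$growth_rate
  grads <- list()
  acc <- function(name, g) {
    if (is.null(grads[[name]])) grads[[name]] <<- g
    else grads[[name]] <<- Map(`+`, grads[[name]], g)
  }

  fb <- conv1_bwd(dlogits, cache$final, network$params[["final.conv"]]$W)
  acc("final.conv", list(W = fb$dW, b = fb$db))
  dX <- fb$dX

  dskip <- vector("list", L)
  for (l in seq_len(L)) {     # decoder ran levels..1; reverse is 1..levels
    dX <- dense_block_bwd(network, sprintf("dec%d", l), dX, cache$dec[[l]], acc)
    sp <- split_c(dX, dim(dX)[4] - cache$tu[[l]]$skip_channels)
    dskip[[l]] <- sp$dB
    cb <- conv3_bwd(sp$dA, cache$tu[[l]]$conv,
                    network$params[[sprintf("tu%d.conv", l)]]$W)
    acc(sprintf("tu%d.conv", l), list(W = cb$dW, b = cb$db))
    dX <- upsample_bwd(cb$dX, cache$tu[[l]]$up)
  }

  dX <- dense_block_bwd(network, "bott", dX, cache$bott, acc)

  for (l in rev(seq_len(L))) {
    dpool <- pool2_bwd(dX, cache$td[[l]]$pool)
    dS <- dense_unit_bwd(network, sprintf("td%d", l), dpool,
                         cache$td[[l]]$unit, acc)
    dS <- dS + dskip[[l]]
    dX <- dense_block_bwd(network, sprintf("enc%d", l), dS, cache$enc[[l]], acc)
  }

  d1 <- dropout_bwd(dX, cache$stem$drop)
  sb <- conv3_bwd(d1, cache$stem$conv, network$params[["stem.conv"]]$W)
  acc("stem.conv", list(W = sb$dW, b = sb$db))
  grads
}

## ---- channel trace ----

#' Channel and resolution trace of the architecture
#'
#' Lists every building block with its output channel count and the spatial
#' resolution at which it computes, mirroring the published architecture
#' table. Pooling halves extents with floor semantics; upsampling restores
#' the exact stored skip extents, so odd sizes are lossless.
#'
#' @param config an [architecture_config()].
#' @param input_size length-2 integer spatial extent (H, W).
#' @return data.frame with columns `block`, `channels`, `height`, `width`.
#' @export
channel_trace <- function(config = architecture_config(),
                          input_size = c(200L, 200L)) {
  if (!inherits(config, "architecture_config")) config <- do.call(architecture_config, config)
  L <- config$levels
  min_ext <- 2^L
  if (any(input_size < min_ext))
    stop("channel_trace: input extent ", paste(input_size, collapse = "x"),
         " below the architecture minimum of ", min_ext, " per axis")
  ch <- arch_channels(config)
  H <- input_size[1]; W <- input_size[2]
  rows <- list()
  push <- function(block, channels, h, w)
    rows[[length(rows) + 1L]] <<- data.frame(block = block, channels = channels,
                                             height = h, width = w,
                                             stringsAsFactors = FALSE)
  push("Input", config$in_channels, H, W)
  push("Convolution + Dropout", config$stem_channels, H, W)
  h <- H; w <- W
  for (l in seq_len(L)) {
    push("Dense block + Transition down", ch$enc_out[l], h, w)
    h <- h %/% 2L; w <- w %/% 2L
  }
  push("Dense block", ch$bott_out, h, w)
  # decoder restores the stored skip extents in reverse
  hs <- H; ws <- W
  ext <- matrix(0L, L, 2L)
  for (l in seq_len(L)) { ext[l, ] <- c(hs, ws); hs <- hs %/% 2L; ws <- ws %/% 2L }
  for (l in rev(seq_len(L)))
    push("Transition up + Dense block", ch$dec_out[l], ext[l, 1], ext[l, 2])
  push("1 x 1 Convolution", config$classes, H, W)
  push("Softmax", config$classes, H, W)
  do.call(rbind, rows)
}
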