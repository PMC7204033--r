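# Slice sampling, the optimization loop, and cross-validation partitioning.

ORIENTATIONS <- c("axial", "coronal", "sagittal")

#' Training hyperparameters
#'
#' Defaults follow the published protocol: batches of 16 slices of random
#' orientation, cross-entropy loss, Adam with learning rate 1e-4 (standard
#' moment parameters beta1 = 0.9, beta2 = 0.999). The stopping rule is a
#' fixed number of epochs of `steps_per_epoch` optimization steps.
#'
#' @param batch_size slices per optimization step.
#' @param learning_rate Adam step size.
#' @param epochs number of training epochs.
#' @param steps_per_epoch optimization steps per epoch.
#' @param seed integer seed controlling slice sampling and dropout.
#' @param orientations subset of `c("axial", "coronal", "sagittal")` to
#'   sample slices from.
#' @return a `training_config` list.
#' @export
training_config <- function(batch_size = 16L, learning_rate = 1e-4,
                            epochs = 5L, steps_per_epoch = 50L, seed = 1L,
                            orientations = ORIENTATIONS) {
  if (batch_size < 1L) stop("training_config: batch_size must be >= 1")
  if (learning_rate < 0) stop("training_config: learning_rate must be >= 0")
  if (epochs < 1L) stop("training_config: epochs must be >= 1")
  orientations <- match.arg(orientations, ORIENTATIONS, several.ok = TRUE)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 optimizer = "adam", loss = "cross-entropy",
                 epochs = as.integer(epochs),
                 steps_per_epoch = as.integer(steps_per_epoch),
                 seed = as.integer(seed), orientations = orientations),
            class = "training_config")
}

#' Deterministic k-fold cross-validation splits
#'
#' Cases are shuffled once (seeded) and partitioned into k test sets whose
#' sizes differ by at most one; each case appears in exactly one test set.
#' The first fold is flagged as the hyperparameter-tuning fold, mirroring the
#' protocol of optimizing hyperparameters on a single split only.
#'
#' @param case_ids character vector of case identifiers.
#' @param k number of folds (>= 2).
#' @param seed integer shuffle seed.
#' @return list of `fold_split` lists with `fold_index`, `train_ids`,
#'   `test_ids`, `is_tuning_fold`.
#' @export
make_cv_splits <- function(case_ids, k, seed = 1L) {
  n <- length(case_ids)
  if (k < 2L) stop("make_cv_splits: k must be >= 2")
  if (k > n) stop("make_cv_splits: k (", k, ") exceeds number of cases (", n, ")")
  shuffled <- with_seed(seed, sample(case_ids))
  sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  lapply(seq_len(k), function(i) {
    test <- shuffled[starts[i]:ends[i]]
    structure(list(fold_index = i, train_ids = setdiff(case_ids, test),
                   test_ids = test, is_tuning_fold = i == 1L),
              class = "fold_split")
  })
}

## ---- slice access ----

# Stack the four normalized channels of a study into (d1, d2, d3, 4).
study_tensor <- function(study) {
  d <- dim(study$t1$values)
  x <- array(0, c(d, 4L))
  x[, , , 1] <- study$t1$values
  x[, , , 2] <- study$t1gad$values
  x[, , , 3] <- study$t2$values
  x[, , , 4] <- study$flair$values
  x
}

# Extract one multi-channel slice: axial fixes axis 3, coronal axis 2,
# sagittal axis 1. Returns (H, W, 4).
extract_slice <- function(tensor, orientation, index) {
  switch(orientation,
         axial = tensor[, , index, , drop = TRUE],
         coronal = tensor[, index, , , drop = TRUE],
         sagittal = tensor[index, , , , drop = TRUE])
}

extract_label_slice <- function(values, orientation, index) {
  switch(orientation,
         axial = values[, , index, drop = TRUE],
         coronal = values[, index, , drop = TRUE],
         sagittal = values[index, , , drop = TRUE])
}

# Indices of slices whose plane intersects the foreground mask.
eligible_slices <- function(fg_values) {
  list(axial = which(apply(fg_values, 3L, any)),
       coronal = which(apply(fg_values, 2L, any)),
       sagittal = which(apply(fg_values, 1L, any)))
}

# Internal prepared form of the training set.
prepare_cases <- function(training_cases) {
  lapply(training_cases, function(cs) {
    x <- study_tensor(cs$study)
    fg <- (x[, , , 1] != 0) | (x[, , , 2] != 0) | (x[, , , 3] != 0) |
      (x[, , , 4] != 0)
    list(x = x, y = cs$reference$values, eligible = eligible_slices(fg))
  })
}

#' Sample a batch of random slices
#'
#' Each slice is drawn by uniformly choosing a case, an orientation from the
#' configured set, and a slice index whose plane intersects that case's brain
#' foreground. Targets are the matching reference slices. Slices are kept at
#' native in-plane size; the batch is returned grouped by slice size so each
#' group can be forwarded as one tensor.
#'
#' @param studies list of `list(study =, reference =)` pairs (normalized).
#' @param config a [training_config()].
#' @param prepared optional output of the internal case preparation (used by
#'   the training loop to avoid re-stacking volumes each step).
#' @return list of groups `list(x, y, orientation, case)`; `x` is
#'   (H, W, n, 4) — channels last — and `y` is (H, W, n).
#' @export
sample_slice_batch <- function(studies, config = training_config(),
                               prepared = NULL) {
  if (length(studies) < 1L) stop("sample_slice_batch: need at least one study")
  if (is.null(prepared)) prepared <- prepare_cases(studies)
  if (all(vapply(prepared, function(p) all(lengths(p$eligible) == 0L), TRUE)))
    stop("sample_slice_batch: no study has foreground voxels")
  n <- config$batch_size
  draws <- vector("list", n)
  for (i in seq_len(n)) {
    repeat {
      ci <- sample.int(length(prepared), 1L)
      oi <- config$orientations[sample.int(length(config$orientations), 1L)]
      el <- prepared[[ci]]$eligible[[oi]]
      if (length(el)) break
    }
    si <- el[sample.int(length(el), 1L)]
    xs <- extract_slice(prepared[[ci]]$x, oi, si)
    ys <- extract_label_slice(prepared[[ci]]$y, oi, si)
    draws[[i]] <- list(x = xs, y = ys, orientation = oi, case = ci)
  }
  sig <- vapply(draws, function(d) paste(dim(d$x)[1:2], collapse = "x"), "")
  groups <- lapply(unique(sig), function(s) {
    sel <- draws[sig == s]
    d2 <- dim(sel[[1]]$x)[1:2]
    x <- array(0, c(d2, length(sel), 4L))    # (H, W, batch, channels)
    y <- array(0, c(d2, length(sel)))
    for (j in seq_along(sel)) { x[, , j, ] <- sel[[j]]$x; y[, , j] <- sel[[j]]$y }
    list(x = x, y = y,
         orientation = vapply(sel, `[[`, "", "orientation"),
         case = vapply(sel, `[[`, 0L, "case"))
  })
  groups
}

## ---- Adam ----

adam_init <- function(params) {
  list(m = lapply(params, function(p) lapply(p, function(a) a * 0)),
       v = lapply(params, function(p) lapply(p, function(a) a * 0)),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) for (f in names(grads[[nm]])) {
    g <- grads[[nm]][[f]]
    state$m[[nm]][[f]] <- beta1 * state$m[[nm]][[f]] + (1 - beta1) * g
    state$v[[nm]][[f]] <- beta2 * state$v[[nm]][[f]] + (1 - beta2) * g^2
    params[[nm]][[f]] <- params[[nm]][[f]] -
      lr * (state$m[[nm]][[f]] / bc1) / (sqrt(state$v[[nm]][[f]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# One optimization step over a grouped batch: cross-entropy averaged over all
# pixels in the batch, gradients accumulated across size groups.
train_step <- function(network, groups) {
  npix <- vapply(groups, function(g) prod(dim(g$y)), 0)
  w <- npix / sum(npix)
  total_loss <- 0
  grads <- NULL
  for (i in seq_along(groups)) {
    fw <- network_forward(network, groups[[i]]$x, training = TRUE)
    network$bn_state <- fw$bn_state
    cg <- ce_loss_grad(fw$logits, groups[[i]]$y)
    total_loss <- total_loss + w[i] * cg$loss
    gi <- network_backward(network, fw$cache, cg$dZ * w[i])
    grads <- if (is.null(grads)) gi else
      Map(function(a, b) Map(`+`, a, b), grads, gi)
  }
  list(loss = total_loss, grads = grads, network = network)
}

#' Train a network on preprocessed cases
#'
#' Optimizes pixel-wise cross-entropy with Adam over randomly sampled slice
#' batches. Deterministic per `config$seed` (sampling and dropout share one
#' seeded stream). A non-finite loss aborts with the failing step index.
#'
#' @param network an `rc_network` from [build_network()].
#' @param training_cases list of `list(study =, reference =)` pairs; studies
#'   must be normalized ([zscore_normalize()]) and references fused.
#' @param config a [training_config()].
#' @return list with `network` (trained) and `loss_history` (per-step mean
#'   cross-entropy).
#' @export
train <- function(network, training_cases, config = training_config()) {
  prepared <- prepare_cases(training_cases)
  steps <- config$epochs * config$steps_per_epoch
  loss_history <- numeric(steps)
  opt <- adam_init(network$params)
  with_seed(config$seed, {
    for (s in seq_len(steps)) {
      groups <- sample_slice_batch(training_cases, config, prepared)
      st <- train_step(network, groups)
      network <- st$network
      if (!is.finite(st$loss))
        stop("train: non-finite loss at step ", s)
      loss_history[s] <- st$loss
      if (config$learning_rate > 0) {
        upd <- adam_step(network$params, st$grads, opt, config$learning_rate)
        network$params <- upd$params
        opt <- upd$state
      }
    }
  })
  list(network = network, loss_history = loss_history)
}
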