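#' Cascade CNN model configuration
#'
#' The network has two routes. The global route takes 40 x 40
#' eight-channel patches through five 3 x 3 convolution layers (ReLU)
#' with 2 x 2 max-pooling after the second and fourth; the local route
#' takes 15 x 15 patches through two 3 x 3 convolution layers. Both
#' routes are flattened and concatenated, the distance-wise attention
#' scalar is appended, and a dropout + two-layer fully-connected head
#' with 4-way softmax classifies the center voxel. Filter counts and the
#' FC width are configurable; the defaults are a compact configuration
#' sized for CPU experiments.
#'
#' @param global_filters integer length-5, filters of the global route.
#' @param local_filters integer length-2, filters of the local route.
#' @param fc_width hidden width of the fully-connected head.
#' @param dropout_p dropout probability before the FC head (default 7%).
#' @param n_classes number of output classes (4).
#' @param dwa_enabled append the distance-wise attention scalar to the
#'   flattened features.
#' @param global_size,local_size patch side lengths.
#' @param n_channels input channels (8).
#' @return list of class `model_config`.
#' @export
model_config <- function(global_filters = c(4L, 4L, 8L, 8L, 16L),
                         local_filters = c(8L, 16L),
                         fc_width = 128L, dropout_p = 0.07,
                         n_classes = 4L, dwa_enabled = TRUE,
                         global_size = 40L, local_size = 15L,
                         n_channels = 8L) {
  stopifnot(length(global_filters) == 5L, length(local_filters) == 2L,
            dropout_p >= 0, dropout_p < 1)
  structure(as.list(environment()), class = "model_config")
}

#' Training configuration
#'
#' Adam with batch size 2, weight decay 1e-5 and initial learning rate
#' 1e-4. The batch size is unusually small for patch training and is
#' overridable. Plain SGD is available as a fallback optimizer.
#'
#' @param optimizer "adam" or "sgd".
#' @param lr learning rate.
#' @param weight_decay L2 penalty coefficient.
#' @param batch_size samples per step.
#' @param epochs passes over the training set.
#' @param seed RNG seed controlling initialization order, shuffling and
#'   dropout.
#' @return list of class `train_config`.
#' @export
train_config <- function(optimizer = "adam", lr = 1e-4,
                         weight_decay = 1e-5, batch_size = 2L,
                         epochs = 3L, seed = 1L) {
  stopifnot(optimizer %in% c("adam", "sgd"))
  structure(as.list(environment()), class = "train_config")
}

# im2col index matrix for a valid 3x3-style convolution on an
# (H, W, C) column-major sample. Rows: output positions (column-major
# over (oH, oW)); columns: kernel elements ordered ki, kj, c.
conv_geom <- function(H, W, C, k = 3L) {
  oH <- H - k + 1L; oW <- W - k + 1L
  oi <- rep(0:(oH - 1L), times = oW)
  oj <- rep(0:(oW - 1L), each = oH)
  base <- oi + oj * H
  ki <- rep(0:(k - 1L), times = k * C)
  kj <- rep(rep(0:(k - 1L), each = k), times = C)
  cc <- rep(0:(C - 1L), each = k * k)
  offs <- ki + kj * H + cc * H * W
  idx <- outer(base, offs, `+`) + 1L
  storage.mode(idx) <- "integer"
  list(idx = idx, in_len = H * W * C, npos = oH * oW, K = k * k * C,
       oH = oH, oW = oW, H = H, W = W, C = C)
}

# Build the per-layer geometry of one route. spec: list of
# list(type = "conv", filters = F) or list(type = "pool").
route_geometry <- function(H, W, C, spec) {
  layers <- list()
  for (s in spec) {
    if (s$type == "conv") {
      g <- conv_geom(H, W, C)
      g$type <- "conv"; g$filters <- s$filters
      layers[[length(layers) + 1L]] <- g
      H <- g$oH; W <- g$oW; C <- s$filters
    } else {
      stopifnot(H %% 2L == 0L, W %% 2L == 0L)
      layers[[length(layers) + 1L]] <-
        list(type = "pool", H = H, W = W, C = C,
             in_len = H * W * C, oH = H %/% 2L, oW = W %/% 2L)
      H <- H %/% 2L; W <- W %/% 2L
    }
  }
  list(layers = layers, out = c(H, W, C), flat = H * W * C)
}

#' Initialize a cascade CNN model
#'
#' He-normal initialization, fully determined by the seed.
#'
#' @param config a [model_config()].
#' @param seed RNG seed.
#' @return object of class `cascade_model` holding `config`, the layer
#'   `geometry` and the parameter list `params`.
#' @export
init_cascade <- function(config = model_config(), seed = 1L) {
  gf <- config$global_filters
  gspec <- list(list(type = "conv", filters = gf[1]),
                list(type = "conv", filters = gf[2]),
                list(type = "pool"),
                list(type = "conv", filters = gf[3]),
                list(type = "conv", filters = gf[4]),
                list(type = "pool"),
                list(type = "conv", filters = gf[5]))
  lf <- config$local_filters
  lspec <- list(list(type = "conv", filters = lf[1]),
                list(type = "conv", filters = lf[2]))
  geom <- list(
    global = route_geometry(config$global_size, config$global_size,
                            config$n_channels, gspec),
    local = route_geometry(config$local_size, config$local_size,
                           config$n_channels, lspec)
  )
  fc_in <- geom$global$flat + geom$local$flat +
    (if (config$dwa_enabled) 1L else 0L)
  set.seed(seed)
  params <- list()
  init_conv <- function(route, prefix) {
    for (i in seq_along(route$layers)) {
      g <- route$layers[[i]]
      if (g$type != "conv") next
      nm <- sprintf("%s%d", prefix, i)
      params[[nm]] <<- list(
        W = matrix(rnorm(g$K * g$filters, 0, sqrt(2 / g$K)), g$K, g$filters),
        b = rep(0, g$filters)
      )
    }
  }
  init_conv(geom$global, "g")
  init_conv(geom$local, "l")
  params$fc1 <- list(
    W = matrix(rnorm(fc_in * config$fc_width, 0, sqrt(2 / fc_in)),
               fc_in, config$fc_width),
    b = rep(0, config$fc_width)
  )
  params$fc2 <- list(
    W = matrix(rnorm(config$fc_width * config$n_classes, 0,
                     sqrt(2 / config$fc_width)),
               config$fc_width, config$n_classes),
    b = rep(0, config$n_classes)
  )
  structure(list(config = config, geometry = geom, params = params,
                 fc_in = fc_in, seed = seed),
            class = "cascade_model")
}

#' @export
print.cascade_model <- function(x, ...) {
  np <- sum(vapply(x$params, function(p) length(p$W) + length(p$b), 1))
  cat(sprintf(paste0("<cascade_model> global %s | local %s | fc %d -> %d -> %d",
                     " | dwa %s | %d parameters\n"),
              paste(x$config$global_filters, collapse = "-"),
              paste(x$config$local_filters, collapse = "-"),
              x$fc_in, x$config$fc_width, x$config$n_classes,
              if (x$config$dwa_enabled) "on" else "off", np))
  invisible(x)
}

# Forward one route. x: sample-major vector; returns list(flat matrix
# (n x flat), cache) where cache holds what backward needs.
route_forward <- function(x, route, params, prefix, n, keep_cache = TRUE) {
  cache <- list()
  for (i in seq_along(route$layers)) {
    g <- route$layers[[i]]
    if (g$type == "conv") {
      nm <- sprintf("%s%d", prefix, i)
      cols <- cpp_im2col(x, g$idx, g$in_len, n)
      pre <- cols %*% params[[nm]]$W
      pre <- pre + rep(params[[nm]]$b, each = nrow(pre))
      act <- pre
      act[act < 0] <- 0
      if (keep_cache) {
        cache[[i]] <- list(x = x, cols = cols, pre = pre)
      }
      dim(act) <- c(g$npos, n, g$filters)
      x <- as.vector(aperm(act, c(1L, 3L, 2L)))
    } else {
      pl <- cpp_maxpool2(x, g$H, g$W, g$C * n)
      if (keep_cache) cache[[i]] <- list(argmax = pl$argmax,
                                         xlen = length(x))
      x <- pl$out
    }
  }
  flat <- t(matrix(x, route$flat, n))
  list(flat = flat, cache = cache)
}

route_backward <- function(dflat, route, params, prefix, n, cache) {
  grads <- list()
  dx <- as.vector(t(dflat))
  for (i in rev(seq_along(route$layers))) {
    g <- route$layers[[i]]
    if (g$type == "conv") {
      nm <- sprintf("%s%d", prefix, i)
      d <- array(dx, dim = c(g$npos, g$filters, n))
      d <- aperm(d, c(1L, 3L, 2L))
      dim(d) <- c(g$npos * n, g$filters)
      d[cache[[i]]$pre <= 0] <- 0
      grads[[nm]] <- list(W = crossprod(cache[[i]]$cols, d),
                          b = colSums(d))
      dcols <- d %*% t(params[[nm]]$W)
      dx <- cpp_col2im(dcols, g$idx, g$in_len, n)
    } else {
      dx <- cpp_maxpool2_bwd(dx, cache[[i]]$argmax, cache[[i]]$xlen)
    }
  }
  list(grads = grads, dx = dx)
}

#' Forward pass of the cascade CNN
#'
#' @param model a `cascade_model`.
#' @param xg global patches: array (40, 40, 8, n) or sample-major vector.
#' @param xl local patches: array (15, 15, 8, n) or vector.
#' @param dwa numeric length n (ignored when DWA is disabled).
#' @param train logical; when TRUE dropout is active (uses the current
#'   RNG state) and caches are kept for the backward pass.
#' @return list with `prob` (n x 4 softmax probabilities, rows sum to 1),
#'   `scores` (unnormalized), and (when `train`) `cache`.
#' @export
cascade_forward <- function(model, xg, xl, dwa = NULL, train = FALSE) {
  cfg <- model$config
  n <- length(xg) / (cfg$global_size^2 * cfg$n_channels)
  stopifnot(n == round(n))
  n <- as.integer(n)
  gf <- route_forward(as.vector(xg), model$geometry$global, model$params,
                      "g", n, keep_cache = train)
  lf <- route_forward(as.vector(xl), model$geometry$local, model$params,
                      "l", n, keep_cache = train)
  feats <- cbind(gf$flat, lf$flat)
  if (cfg$dwa_enabled) {
    if (is.null(dwa)) stop("model expects a DWA value per sample")
    feats <- cbind(feats, as.numeric(dwa))
  }
  drop_mask <- NULL
  if (train && cfg$dropout_p > 0) {
    drop_mask <- matrix(
      (runif(length(feats)) >= cfg$dropout_p) / (1 - cfg$dropout_p),
      nrow(feats), ncol(feats))
    feats_d <- feats * drop_mask
  } else {
    feats_d <- feats
  }
  h_pre <- feats_d %*% model$params$fc1$W +
    rep(model$params$fc1$b, each = n)
  h <- h_pre; h[h < 0] <- 0
  scores <- h %*% model$params$fc2$W + rep(model$params$fc2$b, each = n)
  m <- apply(scores, 1, max)
  e <- exp(scores - m)
  prob <- e / rowSums(e)
  out <- list(prob = prob, scores = scores)
  if (train) {
    out$cache <- list(gf = gf$cache, lf = lf$cache, feats_d = feats_d,
                      drop_mask = drop_mask, h_pre = h_pre, h = h, n = n)
  }
  out
}

#' Cross-entropy loss from unnormalized scores
#'
#' `loss_i = -log(exp(U_p) / sum_d exp(U_d))` for true class p; the batch
#' loss is the mean. Also returns the analytic score gradient
#' (softmax - onehot) / n.
#'
#' @param scores n x 4 matrix of unnormalized scores.
#' @param labels integer class indices 0..3, length n.
#' @return list with `loss`, `prob`, `grad`.
#' @export
cascade_loss <- function(scores, labels) {
  if (any(!is.finite(scores))) stop("non-finite scores in loss")
  n <- nrow(scores)
  m <- apply(scores, 1, max)
  e <- exp(scores - m)
  prob <- e / rowSums(e)
  ix <- cbind(seq_len(n), as.integer(labels) + 1L)
  loss <- -mean(log(pmax(prob[ix], 1e-300)))
  grad <- prob
  grad[ix] <- grad[ix] - 1
  list(loss = loss, prob = prob, grad = grad / n)
}

cascade_backward <- function(model, fwd, dscores) {
  cfg <- model$config
  cache <- fwd$cache
  n <- cache$n
  grads <- list()
  grads$fc2 <- list(W = crossprod(cache$h, dscores), b = colSums(dscores))
  dh <- dscores %*% t(model$params$fc2$W)
  dh[cache$h_pre <= 0] <- 0
  grads$fc1 <- list(W = crossprod(cache$feats_d, dh), b = colSums(dh))
  dfeats <- dh %*% t(model$params$fc1$W)
  if (!is.null(cache$drop_mask)) dfeats <- dfeats * cache$drop_mask
  Dg <- model$geometry$global$flat
  Dl <- model$geometry$local$flat
  gb <- route_backward(dfeats[, seq_len(Dg), drop = FALSE],
                       model$geometry$global, model$params, "g", n, cache$gf)
  lb <- route_backward(dfeats[, Dg + seq_len(Dl), drop = FALSE],
                       model$geometry$local, model$params, "l", n, cache$lf)
  c(grads, gb$grads, lb$grads)
}

#' Train the cascade CNN
#'
#' Mini-batch training with Adam (or SGD), cross-entropy loss and L2
#' weight decay. Fully seeded: the same seed, data and configuration
#' reproduce the final weights bit for bit. Training aborts with
#' diagnostics if the loss turns non-finite.
#'
#' @param model a `cascade_model` from [init_cascade()].
#' @param patches a `patch_set` with labels.
#' @param tcfg a [train_config()].
#' @param verbose print per-epoch losses.
#' @return the trained model, with the per-epoch mean loss attached as
#'   `model$loss_curve`.
#' @export
train_cascade <- function(model, patches, tcfg = train_config(),
                          verbose = FALSE) {
  n <- length(patches$label)
  stopifnot(n >= 1)
  set.seed(tcfg$seed)
  state <- list()  # Adam moments
  step <- 0L
  gsz <- model$config$global_size^2 * model$config$n_channels
  lsz <- model$config$local_size^2 * model$config$n_channels
  gvec <- as.vector(patches$global)
  lvec <- as.vector(patches$local)
  curve <- numeric(0)
  for (ep in seq_len(tcfg$epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1, n, by = tcfg$batch_size)) {
      ids <- ord[start:min(start + tcfg$batch_size - 1L, n)]
      xg <- gather_samples(gvec, ids, gsz)
      xl <- gather_samples(lvec, ids, lsz)
      fwd <- cascade_forward(model, xg, xl, patches$dwa[ids], train = TRUE)
      ls <- cascade_loss(fwd$scores, patches$label[ids])
      if (!is.finite(ls$loss)) {
        stop(sprintf("training diverged at epoch %d (loss %g)", ep, ls$loss))
      }
      losses <- c(losses, ls$loss)
      grads <- cascade_backward(model, fwd, ls$grad)
      step <- step + 1L
      upd <- apply_update(model$params, grads, state, tcfg, step)
      model$params <- upd$params
      state <- upd$state
    }
    curve <- c(curve, mean(losses))
    if (verbose) message(sprintf("epoch %d: loss %.4f", ep, mean(losses)))
  }
  model$loss_curve <- curve
  model
}

gather_samples <- function(vec, ids, sample_len) {
  idx <- as.vector(outer(seq_len(sample_len),
                         (ids - 1L) * sample_len, `+`))
  vec[idx]
}

apply_update <- function(params, grads, state, tcfg, step) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (nm in names(grads)) {
    for (part in c("W", "b")) {
      g <- grads[[nm]][[part]]
      if (part == "W" && tcfg$weight_decay > 0) {
        g <- g + tcfg$weight_decay * params[[nm]][[part]]
      }
      key <- paste0(nm, ".", part)
      if (tcfg$optimizer == "adam") {
        st <- state[[key]]
        if (is.null(st)) st <- list(m = 0 * g, v = 0 * g)
        st$m <- b1 * st$m + (1 - b1) * g
        st$v <- b2 * st$v + (1 - b2) * g^2
        mhat <- st$m / (1 - b1^step)
        vhat <- st$v / (1 - b2^step)
        params[[nm]][[part]] <- params[[nm]][[part]] -
          tcfg$lr * mhat / (sqrt(vhat) + eps)
        state[[key]] <- st
      } else {
        params[[nm]][[part]] <- params[[nm]][[part]] - tcfg$lr * g
      }
    }
  }
  list(params = params, state = state)
}

#' Predict class probabilities for a batch of patch samples
#'
#' @param model trained `cascade_model`.
#' @param patches a `patch_set` (labels optional).
#' @param batch_size forward batch size.
#' @return n x 4 matrix of probabilities.
#' @export
predict_cascade <- function(model, patches, batch_size = 128L) {
  n <- if (!is.null(patches$label)) length(patches$label) else
    dim(patches$global)[4]
  gsz <- model$config$global_size^2 * model$config$n_channels
  lsz <- model$config$local_size^2 * model$config$n_channels
  gvec <- as.vector(patches$global)
  lvec <- as.vector(patches$local)
  out <- matrix(0, n, model$config$n_classes)
  for (start in seq(1, n, by = batch_size)) {
    ids <- start:min(start + batch_size - 1L, n)
    fwd <- cascade_forward(model,
                           gather_samples(gvec, ids, gsz),
                           gather_samples(lvec, ids, lsz),
                           patches$dwa[ids], train = FALSE)
    out[ids, ] <- fwd$prob
  }
  out
}
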