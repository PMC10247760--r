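## U-Net-style convolutional segmenter, implemented natively on BLAS-backed
## im2col convolutions. Architecture: `depth` encoder levels of two 3x3
## same-padded conv+ReLU blocks with 2x max pooling between levels, a
## mirrored decoder using nearest-neighbor upsampling + 3x3 conv and skip
## concatenation, and a 1x1 output conv to per-pixel class logits
## (softmax). Trained with the soft DICE loss over the two foreground
## classes using Adam, from Xavier-uniform initialization; the checkpoint
## with the highest validation DICE is selected.

#' Model architecture configuration
#'
#' @param input_size_px square network input side (>= 32); must be divisible
#'   by `2^(depth - 1)`.
#' @param depth number of encoder levels (>= 2; the deepest level acts as
#'   the bottleneck).
#' @param base_channels channels at the first level; doubled per level.
#' @param n_classes output classes (3: background, acetabulum, head).
#' @param init_scheme weight initialization; only `"xavier-uniform"`.
#' @return list of class `model_config`.
#' @export
model_config <- function(input_size_px = 256, depth = 2, base_channels = 8,
                         n_classes = 3, init_scheme = "xavier-uniform") {
  check_scalar(input_size_px, "input_size_px", min = 32, integer = TRUE)
  check_scalar(depth, "depth", min = 2, integer = TRUE)
  check_scalar(base_channels, "base_channels", min = 1, integer = TRUE)
  check_scalar(n_classes, "n_classes", min = 2, integer = TRUE)
  if (!identical(init_scheme, "xavier-uniform"))
    hs_validation_error("only 'xavier-uniform' initialization is supported")
  if (input_size_px %% 2^(depth - 1) != 0)
    hs_validation_error("'input_size_px' must be divisible by 2^(depth - 1)")
  structure(list(input_size_px = as.integer(input_size_px),
                 depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 n_classes = as.integer(n_classes),
                 init_scheme = init_scheme),
            class = "model_config")
}

#' Training configuration
#'
#' @param epochs training epochs (the selected checkpoint may be earlier).
#' @param batch_size images per optimizer step.
#' @param learning_rate Adam step size.
#' @param split_fractions named `c(train = , val = )` subject fractions.
#' @param seed seed covering initialization, the grouped split and epoch
#'   shuffling; fixed seeds reproduce a run exactly on one device.
#' @param selection_metric checkpoint selection; only `"val_dice"`
#'   (highest validation DICE, ties broken toward the earliest epoch).
#' @return list of class `train_config`.
#' @export
train_config <- function(epochs = 12, batch_size = 1, learning_rate = 3e-3,
                         split_fractions = c(train = 0.8, val = 0.2),
                         seed = 1L, selection_metric = "val_dice") {
  check_scalar(epochs, "epochs", min = 1, integer = TRUE)
  check_scalar(batch_size, "batch_size", min = 1, integer = TRUE)
  check_scalar(learning_rate, "learning_rate", min = 1e-12)
  check_scalar(seed, "seed", integer = TRUE)
  if (abs(sum(split_fractions) - 1) > 1e-9)
    hs_validation_error("'split_fractions' must sum to 1")
  if (!identical(selection_metric, "val_dice"))
    hs_validation_error("only 'val_dice' checkpoint selection is supported")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 split_fractions = split_fractions, seed = as.integer(seed),
                 selection_metric = selection_metric),
            class = "train_config")
}

## ---- layer primitives ----------------------------------------------------

xavier_uniform <- function(fan_in, fan_out, n) {
  lim <- sqrt(6 / (fan_in + fan_out))
  runif(n, -lim, lim)
}

conv_init <- function(c_in, c_out) {
  list(W = matrix(xavier_uniform(9 * c_in, 9 * c_out, 9 * c_in * c_out),
                  9 * c_in, c_out),
       b = numeric(c_out))
}

## im2col: 9 vectorized slice-gathers over the zero-padded input.
im2col3 <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  xp <- array(0, c(H + 2, W + 2, C))
  xp[2:(H + 1), 2:(W + 1), ] <- x
  Xcol <- matrix(0, H * W, 9 * C)
  k <- 1L
  for (ci in 1:C) for (dj in 0:2) for (di in 0:2) {
    Xcol[, k] <- xp[(1:H) + di, (1:W) + dj, ci]
    k <- k + 1L
  }
  Xcol
}

conv3_fwd <- function(x, layer) {
  d <- dim(x)
  Xcol <- im2col3(x)
  y <- Xcol %*% layer$W
  y <- sweep(y, 2, layer$b, "+")
  list(y = array(y, c(d[1], d[2], ncol(layer$W))), Xcol = Xcol)
}

conv3_bwd <- function(dY, Xcol, layer, H, W, C_in) {
  dYm <- matrix(dY, H * W, ncol(layer$W))
  dW <- crossprod(Xcol, dYm)
  db <- colSums(dYm)
  dXcol <- tcrossprod(dYm, layer$W)
  dxp <- array(0, c(H + 2, W + 2, C_in))
  k <- 1L
  for (ci in 1:C_in) for (dj in 0:2) for (di in 0:2) {
    dxp[(1:H) + di, (1:W) + dj, ci] <-
      dxp[(1:H) + di, (1:W) + dj, ci] + matrix(dXcol[, k], H, W)
    k <- k + 1L
  }
  list(dX = dxp[2:(H + 1), 2:(W + 1), , drop = FALSE], dW = dW, db = db)
}

relu_fwd <- function(x) { x[x < 0] <- 0; x }

maxpool2_fwd <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]
  i1 <- seq(1, H, 2); i2 <- seq(2, H, 2); j1 <- seq(1, W, 2); j2 <- seq(2, W, 2)
  a <- x[i1, j1, , drop = FALSE]; b <- x[i2, j1, , drop = FALSE]
  cc <- x[i1, j2, , drop = FALSE]; dd <- x[i2, j2, , drop = FALSE]
  m <- pmax(a, b, cc, dd)
  g1 <- a == m; g2 <- b == m & !g1; g3 <- cc == m & !(g1 | g2)
  g4 <- dd == m & !(g1 | g2 | g3)
  list(y = m, g = list(g1, g2, g3, g4))
}

maxpool2_bwd <- function(dY, g, H, W, C) {
  dX <- array(0, c(H, W, C))
  i1 <- seq(1, H, 2); i2 <- seq(2, H, 2); j1 <- seq(1, W, 2); j2 <- seq(2, W, 2)
  dX[i1, j1, ] <- dY * g[[1]]; dX[i2, j1, ] <- dY * g[[2]]
  dX[i1, j2, ] <- dY * g[[3]]; dX[i2, j2, ] <- dY * g[[4]]
  dX
}

upsample2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , drop = FALSE]
}

upsample2_bwd <- function(dY) {
  d <- dim(dY); H <- d[1]; W <- d[2]
  i1 <- seq(1, H, 2); i2 <- seq(2, H, 2); j1 <- seq(1, W, 2); j2 <- seq(2, W, 2)
  dY[i1, j1, , drop = FALSE] + dY[i2, j1, , drop = FALSE] +
    dY[i1, j2, , drop = FALSE] + dY[i2, j2, , drop = FALSE]
}

softmax3 <- function(z) {
  m <- z[, , 1]
  for (k in 2:dim(z)[3]) m <- pmax(m, z[, , k])
  e <- exp(sweep(z, 1:2, m))
  s <- e[, , 1]
  for (k in 2:dim(z)[3]) s <- s + e[, , k]
  sweep(e, 1:2, s, "/")
}

## ---- model ----------------------------------------------------------------

level_channels <- function(config) config$base_channels * 2^(seq_len(config$depth) - 1)

#' Create an untrained U-Net model
#'
#' Xavier-uniform initialized weights; useful as the untrained reference in
#' sanity checks and as the starting point of [train()].
#'
#' @param config a [model_config()].
#' @param seed integer seed for the initialization draw.
#' @return object of class `unet_model`.
#' @export
unet_model <- function(config = model_config(), seed = 1L) {
  ch <- level_channels(config)
  d <- config$depth
  params <- withr::with_seed(seed, {
    p <- list(enc = vector("list", d), up = vector("list", max(d - 1, 0)),
              dec = vector("list", max(d - 1, 0)))
    for (l in seq_len(d)) {
      c_in <- if (l == 1) 1L else ch[l - 1]
      p$enc[[l]] <- list(a = conv_init(c_in, ch[l]), b = conv_init(ch[l], ch[l]))
    }
    for (l in seq_len(d - 1)) {
      p$up[[l]] <- conv_init(ch[l + 1], ch[l])
      p$dec[[l]] <- list(a = conv_init(2 * ch[l], ch[l]),
                         b = conv_init(ch[l], ch[l]))
    }
    lim <- sqrt(6 / (ch[1] + config$n_classes))
    p$out <- list(W = matrix(runif(ch[1] * config$n_classes, -lim, lim),
                             ch[1], config$n_classes),
                  b = numeric(config$n_classes))
    p
  })
  structure(list(params = params, config = config,
                 checksum = param_checksum(params), trained = FALSE),
            class = "unet_model")
}

unet_forward <- function(params, x, config, keep_cache = FALSE) {
  d <- config$depth
  ch <- level_channels(config)
  cache <- list(enc = vector("list", d), pool = vector("list", d - 1),
                up = vector("list", d - 1), dec = vector("list", d - 1))
  skips <- vector("list", d)
  h <- x
  for (l in seq_len(d)) {
    f1 <- conv3_fwd(h, params$enc[[l]]$a); a1 <- relu_fwd(f1$y)
    f2 <- conv3_fwd(a1, params$enc[[l]]$b); a2 <- relu_fwd(f2$y)
    cache$enc[[l]] <- list(x1 = f1$Xcol, y1 = f1$y, x2 = f2$Xcol, y2 = f2$y,
                           in_dim = dim(h))
    skips[[l]] <- a2
    if (l < d) {
      mp <- maxpool2_fwd(a2)
      cache$pool[[l]] <- mp$g
      h <- mp$y
    } else h <- a2
  }
  for (l in rev(seq_len(d - 1))) {
    u <- upsample2_fwd(h)
    fu <- conv3_fwd(u, params$up[[l]]); au <- relu_fwd(fu$y)
    cat_in <- array(c(au, skips[[l]]), c(dim(au)[1], dim(au)[2],
                                         dim(au)[3] + dim(skips[[l]])[3]))
    f1 <- conv3_fwd(cat_in, params$dec[[l]]$a); a1 <- relu_fwd(f1$y)
    f2 <- conv3_fwd(a1, params$dec[[l]]$b); a2 <- relu_fwd(f2$y)
    cache$up[[l]] <- list(xcol = fu$Xcol, y = fu$y, in_dim = dim(u))
    cache$dec[[l]] <- list(x1 = f1$Xcol, y1 = f1$y, x2 = f2$Xcol, y2 = f2$y,
                           cat_dim = dim(cat_in), up_ch = dim(au)[3])
    h <- a2
  }
  hw <- dim(h)[1] * dim(h)[2]
  z <- matrix(h, hw, dim(h)[3]) %*% params$out$W
  z <- sweep(z, 2, params$out$b, "+")
  z <- array(z, c(dim(h)[1], dim(h)[2], config$n_classes))
  probs <- softmax3(z)
  cache$final_h <- h
  list(probs = probs, cache = if (keep_cache) cache else NULL)
}

## Backward from dL/dprobs through softmax and the whole net; returns
## gradient list shaped like params. Decoder level l runs at the spatial
## resolution of encoder level l (input_size / 2^(l-1)).
unet_backward <- function(params, cache, probs, dprobs, config) {
  d <- config$depth
  ## softmax backward: dz = p * (g - sum_k g_k p_k)
  s <- probs[, , 1] * dprobs[, , 1]
  for (k in 2:config$n_classes) s <- s + probs[, , k] * dprobs[, , k]
  dz <- probs * sweep(dprobs, 1:2, s)
  grads <- list(enc = vector("list", d), up = vector("list", d - 1),
                dec = vector("list", d - 1))
  h <- cache$final_h
  hw <- dim(h)[1] * dim(h)[2]
  dzm <- matrix(dz, hw, config$n_classes)
  hm <- matrix(h, hw, dim(h)[3])
  grads$out <- list(W = crossprod(hm, dzm), b = colSums(dzm))
  dh <- array(tcrossprod(dzm, params$out$W), dim(h))

  ## Decoder backward: reverse of forward order, i.e. shallow to deep.
  dskip <- vector("list", d - 1)
  for (l in seq_len(d - 1)) {
    cc <- cache$dec[[l]]
    Hl <- dim(cc$y1)[1]; Wl <- dim(cc$y1)[2]
    dh[cc$y2 <= 0] <- 0
    b2 <- conv3_bwd(dh, cc$x2, params$dec[[l]]$b, Hl, Wl, dim(cc$y1)[3])
    da1 <- b2$dX
    da1[cc$y1 <= 0] <- 0
    b1 <- conv3_bwd(da1, cc$x1, params$dec[[l]]$a, Hl, Wl, cc$cat_dim[3])
    grads$dec[[l]] <- list(a = list(W = b1$dW, b = b1$db),
                           b = list(W = b2$dW, b = b2$db))
    dcat <- b1$dX
    dau <- dcat[, , seq_len(cc$up_ch), drop = FALSE]
    dskip[[l]] <- dcat[, , (cc$up_ch + 1):cc$cat_dim[3], drop = FALSE]
    cu <- cache$up[[l]]
    dau[cu$y <= 0] <- 0
    bu <- conv3_bwd(dau, cu$xcol, params$up[[l]], Hl, Wl, cu$in_dim[3])
    grads$up[[l]] <- list(W = bu$dW, b = bu$db)
    ## gradient wrt the deeper level's output (decoder l+1, or encoder d)
    dh <- upsample2_bwd(bu$dX)
  }

  ## Encoder backward, deepest level first. `dh` now carries the gradient
  ## at encoder level d's output; `dfrom_deeper` carries, for level l < d,
  ## the gradient wrt level l's pooled output.
  dfrom_deeper <- NULL
  for (l in rev(seq_len(d))) {
    ce <- cache$enc[[l]]
    Hl <- dim(ce$y1)[1]; Wl <- dim(ce$y1)[2]
    dout <- if (l == d) dh else
      dskip[[l]] + maxpool2_bwd(dfrom_deeper, cache$pool[[l]], Hl, Wl,
                                dim(ce$y2)[3])
    dout[ce$y2 <= 0] <- 0
    b2 <- conv3_bwd(dout, ce$x2, params$enc[[l]]$b, Hl, Wl, dim(ce$y1)[3])
    da1 <- b2$dX
    da1[ce$y1 <= 0] <- 0
    b1 <- conv3_bwd(da1, ce$x1, params$enc[[l]]$a, Hl, Wl, ce$in_dim[3])
    grads$enc[[l]] <- list(a = list(W = b1$dW, b = b1$db),
                           b = list(W = b2$dW, b = b2$db))
    dfrom_deeper <- b1$dX
  }
  grads
}

## dL/dp for the soft DICE loss over foreground classes.
dice_loss_grad <- function(probs, truth) {
  d <- dim(probs)
  g <- array(0, d)
  for (k in 1:2) {
    p <- probs[, , k + 1]
    t <- (truth == k) * 1
    S <- sum(p) + sum(t) + DICE_EPS
    I <- sum(p * t)
    g[, , k + 1] <- -0.5 * (2 * t * S - (2 * I + DICE_EPS)) / S^2
  }
  g
}

## ---- Adam -----------------------------------------------------------------

## Flatten/update parameters generically by walking the nested list.
walk_params <- function(p, g, f) {
  if (is.list(p) && !is.null(p$W)) return(f(p, g))
  out <- p
  for (nm in seq_along(p))
    if (is.list(p[[nm]])) out[[nm]] <- walk_params(p[[nm]], g[[nm]], f)
  out
}

adam_state_init <- function(params) {
  walk_params(params, params, function(p, g)
    list(W = p$W * 0, b = p$b * 0))
}

## ---- training -------------------------------------------------------------

#' Train the U-Net segmenter on a phantom dataset
#'
#' Splits the dataset subject-disjointly ([grouped_split()]), preprocesses
#' frames to the model input size (bilinear; masks nearest-neighbor), and
#' minimizes the soft DICE loss with Adam from Xavier-uniform
#' initialization. After every epoch the hard validation DICE (mean over
#' the two foreground classes and validation frames) is recorded, and the
#' checkpoint with the highest validation DICE is returned (ties favor the
#' earliest epoch). The run is reproducible on one device for a fixed seed.
#'
#' @param mconfig a [model_config()].
#' @param tconfig a [train_config()].
#' @param dataset a dataset from [make_dataset()] (lists `images`, `masks`,
#'   data.frame `truth` with `subject_id`).
#' @return list with `model` (class `unet_model`) and `report` (class
#'   `train_report`: per-epoch train loss and validation DICE, selected
#'   epoch, selected-model checksum).
#' @export
train <- function(mconfig, tconfig, dataset) {
  if (!inherits(mconfig, "model_config")) mconfig <- do.call(model_config, mconfig)
  if (!inherits(tconfig, "train_config")) tconfig <- do.call(train_config, tconfig)
  n <- length(dataset$images)
  if (n == 0) hs_validation_error("dataset is empty")
  present <- c(any(vapply(dataset$masks, function(m) any(m == 1L), logical(1))),
               any(vapply(dataset$masks, function(m) any(m == 2L), logical(1))))
  if (!all(present))
    hs_validation_error(sprintf(
      "dataset lacks foreground class %s entirely; cannot train a landmark segmenter",
      paste(which(!present), collapse = ", ")))

  split <- grouped_split(dataset, tconfig$split_fractions, tconfig$seed)
  sz <- mconfig$input_size_px
  xs <- lapply(dataset$images, function(im)
    array(preprocess(im, sz), c(sz, sz, 1)))
  ys <- lapply(dataset$masks, function(m)
    matrix(as.integer(round(resize_nearest(m, sz, sz))), sz, sz))

  model <- unet_model(mconfig, seed = tconfig$seed)
  params <- model$params
  mstate <- adam_state_init(params)
  vstate <- adam_state_init(params)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  lr <- tconfig$learning_rate

  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_dice = numeric(0))
  best <- list(dice = -Inf, epoch = NA_integer_, params = NULL)

  val_dice <- function(params) {
    mean(vapply(split$val_ids, function(i) {
      pr <- unet_forward(params, xs[[i]], mconfig)$probs
      pm <- apply(pr, c(1, 2), which.max) - 1L
      mean(c(hard_dice(pm, ys[[i]], 1L), hard_dice(pm, ys[[i]], 2L)))
    }, numeric(1)))
  }

  withr::with_seed(tconfig$seed, {
    for (ep in seq_len(tconfig$epochs)) {
      order_ids <- sample(split$train_ids)
      losses <- numeric(length(order_ids))
      acc <- NULL; acc_n <- 0L
      for (ii in seq_along(order_ids)) {
        i <- order_ids[ii]
        fw <- unet_forward(params, xs[[i]], mconfig, keep_cache = TRUE)
        losses[ii] <- dice_loss(fw$probs, ys[[i]])
        g <- dice_loss_grad(fw$probs, ys[[i]])
        grads <- unet_backward(params, fw$cache, fw$probs, g, mconfig)
        acc <- if (is.null(acc)) grads else
          mapply_params(acc, grads, function(a, b) list(W = a$W + b$W, b = a$b + b$b))
        acc_n <- acc_n + 1L
        if (acc_n == tconfig$batch_size || ii == length(order_ids)) {
          step <- step + 1L
          sc <- 1 / acc_n
          upd <- adam_apply(params, acc, mstate, vstate, lr, beta1, beta2,
                            eps, step, sc)
          params <- upd$params; mstate <- upd$m; vstate <- upd$v
          acc <- NULL; acc_n <- 0L
        }
      }
      vd <- val_dice(params)
      history <- rbind(history, data.frame(epoch = ep,
                                           train_loss = mean(losses),
                                           val_dice = vd))
      if (vd > best$dice + 1e-12) {
        best$dice <- vd; best$epoch <- ep; best$params <- params
      }
    }
  })

  model$params <- best$params
  model$checksum <- param_checksum(best$params)
  model$trained <- TRUE
  report <- structure(list(
    epochs = history, selected_epoch = best$epoch,
    selected_val_dice = best$dice, selected_checksum = model$checksum,
    optimizer = "adam", learning_rate = lr,
    train_subjects = split$train_subjects, val_subjects = split$val_subjects
  ), class = "train_report")
  list(model = model, report = report)
}

## parallel structural map over two parameter trees
mapply_params <- function(a, b, f) {
  if (is.list(a) && !is.null(a$W)) return(f(a, b))
  out <- a
  for (i in seq_along(a))
    if (is.list(a[[i]])) out[[i]] <- mapply_params(a[[i]], b[[i]], f)
  out
}

adam_apply <- function(params, grads, m, v, lr, beta1, beta2, eps, t, scale) {
  upd_leaf <- function(p, g, ms, vs) {
    gW <- g$W * scale; gb <- g$b * scale
    ms$W <- beta1 * ms$W + (1 - beta1) * gW
    ms$b <- beta1 * ms$b + (1 - beta1) * gb
    vs$W <- beta2 * vs$W + (1 - beta2) * gW^2
    vs$b <- beta2 * vs$b + (1 - beta2) * gb^2
    mhW <- ms$W / (1 - beta1^t); mhb <- ms$b / (1 - beta1^t)
    vhW <- vs$W / (1 - beta2^t); vhb <- vs$b / (1 - beta2^t)
    p$W <- p$W - lr * mhW / (sqrt(vhW) + eps)
    p$b <- p$b - lr * mhb / (sqrt(vhb) + eps)
    list(p = p, m = ms, v = vs)
  }
  rec <- function(p, g, ms, vs) {
    if (is.list(p) && !is.null(p$W)) {
      r <- upd_leaf(p, g, ms, vs)
      return(list(p = r$p, m = r$m, v = r$v))
    }
    np <- p; nm <- ms; nv <- vs
    for (i in seq_along(p)) if (is.list(p[[i]])) {
      r <- rec(p[[i]], g[[i]], ms[[i]], vs[[i]])
      np[[i]] <- r$p; nm[[i]] <- r$m; nv[[i]] <- r$v
    }
    list(p = np, m = nm, v = nv)
  }
  r <- rec(params, grads, m, v)
  list(params = r$p, m = r$m, v = r$v)
}

#' Segment an image with a (trained) model
#'
#' Preprocesses the image to the model input size, runs the forward pass
#' and returns the argmax label mask together with per-class probability
#' grids, both resampled back to the source image dimensions (nearest
#' neighbor for labels, bilinear + renormalization for probabilities, which
#' therefore sum to 1 per pixel to within 1e-5).
#'
#' @param model a `unet_model` (see [train()], [unet_model()]).
#' @param image numeric matrix.
#' @return list with `mask` (labels in \{0, 1, 2\}, source dimensions) and
#'   `probs` (H x W x n_classes array).
#' @export
segment <- function(model, image) {
  if (!inherits(model, "unet_model"))
    hs_validation_error("'model' must be a unet_model")
  x <- array(preprocess(image, model$config$input_size_px),
             c(model$config$input_size_px, model$config$input_size_px, 1))
  pr <- unet_forward(model$params, x, model$config)$probs
  small_mask <- apply(pr, c(1, 2), which.max) - 1L
  H <- nrow(image); W <- ncol(image)
  mask <- matrix(as.integer(round(resize_nearest(small_mask, H, W))), H, W)
  probs <- array(0, c(H, W, model$config$n_classes))
  for (k in seq_len(model$config$n_classes))
    probs[, , k] <- resize_bilinear(pr[, , k], H, W)
  tot <- probs[, , 1]
  for (k in 2:model$config$n_classes) tot <- tot + probs[, , k]
  probs <- sweep(probs, 1:2, tot, "/")
  list(mask = mask, probs = probs)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single file embedding the weights, the
#' `model_config` and a parameter checksum.
#'
#' @param model a `unet_model`.
#' @param path file path.
#' @return `load_checkpoint` returns the `unet_model`.
#' @export
save_checkpoint <- function(model, path) {
  if (!inherits(model, "unet_model"))
    hs_validation_error("'model' must be a unet_model")
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) hs_io_error(sprintf("no checkpoint at '%s'", path))
  model <- readRDS(path)
  if (!inherits(model, "unet_model"))
    hs_io_error("file does not contain a unet_model checkpoint")
  model
}
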