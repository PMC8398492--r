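#' CNN architecture configuration
#'
#' A compact three-block convolutional network for scalogram images: each
#' block is a 3x3 "same" convolution, rectified-linear activation and 2x2 max
#' pooling; the head flattens and applies a dense softmax over the classes.
#' Filter counts and the input size are configurable; the canonical input is
#' 224x224x3 and smaller inputs (divisible by 8) are used for scaled-down
#' runs, preserving all interface contracts.
#'
#' @param input_shape length-3 integer (height, width, channels); height and
#'   width must be divisible by \code{2^length(filters)}.
#' @param filters convolution filter counts per block (default 8, 16, 32).
#' @param kernel_size convolution kernel side (fixed 3).
#' @return An object of class \code{cnn_config}.
#' @export
cnn_config <- function(input_shape = c(224L, 224L, 3L),
                       filters = c(8L, 16L, 32L),
                       kernel_size = 3L) {
  if (length(input_shape) != 3) stop_field("input_shape", "must be length 3")
  if (kernel_size != 3L) stop_field("kernel_size", "only 3x3 kernels supported")
  pool_div <- 2^length(filters)
  if (any(input_shape[1:2] %% pool_div != 0)) {
    stop_field("input_shape", sprintf("height/width must be divisible by %d",
                                      pool_div))
  }
  structure(list(input_shape = as.integer(input_shape),
                 filters = as.integer(filters),
                 kernel_size = 3L),
            class = "cnn_config")
}

#' Training configuration
#'
#' Defaults follow the training regime used throughout the experiments:
#' batch size 32, 20 epochs, learning rate 0.0005, Adam optimizer. SGDM uses
#' momentum 0.9; RMSprop uses decay 0.9 (conventional values, configurable).
#'
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param learning_rate step size.
#' @param optimizer one of \code{"adam"}, \code{"sgdm"}, \code{"rmsprop"}.
#' @param momentum SGDM momentum.
#' @param rho RMSprop/Adam second-moment decay.
#' @param beta1 Adam first-moment decay.
#' @param rng_seed integer seed for weight initialization and shuffling.
#' @return An object of class \code{train_config}.
#' @export
train_config <- function(batch_size = 32L, epochs = 20L,
                         learning_rate = 5e-4,
                         optimizer = c("adam", "sgdm", "rmsprop"),
                         momentum = 0.9, rho = 0.9, beta1 = 0.9,
                         rng_seed = 1L) {
  optimizer <- match.arg(optimizer)
  if (batch_size < 1 || epochs < 1 || learning_rate <= 0) {
    stop_field("train_config", "batch_size, epochs, learning_rate must be positive")
  }
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, optimizer = optimizer,
                 momentum = momentum, rho = rho, beta1 = beta1,
                 rng_seed = as.integer(rng_seed)),
            class = "train_config")
}

#' Build an untrained CNN
#'
#' @param config a \code{\link{cnn_config}}.
#' @param n_classes 2 (binary) or 4 (subtype) classes.
#' @return An object of class \code{wct_cnn} describing the architecture
#'   (weights are initialized at training time from the training seed).
#' @export
build_cnn <- function(config = cnn_config(), n_classes = 2L) {
  stopifnot(inherits(config, "cnn_config"))
  if (!n_classes %in% c(2L, 4L)) {
    stop_field("n_classes", "must be 2 or 4")
  }
  h <- config$input_shape[1]; w <- config$input_shape[2]
  chans <- c(config$input_shape[3], config$filters)
  layers <- list()
  for (b in seq_along(config$filters)) {
    layers[[b]] <- list(type = "conv_block", in_ch = chans[b],
                        out_ch = chans[b + 1], h = h, w = w)
    h <- h %/% 2L; w <- w %/% 2L
  }
  flat_dim <- h * w * chans[length(chans)]
  structure(list(config = config, n_classes = as.integer(n_classes),
                 layers = layers, flat_dim = flat_dim,
                 class_labels = NULL, weights = NULL),
            class = "wct_cnn")
}

#' Number of trainable parameters of a CNN
#'
#' @param model a \code{\link{build_cnn}} model.
#' @return Integer parameter count.
#' @export
cnn_num_params <- function(model) {
  stopifnot(inherits(model, "wct_cnn"))
  k2 <- model$config$kernel_size^2
  n <- 0L
  for (l in model$layers) n <- n + k2 * l$in_ch * l$out_ch + l$out_ch
  n + model$flat_dim * model$n_classes + model$n_classes
}

#' @export
print.wct_cnn <- function(x, ...) {
  cat(sprintf("<wct_cnn> input %s, blocks [%s], %d classes, %d params%s\n",
              paste(x$config$input_shape, collapse = "x"),
              paste(x$config$filters, collapse = ","),
              x$n_classes, cnn_num_params(x),
              if (is.null(x$weights)) " (untrained)" else " (trained)"))
  invisible(x)
}

init_cnn_weights <- function(model) {
  k <- model$config$kernel_size
  weights <- list(conv = list(), dense = NULL)
  for (l in model$layers) {
    fan_in <- k * k * l$in_ch
    # He initialization for rectified-linear units
    weights$conv[[length(weights$conv) + 1]] <- list(
      W = matrix(rnorm(fan_in * l$out_ch, sd = sqrt(2 / fan_in)),
                 fan_in, l$out_ch),
      b = rep(0, l$out_ch)
    )
  }
  weights$dense <- list(
    W = matrix(rnorm(model$flat_dim * model$n_classes,
                     sd = sqrt(1 / model$flat_dim)),
               model$flat_dim, model$n_classes),
    b = rep(0, model$n_classes)
  )
  weights
}

# ---- array plumbing ---------------------------------------------------------
# activations are stored as arrays (H, W, C, N)

# im2col for 3x3 "same" convolution: returns (H*W*N) x (9*C) matrix.
# column order: channel-major within each of the 9 offsets.
im2col3 <- function(x) {
  d <- dim(x)
  h <- d[1]; w <- d[2]; ch <- d[3]; n <- d[4]
  xp <- array(0, dim = c(h + 2L, w + 2L, ch, n))
  xp[2:(h + 1), 2:(w + 1), , ] <- x
  cols <- matrix(0, h * w * n, 9L * ch)
  k <- 0L
  for (dj in 0:2) {
    for (di in 0:2) {
      slice <- xp[di + seq_len(h), dj + seq_len(w), , , drop = FALSE]
      # rows ordered (h, w, n); columns = channels
      cols[, k * ch + seq_len(ch)] <-
        matrix(aperm(slice, c(1, 2, 4, 3)), h * w * n, ch)
      k <- k + 1L
    }
  }
  cols
}

# inverse scatter of im2col3: accumulates gradient columns back onto the input
col2im3 <- function(cols, h, w, ch, n) {
  dxp <- array(0, dim = c(h + 2L, w + 2L, ch, n))
  k <- 0L
  for (dj in 0:2) {
    for (di in 0:2) {
      block <- array(cols[, k * ch + seq_len(ch)], dim = c(h, w, n, ch))
      dxp[di + seq_len(h), dj + seq_len(w), , ] <-
        dxp[di + seq_len(h), dj + seq_len(w), , , drop = FALSE] +
        aperm(block, c(1, 2, 4, 3))
      k <- k + 1L
    }
  }
  dxp[2:(h + 1), 2:(w + 1), , , drop = FALSE]
}

conv_forward <- function(x, wb) {
  d <- dim(x)
  cols <- im2col3(x)
  y <- cols %*% wb$W
  y <- sweep(y, 2, wb$b, `+`)
  out_ch <- ncol(wb$W)
  # rows of y are (h, w, n); reorder to (h, w, ch, n)
  y <- aperm(array(y, dim = c(d[1], d[2], d[4], out_ch)), c(1, 2, 4, 3))
  list(out = y, cols = cols)
}

conv_backward <- function(dy, cache_cols, wb, in_dim) {
  d_out <- dim(dy)
  dy_mat <- matrix(aperm(dy, c(1, 2, 4, 3)), prod(d_out[c(1, 2, 4)]), d_out[3])
  dW <- crossprod(cache_cols, dy_mat)
  db <- colSums(dy_mat)
  dcols <- tcrossprod(dy_mat, wb$W)
  dx <- col2im3(dcols, in_dim[1], in_dim[2], in_dim[3], in_dim[4])
  list(dx = dx, dW = dW, db = db)
}

maxpool_forward <- function(x) {
  d <- dim(x)
  h2 <- d[1] %/% 2L; w2 <- d[2] %/% 2L
  a <- x[seq(1, d[1], 2), seq(1, d[2], 2), , , drop = FALSE]
  b <- x[seq(2, d[1], 2), seq(1, d[2], 2), , , drop = FALSE]
  cc <- x[seq(1, d[1], 2), seq(2, d[2], 2), , , drop = FALSE]
  dd <- x[seq(2, d[1], 2), seq(2, d[2], 2), , , drop = FALSE]
  out <- pmax(a, b, cc, dd)
  # first-match argmax for backward routing
  which1 <- (out == a)
  which2 <- (out == b) & !which1
  which3 <- (out == cc) & !(which1 | which2)
  which4 <- !(which1 | which2 | which3)
  list(out = out, mask = list(which1, which2, which3, which4), in_dim = d)
}

maxpool_backward <- function(dy, cache) {
  d <- cache$in_dim
  dx <- array(0, dim = d)
  m <- cache$mask
  dx[seq(1, d[1], 2), seq(1, d[2], 2), , ] <- dy * m[[1]]
  dx[seq(2, d[1], 2), seq(1, d[2], 2), , ] <- dy * m[[2]]
  dx[seq(1, d[1], 2), seq(2, d[2], 2), , ] <- dy * m[[3]]
  dx[seq(2, d[1], 2), seq(2, d[2], 2), , ] <- dy * m[[4]]
  dx
}

cnn_forward <- function(model, x, keep_cache = FALSE) {
  weights <- model$weights
  caches <- list()
  a <- x
  for (b in seq_along(weights$conv)) {
    cf <- conv_forward(a, weights$conv[[b]])
    relu_mask <- cf$out > 0
    act <- cf$out * relu_mask
    mp <- maxpool_forward(act)
    if (keep_cache) {
      caches[[b]] <- list(cols = cf$cols, relu = relu_mask, pool = mp,
                          in_dim = dim(a))
    }
    a <- mp$out
  }
  n <- dim(a)[4]
  flat <- matrix(a, ncol = n)                  # flat_dim x N
  logits <- crossprod(flat, weights$dense$W) + # N x K
    matrix(weights$dense$b, n, model$n_classes, byrow = TRUE)
  # stable softmax
  z <- logits - apply(logits, 1, max)
  ez <- exp(z)
  probs <- ez / rowSums(ez)
  list(probs = probs, logits = logits, flat = flat, caches = caches,
       pooled_dim = dim(a))
}

cnn_backward <- function(model, fwd, y_onehot) {
  weights <- model$weights
  n <- nrow(y_onehot)
  dlogits <- (fwd$probs - y_onehot) / n          # N x K
  grads <- list(conv = vector("list", length(weights$conv)), dense = NULL)
  grads$dense <- list(W = fwd$flat %*% dlogits,  # D x K
                      b = colSums(dlogits))
  dflat <- weights$dense$W %*% t(dlogits)        # D x N
  da <- array(dflat, dim = fwd$pooled_dim)
  for (b in rev(seq_along(weights$conv))) {
    cache <- fwd$caches[[b]]
    dact <- maxpool_backward(da, cache$pool)
    dconv <- dact * cache$relu
    cb <- conv_backward(dconv, cache$cols, weights$conv[[b]], cache$in_dim)
    grads$conv[[b]] <- list(W = cb$dW, b = cb$db)
    da <- cb$dx
  }
  grads
}

# flatten weights/grads into a single numeric vector and back, so optimizers
# are one code path
weights_to_vec <- function(weights) {
  unlist(lapply(c(weights$conv, list(weights$dense)),
                function(l) c(as.vector(l$W), l$b)), use.names = FALSE)
}

vec_to_weights <- function(v, template) {
  pos <- 1L
  take <- function(n) {
    out <- v[pos:(pos + n - 1L)]
    pos <<- pos + n
    out
  }
  conv <- lapply(template$conv, function(l) {
    W <- matrix(take(length(l$W)), nrow(l$W), ncol(l$W))
    list(W = W, b = take(length(l$b)))
  })
  dW <- matrix(take(length(template$dense$W)),
               nrow(template$dense$W), ncol(template$dense$W))
  list(conv = conv, dense = list(W = dW, b = take(length(template$dense$b))))
}

make_optimizer <- function(cfg, n_par) {
  state <- list(m = numeric(n_par), v = numeric(n_par), t = 0)
  lr <- cfg$learning_rate
  switch(cfg$optimizer,
    adam = function(w, g, st) {
      st$t <- st$t + 1
      st$m <- cfg$beta1 * st$m + (1 - cfg$beta1) * g
      st$v <- cfg$rho * st$v + (1 - cfg$rho) * g^2
      mhat <- st$m / (1 - cfg$beta1^st$t)
      vhat <- st$v / (1 - cfg$rho^st$t)
      list(w = w - lr * mhat / (sqrt(vhat) + 1e-8), state = st)
    },
    sgdm = function(w, g, st) {
      st$m <- cfg$momentum * st$m - lr * g
      list(w = w + st$m, state = st)
    },
    rmsprop = function(w, g, st) {
      st$v <- cfg$rho * st$v + (1 - cfg$rho) * g^2
      list(w = w - lr * g / (sqrt(st$v) + 1e-8), state = st)
    }
  ) -> step
  list(step = step, state = state)
}

# coerce a list of scalogram_image (or a ready-made batch) into
# list(x = H x W x 3 x N array in [0,1], y = factor)
as_image_batch <- function(images, class_levels = NULL) {
  if (is.list(images) && !is.null(images$x)) {
    if (is.null(images$y)) stop("batch must have x and y", call. = FALSE)
    y <- if (is.factor(images$y)) images$y else factor(images$y, levels = class_levels %||% sort(unique(images$y)))
    return(list(x = images$x, y = y))
  }
  stopifnot(all(vapply(images, inherits, logical(1), "scalogram_image")))
  d <- dim(images[[1]]$pixels)
  x <- array(0, dim = c(d[1], d[2], d[3], length(images)))
  for (i in seq_along(images)) x[, , , i] <- images[[i]]$pixels / 255
  labs <- vapply(images, function(im) im$group, character(1))
  y <- factor(labs, levels = class_levels %||% sort(unique(labs)))
  list(x = x, y = y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train a CNN on labeled scalogram images
#'
#' Minibatch training with softmax cross-entropy loss. Weight initialization
#' and per-epoch shuffling are driven by the training seed, so identical seed
#' and data give identical results. Pixel inputs are expected in [0, 1]
#' (\code{scalogram_image} rasters are rescaled automatically).
#'
#' @param model an untrained \code{\link{build_cnn}} model.
#' @param train_set either a list of \code{scalogram_image} or a list with
#'   \code{x} (H x W x C x N array) and \code{y} (labels); must contain >= 2
#'   classes covering all model classes.
#' @param val_set optional validation set in the same form.
#' @param config a \code{\link{train_config}}.
#' @return A trained \code{wct_cnn} with \code{weights}, \code{class_labels}
#'   and a \code{history} data.frame (one row per epoch: loss, accuracy and,
#'   when a validation set is given, val_loss/val_accuracy).
#' @export
train_cnn <- function(model, train_set, val_set = NULL,
                      config = train_config()) {
  stopifnot(inherits(model, "wct_cnn"), inherits(config, "train_config"))
  batch <- as_image_batch(train_set)
  levels_y <- levels(batch$y)
  if (length(unique(as.integer(batch$y))) < 2) {
    stop("training set contains a single class", call. = FALSE)
  }
  if (length(levels_y) != model$n_classes) {
    stop(sprintf("model expects %d classes, training labels have %d",
                 model$n_classes, length(levels_y)), call. = FALSE)
  }
  din <- dim(batch$x)
  if (!all(din[1:3] == model$config$input_shape)) {
    stop(sprintf("input shape %s does not match model %s",
                 paste(din[1:3], collapse = "x"),
                 paste(model$config$input_shape, collapse = "x")), call. = FALSE)
  }
  vb <- if (!is.null(val_set)) as_image_batch(val_set, class_levels = levels_y)
  n <- din[4]
  set.seed(config$rng_seed)
  model$weights <- init_cnn_weights(model)
  model$class_labels <- levels_y
  opt <- make_optimizer(config, length(weights_to_vec(model$weights)))
  state <- opt$state
  onehot <- diag(model$n_classes)[as.integer(batch$y), , drop = FALSE]

  hist <- vector("list", config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_correct <- 0
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      xb <- batch$x[, , , idx, drop = FALSE]
      yb <- onehot[idx, , drop = FALSE]
      fwd <- cnn_forward(model, xb, keep_cache = TRUE)
      p <- pmax(fwd$probs, 1e-12)
      ep_loss <- ep_loss - sum(log(p[cbind(seq_len(nrow(yb)),
                                           max.col(yb, ties.method = "first"))]))
      ep_correct <- ep_correct +
        sum(max.col(fwd$probs, ties.method = "first") ==
              max.col(yb, ties.method = "first"))
      grads <- cnn_backward(model, fwd, yb)
      res <- opt$step(weights_to_vec(model$weights),
                      weights_to_vec(grads), state)
      state <- res$state
      model$weights <- vec_to_weights(res$w, model$weights)
    }
    row <- data.frame(epoch = ep, loss = ep_loss / n, accuracy = ep_correct / n)
    if (!is.null(vb)) {
      vp <- predict(model, vb$x)
      row$val_loss <- -mean(log(pmax(
        vp$probs[cbind(seq_along(vb$y), as.integer(vb$y))], 1e-12)))
      row$val_accuracy <- mean(vp$labels == as.character(vb$y))
    }
    hist[[ep]] <- row
  }
  model$history <- do.call(rbind, hist)
  model
}

#' Predict class probabilities for a batch of images
#'
#' @param object a trained \code{wct_cnn}.
#' @param images array (H x W x C x N), a list of \code{scalogram_image}, or
#'   an \code{x}/\code{y} batch list.
#' @param ... unused.
#' @return List with \code{probs} (N x K matrix, rows sum to 1) and
#'   \code{labels} (argmax class, ties broken by class order). A zero-image
#'   batch returns empty outputs.
#' @export
predict.wct_cnn <- function(object, images, ...) {
  if (is.null(object$weights)) stop("model is untrained", call. = FALSE)
  x <- if (is.array(images) && length(dim(images)) == 4) {
    images
  } else if (is.array(images) && length(dim(images)) == 3) {
    array(images, dim = c(dim(images), 1))
  } else {
    as_image_batch(images, class_levels = object$class_labels)$x
  }
  if (dim(x)[4] == 0) {
    return(list(probs = matrix(0, 0, object$n_classes), labels = character(0)))
  }
  if (!all(dim(x)[1:3] == object$config$input_shape)) {
    stop(sprintf("image shape %s does not match model input %s",
                 paste(dim(x)[1:3], collapse = "x"),
                 paste(object$config$input_shape, collapse = "x")),
         call. = FALSE)
  }
  fwd <- cnn_forward(object, x, keep_cache = FALSE)
  labels <- object$class_labels[max.col(fwd$probs, ties.method = "first")]
  colnames(fwd$probs) <- object$class_labels
  list(probs = fwd$probs, labels = labels)
}

#' Train the same architecture under several optimizers
#'
#' Runs one training per optimizer under a shared configuration and reports
#' the final training/validation metrics side by side, mirroring the
#' optimizer-comparison experiments.
#'
#' @param model an untrained \code{\link{build_cnn}} model.
#' @param train_set,val_set image sets as in \code{\link{train_cnn}}.
#' @param config base \code{\link{train_config}} (its optimizer is ignored).
#' @param optimizers optimizers to compare.
#' @return data.frame with one row per optimizer: final loss/accuracy (and
#'   validation metrics when a validation set is given), plus the trained
#'   models in the \code{"models"} attribute.
#' @export
optimizer_sweep <- function(model, train_set, val_set = NULL,
                            config = train_config(),
                            optimizers = c("rmsprop", "sgdm", "adam")) {
  rows <- list(); models <- list()
  for (op in optimizers) {
    cfg <- config
    cfg$optimizer <- op
    fit <- train_cnn(model, train_set, val_set, cfg)
    last <- fit$history[nrow(fit$history), , drop = FALSE]
    last$optimizer <- op
    rows[[op]] <- last[, c("optimizer", setdiff(names(last), c("optimizer", "epoch")))]
    models[[op]] <- fit
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "models") <- models
  out
}
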