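# A compact VGG-style convolutional network for thermogram classification:
# stacked 3x3 conv + ReLU blocks, each closed by 2x2 max pooling, then a
# fully connected ReLU layer and a softmax head, trained by plain stochastic
# gradient descent. The architecture is the down-scaled desk variant of the
# five-block/thirteen-layer topology: same block structure, fewer filters,
# sized so training runs in seconds on a CPU.

#' CNN configuration
#'
#' @param input_size Image size `c(height, width)`; both must be divisible
#'   by `2^length(blocks)`.
#' @param channels Input channels (3 for RGB thermograms).
#' @param blocks Integer vector of filter counts, one per convolutional
#'   block; each block holds `layers_per_block` 3x3 convolutions and ends in
#'   2x2 max pooling.
#' @param layers_per_block Convolutions per block (default 2).
#' @param dense Width of the fully connected ReLU layer.
#' @param learning_rate SGD learning rate (default 0.01).
#' @param epochs Training epochs (>= 0; 0 leaves the network at its random
#'   initialization).
#' @param batch_size Minibatch size.
#' @param augment Apply random augmentation (shear, zoom, rotation,
#'   horizontal flip, translation) to training images each epoch.
#' @param shear,zoom,rotation,translation Augmentation ranges: shear factor,
#'   zoom fraction, rotation degrees, translation fraction of the frame.
#' @param hflip Include random horizontal flips in augmentation.
#' @param pretrained Request pretrained initialization. No pretrained
#'   weights ship with the package, so `TRUE` is rejected with an
#'   informative error; networks train from random initialization.
#' @return An object of class `cnn_config`.
#' @export
cnn_config <- function(input_size = c(64L, 64L), channels = 3L,
                       blocks = c(8L, 16L), layers_per_block = 2L,
                       dense = 32L, learning_rate = 0.01, epochs = 15L,
                       batch_size = 8L, augment = FALSE,
                       shear = 0.1, zoom = 0.1, rotation = 10,
                       translation = 0.05, hflip = TRUE,
                       pretrained = FALSE) {
  stopifnot_scalar_number(learning_rate, "learning_rate", min = 1e-12)
  stopifnot_scalar_number(epochs, "epochs", min = 0)
  if (any(input_size %% (2^length(blocks)) != 0)) {
    abort("`input_size` must be divisible by 2^length(blocks).",
          class = "tonguetherm_error_input")
  }
  if (isTRUE(pretrained)) {
    abort(paste(
      "Pretrained initialization is not available: no pretrained weights",
      "ship with this package. Use pretrained = FALSE to train from",
      "random initialization."
    ), class = "tonguetherm_error_input")
  }
  structure(
    list(input_size = as.integer(input_size), channels = as.integer(channels),
         blocks = as.integer(blocks),
         layers_per_block = as.integer(layers_per_block),
         dense = as.integer(dense), learning_rate = learning_rate,
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         augment = isTRUE(augment),
         aug = list(shear = shear, zoom = zoom, rotation = rotation,
                    translation = translation, hflip = isTRUE(hflip))),
    class = "cnn_config"
  )
}

# ---- layer plumbing ---------------------------------------------------------

# Linear-index gather table for 3x3 im2col over a zero-padded H x W x C array.
im2col_index <- function(h, w, ch) {
  hp <- h + 2L; wp <- w + 2L
  # centre positions in the padded array
  rr <- rep(seq_len(h) + 1L, times = w)
  cc <- rep(seq_len(w) + 1L, each = h)
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  cols <- list()
  k <- 1L
  for (c0 in seq_len(ch)) {
    base <- (c0 - 1L) * hp * wp
    for (o in seq_len(nrow(offs))) {
      cols[[k]] <- base + (cc + offs$dc[o] - 1L) * hp + (rr + offs$dr[o])
      k <- k + 1L
    }
  }
  do.call(cbind, cols)  # (h*w) x (9*ch)
}

pad_image <- function(x) {
  d <- dim(x)
  xp <- array(0, dim = c(d[1] + 2L, d[2] + 2L, d[3]))
  xp[2:(d[1] + 1L), 2:(d[2] + 1L), ] <- x
  xp
}

conv_forward <- function(x, layer) {
  d <- dim(x)
  col <- matrix(pad_image(x)[layer$idx], nrow = d[1] * d[2])
  out <- col %*% layer$w + matrix(layer$b, d[1] * d[2], length(layer$b),
                                  byrow = TRUE)
  list(out = array(out, dim = c(d[1], d[2], length(layer$b))), col = col)
}

conv_backward <- function(dout, x_dim, layer, col) {
  f <- length(layer$b)
  dmat <- matrix(dout, ncol = f)
  dw <- crossprod(col, dmat)
  db <- colSums(dmat)
  dcol <- dmat %*% t(layer$w)
  hp <- x_dim[1] + 2L; wp <- x_dim[2] + 2L
  dxp <- numeric(hp * wp * x_dim[3])
  rs <- rowsum(as.vector(dcol), group = as.vector(layer$idx))
  dxp[as.integer(rownames(rs))] <- rs
  dxp <- array(dxp, dim = c(hp, wp, x_dim[3]))
  dx <- dxp[2:(x_dim[1] + 1L), 2:(x_dim[2] + 1L), , drop = FALSE]
  list(dx = dx, dw = dw, db = db)
}

maxpool_forward <- function(x) {
  d <- dim(x)
  ro <- seq(1L, d[1], by = 2L); co <- seq(1L, d[2], by = 2L)
  a <- x[ro, co, , drop = FALSE]; b <- x[ro, co + 1L, , drop = FALSE]
  cc <- x[ro + 1L, co, , drop = FALSE]; dd <- x[ro + 1L, co + 1L, , drop = FALSE]
  m <- pmax(a, b, cc, dd)
  list(out = m, which = list(a = m == a, b = m == b & m != a,
                             c = m == cc & m != a & m != b,
                             d = m == dd & m != a & m != b & m != cc))
}

maxpool_backward <- function(dout, which, x_dim) {
  dx <- array(0, dim = x_dim)
  ro <- seq(1L, x_dim[1], by = 2L); co <- seq(1L, x_dim[2], by = 2L)
  dx[ro, co, ] <- dout * which$a
  dx[ro, co + 1L, ] <- dx[ro, co + 1L, , drop = FALSE] + dout * which$b
  dx[ro + 1L, co, ] <- dx[ro + 1L, co, , drop = FALSE] + dout * which$c
  dx[ro + 1L, co + 1L, ] <- dx[ro + 1L, co + 1L, , drop = FALSE] + dout * which$d
  dx
}

# He-scaled random initialization of all parameters.
cnn_init <- function(cfg) {
  layers <- list()
  h <- cfg$input_size[1]; w <- cfg$input_size[2]; ch <- cfg$channels
  for (bi in seq_along(cfg$blocks)) {
    f <- cfg$blocks[bi]
    for (li in seq_len(cfg$layers_per_block)) {
      fan_in <- 9L * ch
      layers[[length(layers) + 1L]] <- list(
        type = "conv",
        w = matrix(stats::rnorm(fan_in * f, sd = sqrt(2 / fan_in)), fan_in, f),
        b = numeric(f),
        idx = im2col_index(h, w, ch)
      )
      ch <- f
    }
    layers[[length(layers) + 1L]] <- list(type = "pool")
    h <- h %/% 2L; w <- w %/% 2L
  }
  flat <- h * w * ch
  layers[[length(layers) + 1L]] <- list(
    type = "dense",
    w = matrix(stats::rnorm(flat * cfg$dense, sd = sqrt(2 / flat)),
               flat, cfg$dense),
    b = numeric(cfg$dense), relu = TRUE
  )
  layers[[length(layers) + 1L]] <- list(
    type = "dense",
    w = matrix(stats::rnorm(cfg$dense * 2L, sd = sqrt(2 / cfg$dense)),
               cfg$dense, 2L),
    b = numeric(2L), relu = FALSE
  )
  layers
}

# Forward pass; returns class probabilities and the caches for backprop.
cnn_forward <- function(x, layers) {
  caches <- vector("list", length(layers))
  cur <- x
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "conv") {
      fw <- conv_forward(cur, ly)
      pre <- fw$out
      cur <- pre * (pre > 0)  # ReLU
      caches[[i]] <- list(
        x_dim = dim(pre), col = fw$col, pre = pre,
        x_in_dim = c(dim(pre)[1], dim(pre)[2], ncol(fw$col) / 9L)
      )
    } else if (ly$type == "pool") {
      fw <- maxpool_forward(cur)
      caches[[i]] <- list(which = fw$which, x_dim = dim(cur))
      cur <- fw$out
    } else {
      if (is.array(cur)) cur <- as.vector(cur)
      pre <- drop(cur %*% ly$w) + ly$b
      caches[[i]] <- list(x = cur, pre = pre)
      cur <- if (ly$relu) pre * (pre > 0) else pre
    }
  }
  z <- cur - max(cur)
  probs <- exp(z) / sum(exp(z))
  list(probs = probs, caches = caches)
}

# Backward pass from the softmax cross-entropy gradient; returns per-layer
# parameter gradients.
cnn_backward <- function(dlogits, layers, caches) {
  grads <- vector("list", length(layers))
  dcur <- dlogits
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]; ca <- caches[[i]]
    if (ly$type == "dense") {
      if (ly$relu) dcur <- dcur * (ca$pre > 0)
      grads[[i]] <- list(dw = outer(ca$x, dcur), db = dcur)
      dcur <- drop(ly$w %*% dcur)
    } else if (ly$type == "pool") {
      dcur <- maxpool_backward(array(dcur, dim = dim(ca$which$a)), ca$which,
                               ca$x_dim)
    } else {
      dcur <- array(dcur, dim = ca$x_dim)
      dcur <- dcur * (ca$pre > 0)
      bw <- conv_backward(dcur, ca$x_in_dim, ly, ca$col)
      grads[[i]] <- list(dw = bw$dw, db = bw$db)
      dcur <- bw$dx
    }
  }
  grads
}

# Loss and gradients for one image/label (label in 1:2).
cnn_loss_grad <- function(x, label, layers) {
  fw <- cnn_forward(x, layers)
  p <- pmax(fw$probs, 1e-12)
  loss <- -log(p[label])
  dlogits <- fw$probs
  dlogits[label] <- dlogits[label] - 1
  list(loss = loss, grads = cnn_backward(dlogits, layers, fw$caches))
}

prepare_cnn_image <- function(img, cfg) {
  if (!is.array(img) || length(dim(img)) != 3L) {
    abort("CNN inputs must be H x W x C arrays.",
          class = "tonguetherm_error_input")
  }
  d <- dim(img)
  if (d[3] != cfg$channels) {
    abort("Image channel count does not match the configuration.",
          class = "tonguetherm_error_input")
  }
  x <- img
  if (max(x) > 1.5) x <- x / 255
  if (d[1] != cfg$input_size[1] || d[2] != cfg$input_size[2]) {
    out <- array(0, dim = c(cfg$input_size, d[3]))
    for (ch in seq_len(d[3])) {
      out[, , ch] <- bilinear_resize_matrix(x[, , ch], cfg$input_size[1],
                                            cfg$input_size[2])
    }
    x <- out
  }
  # centre intensities at zero: plain SGD conditions far better on centered
  # inputs, and it keeps the published 0.01 learning rate workable
  unclass(x) - 0.5
}

#' Train the down-scaled VGG-style CNN on labeled thermograms
#'
#' Stacked 3x3 convolution + ReLU blocks closed by 2x2 max pooling, a fully
#' connected ReLU layer and a softmax head, trained with plain SGD at the
#' configured learning rate. Augmentation (when enabled) is applied to
#' training images only, re-drawn each epoch. Images of a different size
#' than `cfg$input_size` are resized bilinearly.
#'
#' @param x A list of H x W x C image arrays (0..255 or 0..1), uniform size.
#' @param y Labels (normal/diabetic factor or +/-1).
#' @param cfg A [cnn_config()].
#' @param seed Seed for initialization, shuffling and augmentation.
#' @return An object of class `therm_cnn` with the trained layers and the
#'   per-epoch mean training loss.
#' @export
fit_cnn <- function(x, y, cfg = cnn_config(), seed = 7L) {
  if (!is.list(x) || length(x) < 2L) {
    abort("`x` must be a list of at least two images.",
          class = "tonguetherm_error_input")
  }
  y <- as_label_factor(y)
  if (length(x) != length(y)) {
    abort("Images and labels differ in length.",
          class = "tonguetherm_error_input")
  }
  if (any(table(y) < 1L) || nlevels(droplevels(y)) < 2L) {
    abort("Both classes must be present for CNN training.",
          class = "tonguetherm_error_input")
  }
  imgs <- lapply(x, prepare_cnn_image, cfg = cfg)
  lab <- as.integer(y)  # 1 = normal, 2 = diabetic
  history <- numeric(cfg$epochs)
  layers <- with_seed(seed, {
    layers <- cnn_init(cfg)
    n <- length(imgs)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        acc <- NULL
        for (ii in idx) {
          xi <- imgs[[ii]]
          if (cfg$augment) xi <- random_augment(xi, cfg$aug)
          lg <- cnn_loss_grad(xi, lab[ii], layers)
          losses <- c(losses, lg$loss)
          if (is.null(acc)) {
            acc <- lg$grads
          } else {
            for (li in seq_along(acc)) {
              if (!is.null(acc[[li]])) {
                acc[[li]]$dw <- acc[[li]]$dw + lg$grads[[li]]$dw
                acc[[li]]$db <- acc[[li]]$db + lg$grads[[li]]$db
              }
            }
          }
        }
        scale <- cfg$learning_rate / length(idx)
        for (li in seq_along(layers)) {
          if (!is.null(acc[[li]])) {
            layers[[li]]$w <- layers[[li]]$w - scale * acc[[li]]$dw
            layers[[li]]$b <- layers[[li]]$b - scale * acc[[li]]$db
          }
        }
      }
      history[ep] <- mean(losses)
    }
    layers
  })
  structure(
    list(layers = layers, cfg = cfg, levels = levels(y), seed = seed,
         history = history),
    class = "therm_cnn"
  )
}

#' @export
predict.therm_cnn <- function(object, newdata, ...) {
  imgs <- lapply(newdata, prepare_cnn_image, cfg = object$cfg)
  probs <- t(vapply(imgs, function(im) {
    cnn_forward(im, object$layers)$probs
  }, numeric(2)))
  cls <- object$levels[max.col(probs, ties.method = "first")]
  tibble::tibble(
    .pred_class = factor(cls, levels = object$levels),
    .score = probs[, 2] - probs[, 1],
    .posterior_diabetic = probs[, 2]
  )
}

# ---- augmentation -----------------------------------------------------------

# Inverse-mapped affine warp with bilinear sampling (edge-clamped).
affine_warp <- function(img, shear = 0, zoom = 1, rotation = 0,
                        dx = 0, dy = 0, hflip = FALSE) {
  d <- dim(img)
  h <- d[1]; w <- d[2]
  th <- rotation * pi / 180
  # forward map: flip -> shear -> rotate/zoom -> translate, about the centre
  a11 <- cos(th) / zoom; a12 <- (-sin(th) + shear) / zoom
  a21 <- sin(th) / zoom; a22 <- cos(th) / zoom
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  ry <- matrix(seq_len(h), h, w) - cy
  rx <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  sy <- a11 * ry + a12 * rx + cy - dy
  sx <- a21 * ry + a22 * rx + cx - dx
  if (hflip) sx <- (w + 1) - sx
  sy <- pmin(pmax(sy, 1), h); sx <- pmin(pmax(sx, 1), w)
  y0 <- pmin(floor(sy), h - 1); x0 <- pmin(floor(sx), w - 1)
  fy <- sy - y0; fx <- sx - x0
  out <- array(0, dim = d)
  for (ch in seq_len(d[3])) {
    m <- img[, , ch]
    g <- function(rr, cc) m[cbind(as.vector(rr), as.vector(cc))]
    v <- g(y0, x0) * (1 - fy) * (1 - fx) + g(y0, x0 + 1) * (1 - fy) * fx +
      g(y0 + 1, x0) * fy * (1 - fx) + g(y0 + 1, x0 + 1) * fy * fx
    out[, , ch] <- matrix(v, h, w)
  }
  out
}

# One random draw from the augmentation set.
random_augment <- function(img, aug) {
  affine_warp(
    img,
    shear = stats::runif(1, -aug$shear, aug$shear),
    zoom = 1 + stats::runif(1, -aug$zoom, aug$zoom),
    rotation = stats::runif(1, -aug$rotation, aug$rotation),
    dx = stats::runif(1, -1, 1) * aug$translation * dim(img)[2],
    dy = stats::runif(1, -1, 1) * aug$translation * dim(img)[1],
    hflip = aug$hflip && stats::runif(1) < 0.5
  )
}
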