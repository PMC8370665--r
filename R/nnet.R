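#' Compact CNN training engine
#'
#' A self-contained forward/backward implementation of the layer kinds used
#' by the proposed classifier: same-padded stride-1 convolution (via im2col
#' and BLAS matrix products), 2x2/stride-2 max pooling, ReLU, flatten,
#' inverted dropout, dense layers, and a sigmoid or softmax head trained
#' with binary / categorical cross-entropy under RMSprop or Adam. Batches
#' are arrays `H x W x C x N`; pixel inputs on the 0-255 scale are
#' normalized to `[0, 1]` internally.
#'
#' @name cnn_engine
NULL

trainable_kinds <- c("conv", "maxpool", "relu", "flatten", "dropout",
                     "dense", "output")

# im2col gather indices for one image: (k*k*C) x (H*W) into the zero-padded
# array (Hp x Wp x C), pixel order column-major
im2col_idx <- function(H, W, C, k) {
  pad <- (k - 1L) %/% 2L
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  dr <- rep(0:(k - 1L), times = k)
  dc <- rep(0:(k - 1L), each = k)
  off <- as.vector(outer(dc * Hp + dr, (0:(C - 1L)) * Hp * Wp, "+"))
  base <- as.vector(outer(seq_len(H), (seq_len(W) - 1L) * Hp, "+"))
  list(idx = outer(off, base, "+"), Hp = Hp, Wp = Wp, pad = pad)
}

pad_zero_batch <- function(x, pad) {
  d <- dim(x)
  out <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  out
}

#' Initialize a trainable model from a specification
#'
#' He-normal weight initialization, zero biases; seeded and reproducible.
#'
#' @param spec a `cnn_spec` containing only trainable layer kinds (the
#'   proposed CNN; transfer topologies with batch-norm/separable layers are
#'   declarative only).
#' @param seed integer seed.
#' @return object of class `cnn_model`.
#' @export
init_cnn_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cnn_spec"))
  kinds <- vapply(spec$layers, function(l) l$kind, "")
  if (!all(kinds %in% trainable_kinds))
    stop("spec contains layer kinds the training engine does not support: ",
         paste(setdiff(kinds, trainable_kinds), collapse = ", "))
  params <- with_seed(derive_seed(seed, "init"), {
    lapply(spec$layers, function(l) {
      if (l$kind == "conv") {
        fan_in <- prod(l$kernel)
        list(W = matrix(stats::rnorm(l$filters * fan_in, 0, sqrt(2 / fan_in)),
                        l$filters, fan_in),
             b = numeric(l$filters))
      } else if (l$kind %in% c("dense", "output")) {
        list(W = matrix(stats::rnorm(l$units * l$in_features, 0,
                                     sqrt(2 / l$in_features)),
                        l$units, l$in_features),
             b = numeric(l$units))
      } else NULL
    })
  })
  structure(list(spec = spec, params = params), class = "cnn_model")
}

conv_forward <- function(x, W, b, k) {
  d <- dim(x)  # H W C N
  ii <- im2col_idx(d[1], d[2], d[3], k)
  xp <- pad_zero_batch(x, ii$pad)
  per <- ii$Hp * ii$Wp * d[3]
  HW <- d[1] * d[2]
  patches <- matrix(0, nrow(ii$idx), HW * d[4])
  xf <- as.vector(xp)
  for (n in seq_len(d[4]))
    patches[, (n - 1L) * HW + seq_len(HW)] <- xf[ii$idx + (n - 1L) * per]
  out <- W %*% patches + b
  outa <- aperm(array(out, c(nrow(W), HW, d[4])), c(2, 1, 3))
  list(out = array(outa, c(d[1], d[2], nrow(W), d[4])),
       patches = patches, ii = ii, in_dim = d)
}

conv_backward <- function(dout, cache, W) {
  d <- cache$in_dim
  HW <- d[1] * d[2]; FN <- dim(dout)[3]
  dmat <- matrix(aperm(array(dout, c(HW, FN, d[4])), c(2, 1, 3)),
                 FN, HW * d[4])
  dW <- dmat %*% t(cache$patches)
  db <- rowSums(dmat)
  dP <- t(W) %*% dmat
  ii <- cache$ii
  per <- ii$Hp * ii$Wp * d[3]
  dxp <- numeric(per * d[4])
  gidx <- as.vector(ii$idx)
  for (n in seq_len(d[4])) {
    s <- rowsum(as.vector(dP[, (n - 1L) * HW + seq_len(HW)]), gidx)
    dxp[as.integer(rownames(s)) + (n - 1L) * per] <-
      dxp[as.integer(rownames(s)) + (n - 1L) * per] + s[, 1]
  }
  dxp <- array(dxp, c(ii$Hp, ii$Wp, d[3], d[4]))
  p <- ii$pad
  list(dx = dxp[p + seq_len(d[1]), p + seq_len(d[2]), , , drop = FALSE],
       dW = dW, db = db)
}

pool_forward <- function(x) {
  d <- dim(x)
  ro <- seq(1L, d[1], 2L); re <- seq(2L, d[1], 2L)
  co <- seq(1L, d[2], 2L); ce <- seq(2L, d[2], 2L)
  s <- list(x[ro, co, , , drop = FALSE], x[re, co, , , drop = FALSE],
            x[ro, ce, , , drop = FALSE], x[re, ce, , , drop = FALSE])
  out <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  # route gradient to the first maximal cell in a fixed order
  m <- vector("list", 4)
  taken <- array(FALSE, dim(out))
  for (i in 1:4) {
    m[[i]] <- (s[[i]] == out) & !taken
    taken <- taken | m[[i]]
  }
  list(out = out, masks = m, in_dim = d)
}

pool_backward <- function(dout, cache) {
  d <- cache$in_dim
  dx <- array(0, d)
  ro <- seq(1L, d[1], 2L); re <- seq(2L, d[1], 2L)
  co <- seq(1L, d[2], 2L); ce <- seq(2L, d[2], 2L)
  dx[ro, co, , ] <- dout * cache$masks[[1]]
  dx[re, co, , ] <- dout * cache$masks[[2]]
  dx[ro, ce, , ] <- dout * cache$masks[[3]]
  dx[re, ce, , ] <- dout * cache$masks[[4]]
  dx
}

#' Forward pass
#'
#' @param model a [init_cnn_model()] result.
#' @param x batch array `H x W x C x N`, values in `[0, 1]`.
#' @param training apply dropout (uses the current RNG stream).
#' @return list with `out` (final activations, units x N matrix), `caches`
#'   and `shapes` (per-layer output shapes actually produced).
#' @export
cnn_forward <- function(model, x, training = FALSE) {
  spec <- model$spec
  if (!all(dim(x)[1:3] == spec$input_size))
    stop("shape mismatch between data and spec")
  a <- x
  caches <- vector("list", length(spec$layers))
  shapes <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    p <- model$params[[i]]
    if (l$kind == "conv") {
      cf <- conv_forward(a, p$W, p$b, l$kernel[1])
      caches[[i]] <- cf[c("patches", "ii", "in_dim")]
      a <- cf$out
    } else if (l$kind == "maxpool") {
      pf <- pool_forward(a)
      caches[[i]] <- pf[c("masks", "in_dim")]
      a <- pf$out
    } else if (l$kind == "relu") {
      caches[[i]] <- list(mask = a > 0)
      a <- a * caches[[i]]$mask
    } else if (l$kind == "flatten") {
      caches[[i]] <- list(in_dim = dim(a))
      a <- matrix(a, prod(dim(a)[1:3]), dim(a)[4])
    } else if (l$kind == "dropout") {
      if (training && l$rate > 0) {
        mask <- (matrix(stats::runif(length(a)), nrow(a)) >= l$rate) / (1 - l$rate)
        caches[[i]] <- list(mask = mask)
        a <- a * mask
      }
    } else if (l$kind %in% c("dense", "output")) {
      caches[[i]] <- list(a_in = a)
      z <- p$W %*% a + p$b
      act <- if (is.null(l$activation)) "linear" else l$activation
      a <- switch(act,
        relu = { caches[[i]]$mask <- z > 0; z * (z > 0) },
        sigmoid = 1 / (1 + exp(-z)),
        softmax = { e <- exp(sweep(z, 2, apply(z, 2, max))); sweep(e, 2, colSums(e), "/") },
        z)
    }
    shapes[[i]] <- if (is.matrix(a)) nrow(a) else dim(a)[1:3]
  }
  list(out = a, caches = caches, shapes = shapes)
}

# cross-entropy loss and the gradient at the head pre-activation
head_loss <- function(out, y, n_units) {
  n <- ncol(out)
  eps <- 1e-12
  if (n_units == 1) {
    p <- clamp(out[1, ], eps, 1 - eps)
    loss <- -mean(y * log(p) + (1 - y) * log(1 - p))
    dz <- matrix((out[1, ] - y) / n, 1, n)
  } else {
    Y <- matrix(0, n_units, n)
    Y[cbind(y, seq_len(n))] <- 1
    loss <- -mean(log(clamp(out[cbind(y, seq_len(n))], eps, 1)))
    dz <- (out - Y) / n
  }
  list(loss = loss, dz = dz)
}

cnn_backward <- function(model, fw, dz) {
  spec <- model$spec
  grads <- vector("list", length(spec$layers))
  d <- dz
  for (i in rev(seq_along(spec$layers))) {
    l <- spec$layers[[i]]
    p <- model$params[[i]]
    cache <- fw$caches[[i]]
    if (l$kind %in% c("dense", "output")) {
      if (identical(l$activation, "relu")) d <- d * cache$mask
      grads[[i]] <- list(dW = d %*% t(cache$a_in), db = rowSums(d))
      d <- t(p$W) %*% d
    } else if (l$kind == "dropout") {
      if (!is.null(cache$mask)) d <- d * cache$mask
    } else if (l$kind == "flatten") {
      d <- array(d, cache$in_dim)
    } else if (l$kind == "relu") {
      d <- d * cache$mask
    } else if (l$kind == "maxpool") {
      d <- pool_backward(d, cache)
    } else if (l$kind == "conv") {
      cb <- conv_backward(d, cache, p$W)
      grads[[i]] <- list(dW = cb$dW, db = cb$db)
      d <- cb$dx
    }
  }
  grads
}

make_optimizer <- function(kind = c("rmsprop", "adam"), lr = 3e-4) {
  kind <- match.arg(kind)
  state <- new.env(parent = emptyenv())
  state$t <- 0
  step <- function(params, grads) {
    state$t <- state$t + 1
    for (i in seq_along(params)) {
      if (is.null(params[[i]]) || is.null(grads[[i]])) next
      for (nm in c("W", "b")) {
        g <- grads[[i]][[if (nm == "W") "dW" else "db"]]
        key <- paste0("l", i, nm)
        if (kind == "rmsprop") {
          v <- if (is.null(state[[key]])) g * 0 else state[[key]]
          v <- 0.9 * v + 0.1 * g^2
          state[[key]] <- v
          params[[i]][[nm]] <- params[[i]][[nm]] - lr * g / (sqrt(v) + 1e-7)
        } else {
          mkey <- paste0(key, "m"); vkey <- paste0(key, "v")
          m <- if (is.null(state[[mkey]])) g * 0 else state[[mkey]]
          v <- if (is.null(state[[vkey]])) g * 0 else state[[vkey]]
          m <- 0.9 * m + 0.1 * g
          v <- 0.999 * v + 0.001 * g^2
          state[[mkey]] <- m; state[[vkey]] <- v
          mh <- m / (1 - 0.9^state$t)
          vh <- v / (1 - 0.999^state$t)
          params[[i]][[nm]] <- params[[i]][[nm]] - lr * mh / (sqrt(vh) + 1e-8)
        }
      }
    }
    params
  }
  step
}

#' Predict class probabilities
#'
#' @param model a trained `cnn_model`.
#' @param x batch array `H x W x C x N` on the 0-255 scale (rescaled
#'   internally) or already in `[0, 1]` with `scale = FALSE`.
#' @param scale divide by 255 before the forward pass.
#' @return for a sigmoid head, numeric vector of positive-class
#'   probabilities; for softmax, a units x N probability matrix.
#' @export
predict_cnn <- function(model, x, scale = TRUE) {
  if (scale) x <- x / 255
  out <- cnn_forward(model, x, training = FALSE)$out
  if (nrow(out) == 1) as.vector(out) else out
}
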