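# 1-D convolutional alternative to the dense classifier: two convolution
# blocks (two conv layers + max-pool + dropout each), a 256-unit dense layer
# with dropout, and a sigmoid head; RMSprop on binary cross-entropy.

#' CNN configuration
#'
#' Two convolution blocks, each made of two 1-D convolution layers (ReLU), a
#' width-2 max-pool and a dropout layer; then a flatten, a dense layer of
#' `dense_units` ReLU units with dropout, and a 1-unit sigmoid head. All
#' dropout rates default to 0.25. Filter counts and kernel size are not part
#' of the published description; the defaults (16/32 filters, kernel 3) are
#' package choices.
#'
#' @param input_dim input width (default 600).
#' @param filters integer vector of length 2: filters per block.
#' @param kernel convolution kernel width.
#' @param dense_units width of the penultimate dense layer.
#' @param dropout_rate rate shared by all dropout layers.
#' @param seed initialization seed.
#' @return a `cnn_config` list.
#' @export
cnn_config <- function(input_dim = 600L, filters = c(16L, 32L), kernel = 3L,
                       dense_units = 256L, dropout_rate = 0.25, seed = 1L) {
  stopifnot(length(filters) == 2L, kernel >= 2L, dropout_rate >= 0,
            dropout_rate < 1)
  structure(list(input_dim = as.integer(input_dim),
                 filters = as.integer(filters), kernel = as.integer(kernel),
                 dense_units = as.integer(dense_units),
                 dropout_rate = dropout_rate,
                 activation = "relu", head_activation = "sigmoid",
                 optimizer = "rmsprop", loss = "binary_crossentropy",
                 seed = as.integer(seed)),
            class = "cnn_config")
}

# Layer length bookkeeping: 4 valid convolutions and 2 pools.
.cnn_lengths <- function(cfg) {
  L <- cfg$input_dim
  k <- cfg$kernel
  l1 <- L - k + 1L; l2 <- l1 - k + 1L; p1 <- l2 %/% 2L
  l3 <- p1 - k + 1L; l4 <- l3 - k + 1L; p2 <- l4 %/% 2L
  stopifnot(p2 >= 1L)
  list(l1 = l1, l2 = l2, p1 = p1, l3 = l3, l4 = l4, p2 = p2,
       flat = p2 * cfg$filters[2L])
}

#' Build CNN parameters
#' @param cfg a [cnn_config()].
#' @return object of class `cnn_params`.
#' @export
build_cnn <- function(cfg = cnn_config()) {
  stopifnot(inherits(cfg, "cnn_config"))
  k <- cfg$kernel; f1 <- cfg$filters[1L]; f2 <- cfg$filters[2L]
  ln <- .cnn_lengths(cfg)
  he_conv <- function(k, cin, f) {
    lim <- sqrt(6 / (k * cin))
    array(runif(k * cin * f, -lim, lim), dim = c(k, cin, f))
  }
  params <- .with_seed(cfg$seed, {
    list(config = cfg,
         Wc = list(he_conv(k, 1L, f1), he_conv(k, f1, f1),
                   he_conv(k, f1, f2), he_conv(k, f2, f2)),
         bc = list(numeric(f1), numeric(f1), numeric(f2), numeric(f2)),
         Wd = .he_uniform(ln$flat, cfg$dense_units),
         bd = numeric(cfg$dense_units),
         head_w = as.numeric(.he_uniform(cfg$dense_units, 1L)), head_b = 0,
         normalizer = NULL, training_log = NULL)
  })
  class(params) <- "cnn_params"
  params
}

#' @export
print.cnn_params <- function(x, ...) {
  cat(sprintf("<cnn_params: input %d, filters %d/%d, kernel %d, dense %d>\n",
              x$config$input_dim, x$config$filters[1L], x$config$filters[2L],
              x$config$kernel, x$config$dense_units))
  invisible(x)
}

# Valid 1-D convolution of X (n, L, C) with W (k, C, F): returns (n, Lout, F).
.conv1d <- function(X, W, b) {
  n <- dim(X)[1L]; L <- dim(X)[2L]; C <- dim(X)[3L]
  k <- dim(W)[1L]; f <- dim(W)[3L]
  Lout <- L - k + 1L
  acc <- matrix(rep(b, each = n * Lout), n * Lout, f)
  for (j in seq_len(k)) {
    Xj <- matrix(X[, j:(j + Lout - 1L), , drop = FALSE], n * Lout, C)
    acc <- acc + Xj %*% matrix(W[j, , ], C, f)
  }
  array(acc, dim = c(n, Lout, f))
}

# Backward pass of .conv1d: returns grads for W, b and the input.
.conv1d_bwd <- function(X, W, dOut) {
  n <- dim(X)[1L]; C <- dim(X)[3L]
  k <- dim(W)[1L]; f <- dim(W)[3L]
  Lout <- dim(dOut)[2L]
  dOm <- matrix(dOut, n * Lout, f)
  gW <- array(0, dim = dim(W)); dX <- array(0, dim = dim(X))
  for (j in seq_len(k)) {
    Xj <- matrix(X[, j:(j + Lout - 1L), , drop = FALSE], n * Lout, C)
    gW[j, , ] <- crossprod(Xj, dOm)
    dXj <- dOm %*% t(matrix(W[j, , ], C, f))
    dX[, j:(j + Lout - 1L), ] <- dX[, j:(j + Lout - 1L), , drop = FALSE] +
      array(dXj, dim = c(n, Lout, C))
  }
  list(gW = gW, gb = colSums(dOm), dX = dX)
}

# Width-2 stride-2 max-pool along the length axis (trailing odd column
# dropped); ties resolve to the earlier position.
.maxpool2 <- function(X) {
  n <- dim(X)[1L]; L <- dim(X)[2L]; C <- dim(X)[3L]
  Lp <- L %/% 2L
  X1 <- X[, seq(1L, 2L * Lp, 2L), , drop = FALSE]
  X2 <- X[, seq(2L, 2L * Lp, 2L), , drop = FALSE]
  mask <- X1 >= X2
  list(out = ifelse(mask, X1, X2), mask = mask, Lin = L)
}

.maxpool2_bwd <- function(pool, dOut) {
  n <- dim(dOut)[1L]; Lp <- dim(dOut)[2L]; C <- dim(dOut)[3L]
  dX <- array(0, dim = c(n, pool$Lin, C))
  dX[, seq(1L, 2L * Lp, 2L), ] <- dOut * pool$mask
  dX[, seq(2L, 2L * Lp, 2L), ] <- dOut * !pool$mask
  dX
}

# Full forward pass on a normalized batch; keep = TRUE retains intermediates.
.cnn_forward <- function(params, H, keep = FALSE, masks = NULL) {
  n <- nrow(H)
  st <- list()
  X0 <- array(H, dim = c(n, ncol(H), 1L))
  z1 <- .conv1d(X0, params$Wc[[1L]], params$bc[[1L]]); a1 <- .relu(z1)
  z2 <- .conv1d(a1, params$Wc[[2L]], params$bc[[2L]]); a2 <- .relu(z2)
  p1 <- .maxpool2(a2)
  d1 <- if (is.null(masks)) p1$out else p1$out * masks$m1
  z3 <- .conv1d(d1, params$Wc[[3L]], params$bc[[3L]]); a3 <- .relu(z3)
  z4 <- .conv1d(a3, params$Wc[[4L]], params$bc[[4L]]); a4 <- .relu(z4)
  p2 <- .maxpool2(a4)
  d2 <- if (is.null(masks)) p2$out else p2$out * masks$m2
  flat <- matrix(d2, n, prod(dim(d2)[2:3]))
  zd <- sweep(flat %*% params$Wd, 2L, params$bd, "+"); ad <- .relu(zd)
  dd <- if (is.null(masks)) ad else ad * masks$md
  zh <- as.numeric(dd %*% params$head_w) + params$head_b
  p <- .sigmoid(zh)
  if (!keep) return(p)
  list(p = p, X0 = X0, z1 = z1, a1 = a1, z2 = z2, pool1 = p1, d1 = d1,
       z3 = z3, a3 = a3, z4 = z4, pool2 = p2, d2 = d2, flat = flat,
       zd = zd, dd = dd)
}

#' Score a batch with the CNN
#'
#' Dropout is inactive at scoring time; two calls on the same batch agree
#' exactly, and batch scoring equals row-by-row scoring.
#'
#' @param params a `cnn_params` (normalizer fitted by [fit_cnn()]).
#' @param batch numeric matrix `n x input_dim`.
#' @return numeric vector of scores in (0, 1).
#' @export
score_cnn <- function(params, batch) {
  stopifnot(inherits(params, "cnn_params"))
  if (is.null(dim(batch))) batch <- matrix(batch, nrow = 1L)
  if (ncol(batch) != params$config$input_dim) {
    stop(sprintf("shape error: batch has %d columns, model expects %d",
                 ncol(batch), params$config$input_dim))
  }
  H <- normalize_features(params$normalizer, batch)
  p <- .cnn_forward(params, H)
  pmin(pmax(p, .SCORE_EPS), 1 - .SCORE_EPS)
}

.cnn_grads <- function(params, H, y, masks = NULL) {
  fw <- .cnn_forward(params, H, keep = TRUE, masks = masks)
  n <- length(y)
  dz <- (fw$p - y) / n
  g_head_w <- as.numeric(crossprod(fw$dd, dz))
  g_head_b <- sum(dz)
  dAd <- outer(dz, params$head_w)
  if (!is.null(masks)) dAd <- dAd * masks$md
  dZd <- dAd * (fw$zd > 0)
  gWd <- crossprod(fw$flat, dZd)
  gbd <- colSums(dZd)
  dFlat <- dZd %*% t(params$Wd)
  dD2 <- array(dFlat, dim = dim(fw$d2))
  if (!is.null(masks)) dD2 <- dD2 * masks$m2
  dA4 <- .maxpool2_bwd(fw$pool2, dD2)
  dZ4 <- dA4 * (fw$z4 > 0)
  b4 <- .conv1d_bwd(fw$a3, params$Wc[[4L]], dZ4)
  dZ3 <- b4$dX * (fw$z3 > 0)
  b3 <- .conv1d_bwd(fw$d1, params$Wc[[3L]], dZ3)
  dD1 <- b3$dX
  if (!is.null(masks)) dD1 <- dD1 * masks$m1
  dA2 <- .maxpool2_bwd(fw$pool1, dD1)
  dZ2 <- dA2 * (fw$z2 > 0)
  b2 <- .conv1d_bwd(fw$a1, params$Wc[[2L]], dZ2)
  dZ1 <- b2$dX * (fw$z1 > 0)
  b1 <- .conv1d_bwd(fw$X0, params$Wc[[1L]], dZ1)
  list(gWc = list(b1$gW, b2$gW, b3$gW, b4$gW),
       gbc = list(b1$gb, b2$gb, b3$gb, b4$gb),
       gWd = gWd, gbd = gbd, g_head_w = g_head_w, g_head_b = g_head_b,
       loss = .bce(fw$p, y))
}

.rmsprop_step <- function(cache, grads, lr, rho = 0.9, eps = 1e-8) {
  upd <- vector("list", length(grads))
  for (k in seq_along(grads)) {
    cache[[k]] <- rho * cache[[k]] + (1 - rho) * grads[[k]]^2
    upd[[k]] <- lr * grads[[k]] / (sqrt(cache[[k]]) + eps)
  }
  list(cache = cache, upd = upd)
}

#' Train the CNN on labeled pocket-ligand pairs
#'
#' Mini-batch RMSprop on binary cross-entropy, dropout 0.25 after each pool
#' and after the dense layer (training only). Same contracts as
#' [fit_dfcnn()].
#'
#' @inheritParams fit_dfcnn
#' @param params a `cnn_params` from [build_cnn()].
#' @return trained `cnn_params` with a `training_log`.
#' @export
fit_cnn <- function(params, train, val = NULL, epochs = 50L,
                    batch_size = 128L, lr = 1e-3, seed = 1L) {
  stopifnot(inherits(params, "cnn_params"))
  x <- train$x; y <- as.numeric(train$y)
  if (length(unique(y)) < 2L) {
    stop("configuration error: training set must contain both classes")
  }
  params$normalizer <- fit_normalizer(x)
  H <- normalize_features(params$normalizer, x)
  Hval <- if (!is.null(val)) normalize_features(params$normalizer, val$x)
  cfg <- params$config
  ln <- .cnn_lengths(cfg)
  rate <- cfg$dropout_rate
  shapes <- c(lapply(params$Wc, dim), lapply(params$bc, length),
              list(dim(params$Wd), length(params$bd),
                   length(params$head_w), 1L))
  cache <- lapply(shapes, function(s) array(0, dim = s))
  log_tr <- numeric(epochs); log_val <- rep(NA_real_, epochs)
  .with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(nrow(H))
      for (s in seq(1L, nrow(H), by = batch_size)) {
        idx <- ord[s:min(s + batch_size - 1L, nrow(H))]
        nb <- length(idx)
        masks <- NULL
        if (rate > 0) {
          keep <- 1 - rate
          masks <- list(
            m1 = array(rbinom(nb * ln$p1 * cfg$filters[1L], 1L, keep) / keep,
                       dim = c(nb, ln$p1, cfg$filters[1L])),
            m2 = array(rbinom(nb * ln$p2 * cfg$filters[2L], 1L, keep) / keep,
                       dim = c(nb, ln$p2, cfg$filters[2L])),
            md = matrix(rbinom(nb * cfg$dense_units, 1L, keep) / keep,
                        nb, cfg$dense_units))
        }
        g <- .cnn_grads(params, H[idx, , drop = FALSE], y[idx], masks)
        res <- .rmsprop_step(cache, c(g$gWc, g$gbc,
                                      list(g$gWd, g$gbd, g$g_head_w,
                                           g$g_head_b)), lr)
        cache <- res$cache
        for (i in 1:4) {
          params$Wc[[i]] <- params$Wc[[i]] - res$upd[[i]]
          params$bc[[i]] <- params$bc[[i]] - as.numeric(res$upd[[4L + i]])
        }
        params$Wd <- params$Wd - res$upd[[9L]]
        params$bd <- params$bd - as.numeric(res$upd[[10L]])
        params$head_w <- params$head_w - as.numeric(res$upd[[11L]])
        params$head_b <- params$head_b - as.numeric(res$upd[[12L]])
      }
      log_tr[ep] <- .bce(.cnn_forward(params, H), y)
      if (!is.null(val)) {
        log_val[ep] <- .bce(.cnn_forward(params, Hval), as.numeric(val$y))
      }
    }
  })
  params$training_log <- data.frame(epoch = seq_len(epochs),
                                    train_loss = log_tr, val_loss = log_val)
  params
}
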