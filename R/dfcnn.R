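# Dense fully connected binding classifier: each hidden block consumes the
# concatenation of the (normalized) input and all previous block outputs,
# a sigmoid head turns the final concatenation into a binding probability.

.relu <- function(x) pmax(x, 0)
.sigmoid <- function(x) 1 / (1 + exp(-pmin(pmax(x, -500), 500)))
.SCORE_EPS <- 1e-12

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.bce <- function(p, y) {
  p <- pmin(pmax(p, .SCORE_EPS), 1 - .SCORE_EPS)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Feature normalizer (z-score)
#'
#' Per-feature centering and scaling to unit population standard deviation,
#' fitted on training features only. Constant features get their standard
#' deviation floored at `1e-8`, so their transformed values are all zero.
#'
#' @param features numeric matrix (rows = samples).
#' @param floor minimum allowed standard deviation.
#' @return object of class `normalizer` with `mean` and `std` vectors.
#' @export
fit_normalizer <- function(features, floor = 1e-8) {
  stopifnot(is.matrix(features), nrow(features) >= 1L)
  m <- colMeans(features)
  s <- sqrt(colMeans(sweep(features, 2L, m)^2))  # population sd
  s <- pmax(s, floor)
  structure(list(mean = m, std = s), class = "normalizer")
}

#' Apply a normalizer
#' @param norm a `normalizer` (or `NULL` for the identity).
#' @param x numeric matrix with `length(norm$mean)` columns.
#' @return transformed matrix.
#' @export
normalize_features <- function(norm, x) {
  if (is.null(norm)) return(x)
  stopifnot(ncol(x) == length(norm$mean))
  sweep(sweep(x, 2L, norm$mean), 2L, norm$std, "/")
}

#' DFCNN configuration
#'
#' Defaults mirror the published architecture: 600-dimensional input (two
#' concatenated 300-d feature vectors), 10 densely connected blocks of 100
#' ReLU units each, a 1-unit sigmoid head, Adam on binary cross-entropy.
#' Dropout defaults to 0 for this architecture (the published dropout rate
#' belongs to the CNN alternative).
#'
#' @param input_dim input width; must equal twice the feature dimension.
#' @param n_dense_blocks number of dense blocks.
#' @param block_units units per block.
#' @param dropout dropout rate on block outputs during training.
#' @param include_input if `TRUE` (default, DenseNet convention) every block
#'   also sees the normalized raw input, not only previous block outputs.
#' @param seed initialization seed.
#' @return a `dfcnn_config` list.
#' @export
dfcnn_config <- function(input_dim = 600L, n_dense_blocks = 10L,
                         block_units = 100L, dropout = 0,
                         include_input = TRUE, seed = 1L) {
  stopifnot(input_dim >= 1L, n_dense_blocks >= 1L, block_units >= 1L,
            dropout >= 0, dropout < 1)
  structure(list(input_dim = as.integer(input_dim),
                 n_dense_blocks = as.integer(n_dense_blocks),
                 block_units = as.integer(block_units),
                 activation = "relu", head_activation = "sigmoid",
                 optimizer = "adam", loss = "binary_crossentropy",
                 dropout = dropout, include_input = isTRUE(include_input),
                 seed = as.integer(seed)),
            class = "dfcnn_config")
}

# Input width of block i (1-based) and of the head under dense connectivity.
.block_input_dim <- function(cfg, i) {
  if (cfg$include_input) cfg$input_dim + (i - 1L) * cfg$block_units
  else if (i == 1L) cfg$input_dim else (i - 1L) * cfg$block_units
}

.head_input_dim <- function(cfg) {
  if (cfg$include_input)
    cfg$input_dim + cfg$n_dense_blocks * cfg$block_units
  else cfg$n_dense_blocks * cfg$block_units
}

.dfcnn_n_params <- function(cfg) {
  tot <- 0L
  for (i in seq_len(cfg$n_dense_blocks)) {
    tot <- tot + .block_input_dim(cfg, i) * cfg$block_units + cfg$block_units
  }
  tot + .head_input_dim(cfg) + 1L
}

.he_uniform <- function(nr, nc) {
  lim <- sqrt(6 / nr)
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

#' Build a DFCNN parameter set
#'
#' He-uniform initialization, seeded from `cfg$seed`. The dense-connectivity
#' width invariant (block `i` input width = `input_dim + (i-1) * block_units`
#' when the raw input is included) is asserted at build time along with the
#' closed-form parameter count.
#'
#' @param cfg a [dfcnn_config()].
#' @return object of class `dfcnn_params`.
#' @export
build_dfcnn <- function(cfg = dfcnn_config()) {
  stopifnot(inherits(cfg, "dfcnn_config"))
  params <- .with_seed(cfg$seed, {
    W <- vector("list", cfg$n_dense_blocks)
    b <- vector("list", cfg$n_dense_blocks)
    for (i in seq_len(cfg$n_dense_blocks)) {
      din <- .block_input_dim(cfg, i)
      W[[i]] <- .he_uniform(din, cfg$block_units)
      b[[i]] <- numeric(cfg$block_units)
    }
    hd <- .head_input_dim(cfg)
    list(config = cfg, W = W, b = b,
         head_w = as.numeric(.he_uniform(hd, 1L)), head_b = 0,
         normalizer = NULL, training_log = NULL)
  })
  got <- sum(vapply(params$W, length, 0)) + sum(lengths(params$b)) +
    length(params$head_w) + 1L
  stopifnot(got == .dfcnn_n_params(cfg))
  class(params) <- "dfcnn_params"
  params
}

#' @export
print.dfcnn_params <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<dfcnn_params: %d blocks x %d units, input %d, %d parameters%s>\n",
    cfg$n_dense_blocks, cfg$block_units, cfg$input_dim, .dfcnn_n_params(cfg),
    if (is.null(x$normalizer)) ", unnormalized" else ""))
  invisible(x)
}

# Forward pass on an already-normalized batch. Returns the score vector, or
# (keep = TRUE) the intermediates needed for backprop.
.dfcnn_forward <- function(params, H, keep = FALSE, drop_masks = NULL) {
  cfg <- params$config
  K <- cfg$n_dense_blocks
  Z <- if (keep) vector("list", K) else NULL
  A <- H
  for (i in seq_len(K)) {
    Ai <- if (cfg$include_input || i == 1L) A else
      A[, (cfg$input_dim + 1L):ncol(A), drop = FALSE]
    z <- sweep(Ai %*% params$W[[i]], 2L, params$b[[i]], "+")
    r <- .relu(z)
    if (!is.null(drop_masks)) r <- r * drop_masks[[i]]
    if (keep) Z[[i]] <- z
    A <- cbind(A, r)
  }
  Ahead <- if (cfg$include_input) A else
    A[, (cfg$input_dim + 1L):ncol(A), drop = FALSE]
  zhead <- as.numeric(Ahead %*% params$head_w) + params$head_b
  p <- .sigmoid(zhead)
  if (!keep) return(p)
  list(p = p, zhead = zhead, A = A, Z = Z)
}

#' Score a batch of concatenated pocket-ligand vectors
#'
#' Applies the fitted normalizer internally, then the dense forward pass.
#' Scores are strictly inside (0, 1); batch scoring equals row-by-row
#' scoring (no batch-dependent state, dropout inactive).
#'
#' @param params a `dfcnn_params` (normalizer fitted by [fit_dfcnn()], or
#'   `NULL` for identity).
#' @param batch numeric matrix `n x input_dim` (a single vector is accepted).
#' @return numeric vector of `n` scores.
#' @export
score_dfcnn <- function(params, batch) {
  stopifnot(inherits(params, "dfcnn_params"))
  if (is.null(dim(batch))) batch <- matrix(batch, nrow = 1L)
  if (ncol(batch) != params$config$input_dim) {
    stop(sprintf("shape error: batch has %d columns, model expects %d",
                 ncol(batch), params$config$input_dim))
  }
  H <- normalize_features(params$normalizer, batch)
  p <- .dfcnn_forward(params, H)
  pmin(pmax(p, .SCORE_EPS), 1 - .SCORE_EPS)
}

.adam_state <- function(shapes) {
  lapply(shapes, function(s) list(m = array(0, dim = s), v = array(0, dim = s)))
}

.adam_step <- function(state, grads, lr, t, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  upd <- vector("list", length(grads))
  for (k in seq_along(grads)) {
    state[[k]]$m <- beta1 * state[[k]]$m + (1 - beta1) * grads[[k]]
    state[[k]]$v <- beta2 * state[[k]]$v + (1 - beta2) * grads[[k]]^2
    mhat <- state[[k]]$m / (1 - beta1^t)
    vhat <- state[[k]]$v / (1 - beta2^t)
    upd[[k]] <- lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, upd = upd)
}

# Gradients of mean BCE wrt all DFCNN parameters for a normalized batch.
.dfcnn_grads <- function(params, H, y, drop_masks = NULL) {
  cfg <- params$config
  K <- cfg$n_dense_blocks
  fw <- .dfcnn_forward(params, H, keep = TRUE, drop_masks = drop_masks)
  n <- length(y)
  dz <- (fw$p - y) / n                       # dL/dzhead
  Ahead <- if (cfg$include_input) fw$A else
    fw$A[, (cfg$input_dim + 1L):ncol(fw$A), drop = FALSE]
  g_head_w <- as.numeric(crossprod(Ahead, dz))
  g_head_b <- sum(dz)
  # gradient flowing into the full concatenation [H, R1, ..., RK]
  G <- matrix(0, n, ncol(fw$A))
  head_cols <- if (cfg$include_input) seq_len(ncol(fw$A)) else
    (cfg$input_dim + 1L):ncol(fw$A)
  G[, head_cols] <- G[, head_cols] + outer(dz, params$head_w)
  gW <- vector("list", K); gb <- vector("list", K)
  for (i in rev(seq_len(K))) {
    cols_i <- (cfg$input_dim + (i - 1L) * cfg$block_units + 1L):
      (cfg$input_dim + i * cfg$block_units)
    GR <- G[, cols_i, drop = FALSE]
    if (!is.null(drop_masks)) GR <- GR * drop_masks[[i]]
    dZ <- GR * (fw$Z[[i]] > 0)
    in_cols <- if (cfg$include_input || i == 1L)
      seq_len(cfg$input_dim + (i - 1L) * cfg$block_units)
    else (cfg$input_dim + 1L):(cfg$input_dim + (i - 1L) * cfg$block_units)
    Ai <- fw$A[, in_cols, drop = FALSE]
    gW[[i]] <- crossprod(Ai, dZ)
    gb[[i]] <- colSums(dZ)
    G[, in_cols] <- G[, in_cols] + dZ %*% t(params$W[[i]])
  }
  list(gW = gW, gb = gb, g_head_w = g_head_w, g_head_b = g_head_b,
       loss = .bce(fw$p, y))
}

#' Train a DFCNN on labeled pocket-ligand pairs
#'
#' Mini-batch Adam on binary cross-entropy. The input normalizer is fitted
#' on the training features only and stored inside the returned parameters;
#' validation data are monitored, never trained on. Shuffling and dropout
#' use `seed`, so identical calls give identical results.
#'
#' @param params a `dfcnn_params` from [build_dfcnn()].
#' @param train,val pair sets: lists with `x` (matrix `n x input_dim`) and
#'   `y` (0/1 labels); see [make_pair_dataset()]. `val` may be `NULL`.
#' @param epochs,batch_size,lr optimization settings.
#' @param seed RNG seed for shuffling/dropout.
#' @return trained `dfcnn_params` with `training_log` (per-epoch train/val
#'   loss).
#' @export
fit_dfcnn <- function(params, train, val = NULL, epochs = 50L,
                      batch_size = 128L, lr = 1e-3, seed = 1L) {
  stopifnot(inherits(params, "dfcnn_params"))
  x <- train$x; y <- as.numeric(train$y)
  if (length(unique(y)) < 2L) {
    stop("configuration error: training set must contain both classes")
  }
  stopifnot(ncol(x) == params$config$input_dim, nrow(x) == length(y))
  params$normalizer <- fit_normalizer(x)
  H <- normalize_features(params$normalizer, x)
  Hval <- if (!is.null(val)) normalize_features(params$normalizer, val$x)
  cfg <- params$config
  K <- cfg$n_dense_blocks
  shapes <- c(lapply(params$W, dim), lapply(params$b, length),
              list(length(params$head_w), 1L))
  state <- .adam_state(shapes)
  log_tr <- numeric(epochs); log_val <- rep(NA_real_, epochs)
  t_step <- 0L
  .with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(nrow(H))
      starts <- seq(1L, nrow(H), by = batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + batch_size - 1L, nrow(H))]
        masks <- NULL
        if (cfg$dropout > 0) {
          keep <- 1 - cfg$dropout
          masks <- lapply(seq_len(K), function(i) {
            matrix(rbinom(length(idx) * cfg$block_units, 1L, keep) / keep,
                   length(idx), cfg$block_units)
          })
        }
        g <- .dfcnn_grads(params, H[idx, , drop = FALSE], y[idx], masks)
        t_step <- t_step + 1L
        res <- .adam_step(state, c(g$gW, g$gb, list(g$g_head_w, g$g_head_b)),
                          lr, t_step)
        state <- res$state
        for (i in seq_len(K)) {
          params$W[[i]] <- params$W[[i]] - res$upd[[i]]
          params$b[[i]] <- params$b[[i]] - as.numeric(res$upd[[K + i]])
        }
        params$head_w <- params$head_w - as.numeric(res$upd[[2L * K + 1L]])
        params$head_b <- params$head_b - as.numeric(res$upd[[2L * K + 2L]])
      }
      log_tr[ep] <- .bce(.dfcnn_forward(params, H), y)
      if (!is.null(val)) {
        log_val[ep] <- .bce(.dfcnn_forward(params, Hval), as.numeric(val$y))
      }
    }
  })
  params$training_log <- data.frame(epoch = seq_len(epochs),
                                    train_loss = log_tr, val_loss = log_val)
  params
}

#' Persist model parameters
#'
#' Writes a directory containing `weights.rds` (exact binary serialization
#' of the numeric state) and `config.json` (self-describing sidecar with a
#' format version tag and the architecture). [load_params()] refuses
#' sidecars with an unknown version tag.
#'
#' @param params a `dfcnn_params` or `cnn_params`.
#' @param path directory to create/overwrite.
#' @export
save_params <- function(params, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  arch <- if (inherits(params, "dfcnn_params")) "dfcnn" else "cnn"
  jsonlite::write_json(
    list(format = "dfscreen-params", version = 1L, arch = arch,
         config = unclass(params$config)),
    file.path(path, "config.json"), auto_unbox = TRUE, digits = NA)
  saveRDS(params, file.path(path, "weights.rds"))
  invisible(path)
}

#' @rdname save_params
#' @return `load_params()`: the restored parameter object; scores on any
#'   batch are bit-identical to the saved model's.
#' @export
load_params <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "config.json"))
  if (!identical(meta$format, "dfscreen-params") ||
      !identical(as.integer(meta$version), 1L)) {
    stop(structure(
      class = c("params_version_error", "error", "condition"),
      list(message = sprintf("unsupported parameter container version: %s/%s",
                             meta$format, meta$version), call = NULL)))
  }
  readRDS(file.path(path, "weights.rds"))
}
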