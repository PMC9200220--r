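# Dense classifier: construction invariants, scoring, normalization,
# training, persistence; plus the CNN alternative.

test_that("dense connectivity forces the block and head input widths", {
  cfg <- dfcnn_config()
  expect_equal(dfscreen:::.block_input_dim(cfg, 1L), 600L)
  expect_equal(dfscreen:::.block_input_dim(cfg, 2L), 700L)
  expect_equal(dfscreen:::.head_input_dim(cfg), 1600L)
  cfg1 <- dfcnn_config(n_dense_blocks = 1L)
  expect_equal(dfscreen:::.head_input_dim(cfg1), 700L)

  p <- build_dfcnn(dfcnn_config(n_dense_blocks = 3L, block_units = 10L,
                                input_dim = 20L))
  expect_equal(vapply(p$W, nrow, 0L), c(20L, 30L, 40L))
  expect_length(p$head_w, 50L)
  # parameter count matches the closed form
  expect_equal(sum(vapply(p$W, length, 0L)) + sum(lengths(p$b)) +
                 length(p$head_w) + 1L,
               (20 * 10 + 10) + (30 * 10 + 10) + (40 * 10 + 10) + 50 + 1)

  # excluding the raw input shrinks widths accordingly
  cfg_x <- dfcnn_config(n_dense_blocks = 3L, block_units = 10L,
                        input_dim = 20L, include_input = FALSE)
  px <- build_dfcnn(cfg_x)
  expect_equal(vapply(px$W, nrow, 0L), c(20L, 10L, 20L))
  expect_length(px$head_w, 30L)
})

test_that("builds are deterministic per seed", {
  a <- build_dfcnn(dfcnn_config(input_dim = 12L, n_dense_blocks = 2L,
                                block_units = 4L, seed = 9L))
  b <- build_dfcnn(dfcnn_config(input_dim = 12L, n_dense_blocks = 2L,
                                block_units = 4L, seed = 9L))
  expect_identical(a$W, b$W)
  expect_identical(a$head_w, b$head_w)
})

test_that("scoring: sigmoid head, batch equals per-row, shape checked", {
  p <- build_dfcnn(dfcnn_config(input_dim = 8L, n_dense_blocks = 2L,
                                block_units = 3L, seed = 1L))
  # zero weights everywhere -> sigmoid(0) = 0.5
  z <- p
  z$W <- lapply(z$W, function(w) w * 0)
  z$b <- lapply(z$b, function(b) b * 0)
  z$head_w <- z$head_w * 0; z$head_b <- 0
  x <- withr::with_seed(2, matrix(rnorm(40), 5, 8))
  expect_equal(score_dfcnn(z, x), rep(0.5, 5))

  s_batch <- score_dfcnn(p, x)
  s_rows <- vapply(seq_len(nrow(x)), function(i) score_dfcnn(p, x[i, ]), 0)
  expect_equal(s_batch, s_rows)
  expect_true(all(s_batch > 0 & s_batch < 1))
  expect_error(score_dfcnn(p, matrix(0, 2, 7)), "shape error")
})

test_that("a tiny dense forward pass matches hand arithmetic", {
  p <- build_dfcnn(dfcnn_config(input_dim = 4L, n_dense_blocks = 2L,
                                block_units = 2L, seed = 1L))
  p$W[[1]][] <- 0.1; p$b[[1]] <- c(0.1, -0.2)
  p$W[[2]][] <- 0.2; p$b[[2]] <- c(0, 0)
  p$head_w[] <- 0.5; p$head_b <- -1
  p$normalizer <- NULL
  x <- c(1, -1, 0.5, 2)
  # hand: z1 = 0.1*2.5 + b -> relu (0.35, 0.05); z2 = 0.2*(2.5+0.4) = 0.58
  # head: 0.5*(2.5 + 0.4 + 1.16) - 1 = 1.03 -> sigmoid
  expect_equal(score_dfcnn(p, x), 1 / (1 + exp(-1.03)), tolerance = 1e-12)
})

test_that("normalizer gives zero mean and unit population sd", {
  x <- withr::with_seed(4, matrix(rnorm(600, sd = 7, mean = 3), 60, 10))
  x[, 3] <- 5  # constant column
  nm <- fit_normalizer(x)
  h <- normalize_features(nm, x)
  expect_lt(max(abs(colMeans(h))), 1e-6)
  sds <- sqrt(colMeans(sweep(h, 2, colMeans(h))^2))
  expect_lt(max(abs(sds[-3] - 1)), 1e-3)
  expect_equal(h[, 3], rep(0, 60))  # floored std, transformed to zeros

  # hand case: {0, 2} -> {-1, +1} under population sd
  nm2 <- fit_normalizer(matrix(c(0, 2), 2, 1))
  expect_equal(as.numeric(normalize_features(nm2, matrix(c(0, 2), 2, 1))),
               c(-1, 1))

  # already standardized -> near identity
  z <- scale(withr::with_seed(5, matrix(rnorm(500), 100, 5)))
  z <- sweep(z, 2, sqrt(colMeans(sweep(z, 2, colMeans(z))^2)), "/")
  nm3 <- fit_normalizer(z)
  expect_lt(max(abs(normalize_features(nm3, z) - z)), 1e-10)
})

test_that("training separates separable data and is reproducible", {
  set.seed(NULL)
  d <- 16L; n <- 400L
  y <- rep(c(0, 1), each = n / 2)
  x <- withr::with_seed(6, {
    x <- matrix(rnorm(n * d, sd = 0.5), n, d)
    x[, 2] <- x[, 2] + ifelse(y == 1, 2, -2)  # linearly separable direction
    x
  })
  sp <- withr::with_seed(7, sample.int(n))
  tr <- list(x = x[sp[1:300], ], y = y[sp[1:300]])
  te <- list(x = x[sp[301:400], ], y = y[sp[301:400]])
  m <- fit_dfcnn(small_dfcnn(d), tr, epochs = 20, batch_size = 64, seed = 3)
  auc <- roc_auc(score_dfcnn(m, te$x), te$y)
  expect_gte(auc, 0.95)
  # logistic regression baseline confirms the data are linearly separable
  glm_auc <- withr::with_seed(8, {
    df <- data.frame(y = tr$y, tr$x)
    g <- suppressWarnings(glm(y ~ ., data = df, family = binomial))
    roc_auc(predict(g, data.frame(te$x)), te$y)
  })
  expect_gte(glm_auc, 0.95)

  # permuted labels carry no signal
  yp <- withr::with_seed(9, sample(tr$y))
  mp <- fit_dfcnn(small_dfcnn(d), list(x = tr$x, y = yp), epochs = 10,
                  batch_size = 64, seed = 3)
  auc_p <- roc_auc(score_dfcnn(mp, te$x), te$y)
  expect_gte(auc_p, 0.4)
  expect_lte(auc_p, 0.6)

  # identical data and seed -> identical losses and weights
  m2 <- fit_dfcnn(small_dfcnn(d), tr, epochs = 20, batch_size = 64, seed = 3)
  expect_identical(m$training_log$train_loss, m2$training_log$train_loss)
  expect_identical(m$W, m2$W)

  expect_error(fit_dfcnn(small_dfcnn(d), list(x = x, y = rep(1, n))),
               "configuration error")
})

test_that("dropout is inactive at scoring time", {
  p <- build_dfcnn(dfcnn_config(input_dim = 10L, n_dense_blocks = 2L,
                                block_units = 4L, dropout = 0.25, seed = 2L))
  x <- withr::with_seed(3, matrix(rnorm(50), 5, 10))
  expect_identical(score_dfcnn(p, x), score_dfcnn(p, x))
})

test_that("parameters round-trip through persistence bit-identically", {
  w <- small_world_pairs(seed = 41, dim = 10L, n_pockets = 10L,
                         n_ligands = 40L)
  m <- fit_dfcnn(small_dfcnn(20L), w$pairs, epochs = 3, seed = 1)
  dir <- withr::local_tempdir()
  save_params(m, dir)
  m2 <- load_params(dir)
  x <- withr::with_seed(5, matrix(rnorm(100 * 20), 100, 20))
  expect_identical(score_dfcnn(m, x), score_dfcnn(m2, x))

  # version-tag mismatch is a typed error
  meta <- jsonlite::read_json(file.path(dir, "config.json"))
  meta$version <- 99L
  jsonlite::write_json(meta, file.path(dir, "config.json"),
                       auto_unbox = TRUE)
  expect_error(load_params(dir), class = "params_version_error")
})

test_that("CNN mirrors the scoring contracts", {
  cfg <- cnn_config(input_dim = 40L, filters = c(4L, 6L), seed = 1L)
  p <- build_cnn(cfg)
  # zero weights -> 0.5
  z <- p
  z$Wc <- lapply(z$Wc, function(w) w * 0)
  z$bc <- lapply(z$bc, function(b) b * 0)
  z$Wd <- z$Wd * 0; z$bd <- z$bd * 0; z$head_w <- z$head_w * 0; z$head_b <- 0
  x <- withr::with_seed(2, matrix(rnorm(120), 3, 40))
  expect_equal(score_cnn(z, x), rep(0.5, 3))
  # batch equals per-row; deterministic
  s <- score_cnn(p, x)
  expect_equal(s, vapply(1:3, function(i) score_cnn(p, x[i, ]), 0))
  expect_identical(score_cnn(p, x), score_cnn(p, x))
  expect_true(all(s > 0 & s < 1))
  expect_error(score_cnn(p, matrix(0, 2, 39)), "shape error")
})

test_that("CNN forward pass matches a plain-loop oracle", {
  p <- build_cnn(cnn_config(input_dim = 24L, filters = c(3L, 4L),
                            dense_units = 8L, seed = 5L))
  p$bd <- withr::with_seed(6, rnorm(8, sd = 0.1))
  x <- withr::with_seed(7, rnorm(24))
  expect_equal(score_cnn(p, x), cnn_forward_loops(p, x), tolerance = 1e-10)
})

test_that("CNN training separates separable data deterministically", {
  d <- 48L; n <- 400L
  y <- rep(c(0, 1), each = n / 2)
  x <- withr::with_seed(10, {
    x <- matrix(rnorm(n * d, sd = 0.3), n, d)
    x[, 12] <- x[, 12] + ifelse(y == 1, 2, -2)
    x[, 30] <- x[, 30] + ifelse(y == 1, 1.5, -1.5)
    x
  })
  sp <- withr::with_seed(11, sample.int(n))
  tr <- list(x = x[sp[1:300], ], y = y[sp[1:300]])
  te <- list(x = x[sp[301:400], ], y = y[sp[301:400]])
  cfg <- cnn_config(input_dim = d, filters = c(8L, 16L), seed = 1L)
  m <- fit_cnn(build_cnn(cfg), tr, epochs = 40, batch_size = 64, lr = 3e-3,
               seed = 2)
  expect_gte(roc_auc(score_cnn(m, te$x), te$y), 0.95)
  m2 <- fit_cnn(build_cnn(cfg), tr, epochs = 40, batch_size = 64, lr = 3e-3,
                seed = 2)
  expect_identical(m$training_log$train_loss, m2$training_log$train_loss)
  expect_error(fit_cnn(build_cnn(cfg), list(x = tr$x, y = rep(0, 300))),
               "configuration error")
})
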