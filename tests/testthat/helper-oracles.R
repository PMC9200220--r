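# Shared fixtures and independent oracles used across the suite.

cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# Tiny hand-writable embedding table over explicit tokens.
toy_table <- function(tokens, dim = 2L, values = NULL) {
  if (is.null(values)) {
    values <- matrix(seq_len(length(tokens) * dim) / 10,
                     length(tokens), dim)
  }
  rownames(values) <- tokens
  embedding_table(values)
}

# Connected components of a mol_graph (independent of any package graph
# code): plain breadth-first search over the bond list.
mol_components <- function(mol) {
  n <- length(mol$element)
  comp <- rep(0L, n)
  adj <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (comp[v] != 0L) next
      comp[v] <- cur
      queue <- c(queue, adj[[v]][comp[adj[[v]]] == 0L])
    }
  }
  comp
}

# O(n^2) pairwise Mann-Whitney AUC oracle.
auc_pairwise <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Rand index between two partitions (vectors of labels over the same items).
rand_index <- function(a, b) {
  n <- length(a)
  agree <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      agree <- agree + ((a[i] == a[j]) == (b[i] == b[j]))
    }
  }
  agree / choose(n, 2)
}

# Compare two partitions up to label renaming.
same_partition <- function(a, b) isTRUE(all.equal(rand_index(a, b), 1))

# Small planted world for fast model tests: low-dimensional observations so
# the classifier can be small and quick.
small_world_pairs <- function(seed, dim = 25L, n_pockets = 30L,
                              n_ligands = 120L, ratio = 1) {
  w <- generate_world(n_pockets = n_pockets, n_ligands = n_ligands,
                      k = 4L, noise_sd = 0.1, dim = dim, seed = seed)
  list(world = w, pairs = make_pair_dataset(w, ratio = ratio, seed = seed))
}

small_dfcnn <- function(input_dim, seed = 1L) {
  build_dfcnn(dfcnn_config(input_dim = input_dim, n_dense_blocks = 4L,
                           block_units = 16L, seed = seed))
}

# Deterministic train/test split of a pair set.
split_pairs <- function(pairs, n_train, seed = 1L) {
  n <- length(pairs$y)
  stopifnot(n_train < n)
  idx <- withr::with_seed(seed, sample.int(n))
  tr <- idx[seq_len(n_train)]
  te <- idx[(n_train + 1L):n]
  list(train = list(x = pairs$x[tr, , drop = FALSE], y = pairs$y[tr]),
       test = list(x = pairs$x[te, , drop = FALSE], y = pairs$y[te]))
}

# Plain-loop 1-D convolution network oracle mirroring the CNN architecture
# on a single sample; deliberately scalar so it shares no code path with
# the package implementation.
cnn_forward_loops <- function(params, x) {
  conv_relu <- function(inp, W, b) {
    k <- dim(W)[1L]; cin <- dim(W)[2L]; f <- dim(W)[3L]
    L <- nrow(inp)
    out <- matrix(0, L - k + 1L, f)
    for (t in seq_len(L - k + 1L)) {
      for (ff in seq_len(f)) {
        acc <- b[ff]
        for (j in seq_len(k)) for (c in seq_len(cin)) {
          acc <- acc + inp[t + j - 1L, c] * W[j, c, ff]
        }
        out[t, ff] <- max(acc, 0)
      }
    }
    out
  }
  pool2 <- function(inp) {
    Lp <- nrow(inp) %/% 2L
    out <- matrix(0, Lp, ncol(inp))
    for (t in seq_len(Lp)) for (c in seq_len(ncol(inp))) {
      out[t, c] <- max(inp[2L * t - 1L, c], inp[2L * t, c])
    }
    out
  }
  h <- matrix(x, ncol = 1L)
  h <- conv_relu(h, params$Wc[[1L]], params$bc[[1L]])
  h <- conv_relu(h, params$Wc[[2L]], params$bc[[2L]])
  h <- pool2(h)
  h <- conv_relu(h, params$Wc[[3L]], params$bc[[3L]])
  h <- conv_relu(h, params$Wc[[4L]], params$bc[[4L]])
  h <- pool2(h)
  flat <- as.numeric(h)   # column-major: position fastest, filter slowest
  zd <- as.numeric(t(params$Wd) %*% flat) + params$bd
  ad <- pmax(zd, 0)
  zh <- sum(ad * params$head_w) + params$head_b
  1 / (1 + exp(-zh))
}
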