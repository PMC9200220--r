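# Substructure-identifier embeddings: a word2vec-style table mapping Morgan
# identifiers to fixed-length vectors, with a total lookup (unknown tokens
# hit a dedicated UNK vector, never fail).

.UNK_TOKEN <- "UNK"

#' Construct an embedding table
#'
#' @param vectors numeric matrix, one row per token, rownames = identifiers.
#' @param unk_vector vector used for identifiers absent from the table;
#'   defaults to the stored `UNK` row if present, else the zero vector.
#' @return object of class `embedding_table` with fields `dim`, `vectors`,
#'   `unk_vector`.
#' @export
embedding_table <- function(vectors, unk_vector = NULL) {
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)))
  if (is.null(unk_vector)) {
    unk_vector <- if (.UNK_TOKEN %in% rownames(vectors)) {
      vectors[.UNK_TOKEN, ]
    } else rep(0, ncol(vectors))
  }
  stopifnot(length(unk_vector) == ncol(vectors), all(is.finite(vectors)))
  structure(list(dim = ncol(vectors), vectors = vectors,
                 unk_vector = as.numeric(unk_vector)),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table: %d tokens, dim %d>\n",
              nrow(x$vectors), x$dim))
  invisible(x)
}

#' Train a substructure embedding table
#'
#' Skip-gram with negative sampling over a corpus of substructure sentences.
#' Tokens occurring fewer than `min_count` times are replaced by the `UNK`
#' token before training, so rare-token mass trains the unknown vector; with
#' `min_count = 1` (the default) no replacement happens and the unknown
#' vector is zero. Training is single-threaded with a self-contained RNG:
#' the same corpus and seed give bit-identical tables.
#'
#' @param corpus list of `substructure_sentence` objects (or character
#'   vectors of tokens).
#' @param dim embedding dimension (default 300).
#' @param window context window half-width (default 10).
#' @param min_count minimum token frequency kept in the vocabulary
#'   (default 1).
#' @param epochs training passes over the corpus (default 20; corpora here
#'   are small compared to text corpora, so several passes are needed).
#' @param negative negative samples per context pair.
#' @param lr learning rate.
#' @param seed integer seed for the trainer's RNG.
#' @return an `embedding_table`.
#' @export
train_embedding <- function(corpus, dim = 300L, window = 10L, min_count = 1L,
                            epochs = 20L, negative = 5L, lr = 0.025,
                            seed = 1L) {
  if (length(corpus) == 0L) stop("configuration error: empty training corpus")
  stopifnot(dim >= 1L, window >= 1L, epochs >= 1L)
  sentences <- lapply(corpus, function(s) {
    if (inherits(s, "substructure_sentence")) s$tokens else as.character(s)
  })
  counts <- table(unlist(sentences))
  keep <- names(counts)[counts >= min_count]
  has_unk <- length(keep) < length(counts)
  vocab_tokens <- c(sort(keep), if (has_unk) .UNK_TOKEN)
  sentences <- lapply(sentences, function(tk) {
    tk[!tk %in% keep] <- .UNK_TOKEN
    tk
  })
  idx <- match(unlist(sentences), vocab_tokens) - 1L
  lens <- lengths(sentences)
  counts_full <- table(factor(unlist(sentences), levels = vocab_tokens))
  unigram <- as.numeric(counts_full)^0.75

  mat <- .sgns_train_cpp(idx, lens, length(vocab_tokens), as.integer(dim),
                         as.integer(window), as.integer(negative),
                         as.integer(epochs), lr, unigram, as.numeric(seed))
  rownames(mat) <- vocab_tokens
  unk <- if (has_unk) mat[.UNK_TOKEN, ] else rep(0, dim)
  if (!has_unk) mat <- rbind(mat, matrix(0, 1L, dim,
                                         dimnames = list(.UNK_TOKEN, NULL)))
  embedding_table(mat, unk_vector = unk)
}

#' Embed a substructure sentence as a feature vector
#'
#' Elementwise sum (or mean) of the token vectors; tokens absent from the
#' table contribute the table's `unk_vector`. Lookup is total: no token can
#' fail.
#'
#' @param sentence a `substructure_sentence` or character vector of tokens.
#' @param table an `embedding_table`.
#' @param aggregate `"sum"` (Mol2vec convention, default) or `"mean"`.
#' @return a `feature_vector`: numeric vector of length `table$dim` with
#'   attribute `source_id`.
#' @export
embed_molecule <- function(sentence, table, aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(table, "embedding_table"))
  toks <- if (inherits(sentence, "substructure_sentence")) sentence$tokens
          else as.character(sentence)
  sid <- if (inherits(sentence, "substructure_sentence")) sentence$source_id
         else NA_character_
  if (length(toks) == 0L) {
    stop(mol_parse_error("cannot embed an empty sentence", sid))
  }
  hit <- match(toks, rownames(table$vectors))
  v <- numeric(table$dim)
  known <- which(!is.na(hit))
  if (length(known)) {
    v <- v + colSums(table$vectors[hit[known], , drop = FALSE])
  }
  n_unk <- sum(is.na(hit))
  if (n_unk) v <- v + n_unk * table$unk_vector
  if (aggregate == "mean") v <- v / length(toks)
  structure(v, source_id = sid, class = "feature_vector")
}

#' Featurize a whole SMILES library
#'
#' @param records data frame with `smiles`, `id` (see [read_smi()]).
#' @param table an `embedding_table`.
#' @param radii sentence radii (see [mol_to_sentence()]).
#' @param aggregate passed to [embed_molecule()].
#' @return list with `vectors` (matrix n x dim, rownames = ids) and
#'   `failed` (ids of unparseable records).
#' @export
featurize_library <- function(records, table, radii = c(0L, 1L),
                              aggregate = "sum") {
  vecs <- matrix(0, 0L, table$dim)
  ids <- character(0); failed <- character(0)
  for (k in seq_len(nrow(records))) {
    mol <- tryCatch(parse_smiles(records$smiles[k], records$id[k]),
                    mol_parse_error = function(e) NULL)
    if (is.null(mol)) { failed <- c(failed, records$id[k]); next }
    v <- embed_molecule(mol_to_sentence(mol, radii), table, aggregate)
    vecs <- rbind(vecs, as.numeric(v))
    ids <- c(ids, records$id[k])
  }
  rownames(vecs) <- ids
  list(vectors = vecs, failed = failed)
}

#' Save an embedding table as TSV
#'
#' First column `token`, then `d0..d<dim-1>` float columns; values printed
#' with 17 significant digits so [load_embedding_table()] reproduces them
#' bit-identically.
#'
#' @param table an `embedding_table`.
#' @param path output file.
#' @export
save_embedding_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("token", sprintf("d%d", seq_len(table$dim) - 1L)),
                   collapse = "\t"), con)
  toks <- rownames(table$vectors)
  for (k in seq_along(toks)) {
    writeLines(paste(c(toks[k], sprintf("%.17g", table$vectors[k, ])),
                     collapse = "\t"), con)
  }
}

#' Load an embedding table from TSV
#' @param path file written by [save_embedding_table()].
#' @return an `embedding_table`.
#' @export
load_embedding_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character"), check.names = FALSE)
  mat <- matrix(as.numeric(as.matrix(df[, -1L, drop = FALSE])),
                nrow = nrow(df))
  rownames(mat) <- df[[1L]]
  embedding_table(mat)
}
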