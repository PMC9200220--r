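# Streaming screening engine: score a compound library against one pocket
# vector, rank, select by cutoff or top-fraction, and filter by
# drug-likeness.

.score_model <- function(model, batch) {
  if (inherits(model, "dfcnn_params")) score_dfcnn(model, batch)
  else if (inherits(model, "cnn_params")) score_cnn(model, batch)
  else stop("model must be dfcnn_params or cnn_params")
}

.new_screening_result <- function(ids, scores, pocket_id, model_id,
                                  n_failed) {
  ord <- order(-scores, ids)  # descending score, ties by id (byte-stable)
  structure(list(
    rows = data.frame(compound_id = ids[ord], score = scores[ord],
                      stringsAsFactors = FALSE),
    pocket_id = pocket_id, model_id = model_id,
    n_failed = as.integer(n_failed)),
    class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("<screening_result: %d compounds (%d failed), pocket %s>\n",
              nrow(x$rows), x$n_failed, x$pocket_id))
  if (nrow(x$rows)) print(utils::head(x$rows, 5L))
  invisible(x)
}

#' Screen a SMILES library against a pocket vector
#'
#' Streams the library in batches: each compound is parsed, turned into a
#' Morgan sentence, embedded with `table`, concatenated after `pocket_vec`
#' (pocket half first) and scored. Unparseable records are counted in
#' `n_failed` and skipped. The result is independent of `batch_size` and of
#' input order up to tie handling (ties broken by compound id).
#'
#' @param model trained `dfcnn_params` or `cnn_params` with
#'   `input_dim = 2 * length(pocket_vec)`.
#' @param table an `embedding_table` used to featurize ligands.
#' @param pocket_vec the pocket `feature_vector`.
#' @param library data frame with `smiles`, `id` (see [read_smi()]) or a
#'   path to a `.smi` file.
#' @param batch_size compounds scored per batch.
#' @param radii sentence radii for ligand featurization.
#' @return a `screening_result` (rows sorted by descending score).
#' @export
screen_library <- function(model, table, pocket_vec, library,
                           batch_size = 1000L, radii = c(0L, 1L)) {
  if (is.character(library)) library <- read_smi(library)
  pocket_vec <- as.numeric(pocket_vec)
  input_dim <- if (inherits(model, "dfcnn_params") ||
                   inherits(model, "cnn_params")) model$config$input_dim
  else stop("model must be dfcnn_params or cnn_params")
  if (input_dim != 2L * length(pocket_vec)) {
    stop(sprintf("model input width %d != 2 x pocket vector length %d",
                 input_dim, length(pocket_vec)))
  }
  n <- nrow(library)
  ids <- character(0); scores <- numeric(0); n_failed <- 0L
  if (n > 0L) {
    for (s in seq(1L, n, by = batch_size)) {
      chunk <- library[s:min(s + batch_size - 1L, n), , drop = FALSE]
      feats <- featurize_library(chunk, table, radii = radii)
      n_failed <- n_failed + length(feats$failed)
      if (!nrow(feats$vectors)) next
      batch <- cbind(matrix(pocket_vec, nrow(feats$vectors),
                            length(pocket_vec), byrow = TRUE),
                     feats$vectors)
      scores <- c(scores, .score_model(model, batch))
      ids <- c(ids, rownames(feats$vectors))
    }
  }
  .new_screening_result(ids, scores, "pocket", "model", n_failed)
}

#' Screen precomputed ligand vectors against a pocket vector
#'
#' The vector-table route of the engine: used when ligand feature vectors
#' already exist (e.g. the observed vectors of a synthetic binding world).
#'
#' @param model trained `dfcnn_params` or `cnn_params`.
#' @param pocket_vec numeric pocket vector.
#' @param ligand_vectors numeric matrix with rownames as compound ids.
#' @param batch_size compounds scored per batch.
#' @return a `screening_result`.
#' @export
screen_vectors <- function(model, pocket_vec, ligand_vectors,
                           batch_size = 1000L) {
  pocket_vec <- as.numeric(pocket_vec)
  stopifnot(is.matrix(ligand_vectors), !is.null(rownames(ligand_vectors)))
  n <- nrow(ligand_vectors)
  scores <- numeric(0)
  for (s in seq(1L, max(n, 1L), by = batch_size)) {
    if (n == 0L) break
    idx <- s:min(s + batch_size - 1L, n)
    batch <- cbind(matrix(pocket_vec, length(idx), length(pocket_vec),
                          byrow = TRUE),
                   ligand_vectors[idx, , drop = FALSE])
    scores <- c(scores, .score_model(model, batch))
  }
  .new_screening_result(rownames(ligand_vectors), scores, "pocket", "model",
                        0L)
}

#' Select compounds from a screening result
#'
#' `"cutoff"` keeps every compound with score >= `parameter`;
#' `"top_fraction"` keeps the first `ceiling(parameter * n)` rows of the
#' ranked table.
#'
#' @param result a `screening_result`.
#' @param mode `"cutoff"` or `"top_fraction"`.
#' @param parameter score cutoff or fraction; must lie in (0, 1].
#' @return a `selection_report`: list with `mode`, `parameter`,
#'   `selected_ids`, `n_selected`.
#' @export
select_compounds <- function(result, mode = c("cutoff", "top_fraction"),
                             parameter) {
  mode <- match.arg(mode)
  stopifnot(inherits(result, "screening_result"))
  if (!is.numeric(parameter) || length(parameter) != 1L ||
      parameter <= 0 || parameter > 1) {
    stop("configuration error: parameter must lie in (0, 1]")
  }
  rows <- result$rows
  sel <- if (mode == "cutoff") rows$compound_id[rows$score >= parameter]
  else rows$compound_id[seq_len(min(nrow(rows),
                                    ceiling(parameter * nrow(rows))))]
  structure(list(mode = mode, parameter = parameter, selected_ids = sel,
                 n_selected = length(sel)),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report: %s %g -> %d selected>\n",
              x$mode, x$parameter, x$n_selected))
  invisible(x)
}

#' Recall of known actives in the top fractions of a ranked screen
#'
#' `recall(f)` = fraction of `active_ids` ranked within the top
#' `ceiling(f * n)` compounds; non-decreasing in `f`.
#'
#' @param result a `screening_result` covering all `active_ids`.
#' @param active_ids known active compound ids (non-empty subset of the
#'   scored ids).
#' @param fractions top fractions to evaluate.
#' @return named numeric vector, one recall per fraction.
#' @export
recall_at_top <- function(result, active_ids,
                          fractions = c(0.1, 0.2, 0.3, 0.4, 0.5)) {
  stopifnot(inherits(result, "screening_result"))
  if (length(active_ids) == 0L) {
    stop(structure(class = c("undefined_metric_error", "error", "condition"),
                   list(message = "recall undefined: no active compounds",
                        call = NULL)))
  }
  if (!all(active_ids %in% result$rows$compound_id)) {
    stop("active_ids must all be present among scored compounds")
  }
  n <- nrow(result$rows)
  out <- vapply(fractions, function(f) {
    top <- result$rows$compound_id[seq_len(min(n, ceiling(f * n)))]
    sum(active_ids %in% top) / length(active_ids)
  }, 0)
  names(out) <- sprintf("top%g", fractions)
  out
}

#' Lipinski rule-of-five filter
#'
#' Passes iff MW <= 500, logP <= 5, H-bond donors <= 5 and acceptors <= 10
#' (inclusive bounds).
#'
#' @param mw molecular weight (Da).
#' @param logp octanol-water partition estimate.
#' @param hbd hydrogen-bond donor count.
#' @param hba hydrogen-bond acceptor count.
#' @return logical.
#' @export
lipinski_pass <- function(mw, logp, hbd, hba) {
  vals <- list(mw = mw, logp = logp, hbd = hbd, hba = hba)
  bad <- vapply(vals, function(v) !is.numeric(v) || length(v) != 1L ||
                  is.na(v), TRUE)
  if (any(bad)) {
    stop(sprintf("missing or non-numeric descriptor: %s",
                 paste(names(vals)[bad], collapse = ", ")))
  }
  mw <= 500 && logp <= 5 && hbd <= 5 && hba <= 10
}

#' Lipinski filter for SMILES records
#' @param records data frame with `smiles`, `id`.
#' @return data frame `id`, `mw`, `logp`, `hbd`, `hba`, `pass` (unparseable
#'   records get `NA` descriptors and `pass = FALSE`).
#' @export
lipinski_filter <- function(records) {
  out <- data.frame(id = records$id, mw = NA_real_, logp = NA_real_,
                    hbd = NA_integer_, hba = NA_integer_, pass = FALSE,
                    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(records))) {
    mol <- tryCatch(parse_smiles(records$smiles[k], records$id[k]),
                    mol_parse_error = function(e) NULL)
    if (is.null(mol)) next
    d <- mol_descriptors(mol)
    out[k, c("mw", "logp")] <- c(d$mw, d$logp)
    out[k, c("hbd", "hba")] <- c(d$hbd, d$hba)
    out$pass[k] <- lipinski_pass(d$mw, d$logp, d$hbd, d$hba)
  }
  out
}

#' Write a screening result as TSV plus a JSON run manifest
#'
#' @param result a `screening_result`.
#' @param dir output directory (created if needed).
#' @param manifest named list merged into the manifest (model id, seed, ...).
#' @return the directory, invisibly.
#' @export
write_screening_result <- function(result, dir, manifest = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(result$rows, file.path(dir, "scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    c(list(pocket_id = result$pocket_id, model_id = result$model_id,
           n_scored = nrow(result$rows), n_failed = result$n_failed),
      manifest),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
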