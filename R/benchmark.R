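# End-to-end planted-signal benchmark: the package's own check that the
# whole pipeline (world -> cross-combination pairs -> DFCNN -> screening ->
# enrichment statistics) recovers a known signal.

#' Run the planted-signal recovery benchmark
#'
#' Generates a binding world at the default signal settings (latent
#' dimension 4, noise 0.1, prevalence 0.2), trains a DFCNN on 2,000
#' cross-combination pairs, measures held-out pair AUC, then screens a
#' DUD.E-like labeled library drawn from the same world (a pocket with a
#' realistically small binder fraction, decoys filling up to
#' `library_size`) and computes enrichment at cutoffs 0.99 and 0.9 plus
#' recall at the top 10-50%.
#'
#' `epochs` defaults to 25 rather than the [fit_dfcnn()] default 50 purely
#' to bound runtime; the planted signal saturates well before that.
#'
#' @param seed integer seed driving every random choice.
#' @param n_pockets,n_ligands world size (defaults sized so the labeled
#'   library reaches `library_size` compounds).
#' @param n_train_pairs training pairs (positives + matched negatives).
#' @param n_holdout_pairs additional pairs for held-out AUC.
#' @param library_size labeled-library size for the screening stage.
#' @param epochs training epochs.
#' @return list with `auc` (held-out pair AUC), `ratio_099`, `ratio_09`
#'   (`ratio_report`s), `recall` (named vector), `n_active`, `n_library`.
#' @export
signal_recovery_benchmark <- function(seed, n_pockets = 40L,
                                      n_ligands = 6000L,
                                      n_train_pairs = 2000L,
                                      n_holdout_pairs = 500L,
                                      library_size = 5000L, epochs = 25L) {
  world <- generate_world(n_pockets = n_pockets, n_ligands = n_ligands,
                          seed = seed)
  n_pairs <- n_train_pairs + n_holdout_pairs
  pairs <- make_pair_dataset(world, ratio = 1,
                             max_positives = n_pairs %/% 2L, seed = seed)
  idx <- .with_seed(seed + 101L, sample.int(length(pairs$y)))
  tr_idx <- idx[seq_len(n_train_pairs)]
  te_idx <- idx[(n_train_pairs + 1L):min(n_pairs, length(idx))]
  train <- list(x = pairs$x[tr_idx, , drop = FALSE], y = pairs$y[tr_idx])
  test <- list(x = pairs$x[te_idx, , drop = FALSE], y = pairs$y[te_idx])
  model <- fit_dfcnn(build_dfcnn(dfcnn_config(seed = seed)), train,
                     epochs = epochs, seed = seed)
  auc <- roc_auc(score_dfcnn(model, test$x), test$y)

  # DUD.E-like pocket: binder count near 2% of the library so enrichment is
  # not bounded away by prevalence
  binders <- rowSums(world$labels)
  pocket <- which.min(abs(binders - 0.02 * library_size))
  n_act <- binders[pocket]
  lib <- generate_labeled_library(world, pocket = pocket,
                                  n_decoys = min(library_size - n_act,
                                                 n_ligands - n_act),
                                  seed = seed)
  res <- screen_vectors(model, lib$pocket_vec, lib$vectors)
  list(auc = auc,
       ratio_099 = screen_ratio(res, lib$active_ids, 0.99),
       ratio_09 = screen_ratio(res, lib$active_ids, 0.9),
       recall = recall_at_top(res, lib$active_ids),
       n_active = as.integer(n_act), n_library = nrow(res$rows))
}
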