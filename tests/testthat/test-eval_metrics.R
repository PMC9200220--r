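# Confusion metrics, rank AUC, prediction-random ratios, table aggregation.

test_that("confusion counts match a brute-force scan", {
  sc <- c(0.9, 0.8, 0.3, 0.2)
  lb <- c(1, 0, 1, 0)
  cc <- confusion(sc, lb, threshold = 0.5)
  expect_equal(unclass(cc)[c("TP", "FP", "TN", "FN")],
               list(TP = 1L, FP = 1L, TN = 1L, FN = 1L))
  # perfect separation
  cp <- confusion(c(0.9, 0.8, 0.1), c(1, 1, 0), 0.5)
  expect_equal(cp$FP + cp$FN, 0L)
  # all below threshold
  ca <- confusion(c(0.1, 0.2), c(1, 0), 0.5)
  expect_equal(ca$TP + ca$FP, 0L)
  expect_error(confusion(sc, c(1, 0, 2, 0)), "binary")

  # randomized oracle: exhaustive count on 20 items x several replicates
  for (s in 1:5) {
    sc <- withr::with_seed(s, runif(20))
    lb <- withr::with_seed(s + 50, rbinom(20, 1, 0.5))
    if (length(unique(lb)) < 2) next
    cc <- confusion(sc, lb, 0.6)
    tp <- fp <- tn <- fn <- 0L
    for (i in 1:20) {
      if (sc[i] >= 0.6 && lb[i] == 1) tp <- tp + 1L
      else if (sc[i] >= 0.6) fp <- fp + 1L
      else if (lb[i] == 1) fn <- fn + 1L
      else tn <- tn + 1L
    }
    expect_equal(unclass(cc), list(TP = tp, FP = fp, TN = tn, FN = fn))
  }
})

test_that("metrics match the standard formulas, NA on zero denominators", {
  # independent formula oracle on random count tuples
  for (s in 1:20) {
    cts <- withr::with_seed(s, as.list(rpois(4, 20) + 1L))
    names(cts) <- c("TP", "FP", "TN", "FN")
    m <- metrics_from_counts(do.call(confusion_counts, cts))
    with(cts, {
      expect_equal(m$accuracy, (TP + TN) / (TP + FP + TN + FN))
      expect_equal(m$tpr, TP / (TP + FN))
      expect_equal(m$precision, TP / (TP + FP))
      expect_equal(m$mcc, (TP * TN - FP * FN) /
                     sqrt(prod(c(TP + FP, TP + FN, TN + FP, TN + FN))))
    })
    expect_gte(m$mcc, -1); expect_lte(m$mcc, 1)
  }
  # perfect classifier
  expect_equal(metrics_from_counts(confusion_counts(10, 0, 10, 0))$mcc, 1)
  # degenerate cells -> flagged NA, never silent zero
  m0 <- metrics_from_counts(confusion_counts(0, 0, 5, 5))
  expect_true(is.na(m0$precision))
  expect_true(is.na(m0$mcc))
  expect_error(confusion_counts(-1, 0, 0, 0), "non-negative")
})

test_that("rank AUC equals the O(n^2) pairwise probability", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(c(0.5, 0.5, 0.5, 0.5), c(1, 0, 1, 0)), 0.5)
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), "both")
  for (s in 1:25) {
    n <- withr::with_seed(s, sample(10:50, 1))
    sc <- withr::with_seed(s + 100, round(runif(n), 2))  # force some ties
    lb <- withr::with_seed(s + 200, rbinom(n, 1, 0.5))
    if (length(unique(lb)) < 2) next
    expect_equal(roc_auc(sc, lb), auc_pairwise(sc, lb), tolerance = 1e-12)
  }
  # invariance under strictly monotone transforms
  sc <- withr::with_seed(9, runif(30)); lb <- rep(c(0, 1), 15)
  expect_equal(roc_auc(sc, lb), roc_auc(exp(5 * sc) + 2, lb))
  expect_equal(roc_auc(sc, lb), roc_auc(rank(sc), lb))
})

test_that("prediction-random ratios follow both equation forms", {
  # hand arithmetic: (5/10) / (100/10000) = 50
  r <- prediction_random_ratio(5, 10, 100, 10000, cutoff = 0.99)
  expect_equal(r$ratio, 50)
  expect_equal(r$p_tpr, 0.5)
  expect_equal(r$random_rate, 0.01)
  # selection rate equal to prevalence -> ratio 1
  expect_equal(prediction_random_ratio(20, 100, 200, 1000)$ratio, 1)
  # undefined and invalid inputs
  expect_error(prediction_random_ratio(0, 10, 0, 100),
               class = "undefined_metric_error")
  expect_error(prediction_random_ratio(20, 10, 50, 100), "invalid count")
  expect_error(prediction_random_ratio(5, 10, 4, 100), "invalid count")

  # Eq-1 form vs Eq-2 form on random valid tuples (algebraic identity)
  for (s in 1:200) {
    tup <- withr::with_seed(s, {
      N_all <- sample(1000:100000, 1)
      Ntot <- sample.int(min(N_all, 500), 1)
      NNs <- sample.int(N_all, 1)
      Nsel <- sample.int(min(Ntot, NNs), 1)
      c(Nsel, Ntot, NNs, N_all)
    })
    r <- prediction_random_ratio(tup[1], tup[2], tup[3], tup[4])
    eq1 <- (tup[1] / tup[2]) / (tup[3] / tup[4])
    eq2 <- (tup[1] / tup[3]) / (tup[2] / tup[4])
    expect_equal(r$ratio, eq1, tolerance = 1e-12)
    expect_equal(eq1, eq2, tolerance = 1e-12)
  }
})

test_that("case-table summaries match a streaming-mean oracle", {
  tab <- dude_best_cases()
  expect_equal(nrow(tab), 19L)
  m <- summarize_cases(tab)
  stream <- rep(0, ncol(tab) - 1L)
  for (i in seq_len(nrow(tab))) {
    stream <- stream + (as.numeric(tab[i, -1L]) - stream) / i
  }
  expect_equal(unname(m), stream, tolerance = 1e-12)
  # single row summarizes to itself
  expect_equal(unname(summarize_cases(tab[3, ])), as.numeric(tab[3, -1L]))
  # half-up rounding at the table's precision
  expect_equal(unname(summarize_cases(tab, digits = c(4, 4, 4, 4, 4, 1, 1))),
               c(0.8212, 0.8145, 0.8752, 0.8854, 0.4275, 268.5, 90.2))
})

test_that("round_half_up rounds .5 away from zero", {
  expect_equal(round_half_up(0.42745, 4), 0.4275)
  expect_equal(round_half_up(268.45, 1), 268.5)
  expect_equal(round_half_up(-1.25, 1), -1.3)
  expect_equal(round_half_up(2.5), 3)
})

test_that("count reconstruction inverts printed summary rows", {
  # degenerate exact case
  cc <- reconstruct_counts(1.0, 1.0, 40, 7)
  expect_equal(unclass(cc), list(TP = 40L, FP = 0L, TN = 7L, FN = 0L))
  expect_error(reconstruct_counts(1.0, 0.5, 10, 3), "negative")

  # round trip: counts -> metrics -> counts
  for (s in 1:20) {
    cts <- withr::with_seed(s, {
      tp <- sample(5:200, 1); fp <- sample(0:50, 1)
      fn <- sample(0:50, 1); tn <- sample(0:200, 1)
      list(tp = tp, fp = fp, tn = tn, fn = fn)
    })
    m <- metrics_from_counts(confusion_counts(cts$tp, cts$fp, cts$tn,
                                              cts$fn))
    back <- reconstruct_counts(m$tpr, m$precision, cts$tp + cts$fn,
                               cts$tn + cts$fp)
    expect_equal(unclass(back),
                 list(TP = cts$tp, FP = cts$fp, TN = cts$tn, FN = cts$fn))
  }
})

test_that("ratio at 0.99 beats ratio at 0.9 for calibrated planted screens", {
  # scores monotone in true signal: higher cutoff concentrates actives
  ratios <- vapply(1:3, function(s) {
    w <- generate_world(n_pockets = 1, n_ligands = 2000, prevalence = 0.05,
                        noise_sd = 0, seed = 300 + s)
    sig <- as.numeric(w$compat[1, ])
    # monotone calibration whose 0.9 cutoff falls below the binding
    # threshold (admits decoys) while the 0.99 cutoff stays above it
    sc <- 1 / (1 + exp(-(sig - w$threshold + 0.5) * 8))
    rows <- data.frame(compound_id = rownames(w$ligand_obs)[order(-sc)],
                       score = sort(sc, decreasing = TRUE))
    res <- structure(list(rows = rows, pocket_id = "p", model_id = "m",
                          n_failed = 0L), class = "screening_result")
    act <- colnames(w$labels)[w$labels[1, ]]
    c(screen_ratio(res, act, 0.99)$ratio, screen_ratio(res, act, 0.9)$ratio)
  }, c(0, 0))
  expect_true(all(ratios[1, ] > ratios[2, ]))
  expect_true(all(ratios >= 0))
})
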