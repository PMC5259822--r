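test_that("AUC handles separation, ties and reversal correctly", {
  expect_identical(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_identical(roc_auc(rep(0.4, 10), rep(c(1, 0), 5)), 0.5)
  expect_identical(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0)
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("trapezoidal AUC equals the brute-force pairwise statistic", {
  set.seed(17)
  for (i in 1:60) {
    n <- sample(5:150, 1)
    labels <- c(1, 0, stats::rbinom(n - 2, 1, 0.4))
    scores <- if (i %% 3 == 0) {
      sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # heavy ties
    } else {
      stats::runif(n)
    }
    expect_equal(roc_auc(scores, labels), pairwise_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  scores <- stats::runif(80)
  labels <- stats::rbinom(80, 1, 0.3)
  labels[1:2] <- c(0, 1)
  expect_equal(roc_auc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(29)
  scores <- stats::runif(60)
  labels <- c(1, 0, stats::rbinom(58, 1, 0.5))
  base <- roc_auc(scores, labels)
  expect_equal(roc_auc(stats::qlogis(scores * 0.98 + 0.01), labels), base)
  expect_equal(roc_auc(scores^3 + 2, labels), base)
})

test_that("FPR at fixed TPR uses the most conservative reaching threshold", {
  expect_identical(fpr_at_tpr(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0), 0.222), 0)
  expect_identical(fpr_at_tpr(c(0.9, 0.7, 0.6, 0.4), c(1, 0, 1, 0), 0.5), 0)
  expect_identical(fpr_at_tpr(c(0.9, 0.7, 0.6, 0.4), c(1, 0, 1, 0), 1.0), 0.5)
  # anti-separated scores must sweep through every negative first
  expect_identical(fpr_at_tpr(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0), 1.0), 1)
  # non-decreasing in the TPR level
  set.seed(31)
  scores <- stats::runif(100)
  labels <- c(1, 0, stats::rbinom(98, 1, 0.3))
  levels <- seq(0.05, 1, by = 0.05)
  fprs <- vapply(levels, function(t) fpr_at_tpr(scores, labels, t), 0)
  expect_true(all(diff(fprs) >= 0))
})

test_that("accuracy at fixed TPR matches a confusion-matrix oracle", {
  # perfect separation: the separating threshold is reached at TPR 1
  expect_identical(
    accuracy_at_tpr(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0), 1), 1)
  # at level 0.5 the conservative rule keeps one positive below threshold
  expect_identical(
    accuracy_at_tpr(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0), 0.5), 0.75)
  # 1:99 imbalance, tiny TPR level: nearly everything called negative
  scores <- c(1, stats::runif(99, 0, 0.5))
  labels <- c(1, rep(0, 99))
  expect_identical(accuracy_at_tpr(scores, labels, 0.01), 1)
  # independent confusion-matrix computation at the chosen threshold
  set.seed(37)
  scores <- stats::runif(120)
  labels <- c(1, 0, stats::rbinom(118, 1, 0.25))
  for (lvl in c(0.222, 0.389, 0.8)) {
    v <- hmmorf:::.vertex_at_tpr(scores, as.integer(labels), lvl)
    pred <- as.integer(scores >= v$threshold)
    expect_equal(accuracy_at_tpr(scores, labels, lvl),
                 mean(pred == labels))
    expect_equal(fpr_at_tpr(scores, labels, lvl),
                 sum(pred == 1 & labels == 0) / sum(labels == 0))
  }
})

test_that("success rate compares per-sequence means with a strict tie rule", {
  sep <- list(list(scores = c(0.9, 0.8, 0.1), labels = c(1, 1, 0)),
              list(scores = c(0.7, 0.2), labels = c(1, 0)))
  expect_identical(success_rate(sep), 1)
  ties <- list(list(scores = c(0.5, 0.5), labels = c(1, 0)))
  expect_identical(success_rate(ties), 0)
  mixed <- c(sep, list(list(scores = c(0.1, 0.9), labels = c(1, 0))))
  expect_equal(success_rate(mixed), 2 / 3)
  one_class <- c(sep, list(list(scores = c(0.4, 0.6), labels = c(0, 0))))
  expect_message(sr <- success_rate(one_class), "excluded")
  expect_identical(sr, 1)
  expect_error(success_rate(list()), "no sequences")
})

test_that("the report pools residues and evaluates both operating points", {
  per_seq <- list(
    list(scores = c(0.9, 0.85, 0.1, 0.2, 0.3), labels = c(1, 1, 0, 0, 0)),
    list(scores = c(0.8, 0.7, 0.4, 0.1), labels = c(1, 0, 0, 0))
  )
  rep <- evaluation_report(per_seq)
  expect_named(rep$fpr_at_tpr, c("0.222", "0.389"))
  expect_identical(rep$n_pos + rep$n_neg, 9L)
  expect_identical(rep$n_sequences, 2L)
  all_scores <- unlist(lapply(per_seq, `[[`, "scores"))
  all_labels <- unlist(lapply(per_seq, `[[`, "labels"))
  expect_equal(rep$auc, roc_auc(all_scores, all_labels))
})
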