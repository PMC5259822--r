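test_that("the default ensemble is the published nine-model configuration", {
  specs <- default_ensemble_spec()
  expect_length(specs, 9L)
  tab <- data.frame(
    index = vapply(specs, `[[`, 0L, "index"),
    window = vapply(specs, `[[`, 0L, "window"),
    kernel = vapply(specs, `[[`, "", "kernel"),
    gamma = vapply(specs, `[[`, 0, "gamma"),
    cost = vapply(specs, `[[`, 0, "cost"),
    ratio = vapply(specs, `[[`, 0L, "ratio")
  )
  expect_identical(tab$index, 1:9)
  expect_identical(tab$window, c(11L, 7L, 3L, 13L, 9L, 5L, 7L, 13L, 7L))
  expect_identical(tab$kernel,
                   c("radial", "radial", "sigmoid", "radial", "radial",
                     "sigmoid", "radial", "radial", "sigmoid"))
  expect_identical(tab$gamma, c(0.0038, 5, 5, 0.0038, 5, 5, 0.0038, 5, 5))
  expect_identical(sum(tab$kernel == "radial"), 6L)
  expect_identical(sum(tab$kernel == "sigmoid"), 3L)
  expect_identical(sort(unique(tab$window)), c(3L, 5L, 7L, 9L, 11L, 13L))
  expect_true(all(tab$cost == 1000))
  expect_identical(tab$ratio, c(2L, 2L, 2L, 2L, 1L, 2L, 2L, 2L, 1L))
  # window = 2*flank + 1 throughout
  expect_identical(tab$window,
                   2L * vapply(specs, `[[`, 0L, "flank") + 1L)
})

test_that("common averaging fuses tracks elementwise", {
  expect_equal(fuse_scores(list(0.2, 0.4, 0.6)), 0.4)
  x <- c(0.1, 0.9, 0.5)
  expect_identical(fuse_scores(list(x)), x)
  tracks <- list(a = c(0.2, 0.8), b = c(0.4, 0.6), c = c(0.9, 0.1))
  expect_equal(fuse_scores(tracks), fuse_scores(rev(tracks)))
  expect_error(fuse_scores(list(1:3 / 10, 1:4 / 10)), "unequal")
})

test_that("a model separates linearly separable training blobs", {
  set.seed(21)
  pos <- matrix(stats::runif(400, 0.6, 1), 20, 20)
  neg <- matrix(stats::runif(400, 0, 0.4), 20, 20)
  spec <- model_spec(1, "radial", gamma = 0.0038, flank = 0, seed = 1)
  m <- train_model(pos, neg, spec)
  scores <- hmmorf:::.predict_model(m, rbind(pos, neg))
  expect_true(all(scores[1:20] > 0.5))
  expect_true(all(scores[21:40] < 0.5))
})

test_that("identical positive and negative vectors give uninformative scores", {
  x <- matrix(rep(seq(0, 1, length.out = 20), each = 12), 12, 20,
              byrow = TRUE)
  m <- train_model(x, x, model_spec(1, "radial", gamma = 1, flank = 0,
                                    seed = 2))
  scores <- hmmorf:::.predict_model(m, x)
  expect_true(all(abs(scores - 0.5) < 0.2))
})

test_that("training validates dimensions and class presence", {
  spec <- model_spec(1, "radial", gamma = 1, flank = 1)
  x <- matrix(stats::runif(200), 10, 20)
  expect_error(train_model(x, x, spec), "dimension")
  expect_error(train_model(x[0, , drop = FALSE], x,
                           model_spec(1, "radial", gamma = 1, flank = 0)),
               "non-empty")
})

test_that("the ensemble is deterministic under a fixed master seed", {
  sim <- generate_dataset(sim_config(n_sequences = 8, signal = 0.9,
                                     length_range = c(110L, 150L), seed = 4))
  recs <- assemble_records(sim$profiles, sim$annotations)
  held <- sim$profiles[[8]]
  e1 <- train_ensemble(recs[1:7], master_seed = 13)
  e2 <- train_ensemble(recs[1:7], master_seed = 13)
  t1 <- predict_sequence(e1, held)
  t2 <- predict_sequence(e2, held)
  expect_identical(t1$scores, t2$scores)
  expect_identical(t1$per_model, t2$per_model)
  # per-model seeds differ, so the models saw different negative draws
  fps <- vapply(e1$models, `[[`, "", "fingerprint")
  expect_gt(length(unique(fps)), 1L)
})

test_that("fused scores stay within the per-model extremes and [0,1]", {
  sim <- generate_dataset(sim_config(n_sequences = 6, signal = 0.8,
                                     length_range = c(110L, 150L), seed = 6))
  recs <- assemble_records(sim$profiles, sim$annotations)
  ens <- train_ensemble(recs[1:5], master_seed = 2)
  tr <- predict_sequence(ens, sim$profiles[[6]])
  expect_true(all(tr$scores >= 0 & tr$scores <= 1))
  expect_true(all(tr$scores >= apply(tr$per_model, 1, min) - 1e-12))
  expect_true(all(tr$scores <= apply(tr$per_model, 1, max) + 1e-12))
  expect_equal(unname(tr$scores), unname(rowMeans(tr$per_model)))
})

test_that("an ensemble survives a save/load round trip", {
  sim <- generate_dataset(sim_config(n_sequences = 6, signal = 0.9,
                                     length_range = c(110L, 150L), seed = 8))
  recs <- assemble_records(sim$profiles, sim$annotations)
  ens <- train_ensemble(recs[1:5], master_seed = 5)
  dir <- withr::local_tempdir()
  save_ensemble(ens, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- load_ensemble(dir)
  held <- sim$profiles[[6]]
  expect_identical(predict_sequence(back, held)$scores,
                   predict_sequence(ens, held)$scores)
  expect_error(load_ensemble(withr::local_tempdir()), "manifest")
})
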