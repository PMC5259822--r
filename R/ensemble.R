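# The nine-SVM ensemble: model specs, training, prediction, score fusion.

#' Specification of one SVM model of the ensemble
#'
#' @param index Model number (1-9 in the default ensemble).
#' @param kernel `"radial"` (RBF) or `"sigmoid"`.
#' @param gamma Kernel width.
#' @param cost Soft-margin penalty C (1000 for every default model).
#' @param flank Window flank in residues; the window size is
#'   `2 * flank + 1`.
#' @param ratio Negative:positive sampling ratio for this model's
#'   training set.
#' @param seed Seed for this model's negative draw and probability
#'   calibration; filled in by [train_ensemble()] from the master seed.
#' @return A `model_spec` list.
#' @export
model_spec <- function(index, kernel = c("radial", "sigmoid"), gamma,
                       cost = 1000, flank, ratio = 2L, seed = NA_integer_) {
  kernel <- match.arg(kernel)
  stopifnot(gamma > 0, cost > 0, flank >= 0L, ratio >= 1L)
  structure(list(index = as.integer(index), kernel = kernel,
                 gamma = gamma, cost = cost, flank = as.integer(flank),
                 window = 2L * as.integer(flank) + 1L,
                 ratio = as.integer(ratio), seed = as.integer(seed)),
            class = "model_spec")
}

#' The default nine-model ensemble specification
#'
#' Six RBF and three sigmoid SVMs spanning window sizes 3-13, all with
#' C = 1000. RBF models use gamma 0.0038 or 5, sigmoid models gamma 5.
#' Models 5 and 9 train at a 1:1 negative:positive ratio, the others
#' at 1:2.
#'
#' @return List of nine [model_spec()] objects.
#' @export
default_ensemble_spec <- function() {
  tab <- list(
    list(1L, 11L, "radial",  0.0038, 2L),
    list(2L,  7L, "radial",  5,      2L),
    list(3L,  3L, "sigmoid", 5,      2L),
    list(4L, 13L, "radial",  0.0038, 2L),
    list(5L,  9L, "radial",  5,      1L),
    list(6L,  5L, "sigmoid", 5,      2L),
    list(7L,  7L, "radial",  0.0038, 2L),
    list(8L, 13L, "radial",  5,      2L),
    list(9L,  7L, "sigmoid", 5,      1L)
  )
  lapply(tab, function(r) {
    model_spec(index = r[[1]], kernel = r[[3]], gamma = r[[4]],
               cost = 1000, flank = (r[[2]] - 1L) %/% 2L, ratio = r[[5]])
  })
}

#' Train one SVM model on labelled window features
#'
#' Fits a support vector classifier (via libsvm) with the spec's kernel,
#' gamma and C on the positive and negative windows, with Platt-scaled
#' probability estimates so that every model emits a class-membership
#' score in `[0, 1]` comparable across kernels. Features are used on
#' their natural probability scale (no rescaling).
#'
#' @param positives,negatives Feature matrices, one window per row; both
#'   must have `(2*flank + 1) * 20` columns matching `spec`.
#' @param spec A [model_spec()].
#' @return List with the fitted `svm` object, the spec, and the training
#'   set fingerprint.
#' @export
train_model <- function(positives, negatives, spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (nrow(positives) == 0L || nrow(negatives) == 0L) {
    stop("both classes must be non-empty")
  }
  d <- (2L * spec$flank + 1L) * 20L
  if (ncol(positives) != d || ncol(negatives) != d) {
    stop("feature dimension ", ncol(positives), "/", ncol(negatives),
         " does not match the spec's window (expected ", d, ")")
  }
  x <- rbind(positives, negatives)
  y <- factor(rep(c("morf", "other"), c(nrow(positives), nrow(negatives))),
              levels = c("morf", "other"))
  if (!is.na(spec$seed)) set.seed(spec$seed)
  fit <- e1071::svm(x, y, kernel = spec$kernel, gamma = spec$gamma,
                    cost = spec$cost, probability = TRUE, scale = FALSE)
  list(fit = fit, spec = spec,
       fingerprint = .training_fingerprint(x, y))
}

.training_fingerprint <- function(x, y) {
  # cheap content hash: dimensions plus moment summaries, enough to detect
  # a changed training set in a persisted manifest
  sprintf("n=%d;d=%d;npos=%d;sum=%.10g;ss=%.10g",
          nrow(x), ncol(x), sum(y == "morf"), sum(x), sum(x^2))
}

.predict_model <- function(model, features) {
  pr <- stats::predict(model$fit, features, probability = TRUE)
  attr(pr, "probabilities")[, "morf"]
}

#' Train the full SVM ensemble
#'
#' Each model draws its own negative sample (seeded as
#' `master_seed + index` so the nine models see different negative sets)
#' at its own window size and ratio, then trains per [train_model()].
#'
#' @param data List of records with fields `profile` and `labels`, as for
#'   [sample_training_set()].
#' @param specs List of [model_spec()]s; default [default_ensemble_spec()].
#' @param master_seed Integer seed from which all per-model seeds derive.
#' @param verbose Print one line per model while training.
#' @return An object of class `morf_ensemble`.
#' @export
train_ensemble <- function(data, specs = default_ensemble_spec(),
                           master_seed = 1L, verbose = FALSE) {
  stopifnot(length(specs) >= 1L)
  models <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    spec$seed <- as.integer(master_seed) + spec$index
    cfg <- sampling_config(neg_pos_ratio = spec$ratio, seed = spec$seed,
                           flank = spec$flank)
    ts <- sample_training_set(data, cfg)
    if (verbose) {
      message(sprintf(
        "model %d: w=%d %s gamma=%g ratio=1:%d  (%d pos / %d neg)",
        spec$index, spec$window, spec$kernel, spec$gamma, spec$ratio,
        nrow(ts$positives), nrow(ts$negatives)))
    }
    models[[i]] <- train_model(ts$positives, ts$negatives, spec)
  }
  structure(list(models = models, master_seed = as.integer(master_seed),
                 package_version = as.character(utils::packageVersion("hmmorf"))),
            class = "morf_ensemble")
}

#' @export
print.morf_ensemble <- function(x, ...) {
  cat("<morf_ensemble> ", length(x$models), " SVM models, master seed ",
      x$master_seed, "\n", sep = "")
  for (m in x$models) {
    cat(sprintf("  %d: window %2d  %-7s gamma %-6g C %g  ratio 1:%d\n",
                m$spec$index, m$spec$window, m$spec$kernel, m$spec$gamma,
                m$spec$cost, m$spec$ratio))
  }
  invisible(x)
}

#' Fuse per-model score tracks by common averaging
#'
#' @param tracks List of equal-length numeric score vectors, one per
#'   model.
#' @return Elementwise arithmetic mean.
#' @export
fuse_scores <- function(tracks) {
  stopifnot(length(tracks) >= 1L)
  n <- lengths(tracks)
  if (length(unique(n)) != 1L) {
    stop("score tracks have unequal lengths: ",
         paste(unique(n), collapse = ", "))
  }
  rowMeans(do.call(cbind, tracks))
}

#' Score every residue of a sequence with the ensemble
#'
#' Each model scores the window centred on each residue at its own window
#' size; the fused propensity is the common average of the per-model
#' scores.
#'
#' @param ensemble A trained [train_ensemble()] object.
#' @param profile An [hmm_profile()].
#' @return An object of class `prediction_track` with fields `seq_id`,
#'   `scores` (fused, length `L`) and `per_model` (`L x n_models`
#'   matrix).
#' @export
predict_sequence <- function(ensemble, profile) {
  stopifnot(inherits(ensemble, "morf_ensemble"),
            inherits(profile, "hmm_profile"))
  per_model <- vapply(ensemble$models, function(m) {
    .predict_model(m, extract_all(profile, m$spec$flank))
  }, numeric(nrow(profile$probs)))
  per_model <- matrix(per_model, nrow = nrow(profile$probs),
                      dimnames = list(NULL, paste0("model_",
                        vapply(ensemble$models, function(m) m$spec$index, 0L))))
  structure(list(seq_id = profile$seq_id, residues = profile$residues,
                 scores = fuse_scores(asplit(per_model, 2L)),
                 per_model = per_model),
            class = "prediction_track")
}

#' @export
print.prediction_track <- function(x, ...) {
  cat("<prediction_track> ", x$seq_id, ": ", length(x$scores),
      " residues, fused score range [",
      sprintf("%.3f", min(x$scores)), ", ",
      sprintf("%.3f", max(x$scores)), "]\n", sep = "")
  invisible(x)
}

#' Persist a trained ensemble to a directory
#'
#' Writes one serialised model file per ensemble member plus a JSON
#' manifest recording each spec, its seed, the training-set fingerprint
#' and the package version.
#'
#' @param ensemble A [train_ensemble()] object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_ensemble <- function(ensemble, dir) {
  stopifnot(inherits(ensemble, "morf_ensemble"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package_version = ensemble$package_version,
    master_seed = ensemble$master_seed,
    models = lapply(ensemble$models, function(m) {
      c(unclass(m$spec), list(fingerprint = m$fingerprint,
                              file = sprintf("model_%d.rds", m$spec$index)))
    })
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  for (m in ensemble$models) {
    saveRDS(m, file.path(dir, sprintf("model_%d.rds", m$spec$index)))
  }
  invisible(dir)
}

#' Load a persisted ensemble
#'
#' @param dir Directory written by [save_ensemble()].
#' @return A `morf_ensemble` object.
#' @export
load_ensemble <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) {
    stop("'", dir, "' is not a model directory (no manifest.json)")
  }
  manifest <- jsonlite::read_json(mf_path)
  models <- lapply(manifest$models, function(spec) {
    readRDS(file.path(dir, spec$file))
  })
  structure(list(models = models,
                 master_seed = as.integer(manifest$master_seed),
                 package_version = manifest$package_version),
            class = "morf_ensemble")
}
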