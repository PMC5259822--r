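# Ratio-controlled sampling of training windows.

#' Sampling configuration for one training set
#'
#' @param neg_pos_ratio Negatives drawn per positive; the ratios evaluated
#'   for this predictor are 1, 2 and 3 (other positive integers are
#'   accepted with a warning).
#' @param seed RNG seed used for the negative draw; recorded so a model's
#'   training set can be rebuilt exactly.
#' @param flank Window flank (in residues) of the model this set feeds.
#' @return A `sampling_config` list.
#' @export
sampling_config <- function(neg_pos_ratio = 2L, seed = 1L, flank = 3L) {
  neg_pos_ratio <- as.integer(neg_pos_ratio)
  stopifnot(neg_pos_ratio >= 1L, flank >= 0L)
  if (!neg_pos_ratio %in% 1:3) {
    warning("neg_pos_ratio ", neg_pos_ratio,
            " is outside the evaluated set {1, 2, 3}")
  }
  structure(list(neg_pos_ratio = neg_pos_ratio, seed = as.integer(seed),
                 flank = as.integer(flank)),
            class = "sampling_config")
}

#' Build a ratio-controlled training set of window features
#'
#' Positives are the feature windows centred on every MoRF residue
#' (segment A) of every sequence. Negatives are windows centred on
#' `neg_pos_ratio` times as many residues, drawn uniformly without
#' replacement from the pooled Other residues (segment B) of all
#' sequences; Flank residues are never used as negative centres. The draw
#' is seeded so each model of the ensemble can see its own reproducible
#' negative set.
#'
#' @param data List of records, each with fields `profile`
#'   (an [hmm_profile()]) and `labels` (factor from [annotate_regions()]).
#' @param cfg A [sampling_config()].
#' @return List with matrices `positives` and `negatives` (one window per
#'   row) and data.frames `pos_index` / `neg_index` giving the `seq_id`
#'   and `position` of each window centre.
#' @export
sample_training_set <- function(data, cfg) {
  stopifnot(inherits(cfg, "sampling_config"))
  pos_centers <- list()
  pool <- list()
  for (i in seq_along(data)) {
    rec <- data[[i]]
    if (nrow(rec$profile$probs) != length(rec$labels)) {
      stop("sequence '", rec$profile$seq_id,
           "': profile length and label length differ")
    }
    seg <- build_segments(rec$labels)
    if (length(seg$segment_a) > 0L) {
      pos_centers[[length(pos_centers) + 1L]] <-
        data.frame(rec = i, position = seg$segment_a)
    }
    if (length(seg$segment_b) > 0L) {
      pool[[length(pool) + 1L]] <-
        data.frame(rec = i, position = seg$segment_b)
    }
  }
  pos_centers <- do.call(rbind, pos_centers)
  pool <- do.call(rbind, pool)
  if (is.null(pos_centers) || nrow(pos_centers) == 0L) {
    stop("no MoRF residues in the training data")
  }
  n_neg <- cfg$neg_pos_ratio * nrow(pos_centers)
  if (is.null(pool) || nrow(pool) < n_neg) {
    stop("segment B holds ", if (is.null(pool)) 0L else nrow(pool),
         " residues but ", n_neg, " negatives were requested; ",
         "use a lower neg_pos_ratio or more training sequences")
  }
  set.seed(cfg$seed)
  neg_centers <- pool[sample.int(nrow(pool), n_neg), , drop = FALSE]

  feats <- lapply(data, function(r) extract_all(r$profile, cfg$flank))
  grab <- function(centers) {
    out <- matrix(0, nrow(centers), (2L * cfg$flank + 1L) * 20L)
    for (k in seq_len(nrow(centers))) {
      out[k, ] <- feats[[centers$rec[k]]][centers$position[k], ]
    }
    out
  }
  seq_ids <- vapply(data, function(r) r$profile$seq_id, "")
  list(
    positives = grab(pos_centers),
    negatives = grab(neg_centers),
    pos_index = data.frame(seq_id = seq_ids[pos_centers$rec],
                           position = pos_centers$position),
    neg_index = data.frame(seq_id = seq_ids[neg_centers$rec],
                           position = neg_centers$position)
  )
}
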