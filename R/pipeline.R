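# High-level plumbing: matching profiles to annotations, score tracks on
# disk, and end-to-end train/predict helpers.

#' Match profiles with annotations into training records
#'
#' Builds the per-sequence records consumed by [sample_training_set()] and
#' [train_ensemble()]: each profile paired with its region labels derived
#' from the MoRF annotations. Sequences listed in `sequences` (e.g. a
#' FASTA file) that have no profile are skipped with a warning rather
#' than aborting the run.
#'
#' @param profiles Named list of [hmm_profile()] objects.
#' @param annotations Data.frame from [read_annotations()]; sequences
#'   absent from it are treated as MoRF-free.
#' @param sequences Optional named character vector of sequences used to
#'   cross-check identifiers and lengths.
#' @param flank_len Flank width for region labelling.
#' @return List of records with fields `profile` and `labels`.
#' @export
assemble_records <- function(profiles, annotations, sequences = NULL,
                             flank_len = 12L) {
  if (!is.null(sequences)) {
    missing_prof <- setdiff(names(sequences), names(profiles))
    if (length(missing_prof) > 0L) {
      warning("skipping ", length(missing_prof),
              " sequence(s) without a profile: ",
              paste(utils::head(missing_prof, 5L), collapse = ", "),
              if (length(missing_prof) > 5L) ", ..." else "")
    }
    for (id in intersect(names(sequences), names(profiles))) {
      if (nchar(sequences[[id]]) != nchar(profiles[[id]]$residues)) {
        stop("sequence '", id, "': FASTA length ",
             nchar(sequences[[id]]), " != profile length ",
             nchar(profiles[[id]]$residues))
      }
    }
    profiles <- profiles[intersect(names(sequences), names(profiles))]
  }
  unknown <- setdiff(unique(annotations$seq_id), names(profiles))
  if (length(unknown) > 0L) {
    warning("annotations for ", length(unknown),
            " sequence(s) without a profile ignored: ",
            paste(utils::head(unknown, 5L), collapse = ", "))
  }
  lapply(profiles, function(prof) {
    iv <- annotations[annotations$seq_id == prof$seq_id,
                      c("start", "end"), drop = FALSE]
    ann <- annotated_sequence(prof$seq_id, prof$residues, iv)
    list(profile = prof,
         labels = annotate_regions(ann, flank_len = flank_len))
  })
}

#' Predict propensity tracks for a set of profiles
#'
#' @param ensemble A trained [train_ensemble()] object.
#' @param profiles Named list of [hmm_profile()]s.
#' @return Named list of `prediction_track`s.
#' @export
predict_profiles <- function(ensemble, profiles) {
  lapply(profiles, function(p) predict_sequence(ensemble, p))
}

#' Write per-residue score tracks as TSV
#'
#' Columns: `seq_id`, 1-based `position`, `residue`, fused `score`, and
#' optionally one column per ensemble member.
#'
#' @param tracks List of `prediction_track`s from [predict_sequence()].
#' @param path Output path.
#' @param per_model Also write the per-model score columns.
#' @return `path`, invisibly.
#' @export
write_scores <- function(tracks, path, per_model = FALSE) {
  rows <- lapply(tracks, function(tr) {
    df <- data.frame(seq_id = tr$seq_id,
                     position = seq_along(tr$scores),
                     residue = strsplit(tr$residues %||%
                                          strrep("X", length(tr$scores)),
                                        "")[[1]],
                     score = sprintf("%.6f", tr$scores))
    if (per_model && !is.null(tr$per_model)) {
      pm <- apply(tr$per_model, 2L, function(v) sprintf("%.6f", v))
      df <- cbind(df, as.data.frame(matrix(pm, nrow = nrow(df),
                                           dimnames = list(NULL,
                                             colnames(tr$per_model)))))
    }
    df
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a score TSV written by [write_scores()]
#'
#' @param path Path to the TSV.
#' @return Data.frame with at least `seq_id`, `position`, `residue`,
#'   `score`.
#' @export
read_scores <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Evaluate score tracks against MoRF annotations
#'
#' Joins a score table with annotations, labels every annotated-MoRF
#' residue positive and every other residue negative, and produces the
#' standard report.
#'
#' @param scores Data.frame from [read_scores()] (or a list of
#'   `prediction_track`s).
#' @param annotations Data.frame from [read_annotations()].
#' @param tpr_levels TPR operating points.
#' @return See [evaluation_report()].
#' @export
evaluate_scores <- function(scores, annotations,
                            tpr_levels = c(0.222, 0.389)) {
  if (!is.data.frame(scores)) {
    scores <- do.call(rbind, lapply(scores, function(tr) {
      data.frame(seq_id = tr$seq_id, position = seq_along(tr$scores),
                 score = tr$scores)
    }))
  }
  per_sequence <- lapply(split(scores, scores$seq_id), function(df) {
    df <- df[order(df$position), , drop = FALSE]
    lab <- rep(0L, nrow(df))
    iv <- annotations[annotations$seq_id == df$seq_id[1L], , drop = FALSE]
    for (k in seq_len(nrow(iv))) {
      lab[df$position >= iv$start[k] & df$position <= iv$end[k]] <- 1L
    }
    list(scores = df$score, labels = lab)
  })
  evaluation_report(per_sequence, tpr_levels = tpr_levels)
}
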