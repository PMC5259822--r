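# MoRF / Flank / Other region labelling and training segments.

#' Label each residue as MORF, FLANK or OTHER
#'
#' MoRF residues are those inside an annotated interval. Flanks are the
#' `flank_len` residues immediately left and right of each MoRF (truncated
#' at the sequence termini); when the flanks of two nearby MoRFs overlap,
#' the shared residues stay FLANK. Everything else is OTHER.
#'
#' @param x An [annotated_sequence()], or an integer sequence length when
#'   `intervals` is supplied directly.
#' @param flank_len Flank width in residues on each side of a MoRF
#'   (default 12).
#' @param intervals Optional two-column `(start, end)` matrix, used when
#'   `x` is a plain length.
#' @return Factor vector of length `L` with levels `MORF`, `FLANK`,
#'   `OTHER`.
#' @examples
#' ann <- annotated_sequence("s1", strrep("A", 50), cbind(20, 26))
#' table(annotate_regions(ann))
#' @export
annotate_regions <- function(x, flank_len = 12L, intervals = NULL) {
  if (inherits(x, "annotated_sequence")) {
    L <- nchar(x$sequence)
    iv <- x$morf_intervals
  } else {
    L <- as.integer(x)
    iv <- if (is.null(intervals)) {
      matrix(integer(), ncol = 2L)
    } else {
      matrix(as.integer(as.matrix(intervals)), ncol = 2L)
    }
  }
  stopifnot(flank_len >= 0L)
  labels <- rep("OTHER", L)
  for (k in seq_len(nrow(iv))) {
    lo <- max(1L, iv[k, 1L] - flank_len)
    hi <- min(L, iv[k, 2L] + flank_len)
    labels[lo:hi] <- ifelse(labels[lo:hi] == "MORF", "MORF", "FLANK")
  }
  for (k in seq_len(nrow(iv))) {
    labels[iv[k, 1L]:iv[k, 2L]] <- "MORF"
  }
  factor(labels, levels = c("MORF", "FLANK", "OTHER"))
}

#' Split a labelled sequence into training segments
#'
#' Segment A holds the positive-sample centres: all MoRF residues (their
#' feature windows will reach into the flanks). Segment B holds the
#' negative-sample pool: residues that are neither MoRF nor Flank, so that
#' negatives never border an annotated MoRF.
#'
#' @param labels Factor from [annotate_regions()].
#' @return List with integer position vectors `segment_a` (MORF) and
#'   `segment_b` (OTHER).
#' @export
build_segments <- function(labels) {
  list(segment_a = which(labels == "MORF"),
       segment_b = which(labels == "OTHER"))
}
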