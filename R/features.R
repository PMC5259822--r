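# Sliding-window feature extraction from HMM profiles.

#' Extract the window feature vector for one residue
#'
#' Takes the profile rows `center - flank ... center + flank` and flattens
#' them row-major (N-terminal first) into a vector of length
#' `(2 * flank + 1) * 20`. Positions outside the sequence contribute
#' all-zero rows, so windows at the termini keep the fixed dimension the
#' SVMs require.
#'
#' @param profile An [hmm_profile()].
#' @param center 1-based residue position the window is centred on.
#' @param flank Residues taken on each side; window size `w = 2*flank + 1`.
#' @return Numeric vector of length `(2*flank + 1) * 20`.
#' @export
extract_window <- function(profile, center, flank) {
  L <- nrow(profile$probs)
  if (center < 1L || center > L) {
    stop("center ", center, " outside sequence of length ", L)
  }
  stopifnot(flank >= 0L)
  idx <- (center - flank):(center + flank)
  w <- length(idx)
  mat <- matrix(0, w, 20L)
  ok <- idx >= 1L & idx <= L
  mat[ok, ] <- profile$probs[idx[ok], , drop = FALSE]
  as.vector(t(mat))
}

#' Extract window features for every residue of a sequence
#'
#' Slides the window of [extract_window()] over all positions `1..L`.
#'
#' @inheritParams extract_window
#' @return Numeric matrix with `L` rows and `(2*flank + 1) * 20` columns;
#'   row `i` is the feature vector centred on residue `i`.
#' @export
extract_all <- function(profile, flank) {
  stopifnot(flank >= 0L)
  L <- nrow(profile$probs)
  w <- 2L * flank + 1L
  # pad the profile with `flank` zero rows on each side, then gather each
  # window as a block of the padded matrix
  padded <- rbind(matrix(0, flank, 20L), profile$probs,
                  matrix(0, flank, 20L))
  out <- matrix(0, L, w * 20L)
  for (j in seq_len(w)) {
    out[, ((j - 1L) * 20L + 1L):(j * 20L)] <-
      padded[j:(j + L - 1L), , drop = FALSE]
  }
  out
}
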