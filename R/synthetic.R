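# Synthetic benchmark generator: annotated sequences plus .hhm profiles
# with a planted, tunable MoRF composition signal.

#' Configuration for the synthetic benchmark generator
#'
#' The generator plants MoRF regions whose amino-acid emission
#' composition differs from the sequence background by a tunable amount.
#' At `signal = 0` MoRF and background rows are drawn from exactly the
#' same distribution; at `signal = 1` MoRF rows follow a fixed,
#' maximally contrasting composition (enriched in the hydrophobic and
#' aromatic residues that real MoRFs bury in their binding partner).
#' Flank rows blend linearly from MoRF to background composition over
#' `flank_len` residues, mimicking the gradual conservation decay around
#' real binding elements.
#'
#' @param n_sequences Number of sequences to generate.
#' @param length_range Min/max sequence length in residues.
#' @param morfs_per_sequence MoRF regions planted per sequence.
#' @param morf_length_range Min/max MoRF length; default the canonical
#'   5-25 residue range.
#' @param signal Signal strength `s` in `[0, 1]`.
#' @param concentration Gamma shape of the symmetric background
#'   composition prior; larger values pull backgrounds toward the
#'   uniform composition.
#' @param noise_sd Log-normal sd of per-residue emission noise around the
#'   regional composition.
#' @param flank_len Width of the composition ramp flanking each MoRF.
#' @param seed RNG seed; the same seed reproduces the dataset byte for
#'   byte.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_sequences = 10L, length_range = c(60L, 120L),
                       morfs_per_sequence = 1L,
                       morf_length_range = c(5L, 25L), signal = 0.8,
                       concentration = 5, noise_sd = 0.25,
                       flank_len = 12L, seed = 1L) {
  stopifnot(n_sequences >= 1L, length(length_range) == 2L,
            length_range[1L] <= length_range[2L],
            morfs_per_sequence >= 0L,
            morf_length_range[1L] >= 1L,
            morf_length_range[1L] <= morf_length_range[2L],
            signal >= 0, signal <= 1, concentration > 0, noise_sd >= 0,
            flank_len >= 0L)
  structure(list(n_sequences = as.integer(n_sequences),
                 length_range = as.integer(length_range),
                 morfs_per_sequence = as.integer(morfs_per_sequence),
                 morf_length_range = as.integer(morf_length_range),
                 signal = signal, concentration = concentration,
                 noise_sd = noise_sd, flank_len = as.integer(flank_len),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Fixed contrasting MoRF composition: hydrophobic/aromatic-enriched.
.morf_target_composition <- function() {
  q <- rep(0.16 / 13, 20)
  names(q) <- AA_ORDER
  q[c("I", "L", "V", "F", "W", "Y", "M")] <- 0.84 / 7
  q
}

# Place `k` non-overlapping intervals of the given lengths uniformly at
# random in 1..L, or fail if they cannot be packed.
.place_intervals <- function(L, lens) {
  k <- length(lens)
  if (k == 0L) return(matrix(integer(), ncol = 2L))
  if (sum(lens) > L) {
    stop("cannot pack ", k, " MoRF(s) of total length ", sum(lens),
         " into a sequence of length ", L)
  }
  # distribute the spare residues among the k+1 gaps
  spare <- L - sum(lens)
  cuts <- sort(sample.int(spare + k, k))  # stars-and-bars
  gaps <- diff(c(0L, cuts)) - 1L
  starts <- cumsum(gaps) + c(0L, cumsum(lens[-k])) + 1L
  cbind(start = starts, end = starts + lens - 1L)
}

#' Generate a synthetic annotated benchmark
#'
#' For each sequence a background composition is drawn from a symmetric
#' prior; each planted MoRF gets a composition interpolated toward a
#' fixed contrasting profile with weight `signal`. Per-residue emission
#' rows are the regional composition perturbed by log-normal noise and
#' renormalised; flank rows ramp linearly between the two compositions.
#' Rows are quantised to the integer `.hhm` score grid (probabilities
#' below the grid's floor written as `*`), and residue letters are drawn
#' from each row's composition.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Optional directory; when given, writes
#'   `profiles/<id>.hhm`, `sequences.fasta` and `annotations.tsv` there.
#' @return Invisibly (visibly when `out_dir` is `NULL`), a list with
#'   `profiles` (named list of [hmm_profile()]), `sequences` (named
#'   character), `annotations` (data.frame `seq_id`/`start`/`end`) and
#'   `labels` (named list of region-label factors).
#' @export
generate_dataset <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  q <- .morf_target_composition()

  profiles <- list()
  labels <- list()
  sequences <- character()
  ann <- list()
  width <- max(2L, nchar(as.character(cfg$n_sequences)))
  for (i in seq_len(cfg$n_sequences)) {
    id <- sprintf("synth%0*d", width, i)
    L <- sample(cfg$length_range[1L]:cfg$length_range[2L], 1L)
    lens <- if (cfg$morfs_per_sequence > 0L) {
      sample(cfg$morf_length_range[1L]:cfg$morf_length_range[2L],
             cfg$morfs_per_sequence, replace = TRUE)
    } else {
      integer()
    }
    iv <- .place_intervals(L, lens)

    bg <- stats::rgamma(20L, shape = cfg$concentration)
    bg <- bg / sum(bg)
    morf_comp <- (1 - cfg$signal) * bg + cfg$signal * q

    # per-position MoRF mixing weight: 1 inside a MoRF, linear ramp over
    # the flank, 0 in the background
    m <- rep(0, L)
    for (k in seq_len(nrow(iv))) {
      m[iv[k, 1L]:iv[k, 2L]] <- 1
      for (d in seq_len(cfg$flank_len)) {
        ramp <- 1 - d / (cfg$flank_len + 1)
        for (p in c(iv[k, 1L] - d, iv[k, 2L] + d)) {
          if (p >= 1L && p <= L) m[p] <- max(m[p], ramp)
        }
      }
    }

    probs <- matrix(0, L, 20L)
    for (p in seq_len(L)) {
      comp <- (1 - m[p]) * bg + m[p] * morf_comp
      row <- comp * exp(stats::rnorm(20L, 0, cfg$noise_sd))
      probs[p, ] <- row / sum(row)
    }
    res <- vapply(seq_len(L), function(p) {
      sample(AA_ORDER, 1L, prob = probs[p, ])
    }, "")

    # round-trip through the integer score grid so in-memory probabilities
    # equal what a reader of the written .hhm will see
    quant <- matrix(score_to_probability(.prob_to_score(as.vector(probs))),
                    L, 20L)
    prof <- hmm_profile(id, res, quant)
    profiles[[id]] <- prof
    sequences[[id]] <- prof$residues
    labels[[id]] <- annotate_regions(L, flank_len = cfg$flank_len,
                                     intervals = iv)
    if (nrow(iv) > 0L) {
      ann[[id]] <- data.frame(seq_id = id, start = iv[, 1L], end = iv[, 2L])
    }
  }
  ann <- if (length(ann) > 0L) {
    do.call(rbind, c(ann, list(make.row.names = FALSE)))
  } else {
    data.frame(seq_id = character(), start = integer(), end = integer())
  }

  out <- list(profiles = profiles, sequences = sequences,
              annotations = ann, labels = labels)
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "profiles"), recursive = TRUE,
               showWarnings = FALSE)
    for (id in names(profiles)) {
      write_hhm(profiles[[id]],
                file.path(out_dir, "profiles", paste0(id, ".hhm")))
    }
    write_fasta(sequences, file.path(out_dir, "sequences.fasta"))
    write_annotations(ann, file.path(out_dir, "annotations.tsv"))
    return(invisible(out))
  }
  out
}
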