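# Fixtures built in code: hand-assembled .hhm text (independent of
# write_hhm) and tiny in-memory profiles.

# Assemble a single-model .hhm file from a residue string and an L x 20
# character/integer score matrix ("*" allowed). Column order defaults to
# the canonical one but can be permuted to exercise reordering.
make_hhm_text <- function(residues, scores, cols = hmmorf::AA_ORDER,
                          name = "fab1") {
  res <- strsplit(residues, "")[[1]]
  L <- length(res)
  scores <- matrix(as.character(scores), nrow = L)
  lines <- c(
    "HHsearch 1.5",
    paste0("NAME  ", name),
    paste0("LENG  ", L, " match states, ", L,
           " columns in multiple alignment"),
    "SEQ",
    paste0(">", name),
    residues,
    "#",
    paste0("NULL   ", paste(rep(4322L, 20), collapse = "\t")),
    paste0("HMM    ", paste(cols, collapse = "\t")),
    paste0("       ", paste(c("M->M", "M->I", "M->D", "I->M", "I->I",
                              "D->M", "D->D", "Neff", "Neff_I", "Neff_D"),
                            collapse = "\t")),
    paste0("       ", paste(c("0", "*", "*", "0", "*", "0", "*", "*",
                              "*", "*"), collapse = "\t"))
  )
  for (i in seq_len(L)) {
    lines <- c(lines,
               paste0(res[i], " ", i, "\t",
                      paste(scores[i, ], collapse = "\t"), "\t", i),
               paste0("       ",
                      paste(c("0", "*", "*", "*", "*", "*", "*", "1000",
                              "0", "0"), collapse = "\t")))
  }
  c(lines, "//")
}

# A deterministic little profile whose rows are distinct (row i puts mass
# i/(L+1) on the first column, the rest spread evenly).
toy_profile <- function(L = 8L, id = "toy") {
  probs <- t(vapply(seq_len(L), function(i) {
    p <- rep((1 - i / (L + 1)) / 19, 20)
    p[1] <- i / (L + 1)
    p
  }, numeric(20)))
  hmmorf::hmm_profile(id, strrep("A", L), probs)
}

# One-sequence training record with a planted MoRF interval.
toy_record <- function(L = 60L, morf = c(20L, 25L), id = "rec1",
                       flank_len = 12L, seed = 42L) {
  set.seed(seed)
  probs <- matrix(stats::runif(L * 20), L, 20)
  probs <- probs / rowSums(probs)
  probs[morf[1]:morf[2], 1] <- 0.9
  probs[morf[1]:morf[2], -1] <- 0.1 / 19
  prof <- hmmorf::hmm_profile(id, paste(sample(hmmorf::AA_ORDER, L,
                                               replace = TRUE),
                                        collapse = ""), probs)
  labels <- hmmorf::annotate_regions(L, flank_len = flank_len,
                                     intervals = rbind(morf))
  list(profile = prof, labels = labels)
}

# Brute-force pairwise AUC oracle: fraction of positive/negative pairs
# ranked correctly, ties counting one half.
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (n in neg) {
      total <- total + (p > n) + 0.5 * (p == n)
    }
  }
  total / (length(pos) * length(neg))
}
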