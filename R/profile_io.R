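# Reading sequences, MoRF annotations and HH-suite .hhm profiles.

#' Match-emission column order of HH-suite profiles
#'
#' The fixed 20-letter amino-acid order of the match-emission columns in
#' `.hhm` files. All probability matrices produced by this package use this
#' column order, whatever order the input file declares.
#'
#' @format Character vector of 20 single-letter amino-acid codes.
#' @export
AA_ORDER <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Convert HH-suite profile scores to linear probabilities
#'
#' HH-suite stores emission probabilities as integer scores `N` related to
#' the probability by `p = 2^(-N/1000)`; a `*` entry denotes an "infinite"
#' score, i.e. zero probability. This function applies that transform.
#'
#' @param N Integer scores. Either a numeric vector in which `NA` stands for
#'   the `*` sentinel, or a character vector in which the literal `"*"` does.
#' @return Numeric vector of probabilities in `[0, 1]`; `*` maps to `0`.
#' @examples
#' score_to_probability(c(0, 1000, 2000))   # 1, 0.5, 0.25
#' score_to_probability(c("500", "*"))
#' @export
score_to_probability <- function(N) {
  if (is.character(N)) {
    star <- N == "*"
    n <- suppressWarnings(as.numeric(N))
    if (any(is.na(n) & !star)) {
      stop("malformed score token(s): ",
           paste(utils::head(N[is.na(n) & !star], 3L), collapse = ", "))
    }
    n[star] <- NA_real_
    N <- n
  }
  if (any(N < 0, na.rm = TRUE)) {
    stop("negative profile score(s): ",
         paste(utils::head(N[!is.na(N) & N < 0], 3L), collapse = ", "))
  }
  p <- 2^(-N / 1000)
  p[is.na(N)] <- 0
  p
}

#' Construct an HMM profile object
#'
#' @param seq_id Sequence identifier.
#' @param residues Amino-acid string (or character vector of length-1
#'   letters) of length `L`.
#' @param probs `L x 20` numeric matrix of match-emission probabilities,
#'   columns in [AA_ORDER].
#' @param raw_scores Optional `L x 20` integer score matrix (`NA` = `*`).
#' @return An object of class `hmm_profile`.
#' @export
hmm_profile <- function(seq_id, residues, probs, raw_scores = NULL) {
  if (length(residues) > 1L) residues <- paste(residues, collapse = "")
  L <- nchar(residues)
  probs <- as.matrix(probs)
  if (nrow(probs) != L) {
    stop("profile '", seq_id, "': ", nrow(probs), " probability rows for ",
         L, " residues")
  }
  if (ncol(probs) != 20L) {
    stop("profile '", seq_id, "': expected 20 emission columns, got ",
         ncol(probs))
  }
  if (any(probs < 0 | probs > 1)) {
    stop("profile '", seq_id, "': probabilities outside [0, 1]")
  }
  colnames(probs) <- AA_ORDER
  structure(
    list(seq_id = seq_id, residues = residues, probs = probs,
         raw_scores = raw_scores, aa_order = AA_ORDER),
    class = "hmm_profile"
  )
}

#' @export
print.hmm_profile <- function(x, ...) {
  cat("<hmm_profile> ", x$seq_id, ": ", nchar(x$residues),
      " residues x 20 emission probabilities\n", sep = "")
  invisible(x)
}

#' @export
length.hmm_profile <- function(x) nchar(x$residues)

#' Parse an HH-suite `.hhm` profile
#'
#' Reads the text dialect written by `hhmake`/HHblits: header block,
#' optional `SEQ` block, the `HMM` column-header line, one match-emission
#' row plus one insert/transition row per model position, terminated by
#' `//`. Only the 20 match-emission columns are kept; the 10
#' insert/transition columns are parsed and discarded. Scores are converted
#' to probabilities with [score_to_probability()]; `*` entries become 0.
#' Columns are reordered to [AA_ORDER] if the file declares a different
#' order.
#'
#' @param text A single string (possibly with embedded newlines) or a
#'   character vector of lines holding one `.hhm` model.
#' @param seq_id Optional identifier overriding the file's `NAME` field.
#' @return An [hmm_profile()] object.
#' @seealso [read_hhm()] to read from a file path, [write_hhm()] for the
#'   inverse operation.
#' @export
parse_hhm <- function(text, seq_id = NULL) {
  lines <- if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(text)
  }

  if (is.null(seq_id)) {
    name_line <- grep("^NAME\\s", lines, value = TRUE)
    seq_id <- if (length(name_line) >= 1L) {
      strsplit(trimws(sub("^NAME\\s+", "", name_line[1L])), "\\s+")[[1]][1L]
    } else {
      "unnamed"
    }
  }

  leng_line <- grep("^LENG\\s", lines, value = TRUE)
  declared_len <- if (length(leng_line) >= 1L) {
    as.integer(strsplit(trimws(sub("^LENG\\s+", "", leng_line[1L])),
                        "\\s+")[[1]][1L])
  } else {
    NA_integer_
  }

  hdr <- grep("^HMM\\s", lines)
  if (length(hdr) == 0L) stop("not an .hhm model: no 'HMM' header line")
  hdr <- hdr[1L]
  cols <- strsplit(trimws(lines[hdr]), "\\s+")[[1]][-1L]
  if (length(cols) != 20L || !setequal(cols, AA_ORDER)) {
    stop("line ", hdr, ": expected 20 amino-acid emission columns, got: ",
         paste(cols, collapse = " "))
  }
  col_map <- match(AA_ORDER, cols)

  end <- grep("^//\\s*$", lines)
  if (length(end) == 0L) stop("truncated .hhm: missing '//' terminator")
  end <- end[1L]

  # hdr+1 is the transition column header, hdr+2 the begin-state transition
  # row; match rows come in (emission line, transition line) pairs after it.
  body <- lines[seq.int(hdr + 3L, end - 1L)]
  body <- body[nzchar(trimws(body))]
  if (length(body) %% 2L != 0L) {
    stop("malformed .hhm body: odd number of model rows before '//'")
  }
  emit <- body[seq(1L, length(body), by = 2L)]
  L <- length(emit)
  if (!is.na(declared_len) && L != declared_len) {
    stop("declared LENG ", declared_len, " but found ", L, " match rows")
  }

  residues <- character(L)
  raw <- matrix(NA_integer_, L, 20L)
  for (i in seq_len(L)) {
    toks <- strsplit(trimws(emit[i]), "\\s+")[[1]]
    if (length(toks) < 22L) {
      stop("match row ", i, ": expected residue, position and 20 scores, got ",
           length(toks), " fields")
    }
    residues[i] <- toks[1L]
    pos <- suppressWarnings(as.integer(toks[2L]))
    if (is.na(pos) || pos != i) {
      stop("match row ", i, ": position field is '", toks[2L], "'")
    }
    sc <- toks[3:22]
    star <- sc == "*"
    val <- suppressWarnings(as.integer(sc))
    if (any(is.na(val) & !star)) {
      stop("match row ", i, ", column ",
           which(is.na(val) & !star)[1L], ": malformed score '",
           sc[which(is.na(val) & !star)[1L]], "'")
    }
    if (any(val < 0, na.rm = TRUE)) {
      stop("match row ", i, ", column ", which(val < 0)[1L],
           ": negative score ", val[which(val < 0)[1L]])
    }
    raw[i, ] <- val
  }
  raw <- raw[, col_map, drop = FALSE]
  probs <- matrix(score_to_probability(as.vector(raw)), L, 20L)
  hmm_profile(seq_id, residues, probs, raw_scores = raw)
}

#' Read an `.hhm` profile file
#'
#' @param path Path to a single-model `.hhm` file.
#' @param seq_id Optional identifier; defaults to the file's `NAME` field.
#' @return An [hmm_profile()] object.
#' @export
read_hhm <- function(path, seq_id = NULL) {
  parse_hhm(readLines(path, warn = FALSE), seq_id = seq_id)
}

#' Read all `.hhm` profiles in a directory
#'
#' @param dir Directory containing `*.hhm` files.
#' @return Named list of [hmm_profile()] objects, keyed by their `seq_id`.
#' @export
read_hhm_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.hhm$", full.names = TRUE))
  if (length(files) == 0L) stop("no .hhm files found in '", dir, "'")
  profs <- lapply(files, read_hhm)
  stats::setNames(profs, vapply(profs, `[[`, "", "seq_id"))
}

# Fixed null-model scores written in the NULL line (uniform 1/20 background).
.hhm_null_score <- 4322L

.prob_to_score <- function(p) {
  # Inverse of p = 2^(-N/1000), rounded to the integer score grid;
  # probabilities below 2^(-32.767) are written as '*'.
  n <- round(-1000 * log2(p))
  n[!is.finite(n) | n > 32767] <- NA_integer_
  as.integer(n)
}

#' Write an HMM profile as an HH-suite `.hhm` file
#'
#' Serialises a profile in the text dialect read by [parse_hhm()].
#' Probabilities are quantised to the integer score grid by inverting
#' `p = 2^(-N/1000)` with rounding; values below `2^(-32.767)` are written
#' as `*`. The 10 insert/transition columns carry fixed default scores
#' (the predictor discards them on reading).
#'
#' @param profile An [hmm_profile()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hhm <- function(profile, path) {
  stopifnot(inherits(profile, "hmm_profile"))
  L <- nchar(profile$residues)
  res <- strsplit(profile$residues, "")[[1]]
  fmt_score <- function(n) ifelse(is.na(n), "*", as.character(n))

  con <- file(path, open = "wt")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("HHsearch 1.5")
  w("NAME  ", profile$seq_id)
  w("LENG  ", L, " match states, ", L, " columns in multiple alignment")
  w("SEQ")
  w(">", profile$seq_id)
  for (i in seq(1L, L, by = 80L)) {
    w(substr(profile$residues, i, min(i + 79L, L)))
  }
  w("#")
  w("NULL   ", paste(rep(.hhm_null_score, 20L), collapse = "\t"))
  w("HMM    ", paste(AA_ORDER, collapse = "\t"))
  w("       ", paste(c("M->M", "M->I", "M->D", "I->M", "I->I",
                       "D->M", "D->D", "Neff", "Neff_I", "Neff_D"),
                     collapse = "\t"))
  w("       ", paste(c("0", "*", "*", "0", "*", "0", "*", "*", "*", "*"),
                     collapse = "\t"))
  trans <- paste(c("0", "*", "*", "*", "*", "*", "*", "1000", "0", "0"),
                 collapse = "\t")
  for (i in seq_len(L)) {
    n <- .prob_to_score(profile$probs[i, ])
    w(res[i], " ", i, "\t", paste(fmt_score(n), collapse = "\t"), "\t", i)
    w("       ", trans)
  }
  w("//")
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' @param input Path to a FASTA file, or FASTA text itself (recognised by a
#'   leading `>` or embedded newline).
#' @return Named character vector of sequences; names are the first
#'   whitespace-delimited token of each header.
#' @export
read_fasta <- function(input) {
  path <- input
  if (length(input) == 1L &&
      (startsWith(input, ">") || grepl("\n", input, fixed = TRUE))) {
    path <- tempfile(fileext = ".fasta")
    writeLines(input, path)
    on.exit(unlink(path))
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in input")
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, "", 1L)
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    stop("empty sequence for record(s): ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  if (anyDuplicated(ids)) {
    stop("duplicated sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  stats::setNames(seqs, ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = 80L)
    writeLines(substring(s, starts, pmin(starts + 79L, nchar(s))), con)
  }
  invisible(path)
}

#' Read MoRF annotations from TSV
#'
#' Expects tab-separated columns `seq_id`, `morf_start`, `morf_end`
#' (1-based, inclusive). A header line is optional and `#` comment lines
#' are ignored. Multiple rows per sequence are allowed; intervals are
#' sorted per sequence and checked for `start <= end` and non-overlap.
#'
#' @param input Path to the TSV file, or its text (recognised by an
#'   embedded newline or tab).
#' @return A `data.frame` with columns `seq_id`, `start`, `end`, sorted by
#'   sequence id and start position.
#' @export
read_annotations <- function(input) {
  lines <- if (length(input) == 1L && !grepl("[\t\n]", input)) {
    readLines(input, warn = FALSE)
  } else if (length(input) == 1L) {
    strsplit(input, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(input)
  }
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) > 0L &&
      grepl("^seq_id\\b", lines[1L], ignore.case = TRUE)) {
    lines <- lines[-1L]
  }
  if (length(lines) == 0L) {
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 0L) < 3L
  if (any(bad)) {
    stop("annotation line(s) with fewer than 3 tab-separated fields: '",
         lines[which(bad)[1L]], "'")
  }
  ann <- data.frame(
    seq_id = vapply(parts, `[[`, "", 1L),
    start = suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L))),
    end = suppressWarnings(as.integer(vapply(parts, `[[`, "", 3L))),
    stringsAsFactors = FALSE
  )
  if (anyNA(ann$start) || anyNA(ann$end)) {
    stop("non-integer MoRF interval bounds in annotations")
  }
  bad <- ann$start > ann$end
  if (any(bad)) {
    stop("MoRF interval with start > end for sequence '",
         ann$seq_id[which(bad)[1L]], "' (", ann$start[which(bad)[1L]], " > ",
         ann$end[which(bad)[1L]], ")")
  }
  if (any(ann$start < 1L)) {
    stop("MoRF interval starting before position 1 for sequence '",
         ann$seq_id[which(ann$start < 1L)[1L]], "'")
  }
  ann <- ann[order(ann$seq_id, ann$start), , drop = FALSE]
  for (id in unique(ann$seq_id)) {
    a <- ann[ann$seq_id == id, , drop = FALSE]
    if (nrow(a) > 1L && any(a$start[-1L] <= a$end[-nrow(a)])) {
      stop("overlapping MoRF intervals for sequence '", id, "'")
    }
  }
  rownames(ann) <- NULL
  ann
}

#' Write MoRF annotations to TSV
#'
#' @param ann `data.frame` with columns `seq_id`, `start`, `end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("seq_id\tmorf_start\tmorf_end", con)
  if (nrow(ann) > 0L) {
    writeLines(paste(ann$seq_id, ann$start, ann$end, sep = "\t"), con)
  }
  invisible(path)
}

#' Attach a sequence to its MoRF intervals
#'
#' Builds an annotated-sequence record and validates the intervals against
#' the sequence length. Interval lengths outside the canonical 5-25 residue
#' MoRF range are allowed with a warning.
#'
#' @param seq_id Identifier.
#' @param sequence Amino-acid string.
#' @param intervals Two-column matrix or data.frame of 1-based inclusive
#'   `(start, end)` MoRF intervals; may have zero rows.
#' @return An object of class `annotated_sequence` with fields `seq_id`,
#'   `sequence` and `morf_intervals` (integer matrix with columns
#'   `start`, `end`).
#' @export
annotated_sequence <- function(seq_id, sequence, intervals) {
  L <- nchar(sequence)
  iv <- matrix(as.integer(as.matrix(intervals)), ncol = 2L,
               dimnames = list(NULL, c("start", "end")))
  if (nrow(iv) > 0L) {
    iv <- iv[order(iv[, 1L]), , drop = FALSE]
    if (any(iv[, 1L] > iv[, 2L])) {
      stop("sequence '", seq_id, "': interval with start > end")
    }
    if (any(iv[, 1L] < 1L) || any(iv[, 2L] > L)) {
      stop("sequence '", seq_id, "': MoRF interval outside [1, ", L, "]")
    }
    if (nrow(iv) > 1L && any(iv[-1L, 1L] <= iv[-nrow(iv), 2L])) {
      stop("sequence '", seq_id, "': overlapping MoRF intervals")
    }
    len <- iv[, 2L] - iv[, 1L] + 1L
    if (any(len < 5L | len > 25L)) {
      warning("sequence '", seq_id, "': ", sum(len < 5L | len > 25L),
              " MoRF interval(s) outside the canonical 5-25 residue range")
    }
  }
  structure(list(seq_id = seq_id, sequence = sequence, morf_intervals = iv),
            class = "annotated_sequence")
}
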