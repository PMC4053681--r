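# Classification of coxL nucleotide sequences by the conserved seven-residue
# active-site signature of the CO dehydrogenase large subunit:
#   type I           AYXCSFR  (X = exactly one arbitrary residue)
#   type II          AYRGAGR
#   atypical type II PYRGAGR
# Exact motifs outrank the wildcarded type I pattern when several match.

.MOTIF_PRECEDENCE <- c("TYPE_II", "ATYPICAL_II", "TYPE_I")

.as_dna <- function(seq) {
  if (inherits(seq, "DNAString")) return(seq)
  if (inherits(seq, "DNAStringSet")) {
    stopifnot(length(seq) == 1L)
    return(seq[[1L]])
  }
  stopifnot(is.character(seq), length(seq) == 1L)
  Biostrings::DNAString(seq)
}

#' Six-frame in silico translation
#'
#' Translates a nucleotide sequence in all six reading frames (three forward,
#' three on the reverse complement) under the standard genetic code.
#' Ambiguous codons become `X`; internal stop codons are retained as `*`.
#'
#' @param seq nucleotide sequence: a single character string, `DNAString`,
#'   or length-one `DNAStringSet` (IUPAC alphabet).
#' @return named character vector of six amino-acid strings, frames
#'   `"+1" "+2" "+3" "-1" "-2" "-3"`.
#' @examples
#' translate_frames("ATGGCAGCAGCAGCAGCAGCAGCA")[["+1"]]
#' @export
translate_frames <- function(seq) {
  dna <- .as_dna(seq)
  n <- length(dna)
  if (n < 21L)
    .stopf("sequence too short for frame analysis (%d nt < 21 nt)", n)
  rc <- Biostrings::reverseComplement(dna)
  one <- function(s, off) {
    len <- length(s) - off
    len <- len - (len %% 3L)
    if (len < 3L) return("")
    sub <- Biostrings::subseq(s, start = off + 1L, width = len)
    as.character(Biostrings::translate(sub, if.fuzzy.codon = "X"))
  }
  out <- c(vapply(0:2, function(o) one(dna, o), character(1)),
           vapply(0:2, function(o) one(rc, o), character(1)))
  names(out) <- c("+1", "+2", "+3", "-1", "-2", "-3")
  out
}

# Find motif hits of one pattern in one frame, dropping matches with a stop
# codon within `stop_window` residues of the motif (out-of-frame guard).
.motif_hits <- function(aa, pattern, stop_window) {
  m <- gregexpr(pattern, aa)[[1L]]
  if (m[1L] == -1L) return(integer())
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  keep <- vapply(seq_along(starts), function(i) {
    lo <- max(1L, starts[i] - stop_window)
    hi <- min(nchar(aa), starts[i] + lens[i] - 1L + stop_window)
    !grepl("*", substr(aa, lo, hi), fixed = TRUE)
  }, logical(1))
  starts[keep]
}

#' Classify translated frames by the active-site signature
#'
#' Scans all six frames for the CODH active-site signatures. When several
#' signatures match (possible in chimeric synthetic inputs) the exact motifs
#' outrank the wildcarded one: `AYRGAGR` (type II) > `PYRGAGR` (atypical
#' type II) > `AY.CSFR` (type I), with a warning. A match with a stop codon
#' within `stop_window` residues is rejected as an out-of-frame artifact.
#' No acceptable match gives `UNCLASSIFIED`.
#'
#' @param aa_frames named character vector from [translate_frames()].
#' @param stop_window residues around the motif that must be stop-free.
#' @return one-row data frame: `motif_class`, `frame`, `motif_start_aa`
#'   (0-based, `NA` when unclassified), `matched_motif`.
#' @examples
#' fr <- translate_frames("ATGGCATACGCATGCTCATTTCGCGCAGCAGCA")
#' classify_motif(fr)$motif_class
#' @export
classify_motif <- function(aa_frames, stop_window = 20L) {
  stopifnot(is.character(aa_frames), !is.null(names(aa_frames)))
  found <- list()
  for (cls in .MOTIF_PRECEDENCE) {
    pat <- .MOTIF_PATTERNS[[cls]]
    for (fr in names(aa_frames)) {
      starts <- .motif_hits(aa_frames[[fr]], pat, stop_window)
      if (length(starts)) {
        found[[cls]] <- list(frame = fr, start = starts[1L],
                             motif = substr(aa_frames[[fr]], starts[1L],
                                            starts[1L] + 6L))
        break
      }
    }
  }
  if (length(found) == 0L)
    return(data.frame(motif_class = "UNCLASSIFIED", frame = NA_character_,
                      motif_start_aa = NA_integer_,
                      matched_motif = NA_character_,
                      stringsAsFactors = FALSE))
  if (length(found) > 1L)
    .warnf("multiple signature classes matched (%s); keeping %s by precedence",
           paste(names(found), collapse = ", "), names(found)[1L])
  hit <- found[[1L]]
  data.frame(motif_class = names(found)[1L], frame = hit$frame,
             motif_start_aa = hit$start - 1L, matched_motif = hit$motif,
             stringsAsFactors = FALSE)
}

#' Classify a clone library and summarize class proportions per sample
#'
#' Runs six-frame translation and signature classification on every record
#' of a coxL library and tabulates relative class abundances per sample,
#' mirroring clone-library composition profiles by land use.
#'
#' @param fasta path to a FASTA file, a named character vector, or a
#'   `DNAStringSet` of coxL nucleotide sequences.
#' @param sample_map optional data frame `seq_id`, `sample_id`; records
#'   absent from the map fall into `default_sample`.
#' @param default_sample sample label for unmapped records.
#' @param stop_window passed to [classify_motif()].
#' @return object of class `coxl_classification`: list with
#'   `classifications` (per-sequence table), `proportions` (class x sample
#'   matrix, columns summing to 1), `counts` (same shape, counts) and
#'   `type_ratio` (type I : type II count ratio per sample).
#' @examples
#' lib <- simulate_clone_library(24, c(TYPE_I = 1), seed = 1)
#' cl <- classify_library(lib$sequences, lib$sample_map)
#' cl$proportions
#' @export
classify_library <- function(fasta, sample_map = NULL,
                             default_sample = "sample1", stop_window = 20L) {
  seqs <- if (is.character(fasta) && length(fasta) == 1L &&
              file.exists(fasta)) {
    Biostrings::readDNAStringSet(fasta)
  } else if (inherits(fasta, "DNAStringSet")) {
    fasta
  } else {
    stopifnot(is.character(fasta), !is.null(names(fasta)))
    Biostrings::DNAStringSet(fasta)
  }
  ids <- names(seqs)
  if (anyDuplicated(ids))
    .stopf("duplicate FASTA ids: %s",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
  samples <- rep(default_sample, length(ids))
  if (!is.null(sample_map)) {
    stopifnot(all(c("seq_id", "sample_id") %in% names(sample_map)))
    hit <- match(ids, sample_map$seq_id)
    samples[!is.na(hit)] <- sample_map$sample_id[hit[!is.na(hit)]]
  }
  rows <- lapply(seq_along(seqs), function(i)
    classify_motif(translate_frames(seqs[[i]]), stop_window = stop_window))
  tab <- do.call(rbind, rows)
  tab <- cbind(data.frame(seq_id = ids, sample_id = samples,
                          stringsAsFactors = FALSE), tab)
  counts <- table(factor(tab$motif_class, levels = .MOTIF_CLASSES),
                  factor(tab$sample_id))
  counts <- unclass(counts)
  props <- sweep(counts, 2L, colSums(counts), "/")
  ratio <- counts["TYPE_I", ] / counts["TYPE_II", ]
  structure(list(classifications = tab, proportions = props,
                 counts = counts, type_ratio = ratio),
            class = "coxl_classification")
}

#' @export
print.coxl_classification <- function(x, ...) {
  n <- nrow(x$classifications)
  cat("coxL signature classification:", n, "sequences,",
      ncol(x$proportions), "sample(s)\n")
  print(round(x$proportions, 3))
  invisible(x)
}
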