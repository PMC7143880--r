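# Pairwise 16S rDNA identity, reported the way taxonomy papers print it:
# matches / compared positions, e.g. 1450/1451 = 99.93% (1 nt difference).
# Columns holding a gap or an undetermined base (N) in either sequence are
# excluded from the denominator, so it counts compared positions only.

#' Pairwise nucleotide identity between two sequences
#'
#' For pre-aligned input the two sequences are compared column by column;
#' otherwise a global Needleman-Wunsch alignment (match +2, mismatch -1,
#' gap open -5, gap extend -2) is computed first. Columns with a gap or `N`
#' in either sequence are excluded from the compared positions; `U` is read
#' as `T`; comparison is case-insensitive. Other IUPAC ambiguity codes are
#' compared literally.
#'
#' @param seq1,seq2 character strings (or `Biostrings::DNAString`) over the
#'   nucleotide alphabet, with `-` allowed in pre-aligned input.
#' @param prealigned if `TRUE` the sequences must be equal length and are
#'   taken as alignment rows.
#' @return a `bgc_seqpair` list: `compared_positions`, `matches`,
#'   `differences`, `similarity_pct` (half-up rounded to 2 decimals).
#' @examples
#' pairwise_identity("ACGTACGT", "ACGTACGA", prealigned = TRUE)
#' @export
pairwise_identity <- function(seq1, seq2, prealigned = FALSE) {
  s1 <- toupper(as.character(seq1)); s2 <- toupper(as.character(seq2))
  if (!nzchar(s1) || !nzchar(s2)) {
    bgc_stop("bgcrep_empty_sequence", "empty input sequence")
  }
  s1 <- chartr("U", "T", s1); s2 <- chartr("U", "T", s2)
  if (!prealigned) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(gsub("-", "", s1, fixed = TRUE)),
      Biostrings::DNAString(gsub("-", "", s2, fixed = TRUE)),
      type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 2, mismatch = -1, baseOnly = FALSE),
      gapOpening = 5, gapExtension = 2)
    s1 <- as.character(Biostrings::alignedPattern(aln))
    s2 <- as.character(Biostrings::alignedSubject(aln))
  } else if (nchar(s1) != nchar(s2)) {
    bgc_stop("bgcrep_length_mismatch",
             sprintf("pre-aligned sequences differ in length (%d vs %d)",
                     nchar(s1), nchar(s2)))
  }
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  keep <- !(a %in% c("-", "N") | b %in% c("-", "N"))
  compared <- sum(keep)
  matches <- sum(a[keep] == b[keep])
  structure(list(
    compared_positions = compared,
    matches = matches,
    differences = compared - matches,
    similarity_pct = if (compared > 0)
      round_half_up(100 * matches / compared, 2) else NA_real_),
    class = "bgc_seqpair")
}

#' @export
print.bgc_seqpair <- function(x, ...) {
  cat(sprintf("%d/%d identical (%d nt difference), %.2f%% similarity\n",
              x$matches, x$compared_positions, x$differences,
              x$similarity_pct))
  invisible(x)
}

#' All pairwise identities among the records of a FASTA file
#'
#' @param path FASTA file (single or multiple records).
#' @param prealigned treat records as alignment rows.
#' @return data frame with one row per unordered record pair.
#' @export
fasta_pairwise_identity <- function(path, prealigned = FALSE) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) < 2) {
    bgc_stop("bgcrep_format_error", "need at least two FASTA records")
  }
  ids <- names(seqs)
  out <- list()
  for (i in seq_len(length(seqs) - 1)) {
    for (j in seq(i + 1, length(seqs))) {
      st <- pairwise_identity(seqs[[i]], seqs[[j]], prealigned = prealigned)
      out[[length(out) + 1L]] <- data.frame(
        id1 = ids[i], id2 = ids[j],
        compared_positions = st$compared_positions, matches = st$matches,
        differences = st$differences, similarity_pct = st$similarity_pct,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
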