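#' Phred-scaled assembly quality arithmetic
#'
#' Converts between a Merqury-style consensus quality value
#' (QV = -10 log10 e), the per-base error rate e, and the implied
#' percent accuracy 100 (1 - e).
#'
#' @param qv Phred-scaled quality value(s).
#' @return `qv_to_error_rate`: per-base error probability.
#' @examples
#' qv_to_error_rate(51.17)      # ~7.64e-06
#' error_rate_to_qv(1.65e-05)   # ~47.8
#' implied_accuracy(1.65e-05)   # 99.99835
#' @export
qv_to_error_rate <- function(qv) {
  stopifnot(is.numeric(qv), all(is.finite(qv)))
  10^(-qv / 10)
}

#' @rdname qv_to_error_rate
#' @param e per-base error probability in (0, 1].
#' @export
error_rate_to_qv <- function(e) {
  stopifnot(is.numeric(e))
  if (any(e <= 0)) stop("error rate must be positive (QV undefined at 0)")
  if (any(e > 1)) stop("error rate cannot exceed 1")
  -10 * log10(e)
}

#' @rdname qv_to_error_rate
#' @export
implied_accuracy <- function(e) {
  stopifnot(is.numeric(e), all(e >= 0 & e <= 1))
  100 * (1 - e)
}

#' Scan chromosome termini for telomeric repeats
#'
#' Counts non-overlapping occurrences of the telomere motif (vertebrate
#' default TTAGGG) and of its reverse complement in a terminal window at
#' each end of every sequence. Density is motif bp / window bp, so a
#' perfect telomeric array has density 1; a terminus is flagged telomeric
#' when density reaches `threshold`. Ambiguous bases never match.
#'
#' @param fasta path to a FASTA file, or a [Biostrings::DNAStringSet].
#' @param motif telomere repeat unit.
#' @param window_bp terminal window size (bp); clipped to the sequence
#'   length for short sequences.
#' @param threshold minimum density to call a terminus telomeric. The
#'   choice of cutoff is a convention, not an estimate; 0.1 flags any
#'   terminus where at least 10% of the window is telomeric repeat.
#' @return data.frame with one row per sequence end: `chromosome`, `end`
#'   (left/right), `window_bp`, `motif_count` (both strands), `density`,
#'   `telomeric`.
#' @export
telomere_scan <- function(fasta, motif = "TTAGGG", window_bp = 100000,
                          threshold = 0.1) {
  seqs <- if (inherits(fasta, "DNAStringSet")) fasta
          else Biostrings::readDNAStringSet(fasta)
  if (length(seqs) == 0) stop("no sequences")
  if (any(Biostrings::width(seqs) == 0)) stop("empty sequence")
  bad <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE)[, "other"]
  if (any(bad > 0))
    warning("non-ACGT bases present; ambiguous bases never match the motif")
  m <- Biostrings::DNAString(motif)
  rc <- Biostrings::reverseComplement(m)
  out <- list()
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    w <- min(window_bp, length(s))
    for (side in c("left", "right")) {
      win <- if (side == "left") Biostrings::subseq(s, 1, w)
             else Biostrings::subseq(s, length(s) - w + 1, length(s))
      cnt <- count_nonoverlapping(win, m) + count_nonoverlapping(win, rc)
      out[[length(out) + 1]] <- data.frame(
        chromosome = names(seqs)[i], end = side, window_bp = w,
        motif_count = cnt, density = cnt * length(m) / w,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res$telomeric <- res$density >= threshold
  res
}

# Greedy left-to-right non-overlapping match count, so that
# count * nchar(motif) is interpretable as covered bases.
count_nonoverlapping <- function(subject, pattern) {
  hits <- Biostrings::matchPattern(pattern, subject)
  starts <- sort(Biostrings::start(hits))
  if (length(starts) == 0) return(0L)
  n <- 0L
  next_free <- -Inf
  plen <- length(pattern)
  for (st in starts) {
    if (st >= next_free) {
      n <- n + 1L
      next_free <- st + plen
    }
  }
  n
}
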