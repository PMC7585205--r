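#' Find the longest open reading frame
#'
#' Scans the three forward frames of the oriented transcript sequence for
#' complete ORFs (ATG start codon through an in-frame stop) and returns the
#' longest one meeting the minimum length, the long-read annotation
#' convention of keeping predicted proteins of at least 100 amino acids.
#' Codons containing N are treated as non-coding and break an ORF. Ties on
#' length go to the 5'-most start.
#'
#' @param sequence Nucleotide string over A, C, G, T, N (oriented 5' to 3';
#'   transcripts are stranded, so reverse frames are not scanned).
#' @param min_aa Minimum ORF length in amino acids (start codon included,
#'   stop excluded); default 100.
#' @return A list of class `orf_call` with `frame` (0-2), `start`, `end`
#'   (0-based half-open transcript coordinates including the stop codon) and
#'   `length_aa`, or `NULL` when no qualifying ORF exists.
#' @examples
#' orf <- find_longest_orf(paste0("ATG", strrep("GCT", 120), "TAA"), min_aa = 100)
#' orf$length_aa
#' @export
find_longest_orf <- function(sequence, min_aa = 100) {
  sequence <- toupper(as.character(sequence))
  if (grepl("[^ACGTN]", sequence)) stop2("sequence must be over A,C,G,T,N")
  n <- nchar(sequence)
  best <- NULL
  stops <- c("TAA", "TAG", "TGA")
  for (frame in 0:2) {
    pos <- seq(frame + 1, n - 2, by = 3)
    if (length(pos) == 0L) next
    codons <- substring(sequence, pos, pos + 2)
    breaker <- codons %in% stops | grepl("N", codons, fixed = TRUE)
    is_start <- codons == "ATG"
    i <- 1L
    while (i <= length(codons)) {
      if (is_start[i]) {
        j <- i
        while (j <= length(codons) && !breaker[j]) j <- j + 1L
        if (j <= length(codons) && codons[j] %in% stops) {
          len_aa <- j - i
          if (len_aa >= min_aa &&
              (is.null(best) || len_aa > best$length_aa ||
               (len_aa == best$length_aa && pos[i] - 1L < best$start))) {
            best <- structure(list(frame = frame, start = pos[i] - 1L,
                                   end = pos[j] + 2L, length_aa = len_aa),
                              class = "orf_call")
          }
          i <- j + 1L
        } else {
          # no stop before a breaker/sequence end: skip past the region
          i <- j + 1L
        }
      } else {
        i <- i + 1L
      }
    }
  }
  best
}
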