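# exon-chain builders ---------------------------------------------------

# mk_exons(c(0,100, 200,300)) -> exon table rows for one transcript
mk_exons <- function(bounds, tid = "t1", gid = "g1", chrom = "chr1",
                     strand = "+") {
  m <- matrix(bounds, ncol = 2, byrow = TRUE)
  data.frame(transcript_id = tid, gene_id = gid, chrom = chrom,
             strand = strand, start = m[, 1], end = m[, 2],
             stringsAsFactors = FALSE)
}

mk_ann <- function(..., min_intron = 20, max_intron = 20000) {
  annotation_set(do.call(rbind, list(...)), min_intron = min_intron,
                 max_intron = max_intron)
}

mk_tm <- function(bounds, tid = "t1", gid = "g1", strand = "+") {
  transcript_model(mk_ann(mk_exons(bounds, tid = tid, gid = gid,
                                   strand = strand)), tid)
}

# a transcript pair on a shared gene, ready for pairwise_events
mk_pair <- function(b1, b2, strand = "+") {
  ann <- mk_ann(mk_exons(b1, tid = "tA", strand = strand),
                mk_exons(b2, tid = "tB", strand = strand))
  list(transcript_model(ann, "tA"), transcript_model(ann, "tB"))
}

# read builders ----------------------------------------------------------

test_primers <- primer_config()
P5 <- test_primers$five_prime_primer
P3RC <- as.character(
  Biostrings::reverseComplement(Biostrings::DNAString(
    test_primers$three_prime_primer)))

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

# canonical full-length read: 5' primer + insert + A-tail + revcomp(3')
mk_read <- function(insert, tail = 25, p5 = TRUE, p3 = TRUE,
                    internal = NULL) {
  paste0(if (p5) P5 else "", insert,
         if (!is.null(internal)) paste0(internal, insert) else "",
         if (tail > 0) strrep("A", tail) else "", if (p3) P3RC else "")
}

# enumeration universe for AS-event cross-checks ------------------------

# all exon chains with <= max_exons exons over a fixed boundary grid
enumerate_chains <- function(positions = seq(100, 800, by = 100),
                             max_exons = 4) {
  chains <- list()
  for (k in seq_len(max_exons)) {
    combos <- utils::combn(positions, 2 * k)
    for (j in seq_len(ncol(combos))) {
      chains[[length(chains) + 1L]] <- combos[, j]
    }
  }
  chains
}
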