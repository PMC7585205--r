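#' Primer configuration for read classification
#'
#' @param five_prime_primer,three_prime_primer cDNA primer sequences (DNA
#'   alphabet). The package ships a default pair of 24-nt primers used by
#'   the simulator.
#' @param max_mismatch_fraction Maximum edit-distance fraction of the primer
#'   length tolerated in a match (default 0.1; must be in \[0, 0.3\]).
#' @return A `primer_config` list.
#' @export
primer_config <- function(five_prime_primer = default_primers()$five_prime,
                          three_prime_primer = default_primers()$three_prime,
                          max_mismatch_fraction = 0.1) {
  five_prime_primer <- toupper(as.character(five_prime_primer))
  three_prime_primer <- toupper(as.character(three_prime_primer))
  if (!nzchar(five_prime_primer) || !nzchar(three_prime_primer))
    stop2("primers must be non-empty")
  if (max_mismatch_fraction < 0 || max_mismatch_fraction > 0.3)
    stop2("max_mismatch_fraction must lie in [0, 0.3]")
  structure(list(five_prime_primer = five_prime_primer,
                 three_prime_primer = three_prime_primer,
                 max_mismatch_fraction = max_mismatch_fraction),
            class = "primer_config")
}

#' Default cDNA primer pair
#'
#' Two fixed 24-nt primer sequences shipped with the package; the simulator
#' attaches them to generated reads and the classifier searches for them by
#' default.
#'
#' @return list with elements `five_prime` and `three_prime`.
#' @export
default_primers <- function() {
  list(five_prime = "AAGCAGTGGTATCAACGCAGAGTA",
       three_prime = "ATCGTTACGCTAGGTACCGAGTCA")
}

#' Locate primer hits in a read
#'
#' Finds approximate occurrences (edit distance up to
#' `max_mismatch_fraction` of the primer length, indels allowed) of both
#' primers and their reverse complements, and classifies each hit as
#' terminal (within `terminal_margin` nt of a read end) or internal.
#' Internal primer copies are the signature of chimeric (concatemeric)
#' reads.
#'
#' @param read Read sequence (character or `DNAString`).
#' @param primers A [primer_config()].
#' @param terminal_margin Distance (nt) from a read end within which a hit
#'   counts as terminal (default 100).
#' @return data.frame with one row per hit: `kind` (`five_prime` /
#'   `three_prime`), `orientation` (`forward` / `revcomp`), `start`, `end`
#'   (1-based inclusive read coordinates), `location` (`terminal5`,
#'   `terminal3`, `internal`).
#' @export
detect_primers <- function(read, primers = primer_config(),
                           terminal_margin = 100) {
  stopifnot(inherits(primers, "primer_config"))
  subject <- if (inherits(read, "DNAString")) read else
    Biostrings::DNAString(as.character(read))
  n <- length(subject)
  hits <- list()
  for (kind in c("five_prime", "three_prime")) {
    pat <- primers[[paste0(kind, "_primer")]]
    max_mm <- floor(primers$max_mismatch_fraction * nchar(pat))
    for (orientation in c("forward", "revcomp")) {
      p <- if (orientation == "forward") Biostrings::DNAString(pat) else
        Biostrings::reverseComplement(Biostrings::DNAString(pat))
      m <- Biostrings::matchPattern(p, subject, max.mismatch = max_mm,
                                    with.indels = TRUE)
      if (length(m) == 0L) next
      # indel wiggle yields stacks of near-identical matches; keep one per locus
      r <- IRanges::reduce(IRanges::ranges(m))
      hits[[length(hits) + 1L]] <- data.frame(
        kind = kind, orientation = orientation,
        start = IRanges::start(r), end = IRanges::end(r),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(kind = character(), orientation = character(),
               start = integer(), end = integer())
  out$location <- ifelse(out$start <= terminal_margin, "terminal5",
                         ifelse(out$end > n - terminal_margin, "terminal3",
                                "internal"))
  out[order(out$start), , drop = FALSE]
}

#' Classify one read of insert
#'
#' A read is full-length (FL) when it carries the 5' primer, the 3' primer
#' and a poly(A) tail simultaneously; otherwise it is non-full-length (nFL).
#' An FL read with an internal primer copy is chimeric; FL and non-chimeric
#' reads are the FLNC set used for isoform analysis. Poly(A) presence is
#' decided by the explicit tail rule of [call_tail()] applied to the region
#' 5' of the 3'-primer hit. Reads in reverse orientation (5' primer at the
#' 3' end, as reverse-complemented inserts) are reoriented before
#' classification.
#'
#' @inheritParams detect_primers
#' @param read_id Identifier recorded in the result.
#' @param sample_label Optional sample label carried through to summaries.
#' @return One-row data.frame: `read_id`, `sample_label`, `has_five_prime`,
#'   `has_three_prime`, `has_polya`, `is_full_length`, `is_chimeric`,
#'   `is_flnc`, `trimmed_length`, `trimmed_insert`.
#' @export
classify_read <- function(read, primers = primer_config(), read_id = "read",
                          sample_label = NA_character_,
                          terminal_margin = 100) {
  seqchr <- toupper(as.character(read))
  hits <- detect_primers(seqchr, primers, terminal_margin)
  fwd_evidence <- sum(hits$kind == "five_prime" & hits$orientation == "forward" &
                        hits$location == "terminal5") +
    sum(hits$kind == "three_prime" & hits$orientation == "revcomp" &
          hits$location == "terminal3")
  rev_evidence <- sum(hits$kind == "five_prime" & hits$orientation == "revcomp" &
                        hits$location == "terminal3") +
    sum(hits$kind == "three_prime" & hits$orientation == "forward" &
          hits$location == "terminal5")
  if (rev_evidence > fwd_evidence) {
    seqchr <- revcomp_chr(seqchr)
    hits <- detect_primers(seqchr, primers, terminal_margin)
  }
  n <- nchar(seqchr)
  h5 <- hits[hits$kind == "five_prime" & hits$orientation == "forward" &
               hits$location == "terminal5", , drop = FALSE]
  h3 <- hits[hits$kind == "three_prime" & hits$orientation == "revcomp" &
               hits$location == "terminal3", , drop = FALSE]
  has5 <- nrow(h5) > 0L
  has3 <- nrow(h3) > 0L
  insert_end <- if (has3) min(h3$start) - 1L else n
  insert_start <- if (has5) max(h5$end) + 1L else 1L
  region <- if (insert_end >= insert_start)
    substr(seqchr, insert_start, insert_end) else ""
  tail <- if (nzchar(region)) call_tail(region) else NULL
  has_polya <- !is.null(tail)
  trimmed <- if (has_polya)
    substr(region, 1L, tail$tail_start - 1L) else region
  chimeric <- any(hits$location == "internal")
  fl <- has5 && has3 && has_polya
  data.frame(read_id = read_id, sample_label = sample_label,
             has_five_prime = has5, has_three_prime = has3,
             has_polya = has_polya, is_full_length = fl,
             is_chimeric = chimeric, is_flnc = fl && !chimeric,
             tail_start = if (has_polya)
               insert_start + tail$tail_start - 1L else NA_integer_,
             tail_length = if (has_polya) tail$tail_length else NA_integer_,
             trimmed_length = nchar(trimmed), trimmed_insert = trimmed,
             stringsAsFactors = FALSE)
}

#' Classify a set of reads
#'
#' @param reads Named `DNAStringSet` or named character vector of read
#'   sequences.
#' @param sample_labels Optional vector of sample labels, one per read.
#' @inheritParams classify_read
#' @return data.frame with one row per read (see [classify_read()]).
#' @export
classify_reads <- function(reads, primers = primer_config(),
                           sample_labels = NULL, terminal_margin = 100) {
  seqs <- as.character(reads)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("read", seq_along(seqs))
  if (is.null(sample_labels)) sample_labels <- rep(NA_character_, length(seqs))
  rows <- lapply(seq_along(seqs), function(i)
    classify_read(seqs[[i]], primers, read_id = ids[i],
                  sample_label = sample_labels[i],
                  terminal_margin = terminal_margin))
  if (length(rows) == 0L)
    return(classify_read("ACGT", primers)[0, , drop = FALSE])
  do.call(rbind, rows)
}

#' Summarise read classifications
#'
#' Builds the per-sample and total classification summary of a read set:
#' counts of reads of insert, primer-positive and poly(A)-positive reads,
#' nFL/FL/FLNC/chimeric reads, and the mean trimmed FLNC read length. The
#' conservation identities FL + nFL = total and FLNC + chimeric = FL hold by
#' construction.
#'
#' @param classifications data.frame from [classify_reads()].
#' @param sample_labels Optional explicit ordering of sample labels.
#' @return A `classification_summary`: data.frame with one row per sample
#'   plus a `Total` row, and percentage columns (`fl_pct`, `nfl_pct`,
#'   `flnc_pct` of reads of insert, two decimals, half-up).
#' @export
summarize_classification <- function(classifications, sample_labels = NULL) {
  cls <- classifications
  if (is.null(sample_labels)) {
    sample_labels <- unique(cls$sample_label)
    sample_labels <- sample_labels[!is.na(sample_labels)]
    if (length(sample_labels) == 0L) sample_labels <- "all"
  }
  if (nrow(cls) > 0 && all(is.na(cls$sample_label)))
    cls$sample_label <- "all"
  one <- function(sub, label) {
    flnc_len <- sub$trimmed_length[sub$is_flnc]
    data.frame(
      sample = label,
      reads_of_insert = nrow(sub),
      five_prime_reads = sum(sub$has_five_prime),
      three_prime_reads = sum(sub$has_three_prime),
      polya_reads = sum(sub$has_polya),
      nfl_reads = sum(!sub$is_full_length),
      fl_reads = sum(sub$is_full_length),
      flnc_reads = sum(sub$is_flnc),
      chimeric_reads = sum(sub$is_full_length & sub$is_chimeric),
      mean_flnc_length = if (length(flnc_len)) round_half_up(mean(flnc_len), 2)
      else NA_real_,
      stringsAsFactors = FALSE)
  }
  rows <- lapply(sample_labels, function(s)
    one(cls[!is.na(cls$sample_label) & cls$sample_label == s, , drop = FALSE],
        s))
  rows[[length(rows) + 1L]] <- one(cls, "Total")
  out <- do.call(rbind, rows)
  out <- classification_summary(out)
  out
}

#' Attach rates to a classification-summary table
#'
#' Validates the conservation identities (FL + nFL = reads of insert,
#' FLNC + chimeric = FL, each primer/poly(A) count no larger than the read
#' total) and adds the percentage columns used in published summaries.
#' Accepts a counts table directly, so printed summary totals can be checked
#' for internal consistency.
#'
#' @param counts data.frame with columns `sample`, `reads_of_insert`,
#'   `five_prime_reads`, `three_prime_reads`, `polya_reads`, `nfl_reads`,
#'   `fl_reads`, `flnc_reads`, `chimeric_reads` and optionally
#'   `mean_flnc_length`.
#' @return The table with `fl_pct`, `nfl_pct` and `flnc_pct` columns,
#'   classed `classification_summary`.
#' @export
classification_summary <- function(counts) {
  required <- c("sample", "reads_of_insert", "five_prime_reads",
                "three_prime_reads", "polya_reads", "nfl_reads", "fl_reads",
                "flnc_reads", "chimeric_reads")
  missing_cols <- setdiff(required, names(counts))
  if (length(missing_cols))
    stop2("summary lacks columns: ", comma(missing_cols))
  with(counts, {
    if (any(fl_reads + nfl_reads != reads_of_insert))
      stop2("conservation violated: fl + nfl != reads_of_insert")
    if (any(flnc_reads + chimeric_reads != fl_reads))
      stop2("conservation violated: flnc + chimeric != fl")
    if (any(five_prime_reads > reads_of_insert |
            three_prime_reads > reads_of_insert |
            polya_reads > reads_of_insert))
      stop2("component count exceeds reads_of_insert")
  })
  pct <- function(a, b) ifelse(b > 0, round_half_up(100 * a / b, 2), NA_real_)
  counts$fl_pct <- pct(counts$fl_reads, counts$reads_of_insert)
  counts$nfl_pct <- pct(counts$nfl_reads, counts$reads_of_insert)
  counts$flnc_pct <- pct(counts$flnc_reads, counts$reads_of_insert)
  class(counts) <- c("classification_summary", "data.frame")
  counts
}

#' @export
print.classification_summary <- function(x, ...) {
  cat("read classification summary (", nrow(x) - 1, "samples )\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Write a classification summary as TSV
#'
#' @param x A `classification_summary`.
#' @param path Output path.
#' @export
write_classification_summary <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read reads of insert from FASTA or FASTQ
#'
#' @param path Sequence file; format inferred from the extension.
#' @return Named `DNAStringSet`.
#' @export
read_reads <- function(path) {
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
    "fastq" else "fasta"
  Biostrings::readDNAStringSet(path, format = fmt)
}
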