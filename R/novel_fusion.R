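#' Identify novel intergenic transcripts
#'
#' Returns isoforms none of whose exons overlap any reference gene span.
#' Overlap is strand-agnostic and any-overlap (a single shared base pair
#' disqualifies an isoform), so only transcripts in genuine annotation gaps
#' are reported.
#'
#' @param isoforms,reference `annotation_set` objects on the same genome.
#' @return Named list of `transcript_model` objects (possibly empty).
#' @export
identify_novel_intergenic <- function(isoforms, reference) {
  stopifnot(inherits(isoforms, "annotation_set"),
            inherits(reference, "annotation_set"))
  unknown <- setdiff(unique(isoforms$exons$chrom),
                     unique(reference$exons$chrom))
  if (length(unknown))
    stop2("chromosomes absent from the reference annotation: ",
          comma(unknown))
  if (nrow(isoforms$exons) == 0L) return(list())
  ex <- exon_ranges(isoforms)
  ref <- gene_ranges(reference)
  hits <- GenomicRanges::findOverlaps(ex, ref, ignore.strand = TRUE)
  hit_tx <- unique(S4Vectors::mcols(ex)$transcript_id[
    S4Vectors::queryHits(hits)])
  novel <- setdiff(isoforms$transcripts$transcript_id, hit_tx)
  setNames(lapply(novel, function(t) transcript_model(isoforms, t)), novel)
}

#' Detect fusion-transcript candidates from split alignments
#'
#' A read is a fusion candidate when it aligns in two or more segments, each
#' covering at least `min_segment_coverage` of the read and together at
#' least `min_total_coverage`, that map to distinct loci: different
#' chromosomes (class `interchromosomal`) or positions on one chromosome
#' separated by more than `max_locus_distance` (class `intrachromosomal`).
#'
#' @param read_segments data.frame with columns `read_id`, `chrom`, `start`,
#'   `end` (0-based half-open genomic), `strand`, `coverage` (aligned
#'   fraction of the read in this segment).
#' @param min_segment_coverage Minimum per-segment read fraction
#'   (default 0.05).
#' @param min_total_coverage Minimum summed read fraction over qualifying
#'   segments (default 0.95).
#' @param max_locus_distance Same-chromosome separation (nt) beyond which
#'   two segments count as distinct loci (default 1e5).
#' @return data.frame of candidates: `read_id`, `class`, `n_segments`,
#'   `chroms` (comma-separated); the qualifying segments of each candidate
#'   are in `attr(, "segments")`.
#' @export
detect_fusion_candidates <- function(read_segments,
                                     min_segment_coverage = 0.05,
                                     min_total_coverage = 0.95,
                                     max_locus_distance = 1e5) {
  required <- c("read_id", "chrom", "start", "end", "strand", "coverage")
  missing_cols <- setdiff(required, names(read_segments))
  if (length(missing_cols))
    stop2("segment table lacks columns: ", comma(missing_cols))
  out <- list()
  seg_keep <- list()
  for (rid in unique(read_segments$read_id)) {
    s <- read_segments[read_segments$read_id == rid &
                         read_segments$coverage >= min_segment_coverage, ,
                       drop = FALSE]
    if (nrow(s) < 2L || sum(s$coverage) < min_total_coverage) next
    chroms <- unique(s$chrom)
    if (length(chroms) >= 2L) {
      cls <- "interchromosomal"
    } else {
      # distinct loci on one chromosome: proximity components > 1
      mids <- sort((s$start + s$end) / 2)
      if (all(diff(mids) <= max_locus_distance)) next
      cls <- "intrachromosomal"
    }
    out[[length(out) + 1L]] <- data.frame(
      read_id = rid, class = cls, n_segments = nrow(s),
      chroms = paste(sort(chroms), collapse = ","), stringsAsFactors = FALSE)
    seg_keep[[rid]] <- s
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(read_id = character(), class = character(),
               n_segments = integer(), chroms = character())
  attr(res, "segments") <- seg_keep
  res
}
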