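#' Read or write transcript-to-genome alignments
#'
#' A simple tabular exchange format for alignment footprints, one row per
#' aligned transcript/read: `query_id`, `chrom`, `strand`, `blocks`
#' (comma-separated `start:end` exon blocks, 0-based half-open, sorted),
#' `coverage` (aligned fraction of the query, in \[0,1\]) and `identity`
#' (matching fraction, in \[0,1\]).
#'
#' @param path File path (TSV with header).
#' @return data.frame with the columns above.
#' @export
read_aligned_transcripts <- function(path) {
  if (!file.exists(path)) stop2("alignment file not found: ", path)
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   quote = "", comment.char = "")
  required <- c("query_id", "chrom", "strand", "blocks", "coverage", "identity")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop2("alignment table lacks columns: ", comma(missing_cols))
  validate_alignments(df)
  df
}

#' @rdname read_aligned_transcripts
#' @param alignments data.frame of alignments as above.
#' @export
write_aligned_transcripts <- function(alignments, path) {
  validate_alignments(alignments)
  write.table(alignments, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_alignments <- function(df) {
  stopifnot(is.data.frame(df))
  if (nrow(df) == 0L) return(invisible(TRUE))
  if (any(df$coverage < 0 | df$coverage > 1 | df$identity < 0 |
          df$identity > 1))
    stop2("coverage and identity must lie in [0, 1]")
  if (any(!df$strand %in% c("+", "-")))
    stop2("unknown strand symbol in alignment table")
  invisible(TRUE)
}

# "100:200,300:400" -> 2-column integer matrix (start, end)
parse_blocks <- function(blocks) {
  lapply(strsplit(as.character(blocks), ",", fixed = TRUE), function(b) {
    m <- do.call(rbind, strsplit(b, ":", fixed = TRUE))
    m <- matrix(as.integer(m), ncol = 2,
                dimnames = list(NULL, c("start", "end")))
    m[order(m[, 1]), , drop = FALSE]
  })
}

format_blocks <- function(block_list) {
  vapply(block_list, function(m) paste(paste0(m[, 1], ":", m[, 2]),
                                       collapse = ","), character(1))
}

# intron chain key of a block matrix ("" for single-exon)
chain_key <- function(m) {
  if (nrow(m) < 2L) return("")
  paste(m[-nrow(m), 2], m[-1, 1], sep = "-", collapse = ";")
}

#' Collapse aligned transcripts into unique isoforms
#'
#' Alignments below the coverage or identity thresholds are dropped (the
#' long-read collapse convention of requiring at least 80% query coverage and
#' 70% identity). Surviving multi-exon alignments with identical intron
#' chains whose 5' and 3' end points lie within the configured tolerances
#' merge into one isoform; single-exon alignments merge when they overlap
#' reciprocally beyond `single_exon_overlap`. Merging uses single-linkage
#' components of the pairwise mergeability relation, so the result does not
#' depend on input order. A merged isoform takes the outermost observed exon
#' boundaries and records its supporting alignment count. Merged isoforms are
#' then grouped into gene loci by span overlap on the same strand.
#'
#' @param alignments data.frame as produced by [read_aligned_transcripts()].
#' @param min_coverage,min_identity Retention thresholds (defaults 0.8, 0.7).
#' @param five_prime_tolerance,three_prime_tolerance Maximum end-point
#'   distance (nt) for merging identical intron chains; the 5' tolerance is
#'   loose (1000 nt) because long-read 5' ends are degradation-prone, the 3'
#'   tolerance tight (100 nt) because 3' ends are anchored at poly(A) sites.
#' @param single_exon_overlap Minimum reciprocal overlap for merging
#'   single-exon alignments (default 0.5).
#' @return An `annotation_set`; transcripts carry their supporting read count
#'   in `$transcripts$support` and gene ids of the form `PBG.<k>`.
#' @export
collapse_transcripts <- function(alignments, min_coverage = 0.8,
                                 min_identity = 0.7,
                                 five_prime_tolerance = 1000,
                                 three_prime_tolerance = 100,
                                 single_exon_overlap = 0.5) {
  if (is.null(alignments) || nrow(alignments) == 0L)
    return(annotation_set(data.frame(transcript_id = character(),
                                     gene_id = character(),
                                     chrom = character(), strand = character(),
                                     start = integer(), end = integer())))
  validate_alignments(alignments)
  keep <- alignments$coverage >= min_coverage &
    alignments$identity >= min_identity
  aln <- alignments[keep, , drop = FALSE]
  if (nrow(aln) == 0L)
    return(collapse_transcripts(aln[0, ]))
  blocks <- parse_blocks(aln$blocks)
  keys <- vapply(blocks, chain_key, character(1))
  group <- paste(aln$chrom, aln$strand, keys, sep = "|")

  iso_rows <- list()
  for (grp in unique(group)) {
    idx <- which(group == grp)
    b <- blocks[idx]
    starts <- vapply(b, function(m) m[1, 1], integer(1))
    ends <- vapply(b, function(m) m[nrow(m), 2], integer(1))
    single <- nrow(b[[1]]) == 1L && keys[idx[1]] == ""
    comp <- merge_components(starts, ends, strand = aln$strand[idx[1]],
                             single = single,
                             tol5 = five_prime_tolerance,
                             tol3 = three_prime_tolerance,
                             min_overlap = single_exon_overlap)
    for (cid in unique(comp)) {
      members <- idx[comp == cid]
      bm <- blocks[members]
      lo <- min(vapply(bm, function(m) m[1, 1], integer(1)))
      hi <- max(vapply(bm, function(m) m[nrow(m), 2], integer(1)))
      proto <- bm[[1]]
      proto[1, 1] <- lo
      proto[nrow(proto), 2] <- hi
      iso_rows[[length(iso_rows) + 1L]] <- list(
        chrom = aln$chrom[members[1]], strand = aln$strand[members[1]],
        blocks = proto, support = length(members),
        queries = aln$query_id[members])
    }
  }

  # group isoforms into loci by span overlap (same chrom and strand)
  spans <- GenomicRanges::GRanges(
    vapply(iso_rows, `[[`, character(1), "chrom"),
    IRanges::IRanges(
      vapply(iso_rows, function(r) r$blocks[1, 1] + 1L, integer(1)),
      vapply(iso_rows, function(r) r$blocks[nrow(r$blocks), 2], integer(1))),
    strand = vapply(iso_rows, `[[`, character(1), "strand"))
  hits <- GenomicRanges::findOverlaps(spans, spans)
  gidx <- connected_components(length(iso_rows),
                               S4Vectors::queryHits(hits),
                               S4Vectors::subjectHits(hits))
  gene_ids <- paste0("PBG.", match(gidx, unique(gidx)))

  exon_rows <- list()
  support <- integer()
  counter <- integer(length(unique(gene_ids)))
  names(counter) <- unique(gene_ids)
  for (i in seq_along(iso_rows)) {
    g <- gene_ids[i]
    counter[g] <- counter[g] + 1L
    tid <- paste0(g, ".", counter[g])
    m <- iso_rows[[i]]$blocks
    exon_rows[[i]] <- data.frame(
      transcript_id = tid, gene_id = g, chrom = iso_rows[[i]]$chrom,
      strand = iso_rows[[i]]$strand, start = m[, 1], end = m[, 2],
      stringsAsFactors = FALSE)
    support[tid] <- iso_rows[[i]]$support
  }
  annotation_set(do.call(rbind, exon_rows), support = support,
                 min_intron = 1, max_intron = .Machine$integer.max)
}

# single-linkage components of the pairwise mergeability relation
merge_components <- function(starts, ends, strand, single, tol5, tol3,
                             min_overlap) {
  n <- length(starts)
  if (n == 1L) return(1L)
  from <- integer(); to <- integer()
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      ok <- if (single) {
        ov <- min(ends[i], ends[j]) - max(starts[i], starts[j])
        len_i <- ends[i] - starts[i]; len_j <- ends[j] - starts[j]
        ov > 0 && ov / len_i >= min_overlap && ov / len_j >= min_overlap
      } else {
        d_start <- abs(starts[i] - starts[j])
        d_end <- abs(ends[i] - ends[j])
        if (strand == "+") d_start <= tol5 && d_end <= tol3
        else d_start <= tol3 && d_end <= tol5
      }
      if (ok) { from <- c(from, i); to <- c(to, j) }
    }
  }
  connected_components(n, from, to)
}

# union-find over n nodes with edge lists
connected_components <- function(n, from, to) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(from)) {
    a <- find(from[k]); b <- find(to[k])
    if (a != b) parent[b] <- a
  }
  vapply(seq_len(n), find, integer(1))
}
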