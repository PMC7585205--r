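#' Call a poly(A) tail at the 3' end of a sequence
#'
#' Applies the tail rule used for full-length read classification: within
#' the terminal window of up to 30 bases, the tail is the longest suffix
#' containing more than eight A bases and fewer than two non-A bases
#' (i.e. at least 9 A and at most 1 non-A). Returns `NULL` when no suffix
#' qualifies.
#'
#' @param sequence The 3' region of a read (character or `DNAString`).
#' @param window Terminal window size inspected (default 30 nt).
#' @param min_a Minimum A count in the tail (default 9, "more than eight").
#' @param max_non_a Maximum non-A count (default 1, "less than two").
#' @return A `tail_call` list with `tail_start` (1-based position in
#'   `sequence`), `tail_length` and `non_a_count`, or `NULL`.
#' @examples
#' call_tail(paste0("GATTACA", strrep("A", 25)))
#' call_tail("GGGGGGGGTTTT") # NULL
#' @export
call_tail <- function(sequence, window = 30, min_a = 9, max_non_a = 1) {
  s <- toupper(as.character(sequence))
  n <- nchar(s)
  if (n == 0L) stop2("sequence must be non-empty")
  lmax <- min(window, n)
  tail_chars <- strsplit(substr(s, n - lmax + 1L, n), "")[[1]]
  is_a <- rev(tail_chars) == "A"      # suffix of length L = first L entries
  cum_a <- cumsum(is_a)
  L <- seq_len(lmax)
  ok <- cum_a >= min_a & (L - cum_a) <= max_non_a
  if (!any(ok)) return(NULL)
  len <- max(L[ok])
  structure(list(tail_start = n - len + 1L, tail_length = len,
                 non_a_count = len - cum_a[len]),
            class = "tail_call")
}

#' Map a called tail to its genomic cleavage site
#'
#' The cleavage site is the genomic coordinate of the last aligned
#' transcribed base before the untemplated tail: the rightmost aligned base
#' for a + strand alignment, the leftmost for a - strand alignment
#' (transcript orientation).
#'
#' @param alignment One alignment row (as in [read_aligned_transcripts()]):
#'   fields `chrom`, `strand`, `blocks`.
#' @param tail A `tail_call` from [call_tail()]; required.
#' @return data.frame row: `chrom`, `strand`, `position` (0-based),
#'   `read_id`.
#' @export
map_cleavage_site <- function(alignment, tail) {
  if (is.null(tail)) stop2("no poly(A) tail was called for this read")
  if (is.null(alignment) || !all(c("chrom", "strand", "blocks") %in%
                                 names(alignment)))
    stop2("read is not aligned")
  b <- parse_blocks(alignment$blocks)[[1]]
  pos <- if (alignment$strand == "+") b[nrow(b), 2] - 1L else b[1, 1]
  data.frame(chrom = alignment$chrom, strand = alignment$strand,
             position = as.integer(pos),
             read_id = if ("query_id" %in% names(alignment))
               alignment$query_id else NA_character_,
             stringsAsFactors = FALSE)
}

#' Cluster poly(A) cleavage sites and assign them to genes
#'
#' Sites on the same chromosome and strand within `merge_window` of each
#' other (single-linkage along the sorted positions) merge into one site at
#' the support-weighted modal position (ties to the smaller coordinate),
#' summing read support. Each merged site is assigned to the nearest gene
#' whose span, extended by `merge_window`, contains it; unassigned sites are
#' kept with `gene_id = NA`.
#'
#' @param sites data.frame of cleavage sites: `chrom`, `strand`, `position`,
#'   optional `support` (default 1 per row).
#' @param annotation An `annotation_set` providing gene spans.
#' @param merge_window Clustering/assignment window in nt (default 24, the
#'   usual alternative-polyadenylation clustering scale).
#' @return List of class `polya_clusters`: `sites` (merged site table with
#'   `support` and `gene_id`), `per_gene` (site count per gene, zero rows
#'   included), and `stats` (`n_genes`, `genes_with_site`,
#'   `frac_genes_ge1`, `frac_genes_ge5`, `mean_sites_per_gene` over genes
#'   with at least one site, two decimals).
#' @export
cluster_sites <- function(sites, annotation, merge_window = 24) {
  stopifnot(inherits(annotation, "annotation_set"))
  if (!"support" %in% names(sites)) sites$support <- 1L
  merged <- list()
  if (nrow(sites) > 0) {
    sites <- sites[order(sites$chrom, sites$strand, sites$position), ,
                   drop = FALSE]
    grp <- paste(sites$chrom, sites$strand)
    for (g in unique(grp)) {
      s <- sites[grp == g, , drop = FALSE]
      brk <- c(0L, cumsum(diff(s$position) > merge_window))
      for (k in unique(brk)) {
        cl <- s[brk == k, , drop = FALSE]
        by_pos <- tapply(cl$support, cl$position, sum)
        best <- as.integer(names(by_pos)[which.max(by_pos)]) # first = smallest
        merged[[length(merged) + 1L]] <- data.frame(
          chrom = cl$chrom[1], strand = cl$strand[1], position = best,
          support = sum(cl$support), stringsAsFactors = FALSE)
      }
    }
  }
  msites <- if (length(merged)) do.call(rbind, merged) else
    data.frame(chrom = character(), strand = character(),
               position = integer(), support = integer())
  # gene assignment: nearest gene span (+/- window) containing the site
  g <- annotation$genes
  msites$gene_id <- NA_character_
  if (nrow(msites) > 0 && nrow(g) > 0) {
    for (i in seq_len(nrow(msites))) {
      cand <- g[g$chrom == msites$chrom[i] & g$strand == msites$strand[i] &
                  g$start - merge_window <= msites$position[i] &
                  g$end + merge_window > msites$position[i], , drop = FALSE]
      if (nrow(cand) == 0L) next
      d <- pmax(cand$start - msites$position[i],
                msites$position[i] - (cand$end - 1L), 0L)
      cand <- cand[order(d, cand$gene_id), , drop = FALSE]
      msites$gene_id[i] <- cand$gene_id[1]
    }
  }
  counts <- table(factor(msites$gene_id, levels = g$gene_id))
  per_gene <- data.frame(gene_id = names(counts),
                         n_sites = as.integer(counts),
                         stringsAsFactors = FALSE)
  with_site <- sum(per_gene$n_sites >= 1)
  stats <- list(
    n_genes = nrow(g), genes_with_site = with_site,
    genes_ge5 = sum(per_gene$n_sites >= 5),
    frac_genes_ge1 = if (nrow(g)) round_half_up(with_site / nrow(g), 4) else NA,
    frac_genes_ge5 = if (nrow(g))
      round_half_up(sum(per_gene$n_sites >= 5) / nrow(g), 4) else NA,
    mean_sites_per_gene = if (with_site)
      round_half_up(mean(per_gene$n_sites[per_gene$n_sites >= 1]), 2) else NA,
    n_unassigned = sum(is.na(msites$gene_id)))
  structure(list(sites = msites, per_gene = per_gene, stats = stats),
            class = "polya_clusters")
}

#' @export
print.polya_clusters <- function(x, ...) {
  cat("poly(A) sites:", nrow(x$sites), "merged sites;",
      x$stats$genes_with_site, "of", x$stats$n_genes, "genes with >= 1 site;",
      "mean", x$stats$mean_sites_per_gene, "sites per gene\n")
  invisible(x)
}

# Extract flanking windows in transcript orientation; NULL when truncated.
flank_window <- function(genome, chrom, strand, position, up, down) {
  seqs <- if (is.character(genome)) genome else as.character(genome)
  if (!chrom %in% names(seqs)) return(NULL)
  chrlen <- nchar(seqs[[chrom]])
  if (strand == "+") { lo <- position - up; hi <- position + down }
  else { lo <- position - down; hi <- position + up }
  if (lo < 0 || hi >= chrlen) return(NULL)
  s <- substr(seqs[[chrom]], lo + 1L, hi + 1L)
  if (strand == "-") s <- revcomp_chr(s)
  s
}

#' Nucleotide composition around poly(A) cleavage sites
#'
#' Computes per-offset A/C/G/U frequencies in windows of `flank` nt on
#' either side of each cleavage site (101 columns for the default 50),
#' taking sequences in transcript orientation (reverse-complemented for -
#' strand sites). Sites whose window would run past a chromosome edge are
#' excluded and counted.
#'
#' @param sites Site table (`chrom`, `strand`, `position`), e.g.
#'   `cluster_sites(...)$sites`.
#' @param genome Named character vector or `DNAStringSet` of chromosome
#'   sequences.
#' @param flank Flank size in nt (default 50).
#' @return `polya_profile`: list with `offsets` (-flank..flank), `freq`
#'   (4 x 101 matrix, rows A/C/G/U; columns sum to 1), `n_sites`,
#'   `n_excluded`.
#' @export
nucleotide_profile <- function(sites, genome, flank = 50) {
  wins <- character()
  excluded <- 0L
  for (i in seq_len(nrow(sites))) {
    w <- flank_window(genome, sites$chrom[i], sites$strand[i],
                      sites$position[i], flank, flank)
    if (is.null(w)) excluded <- excluded + 1L else wins <- c(wins, w)
  }
  if (length(wins) == 0L) stop2("no usable sites (all truncated or empty)")
  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(wins),
                                    as.prob = TRUE, baseOnly = TRUE)
  freq <- cm[c("A", "C", "G", "T"), , drop = FALSE]
  rownames(freq) <- c("A", "C", "G", "U")
  colnames(freq) <- as.character(seq(-flank, flank))
  structure(list(offsets = seq(-flank, flank), freq = freq,
                 n_sites = length(wins), n_excluded = excluded),
            class = "polya_profile")
}

#' @export
print.polya_profile <- function(x, ...) {
  cat("poly(A) flanking profile over", x$n_sites, "sites (",
      x$n_excluded, "excluded at chromosome edges)\n")
  up <- x$offsets < 0
  cat("  mean upstream U:", round_half_up(mean(x$freq["U", up]), 3),
      " mean downstream A:", round_half_up(mean(x$freq["A", !up]), 3), "\n")
  invisible(x)
}

#' Write a flanking profile as TSV (offset x nucleotide)
#'
#' @param profile A `polya_profile`.
#' @param path Output path.
#' @export
write_profile <- function(profile, path) {
  df <- data.frame(offset = profile$offsets, t(profile$freq))
  names(df) <- c("offset", "A", "C", "G", "U")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Count polyadenylation motifs upstream of cleavage sites
#'
#' Exact occurrences of the given RNA motifs (U matched as T) in the
#' `upstream_window` nt 5' of each cleavage site, in transcript
#' orientation. Overlapping occurrences count.
#'
#' @inheritParams nucleotide_profile
#' @param motifs RNA-alphabet motifs (default the canonical AAUAAA
#'   polyadenylation signal and the UGUA upstream element).
#' @param upstream_window Window size in nt (default 50).
#' @return List of class `motif_counts`: per motif, `occurrences` (total),
#'   `sites_with_hit`, `histogram` (named vector over offsets of the motif
#'   start relative to the cleavage site, -window .. -motif length);
#'   plus `n_sites` scanned.
#' @export
count_motifs <- function(sites, genome, motifs = c("AAUAAA", "UGUA"),
                         upstream_window = 50) {
  dna <- chartr("Uu", "Tt", toupper(motifs))
  res <- lapply(seq_along(motifs), function(k) {
    occ <- 0L; with_hit <- 0L
    hist <- integer(upstream_window)
    names(hist) <- as.character(seq(-upstream_window, -1L))
    for (i in seq_len(nrow(sites))) {
      w <- flank_window(genome, sites$chrom[i], sites$strand[i],
                        sites$position[i], upstream_window, 0)
      if (is.null(w)) next
      w <- substr(w, 1L, upstream_window)  # upstream only, offset -W..-1
      m <- gregexpr(paste0("(?=", dna[k], ")"), w, perl = TRUE)[[1]]
      if (m[1] == -1L) next
      occ <- occ + length(m)
      with_hit <- with_hit + 1L
      off <- m - upstream_window - 1L
      for (o in off) hist[as.character(o)] <- hist[as.character(o)] + 1L
    }
    list(motif = motifs[k], occurrences = occ, sites_with_hit = with_hit,
         histogram = hist)
  })
  names(res) <- motifs
  structure(c(res, list(n_sites = nrow(sites))), class = "motif_counts")
}

#' Write cleavage sites as BED6
#'
#' Each site becomes a 1-bp interval; read support goes in the score column.
#'
#' @param sites Site table with `chrom`, `strand`, `position`, `support`.
#' @param path Output path.
#' @export
write_sites_bed <- function(sites, path) {
  name <- if ("gene_id" %in% names(sites))
    ifelse(is.na(sites$gene_id), ".", sites$gene_id) else "."
  bed <- data.frame(sites$chrom, sites$position, sites$position + 1L,
                    name, sites$support, sites$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
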