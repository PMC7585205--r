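#' Build an annotation set from an exon table
#'
#' The central container of the package: a set of gene models, each a set of
#' transcript isoforms, each an ordered chain of exons. Coordinates are
#' 0-based half-open internally; GTF/GFF3 input and output convert from and
#' to the 1-based inclusive convention of those formats.
#'
#' @param exons data.frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand`, `start`, `end` (0-based half-open). One row per exon.
#' @param support Optional named vector of supporting read counts per
#'   transcript id.
#' @param min_intron,max_intron Permitted intron length range in nt. Introns
#'   outside the range indicate a broken transcript model and are an error.
#' @return An object of class `annotation_set` with components `exons`
#'   (sorted exon table), `transcripts` and `genes` (per-feature tables).
#' @examples
#' ex <- data.frame(transcript_id = "t1", gene_id = "g1", chrom = "chr1",
#'                  strand = "+", start = c(0, 200), end = c(100, 300))
#' ann <- annotation_set(ex)
#' introns(ann)
#' @export
annotation_set <- function(exons, support = NULL, min_intron = 20,
                           max_intron = 20000) {
  required <- c("transcript_id", "gene_id", "chrom", "strand", "start", "end")
  if (!is.data.frame(exons)) stop2("`exons` must be a data.frame")
  missing_cols <- setdiff(required, names(exons))
  if (length(missing_cols))
    stop2("`exons` lacks columns: ", comma(missing_cols))
  exons <- exons[required]
  if (nrow(exons) == 0L) {
    empty <- exons
    out <- structure(
      list(exons = empty,
           transcripts = data.frame(transcript_id = character(),
                                    gene_id = character(), chrom = character(),
                                    strand = character(), start = integer(),
                                    end = integer(), n_exons = integer(),
                                    support = integer()),
           genes = data.frame(gene_id = character(), chrom = character(),
                              strand = character(), start = integer(),
                              end = integer(), n_transcripts = integer()),
           min_intron = min_intron, max_intron = max_intron),
      class = "annotation_set")
    return(out)
  }
  exons$transcript_id <- as.character(exons$transcript_id)
  exons$gene_id <- as.character(exons$gene_id)
  exons$chrom <- as.character(exons$chrom)
  exons$strand <- as.character(exons$strand)
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)

  bad_strand <- setdiff(unique(exons$strand), c("+", "-"))
  if (length(bad_strand))
    stop2("unknown strand symbol: ", comma(bad_strand))
  if (any(exons$chrom == "" | is.na(exons$chrom)))
    stop2("empty chromosome name in exon table")
  bad_len <- exons$start >= exons$end
  if (any(bad_len))
    stop2("exon with start >= end in transcript(s): ",
          comma(unique(exons$transcript_id[bad_len])))

  exons <- exons[order(exons$transcript_id, exons$start, exons$end), ,
                 drop = FALSE]
  rownames(exons) <- NULL

  # per-transcript structural checks
  by_tx <- split(seq_len(nrow(exons)), exons$transcript_id)
  tx_rows <- lapply(names(by_tx), function(tid) {
    idx <- by_tx[[tid]]
    e <- exons[idx, , drop = FALSE]
    if (length(unique(e$chrom)) > 1L || length(unique(e$strand)) > 1L ||
        length(unique(e$gene_id)) > 1L)
      stop2("transcript ", tid, " mixes chrom/strand/gene assignments")
    if (nrow(e) > 1L) {
      if (any(e$start[-1] < e$end[-nrow(e)]))
        stop2("overlapping exons in transcript ", tid)
      ilen <- e$start[-1] - e$end[-nrow(e)]
      if (any(ilen < min_intron))
        stop2("intron shorter than ", min_intron, " nt in transcript ", tid)
      if (any(ilen > max_intron))
        stop2("intron longer than ", max_intron, " nt in transcript ", tid)
    }
    data.frame(transcript_id = tid, gene_id = e$gene_id[1], chrom = e$chrom[1],
               strand = e$strand[1], start = min(e$start), end = max(e$end),
               n_exons = nrow(e), stringsAsFactors = FALSE)
  })
  transcripts <- do.call(rbind, tx_rows)
  rownames(transcripts) <- NULL
  transcripts$support <- if (is.null(support)) NA_integer_ else
    as.integer(support[transcripts$transcript_id])

  by_gene <- split(transcripts, transcripts$gene_id)
  genes <- do.call(rbind, lapply(by_gene, function(g) {
    if (length(unique(g$chrom)) > 1L || length(unique(g$strand)) > 1L)
      stop2("gene ", g$gene_id[1], " has transcripts on multiple ",
            "chromosomes or strands")
    data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1],
               strand = g$strand[1], start = min(g$start), end = max(g$end),
               n_transcripts = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(genes) <- NULL

  structure(list(exons = exons, transcripts = transcripts, genes = genes,
                 min_intron = min_intron, max_intron = max_intron),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set:", nrow(x$genes), "genes,", nrow(x$transcripts),
      "transcripts,", nrow(x$exons), "exons\n")
  multi <- sum(x$transcripts$n_exons >= 2)
  if (nrow(x$transcripts) > 0)
    cat("  multi-exon transcripts:", multi, "(",
        percentage(multi, nrow(x$transcripts)), "%)\n")
  invisible(x)
}

#' Derive intron chains
#'
#' Introns are the 0-based half-open gaps between consecutive exons of a
#' transcript; a transcript with n exons has n - 1 introns.
#'
#' @param x An `annotation_set`.
#' @param transcript_id Optional transcript ids to restrict to.
#' @return data.frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand`, `start`, `end`, ordered by genomic start within transcript.
#' @export
introns <- function(x, transcript_id = NULL) {
  stopifnot(inherits(x, "annotation_set"))
  e <- x$exons
  if (!is.null(transcript_id)) e <- e[e$transcript_id %in% transcript_id, ]
  if (nrow(e) == 0L)
    return(data.frame(transcript_id = character(), gene_id = character(),
                      chrom = character(), strand = character(),
                      start = integer(), end = integer()))
  parts <- lapply(split(e, e$transcript_id), function(t) {
    if (nrow(t) < 2L) return(NULL)
    data.frame(transcript_id = t$transcript_id[1], gene_id = t$gene_id[1],
               chrom = t$chrom[1], strand = t$strand[1],
               start = t$end[-nrow(t)], end = t$start[-1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  if (is.null(out)) out <- data.frame(transcript_id = character(),
                                      gene_id = character(),
                                      chrom = character(), strand = character(),
                                      start = integer(), end = integer())
  rownames(out) <- NULL
  out
}

#' Extract one transcript model
#'
#' @param x An `annotation_set`.
#' @param transcript_id A single transcript id present in `x`.
#' @return A `transcript_model` list: ids, chrom, strand and the exon table.
#' @export
transcript_model <- function(x, transcript_id) {
  stopifnot(inherits(x, "annotation_set"), length(transcript_id) == 1L)
  e <- x$exons[x$exons$transcript_id == transcript_id, , drop = FALSE]
  if (nrow(e) == 0L) stop2("unknown transcript: ", transcript_id)
  structure(list(transcript_id = transcript_id, gene_id = e$gene_id[1],
                 chrom = e$chrom[1], strand = e$strand[1],
                 exons = data.frame(start = e$start, end = e$end)),
            class = "transcript_model")
}

# GRanges views of an annotation set (internal).
gene_ranges <- function(x) {
  g <- x$genes
  GenomicRanges::GRanges(g$chrom,
                         IRanges::IRanges(g$start + 1L, g$end),
                         strand = g$strand, gene_id = g$gene_id)
}

exon_ranges <- function(x) {
  e <- x$exons
  GenomicRanges::GRanges(e$chrom, IRanges::IRanges(e$start + 1L, e$end),
                         strand = e$strand, transcript_id = e$transcript_id,
                         gene_id = e$gene_id)
}

# Pre-scan a GTF/GFF file for malformed lines so errors carry line numbers.
scan_annotation_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  bad <- character()
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8) {
      bad <- c(bad, paste0("line ", i, ": expected >= 8 tab-separated fields"))
      next
    }
    if (is.na(suppressWarnings(as.integer(f[4]))) ||
        is.na(suppressWarnings(as.integer(f[5]))))
      bad <- c(bad, paste0("line ", i, ": non-numeric coordinates"))
    if (!f[7] %in% c("+", "-", ".", "?"))
      bad <- c(bad, paste0("line ", i, ": unknown strand symbol '", f[7], "'"))
  }
  if (length(bad))
    stop2("invalid annotation records in ", path, ":\n  ",
          paste(bad, collapse = "\n  "))
  invisible(TRUE)
}

#' Read a GTF or GFF3 annotation
#'
#' Exon features are read (via rtracklayer) and assembled into transcript and
#' gene models with derived intron chains. GTF records must carry `gene_id`
#' and `transcript_id` attributes; GFF3 exons must name their transcript in
#' `Parent`, and transcript features their gene. Malformed lines are reported
#' with their line numbers; structurally invalid transcripts (overlapping
#' exons, unknown strand) raise an error naming the transcript.
#'
#' @param path File path; format is taken from the extension unless given.
#' @param format `"gtf"` or `"gff3"`.
#' @inheritParams annotation_set
#' @return An `annotation_set`.
#' @export
read_annotation <- function(path, format = c("auto", "gtf", "gff3"),
                            min_intron = 20, max_intron = 20000) {
  format <- match.arg(format)
  if (!file.exists(path)) stop2("annotation file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "gtf"
  }
  scan_annotation_lines(path)
  gr <- rtracklayer::import(path, format = format)
  md <- S4Vectors::mcols(gr)
  is_exon <- !is.na(md$type) & tolower(as.character(md$type)) == "exon"
  ex <- gr[is_exon]
  if (length(ex) == 0L) stop2("no exon records in ", path)
  exd <- S4Vectors::mcols(ex)
  if (format == "gtf") {
    tid <- as.character(exd$transcript_id)
    gid <- as.character(exd$gene_id)
  } else {
    parent <- as.character(S4Vectors::unstrsplit(exd$Parent, ","))
    tid <- parent
    # transcript-level features map transcript -> gene
    feat <- gr[!is_exon]
    fd <- S4Vectors::mcols(feat)
    has_id <- !is.na(fd$ID)
    tx2gene <- setNames(
      as.character(S4Vectors::unstrsplit(fd$Parent[has_id], ",")),
      as.character(fd$ID[has_id]))
    gid <- unname(tx2gene[tid])
    gid[is.na(gid) | gid == ""] <- tid[is.na(gid) | gid == ""]
  }
  if (any(is.na(tid) | tid == ""))
    stop2("exon records without a transcript identifier in ", path)
  if (any(is.na(gid) | gid == ""))
    stop2("exon records without a gene identifier in ", path)
  exons <- data.frame(transcript_id = tid, gene_id = gid,
                      chrom = as.character(GenomicRanges::seqnames(ex)),
                      strand = as.character(GenomicRanges::strand(ex)),
                      start = GenomicRanges::start(ex) - 1L,
                      end = GenomicRanges::end(ex),
                      stringsAsFactors = FALSE)
  bad_strand <- exons$strand %in% c("*", ".")
  if (any(bad_strand))
    stop2("unknown strand symbol for transcript(s): ",
          comma(unique(exons$transcript_id[bad_strand])))
  annotation_set(exons, min_intron = min_intron, max_intron = max_intron)
}

#' Write an annotation set as GTF or GFF3
#'
#' Writes one exon record per exon (plus gene/mRNA features for GFF3),
#' converting internal 0-based half-open coordinates to the formats'
#' 1-based inclusive convention. Re-reading a written file reproduces the
#' exon coordinates exactly.
#'
#' @param x An `annotation_set`.
#' @param path Output path.
#' @param format `"gtf"` or `"gff3"`.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(x, path, format = c("gtf", "gff3")) {
  stopifnot(inherits(x, "annotation_set"))
  format <- match.arg(format)
  e <- x$exons
  if (format == "gtf") {
    gr <- GenomicRanges::GRanges(e$chrom,
                                 IRanges::IRanges(e$start + 1L, e$end),
                                 strand = e$strand)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      source = "flsplice", type = "exon",
      gene_id = e$gene_id, transcript_id = e$transcript_id)
    rtracklayer::export(gr, path, format = "gtf")
  } else {
    tx <- x$transcripts
    g <- x$genes
    rows <- c(
      GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start + 1L, g$end),
                             strand = g$strand, type = "gene",
                             ID = g$gene_id, Parent = NA_character_),
      GenomicRanges::GRanges(tx$chrom, IRanges::IRanges(tx$start + 1L, tx$end),
                             strand = tx$strand, type = "mRNA",
                             ID = tx$transcript_id, Parent = tx$gene_id),
      GenomicRanges::GRanges(e$chrom, IRanges::IRanges(e$start + 1L, e$end),
                             strand = e$strand, type = "exon",
                             ID = NA_character_, Parent = e$transcript_id))
    rtracklayer::export(rows, path, format = "gff3")
  }
  # drop volatile header comments (date stamps) for reproducible output
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^##(date|source-version)", lines)
  writeLines(lines[keep], path)
  invisible(path)
}
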