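#' @name as_events
#' @title Alternative-splicing event classification
#'
#' @description
#' Two isoforms of a gene are compared through their splice-site chains
#' within the genomic span they share. Splice sites strictly inside the
#' shared span that occur in both chains (same position and same role,
#' donor or acceptor) are anchors; each maximal run of differing sites
#' between consecutive anchors (or the span boundaries) is a "bubble" and
#' yields one event. The bubble's site pattern, read in transcript
#' orientation, is matched against the five canonical templates:
#'
#' * intron retention (IR, code `1^2-,0`): one chain has a complete intron
#'   (donor then acceptor) where the other is exonic throughout;
#' * exon skipping (ES, code `1-2^,0`): one chain has an extra exon
#'   (acceptor then donor) inside an intron of the other;
#' * alternative acceptor (AA, code `1-,2-`): a shared donor spliced to two
#'   different acceptors;
#' * alternative donor (AD, code `1^,2^`): two different donors spliced to a
#'   shared acceptor;
#' * mutually exclusive exons (MX, code `1-2^,3-4^`): two non-overlapping
#'   exon alternatives between shared flanks, each spliced to both.
#'
#' Bubbles matching none of the templates are typed `other`, never forced
#' into one of the five. Differences confined to terminal exon extents
#' (alternative first/last exons, TSS/TES shifts) produce no sites inside
#' the shared span and are not events. The code strings follow the
#' AStalavista site-code notation; the typographic dashes sometimes seen in
#' print (`1–2^,0`) are emitted as ASCII hyphens.
NULL

event_codes <- c(IR = "1^2-,0", ES = "1-2^,0", AA = "1-,2-", AD = "1^,2^",
                 MX = "1-2^,3-4^", other = "complex")

# splice sites of a transcript model: 0-based boundary positions with roles.
# In transcript orientation a donor is the 5' boundary of an intron and an
# acceptor its 3' boundary; genomically that flips on the - strand.
splice_sites <- function(tm) {
  e <- tm$exons
  if (nrow(e) < 2L)
    return(data.frame(pos = integer(), kind = character()))
  istart <- e$end[-nrow(e)]
  iend <- e$start[-1]
  if (tm$strand == "+") {
    data.frame(pos = c(istart, iend),
               kind = rep(c("donor", "acceptor"), each = length(istart)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(pos = c(istart, iend),
               kind = rep(c("acceptor", "donor"), each = length(istart)),
               stringsAsFactors = FALSE)
  }
}

# pattern of a site set in transcript orientation, e.g. "donor,acceptor"
site_pattern <- function(sites, strand) {
  if (nrow(sites) == 0L) return("")
  ord <- order(if (strand == "+") sites$pos else -sites$pos)
  paste(sites$kind[ord], collapse = ",")
}

# does the transcript run exonically (or intronically) across [a, b)?
covers_exonically <- function(tm, a, b) {
  any(tm$exons$start <= a & tm$exons$end >= b)
}
covers_intronically <- function(tm, a, b) {
  e <- tm$exons
  if (nrow(e) < 2L) return(FALSE)
  any(e$end[-nrow(e)] <= a & e$start[-1] >= b)
}

classify_bubble <- function(v1, v2, t1, t2, a, b, strand) {
  p1 <- site_pattern(v1, strand)
  p2 <- site_pattern(v2, strand)
  # a transcript with no sites in the bubble is either exonic or intronic
  # across it; IR and ES demand one or the other, so check the geometry
  if (p1 == "" || p2 == "") {
    full <- if (p1 == "") list(p = p2, tm = t1) else list(p = p1, tm = t2)
    if (full$p == "donor,acceptor" && covers_exonically(full$tm, a, b))
      return("IR")
    if (full$p == "acceptor,donor" && covers_intronically(full$tm, a, b))
      return("ES")
    return("other")
  }
  if (p1 == "acceptor" && p2 == "acceptor") return("AA")
  if (p1 == "donor" && p2 == "donor") return("AD")
  if (p1 == "acceptor,donor" && p2 == "acceptor,donor") {
    ex1 <- range(v1$pos); ex2 <- range(v2$pos)
    if (ex1[2] <= ex2[1] || ex2[2] <= ex1[1]) return("MX")
  }
  "other"
}

#' Classify splicing events between two isoforms
#'
#' @param t1,t2 `transcript_model` objects (see [transcript_model()]) of the
#'   same gene, chromosome and strand.
#' @return data.frame with one row per event: `gene_id`, `event_type`,
#'   `code`, `flank_left`, `flank_right` (genomic 0-based anchor
#'   positions), `variant_sites` (semicolon-separated `pos:kind`),
#'   `transcript_1`, `transcript_2`.
#' @seealso [as_events] for the classification rules.
#' @export
pairwise_events <- function(t1, t2) {
  stopifnot(inherits(t1, "transcript_model"), inherits(t2, "transcript_model"))
  if (t1$gene_id != t2$gene_id || t1$chrom != t2$chrom ||
      t1$strand != t2$strand)
    stop2("transcripts must share gene, chromosome and strand")
  empty <- data.frame(gene_id = character(), event_type = character(),
                      code = character(), flank_left = integer(),
                      flank_right = integer(), variant_sites = character(),
                      transcript_1 = character(), transcript_2 = character())
  span_lo <- max(min(t1$exons$start), min(t2$exons$start))
  span_hi <- min(max(t1$exons$end), max(t2$exons$end))
  if (span_lo >= span_hi) return(empty)
  s1 <- splice_sites(t1)
  s2 <- splice_sites(t2)
  s1 <- s1[s1$pos > span_lo & s1$pos < span_hi, , drop = FALSE]
  s2 <- s2[s2$pos > span_lo & s2$pos < span_hi, , drop = FALSE]
  k1 <- paste(s1$pos, s1$kind)
  k2 <- paste(s2$pos, s2$kind)
  common <- intersect(k1, k2)
  anchors <- sort(c(span_lo, s1$pos[k1 %in% common], span_hi))
  v1 <- s1[!k1 %in% common, , drop = FALSE]
  v2 <- s2[!k2 %in% common, , drop = FALSE]
  rows <- list()
  for (i in seq_len(length(anchors) - 1L)) {
    a <- anchors[i]; b <- anchors[i + 1L]
    b1 <- v1[v1$pos > a & v1$pos < b, , drop = FALSE]
    b2 <- v2[v2$pos > a & v2$pos < b, , drop = FALSE]
    if (nrow(b1) + nrow(b2) == 0L) next
    type <- classify_bubble(b1, b2, t1, t2, a, b, t1$strand)
    allv <- rbind(b1, b2)
    allv <- allv[order(allv$pos, allv$kind), , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = t1$gene_id, event_type = type,
      code = unname(event_codes[type]), flank_left = a, flank_right = b,
      variant_sites = paste(paste0(allv$pos, ":", allv$kind),
                            collapse = ";"),
      transcript_1 = t1$transcript_id, transcript_2 = t2$transcript_id,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty)
  do.call(rbind, rows)
}

#' Classify all splicing events of one gene
#'
#' Runs [pairwise_events()] over every transcript pair of a gene and
#' deduplicates events by their (type, flanks, variant sites) signature, so
#' a bubble shared by several pairs counts once. Single-transcript genes
#' contribute nothing.
#'
#' @param annotation An `annotation_set`.
#' @param gene_id One gene id in `annotation`.
#' @return Event data.frame as in [pairwise_events()] (deduplicated;
#'   `transcript_1`/`transcript_2` record the first pair exhibiting each
#'   event).
#' @export
gene_events <- function(annotation, gene_id) {
  stopifnot(inherits(annotation, "annotation_set"))
  tids <- annotation$transcripts$transcript_id[
    annotation$transcripts$gene_id == gene_id]
  if (length(tids) < 2L)
    return(pairwise_events_empty())
  tms <- lapply(tids, function(t) transcript_model(annotation, t))
  rows <- list()
  for (i in seq_len(length(tms) - 1L)) {
    for (j in seq(i + 1L, length(tms))) {
      ev <- pairwise_events(tms[[i]], tms[[j]])
      if (nrow(ev)) rows[[length(rows) + 1L]] <- ev
    }
  }
  if (length(rows) == 0L) return(pairwise_events_empty())
  ev <- do.call(rbind, rows)
  sig <- paste(ev$event_type, ev$flank_left, ev$flank_right, ev$variant_sites)
  ev <- ev[!duplicated(sig), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

pairwise_events_empty <- function() {
  data.frame(gene_id = character(), event_type = character(),
             code = character(), flank_left = integer(),
             flank_right = integer(), variant_sites = character(),
             transcript_1 = character(), transcript_2 = character())
}

#' Event summary over an annotation set
#'
#' Detects events in every gene and tabulates counts and percentages per
#' event type, for events (denominator: all events, `other` included) and
#' for genes (a gene counts for a type when it has at least one event of
#' that type; denominator: all genes with at least one event).
#'
#' @param annotation An `annotation_set`.
#' @return `event_summary` list: `events` (full event table), `by_type`
#'   (type, n_events, pct_events, n_genes, pct_genes), `total_events`,
#'   `total_as_genes`.
#' @export
summarize_events <- function(annotation) {
  stopifnot(inherits(annotation, "annotation_set"))
  evs <- lapply(annotation$genes$gene_id,
                function(g) gene_events(annotation, g))
  ev <- do.call(rbind, evs)
  if (is.null(ev)) ev <- pairwise_events_empty()
  event_summary(ev)
}

#' Build an event summary from an event table
#'
#' @param events Event data.frame (as from [gene_events()]).
#' @return An `event_summary` (see [summarize_events()]).
#' @export
event_summary <- function(events) {
  types <- c("IR", "ES", "AA", "AD", "MX", "other")
  total <- nrow(events)
  as_genes <- unique(events$gene_id)
  by_type <- do.call(rbind, lapply(types, function(ty) {
    sub <- events[events$event_type == ty, , drop = FALSE]
    data.frame(type = ty, n_events = nrow(sub),
               pct_events = if (total) percentage(nrow(sub), total) else NA,
               n_genes = length(unique(sub$gene_id)),
               pct_genes = if (length(as_genes))
                 percentage(length(unique(sub$gene_id)), length(as_genes))
               else NA,
               stringsAsFactors = FALSE)
  }))
  structure(list(events = events, by_type = by_type, total_events = total,
                 total_as_genes = length(as_genes)),
            class = "event_summary")
}

#' @export
print.event_summary <- function(x, ...) {
  cat("AS events:", x$total_events, "events in", x$total_as_genes, "genes\n")
  print.data.frame(x$by_type, row.names = FALSE)
  invisible(x)
}

#' Write an event table and summary
#'
#' @param x An `event_summary`.
#' @param events_path,summary_path Output TSV paths (either may be `NULL`).
#' @export
write_events <- function(x, events_path = NULL, summary_path = NULL) {
  stopifnot(inherits(x, "event_summary"))
  if (!is.null(events_path))
    write.table(x$events, events_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(summary_path))
    write.table(x$by_type, summary_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(x)
}

#' Compare per-gene isoform counts between two annotations
#'
#' For every gene with at least one isoform in both sets, computes
#' `log2(n_query / n_reference)` and assigns the gene to group I
#' (ratio <= -1: fewer isoforms in the query), group II (between -1 and 1:
#' comparable) or group III (ratio >= 1: more isoforms in the query).
#'
#' @param query,reference `annotation_set` objects sharing gene ids.
#' @return data.frame: `gene_id`, `n_isoforms_query`,
#'   `n_isoforms_reference`, `log2_ratio`, `group`.
#' @export
isoform_count_ratio <- function(query, reference) {
  stopifnot(inherits(query, "annotation_set"),
            inherits(reference, "annotation_set"))
  q <- query$genes[, c("gene_id", "n_transcripts")]
  r <- reference$genes[, c("gene_id", "n_transcripts")]
  m <- merge(q, r, by = "gene_id", suffixes = c("_query", "_reference"))
  if (nrow(m) == 0L)
    return(data.frame(gene_id = character(), n_isoforms_query = integer(),
                      n_isoforms_reference = integer(),
                      log2_ratio = numeric(), group = character()))
  ratio <- log2(m$n_transcripts_query / m$n_transcripts_reference)
  data.frame(gene_id = m$gene_id,
             n_isoforms_query = m$n_transcripts_query,
             n_isoforms_reference = m$n_transcripts_reference,
             log2_ratio = ratio,
             group = isoform_ratio_group(ratio),
             stringsAsFactors = FALSE)
}

#' Assign log2 isoform-count ratios to groups I / II / III
#'
#' @param log2_ratio Numeric vector of log2 count ratios.
#' @return Character vector: `"I"` (<= -1), `"II"` (-1 to 1, exclusive),
#'   `"III"` (>= 1).
#' @export
isoform_ratio_group <- function(log2_ratio) {
  ifelse(log2_ratio <= -1, "I", ifelse(log2_ratio >= 1, "III", "II"))
}
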