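# Independent oracles used to cross-check the implementation.

# --- AS-event oracle: exon-geometry template matcher -------------------
# Classifies each bubble from the clipped exon segments of the two
# transcripts (interval arithmetic), not from splice-site role sequences,
# so it exercises a different route than the package classifier.

oracle_clip <- function(exons, a, b) {
  s <- pmax(exons$start, a)
  e <- pmin(exons$end, b)
  keep <- s < e
  cbind(start = s[keep], end = e[keep])
}

oracle_boundaries <- function(tm) {
  e <- tm$exons
  if (nrow(e) < 2) return(data.frame(pos = integer(), dir = character()))
  # transitions at internal boundaries, genomic left-to-right
  data.frame(pos = c(e$end[-nrow(e)], e$start[-1]),
             dir = rep(c("exon_to_intron", "intron_to_exon"),
                       each = nrow(e) - 1), stringsAsFactors = FALSE)
}

oracle_classify_gap <- function(t1, t2, a, b) {
  # an event needs at least one splice boundary strictly inside the gap;
  # differences driven only by boundaries at the flanks are terminal
  bd <- c(oracle_boundaries(t1)$pos, oracle_boundaries(t2)$pos)
  if (!any(bd > a & bd < b)) return(NULL)
  s1 <- oracle_clip(t1$exons, a, b)
  s2 <- oracle_clip(t2$exons, a, b)
  if (identical(s1, s2)) return(NULL)
  strand <- t1$strand
  full <- function(s) nrow(s) == 1 && s[1, 1] == a && s[1, 2] == b
  two_bridging <- function(s) nrow(s) == 2 && s[1, 1] == a && s[2, 2] == b &&
    s[1, 2] < s[2, 1]
  inside <- function(s) nrow(s) == 1 && s[1, 1] > a && s[1, 2] < b
  right_only <- function(s) nrow(s) == 1 && s[1, 1] > a && s[1, 2] == b
  left_only <- function(s) nrow(s) == 1 && s[1, 1] == a && s[1, 2] < b
  if ((full(s1) && two_bridging(s2)) || (full(s2) && two_bridging(s1)))
    return("IR")
  if ((nrow(s1) == 0 && inside(s2)) || (nrow(s2) == 0 && inside(s1)))
    return("ES")
  if (right_only(s1) && right_only(s2) && s1[1, 1] != s2[1, 1])
    return(if (strand == "+") "AA" else "AD")
  if (left_only(s1) && left_only(s2) && s1[1, 2] != s2[1, 2])
    return(if (strand == "+") "AD" else "AA")
  if (inside(s1) && inside(s2)) {
    if (s1[1, 2] <= s2[1, 1] || s2[1, 2] <= s1[1, 1]) return("MX")
  }
  "other"
}

# sorted event-type multiset for a transcript pair
oracle_pair_events <- function(t1, t2) {
  a0 <- max(min(t1$exons$start), min(t2$exons$start))
  b0 <- min(max(t1$exons$end), max(t2$exons$end))
  if (a0 >= b0) return(character())
  bd1 <- oracle_boundaries(t1)
  bd2 <- oracle_boundaries(t2)
  bd1 <- bd1[bd1$pos > a0 & bd1$pos < b0, , drop = FALSE]
  bd2 <- bd2[bd2$pos > a0 & bd2$pos < b0, , drop = FALSE]
  shared <- intersect(paste(bd1$pos, bd1$dir), paste(bd2$pos, bd2$dir))
  anchors <- sort(unique(c(a0, as.integer(sub(" .*", "", shared)), b0)))
  types <- character()
  for (i in seq_len(length(anchors) - 1)) {
    ty <- oracle_classify_gap(t1, t2, anchors[i], anchors[i + 1])
    if (!is.null(ty)) types <- c(types, ty)
  }
  sort(types)
}

# per-pair event keys (type + flanks + variant-site signature), for
# cross-checking gene-level deduplication
oracle_pair_keys <- function(t1, t2) {
  a0 <- max(min(t1$exons$start), min(t2$exons$start))
  b0 <- min(max(t1$exons$end), max(t2$exons$end))
  empty <- data.frame(type = character(), a = integer(), b = integer(),
                      vkey = character())
  if (a0 >= b0) return(empty)
  strand <- t1$strand
  to_kind <- function(dir)
    if (strand == "+") ifelse(dir == "exon_to_intron", "donor", "acceptor")
  else ifelse(dir == "exon_to_intron", "acceptor", "donor")
  bd1 <- oracle_boundaries(t1); bd1 <- bd1[bd1$pos > a0 & bd1$pos < b0, ]
  bd2 <- oracle_boundaries(t2); bd2 <- bd2[bd2$pos > a0 & bd2$pos < b0, ]
  k1 <- paste(bd1$pos, bd1$dir); k2 <- paste(bd2$pos, bd2$dir)
  shared <- intersect(k1, k2)
  anchors <- sort(unique(c(a0, bd1$pos[k1 %in% shared], b0)))
  rows <- empty
  for (i in seq_len(length(anchors) - 1)) {
    a <- anchors[i]; b <- anchors[i + 1]
    ty <- oracle_classify_gap(t1, t2, a, b)
    if (is.null(ty)) next
    v <- rbind(bd1[!k1 %in% shared & bd1$pos > a & bd1$pos < b, ],
               bd2[!k2 %in% shared & bd2$pos > a & bd2$pos < b, ])
    v$kind <- to_kind(v$dir)
    v <- v[order(v$pos, v$kind), ]
    rows <- rbind(rows, data.frame(
      type = ty, a = a, b = b,
      vkey = paste(paste0(v$pos, ":", v$kind), collapse = ";")))
  }
  rows
}

# --- collapse oracle: naive transitive closure -------------------------
# Same mergeability definition as documented, computed by O(n^3) Warshall
# closure over the pairwise relation; returns a canonical multiset of
# merged isoform descriptors "chrom|strand|chain|start|end|support".

oracle_collapse <- function(aln, min_coverage = 0.8, min_identity = 0.7,
                            tol5 = 1000, tol3 = 100, min_overlap = 0.5) {
  keep <- aln$coverage >= min_coverage & aln$identity >= min_identity
  aln <- aln[keep, , drop = FALSE]
  n <- nrow(aln)
  if (n == 0) return(character())
  blocks <- lapply(strsplit(aln$blocks, ","), function(b) {
    m <- do.call(rbind, strsplit(b, ":"))
    matrix(as.integer(m), ncol = 2)
  })
  chain <- vapply(blocks, function(m)
    if (nrow(m) < 2) "" else paste(m[-nrow(m), 2], m[-1, 1], collapse = ";"),
    character(1))
  starts <- vapply(blocks, function(m) m[1, 1], integer(1))
  ends <- vapply(blocks, function(m) m[nrow(m), 2], integer(1))
  M <- diag(n) > 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (aln$chrom[i] != aln$chrom[j] || aln$strand[i] != aln$strand[j] ||
        chain[i] != chain[j]) next
    ok <- if (chain[i] == "") {
      ov <- min(ends[i], ends[j]) - max(starts[i], starts[j])
      ov > 0 && ov / (ends[i] - starts[i]) >= min_overlap &&
        ov / (ends[j] - starts[j]) >= min_overlap
    } else {
      d5 <- if (aln$strand[i] == "+") abs(starts[i] - starts[j]) else
        abs(ends[i] - ends[j])
      d3 <- if (aln$strand[i] == "+") abs(ends[i] - ends[j]) else
        abs(starts[i] - starts[j])
      d5 <= tol5 && d3 <= tol3
    }
    if (ok) M[i, j] <- TRUE
  }
  for (k in seq_len(n)) M <- M | (M[, k] %o% M[k, ])
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      cid <- cid + 1
      comp[which(M[i, ])] <- cid
    }
  }
  out <- vapply(seq_len(cid), function(c) {
    m <- which(comp == c)
    paste(aln$chrom[m[1]], aln$strand[m[1]], chain[m[1]],
          min(starts[m]), max(ends[m]), length(m), sep = "|")
  }, character(1))
  sort(out)
}

# canonical descriptors of a collapsed annotation_set, for comparison
collapsed_descriptors <- function(ann) {
  out <- vapply(ann$transcripts$transcript_id, function(tid) {
    e <- ann$exons[ann$exons$transcript_id == tid, ]
    chain <- if (nrow(e) < 2) "" else
      paste(e$end[-nrow(e)], e$start[-1], collapse = ";")
    paste(e$chrom[1], e$strand[1], chain, min(e$start), max(e$end),
          ann$transcripts$support[ann$transcripts$transcript_id == tid],
          sep = "|")
  }, character(1))
  sort(unname(out))
}

# --- two-sample KS oracle: brute-force ECDF sweep ----------------------
oracle_ks_d <- function(a, b) {
  xs <- sort(unique(c(a, b)))
  max(vapply(xs, function(x)
    abs(mean(a <= x) - mean(b <= x)), numeric(1)))
}
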