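#' Merge splice-junction call sets and apply the consensus rule
#'
#' Junctions are keyed by exact chromosome, strand, donor and acceptor
#' boundary; a junction is retained when at least `min_sources` callers
#' report it and its maximum per-source read support is at least
#' `min_reads` ("at least two software identified and at least five reads
#' supported"). Support is aggregated across sources by maximum, which is
#' conservative against counting the same reads once per aligner. Boundary
#' conventions: `donor` and `acceptor` are 0-based intron boundary
#' positions, with donor < acceptor on the + strand and donor > acceptor on
#' the - strand; violations are normalised by swapping, with a warning.
#'
#' @param call_sets A named list of per-source data.frames (`chrom`,
#'   `strand`, `donor`, `acceptor`, `support`), or one data.frame with a
#'   `source` column.
#' @param min_sources Minimum number of supporting callers (default 2).
#' @param min_reads Minimum read support in the best source (default 5).
#' @return data.frame of class `consensus_junctions`: one row per distinct
#'   junction with `n_sources`, `sources` (comma-separated), `max_support`
#'   and the `retained` flag; the long per-source support table is kept in
#'   `attr(, "support_by_source")`.
#' @export
consensus_filter <- function(call_sets, min_sources = 2, min_reads = 5) {
  if (is.data.frame(call_sets)) {
    if (!"source" %in% names(call_sets))
      stop2("a single call table needs a `source` column")
    calls <- call_sets
  } else {
    if (length(call_sets) == 0L) stop2("at least one call set is required")
    nms <- names(call_sets)
    if (is.null(nms)) nms <- paste0("source", seq_along(call_sets))
    calls <- do.call(rbind, lapply(seq_along(call_sets), function(i) {
      df <- call_sets[[i]]
      df$source <- nms[i]
      df
    }))
  }
  required <- c("chrom", "strand", "donor", "acceptor", "support", "source")
  missing_cols <- setdiff(required, names(calls))
  if (length(missing_cols))
    stop2("junction calls lack columns: ", comma(missing_cols))
  if (any(calls$donor == calls$acceptor))
    stop2("junction with donor == acceptor")
  if (any(!calls$strand %in% c("+", "-")))
    stop2("unknown strand symbol in junction calls")
  wrong <- (calls$strand == "+" & calls$donor > calls$acceptor) |
    (calls$strand == "-" & calls$donor < calls$acceptor)
  if (any(wrong)) {
    warning(sum(wrong), " junction(s) with boundary order violating the ",
            "strand convention; donor/acceptor swapped")
    tmp <- calls$donor[wrong]
    calls$donor[wrong] <- calls$acceptor[wrong]
    calls$acceptor[wrong] <- tmp
  }
  key <- paste(calls$chrom, calls$strand, calls$donor, calls$acceptor,
               sep = "|")
  # best support per source within a junction, then aggregate across sources
  agg <- lapply(split(seq_len(nrow(calls)), key), function(idx) {
    sub <- calls[idx, , drop = FALSE]
    per_source <- tapply(sub$support, sub$source, max)
    data.frame(chrom = sub$chrom[1], strand = sub$strand[1],
               donor = sub$donor[1], acceptor = sub$acceptor[1],
               n_sources = length(per_source),
               sources = paste(sort(names(per_source)), collapse = ","),
               max_support = max(per_source), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$chrom, pmin(out$donor, out$acceptor),
                   pmax(out$donor, out$acceptor), out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out$retained <- out$n_sources >= min_sources & out$max_support >= min_reads
  per_src <- calls[, c("chrom", "strand", "donor", "acceptor", "source",
                       "support")]
  per_src <- per_src[order(per_src$chrom, per_src$donor, per_src$acceptor,
                           per_src$source, per_src$support), , drop = FALSE]
  rownames(per_src) <- NULL
  attr(out, "support_by_source") <- per_src
  class(out) <- c("consensus_junctions", "data.frame")
  out
}

#' Read or write junction tables
#'
#' The native junction format is TSV with header columns `chrom`, `donor`,
#' `acceptor`, `strand`, `support`, `source`.
#'
#' @param path File path.
#' @return data.frame of junction calls.
#' @export
read_junctions <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  required <- c("chrom", "donor", "acceptor", "strand", "support")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop2("junction table lacks columns: ", comma(missing_cols))
  df
}

#' @rdname read_junctions
#' @param junctions Junction data.frame.
#' @export
write_junctions <- function(junctions, path) {
  write.table(as.data.frame(junctions), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a STAR-style SJ.out.tab junction file
#'
#' Column map: chromosome, 1-based first and last intron base, strand code
#' (1 = +, 2 = -; 0 = undefined, dropped with a message), intron motif,
#' annotated flag, unique-read support, multi-read support, overhang.
#' Unique-read counts become `support`; boundaries convert to the package's
#' 0-based donor/acceptor convention.
#'
#' @param path File path.
#' @param source Caller label to attach.
#' @return Junction data.frame as accepted by [consensus_filter()].
#' @export
read_star_sj <- function(path, source = "star") {
  df <- read.table(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 7) stop2("expected >= 7 columns in SJ file ", path)
  names(df)[1:7] <- c("chrom", "first", "last", "strand_code", "motif",
                      "annotated", "unique_reads")
  undef <- df$strand_code == 0
  if (any(undef)) {
    message("dropping ", sum(undef), " junctions with undefined strand")
    df <- df[!undef, , drop = FALSE]
  }
  strand <- ifelse(df$strand_code == 1, "+", "-")
  istart <- df$first - 1L   # 0-based first intron base
  iend <- df$last           # 0-based exclusive end
  data.frame(chrom = df$chrom, strand = strand,
             donor = ifelse(strand == "+", istart, iend),
             acceptor = ifelse(strand == "+", iend, istart),
             support = df$unique_reads, source = source,
             stringsAsFactors = FALSE)
}
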