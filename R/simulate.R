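#' Configuration for the synthetic-transcriptome simulator
#'
#' Bundles every tunable of the generators with defaults chosen to mimic a
#' desk-scale full-length transcriptome experiment: a small multi-gene
#' genome, multi-exon gene models with planted splicing events of the five
#' canonical types, full-length reads carrying both primers and poly(A)
#' tails with realistic non-full-length (18%) and chimera (6%) fractions,
#' junction call sets from three imperfect callers, and lognormal
#' expression with planted group-exclusive isoforms. The seed is mandatory;
#' identical configuration and seed give bit-identical outputs.
#'
#' @param seed Integer RNG seed (required).
#' @param ... Overrides of the defaults listed below.
#' @return A `simulation_config` list. Key fields: `n_chromosomes`,
#'   `chromosome_length`, `gc_bias`; `n_genes`, `exons_per_gene`,
#'   `exon_length`, `intron_length` (ranges); `planted_events` (named
#'   counts for IR/ES/AA/AD/MX), `boundary_shift`, `mx_exon_length`;
#'   `primers`, `tail_length` (range), `chimera_rate`, `nfl_rate`,
#'   `error_rate`, `reads_per_isoform`, `read_samples`; `tissues`,
#'   `stages`, `reps_per_group`, `exclusive_fraction`, `expr_meanlog`,
#'   `expr_sigma`, `trend_fraction`, `trend_base`, `trend_fold`,
#'   `trend_sigma`; `junction_sources`, `sensitivity`, `fp_rate`,
#'   `support_lambda`.
#' @export
simulation_config <- function(seed, ...) {
  if (missing(seed) || !is_scalar_number(seed))
    stop2("a scalar integer `seed` is required")
  defaults <- list(
    seed = as.integer(seed),
    # genome
    n_chromosomes = 2L, chromosome_length = 200000L, gc_bias = 0.5,
    # gene models
    n_genes = 24L, exons_per_gene = c(6L, 9L), exon_length = c(120L, 240L),
    intron_length = c(150L, 1200L),
    planted_events = c(IR = 8L, ES = 6L, AA = 6L, AD = 6L, MX = 4L),
    boundary_shift = 18L, mx_exon_length = 120L,
    # reads
    primers = default_primers(), tail_length = c(20L, 60L),
    chimera_rate = 0.06, nfl_rate = 0.18, error_rate = 0.01,
    reads_per_isoform = 4L,
    read_samples = c("root", "leaf", "shoot_tip", "flower",
                     "S1", "S2", "S3", "S4"),
    # expression
    tissues = c("root", "leaf", "shoot_tip", "flower", "peg"),
    stages = c("S1", "S2", "S3", "S4"), reps_per_group = 2L,
    exclusive_fraction = 0.25, expr_meanlog = log(20), expr_sigma = 0.5,
    trend_fraction = 0.5, trend_base = 5, trend_fold = 2, trend_sigma = 0.2,
    # junction call sets
    junction_sources = c("tophat", "mapsplice", "star"),
    sensitivity = 0.95, fp_rate = 0.05, support_lambda = 20)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) stop2("unknown simulation parameters: ",
                             comma(unknown))
  cfg <- modifyList(defaults, over)
  rates <- c(cfg$chimera_rate, cfg$nfl_rate, cfg$error_rate, cfg$gc_bias,
             cfg$exclusive_fraction, cfg$sensitivity, cfg$fp_rate,
             cfg$trend_fraction)
  if (any(rates < 0 | rates > 1)) stop2("all rates must lie in [0, 1]")
  structure(cfg, class = "simulation_config")
}

sample_range <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n) else
    sample(seq(range[1], range[2]), n, replace = TRUE)
}

#' Generate a random genome
#'
#' I.i.d. nucleotides with the configured GC fraction; deterministic under
#' the configuration seed.
#'
#' @param config A [simulation_config()].
#' @return Named `DNAStringSet` (chr1, chr2, ...).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$chromosome_length < 10000)
    stop2("chromosome_length must be >= 10 kb")
  with_seed(config$seed, {
    gc <- config$gc_bias
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seqs <- vapply(seq_len(config$n_chromosomes), function(i)
      paste(sample(names(probs), config$chromosome_length, replace = TRUE,
                   prob = probs), collapse = ""), character(1))
    names(seqs) <- paste0("chr", seq_along(seqs))
    Biostrings::DNAStringSet(seqs)
  })
}

# overwrite genome substring (1-based) on a character vector of chromosomes
poke <- function(seqs, chrom, at, value) {
  substr(seqs[[chrom]], at, at + nchar(value) - 1L) <- value
  seqs
}

#' Generate an annotation with planted splicing events
#'
#' Places non-overlapping genes on the genome; each gene gets a base
#' isoform, and each planted event adds one variant isoform realising it
#' (intron retained, exon skipped, shifted acceptor/donor, or a mutually
#' exclusive exon swapped in). At most two events are planted per gene, at
#' well-separated positions, so each event forms its own simple bubble.
#' Canonical GT..AG dinucleotides are written into the genome at every
#' intron boundary.
#'
#' @param config A [simulation_config()].
#' @param genome A `DNAStringSet` from [generate_genome()].
#' @return List of class `sim_annotation`: `annotation` (an
#'   `annotation_set`), `manifest` (list with `$events`: data.frame
#'   `gene_id`, `type`, `base_transcript`, `variant_transcript`), and
#'   `genome` (the genome with splice motifs written in).
#' @export
generate_annotation <- function(config, genome) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed + 1L, {
    ev_pool <- rep(names(config$planted_events), config$planted_events)
    if (length(ev_pool) > 2L * config$n_genes)
      stop2("more planted events than gene slots (2 per gene); ",
            "increase n_genes")
    # round-robin: slot 1 of each gene first, then slot 2
    slots <- data.frame(gene = rep(seq_len(config$n_genes), 2L),
                        slot = rep(1:2, each = config$n_genes))
    plan <- vector("list", config$n_genes)
    for (i in seq_along(ev_pool))
      plan[[slots$gene[i]]] <- c(plan[[slots$gene[i]]], ev_pool[i])

    chrlens <- setNames(Biostrings::width(genome), names(genome))
    seqs <- as.character(genome)
    cursor <- setNames(rep(1000L, length(chrlens)), names(chrlens))
    chrom_i <- 1L
    exon_rows <- list()
    man_rows <- list()

    for (g in seq_len(config$n_genes)) {
      gene_id <- sprintf("G%02d", g)
      strand <- sample(c("+", "-"), 1)
      events <- plan[[g]]
      n_ex <- sample_range(1, config$exons_per_gene)
      elens <- sample_range(n_ex, config$exon_length)
      ilens <- sample_range(n_ex - 1L, config$intron_length)
      # slot positions: first event at intron/exon index 2, second at n_ex - 2
      slot_idx <- c(2L, n_ex - 2L)
      # MX needs room in the hosting intron for the alternative exon
      for (si in seq_along(events)) {
        if (events[si] == "MX") {
          k <- slot_idx[si]
          need <- config$mx_exon_length + 200L
          if (ilens[k] < need) ilens[k] <- need
        }
      }
      span <- sum(elens) + sum(ilens)
      placed <- FALSE
      while (!placed) {
        if (chrom_i > length(chrlens))
          stop2("insufficient genome space for ", config$n_genes,
                " genes; increase chromosome_length or n_chromosomes")
        chrom <- names(chrlens)[chrom_i]
        at <- cursor[chrom]
        if (at + span + 1000L < chrlens[chrom]) {
          cursor[chrom] <- at + span + sample(800:1500, 1)
          placed <- TRUE
        } else chrom_i <- chrom_i + 1L
      }
      starts <- integer(n_ex); ends <- integer(n_ex)
      pos <- at
      for (k in seq_len(n_ex)) {
        starts[k] <- pos; ends[k] <- pos + elens[k]
        pos <- ends[k] + if (k < n_ex) ilens[k] else 0L
      }
      base_id <- paste0(gene_id, ".t1")
      exon_rows[[length(exon_rows) + 1L]] <- data.frame(
        transcript_id = base_id, gene_id = gene_id, chrom = chrom,
        strand = strand, start = starts, end = ends,
        stringsAsFactors = FALSE)

      for (si in seq_along(events)) {
        type <- events[si]
        k <- slot_idx[si]
        vid <- paste0(gene_id, ".t", si + 1L)
        vs <- starts; ve <- ends
        if (type == "IR") {
          # retain intron k: merge exons k and k+1
          vs <- vs[-(k + 1L)]
          ve <- ve[-k]
        } else if (type == "ES") {
          vs <- vs[-k]; ve <- ve[-k]
        } else if (type == "AA") {
          d <- config$boundary_shift
          if (strand == "+") vs[k + 1L] <- vs[k + 1L] + d
          else ve[k] <- ve[k] - d
        } else if (type == "AD") {
          d <- config$boundary_shift
          if (strand == "+") ve[k] <- ve[k] - d
          else vs[k + 1L] <- vs[k + 1L] + d
        } else if (type == "MX") {
          alt_start <- ends[k] + 80L
          vs[k] <- alt_start
          ve[k] <- alt_start + config$mx_exon_length
        }
        exon_rows[[length(exon_rows) + 1L]] <- data.frame(
          transcript_id = vid, gene_id = gene_id, chrom = chrom,
          strand = strand, start = vs, end = ve, stringsAsFactors = FALSE)
        man_rows[[length(man_rows) + 1L]] <- data.frame(
          gene_id = gene_id, type = type, base_transcript = base_id,
          variant_transcript = vid, stringsAsFactors = FALSE)
      }
    }
    ann <- annotation_set(do.call(rbind, exon_rows))
    # canonical splice dinucleotides at every intron of every isoform
    intr <- introns(ann)
    for (i in seq_len(nrow(intr))) {
      if (intr$strand[i] == "+") {
        seqs <- poke(seqs, intr$chrom[i], intr$start[i] + 1L, "GT")
        seqs <- poke(seqs, intr$chrom[i], intr$end[i] - 1L, "AG")
      } else {
        seqs <- poke(seqs, intr$chrom[i], intr$start[i] + 1L, "CT")
        seqs <- poke(seqs, intr$chrom[i], intr$end[i] - 1L, "AC")
      }
    }
    events_df <- if (length(man_rows)) do.call(rbind, man_rows) else
      data.frame(gene_id = character(), type = character(),
                 base_transcript = character(),
                 variant_transcript = character())
    structure(list(annotation = ann,
                   manifest = list(events = events_df),
                   genome = Biostrings::DNAStringSet(seqs)),
              class = "sim_annotation")
  })
}

# spliced cDNA of a transcript (transcript orientation)
spliced_sequence <- function(genome, tm) {
  seqs <- if (is.character(genome)) genome else as.character(genome)
  parts <- substring(seqs[[tm$chrom]], tm$exons$start + 1L, tm$exons$end)
  s <- paste(parts, collapse = "")
  if (tm$strand == "-") s <- revcomp_chr(s)
  s
}

mutate_sequence <- function(s, rate) {
  if (rate <= 0) return(s)
  n <- nchar(s)
  k <- rbinom(1, n, rate)
  if (k == 0) return(s)
  pos <- sample.int(n, k)
  ch <- strsplit(s, "")[[1]]
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

#' Simulate full-length reads of insert
#'
#' Reads are built as 5' primer + spliced transcript + poly(A) tail +
#' reverse-complemented 3' primer. A configured fraction are
#' non-full-length (one of the three structural elements dropped at
#' random) and a fraction chimeric (two inserts concatenated around an
#' internal 5'-primer copy); substitution errors are applied at the
#' configured per-base rate. The truth manifest records every structural
#' label and the true genomic cleavage site of each read's isoform.
#'
#' @param config A [simulation_config()].
#' @param sim A `sim_annotation` from [generate_annotation()] (or a list
#'   with `annotation` and `genome`).
#' @return List of class `sim_reads`: `reads` (named `DNAStringSet`),
#'   `manifest` (data.frame: read_id, transcript_id, sample_label,
#'   category, has_five_prime, has_three_prime, has_polya, is_full_length,
#'   is_chimeric, is_flnc, tail_length, cleavage_chrom, cleavage_strand,
#'   cleavage_position), `alignments` (perfect alignment footprints in
#'   [read_aligned_transcripts()] format).
#' @export
simulate_flnc_reads <- function(config, sim) {
  stopifnot(inherits(config, "simulation_config"))
  ann <- sim$annotation
  genome <- sim$genome
  with_seed(config$seed + 2L, {
    tids <- ann$transcripts$transcript_id
    tms <- lapply(tids, function(t) transcript_model(ann, t))
    names(tms) <- tids
    cdna <- vapply(tms, function(tm) spliced_sequence(genome, tm),
                   character(1))
    p5 <- config$primers$five_prime
    p3rc <- revcomp_chr(config$primers$three_prime)
    reads <- character(); man <- list(); aln <- list()
    idx <- 0L
    for (tid in tids) {
      tm <- tms[[tid]]
      cleav_pos <- if (tm$strand == "+")
        tm$exons$end[nrow(tm$exons)] - 1L else tm$exons$start[1]
      for (r in seq_len(config$reads_per_isoform)) {
        idx <- idx + 1L
        rid <- sprintf("read%05d", idx)
        sample_label <- config$read_samples[
          (idx - 1L) %% length(config$read_samples) + 1L]
        tail_len <- sample_range(1, config$tail_length)
        u <- runif(1)
        if (u < config$chimera_rate) {
          category <- "chimeric"
          other <- sample(tids, 1)
          s <- paste0(p5, cdna[[tid]], p5, cdna[[other]],
                      strrep("A", tail_len), p3rc)
          has5 <- TRUE; has3 <- TRUE; polya <- TRUE
        } else if (u < config$chimera_rate + config$nfl_rate) {
          category <- "nfl"
          drop <- sample(c("five", "three", "tail"), 1)
          s <- paste0(if (drop == "five") "" else p5,
                      cdna[[tid]],
                      if (drop == "tail") "" else strrep("A", tail_len),
                      if (drop == "three") "" else p3rc)
          has5 <- drop != "five"; has3 <- drop != "three"
          polya <- drop != "tail"
          if (drop == "tail") tail_len <- 0L
        } else {
          category <- "flnc"
          s <- paste0(p5, cdna[[tid]], strrep("A", tail_len), p3rc)
          has5 <- TRUE; has3 <- TRUE; polya <- TRUE
        }
        s <- mutate_sequence(s, config$error_rate)
        reads[rid] <- s
        is_fl <- has5 && has3 && polya
        man[[idx]] <- data.frame(
          read_id = rid, transcript_id = tid, sample_label = sample_label,
          category = category, has_five_prime = has5, has_three_prime = has3,
          has_polya = polya, is_full_length = is_fl,
          is_chimeric = category == "chimeric",
          is_flnc = is_fl && category != "chimeric",
          tail_length = tail_len, cleavage_chrom = tm$chrom,
          cleavage_strand = tm$strand, cleavage_position = cleav_pos,
          stringsAsFactors = FALSE)
        aln[[idx]] <- data.frame(
          query_id = rid, chrom = tm$chrom, strand = tm$strand,
          blocks = format_blocks(list(as.matrix(tm$exons))),
          coverage = 1.0, identity = 1.0, stringsAsFactors = FALSE)
      }
    }
    structure(list(reads = Biostrings::DNAStringSet(reads),
                   manifest = do.call(rbind, man),
                   alignments = do.call(rbind, aln)),
              class = "sim_reads")
  })
}

#' Write simulated reads as FASTQ (constant quality)
#'
#' @param reads Named `DNAStringSet`.
#' @param path Output path.
#' @export
write_reads_fastq <- function(reads, path) {
  quals <- Biostrings::BStringSet(vapply(Biostrings::width(reads),
                                         function(w) strrep("I", w),
                                         character(1)))
  Biostrings::writeXStringSet(reads, path, format = "fastq",
                              qualities = quals)
  invisible(path)
}

#' Simulate an expression matrix with planted exclusivity and trends
#'
#' A configured fraction of isoforms is exclusive to one group (nonzero
#' lognormal abundance only in that group's samples, exact zeros
#' elsewhere); the rest are expressed in all groups. In stage mode, a
#' fraction of the shared isoforms additionally receives a planted
#' monotone trend, half increasing and half decreasing across the ordered
#' stages.
#'
#' @param config A [simulation_config()].
#' @param annotation An `annotation_set` (isoform ids are taken from it).
#' @param mode `"tissue"` (groups = `config$tissues`) or `"stage"`
#'   (groups = `config$stages`, trends planted).
#' @return List of class `sim_expression`: `values` (matrix isoforms x
#'   samples), `groups` (named sample -> group vector), `manifest`
#'   (data.frame: isoform, exclusive_group (NA when shared), trend
#'   (`up`/`down`/`none`)).
#' @export
simulate_expression <- function(config, annotation,
                                mode = c("tissue", "stage")) {
  stopifnot(inherits(config, "simulation_config"))
  mode <- match.arg(mode)
  with_seed(config$seed + 3L + (mode == "stage"), {
    iso <- annotation$transcripts$transcript_id
    grp_levels <- if (mode == "tissue") config$tissues else config$stages
    samples <- paste(rep(grp_levels, each = config$reps_per_group),
                     seq_len(config$reps_per_group), sep = "_")
    groups <- setNames(rep(grp_levels, each = config$reps_per_group),
                       samples)
    n <- length(iso)
    n_excl <- round(config$exclusive_fraction * n)
    excl_iso <- sample(iso, n_excl)
    excl_group <- setNames(sample(grp_levels, n_excl, replace = TRUE),
                           excl_iso)
    shared <- setdiff(iso, excl_iso)
    trend <- setNames(rep("none", n), iso)
    if (mode == "stage" && length(shared) > 0) {
      n_trend <- round(config$trend_fraction * length(shared))
      tr_iso <- sample(shared, n_trend)
      half <- floor(n_trend / 2)
      trend[tr_iso[seq_len(half)]] <- "up"
      if (n_trend > half) trend[tr_iso[(half + 1):n_trend]] <- "down"
    }
    values <- matrix(0, nrow = n, ncol = length(samples),
                     dimnames = list(iso, samples))
    for (i in iso) {
      if (i %in% excl_iso) {
        cols <- which(groups == excl_group[[i]])
        values[i, cols] <- rlnorm(length(cols), config$expr_meanlog,
                                  config$expr_sigma)
      } else if (trend[[i]] %in% c("up", "down")) {
        stage_means <- config$trend_base *
          config$trend_fold^(seq_along(grp_levels) - 1)
        if (trend[[i]] == "down") stage_means <- rev(stage_means)
        for (s in seq_along(grp_levels)) {
          cols <- which(groups == grp_levels[s])
          values[i, cols] <- stage_means[s] *
            exp(rnorm(length(cols), 0, config$trend_sigma))
        }
      } else {
        values[i, ] <- rlnorm(length(samples), config$expr_meanlog,
                              config$expr_sigma)
      }
    }
    manifest <- data.frame(
      isoform = iso,
      exclusive_group = ifelse(iso %in% excl_iso, excl_group[iso],
                               NA_character_),
      trend = unname(trend[iso]), stringsAsFactors = FALSE)
    structure(list(values = values, groups = groups, manifest = manifest),
              class = "sim_expression")
  })
}

#' Simulate junction call sets from imperfect callers
#'
#' The true junction set is the union of annotated introns (oriented
#' donor/acceptor boundaries). Each configured source reports each true
#' junction with probability `sensitivity`, with read support drawn as
#' `1 + Poisson(support_lambda - 1)`, plus source-specific false junctions
#' at rate `fp_rate` (relative to the true set size).
#'
#' @param config A [simulation_config()].
#' @param annotation An `annotation_set`.
#' @return List of class `sim_junctions`: `call_sets` (named list of
#'   per-source junction data.frames) and `truth` (data.frame of true
#'   junctions: chrom, strand, donor, acceptor).
#' @export
simulate_junction_callsets <- function(config, annotation) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed + 5L, {
    intr <- introns(annotation)
    truth <- unique(data.frame(
      chrom = intr$chrom, strand = intr$strand,
      donor = ifelse(intr$strand == "+", intr$start, intr$end),
      acceptor = ifelse(intr$strand == "+", intr$end, intr$start),
      stringsAsFactors = FALSE))
    rownames(truth) <- NULL
    true_keys <- paste(truth$chrom, truth$strand, truth$donor,
                       truth$acceptor)
    lambda <- max(config$support_lambda - 1, 0.1)
    call_sets <- lapply(config$junction_sources, function(src) {
      hit <- rbinom(nrow(truth), 1, config$sensitivity) == 1
      calls <- truth[hit, , drop = FALSE]
      calls$support <- 1L + rpois(nrow(calls), lambda)
      n_fp <- round(config$fp_rate * nrow(truth))
      if (n_fp > 0) {
        chroms <- unique(truth$chrom)
        fp <- data.frame(
          chrom = sample(chroms, n_fp, replace = TRUE),
          strand = sample(c("+", "-"), n_fp, replace = TRUE),
          donor = sample.int(config$chromosome_length - 6000L, n_fp),
          stringsAsFactors = FALSE)
        len <- sample(60:5000, n_fp, replace = TRUE)
        fp$acceptor <- ifelse(fp$strand == "+", fp$donor + len,
                              fp$donor - pmin(len, fp$donor - 1L))
        fp <- fp[!paste(fp$chrom, fp$strand, fp$donor, fp$acceptor) %in%
                   true_keys, , drop = FALSE]
        fp$support <- 1L + rpois(nrow(fp), lambda)
        calls <- rbind(calls, fp)
      }
      calls$source <- src
      rownames(calls) <- NULL
      calls
    })
    names(call_sets) <- config$junction_sources
    structure(list(call_sets = call_sets, truth = truth),
              class = "sim_junctions")
  })
}

#' Write a truth manifest as JSON
#'
#' @param manifest Any manifest component of the simulators (list or
#'   data.frame).
#' @param path Output path.
#' @export
write_truth_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, dataframe = "rows", auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}
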