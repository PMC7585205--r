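pipeline_defaults <- function() {
  list(
    seed = 1L, outdir = "flsplice_out",
    steps = c("simulate", "classify", "collapse", "events", "polya",
              "junctions", "specificity"),
    # input paths (filled by the simulate step when it runs)
    genome = NULL, annotation = NULL, reads = NULL, alignments = NULL,
    junction_files = NULL, expression = NULL, sample_mapping = NULL,
    # simulator size
    n_genes = 24L, reads_per_isoform = 4L, error_rate = 0.01,
    chimera_rate = 0.06, nfl_rate = 0.18,
    # module parameters
    max_mismatch_fraction = 0.1, terminal_margin = 100L,
    min_coverage = 0.8, min_identity = 0.7,
    five_prime_tolerance = 1000L, three_prime_tolerance = 100L,
    merge_window = 24L, flank = 50L, upstream_window = 50L,
    min_sources = 2L, min_reads = 5L, presence_threshold = 0.1)
}

#' Assemble and validate a pipeline configuration
#'
#' Configuration is a flat key-value set (YAML file and/or named
#' arguments); unknown keys are rejected by name. Every parameter is
#' echoed into the run manifest that [run_pipeline()] writes.
#'
#' @param path Optional YAML config file.
#' @param ... Named overrides of the defaults (paths, simulator sizes and
#'   per-module parameters; see the fields of the returned list).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(path = NULL, ...) {
  cfg <- pipeline_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop2("config file not found: ", path)
    file_cfg <- yaml::read_yaml(path)
    unknown <- setdiff(names(file_cfg), names(cfg))
    if (length(unknown)) stop2("unknown configuration key(s): ",
                               comma(unknown))
    cfg <- modifyList(cfg, file_cfg)
  }
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop2("unknown configuration key(s): ",
                             comma(unknown))
  cfg <- modifyList(cfg, over)
  structure(cfg, class = "pipeline_config")
}

pipeline_log <- function(...) message("[flsplice] ", ...)

require_input <- function(cfg, key, step) {
  p <- cfg[[key]]
  if (is.null(p) || !all(file.exists(p)))
    stop2("step `", step, "` needs input `", key, "` (",
          if (is.null(p)) "not set" else paste(p[!file.exists(p)],
                                               collapse = ", "),
          ")")
  p
}

#' Run the analysis pipeline
#'
#' Executes the configured steps in analysis order — simulate (synthetic
#' inputs with truth manifest), classify (read classification and
#' summary), collapse (alignment collapse to unique isoforms), events
#' (AS-event classification and summary), polya (cleavage-site calling,
#' clustering, profile and motifs), junctions (consensus filtering),
#' specificity (exclusive isoforms and JS scores) — writing per-stage
#' TSV/JSON reports and a machine-readable run manifest into the output
#' directory. Reruns with an identical configuration and seed produce
#' byte-identical reports.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list of written report paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  path <- function(f) file.path(cfg$outdir, f)
  primers <- primer_config(max_mismatch_fraction = cfg$max_mismatch_fraction)

  if ("simulate" %in% cfg$steps) {
    pipeline_log("simulate: n_genes=", cfg$n_genes, " seed=", cfg$seed)
    ev <- c(IR = 8L, ES = 6L, AA = 6L, AD = 6L, MX = 4L)
    slots <- 2L * cfg$n_genes
    if (sum(ev) > slots) ev <- pmax(floor(ev * slots / sum(ev)), 1L)
    scfg <- simulation_config(seed = cfg$seed, n_genes = cfg$n_genes,
                              planted_events = ev,
                              reads_per_isoform = cfg$reads_per_isoform,
                              error_rate = cfg$error_rate,
                              chimera_rate = cfg$chimera_rate,
                              nfl_rate = cfg$nfl_rate)
    genome <- generate_genome(scfg)
    sim <- generate_annotation(scfg, genome)
    reads <- simulate_flnc_reads(scfg, sim)
    expr <- simulate_expression(scfg, sim$annotation, mode = "tissue")
    jx <- simulate_junction_callsets(scfg, sim$annotation)
    Biostrings::writeXStringSet(sim$genome, path("genome.fasta"))
    write_annotation(sim$annotation, path("annotation.gtf"))
    write_reads_fastq(reads$reads, path("reads.fastq"))
    write_aligned_transcripts(reads$alignments, path("alignments.tsv"))
    write_expression_matrix(expr$values, expr$groups, path("expression.tsv"),
                            path("samples.tsv"))
    jfiles <- vapply(names(jx$call_sets), function(src) {
      f <- path(paste0("junctions_", src, ".tsv"))
      write_junctions(jx$call_sets[[src]], f)
      f
    }, character(1))
    write_truth_manifest(list(events = sim$manifest$events,
                              reads = reads$manifest,
                              expression = expr$manifest,
                              junctions = jx$truth), path("truth.json"))
    cfg$genome <- path("genome.fasta")
    cfg$annotation <- path("annotation.gtf")
    cfg$reads <- path("reads.fastq")
    cfg$alignments <- path("alignments.tsv")
    cfg$expression <- path("expression.tsv")
    cfg$sample_mapping <- path("samples.tsv")
    cfg$junction_files <- unname(jfiles)
    out$truth <- path("truth.json")
  }

  cls <- NULL
  if ("classify" %in% cfg$steps) {
    f <- require_input(cfg, "reads", "classify")
    pipeline_log("classify: ", f)
    reads <- read_reads(f)
    labels <- NULL
    if (!is.null(cfg$alignments) || "simulate" %in% cfg$steps) {
      tf <- path("truth.json")
      if (file.exists(tf)) {
        truth <- jsonlite::read_json(tf, simplifyVector = TRUE)
        labels <- truth$reads$sample_label[
          match(names(reads), truth$reads$read_id)]
      }
    }
    cls <- classify_reads(reads, primers, sample_labels = labels,
                          terminal_margin = cfg$terminal_margin)
    write.table(cls[, setdiff(names(cls), "trimmed_insert")],
                path("classifications.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write_classification_summary(summarize_classification(cls),
                                 path("classification_summary.tsv"))
    out$classification <- path("classification_summary.tsv")
  }

  collapsed <- NULL
  if ("collapse" %in% cfg$steps) {
    f <- require_input(cfg, "alignments", "collapse")
    pipeline_log("collapse: ", f)
    aln <- read_aligned_transcripts(f)
    collapsed <- collapse_transcripts(
      aln, min_coverage = cfg$min_coverage, min_identity = cfg$min_identity,
      five_prime_tolerance = cfg$five_prime_tolerance,
      three_prime_tolerance = cfg$three_prime_tolerance)
    write_annotation(collapsed, path("collapsed.gtf"))
    write.table(collapsed$transcripts, path("collapsed_support.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    out$collapsed <- path("collapsed.gtf")
  }

  if ("events" %in% cfg$steps) {
    f <- require_input(cfg, "annotation", "events")
    pipeline_log("events: ", f)
    ann <- read_annotation(f)
    es <- summarize_events(ann)
    write_events(es, path("events.tsv"), path("event_summary.tsv"))
    jsonlite::write_json(
      list(total_events = es$total_events,
           total_as_genes = es$total_as_genes, by_type = es$by_type),
      path("event_summary.json"), dataframe = "rows", auto_unbox = TRUE,
      digits = NA)
    out$events <- path("event_summary.tsv")
  }

  if ("polya" %in% cfg$steps) {
    fa <- require_input(cfg, "alignments", "polya")
    fg <- require_input(cfg, "genome", "polya")
    fr <- require_input(cfg, "reads", "polya")
    fann <- require_input(cfg, "annotation", "polya")
    pipeline_log("polya")
    genome <- Biostrings::readDNAStringSet(fg)
    names(genome) <- sub("\\s.*$", "", names(genome))
    ann <- read_annotation(fann)
    aln <- read_aligned_transcripts(fa)
    if (is.null(cls)) {
      reads <- read_reads(fr)
      cls <- classify_reads(reads, primers,
                            terminal_margin = cfg$terminal_margin)
    }
    flnc <- cls$read_id[cls$is_flnc]
    rows <- list()
    for (rid in intersect(flnc, aln$query_id)) {
      a <- aln[aln$query_id == rid, , drop = FALSE][1, ]
      i <- match(rid, cls$read_id)
      tail <- structure(list(tail_start = cls$tail_start[i],
                             tail_length = cls$tail_length[i],
                             non_a_count = NA_integer_),
                        class = "tail_call")
      rows[[rid]] <- map_cleavage_site(a, tail)
    }
    sites <- do.call(rbind, rows)
    cl <- cluster_sites(sites, ann, merge_window = cfg$merge_window)
    write_sites_bed(cl$sites, path("polya_sites.bed"))
    prof <- nucleotide_profile(cl$sites, genome, flank = cfg$flank)
    write_profile(prof, path("polya_profile.tsv"))
    mot <- count_motifs(cl$sites, genome,
                        upstream_window = cfg$upstream_window)
    jsonlite::write_json(
      list(stats = cl$stats,
           motifs = lapply(mot[names(mot) != "n_sites"], function(m)
             list(motif = m$motif, occurrences = m$occurrences,
                  sites_with_hit = m$sites_with_hit))),
      path("polya_stats.json"), auto_unbox = TRUE, digits = NA)
    out$polya <- path("polya_stats.json")
  }

  if ("junctions" %in% cfg$steps) {
    files <- require_input(cfg, "junction_files", "junctions")
    pipeline_log("junctions: ", length(files), " call sets")
    sets <- lapply(files, read_junctions)
    names(sets) <- sub("\\.tsv$", "", basename(files))
    cj <- consensus_filter(sets, min_sources = cfg$min_sources,
                           min_reads = cfg$min_reads)
    write_junctions(cj, path("consensus_junctions.tsv"))
    out$junctions <- path("consensus_junctions.tsv")
  }

  if ("specificity" %in% cfg$steps) {
    fe <- require_input(cfg, "expression", "specificity")
    fm <- require_input(cfg, "sample_mapping", "specificity")
    pipeline_log("specificity: ", fe)
    em <- read_expression_matrix(fe, fm)
    es <- exclusive_isoforms(em$values, em$groups,
                             presence_threshold = cfg$presence_threshold)
    js <- js_specificity_matrix(em$values, em$groups)
    write.table(js, path("js_scores.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    jsonlite::write_json(
      list(exclusive_counts = lapply(es$exclusive, length),
           combinations = as.list(es$combos)),
      path("exclusive_isoforms.json"), auto_unbox = TRUE, digits = NA)
    out$specificity <- path("exclusive_isoforms.json")
  }

  manifest <- list(
    package = "flsplice",
    version = as.character(utils::packageVersion("flsplice")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    steps = cfg$steps,
    parameters = cfg[setdiff(names(cfg), c("steps"))])
  jsonlite::write_json(manifest, path("run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  out$run_manifest <- path("run_manifest.json")
  invisible(out)
}
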