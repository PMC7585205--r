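small_cfg <- function(seed, ...) {
  simulation_config(seed = seed, n_genes = 8,
                    planted_events = c(IR = 2L, ES = 2L, AA = 2L), ...)
}

test_that("generators are bit-reproducible under config and seed", {
  cfg <- small_cfg(123)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(as.character(g1), as.character(g2))
  s1 <- generate_annotation(cfg, g1)
  s2 <- generate_annotation(cfg, g2)
  expect_identical(s1$annotation$exons, s2$annotation$exons)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  r1 <- simulate_flnc_reads(cfg, s1)
  r2 <- simulate_flnc_reads(cfg, s2)
  expect_identical(as.character(r1$reads), as.character(r2$reads))
  expect_identical(r1$manifest, r2$manifest)
  e1 <- simulate_expression(cfg, s1$annotation)
  e2 <- simulate_expression(cfg, s2$annotation)
  expect_identical(e1$values, e2$values)
  j1 <- simulate_junction_callsets(cfg, s1$annotation)
  j2 <- simulate_junction_callsets(cfg, s2$annotation)
  expect_identical(j1$call_sets, j2$call_sets)
  # different seed, different draws
  expect_false(identical(as.character(generate_genome(small_cfg(124))),
                         as.character(g1)))
})

test_that("genome dimensions and composition follow the config", {
  cfg <- simulation_config(seed = 3, n_chromosomes = 2L,
                           chromosome_length = 50000L)
  g <- generate_genome(cfg)
  expect_equal(length(g), 2L)
  expect_equal(unname(Biostrings::width(g)), c(50000L, 50000L))
  expect_error(generate_genome(simulation_config(seed = 3,
                                                 chromosome_length = 5000L)),
               "10 kb")

  biased <- simulation_config(seed = 4, chromosome_length = 50000L,
                              n_chromosomes = 1L, gc_bias = 0.6)
  gb <- generate_genome(biased)
  counts <- Biostrings::alphabetFrequency(gb)[1, c("A", "C", "G", "T")]
  gc <- sum(counts[c("C", "G")]) / sum(counts)
  expect_lt(abs(gc - 0.6), 3 * sqrt(0.6 * 0.4 / 50000))
})

test_that("annotations respect structural invariants and plant GT..AG", {
  cfg <- small_cfg(9)
  sim <- generate_annotation(cfg, generate_genome(cfg))
  ann <- sim$annotation
  expect_s3_class(ann, "annotation_set")  # constructor enforces invariants
  # genes do not overlap
  g <- ann$genes[order(ann$genes$chrom, ann$genes$start), ]
  by_chrom <- split(g, g$chrom)
  for (gc in by_chrom)
    if (nrow(gc) > 1) expect_true(all(gc$start[-1] >= gc$end[-nrow(gc)]))
  # canonical dinucleotides at intron boundaries
  seqs <- as.character(sim$genome)
  intr <- introns(ann)
  for (i in seq_len(nrow(intr))) {
    s <- substr(seqs[[intr$chrom[i]]], intr$start[i] + 1, intr$start[i] + 2)
    e <- substr(seqs[[intr$chrom[i]]], intr$end[i] - 1, intr$end[i])
    if (intr$strand[i] == "+") expect_equal(paste0(s, e), "GTAG")
    else expect_equal(paste0(s, e), "CTAC")
  }
})

test_that("planting more events than slots is a hard error", {
  expect_error(
    generate_annotation(simulation_config(seed = 1, n_genes = 2),
                        generate_genome(simulation_config(seed = 1))),
    "more planted events")
})

test_that("manifests cover every generated entity exactly once", {
  cfg <- small_cfg(33)
  sim <- generate_annotation(cfg, generate_genome(cfg))
  rd <- simulate_flnc_reads(cfg, sim)
  expect_equal(sort(rd$manifest$read_id), sort(names(rd$reads)))
  expect_equal(anyDuplicated(rd$manifest$read_id), 0L)
  expect_equal(nrow(rd$manifest),
               nrow(sim$annotation$transcripts) * cfg$reads_per_isoform)
  ex <- simulate_expression(cfg, sim$annotation)
  expect_setequal(ex$manifest$isoform, rownames(ex$values))
  expect_equal(anyDuplicated(ex$manifest$isoform), 0L)
  jx <- simulate_junction_callsets(cfg, sim$annotation)
  expect_equal(anyDuplicated(with(jx$truth,
                                  paste(chrom, strand, donor, acceptor))), 0L)
})

test_that("chimeric fraction tracks the configured rate", {
  cfg <- small_cfg(44, chimera_rate = 0.1, reads_per_isoform = 25L,
                   error_rate = 0)
  sim <- generate_annotation(cfg, generate_genome(cfg))
  rd <- simulate_flnc_reads(cfg, sim)
  n <- nrow(rd$manifest)
  expect_gte(n, 250)
  frac <- mean(rd$manifest$is_chimeric)
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / n))
})

test_that("planted cleavage sites are recovered exactly at zero noise", {
  cfg <- small_cfg(52, error_rate = 0, chimera_rate = 0, nfl_rate = 0)
  sim <- generate_annotation(cfg, generate_genome(cfg))
  rd <- simulate_flnc_reads(cfg, sim)
  cls <- classify_reads(rd$reads, test_primers)
  sites <- do.call(rbind, lapply(which(cls$is_flnc), function(i) {
    rid <- cls$read_id[i]
    a <- rd$alignments[rd$alignments$query_id == rid, ][1, ]
    map_cleavage_site(a, structure(list(tail_start = cls$tail_start[i],
                                        tail_length = cls$tail_length[i],
                                        non_a_count = 0L),
                                   class = "tail_call"))
  }))
  got <- unique(sites[c("chrom", "strand", "position")])
  want <- unique(data.frame(chrom = rd$manifest$cleavage_chrom,
                            strand = rd$manifest$cleavage_strand,
                            position = rd$manifest$cleavage_position))
  o1 <- got[order(got$chrom, got$position), ]
  o2 <- want[order(want$chrom, want$position), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})

test_that("FASTQ output is readable and preserves sequences", {
  cfg <- small_cfg(61)
  sim <- generate_annotation(cfg, generate_genome(cfg))
  rd <- simulate_flnc_reads(cfg, sim)
  f <- withr::local_tempfile(fileext = ".fastq")
  write_reads_fastq(rd$reads, f)
  back <- read_reads(f)
  expect_identical(as.character(back), as.character(rd$reads))
})
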