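test_that("tail calling follows the 30-base window rule", {
  t1 <- call_tail(paste0("GGTT", strrep("A", 30)))
  expect_equal(t1$tail_length, 30)
  expect_equal(t1$non_a_count, 0)

  # 9 A and 1 non-A qualifies ("more than eight A, less than two non-A")
  t2 <- call_tail(paste0("CCCCGG", "AAAAGAAAAA"))
  expect_false(is.null(t2))
  expect_equal(t2$tail_length, 10)
  expect_equal(t2$non_a_count, 1)

  # exactly 8 A preceded by C fails the "more than eight" rule
  expect_null(call_tail(paste0("GGGGC", strrep("A", 8))))
})

test_that("tail-rule boundary properties hold on generated suffixes", {
  set.seed(5)
  for (i in 1:50) {
    body <- rand_seq(40)
    with_tail <- paste0(body, "C", strrep("A", sample(9:30, 1)))
    expect_false(is.null(call_tail(with_tail)))
    # terminal 30 bases with at most 8 As can never qualify
    low_a <- paste0(body, paste(sample(c("C", "G", "T", "A"), 30,
                                       replace = TRUE,
                                       prob = c(0.35, 0.35, 0.2, 0.1)),
                                collapse = ""))
    last30 <- substr(low_a, nchar(low_a) - 29, nchar(low_a))
    n_a <- sum(strsplit(last30, "")[[1]] == "A")
    if (n_a <= 8) expect_null(call_tail(low_a))
  }
})

test_that("cleavage sites map to the strand-appropriate alignment end", {
  aln_plus <- data.frame(query_id = "r1", chrom = "chr1", strand = "+",
                         blocks = "100:500,700:1000")
  tail <- call_tail(strrep("A", 20))
  s <- map_cleavage_site(aln_plus, tail)
  expect_equal(s$position, 999)   # last aligned base, 0-based

  aln_minus <- data.frame(query_id = "r2", chrom = "chr1", strand = "-",
                          blocks = "2000:2400,2600:3000")
  expect_equal(map_cleavage_site(aln_minus, tail)$position, 2000)

  expect_error(map_cleavage_site(aln_plus, NULL), "no poly\\(A\\) tail")
})

test_that("site clustering merges within the window and sums support", {
  ann <- mk_ann(mk_exons(c(900, 1100)))
  sites <- data.frame(chrom = "chr1", strand = "+",
                      position = c(1000, 1010), support = c(3L, 1L))
  cl <- cluster_sites(sites, ann, merge_window = 24)
  expect_equal(nrow(cl$sites), 1L)
  expect_equal(cl$sites$support, 4L)
  expect_equal(cl$sites$position, 1000)  # support-weighted mode
  expect_equal(cl$sites$gene_id, "g1")

  far <- data.frame(chrom = "chr1", strand = "+",
                    position = c(1000, 1030), support = 1L)
  expect_equal(nrow(cluster_sites(far, ann, merge_window = 24)$sites), 2L)
})

test_that("site clustering is invariant to input order", {
  set.seed(8)
  ann <- mk_ann(mk_exons(c(0, 5000)))
  sites <- data.frame(chrom = "chr1",
                      strand = sample(c("+", "-"), 40, replace = TRUE),
                      position = sample(0:5000, 40),
                      support = sample(1:5, 40, replace = TRUE))
  a <- cluster_sites(sites, ann)
  for (p in 1:5) {
    b <- cluster_sites(sites[sample(nrow(sites)), ], ann)
    expect_equal(b$sites, a$sites)
  }
})

test_that("per-gene statistics report detection fractions", {
  ann <- mk_ann(mk_exons(c(0, 1000), tid = "t1", gid = "g1"),
                mk_exons(c(5000, 6000), tid = "t2", gid = "g2"))
  sites <- data.frame(chrom = "chr1", strand = "+",
                      position = c(990, 500, 100, 300, 700, 900),
                      support = 1L)
  # positions within g1 span cluster into 5 separated sites (window 24)
  cl <- cluster_sites(sites, ann, merge_window = 24)
  expect_equal(cl$stats$genes_with_site, 1L)
  expect_equal(cl$stats$frac_genes_ge1, 0.5)
  expect_equal(cl$stats$genes_ge5, 1L)
  expect_equal(cl$stats$mean_sites_per_gene, 6)
})

test_that("single-site profile is the one-hot encoding of its flanks", {
  chr <- paste(rep(c("A", "C", "G", "T"), length.out = 301), collapse = "")
  genome <- c(chrZ = chr)
  sites <- data.frame(chrom = "chrZ", strand = "+", position = 150)
  prof <- nucleotide_profile(sites, genome, flank = 50)
  expect_equal(dim(prof$freq), c(4L, 101L))
  expect_true(all(abs(colSums(prof$freq) - 1) < 1e-9))
  expect_true(all(prof$freq %in% c(0, 1)))
  # offset 0 must be the base at the cleavage position itself
  base0 <- substr(chr, 151, 151)
  base0 <- chartr("T", "U", base0)
  expect_equal(unname(prof$freq[base0, "0"]), 1)
})

test_that("minus-strand profiles equal the reverse-complement view", {
  set.seed(21)
  chr <- rand_seq(2000)
  genome_fwd <- c(chr1 = chr)
  genome_rev <- c(chr1 = as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(chr))))
  pos <- c(300, 700, 1200)
  p_plus <- nucleotide_profile(
    data.frame(chrom = "chr1", strand = "+", position = pos),
    genome_fwd, flank = 50)
  p_minus <- nucleotide_profile(
    data.frame(chrom = "chr1", strand = "-", position = 2000 - pos - 1),
    genome_rev, flank = 50)
  expect_equal(p_plus$freq, p_minus$freq)
})

test_that("profile on a uniform random genome is flat at 0.25", {
  cfg <- simulation_config(seed = 55, n_genes = 2, chromosome_length = 60000L,
                           planted_events = c(IR = 0L))
  genome <- generate_genome(cfg)
  set.seed(56)
  sites <- data.frame(chrom = sample(names(genome), 400, replace = TRUE),
                      strand = sample(c("+", "-"), 400, replace = TRUE),
                      position = sample(100:59000, 400))
  prof <- nucleotide_profile(sites, genome, flank = 50)
  se3 <- 3 * sqrt(0.25 * 0.75 / prof$n_sites)
  expect_true(all(abs(prof$freq - 0.25) <= se3 + 0.02))
})

test_that("motif counting finds exact upstream occurrences at offsets", {
  # upstream window = genomic 100..149; motif starts 26 nt before cleavage
  up <- paste0(strrep("CG", 12), "AATAAA", strrep("CT", 10))
  chr <- paste0(strrep("G", 100), up, "CTTTT")
  genome <- c(chr1 = chr)
  sites <- data.frame(chrom = "chr1", strand = "+", position = 150)
  mc <- count_motifs(sites, genome, motifs = c("AAUAAA", "UGUA"),
                     upstream_window = 50)
  expect_equal(mc$AAUAAA$occurrences, 1L)
  expect_equal(unname(mc$AAUAAA$histogram["-26"]), 1L)
  expect_equal(mc$UGUA$occurrences, 0L)
})

test_that("planted motif frequency is recovered within sampling error", {
  set.seed(61)
  n <- 500
  plant_rate <- 0.6
  chrlen <- 400
  seqs <- character(n)
  planted <- runif(n) < plant_rate
  for (i in 1:n) {
    s <- rand_seq(chrlen)
    s <- gsub("AATAAA", "CAGTCA", s, fixed = TRUE)  # remove chance hits
    if (planted[i]) substr(s, 200 - 25, 200 - 20) <- "AATAAA"
    seqs[i] <- s
  }
  names(seqs) <- paste0("c", 1:n)
  sites <- data.frame(chrom = names(seqs), strand = "+", position = 199)
  mc <- count_motifs(sites, seqs, motifs = "AAUAAA", upstream_window = 50)
  freq <- mc$AAUAAA$sites_with_hit / n
  se3 <- 3 * sqrt(plant_rate * (1 - plant_rate) / n)
  expect_lt(abs(freq - plant_rate), se3 + 0.01)
})
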