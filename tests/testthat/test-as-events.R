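test_that("intron retention is detected with its site code", {
  # tA splices out [200,300); tB is exonic across it
  p <- mk_pair(c(0, 200, 300, 500), c(0, 500))
  ev <- pairwise_events(p[[1]], p[[2]])
  expect_equal(ev$event_type, "IR")
  expect_equal(ev$code, "1^2-,0")
})

test_that("identical exon chains yield no events", {
  p <- mk_pair(c(0, 100, 200, 300), c(0, 100, 200, 300))
  expect_equal(nrow(pairwise_events(p[[1]], p[[2]])), 0L)
})

test_that("the five canonical templates classify as named", {
  # ES: tA keeps exon [250,300) between shared introns
  es <- mk_pair(c(0, 100, 250, 300, 400, 500), c(0, 100, 400, 500))
  expect_equal(pairwise_events(es[[1]], es[[2]])$event_type, "ES")
  # AA (+ strand): shared donor at 100, acceptors at 200 vs 240
  aa <- mk_pair(c(0, 100, 200, 500), c(0, 100, 240, 500))
  expect_equal(pairwise_events(aa[[1]], aa[[2]])$event_type, "AA")
  # AD (+ strand): donors 100 vs 140, shared acceptor 300
  ad <- mk_pair(c(0, 100, 300, 500), c(0, 140, 300, 500))
  expect_equal(pairwise_events(ad[[1]], ad[[2]])$event_type, "AD")
  # MX: alternative exons [200,260) vs [300,360) between shared flanks
  mx <- mk_pair(c(0, 100, 200, 260, 500, 600),
                c(0, 100, 300, 360, 500, 600))
  expect_equal(pairwise_events(mx[[1]], mx[[2]])$event_type, "MX")
  # overlapping alternatives are not MX
  ovl <- mk_pair(c(0, 100, 200, 260, 500, 600),
                 c(0, 100, 230, 300, 500, 600))
  expect_equal(pairwise_events(ovl[[1]], ovl[[2]])$event_type, "other")
})

test_that("strand flips donor/acceptor roles", {
  aa_minus <- mk_pair(c(0, 100, 200, 500), c(0, 100, 240, 500),
                      strand = "-")
  expect_equal(pairwise_events(aa_minus[[1]], aa_minus[[2]])$event_type,
               "AD")
  ad_minus <- mk_pair(c(0, 100, 300, 500), c(0, 140, 300, 500),
                      strand = "-")
  expect_equal(pairwise_events(ad_minus[[1]], ad_minus[[2]])$event_type,
               "AA")
})

test_that("terminal-exon differences are not events", {
  # same intron chain, different TSS/TES extents
  p <- mk_pair(c(0, 100, 200, 300), c(50, 100, 200, 280))
  expect_equal(nrow(pairwise_events(p[[1]], p[[2]])), 0L)
})

test_that("mismatched gene/strand/chrom is a hard error", {
  t1 <- mk_tm(c(0, 100), tid = "a", gid = "g1")
  t2 <- mk_tm(c(0, 100), tid = "b", gid = "g2")
  expect_error(pairwise_events(t1, t2), "share gene")
})

test_that("pairwise comparison is symmetric", {
  set.seed(17)
  chains <- enumerate_chains(seq(100, 700, by = 100), max_exons = 3)
  for (i in 1:60) {
    b <- sample(chains, 2)
    strand <- sample(c("+", "-"), 1)
    p <- mk_pair(b[[1]], b[[2]], strand = strand)
    e12 <- pairwise_events(p[[1]], p[[2]])
    e21 <- pairwise_events(p[[2]], p[[1]])
    expect_equal(e12[c("event_type", "flank_left", "flank_right",
                       "variant_sites")],
                 e21[c("event_type", "flank_left", "flank_right",
                       "variant_sites")])
  }
})

test_that("classification agrees with the exon-geometry oracle", {
  set.seed(18)
  chains <- enumerate_chains(seq(100, 800, by = 100), max_exons = 4)
  for (i in 1:400) {
    b <- sample(chains, 2)
    strand <- sample(c("+", "-"), 1)
    p <- mk_pair(b[[1]], b[[2]], strand = strand)
    got <- sort(pairwise_events(p[[1]], p[[2]])$event_type)
    want <- oracle_pair_events(p[[1]], p[[2]])
    expect_identical(got, want)
  }
})

test_that("gene-level events deduplicate shared bubbles", {
  ann <- mk_ann(mk_exons(c(0, 200, 300, 500), tid = "t1"),
                mk_exons(c(0, 500), tid = "t2"),
                mk_exons(c(0, 500), tid = "t3"))
  ev <- gene_events(ann, "g1")
  # the same IR bubble appears in pairs (t1,t2) and (t1,t3): counted once
  expect_equal(sum(ev$event_type == "IR"), 1L)
  # single-transcript genes contribute nothing
  solo <- mk_ann(mk_exons(c(0, 100)))
  expect_equal(nrow(gene_events(solo, "g1")), 0L)
})

test_that("planted simulator events are recovered exactly by type", {
  cfg <- simulation_config(seed = 23, n_genes = 14,
                           planted_events = c(IR = 5L, ES = 4L, AA = 4L,
                                              AD = 4L, MX = 3L))
  sim <- generate_annotation(cfg, generate_genome(cfg))
  es <- summarize_events(sim$annotation)
  truth <- table(sim$manifest$events$type)
  for (ty in names(truth))
    expect_equal(es$by_type$n_events[es$by_type$type == ty],
                 unname(truth[ty]), label = ty)
  expect_equal(es$by_type$n_events[es$by_type$type == "other"], 0L)
})

test_that("event summary percentages use the documented denominators", {
  ann <- mk_ann(mk_exons(c(0, 200, 300, 500), tid = "t1", gid = "gA"),
                mk_exons(c(0, 500), tid = "t2", gid = "gA"),
                mk_exons(c(1000, 1100, 1200, 1400), tid = "t3", gid = "gB"),
                mk_exons(c(1000, 1100, 1240, 1400), tid = "t4", gid = "gB"))
  es <- summarize_events(ann)
  expect_equal(es$total_events, 2L)
  expect_equal(es$total_as_genes, 2L)
  ir <- es$by_type[es$by_type$type == "IR", ]
  expect_equal(ir$pct_events, 50)
  expect_equal(ir$pct_genes, 50)
  # fraction identity: pct * total / 100 == count (within rounding)
  for (i in seq_len(nrow(es$by_type)))
    expect_lt(abs(es$by_type$pct_events[i] * es$total_events / 100 -
                    es$by_type$n_events[i]), 0.01 * es$total_events + 1e-9)
})

test_that("annotations with only single-transcript genes give all zeros", {
  ann <- mk_ann(mk_exons(c(0, 100), tid = "t1", gid = "g1"),
                mk_exons(c(500, 700), tid = "t2", gid = "g2"))
  es <- summarize_events(ann)
  expect_equal(es$total_events, 0L)
  expect_true(all(es$by_type$n_events == 0))
})

test_that("isoform-count ratios and groups match the log2 thresholds", {
  q <- mk_ann(do.call(rbind, lapply(1:15, function(i)
    mk_exons(c(0, 100), tid = paste0("q", i), gid = "gX"))),
    mk_exons(c(500, 700), tid = "q16", gid = "gY"))
  r <- mk_ann(mk_exons(c(0, 100), tid = "r1", gid = "gX"),
              do.call(rbind, lapply(1:5, function(i)
                mk_exons(c(500, 700), tid = paste0("r", i + 1), gid = "gY"))))
  out <- isoform_count_ratio(q, r)
  gx <- out[out$gene_id == "gX", ]
  expect_equal(round(gx$log2_ratio, 2), 3.91)
  expect_equal(gx$group, "III")
  gy <- out[out$gene_id == "gY", ]
  expect_equal(round(gy$log2_ratio, 2), -2.32)
  expect_equal(gy$group, "I")
  expect_equal(isoform_ratio_group(0), "II")
  expect_equal(isoform_ratio_group(c(-1, 1, 0.99)), c("I", "III", "II"))
})
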