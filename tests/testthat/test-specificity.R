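mk_matrix <- function(rows, samples) {
  m <- do.call(rbind, rows)
  dimnames(m) <- list(names(rows), samples)
  m
}

test_that("JS specificity closed forms", {
  one <- js_specificity(c(root = 10, leaf = 0, flower = 0))
  expect_equal(one$max_score, 1)
  expect_equal(one$argmax, "root")

  # uniform over two tissues: 1 - sqrt(H(3/4, 1/4) - 1/2)
  two <- js_specificity(c(a = 1, b = 1))
  h <- -(0.75 * log2(0.75) + 0.25 * log2(0.25))
  expect_equal(unname(two$scores["a"]), 1 - sqrt(h - 0.5), tolerance = 1e-12)
  expect_equal(round(two$max_score, 4), 0.4421)

  zero <- js_specificity(c(a = 0, b = 0))
  expect_true(zero$undefined)
  expect_true(is.na(zero$max_score))
})

test_that("JS scores are scale-invariant, bounded, and maximal iff exclusive", {
  set.seed(71)
  for (i in 1:30) {
    x <- stats::runif(sample(2:6, 1), 0, 50)
    if (sum(x) == 0) next
    s1 <- js_specificity(x)
    s2 <- js_specificity(x * stats::runif(1, 0.01, 100))
    expect_equal(s1$scores, s2$scores, tolerance = 1e-9)
    expect_true(all(s1$scores >= 0 & s1$scores <= 1))
    expect_equal(s1$max_score == 1, sum(x > 0) == 1)
  }
  # argmax ties break lexicographically
  tie <- js_specificity(c(b = 2, a = 2))
  expect_equal(tie$argmax, "a")
})

test_that("KS comparison matches closed forms and the brute-force oracle", {
  expect_equal(compare_score_distributions(c(1, 2, 3), c(1, 2, 3))$D, 0)
  expect_equal(compare_score_distributions(c(1, 2), c(5, 6))$D, 1)
  set.seed(72)
  for (i in 1:10) {
    a <- rnorm(sample(10:100, 1))
    b <- rnorm(sample(10:100, 1), mean = runif(1, -1, 1))
    got <- compare_score_distributions(a, b)$D
    expect_equal(got, oracle_ks_d(a, b), tolerance = 1e-12)
  }
  expect_error(compare_score_distributions(numeric(0), 1), "non-empty")
})

test_that("exclusive isoforms follow the presence rule", {
  samples <- c("r1", "r2", "l1", "l2")
  groups <- setNames(c("root", "root", "leaf", "leaf"), samples)
  m <- mk_matrix(list(only_root = c(5, 0, 0, 0),
                      both = c(2, 2, 3, 3),
                      weak = c(0.05, 0.09, 0, 0),
                      only_leaf = c(0, 0, 0.2, 0)), samples)
  es <- exclusive_isoforms(m, groups, presence_threshold = 0.1)
  expect_equal(es$exclusive$root, "only_root")
  expect_equal(es$exclusive$leaf, "only_leaf")
  expect_equal(unname(es$combos["leaf+root"]), 1L)
  expect_false("weak" %in% unlist(es$exclusive))
  # exclusive sets are pairwise disjoint
  expect_equal(anyDuplicated(unlist(es$exclusive)), 0L)
  # invariant to sample order
  perm <- sample(ncol(m))
  es2 <- exclusive_isoforms(m[, perm], groups, presence_threshold = 0.1)
  expect_equal(es2$exclusive, es$exclusive)
  expect_error(exclusive_isoforms(m, factor(groups,
                                            levels = c("root", "leaf", "x")),
                                  0.1), "without samples")
})

test_that("planted exclusives are recovered exactly at zero noise", {
  cfg <- simulation_config(seed = 81, n_genes = 20,
                           planted_events = c(IR = 5L),
                           exclusive_fraction = 0.4)
  sim <- generate_annotation(cfg, generate_genome(cfg))
  ex <- simulate_expression(cfg, sim$annotation, mode = "tissue")
  es <- exclusive_isoforms(ex$values, ex$groups)
  man <- ex$manifest
  for (g in cfg$tissues) {
    want <- sort(man$isoform[!is.na(man$exclusive_group) &
                               man$exclusive_group == g])
    expect_equal(sort(es$exclusive[[g]]), want, label = g)
  }
  # single-group isoforms score 1
  if (length(es$exclusive$peg)) {
    js <- js_specificity_matrix(ex$values, ex$groups)
    expect_true(all(js$max_score[js$isoform %in% es$exclusive$peg] == 1))
  }
})

test_that("stage-exclusive isoforms report parent-gene counts", {
  samples <- paste0("S", rep(1:4, each = 1))
  stages <- setNames(samples, samples)
  m <- mk_matrix(list(a1 = c(5, 0, 0, 0), a2 = c(3, 0, 0, 0),
                      b1 = c(0, 2, 0, 0), everywhere = c(1, 1, 1, 1),
                      s12 = c(4, 4, 0, 0)), samples)
  gene_map <- c(a1 = "gA", a2 = "gA", b1 = "gB", everywhere = "gC",
                s12 = "gD")
  out <- stage_specific(m, stages, gene_map)
  expect_equal(unname(out$isoform_counts[c("S1", "S2", "S3", "S4")]),
               c(2L, 1L, 0L, 0L))
  expect_equal(unname(out$gene_counts["S1"]), 1L)   # a1, a2 share gene gA
  expect_false("s12" %in% unlist(out$exclusive_set$exclusive))
})

test_that("differential selection keeps contrasting isoforms", {
  samples <- paste0("S", 1:4)
  stages <- setNames(samples, samples)
  m <- mk_matrix(list(flat = c(5, 5, 5, 5), rising = c(1, 2, 4, 8),
                      low = c(0.1, 0.2, 0.4, 0.8), off_on = c(0, 0, 3, 3)),
                 samples)
  kept <- select_differential(m, stages)
  expect_setequal(kept, c("rising", "off_on"))
})

test_that("time-course clustering labels monotone trends", {
  samples <- paste0("S", 1:4)
  stages <- setNames(samples, samples)
  m <- mk_matrix(list(up = c(1, 2, 3, 4), down = c(8, 4, 2, 1),
                      up2 = c(2, 3, 5, 9), flat = c(3, 3, 3, 3)), samples)
  expect_message(cl <- timecourse_clusters(m, stages), "constant profile")
  expect_equal(cl$cluster[cl$isoform == "up"], "up")
  expect_equal(cl$cluster[cl$isoform == "up2"], "up")
  expect_equal(cl$cluster[cl$isoform == "down"], "down")
  expect_false("flat" %in% cl$isoform)
})

test_that("planted up/down trends are recovered at >= 95% agreement", {
  # 150 isoforms, half of the shared ones carrying planted trends
  ex_rows <- do.call(rbind, lapply(1:150, function(i)
    mk_exons(c(0, 2000), tid = paste0("iso", i), gid = paste0("gene", i),
             chrom = "chr1")))
  ann <- annotation_set(ex_rows)
  cfg <- simulation_config(seed = 91, exclusive_fraction = 0.2,
                           trend_fraction = 0.9)
  ex <- simulate_expression(cfg, ann, mode = "stage")
  man <- ex$manifest
  planted <- man[man$trend %in% c("up", "down"), ]
  expect_gte(nrow(planted), 100)
  cl <- timecourse_clusters(ex$values[planted$isoform, ], ex$groups)
  agree <- mean(cl$cluster == planted$trend[match(cl$isoform,
                                                  planted$isoform)])
  expect_gte(agree, 0.95)
})

test_that("expression matrices round-trip with their sample mapping", {
  samples <- c("r1", "l1")
  groups <- setNames(c("root", "leaf"), samples)
  m <- mk_matrix(list(x = c(1.5, 0), y = c(2, 3)), samples)
  f <- withr::local_tempfile(fileext = ".tsv")
  fm <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(m, groups, f, fm)
  back <- read_expression_matrix(f, fm)
  expect_equal(back$values, m)
  expect_equal(back$groups, groups)
})
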