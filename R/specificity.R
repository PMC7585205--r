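#' Read or write an expression matrix with sample grouping
#'
#' The matrix is TSV with isoform ids in the first column and one column
#' per sample (FPKM-like non-negative values); the sidecar mapping is TSV
#' with columns `sample` and `group` (tissue or stage).
#'
#' @param path Matrix TSV path.
#' @param mapping_path Sidecar TSV path mapping samples to groups.
#' @return List with `values` (numeric matrix, isoforms x samples) and
#'   `groups` (named character vector, sample -> group).
#' @export
read_expression_matrix <- function(path, mapping_path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  ids <- df[[1]]
  if (anyDuplicated(ids)) stop2("duplicate isoform ids in ", path)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- ids
  if (any(values < 0)) stop2("negative abundance values in ", path)
  map <- read.table(mapping_path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(map)))
    stop2("mapping needs `sample` and `group` columns")
  groups <- setNames(map$group, map$sample)
  missing_samples <- setdiff(colnames(values), names(groups))
  if (length(missing_samples))
    stop2("samples without group mapping: ", comma(missing_samples))
  list(values = values, groups = groups[colnames(values)])
}

#' @rdname read_expression_matrix
#' @param values Numeric matrix (isoforms x samples).
#' @param groups Named character vector mapping samples to groups.
#' @export
write_expression_matrix <- function(values, groups, path, mapping_path) {
  df <- data.frame(isoform = rownames(values), values, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample = names(groups), group = unname(groups)),
              mapping_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

presence_by_group <- function(values, groups, presence_threshold) {
  stopifnot(is.matrix(values))
  lv <- if (is.factor(groups)) levels(groups) else
    unique(unname(groups[colnames(values)]))
  groups <- as.character(groups)[match(colnames(values), names(groups))]
  names(groups) <- colnames(values)
  pres <- vapply(lv, function(g) {
    cols <- which(groups == g)
    if (length(cols) == 0L) stop2("group without samples: ", g)
    apply(values[, cols, drop = FALSE] >= presence_threshold, 1, any)
  }, logical(nrow(values)))
  if (nrow(values) == 1L) pres <- matrix(pres, nrow = 1,
                                         dimnames = list(rownames(values), lv))
  pres
}

#' Group-exclusive isoforms and overlap counts
#'
#' An isoform is present in a group when any sample of the group reaches
#' the presence threshold, and exclusive to the group when present there
#' and nowhere else. All presence-pattern combination counts are returned
#' for Venn-style rendering.
#'
#' @param values Numeric matrix (isoforms x samples), non-negative.
#' @param groups Named character vector mapping samples to groups (at least
#'   two distinct groups).
#' @param presence_threshold Detection threshold on the abundance value
#'   (default 0.1).
#' @return List of class `exclusive_set`: `exclusive` (named list of
#'   isoform-id vectors per group), `combos` (named count vector over
#'   presence patterns like `"leaf+root"`), `presence` (logical matrix
#'   isoforms x groups).
#' @export
exclusive_isoforms <- function(values, groups, presence_threshold = 0.1) {
  if (length(unique(unname(groups[colnames(values)]))) < 2L)
    stop2("at least two groups are required")
  pres <- presence_by_group(values, groups, presence_threshold)
  lv <- colnames(pres)
  exclusive <- lapply(lv, function(g)
    rownames(pres)[pres[, g] & rowSums(pres) == 1L])
  names(exclusive) <- lv
  pattern <- apply(pres, 1, function(p)
    paste(sort(lv[p]), collapse = "+"))
  pattern <- pattern[nzchar(pattern)]
  combos <- table(pattern)
  structure(list(exclusive = exclusive,
                 combos = setNames(as.integer(combos), names(combos)),
                 presence = pres),
            class = "exclusive_set")
}

#' @export
print.exclusive_set <- function(x, ...) {
  cat("group-exclusive isoforms:\n")
  for (g in names(x$exclusive))
    cat("  ", g, ": ", length(x$exclusive[[g]]), "\n", sep = "")
  invisible(x)
}

# base-2 Shannon entropy with 0 log 0 := 0
entropy2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Jensen-Shannon divergence of two distributions (base-2; bounded by 1)
js_divergence <- function(p, q) {
  m <- (p + q) / 2
  entropy2(m) - (entropy2(p) + entropy2(q)) / 2
}

#' Jensen-Shannon tissue-specificity scores
#'
#' The expression vector is normalised to a distribution p; the score for
#' tissue t is `1 - sqrt(JSD(p, e_t))`, where e_t is the ideal pattern
#' expressed only in t and JSD is the Jensen-Shannon divergence with
#' base-2 entropy (so scores lie in \[0, 1\]). The square-root transform
#' makes the distance a metric. A score of 1 means expression confined to
#' one tissue; the maximal score and its tissue are reported, ties broken
#' lexicographically by tissue label.
#'
#' @param x Non-negative expression vector across tissues (named, or
#'   `labels` given).
#' @param labels Optional tissue labels.
#' @return List of class `js_specificity`: `p` (normalised pattern),
#'   `scores` (per tissue), `max_score`, `argmax`, `undefined` (TRUE for an
#'   all-zero input, in which case scores are NA and the isoform should be
#'   excluded from score distributions).
#' @examples
#' js_specificity(c(root = 10, leaf = 0, flower = 0))$max_score # 1
#' @export
js_specificity <- function(x, labels = NULL) {
  if (is.null(labels)) labels <- names(x)
  x <- as.numeric(x)
  if (any(x < 0) || any(!is.finite(x))) stop2("expression must be >= 0")
  if (is.null(labels)) labels <- paste0("tissue", seq_along(x))
  if (sum(x) == 0) {
    return(structure(list(p = rep(NA_real_, length(x)),
                          scores = setNames(rep(NA_real_, length(x)), labels),
                          max_score = NA_real_, argmax = NA_character_,
                          undefined = TRUE), class = "js_specificity"))
  }
  p <- x / sum(x)
  scores <- vapply(seq_along(x), function(t) {
    e <- rep(0, length(x)); e[t] <- 1
    1 - sqrt(js_divergence(p, e))
  }, numeric(1))
  names(scores) <- labels
  ord <- order(-scores, labels)
  structure(list(p = setNames(p, labels), scores = scores,
                 max_score = scores[[ord[1]]], argmax = labels[ord[1]],
                 undefined = FALSE), class = "js_specificity")
}

#' JS specificity for every isoform of an expression matrix
#'
#' Samples are first averaged within tissue groups; all-zero isoforms are
#' flagged undefined and excluded.
#'
#' @inheritParams exclusive_isoforms
#' @return data.frame: `isoform`, `max_score`, `argmax`, plus one score
#'   column per tissue. All-zero isoforms are dropped (with a message).
#' @export
js_specificity_matrix <- function(values, groups) {
  groups <- groups[colnames(values)]
  lv <- sort(unique(unname(groups)))
  means <- vapply(lv, function(g)
    rowMeans(values[, groups == g, drop = FALSE]), numeric(nrow(values)))
  if (nrow(values) == 1L)
    means <- matrix(means, nrow = 1, dimnames = list(rownames(values), lv))
  zero <- rowSums(means) == 0
  if (any(zero))
    message(sum(zero), " all-zero isoform(s) excluded from JS scoring")
  means <- means[!zero, , drop = FALSE]
  res <- lapply(seq_len(nrow(means)), function(i)
    js_specificity(means[i, ], labels = lv))
  scores <- do.call(rbind, lapply(res, `[[`, "scores"))
  data.frame(isoform = rownames(means),
             max_score = vapply(res, `[[`, numeric(1), "max_score"),
             argmax = vapply(res, `[[`, character(1), "argmax"),
             scores, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Compare two score distributions (two-sample KS test)
#'
#' Two-sided two-sample Kolmogorov-Smirnov test: D is the supremum distance
#' between the empirical CDFs, with the asymptotic p-value.
#'
#' @param scores_a,scores_b Non-empty numeric samples.
#' @return List with `D` and `p_value`.
#' @export
compare_score_distributions <- function(scores_a, scores_b) {
  if (length(scores_a) == 0L || length(scores_b) == 0L)
    stop2("both samples must be non-empty")
  kt <- suppressWarnings(stats::ks.test(scores_a, scores_b, exact = FALSE))
  list(D = unname(kt$statistic), p_value = kt$p.value)
}

#' Stage-exclusive isoforms with parent-gene counts
#'
#' Applies [exclusive_isoforms()] to a stage-resolved matrix and counts the
#' distinct parent genes of each stage's exclusive isoforms.
#'
#' @inheritParams exclusive_isoforms
#' @param stages Named character vector mapping samples to ordered stages.
#' @param gene_map Named character vector mapping isoform ids to gene ids.
#' @return List: `exclusive_set` (see [exclusive_isoforms()]),
#'   `isoform_counts` and `gene_counts` (named by stage).
#' @export
stage_specific <- function(values, stages, gene_map,
                           presence_threshold = 0.1) {
  es <- exclusive_isoforms(values, stages, presence_threshold)
  iso_counts <- vapply(es$exclusive, length, integer(1))
  gene_counts <- vapply(es$exclusive, function(ids)
    length(unique(gene_map[ids])), integer(1))
  list(exclusive_set = es, isoform_counts = iso_counts,
       gene_counts = gene_counts)
}

#' Select differentially expressed isoforms across stages
#'
#' A simple stage-contrast filter standing in for a formal
#' differential-expression test: an isoform is kept when its largest stage
#' mean is at least `min_expr` and at least `min_fold` times its smallest
#' stage mean (isoforms absent in some stage pass the fold criterion by
#' construction).
#'
#' @inheritParams stage_specific
#' @param min_fold Minimum max/min stage-mean fold change (default 2).
#' @param min_expr Minimum maximal stage mean (default 1.0).
#' @return Character vector of isoform ids.
#' @export
select_differential <- function(values, stages, min_fold = 2,
                                min_expr = 1.0) {
  stages <- stages[colnames(values)]
  lv <- unique(unname(stages))
  means <- vapply(lv, function(g)
    rowMeans(values[, stages == g, drop = FALSE]), numeric(nrow(values)))
  if (nrow(values) == 1L)
    means <- matrix(means, nrow = 1, dimnames = list(rownames(values), lv))
  mx <- apply(means, 1, max)
  mn <- apply(means, 1, min)
  rownames(values)[mx >= min_expr & mx >= min_fold * mn]
}

#' Cluster time-course profiles into monotone trend groups
#'
#' Stage-mean profiles are z-scored per isoform and clustered with k-means
#' (fixed seed, multiple random starts); clusters are relabelled `up` or
#' `down` by the sign of the mean last-minus-first difference of their
#' member profiles. Constant (zero-variance) profiles cannot be z-scored
#' and are excluded with a message.
#'
#' @param values Numeric matrix, isoforms x samples.
#' @param stages Named character vector mapping samples to ordered stages;
#'   order of first appearance defines the time order.
#' @param k Number of clusters (default 2).
#' @param seed RNG seed for k-means initialisation (default 1).
#' @return data.frame `isoform`, `cluster` (`up`/`down`); z-scored profiles
#'   in `attr(, "profiles")`.
#' @export
timecourse_clusters <- function(values, stages, k = 2, seed = 1) {
  stages <- stages[colnames(values)]
  lv <- unique(unname(stages))
  if (length(lv) < 2L) stop2("need at least two stages")
  means <- vapply(lv, function(g)
    rowMeans(values[, stages == g, drop = FALSE]), numeric(nrow(values)))
  if (nrow(values) == 1L)
    means <- matrix(means, nrow = 1, dimnames = list(rownames(values), lv))
  sds <- apply(means, 1, sd)
  flat <- sds == 0 | !is.finite(sds)
  if (any(flat))
    message(sum(flat), " constant profile(s) excluded from clustering")
  means <- means[!flat, , drop = FALSE]
  if (nrow(means) < k) stop2("fewer usable profiles than clusters")
  z <- t(scale(t(means)))
  km <- with_seed(seed, kmeans(z, centers = k, nstart = 10))
  delta <- z[, ncol(z)] - z[, 1]
  lab <- vapply(seq_len(k), function(c)
    if (mean(delta[km$cluster == c]) >= 0) "up" else "down", character(1))
  out <- data.frame(isoform = rownames(z), cluster = lab[km$cluster],
                    stringsAsFactors = FALSE)
  attr(out, "profiles") <- z
  out
}
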