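test_that("Fisher enrichment matches enumeration and worked examples", {
  # symmetric 2x2 of ones: P = 5/6 by enumerating the hypergeometric support
  expect_equal(fisher_enrichment(c(1, 1, 1, 1))$p_value, 5 / 6)
  # perfect separation 5/0/0/5: only one table as or more extreme: 1/C(10,5)
  expect_equal(fisher_enrichment(c(5, 0, 0, 5))$p_value, 1 / choose(10, 5))
  # random tables vs the choose()-based enumeration oracle
  set.seed(15)
  for (k in 1:50) {
    tab <- matrix(rpois(4, 6), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_enrichment(tab)$p_value,
                 bf_fisher_greater(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 tolerance = 1e-9)
  }
  # sample odds ratio, two-sided option, degenerate input
  fr <- fisher_enrichment(matrix(c(20, 15, 48, 120), 2, byrow = TRUE))
  expect_equal(fr$odds_ratio, (20 * 120) / (15 * 48))
  expect_equal(fisher_enrichment(c(2, 8, 8, 2), "two.sided")$p_value,
               fisher.test(matrix(c(2, 8, 8, 2), 2, byrow = TRUE))$p.value)
  expect_error(fisher_enrichment(c(0, 0, 0, 0)), "all-zero")
})

test_that("co-regulation P-values are hypergeometric and monotone in overlap", {
  universe <- sprintf("g%04d", 1:2000)
  s1 <- universe[1:50]
  sets <- list(A = s1, B = s1, C = universe[1001:1050])
  res <- coregulation_pairs(sets, universe, alpha = 0.05)
  ab <- res$pairs[res$pairs$tf1 == "A" & res$pairs$tf2 == "B", ]
  expect_lt(ab$p, 1e-20)   # identical 50-gene sets overlap maximally
  expect_true(all(c("A", "B") %in% unlist(res$significant[, 1:2])))
  expect_lte(nrow(res$pairs), 3L)  # T(T-1)/2 bound
  # P decreases as the overlap grows at fixed set sizes
  ps <- vapply(c(2, 5, 10, 20), function(ov) {
    sets2 <- list(X = universe[1:50], Y = c(universe[1:ov], universe[100:(149 - ov)]))
    coregulation_pairs(sets2, universe)$pairs$p
  }, 0)
  expect_true(all(diff(ps) < 0))
  # one-sided Fisher equivalence on one pair
  ov <- length(intersect(sets$A, sets$C))
  tab <- matrix(c(ov, 50 - ov, 50 - ov, 2000 - 100 + ov), 2, byrow = TRUE)
  expect_equal(res$pairs$p[res$pairs$tf1 == "A" & res$pairs$tf2 == "C"],
               fisher.test(tab, alternative = "greater")$p.value,
               tolerance = 1e-9)
  # class composition with sensitivity labels
  res2 <- coregulation_pairs(sets, universe,
                             labels = c(A = TRUE, B = TRUE, C = FALSE))
  expect_equal(unname(res2$class_counts["SS"]), 1L)
  expect_error(coregulation_pairs(sets["A"], universe), "at least 2")
  expect_error(coregulation_pairs(sets, character()), "empty universe")
})

test_that("genome binning tiles contigs and labels by peak overlap", {
  bins <- bin_genome_and_label(c(chrI = 1000L), width = 100L,
                               peaks = data.frame(contig = "chrI",
                                                  start = 250L, end = 420L))
  expect_equal(nrow(bins), 10L)
  expect_equal(bins$start, seq(0L, 900L, 100L))
  pos <- bins$start[bins$label == 1L]
  expect_equal(pos, c(200L, 300L, 400L))
  expect_error(bin_genome_and_label(integer(), peaks = NULL), "empty genome")
  # splitting a peak into abutting pieces leaves labels unchanged
  split_peaks <- data.frame(contig = "chrI", start = c(250L, 300L, 350L),
                            end = c(300L, 350L, 420L))
  bins2 <- bin_genome_and_label(c(chrI = 1000L), width = 100L, peaks = split_peaks)
  expect_equal(bins$label, bins2$label)
  # brute-force overlap enumeration on random peak sets
  set.seed(16)
  for (k in 1:20) {
    pk <- data.frame(contig = "chrI", start = sample(0:900, 5))
    pk$end <- pk$start + sample(10:300, 5, TRUE)
    got <- bin_genome_and_label(c(chrI = 1000L), 100L, pk)
    want <- vapply(seq(0L, 900L, 100L), function(s) {
      as.integer(any(pk$start < s + 100L & pk$end > s))
    }, 0L)
    expect_equal(got$label, want)
  }
})

test_that("rank-sum group comparison detects shifts and respects nulls", {
  set.seed(17)
  # planted 1 SD shift, n = 30/30: significant in most draws
  hits <- vapply(1:50, function(i) {
    v <- c(rnorm(30, 1), rnorm(30))
    names(v) <- paste0("TF", 1:60)
    lab <- stats::setNames(rep(c(TRUE, FALSE), each = 30), names(v))
    group_attribute_compare(lab, v)$p_value < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.8)
  # null: rejection close to the nominal rate
  null_hits <- vapply(1:200, function(i) {
    v <- rnorm(60); names(v) <- paste0("TF", 1:60)
    lab <- stats::setNames(rep(c(TRUE, FALSE), each = 30), names(v))
    group_attribute_compare(lab, v)$p_value < 0.05
  }, TRUE)
  expect_lte(mean(null_hits), 0.08)
  v <- rnorm(5); names(v) <- paste0("TF", 1:5)
  expect_error(group_attribute_compare(
    stats::setNames(rep(TRUE, 5), names(v)), v), "nonempty")
})

test_that("TFBS classification applies the ChIP and proximity filters", {
  gene_pvals <- c(gA = 0.001, gB = 0.8, gC = 0.6, gD = 0.2)
  sites <- data.frame(
    gene_id = c("gA", "gB", "gC", "gD"),
    contig = "chrI",
    start = c(1000L, 2010L, 4020L, 7000L),
    end = c(1010L, 2020L, 4030L, 7010L))
  cls <- classify_tfbs(sites, gene_pvals, exclusion_bp = 2000L)
  expect_equal(cls$verified$gene_id, "gA")
  # gB's site is 1 kb from the verified site -> excluded; gC at 3 kb -> kept
  expect_equal(cls$nonverified$gene_id, "gC")
  expect_equal(unname(cls$counts["excluded_near_verified"]), 1L)
  # gD (P = 0.2) is neither clearly bound nor clearly unbound
  expect_false("gD" %in% c(cls$verified$gene_id, cls$nonverified$gene_id))
})

test_that("site-level contrasts recover planted occupancy depletion", {
  # deterministic motifs isolate the chromatin contrast from scan misses
  w <- cached_world("sites1", synthetic_config(
    n_genes = 600L, n_tfs = 4L, orf_len = 400L, target_prevalence = 0.2,
    two_conditions = FALSE, motif_plant_prob = 1.0,
    motif_concentration = 1.0, seed = 23L))
  tf <- w$tf_info$tf[w$tf_info$direct][1]
  sites <- promoter_motif_sites(w$pssms[[tf]], w$genome, w$annotation,
                                w$config$promoter_len,
                                bg = background_from_gc(w$config$gc))
  # every planted consensus instance is rediscovered by the scan
  planted <- w$truth$planted_sites[w$truth$planted_sites$tf == tf, ]
  key <- function(df) paste(df$gene_id, df$start, df$end)
  expect_gt(mean(key(planted) %in% key(sites)), 0.99)
  cls <- classify_tfbs(sites, w$pvalues$A[, tf], dedupe_per_gene = TRUE)
  res <- verified_vs_nonverified(cls, w$tracks$A)
  occ <- res[res$modification %in% w$truth$occupancy_mods, ]
  # bound (verified) sites carry the planted occupancy depletion
  expect_true(all(occ$t < 0))
  expect_true(all(occ$p < 0.01))
  expect_error(verified_vs_nonverified(
    list(verified = cls$verified[0, ], nonverified = cls$nonverified),
    w$tracks$A), "nonempty")
})

test_that("condition comparison errors when a condition lacks genes", {
  fx_w <- small_world(77L)
  sigA <- world_signals(fx_w, "A")
  labels <- call_targets(fx_w$pvalues$B)[, 1]
  sig_sub <- sigA[1:50, , drop = FALSE]
  attr(sig_sub, "col_info") <- attr(sigA, "col_info")
  class(sig_sub) <- class(sigA)
  ms <- stats::setNames(runif(nrow(sigA)), rownames(sigA))
  expect_error(condition_compare(labels, sig_sub, sigA, ms), "missing from one condition")
})

test_that("cross-PSSM matrix has the right shape with own-PSSM diagonal", {
  w <- cached_world("xp1", synthetic_config(
    n_genes = 600L, n_tfs = 3L, orf_len = 400L, target_prevalence = 0.12,
    two_conditions = FALSE, seed = 31L))
  sig <- world_signals(w)
  labels <- call_targets(w$pvalues$A)
  prom <- promoter_sequences(w$genome, w$annotation, w$config$promoter_len)
  ms <- lapply(w$pssms, function(p) cumulative_scores(p, prom))
  res <- cross_pssm_aucs(labels, sig, ms, repeats = 1L, seed = 3L)
  expect_equal(dim(res$auc), c(3L, 3L))
  expect_equal(rownames(res$auc), colnames(res$auc))
  expect_true(all(is.na(res$auc) | (res$auc >= 0 & res$auc <= 1)))
})
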