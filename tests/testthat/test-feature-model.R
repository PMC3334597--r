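test_that("target calling uses a strict P-value cutoff", {
  p <- c(g1 = 0.005, g2 = 0.01, g3 = 0.5, g4 = NA)
  lab <- call_targets(p, cutoff = 0.01)
  expect_equal(lab[["g1"]], 1L)   # below the cutoff: target
  expect_equal(lab[["g2"]], 0L)   # exactly the cutoff: non-target
  expect_equal(lab[["g3"]], 0L)
  expect_true(is.na(lab[["g4"]]))
  expect_error(call_targets(p, cutoff = 0), "strictly between")
  expect_error(call_targets(c(g1 = 1.5)), "outside")
  m <- matrix(c(0.001, 0.2), 2, 1, dimnames = list(c("a", "b"), "TF1"))
  expect_equal(unname(call_targets(m)[, 1]), c(1L, 0L))
})

make_signals <- function(n = 60, n_mods = 3, seed = 1) {
  set.seed(seed)
  genes <- sprintf("g%03d", 1:n)
  probes <- data.frame(contig = "chrI", start = seq(0L, by = 50L, length.out = n * 40L))
  probes$end <- probes$start + 50L
  mods <- lapply(seq_len(n_mods), function(i) {
    probes$value <- rnorm(nrow(probes)); probes
  })
  names(mods) <- paste0("m", seq_len(n_mods))
  ann <- data.frame(gene_id = genes, contig = "chrI",
                    atg = seq(500L, by = 2000L, length.out = n),
                    strand = "+", stringsAsFactors = FALSE)
  ann$orf_start <- ann$atg; ann$orf_end <- ann$atg + 600L
  ann$ir_start <- ann$atg - 400L; ann$ir_end <- ann$atg
  build_gene_signal_matrix(ann, signal_track(mods), widths = c(500L, 1000L))
}

test_that("feature assembly selects the requested groups and columns", {
  sig <- make_signals(n = 60, n_mods = 3)
  genes <- rownames(sig)
  labels <- stats::setNames(rep(c(1L, 0L), c(12, 48)), genes)
  ms <- stats::setNames(runif(60), genes)
  expr <- stats::setNames(rlnorm(60), genes)
  ft_p <- assemble_features(labels, motif_scores = ms, groups = "pssm")
  expect_equal(ncol(ft_p$x), 1L)
  ft_hm <- assemble_features(labels, signals = sig, groups = "hm",
                             regions = c("up1000", "down1000"))
  expect_equal(ncol(ft_hm$x), 6L)  # 3 modifications x 2 regions
  ft_all <- assemble_features(labels, signals = sig, motif_scores = ms,
                              expression = expr,
                              groups = c("hm", "pssm", "expression"))
  expect_equal(ncol(ft_all$x), 8L)
  expect_true("expression" %in% colnames(ft_all$x))
  # genes with missing labels are dropped
  labels2 <- labels; labels2[1:5] <- NA
  ft2 <- assemble_features(labels2, motif_scores = ms, groups = "pssm")
  expect_equal(nrow(ft2$x), 55L)
  # disjoint gene sets are an error
  expect_error(assemble_features(stats::setNames(1L, "zz"),
                                 motif_scores = ms, groups = "pssm"),
               "empty intersection|both classes")
  # single-class labels are an error
  expect_error(assemble_features(stats::setNames(rep(0L, 60), genes),
                                 motif_scores = ms, groups = "pssm"),
               "both classes")
})

test_that("rank AUC matches concordant-pair enumeration", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))$auc, 0.75)
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), "both classes")
  set.seed(2)
  for (k in 1:50) {
    n <- sample(6:30, 1)
    scores <- round(runif(n), 2)  # coarse scores force ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, bf_auc(scores, labels))
    expect_true(all(diff(r$roc$fpr) >= 0))
    expect_true(all(diff(r$roc$tpr) >= 0))
    expect_equal(utils::tail(r$roc, 1)$tpr, 1)
    # trapezoidal area under the ROC equals the rank AUC
    trap <- sum(diff(r$roc$fpr) * (utils::head(r$roc$tpr, -1) + utils::tail(r$roc$tpr, -1)) / 2)
    expect_equal(trap, r$auc, tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(3)
  scores <- rnorm(50); labels <- rbinom(50, 1, 0.3)
  a <- roc_auc(scores, labels)$auc
  expect_equal(roc_auc(exp(scores), labels)$auc, a)
  expect_equal(roc_auc(5 * scores - 2, labels)$auc, a)
  expect_equal(roc_auc(stats::plogis(scores), labels)$auc, a)
})

test_that("PPV counts true positives among the top-k", {
  expect_equal(ppv(c(0.9, 0.8, 0.7), c(1, 1, 0), 2), 1.0)
  expect_equal(ppv(c(0.9, 0.8, 0.7), c(1, 0, 1), 2), 0.5)
  labels <- rbinom(40, 1, 0.3); scores <- runif(40)
  expect_equal(ppv(scores, labels, 40), mean(labels))  # k = n -> prevalence
  expect_error(ppv(scores, labels, 0), "between 1")
})

test_that("fold standardisation uses training statistics only", {
  set.seed(4)
  train <- matrix(rnorm(200), 50, 4)
  test <- matrix(rnorm(40), 10, 4)
  std <- fold_standardize(train, test)
  expect_equal(unname(colMeans(std$train)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(std$train, 2, sd)), rep(1, 4), tolerance = 1e-12)
  # a gross outlier in the test fold must not change the train transform
  test2 <- test; test2[1, 1] <- 1e6
  std2 <- fold_standardize(train, test2)
  expect_identical(std$train, std2$train)
  expect_equal(std$test[-1, ], std2$test[-1, ])
})

test_that("cross-validation enforces preconditions and is seeded", {
  sig <- make_signals(n = 80, n_mods = 3, seed = 6)
  genes <- rownames(sig)
  set.seed(7)
  labels <- stats::setNames(rbinom(80, 1, 0.3), genes)
  ms <- stats::setNames(runif(80), genes)
  ft <- assemble_features(labels, signals = sig, motif_scores = ms)
  e1 <- cv_train_evaluate(ft, repeats = 2, folds = 2, seed = 99)
  e2 <- cv_train_evaluate(ft, repeats = 2, folds = 2, seed = 99)
  expect_equal(e1$auc, e2$auc)
  expect_equal(e1$per_fold, e2$per_fold)
  expect_equal(nrow(e1$per_fold), 4L)
  expect_true(e1$auc >= 0 && e1$auc <= 1)
  # positive-count floor
  few <- stats::setNames(c(rep(1L, 3), rep(0L, 77)), genes)
  ft_few <- assemble_features(few, signals = sig, motif_scores = ms)
  expect_error(cv_train_evaluate(ft_few, repeats = 1, min_positives = 10),
               "too few positives")
})

test_that("an informative synthetic world is learnable; noise features change little", {
  w <- cached_world("fm2000", synthetic_config(n_genes = 2000L, n_tfs = 20L,
                                               seed = 19L))
  sig <- world_signals(w)
  labels <- call_targets(w$pvalues$A)
  tf <- w$tf_info$tf[w$tf_info$sensitive & w$tf_info$direct][1]
  prom <- promoter_sequences(w$genome, w$annotation, w$config$promoter_len)
  ms <- cumulative_scores(w$pssms[[tf]], prom,
                          bg = background_from_gc(w$config$gc))
  ft <- assemble_features(labels[, tf], signals = sig, motif_scores = ms)
  ev <- cv_train_evaluate(ft, repeats = 2, folds = 2, seed = 5)
  expect_gt(ev$auc, 0.6)
  # adding pure-noise columns barely moves the AUC
  set.seed(8)
  ft_noise <- ft
  noise <- matrix(rnorm(nrow(ft$x) * 5), ncol = 5,
                  dimnames = list(rownames(ft$x), paste0("noise", 1:5)))
  ft_noise$x <- cbind(ft$x, noise)
  ev_noise <- cv_train_evaluate(ft_noise, repeats = 2, folds = 2, seed = 5)
  expect_lt(abs(ev_noise$auc - ev$auc), 0.05)
})
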