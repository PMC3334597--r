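profile_fixture <- function(n_genes = 200, seed = 1) {
  set.seed(seed)
  w <- generate_world(synthetic_config(
    n_genes = n_genes, n_tfs = 6L, orf_len = 400L,
    target_prevalence = 0.15, two_conditions = FALSE, seed = seed))
  sig <- build_gene_signal_matrix(w$annotation, w$tracks$A,
                                  contig_lengths = w$contig_lengths)
  list(world = w, sig = sig, labels = w$truth$targets$A * 1L)
}

test_that("target profiles are group means, z-normalised across TFs", {
  fx <- profile_fixture(seed = 3)
  prof <- target_mod_profiles(fx$labels, fx$sig, min_targets = 5L)
  expect_equal(ncol(prof$raw), 25L)
  # brute-force group mean per TF over the profile columns
  cols <- profile_columns(fx$sig)
  m <- unclass(fx$sig)[, cols]
  for (tf in rownames(prof$raw)) {
    genes <- rownames(fx$labels)[fx$labels[, tf] == 1L]
    expect_equal(unname(prof$raw[tf, ]), unname(colMeans(m[genes, ])),
                 tolerance = 1e-12)
  }
  # normalisation: each modification has mean 0, SD 1 across TFs
  expect_equal(unname(colMeans(prof$z)), rep(0, 25), tolerance = 1e-9)
  expect_equal(unname(apply(prof$z, 2, sd)), rep(1, 25), tolerance = 1e-9)
})

test_that("TFs below the target floor are excluded, singleton means are exact", {
  fx <- profile_fixture(seed = 4)
  labels <- fx$labels
  labels[, 1] <- 0L
  labels[1, 1] <- 1L  # single target
  expect_warning(prof <- target_mod_profiles(labels, fx$sig, min_targets = 5L),
                 "excluded")
  expect_false(colnames(labels)[1] %in% rownames(prof$raw))
  # with floor 1 the singleton profile equals that gene's signal row
  prof1 <- suppressWarnings(target_mod_profiles(labels, fx$sig, min_targets = 1L))
  cols <- profile_columns(fx$sig)
  expect_equal(unname(prof1$raw[colnames(labels)[1], ]),
               unname(unclass(fx$sig)[1, cols]))
  # zero targets anywhere -> error
  zero <- labels; zero[] <- 0L
  expect_error(suppressWarnings(target_mod_profiles(zero, fx$sig)),
               "no TF has enough targets")
})

planted_profiles <- function(n_tfs = 60, n_mods = 25, shift = 1.0,
                             n_shifted_mods = 10, frac_sens = 1 / 3, seed = 1) {
  set.seed(seed)
  sens <- rep(c(TRUE, FALSE), c(round(frac_sens * n_tfs),
                                n_tfs - round(frac_sens * n_tfs)))
  z <- matrix(rnorm(n_tfs * n_mods, sd = 0.3), n_tfs, n_mods,
              dimnames = list(sprintf("TF%02d", 1:n_tfs),
                              sprintf("m%02d", 1:n_mods)))
  signs <- sample(c(-1, 1), n_shifted_mods, TRUE)
  z[sens, seq_len(n_shifted_mods)] <-
    z[sens, seq_len(n_shifted_mods)] + rep(signs * shift, each = sum(sens))
  list(z = scale(z), sens = sens)
}

test_that("k-means recovers planted sensitivity structure and labels the high-|z| cluster", {
  agree <- vapply(1:5, function(s) {
    px <- planted_profiles(seed = s)
    lab <- cluster_sensitivity(px$z, seed = s)
    mean(lab$sensitive == px$sens)
  }, 0)
  expect_true(all(agree >= 0.9))
})

test_that("cluster labels are invariant to TF input order", {
  px <- planted_profiles(seed = 11)
  lab1 <- cluster_sensitivity(px$z, seed = 2)
  perm <- sample(nrow(px$z))
  lab2 <- cluster_sensitivity(px$z[perm, ], seed = 2)
  m <- match(lab1$tf, lab2$tf)
  expect_equal(lab1$sensitive, lab2$sensitive[m])
})

test_that("degenerate identical profiles yield an all-insensitive labelling", {
  z <- matrix(0.5, 10, 5, dimnames = list(paste0("TF", 1:10), paste0("m", 1:5)))
  expect_warning(lab <- cluster_sensitivity(z, seed = 1), "degenerate")
  expect_true(all(!lab$sensitive))
  expect_error(cluster_sensitivity(z[1, , drop = FALSE], k = 2), "fewer TFs")
})

test_that("differential profiles are Welch t-statistics with target-minus-nontarget sign", {
  fx <- profile_fixture(seed = 6)
  dp <- diff_mod_profiles(fx$labels, fx$sig)
  cols <- profile_columns(fx$sig)
  m <- unclass(fx$sig)[, cols]
  # cross-check a handful of cells against stats::t.test
  for (tf in rownames(dp$t)[1:3]) {
    grp <- fx$labels[, tf] == 1L
    for (j in c(1, 13, 25)) {
      tt <- t.test(m[grp, j], m[!grp, j])
      expect_equal(unname(dp$t[tf, j]), unname(tt$statistic), tolerance = 1e-9)
      expect_equal(unname(dp$p[tf, j]), tt$p.value, tolerance = 1e-9)
    }
  }
  # planted shift on affected modifications gives positive significant t
  w <- fx$world
  sens_tf <- w$tf_info$tf[w$tf_info$sensitive][1]
  aff_w <- intersect(w$truth$affected_mods,
                     names(w$tracks$A$groups)[w$tracks$A$groups == "windowed"])
  expect_true(all(dp$t[sens_tf, aff_w] > 0))
  expect_true(all(dp$p[sens_tf, aff_w] < 0.01))
})

test_that("null differential profiles are small; constant groups are missing", {
  set.seed(12)
  # no effect: both groups from one distribution
  vals <- matrix(rnorm(1000 * 10), 1000, 10, dimnames = list(NULL, paste0("m", 1:10)))
  grp <- rep(c(TRUE, FALSE), 500)
  w <- chromtarget:::welch_t_columns(vals, grp)
  expect_true(mean(abs(w$t) < 4) >= 0.99)
  # zero variance in both groups -> undefined t
  const <- matrix(1, 10, 2)
  wc <- chromtarget:::welch_t_columns(const, rep(c(TRUE, FALSE), 5))
  expect_true(all(is.na(wc$t)))
})

test_that("modification correlation network finds duplicated and negated columns", {
  set.seed(13)
  t0 <- matrix(rnorm(40 * 4), 40, 4, dimnames = list(NULL, paste0("m", 1:4)))
  tmat <- cbind(t0, dup = t0[, 1], neg = -t0[, 2], const = rep(1, 40))
  net <- modification_correlation_network(tmat, threshold = 0.5)
  dup_edge <- net[net$mod1 == "m1" & net$mod2 == "dup", ]
  expect_equal(dup_edge$r, 1)
  expect_equal(dup_edge$sign, "positive")
  neg_edge <- net[net$mod1 == "m2" & net$mod2 == "neg", ]
  expect_equal(neg_edge$r, -1)
  expect_equal(neg_edge$sign, "negative")
  expect_false(any(net$mod1 == "const" | net$mod2 == "const"))
  # independent columns at 100 TFs rarely exceed |r| > 0.5
  set.seed(14)
  null_edges <- vapply(1:3, function(i) {
    nrow(modification_correlation_network(
      matrix(rnorm(100 * 10), 100, 10,
             dimnames = list(NULL, paste0("x", 1:10)))))
  }, 0L)
  expect_true(all(null_edges == 0L))
})
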