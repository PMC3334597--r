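toy_ann <- function(strand = "+", atg = 5000L, orf_len = 900L,
                    ir_len = 600L) {
  if (strand == "+") {
    data.frame(gene_id = "g1", contig = "chrI", atg = atg, strand = strand,
               orf_start = atg, orf_end = atg + orf_len,
               ir_start = atg - ir_len, ir_end = atg, stringsAsFactors = FALSE)
  } else {
    data.frame(gene_id = "g1", contig = "chrI", atg = atg, strand = strand,
               orf_start = atg + 1L - orf_len, orf_end = atg + 1L,
               ir_start = atg + 1L, ir_end = atg + 1L + ir_len,
               stringsAsFactors = FALSE)
  }
}

test_that("gene windows follow the ATG-anchored definitions", {
  w <- gene_windows(toy_ann("+", 5000L), widths = 1000L)
  up <- w[w$region == "up1000", ]; dn <- w[w$region == "down1000", ]
  expect_equal(c(up$start, up$end), c(4000L, 5000L))
  expect_equal(c(dn$start, dn$end), c(5000L, 6000L))
  # minus strand: mirrored around the stored ATG base
  w2 <- gene_windows(toy_ann("-", 5000L), widths = 1000L)
  up2 <- w2[w2$region == "up1000", ]; dn2 <- w2[w2$region == "down1000", ]
  expect_equal(c(up2$start, up2$end), c(5001L, 6001L))
  expect_equal(c(dn2$start, dn2$end), c(4001L, 5001L))
  # truncation at the contig start
  w3 <- gene_windows(toy_ann("+", 300L, ir_len = 200L), widths = 1000L)
  up3 <- w3[w3$region == "up1000", ]
  expect_equal(c(up3$start, up3$end), c(0L, 300L))
  # off-contig gene is rejected
  expect_error(gene_windows(toy_ann("+", 5000L), widths = 500L,
                            contig_lengths = c(chrI = 4000L)), "off contig")
})

test_that("region aggregation averages overlapping probes", {
  tr <- signal_track(list(m1 = data.frame(
    contig = "chrI", start = c(100L, 150L, 400L), end = c(160L, 210L, 460L),
    value = c(1.0, 3.0, 99))), condition = "A")
  expect_equal(aggregate_region_signal(tr, list(contig = "chrI", start = 120L, end = 140L), "m1"), 1.0)
  expect_equal(aggregate_region_signal(tr, list(contig = "chrI", start = 120L, end = 200L), "m1"), 2.0)
  expect_true(is.na(aggregate_region_signal(tr, list(contig = "chrI", start = 220L, end = 300L), "m1")))
  expect_error(aggregate_region_signal(tr, list(contig = "chrI", start = 0L, end = 10L), "nope"),
               "unknown modification")
})

test_that("aggregation equals a brute-force overlap scan", {
  set.seed(5)
  probes <- data.frame(
    contig = sample(c("chrI", "chrII"), 300, TRUE),
    start = sample(0:5000, 300, TRUE))
  probes$end <- probes$start + sample(20:80, 300, TRUE)
  probes$value <- rnorm(300)
  tr <- signal_track(list(m = probes), condition = "A")
  for (k in 1:200) {
    ctg <- sample(c("chrI", "chrII"), 1)
    s <- sample(0:5000, 1); e <- s + sample(1:400, 1)
    got <- aggregate_region_signal(tr, list(contig = ctg, start = s, end = e), "m")
    want <- bf_region_mean(probes, ctg, s, e)
    expect_equal(got, want)
  }
})

test_that("signal matrix has the expected columns and missingness", {
  ann <- toy_ann("+", 5000L)
  probes <- data.frame(contig = "chrI",
                       start = seq(3000L, 6900L, by = 100L))
  probes$end <- probes$start + 100L
  probes$value <- 2.5
  tr <- signal_track(list(m1 = probes), condition = "A")
  gsm <- build_gene_signal_matrix(ann, tr, widths = c(500L, 1000L))
  expect_equal(sort(colnames(gsm)),
               sort(c("m1.up500", "m1.up1000", "m1.down500", "m1.down1000")))
  expect_equal(unname(unclass(gsm)[1, ]), rep(2.5, 4))
  # an ir_orf modification contributes IR and ORF columns instead
  tr2 <- signal_track(list(m1 = probes, ac1 = probes),
                      groups = c(m1 = "windowed", ac1 = "ir_orf"))
  gsm2 <- build_gene_signal_matrix(ann, tr2, widths = c(500L, 1000L))
  expect_equal(ncol(gsm2), 6L)
  expect_true(all(c("ac1.IR", "ac1.ORF") %in% colnames(gsm2)))
  info <- signal_col_info(gsm2)
  expect_equal(info$missing_frac, rep(0, 6))
})

test_that("full-coverage synthetic world gives a complete matrix with centred columns", {
  w <- cached_world("cov1", synthetic_config(
    n_genes = 400L, n_tfs = 0L, probe_coverage = 1.0, orf_len = 400L,
    spacer_len = 100L, promoter_len = 300L, two_conditions = FALSE,
    seed = 5L))
  gsm <- world_signals(w)
  expect_equal(sum(is.na(gsm)), 0L)
  # no TFs -> no shifts: column means are CLT-close to 0 (78 columns, so
  # allow the occasional 3-sigma excursion but nothing near 4 sigma)
  mu <- colMeans(unclass(gsm))
  expect_true(all(abs(mu) < 4 / sqrt(nrow(gsm))))
  expect_gte(mean(abs(mu) < 3 / sqrt(nrow(gsm))), 0.95)
})

test_that("splitting each probe in half leaves aggregates unchanged", {
  set.seed(9)
  probes <- data.frame(contig = "chrI", start = seq(0L, 1980L, by = 60L))
  probes$end <- probes$start + 60L
  probes$value <- rnorm(nrow(probes))
  halves <- rbind(
    data.frame(contig = "chrI", start = probes$start,
               end = probes$start + 30L, value = probes$value),
    data.frame(contig = "chrI", start = probes$start + 30L,
               end = probes$end, value = probes$value))
  tr1 <- signal_track(list(m = probes))
  tr2 <- signal_track(list(m = halves))
  # probe-aligned regions: every overlapped probe is counted with the same
  # multiplicity before and after the split, so the unweighted mean is
  # invariant (unaligned regions can clip a single half of an edge probe)
  for (k in 1:50) {
    s <- 60 * sample(0:30, 1); e <- s + 60 * sample(1:3, 1)
    r <- list(contig = "chrI", start = s, end = e)
    a1 <- aggregate_region_signal(tr1, r, "m")
    a2 <- aggregate_region_signal(tr2, r, "m")
    if (is.na(a1)) expect_true(is.na(a2)) else expect_equal(a1, a2)
  }
})

test_that("probe tables are validated", {
  expect_error(signal_track(list(m = data.frame(
    contig = "c", start = 10L, end = 10L, value = 1))), "start >= end")
  expect_error(signal_track(list(m = data.frame(
    contig = "c", start = 0L, end = 10L, value = NaN))), "non-finite")
})
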