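# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately naive (explicit loops, no shared code paths).

bf_revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
}

# score one window against a pssm matrix with pseudocount-renormalised
# log2 odds; NA if the window contains a non-ACGT base
bf_window_score <- function(mat, window, bg, pseudocount) {
  bases <- strsplit(window, "")[[1]]
  s <- 0
  for (i in seq_along(bases)) {
    j <- match(bases[i], c("A", "C", "G", "T"))
    if (is.na(j)) return(NA_real_)
    w <- (mat[i, ] + pseudocount) / sum(mat[i, ] + pseudocount)
    s <- s + log2(w[j] / bg[j])
  }
  s
}

bf_scan <- function(x, seq, bg, threshold, pseudocount = 0.01,
                    both_strands = TRUE) {
  n <- nrow(x$mat)
  out <- list()
  L <- nchar(seq)
  if (L < n) {
    return(data.frame(offset = integer(), strand = character(),
                      score = numeric()))
  }
  for (o in 0:(L - n)) {
    window <- substr(seq, o + 1, o + n)
    s <- bf_window_score(x$mat, window, bg, pseudocount)
    if (!is.na(s) && s >= threshold) {
      out[[length(out) + 1]] <- data.frame(offset = o, strand = "+", score = s)
    }
    if (both_strands) {
      s2 <- bf_window_score(x$mat, bf_revcomp(window), bg, pseudocount)
      if (!is.na(s2) && s2 >= threshold) {
        out[[length(out) + 1]] <- data.frame(offset = o, strand = "-", score = s2)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(offset = integer(), strand = character(),
                      score = numeric()))
  }
  res <- do.call(rbind, out)
  res[order(res$offset, res$strand), , drop = FALSE]
}

# AUC by exhaustive pairwise concordance (ties count half)
bf_auc <- function(scores, labels) {
  labels <- as.integer(as.character(labels) == "1" | labels == 1)
  pos <- which(labels == 1); neg <- which(labels == 0)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + if (scores[i] > scores[j]) 1 else if (scores[i] == scores[j]) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# mean of probe values overlapping a region by >= 1 bp, by explicit loop
bf_region_mean <- function(probes, contig, start, end) {
  vals <- c()
  for (k in seq_len(nrow(probes))) {
    if (probes$contig[k] == contig && probes$start[k] < end &&
        probes$end[k] > start) {
      vals <- c(vals, probes$value[k])
    }
  }
  if (length(vals) == 0) NA_real_ else mean(vals)
}

# one-sided (greater) Fisher P by full enumeration of the hypergeometric
# support with choose()
bf_fisher_greater <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  total <- choose(m + n, k)
  sum(vapply(a:hi, function(x) choose(m, x) * choose(n, k - x), 0)) / total
}

random_pssm <- function(n, id = "r") {
  mat <- matrix(stats::rexp(n * 4), n, 4)
  pssm(id, mat / rowSums(mat))
}

random_seq <- function(L, letters = c("A", "C", "G", "T"),
                       prob = rep(0.25, length(letters))) {
  paste(sample(letters, L, replace = TRUE, prob = prob), collapse = "")
}
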