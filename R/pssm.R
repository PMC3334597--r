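#' Position-specific scoring matrix (PSSM)
#'
#' A PSSM stores, for each motif position, the probability of observing each
#' nucleotide. Rows are positions, columns are `A`, `C`, `G`, `T`. Each row
#' must sum to 1 (tolerance 1e-9) and all weights must be non-negative.
#'
#' @param id Motif identifier (single string).
#' @param mat Numeric matrix with 4 columns (A, C, G, T) and one row per
#'   motif position.
#' @return An object of class `pssm`: a list with elements `id`, `mat`
#'   (row-stochastic matrix) and `n` (motif length).
#' @examples
#' m <- pssm("toy", matrix(c(1, 0, 0, 0, 0.25, 0.25, 0.25, 0.25),
#'   nrow = 2, byrow = TRUE))
#' m$n
#' @export
pssm <- function(id, mat) {
  stopifnot(is.character(id), length(id) == 1L, !is.na(id), nzchar(id))
  mat <- as.matrix(mat)
  if (ncol(mat) != 4L) stop("PSSM matrix must have 4 columns (A, C, G, T)")
  if (nrow(mat) < 1L) stop("PSSM must have at least one position")
  if (any(!is.finite(mat)) || any(mat < 0)) {
    stop("PSSM weights must be finite and non-negative")
  }
  rs <- rowSums(mat)
  if (any(abs(rs - 1) > 1e-9)) {
    bad <- which(abs(rs - 1) > 1e-9)[1L]
    stop(sprintf("PSSM '%s': row %d sums to %.6g, not 1", id, bad, rs[bad]))
  }
  colnames(mat) <- DNA_BASES
  rownames(mat) <- NULL
  structure(list(id = id, mat = mat, n = nrow(mat)), class = "pssm")
}

DNA_BASES <- c("A", "C", "G", "T")

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("PSSM '%s' (%d positions), consensus %s\n",
              x$id, x$n, pssm_consensus(x)))
  print(round(x$mat, 3))
  invisible(x)
}

#' Consensus sequence of a PSSM
#'
#' The highest-probability base at each position (ties broken in favour of
#' the earlier base in A, C, G, T order).
#'
#' @param x A [pssm()].
#' @return A single string of length `x$n`.
#' @export
pssm_consensus <- function(x) {
  stopifnot(inherits(x, "pssm"))
  paste(DNA_BASES[apply(x$mat, 1L, which.max)], collapse = "")
}

#' Background nucleotide frequencies from GC content
#'
#' Builds a strand-symmetric background distribution from a GC fraction:
#' A = T = (1 - gc)/2 and C = G = gc/2. The yeast genome background used
#' throughout this package corresponds to `gc = 0.37`.
#'
#' @param gc GC fraction, strictly between 0 and 1.
#' @return Named numeric vector of length 4 (A, C, G, T) summing to 1.
#' @examples
#' background_from_gc(0.37)
#' @export
background_from_gc <- function(gc) {
  if (!is.numeric(gc) || length(gc) != 1L || is.na(gc) || gc <= 0 || gc >= 1) {
    stop("gc must be a single number strictly between 0 and 1")
  }
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

check_background <- function(bg) {
  stopifnot(is.numeric(bg), length(bg) == 4L, all(bg > 0),
            abs(sum(bg) - 1) < 1e-6)
  if (is.null(names(bg))) names(bg) <- DNA_BASES
  bg[DNA_BASES]
}

#' Information content of a PSSM
#'
#' Relative entropy (in bits) of the motif against the background:
#' \deqn{IC = \sum_i \sum_j p_{i,j} \log_2(p_{i,j} / p_b(j))}
#' Higher values indicate a more specific motif. The measure is additive over
#' positions and is 0 exactly when every position matches the background.
#'
#' @param x A [pssm()].
#' @param bg Background frequencies, e.g. [background_from_gc()].
#' @param pseudocount Non-negative weight added to each probability (and
#'   renormalised per row) before taking logs. The default 0 treats
#'   zero-probability entries as contributing 0 (the 0*log(0) limit).
#' @return Information content in bits (non-negative).
#' @examples
#' bg <- background_from_gc(0.37)
#' onehot <- pssm("a", matrix(c(1, 0, 0, 0), nrow = 1))
#' information_content(onehot, bg) # log2(1/0.315)
#' @export
information_content <- function(x, bg = background_from_gc(0.37),
                                pseudocount = 0) {
  stopifnot(inherits(x, "pssm"), pseudocount >= 0)
  bg <- check_background(bg)
  w <- x$mat + pseudocount
  w <- w / rowSums(w)
  term <- w * log2(sweep(w, 2L, bg, "/"))
  term[w == 0] <- 0
  sum(term)
}

#' Similarity between two PSSMs
#'
#' For motifs of equal length n the similarity is the averaged per-position
#' dot product \eqn{(1/n) \sum_i \sum_j p_1(i,j) p_2(i,j)}, which lies in
#' [0, 1]. For unequal lengths every ungapped alignment of the two matrices
#' is scored over its overlap (dividing by the overlap length) and the
#' maximum is returned; alignments shorter than
#' `min(min_overlap, n1, n2)` positions are not considered.
#'
#' @param p1,p2 [pssm()] objects.
#' @param min_overlap Minimum positions two unequal-length motifs must share
#'   in an alignment (default 3).
#' @return Similarity score in [0, 1]; symmetric in its arguments.
#' @export
pssm_similarity <- function(p1, p2, min_overlap = 3L) {
  stopifnot(inherits(p1, "pssm"), inherits(p2, "pssm"))
  n1 <- p1$n; n2 <- p2$n
  minov <- min(min_overlap, n1, n2)
  best <- 0
  for (off in seq(-(n2 - minov), n1 - minov)) {
    # p2 position k aligns with p1 position k + off
    i1 <- max(1L, 1L + off):min(n1, n2 + off)
    if (length(i1) < minov) next
    i2 <- i1 - off
    ov <- length(i1)
    s <- sum(p1$mat[i1, , drop = FALSE] * p2$mat[i2, , drop = FALSE]) / ov
    if (s > best) best <- s
  }
  best
}

#' Log-odds score matrix of a PSSM
#'
#' Converts probabilities to per-position log2 odds against the background,
#' after adding a pseudocount and renormalising rows (so that zero weights
#' score finitely).
#'
#' @inheritParams information_content
#' @param pseudocount Pseudocount added before renormalisation (default 0.01).
#' @return Numeric n x 4 matrix of bit scores.
#' @export
pssm_log_odds <- function(x, bg = background_from_gc(0.37), pseudocount = 0.01) {
  stopifnot(inherits(x, "pssm"), pseudocount >= 0)
  bg <- check_background(bg)
  w <- x$mat + pseudocount
  w <- w / rowSums(w)
  log2(sweep(w, 2L, bg, "/"))
}

#' Maximum achievable log-odds score of a PSSM
#'
#' Sum over positions of the best per-position log-odds score. Used to set
#' relative hit thresholds for [scan_sequence()].
#'
#' @inheritParams pssm_log_odds
#' @return Maximum window score in bits.
#' @export
pssm_max_score <- function(x, bg = background_from_gc(0.37), pseudocount = 0.01) {
  sum(apply(pssm_log_odds(x, bg, pseudocount), 1L, max))
}

# Encode an ACGTN string as integers 1..4 (NA for anything else).
encode_dna <- local({
  map <- rep(NA_integer_, 127L)
  map[utf8ToInt("A")] <- 1L; map[utf8ToInt("a")] <- 1L
  map[utf8ToInt("C")] <- 2L; map[utf8ToInt("c")] <- 2L
  map[utf8ToInt("G")] <- 3L; map[utf8ToInt("g")] <- 3L
  map[utf8ToInt("T")] <- 4L; map[utf8ToInt("t")] <- 4L
  function(seq) {
    stopifnot(is.character(seq), length(seq) == 1L)
    if (nchar(seq) == 0L) return(integer())
    map[utf8ToInt(seq)]
  }
})

COMPLEMENT_IDX <- c(4L, 3L, 2L, 1L)

#' Scan a sequence for PSSM matches
#'
#' Scores every window of motif length on the forward (and optionally
#' reverse) strand with the log-odds matrix and reports windows whose score
#' reaches the threshold. Windows containing any non-ACGT base are skipped.
#' Offsets are 0-based forward-strand coordinates of the window start, so a
#' reverse-strand hit at offset `o` means the reverse complement of
#' `substr(seq, o + 1, o + n)` matches the motif.
#'
#' @param x A [pssm()].
#' @param seq Nucleotide string over A, C, G, T, N (case-insensitive).
#' @param bg Background frequencies.
#' @param score_threshold Minimum bit score for a hit. Default: 60% of the
#'   motif's maximum achievable score.
#' @param both_strands Scan the reverse strand as well (default TRUE).
#' @param pseudocount Pseudocount for the log-odds matrix.
#' @param seq_id Identifier recorded in the output.
#' @return data.frame of hits with columns `seq_id`, `offset` (0-based),
#'   `strand` (+/-), `score` (bits), sorted by offset. Sequences shorter than
#'   the motif yield an empty data.frame.
#' @export
scan_sequence <- function(x, seq, bg = background_from_gc(0.37),
                          score_threshold = NULL, both_strands = TRUE,
                          pseudocount = 0.01, seq_id = NA_character_) {
  stopifnot(inherits(x, "pssm"))
  if (is.null(score_threshold)) {
    score_threshold <- 0.6 * pssm_max_score(x, bg, pseudocount)
  }
  stopifnot(is.finite(score_threshold) || score_threshold == Inf)
  empty <- data.frame(seq_id = character(), offset = integer(),
                      strand = character(), score = numeric(),
                      stringsAsFactors = FALSE)
  code <- encode_dna(seq)
  n <- x$n
  if (length(code) < n) return(empty)
  lo <- pssm_log_odds(x, bg, pseudocount)
  res <- list(scan_strand(lo, code, score_threshold, "+", seq_id))
  if (both_strands) {
    lo_rc <- lo[rev(seq_len(n)), COMPLEMENT_IDX, drop = FALSE]
    res[[2L]] <- scan_strand(lo_rc, code, score_threshold, "-", seq_id)
  }
  hits <- do.call(rbind, res)
  if (nrow(hits) == 0L) return(empty)
  hits <- hits[order(hits$offset, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

scan_strand <- function(lo, code, threshold, strand, seq_id) {
  n <- nrow(lo)
  nw <- length(code) - n + 1L
  sc <- numeric(nw)
  valid <- rep(TRUE, nw)
  for (i in seq_len(n)) {
    idx <- code[i:(i + nw - 1L)]
    bad <- is.na(idx)
    valid <- valid & !bad
    idx[bad] <- 1L
    sc <- sc + lo[i, idx]
  }
  keep <- valid & sc >= threshold
  data.frame(seq_id = rep(seq_id, sum(keep)), offset = which(keep) - 1L,
             strand = rep(strand, sum(keep)), score = sc[keep],
             stringsAsFactors = FALSE)
}

#' Cumulative matching score of motif hits
#'
#' Sum of the bit scores of all motif occurrences found in one gene's
#' promoter; 0 when there are no hits. Overlapping occurrences all count.
#' This is the motif feature fed to the target-prediction classifier.
#'
#' @param hits Hit data.frame from [scan_sequence()] for one gene/motif pair.
#' @return Single numeric score.
#' @export
cumulative_match_score <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0L) return(0)
  stopifnot(is.numeric(hits$score), all(is.finite(hits$score)))
  sum(hits$score)
}

#' Cumulative motif scores across a set of promoters
#'
#' Convenience wrapper: scans each promoter with one PSSM and returns the
#' per-gene cumulative matching score.
#'
#' @inheritParams scan_sequence
#' @param promoters Named character vector of promoter sequences.
#' @return Named numeric vector of cumulative scores (0 for no hits).
#' @export
cumulative_scores <- function(x, promoters, bg = background_from_gc(0.37),
                              score_threshold = NULL, both_strands = TRUE,
                              pseudocount = 0.01) {
  stopifnot(is.character(promoters), inherits(x, "pssm"))
  if (is.null(score_threshold)) {
    score_threshold <- 0.6 * pssm_max_score(x, bg, pseudocount)
  }
  n <- x$n
  # scan all promoters as one code vector with NA spacers (windows crossing
  # a spacer contain NA and are skipped), then attribute hits by offset
  lens <- nchar(promoters)
  big <- encode_dna(paste(c(rbind(promoters, strrep("N", n))), collapse = ""))
  out <- stats::setNames(numeric(length(promoters)), names(promoters))
  if (length(big) < n) return(out)
  starts <- cumsum(c(0L, utils::head(lens + n, -1L)))
  lo <- pssm_log_odds(x, bg, pseudocount)
  hits <- scan_strand(lo, big, score_threshold, "+", "all")
  if (both_strands) {
    lo_rc <- lo[rev(seq_len(n)), COMPLEMENT_IDX, drop = FALSE]
    hits <- rbind(hits, scan_strand(lo_rc, big, score_threshold, "-", "all"))
  }
  if (nrow(hits) == 0L) return(out)
  idx <- findInterval(hits$offset, starts)
  acc <- rowsum(hits$score, group = idx)
  out[as.integer(rownames(acc))] <- acc[, 1L]
  out
}

#' Export motif hits as BED6 records
#'
#' @param hits Hit data.frame from [scan_sequence()] (with `seq_id` set to
#'   the contig name and offsets in contig coordinates).
#' @param n Motif length used to derive interval ends.
#' @param max_score Score mapped to the BED maximum of 1000; defaults to the
#'   largest hit score.
#' @return data.frame in BED6 column order (0-based half-open intervals).
#' @export
hits_to_bed <- function(hits, n, max_score = NULL) {
  stopifnot(nrow(hits) >= 0L, n >= 1L)
  if (nrow(hits) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = integer(),
                      strand = character()))
  }
  if (is.null(max_score)) max_score <- max(hits$score)
  sc <- pmax(0, pmin(1000L, as.integer(round(1000 * hits$score / max_score))))
  data.frame(chrom = hits$seq_id, start = hits$offset,
             end = hits$offset + n,
             name = sprintf("hit%d", seq_len(nrow(hits))),
             score = sc, strand = hits$strand, stringsAsFactors = FALSE)
}
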