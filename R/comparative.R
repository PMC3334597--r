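#' Cross-PSSM target prediction scan (TF cooperativity)
#'
#' Trains the chromatin + motif model for every combination of a TF's
#' target labels with every PSSM's motif scores and records the mean
#' cross-validated AUC. When another factor's PSSM predicts a TF's targets
#' better than its own PSSM by more than `margin`, the pair is flagged as a
#' candidate cooperative (indirect-binding) interaction. Within a row all
#' cells share the same CV splits, so AUC differences are paired.
#'
#' @param labels Gene x TF matrix of 0/1/NA target labels (e.g. from
#'   [call_targets()]).
#' @param signals A `gene_signal_matrix`.
#' @param motif_scores Named list (one element per PSSM) of per-gene
#'   cumulative matching score vectors.
#' @param repeats,folds,seed CV configuration (see [cv_train_evaluate()]).
#' @param margin AUC improvement needed to flag a pair (default 0.02).
#' @param regions Signal regions used as chromatin features.
#' @param classifier Classifier contract.
#' @param min_positives Positive-count floor per TF.
#' @return List of class `cross_pssm_result`: `auc` (TF x PSSM matrix, own
#'   PSSM on the diagonal where names match), `flagged` (data.frame `tf`,
#'   `pssm`, `auc_own`, `auc_other`, `delta`), `margin`. Cells whose CV
#'   errors (e.g. too few positives) are `NA`.
#' @export
cross_pssm_aucs <- function(labels, signals, motif_scores, repeats = 5L,
                            folds = 2L, seed = 1L, margin = 0.02,
                            regions = c("up1000", "down1000"),
                            classifier = svm_classifier(),
                            min_positives = 10L) {
  stopifnot(is.matrix(labels), ncol(labels) >= 2L, is.list(motif_scores),
            !is.null(names(motif_scores)))
  tfs <- colnames(labels)
  pssm_ids <- names(motif_scores)
  auc <- matrix(NA_real_, length(tfs), length(pssm_ids),
                dimnames = list(tfs, pssm_ids))
  for (i in seq_along(tfs)) {
    row_seed <- seed + i
    for (j in seq_along(pssm_ids)) {
      auc[i, j] <- tryCatch({
        ft <- assemble_features(labels[, tfs[i]], signals = signals,
                                motif_scores = motif_scores[[j]],
                                groups = c("hm", "pssm"), regions = regions)
        cv_train_evaluate(ft, repeats = repeats, folds = folds,
                          seed = row_seed, classifier = classifier,
                          min_positives = min_positives)$auc
      }, error = function(e) NA_real_)
    }
  }
  flagged <- list()
  for (tf in intersect(tfs, pssm_ids)) {
    own <- auc[tf, tf]
    if (is.na(own)) next
    for (p in setdiff(pssm_ids, tf)) {
      if (!is.na(auc[tf, p]) && auc[tf, p] > own + margin) {
        flagged[[length(flagged) + 1L]] <- data.frame(
          tf = tf, pssm = p, auc_own = own, auc_other = auc[tf, p],
          delta = auc[tf, p] - own, stringsAsFactors = FALSE)
      }
    }
  }
  flagged <- if (length(flagged) > 0L) do.call(rbind, flagged) else
    data.frame(tf = character(), pssm = character(), auc_own = numeric(),
               auc_other = numeric(), delta = numeric(), stringsAsFactors = FALSE)
  structure(list(auc = auc, flagged = flagged, margin = margin),
            class = "cross_pssm_result")
}

#' Condition-matched versus mismatched model comparison
#'
#' Evaluates two models against the same (condition-B) target labels with
#' identical CV splits: the matched model uses chromatin signals from the
#' target condition, the mismatched model uses signals from the other
#' condition; both use the same motif scores (binding specificity is assumed
#' condition-invariant).
#'
#' @param labels Named 0/1/NA target labels under the target condition.
#' @param signals_matched `gene_signal_matrix` from the target condition.
#' @param signals_mismatched `gene_signal_matrix` from the other condition.
#' @param motif_scores Named per-gene cumulative motif scores.
#' @param repeats,folds,seed CV configuration (same seed for both models).
#' @param regions Signal regions used as features.
#' @param classifier Classifier contract.
#' @return List: `auc_matched`, `auc_mismatched`, and the two `eval_result`
#'   objects.
#' @export
condition_compare <- function(labels, signals_matched, signals_mismatched,
                              motif_scores, repeats = 5L, folds = 2L,
                              seed = 1L, regions = c("up1000", "down1000"),
                              classifier = svm_classifier()) {
  genes <- names(labels)[!is.na(labels)]
  for (s in list(signals_matched, signals_mismatched)) {
    missing <- setdiff(genes, rownames(s))
    if (length(missing) > 0L) {
      stop(sprintf("%d gene(s) missing from one condition's signals (e.g. %s)",
                   length(missing), missing[1L]))
    }
  }
  run <- function(sig) {
    ft <- assemble_features(labels, signals = sig, motif_scores = motif_scores,
                            groups = c("hm", "pssm"), regions = regions)
    cv_train_evaluate(ft, repeats = repeats, folds = folds, seed = seed,
                      classifier = classifier)
  }
  em <- run(signals_matched)
  ex <- run(signals_mismatched)
  list(auc_matched = em$auc, auc_mismatched = ex$auc,
       eval_matched = em, eval_mismatched = ex)
}

#' Split motif-matching sites into ChIP-verified and non-verified classes
#'
#' Sites (short genomic intervals matching a TF's motif, each assigned to a
#' gene) are verified when their gene is bound in the ChIP data
#' (P < `bound_cutoff`) and candidate non-verified when the gene is clearly
#' unbound (P > `unbound_cutoff`). Non-verified candidates within
#' `exclusion_bp` of any verified site are removed.
#'
#' @param sites data.frame with `gene_id`, `contig`, `start`, `end`
#'   (0-based half-open site intervals).
#' @param gene_pvals Named per-gene ChIP binding P-values.
#' @param bound_cutoff P-value below which a gene counts as bound
#'   (default 0.01).
#' @param unbound_cutoff P-value above which a gene counts as unbound
#'   (default 0.4).
#' @param exclusion_bp Non-verified sites closer than this to a verified
#'   site are dropped (default 2000).
#' @param dedupe_per_gene Keep only the best-scoring site per gene in each
#'   class (default FALSE). Sites within one promoter share most of their
#'   chromatin context, so treating them as independent observations
#'   inflates downstream t-statistics; deduplication makes the per-site
#'   tests calibrated.
#' @return List: `verified`, `nonverified` (data.frames) and `counts`
#'   (candidates at each filter step).
#' @export
classify_tfbs <- function(sites, gene_pvals, bound_cutoff = 0.01,
                          unbound_cutoff = 0.4, exclusion_bp = 2000L,
                          dedupe_per_gene = FALSE) {
  stopifnot(all(c("gene_id", "contig", "start", "end") %in% names(sites)))
  p <- gene_pvals[sites$gene_id]
  verified <- sites[!is.na(p) & p < bound_cutoff, , drop = FALSE]
  cand <- sites[!is.na(p) & p > unbound_cutoff, , drop = FALSE]
  excluded <- 0L
  if (nrow(cand) > 0L && nrow(verified) > 0L) {
    vg <- GenomicRanges::GRanges(verified$contig,
                                 IRanges::IRanges(verified$start + 1L, verified$end))
    cg <- GenomicRanges::GRanges(cand$contig,
                                 IRanges::IRanges(cand$start + 1L, cand$end))
    d <- GenomicRanges::distanceToNearest(cg, vg)
    dist <- rep(Inf, nrow(cand))
    dist[S4Vectors::queryHits(d)] <- S4Vectors::mcols(d)$distance
    keep <- dist >= exclusion_bp
    excluded <- sum(!keep)
    cand <- cand[keep, , drop = FALSE]
  }
  if (dedupe_per_gene) {
    best_per_gene <- function(df) {
      if (nrow(df) <= 1L) return(df)
      key <- if ("score" %in% names(df)) df$score else -seq_len(nrow(df))
      keep <- unlist(lapply(split(seq_len(nrow(df)), df$gene_id), function(i) {
        i[which.max(key[i])]
      }))
      df[sort(keep), , drop = FALSE]
    }
    verified <- best_per_gene(verified)
    cand <- best_per_gene(cand)
  }
  list(verified = verified, nonverified = cand,
       counts = c(sites = nrow(sites), verified = nrow(verified),
                  unbound_candidates = excluded + nrow(cand),
                  excluded_near_verified = excluded,
                  nonverified = nrow(cand)))
}

site_mean_signals <- function(sites, track) {
  mods <- names(track$mods)
  out <- matrix(NA_real_, nrow(sites), length(mods),
                dimnames = list(NULL, mods))
  if (nrow(sites) == 0L) return(out)
  sg <- GenomicRanges::GRanges(sites$contig,
                               IRanges::IRanges(sites$start + 1L, sites$end))
  for (m in mods) {
    df <- track$mods[[m]]
    pg <- probes_granges(df)
    hits <- GenomicRanges::findOverlaps(sg, pg, minoverlap = 1L)
    q <- S4Vectors::queryHits(hits)
    cnt <- tabulate(q, nbins = nrow(sites))
    sums <- rep(0, nrow(sites))
    if (length(q) > 0L) {
      acc <- rowsum(df$value[S4Vectors::subjectHits(hits)], group = q)
      sums[as.integer(rownames(acc))] <- acc[, 1L]
    }
    v <- ifelse(cnt > 0L, sums / cnt, NA_real_)
    none <- cnt == 0L
    if (any(none)) {
      # widen uncovered sites to the nearest probe
      d <- GenomicRanges::distanceToNearest(sg[none], pg)
      v[which(none)[S4Vectors::queryHits(d)]] <- df$value[S4Vectors::subjectHits(d)]
    }
    out[, m] <- v
  }
  out
}

#' Chromatin contrasts between verified and non-verified binding sites
#'
#' Computes the mean probe signal over each site (probes overlapping the
#' site; uncovered sites are widened to the nearest probe) for every
#' modification in the track, then contrasts verified against non-verified
#' sites with a Welch t-test per modification. The sign of t is verified
#' mean minus non-verified mean, so nucleosome depletion at bound sites
#' appears as negative t for occupancy-like features.
#'
#' @param sites Output of [classify_tfbs()], or a list with `verified` and
#'   `nonverified` site data.frames.
#' @param track A [signal_track()].
#' @return data.frame: `modification`, `t`, `df`, `p`, `n_verified`,
#'   `n_nonverified`.
#' @export
verified_vs_nonverified <- function(sites, track) {
  v <- sites$verified; nv <- sites$nonverified
  if (nrow(v) == 0L || nrow(nv) == 0L) {
    stop("both site classes must be nonempty after filtering")
  }
  vals <- rbind(site_mean_signals(v, track), site_mean_signals(nv, track))
  grp <- c(rep(TRUE, nrow(v)), rep(FALSE, nrow(nv)))
  w <- welch_t_columns(vals, grp)
  data.frame(modification = names(track$mods), t = unname(w$t),
             df = unname(w$df), p = unname(w$p),
             n_verified = nrow(v), n_nonverified = nrow(nv),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Tile the genome into fixed-width bins labelled by peak overlap
#'
#' Bins tile each contig without overlap (the last bin of a contig may be
#' shorter). A bin is positive when it overlaps any peak by at least
#' `min_overlap` bases.
#'
#' @param contig_lengths Named integer vector of contig lengths.
#' @param width Bin width in bp (default 100).
#' @param peaks data.frame with `contig`, `start`, `end` (0-based
#'   half-open) peak intervals.
#' @param min_overlap Minimum overlap in bp for a positive label (default 1).
#' @return data.frame: `contig`, `start`, `end`, `label` (0/1).
#' @export
bin_genome_and_label <- function(contig_lengths, width = 100L, peaks,
                                 min_overlap = 1L) {
  stopifnot(width > 0L)
  if (length(contig_lengths) == 0L || all(contig_lengths <= 0)) {
    stop("empty genome")
  }
  bins <- do.call(rbind, lapply(names(contig_lengths), function(ctg) {
    len <- contig_lengths[[ctg]]
    starts <- seq.int(0L, len - 1L, by = width)
    data.frame(contig = ctg, start = starts,
               end = pmin(starts + width, len), stringsAsFactors = FALSE)
  }))
  lab <- rep(0L, nrow(bins))
  if (!is.null(peaks) && nrow(peaks) > 0L) {
    bg <- GenomicRanges::GRanges(bins$contig,
                                 IRanges::IRanges(bins$start + 1L, bins$end))
    pg <- GenomicRanges::GRanges(peaks$contig,
                                 IRanges::IRanges(peaks$start + 1L, peaks$end))
    hits <- GenomicRanges::findOverlaps(bg, pg, minoverlap = min_overlap)
    lab[unique(S4Vectors::queryHits(hits))] <- 1L
  }
  bins$label <- lab
  bins
}

#' Per-bin feature table for binding-site level prediction
#'
#' Reuses the target-prediction machinery at bin resolution: per-bin mean
#' modification signals (any-overlap aggregation) and, when a PSSM is
#' given, the per-bin cumulative motif matching score of the bin sequence.
#'
#' @param bins Labelled bins from [bin_genome_and_label()].
#' @param track A [signal_track()].
#' @param genome Named character vector of contig sequences (needed for the
#'   motif feature).
#' @param x Optional [pssm()] for the motif feature.
#' @param groups Feature groups: subset of `"hm"`, `"pssm"`.
#' @param ... Passed to [cumulative_scores()] (threshold etc.).
#' @return A `feature_table` whose rows are bins.
#' @export
bin_feature_table <- function(bins, track, genome = NULL, x = NULL,
                              groups = c("hm", "pssm"), ...) {
  stopifnot(nrow(bins) > 0L)
  ids <- sprintf("%s:%d-%d", bins$contig, bins$start, bins$end)
  blocks <- list()
  if ("hm" %in% groups) {
    hm <- site_mean_signals(bins, track)
    rownames(hm) <- ids
    blocks$hm <- hm
  }
  if ("pssm" %in% groups) {
    stopifnot(!is.null(genome), inherits(x, "pssm"))
    seqs <- substring(genome[bins$contig], bins$start + 1L, bins$end)
    sc <- cumulative_scores(x, stats::setNames(seqs, ids), ...)
    blocks$pssm <- matrix(sc, ncol = 1L, dimnames = list(ids, "pssm_score"))
  }
  xmat <- do.call(cbind, blocks)
  keep <- rowSums(is.na(xmat)) == 0L
  xmat <- xmat[keep, , drop = FALSE]
  y <- factor(bins$label[keep], levels = c(0L, 1L))
  if (nlevels(droplevels(y)) < 2L) stop("both bin classes must be present")
  structure(list(x = xmat, y = y, genes = rownames(xmat)),
            class = "feature_table")
}

#' Fisher's exact enrichment test on a 2x2 table
#'
#' One-sided (enrichment) by default, matching the convention used for
#' group-membership contrasts; exact hypergeometric P-value and the sample
#' odds ratio ad/bc.
#'
#' @param table 2x2 matrix, or length-4 vector (a, b, c, d) read row-wise.
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @return List of class `fisher_result`: `p_value`, `odds_ratio`, `table`,
#'   `alternative`.
#' @export
fisher_enrichment <- function(table, alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (!is.matrix(table)) {
    stopifnot(length(table) == 4L)
    table <- matrix(as.numeric(table), 2L, 2L, byrow = TRUE)
  }
  stopifnot(all(dim(table) == 2L), all(table >= 0),
            all(table == round(table)))
  if (sum(table) == 0) stop("all-zero contingency table")
  p <- stats::fisher.test(table, alternative = alternative)$p.value
  or <- (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
  structure(list(p_value = p, odds_ratio = or, table = table,
                 alternative = alternative), class = "fisher_result")
}

#' @export
print.fisher_result <- function(x, ...) {
  cat(sprintf("Fisher exact (%s): P = %.4g, sample OR = %.3g\n",
              x$alternative, x$p_value, x$odds_ratio))
  invisible(x)
}

#' Co-regulatory TF pairs by target-set overlap
#'
#' Two TFs are co-regulatory when their target sets overlap more than
#' expected under the hypergeometric null over the gene universe
#' (one-sided Fisher's exact test, P < `alpha`). When sensitivity labels
#' are supplied, significant pairs are partitioned by class composition:
#' SS (both sensitive), II (both insensitive), SI (mixed).
#'
#' @param target_sets Named list of target gene-id vectors, or a gene x TF
#'   0/1 matrix.
#' @param universe Character vector of gene ids (or a single integer
#'   universe size; target sets are then assumed to be within it).
#' @param alpha Significance threshold (default 0.05).
#' @param labels Optional named logical (TRUE = sensitive) or a
#'   `sensitivity_labels` data.frame.
#' @return List: `pairs` (all pairs with overlap and P), `significant`
#'   (P < alpha), `class_counts` (named counts SS/II/SI when labels given).
#' @export
coregulation_pairs <- function(target_sets, universe, alpha = 0.05,
                               labels = NULL) {
  target_sets <- normalize_target_sets(target_sets)
  if (length(target_sets) < 2L) stop("need at least 2 TFs")
  if (is.numeric(universe) && length(universe) == 1L) {
    n_univ <- as.integer(universe)
  } else {
    n_univ <- length(unique(universe))
    target_sets <- lapply(target_sets, intersect, y = universe)
  }
  if (n_univ == 0L) stop("empty universe")
  if (inherits(labels, "sensitivity_labels")) {
    labels <- stats::setNames(labels$sensitive, labels$tf)
  }
  tfs <- names(target_sets)
  combs <- utils::combn(tfs, 2L)
  res <- data.frame(tf1 = combs[1L, ], tf2 = combs[2L, ],
                    overlap = NA_integer_, p = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_len(ncol(combs))) {
    s1 <- target_sets[[combs[1L, k]]]; s2 <- target_sets[[combs[2L, k]]]
    ov <- length(intersect(s1, s2))
    res$overlap[k] <- ov
    # one-sided Fisher == hypergeometric upper tail
    res$p[k] <- stats::phyper(ov - 1L, length(s1), n_univ - length(s1),
                              length(s2), lower.tail = FALSE)
  }
  if (!is.null(labels)) {
    cls <- function(a, b) {
      sa <- labels[[a]]; sb <- labels[[b]]
      if (isTRUE(sa) && isTRUE(sb)) "SS" else if (!isTRUE(sa) && !isTRUE(sb)) "II" else "SI"
    }
    res$class <- mapply(cls, res$tf1, res$tf2)
  }
  sig <- res[res$p < alpha, , drop = FALSE]
  class_counts <- if (!is.null(labels)) {
    table(factor(sig$class, levels = c("SS", "II", "SI")))
  } else NULL
  list(pairs = res, significant = sig, class_counts = class_counts,
       alpha = alpha, universe_size = n_univ)
}

#' Compare a per-TF attribute between sensitivity classes
#'
#' Two-sided Wilcoxon rank-sum test of an attribute (target counts, PPI
#' degree, expression, hierarchy level, ...) between histone-sensitive and
#' -insensitive TFs.
#'
#' @param labels Named logical (TRUE = sensitive) or `sensitivity_labels`
#'   data.frame.
#' @param values Named numeric attribute per TF.
#' @return List: `statistic` (W), `p_value`, group sizes and medians.
#' @export
group_attribute_compare <- function(labels, values) {
  if (inherits(labels, "sensitivity_labels")) {
    labels <- stats::setNames(labels$sensitive, labels$tf)
  }
  stopifnot(!is.null(names(labels)), !is.null(names(values)))
  common <- intersect(names(labels), names(values))
  lab <- labels[common]; val <- values[common]
  a <- val[lab]; b <- val[!lab]
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be nonempty")
  wt <- stats::wilcox.test(a, b, alternative = "two.sided", exact = FALSE)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_sensitive = length(a), n_insensitive = length(b),
       median_sensitive = stats::median(a), median_insensitive = stats::median(b))
}
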