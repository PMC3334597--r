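#' Default profile columns: 1-kb upstream windowed + intergenic acetylation
#'
#' The 25-feature space used for TF profiling: the `up1000` window of each
#' windowed modification and the `IR` region of each intergenic/ORF
#' modification.
#'
#' @param signals A `gene_signal_matrix`.
#' @return Character vector of column names.
#' @export
profile_columns <- function(signals) {
  info <- signal_col_info(signals)
  windowed <- info$column[info$region == "up1000"]
  ir <- info$column[info$region == "IR"]
  c(windowed, ir)
}

normalize_target_sets <- function(target_sets) {
  if (is.matrix(target_sets)) {
    stopifnot(!is.null(rownames(target_sets)), !is.null(colnames(target_sets)))
    m <- target_sets
    target_sets <- lapply(stats::setNames(colnames(m), colnames(m)), function(tf) {
      rownames(m)[which(m[, tf] == 1L)]
    })
  }
  stopifnot(is.list(target_sets), !is.null(names(target_sets)))
  target_sets
}

#' Target histone-modification profiles of TFs
#'
#' For each TF, averages the selected modification signals over its target
#' genes, then z-normalises each modification across TFs. TFs with fewer
#' than `min_targets` targets carrying signal are excluded with a warning.
#'
#' @param target_sets Named list of target gene-id vectors per TF, or a
#'   gene x TF 0/1 label matrix.
#' @param signals A `gene_signal_matrix`.
#' @param columns Signal columns forming the profile; default
#'   [profile_columns()] (1-kb upstream + IR set).
#' @param min_targets Minimum targets per TF (default 10).
#' @return List of class `target_profiles`: `raw` and `z` (TF x modification
#'   matrices) and `n_targets`.
#' @export
target_mod_profiles <- function(target_sets, signals, columns = NULL,
                                min_targets = 10L) {
  target_sets <- normalize_target_sets(target_sets)
  if (is.null(columns)) columns <- profile_columns(signals)
  m <- unclass(signals)[, columns, drop = FALSE]
  keep_tf <- character()
  rows <- list()
  nt <- integer()
  for (tf in names(target_sets)) {
    genes <- intersect(target_sets[[tf]], rownames(m))
    sub <- m[genes, , drop = FALSE]
    with_signal <- sum(rowSums(!is.na(sub)) > 0L)
    if (with_signal < min_targets) {
      warning(sprintf("TF '%s' excluded: %d target(s) with signal < %d",
                      tf, with_signal, min_targets))
      next
    }
    rows[[tf]] <- colMeans(sub, na.rm = TRUE)
    keep_tf <- c(keep_tf, tf)
    nt <- c(nt, length(genes))
  }
  if (length(rows) == 0L) stop("no TF has enough targets for a profile")
  raw <- do.call(rbind, rows)
  mods <- signal_col_info(signals)
  colnames(raw) <- mods$modification[match(columns, mods$column)]
  z <- scale(raw)
  cs <- apply(raw, 2L, stats::sd)
  z[, !is.finite(cs) | cs == 0] <- 0
  attr(z, "scaled:center") <- NULL; attr(z, "scaled:scale") <- NULL
  structure(list(raw = raw, z = z,
                 n_targets = stats::setNames(nt, keep_tf)),
            class = "target_profiles")
}

#' Classify TFs as histone-sensitive or -insensitive by k-means
#'
#' Runs k-means (Euclidean, best of `restarts` random starts) on the
#' normalised target modification profiles and splits the TFs into two
#' clusters. The cluster whose members have the larger mean absolute
#' normalised signal - i.e. more high and low modification values around
#' their targets - is labelled histone-sensitive.
#'
#' @param profiles A `target_profiles` object (its `z` matrix is used) or a
#'   numeric TF x modification matrix.
#' @param k Number of clusters (default 2).
#' @param restarts Random restarts for k-means (default 50).
#' @param seed RNG seed.
#' @return data.frame of class `sensitivity_labels` with columns `tf`,
#'   `cluster`, `sensitive`; attributes `inertia`, `restarts`, `seed`.
#' @export
cluster_sensitivity <- function(profiles, k = 2L, restarts = 50L, seed = 1L) {
  z <- if (inherits(profiles, "target_profiles")) profiles$z else as.matrix(profiles)
  if (nrow(z) < k) stop("fewer TFs than clusters")
  if (nrow(z) < 2L * k) {
    warning(sprintf("only %d TFs for k = %d clusters; labels may be unstable",
                    nrow(z), k))
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  km <- tryCatch(stats::kmeans(z, centers = k, nstart = restarts),
                 error = function(e) NULL)
  if (is.null(km)) {
    warning("degenerate profiles (fewer distinct points than clusters); all TFs labelled insensitive")
    out <- data.frame(tf = rownames(z), cluster = 1L, sensitive = FALSE,
                      stringsAsFactors = FALSE)
    return(structure(out, inertia = 0, restarts = restarts, seed = seed,
                     class = c("sensitivity_labels", "data.frame")))
  }
  amp <- rowMeans(abs(z))
  cluster_amp <- tapply(amp, km$cluster, mean)
  sensitive_cluster <- as.integer(names(which.max(cluster_amp)))
  out <- data.frame(tf = rownames(z), cluster = km$cluster,
                    sensitive = km$cluster == sensitive_cluster,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, inertia = km$tot.withinss, restarts = restarts, seed = seed,
            class = c("sensitivity_labels", "data.frame"))
}

# Vectorised Welch t-statistics per column of `values` between two groups.
welch_t_columns <- function(values, grp) {
  stopifnot(is.logical(grp), nrow(values) == length(grp))
  a <- values[grp, , drop = FALSE]; b <- values[!grp, , drop = FALSE]
  n1 <- colSums(!is.na(a)); n0 <- colSums(!is.na(b))
  m1 <- colMeans(a, na.rm = TRUE); m0 <- colMeans(b, na.rm = TRUE)
  v1 <- apply(a, 2L, stats::var, na.rm = TRUE)
  v0 <- apply(b, 2L, stats::var, na.rm = TRUE)
  se2 <- v1 / n1 + v0 / n0
  t <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  bad <- n1 < 2L | n0 < 2L | !is.finite(t)
  t[bad] <- NA_real_; df[bad] <- NA_real_
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  list(t = t, df = df, p = p, n1 = n1, n0 = n0)
}

#' Differential modification profiles (target vs non-target t-statistics)
#'
#' For each TF and each modification, computes the Welch (unequal-variance)
#' t-statistic contrasting the modification signal of the TF's target genes
#' against its non-target genes; the sign is target mean minus non-target
#' mean. Degenerate cases (a group with fewer than 2 genes, or zero variance
#' in both groups) yield missing entries with a warning.
#'
#' @inheritParams target_mod_profiles
#' @return List of class `diff_profiles`: matrices `t` and `p`
#'   (TF x modification).
#' @export
diff_mod_profiles <- function(target_sets, signals, columns = NULL) {
  target_sets <- normalize_target_sets(target_sets)
  if (is.null(columns)) columns <- profile_columns(signals)
  m <- unclass(signals)[, columns, drop = FALSE]
  mods <- signal_col_info(signals)
  mod_names <- mods$modification[match(columns, mods$column)]
  tmat <- matrix(NA_real_, length(target_sets), length(columns),
                 dimnames = list(names(target_sets), mod_names))
  pmat <- tmat
  for (tf in names(target_sets)) {
    grp <- rownames(m) %in% target_sets[[tf]]
    if (sum(grp) < 2L || sum(!grp) < 2L) {
      warning(sprintf("TF '%s': fewer than 2 genes in a group; t undefined", tf))
      next
    }
    w <- welch_t_columns(m, grp)
    if (anyNA(w$t)) {
      warning(sprintf("TF '%s': %d modification(s) with undefined t (zero variance)",
                      tf, sum(is.na(w$t))))
    }
    tmat[tf, ] <- w$t
    pmat[tf, ] <- w$p
  }
  structure(list(t = tmat, p = pmat), class = "diff_profiles")
}

#' Correlation network of modifications over differential profiles
#'
#' Pearson correlation of every modification pair across the TFs'
#' differential (t-statistic) profiles; pairs with |r| above the threshold
#' become edges, classed by sign. Constant columns are excluded.
#'
#' @param tmat TF x modification matrix of t-statistics (e.g. the `t`
#'   element of [diff_mod_profiles()]).
#' @param threshold Absolute correlation threshold (default 0.5, strict).
#' @return data.frame with columns `mod1`, `mod2`, `r`, `sign`
#'   (`"positive"`/`"negative"`).
#' @export
modification_correlation_network <- function(tmat, threshold = 0.5) {
  if (inherits(tmat, "diff_profiles")) tmat <- tmat$t
  stopifnot(is.matrix(tmat), nrow(tmat) >= 3L)
  sds <- apply(tmat, 2L, stats::sd, na.rm = TRUE)
  keep <- is.finite(sds) & sds > 0
  tmat <- tmat[, keep, drop = FALSE]
  if (ncol(tmat) < 2L) {
    return(data.frame(mod1 = character(), mod2 = character(), r = numeric(),
                      sign = character(), stringsAsFactors = FALSE))
  }
  cm <- stats::cor(tmat, use = "pairwise.complete.obs")
  idx <- which(upper.tri(cm) & abs(cm) > threshold, arr.ind = TRUE)
  data.frame(mod1 = colnames(cm)[idx[, 1L]], mod2 = colnames(cm)[idx[, 2L]],
             r = cm[idx], sign = ifelse(cm[idx] > 0, "positive", "negative"),
             stringsAsFactors = FALSE)
}
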