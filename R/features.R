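#' Call target genes from ChIP binding P-values
#'
#' A gene is a target of a TF when its binding P-value is strictly below the
#' cutoff (default 0.01); a P-value of exactly the cutoff is a non-target.
#' Missing P-values give missing labels.
#'
#' @param pvals Numeric vector or gene x TF matrix of P-values in [0, 1].
#' @param cutoff P-value cutoff, strictly between 0 and 1 (default 0.01).
#' @return Integer labels (1 target, 0 non-target, NA missing) of the same
#'   shape as `pvals`.
#' @export
call_targets <- function(pvals, cutoff = 0.01) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0 || cutoff >= 1) {
    stop("cutoff must be a single probability strictly between 0 and 1")
  }
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("P-values outside [0, 1]")
  out <- ifelse(is.na(pvals), NA_integer_, as.integer(pvals < cutoff))
  if (is.matrix(pvals)) {
    out <- matrix(out, nrow(pvals), ncol(pvals), dimnames = dimnames(pvals))
  } else {
    names(out) <- names(pvals)
  }
  out
}

#' Assemble a per-TF feature table
#'
#' Joins the selected feature groups over the common gene universe:
#' chromatin signal columns (group `"hm"`), the cumulative motif matching
#' score (group `"pssm"`) and optionally log-transformed expression (group
#' `"expression"`). Genes with missing labels are dropped; genes missing
#' more than `max_missing` of the feature columns are dropped; remaining
#' missing values are mean-imputed per column. Features are returned
#' unstandardised: cross-validation standardises per fold with training-fold
#' statistics only (see [cv_train_evaluate()]).
#'
#' @param labels Named integer/logical target labels (1/0/NA) per gene.
#' @param signals A `gene_signal_matrix` (required when `"hm"` is in
#'   `groups`).
#' @param motif_scores Named numeric vector of per-gene cumulative matching
#'   scores (required when `"pssm"` is in `groups`).
#' @param expression Named numeric vector of expression levels (required
#'   when `"expression"` is in `groups`).
#' @param groups Feature groups to include: subset of `"hm"`, `"pssm"`,
#'   `"expression"`.
#' @param regions Regions of the signal matrix to use (default the 1-kb
#'   upstream and downstream windows).
#' @param modifications Optional modification subset for the `"hm"` group.
#' @param max_missing Drop genes missing more than this fraction of feature
#'   columns (default 0.5).
#' @return List of class `feature_table`: `x` (numeric matrix), `y` (factor
#'   with levels `0`, `1`), `genes`.
#' @export
assemble_features <- function(labels, signals = NULL, motif_scores = NULL,
                              expression = NULL, groups = c("hm", "pssm"),
                              regions = c("up1000", "down1000"),
                              modifications = NULL, max_missing = 0.5) {
  groups <- match.arg(groups, c("hm", "pssm", "expression"), several.ok = TRUE)
  stopifnot(length(groups) >= 1L, !is.null(names(labels)))
  universe <- names(labels)
  blocks <- list()
  if ("hm" %in% groups) {
    if (is.null(signals)) stop("'hm' group requested but no signal matrix given")
    hm <- select_signal_columns(signals, regions = regions,
                                modifications = modifications)
    universe <- intersect(universe, rownames(hm))
    blocks$hm <- hm
  }
  if ("pssm" %in% groups) {
    if (is.null(motif_scores)) stop("'pssm' group requested but no motif scores given")
    universe <- intersect(universe, names(motif_scores))
    blocks$pssm <- matrix(motif_scores, ncol = 1L,
                          dimnames = list(names(motif_scores), "pssm_score"))
  }
  if ("expression" %in% groups) {
    if (is.null(expression)) stop("'expression' group requested but no expression given")
    universe <- intersect(universe, names(expression))
    blocks$expression <- matrix(log(expression), ncol = 1L,
                                dimnames = list(names(expression), "expression"))
  }
  if (length(universe) == 0L) stop("empty intersection of gene sets")
  x <- do.call(cbind, lapply(blocks, function(b) b[universe, , drop = FALSE]))
  y <- labels[universe]
  keep <- !is.na(y)
  x <- x[keep, , drop = FALSE]; y <- y[keep]
  frac_missing <- rowMeans(is.na(x))
  keep <- frac_missing <= max_missing
  x <- x[keep, , drop = FALSE]; y <- y[keep]
  if (nrow(x) == 0L) stop("no genes left after filtering")
  # mean-impute remaining missing values per column
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) {
      mu <- mean(x[!nas, j])
      x[nas, j] <- if (is.finite(mu)) mu else 0
    }
  }
  y <- factor(as.integer(y), levels = c(0L, 1L))
  if (nlevels(droplevels(y)) < 2L) {
    stop("both classes must be present (no positives or no negatives)")
  }
  structure(list(x = x, y = y, genes = rownames(x)), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d genes x %d features, %d positives\n",
              nrow(x$x), ncol(x$x), sum(x$y == "1")))
  invisible(x)
}

#' Standardise features with training-fold statistics
#'
#' Centers and scales both matrices by the training matrix's column means
#' and standard deviations (constant columns get scale 1). Keeping the test
#' fold out of the statistics avoids information leakage during
#' cross-validation.
#'
#' @param train,test Numeric matrices with identical columns.
#' @return List with standardised `train` and `test` matrices.
#' @export
fold_standardize <- function(train, test) {
  mu <- colMeans(train)
  sd <- apply(train, 2L, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(train = sweep(sweep(train, 2L, mu), 2L, sd, "/"),
       test = sweep(sweep(test, 2L, mu), 2L, sd, "/"))
}

#' Radial-kernel SVM classifier contract
#'
#' The default learner: a C-classification SVM with radial basis kernel,
#' cost 1 and kernel width 1/number-of-features. Because target genes are a
#' small minority (a few percent of genes at the usual ChIP cutoff), classes
#' are weighted inversely to their frequencies by default; without this the
#' minority class can fall entirely inside the margin and the decision
#' function degenerates for low-dimensional feature sets. Prediction scores
#' are decision values mapped through a logistic link to [0, 1]; the mapping
#' is strictly monotone, so ranking metrics (ROC/AUC, PPV) are unaffected by
#' the choice of link.
#'
#' @param cost SVM cost parameter.
#' @param gamma Kernel width; `NULL` uses 1/ncol(x).
#' @param class_weights `"balanced"` (default) weights each class by
#'   n/(2 * class count); `NULL` disables weighting.
#' @return List of class `ct_classifier` with functions `fit(x, y)` and
#'   `score(model, x)` returning per-row scores in [0, 1].
#' @export
svm_classifier <- function(cost = 1, gamma = NULL, class_weights = "balanced") {
  structure(list(
    fit = function(x, y) {
      cw <- NULL
      if (identical(class_weights, "balanced")) {
        tab <- table(y)
        tab <- tab[tab > 0]
        cw <- as.numeric(length(y) / (length(tab) * tab))
        names(cw) <- names(tab)
      }
      e1071::svm(x, y, type = "C-classification", kernel = "radial",
                 cost = cost, gamma = if (is.null(gamma)) 1 / ncol(x) else gamma,
                 class.weights = cw, scale = FALSE)
    },
    score = function(model, x) {
      pr <- stats::predict(model, x, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      pos_first <- strsplit(colnames(dv)[1L], "/", fixed = TRUE)[[1L]][1L] == "1"
      stats::plogis(if (pos_first) dv[, 1L] else -dv[, 1L])
    }
  ), class = "ct_classifier")
}
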