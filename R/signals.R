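#' Probe-level chromatin signal track
#'
#' A `signal_track` bundles probe-level measurements for a set of chromatin
#' modifications under one condition. Each modification holds a data.frame of
#' probe records (`contig`, `start`, `end`, `value`; 0-based half-open).
#' Probes may overlap and may leave gaps (tiling arrays typically cover only
#' part of the genome). Each modification belongs to a source group:
#' `"windowed"` features are aggregated over ATG-anchored windows,
#' `"ir_orf"` features over intergenic and coding regions.
#'
#' @param mods Named list of probe data.frames (one per modification).
#' @param groups Named character vector mapping modification id to
#'   `"windowed"` or `"ir_orf"`. Defaults to `"windowed"` for all.
#' @param condition Condition tag (e.g. `"YPD"`); free-form string.
#' @return An object of class `signal_track`.
#' @export
signal_track <- function(mods, groups = NULL, condition = "A") {
  stopifnot(is.list(mods), length(names(mods)) == length(mods),
            !anyDuplicated(names(mods)))
  for (m in names(mods)) {
    df <- mods[[m]]
    need <- c("contig", "start", "end", "value")
    if (!all(need %in% names(df))) {
      stop(sprintf("modification '%s': probe table needs columns %s",
                   m, paste(need, collapse = ", ")))
    }
    if (any(df$start >= df$end)) {
      stop(sprintf("modification '%s': probe with start >= end", m))
    }
    if (any(!is.finite(df$value))) {
      stop(sprintf("modification '%s': non-finite probe value", m))
    }
    o <- order(df$contig, df$start, df$end)
    if (any(o != seq_along(o))) mods[[m]] <- df[o, , drop = FALSE]
    rownames(mods[[m]]) <- NULL
  }
  if (is.null(groups)) {
    groups <- stats::setNames(rep("windowed", length(mods)), names(mods))
  }
  stopifnot(all(names(mods) %in% names(groups)),
            all(groups %in% c("windowed", "ir_orf")))
  structure(list(mods = mods, groups = groups[names(mods)],
                 condition = condition), class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("signal_track: %d modifications (%d windowed, %d IR/ORF), condition '%s'\n",
              length(x$mods), sum(x$groups == "windowed"),
              sum(x$groups == "ir_orf"), x$condition))
  invisible(x)
}

probes_granges <- function(df) {
  GenomicRanges::GRanges(df$contig,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}

#' Mean probe signal over a genomic region
#'
#' Averages the values of all probes overlapping the region by at least one
#' base (unweighted mean; partial overlaps count fully). Returns `NA` when no
#' probe overlaps, marking the region signal as missing.
#'
#' @param track A [signal_track()].
#' @param region List or one-row data.frame with `contig`, `start`, `end`
#'   (0-based half-open).
#' @param modification Modification id present in the track.
#' @return Mean signal (numeric) or `NA_real_`.
#' @export
aggregate_region_signal <- function(track, region, modification) {
  stopifnot(inherits(track, "signal_track"))
  if (!modification %in% names(track$mods)) {
    stop(sprintf("unknown modification id '%s'", modification))
  }
  stopifnot(region$end >= region$start)
  df <- track$mods[[modification]]
  sel <- df$contig == region$contig & df$start < region$end &
    df$end > region$start
  if (!any(sel)) return(NA_real_)
  mean(df$value[sel])
}

#' Per-gene chromatin signal matrix
#'
#' Builds the gene x (modification, region) matrix of mean probe signals:
#' windowed modifications are aggregated over the upstream/downstream ATG
#' windows for each requested width, IR/ORF modifications over the intergenic
#' and coding regions. Columns are named `<modification>.<region>`. Regions
#' with no overlapping probe are `NA`; per-column missingness is recorded.
#'
#' @param ann Annotation data.frame (see [validate_annotation()]).
#' @param track A [signal_track()].
#' @param widths Window widths in bp for the windowed group.
#' @param contig_lengths Optional named contig lengths for truncation.
#' @return Numeric matrix (genes x columns) of class `gene_signal_matrix`
#'   with attributes `col_info` (data.frame: column, modification, region,
#'   condition, missing_frac) and `condition`.
#' @export
build_gene_signal_matrix <- function(ann, track, widths = c(500L, 1000L),
                                     contig_lengths = NULL) {
  stopifnot(inherits(track, "signal_track"))
  ann <- validate_annotation(ann)
  if (nrow(ann) == 0L) stop("no genes in annotation")
  if (length(track$mods) == 0L) stop("track has no modifications")
  regions <- gene_windows(ann, widths, contig_lengths)
  reg_gr <- GenomicRanges::GRanges(
    regions$contig,
    IRanges::IRanges(start = regions$start + 1L,
                     end = pmax(regions$end, regions$start)))
  win_regions <- as.vector(outer(c("up", "down"), widths, paste0))
  mod_regions <- function(m) {
    if (track$groups[[m]] == "windowed") win_regions else c("IR", "ORF")
  }
  genes <- ann$gene_id
  cols <- unlist(lapply(names(track$mods), function(m) {
    paste(m, mod_regions(m), sep = ".")
  }))
  out <- matrix(NA_real_, nrow = length(genes), ncol = length(cols),
                dimnames = list(genes, cols))

  # group modifications sharing an identical probe grid: one overlap query each
  grids <- integer(length(track$mods))
  ref <- list()
  for (i in seq_along(track$mods)) {
    df <- track$mods[[i]]
    found <- 0L
    for (g in seq_along(ref)) {
      r <- ref[[g]]
      if (identical(df$contig, r$contig) && identical(df$start, r$start) &&
          identical(df$end, r$end)) { found <- g; break }
    }
    if (found == 0L) { ref[[length(ref) + 1L]] <- df; found <- length(ref) }
    grids[i] <- found
  }
  region_key <- paste(regions$gene_id, regions$region, sep = "\r")
  row_idx <- match(regions$gene_id, genes)
  for (g in seq_along(ref)) {
    probe_gr <- probes_granges(ref[[g]])
    hits <- GenomicRanges::findOverlaps(reg_gr, probe_gr, minoverlap = 1L)
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    cnt <- tabulate(q, nbins = nrow(regions))
    for (m in names(track$mods)[grids == g]) {
      v <- track$mods[[m]]$value
      sums <- rep(0, nrow(regions))
      acc <- rowsum(v[s], group = q)
      sums[as.integer(rownames(acc))] <- acc[, 1L]
      means <- ifelse(cnt > 0L, sums / cnt, NA_real_)
      for (r in mod_regions(m)) {
        sel <- regions$region == r
        out[row_idx[sel], paste(m, r, sep = ".")] <- means[sel]
      }
    }
  }
  info <- data.frame(
    column = cols,
    modification = sub("\\.[^.]+$", "", cols),
    region = sub("^.*\\.", "", cols),
    condition = track$condition,
    missing_frac = colMeans(is.na(out)),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, col_info = info, condition = track$condition,
            class = c("gene_signal_matrix", "matrix", "array"))
}

#' Column metadata of a gene signal matrix
#'
#' @param x A `gene_signal_matrix` from [build_gene_signal_matrix()].
#' @return data.frame with one row per column: modification, region,
#'   condition and missing fraction.
#' @export
signal_col_info <- function(x) {
  info <- attr(x, "col_info")
  if (is.null(info)) stop("not a gene_signal_matrix: no col_info attribute")
  info
}

#' Select gene signal matrix columns by region and modification
#'
#' @param x A `gene_signal_matrix`.
#' @param regions Region names to keep (e.g. `c("up1000", "down1000")`);
#'   `NULL` keeps all.
#' @param modifications Modification ids to keep; `NULL` keeps all.
#' @return Plain numeric matrix of the selected columns.
#' @export
select_signal_columns <- function(x, regions = NULL, modifications = NULL) {
  info <- signal_col_info(x)
  keep <- rep(TRUE, nrow(info))
  if (!is.null(regions)) keep <- keep & info$region %in% regions
  if (!is.null(modifications)) keep <- keep & info$modification %in% modifications
  if (!any(keep)) stop("no columns match the requested regions/modifications")
  unclass(x)[, info$column[keep], drop = FALSE]
}
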