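#' Read a gene annotation TSV
#'
#' Expects columns `gene_id`, `contig`, `atg`, `strand`, `orf_start`,
#' `orf_end`, `ir_start`, `ir_end`. Coordinates are 0-based half-open by
#' default; a leading comment line `# coords: 1-based` declares 1-based
#' closed input, which is converted on read (starts and the ATG shift down
#' by one).
#'
#' @param path TSV path.
#' @return Validated annotation data.frame in 0-based half-open coordinates.
#' @export
read_annotation <- function(path) {
  stopifnot(file.exists(path))
  first <- readLines(path, n = 1L)
  one_based <- grepl("^#\\s*coords:\\s*1-based", first)
  dt <- data.table::fread(path, sep = "\t", skip = if (one_based) 1L else 0L)
  ann <- as.data.frame(dt)
  if (one_based) {
    for (col in c("atg", "orf_start", "ir_start")) ann[[col]] <- ann[[col]] - 1L
  }
  validate_annotation(ann)
}

#' Write a gene annotation TSV (0-based half-open)
#'
#' @param ann Annotation data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  validate_annotation(ann)
  data.table::fwrite(ann, path, sep = "\t")
  invisible(path)
}

#' Read chromatin signal tracks
#'
#' Accepts either one wide TSV (header `contig`, `start`, `end` followed by
#' one column per modification) or several 4-column bedGraph-style files
#' (contig, start, end, value; modification named after the file). Records
#' are validated (numeric values, `start < end`, with the offending line
#' reported) and sorted per contig.
#'
#' @param paths One wide TSV path, or a character vector of bedGraph paths.
#' @param condition Condition tag to attach.
#' @param groups Optional named group vector (`"windowed"` / `"ir_orf"`) per
#'   modification; defaults to `"windowed"`.
#' @return A [signal_track()].
#' @export
read_signal_tracks <- function(paths, condition = "A", groups = NULL) {
  stopifnot(length(paths) >= 1L, all(file.exists(paths)))
  mods <- list()
  if (length(paths) == 1L) {
    dt <- data.table::fread(paths, sep = "\t")
    if (ncol(dt) < 4L) stop("track file must have at least 4 columns")
    if (all(c("contig", "start", "end") %in% names(dt))) {
      mod_cols <- setdiff(names(dt), c("contig", "start", "end"))
      check_track_rows(dt, paths, mod_cols)
      for (m in mod_cols) {
        mods[[m]] <- data.frame(contig = dt$contig, start = dt$start,
                                end = dt$end, value = dt[[m]],
                                stringsAsFactors = FALSE)
      }
      return(signal_track(mods, groups, condition))
    }
  }
  for (p in paths) {
    dt <- data.table::fread(p, sep = "\t", header = FALSE)
    if (ncol(dt) != 4L) stop(sprintf("'%s': bedGraph needs 4 columns", p))
    data.table::setnames(dt, c("contig", "start", "end", "value"))
    check_track_rows(dt, p, "value")
    m <- sub("\\.(bedgraph|bedGraph|tsv|txt)$", "", basename(p))
    mods[[m]] <- as.data.frame(dt)
  }
  signal_track(mods, groups, condition)
}

check_track_rows <- function(dt, path, value_cols) {
  for (vc in value_cols) {
    if (!is.numeric(dt[[vc]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(dt[[vc]])))))[1L]
      stop(sprintf("'%s': non-numeric value in column '%s' (line %d)",
                   path, vc, bad + 1L))
    }
  }
  if (!is.numeric(dt$start) || !is.numeric(dt$end)) {
    stop(sprintf("'%s': non-numeric coordinates", path))
  }
  bad <- which(dt$start >= dt$end)
  if (length(bad) > 0L) {
    stop(sprintf("'%s': start >= end (line %d)", path, bad[1L] + 1L))
  }
  invisible(TRUE)
}

#' Write a signal track as one wide TSV
#'
#' Requires all modifications to share the same probe grid (as produced by
#' [generate_world()]); use [write_bedgraph()] per modification otherwise.
#'
#' @param track A [signal_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal_track <- function(track, path) {
  stopifnot(inherits(track, "signal_track"), length(track$mods) > 0L)
  ref <- track$mods[[1L]]
  for (m in names(track$mods)) {
    df <- track$mods[[m]]
    if (!identical(df$start, ref$start) || !identical(df$contig, ref$contig)) {
      stop("modifications use different probe grids; write per-modification bedGraphs instead")
    }
  }
  dt <- data.table::data.table(contig = ref$contig, start = ref$start,
                               end = ref$end)
  for (m in names(track$mods)) dt[[m]] <- track$mods[[m]]$value
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Write one modification as a 4-column bedGraph file
#'
#' @param probe_df data.frame with `contig`, `start`, `end`, `value`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(probe_df, path) {
  stopifnot(all(c("contig", "start", "end", "value") %in% names(probe_df)))
  data.table::fwrite(probe_df[, c("contig", "start", "end", "value")], path,
                     sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a ChIP binding P-value matrix
#'
#' TSV with genes as rows (first column `gene_id`) and one column per TF.
#'
#' @param path TSV path.
#' @return Numeric matrix (genes x TFs) with dimnames.
#' @export
read_pvalue_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  df <- as.data.frame(dt)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- dt[[1L]]
  if (ncol(m) > 0L && (any(m < 0, na.rm = TRUE) || any(m > 1, na.rm = TRUE))) {
    stop("P-values outside [0, 1]")
  }
  m
}

#' Write a gene signal matrix as TSV
#'
#' The header names each column `<modification>.<region>`; the condition and
#' per-column missingness travel in a sidecar attribute block re-derived on
#' read.
#'
#' @param x A `gene_signal_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_signal_matrix <- function(x, path) {
  info <- signal_col_info(x)
  dt <- data.table::data.table(gene_id = rownames(x))
  dt <- cbind(dt, data.table::as.data.table(unclass(x)))
  con <- file(path, "w")
  writeLines(sprintf("# condition: %s", attr(x, "condition")), con)
  close(con)
  data.table::fwrite(dt, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read a gene signal matrix TSV written by [write_gene_signal_matrix()]
#'
#' @param path TSV path.
#' @param groups Optional named modification-to-group vector used to rebuild
#'   column metadata.
#' @return A `gene_signal_matrix`.
#' @export
read_gene_signal_matrix <- function(path, groups = NULL) {
  first <- readLines(path, n = 1L)
  condition <- sub("^#\\s*condition:\\s*", "", first)
  dt <- data.table::fread(path, sep = "\t", skip = 1L)
  df <- as.data.frame(dt)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- dt$gene_id
  cols <- colnames(m)
  info <- data.frame(
    column = cols,
    modification = sub("\\.[^.]+$", "", cols),
    region = sub("^.*\\.", "", cols),
    condition = condition,
    missing_frac = colMeans(is.na(m)),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(m, col_info = info, condition = condition,
            class = c("gene_signal_matrix", "matrix", "array"))
}
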