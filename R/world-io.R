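#' Write a synthetic world to disk
#'
#' Emits every component of a [generate_world()] result in plain-text
#' interchange formats: genome FASTA, annotation TSV (0-based half-open),
#' MEME motif file, one wide bedGraph-style TSV per condition
#' (contig, start, end, one column per modification), ChIP P-value TSVs,
#' expression and attribute TSVs, truth tables, the YAML config, and a JSON
#' manifest with an MD5 checksum per file.
#'
#' @param world A `synthetic_world`.
#' @param dir Output directory (created if needed).
#' @return data.frame manifest (`file`, `md5`), invisibly; also written as
#'   `manifest.json`.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "synthetic_world"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(dir, mode = 2L) != 0L) stop("directory not writable: ", dir)

  Biostrings::writeXStringSet(Biostrings::DNAStringSet(world$genome),
                              file.path(dir, "genome.fasta"))
  write_annotation(world$annotation, file.path(dir, "annotation.tsv"))
  write_pssms(world$pssms, file.path(dir, "motifs.meme"),
              bg = background_from_gc(world$config$gc))
  for (cond in names(world$tracks)) {
    write_signal_track(world$tracks[[cond]],
                       file.path(dir, sprintf("tracks_%s.tsv", cond)))
    pv <- world$pvalues[[cond]]
    pv_dt <- data.table::data.table(gene_id = rownames(pv))
    if (ncol(pv) > 0L) pv_dt <- cbind(pv_dt, data.table::as.data.table(pv))
    data.table::fwrite(pv_dt, file.path(dir, sprintf("pvalues_%s.tsv", cond)),
                       sep = "\t")
  }
  data.table::fwrite(
    data.table::data.table(modification = names(world$tracks[[1L]]$groups),
                           group = as.character(world$tracks[[1L]]$groups)),
    file.path(dir, "mod_groups.tsv"), sep = "\t")
  data.table::fwrite(
    data.table::data.table(gene_id = names(world$expression),
                           expression = world$expression),
    file.path(dir, "expression.tsv"), sep = "\t")
  data.table::fwrite(world$attributes, file.path(dir, "tf_attributes.tsv"),
                     sep = "\t")
  data.table::fwrite(world$tf_info, file.path(dir, "tf_info.tsv"), sep = "\t")
  for (cond in names(world$truth$targets)) {
    tm <- world$truth$targets[[cond]]
    dt <- data.table::data.table(gene_id = rownames(tm))
    if (ncol(tm) > 0L) dt <- cbind(dt, data.table::as.data.table(tm))
    data.table::fwrite(dt, file.path(dir, sprintf("true_targets_%s.tsv", cond)),
                       sep = "\t")
  }
  data.table::fwrite(world$truth$planted_sites,
                     file.path(dir, "planted_sites.tsv"), sep = "\t")
  writeLines(world$truth$affected_mods, file.path(dir, "affected_mods.txt"))
  cfg <- world$config
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))

  files <- sort(setdiff(list.files(dir), "manifest.json"))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(dir, files))),
    stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", pretty = TRUE)
  invisible(manifest)
}

#' Read a synthetic world back from disk
#'
#' Inverse of [write_world()]: reconstructs the data components (genome,
#' annotation, PSSMs, tracks, P-values, expression, attributes, truth) from
#' the written files. Numeric values round-trip within 1e-9.
#'
#' @param dir Directory written by [write_world()].
#' @return A list of class `synthetic_world` (the `config` element is the
#'   parsed YAML config).
#' @export
read_world <- function(dir) {
  stopifnot(dir.exists(dir))
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  genome_ss <- Biostrings::readDNAStringSet(file.path(dir, "genome.fasta"))
  genome <- stats::setNames(as.character(genome_ss), names(genome_ss))
  ann <- read_annotation(file.path(dir, "annotation.tsv"))
  pssms <- read_pssms(file.path(dir, "motifs.meme"))
  groups_df <- as.data.frame(data.table::fread(file.path(dir, "mod_groups.tsv")))
  groups <- stats::setNames(groups_df$group, groups_df$modification)
  conds <- sub("^tracks_(.*)\\.tsv$", "\\1",
               list.files(dir, pattern = "^tracks_.*\\.tsv$"))
  tracks <- lapply(stats::setNames(conds, conds), function(cond) {
    read_signal_tracks(file.path(dir, sprintf("tracks_%s.tsv", cond)),
                       condition = cond, groups = groups)
  })
  pvalues <- lapply(stats::setNames(conds, conds), function(cond) {
    dt <- data.table::fread(file.path(dir, sprintf("pvalues_%s.tsv", cond)))
    df <- as.data.frame(dt)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- dt$gene_id
    m
  })
  expr_dt <- data.table::fread(file.path(dir, "expression.tsv"))
  targets <- lapply(stats::setNames(conds, conds), function(cond) {
    dt <- data.table::fread(file.path(dir, sprintf("true_targets_%s.tsv", cond)))
    df <- as.data.frame(dt)
    m <- as.matrix(df[, -1L, drop = FALSE]) == TRUE
    rownames(m) <- dt$gene_id
    m
  })
  tf_info <- as.data.frame(data.table::fread(file.path(dir, "tf_info.tsv"),
                                             na.strings = c("NA", "")))
  structure(list(
    config = cfg,
    genome = genome,
    contig_lengths = stats::setNames(nchar(genome), names(genome)),
    annotation = ann,
    pssms = pssms,
    tf_info = tf_info,
    tracks = tracks,
    pvalues = pvalues,
    expression = stats::setNames(expr_dt$expression, expr_dt$gene_id),
    attributes = as.data.frame(data.table::fread(file.path(dir, "tf_attributes.tsv"))),
    truth = list(
      targets = targets,
      sensitive = stats::setNames(tf_info$sensitive, tf_info$tf),
      affected_mods = readLines(file.path(dir, "affected_mods.txt")),
      planted_sites = as.data.frame(
        data.table::fread(file.path(dir, "planted_sites.tsv"))),
      occupancy_mods = utils::head(names(groups)[groups == "windowed"], 2L))
  ), class = "synthetic_world")
}
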