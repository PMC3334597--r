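#' Validate a gene annotation table
#'
#' The annotation anchors every chromatin window. It is a data.frame with
#' columns `gene_id`, `contig`, `atg` (0-based coordinate of the first base
#' of the start codon, stored explicitly for both strands), `strand`
#' (+/-), `orf_start`, `orf_end` (0-based half-open ORF extent) and
#' `ir_start`, `ir_end` (the upstream intergenic interval, to the previous
#' annotated feature or the contig edge).
#'
#' @param ann data.frame as described above.
#' @return The validated data.frame (invisibly usable downstream).
#' @export
validate_annotation <- function(ann) {
  need <- c("gene_id", "contig", "atg", "strand", "orf_start", "orf_end",
            "ir_start", "ir_end")
  miss <- setdiff(need, names(ann))
  if (length(miss) > 0L) {
    stop("annotation missing column(s): ", paste(miss, collapse = ", "))
  }
  stopifnot(!anyDuplicated(ann$gene_id), all(ann$strand %in% c("+", "-")),
            all(ann$orf_start < ann$orf_end), all(ann$ir_start <= ann$ir_end))
  ok_atg <- ifelse(ann$strand == "+", ann$atg == ann$orf_start,
                   ann$atg == ann$orf_end - 1L)
  if (!all(ok_atg)) {
    stop("atg must equal orf_start (+ strand) or orf_end - 1 (- strand)")
  }
  ann
}

#' Per-gene chromatin regions
#'
#' Computes the fixed-width windows around each gene's ATG plus the
#' intergenic (IR) and ORF coding regions, in 0-based half-open coordinates.
#' On the + strand the upstream window is `[atg - width, atg)` and the
#' downstream window `[atg, atg + width)`; on the - strand the windows are
#' mirrored around the stored ATG base (upstream `[atg + 1, atg + 1 + width)`).
#' Windows are truncated at contig bounds.
#'
#' @param ann Annotation data.frame (see [validate_annotation()]).
#' @param widths Integer vector of window widths in bp (default 500 and 1000).
#' @param contig_lengths Named integer vector of contig lengths used for
#'   truncation; regions are always clipped at 0.
#' @return data.frame with columns `gene_id`, `region` (e.g. `up1000`,
#'   `down500`, `IR`, `ORF`), `contig`, `start`, `end`.
#' @export
gene_windows <- function(ann, widths = c(500L, 1000L), contig_lengths = NULL) {
  ann <- validate_annotation(ann)
  stopifnot(all(widths > 0))
  if (!is.null(contig_lengths)) {
    len <- contig_lengths[ann$contig]
    if (any(is.na(len))) stop("contig missing from contig_lengths")
    if (any(ann$atg < 0L | ann$atg >= len)) stop("gene ATG off contig")
  }
  plus <- ann$strand == "+"
  # anchor such that upstream/downstream abut at the ATG on both strands
  anchor <- ifelse(plus, ann$atg, ann$atg + 1L)
  pieces <- list()
  for (w in widths) {
    up_start <- ifelse(plus, anchor - w, anchor)
    up_end <- ifelse(plus, anchor, anchor + w)
    dn_start <- ifelse(plus, anchor, anchor - w)
    dn_end <- ifelse(plus, anchor + w, anchor)
    pieces[[paste0("up", w)]] <- data.frame(
      gene_id = ann$gene_id, region = paste0("up", w), contig = ann$contig,
      start = up_start, end = up_end, stringsAsFactors = FALSE)
    pieces[[paste0("down", w)]] <- data.frame(
      gene_id = ann$gene_id, region = paste0("down", w), contig = ann$contig,
      start = dn_start, end = dn_end, stringsAsFactors = FALSE)
  }
  pieces[["IR"]] <- data.frame(
    gene_id = ann$gene_id, region = "IR", contig = ann$contig,
    start = ann$ir_start, end = ann$ir_end, stringsAsFactors = FALSE)
  pieces[["ORF"]] <- data.frame(
    gene_id = ann$gene_id, region = "ORF", contig = ann$contig,
    start = ann$orf_start, end = ann$orf_end, stringsAsFactors = FALSE)
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out$start <- pmax(out$start, 0L)
  if (!is.null(contig_lengths)) {
    out$end <- pmin(out$end, as.integer(contig_lengths[out$contig]))
  }
  out$end <- pmax(out$end, out$start)
  out
}

#' Extract promoter sequences
#'
#' Returns, for each gene, the promoter defined as the `len` bases from the
#' start codon upstream of the ORF (truncated at contig bounds), oriented
#' 5'->3' relative to the gene (reverse-complemented for - strand genes).
#'
#' @param genome Named character vector of contig sequences.
#' @param ann Annotation data.frame.
#' @param len Promoter length in bp (default 800).
#' @return Named character vector of promoter sequences.
#' @export
promoter_sequences <- function(genome, ann, len = 800L) {
  ann <- validate_annotation(ann)
  stopifnot(all(ann$contig %in% names(genome)))
  L <- nchar(genome)[ann$contig]
  plus <- ann$strand == "+"
  s <- ifelse(plus, pmax(0L, ann$atg - len), ann$atg + 1L)
  e <- ifelse(plus, ann$atg, pmin(L, ann$atg + 1L + len))
  out <- substring(genome[ann$contig], s + 1L, e)
  minus <- which(!plus)
  out[minus] <- vapply(out[minus], reverse_complement, character(1L),
                       USE.NAMES = FALSE)
  names(out) <- ann$gene_id
  out
}

#' Genome-coordinate motif sites in promoters
#'
#' Scans every gene's promoter with a PSSM and reports the hits as genomic
#' intervals (0-based half-open) together with the gene they belong to.
#' Promoters are oriented 5'->3' relative to the gene before scanning; hit
#' coordinates are mapped back to the forward strand of the contig.
#'
#' @inheritParams scan_sequence
#' @param genome Named character vector of contig sequences.
#' @param ann Annotation data.frame.
#' @param promoter_len Promoter length in bp.
#' @return data.frame: `gene_id`, `contig`, `start`, `end`, `strand`
#'   (orientation of the match relative to the contig), `score`.
#' @export
promoter_motif_sites <- function(x, genome, ann, promoter_len = 800L,
                                 bg = background_from_gc(0.37),
                                 score_threshold = NULL, pseudocount = 0.01) {
  stopifnot(inherits(x, "pssm"))
  ann <- validate_annotation(ann)
  if (is.null(score_threshold)) {
    score_threshold <- 0.6 * pssm_max_score(x, bg, pseudocount)
  }
  proms <- promoter_sequences(genome, ann, promoter_len)
  L <- nchar(genome)[ann$contig]
  plus <- ann$strand == "+"
  p_start <- ifelse(plus, pmax(0L, ann$atg - promoter_len), ann$atg + 1L)
  p_end <- ifelse(plus, ann$atg, pmin(L, ann$atg + 1L + promoter_len))
  out <- vector("list", nrow(ann))
  for (k in seq_len(nrow(ann))) {
    hits <- scan_sequence(x, proms[[k]], bg, score_threshold,
                          both_strands = TRUE, pseudocount = pseudocount,
                          seq_id = ann$gene_id[k])
    if (nrow(hits) == 0L) next
    if (plus[k]) {
      gs <- p_start[k] + hits$offset
      strand <- hits$strand
    } else {
      gs <- p_end[k] - hits$offset - x$n
      strand <- ifelse(hits$strand == "+", "-", "+")
    }
    out[[k]] <- data.frame(gene_id = ann$gene_id[k], contig = ann$contig[k],
                           start = gs, end = gs + x$n, strand = strand,
                           score = hits$score, stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0L) {
    return(data.frame(gene_id = character(), contig = character(),
                      start = integer(), end = integer(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Reverse complement of a nucleotide string
#'
#' @param seq Character string over A, C, G, T, N (case-insensitive).
#' @return Reverse-complemented string (uppercase).
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) return(seq)
  intToUtf8(rev(utf8ToInt(chartr("ACGTacgt", "TGCATGCA", seq))))
}
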