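#' Read PSSMs from a MEME motif file
#'
#' Parses the minimal MEME motif text format (version line, optional
#' background, `MOTIF` blocks with `letter-probability matrix:` headers).
#' Rows are validated to sum to 1 within `tol` and renormalised exactly;
#' rows beyond tolerance raise an error naming the motif and position.
#'
#' @param path Path to a MEME motif format file.
#' @param tol Row-sum tolerance before a row is rejected (default 1e-6).
#' @return Named list of [pssm()] objects (possibly empty, with a warning).
#' @export
read_pssms <- function(path, tol = 1e-6) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  motif_idx <- grep("^MOTIF\\b", lines)
  if (length(motif_idx) == 0L) {
    warning(sprintf("no motifs found in '%s'", path))
    return(structure(list(), names = character()))
  }
  out <- vector("list", length(motif_idx))
  ids <- character(length(motif_idx))
  bounds <- c(motif_idx, length(lines) + 1L)
  for (k in seq_along(motif_idx)) {
    block <- lines[motif_idx[k]:(bounds[k + 1L] - 1L)]
    id <- strsplit(block[1L], "[[:space:]]+")[[1L]][2L]
    if (is.na(id)) stop(sprintf("MOTIF line %d has no identifier", motif_idx[k]))
    hdr <- grep("^letter-probability matrix:", block)
    if (length(hdr) != 1L) {
      stop(sprintf("motif '%s': expected one letter-probability matrix block", id))
    }
    w <- sub(".*\\bw=\\s*([0-9]+).*", "\\1", block[hdr])
    w <- suppressWarnings(as.integer(w))
    rows <- block[-seq_len(hdr)]
    rows <- rows[nzchar(rows)]
    num <- grepl("^[-0-9.eE+[:space:]]+$", rows)
    rows <- rows[cumsum(!num) == 0L]  # stop at first non-numeric line
    if (!is.na(w)) rows <- utils::head(rows, w)
    if (length(rows) == 0L) stop(sprintf("motif '%s': empty probability matrix", id))
    mat <- do.call(rbind, lapply(rows, function(r) {
      as.numeric(strsplit(r, "[[:space:]]+")[[1L]])
    }))
    if (ncol(mat) != 4L) stop(sprintf("motif '%s': expected 4 columns", id))
    if (!is.na(w) && nrow(mat) != w) {
      stop(sprintf("motif '%s': header says w=%d but %d rows found", id, w, nrow(mat)))
    }
    if (any(mat < 0)) stop(sprintf("motif '%s': negative weight", id))
    rs <- rowSums(mat)
    bad <- which(abs(rs - 1) > tol)
    if (length(bad) > 0L) {
      stop(sprintf("motif '%s': row %d sums to %.6g (tolerance %g)",
                   id, bad[1L], rs[bad[1L]], tol))
    }
    mat <- mat / rs
    ids[k] <- id
    out[[k]] <- pssm(id, mat)
  }
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate motif id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  names(out) <- ids
  out
}

#' Write PSSMs to a MEME motif file
#'
#' @param pssms List of [pssm()] objects.
#' @param path Output path.
#' @param bg Background frequencies written to the header.
#' @return `path`, invisibly.
#' @export
write_pssms <- function(pssms, path, bg = background_from_gc(0.37)) {
  stopifnot(is.list(pssms))
  bg <- check_background(bg)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "", "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f",
                       bg["A"], bg["C"], bg["G"], bg["T"]), ""), con)
  for (p in pssms) {
    stopifnot(inherits(p, "pssm"))
    writeLines(sprintf("MOTIF %s", p$id), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0", p$n), con)
    writeLines(apply(p$mat, 1L, function(r) {
      paste(sprintf("%.9f", r), collapse = " ")
    }), con)
    writeLines("", con)
  }
  invisible(path)
}
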