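#' Configuration for a synthetic regulatory world
#'
#' Bundles and validates the parameters of [generate_world()]. The defaults
#' describe the emulated study system: ~2 kb of genome per gene at 37% GC
#' (800 bp promoters), 25 chromatin features split into 14 ATG-window
#' modifications and 11 intergenic/ORF acetylations, 60 bp probes tiling 85%
#' of the genome, per-TF target prevalence 5%, and a two-condition design in
#' which condition-specific factors change their target sets.
#'
#' @param n_genes Number of genes.
#' @param n_tfs Number of transcription factors. A warning is issued when
#'   `n_genes < 10 * n_tfs` (too few genes per factor for stable models).
#' @param promoter_len Promoter length in bp (scanning window upstream of the
#'   start codon).
#' @param gc Genome GC fraction for the i.i.d. background sequence.
#' @param n_windowed,n_ir Number of modifications in the ATG-window group and
#'   the intergenic/ORF acetylation group.
#' @param probe_len Probe length in bp.
#' @param probe_coverage Fraction of the genome tiled by probes.
#' @param target_prevalence Per-gene probability of being a target of each TF.
#' @param motif_plant_prob Probability that a target promoter of a
#'   direct-binding TF receives a planted motif instance.
#' @param sensitive_fraction Fraction of TFs that are histone-sensitive.
#' @param modification_effect Shift (in SD units) added to the upstream/IR
#'   signal of sensitive-TF target genes, on the affected modifications.
#' @param n_affected_windowed,n_affected_ir How many modifications of each
#'   group carry the sensitivity shift.
#' @param pvalue_shape Two Beta shape parameters of the skewed ChIP P-value
#'   distribution for true targets (non-targets are Uniform(0,1)).
#' @param condition_shift Shift applied in condition "B" tracks to targets of
#'   sensitive TFs under condition B.
#' @param condition_specific_fraction Fraction of TFs whose condition-B
#'   target set is redrawn independently of condition A.
#' @param two_conditions Generate condition "B" tracks/targets as well.
#' @param site_depletion_effect Occupancy depletion (SD units, subtracted)
#'   applied to the first two windowed features (H3/H4 occupancy-like) at
#'   probes covering planted binding sites.
#' @param probe_noise_sd SD of probe-level noise around the region value.
#' @param orf_len,spacer_len ORF and intergenic spacer lengths in bp.
#' @param motif_len Motif length of generated PSSMs.
#' @param motif_concentration Probability of the dominant base at each PSSM
#'   position (1 gives deterministic one-hot motifs).
#' @param n_cooperative Number of cooperative TF pairs: in a pair (A, B), A is
#'   an indirect binder whose target promoters carry B's motif while A's own
#'   PSSM is a decoy.
#' @param expression_meanlog,expression_sdlog Log-normal expression
#'   parameters.
#' @param seed Integer RNG seed; the whole world is deterministic given the
#'   config.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 2000L, n_tfs = 20L, promoter_len = 800L,
                             gc = 0.37, n_windowed = 14L, n_ir = 11L,
                             probe_len = 60L, probe_coverage = 0.85,
                             target_prevalence = 0.05, motif_plant_prob = 0.8,
                             sensitive_fraction = 0.35,
                             modification_effect = 1.0,
                             n_affected_windowed = 6L, n_affected_ir = 4L,
                             pvalue_shape = c(0.1, 1), condition_shift = 1.0,
                             condition_specific_fraction = 0.5,
                             two_conditions = TRUE,
                             site_depletion_effect = 1.5,
                             probe_noise_sd = 0.25,
                             orf_len = 1000L, spacer_len = 200L,
                             motif_len = 8L, motif_concentration = 0.85,
                             n_cooperative = 0L,
                             expression_meanlog = 5, expression_sdlog = 1,
                             seed = 1L) {
  cfg <- as.list(environment())
  fracs <- c(probe_coverage = probe_coverage,
             target_prevalence = target_prevalence,
             motif_plant_prob = motif_plant_prob,
             sensitive_fraction = sensitive_fraction,
             condition_specific_fraction = condition_specific_fraction)
  if (any(fracs < 0 | fracs > 1)) {
    bad <- names(fracs)[fracs < 0 | fracs > 1]
    stop("fraction parameter(s) outside [0, 1]: ", paste(bad, collapse = ", "))
  }
  if (gc <= 0 || gc >= 1) stop("gc must be strictly between 0 and 1")
  stopifnot(n_genes >= 1L, n_tfs >= 0L, motif_len >= 1L, probe_len >= 1L,
            orf_len >= 1L, spacer_len >= 0L, length(pvalue_shape) == 2L,
            all(pvalue_shape > 0), motif_concentration >= 0.25,
            motif_concentration <= 1, n_cooperative >= 0L,
            2L * n_cooperative <= n_tfs, n_affected_windowed <= n_windowed,
            n_affected_ir <= n_ir)
  if (promoter_len < motif_len) {
    stop("promoter_len must be at least the motif length")
  }
  if (n_tfs > 0L && n_genes < 10L * n_tfs) {
    warning(sprintf("n_genes = %d is below the recommended 10 * n_tfs = %d",
                    n_genes, 10L * n_tfs))
  }
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "synthetic_config")
}

windowed_mod_names <- function(n) {
  base <- c("H3", "H4", "H3K4me1", "H3K4me2", "H3K4me3", "H3K9ac",
            "H3K14ac", "H3K36me3", "H3K79me3", "H4ac", "H3K27ac", "H2AZ",
            "H3K56ac", "H3K18ac")
  if (n <= length(base)) base[seq_len(n)] else c(base, sprintf("HM%02d", seq_len(n - length(base))))
}

ir_mod_names <- function(n) {
  base <- c("acH2AK7", "acH2BK11", "acH2BK16", "acH3K9", "acH3K14",
            "acH3K18", "acH3K23", "acH4K5", "acH4K8", "acH4K12", "acH4K16")
  if (n <= length(base)) base[seq_len(n)] else c(base, sprintf("acX%02d", seq_len(n - length(base))))
}

sample_pssm_instance <- function(x) {
  paste(vapply(seq_len(x$n), function(i) {
    sample(DNA_BASES, 1L, prob = x$mat[i, ])
  }, character(1L)), collapse = "")
}

#' Generate a synthetic regulatory world
#'
#' Builds a complete, seeded synthetic data set with known ground truth:
#' an i.i.d. background genome organised as tandem gene cassettes
#' (spacer + promoter + ORF, random strand), per-TF PSSMs with motif
#' instances planted in target promoters, probe-level chromatin tracks in
#' which sensitive-TF target regions carry planted signal shifts (and
#' planted binding sites deplete the occupancy-like features), skewed ChIP
#' binding P-values for targets, expression levels and per-TF attribute
#' tables. Everything downstream of the generator can therefore be checked
#' against truth.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_world` with elements `config`,
#'   `genome` (named character), `contig_lengths`, `annotation`, `pssms`,
#'   `tf_info`, `tracks` (named list of [signal_track()] per condition),
#'   `pvalues` (gene x TF matrix per condition), `expression`, `attributes`
#'   and `truth` (target matrices, sensitivity labels, affected
#'   modifications, planted sites).
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  set.seed(cfg$seed)
  n_genes <- cfg$n_genes; n_tfs <- cfg$n_tfs
  cassette <- cfg$spacer_len + cfg$promoter_len + cfg$orf_len
  contig <- "chrI"
  contig_len <- n_genes * cassette
  bg <- background_from_gc(cfg$gc)

  tf_ids <- if (n_tfs > 0L) sprintf("TF%02d", seq_len(n_tfs)) else character()
  n_sens <- round(cfg$sensitive_fraction * n_tfs)
  sensitive <- stats::setNames(rep(FALSE, n_tfs), tf_ids)
  if (n_sens > 0L) sensitive[sample(n_tfs, n_sens)] <- TRUE
  n_cond <- round(cfg$condition_specific_fraction * n_tfs)
  cond_specific <- stats::setNames(rep(FALSE, n_tfs), tf_ids)
  if (n_cond > 0L) cond_specific[sample(n_tfs, n_cond)] <- TRUE
  # keep the two analyses jointly exercisable: ensure at least one sensitive
  # factor is condition-specific whenever both sets are nonempty
  if (any(sensitive) && any(cond_specific) && !any(sensitive & cond_specific)) {
    cond_specific[names(which(sensitive))[1L]] <- TRUE
  }
  partner <- stats::setNames(rep(NA_character_, n_tfs), tf_ids)
  direct <- stats::setNames(rep(TRUE, n_tfs), tf_ids)
  if (cfg$n_cooperative > 0L) {
    picked <- sample(n_tfs, 2L * cfg$n_cooperative)
    for (k in seq_len(cfg$n_cooperative)) {
      a <- picked[2L * k - 1L]; b <- picked[2L * k]
      direct[a] <- FALSE
      partner[a] <- tf_ids[b]
    }
  }

  # target truth per condition: independent Bernoulli per gene
  draw_targets <- function() {
    matrix(stats::runif(n_genes * n_tfs) < cfg$target_prevalence,
           nrow = n_genes, ncol = n_tfs,
           dimnames = list(sprintf("g%04d", seq_len(n_genes)), tf_ids))
  }
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  targets <- list(A = draw_targets())
  if (cfg$two_conditions) {
    tb <- targets$A
    if (any(cond_specific)) {
      redraw <- draw_targets()
      tb[, cond_specific] <- redraw[, cond_specific]
    }
    targets$B <- tb
  }

  # PSSMs: one dominant base per position
  pssms <- lapply(tf_ids, function(id) {
    dom <- sample.int(4L, cfg$motif_len, replace = TRUE)
    mat <- matrix((1 - cfg$motif_concentration) / 3, cfg$motif_len, 4L)
    mat[cbind(seq_len(cfg$motif_len), dom)] <- cfg$motif_concentration
    pssm(id, mat / rowSums(mat))
  })
  names(pssms) <- tf_ids

  # annotation: tandem cassettes, random strand
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  cs <- (seq_len(n_genes) - 1L) * cassette
  plus <- strand == "+"
  orf_start <- ifelse(plus, cs + cfg$spacer_len + cfg$promoter_len, cs)
  orf_end <- orf_start + cfg$orf_len
  atg <- ifelse(plus, orf_start, orf_end - 1L)
  ir_start <- ifelse(plus, cs, orf_end)
  ir_end <- ifelse(plus, orf_start, cs + cassette)
  ann <- data.frame(gene_id = gene_ids, contig = contig, atg = as.integer(atg),
                    strand = strand, orf_start = as.integer(orf_start),
                    orf_end = as.integer(orf_end),
                    ir_start = as.integer(ir_start),
                    ir_end = as.integer(ir_end), stringsAsFactors = FALSE)
  # genomic promoter interval (motif planting space)
  prom_start <- ifelse(plus, atg - cfg$promoter_len, atg + 1L)
  prom_end <- ifelse(plus, atg, atg + 1L + cfg$promoter_len)

  chars <- sample(DNA_BASES, contig_len, replace = TRUE, prob = bg)

  # plant motif instances in target promoters (condition A target sets)
  planted <- vector("list", 256L); np <- 0L
  occupied <- vector("list", n_genes)
  for (t in seq_len(n_tfs)) {
    src <- if (direct[t]) pssms[[t]] else pssms[[partner[t]]]
    if (is.null(src)) next
    gsel <- which(targets$A[, t])
    gsel <- gsel[stats::runif(length(gsel)) < cfg$motif_plant_prob]
    for (g in gsel) {
      inst <- sample_pssm_instance(src)
      st <- sample(c("+", "-"), 1L)
      written <- if (st == "-") reverse_complement(inst) else inst
      lo <- prom_start[g]; hi <- prom_end[g] - cfg$motif_len
      pos <- NA_integer_
      for (try in seq_len(50L)) {
        cand <- lo + sample.int(hi - lo + 1L, 1L) - 1L
        occ <- occupied[[g]]
        if (is.null(occ) ||
            all(cand + cfg$motif_len <= occ[, 1L] | cand >= occ[, 2L])) {
          pos <- cand; break
        }
      }
      if (is.na(pos)) pos <- lo + sample.int(hi - lo + 1L, 1L) - 1L
      chars[(pos + 1L):(pos + cfg$motif_len)] <- strsplit(written, "", fixed = TRUE)[[1L]]
      occupied[[g]] <- rbind(occupied[[g]], c(pos, pos + cfg$motif_len))
      np <- np + 1L
      if (np > length(planted)) planted <- c(planted, vector("list", length(planted)))
      planted[[np]] <- data.frame(tf = tf_ids[t], gene_id = gene_ids[g],
                                  contig = contig, start = pos,
                                  end = pos + cfg$motif_len, strand = st,
                                  stringsAsFactors = FALSE)
    }
  }
  planted_sites <- if (np > 0L) do.call(rbind, planted[seq_len(np)]) else
    data.frame(tf = character(), gene_id = character(), contig = character(),
               start = integer(), end = integer(), strand = character(),
               stringsAsFactors = FALSE)
  genome <- stats::setNames(paste(chars, collapse = ""), contig)

  # probe grid: regular tiling, then random gaps down to the target coverage
  all_starts <- seq.int(0L, contig_len - cfg$probe_len, by = cfg$probe_len)
  n_keep <- round(cfg$probe_coverage * length(all_starts))
  keep <- sort(sample(length(all_starts), n_keep))
  probe_start <- all_starts[keep]
  probe_df <- data.frame(contig = contig, start = probe_start,
                         end = probe_start + cfg$probe_len,
                         stringsAsFactors = FALSE)
  # zone of each probe midpoint: upstream/IR zone or ORF zone of its cassette
  mid <- probe_start + cfg$probe_len / 2
  pg <- pmin(n_genes, floor(mid / cassette) + 1L)
  within <- mid - (pg - 1L) * cassette
  in_up <- ifelse(plus[pg], within < cfg$spacer_len + cfg$promoter_len,
                  within >= cfg$orf_len)

  mods_w <- windowed_mod_names(cfg$n_windowed)
  mods_i <- ir_mod_names(cfg$n_ir)
  all_mods <- c(mods_w, mods_i)
  groups <- stats::setNames(c(rep("windowed", cfg$n_windowed),
                              rep("ir_orf", cfg$n_ir)), all_mods)
  # the first two windowed features act as H3/H4 occupancy: they carry the
  # binding-site depletion and are excluded from the sensitivity-shift draw
  occupancy_mods <- utils::head(mods_w, 2L)
  shiftable <- setdiff(mods_w, occupancy_mods)
  if (cfg$n_affected_windowed > length(shiftable)) {
    stop("n_affected_windowed exceeds the number of non-occupancy windowed modifications")
  }
  affected <- c(if (cfg$n_affected_windowed > 0L) sample(shiftable, cfg$n_affected_windowed),
                if (cfg$n_affected_ir > 0L) sample(mods_i, cfg$n_affected_ir))
  depleted_probe <- rep(FALSE, nrow(probe_df))
  if (nrow(planted_sites) > 0L && cfg$site_depletion_effect != 0) {
    site_gr <- GenomicRanges::GRanges(
      planted_sites$contig,
      IRanges::IRanges(planted_sites$start + 1L, planted_sites$end))
    hit <- GenomicRanges::findOverlaps(probes_granges(probe_df), site_gr)
    depleted_probe[unique(S4Vectors::queryHits(hit))] <- TRUE
  }

  make_track <- function(cond) {
    tmat <- targets[[cond]]
    eff <- if (cond == "A") cfg$modification_effect else cfg$condition_shift
    shift_up <- rep(0, n_genes)  # per-gene shift reused per affected mod
    if (n_tfs > 0L && any(sensitive)) {
      ntarg <- rowSums(tmat[, sensitive, drop = FALSE])
      shift_up <- eff * ntarg
    }
    mods <- vector("list", length(all_mods))
    names(mods) <- all_mods
    for (m in all_mods) {
      upv <- stats::rnorm(n_genes)
      orfv <- stats::rnorm(n_genes)
      if (m %in% affected) upv <- upv + shift_up
      zone_val <- ifelse(in_up, upv[pg], orfv[pg])
      v <- zone_val + stats::rnorm(nrow(probe_df), sd = cfg$probe_noise_sd)
      if (m %in% occupancy_mods) v[depleted_probe] <- v[depleted_probe] - cfg$site_depletion_effect
      mods[[m]] <- data.frame(probe_df, value = v, stringsAsFactors = FALSE)
    }
    signal_track(mods, groups, condition = cond)
  }
  conds <- if (cfg$two_conditions) c("A", "B") else "A"
  tracks <- lapply(stats::setNames(conds, conds), make_track)

  make_pvals <- function(cond) {
    tmat <- targets[[cond]]
    p <- matrix(stats::runif(n_genes * n_tfs), n_genes, n_tfs,
                dimnames = dimnames(tmat))
    if (any(tmat)) {
      p[tmat] <- stats::rbeta(sum(tmat), cfg$pvalue_shape[1L], cfg$pvalue_shape[2L])
    }
    p
  }
  pvalues <- lapply(stats::setNames(conds, conds), make_pvals)

  expression <- stats::setNames(
    stats::rlnorm(n_genes, cfg$expression_meanlog, cfg$expression_sdlog),
    gene_ids)

  attributes_df <- data.frame(
    tf = tf_ids,
    hierarchy_level = if (n_tfs > 0L) {
      vapply(seq_len(n_tfs), function(t) {
        pr <- if (sensitive[t]) c(0.5, 0.3, 0.2) else c(0.2, 0.3, 0.5)
        sample(3L, 1L, prob = pr)
      }, integer(1L))
    } else integer(),
    ppi_degree = stats::rpois(n_tfs, lambda = ifelse(sensitive, 15, 8)),
    stringsAsFactors = FALSE)

  tf_info <- data.frame(tf = tf_ids, sensitive = as.logical(sensitive),
                        direct = as.logical(direct),
                        condition_specific = as.logical(cond_specific),
                        partner = as.character(partner),
                        stringsAsFactors = FALSE)

  structure(list(
    config = cfg,
    genome = genome,
    contig_lengths = stats::setNames(contig_len, contig),
    annotation = ann,
    pssms = pssms,
    tf_info = tf_info,
    tracks = tracks,
    pvalues = pvalues,
    expression = expression,
    attributes = attributes_df,
    truth = list(targets = targets, sensitive = sensitive,
                 affected_mods = affected, planted_sites = planted_sites,
                 occupancy_mods = occupancy_mods)
  ), class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "synthetic_world: %d genes, %d TFs (%d sensitive), %d condition(s), %d planted sites, seed %d\n",
    x$config$n_genes, x$config$n_tfs, sum(x$truth$sensitive),
    length(x$tracks), nrow(x$truth$planted_sites), x$config$seed))
  invisible(x)
}
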