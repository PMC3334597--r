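#' Run the integrated analysis pipeline
#'
#' Executes the requested stages in dependency order on a synthetic world
#' and writes all stage outputs as TSV plus a JSON run manifest recording
#' the package version, seeds and every resolved default. Stages:
#'
#' * `simulate` - generate the synthetic world and write it to
#'   `<out_dir>/world/`.
#' * `scan` - scan every promoter with every PSSM, producing per-gene
#'   cumulative matching scores (needs `simulate`).
#' * `signals` - build the per-gene signal matrix per condition (needs
#'   `simulate`).
#' * `train` - call targets at the P-value cutoff and run cross-validated
#'   models per TF and feature group (needs `scan` and `signals`).
#' * `profiles` - target and differential modification profiles (needs
#'   `signals` and `train`).
#' * `sensitivity` - k-means histone-sensitivity classification and the
#'   modification correlation network (needs `profiles`).
#'
#' A stage whose prerequisites are not part of the run raises a dependency
#' error.
#'
#' @param config Named list (or path to a YAML file) with entries
#'   `seed`, `synthetic` (arguments for [synthetic_config()]), and optional
#'   `cutoff` (default 0.01), `regions` (default up1000/down1000),
#'   `feature_groups` (default hm, pssm and hm+pssm), `repeats` (default
#'   50), `folds` (default 2), `tfs` (TF subset to model; default all),
#'   `motif_threshold_frac` (default 0.6), `correlation_threshold`
#'   (default 0.5), `min_targets` (default 10).
#' @param stages Character vector of stages to run.
#' @param out_dir Output directory.
#' @return List with the in-memory stage results (`world`, `motif_scores`,
#'   `signals`, `labels`, `evals`, `profiles`, `sensitivity`, `network`)
#'   and the `manifest`, invisibly.
#' @export
run_pipeline <- function(config, stages = c("simulate", "scan", "signals", "train"),
                         out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  all_stages <- c("simulate", "scan", "signals", "train", "profiles", "sensitivity")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  deps <- list(simulate = character(), scan = "simulate", signals = "simulate",
               train = c("scan", "signals"), profiles = c("signals", "train"),
               sensitivity = "profiles")
  for (s in stages) {
    miss <- setdiff(deps[[s]], stages)
    if (length(miss) > 0L) {
      stop(sprintf("stage '%s' requires missing upstream stage(s): %s",
                   s, paste(miss, collapse = ", ")))
    }
  }
  stages <- all_stages[all_stages %in% stages]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  seed <- if (!is.null(config$seed)) as.integer(config$seed) else 1L
  cutoff <- config$cutoff %||% 0.01
  regions <- config$regions %||% c("up1000", "down1000")
  repeats <- config$repeats %||% 50L
  folds <- config$folds %||% 2L
  groups_list <- config$feature_groups %||%
    list(hm = "hm", pssm = "pssm", hm_pssm = c("hm", "pssm"))
  thr_frac <- config$motif_threshold_frac %||% 0.6
  cor_thr <- config$correlation_threshold %||% 0.5
  min_targets <- config$min_targets %||% 10L

  log_lines <- c(
    sprintf("chromtarget %s", as.character(utils::packageVersion("chromtarget"))),
    sprintf("seed: %d", seed),
    sprintf("target P-value cutoff: %g (strict <)", cutoff),
    sprintf("signal regions: %s", paste(regions, collapse = ", ")),
    sprintf("motif hit threshold: %g of maximum achievable score", thr_frac),
    sprintf("probe inclusion rule: any-overlap (>= 1 bp), unweighted mean"),
    sprintf("log-odds pseudocount: 0.01"),
    sprintf("CV: %d repeats x %d folds", repeats, folds))
  state <- list()

  if ("simulate" %in% stages) {
    syn_args <- config$synthetic %||% list()
    syn_args$seed <- syn_args$seed %||% seed
    cfg <- do.call(synthetic_config, syn_args)
    state$world <- generate_world(cfg)
    write_world(state$world, file.path(out_dir, "world"))
  }
  world <- state$world
  bg <- background_from_gc(world$config$gc)

  if ("scan" %in% stages) {
    promoters <- promoter_sequences(world$genome, world$annotation,
                                    len = world$config$promoter_len)
    state$motif_scores <- lapply(world$pssms, function(p) {
      cumulative_scores(p, promoters, bg = bg,
                        score_threshold = thr_frac * pssm_max_score(p, bg))
    })
    sc <- do.call(cbind, state$motif_scores)
    if (!is.null(sc)) {
      data.table::fwrite(
        data.table::data.table(gene_id = rownames(sc), sc),
        file.path(out_dir, "motif_scores.tsv"), sep = "\t")
    }
  }

  if ("signals" %in% stages) {
    state$signals <- lapply(world$tracks, function(tr) {
      build_gene_signal_matrix(world$annotation, tr,
                               contig_lengths = world$contig_lengths)
    })
    for (cond in names(state$signals)) {
      write_gene_signal_matrix(state$signals[[cond]],
                               file.path(out_dir, sprintf("signals_%s.tsv", cond)))
    }
  }

  if ("train" %in% stages) {
    state$labels <- call_targets(world$pvalues$A, cutoff = cutoff)
    tfs <- config$tfs %||% colnames(state$labels)
    evals <- list()
    rows <- list()
    for (tf in tfs) {
      for (gname in names(groups_list)) {
        ev <- tryCatch(
          cv_train_evaluate(
            assemble_features(state$labels[, tf], signals = state$signals$A,
                              motif_scores = state$motif_scores[[tf]],
                              groups = groups_list[[gname]], regions = regions),
            repeats = repeats, folds = folds, seed = seed),
          error = function(e) e)
        if (inherits(ev, "error")) {
          message(sprintf("train: skipping %s/%s: %s", tf, gname, conditionMessage(ev)))
          next
        }
        evals[[paste(tf, gname, sep = ".")]] <- ev
        rows[[length(rows) + 1L]] <- data.frame(
          tf = tf, model = gname, auc = ev$auc, ppv = ev$ppv_topk,
          n_pos = ev$n_pos, stringsAsFactors = FALSE)
      }
    }
    state$evals <- evals
    state$eval_table <- if (length(rows) > 0L) do.call(rbind, rows) else NULL
    if (!is.null(state$eval_table)) {
      data.table::fwrite(state$eval_table, file.path(out_dir, "model_aucs.tsv"),
                         sep = "\t")
    }
  }

  if ("profiles" %in% stages) {
    state$profiles <- target_mod_profiles(state$labels, state$signals$A,
                                          min_targets = min_targets)
    state$diff_profiles <- diff_mod_profiles(state$labels, state$signals$A)
    data.table::fwrite(
      data.table::data.table(tf = rownames(state$profiles$z), state$profiles$z),
      file.path(out_dir, "target_profiles_z.tsv"), sep = "\t")
    data.table::fwrite(
      data.table::data.table(tf = rownames(state$diff_profiles$t),
                             state$diff_profiles$t),
      file.path(out_dir, "diff_profiles_t.tsv"), sep = "\t")
  }

  if ("sensitivity" %in% stages) {
    state$sensitivity <- cluster_sensitivity(state$profiles, seed = seed)
    state$network <- modification_correlation_network(state$diff_profiles$t,
                                                      threshold = cor_thr)
    data.table::fwrite(state$sensitivity, file.path(out_dir, "sensitivity.tsv"),
                       sep = "\t")
    data.table::fwrite(state$network, file.path(out_dir, "mod_network.tsv"),
                       sep = "\t")
  }

  manifest <- list(
    package = "chromtarget",
    version = as.character(utils::packageVersion("chromtarget")),
    stages = stages,
    seed = seed,
    parameters = list(cutoff = cutoff, regions = regions, repeats = repeats,
                      folds = folds, motif_threshold_frac = thr_frac,
                      correlation_threshold = cor_thr,
                      min_targets = min_targets),
    log = log_lines)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  state$manifest <- manifest
  invisible(state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
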