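# Shared synthetic worlds, built once per test run and cached by key.
.world_cache <- new.env(parent = emptyenv())

cached_world <- function(key, cfg) {
  if (!exists(key, envir = .world_cache)) {
    assign(key, generate_world(cfg), envir = .world_cache)
  }
  get(key, envir = .world_cache)
}

# small fast world for plumbing tests
small_world <- function(seed = 42L) {
  cached_world(paste0("small", seed), synthetic_config(
    n_genes = 120L, n_tfs = 4L, orf_len = 400L, spacer_len = 100L,
    promoter_len = 300L, target_prevalence = 0.15, seed = seed))
}

world_signals <- function(world, cond = "A") {
  key <- paste0("sig_", world$config$seed, "_", world$config$n_genes, "_", cond)
  if (!exists(key, envir = .world_cache)) {
    assign(key, build_gene_signal_matrix(world$annotation, world$tracks[[cond]],
                                         contig_lengths = world$contig_lengths),
           envir = .world_cache)
  }
  get(key, envir = .world_cache)
}
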