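# Shared fixtures built in code.

toy_counts <- function(mat, lanes = NULL) {
  if (is.null(lanes)) lanes <- paste0("L", seq_len(ncol(mat)))
  colnames(mat) <- lanes
  tibble::tibble(gene_id = paste0("g", seq_len(nrow(mat)))) |>
    dplyr::bind_cols(tibble::as_tibble(mat))
}

toy_features <- function(gc, ids = paste0("g", seq_along(gc))) {
  tibble::tibble(gene_id = ids, gc = gc, length_bp = 1000L)
}

# Null 8-lane simulation with library-specific GC bias, fully normalized
# (full-quantile within lanes, then full-quantile between lanes).
null_pipeline <- function(seed, n_genes = 2000, phi = 0.078, K = 50) {
  sim <- simulate_counts(sim_config(n_genes = n_genes, phi = phi, seed = seed))
  counts <- filter_low_counts(sim$counts, sim$meta)
  feats <- sim$features[match(counts$gene_id, sim$features$gene_id), ]
  norm <- normalize_within_lane(counts, feats, method = "full", K = K) |>
    between_lane_fq()
  list(sim = sim, counts = counts, features = feats, norm = norm,
       splits = enumerate_balanced_splits(sim$meta$lane_id))
}
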