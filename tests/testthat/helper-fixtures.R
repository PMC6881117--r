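# shared small fixtures, built in code at test time

small_config <- function(seed = 7L, ...) {
  args <- utils::modifyList(
    list(n_types = 12, n_subclasses = 4, n_cells_per_area = 200,
         n_genes_background = 50, seed = seed),
    list(...))
  do.call(synth_config, args)
}

small_dataset <- function(seed = 7L, ...) {
  cfg <- small_config(seed = seed, ...)
  taxonomy <- generate_taxonomy(cfg)
  ds <- generate_dataset(taxonomy, np_gene_fixture(), cfg)
  ds
}

# latent blobs: one well-separated Gaussian cluster per taxonomy leaf
blob_embedding <- function(taxonomy, n_per_leaf = 40, d = 3, sep = 8,
                           seed = 1L) {
  leaves <- taxonomy_leaves(taxonomy)
  withr::with_seed(seed, {
    centers <- matrix(stats::rnorm(length(leaves) * d), length(leaves), d)
    centers <- centers / sqrt(rowSums(centers^2)) * sep *
      seq_along(leaves)  # distinct radii keep the clusters apart
    z <- do.call(rbind, lapply(seq_along(leaves), function(i) {
      matrix(stats::rnorm(n_per_leaf * d, sd = 0.2), n_per_leaf, d) +
        matrix(centers[i, ], n_per_leaf, d, byrow = TRUE)
    }))
    rownames(z) <- sprintf("cell%04d", seq_len(nrow(z)))
    list(z = z, labels = rep(leaves, each = n_per_leaf))
  })
}

# peak table taken directly from the published fixture columns
fixture_peak_table <- function(tab = np_gene_fixture()) {
  out <- tibble::tibble(
    gene = tab$gene,
    peak_value = tab$peak_fpkm,
    percentile_rank = tab$pfpkm_percentile,
    absolute_rank = rank(-tab$peak_fpkm, ties.method = "first"),
    detection_fraction = tab$pct_cells / 100
  )
  structure(out, class = c("peak_expression_table", class(out)))
}
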