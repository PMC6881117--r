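#' Run the analysis pipeline end to end
#'
#' Convenience driver wiring the package's stages over a synthetic dataset:
#' `simulate` (generate taxonomy, NP gene table and expression),
#' `stats` (peak-expression ranking, detection fractions, co-expression
#' histograms, cross-area conservation), `select` (gene screening, NP gene
#' selection, cognate pairs), `classify` (reference + linked autoencoder,
#' hierarchical RI), `couple` (per-pair coupling matrices, CSV export) and
#' `aggregate` (G-alpha family channels). `"all"` runs everything. Outputs
#' are written under `outdir` together with a machine-readable JSON
#' manifest recording inputs, parameters, seed, package version and file
#' checksums; on stage failure the manifest records the error and partial
#' outputs are retained.
#'
#' @param stages Character vector of stage names (see above).
#' @param config Named list overriding [synth_config()] fields and the
#'   stage parameters `threshold` (detection, default 1), `min_peak_percentile`
#'   (default 80), `reference_epochs` (default 300), `linked_epochs`
#'   (default 150), `latent_dim` (default 5), `lambda` (default 100),
#'   `folds` (default 13), `n_he` (reference gene count, default 200).
#' @param seed Global seed propagated to every stochastic stage.
#' @param outdir Output directory.
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(stages = "all", config = list(), seed = 1L,
                         outdir = tempfile("pepnet_run")) {
  all_stages <- c("simulate", "stats", "select", "classify", "couple",
                  "aggregate")
  if ("all" %in% stages) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  defaults <- list(threshold = 1, min_peak_percentile = 80,
                   reference_epochs = 300, linked_epochs = 150,
                   latent_dim = 5, lambda = 100, folds = 13, n_he = 200)
  params <- utils::modifyList(defaults, config)
  cfg_fields <- names(formals(synth_config))
  cfg <- do.call(synth_config,
                 c(params[intersect(names(params), cfg_fields)],
                   list(seed = seed)))
  manifest <- list(package = "pepnet",
                   version = as.character(utils::packageVersion("pepnet")),
                   seed = seed, stages = stages, parameters = params,
                   status = "running")
  results <- list()
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  on.exit({
    files <- setdiff(list.files(outdir, recursive = TRUE,
                                full.names = TRUE),
                     file.path(outdir, "manifest.json"))
    manifest$checksums <- as.list(tools::md5sum(files))
    write_manifest()
  })

  tryCatch({
    # data are always needed downstream
    tab <- np_gene_fixture()
    taxonomy <- generate_taxonomy(cfg)
    ds <- generate_dataset(taxonomy, tab, cfg)
    if ("simulate" %in% stages) {
      write_expression(ds$counts, file.path(outdir, "counts.tsv"))
      readr::write_tsv(ds$annotation, file.path(outdir, "annotation.tsv"))
      write_taxonomy(taxonomy, file.path(outdir, "taxonomy.json"))
      write_np_gene_table(tab, file.path(outdir, "np_gene_table.tsv"))
      results$simulate <- ds
    }
    cpm <- ds$cpm
    ann <- ds$annotation
    pairs <- build_cognate_pairs(tab$gene[tab$role == "NPP"],
                                 tab$gene[tab$role == "NP-GPCR"], tab)
    if ("stats" %in% stages) {
      pk <- peak_rank_table(cpm, threshold = params$threshold)
      readr::write_tsv(pk, file.path(outdir, "peak_rank_table.tsv"))
      det <- purrr::map_dfr(c("VISp", "ALM"), function(a) {
        cells <- ann$cell_id[ann$area == a]
        tibble::tibble(area = a, gene = tab$gene,
                       detection_fraction = vapply(tab$gene, function(g)
                         detection_fraction(cpm, g, params$threshold,
                                            cells = cells), numeric(1)))
      })
      readr::write_tsv(det, file.path(outdir, "detection_fractions.tsv"))
      wide <- tidyr::pivot_wider(det, names_from = "area",
                                 values_from = "detection_fraction")
      cons <- area_conservation(wide$VISp, wide$ALM)
      readr::write_tsv(cons, file.path(outdir, "conservation.tsv"))
      co <- coexpression_counts(cpm, tab$gene[tab$role == "NPP"],
                                threshold = params$threshold)
      readr::write_tsv(co$histogram,
                       file.path(outdir, "npp_coexpression_histogram.tsv"))
      results$stats <- list(peak = pk, detection = det, conservation = cons,
                            coexpression = co$histogram)
    }
    if ("select" %in% stages) {
      pk <- peak_rank_table(cpm, threshold = params$threshold)
      sel <- select_np_genes(tab, pk,
                             min_peak_percentile = params$min_peak_percentile)
      readr::write_tsv(sel$report, file.path(outdir, "selection_report.tsv"))
      sel_pairs <- build_cognate_pairs(sel$npp, sel$npgpcr, tab,
                                       peak_table = pk)
      prof <- type_mean_expression(cpm, ann, genes = tab$gene,
                                   taxonomy = taxonomy)
      sel_pairs <- pair_type_fractions(sel_pairs, prof)
      readr::write_tsv(sel_pairs, file.path(outdir, "cognate_pairs.tsv"))
      results$select <- list(selection = sel, pairs = sel_pairs)
    }
    if ("classify" %in% stages) {
      he <- select_gene_sets(cpm, ann, type = "HE",
                             n = min(params$n_he, ncol(cpm$values)))
      X <- preprocess_expression(cpm, he)[ann$cell_id, , drop = FALSE]
      ref <- train_reference_autoencoder(
        X, autoencoder_spec(length(he), latent_dim = params$latent_dim,
                            epochs = params$reference_epochs,
                            seed = seed))
      np_set <- intersect(tab$gene, gene_ids(cpm))
      cmp <- compare_gene_sets(
        cpm, ann, taxonomy,
        sets = list(np = np_set,
                    rand = select_gene_sets(cpm, ann, type = "Rand47",
                                            n = length(np_set),
                                            seed = seed)),
        z1 = ref$embedding, linked_epochs = params$linked_epochs,
        lambda = params$lambda, k = params$folds, seed = seed)
      readr::write_tsv(cmp$runs, file.path(outdir, "ri_runs.tsv"))
      readr::write_tsv(tidy(cmp$ri_results$np),
                       file.path(outdir, "ri_per_cell_np.tsv"))
      results$classify <- cmp
    }
    if (any(c("couple", "aggregate") %in% stages)) {
      couplings <- list()
      for (a in c("VISp", "ALM")) {
        prof <- type_mean_expression(cpm, ann, area = a, genes = tab$gene,
                                     taxonomy = taxonomy)
        couplings[[a]] <- lapply(seq_len(nrow(pairs)), function(i)
          coupling_matrix(pairs[i, ], prof))
      }
      if ("couple" %in% stages) {
        for (a in names(couplings)) {
          export_adjacency(couplings[[a]], file.path(outdir, "coupling"))
        }
        results$couple <- couplings
      }
      if ("aggregate" %in% stages) {
        for (a in names(couplings)) {
          ch <- aggregate_by_galpha(couplings[[a]])
          for (f in names(ch$channels)) {
            fn <- sprintf("%s_channel_%s.csv", a, gsub("/", "", f))
            tab_out <- data.frame(type = rownames(ch$channels[[f]]),
                                  ch$channels[[f]], check.names = FALSE)
            utils::write.table(tab_out,
                               file.path(outdir, fn), sep = ",",
                               quote = FALSE, row.names = FALSE)
          }
          results$aggregate[[a]] <- ch
        }
      }
    }
    manifest$status <- "ok"
  }, error = function(e) {
    manifest$status <<- "failed"
    manifest$error <<- conditionMessage(e)
    stop(e)
  })
  invisible(list(results = results, manifest = manifest, outdir = outdir))
}
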