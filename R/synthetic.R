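#' Configuration for the synthetic cortical census generator
#'
#' The generator emulates the statistical structure of a two-area
#' single-cell RNA-seq census of cortical neurons: a class / subclass / type
#' hierarchy; background genes with low type-to-type variability;
#' neuropeptide-like (NP-like) genes expressed in a minority of types at
#' levels spanning several decades and exactly zero elsewhere; overdispersed
#' (gamma-Poisson) counts with log-normal library sizes; and two areas whose
#' type-level profiles agree up to a controllable log-scale perturbation.
#'
#' @param n_types Number of leaf cell types (default 100).
#' @param n_subclasses Number of subclasses, split 7:5 between the GABAergic
#'   and glutamatergic classes as in the cortical taxonomy (default 12).
#' @param n_cells_per_area Cells sampled per area (default 2500).
#' @param n_genes_background Background (non-NP) genes (default 400).
#' @param n_genes_np_like NP-like genes when no gene table is supplied
#'   (default 47).
#' @param dynamic_range_log10 Decades spanned by NP-like expression across
#'   expressor types (default 4).
#' @param expressor_fraction_range Range of the per-gene fraction of types
#'   expressing an NP-like gene, drawn uniformly (default `c(0.05, 0.6)`).
#' @param nb_dispersion Negative-binomial dispersion (1/size); 0 gives
#'   Poisson counts (default 0.5).
#' @param library_size_meanlog,library_size_sdlog Log-normal library-size
#'   parameters (defaults `log(2e4)`, 0.3).
#' @param area_perturbation_sd Log-scale sd of the independent area-specific
#'   deviation of type means (default 0.05).
#' @param class_proportions Sampling proportions of GABAergic and
#'   glutamatergic cells; the census is enriched to roughly half GABAergic
#'   (default `c(GABAergic = 0.47, glutamatergic = 0.53)`).
#' @param seed Integer seed; a fixed config yields byte-identical output.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_types = 100, n_subclasses = 12,
                         n_cells_per_area = 2500,
                         n_genes_background = 400, n_genes_np_like = 47,
                         dynamic_range_log10 = 4,
                         expressor_fraction_range = c(0.05, 0.6),
                         nb_dispersion = 0.5,
                         library_size_meanlog = log(2e4),
                         library_size_sdlog = 0.3,
                         area_perturbation_sd = 0.05,
                         class_proportions = c(GABAergic = 0.47,
                                               glutamatergic = 0.53),
                         seed = 1L) {
  stopifnot(n_subclasses <= n_types, n_types >= 1, n_subclasses >= 1,
            n_cells_per_area >= 1, n_genes_background >= 1,
            n_genes_np_like >= 0, dynamic_range_log10 > 0,
            length(expressor_fraction_range) == 2,
            all(expressor_fraction_range >= 0),
            all(expressor_fraction_range <= 1),
            nb_dispersion >= 0, area_perturbation_sd >= 0)
  structure(as.list(environment()), class = "synth_config")
}

#' Generate a balanced two-class taxonomy
#'
#' Builds the fixed-depth hierarchy root -> class -> subclass -> type with
#' unit heights (leaves 0, subclasses 1, classes 2, root 3). Types are dealt
#' to subclasses as evenly as possible (sizes differ by at most one) and
#' subclasses to the two classes in a 7:5 GABAergic:glutamatergic ratio.
#'
#' @param cfg A [synth_config()].
#' @return An `np_taxonomy`.
#' @export
generate_taxonomy <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  n_gaba <- max(1L, min(cfg$n_subclasses - 1L,
                        round(cfg$n_subclasses * 7 / 12)))
  if (cfg$n_subclasses == 1L) n_gaba <- 1L
  sub_class <- c(rep("GABAergic", n_gaba),
                 rep("glutamatergic", cfg$n_subclasses - n_gaba))
  # deal types round-robin so subclass sizes differ by <= 1
  type_sub <- rep(seq_len(cfg$n_subclasses), length.out = cfg$n_types)
  type_sub <- sort(type_sub)
  labels <- c("neurons")
  parent <- c(NA_integer_)
  classes <- unique(sub_class)
  class_id <- stats::setNames(seq_along(classes) + 1L, classes)
  labels <- c(labels, classes)
  parent <- c(parent, rep(1L, length(classes)))
  sub_ids <- integer(cfg$n_subclasses)
  for (i in seq_len(cfg$n_subclasses)) {
    labels <- c(labels, sprintf("subclass_%02d", i))
    parent <- c(parent, class_id[[sub_class[i]]])
    sub_ids[i] <- length(labels)
  }
  for (j in seq_len(cfg$n_types)) {
    labels <- c(labels, sprintf("type_%03d", j))
    parent <- c(parent, sub_ids[type_sub[j]])
  }
  np_taxonomy(parent, labels)
}

#' Generate a synthetic NP gene annotation table
#'
#' Each NPP-like gene is linked to 1-4 receptor-like genes; each receptor is
#' assigned a primary G-alpha family uniformly at random. Link multiplicities
#' can be supplied explicitly (e.g. copied from the shipped fixture), in
#' which case the pair count equals their sum.
#'
#' @param cfg A [synth_config()].
#' @param n_npp,n_npgpcr Gene counts; default split of `n_genes_np_like`
#'   mirrors the 18:29 precursor:receptor ratio.
#' @param multiplicities Optional integer vector (length `n_npp`, values
#'   1-4): receptors linked per NPP.
#' @return An `np_gene_table`.
#' @export
generate_np_gene_table <- function(cfg,
                                   n_npp = round(cfg$n_genes_np_like * 18 / 47),
                                   n_npgpcr = cfg$n_genes_np_like - n_npp,
                                   multiplicities = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  if (n_npp == 0) {
    return(np_gene_table(tibble::tibble(gene = character(),
                                        role = character(),
                                        galpha_family = character(),
                                        cognate_partners = list())))
  }
  stopifnot(n_npgpcr >= 1)
  withr::with_seed(cfg$seed + 101L, {
    npp <- sprintf("NPP%02d", seq_len(n_npp))
    rec <- sprintf("NPR%02d", seq_len(n_npgpcr))
    fam <- sample(c("Gi/o", "Gs", "Gq/11"), n_npgpcr, replace = TRUE)
    if (is.null(multiplicities)) {
      multiplicities <- sample(seq_len(min(4L, n_npgpcr)), n_npp,
                               replace = TRUE)
    }
    stopifnot(length(multiplicities) == n_npp,
              all(multiplicities >= 1), all(multiplicities <= 4),
              all(multiplicities <= n_npgpcr))
    # deal receptors so every receptor gets at least one link where possible
    pool <- sample(rec)
    links <- vector("list", n_npp)
    k <- 0L
    for (i in seq_len(n_npp)) {
      m <- multiplicities[i]
      take <- character(0)
      while (length(take) < m) {
        if (k >= length(pool)) {
          k <- 0L
          pool <- sample(rec)
        }
        k <- k + 1L
        if (!pool[k] %in% take) take <- c(take, pool[k])
      }
      links[[i]] <- sort(take)
    }
    tab <- tibble::tibble(
      gene = c(npp, rec),
      role = c(rep("NPP", n_npp), rep("NP-GPCR", n_npgpcr)),
      galpha_family = c(rep(NA_character_, n_npp), fam),
      cognate_partners = c(links, rep(list(character(0)), n_npgpcr))
    )
    np_gene_table(tab)
  })
}

#' Generate a synthetic two-area expression dataset
#'
#' Draws per-type per-gene mean profiles (background genes: log-normal with
#' low type-to-type variability; NP-like genes: exactly zero outside a random
#' subset of expressor types and log-uniform over
#' `dynamic_range_log10` decades inside it), perturbs them independently per
#' area on the log scale, normalizes each type profile to CPM, and samples
#' negative-binomial counts with log-normal library sizes. Every type is
#' guaranteed at least one NP-like expressor gene (when any NP-like genes
#' exist).
#'
#' @param taxonomy An `np_taxonomy` (see [generate_taxonomy()]).
#' @param gene_table An `np_gene_table` of NP-like genes, or `NULL` to use
#'   anonymous NP-like genes.
#' @param cfg A [synth_config()].
#' @param expressor_fractions Optional named per-gene expressor-type
#'   fractions overriding the uniform draw.
#' @return List of class `np_synth_dataset` with elements `counts` and `cpm`
#'   (`np_expression`), `annotation` (tibble), `ground_truth` (per-area
#'   genes x types CPM mean matrices), `taxonomy`, `gene_table`, `config`.
#' @export
generate_dataset <- function(taxonomy, gene_table, cfg,
                             expressor_fractions = NULL) {
  stopifnot(inherits(cfg, "synth_config"), inherits(taxonomy, "np_taxonomy"))
  types <- taxonomy_leaves(taxonomy)
  n_types <- length(types)
  np_genes <- if (!is.null(gene_table) && nrow(gene_table)) gene_table$gene
              else if (cfg$n_genes_np_like > 0)
                sprintf("NP%02d", seq_len(cfg$n_genes_np_like))
              else character(0)
  bg_genes <- sprintf("BG%03d", seq_len(cfg$n_genes_background))
  genes <- c(bg_genes, np_genes)
  areas <- c("VISp", "ALM")

  withr::with_seed(cfg$seed, {
    # --- type-level relative means -------------------------------------
    mu <- matrix(0, length(genes), n_types, dimnames = list(genes, types))
    base <- 10^stats::rnorm(length(bg_genes), mean = 1.5, sd = 0.6)
    mu[bg_genes, ] <- base *
      exp(matrix(stats::rnorm(length(bg_genes) * n_types, 0, 0.2),
                 length(bg_genes), n_types))
    if (length(np_genes)) {
      fr <- stats::runif(length(np_genes), cfg$expressor_fraction_range[1],
                         cfg$expressor_fraction_range[2])
      names(fr) <- np_genes
      if (!is.null(expressor_fractions)) {
        fr[names(expressor_fractions)] <- expressor_fractions
      }
      perms <- lapply(np_genes, function(g) sample.int(n_types))
      names(perms) <- np_genes
      for (g in np_genes) {
        k <- ceiling(fr[[g]] * n_types)
        if (k > 0) {
          idx <- perms[[g]][seq_len(k)]
          mu[g, idx] <- 10^stats::runif(k, 0, cfg$dynamic_range_log10)
        }
      }
      # guarantee every type at least one NP-like expressor
      orphan <- which(colSums(mu[np_genes, , drop = FALSE] > 0) == 0)
      for (t in orphan) {
        g <- sample(np_genes, 1)
        mu[g, t] <- 10^stats::runif(1, cfg$dynamic_range_log10 / 2,
                                    cfg$dynamic_range_log10)
      }
    }
    # --- area-specific CPM profiles ------------------------------------
    ground <- lapply(areas, function(a) {
      dev <- exp(matrix(stats::rnorm(length(mu), 0, cfg$area_perturbation_sd),
                        nrow(mu), ncol(mu)))
      m <- mu * dev
      sweep(m, 2, colSums(m), "/") * 1e6
    })
    names(ground) <- areas

    # --- cells -----------------------------------------------------------
    cls <- taxonomy$leaf_class[types]
    type_by_class <- split(types, cls)
    pc <- cfg$class_proportions / sum(cfg$class_proportions)
    ann <- purrr::map_dfr(areas, function(a) {
      cell_class <- sample(names(pc), cfg$n_cells_per_area, replace = TRUE,
                           prob = pc)
      # classes missing from the taxonomy fall back to a uniform type draw
      leaf <- vapply(cell_class, function(k) {
        pool <- type_by_class[[k]] %||% types
        pool[sample.int(length(pool), 1)]
      }, character(1), USE.NAMES = FALSE)
      tibble::tibble(area = a, leaf_type = leaf)
    })
    ann$cell_id <- sprintf("%s_c%05d", ann$area, seq_len(nrow(ann)))
    ann$subclass <- unname(taxonomy$leaf_subclass[ann$leaf_type])
    ann$class <- unname(taxonomy$leaf_class[ann$leaf_type])
    ann <- ann[, c("cell_id", "area", "leaf_type", "subclass", "class")]

    # --- counts ----------------------------------------------------------
    lib <- stats::rlnorm(nrow(ann), cfg$library_size_meanlog,
                         cfg$library_size_sdlog)
    mean_mat <- matrix(0, length(genes), nrow(ann))
    for (a in areas) {
      idx <- which(ann$area == a)
      mean_mat[, idx] <- ground[[a]][, ann$leaf_type[idx], drop = FALSE]
    }
    mean_mat <- sweep(mean_mat, 2, lib / 1e6, "*")
    counts <- if (cfg$nb_dispersion > 0) {
      stats::rnbinom(length(mean_mat), mu = mean_mat,
                     size = 1 / cfg$nb_dispersion)
    } else {
      stats::rpois(length(mean_mat), mean_mat)
    }
    counts <- matrix(counts, length(genes), nrow(ann),
                     dimnames = list(genes, ann$cell_id))
    empty <- colSums(counts) == 0
    if (any(empty)) {
      warning(sum(empty), " cells with zero total counts dropped")
      counts <- counts[, !empty, drop = FALSE]
      ann <- ann[!empty, , drop = FALSE]
    }
    counts_m <- np_expression(t(counts), units = "counts")
    structure(
      list(counts = counts_m, cpm = counts_to_cpm(counts_m),
           annotation = ann, ground_truth = ground, taxonomy = taxonomy,
           gene_table = gene_table, config = cfg,
           np_genes = np_genes, background_genes = bg_genes),
      class = "np_synth_dataset"
    )
  })
}

#' @export
print.np_synth_dataset <- function(x, ...) {
  cat(sprintf(
    "<np_synth_dataset> %d cells x %d genes, %d types, 2 areas\n",
    nrow(x$cpm$values), ncol(x$cpm$values), sum(x$taxonomy$is_leaf)))
  invisible(x)
}

#' Materialize demo fixtures on disk
#'
#' Writes the shipped NP gene annotations plus a small synthetic demo dataset
#' (expression TSVs, annotation TSV, taxonomy JSON) into a directory, in the
#' package's standard file formats.
#'
#' @param dir Output directory (created if needed).
#' @param cfg A [synth_config()]; defaults to a small demo configuration.
#' @return `dir`, invisibly.
#' @export
write_demo_fixtures <- function(dir,
                                cfg = synth_config(n_types = 12,
                                                   n_subclasses = 4,
                                                   n_cells_per_area = 150,
                                                   n_genes_background = 60,
                                                   seed = 42L)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- np_gene_fixture()
  write_np_gene_table(tab, file.path(dir, "np_gene_table.tsv"))
  taxonomy <- generate_taxonomy(cfg)
  ds <- generate_dataset(taxonomy, tab, cfg)
  write_expression(ds$counts, file.path(dir, "counts.tsv"))
  write_expression(ds$cpm, file.path(dir, "cpm.tsv"))
  readr::write_tsv(ds$annotation, file.path(dir, "annotation.tsv"))
  write_taxonomy(taxonomy, file.path(dir, "taxonomy.json"))
  invisible(dir)
}
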