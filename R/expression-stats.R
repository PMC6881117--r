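#' Peak expression of a gene across a cell population
#'
#' The peak-expression metric summarizes the expression of a gene in the
#' highly expressing subset of a population with very differential
#' expression: single-cell values are ranked and the value at the ascending
#' 99.9th percentile point is reported (nearest-rank convention: the sorted
#' element at 1-based index `ceiling(q * n)`, clamped to `n`). Applied to
#' FPKM input this is the pFPKM metric; applied to CPM it is peak CPM.
#'
#' @param m An `np_expression`.
#' @param gene Gene symbol (exact match).
#' @param quantile Ascending percentile point (default 0.999).
#' @param cells Optional subset of cell ids.
#' @return A single nonnegative number.
#' @examples
#' m <- np_expression(matrix(1:10000, ncol = 1, dimnames = list(NULL, "g")),
#'                    units = "FPKM")
#' peak_expression(m, "g")  # 9990
#' @export
peak_expression <- function(m, gene, quantile = 0.999, cells = NULL) {
  x <- expression_values(m, gene)[, 1]
  if (!is.null(cells)) x <- x[cells]
  if (!length(x)) stop("no cells selected", call. = FALSE)
  nearest_rank_ascending(x, quantile)
}

nearest_rank_ascending <- function(x, q) {
  n <- length(x)
  idx <- min(n, max(1L, ceiling(q * n)))
  unname(sort(x, method = "quick")[idx])
}

#' Peak-expression ranking table over a gene universe
#'
#' Ranks peak-expression values across a reference universe of genes
#' (absolute rank 1 = highest peak; percentile rank 100 = top). Ties in peak
#' value are broken by lexicographic gene symbol so ranks are deterministic.
#' Also reports each gene's detection fraction, the fraction of cells with
#' expression strictly above `threshold`.
#'
#' @param m An `np_expression`.
#' @param gene_universe Character vector of genes (must all be in `m`).
#' @param threshold Detection threshold (default 1; strict inequality).
#' @param quantile Peak percentile point (default 0.999).
#' @return Tibble of class `peak_expression_table`: `gene`, `peak_value`,
#'   `percentile_rank`, `absolute_rank`, `detection_fraction`.
#' @export
peak_rank_table <- function(m, gene_universe = gene_ids(m), threshold = 1,
                            quantile = 0.999) {
  if (!length(gene_universe)) stop("empty gene universe", call. = FALSE)
  vals <- expression_values(m, gene_universe)
  peaks <- apply(vals, 2, nearest_rank_ascending, q = quantile)
  n <- length(gene_universe)
  ord <- order(-peaks, gene_universe, method = "radix")
  rank <- integer(n)
  rank[ord] <- seq_len(n)
  out <- tibble::tibble(
    gene = gene_universe,
    peak_value = unname(peaks),
    percentile_rank = 100 * (n - rank + 1) / n,
    absolute_rank = rank,
    detection_fraction = colMeans(vals > threshold)
  )
  structure(out, class = c("peak_expression_table", class(out)))
}

#' Descending single-cell expression curves
#'
#' For each gene (or for the per-cell maximum over a gene set) sorts
#' single-cell values in descending order along a population percentile axis
#' `100 * (rank - 0.5) / n`. These curves expose the transition from high to
#' very low (commonly zero) expression that characterizes highly
#' differential genes; the `max_over_set` curve shows what fraction of cells
#' express at least one gene of the set at any given level.
#'
#' @param m An `np_expression`.
#' @param genes Genes to plot.
#' @param mode `"per_gene"` (one curve per gene) or `"max_over_set"` (single
#'   curve of per-cell maxima).
#' @param cells Optional subset of cell ids.
#' @return Tidy tibble: `curve`, `percentile`, `value`.
#' @export
expression_curves <- function(m, genes, mode = c("per_gene", "max_over_set"),
                              cells = NULL) {
  mode <- match.arg(mode)
  if (!length(genes)) stop("empty gene set", call. = FALSE)
  vals <- expression_values(m, genes)
  if (!is.null(cells)) vals <- vals[cells, , drop = FALSE]
  n <- nrow(vals)
  pct <- 100 * (seq_len(n) - 0.5) / n
  if (mode == "per_gene") {
    purrr::map_dfr(genes, function(g) {
      tibble::tibble(curve = g, percentile = pct,
                     value = unname(sort(vals[, g], decreasing = TRUE)))
    })
  } else {
    mx <- apply(vals, 1, max)
    tibble::tibble(curve = "max_over_set", percentile = pct,
                   value = unname(sort(mx, decreasing = TRUE)))
  }
}

#' Fraction of cells expressing a gene
#'
#' Detection uses a strict inequality: a cell expresses the gene when its
#' value exceeds `threshold` (default 1 CPM).
#'
#' @param m An `np_expression`.
#' @param gene Gene symbol.
#' @param threshold Detection threshold.
#' @param cells Optional subset of cell ids (e.g. one area or one type).
#' @return Fraction in \[0, 1\].
#' @export
detection_fraction <- function(m, gene, threshold = 1, cells = NULL) {
  x <- expression_values(m, gene)[, 1]
  if (!is.null(cells)) x <- x[cells]
  if (!length(x)) stop("empty cell group", call. = FALSE)
  mean(x > threshold)
}

#' Per-cell co-expression counts over a gene set
#'
#' Counts, for every cell, how many genes of the set are detected (value
#' strictly above `threshold`), and tabulates the histogram over multiples
#' 0..`length(genes)`.
#'
#' @inheritParams detection_fraction
#' @param genes Gene set.
#' @return List with `counts` (named integer vector per cell) and
#'   `histogram` (tibble `n_genes`, `n_cells`; sums to the group size).
#' @export
coexpression_counts <- function(m, genes, threshold = 1, cells = NULL) {
  if (!length(genes)) stop("empty gene set", call. = FALSE)
  vals <- expression_values(m, genes)
  if (!is.null(cells)) vals <- vals[cells, , drop = FALSE]
  if (!nrow(vals)) stop("empty cell group", call. = FALSE)
  counts <- rowSums(vals > threshold)
  hist <- tibble::tibble(
    n_genes = 0:length(genes),
    n_cells = vapply(0:length(genes), function(k) sum(counts == k),
                     numeric(1))
  )
  list(counts = counts, histogram = hist)
}

#' Cognate-pair co-expression fractions
#'
#' For each (NPP, NP-GPCR) pair, the fraction of cells expressing both
#' members above `threshold` — autocrine-candidate cells when the pair is
#' cognate. The fraction is bounded above by each member's detection
#' fraction.
#'
#' @param m An `np_expression`.
#' @param pairs Data frame with columns `npp_gene`, `npgpcr_gene` (e.g. from
#'   [build_cognate_pairs()] or [cognate_links()]).
#' @param threshold Detection threshold.
#' @param cells Optional subset of cell ids.
#' @return Tibble: `npp_gene`, `npgpcr_gene`, `fraction_both`,
#'   `fraction_npp`, `fraction_npgpcr`.
#' @export
cognate_pair_coexpression <- function(m, pairs, threshold = 1, cells = NULL) {
  genes <- unique(c(pairs$npp_gene, pairs$npgpcr_gene))
  vals <- expression_values(m, genes)
  if (!is.null(cells)) vals <- vals[cells, , drop = FALSE]
  det <- vals > threshold
  purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    g <- pairs$npp_gene[i]
    h <- pairs$npgpcr_gene[i]
    tibble::tibble(npp_gene = g, npgpcr_gene = h,
                   fraction_both = mean(det[, g] & det[, h]),
                   fraction_npp = mean(det[, g]),
                   fraction_npgpcr = mean(det[, h]))
  })
}

#' Cross-area conservation correlation
#'
#' Correlates a per-gene statistic (detection fractions, type-profile rows,
#' ...) measured in one area against the same statistic in another area.
#'
#' @param x,y Equal-length numeric vectors (n >= 3).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Tibble: `estimate` (rho), `p_value`, `n`, `method`.
#' @export
area_conservation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 paired values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for zero-variance input", call. = FALSE)
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  tibble::tibble(estimate = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x), method = method)
}

#' Neuron-type expression profiles (trimmed mean or median)
#'
#' Aggregates single-cell expression into a genes x types matrix per area
#' using the 5%-trimmed mean (default): within each type, the top and bottom
#' 5% of cells (fraction rounded down per tail) are removed before
#' averaging. Types left with no cells after trimming fall back to the plain
#' mean; types with zero cells are omitted with a warning.
#'
#' @param m An `np_expression` (CPM recommended).
#' @param ann Annotation tibble (`cell_id`, `area`, `leaf_type`, ...).
#' @param statistic `"trimmed_mean_5pct"` or `"median"`.
#' @param area Optional area filter (`"VISp"` or `"ALM"`); `NULL` pools
#'   areas.
#' @param genes Optional gene subset.
#' @param taxonomy Optional `np_taxonomy`; when given, type columns follow
#'   taxonomy leaf order.
#' @return Object of class `type_expression` wrapping a genes x types
#'   matrix, with attributes `statistic`, `area`, `units`.
#' @export
type_mean_expression <- function(m, ann,
                                 statistic = c("trimmed_mean_5pct", "median"),
                                 area = NULL, genes = NULL, taxonomy = NULL) {
  statistic <- match.arg(statistic)
  if (!is.null(area)) ann <- ann[ann$area == area, , drop = FALSE]
  vals <- expression_values(m, genes)
  vals <- vals[ann$cell_id, , drop = FALSE]
  types <- unique(ann$leaf_type)
  if (!is.null(taxonomy)) {
    ordered <- taxonomy_leaves(taxonomy)
    absent <- setdiff(ordered, types)
    if (length(absent)) {
      warning("types with no cells omitted: ",
              paste(utils::head(absent, 5), collapse = ", "))
    }
    types <- intersect(ordered, types)
  }
  agg <- function(x) {
    if (statistic == "median") return(stats::median(x))
    k <- floor(0.05 * length(x))
    if (length(x) - 2 * k < 1) return(mean(x))
    mean(x, trim = 0.05)
  }
  prof <- vapply(types, function(t) {
    idx <- which(ann$leaf_type == t)
    apply(vals[idx, , drop = FALSE], 2, agg)
  }, numeric(ncol(vals)))
  prof <- matrix(prof, nrow = ncol(vals), ncol = length(types),
                 dimnames = list(colnames(vals), types))
  structure(list(values = prof, statistic = statistic,
                 area = area %||% "both", units = m$units),
            class = "type_expression")
}

#' @export
print.type_expression <- function(x, ...) {
  cat(sprintf("<type_expression> %d genes x %d types [%s, %s, %s]\n",
              nrow(x$values), ncol(x$values), x$units, x$statistic, x$area))
  invisible(x)
}

#' Type-expression profile as a tidy table
#' @param x A `type_expression`.
#' @param ... Unused.
#' @return Tibble: `gene`, `leaf_type`, `value`, `area`, `statistic`.
#' @export
tidy.type_expression <- function(x, ...) {
  tibble::as_tibble(as.data.frame.table(x$values,
                                        responseName = "value",
                                        stringsAsFactors = FALSE)) |>
    stats::setNames(c("gene", "leaf_type", "value")) |>
    dplyr::mutate(area = x$area, statistic = x$statistic)
}

#' Within-subclass versus global coefficient of variation
#'
#' Quantifies how much of a gene's type-to-type expression variability
#' survives inside subclasses. For each gene, the coefficient of variation
#' (sample sd / mean) is computed over the type-level values of each
#' subclass and globally over all types; `ratio_mean` averages
#' within-subclass CV / global CV over subclasses. Subclasses containing a
#' single type are excluded (their CV is undefined), and strata where the
#' mean is zero are reported as missing.
#'
#' @param t A `type_expression`.
#' @param taxonomy An `np_taxonomy` providing the leaf -> subclass map.
#' @return List with `by_subclass` (tibble `gene`, `subclass`, `cv`,
#'   `n_types`) and `summary` (tibble `gene`, `global_cv`, `ratio_mean`).
#' @export
cv_within_subclass <- function(t, taxonomy) {
  stopifnot(inherits(t, "type_expression"))
  sub <- taxonomy$leaf_subclass[colnames(t$values)]
  keep <- names(table(sub))[table(sub) >= 2]
  cv <- function(x) {
    if (length(x) < 2 || mean(x) == 0) return(NA_real_)
    stats::sd(x) / mean(x)
  }
  by_sub <- purrr::map_dfr(rownames(t$values), function(g) {
    purrr::map_dfr(keep, function(s) {
      x <- t$values[g, sub == s]
      tibble::tibble(gene = g, subclass = s, cv = cv(x), n_types = length(x))
    })
  })
  summary <- purrr::map_dfr(rownames(t$values), function(g) {
    gcv <- cv(t$values[g, ])
    sc <- by_sub$cv[by_sub$gene == g]
    tibble::tibble(gene = g, global_cv = gcv,
                   ratio_mean = if (is.na(gcv) || gcv == 0) NA_real_ else
                     mean(sc / gcv, na.rm = TRUE))
  })
  list(by_subclass = by_sub, summary = summary)
}
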