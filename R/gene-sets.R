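#' Reference gene sets for the classification benchmark
#'
#' Builds the comparison gene sets used alongside the neuropeptide genes:
#'
#' * `HE(n)` — the n genes with the largest single-cell maximum across all
#'   cells (highly expressed).
#' * `DE(n)` — the n genes most differential across leaf types, scored by
#'   the Kruskal-Wallis statistic of `log10(CPM + 1)` across type labels
#'   (a pragmatic one-vs-rest stand-in for an externally defined
#'   differential-expression list).
#' * `DE47` — the `n` most variable genes (variance of type-level mean
#'   `log10(CPM + 1)`) within a DE pool of size `n_de_pool`.
#' * `Rand47(seed)` — n genes drawn uniformly from the HE pool.
#' * `Rand47_ExpMatched(seed, reference)` — n genes drawn so the
#'   distribution of `log10(max + 1)` matches the reference set's, by
#'   sampling within decile bins of the pool's maxima.
#'
#' @param m An `np_expression` (CPM).
#' @param ann Annotation tibble with `cell_id`, `leaf_type` (needed for DE
#'   scores).
#' @param type One of `"HE"`, `"DE"`, `"DE47"`, `"Rand47"`,
#'   `"Rand47_ExpMatched"`.
#' @param n Set size (default 47).
#' @param pool Candidate pool for the random draws (default: all genes).
#' @param n_de_pool DE pool size feeding `DE47` (default `max(4 * n, 100)`).
#' @param reference Reference gene set for expression matching.
#' @param seed Seed for the random draws.
#' @return Character vector of gene symbols.
#' @export
select_gene_sets <- function(m, ann = NULL,
                             type = c("HE", "DE", "DE47", "Rand47",
                                      "Rand47_ExpMatched"),
                             n = 47, pool = gene_ids(m),
                             n_de_pool = max(4 * n, 100), reference = NULL,
                             seed = 1L) {
  type <- match.arg(type)
  vals <- expression_values(m, pool)
  if (n > length(pool)) stop("gene pool smaller than requested set size",
                             call. = FALSE)
  gene_max <- apply(vals, 2, max)
  if (type == "HE") {
    return(pool[order(-gene_max, pool, method = "radix")][seq_len(n)])
  }
  if (type == "Rand47") {
    return(withr::with_seed(seed, sample(pool, n)))
  }
  if (type == "Rand47_ExpMatched") {
    if (is.null(reference)) stop("reference set required", call. = FALSE)
    lmax <- log10(gene_max + 1)
    breaks <- unique(stats::quantile(lmax, probs = seq(0, 1, 0.1)))
    bin <- cut(lmax, breaks = breaks, include.lowest = TRUE, labels = FALSE)
    names(bin) <- pool
    ref_max <- log10(apply(expression_values(m, reference), 2, max) + 1)
    ref_bin <- cut(ref_max, breaks = breaks, include.lowest = TRUE,
                   labels = FALSE)
    ref_bin[is.na(ref_bin)] <- max(bin, na.rm = TRUE)
    return(withr::with_seed(seed, {
      vapply(ref_bin, function(b) {
        cand <- pool[!is.na(bin) & bin == b]
        if (!length(cand)) cand <- pool
        cand[sample.int(length(cand), 1)]
      }, character(1), USE.NAMES = FALSE)
    }))
  }
  # DE scoring
  if (is.null(ann)) stop("annotation required for DE gene sets", call. = FALSE)
  lx <- log10(vals[ann$cell_id, , drop = FALSE] + 1)
  grp <- factor(ann$leaf_type)
  kw <- apply(lx, 2, function(col) {
    if (stats::sd(col) == 0) return(0)
    unname(stats::kruskal.test(col, grp)$statistic)
  })
  de_order <- pool[order(-kw, pool, method = "radix")]
  if (type == "DE") return(de_order[seq_len(n)])
  # DE47: most variable type-level means within the DE pool
  de_pool <- de_order[seq_len(min(n_de_pool, length(de_order)))]
  tm <- vapply(split(seq_len(nrow(lx)), grp), function(idx) {
    colMeans(lx[idx, de_pool, drop = FALSE])
  }, numeric(length(de_pool)))
  tv <- apply(matrix(tm, nrow = length(de_pool),
                     dimnames = list(de_pool, NULL)), 1, stats::var)
  de_pool[order(-tv, de_pool, method = "radix")][seq_len(n)]
}
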