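#' Screen candidate genes by per-type median expression
#'
#' A candidate passes when its median CPM exceeds `min_median_cpm` in at
#' least one neuron type — the first screening step that reduces the broad
#' neuropeptide-precursor candidate list to the cortically expressed subset.
#'
#' @param candidates Character vector of gene symbols (all present in `m`).
#' @param m An `np_expression` in CPM.
#' @param ann Annotation tibble with `cell_id`, `leaf_type`.
#' @param min_median_cpm Threshold (default 10, strict `>`).
#' @return Tibble: `gene`, `max_type_median`, `retained`.
#' @export
screen_candidates_by_type_median <- function(candidates, m, ann,
                                             min_median_cpm = 10) {
  med <- type_mean_expression(m, ann, statistic = "median",
                              genes = candidates)
  mx <- apply(med$values, 1, max)
  tibble::tibble(gene = candidates,
                 max_type_median = unname(mx[candidates]),
                 retained = unname(mx[candidates]) > min_median_cpm)
}

#' Select NPP and NP-GPCR gene sets by peak expression and cognate pairing
#'
#' Implements the two selection criteria for the focused NP gene sets:
#' an NPP gene is retained when (1) its peak-expression percentile over the
#' reference gene universe is at least `min_peak_percentile` (top quintile by
#' default) and (2) at least one cognate receptor passes the local
#' receptor-expression criterion. An NP-GPCR gene is retained when it passes
#' the receptor criterion and is cognate to at least one retained NPP, so
#' the two lists are mutually closed under the cognate relation.
#'
#' The receptor criterion is deliberately permissive (receptor transcripts
#' never reach precursor-like peak levels, spanning roughly the 40th-95th
#' peak percentile in cortex): detection in at least
#' `min_receptor_detection` of cells at the detection threshold, or peak
#' percentile at least `min_receptor_percentile`. The default detection
#' floor of 0.5% is the envelope of the published receptor set (its least
#' detected member is expressed in 0.5% of cells).
#'
#' @param candidates An `np_gene_table` of candidate genes.
#' @param peak_table A `peak_expression_table` covering the candidates.
#' @param min_peak_percentile NPP percentile criterion (default 80).
#' @param min_receptor_detection Receptor detection-fraction criterion
#'   (default 0.005).
#' @param min_receptor_percentile Receptor percentile alternative
#'   (default 50).
#' @return List with `npp`, `npgpcr` (character vectors) and `report`
#'   (tibble of per-gene criterion flags).
#' @export
select_np_genes <- function(candidates, peak_table, min_peak_percentile = 80,
                            min_receptor_detection = 0.005,
                            min_receptor_percentile = 50) {
  missing <- setdiff(candidates$gene, peak_table$gene)
  if (length(missing)) {
    stop("peak table does not cover: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  pt <- peak_table[match(candidates$gene, peak_table$gene), ]
  pct <- stats::setNames(pt$percentile_rank, candidates$gene)
  det <- stats::setNames(pt$detection_fraction, candidates$gene)
  role <- stats::setNames(candidates$role, candidates$gene)
  partners <- stats::setNames(candidates$cognate_partners, candidates$gene)

  no_partner <- candidates$gene[lengths(partners) == 0]
  if (length(no_partner)) {
    warning("candidates without cognate annotation excluded: ",
            paste(no_partner, collapse = ", "))
  }

  receptors <- candidates$gene[role == "NP-GPCR"]
  rec_pass <- receptors[det[receptors] >= min_receptor_detection |
                          pct[receptors] >= min_receptor_percentile]
  npps <- candidates$gene[role == "NPP"]
  npp_sel <- npps[pct[npps] >= min_peak_percentile &
                    vapply(partners[npps],
                           function(p) any(p %in% rec_pass), logical(1))]
  rec_sel <- receptors[receptors %in% rec_pass &
                         vapply(partners[receptors],
                                function(p) any(p %in% npp_sel), logical(1))]
  report <- tibble::tibble(
    gene = candidates$gene,
    role = unname(role[candidates$gene]),
    percentile_rank = unname(pct[candidates$gene]),
    detection_fraction = unname(det[candidates$gene]),
    passes_peak = unname(pct[candidates$gene]) >= min_peak_percentile,
    passes_receptor_criterion = candidates$gene %in% rec_pass,
    has_cognate_annotation = lengths(partners[candidates$gene]) > 0,
    selected = candidates$gene %in% c(npp_sel, rec_sel)
  )
  list(npp = npp_sel, npgpcr = rec_sel, report = report)
}

#' Enumerate cognate pairs among selected genes
#'
#' One pair per (NPP, receptor) cognate link with both members selected —
#' the edges of the bipartite cognate graph restricted to the selection.
#' Order is deterministic: NPPs by peak rank when a peak table is supplied
#' (else by symbol), receptors by symbol within an NPP.
#'
#' @param npp,npgpcr Character vectors of selected genes.
#' @param table An `np_gene_table` carrying the cognate relation and
#'   G-alpha families.
#' @param peak_table Optional `peak_expression_table` used to order NPPs.
#' @return Tibble of class `cognate_pairs`: `npp_gene`, `npgpcr_gene`,
#'   `galpha_family`.
#' @export
build_cognate_pairs <- function(npp, npgpcr, table, peak_table = NULL) {
  links <- cognate_links(table)
  pairs <- links[links$npp_gene %in% npp & links$npgpcr_gene %in% npgpcr, ]
  if (!is.null(peak_table)) {
    rk <- stats::setNames(peak_table$absolute_rank, peak_table$gene)
    pairs <- pairs[order(rk[pairs$npp_gene], pairs$npgpcr_gene), ]
  } else {
    pairs <- pairs[order(pairs$npp_gene, pairs$npgpcr_gene), ]
  }
  pairs <- tibble::as_tibble(pairs)
  structure(pairs, class = c("cognate_pairs", class(pairs)))
}

#' Fraction of type pairs over which a cognate pair is available
#'
#' Over all ordered (source, target) type pairs, the fraction where the NPP
#' gene meets `theta_npp` in the source type and the receptor meets
#' `theta_gpcr` in the target type; because the two conditions are
#' independent this equals the product of the two expressing-type fractions.
#'
#' @param pair One-row data frame (or list) with `npp_gene`, `npgpcr_gene`.
#' @param t A `type_expression` profile.
#' @param theta_npp,theta_gpcr Type-level expression thresholds in CPM
#'   (default 1; inclusive `>=`).
#' @return Fraction in \[0, 1\].
#' @export
fraction_of_type_pairs <- function(pair, t, theta_npp = 1, theta_gpcr = 1) {
  stopifnot(inherits(t, "type_expression"))
  g <- pair$npp_gene
  h <- pair$npgpcr_gene
  missing <- setdiff(c(g, h), rownames(t$values))
  if (length(missing)) {
    stop("genes absent from type profile: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  mean(t$values[g, ] >= theta_npp) * mean(t$values[h, ] >= theta_gpcr)
}

#' Annotate cognate pairs with their fraction of type pairs
#'
#' @param pairs A `cognate_pairs` tibble.
#' @param t A `type_expression` profile containing all pair members.
#' @inheritParams fraction_of_type_pairs
#' @return `pairs` with an added `fraction_of_type_pairs` column.
#' @export
pair_type_fractions <- function(pairs, t, theta_npp = 1, theta_gpcr = 1) {
  pairs$fraction_of_type_pairs <- vapply(seq_len(nrow(pairs)), function(i) {
    fraction_of_type_pairs(pairs[i, ], t, theta_npp, theta_gpcr)
  }, numeric(1))
  pairs
}
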