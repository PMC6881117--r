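#' Peptidergic coupling matrix for a cognate pair
#'
#' The coupling matrix of a cognate (NPP, NP-GPCR) pair over an area's
#' neuron types is the outer product of the NPP gene's type-expression
#' vector (sources, rows) and the receptor gene's type-expression vector
#' (targets, columns), in CPM x CPM units — a rank-1 weighted adjacency
#' matrix of the predicted directed modulatory network. A log10 display
#' copy is kept with values floored at `eps_log` (the outer product is
#' commonly exactly zero, where the logarithm is undefined).
#'
#' @param pair One-row data frame (or list) with `npp_gene`, `npgpcr_gene`
#'   and optionally `galpha_family`.
#' @param t A `type_expression` profile containing both genes.
#' @param eps_log Floor applied before log10 (default 1e-2 CPM·CPM).
#' @return Object of class `np_coupling`: `values` (linear), `log_values`,
#'   `pair`, `area`, `level`.
#' @export
coupling_matrix <- function(pair, t, eps_log = 1e-2) {
  stopifnot(inherits(t, "type_expression"))
  g <- pair$npp_gene
  h <- pair$npgpcr_gene
  missing <- setdiff(c(g, h), rownames(t$values))
  if (length(missing)) {
    stop("genes absent from type profile: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  u <- t$values[g, ]
  v <- t$values[h, ]
  lin <- outer(u, v)
  dimnames(lin) <- list(colnames(t$values), colnames(t$values))
  structure(
    list(values = lin, log_values = log10(pmax(lin, eps_log)),
         pair = tibble::tibble(npp_gene = g, npgpcr_gene = h,
                               galpha_family = pair$galpha_family %||%
                                 NA_character_),
         area = t$area, level = "type", eps_log = eps_log),
    class = "np_coupling"
  )
}

#' @export
print.np_coupling <- function(x, ...) {
  cat(sprintf("<np_coupling> %s -> %s (%s), %d x %d %ss, area %s\n",
              x$pair$npp_gene, x$pair$npgpcr_gene,
              x$pair$galpha_family %||% "?", nrow(x$values), ncol(x$values),
              x$level, x$area))
  invisible(x)
}

#' Pool a type profile or coupling matrix to the subclass level
#'
#' Subclass pooling takes unweighted means over the neuron types of each
#' subclass: for a profile, the mean of its type columns; for a coupling
#' matrix, the mean over each subclass x subclass block. Because coupling
#' matrices are rank-1 outer products, the two routes commute exactly
#' (block mean of an outer product = outer product of factor means).
#'
#' @param x A `type_expression` or `np_coupling`.
#' @param taxonomy An `np_taxonomy` providing the leaf -> subclass map.
#' @return Object of the same class at subclass resolution; subclasses with
#'   no types present are omitted.
#' @export
pool_by_subclass <- function(x, taxonomy) {
  UseMethod("pool_by_subclass")
}

#' @export
pool_by_subclass.type_expression <- function(x, taxonomy) {
  sub <- taxonomy$leaf_subclass[colnames(x$values)]
  subs <- unique(unname(sub))
  pooled <- vapply(subs, function(s) {
    rowMeans(x$values[, sub == s, drop = FALSE])
  }, numeric(nrow(x$values)))
  pooled <- matrix(pooled, nrow = nrow(x$values),
                   dimnames = list(rownames(x$values), subs))
  structure(list(values = pooled, statistic = x$statistic, area = x$area,
                 units = x$units, level = "subclass"),
            class = "type_expression")
}

#' @export
pool_by_subclass.np_coupling <- function(x, taxonomy) {
  sub <- taxonomy$leaf_subclass[rownames(x$values)]
  subs <- unique(unname(sub))
  pooled <- matrix(0, length(subs), length(subs),
                   dimnames = list(subs, subs))
  for (a in subs) {
    for (b in subs) {
      pooled[a, b] <- mean(x$values[sub == a, sub == b, drop = FALSE])
    }
  }
  structure(list(values = pooled, log_values = log10(pmax(pooled, x$eps_log)),
                 pair = x$pair, area = x$area, level = "subclass",
                 eps_log = x$eps_log),
            class = "np_coupling")
}

#' Aggregate coupling matrices into G-alpha family channels
#'
#' Predicts the net transduction impact per (source, target) pair of types
#' by pooling cognate-pair networks over their receptors' primary G-alpha
#' family: Gi/o (cAMP-inhibiting), Gs (cAMP-stimulating), Gq/11
#' (calcium-amplifying) — the red, green and blue channels of the combined
#' display. The default order follows the figure-legend recipe: each pair's
#' log10 matrix is shifted to minimum 0 and scaled to maximum 1, the
#' normalized matrices are summed within each family, and each family
#' channel is rescaled to \[0, 1\]. `order = "sum_log_norm"` instead sums
#' linear matrices per family first, then logs and normalizes.
#'
#' @param matrices List of `np_coupling` objects (same area and dimensions),
#'   each with a `galpha_family` on its pair.
#' @param families Channel order (default `c("Gi/o", "Gs", "Gq/11")`).
#' @param order `"log_norm_sum"` (default) or `"sum_log_norm"`.
#' @return Object of class `np_channels`: named list `channels` of matrices
#'   in \[0, 1\], plus `n_pairs` per family, `area`, `level`.
#' @export
aggregate_by_galpha <- function(matrices,
                                families = c("Gi/o", "Gs", "Gq/11"),
                                order = c("log_norm_sum", "sum_log_norm")) {
  order <- match.arg(order)
  fam <- vapply(matrices, function(m) m$pair$galpha_family, character(1))
  if (anyNA(fam)) stop("every pair needs a galpha_family", call. = FALSE)
  dims <- dim(matrices[[1]]$values)
  channels <- list()
  n_pairs <- stats::setNames(integer(length(families)), families)
  for (f in families) {
    members <- matrices[fam == f]
    n_pairs[f] <- length(members)
    if (!length(members)) {
      warning("no cognate pairs in family ", f, "; channel all zero")
      channels[[f]] <- matrix(0, dims[1], dims[2],
                              dimnames = dimnames(matrices[[1]]$values))
      next
    }
    if (order == "log_norm_sum") {
      S <- Reduce(`+`, lapply(members, function(m) {
        lv <- m$log_values - min(m$log_values)
        mx <- max(lv)
        if (mx > 0) lv / mx else lv
      }))
    } else {
      S <- Reduce(`+`, lapply(members, function(m) m$values))
      S <- log10(pmax(S, members[[1]]$eps_log))
      S <- S - min(S)
    }
    mx <- max(S)
    channels[[f]] <- if (mx > 0) S / mx else S
  }
  structure(list(channels = channels, n_pairs = n_pairs,
                 area = matrices[[1]]$area, level = matrices[[1]]$level,
                 order = order),
            class = "np_channels")
}

#' @export
print.np_channels <- function(x, ...) {
  cat(sprintf("<np_channels> area %s, level %s: %s\n", x$area, x$level,
              paste(sprintf("%s (%d pairs)", names(x$n_pairs), x$n_pairs),
                    collapse = ", ")))
  invisible(x)
}

#' Export coupling matrices as CSV adjacency files
#'
#' One CSV per coupling matrix, named `<area>_<npp>__<gpcr>.csv`, with type
#' labels as row and column headers and linear CPM·CPM values — re-export
#' is byte-identical.
#'
#' @param matrices A single `np_coupling` or a list of them.
#' @param dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
export_adjacency <- function(matrices, dir) {
  if (inherits(matrices, "np_coupling")) matrices <- list(matrices)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- vapply(matrices, function(m) {
    fn <- file.path(dir, sprintf("%s_%s__%s.csv", m$area, m$pair$npp_gene,
                                 m$pair$npgpcr_gene))
    tab <- data.frame(type = rownames(m$values), m$values,
                      check.names = FALSE)
    utils::write.table(tab, fn, sep = ",", quote = FALSE, row.names = FALSE)
    fn
  }, character(1))
  invisible(files)
}

#' Tidy a coupling matrix into long form
#' @param x An `np_coupling`.
#' @param ... Unused.
#' @return Tibble: `source_type`, `target_type`, `value`, `log_value`, plus
#'   pair and area columns.
#' @export
tidy.np_coupling <- function(x, ...) {
  long <- as.data.frame.table(x$values, responseName = "value",
                              stringsAsFactors = FALSE)
  names(long) <- c("source_type", "target_type", "value")
  long$log_value <- as.vector(x$log_values)
  tibble::as_tibble(long) |>
    dplyr::mutate(npp_gene = x$pair$npp_gene,
                  npgpcr_gene = x$pair$npgpcr_gene,
                  galpha_family = x$pair$galpha_family, area = x$area)
}
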