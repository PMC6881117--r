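#' Construct a cell-by-gene expression matrix
#'
#' Light matrix-backed container for single-cell expression values. Rows are
#' cells, columns are genes; absent measurements are zeros, never `NA`.
#' The unit tag (`"counts"`, `"CPM"` or `"FPKM"`) travels with the object so
#' downstream statistics can refuse unit-inconsistent input. No conversion
#' between CPM and FPKM is offered: it would require exon lengths.
#'
#' @param values Numeric matrix, cells x genes, nonnegative, no `NA`.
#' @param units One of `"counts"`, `"CPM"`, `"FPKM"`.
#' @param cell_ids,gene_ids Unique identifiers; default to dimnames of
#'   `values`.
#' @param is_full_transcriptome Logical; when `TRUE` and `units == "CPM"`,
#'   each cell's row is checked to sum to 1e6 (relative tolerance 1e-6).
#' @return An object of class `np_expression`.
#' @examples
#' m <- np_expression(matrix(rpois(6, 5), 2, 3), units = "counts")
#' dim(m)
#' @export
np_expression <- function(values, units = c("counts", "CPM", "FPKM"),
                          cell_ids = rownames(values),
                          gene_ids = colnames(values),
                          is_full_transcriptome = FALSE) {
  units <- match.arg(units)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(values)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(values)))
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(values) || length(gene_ids) != ncol(values)) {
    stop("identifier lengths do not match matrix dimensions", call. = FALSE)
  }
  if (anyDuplicated(cell_ids)) stop("duplicate cell identifiers", call. = FALSE)
  if (anyDuplicated(gene_ids)) stop("duplicate gene identifiers", call. = FALSE)
  if (anyNA(values)) stop("expression values must not contain NA", call. = FALSE)
  if (any(values < 0)) stop("expression values must be nonnegative", call. = FALSE)
  dimnames(values) <- list(cell_ids, gene_ids)
  x <- structure(
    list(values = values, units = units,
         is_full_transcriptome = isTRUE(is_full_transcriptome)),
    class = "np_expression"
  )
  if (units == "CPM" && isTRUE(is_full_transcriptome)) {
    rs <- rowSums(values)
    if (any(abs(rs - 1e6) > 1e-6 * 1e6)) {
      stop("CPM rows of a full-transcriptome matrix must sum to 1e6",
           call. = FALSE)
    }
  }
  x
}

#' @export
dim.np_expression <- function(x) dim(x$values)

#' @export
print.np_expression <- function(x, ...) {
  cat(sprintf("<np_expression> %d cells x %d genes [%s]%s\n",
              nrow(x$values), ncol(x$values), x$units,
              if (x$is_full_transcriptome) ", full transcriptome" else ""))
  invisible(x)
}

#' @rdname np_expression
#' @param x An `np_expression` object.
#' @export
cell_ids <- function(x) rownames(x$values)

#' @rdname np_expression
#' @export
gene_ids <- function(x) colnames(x$values)

#' Extract the value matrix of an expression container
#'
#' @param x An `np_expression` object.
#' @param genes Optional character vector of genes to keep (exact,
#'   case-sensitive symbols).
#' @return Numeric cells x genes matrix.
#' @export
expression_values <- function(x, genes = NULL) {
  stopifnot(inherits(x, "np_expression"))
  if (is.null(genes)) return(x$values)
  missing <- setdiff(genes, colnames(x$values))
  if (length(missing)) {
    stop("genes absent from matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x$values[, genes, drop = FALSE]
}

#' Read a cell-by-gene expression matrix from disk
#'
#' Two layouts are supported: a dense delimited file (one header line of gene
#' identifiers, first column of cell identifiers) and a Matrix Market triplet
#' file with sidecar one-column TSVs naming cells (rows) and genes (columns).
#'
#' @param path File path; for `layout = "sparse-triplet"` the `.mtx` file,
#'   with `<path>.cells.tsv` and `<path>.genes.tsv` alongside (or pass
#'   `cells_path`/`genes_path`).
#' @param units Unit tag recorded on the result.
#' @param layout `"dense-delimited"` or `"sparse-triplet"`.
#' @param cells_path,genes_path Optional explicit sidecar paths.
#' @param is_full_transcriptome Passed through to [np_expression()].
#' @return An `np_expression` object.
#' @export
read_expression <- function(path, units = c("counts", "CPM", "FPKM"),
                            layout = c("dense-delimited", "sparse-triplet"),
                            cells_path = NULL, genes_path = NULL,
                            is_full_transcriptome = FALSE) {
  units <- match.arg(units)
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (layout == "dense-delimited") {
    tab <- utils::read.delim(path, sep = guess_delim(path), header = TRUE,
                             check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 2) stop("malformed expression file: ", path, call. = FALSE)
    cells <- as.character(tab[[1]])
    vals <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(vals)) {
      stop("non-numeric expression values in ", path, call. = FALSE)
    }
    m <- np_expression(vals, units = units, cell_ids = cells,
                       gene_ids = colnames(tab)[-1],
                       is_full_transcriptome = is_full_transcriptome)
  } else {
    if (is.null(cells_path)) cells_path <- paste0(path, ".cells.tsv")
    if (is.null(genes_path)) genes_path <- paste0(path, ".genes.tsv")
    sm <- Matrix::readMM(path)
    cells <- readLines(cells_path)
    genes <- readLines(genes_path)
    if (nrow(sm) != length(cells) || ncol(sm) != length(genes)) {
      stop("sparse matrix dimensions do not match sidecar identifier files",
           call. = FALSE)
    }
    m <- np_expression(as.matrix(sm), units = units, cell_ids = cells,
                       gene_ids = genes,
                       is_full_transcriptome = is_full_transcriptome)
  }
  m
}

#' Write an expression matrix as a dense delimited file
#'
#' @param x An `np_expression` object.
#' @param path Output path (tab-separated; one header line of genes, first
#'   column `cell_id`).
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "np_expression"))
  tab <- data.frame(cell_id = rownames(x$values), x$values,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

guess_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Convert raw counts to counts-per-million
#'
#' `CPM[c, g] = 1e6 * count[c, g] / sum_g count[c, g]`. Every cell must have a
#' positive total.
#'
#' @param m An `np_expression` with `units = "counts"`.
#' @return An `np_expression` with `units = "CPM"`; row sums are 1e6.
#' @examples
#' m <- np_expression(matrix(c(1, 1, 2), 1, 3), units = "counts")
#' expression_values(counts_to_cpm(m))
#' @export
counts_to_cpm <- function(m) {
  stopifnot(inherits(m, "np_expression"))
  if (m$units != "counts") stop("input units must be counts", call. = FALSE)
  totals <- rowSums(m$values)
  bad <- totals <= 0
  if (any(bad)) {
    stop("cells with zero total counts: ",
         paste(utils::head(rownames(m$values)[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  np_expression(m$values / totals * 1e6, units = "CPM",
                cell_ids = rownames(m$values), gene_ids = colnames(m$values),
                is_full_transcriptome = TRUE)
}

#' Validate a cell annotation table against a taxonomy
#'
#' Checks that every `leaf_type` is a taxonomy leaf and that the stated
#' `subclass` and `class` agree with the leaf's ancestors in the tree.
#'
#' @param ann Data frame with columns `cell_id`, `area`, `leaf_type`,
#'   `subclass`, `class`.
#' @param taxonomy An `np_taxonomy` (see [read_taxonomy()]).
#' @return The annotation as a tibble, invisibly validated.
#' @export
validate_annotation <- function(ann, taxonomy) {
  required <- c("cell_id", "area", "leaf_type", "subclass", "class")
  missing <- setdiff(required, names(ann))
  if (length(missing)) {
    stop("annotation lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ann <- tibble::as_tibble(ann)
  if (anyDuplicated(ann$cell_id)) stop("duplicate cell_id", call. = FALSE)
  bad_area <- setdiff(unique(ann$area), c("VISp", "ALM"))
  if (length(bad_area)) {
    stop("unknown area: ", paste(bad_area, collapse = ", "), call. = FALSE)
  }
  leaves <- taxonomy_leaves(taxonomy)
  unknown <- setdiff(unique(ann$leaf_type), leaves)
  if (length(unknown)) {
    stop("leaf types absent from taxonomy: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  sub_map <- taxonomy$leaf_subclass
  cls_map <- taxonomy$leaf_class
  if (!all(ann$subclass == sub_map[ann$leaf_type])) {
    stop("annotation subclass inconsistent with taxonomy strata", call. = FALSE)
  }
  if (!all(ann$class == cls_map[ann$leaf_type])) {
    stop("annotation class inconsistent with taxonomy strata", call. = FALSE)
  }
  ann
}

#' Read a cell annotation TSV
#'
#' @param path TSV with columns `cell_id`, `area`, `leaf_type`, `subclass`,
#'   `class`.
#' @param taxonomy Optional `np_taxonomy` used to validate strata.
#' @return Tibble of annotations.
#' @export
read_annotation <- function(path, taxonomy = NULL) {
  ann <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(taxonomy)) ann <- validate_annotation(ann, taxonomy)
  tibble::as_tibble(ann)
}
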