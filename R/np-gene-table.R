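#' Read an NPP / NP-GPCR gene annotation table
#'
#' The table mirrors the published gene annotations: one row per gene with
#' its role (`NPP` = neuropeptide precursor, `NP-GPCR` = neuropeptide-selective
#' G-protein-coupled receptor), its cognate partners (`|`-separated gene
#' symbols), and for receptors the primary G-alpha transduction family
#' (`Gi/o`, `Gs` or `Gq/11`). The cognate relation is made symmetric on read:
#' a link listed on either side is added to both. Gene symbols match
#' case-sensitively throughout the package.
#'
#' @param path TSV with columns `gene`, `role`, `galpha_family`,
#'   `cognate_partners`; extra columns (peak statistics, product names) are
#'   kept.
#' @return A tibble of class `np_gene_table` with list-column
#'   `cognate_partners`.
#' @seealso [np_gene_fixture()] for the annotations shipped with the package.
#' @export
read_np_gene_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- if (file.size(path) == 0) tibble::tibble() else
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE, na = "NA")
  if (nrow(tab) == 0) {
    tab <- tibble::tibble(gene = character(), role = character(),
                          galpha_family = character(),
                          cognate_partners = list())
    return(structure(tab, class = c("np_gene_table", class(tab))))
  }
  required <- c("gene", "role", "cognate_partners")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("NP gene table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"galpha_family" %in% names(tab)) tab$galpha_family <- NA_character_
  tab$cognate_partners <- lapply(tab$cognate_partners, function(s) {
    if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, "|", fixed = TRUE)[[1]]
  })
  np_gene_table(tab)
}

#' Validate (and symmetrically close) an NP gene table
#'
#' @param tab Data frame with columns `gene`, `role`, `galpha_family` and a
#'   list-column `cognate_partners`.
#' @return A validated `np_gene_table` tibble.
#' @export
np_gene_table <- function(tab) {
  tab <- tibble::as_tibble(tab)
  if (anyDuplicated(tab$gene)) stop("duplicate gene symbols", call. = FALSE)
  bad_role <- setdiff(unique(tab$role), c("NPP", "NP-GPCR"))
  if (length(bad_role)) {
    stop("unknown role: ", paste(bad_role, collapse = ", "), call. = FALSE)
  }
  is_rec <- tab$role == "NP-GPCR"
  if (any(is_rec & (is.na(tab$galpha_family) | !nzchar(tab$galpha_family)))) {
    stop("every NP-GPCR row needs a galpha_family", call. = FALSE)
  }
  if (any(!is_rec & !is.na(tab$galpha_family))) {
    stop("galpha_family must be absent on NPP rows", call. = FALSE)
  }
  bad_fam <- setdiff(stats::na.omit(unique(tab$galpha_family)),
                     c("Gi/o", "Gs", "Gq/11"))
  if (length(bad_fam)) {
    stop("unknown G-alpha family: ", paste(bad_fam, collapse = ", "),
         call. = FALSE)
  }
  role_of <- stats::setNames(tab$role, tab$gene)
  partners <- stats::setNames(tab$cognate_partners, tab$gene)
  for (i in seq_len(nrow(tab))) {
    g <- tab$gene[i]
    for (h in partners[[g]]) {
      if (!h %in% tab$gene) {
        stop("cognate partner not in table: ", h, " (of ", g, ")",
             call. = FALSE)
      }
      if (role_of[[h]] == role_of[[g]]) {
        stop("cognate link joins two genes of the same role: ", g, " - ", h,
             call. = FALSE)
      }
      partners[[h]] <- union(partners[[h]], g)  # symmetric closure
    }
  }
  tab$cognate_partners <- unname(partners[tab$gene])
  structure(tab, class = unique(c("np_gene_table", class(tab))))
}

#' NP gene annotations shipped with the package
#'
#' The 18 NPP and 29 NP-GPCR genes of the mouse neocortex analysis, with
#' cognate partners, primary G-alpha families, peak-FPKM statistics and
#' detection percentages, encoded from the published tables.
#'
#' @return An `np_gene_table` tibble (47 rows).
#' @export
np_gene_fixture <- function() {
  read_np_gene_table(system.file("extdata", "np_gene_table.tsv",
                                 package = "pepnet", mustWork = TRUE))
}

#' Published cognate-pair table shipped with the package
#'
#' The 37 cognate NPP/NP-GPCR pairs with their primary G-alpha family and the
#' published fraction-of-type-pairs column.
#'
#' @return Tibble with columns `pair_index`, `npp_gene`, `npgpcr_gene`,
#'   `galpha_family`, `fraction_of_type_pairs`.
#' @export
cognate_pair_fixture <- function() {
  readr::read_tsv(system.file("extdata", "cognate_pair_fractions.tsv",
                              package = "pepnet", mustWork = TRUE),
                  show_col_types = FALSE, progress = FALSE)
}

#' All cognate (NPP, NP-GPCR) links of an NP gene table
#'
#' @param tab An `np_gene_table`.
#' @return Tibble with one row per directed NPP -> receptor link: `npp_gene`,
#'   `npgpcr_gene`, `galpha_family`.
#' @export
cognate_links <- function(tab) {
  npp <- tab$gene[tab$role == "NPP"]
  fam <- stats::setNames(tab$galpha_family, tab$gene)
  partners <- stats::setNames(tab$cognate_partners, tab$gene)
  rows <- purrr::map_dfr(npp, function(g) {
    hs <- partners[[g]]
    if (!length(hs)) return(tibble::tibble())
    tibble::tibble(npp_gene = g, npgpcr_gene = hs,
                   galpha_family = unname(fam[hs]))
  })
  if (!nrow(rows)) {
    rows <- tibble::tibble(npp_gene = character(), npgpcr_gene = character(),
                           galpha_family = character())
  }
  rows
}

#' Write an NP gene table back to TSV
#'
#' @param tab An `np_gene_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_np_gene_table <- function(tab, path) {
  out <- tab
  out$cognate_partners <- vapply(tab$cognate_partners, paste,
                                 character(1), collapse = "|")
  readr::write_tsv(tibble::as_tibble(out), path, na = "NA")
  invisible(path)
}
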