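test_that("expression container validates values and identifiers", {
  m <- np_expression(matrix(0, 3, 2), units = "counts")
  expect_equal(dim(m), c(3, 2))
  expect_error(np_expression(matrix(-1, 1, 1), units = "counts"),
               "nonnegative")
  expect_error(np_expression(matrix(NA_real_, 1, 1), units = "counts"), "NA")
  expect_error(np_expression(matrix(0, 2, 2),
                             cell_ids = c("a", "a"),
                             gene_ids = c("g1", "g2"), units = "counts"),
               "duplicate cell")
  expect_error(np_expression(matrix(0, 2, 2),
                             cell_ids = c("a", "b"),
                             gene_ids = c("g", "g"), units = "counts"),
               "duplicate gene")
  # full-transcriptome CPM rows must sum to one million
  bad <- matrix(c(5e5, 4e5), 1, 2)
  expect_error(np_expression(bad, units = "CPM", is_full_transcriptome = TRUE),
               "sum to 1e6")
})

test_that("dense and sparse readers agree and reject malformed input", {
  dense <- file.path(tempdir(), "dense.csv")
  writeLines(c("cell_id,g1,g2", "c1,0,0", "c2,0,0", "c3,0,0"), dense)
  m <- read_expression(dense, units = "counts", layout = "dense-delimited")
  expect_equal(unname(expression_values(m)), matrix(0, 3, 2))
  expect_equal(cell_ids(m), c("c1", "c2", "c3"))

  # sparse triplet with one entry (c1, g1, 5) over a 2 x 2 grid
  mtx <- file.path(tempdir(), "m.mtx")
  Matrix::writeMM(Matrix::sparseMatrix(i = 1, j = 1, x = 5, dims = c(2, 2)),
                  mtx)
  writeLines(c("c1", "c2"), paste0(mtx, ".cells.tsv"))
  writeLines(c("g1", "g2"), paste0(mtx, ".genes.tsv"))
  sm <- read_expression(mtx, units = "counts", layout = "sparse-triplet")
  expect_equal(unname(expression_values(sm)),
               matrix(c(5, 0, 0, 0), 2, 2))

  neg <- file.path(tempdir(), "neg.csv")
  writeLines(c("cell_id,g1", "c1,-3"), neg)
  expect_error(read_expression(neg, units = "counts"), "nonnegative")

  dup <- file.path(tempdir(), "dup.csv")
  writeLines(c("cell_id,g1,g1", "c1,1,2"), dup)
  expect_error(read_expression(dup, units = "counts"), "duplicate gene")
})

test_that("expression write -> read round-trips all fields", {
  ds <- small_dataset()
  path <- file.path(tempdir(), "roundtrip.tsv")
  write_expression(ds$counts, path)
  back <- read_expression(path, units = "counts")
  expect_equal(expression_values(back), expression_values(ds$counts))
  expect_identical(back$units, "counts")
})

test_that("counts_to_cpm matches the definition and is scale invariant", {
  m <- np_expression(matrix(c(1, 1, 2), 1, 3), units = "counts")
  expect_equal(unname(expression_values(counts_to_cpm(m))[1, ]),
               c(250000, 250000, 500000))
  zero <- np_expression(matrix(0, 1, 2), units = "counts",
                        cell_ids = "bad_cell")
  expect_error(counts_to_cpm(zero), "bad_cell")

  withr::with_seed(3, {
    counts <- matrix(rpois(200, 5) + 1, 10, 20)
    cpm <- counts_to_cpm(np_expression(counts, units = "counts"))
    expect_true(all(abs(rowSums(expression_values(cpm)) - 1e6) < 1e-6 * 1e6))
    # scaling any cell's counts leaves its CPM row unchanged
    scaled <- counts
    scaled[4, ] <- scaled[4, ] * 17
    cpm2 <- counts_to_cpm(np_expression(scaled, units = "counts"))
    expect_equal(expression_values(cpm2)[4, ], expression_values(cpm)[4, ],
                 tolerance = 1e-12)
  })
  expect_error(counts_to_cpm(counts_to_cpm(m)), "units")
})

test_that("newick taxonomies get unit-merge heights and strata", {
  nwk <- file.path(tempdir(), "t.nwk")
  writeLines("((a,b),(c,d));", nwk)
  tax <- read_taxonomy(nwk, format = "newick-with-heights")
  td <- tidy(tax)
  expect_equal(td$height[td$label == tax$label[tax$root]], 2)
  expect_equal(sort(td$height[td$is_leaf]), rep(0, 4))
  expect_equal(sort(unique(td$height)), c(0, 1, 2))

  # a single leaf has no positive root height and is rejected
  single <- file.path(tempdir(), "single.nwk")
  writeLines("a;", single)
  expect_error(read_taxonomy(single, format = "newick-with-heights"))
})

test_that("a deep two-class hierarchy reads with all leaves and strata", {
  # 115-leaf tree shaped like the cortical neurotaxonomy: 2 classes,
  # 12 subclasses, unit merge heights
  cfg <- synth_config(n_types = 115, n_subclasses = 12, seed = 1)
  tax <- generate_taxonomy(cfg)
  path <- file.path(tempdir(), "tax115.nwk")
  write_taxonomy(tax, path, format = "newick-with-heights")
  back <- read_taxonomy(path, format = "newick-with-heights")
  expect_length(taxonomy_leaves(back), 115)
  expect_setequal(unique(back$leaf_class), c("GABAergic", "glutamatergic"))
  expect_length(unique(back$leaf_subclass), 12)
  expect_equal(back$height[back$root], 3)
})

test_that("taxonomy JSON write -> read is identity on fields", {
  tax <- generate_taxonomy(small_config())
  path <- file.path(tempdir(), "tax.json")
  write_taxonomy(tax, path, format = "nested-json")
  back <- read_taxonomy(path, format = "nested-json")
  # node indices may differ (depth-first serialization); compare the
  # label-keyed structure instead
  canon <- function(t) {
    td <- tidy(t)
    td[order(td$label), c("label", "parent", "height", "is_leaf", "ri")]
  }
  expect_equal(canon(back), canon(tax))
  expect_identical(back$leaf_subclass[sort(names(back$leaf_subclass))],
                   tax$leaf_subclass[sort(names(tax$leaf_subclass))])
  expect_identical(back$leaf_class[sort(names(back$leaf_class))],
                   tax$leaf_class[sort(names(tax$leaf_class))])
})

test_that("the NP gene table enforces role/family invariants", {
  tab <- np_gene_fixture()
  expect_equal(nrow(tab), 47)
  expect_equal(sum(tab$role == "NPP"), 18)
  expect_equal(sum(tab$role == "NP-GPCR"), 29)
  links <- cognate_links(tab)
  expect_equal(nrow(links), 37)
  expect_equal(as.vector(table(links$galpha_family)[c("Gi/o", "Gs", "Gq/11")]),
               c(18L, 9L, 10L))
  # symmetric closure: every receptor lists its precursors back
  npy_partners <- tab$cognate_partners[[which(tab$gene == "Npy1r")]]
  expect_true("Npy" %in% npy_partners)
  sst_partners <- tab$cognate_partners[[which(tab$gene == "Sst")]]
  expect_setequal(sst_partners, c("Sstr1", "Sstr2", "Sstr3", "Sstr4"))

  bad <- tibble::tibble(gene = c("A", "B"), role = c("NPP", "NP-GPCR"),
                        galpha_family = c("Gs", "Gs"),
                        cognate_partners = list("B", character(0)))
  expect_error(np_gene_table(bad), "absent on NPP")
  # same-role link rejected
  bad2 <- tibble::tibble(gene = c("A", "B"), role = c("NPP", "NPP"),
                         galpha_family = c(NA, NA),
                         cognate_partners = list("B", character(0)))
  expect_error(np_gene_table(bad2), "same role")
})

test_that("an empty NP gene table file yields zero genes and pairs", {
  empty <- file.path(tempdir(), "empty.tsv")
  file.create(empty)
  tab <- read_np_gene_table(empty)
  expect_equal(nrow(tab), 0)
  expect_equal(nrow(cognate_links(tab)), 0)
})

test_that("NP gene table write -> read round-trips", {
  tab <- np_gene_fixture()
  path <- file.path(tempdir(), "np.tsv")
  write_np_gene_table(tab, path)
  back <- read_np_gene_table(path)
  expect_identical(back$gene, tab$gene)
  expect_identical(back$role, tab$role)
  expect_identical(back$galpha_family, tab$galpha_family)
  expect_identical(back$cognate_partners, tab$cognate_partners)
})

test_that("annotations are validated against taxonomy strata", {
  ds <- small_dataset()
  expect_silent(validate_annotation(ds$annotation, ds$taxonomy))
  broken <- ds$annotation
  broken$subclass[1] <- "not_a_subclass"
  expect_error(validate_annotation(broken, ds$taxonomy), "subclass")
  broken2 <- ds$annotation
  broken2$leaf_type[1] <- "no_such_type"
  expect_error(validate_annotation(broken2, ds$taxonomy), "absent")
})
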