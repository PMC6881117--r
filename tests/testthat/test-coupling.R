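profile_of <- function(vals, area = "VISp") {
  structure(list(values = vals, statistic = "trimmed_mean_5pct",
                 area = area, units = "CPM"),
            class = "type_expression")
}

test_that("coupling matrices are exact outer products", {
  vals <- rbind(P = c(10, 0), R = c(1, 100))
  colnames(vals) <- c("t1", "t2")
  cm <- coupling_matrix(list(npp_gene = "P", npgpcr_gene = "R",
                             galpha_family = "Gs"), profile_of(vals))
  expect_equal(unname(cm$values), rbind(c(10, 1000), c(0, 0)))
  expect_lte(qr(cm$values)$rank, 1)
  expect_equal(cm$log_values, log10(pmax(cm$values, 1e-2)))
  expect_error(coupling_matrix(list(npp_gene = "X", npgpcr_gene = "R"),
                               profile_of(vals)), "absent")

  # log additivity wherever both factors clear the floor
  withr::with_seed(61, {
    u <- rlnorm(8, 2, 2)
    v <- rlnorm(8, 2, 2)
    vals2 <- rbind(P = u, R = v)
    colnames(vals2) <- paste0("t", 1:8)
    cm2 <- coupling_matrix(list(npp_gene = "P", npgpcr_gene = "R"),
                           profile_of(vals2))
    expected <- outer(log10(u), log10(v), `+`)
    ok <- outer(u, v) > 1e-2
    expect_equal(unname(cm2$log_values[ok]), expected[ok], tolerance = 1e-12)
  })

  # symmetric factors give a symmetric coupling matrix
  sym <- rbind(P = c(1, 5, 2), R = c(1, 5, 2))
  colnames(sym) <- paste0("t", 1:3)
  cs <- coupling_matrix(list(npp_gene = "P", npgpcr_gene = "R"),
                        profile_of(sym))
  expect_equal(cs$values, t(cs$values))
})

test_that("subclass pooling commutes with the outer product", {
  tax <- generate_taxonomy(synth_config(n_types = 12, n_subclasses = 4,
                                        seed = 8))
  types <- taxonomy_leaves(tax)
  withr::with_seed(62, {
    for (i in 1:100) {
      u <- rlnorm(12, 1, 2)
      v <- rlnorm(12, 1, 2)
      vals <- rbind(P = u, R = v)
      colnames(vals) <- types
      prof <- profile_of(vals)
      cm <- coupling_matrix(list(npp_gene = "P", npgpcr_gene = "R"), prof)
      pooled_coupling <- pool_by_subclass(cm, tax)
      pooled_profile <- pool_by_subclass(prof, tax)
      outer_of_means <- coupling_matrix(list(npp_gene = "P",
                                             npgpcr_gene = "R"),
                                        pooled_profile)
      err <- max(abs(pooled_coupling$values -
                       outer_of_means$values[rownames(pooled_coupling$values),
                                             colnames(pooled_coupling$values)]))
      expect_lt(err, 1e-12 * max(1, max(pooled_coupling$values)))
    }
  })
  # a three-type subclass with rows 2, 4, 3 pools to their mean, 3
  two <- rbind(P = c(2, 4, 3, 1, 1, 1, 1, 1, 1, 1, 1, 1),
               R = rep(1, 12))
  colnames(two) <- types
  pooled <- pool_by_subclass(profile_of(two), tax)
  first_sub <- unname(tax$leaf_subclass[types[1]])
  expect_equal(unname(pooled$values["P", first_sub]), 3)
  # 12 types in 4 subclasses -> 4 x 4 pooled coupling
  cm12 <- coupling_matrix(list(npp_gene = "P", npgpcr_gene = "R"),
                          profile_of(two))
  expect_equal(dim(pool_by_subclass(cm12, tax)$values), c(4, 4))
})

test_that("G-alpha channel aggregation normalizes to [0, 1] per family", {
  vals <- rbind(P1 = c(100, 1), P2 = c(1, 50), R1 = c(3, 30), R2 = c(20, 2))
  colnames(vals) <- c("t1", "t2")
  prof <- profile_of(vals)
  mk <- function(p, r, fam) coupling_matrix(list(npp_gene = p, npgpcr_gene = r,
                                                 galpha_family = fam), prof)
  ms <- list(mk("P1", "R1", "Gi/o"), mk("P2", "R2", "Gi/o"),
             mk("P1", "R2", "Gs"))
  expect_warning(ch <- aggregate_by_galpha(ms), "Gq/11")
  for (f in c("Gi/o", "Gs")) {
    expect_true(all(ch$channels[[f]] >= 0 & ch$channels[[f]] <= 1))
    expect_equal(max(ch$channels[[f]]), 1)
  }
  expect_true(all(ch$channels[["Gq/11"]] == 0))
  expect_equal(unname(ch$n_pairs), c(2L, 1L, 0L))

  # a single pair in a family: the channel is that pair's normalized matrix
  single <- ch$channels[["Gs"]]
  lv <- ms[[3]]$log_values
  lv <- lv - min(lv)
  expect_equal(single, lv / max(lv))
  # duplicated pairs renormalize to the same channel as one
  ch2 <- suppressWarnings(aggregate_by_galpha(list(ms[[3]], ms[[3]])))
  expect_equal(ch2$channels[["Gs"]], single)
  # the alternative aggregation order also yields bounded channels
  ch3 <- suppressWarnings(aggregate_by_galpha(ms, order = "sum_log_norm"))
  expect_true(all(unlist(ch3$channels) >= 0 & unlist(ch3$channels) <= 1))
})

test_that("fixture pairs aggregate into 18 / 9 / 10 family channels", {
  ds <- small_dataset(seed = 63)
  tab <- ds$gene_table
  pairs <- build_cognate_pairs(tab$gene[tab$role == "NPP"],
                               tab$gene[tab$role == "NP-GPCR"], tab)
  prof <- type_mean_expression(ds$cpm, ds$annotation, area = "VISp",
                               genes = tab$gene, taxonomy = ds$taxonomy)
  ms <- lapply(seq_len(nrow(pairs)), function(i)
    coupling_matrix(pairs[i, ], prof))
  ch <- aggregate_by_galpha(ms)
  expect_equal(unname(ch$n_pairs[c("Gi/o", "Gs", "Gq/11")]), c(18L, 9L, 10L))
})

test_that("adjacency export writes deterministic per-pair CSVs", {
  ds <- small_dataset(seed = 64)
  tab <- ds$gene_table
  pairs <- build_cognate_pairs(tab$gene[tab$role == "NPP"],
                               tab$gene[tab$role == "NP-GPCR"], tab)
  files_per_area <- list()
  for (a in c("VISp", "ALM")) {
    prof <- type_mean_expression(ds$cpm, ds$annotation, area = a,
                                 genes = tab$gene, taxonomy = ds$taxonomy)
    ms <- lapply(seq_len(nrow(pairs)), function(i)
      coupling_matrix(pairs[i, ], prof))
    dir <- file.path(tempdir(), paste0("adj_", a))
    unlink(dir, recursive = TRUE)
    files_per_area[[a]] <- export_adjacency(ms, dir)
  }
  # one file per cognate pair per area; 37 x 2 = 74 directed networks
  expect_length(files_per_area$VISp, 37)
  expect_length(unlist(files_per_area), 74)
  expect_true(all(file.exists(unlist(files_per_area))))
  # a 2x2 matrix gives a 3-line CSV with a header row
  small_vals <- rbind(P = c(1, 2), R = c(3, 4))
  colnames(small_vals) <- c("t1", "t2")
  small <- coupling_matrix(list(npp_gene = "P", npgpcr_gene = "R"),
                           profile_of(small_vals))
  f <- export_adjacency(small, file.path(tempdir(), "adj_small"))
  expect_length(readLines(f), 3)
  # re-export is byte-identical
  md5_before <- tools::md5sum(files_per_area$VISp)
  prof <- type_mean_expression(ds$cpm, ds$annotation, area = "VISp",
                               genes = tab$gene, taxonomy = ds$taxonomy)
  ms <- lapply(seq_len(nrow(pairs)), function(i)
    coupling_matrix(pairs[i, ], prof))
  again <- export_adjacency(ms, file.path(tempdir(), "adj_VISp"))
  expect_identical(unname(tools::md5sum(again)), unname(md5_before))
})
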