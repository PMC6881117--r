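test_that("peak expression follows the ascending nearest-rank rule", {
  m <- np_expression(matrix(0, 5, 1, dimnames = list(NULL, "z")),
                     units = "CPM")
  expect_equal(peak_expression(m, "z"), 0)
  expect_equal(peak_expression(m, "z", quantile = 0.5), 0)

  m2 <- np_expression(matrix(1:10000, ncol = 1, dimnames = list(NULL, "g")),
                      units = "FPKM")
  expect_equal(peak_expression(m2, "g"), 9990)  # ceiling(0.999 * 10000)
  expect_error(peak_expression(m2, "nope"), "absent")
})

test_that("peak expression matches a brute-force sort oracle and scales", {
  withr::with_seed(42, {
    for (i in 1:200) {
      n <- sample(3:500, 1)
      x <- rlnorm(n, 3, 2) * rbinom(n, 1, 0.6)
      m <- np_expression(matrix(x, ncol = 1, dimnames = list(NULL, "g")),
                         units = "CPM")
      q <- runif(1, 0.5, 0.9999)
      oracle <- sort(x)[min(n, max(1, ceiling(q * n)))]
      expect_identical(peak_expression(m, "g", quantile = q), oracle)
    }
    # homogeneity: peak(k * x) = k * peak(x)
    x <- rlnorm(200)
    m <- np_expression(cbind(g = x, h = 3.5 * x), units = "CPM")
    expect_equal(peak_expression(m, "h"), 3.5 * peak_expression(m, "g"))
  })
})

test_that("peak ranking is a deterministic permutation with ties broken", {
  vals <- cbind(a = c(10, 10), b = c(5, 5), c = c(10, 10))
  m <- np_expression(vals, units = "CPM")
  pt <- peak_rank_table(m, c("a", "b", "c"))
  expect_setequal(pt$absolute_rank, 1:3)
  # ties between a and c broken lexicographically
  expect_equal(pt$absolute_rank[pt$gene == "a"], 1L)
  expect_equal(pt$absolute_rank[pt$gene == "c"], 2L)
  expect_equal(pt$absolute_rank[pt$gene == "b"], 3L)
  # percentile monotone decreasing in rank
  expect_true(all(diff(pt$percentile_rank[order(pt$absolute_rank)]) < 0))

  single <- peak_rank_table(m, "b")
  expect_equal(single$percentile_rank, 100)
  expect_equal(single$absolute_rank, 1L)
  expect_error(peak_rank_table(m, character(0)), "empty")

  withr::with_seed(9, {
    big <- matrix(rlnorm(50 * 1000), 50, 1000,
                  dimnames = list(NULL, sprintf("g%04d", 1:1000)))
    big[, "g0500"] <- 1e9  # engineered top gene
    pt2 <- peak_rank_table(np_expression(big, units = "CPM"))
    expect_equal(pt2$absolute_rank[pt2$gene == "g0500"], 1L)
    expect_equal(pt2$percentile_rank[pt2$gene == "g0500"], 100)
  })
})

test_that("expression curves sort descending on the percentile axis", {
  m <- np_expression(cbind(a = c(5, 0, 10), b = c(1, 2, 0)), units = "CPM")
  cu <- expression_curves(m, "a")
  expect_equal(cu$value, c(10, 5, 0))
  expect_equal(cu$percentile, 100 * (1:3 - 0.5) / 3)

  mx <- expression_curves(m, c("a", "b"), mode = "max_over_set")
  expect_equal(mx$value, c(10, 5, 2))

  m2 <- np_expression(cbind(A = c(1, 0), B = c(0, 2)), units = "CPM")
  mx2 <- expression_curves(m2, c("A", "B"), mode = "max_over_set")
  expect_equal(mx2$value, c(2, 1))

  # dominance: the max curve lies pointwise above every per-gene curve
  withr::with_seed(8, {
    vals <- matrix(rlnorm(100 * 5), 100, 5,
                   dimnames = list(NULL, letters[1:5]))
    mm <- np_expression(vals, units = "CPM")
    mxc <- expression_curves(mm, letters[1:5], mode = "max_over_set")$value
    for (g in letters[1:5]) {
      expect_true(all(mxc >= expression_curves(mm, g)$value))
    }
  })
  expect_error(expression_curves(m, character(0)), "empty")
})

test_that("detection fractions use strict thresholds and shrink with them", {
  m <- np_expression(cbind(g = c(2, 0.5, 3, 0), z = rep(0, 4)),
                     units = "CPM")
  expect_equal(detection_fraction(m, "g", threshold = 1), 0.5)
  expect_equal(detection_fraction(m, "z"), 0)
  expect_error(detection_fraction(m, "g", cells = character(0)), "empty")
  withr::with_seed(11, {
    x <- rlnorm(500)
    mm <- np_expression(matrix(x, ncol = 1, dimnames = list(NULL, "g")),
                        units = "CPM")
    th <- sort(runif(10, 0, 5))
    fr <- vapply(th, function(t) detection_fraction(mm, "g", t), numeric(1))
    expect_true(all(diff(fr) <= 0))
  })
})

test_that("co-expression counts conserve the cell total", {
  m <- np_expression(matrix(0, 4, 3,
                            dimnames = list(NULL, c("a", "b", "c"))),
                     units = "CPM")
  co <- coexpression_counts(m, c("a", "b", "c"))
  expect_true(all(co$counts == 0))
  expect_equal(co$histogram$n_cells[1], 4)

  m2 <- np_expression(matrix(c(2, 3, 0), 1, 3,
                             dimnames = list(NULL, c("a", "b", "c"))),
                      units = "CPM")
  expect_equal(unname(coexpression_counts(m2, c("a", "b", "c"))$counts), 2)

  withr::with_seed(5, {
    vals <- matrix(rlnorm(200 * 6) * rbinom(1200, 1, 0.5), 200, 6,
                   dimnames = list(NULL, letters[1:6]))
    co2 <- coexpression_counts(np_expression(vals, units = "CPM"),
                               letters[1:6])
    expect_equal(sum(co2$histogram$n_cells), 200)
  })
})

test_that("pair co-expression is bounded by each member's detection", {
  m <- np_expression(cbind(p = c(2, 2, 0, 0), r = c(0, 0, 2, 2)),
                     units = "CPM")
  pairs <- tibble::tibble(npp_gene = "p", npgpcr_gene = "r")
  expect_equal(cognate_pair_coexpression(m, pairs)$fraction_both, 0)

  m2 <- np_expression(cbind(p = c(2, 2, 0, 0, 0), r = c(2, 2, 0, 0, 0)),
                      units = "CPM")
  expect_equal(cognate_pair_coexpression(m2, pairs)$fraction_both, 0.4)

  withr::with_seed(13, {
    vals <- matrix(rlnorm(300 * 4) * rbinom(1200, 1, 0.4), 300, 4,
                   dimnames = list(NULL, c("p1", "p2", "r1", "r2")))
    pp <- tibble::tibble(npp_gene = c("p1", "p2"), npgpcr_gene = c("r1", "r2"))
    res <- cognate_pair_coexpression(np_expression(vals, units = "CPM"), pp)
    expect_true(all(res$fraction_both <=
                      pmin(res$fraction_npp, res$fraction_npgpcr)))
  })
})

test_that("area conservation correlation handles limits and errors", {
  x <- c(1, 2, 3, 5)
  expect_equal(area_conservation(x, x)$estimate, 1)
  expect_equal(area_conservation(x, -x)$estimate, -1)
  expect_error(area_conservation(x, rep(1, 4)), "zero-variance")
  expect_error(area_conservation(1:2, 1:2), "at least 3")
  sp <- area_conservation(x, x^3, method = "spearman")
  expect_equal(sp$estimate, 1)
})

test_that("type profiles use the 5% trimmed mean with median fallback", {
  ann <- tibble::tibble(cell_id = sprintf("c%02d", 1:20),
                        area = "VISp", leaf_type = "t1",
                        subclass = "s1", class = "GABAergic")
  vals <- matrix(c(rep(0, 19), 1e6), 20, 1, dimnames = list(ann$cell_id, "g"))
  m <- np_expression(vals, units = "CPM")
  prof <- type_mean_expression(m, ann)
  expect_equal(unname(prof$values["g", "t1"]), 0)  # outlier trimmed away

  const <- np_expression(matrix(7, 20, 1,
                                dimnames = list(ann$cell_id, "g")),
                         units = "CPM")
  expect_equal(unname(type_mean_expression(const, ann)$values["g", "t1"]), 7)

  ann3 <- ann[1:3, ]
  med <- np_expression(matrix(c(1, 2, 100), 3, 1,
                              dimnames = list(ann3$cell_id, "g")),
                       units = "CPM")
  expect_equal(unname(type_mean_expression(med, ann3,
                                           statistic = "median")$values[1, 1]),
               2)
  # trim removing zero elements equals the plain mean, and the trimmed
  # mean always lies within the untrimmed range
  withr::with_seed(19, {
    x <- rlnorm(9)
    mm <- np_expression(matrix(x, 9, 1, dimnames = list(ann$cell_id[1:9], "g")),
                        units = "CPM")
    pr <- type_mean_expression(mm, ann[1:9, ])
    expect_equal(unname(pr$values[1, 1]), mean(x))
    x2 <- rlnorm(50)
    mm2 <- np_expression(matrix(x2, 50, 1,
                                dimnames = list(sprintf("d%02d", 1:50), "g")),
                         units = "CPM")
    ann50 <- tibble::tibble(cell_id = sprintf("d%02d", 1:50), area = "VISp",
                            leaf_type = "t1", subclass = "s1",
                            class = "GABAergic")
    tm <- unname(type_mean_expression(mm2, ann50)$values[1, 1])
    expect_gte(tm, min(x2))
    expect_lte(tm, max(x2))
  })
})

test_that("within-subclass CV excludes singletons and detects structure", {
  cfg <- synth_config(n_types = 9, n_subclasses = 3, seed = 3)
  tax <- generate_taxonomy(cfg)
  types <- taxonomy_leaves(tax)
  # gene A constant; gene B varies only between subclasses; gene C = [1,3]
  # pattern within each subclass
  sub <- tax$leaf_subclass[types]
  vals <- rbind(
    A = rep(5, 9),
    B = as.numeric(factor(sub)) * 10,
    C = rep(c(1, 3, 2), 3)
  )
  colnames(vals) <- types
  t <- structure(list(values = vals, statistic = "trimmed_mean_5pct",
                      area = "VISp", units = "CPM"),
                 class = "type_expression")
  cv <- cv_within_subclass(t, tax)
  expect_true(all(cv$by_subclass$cv[cv$by_subclass$gene == "A"] == 0))
  expect_equal(cv$summary$global_cv[cv$summary$gene == "A"], 0)
  expect_true(all(cv$by_subclass$cv[cv$by_subclass$gene == "B"] == 0))
  expect_gt(cv$summary$global_cv[cv$summary$gene == "B"], 0)
  expect_equal(cv$summary$ratio_mean[cv$summary$gene == "B"], 0)

  # sample-sd convention: values [1, 3] in a two-type subclass give 0.7071
  two <- matrix(c(1, 3, 8, 8), 1, 4,
                dimnames = list("g", paste0("type_", sprintf("%03d", 1:4))))
  cfg2 <- synth_config(n_types = 4, n_subclasses = 2, seed = 3)
  tax2 <- generate_taxonomy(cfg2)
  t2 <- structure(list(values = two, statistic = "trimmed_mean_5pct",
                       area = "VISp", units = "CPM"),
                  class = "type_expression")
  cv2 <- cv_within_subclass(t2, tax2)
  first_sub <- cv2$by_subclass$cv[cv2$by_subclass$subclass ==
                                    unname(tax2$leaf_subclass[1])]
  expect_equal(first_sub, sd(c(1, 3)) / mean(c(1, 3)), tolerance = 1e-6)
  expect_equal(round(first_sub, 4), 0.7071)
})
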