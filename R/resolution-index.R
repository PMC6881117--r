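#' Resolution index of taxonomy nodes
#'
#' The resolution index (RI) normalizes dendrogram node heights so the root
#' (the class split) sits at 0 and every leaf type at 1:
#' `RI(v) = 1 - height(v) / height(root)`. A classified cell inherits the RI
#' of the finest taxonomy node at which its predicted label is correct, so
#' per-cell RI lies in \[0, 1\].
#'
#' @param taxonomy An `np_taxonomy`.
#' @return Tibble: `label`, `height`, `ri`, `is_leaf`.
#' @export
node_resolution_index <- function(taxonomy) {
  h_root <- taxonomy$height[taxonomy$root]
  if (h_root <= 0) stop("degenerate taxonomy: root height 0", call. = FALSE)
  tibble::tibble(label = taxonomy$label, height = taxonomy$height,
                 ri = 1 - taxonomy$height / h_root,
                 is_leaf = taxonomy$is_leaf)
}

# ---- ridge-regularized Gaussian QDA -----------------------------------

qda_ridge_fit <- function(X, labels, ridge = 1e-4) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  d <- ncol(X)
  eps <- ridge * mean(apply(X, 2, stats::var))
  if (!is.finite(eps) || eps <= 0) eps <- ridge
  fits <- lapply(classes, function(k) {
    Xi <- X[labels == k, , drop = FALSE]
    mu <- colMeans(Xi)
    S <- if (nrow(Xi) >= 2) stats::cov(Xi) else matrix(0, d, d)
    S <- S + diag(eps, d)
    ch <- chol(S)
    list(mu = mu, chol_inv = backsolve(ch, diag(d)),
         logdet = 2 * sum(log(diag(ch))),
         logprior = log(nrow(Xi) / nrow(X)))
  })
  names(fits) <- classes
  structure(list(fits = fits, classes = classes, d = d), class = "qda_ridge")
}

qda_ridge_predict <- function(fit, X) {
  scores <- vapply(fit$fits, function(f) {
    Y <- sweep(X, 2, f$mu, "-") %*% f$chol_inv
    -0.5 * rowSums(Y^2) - 0.5 * f$logdet + f$logprior
  }, numeric(nrow(X)))
  scores <- matrix(scores, nrow = nrow(X))
  fit$classes[max.col(scores, ties.method = "first")]
}

# merged label of every leaf after collapsing the given internal nodes:
# a leaf takes the label of its highest merged ancestor (itself if none)
merged_label_map <- function(taxonomy, merged_ids) {
  leaves <- which(taxonomy$is_leaf)
  lab <- character(length(leaves))
  for (i in seq_along(leaves)) {
    v <- leaves[i]
    best <- v
    w <- v
    while (!is.na(taxonomy$parent[w])) {
      w <- taxonomy$parent[w]
      if (w %in% merged_ids) best <- w
    }
    lab[i] <- taxonomy$label[best]
  }
  stats::setNames(lab, taxonomy$label[leaves])
}

#' Hierarchical QDA classification with per-cell resolution index
#'
#' Benchmarks how finely a latent representation resolves the cell-type
#' taxonomy. Under k-fold cross-validation, a ridge-regularized QDA is first
#' trained on all leaf-type labels; test cells predicted correctly receive
#' RI = 1. Misclassified cells are re-labeled by classifiers retrained on
#' successively coarser label sets — internal nodes are collapsed one at a
#' time in ascending height order (finest splits first, ties broken by
#' label) — until the prediction matches, at which point the cell receives
#' the RI of the node carrying its then-current label. At the root all
#' labels coincide, so every cell resolves and cells wrong above the class
#' level floor out at RI = 0.
#'
#' @param z Cells x d latent coordinate matrix (rownames = cell ids).
#' @param labels Character vector of true leaf-type labels per cell.
#' @param taxonomy An `np_taxonomy` containing all labels as leaves.
#' @param k Cross-validation folds (default 13).
#' @param qda_ridge Ridge fraction for the per-class covariance
#'   regularization (epsilon = `qda_ridge` x mean latent variance).
#' @param fold_seed Seed for the fold assignment.
#' @return Object of class `np_ri_result`: per-cell tibble (`cell_id`,
#'   `leaf_type`, `fold`, `ri`, `resolved_label`), `mean_ri`, node RI table
#'   and fold count.
#' @export
hierarchical_ri_classify <- function(z, labels, taxonomy, k = 13,
                                     qda_ridge = 1e-4, fold_seed = 1L) {
  stopifnot(nrow(z) == length(labels), all(is.finite(z)))
  labels <- as.character(labels)
  leaves <- taxonomy$label[taxonomy$is_leaf]
  unknown <- setdiff(unique(labels), leaves)
  if (length(unknown)) {
    stop("labels not in taxonomy: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  node_ri <- node_resolution_index(taxonomy)
  ri_of <- stats::setNames(node_ri$ri, node_ri$label)
  internal <- which(!taxonomy$is_leaf)
  ord <- internal[order(taxonomy$height[internal], taxonomy$label[internal],
                        method = "radix")]
  # label maps per merge level: level 0 = leaves, level j merges ord[1..j]
  maps <- c(list(stats::setNames(leaves, leaves)),
            lapply(seq_along(ord), function(j)
              merged_label_map(taxonomy, ord[seq_len(j)])))
  n <- nrow(z)
  folds <- withr::with_seed(fold_seed, sample(rep(seq_len(k), length.out = n)))
  ri <- rep(NA_real_, n)
  resolved <- rep(NA_character_, n)
  for (f in seq_len(k)) {
    test <- which(folds == f)
    train <- which(folds != f)
    pending <- test
    for (lvl in seq_along(maps)) {
      if (!length(pending)) break
      map <- maps[[lvl]]
      tr_lab <- map[labels[train]]
      if (length(unique(tr_lab)) == 1L) {
        pred <- rep(unique(tr_lab), length(pending))
      } else {
        fit <- qda_ridge_fit(z[train, , drop = FALSE], tr_lab,
                             ridge = qda_ridge)
        pred <- qda_ridge_predict(fit, z[pending, , drop = FALSE])
      }
      truth <- map[labels[pending]]
      hit <- pred == truth
      if (any(hit)) {
        got <- pending[hit]
        ri[got] <- unname(ri_of[truth[hit]])
        resolved[got] <- unname(truth[hit])
        pending <- pending[!hit]
      }
    }
    if (length(pending)) {  # unreachable: the root level matches everything
      ri[pending] <- 0
      resolved[pending] <- taxonomy$label[taxonomy$root]
    }
  }
  per_cell <- tibble::tibble(
    cell_id = rownames(z) %||% as.character(seq_len(n)),
    leaf_type = labels, fold = folds, ri = ri, resolved_label = resolved
  )
  structure(list(per_cell = per_cell, mean_ri = mean(ri),
                 node_ri = node_ri, k = k),
            class = "np_ri_result")
}

#' @export
print.np_ri_result <- function(x, ...) {
  cat(sprintf("<np_ri_result> %d cells, %d folds, mean RI = %.3f\n",
              nrow(x$per_cell), x$k, x$mean_ri))
  invisible(x)
}

#' Tidy per-cell resolution indices
#' @param x An `np_ri_result`.
#' @param ... Unused.
#' @export
tidy.np_ri_result <- function(x, ...) x$per_cell

#' One-row summary of a resolution-index result
#' @param x An `np_ri_result`.
#' @param ... Unused.
#' @export
glance.np_ri_result <- function(x, ...) {
  tibble::tibble(mean_ri = x$mean_ri,
                 median_ri = stats::median(x$per_cell$ri),
                 frac_leaf_correct = mean(x$per_cell$ri == 1),
                 n_cells = nrow(x$per_cell), k = x$k)
}

#' Bootstrap p-value that one group of mean-RI values exceeds another
#'
#' Resamples each group with replacement and reports the fraction of
#' bootstrap draws in which the first group's mean does not exceed the
#' second's (plus-one corrected). Degenerate single-value groups resample to
#' themselves, so with one benchmark value against n alternatives this
#' approaches the empirical exceedance probability.
#'
#' @param x,y Numeric vectors of per-run mean RI values.
#' @param n_boot Bootstrap draws (default 2000).
#' @param seed Seed.
#' @return p-value in (0, 1\].
#' @export
ri_bootstrap_p <- function(x, y, n_boot = 2000, seed = 1L) {
  withr::with_seed(seed, {
    stat <- vapply(seq_len(n_boot), function(i) {
      mean(sample(x, replace = TRUE)) <= mean(sample(y, replace = TRUE))
    }, logical(1))
    (1 + sum(stat)) / (n_boot + 1)
  })
}

#' Compare gene sets by linked-autoencoder resolution index
#'
#' Runs the full gene-subset benchmark for each candidate gene set: link a
#' small autoencoder to the frozen reference embedding `z1`, embed all cells
#' as `z2`, classify hierarchically with QDA, and summarize mean RI. Each
#' element of `sets` is either a character vector (one gene set, evaluated
#' `n_replicates` times with distinct seeds) or a list of character vectors
#' (e.g. 100 random draws, each evaluated once). The first set is the
#' benchmark; a bootstrap p-value for its mean RI exceeding each other set's
#' is reported.
#'
#' @param m An `np_expression` (CPM).
#' @param ann Annotation tibble (`cell_id`, `leaf_type`).
#' @param taxonomy An `np_taxonomy`.
#' @param sets Named list of gene sets (see above).
#' @param z1 Reference latent embedding (cells x d), row-aligned with `ann`.
#' @param linked_epochs,linked_width Linked autoencoder size (defaults 200
#'   epochs, width 50).
#' @param lambda Latent-mismatch weight (default 100).
#' @param k Cross-validation folds (default 13).
#' @param n_replicates Replicates per plain character-vector set.
#' @param transform Input preprocessing (see [preprocess_expression()]).
#' @param seed Base seed; every training and fold draw derives from it.
#' @return List of class `np_set_comparison`: `runs` (tibble `set`, `run`,
#'   `mean_ri`), `summary` (per-set mean, sd, n), `comparisons` (bootstrap
#'   p-values vs the first set), `ri_results` (first run per set).
#' @export
compare_gene_sets <- function(m, ann, taxonomy, sets, z1,
                              linked_epochs = 200, linked_width = 50,
                              lambda = 100, k = 13, n_replicates = 1,
                              transform = "log1p_standardize", seed = 1L) {
  stopifnot(length(names(sets)) == length(sets), n_replicates >= 1)
  d <- ncol(z1)
  run_one <- function(genes, run_seed) {
    X <- preprocess_expression(m, genes, transform = transform)
    X <- X[ann$cell_id, , drop = FALSE]
    spec <- autoencoder_spec(input_dim = length(genes),
                             hidden_widths = rep(linked_width, 4),
                             latent_dim = d, input_dropout_rate = 0,
                             epochs = linked_epochs, seed = run_seed)
    fit <- train_linked_autoencoder(X, z1, spec, lambda = lambda)
    hierarchical_ri_classify(fit$embedding, ann$leaf_type, taxonomy, k = k,
                             fold_seed = run_seed)
  }
  runs <- list()
  first_results <- list()
  counter <- 0L
  for (nm in names(sets)) {
    draws <- if (is.list(sets[[nm]])) sets[[nm]] else
      rep(list(sets[[nm]]), n_replicates)
    for (r in seq_along(draws)) {
      counter <- counter + 1L
      res <- run_one(draws[[r]], run_seed = seed + counter)
      if (r == 1L) first_results[[nm]] <- res
      runs[[counter]] <- tibble::tibble(set = nm, run = r,
                                        mean_ri = res$mean_ri)
    }
  }
  runs <- dplyr::bind_rows(runs)
  summary <- runs |>
    dplyr::group_by(.data$set) |>
    dplyr::summarise(sd_ri = stats::sd(.data$mean_ri),
                     mean_ri = mean(.data$mean_ri),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::select("set", "mean_ri", "sd_ri", "n")
  ref <- names(sets)[1]
  others <- setdiff(names(sets), ref)
  comparisons <- purrr::map_dfr(others, function(nm) {
    tibble::tibble(
      set = nm, reference = ref,
      p_value = ri_bootstrap_p(runs$mean_ri[runs$set == ref],
                               runs$mean_ri[runs$set == nm],
                               seed = seed)
    )
  })
  structure(list(runs = runs, summary = summary, comparisons = comparisons,
                 ri_results = first_results),
            class = "np_set_comparison")
}

#' @export
print.np_set_comparison <- function(x, ...) {
  cat("<np_set_comparison>\n")
  print(x$summary)
  if (nrow(x$comparisons)) print(x$comparisons)
  invisible(x)
}

#' @rdname compare_gene_sets
#' @param x An `np_set_comparison`.
#' @param ... Unused.
#' @export
tidy.np_set_comparison <- function(x, ...) x$runs

#' @rdname compare_gene_sets
#' @export
glance.np_set_comparison <- function(x, ...) {
  dplyr::left_join(x$summary, x$comparisons, by = "set")
}
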