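#' Rooted cell-type taxonomy with node heights
#'
#' A neurotaxonomy is a rooted tree whose leaves are transcriptomic cell
#' types, with two named strata (subclass and class) and a nonnegative height
#' per node. Leaves sit at height 0 and the root strictly above 0; heights
#' are the backbone of the classification resolution index
#' (see [node_resolution_index()]). When a tree carries no usable heights the
#' unit-merge convention is applied: a node's height is the maximum number of
#' edges down to any descendant leaf.
#'
#' @param parent Integer vector: `parent[i]` is the id of node `i`'s parent,
#'   `NA` for the root.
#' @param label Character vector of node labels (unique).
#' @param height Numeric heights, or `NULL` to apply the unit-merge
#'   convention.
#' @param strata Optional data frame with columns `leaf_type`, `subclass`,
#'   `class`; defaults are derived from tree topology (class = child of the
#'   root above each leaf, subclass = grandchild of the root, falling back to
#'   the leaf itself in shallow trees).
#' @return An object of class `np_taxonomy`.
#' @export
np_taxonomy <- function(parent, label, height = NULL, strata = NULL) {
  n <- length(parent)
  stopifnot(length(label) == n)
  if (anyDuplicated(label)) stop("duplicate node labels", call. = FALSE)
  roots <- which(is.na(parent))
  if (length(roots) != 1L) {
    stop("taxonomy must have exactly one root", call. = FALSE)
  }
  root <- roots
  children <- split(seq_len(n), factor(parent, levels = seq_len(n)))
  is_leaf <- unname(lengths(children) == 0L)
  # reachability / cycle check
  seen <- logical(n)
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (seen[v]) stop("cycle detected in taxonomy", call. = FALSE)
    seen[v] <- TRUE
    stack <- c(stack, children[[v]])
  }
  if (!all(seen)) stop("nodes unreachable from root", call. = FALSE)
  if (is.null(height)) {
    height <- rep(NA_real_, n)
    order_up <- order(!is_leaf)  # leaves first, then fill parents bottom-up
    height[is_leaf] <- 0
    # iterate until fixed point (tree depth passes)
    repeat {
      changed <- FALSE
      for (v in which(!is_leaf)) {
        ch <- children[[v]]
        if (all(!is.na(height[ch]))) {
          h <- max(height[ch]) + 1
          if (is.na(height[v]) || height[v] != h) {
            height[v] <- h
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
  }
  if (any(height[is_leaf] != 0)) stop("leaf heights must be 0", call. = FALSE)
  if (height[root] <= 0) {
    stop("root height must be positive (degenerate single-node tree?)",
         call. = FALSE)
  }
  for (v in seq_len(n)) {
    if (!is.na(parent[v]) && height[parent[v]] < height[v]) {
      stop("height must be non-decreasing towards the root", call. = FALSE)
    }
  }
  leaves <- label[is_leaf]
  if (is.null(strata)) {
    strata <- derive_strata(parent, label, root, children, is_leaf)
  } else {
    stopifnot(all(c("leaf_type", "subclass", "class") %in% names(strata)))
    if (!setequal(strata$leaf_type, leaves)) {
      stop("strata table must cover exactly the taxonomy leaves", call. = FALSE)
    }
  }
  sub_map <- stats::setNames(as.character(strata$subclass), strata$leaf_type)
  cls_map <- stats::setNames(as.character(strata$class), strata$leaf_type)
  structure(
    list(parent = parent, label = label, height = height, root = root,
         children = children, is_leaf = is_leaf,
         leaf_subclass = sub_map[leaves], leaf_class = cls_map[leaves]),
    class = "np_taxonomy"
  )
}

derive_strata <- function(parent, label, root, children, is_leaf) {
  anc_path <- function(v) {
    path <- v
    while (!is.na(parent[path[1]])) path <- c(parent[path[1]], path)
    path  # root .. v
  }
  leaves <- which(is_leaf)
  cls <- sub <- character(length(leaves))
  for (i in seq_along(leaves)) {
    p <- anc_path(leaves[i])
    cls[i] <- label[if (length(p) >= 2) p[2] else p[1]]
    sub[i] <- label[if (length(p) >= 3) p[3] else p[length(p)]]
  }
  data.frame(leaf_type = label[leaves], subclass = sub, class = cls,
             stringsAsFactors = FALSE)
}

#' @export
print.np_taxonomy <- function(x, ...) {
  cat(sprintf("<np_taxonomy> %d leaves, %d nodes, root height %g\n",
              sum(x$is_leaf), length(x$label), x$height[x$root]))
  invisible(x)
}

#' Leaf labels of a taxonomy, in tree order
#' @param taxonomy An `np_taxonomy`.
#' @return Character vector of leaf-type labels.
#' @export
taxonomy_leaves <- function(taxonomy) {
  # depth-first from the root so leaf order follows the dendrogram layout
  out <- character(0)
  stack <- taxonomy$root
  while (length(stack)) {
    v <- stack[1]
    stack <- stack[-1]
    if (taxonomy$is_leaf[v]) {
      out <- c(out, taxonomy$label[v])
    } else {
      stack <- c(taxonomy$children[[v]], stack)
    }
  }
  out
}

#' Leaves descending from each node
#' @param taxonomy An `np_taxonomy`.
#' @return Named list: node label -> character vector of descendant leaves
#'   (a leaf's own entry is itself).
#' @export
taxonomy_node_leaves <- function(taxonomy) {
  n <- length(taxonomy$label)
  memo <- vector("list", n)
  rec <- function(v) {
    if (!is.null(memo[[v]])) return(memo[[v]])
    res <- if (taxonomy$is_leaf[v]) taxonomy$label[v] else
      unlist(lapply(taxonomy$children[[v]], rec), use.names = FALSE)
    memo[[v]] <<- res
    res
  }
  rec(taxonomy$root)
  stats::setNames(memo, taxonomy$label)
}

#' Read a taxonomy from newick or nested JSON
#'
#' Newick trees are parsed with \pkg{ape}; when branch lengths are absent (or
#' `use_branch_lengths = FALSE`) the unit-merge height convention is used,
#' otherwise a node's height is its maximum path length down to a leaf.
#' Nested JSON is an object `{"label": ..., "children": [...]}`; heights are
#' recomputed by the unit-merge rule unless every node carries a `"height"`.
#'
#' @param path File path.
#' @param format `"newick-with-heights"` or `"nested-json"`.
#' @param strata Optional strata data frame (see [np_taxonomy()]).
#' @param use_branch_lengths Honour newick branch lengths when present.
#' @return An `np_taxonomy`.
#' @export
read_taxonomy <- function(path,
                          format = c("newick-with-heights", "nested-json"),
                          strata = NULL, use_branch_lengths = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "newick-with-heights") {
    phy <- tryCatch(ape::read.tree(path),
                    error = function(e) stop("malformed newick: ",
                                             conditionMessage(e), call. = FALSE))
    if (is.null(phy)) stop("malformed newick file", call. = FALSE)
    taxonomy_from_phylo(phy, strata = strata,
                        use_branch_lengths = use_branch_lengths)
  } else {
    node <- jsonlite::read_json(path, simplifyVector = FALSE)
    taxonomy_from_nested(node, strata = strata)
  }
}

#' Convert an ape phylo tree to a taxonomy
#'
#' @param phy An `ape::phylo` object.
#' @inheritParams read_taxonomy
#' @return An `np_taxonomy`.
#' @export
taxonomy_from_phylo <- function(phy, strata = NULL, use_branch_lengths = TRUE) {
  ntip <- length(phy$tip.label)
  if (ntip < 2) stop("taxonomy needs at least two leaves", call. = FALSE)
  nnode <- phy$Nnode
  n <- ntip + nnode
  parent <- rep(NA_integer_, n)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  inner_labels <- phy$node.label
  if (is.null(inner_labels) || !length(inner_labels) ||
      any(!nzchar(inner_labels))) {
    inner_labels <- paste0("node", seq_len(nnode))
  }
  label <- c(phy$tip.label, inner_labels)
  height <- NULL
  if (use_branch_lengths && !is.null(phy$edge.length)) {
    height <- rep(0, n)
    # max path length to a descendant leaf, bottom-up over edges
    ord <- order(node_depth(parent), decreasing = TRUE)
    for (v in ord) {
      p <- parent[v]
      if (!is.na(p)) {
        el <- phy$edge.length[which(phy$edge[, 2] == v)]
        height[p] <- max(height[p], height[v] + el)
      }
    }
  }
  np_taxonomy(parent, label, height = height, strata = strata)
}

node_depth <- function(parent) {
  vapply(seq_along(parent), function(v) {
    d <- 0L
    while (!is.na(parent[v])) {
      v <- parent[v]
      d <- d + 1L
    }
    d
  }, integer(1))
}

taxonomy_from_nested <- function(node, strata = NULL) {
  parent <- integer(0)
  label <- character(0)
  height <- numeric(0)
  any_missing_height <- FALSE
  add <- function(nd, par) {
    id <- length(label) + 1L
    label[id] <<- nd$label %||% paste0("node", id)
    parent[id] <<- par
    h <- nd$height
    if (is.null(h)) {
      any_missing_height <<- TRUE
      height[id] <<- NA_real_
    } else {
      height[id] <<- as.numeric(h)
    }
    for (ch in nd$children %||% list()) add(ch, id)
    id
  }
  add(node, NA_integer_)
  np_taxonomy(parent, label,
              height = if (any_missing_height) NULL else height,
              strata = strata)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a taxonomy to nested JSON (round-trip exact) or newick
#'
#' @param taxonomy An `np_taxonomy`.
#' @param path Output path.
#' @param format `"nested-json"` keeps heights and labels exactly;
#'   `"newick-with-heights"` encodes heights as branch lengths.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path,
                           format = c("nested-json", "newick-with-heights")) {
  format <- match.arg(format)
  if (format == "nested-json") {
    rec <- function(v) {
      out <- list(label = taxonomy$label[v], height = taxonomy$height[v])
      ch <- taxonomy$children[[v]]
      if (length(ch)) out$children <- lapply(ch, rec)
      out
    }
    jsonlite::write_json(rec(taxonomy$root), path, auto_unbox = TRUE,
                         digits = NA)
  } else {
    rec <- function(v) {
      ch <- taxonomy$children[[v]]
      if (!length(ch)) return(taxonomy$label[v])
      inner <- vapply(ch, function(w) {
        paste0(rec(w), ":", taxonomy$height[v] - taxonomy$height[w])
      }, character(1))
      paste0("(", paste(inner, collapse = ","), ")", taxonomy$label[v])
    }
    writeLines(paste0(rec(taxonomy$root), ";"), path)
  }
  invisible(path)
}

#' Taxonomy as a tidy node table
#'
#' @param x An `np_taxonomy`.
#' @param ... Unused.
#' @return Tibble with one row per node: `label`, `parent`, `height`,
#'   `is_leaf`, and the resolution index `ri = 1 - height / height(root)`.
#' @export
tidy.np_taxonomy <- function(x, ...) {
  tibble::tibble(
    label = x$label,
    parent = ifelse(is.na(x$parent), NA_character_, x$label[x$parent]),
    height = x$height,
    is_leaf = x$is_leaf,
    ri = 1 - x$height / x$height[x$root]
  )
}
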