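#' Read a set of trees from Newick or Nexus
#'
#' Reads a posterior sample of trees (one Newick string per line, or a Nexus
#' trees block with an optional translate table) and validates it as a tree
#' set: every member must carry the same tip-label set and unique tip labels.
#'
#' @param path Path to the tree file.
#' @param format `"auto"` (by extension/content), `"newick"` or `"nexus"`.
#' @param provenance Free-text tag stored on the result (e.g. `"posterior"`
#'   or `"mcc"`).
#' @return A `multiPhylo` object with attributes `provenance` and `source`.
#' @examples
#' tf <- tempfile(fileext = ".nwk")
#' writeLines(c("(A:1,B:1);", "(A:1.1,B:1.1);"), tf)
#' trees <- read_tree_set(tf)
#' length(trees)
#' @export
read_tree_set <- function(path, format = c("auto", "newick", "nexus"),
                          provenance = "posterior") {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("tree file not found: ", path), class = "phyniche_io_error")
  }
  if (format == "auto") {
    first <- toupper(trimws(readLines(path, n = 1L, warn = FALSE)))
    format <- if (startsWith(first, "#NEXUS")) "nexus" else "newick"
  }
  trees <- if (format == "nexus") {
    ape::read.nexus(path)
  } else {
    read_newick_lines(path)
  }
  if (inherits(trees, "phylo")) {
    trees <- structure(list(trees), class = "multiPhylo")
  }
  trees <- validate_tree_set(trees)
  attr(trees, "provenance") <- provenance
  attr(trees, "source") <- path
  trees
}

# Parse one Newick tree per non-empty line, reporting the line of a failure.
read_newick_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  trees <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    tr <- tryCatch(suppressWarnings(ape::read.tree(text = lines[keep[i]])),
                   error = function(e) NULL)
    if (is.null(tr)) {
      abort(paste0("malformed Newick on line ", keep[i], " of the tree file"),
            class = "phyniche_parse_error")
    }
    trees[[i]] <- tr
  }
  structure(trees, class = "multiPhylo")
}

#' Validate a tree set
#'
#' Checks that the collection is non-empty, that every tree has unique tip
#' labels and non-negative branch lengths, and that all trees share one tip
#' set. Trees that are not ultrametric within tolerance trigger a warning
#' (operations that require ultrametricity re-check and error).
#'
#' @param trees A `multiPhylo` or list of `phylo` objects.
#' @return The validated `multiPhylo`.
#' @export
validate_tree_set <- function(trees) {
  if (inherits(trees, "phylo")) trees <- structure(list(trees), class = "multiPhylo")
  if (length(trees) == 0L) {
    abort("tree set is empty", class = "phyniche_validation_error")
  }
  ref <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    if (anyDuplicated(tr$tip.label)) {
      abort(paste0("duplicate tip labels in tree ", i),
            class = "phyniche_validation_error")
    }
    if (!is.null(tr$edge.length) && any(tr$edge.length < 0)) {
      abort(paste0("negative branch lengths in tree ", i),
            class = "phyniche_validation_error")
    }
    if (!identical(sort(tr$tip.label), ref)) {
      abort("trees in a set must share an identical tip-label set",
            class = "phyniche_validation_error")
    }
  }
  if (!inherits(trees, "multiPhylo")) class(trees) <- "multiPhylo"
  trees
}

#' Write a tree set as Newick
#'
#' One tree per line, branch lengths at 9 significant digits.
#'
#' @param trees A `phylo` or `multiPhylo`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree_set <- function(trees, path) {
  if (inherits(trees, "phylo")) trees <- structure(list(trees), class = "multiPhylo")
  txt <- vapply(trees, function(tr) ape::write.tree(tr, digits = 9), character(1))
  writeLines(txt, path)
  invisible(path)
}

#' Root-to-tip depths and ultrametricity
#'
#' @param tree A `phylo`.
#' @param tol Relative tolerance as a fraction of tree height.
#' @return `tree_height()`: the maximum root-to-tip depth.
#'   `is_ultrametric()`: logical.
#' @export
tree_height <- function(tree) {
  max(ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))])
}

#' @rdname tree_height
#' @export
is_ultrametric <- function(tree, tol = 1e-6) {
  d <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  h <- max(d)
  if (h <= 0) return(TRUE)
  (max(d) - min(d)) <= tol * h
}

#' Cophenetic (patristic) distance matrix
#'
#' Symmetric tip-by-tip matrix of path-length distances: the sum of branch
#' lengths along the path connecting two tips.
#'
#' @param tree A `phylo` with branch lengths.
#' @return A symmetric numeric matrix with zero diagonal, tip labels as
#'   dimnames.
#' @export
cophenetic_matrix <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) {
    abort("tree has no branch lengths", class = "phyniche_validation_error")
  }
  stats::cophenetic(tree)
}

#' Pagel's lambda branch-length transform
#'
#' Multiplies every internal branch by `lambda` and stretches each pendant
#' (tip) branch so that every root-to-tip depth is preserved. `lambda = 1`
#' returns the tree unchanged; `lambda = 0` collapses all internal branches,
#' i.e. a star phylogeny.
#'
#' @param tree An ultrametric `phylo`.
#' @param lambda Value in \[0, 1\].
#' @return The transformed `phylo`.
#' @export
lambda_transform <- function(tree, lambda) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 || lambda > 1) {
    abort("lambda must be a single value in [0, 1]",
          class = "phyniche_validation_error")
  }
  if (!is_ultrametric(tree)) {
    abort("lambda_transform requires an ultrametric tree (depth preservation is undefined otherwise)",
          class = "phyniche_validation_error")
  }
  ntip <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)
  h <- max(depth[seq_len(ntip)])
  parent <- tree$edge[, 1]
  child <- tree$edge[, 2]
  is_tip_edge <- child <= ntip
  new_len <- tree$edge.length
  new_len[!is_tip_edge] <- lambda * new_len[!is_tip_edge]
  # pendant edge: tip depth h minus the (scaled) depth of its parent
  new_len[is_tip_edge] <- h - lambda * depth[parent[is_tip_edge]]
  out <- tree
  out$edge.length <- new_len
  out
}

#' Clade anchors: node identity across topologically varying trees
#'
#' A node of interest is identified as the most recent common ancestor (MRCA)
#' of a fixed reference tip subset, so that "the same" node can be located in
#' every tree of a posterior sample even when topologies differ. Whether the
#' anchor set is exactly monophyletic in a given tree is recorded separately.
#'
#' @param tips Character vector of at least two tip labels.
#' @param label Optional anchor name (defaults to a digest of the tips).
#' @return A `node_anchor` object.
#' @export
node_anchor <- function(tips, label = NULL) {
  tips <- unique(as.character(tips))
  if (length(tips) < 2L) {
    abort("an anchor needs at least two tips", class = "phyniche_validation_error")
  }
  label <- label %||% paste(sort(tips)[1:2], collapse = "+")
  structure(list(tips = tips, label = label), class = "node_anchor")
}

#' @export
print.node_anchor <- function(x, ...) {
  cat("<node_anchor>", x$label, ":", length(x$tips), "tips\n")
  invisible(x)
}

#' Resolve anchors on a tree
#'
#' @param tree A `phylo`.
#' @param anchors A `node_anchor` or list of them.
#' @return A tibble with one row per anchor: `anchor`, `node` (ape node id),
#'   `monophyletic` (descendant tip set equals the anchor set exactly), and
#'   `n_descendants`.
#' @export
resolve_anchors <- function(tree, anchors) {
  if (inherits(anchors, "node_anchor")) anchors <- list(anchors)
  purrr::map_dfr(anchors, function(a) {
    missing <- setdiff(a$tips, tree$tip.label)
    if (length(missing) > 0) {
      abort(paste0("anchor '", a$label, "' refers to tips absent from the tree: ",
                   paste(missing, collapse = ", ")),
            class = "phyniche_validation_error")
    }
    node <- ape::getMRCA(tree, a$tips)
    desc <- clade_tips(tree, node)
    tibble(anchor = a$label, node = node,
           monophyletic = setequal(desc, a$tips),
           n_descendants = length(desc))
  })
}

# Tip labels descending from a node (the node itself if it is a tip).
clade_tips <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(tree$tip.label[node])
  tree$tip.label[unlist(ape::prop.part(tree)[node - ntip])]
}
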