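# Labeled rooted trees: a thin layer over ape's phylo that exposes internal
# node labels (integers, by convention assigned by depth) and the ancestry
# queries the gene-dating analyses need.

#' Read a rooted Newick tree with labeled internal nodes
#'
#' @param path Newick file; internal nodes must carry unique labels.
#' @return an object of class `labeled_tree` wrapping an `ape::phylo`.
#' @export
read_labeled_tree <- function(path) {
  labeled_tree(ape::read.tree(path))
}

#' Wrap an ape phylogeny as a labeled tree
#'
#' @param phy an `ape::phylo`, rooted, with unique internal node labels.
#' @return a `labeled_tree`.
#' @export
labeled_tree <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  if (is.null(phy$node.label) || any(!nzchar(phy$node.label))) {
    stop("internal node labels are required")
  }
  if (anyDuplicated(phy$node.label)) stop("internal node labels must be unique")
  structure(list(phylo = phy), class = "labeled_tree")
}

#' @export
print.labeled_tree <- function(x, ...) {
  cat("<labeled_tree> ", length(x$phylo$tip.label), " leaves, internal nodes: ",
      paste(x$phylo$node.label, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' The bundled pandoravirus phylogeny
#'
#' Ten-strain rooted topology with internal nodes labeled 1-9 by depth:
#' node 1 is the root, node 2 the clade-A root, node 9 the most recent
#' common ancestor of p. celtis and p. quercus. Branch lengths are
#' illustrative (substitutions/site); the labeled topology is what the
#' dating analyses consume.
#'
#' @return a `labeled_tree`.
#' @export
pandoravirus_tree <- function() {
  read_labeled_tree(system.file("extdata", "pandoravirus_tree.nwk",
                                package = "microevo"))
}

#' Leaf names of a labeled tree
#' @param tree a `labeled_tree`.
#' @return character vector of leaf names.
#' @export
tree_leaves <- function(tree) tree$phylo$tip.label

# internal: ape node number for an internal label
node_number <- function(tree, label) {
  phy <- tree$phylo
  i <- match(as.character(label), phy$node.label)
  if (is.na(i)) stop("unknown internal node label: ", label)
  length(phy$tip.label) + i
}

# internal: internal label for an ape node number
node_label_of <- function(tree, number) {
  phy <- tree$phylo
  phy$node.label[number - length(phy$tip.label)]
}

#' Leaves descending from a labeled internal node
#'
#' @param tree a `labeled_tree`.
#' @param label internal node label.
#' @return character vector of leaf names below that node.
#' @export
node_leaves <- function(tree, label) {
  phy <- tree$phylo
  desc <- descendant_tips(phy, node_number(tree, label))
  phy$tip.label[desc]
}

# tip numbers below a node, by edge traversal
descendant_tips <- function(phy, node) {
  ntip <- length(phy$tip.label)
  if (node <= ntip) return(node)
  kids <- phy$edge[phy$edge[, 1] == node, 2]
  unlist(lapply(kids, function(k) descendant_tips(phy, k)))
}

#' Label of the most recent common ancestor of a leaf set
#'
#' @param tree a `labeled_tree`.
#' @param leaves character vector of leaf names (length >= 1). A single
#'   leaf has no internal MRCA and yields `NA`.
#' @return internal node label (character) or `NA_character_`.
#' @export
mrca_label <- function(tree, leaves) {
  phy <- tree$phylo
  missing <- setdiff(leaves, phy$tip.label)
  if (length(missing) > 0L) {
    stop("leaves not in tree: ", paste(missing, collapse = ", "))
  }
  leaves <- unique(leaves)
  if (length(leaves) < 2L) return(NA_character_)
  node_label_of(tree, ape::getMRCA(phy, leaves))
}

#' Is node `a` an ancestor of (or equal to) node `b`?
#'
#' Both arguments are internal node labels or leaf names.
#' @param tree a `labeled_tree`.
#' @param a,b internal node label or leaf name.
#' @return logical.
#' @export
is_ancestor <- function(tree, a, b) {
  phy <- tree$phylo
  num <- function(x) {
    i <- match(x, phy$tip.label)
    if (!is.na(i)) return(i)
    node_number(tree, x)
  }
  na <- num(a); nb <- num(b)
  root <- length(phy$tip.label) + 1L
  parent <- function(n) phy$edge[phy$edge[, 2] == n, 1]
  n <- nb
  repeat {
    if (n == na) return(TRUE)
    if (n == root) return(FALSE)
    n <- parent(n)
  }
}

# internal: child-node label of every branch as (parent_label -> child) edge
# table; leaves appear as child with their tip name.
tree_edge_table <- function(tree) {
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  lab <- function(n) {
    ifelse(n <= ntip, phy$tip.label[n], phy$node.label[n - ntip])
  }
  tibble::tibble(
    parent = vapply(phy$edge[, 1], lab, character(1)),
    child = vapply(phy$edge[, 2], lab, character(1)),
    length = phy$edge.length %||% rep(1, nrow(phy$edge)),
    child_is_leaf = phy$edge[, 2] <= ntip
  )
}
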