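#' Read a rooted binary tree
#'
#' Parses a newick file and validates that the tree is rooted, strictly
#' binary and has named tips. Branch lengths, if present, are kept but node
#' ages remain unset until dating (or simulation) assigns them.
#'
#' @param path newick file, or a newick string ending in `;`.
#' @return an `ape` `phylo` object.
#' @export
read_tree <- function(path) {
  phy <- if (grepl(";", path, fixed = TRUE)) ape::read.tree(text = path)
         else ape::read.tree(path)
  if (is.null(phy)) stop("could not parse newick input", call. = FALSE)
  validate_tree(phy)
  phy
}

#' @rdname read_tree
#' @param tree `phylo` or [dated_tree()] to serialize.
#' @export
write_tree <- function(tree, path) {
  if (inherits(tree, "dated_tree")) tree <- dated_to_phylo(tree)
  ape::write.tree(tree, file = path)
  invisible(path)
}

validate_tree <- function(phy) {
  if (!inherits(phy, "phylo")) stop("not a phylo object", call. = FALSE)
  if (is.null(phy$tip.label) || anyDuplicated(phy$tip.label))
    stop("tree tips must carry unique names", call. = FALSE)
  tab <- tabulate(phy$edge[, 1], nbins = ape::Ntip(phy) + phy$Nnode)
  poly <- which(tab > 2L)
  if (length(poly))
    stop("tree is not binary: node ", poly[1], " (",
         paste(node_label(phy, poly[1]), collapse = ""),
         ") has ", tab[poly[1]], " children", call. = FALSE)
  root <- ape::Ntip(phy) + 1L
  if (tab[root] != 2L)
    stop("tree is not rooted: root node ", root, " has ", tab[root],
         " children", call. = FALSE)
  invisible(phy)
}

node_label <- function(phy, node) {
  nt <- ape::Ntip(phy)
  if (node <= nt) phy$tip.label[node]
  else if (!is.null(phy$node.label) && nzchar(phy$node.label[node - nt]))
    phy$node.label[node - nt]
  else paste0("node", node)
}

#' Most recent common ancestor of a taxon pair
#'
#' Calibrations are attached to internal nodes designated by a pair of
#' descendant taxa; a pair naming a single tip is rejected.
#'
#' @param tree `phylo` or [dated_tree()].
#' @param taxon_pair character vector of two tip names.
#' @return internal node number (ape numbering).
#' @export
resolve_mrca <- function(tree, taxon_pair) {
  phy <- if (inherits(tree, "dated_tree")) tree$phy else tree
  taxon_pair <- as.character(taxon_pair)
  missing <- setdiff(taxon_pair, phy$tip.label)
  if (length(missing))
    stop("unknown taxa: ", paste(missing, collapse = ", "), call. = FALSE)
  if (length(unique(taxon_pair)) < 2L)
    stop("MRCA of a single taxon is the tip itself; calibrations must name ",
         "two distinct taxa", call. = FALSE)
  ape::getMRCA(phy, taxon_pair)
}

#' A rooted time-tree: topology plus node ages
#'
#' Ages are in Ma before present, indexed by ape node number (tips
#' `1..Ntip`, internals `Ntip+1..`). Tips must sit at 0 and every internal
#' node must be strictly older than each of its children.
#'
#' @param phy rooted binary `phylo` (topology only; edge lengths ignored).
#' @param ages numeric vector of length `Ntip + Nnode`.
#' @return object of class `dated_tree` with elements `phy` and `ages`.
#' @export
dated_tree <- function(phy, ages) {
  validate_tree(phy)
  n <- ape::Ntip(phy) + phy$Nnode
  if (length(ages) != n) stop("ages must have one entry per node", call. = FALSE)
  if (any(abs(ages[seq_len(ape::Ntip(phy))]) > 1e-12))
    stop("tip ages must all be 0", call. = FALSE)
  pa <- ages[phy$edge[, 1]]
  ca <- ages[phy$edge[, 2]]
  if (any(pa <= ca))
    stop("node ages must strictly decrease from root to tips", call. = FALSE)
  structure(list(phy = phy, ages = as.numeric(ages)), class = "dated_tree")
}

#' @export
print.dated_tree <- function(x, ...) {
  cat(sprintf("Dated tree: %d tips, root age %.4g Ma\n",
              ape::Ntip(x$phy), root_age(x)))
  invisible(x)
}

root_age <- function(tree) tree$ages[ape::Ntip(tree$phy) + 1L]

#' Convert an ultrametric phylo (branch lengths in Ma) to a dated tree
#' @param phy ultrametric `phylo` with edge lengths in time units.
#' @export
as_dated_tree <- function(phy) {
  validate_tree(phy)
  if (is.null(phy$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  depth <- ape::node.depth.edgelength(phy)
  ages <- max(depth) - depth
  ages[seq_len(ape::Ntip(phy))] <- 0
  dated_tree(phy, ages)
}

#' Dated tree back to phylo with branch lengths in Ma
#' @param tree a [dated_tree()].
#' @export
dated_to_phylo <- function(tree) {
  phy <- tree$phy
  phy$edge.length <- tree$ages[phy$edge[, 1]] - tree$ages[phy$edge[, 2]]
  phy
}

# children of each node as a list indexed by node number
child_list <- function(phy) {
  n <- ape::Ntip(phy) + phy$Nnode
  split(phy$edge[, 2], factor(phy$edge[, 1], levels = seq_len(n)))
}

# internal nodes in postorder (children before parents)
postorder_nodes <- function(phy) {
  unique(phy$edge[ape::postorder(phy), 1])
}
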