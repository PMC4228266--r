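# Internal helpers around ape "phylo" trees. Conventions: node ids are ape
# ids (tips 1..Ntip, root Ntip+1); internal nodes may carry labels in
# tree$node.label, and those labels are accepted anywhere a node id is.

n_tips <- function(tree) length(tree$tip.label)

root_id <- function(tree) n_tips(tree) + 1L

# resolve a node given as id or internal-node label
resolve_node <- function(tree, node) {
  if (is.numeric(node)) {
    node <- as.integer(node)
    if (node < 1L || node > n_tips(tree) + tree$Nnode)
      stop("node id out of range: ", node, call. = FALSE)
    return(node)
  }
  hit <- match(node, tree$node.label)
  if (!is.na(hit)) return(n_tips(tree) + hit)
  hit <- match(node, tree$tip.label)
  if (!is.na(hit)) return(hit)
  if (grepl("^node[0-9]+$", node))     # fabricated label for unnamed nodes
    return(resolve_node(tree, as.integer(sub("^node", "", node))))
  stop("unknown node: ", node, call. = FALSE)
}

node_label <- function(tree, id) {
  nt <- n_tips(tree)
  if (id <= nt) return(tree$tip.label[id])
  if (!is.null(tree$node.label) && !is.na(tree$node.label[id - nt]) &&
      nzchar(tree$node.label[id - nt]))
    return(tree$node.label[id - nt])
  paste0("node", id)
}

internal_ids <- function(tree) root_id(tree) + seq_len(tree$Nnode) - 1L

# postorder edge matrix (children before parents) with branch lengths
postorder_edges <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  list(edge = tr$edge, length = tr$edge.length)
}

# check leaf-name agreement between tree and a set of names
check_taxa <- function(tree, taxa) {
  missing <- setdiff(tree$tip.label, taxa)
  extra <- setdiff(taxa, tree$tip.label)
  if (length(missing) || length(extra)) {
    stop("taxa mismatch between tree and data",
         if (length(missing)) paste0("; absent from data: ",
                                     paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; absent from tree: ",
                                   paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Root an unrooted tree with an outgroup
#'
#' Places the root on the branch separating a monophyletic outgroup from the
#' remaining taxa, splitting that branch's length equally between the two
#' root-adjacent edges.
#'
#' @param tree an ape `phylo` tree (unrooted or rooted).
#' @param outgroup character vector of outgroup taxon names.
#' @return rooted `phylo` tree.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  outgroup <- as.character(outgroup)
  bad <- setdiff(outgroup, tree$tip.label)
  if (length(bad))
    stop("outgroup taxa not in tree: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (length(outgroup) >= length(tree$tip.label))
    stop("outgroup cannot contain all taxa", call. = FALSE)
  ut <- ape::unroot(tree)
  if (length(outgroup) > 1L &&
      !ape::is.monophyletic(ut, outgroup, reroot = TRUE)) {
    stop("outgroup is not monophyletic on the unrooted tree: ",
         paste(outgroup, collapse = ", "), call. = FALSE)
  }
  rt <- ape::root(ut, outgroup = outgroup, resolve.root = TRUE,
                  edgelabel = TRUE)
  # split the divided branch equally between the two root-adjacent edges
  ridx <- which(rt$edge[, 1] == root_id(rt))
  if (length(ridx) == 2L) {
    tot <- sum(rt$edge.length[ridx])
    rt$edge.length[ridx] <- tot / 2
  }
  rt
}
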