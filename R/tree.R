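#' Read a Newick tree with branch lengths
#'
#' Thin wrapper over [ape::read.tree()] that enforces what the comparative
#' analyses need: unique tip labels and branch lengths on every edge.
#'
#' @param x a Newick string or a path to a Newick file.
#' @param normalize_names fold tip labels with [normalize_species()]?
#' @return an `ape` `phylo` object.
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' ape::Ntip(tr)
read_newick <- function(x, normalize_names = FALSE) {
  tree <- if (length(x) == 1L && grepl("\\(", x))
    tryCatch(suppressWarnings(ape::read.tree(text = x)),
             error = function(e) NULL)
  else
    tryCatch(suppressWarnings(ape::read.tree(x)), error = function(e) NULL)
  if (is.null(tree)) stopf("could not parse Newick input")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stopf("tree has missing branch lengths")
  if (anyDuplicated(tree$tip.label))
    stopf("duplicated tip labels: %s",
          paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                collapse = ", "))
  if (normalize_names) tree$tip.label <- normalize_species(tree$tip.label)
  tree
}

#' Prune a phylogeny to the species shared with a dataset
#'
#' Restricts the tree to the tips present in `species` (matched after
#' [normalize_species()] folding), collapsing unary nodes and summing their
#' branch lengths so all patristic distances among retained tips are
#' preserved.  Species dropped on either side are reported as attributes.
#'
#' @param tree a `phylo` object.
#' @param species character vector of species to keep.
#' @return the pruned `phylo`, with attributes `dropped_tips` (tips absent
#'   from `species`) and `dropped_species` (requested species absent from
#'   the tree).
#' @export
prune_to_overlap <- function(tree, species) {
  key_tree <- normalize_species(tree$tip.label)
  key_sp <- normalize_species(species)
  keep <- tree$tip.label[key_tree %in% key_sp]
  if (length(keep) == 0L)
    stopf("no overlap between tree tips and the %d supplied species",
          length(species))
  dropped_tips <- setdiff(tree$tip.label, keep)
  dropped_species <- species[!(key_sp %in% key_tree)]
  out <- if (length(dropped_tips)) ape::keep.tip(tree, keep) else tree
  attr(out, "dropped_tips") <- dropped_tips
  attr(out, "dropped_species") <- dropped_species
  out
}

#' Brownian-motion covariance matrix of a rooted tree
#'
#' Under Brownian trait evolution the covariance between two tips is the
#' branch length they share on the path from the root: `C[i, j]` is the
#' depth of their most recent common ancestor and `C[i, i]` the root-to-tip
#' distance.  This is the error covariance (up to a rate) used by PGLS.
#'
#' @param tree a rooted `phylo` with nonnegative branch lengths.
#' @return symmetric numeric matrix with tip labels as dimnames.
#' @export
bm_covariance <- function(tree) {
  if (!inherits(tree, "phylo")) stopf("'tree' must be a phylo object")
  if (is.null(tree$edge.length)) stopf("tree has no branch lengths")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stopf("branch lengths must be finite and nonnegative")
  n <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)  # root-to-node distances
  if (n == 1L) {
    C <- matrix(depth[1L], 1L, 1L,
                dimnames = list(tree$tip.label, tree$tip.label))
    return(C)
  }
  anc <- ape::mrca(tree)                      # tip x tip MRCA node numbers
  C <- matrix(depth[anc], n, n,
              dimnames = list(tree$tip.label, tree$tip.label))
  diag(C) <- depth[seq_len(n)]
  C
}
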