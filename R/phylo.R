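#' Read a rooted time-calibrated tree from a Newick file
#'
#' Reads a Newick tree (trailing semicolon required, branch lengths required
#' on all edges except optionally the root edge) and validates it for use in
#' phylogenetic comparative analyses: tip labels must be unique and nonempty,
#' branch lengths nonnegative, and the tree rooted. Non-ultrametric trees are
#' accepted with a warning, so that trees with branch lengths in substitutions
#' per site can be used for robustness checks.
#'
#' @param path Path to a Newick file.
#' @return An object of class \code{"phylo"} (from \pkg{ape}) with an added
#'   attribute \code{ultrametric} (logical).
#' @seealso [tree_vcv()], [prune_tree()]
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  if (!grepl(";", txt, fixed = TRUE)) {
    stop("Newick format error: no trailing semicolon in ", path)
  }
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("Newick parse failure: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse failure: could not read ", path)
  validate_tree(tree)
}

#' @keywords internal
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylogenetic tree")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (length(tree$edge.length) < nrow(tree$edge)) {
    stop("missing branch lengths on some edges")
  }
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0)) {
    stop("branch lengths must be finite and nonnegative")
  }
  if (any(!nzchar(tree$tip.label))) stop("empty tip labels")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  # Newick input is interpreted as rooted at its outermost node; a basal
  # polytomy (e.g. a star tree) is accepted as a rooted multifurcation
  ultra <- is_ultrametric_tree(tree)
  if (!ultra) {
    warning("tree is not ultrametric; root-to-tip depths differ")
  }
  attr(tree, "ultrametric") <- ultra
  tree
}

#' Test whether a tree is ultrametric
#'
#' A tree is considered ultrametric when all root-to-tip path lengths agree
#' within a relative tolerance.
#'
#' @param tree A \code{"phylo"} object with branch lengths.
#' @param tol Relative tolerance on root-to-tip depths (default \code{1e-6}).
#' @return Logical scalar.
#' @export
is_ultrametric_tree <- function(tree, tol = 1e-6) {
  d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  mx <- max(d)
  if (mx == 0) return(TRUE)
  (max(d) - min(d)) / mx <= tol
}

#' Tree height (maximum root-to-tip depth)
#' @param tree A \code{"phylo"} object.
#' @return Numeric scalar, in the tree's branch-length units.
#' @export
tree_height <- function(tree) {
  max(ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)])
}

#' Phylogenetic (species) covariance matrix
#'
#' Under Brownian Motion with branch lengths proportional to time, the
#' covariance of trait values between species i and j is proportional to the
#' depth of their most recent common ancestor measured from the root:
#' \code{C[i, j] = depth(MRCA(i, j))}, with \code{C[i, i]} the root-to-tip
#' depth of tip i. This matrix is symmetric positive semidefinite and carries
#' all of the tree's imprint that the model uses.
#'
#' @param tree A rooted \code{"phylo"} object with branch lengths.
#' @return An n x n numeric matrix with tip labels as dimnames, rows/columns
#'   in tip-label order.
#' @export
tree_vcv <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylogenetic tree")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  C <- ape::vcv(tree)
  # a retained root edge (e.g. after pruning) is history shared by all tips
  re <- tree$root.edge
  if (!is.null(re) && length(re) == 1 && is.finite(re) && re > 0) C <- C + re
  C[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Prune a tree to a subset of tips
#'
#' Returns the induced subtree on \code{keep}; internal nodes of degree two
#' are collapsed with their branch lengths summed, so path lengths between
#' retained tips are preserved. If the most recent common ancestor of the
#' kept tips lies below the original root, the stem is retained as the root
#' edge, so [tree_vcv()] of the pruned tree is exactly the corresponding
#' submatrix of the full tree's covariance.
#'
#' @param tree A \code{"phylo"} object.
#' @param keep Character vector of tip labels to retain (at least 2).
#' @return A \code{"phylo"} object (possibly with a \code{root.edge}).
#' @export
prune_tree <- function(tree, keep) {
  keep <- unique(as.character(keep))
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown) > 0) {
    stop("unknown tip labels: ", paste(unknown, collapse = ", "))
  }
  if (length(keep) < 2) stop("at least 2 tips must be kept")
  drop <- setdiff(tree$tip.label, keep)
  if (length(drop) == 0) return(tree)
  pruned <- ape::keep.tip(tree, keep)
  # depth of the kept tips' MRCA below the original root becomes the stem
  mrca <- ape::getMRCA(tree, keep)
  stem <- ape::node.depth.edgelength(tree)[mrca]
  if (!is.null(tree$root.edge) && is.finite(tree$root.edge)) {
    stem <- stem + tree$root.edge
  }
  if (is.finite(stem) && stem > 0) pruned$root.edge <- stem
  pruned
}

#' Write a species covariance matrix as TSV
#'
#' @param C Covariance matrix from [tree_vcv()].
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_vcv_tsv <- function(C, path) {
  df <- data.frame(species = rownames(C), C, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
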