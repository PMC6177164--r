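#' Parse a Newick string into a phylogeny
#'
#' Thin validating wrapper around [ape::read.tree()]. The standard Newick
#' dialect is accepted (labels, colon-separated branch lengths, nested
#' parentheses, terminal semicolon). NHX-style square-bracket comments are
#' stripped with a warning. Tip labels are preserved byte-for-byte.
#'
#' @param text A single Newick string ending in `;`.
#' @return An object of class `phylo`.
#' @examples
#' tr <- parseNewick("((A:1,B:1):1,C:2);")
#' tr$tip.label
#' @export
parseNewick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (grepl("\\[", text)) {
    warning("square-bracket (NHX) comments stripped")
    text <- gsub("\\[[^]]*\\]", "", text)
  }
  .checkNewickSyntax(text)
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("malformed Newick string")
  validatePhylogeny(tr)
  tr
}

# Locate gross syntax errors before handing off to ape, so the error
# message can name the offending character position.
.checkNewickSyntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("malformed Newick: unmatched ')' at position %d", i))
    }
  }
  if (depth > 0L)
    stop(sprintf("malformed Newick: %d unclosed '(' at end of string", depth))
  if (!grepl(";[[:space:]]*$", text))
    stop(sprintf("malformed Newick: missing terminal ';' at position %d",
                 nchar(text)))
  invisible(TRUE)
}

#' Validate a phylogeny
#'
#' Checks the structural invariants assumed throughout the package: unique
#' non-empty tip labels, a single root, non-negative branch lengths with at
#' least one positive length.
#'
#' @param tree A `phylo` object.
#' @return The tree, invisibly, if valid; otherwise an error is thrown.
#' @export
validatePhylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  tl <- tree$tip.label
  if (anyDuplicated(tl))
    stop("duplicate tip labels: ",
         paste(unique(tl[duplicated(tl)]), collapse = ", "))
  if (any(!nzchar(tl))) stop("empty tip labels are not allowed")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (!any(tree$edge.length > 0)) stop("all branch lengths are zero")
  # single root: exactly one node that never appears as a child
  children <- tree$edge[, 2]
  parents <- unique(tree$edge[, 1])
  roots <- setdiff(parents, children)
  if (length(roots) != 1L) stop("tree must have exactly one root")
  invisible(tree)
}

#' Serialize a phylogeny to Newick
#'
#' @param tree A valid `phylo` object.
#' @return A single Newick string (terminal semicolon included). Re-parsing
#'   it yields a tree with identical topology and branch lengths.
#' @export
writeNewick <- function(tree) {
  validatePhylogeny(tree)
  ape::write.tree(tree)
}

#' Read a chronogram from a Newick file
#'
#' Reads the file, validates the tree, and checks ultrametricity at a
#' relative tolerance. The bundled 32-species chronogram has branch lengths
#' in millions of years; all regression statistics downstream are invariant
#' to the unit.
#'
#' @param path Path to a Newick file. Defaults to the bundled chronogram.
#' @param tol Relative ultrametricity tolerance (fraction of maximum
#'   root-to-tip depth). Default `1e-3`.
#' @return A `phylo` object.
#' @export
readChronogram <- function(path = system.file("extdata", "chronogram_32sp.nwk",
                                              package = "altripgls"),
                           tol = 1e-3) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  tr <- parseNewick(txt)
  u <- isUltrametric(tr, tol = tol)
  if (!u$ultrametric)
    stop(sprintf("tree in '%s' is not ultrametric (max relative deviation %.3g)",
                 path, u$max_deviation / u$max_depth))
  if (any(tr$edge.length[tr$edge[, 2] <= ape::Ntip(tr)] == 0))
    warning("tree has zero-length terminal branches")
  tr
}

# root-to-tip depth of every node (tips first, then internal), by
# preorder accumulation over the edge matrix
.nodeDepths <- function(tree) {
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  depth <- numeric(n + m)
  root <- n + 1L
  ord <- rev(ape::postorder(tree))  # parent edges before child edges
  for (k in ord) {
    p <- tree$edge[k, 1]
    ch <- tree$edge[k, 2]
    depth[ch] <- depth[p] + tree$edge.length[k]
  }
  depth
}

#' Test ultrametricity
#'
#' A tree is treated as ultrametric when all root-to-tip path sums agree
#' within `tol` times the maximum depth.
#'
#' @param tree A valid `phylo` object.
#' @param tol Relative tolerance.
#' @return A list with elements `ultrametric` (logical), `max_deviation`
#'   (largest pairwise depth discrepancy, in branch-length units) and
#'   `max_depth`.
#' @export
isUltrametric <- function(tree, tol = 1e-3) {
  validatePhylogeny(tree)
  d <- .nodeDepths(tree)[seq_len(ape::Ntip(tree))]
  dev <- max(d) - min(d)
  list(ultrametric = dev <= tol * max(d),
       max_deviation = dev,
       max_depth = max(d))
}

#' Prune a phylogeny to a set of tips
#'
#' Retains exactly the requested tips, collapsing degree-2 internal nodes
#' (their branch lengths are summed), so root-to-tip depths of the retained
#' tips are unchanged.
#'
#' @param tree A valid `phylo` object.
#' @param keep Character vector of tip labels to retain (at least 2).
#' @return The pruned `phylo` object.
#' @export
pruneTo <- function(tree, keep) {
  validatePhylogeny(tree)
  keep <- unique(as.character(keep))
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing))
    stop("tip labels not in tree: ", paste(missing, collapse = ", "))
  if (length(keep) < 2L) stop("need at least 2 tips to keep")
  ape::keep.tip(tree, keep)
}

#' Phylogenetic variance-covariance matrix
#'
#' Builds the Brownian-motion trait covariance matrix implied by a tree:
#' `C[i, j]` is the root-to-tip depth of the most recent common ancestor of
#' tips i and j, and `C[i, i]` the depth of tip i. Computed in-package by
#' accumulating each edge's length over all tip pairs descending from it;
#' polytomies are handled natively.
#'
#' @param tree A valid `phylo` object with at least 2 tips.
#' @param order Optional character vector giving the species order of the
#'   rows/columns; defaults to the tree's tip-label order.
#' @return An n x n numeric matrix with `dimnames` set to the species order.
#' @examples
#' phyloVCV(parseNewick("((A:1,B:1):1,C:2);"))
#' @export
phyloVCV <- function(tree, order = NULL) {
  validatePhylogeny(tree)
  n <- ape::Ntip(tree)
  if (n < 2L) stop("need at least 2 tips for a covariance matrix")
  # tip sets below every node, postorder so children precede parents
  tipsBelow <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) tipsBelow[[i]] <- i
  for (k in ape::postorder(tree)) {
    p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
    tipsBelow[[p]] <- c(tipsBelow[[p]], tipsBelow[[ch]])
  }
  C <- matrix(0, n, n)
  for (k in seq_len(nrow(tree$edge))) {
    idx <- tipsBelow[[tree$edge[k, 2]]]
    C[idx, idx] <- C[idx, idx] + tree$edge.length[k]
  }
  dimnames(C) <- list(tree$tip.label, tree$tip.label)
  if (!is.null(order)) {
    missing <- setdiff(order, tree$tip.label)
    if (length(missing))
      stop("order contains labels not in tree: ",
           paste(missing, collapse = ", "))
    C <- C[order, order, drop = FALSE]
  }
  C
}

#' Pagel's lambda transform of a covariance matrix
#'
#' Multiplies the off-diagonal entries of a phylogenetic covariance matrix
#' by `lambda`, leaving the diagonal untouched. `lambda = 1` returns the
#' input; `lambda = 0` the diagonal matrix of tip depths (phylogenetic
#' independence).
#'
#' @param C Symmetric phylogenetic covariance matrix.
#' @param lambda Scalar in `[0, 1]`.
#' @return The transformed matrix.
#' @export
lambdaTransform <- function(C, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1)
    stop("lambda must be a single value in [0, 1]")
  .checkVCV(C)
  V <- C * lambda
  diag(V) <- diag(C)
  V
}

.checkVCV <- function(C) {
  if (!is.matrix(C) || nrow(C) != ncol(C))
    stop("C must be a square matrix")
  if (max(abs(C - t(C))) > 1e-10 * max(1, max(abs(C))))
    stop("C must be symmetric")
  invisible(C)
}
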