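#' Ultrametric clock trees
#'
#' A `clock_tree` wraps an [ape::phylo] object together with a vector of node
#' ages measured from the present (tips at age 0), in units of expected
#' substitutions per site.  It is the unit of input for GMYC fitting and the
#' form in which simulated gene trees are returned.
#'
#' @param phy A rooted, binary `phylo` object with branch lengths.
#' @param tolerance Maximum allowed relative spread of root-to-tip path
#'   lengths, `(max - min) / max`.  Trees within tolerance are snapped to
#'   ultrametric by averaging root-to-tip paths; trees beyond it are rejected.
#' @return An object of class `clock_tree`: a list with elements `phylo`
#'   (branch lengths recomputed from the snapped ages) and `age` (numeric,
#'   length `Ntip + Nnode`, indexed by ape node id; tips are exactly 0).
#' @export
clock_tree <- function(phy, tolerance = 1e-6) {
  if (!inherits(phy, "phylo")) stop("'phy' must be a phylo object")
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  ntip <- length(phy$tip.label)
  if (ntip < 2L) stop("a clock_tree needs at least 2 tips")
  if (anyDuplicated(phy$tip.label)) stop("duplicate tip labels")
  # explicit child counts: ape's is.binary reads a basal trichotomy as an
  # unrooted binary tree, which would misreport the problem
  kidcount <- tabulate(phy$edge[, 1L], nbins = ntip + phy$Nnode)
  if (any(kidcount > 2L)) {
    stop("tree contains polytomies; resolve them first with resolve_polytomies()")
  }
  if (phy$Nnode != ntip - 1L) stop("tree must be rooted")
  depth <- ape::node.depth.edgelength(phy)   # distance from root, all nodes
  tipd <- depth[seq_len(ntip)]
  H <- max(tipd)
  spread <- if (H > 0) (max(tipd) - min(tipd)) / H else 0
  if (spread > tolerance) {
    stop(sprintf(
      "tree is not ultrametric: relative root-to-tip spread %.3g exceeds tolerance %.3g",
      spread, tolerance))
  }
  Hbar <- mean(tipd)
  age <- Hbar - depth
  age[seq_len(ntip)] <- 0
  # guard against age inversions created by snapping near-zero branches
  par <- phy$edge[, 1L]; chi <- phy$edge[, 2L]
  bad <- age[par] < age[chi] - 1e-12 * max(Hbar, 1)
  if (any(bad)) stop("parent node younger than child after snapping; tree malformed")
  age[par[age[par] < age[chi]]] <- age[chi[age[par] < age[chi]]]
  phy$edge.length <- age[par] - age[chi]
  structure(list(phylo = phy, age = age), class = "clock_tree")
}

#' Read and validate an ultrametric Newick tree
#'
#' @param path Path to a Newick file, or a literal Newick string via `text`.
#' @param text Optional Newick string (overrides `path`).
#' @param tolerance See [clock_tree()].
#' @return A [clock_tree()].
#' @examples
#' tr <- read_ultrametric_tree(text = "((a:1,b:1):1,c:2);")
#' max(tr$age)  # root age 2
#' @export
read_ultrametric_tree <- function(path = NULL, text = NULL, tolerance = 1e-6) {
  phy <- if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(path)
  if (is.null(phy)) stop("could not parse Newick input")
  clock_tree(phy, tolerance = tolerance)
}

#' Write a clock tree to Newick
#'
#' Branch lengths are written from the snapped node ages with full precision,
#' so write/read round trips reproduce ages to 1e-12.
#' @param tree A [clock_tree()].
#' @param path Output file path.
#' @export
write_clock_tree <- function(tree, path) {
  stopifnot(inherits(tree, "clock_tree"))
  ape::write.tree(tree$phylo, file = path, digits = 15)
  invisible(path)
}

#' Resolve polytomies deterministically
#'
#' Polytomies are expanded to binary nodes (in the order returned by
#' [ape::multi2di()] with `random = FALSE`) and each inserted zero-length
#' branch is given a small age offset so node ages are strictly decreasing
#' from root to tips, as GMYC requires.
#'
#' @param phy A `phylo` object with branch lengths.
#' @param eps Relative age offset for inserted nodes.
#' @return A binary `phylo` object.
#' @export
resolve_polytomies <- function(phy, eps = 1e-9) {
  phy2 <- ape::multi2di(phy, random = FALSE)
  ntip <- length(phy2$tip.label)
  depth <- ape::node.depth.edgelength(phy2)
  H <- max(depth[seq_len(ntip)])
  age <- max(depth) - depth
  age <- H - depth
  # push tied internal children just below their parents, preorder
  ord <- ape::reorder.phylo(phy2, "cladewise")$edge
  for (k in seq_len(nrow(ord))) {
    p <- ord[k, 1L]; ch <- ord[k, 2L]
    if (ch > ntip && age[ch] >= age[p]) age[ch] <- age[p] * (1 - eps) - eps * H
  }
  phy2$edge.length <- age[phy2$edge[, 1L]] - age[phy2$edge[, 2L]]
  phy2
}

#' @export
print.clock_tree <- function(x, ...) {
  cat(sprintf("clock_tree: %d tips, root age %.6g\n",
              length(x$phylo$tip.label), max(x$age)))
  invisible(x)
}

n_tips <- function(tree) length(tree$phylo$tip.label)

root_age <- function(tree) max(tree$age)

# internal node ids (ape convention) for a phylo with n tips
internal_ids <- function(phy) {
  ntip <- length(phy$tip.label)
  seq.int(ntip + 1L, ntip + phy$Nnode)
}

# children list indexed by node id
children_list <- function(phy) {
  M <- length(phy$tip.label) + phy$Nnode
  kids <- vector("list", M)
  for (k in seq_len(nrow(phy$edge))) {
    p <- phy$edge[k, 1L]
    kids[[p]] <- c(kids[[p]], phy$edge[k, 2L])
  }
  kids
}

parent_vec <- function(phy) {
  M <- length(phy$tip.label) + phy$Nnode
  par <- integer(M)
  par[phy$edge[, 2L]] <- phy$edge[, 1L]
  par  # root keeps 0
}

root_id <- function(phy) length(phy$tip.label) + 1L

# descendant node ids (including v) for every node, as a list
clade_list <- function(phy) {
  M <- length(phy$tip.label) + phy$Nnode
  kids <- children_list(phy)
  res <- vector("list", M)
  po <- postorder_ids(phy)
  for (v in po) {
    res[[v]] <- c(v, unlist(res[kids[[v]]], use.names = FALSE))
  }
  res
}

postorder_ids <- function(phy) {
  edg <- ape::reorder.phylo(phy, "postorder")$edge
  unique(c(edg[, 2L], edg[nrow(edg), 1L]))
}
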