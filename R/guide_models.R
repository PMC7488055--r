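#' Guide trees and delimitation models
#'
#' A guide tree is a rooted binary tree over candidate-species labels.  A
#' delimitation model assigns a split/collapsed state to every internal
#' node under the constraint that a node may be split only if its parent is
#' split (the root has no parent); the induced species partition consists of
#' the maximal collapsed clades plus the tips hanging off split nodes.
#'
#' @param x A `phylo` object, a Newick string, or a file path.
#' @return A validated `phylo` object of class `c("guide_tree", "phylo")`.
#' @export
guide_tree <- function(x) {
  phy <- if (inherits(x, "phylo")) x
  else if (is.character(x) && grepl("\\(", x)) ape::read.tree(text = x)
  else ape::read.tree(x)
  if (is.null(phy)) stop("could not parse guide tree")
  ntip <- length(phy$tip.label)
  kidcount <- tabulate(phy$edge[, 1L], nbins = ntip + phy$Nnode)
  if (any(kidcount > 2L) || phy$Nnode != ntip - 1L) {
    stop("guide tree must be rooted and binary")
  }
  if (anyDuplicated(phy$tip.label)) stop("duplicate species labels in guide tree")
  class(phy) <- c("guide_tree", "phylo")
  phy
}

#' A delimitation model on a guide tree
#'
#' @param split Logical vector, one flag per internal node in ape order
#'   (node ids `Ntip+1 .. Ntip+Nnode`); `TRUE` = the speciation at that node
#'   is retained.
#' @param g A [guide_tree()].
#' @return Object of class `delim_model` (named logical vector).
#' @export
delim_model <- function(split, g) {
  if (length(split) != g$Nnode) stop("one split flag per internal node required")
  par <- parent_vec(g)
  ntip <- length(g$tip.label)
  ids <- internal_ids(g)
  for (v in ids) {
    if (split[v - ntip] && par[v] != 0L && !split[par[v] - ntip]) {
      stop("a node may be split only if its parent is split")
    }
  }
  structure(stats::setNames(split, ids), class = "delim_model")
}

model_key <- function(split) paste0(as.integer(split), collapse = "")

#' Enumerate all delimitation models on a guide tree
#'
#' @param g A [guide_tree()].
#' @return List of [delim_model()] objects, including the fully collapsed
#'   (one species) and fully split models; length equals
#'   [count_delimitation_models()].
#' @export
enumerate_delimitation_models <- function(g) {
  ntip <- length(g$tip.label)
  kids <- children_list(g)
  rec <- function(v) {
    # returns list of flag assignments for the internal nodes in clade(v),
    # as named logical vectors
    if (v <= ntip) return(list(logical(0)))
    collapsed <- stats::setNames(rep(FALSE, sum(clade_internal(v))),
                                 names_in(v))
    left <- rec(kids[[v]][1]); right <- rec(kids[[v]][2])
    out <- list(collapsed)
    for (a in left) for (b in right) {
      out[[length(out) + 1L]] <- c(stats::setNames(TRUE, as.character(v)), a, b)
    }
    out
  }
  clades <- clade_list(g)
  clade_internal <- function(v) clades[[v]] > ntip
  names_in <- function(v) as.character(clades[[v]][clades[[v]] > ntip])
  flags <- rec(root_id(g))
  ids <- as.character(internal_ids(g))
  lapply(flags, function(f) {
    v <- stats::setNames(rep(FALSE, length(ids)), ids)
    v[names(f)] <- f
    structure(v == TRUE, class = "delim_model", names = ids)
  })
}

#' Count delimitation models by recursion
#'
#' `f(tip) = 1` and `f(v) = 1 + f(left) * f(right)`; the value at the root
#' equals the number of collapse/split assignments satisfying the
#' ancestor-must-be-split constraint.
#'
#' @param g A [guide_tree()].
#' @return Integer model count.
#' @export
count_delimitation_models <- function(g) {
  ntip <- length(g$tip.label)
  kids <- children_list(g)
  f <- numeric(ntip + g$Nnode)
  for (v in postorder_ids(g)) {
    f[v] <- if (v <= ntip) 1 else 1 + f[kids[[v]][1]] * f[kids[[v]][2]]
  }
  f[root_id(g)]
}

#' Number of labelled histories of a rooted binary tree
#'
#' A labelled history is the topology together with a total temporal order
#' of its internal nodes; the count is `(n-1)! / prod_v k_v` where `k_v` is
#' the number of internal nodes in the clade of internal node `v`.
#'
#' @param phy A rooted binary `phylo` object.
#' @return Number of labelled histories.
#' @export
labelled_history_count <- function(phy) {
  ntip <- length(phy$tip.label)
  if (ntip < 2L) return(1)
  clades <- clade_list(phy)
  k <- vapply(internal_ids(phy), function(v) sum(clades[[v]] > ntip), numeric(1))
  exp(lfactorial(ntip - 1) - sum(log(k)))
}

# labelled-history count of the species tree induced by collapsing a model:
# its internal nodes are exactly the split nodes of the guide tree
induced_history_count <- function(split, g) {
  ntip <- length(g$tip.label)
  ids <- internal_ids(g)
  sp <- ids[split]
  if (length(sp) == 0L) return(1)
  clades <- clade_list(g)
  k <- vapply(sp, function(v) sum(clades[[v]] %in% sp), numeric(1))
  exp(lfactorial(length(sp)) - sum(log(k)))
}

#' Log prior probability of a delimitation model
#'
#' Prior 1 (the default) is uniform over all delimitation models of the
#' guide tree.  Prior 0 weights each model by the number of labelled
#' histories of its induced (collapsed) species tree, so balanced trees get
#' higher probability than unbalanced ones; both are normalised over the
#' model set.
#'
#' @param model A [delim_model()] (or plain logical vector of split flags).
#' @param g A [guide_tree()].
#' @param prior_id 0 or 1.
#' @param log_norm Optional precomputed log normaliser (see
#'   [model_prior_norm()]); computed by enumeration when `NULL`.
#' @return Log prior probability.
#' @export
model_prior_log <- function(model, g, prior_id = 1, log_norm = NULL) {
  if (!prior_id %in% c(0, 1)) stop("unsupported model prior (use 0 or 1)")
  if (is.null(log_norm)) log_norm <- model_prior_norm(g, prior_id)
  if (prior_id == 1) return(-log_norm)
  log(induced_history_count(as.logical(model), g)) - log_norm
}

#' Log normaliser of the model prior
#' @inheritParams model_prior_log
#' @export
model_prior_norm <- function(g, prior_id = 1) {
  if (prior_id == 1) return(log(count_delimitation_models(g)))
  logsumexp(vapply(enumerate_delimitation_models(g), function(m) {
    log(induced_history_count(as.logical(m), g))
  }, numeric(1)))
}

#' Species partition induced by a delimitation model
#'
#' @param model A [delim_model()] (split flags).
#' @param g A [guide_tree()].
#' @return Named character vector: candidate species -> delimited unit.
#'   Units are named after the guide-tree tip labels they contain (joined
#'   with `+`).
#' @export
species_partition <- function(model, g) {
  split <- as.logical(model)
  ntip <- length(g$tip.label)
  par <- parent_vec(g)
  clades <- clade_list(g)
  is_split <- function(v) v > ntip && split[v - ntip]
  unit_roots <- Filter(function(v) {
    !is_split(v) && (par[v] == 0L || is_split(par[v]))
  }, seq_len(ntip + g$Nnode))
  out <- character(ntip)
  for (v in unit_roots) {
    tips <- clades[[v]][clades[[v]] <= ntip]
    out[tips] <- paste(g$tip.label[sort(tips)], collapse = "+")
  }
  stats::setNames(out, g$tip.label)
}
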