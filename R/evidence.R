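#' Partitions of individuals
#'
#' @param x Named character vector (individual -> unit), a [taxon_map()], or
#'   a data.frame with individual/unit columns.
#' @param source Optional source tag (e.g. `"gmyc:mtSSU"`).
#' @return Named character vector of class `partition`.
#' @export
as_partition <- function(x, source = NULL) {
  p <- if (inherits(x, "taxon_map")) stats::setNames(x$species, x$individual)
  else if (is.data.frame(x)) stats::setNames(as.character(x[[2L]]),
                                             as.character(x[[1L]]))
  else x
  if (is.null(names(p)) || anyDuplicated(names(p))) {
    stop("a partition needs unique individual names")
  }
  structure(p, class = "partition", source = source)
}

#' Adjusted Rand index between two partitions
#'
#' Rand index corrected by its expectation under the permutation model;
#' 1 for identical partitions, around 0 for independent ones.
#'
#' @param p1,p2 Partitions over the same individuals (see [as_partition()]).
#' @return Numeric ARI.
#' @export
adjusted_rand_index <- function(p1, p2) {
  p1 <- as_partition(p1); p2 <- as_partition(p2)
  if (!setequal(names(p1), names(p2))) {
    stop("partitions cover different individual sets")
  }
  p2 <- p2[names(p1)]
  tab <- table(unname(p1), unname(p2))
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)   # both partitions trivial and identical
  (sij - expected) / (maxi - expected)
}

#' Permutation chi-square test of trait-partition association
#'
#' The chi-square statistic of the unit-by-level contingency table is
#' compared with its permutation distribution under random relabelling of
#' trait values across individuals:
#' `p = (1 + #{permuted >= observed}) / (n_perm + 1)`.
#' Individuals with missing trait values are dropped (with a count in the
#' result).
#'
#' @param partition A partition of individuals (see [as_partition()]).
#' @param traits data.frame of traits with individuals as rownames.
#' @param trait_name Column to test.
#' @param n_perm Number of permutations (>= 99).
#' @param seed Optional RNG seed.
#' @return List with `table` (contingency), `statistic`, `p`, `n_perm`,
#'   `n_dropped`.
#' @export
trait_association_test <- function(partition, traits, trait_name,
                                   n_perm = 999, seed = NULL) {
  if (!trait_name %in% names(traits)) {
    stop(sprintf("trait '%s' absent from the trait table", trait_name))
  }
  if (n_perm < 99) stop("use at least 99 permutations")
  if (!is.null(seed)) set.seed(seed)
  p <- as_partition(partition)
  tr <- traits[names(p), trait_name]
  keep <- !is.na(tr)
  n_dropped <- sum(!keep)
  u <- unname(p[keep]); tr <- as.character(tr[keep])
  tab <- table(u, tr)
  stat_of <- function(y) {
    t2 <- table(u, y)
    if (nrow(t2) < 2L || ncol(t2) < 2L) return(0)
    e <- outer(rowSums(t2), colSums(t2)) / sum(t2)
    sum((t2 - e)^2 / e)
  }
  obs <- stat_of(tr)
  if (obs == 0) {
    return(list(table = tab, statistic = 0, p = 1, n_perm = n_perm,
                n_dropped = n_dropped))
  }
  ge <- 0L
  for (i in seq_len(n_perm)) {
    if (stat_of(sample(tr)) >= obs - 1e-12) ge <- ge + 1L
  }
  list(table = tab, statistic = obs, p = (1 + ge) / (n_perm + 1),
       n_perm = n_perm, n_dropped = n_dropped)
}

#' Aggregate species support across prior settings
#'
#' The conservative rule: a split (or candidate species) is well supported
#' only when its posterior probability strictly exceeds the threshold under
#' every prior combination; anything crossing the threshold under some but
#' not all combinations is flagged prior-sensitive.
#'
#' @param support Matrix or data.frame of posterior probabilities, rows =
#'   splits/species, columns = prior combinations (no missing columns
#'   allowed).
#' @param threshold Strong-support threshold (strict `>`).
#' @return List with `supported` (row names passing under all priors),
#'   `sensitive` (row names crossing under some but not all), and `table`
#'   (per row: min/max PP, supported, sensitive).
#' @export
aggregate_supported_species <- function(support, threshold = 0.95) {
  m <- as.matrix(support)
  if (anyNA(m)) stop("missing posterior probabilities for some prior combination")
  if (any(m < 0 | m > 1)) stop("posterior probabilities must lie in [0, 1]")
  if (is.null(rownames(m))) rownames(m) <- paste0("split", seq_len(nrow(m)))
  pass <- m > threshold
  supported <- apply(pass, 1L, all)
  sensitive <- apply(pass, 1L, function(x) any(x) && !all(x))
  tab <- data.frame(min_pp = apply(m, 1L, min), max_pp = apply(m, 1L, max),
                    supported = supported, sensitive = sensitive)
  list(supported = rownames(m)[supported], sensitive = rownames(m)[sensitive],
       table = tab, threshold = threshold)
}
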