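#' Prior configuration for the multispecies-coalescent stage
#'
#' Inverse-gamma priors with shape `alpha` on every population theta and on
#' the root divergence age; the rate parameters are set from the requested
#' means (`mean = rate / (alpha - 1)`), so means of 0.1 and 0.01 reproduce
#' the standard diffuse-prior grid.  Non-root divergence ages have a flat
#' joint prior over the order-compatible region below the root age, with the
#' exact per-topology normalising constant (required for valid
#' cross-dimension reversible-jump moves).
#'
#' @param theta_mean Prior mean of the population-size parameter theta = 4Neu.
#' @param tau_mean Prior mean of the root divergence age.
#' @param alpha Inverse-gamma shape (> 1 so the mean exists; default 2).
#' @param model_prior 0 (labelled-history weighted) or 1 (uniform over models).
#' @param integrate_theta Integrate theta out analytically.
#' @return Object of class `prior_config`.
#' @export
prior_config <- function(theta_mean = 0.1, tau_mean = 0.1, alpha = 2,
                         model_prior = 1, integrate_theta = TRUE) {
  if (alpha <= 1) stop("alpha must exceed 1 so the prior mean exists")
  if (!model_prior %in% c(0, 1)) stop("model_prior must be 0 or 1")
  structure(list(alpha = alpha,
                 beta_theta = theta_mean * (alpha - 1),
                 beta_tau = tau_mean * (alpha - 1),
                 theta_mean = theta_mean, tau_mean = tau_mean,
                 model_prior = model_prior,
                 integrate_theta = isTRUE(integrate_theta)),
            class = "prior_config")
}

#' Inverse-gamma prior log-density for theta or the root age
#'
#' @param kind `"theta"` or `"tau_root"`.
#' @param x Positive value.
#' @param prior A [prior_config()].
#' @return Log density.
#' @export
prior_logpdf <- function(kind = c("theta", "tau_root"), x, prior) {
  kind <- match.arg(kind)
  if (any(x <= 0)) stop("x must be positive")
  beta <- if (kind == "theta") prior$beta_theta else prior$beta_tau
  dinvgamma(x, prior$alpha, beta, log = TRUE)
}

#' Precompute gene-tree summaries against a guide tree
#'
#' Gene trees are fixed data for the MSC stage; this computes, once, the
#' per-locus event ages (rescaled by the locus rate), the guide-tree MRCA of
#' every coalescence, and the per-clade event lists the likelihood kernel
#' sweeps for any delimitation model and tau vector.
#'
#' @param gene_trees List of [clock_tree()] gene trees (loci).
#' @param map A [taxon_map()] resolving gene-tree tips to candidate species.
#' @param g A [guide_tree()] whose tip labels are the candidate species.
#' @param heredity Per-locus heredity scalars on effective theta.
#' @param rates Per-locus relative rates (gene-tree ages are divided by
#'   these before the sweep).
#' @param diploid When TRUE all heredity scalars are doubled (nuclear loci
#'   at heredity 1 get effective theta 2 theta; a mitochondrial locus at 1/4
#'   becomes 1/2), for the diploid sensitivity analysis.
#' @return Object of class `msc_prep` used by [msc_loglik()],
#'   [msc_loglik_integrated()] and [run_rjmcmc()].
#' @export
msc_prepare <- function(gene_trees, map, g, heredity = rep(1, length(gene_trees)),
                        rates = rep(1, length(gene_trees)), diploid = FALSE) {
  stopifnot(inherits(g, "phylo"))
  L <- length(gene_trees)
  heredity <- rep_len(heredity, L)
  rates <- rep_len(rates, L)
  if (diploid) heredity <- 2 * heredity
  ntip <- length(g$tip.label)
  M <- ntip + g$Nnode
  par <- parent_vec(g)
  clades <- clade_list(g)
  anc <- ancestor_paths(g)
  ev <- vector("list", L)
  n0 <- matrix(0L, L, M)
  emin <- matrix(Inf, L, M)
  n_l <- integer(L)
  for (l in seq_len(L)) {
    gt <- gene_trees[[l]]
    phy <- gt$phylo
    tips <- phy$tip.label
    n_l[l] <- length(tips)
    sp <- map_species(map, tips)
    gid <- match(sp, g$tip.label)
    if (anyNA(gid)) {
      stop(sprintf("species '%s' is not a guide-tree tip", sp[which(is.na(gid))[1L]]))
    }
    N <- length(tips)
    kids <- children_list(phy)
    mg <- integer(N + phy$Nnode)
    mg[seq_len(N)] <- gid
    for (v in postorder_ids(phy)) {
      if (v > N) {
        mg[v] <- guide_mrca(anc, mg[kids[[v]][1L]], mg[kids[[v]][2L]])
      }
    }
    ages <- gt$age[seq.int(N + 1L, N + phy$Nnode)] / rates[l]
    mgi <- mg[seq.int(N + 1L, N + phy$Nnode)]
    evl <- vector("list", M)
    for (u in seq_len(M)) {
      sel <- mgi %in% clades[[u]]
      evl[[u]] <- sort(ages[sel])
      n0[l, u] <- sum(gid %in% clades[[u]][clades[[u]] <= ntip])
      own <- ages[mgi == u]
      if (length(own)) emin[l, u] <- min(own)
    }
    ev[[l]] <- evl
  }
  structure(list(g = g, ntip = ntip, M = M, parent = par, ev = ev, n0 = n0,
                 emin = emin, heredity = heredity, rates = rates, L = L,
                 n_l = n_l),
            class = "msc_prep")
}

ancestor_paths <- function(g) {
  par <- parent_vec(g)
  M <- length(g$tip.label) + g$Nnode
  lapply(seq_len(M), function(v) {
    path <- v
    while (par[v] != 0L) { v <- par[v]; path <- c(path, v) }
    path
  })
}

guide_mrca <- function(anc, a, b) {
  if (a == b) return(a)
  pa <- anc[[a]]
  pb <- anc[[b]]
  pa[match(TRUE, pa %in% pb)]
}

# split flags by node id (tips FALSE) from a delim_model / logical vector
full_split <- function(prep, model) {
  c(rep(FALSE, prep$ntip), as.logical(model))
}

msc_summaries_raw <- function(prep, model, taus) {
  .msc_summaries_cpp(prep$ev, prep$n0, prep$emin, full_split(prep, model),
                     taus, prep$parent, prep$ntip)
}

# integrated log marginal + per-population conjugate summaries, taking the
# split vector over all node ids (sampler hot path; no attribute frames)
lint_full <- function(prep, split_full, taus, prior) {
  res <- .msc_summaries_cpp(prep$ev, prep$n0, prep$emin, split_full,
                            taus, prep$parent, prep$ntip)
  if (!res$feasible) return(list(ll = -Inf, C = NULL, B = NULL))
  a <- prior$alpha; b <- prior$beta_theta
  Cp <- colSums(res$c)
  Bp <- colSums(res$B / prep$heredity)
  hterm <- -colSums(res$c * log(prep$heredity))
  lm <- Cp * log(2) + hterm + a * log(b) - lgamma(a) +
    lgamma(a + Cp) - (a + Cp) * log(b + Bp)
  list(ll = sum(lm[Cp > 0 | Bp > 0]), C = Cp, B = Bp)
}

#' Per-population coalescent summaries for one gene tree
#'
#' Sweeps a gene tree through the population segments defined by a
#' delimitation model and its divergence ages, returning per population the
#' number of coalescences `c` and the waiting-time integral
#' `B = sum n(n-1) dt`.  A coalescence joining lineages of populations that
#' have not yet merged raises an infeasibility error (condition class
#' `coaldelim_infeasible`).
#'
#' @param gene_tree A [clock_tree()].
#' @param map A [taxon_map()].
#' @param g A [guide_tree()].
#' @param model A [delim_model()] or logical split-flag vector.
#' @param taus Numeric vector of divergence ages indexed by guide node id
#'   (NA at unsplit nodes).
#' @param heredity,rate Locus heredity scalar and relative rate.
#' @return data.frame with columns `population` (guide node id), `unit`
#'   (species-unit label for extant populations, `"anc<id>"` for ancestral),
#'   `c` and `B`.
#' @export
coalescent_summaries <- function(gene_tree, map, g, model, taus,
                                 heredity = 1, rate = 1) {
  prep <- msc_prepare(list(gene_tree), map, g, heredity = heredity,
                      rates = rate)
  res <- msc_summaries_raw(prep, model, taus)
  if (!res$feasible) {
    stop(structure(class = c("coaldelim_infeasible", "error", "condition"),
                   list(message = paste("infeasible configuration: a coalescence",
                                        "predates the merge of its populations"),
                        call = sys.call())))
  }
  pops <- which(pop_mask(prep, model))
  labels <- species_partition(as.logical(model), g)
  unit <- vapply(pops, function(u) {
    if (u <= prep$ntip) unname(labels[g$tip.label[u]]) else paste0("anc", u)
  }, character(1))
  data.frame(population = pops, unit = unit,
             c = res$c[1L, pops], B = res$B[1L, pops])
}

pop_mask <- function(prep, model) {
  split <- full_split(prep, model)
  par <- prep$parent
  split | (!split & (par == 0L | split[pmax(par, 1L)]))
}

#' Multispecies-coalescent log-likelihood of fixed gene trees
#'
#' Conditional on the gene trees (treated as data), the censored-coalescent
#' log-density is `sum_{p,l} c_pl log(2 / (h_l theta_p)) - B_pl / (h_l
#' theta_p)` after rescaling each locus' ages by its rate.
#'
#' @param prep An [msc_prepare()] object.
#' @param model Split flags.
#' @param taus Divergence ages by guide node id (NA at unsplit nodes).
#' @param thetas Per-population theta by guide node id (NA allowed for
#'   populations without coalescent content).
#' @return Log-likelihood (`-Inf` for infeasible configurations).
#' @export
msc_loglik <- function(prep, model, taus, thetas) {
  res <- msc_summaries_raw(prep, model, taus)
  if (!res$feasible) return(-Inf)
  ll <- 0
  for (u in seq_len(prep$M)) {
    cs <- res$c[, u]; Bs <- res$B[, u]
    if (all(cs == 0) && all(Bs == 0)) next
    th <- thetas[u]
    if (is.na(th) || th <= 0) stop(sprintf("missing theta for population %d", u))
    eff <- prep$heredity * th
    ll <- ll + sum(cs * log(2 / eff) - Bs / eff)
  }
  ll
}

#' MSC log-likelihood with theta integrated out analytically
#'
#' Under an inverse-gamma IG(alpha, beta) prior on each population theta the
#' marginal likelihood of population p is
#' `2^C_p * prod_l h_l^{-c_pl} * beta^alpha Gamma(alpha + C_p) /
#'  (Gamma(alpha) (beta + B'_p)^{alpha + C_p})`
#' with `C_p = sum_l c_pl` and `B'_p = sum_l B_pl / h_l`.
#'
#' @inheritParams msc_loglik
#' @param prior A [prior_config()].
#' @return Sum of log marginals (`-Inf` if infeasible), with attribute
#'   `pop`: data.frame of per-population `C` and `B` for conjugate draws of
#'   theta (the conditional is IG(alpha + C, beta + B')).
#' @export
msc_loglik_integrated <- function(prep, model, taus, prior) {
  r <- lint_full(prep, full_split(prep, model), taus, prior)
  if (!is.finite(r$ll)) return(-Inf)
  out <- r$ll
  attr(out, "pop") <- data.frame(node = seq_len(prep$M), C = r$C, B = r$B)
  out
}

#' Log prior density of a tau vector
#'
#' The root age has the inverse-gamma prior; conditional on it, the interior
#' split ages are jointly flat over the order-compatible region (each child
#' younger than its parent), with exact normaliser
#' `prod_v n_v / tau_root^k` where `n_v` counts split nodes in the clade of
#' interior split node `v`.
#'
#' @param model Split flags.
#' @param taus Divergence ages by guide node id.
#' @param g A [guide_tree()].
#' @param prior A [prior_config()].
#' @param clades Optional precomputed clade membership list (internal use;
#'   avoids recomputation inside samplers).
#' @return Log density (`-Inf` outside the order-compatible region).
#' @export
tau_prior_log <- function(model, taus, g, prior, clades = NULL) {
  split <- as.logical(model)
  ntip <- length(g$tip.label)
  ids <- internal_ids(g)
  sp <- ids[split]
  if (length(sp) == 0L) return(0)
  par <- parent_vec(g)
  rt <- root_id(g)
  if (!split[rt - ntip]) return(-Inf)  # ancestor-split constraint
  t_root <- taus[rt]
  if (is.na(t_root) || t_root <= 0) return(-Inf)
  for (v in sp) {
    if (is.na(taus[v]) || taus[v] <= 0) return(-Inf)
    if (par[v] != 0L && !(taus[v] < taus[par[v]])) return(-Inf)
  }
  k <- length(sp) - 1L
  lp <- prior_logpdf("tau_root", t_root, prior)
  if (k > 0L) {
    if (is.null(clades)) clades <- clade_list(g)
    interior <- setdiff(sp, rt)
    n_v <- vapply(interior, function(v) sum(clades[[v]] %in% sp), numeric(1))
    lp <- lp + sum(log(n_v)) - k * log(t_root)
  }
  lp
}
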