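#' Simulation scenario for multilocus coalescent data
#'
#' Bundles the parameters of the synthetic-data generator.  The defaults
#' emulate the structure of a small multilocus lichen-fungus study: 8
#' candidate species, 63 individuals unevenly assigned, 4 loci of which the
#' first is mitochondrial (heredity scalar 1/4), population-size parameters
#' drawn from an inverse-gamma with shape 2 and mean 0.05, root divergence
#' 0.1 expected substitutions per site, and a three-level categorical trait
#' shown with probability 0.9 (the "fidelity") as the species' modal level.
#'
#' @param s Number of species.
#' @param tau_root Root divergence age (expected substitutions/site).
#' @param theta_scale Mean of the inverse-gamma (shape 2) distribution the
#'   true per-population thetas are drawn from.
#' @param n_per_species Individuals sampled per species (recycled to `s`).
#' @param n_loci Number of loci.
#' @param heredity Per-locus heredity scalars multiplying effective theta
#'   (1/4 for a haploid, maternally inherited mitochondrial locus).
#' @param locus_rates Optional per-locus relative rates with mean exactly 1;
#'   when `NULL` they are drawn from a symmetric Dirichlet (concentration 2)
#'   scaled to mean 1.
#' @param trait_fidelity Probability an individual shows its species' modal
#'   trait level.
#' @param trait_levels Categorical trait levels.
#' @param seq_lengths Per-locus alignment lengths for sequence simulation.
#' @param seed RNG seed.
#' @return Object of class `sim_scenario`.
#' @export
sim_scenario <- function(s = 8, tau_root = 0.1, theta_scale = 0.05,
                         n_per_species = c(14, 12, 10, 8, 7, 5, 4, 3),
                         n_loci = 4, heredity = c(0.25, 1, 1, 1),
                         locus_rates = NULL, trait_fidelity = 0.9,
                         trait_levels = c("clusters", "short chains", "long chains"),
                         seq_lengths = c(825, 624, 621, 1962), seed = 1L) {
  stopifnot(s >= 1, tau_root > 0, theta_scale > 0, n_loci >= 1,
            trait_fidelity >= 0, trait_fidelity <= 1)
  n_per_species <- rep_len(n_per_species, s)
  heredity <- rep_len(heredity, n_loci)
  seq_lengths <- rep_len(seq_lengths, n_loci)
  stopifnot(all(n_per_species >= 1), all(heredity > 0))
  if (!is.null(locus_rates)) {
    locus_rates <- rep_len(locus_rates, n_loci)
    if (abs(mean(locus_rates) - 1) > 1e-12) {
      stop("mean of locus_rates must equal 1")
    }
  }
  structure(list(s = s, tau_root = tau_root, theta_scale = theta_scale,
                 n_per_species = n_per_species, n_loci = n_loci,
                 heredity = heredity, locus_rates = locus_rates,
                 trait_fidelity = trait_fidelity, trait_levels = trait_levels,
                 seq_lengths = seq_lengths, seed = as.integer(seed)),
            class = "sim_scenario")
}

#' The default multilocus study-scale scenario
#' @param seed RNG seed.
#' @return A [sim_scenario()] with the default ("rostania-like") settings.
#' @export
rostania_scenario <- function(seed = 1L) sim_scenario(seed = seed)

#' Simulate a species tree under a Yule process
#'
#' Topology follows the Yule label-history distribution (every labelled
#' history equally probable); internal node ages come from exponential
#' waiting times rescaled so the root age equals `tau_root`.  Node ages are
#' strictly decreasing from root to tips.
#'
#' @param s Number of species (tips, labelled `sp1..sps`).
#' @param tau_root Root age.
#' @param seed Optional RNG seed (NULL continues the current stream).
#' @return A [clock_tree()] for `s >= 2`; for `s = 1` a degenerate
#'   single-tip object of class `singleton_tree` with no divergence.
#' @export
simulate_species_tree <- function(s, tau_root = 0.1, seed = NULL) {
  if (s < 1) stop("s must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  labels <- paste0("sp", seq_len(s))
  if (s == 1L) {
    return(structure(list(phylo = NULL, age = 0, labels = labels),
                     class = "singleton_tree"))
  }
  # forward Yule waiting times; ages then rescaled to the required root age
  w <- stats::rexp(s, rate = seq_len(s))
  split_t <- cumsum(w)[seq_len(s - 1L)]
  Ttot <- sum(w)
  fwd_age <- Ttot - split_t              # age of j-th forward split
  # backward join j (youngest first) corresponds to forward split s - j
  join_age <- fwd_age[s - seq_len(s - 1L)]
  join_age <- join_age * (tau_root / join_age[s - 1L])
  age <- c(rep(0, s), numeric(s - 1L))
  active <- seq_len(s)
  edge <- matrix(0L, 2L * (s - 1L), 2L)
  elen <- numeric(2L * (s - 1L))
  r <- 0L
  for (j in seq_len(s - 1L)) {
    v <- 2L * s - j                      # root (last join) gets id s + 1
    pick <- sample.int(length(active), 2L)
    a <- active[pick[1L]]; b <- active[pick[2L]]
    age[v] <- join_age[j]
    edge[r + 1L, ] <- c(v, a); elen[r + 1L] <- age[v] - age[a]
    edge[r + 2L, ] <- c(v, b); elen[r + 2L] <- age[v] - age[b]
    r <- r + 2L
    active <- c(active[-pick], v)
  }
  phy <- structure(list(edge = edge, edge.length = elen,
                        tip.label = labels, Nnode = s - 1L),
                   class = "phylo")
  phy <- ape::reorder.phylo(phy, "cladewise")
  structure(list(phylo = phy, age = age), class = "clock_tree")
}

#' Simulate gene trees under the censored multispecies coalescent
#'
#' Lineages coalesce only within the species-tree population they currently
#' occupy, with pairwise rate `2 / (h_l * theta)`; at each divergence age the
#' surviving lineages merge into the ancestral population.  Node ages are
#' finally multiplied by the locus rate `r_l`.
#'
#' @param species_tree A [clock_tree()] from [simulate_species_tree()] (or a
#'   `singleton_tree` for one species).
#' @param thetas Numeric vector of per-population theta, indexed by species
#'   tree node id (tips first, then internal nodes; length `2s - 1`).
#' @param n_per_species Individuals sampled per species.
#' @param n_loci Number of loci.
#' @param heredity Per-locus heredity scalars.
#' @param locus_rates Per-locus relative rates.
#' @param seed Optional RNG seed.
#' @return List with `gene_trees` (list of [clock_tree()], tip labels
#'   `<species>_<i>`) and `taxon_map` (a [taxon_map()]).
#' @export
simulate_gene_trees <- function(species_tree, thetas, n_per_species,
                                n_loci = 1L, heredity = rep(1, n_loci),
                                locus_rates = rep(1, n_loci), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  single <- inherits(species_tree, "singleton_tree")
  labels <- if (single) species_tree$labels else species_tree$phylo$tip.label
  s <- length(labels)
  n_per_species <- rep_len(n_per_species, s)
  heredity <- rep_len(heredity, n_loci)
  locus_rates <- rep_len(locus_rates, n_loci)
  M <- 2L * s - 1L
  if (length(thetas) != M || anyNA(thetas) || any(thetas <= 0)) {
    stop(sprintf("need a positive theta for every population (%d values)", M))
  }
  inds <- unlist(lapply(seq_len(s), function(i) {
    paste0(labels[i], "_", seq_len(n_per_species[i]))
  }))
  map <- taxon_map(inds, rep(labels, n_per_species))
  if (!single) {
    kids <- children_list(species_tree$phylo)
    po <- postorder_ids(species_tree$phylo)
    sage <- species_tree$age
    rt <- root_id(species_tree$phylo)
    par <- parent_vec(species_tree$phylo)
  }
  gene_trees <- vector("list", n_loci)
  for (l in seq_len(n_loci)) {
    N <- sum(n_per_species)
    tip_age <- numeric(N)
    tip_of <- split(seq_len(N), rep(seq_len(s), n_per_species))
    joins_a <- integer(N - 1L); joins_b <- integer(N - 1L)
    joins_t <- numeric(N - 1L); nj <- 0L
    node_age <- c(tip_age, numeric(N - 1L))
    # pop simulation: ids are tip ids (1..N) or N + join index
    sim_pop <- function(lin, theta_eff, t0, t1) {
      t <- t0
      while (length(lin) >= 2L) {
        n <- length(lin)
        t <- t + stats::rexp(1L, rate = n * (n - 1) / theta_eff)
        if (t >= t1) break
        pick <- sample.int(n, 2L)
        nj <<- nj + 1L
        joins_a[nj] <<- lin[pick[1L]]; joins_b[nj] <<- lin[pick[2L]]
        joins_t[nj] <<- t
        node_age[N + nj] <<- t
        lin <- c(lin[-pick], N + nj)
      }
      lin
    }
    if (single) {
      sim_pop(tip_of[[1L]], heredity[l] * thetas[1L], 0, Inf)
    } else {
      surv <- vector("list", M)
      for (v in po) {
        if (v <= s) {
          enter <- tip_of[[v]]
          t0 <- 0
        } else {
          enter <- unlist(surv[kids[[v]]], use.names = FALSE)
          t0 <- sage[v]
        }
        t1 <- if (v == rt) Inf else sage[par[v]]
        surv[[v]] <- sim_pop(enter, heredity[l] * thetas[v], t0, t1)
      }
    }
    # assemble phylo: root (= oldest join) must get id N + 1
    ord <- order(joins_t, decreasing = TRUE)
    new_id <- integer(N - 1L)
    new_id[ord] <- N + seq_len(N - 1L)
    remap <- function(x) ifelse(x > N, new_id[x - N], x)
    age <- numeric(2L * N - 1L)
    age[N + seq_len(N - 1L)] <- joins_t[ord] * locus_rates[l]
    edge <- matrix(0L, 2L * (N - 1L), 2L)
    for (j in seq_len(N - 1L)) {
      edge[2L * j - 1L, ] <- c(new_id[j], remap(joins_a[j]))
      edge[2L * j, ] <- c(new_id[j], remap(joins_b[j]))
    }
    elen <- age[edge[, 1L]] - age[edge[, 2L]]
    phy <- structure(list(edge = edge, edge.length = elen,
                          tip.label = inds, Nnode = N - 1L),
                     class = "phylo")
    phy <- ape::reorder.phylo(phy, "cladewise")
    gene_trees[[l]] <- structure(list(phylo = phy, age = age),
                                 class = "clock_tree")
  }
  list(gene_trees = gene_trees, taxon_map = map)
}

#' Simulate a JC69 alignment along a gene tree
#'
#' @param gene_tree A [clock_tree()] with branch lengths in expected
#'   substitutions per site.
#' @param length Number of sites (>= 1).
#' @param seed Optional RNG seed.
#' @return A [dna_alignment()].
#' @export
simulate_alignment <- function(gene_tree, length, seed = NULL) {
  if (length < 1) stop("alignment length must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  sim <- phangorn::simSeq(gene_tree$phylo, l = length, type = "DNA")
  m <- toupper(as.character(sim))
  dna_alignment(m, locus = "simulated")
}

#' Simulate categorical traits with species fidelity
#'
#' Each species has a modal trait level (assigned cyclically over the level
#' set unless given); each individual shows the modal level with probability
#' `fidelity` and otherwise a uniform draw from the remaining levels.
#'
#' @param map A [taxon_map()] giving the species partition.
#' @param trait_levels Character vector of levels (>= 2 unless fidelity = 1).
#' @param trait_fidelity Probability of the modal level.
#' @param seed Optional RNG seed.
#' @param trait_name Column name of the trait.
#' @param modal Optional named character vector species -> modal level.
#' @return data.frame with rownames = individuals and one factor column.
#' @export
simulate_traits <- function(map, trait_levels, trait_fidelity, seed = NULL,
                            trait_name = "morphotype", modal = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(trait_levels) < 2 && trait_fidelity < 1) {
    stop("need at least 2 trait levels when fidelity < 1")
  }
  sp <- sort(unique(map$species))
  if (is.null(modal)) {
    modal <- stats::setNames(
      trait_levels[(seq_along(sp) - 1L) %% length(trait_levels) + 1L], sp)
  }
  lev <- vapply(seq_len(nrow(map)), function(i) {
    m <- modal[[map$species[i]]]
    if (stats::runif(1) < trait_fidelity) m
    else sample(setdiff(trait_levels, m), 1L)
  }, character(1))
  out <- data.frame(row.names = map$individual,
                    x = factor(lev, levels = trait_levels))
  names(out) <- trait_name
  out
}

#' Simulate a complete truth bundle
#'
#' Draws the species tree, per-population thetas, locus rates, censored
#' coalescent gene trees, JC69 alignments and traits for a [sim_scenario()].
#'
#' @param scenario A [sim_scenario()].
#' @param alignments Simulate per-locus alignments too (slower).
#' @return Object of class `truth_bundle`: list with `scenario`,
#'   `species_tree`, `thetas`, `locus_rates`, `taxon_map` (the true
#'   delimitation), `gene_trees`, `alignments` and `traits`.
#' @export
simulate_truth_bundle <- function(scenario, alignments = FALSE) {
  set.seed(scenario$seed)
  sp_tree <- simulate_species_tree(scenario$s, scenario$tau_root)
  M <- 2L * scenario$s - 1L
  thetas <- rinvgamma(M, shape = 2, rate = scenario$theta_scale)
  rates <- scenario$locus_rates
  if (is.null(rates)) {
    g <- stats::rgamma(scenario$n_loci, shape = 2)
    rates <- scenario$n_loci * g / sum(g)
  }
  gg <- simulate_gene_trees(sp_tree, thetas, scenario$n_per_species,
                            n_loci = scenario$n_loci,
                            heredity = scenario$heredity, locus_rates = rates)
  alns <- NULL
  if (alignments) {
    alns <- lapply(seq_len(scenario$n_loci), function(l) {
      a <- simulate_alignment(gg$gene_trees[[l]], scenario$seq_lengths[l])
      a$locus <- paste0("locus", l)
      a
    })
  }
  traits <- simulate_traits(gg$taxon_map, scenario$trait_levels,
                            scenario$trait_fidelity)
  structure(list(scenario = scenario, species_tree = sp_tree, thetas = thetas,
                 locus_rates = rates, taxon_map = gg$taxon_map,
                 gene_trees = gg$gene_trees, alignments = alns,
                 traits = traits),
            class = "truth_bundle")
}
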