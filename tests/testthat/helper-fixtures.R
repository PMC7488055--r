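# shared builders for small in-code fixtures

toy_alignment <- function(seqs, locus = "toy") {
  dna_alignment(lapply(seqs, function(s) strsplit(s, "")[[1]]), locus = locus)
}

write_fasta_tmp <- function(seqs) {
  path <- tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(names(seqs), function(nm) c(paste0(">", nm), seqs[[nm]]))),
             path)
  path
}

random_alignment <- function(ntaxa, nsites, gap_p = 0.1) {
  syms <- c("A", "C", "G", "T", "-", "N")
  pr <- c(rep((1 - gap_p - 0.02) / 4, 4), gap_p, 0.02)
  m <- matrix(sample(syms, ntaxa * nsites, replace = TRUE, prob = pr),
              nrow = ntaxa, dimnames = list(paste0("t", seq_len(ntaxa)), NULL))
  dna_alignment(m, locus = "rand")
}

# independent per-column parsimony-informative oracle (table-based)
pis_oracle <- function(a) {
  sum(apply(a$mat, 2, function(col) {
    tab <- table(col[col %in% c("A", "C", "G", "T")])
    sum(tab >= 2) >= 2
  }))
}

random_guide_tree <- function(ntip) {
  guide_tree(ape::rtree(ntip, rooted = TRUE, tip.label = paste0("s", seq_len(ntip))))
}

# brute-force delimitation-model enumeration over all flag assignments
brute_models <- function(g) {
  ntip <- length(g$tip.label)
  ids <- (ntip + 1):(ntip + g$Nnode)
  par <- integer(ntip + g$Nnode)
  par[g$edge[, 2]] <- g$edge[, 1]
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), g$Nnode))
  ok <- apply(grid, 1, function(fl) {
    all(vapply(seq_along(ids), function(i) {
      v <- ids[i]
      !fl[i] || par[v] == 0 || fl[par[v] - ntip]
    }, logical(1)))
  })
  grid[ok, , drop = FALSE]
}

# batch-means standard error for autocorrelated MCMC indicator streams
bm_se <- function(x, n_batch = 25) {
  f <- cut(seq_along(x), n_batch)
  m <- tapply(x, f, mean)
  stats::sd(m) / sqrt(n_batch)
}

# small strongly-divergent multispecies scenario for sampler tests
divergent_case <- function(s = 3, seed = 1, n_loci = 2, n_per = 2,
                           tau_root = 0.05, theta_mean = 0.01) {
  set.seed(seed)
  st <- simulate_species_tree(s, tau_root = tau_root)
  th <- rinvgamma(2 * s - 1, 2, theta_mean)
  gg <- simulate_gene_trees(st, th, n_per_species = n_per, n_loci = n_loci)
  list(species_tree = st, thetas = th, gene_trees = gg$gene_trees,
       map = gg$taxon_map, guide = guide_tree(st$phylo))
}
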