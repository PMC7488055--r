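test_that("species-tree simulation handles degenerate sizes and fixes the root age", {
  expect_error(simulate_species_tree(0), ">= 1")
  s1 <- simulate_species_tree(1, seed = 1)
  expect_s3_class(s1, "singleton_tree")
  expect_equal(s1$age, 0)
  s2 <- simulate_species_tree(2, tau_root = 0.07, seed = 1)
  expect_equal(max(s2$age), 0.07)
  s8 <- simulate_species_tree(8, tau_root = 0.1, seed = 2)
  expect_equal(max(s8$age), 0.1)
  # taus strictly decrease from root to tips
  par <- s8$phylo$edge[, 1]; chi <- s8$phylo$edge[, 2]
  expect_true(all(s8$age[par] > s8$age[chi]))
})

test_that("simulated topologies are uniform over labelled histories (s = 4)", {
  # for 4 tips there are exactly 18 labelled histories, each with
  # probability 1/18 under the Yule process; classify replicates by their
  # ranked-merge signature and test uniformity
  set.seed(10)
  hist_key <- function(st) {
    M <- 7; n <- 4
    kids <- vector("list", M)
    for (k in seq_len(nrow(st$phylo$edge)))
      kids[[st$phylo$edge[k, 1]]] <- c(kids[[st$phylo$edge[k, 1]]], st$phylo$edge[k, 2])
    tips_of <- function(v) if (v <= n) st$phylo$tip.label[v] else
      unlist(lapply(kids[[v]], tips_of))
    ints <- (n + 1):M
    ord <- ints[order(st$age[ints])]
    paste(vapply(ord, function(v) paste(sort(tips_of(v)), collapse = ""),
                 character(1)), collapse = "|")
  }
  keys <- replicate(9000, hist_key(simulate_species_tree(4, tau_root = 1)))
  tab <- table(keys)
  expect_equal(length(tab), 18L)
  gof <- stats::chisq.test(tab, p = rep(1 / 18, 18))
  expect_gt(gof$p.value, 0.01)
})

test_that("pairwise coalescence times match theory, including heredity scaling", {
  st1 <- simulate_species_tree(1, seed = 3)
  set.seed(4)
  gg <- simulate_gene_trees(st1, 0.1, n_per_species = 2, n_loci = 8000)
  t2 <- vapply(gg$gene_trees, function(t) max(t$age), numeric(1))
  # E[T2] = theta / 2 = 0.05; 3 SE band
  expect_lt(abs(mean(t2) - 0.05), 3 * stats::sd(t2) / sqrt(length(t2)))

  set.seed(5)
  gh <- simulate_gene_trees(st1, 0.1, n_per_species = 2, n_loci = 8000,
                            heredity = 0.25)
  th <- vapply(gh$gene_trees, function(t) max(t$age), numeric(1))
  # mitochondrial-style scaling: E[T2] = h * theta / 2 = 0.0125
  expect_lt(abs(mean(th) - 0.0125), 3 * stats::sd(th) / sqrt(length(th)))
})

test_that("single-population gene trees match coalescent closed forms (n = 6)", {
  st1 <- simulate_species_tree(1, seed = 6)
  set.seed(7)
  theta <- 0.08; n <- 6
  gg <- simulate_gene_trees(st1, theta, n_per_species = n, n_loci = 6000)
  h <- vapply(gg$gene_trees, function(t) max(t$age), numeric(1))
  ks <- 2:n
  mu <- sum(theta / (ks * (ks - 1)))          # E[height] = theta (1 - 1/n)
  va <- sum((theta / (ks * (ks - 1)))^2)
  expect_lt(abs(mean(h) - mu), 3 * stats::sd(h) / sqrt(length(h)))
  expect_lt(abs(stats::var(h) - va), 3 * va / sqrt(length(h) / 10))
})

test_that("censoring: no inter-species coalescence predates the divergence", {
  set.seed(8)
  st <- simulate_species_tree(2, tau_root = 0.1)
  gg <- simulate_gene_trees(st, rep(0.05, 3), n_per_species = 3, n_loci = 300)
  for (gt in gg$gene_trees) {
    phy <- gt$phylo; n <- length(phy$tip.label)
    sp <- substr(phy$tip.label, 1, 3)
    kids <- children_of <- lapply(seq_len(n + phy$Nnode), function(v)
      phy$edge[phy$edge[, 1] == v, 2])
    tips_under <- function(v) if (v <= n) v else unlist(lapply(kids[[v]], tips_under))
    for (v in (n + 1):(n + phy$Nnode)) {
      spv <- unique(sp[tips_under(v)])
      if (length(spv) > 1) expect_gte(gt$age[v], 0.1)
    }
  }
})

test_that("relabelling individuals within a species leaves gene-tree law unchanged", {
  # the MRCA age of individuals (1,2) and of (2,3) of one species must have
  # the same distribution by exchangeability
  set.seed(9)
  st1 <- simulate_species_tree(1)
  gg <- simulate_gene_trees(st1, 0.05, n_per_species = 3, n_loci = 1500)
  mrca_age <- function(gt, a, b) {
    phy <- gt$phylo
    gt$age[ape::getMRCA(phy, c(a, b))]
  }
  x <- vapply(gg$gene_trees, mrca_age, numeric(1), "sp1_1", "sp1_2")
  y <- vapply(gg$gene_trees, mrca_age, numeric(1), "sp1_2", "sp1_3")
  expect_gt(suppressWarnings(stats::ks.test(x, y)$p.value), 0.01)
})

test_that("JC69 alignments behave as the model predicts", {
  tr0 <- read_ultrametric_tree(text = "((a:0,b:0):0,c:0);")
  a0 <- simulate_alignment(tr0, 50, seed = 10)
  expect_equal(a0$mat["a", ], a0$mat["b", ], ignore_attr = TRUE)

  tr <- read_ultrametric_tree(text = "(a:0.05,b:0.05);")  # distance 0.1
  a <- simulate_alignment(tr, 10000, seed = 11)
  p_obs <- mean(a$mat["a", ] != a$mat["b", ])
  p_exp <- 0.75 * (1 - exp(-4 * 0.1 / 3))
  se <- sqrt(p_exp * (1 - p_exp) / 10000)
  expect_lt(abs(p_obs - p_exp), 3 * se)
  expect_equal(n_sites(simulate_alignment(tr, 825, seed = 12)), 825L)
  expect_error(simulate_alignment(tr, 0), ">= 1")
})

test_that("trait simulation respects fidelity and modal levels", {
  map <- taxon_map(paste0("i", 1:6), rep(c("spA", "spB"), each = 3))
  t1 <- simulate_traits(map, c("x", "y", "z"), 1, seed = 13)
  expect_equal(length(unique(t1[1:3, 1])), 1L)
  expect_equal(length(unique(t1[4:6, 1])), 1L)
  expect_equal(adjusted_rand_index(
    as_partition(map), as_partition(stats::setNames(as.character(t1[[1]]),
                                                    rownames(t1)))), 1)
  expect_error(simulate_traits(map, "only", 0.5), "at least 2")

  big <- taxon_map(paste0("i", 1:10000), rep("spA", 10000))
  tb <- simulate_traits(big, c("x", "y", "z"), 0.5, seed = 14)
  f <- mean(tb[[1]] == "x")
  expect_lt(abs(f - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("truth bundles are internally consistent and rates average to one", {
  sc <- sim_scenario(s = 4, n_per_species = c(3, 2, 2, 2), n_loci = 3,
                     heredity = c(0.25, 1, 1), seed = 15)
  tb <- simulate_truth_bundle(sc)
  expect_equal(mean(tb$locus_rates), 1, tolerance = 1e-12)
  expect_equal(length(tb$gene_trees), 3L)
  expect_equal(nrow(tb$taxon_map), 9L)
  expect_equal(sort(unique(tb$taxon_map$species)), paste0("sp", 1:4))
  expect_error(sim_scenario(locus_rates = c(2, 1, 1, 1)), "mean")
  # identical seeds reproduce identical bundles
  tb2 <- simulate_truth_bundle(sc)
  expect_identical(tb$thetas, tb2$thetas)
  expect_identical(tb$gene_trees[[2]]$age, tb2$gene_trees[[2]]$age)
})
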