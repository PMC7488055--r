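test_that("coalescent summaries match hand-computed counts and integrals", {
  g <- guide_tree("(spA,spB);")
  m2 <- taxon_map(c("spA_1", "spA_2"), c("spA", "spA"))
  gt2 <- read_ultrametric_tree(text = "(spA_1:0.05,spA_2:0.05);")
  cs <- coalescent_summaries(gt2, m2, g, c(FALSE), rep(NA_real_, 3))
  expect_equal(cs$c[cs$population == 3], 1L)
  expect_equal(cs$B[cs$population == 3], 0.1)

  # 3 lineages, events at 0.02 and 0.05: B = 6*0.02 + 2*0.03 = 0.18
  m3 <- taxon_map(paste0("spA_", 1:3), rep("spA", 3))
  gt3 <- read_ultrametric_tree(
    text = "((spA_1:0.02,spA_2:0.02):0.03,spA_3:0.05);")
  cs3 <- coalescent_summaries(gt3, m3, g, c(FALSE), rep(NA_real_, 3))
  expect_equal(cs3$c[cs3$population == 3], 2L)
  expect_equal(cs3$B[cs3$population == 3], 0.18)

  # a coalescence at 0.08 joining lineages of populations split at 0.1
  mab <- taxon_map(c("a1", "b1"), c("spA", "spB"))
  gtab <- read_ultrametric_tree(text = "(a1:0.08,b1:0.08);")
  taus <- c(NA, NA, 0.1)
  expect_error(coalescent_summaries(gtab, mab, g, c(TRUE), taus),
               class = "coaldelim_infeasible")
})

test_that("the MSC log-likelihood matches closed forms and is additive over loci", {
  g <- guide_tree("(spA,spB);")
  m2 <- taxon_map(c("spA_1", "spA_2"), c("spA", "spA"))
  gt2 <- read_ultrametric_tree(text = "(spA_1:0.05,spA_2:0.05);")
  prep1 <- msc_prepare(list(gt2), m2, g)
  th <- c(NA, NA, 0.1)
  expect_equal(msc_loglik(prep1, c(FALSE), rep(NA_real_, 3), th), log(20) - 1)

  prep2 <- msc_prepare(list(gt2, gt2), m2, g)
  expect_equal(msc_loglik(prep2, c(FALSE), rep(NA_real_, 3), th),
               2 * (log(20) - 1))

  # 3-lineage labelled density: (2/theta)^2 exp(-(6 t1 + 2 (t2-t1))/theta)
  m3 <- taxon_map(paste0("spA_", 1:3), rep("spA", 3))
  gt3 <- read_ultrametric_tree(
    text = "((spA_1:0.02,spA_2:0.02):0.03,spA_3:0.05);")
  prep3 <- msc_prepare(list(gt3), m3, g)
  theta <- 0.07
  expect_equal(msc_loglik(prep3, c(FALSE), rep(NA_real_, 3),
                          c(NA, NA, theta)),
               2 * log(2 / theta) - (6 * 0.02 + 2 * 0.03) / theta)

  # infeasible configuration gives -Inf
  mab <- taxon_map(c("a1", "b1"), c("spA", "spB"))
  gtab <- read_ultrametric_tree(text = "(a1:0.08,b1:0.08);")
  prepab <- msc_prepare(list(gtab), mab, g)
  expect_identical(msc_loglik(prepab, c(TRUE), c(NA, NA, 0.1), c(NA, NA, 0.1)),
                   -Inf)
})

test_that("analytic theta integration matches its closed example and quadrature", {
  g <- guide_tree("(spA,spB);")
  m2 <- taxon_map(c("spA_1", "spA_2"), c("spA", "spA"))
  gt2 <- read_ultrametric_tree(text = "(spA_1:0.05,spA_2:0.05);")
  prep <- msc_prepare(list(gt2), m2, g)
  pr <- prior_config(theta_mean = 0.1, alpha = 2)
  # C = 1, B = 0.1, alpha = 2, beta = 0.1: marginal = 5 exactly
  lint <- msc_loglik_integrated(prep, c(FALSE), rep(NA_real_, 3), pr)
  expect_equal(as.numeric(lint), log(5), tolerance = 1e-12)
  # quadrature oracle on the same case
  num <- stats::integrate(function(th) {
    vapply(th, function(t) exp(msc_loglik(prep, c(FALSE), rep(NA_real_, 3),
                                          c(NA, NA, t))) *
             dinvgamma(t, 2, 0.1), numeric(1))
  }, 0, Inf, rel.tol = 1e-10)$value
  expect_equal(exp(as.numeric(lint)), num, tolerance = 1e-8)
})

test_that("theta integration matches nested quadrature on two-population cases", {
  # one species carries a single lineage, so exactly two populations (the
  # multi-individual species and the root) have coalescent content and the
  # marginal is a two-dimensional integral
  for (rep in 1:3) {
    set.seed(130 + rep)
    st <- simulate_species_tree(2, tau_root = 0.04)
    th_true <- rinvgamma(3, 2, 0.02)
    gg <- simulate_gene_trees(st, th_true, n_per_species = c(3, 1), n_loci = 2)
    g <- guide_tree(st$phylo)
    prep <- msc_prepare(gg$gene_trees, gg$taxon_map, g)
    pr <- prior_config(theta_mean = 0.02)
    taus <- c(NA, NA, 0.04)
    model <- c(TRUE)
    lint <- as.numeric(msc_loglik_integrated(prep, model, taus, pr))
    res <- coaldelim:::msc_summaries_raw(prep, model, taus)
    content <- which(colSums(res$c) > 0 | colSums(res$B) > 0)
    expect_equal(length(content), 2L)
    f_inner <- function(th_ab) {
      th <- rep(NA_real_, 3); th[content] <- th_ab
      exp(msc_loglik(prep, model, taus, th) - lint) *
        prod(dinvgamma(th_ab, 2, pr$beta_theta))
    }
    # finite upper bound: the inverse-gamma tail beyond theta = 50
    # contributes < 1e-7 of the mass
    val <- stats::integrate(function(a_) vapply(a_, function(a) {
      stats::integrate(function(b_) vapply(b_, function(b)
        f_inner(c(a, b)), numeric(1)),
        0, 50, rel.tol = 1e-9)$value
    }, numeric(1)), 0, 50, rel.tol = 1e-9)$value
    expect_equal(val, 1, tolerance = 1e-6)
  }
})

test_that("lineage conservation holds for every locus under random submodels", {
  set.seed(31)
  cs <- divergent_case(4, seed = 31, n_loci = 3, n_per = 3)
  prep <- msc_prepare(cs$gene_trees, cs$map, cs$guide)
  ms <- enumerate_delimitation_models(cs$guide)
  taus <- cs$species_tree$age
  for (m in ms) {
    split <- as.logical(m)
    tt <- ifelse(c(rep(FALSE, 4), split), taus, NA_real_)
    res <- coaldelim:::msc_summaries_raw(prep, split, tt)
    expect_true(res$feasible)
    expect_equal(unname(rowSums(res$c)), prep$n_l - 1L)
  }
})

test_that("the theta/tau prior density behaves as an inverse gamma", {
  pr <- prior_config(theta_mean = 0.1, tau_mean = 0.1, alpha = 2)
  # mean of IG(2, 0.1) is 0.1
  mu <- stats::integrate(function(x) x * dinvgamma(x, 2, 0.1), 0, Inf,
                         rel.tol = 1e-10)$value
  expect_equal(mu, 0.1, tolerance = 1e-8)
  norm <- stats::integrate(function(x) dinvgamma(x, 2, 0.1), 0, Inf,
                           rel.tol = 1e-10)$value
  expect_equal(norm, 1, tolerance = 1e-8)
  # log pdf at x = 0.05: 2 log(0.1) - 3 log(0.05) - 2
  expect_equal(prior_logpdf("theta", 0.05, pr),
               2 * log(0.1) - 3 * log(0.05) - 2, tolerance = 1e-12)
  expect_error(prior_logpdf("theta", -1, pr), "positive")
  expect_error(prior_config(alpha = 1), "exceed 1")
})

test_that("the non-root tau prior normalises over the order-compatible region", {
  # volume of the order region as a fraction of the cube is 1 / prod(n_v);
  # the flat prior uses exactly that normaliser
  set.seed(32)
  for (s in c(3, 4, 5)) {
    st <- simulate_species_tree(s, tau_root = 1, seed = 40 + s)
    g <- guide_tree(st$phylo)
    ids <- (s + 1):(2 * s - 1)
    par <- coaldelim:::parent_vec(g)
    clades <- coaldelim:::clade_list(g)
    interior <- setdiff(ids, s + 1)
    k <- length(interior)
    n_v <- vapply(interior, function(v) sum(clades[[v]] %in% ids), numeric(1))
    nmc <- 40000
    ok <- replicate(nmc, {
      taus <- rep(NA_real_, 2 * s - 1)
      taus[s + 1] <- 1
      taus[interior] <- stats::runif(k)
      all(vapply(interior, function(v) taus[v] < taus[par[v]], logical(1)))
    })
    p_hat <- mean(ok); p_th <- 1 / prod(n_v)
    expect_lte(abs(p_hat - p_th), 3 * sqrt(p_th * (1 - p_th) / nmc))
  }
})

test_that("tau_prior_log rejects order violations and integrates the root prior", {
  g <- guide_tree("((a,b),c);")
  pr <- prior_config(tau_mean = 0.1)
  expect_equal(tau_prior_log(c(FALSE, FALSE), rep(NA_real_, 5), g, pr), 0)
  taus_ok <- c(NA, NA, NA, 0.1, 0.05)
  taus_bad <- c(NA, NA, NA, 0.1, 0.2)
  expect_true(is.finite(tau_prior_log(c(TRUE, TRUE), taus_ok, g, pr)))
  expect_identical(tau_prior_log(c(TRUE, TRUE), taus_bad, g, pr), -Inf)
  # with one interior node, density = dIG(root) * 1/root on the region
  expect_equal(tau_prior_log(c(TRUE, TRUE), taus_ok, g, pr),
               dinvgamma(0.1, 2, 0.1, log = TRUE) - log(0.1))
})
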