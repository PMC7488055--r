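test_that("identical seeds give identical sample streams", {
  cs <- divergent_case(3, seed = 60)
  cfg <- mcmc_config(4000, 2, 500, seed = 61)
  r1 <- run_rjmcmc(cs$gene_trees, cs$map, cs$guide, cfg)
  r2 <- run_rjmcmc(cs$gene_trees, cs$map, cs$guide, cfg)
  expect_identical(r1$samples$model, r2$samples$model)
  expect_identical(r1$samples$taus, r2$samples$taus)
  expect_identical(r1$model_pp, r2$model_pp)
})

test_that("with zero loci the chain recovers the model prior (priors 0 and 1)", {
  g <- guide_tree("((a,b),c);")
  map <- taxon_map("x1", "a")
  for (pid in c(1, 0)) {
    cfg <- mcmc_config(40000, 2, 2000, seed = 62 + pid,
                       prior = prior_config(model_prior = pid))
    ps <- run_rjmcmc(list(), map, g, cfg)
    ms <- enumerate_delimitation_models(g)
    for (m in ms) {
      key <- paste0(as.integer(as.logical(m)), collapse = "")
      target <- exp(model_prior_log(as.logical(m), g, pid))
      ind <- as.numeric(ps$samples$model == key)
      se <- max(bm_se(ind), 1e-3)
      expect_lt(abs(mean(ind) - target), 3 * se)
    }
  }
})

test_that("the sampler matches the exhaustive posterior on small scenarios", {
  tvs <- numeric(2)
  for (i in 1:2) {
    cs <- divergent_case(3, seed = 70 + i, n_loci = 2, n_per = 2)
    pr <- prior_config(theta_mean = 0.01, tau_mean = 0.05)
    ex <- exhaustive_posterior(cs$gene_trees, cs$map, cs$guide, pr)
    cfg <- mcmc_config(40000, 2, 4000, seed = 170 + i, prior = pr)
    mc <- run_rjmcmc(cs$gene_trees, cs$map, cs$guide, cfg)
    keys <- names(ex$model_pp)
    mcp <- vapply(keys, function(k) {
      v <- mc$model_pp[k]; if (is.na(v)) 0 else as.numeric(v)
    }, numeric(1))
    tvs[i] <- 0.5 * sum(abs(mcp - ex$model_pp))
  }
  expect_lt(max(tvs), 0.05)
})

test_that("exhaustive posterior handles the no-data and size limits", {
  g <- guide_tree("((a,b),c);")
  map <- taxon_map("x1", "a")
  ex <- exhaustive_posterior(list(), map, g, prior_config(model_prior = 1))
  expect_equal(unname(ex$model_pp), rep(1 / 3, 3), tolerance = 1e-9)
  expect_equal(sum(ex$model_pp), 1, tolerance = 1e-9)
  g5 <- random_guide_tree(5)
  expect_error(exhaustive_posterior(list(), map, g5), "run_rjmcmc")
})

test_that("posterior summaries merge runs and respect split identities", {
  cs <- divergent_case(3, seed = 72)
  cfg1 <- mcmc_config(6000, 2, 500, seed = 73)
  cfg2 <- mcmc_config(6000, 2, 500, seed = 74)
  r1 <- run_rjmcmc(cs$gene_trees, cs$map, cs$guide, cfg1)
  r2 <- run_rjmcmc(cs$gene_trees, cs$map, cs$guide, cfg2)
  sm <- summarize_posterior(list(r1, r2))
  expect_equal(sm$n_runs, 2L)
  expect_equal(sum(sm$model_pp), 1, tolerance = 1e-9)
  # identical runs: mean equals either
  sm1 <- summarize_posterior(list(r1, r1))
  expect_equal(sm1$split_pp, r1$split_pp)
  expect_equal(sm1$max_split_discrepancy, 0)
  # split PP equals the sum of PPs of models containing that split
  ids <- as.character((4):(5))
  for (j in seq_along(ids)) {
    keys <- names(r1$model_pp)
    has <- vapply(keys, function(k) substr(k, j, j) == "1", logical(1))
    expect_equal(unname(r1$split_pp[j]), sum(r1$model_pp[has]),
                 tolerance = 1e-9)
  }
  # ancestor split PP >= descendant split PP (root is node 4)
  expect_gte(sm$split_pp[["4"]], sm$split_pp[["5"]])
})

test_that("theta-sampled and theta-integrated chains agree; so do algorithms 0 and 1", {
  cs <- divergent_case(3, seed = 75)
  base <- prior_config(theta_mean = 0.01, tau_mean = 0.05)
  pr_s <- prior_config(theta_mean = 0.01, tau_mean = 0.05, integrate_theta = FALSE)
  mi <- run_rjmcmc(cs$gene_trees, cs$map, cs$guide,
                   mcmc_config(30000, 2, 3000, seed = 76, prior = base))
  ms <- run_rjmcmc(cs$gene_trees, cs$map, cs$guide,
                   mcmc_config(30000, 2, 3000, seed = 77, prior = pr_s))
  a1 <- run_rjmcmc(cs$gene_trees, cs$map, cs$guide,
                   mcmc_config(30000, 2, 3000, seed = 78, prior = base,
                               algorithm = 1))
  expect_lt(max(abs(mi$split_pp - ms$split_pp)), 0.02)
  expect_lt(max(abs(mi$split_pp - a1$split_pp)), 0.05)
})

test_that("a fixed model constrains the chain to parameter moves", {
  cs <- divergent_case(3, seed = 79)
  cfg <- mcmc_config(3000, 2, 300, seed = 80, fixed_model = c(TRUE, TRUE))
  mc <- run_rjmcmc(cs$gene_trees, cs$map, cs$guide, cfg)
  expect_equal(unique(mc$samples$model), "11")
  expect_true(all(is.finite(mc$samples$taus[, 4:5])))
})

test_that("the prior-sensitivity scan produces four combinations with flags", {
  cs <- divergent_case(3, seed = 81, n_loci = 2, n_per = 3,
                       tau_root = 0.1, theta_mean = 0.005)
  scan <- prior_sensitivity_scan(cs$gene_trees, cs$map, cs$guide,
                                 mcmc_config(5000, 2, 500, seed = 82),
                                 runs_per = 2)
  expect_equal(nrow(scan$table), 4L)
  expect_equal(ncol(scan$split_pp), 4L)
  expect_equal(length(scan$summaries), 4L)
  expect_true(all(vapply(scan$summaries, function(s) s$n_runs, numeric(1)) == 2))
  # overwhelming signal: fully split wins everywhere, nothing prior-sensitive
  expect_true(all(scan$table$best_model == "11"))
  expect_false(any(scan$sensitive))
})

test_that("the configuration matrix mirrors the full study design", {
  cm1 <- build_config_matrix(guide_modes = "guided", max_species = 8,
                             tau_means = 0.1, theta_means = 0.1, runs_per = 1)
  expect_equal(nrow(cm1), 1L)
  cm <- build_config_matrix()
  expect_equal(length(unique(cm$analysis_id)), 16L)
  expect_equal(nrow(cm), 32L)
  expect_true(all(table(cm$analysis_id) == 2))
  # distinct seeds for the two runs of each analysis
  for (id in unique(cm$analysis_id)) {
    expect_equal(length(unique(cm$seed[cm$analysis_id == id])), 2L)
  }
  expect_true(all(cm$supported == (cm$guide_mode == "guided")))
  expect_true(all(cm$generations[cm$max_species == 13] == 1000000L))
  expect_true(all(cm$sample_every[cm$max_species == 8] == 2L))
})
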