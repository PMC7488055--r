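#' MCMC configuration for guided delimitation
#'
#' The default schedule mirrors common practice for an 8-species guide tree:
#' 10,000 generations of pre-burnin followed by 200,000 generations sampled
#' every second generation; larger (13-species-scale) model spaces use
#' 100,000 + 1,000,000 sampled every fifth (see [build_config_matrix()]).
#'
#' @param generations Post-burnin generations.
#' @param sample_every Thinning interval.
#' @param pre_burnin Discarded initial generations.
#' @param seed RNG seed (a run is exactly reproducible given its seed).
#' @param algorithm 0 or 1; both target the same posterior.  Variant 1 adds
#'   a multiplier refresh of the parent divergence age after every accepted
#'   dimension move.
#' @param prior A [prior_config()]; its `integrate_theta` flag selects the
#'   analytically integrated or the theta-sampling chain.
#' @param heredity Per-locus heredity scalars.
#' @param locus_rates Per-locus relative rates (treated as known).
#' @param diploid Double all heredity scalars (diploid sensitivity setting).
#' @param fixed_model Optional logical split-flag vector (one per guide-tree
#'   internal node): run the chain at this delimitation model only (no
#'   dimension moves), e.g. for parameter estimation at the preferred model.
#' @return Object of class `mcmc_config`.
#' @export
mcmc_config <- function(generations = 200000, sample_every = 2,
                        pre_burnin = 10000, seed = 1L, algorithm = 0,
                        prior = prior_config(), heredity = NULL,
                        locus_rates = NULL, diploid = FALSE,
                        fixed_model = NULL) {
  stopifnot(generations > 0, sample_every >= 1, pre_burnin >= 0,
            algorithm %in% c(0, 1))
  structure(list(generations = as.integer(generations),
                 sample_every = as.integer(sample_every),
                 pre_burnin = as.integer(pre_burnin), seed = as.integer(seed),
                 algorithm = algorithm, prior = prior, heredity = heredity,
                 locus_rates = locus_rates, diploid = isTRUE(diploid),
                 fixed_model = fixed_model),
            class = "mcmc_config")
}

#' Guided reversible-jump MCMC over delimitation models
#'
#' Samples (model, taus, and optionally thetas) on a fixed guide tree.
#' Split moves pick a splittable node uniformly and propose its new
#' divergence age uniformly below the smaller of the parent age and the
#' gene-tree feasibility bound (the youngest coalescence whose species MRCA
#' is that node, across loci); the root age is proposed from its
#' inverse-gamma prior.  Join moves are the exact reverse.  Within-model
#' moves are log-scale multiplier updates of each divergence age (and of
#' each theta when theta is sampled, with a periodic conjugate refresh).
#' All Hastings ratios include the exact cross-dimension prior normalisers.
#'
#' @param gene_trees List of [clock_tree()] gene trees.
#' @param map A [taxon_map()].
#' @param g A [guide_tree()].
#' @param config An [mcmc_config()].
#' @return Object of class `posterior_summary`: per-model posterior
#'   probabilities, per-split posterior probabilities, parameter samples,
#'   acceptance rates and the run configuration.
#' @export
run_rjmcmc <- function(gene_trees, map, g, config = mcmc_config()) {
  stopifnot(inherits(config, "mcmc_config"))
  prior <- config$prior
  L <- length(gene_trees)
  her <- if (is.null(config$heredity)) rep(1, max(L, 1L)) else config$heredity
  rat <- if (is.null(config$locus_rates)) rep(1, max(L, 1L)) else config$locus_rates
  prep <- msc_prepare(gene_trees, map, g, heredity = her, rates = rat,
                      diploid = config$diploid)
  set.seed(config$seed)
  ntip <- prep$ntip; M <- prep$M
  par <- prep$parent; rt <- root_id(g)
  kids <- children_list(g)
  ids <- internal_ids(g)
  fbv <- if (L > 0) apply(prep$emin, 2, min) else rep(Inf, M)
  log_norm <- model_prior_norm(g, prior$model_prior)
  n_models <- count_delimitation_models(g)
  integrate <- prior$integrate_theta
  a <- prior$alpha; b_th <- prior$beta_theta

  lik <- function(split, taus, thetas) {
    if (integrate) lint_full(prep, split, taus, prior)$ll
    else {
      pops <- which(pop_mask(prep, split[ids]))
      lp <- sum(dinvgamma(thetas[pops], a, b_th, log = TRUE))
      if (!is.finite(lp)) return(-Inf)
      lp + msc_loglik(prep, split[ids], taus, thetas)
    }
  }
  clades <- clade_list(g)
  tau_prior_fast <- function(split, taus) {
    sp <- ids[split[ids]]
    if (length(sp) == 0L) return(0)
    if (!split[rt]) return(-Inf)
    t_root <- taus[rt]
    if (is.na(t_root) || t_root <= 0) return(-Inf)
    for (v in sp) {
      if (is.na(taus[v]) || taus[v] <= 0) return(-Inf)
      if (par[v] != 0L && !(taus[v] < taus[par[v]])) return(-Inf)
    }
    lp <- dinvgamma(t_root, a, prior$beta_tau, log = TRUE)
    k <- length(sp) - 1L
    if (k > 0L) {
      interior <- sp[sp != rt]
      n_v <- vapply(interior, function(v) sum(clades[[v]] %in% sp), numeric(1))
      lp <- lp + sum(log(n_v)) - k * log(t_root)
    }
    lp
  }
  log_post <- function(split, taus, thetas) {
    lp <- model_prior_log(split[ids], g, prior$model_prior, log_norm) +
      tau_prior_fast(split, taus)
    if (!is.finite(lp)) return(lp)
    lp + lik(split, taus, thetas)
  }
  cond_pars <- function(split, taus) {
    # conditional IG(alpha + C, beta + B') parameters per population
    r <- lint_full(prep, split, taus, prior)
    if (is.null(r$C)) return(NULL)
    list(C = r$C, B = r$B)
  }

  # state: fully collapsed start (always feasible), unless a model is fixed
  split <- rep(FALSE, M)
  taus <- rep(NA_real_, M)
  thetas <- rep(NA_real_, M)
  do_rj <- is.null(config$fixed_model) && n_models > 1
  if (!is.null(config$fixed_model)) {
    split[ids] <- as.logical(config$fixed_model)
    # feasible initialisation: just below the parent age / feasibility bound
    for (v in preorder_ids(g)) {
      if (v > ntip && split[v]) {
        ub <- min(if (par[v] != 0L) taus[par[v]] else Inf, fbv[v])
        if (!is.finite(ub)) ub <- 2 * prior$tau_mean
        taus[v] <- 0.95 * ub
      }
    }
  }
  if (!integrate) {
    pops0 <- which(pop_mask(prep, split[ids]))
    thetas[pops0] <- rinvgamma(length(pops0), a, b_th)
  }
  cur <- log_post(split, taus, thetas)

  total <- config$pre_burnin + config$generations
  keep <- seq.int(config$pre_burnin + config$sample_every, total,
                  by = config$sample_every)
  n_keep <- length(keep)
  sm_model <- character(n_keep)
  sm_split <- matrix(0, n_keep, length(ids), dimnames = list(NULL, ids))
  sm_tau <- matrix(NA_real_, n_keep, M)
  sm_theta <- matrix(NA_real_, n_keep, M)
  acc <- c(rj = 0, rj_try = 0, tau = 0, tau_try = 0, theta = 0, theta_try = 0)
  ki <- 1L
  w_tau <- 0.7; w_th <- 0.7

  propose_rj <- function() {
    S <- ids[!split[ids] & (ids == rt | split[pmax(par[ids], 1L)])]
    J <- ids[split[ids]]
    J <- J[vapply(J, function(v) {
      ch <- kids[[v]]; !any(ch > ntip & split[ch])
    }, logical(1))]
    p_split_here <- if (length(S) && length(J)) 0.5 else if (length(S)) 1 else 0
    do_split <- stats::runif(1) < p_split_here
    if (do_split) {
      v <- if (length(S) == 1L) S else sample(S, 1L)
      new_split <- split; new_split[v] <- TRUE
      new_taus <- taus
      if (v == rt) {
        tstar <- rinvgamma(1, a, prior$beta_tau)
        lqf <- dinvgamma(tstar, a, prior$beta_tau, log = TRUE)
      } else {
        U <- min(taus[par[v]], fbv[v])
        if (!is.finite(U) || U <= 0) return(NULL)
        tstar <- stats::runif(1, 0, U)
        lqf <- -log(U)
      }
      new_taus[v] <- tstar
      lqf <- lqf - log(length(S)) + log(p_split_here)
      # reverse join pick in the new state
      S2 <- ids[!new_split[ids] & (ids == rt | new_split[pmax(par[ids], 1L)])]
      J2 <- ids[new_split[ids]]
      J2 <- J2[vapply(J2, function(u) {
        ch <- kids[[u]]; !any(ch > ntip & new_split[ch])
      }, logical(1))]
      p_join_new <- if (length(S2) && length(J2)) 0.5 else if (length(J2)) 1 else 0
      lqr <- -log(length(J2)) + log(p_join_new)
      new_thetas <- thetas
      if (!integrate) {
        cp <- cond_pars(new_split, new_taus)
        if (is.null(cp)) return(NULL)
        aff <- c(v, kids[[v]])
        for (u in aff) {
          new_thetas[u] <- rinvgamma(1, a + cp$C[u], b_th + cp$B[u])
          lqf <- lqf + dinvgamma(new_thetas[u], a + cp$C[u], b_th + cp$B[u],
                                 log = TRUE)
        }
        cpo <- cond_pars(split, taus)
        lqr <- lqr + dinvgamma(thetas[v], a + cpo$C[v], b_th + cpo$B[v],
                               log = TRUE)
      }
      list(split = new_split, taus = new_taus, thetas = new_thetas,
           lq = lqr - lqf, node = v)
    } else {
      if (!length(J)) return(NULL)
      v <- if (length(J) == 1L) J else sample(J, 1L)
      new_split <- split; new_split[v] <- FALSE
      new_taus <- taus; new_taus[v] <- NA_real_
      lqf <- -log(length(J)) + log(1 - p_split_here)
      S2 <- ids[!new_split[ids] & (ids == rt | new_split[pmax(par[ids], 1L)])]
      J2 <- ids[new_split[ids]]
      J2 <- J2[vapply(J2, function(u) {
        ch <- kids[[u]]; !any(ch > ntip & new_split[ch])
      }, logical(1))]
      p_split_new <- if (length(S2) && length(J2)) 0.5 else if (length(S2)) 1 else 0
      if (v == rt) {
        lqr <- dinvgamma(taus[v], a, prior$beta_tau, log = TRUE)
      } else {
        U <- min(new_taus[par[v]], fbv[v])
        if (!is.finite(U) || U <= 0) return(NULL)
        lqr <- -log(U)
      }
      lqr <- lqr - log(length(S2)) + log(p_split_new)
      new_thetas <- thetas
      if (!integrate) {
        cp <- cond_pars(new_split, new_taus)
        if (is.null(cp)) return(NULL)
        new_thetas[kids[[v]]] <- NA_real_
        new_thetas[v] <- rinvgamma(1, a + cp$C[v], b_th + cp$B[v])
        lqf <- lqf + dinvgamma(new_thetas[v], a + cp$C[v], b_th + cp$B[v],
                               log = TRUE)
        cpo <- cond_pars(split, taus)
        for (u in c(v, kids[[v]])) {
          lqr <- lqr + dinvgamma(thetas[u], a + cpo$C[u], b_th + cpo$B[u],
                                 log = TRUE)
        }
      }
      list(split = new_split, taus = new_taus, thetas = new_thetas,
           lq = lqr - lqf, node = v)
    }
  }

  mult_update <- function(v) {
    u <- stats::runif(1, -w_tau, w_tau)
    new_taus <- taus; new_taus[v] <- taus[v] * exp(u)
    lp <- log_post(split, new_taus, thetas)
    acc["tau_try"] <<- acc["tau_try"] + 1
    if (is.finite(lp) && log(stats::runif(1)) < lp - cur + u) {
      taus <<- new_taus; cur <<- lp; acc["tau"] <<- acc["tau"] + 1
    }
  }

  for (it in seq_len(total)) {
    if (do_rj && stats::runif(1) < 0.5) {
      prop <- propose_rj()
      acc["rj_try"] <- acc["rj_try"] + 1
      if (!is.null(prop)) {
        lp <- log_post(prop$split, prop$taus, prop$thetas)
        if (is.finite(lp) && log(stats::runif(1)) < lp - cur + prop$lq) {
          split <- prop$split; taus <- prop$taus; thetas <- prop$thetas
          cur <- lp; acc["rj"] <- acc["rj"] + 1
          if (config$algorithm == 1 && par[prop$node] != 0L &&
              split[par[prop$node]]) {
            mult_update(par[prop$node])
          }
        }
      }
    } else {
      for (v in ids[split[ids]]) mult_update(v)
      if (!integrate) {
        pops <- which(pop_mask(prep, split[ids]))
        if (it %% 10 == 0) {
          cp <- cond_pars(split, taus)
          for (u in pops) thetas[u] <- rinvgamma(1, a + cp$C[u], b_th + cp$B[u])
          cur <- log_post(split, taus, thetas)
        } else {
          for (u in pops) {
            z <- stats::runif(1, -w_th, w_th)
            new_th <- thetas; new_th[u] <- thetas[u] * exp(z)
            lp <- log_post(split, taus, new_th)
            acc["theta_try"] <- acc["theta_try"] + 1
            if (is.finite(lp) && log(stats::runif(1)) < lp - cur + z) {
              thetas <- new_th; cur <- lp; acc["theta"] <- acc["theta"] + 1
            }
          }
        }
      }
    }
    if (ki <= n_keep && it == keep[ki]) {
      sm_model[ki] <- model_key(split[ids])
      sm_split[ki, ] <- split[ids]
      sm_tau[ki, ] <- taus
      if (integrate) {
        cp <- cond_pars(split, taus)
        pops <- which(pop_mask(prep, split[ids]))
        th <- rep(NA_real_, M)
        th[pops] <- rinvgamma(length(pops), a + cp$C[pops], b_th + cp$B[pops])
        sm_theta[ki, ] <- th
      } else {
        sm_theta[ki, ] <- thetas
      }
      ki <- ki + 1L
    }
  }
  model_pp <- sort(table(sm_model) / n_keep, decreasing = TRUE)
  split_pp <- colMeans(sm_split)
  structure(list(model_pp = c(model_pp), split_pp = split_pp,
                 samples = list(model = sm_model, taus = sm_tau,
                                thetas = sm_theta),
                 acceptance = acc, guide = g, config = config,
                 n_samples = n_keep,
                 run_label = sprintf("seed%d", config$seed)),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat("Guided MSC delimitation posterior (", x$n_samples, " samples)\n", sep = "")
  top <- utils::head(x$model_pp, 5)
  for (i in seq_along(top)) {
    cat(sprintf("  model %s  PP = %.4f\n", names(top)[i], top[i]))
  }
  cat("per-split PP:\n")
  print(round(x$split_pp, 4))
  invisible(x)
}

#' Exhaustive posterior over delimitation models (small guide trees)
#'
#' For guide trees with at most 4 species the per-model marginal likelihood
#' is computed by tensor Gauss-Legendre quadrature over the divergence ages
#' (theta integrated analytically); the posterior is the normalised product
#' with the model prior.  Used as the validation oracle for [run_rjmcmc()].
#'
#' @inheritParams run_rjmcmc
#' @param prior A [prior_config()].
#' @param heredity,locus_rates Per-locus constants.
#' @param nq Quadrature nodes per dimension; by default 256 for
#'   one-dimensional models, 96 for two, 40 for three (the likelihood can be
#'   sharply peaked relative to the prior, so low orders under-resolve it).
#' @return List with `model_pp` (named, sums to 1), `split_pp`, and
#'   per-model log marginal likelihoods.
#' @export
exhaustive_posterior <- function(gene_trees, map, g, prior = prior_config(),
                                 heredity = rep(1, length(gene_trees)),
                                 locus_rates = rep(1, length(gene_trees)),
                                 nq = NULL) {
  if (length(g$tip.label) > 4L) {
    stop("exhaustive posterior is limited to guide trees with <= 4 species; use run_rjmcmc()")
  }
  prep <- msc_prepare(gene_trees, map, g, heredity = heredity,
                      rates = locus_rates)
  ids <- internal_ids(g)
  ntip <- length(g$tip.label)
  par <- parent_vec(g)
  rt <- root_id(g)
  clades <- clade_list(g)
  models <- enumerate_delimitation_models(g)
  a <- prior$alpha
  logmarg <- vapply(models, function(m) {
    split <- as.logical(m)
    sp <- ids[split]
    if (length(sp) == 0L) {
      taus <- rep(NA_real_, prep$M)
      return(as.numeric(msc_loglik_integrated(prep, split, taus, prior)))
    }
    interior <- setdiff(sp[order(match(sp, preorder_ids(g)))], rt)
    k <- length(interior)
    n_v <- if (k) vapply(interior, function(v) sum(clades[[v]] %in% sp),
                         numeric(1)) else numeric(0)
    dims <- k + 1L
    nq_d <- if (is.null(nq)) c(256L, 96L, 40L)[min(dims, 3L)] else nq
    gl <- pracma::gaussLegendre(nq_d, 0, 1)
    # integrate each age only over its feasible range (bounded by the parent
    # age and the youngest own-MRCA coalescence), so the integrand is smooth
    fb <- if (prep$L > 0) apply(prep$emin, 2L, min) else rep(Inf, prep$M)
    pmax_root <- if (is.finite(fb[rt])) pinvgamma(fb[rt], a, prior$beta_tau) else 1
    grid <- do.call(expand.grid, rep(list(seq_len(nq_d)), dims))
    vals <- apply(as.matrix(grid), 1L, function(ix) {
      taus <- rep(NA_real_, prep$M)
      taus[rt] <- qinvgamma(gl$x[ix[1L]] * pmax_root, a, prior$beta_tau)
      lw <- log(gl$w[ix[1L]]) + log(pmax_root)
      ljac <- 0
      if (k) for (j in seq_len(k)) {
        v <- interior[j]
        umax <- min(taus[par[v]], fb[v])
        taus[v] <- umax * gl$x[ix[j + 1L]]
        lw <- lw + log(gl$w[ix[j + 1L]])
        ljac <- ljac + log(umax)
      }
      ll <- msc_loglik_integrated(prep, split, taus, prior)
      if (!is.finite(ll)) return(-Inf)
      lflat <- if (k) sum(log(n_v)) - k * log(taus[rt]) else 0
      lw + ll + lflat + ljac
    })
    logsumexp(vals)
  }, numeric(1))
  lprior <- vapply(models, function(m) {
    model_prior_log(as.logical(m), g, prior$model_prior)
  }, numeric(1))
  lpost <- lprior + logmarg
  pp <- exp(lpost - logsumexp(lpost))
  keys <- vapply(models, function(m) model_key(as.logical(m)), character(1))
  names(pp) <- keys
  flags <- do.call(rbind, lapply(models, as.logical))
  split_pp <- colSums(flags * pp)
  names(split_pp) <- ids
  list(model_pp = pp, split_pp = split_pp,
       log_marginal = stats::setNames(logmarg, keys))
}

preorder_ids <- function(phy) {
  edg <- ape::reorder.phylo(phy, "cladewise")$edge
  unique(c(edg[1L, 1L], edg[, 2L]))
}

#' Merge posterior summaries across runs
#'
#' Per-model and per-split posterior probabilities are averaged across runs
#' (the usual dual-run practice); per-run values are retained and the
#' maximum per-split discrepancy between runs is reported as a convergence
#' diagnostic rather than silently averaged away.
#'
#' @param runs List of `posterior_summary` objects over the same guide tree.
#' @param discrepancy_threshold Maximum tolerated per-split PP difference.
#' @return Object of class `merged_posterior`.
#' @export
summarize_posterior <- function(runs, discrepancy_threshold = 0.05) {
  stopifnot(length(runs) >= 1L)
  splits <- lapply(runs, `[[`, "split_pp")
  if (length(unique(vapply(splits, length, integer(1)))) != 1L) {
    stop("runs cover different model spaces")
  }
  keys <- sort(unique(unlist(lapply(runs, function(r) names(r$model_pp)))))
  mp <- sapply(keys, function(k) {
    mean(vapply(runs, function(r) {
      v <- r$model_pp[k]; if (is.na(v)) 0 else as.numeric(v)
    }, numeric(1)))
  })
  sp <- Reduce(`+`, splits) / length(runs)
  disc <- if (length(runs) > 1L) {
    max(apply(do.call(rbind, splits), 2L, function(x) diff(range(x))))
  } else 0
  structure(list(model_pp = sort(mp, decreasing = TRUE), split_pp = sp,
                 per_run = list(model_pp = lapply(runs, `[[`, "model_pp"),
                                split_pp = splits),
                 max_split_discrepancy = disc,
                 converged = disc <= discrepancy_threshold,
                 n_runs = length(runs)),
            class = "merged_posterior")
}

#' Prior-sensitivity scan over the inverse-gamma mean grid
#'
#' Runs the guided delimitation under the four (tau mean, theta mean)
#' combinations of the standard grid, each with `runs_per` independent
#' chains, and flags every split whose support crosses the strong-support
#' threshold under some but not all prior settings.
#'
#' @inheritParams run_rjmcmc
#' @param config Base [mcmc_config()] (its prior means are overridden).
#' @param tau_means,theta_means Prior-mean grids (defaults 0.1 and 0.01).
#' @param runs_per Chains per combination.
#' @param threshold Strong-support threshold on posterior probability.
#' @return Object of class `sensitivity_scan`: `table` (one row per
#'   combination: best model and its PP, convergence), `split_pp` (splits x
#'   combinations), `sensitive` (logical per split), `summaries` (merged
#'   posteriors per combination).
#' @export
prior_sensitivity_scan <- function(gene_trees, map, g, config = mcmc_config(),
                                   tau_means = c(0.1, 0.01),
                                   theta_means = c(0.1, 0.01),
                                   runs_per = 2, threshold = 0.95) {
  combos <- expand.grid(theta_mean = theta_means, tau_mean = tau_means,
                        KEEP.OUT.ATTRS = FALSE)
  combos <- combos[order(-combos$tau_mean, -combos$theta_mean), , drop = FALSE]
  summaries <- vector("list", nrow(combos))
  rows <- vector("list", nrow(combos))
  split_pp <- NULL
  for (i in seq_len(nrow(combos))) {
    pr <- prior_config(theta_mean = combos$theta_mean[i],
                       tau_mean = combos$tau_mean[i],
                       alpha = config$prior$alpha,
                       model_prior = config$prior$model_prior,
                       integrate_theta = config$prior$integrate_theta)
    runs <- lapply(seq_len(runs_per), function(r) {
      cfg <- config
      cfg$prior <- pr
      cfg$seed <- as.integer((config$seed + 9973L * i + r) %% .Machine$integer.max)
      run_rjmcmc(gene_trees, map, g, cfg)
    })
    sm <- summarize_posterior(runs)
    summaries[[i]] <- sm
    rows[[i]] <- data.frame(
      combo = sprintf("tau(%g), theta(%g)", combos$tau_mean[i], combos$theta_mean[i]),
      tau_mean = combos$tau_mean[i], theta_mean = combos$theta_mean[i],
      best_model = names(sm$model_pp)[1L], best_pp = as.numeric(sm$model_pp[1L]),
      max_split_discrepancy = sm$max_split_discrepancy,
      converged = sm$converged)
    split_pp <- cbind(split_pp, sm$split_pp)
  }
  tab <- do.call(rbind, rows)
  colnames(split_pp) <- tab$combo
  strong <- split_pp > threshold
  sensitive <- apply(strong, 1L, function(x) any(x) && !all(x))
  structure(list(table = tab, split_pp = split_pp, sensitive = sensitive,
                 threshold = threshold, summaries = summaries),
            class = "sensitivity_scan")
}

#' Build the full analysis configuration matrix
#'
#' Cartesian product of guide modes, maximum species counts and the four
#' prior combinations, each expanded to `runs_per` seeded chains.  Entries
#' in unguided mode are marked unsupported by the core sampler (the model
#' space here is always conditional on a guide tree); they document the
#' full study design rather than runnable configurations.
#'
#' @param guide_modes Character subset of `c("guided", "unguided")`.
#' @param max_species Integer vector of maximum species counts.
#' @param tau_means,theta_means Prior-mean grids.
#' @param runs_per Chains per analysis.
#' @param base_seed Seed from which per-chain seeds are derived.
#' @return data.frame with one row per chain: `analysis_id`, `guide_mode`,
#'   `max_species`, `tau_mean`, `theta_mean`, `run`, `seed`, `generations`,
#'   `sample_every`, `pre_burnin`, `supported`.
#' @export
build_config_matrix <- function(guide_modes = c("guided", "unguided"),
                                max_species = c(8, 13),
                                tau_means = c(0.1, 0.01),
                                theta_means = c(0.1, 0.01),
                                runs_per = 2, base_seed = 1L) {
  stopifnot(length(guide_modes) > 0, length(max_species) > 0, runs_per >= 1)
  an <- expand.grid(theta_mean = theta_means, tau_mean = tau_means,
                    max_species = max_species, guide_mode = guide_modes,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  an$analysis_id <- sprintf("%s-%dsp-tau%g-theta%g", an$guide_mode,
                            an$max_species, an$tau_mean, an$theta_mean)
  out <- do.call(rbind, lapply(seq_len(runs_per), function(r) {
    d <- an
    d$run <- r
    d$seed <- as.integer((base_seed + 7919L * seq_len(nrow(an)) + 131L * r) %%
                           .Machine$integer.max)
    d
  }))
  big <- out$max_species > 8
  out$generations <- ifelse(big, 1000000L, 200000L)
  out$sample_every <- ifelse(big, 5L, 2L)
  out$pre_burnin <- ifelse(big, 100000L, 10000L)
  out$supported <- out$guide_mode == "guided"
  rownames(out) <- NULL
  out[, c("analysis_id", "guide_mode", "max_species", "tau_mean", "theta_mean",
          "run", "seed", "generations", "sample_every", "pre_burnin",
          "supported")]
}
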