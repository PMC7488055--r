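#' Fit the single-threshold generalized mixed Yule-coalescent model
#'
#' GMYC separates between-species (Yule) from within-species (coalescent)
#' branching on an ultrametric tree with a single threshold age T.  Nodes at
#' or above T are speciation events among the species-level branches; each
#' maximal subtree younger than T is a coalescent cluster.  Between
#' successive node ages the total branching rate is
#' `lambda1 * n^p1 + lambda2 * sum_j (n_j (n_j - 1))^p2`, where `n` counts
#' species-level branches present in the interval and `n_j` the lineages of
#' cluster j; each node contributes the rate component of its own process.
#' The scale parameters `lambda1`, `lambda2` (and optionally the exponents
#' `p1`, `p2`) are maximised numerically per candidate threshold; the
#' threshold is profiled over all internal-node ages plus the above-root
#' configuration, which makes the single-coalescent null nested in the
#' candidate set.
#'
#' By default the exponents are fixed at 1 (pure Yule against pure Kingman
#' coalescent): free rate-scaling exponents let extreme thresholds mimic the
#' single-coalescent null (`n^p1` with `p1 ~ 2` reproduces pairwise
#' coalescent rates), which degrades both the calibration of the
#' likelihood-ratio test and threshold recovery; `fix_exponents = FALSE`
#' restores the fully flexible variant.
#'
#' @param tree A [clock_tree()] with at least 3 tips.  Tied node ages are
#'   perturbed by a deterministic relative jitter of 1e-9 before profiling.
#' @param fix_exponents Fix `p1 = p2 = 1` (default) instead of estimating
#'   them.
#' @param exponent_bounds Box bounds for the exponent search.
#' @param df Degrees of freedom used by [gmyc_lrt()] (null has 2 free
#'   parameters, the alternative 5 with the threshold profiled out).
#' @return Object of class `gmyc_fit` with elements `threshold`, `lambda1`,
#'   `p1`, `lambda2`, `p2`, `logL`, `logL0`, `n_entities`, `profile`
#'   (data.frame: threshold, n_entities, logL), `df` and `tree`.
#' @export
fit_gmyc <- function(tree, fix_exponents = TRUE, exponent_bounds = c(0.05, 4),
                     df = 3) {
  stopifnot(inherits(tree, "clock_tree"))
  phy <- tree$phylo
  n <- length(phy$tip.label)
  if (n < 3L) stop("GMYC needs a tree with at least 3 tips")
  M <- n + phy$Nnode
  aget <- tree$age
  ints <- internal_ids(phy)
  # deterministic jitter of tied internal ages (relative 1e-9)
  ia <- aget[ints]
  if (anyDuplicated(ia)) {
    k <- stats::ave(ia, ia, FUN = seq_along)
    aget[ints] <- ia * (1 + (k - 1) * 1e-9)
  }
  par <- parent_vec(phy)
  clades <- clade_list(phy)
  tipcount <- vapply(clades, function(cl) sum(cl <= n), integer(1))
  rt <- root_id(phy)
  ev_t <- sort(aget[ints])
  t_lo <- c(0, ev_t[-(n - 1L)]); t_hi <- ev_t
  x <- t_hi - t_lo
  ev_node <- ints[order(aget[ints])]      # node id of the event ending interval k

  interval_of_age <- function(a) match(a, ev_t)   # ages are exact event times

  threshold_stats <- function(Tc) {
    is_int <- rep(FALSE, M); is_int[ints] <- TRUE
    yule <- is_int & aget >= Tc
    # entity roots: maximal non-yule subtrees and singleton tips
    ent <- logical(M)
    ent[ints] <- !yule[ints] & (par[ints] == 0L | yule[pmax(par[ints], 1L)])
    ent[seq_len(n)] <- par[seq_len(n)] != 0L & yule[par[seq_len(n)]]
    cluster_roots <- which(ent & is_int)
    n_entities <- length(cluster_roots) + sum(ent[seq_len(n)])
    # species-level branches: child is a yule node (non-root) or entity root with parent
    div_child <- which((yule | ent) & par != 0L)
    # per-interval count of species-level branches, by difference array
    inc <- integer(n)
    for (v in div_child) {
      a_c <- aget[v]
      k_from <- if (a_c <= 0) 1L else interval_of_age(a_c) + 1L
      k_to <- interval_of_age(aget[par[v]])
      if (!is.na(k_from) && !is.na(k_to) && k_from <= k_to) {
        inc[k_from] <- inc[k_from] + 1L
        if (k_to + 1L <= n) inc[k_to + 1L] <- inc[k_to + 1L] - 1L
      }
    }
    n_div <- cumsum(inc)[seq_len(n - 1L)]
    # coalescent clusters: (interval, lineage count) pairs with L >= 2
    cl_k <- integer(0); cl_L <- integer(0)
    ev_is_yule <- yule[ev_node]
    ev_L <- rep(NA_integer_, n - 1L)
    for (cr in cluster_roots) {
      sub <- clades[[cr]]
      evc <- sort(aget[sub[sub > n]])
      m_c <- tipcount[cr]
      k_end <- interval_of_age(aget[cr])
      ks <- seq_len(k_end)
      L <- m_c - findInterval(t_lo[ks], evc)
      keep <- L >= 2
      cl_k <- c(cl_k, ks[keep]); cl_L <- c(cl_L, L[keep])
      kev <- interval_of_age(evc)
      ev_L[kev] <- (m_c - findInterval(t_lo[kev], evc))
    }
    list(n_div = n_div, cl_k = cl_k, cl_L = cl_L,
         ev_is_yule = ev_is_yule, ev_L = ev_L, n_entities = n_entities)
  }

  maximise <- function(st) {
    k1 <- sum(st$ev_is_yule); k2 <- (n - 1L) - k1
    ndv <- st$n_div
    cl_pairs <- st$cl_L * (st$cl_L - 1)
    # interval waiting times are exponential with the combined rate
    # b_i = lambda1 * n_i^p1 + lambda2 * sum_j (L_ij (L_ij - 1))^p2 and
    # each node contributes the interval's combined rate (the classic
    # single-threshold mixed-likelihood form)
    S_of <- function(p2) {
      S <- numeric(n - 1L)
      if (length(cl_pairs)) {
        agg <- rowsum(cl_pairs^p2 * 1.0, st$cl_k)
        S[as.integer(rownames(agg))] <- agg[, 1L]
      }
      S
    }
    has_y <- any(ndv > 0)
    has_c <- length(cl_pairs) > 0
    eval_ll <- function(lam1, p1, lam2, p2) {
      b <- numeric(n - 1L)
      if (has_y) b <- b + lam1 * ifelse(ndv > 0, ndv^p1, 0)
      if (has_c) b <- b + lam2 * S_of(p2)
      if (any(b <= 0) || anyNA(b)) return(-Inf)
      sum(log(b)) - sum(b * x)
    }
    # active parameters: log-scales always (when the component exists),
    # exponents only when estimated
    free_p <- !fix_exponents
    decode <- function(q) {
      i <- 0L
      lam1 <- 1; p1 <- 1; lam2 <- 1; p2 <- 1
      if (has_y) { lam1 <- exp(q[i + 1L]); i <- i + 1L }
      if (has_y && free_p) { p1 <- q[i + 1L]; i <- i + 1L }
      if (has_c) { lam2 <- exp(q[i + 1L]); i <- i + 1L }
      if (has_c && free_p) { p2 <- q[i + 1L]; i <- i + 1L }
      list(lam1 = lam1, p1 = p1, lam2 = lam2, p2 = p2)
    }
    obj <- function(q) {
      d <- decode(q)
      v <- eval_ll(d$lam1, d$p1, d$lam2, d$p2)
      if (!is.finite(v)) -1e9 else v
    }
    l1_0 <- if (has_y) log(max(k1, 0.5) / max(sum(ndv * x), 1e-12)) else NULL
    l2_0 <- if (has_c) log(max(k2, 0.5) / max(sum(S_of(1) * x), 1e-12)) else NULL
    p_starts <- if (free_p) list(c(1, 1), c(0.5, 1.5), c(1.8, 0.6)) else list(c(1, 1))
    lo <- c(if (has_y) -40, if (has_y && free_p) exponent_bounds[1],
            if (has_c) -40, if (has_c && free_p) exponent_bounds[1])
    hi <- c(if (has_y) 40, if (has_y && free_p) exponent_bounds[2],
            if (has_c) 40, if (has_c && free_p) exponent_bounds[2])
    best <- NULL
    for (ps in p_starts) {
      q0 <- c(if (has_y) l1_0, if (has_y && free_p) ps[1],
              if (has_c) l2_0, if (has_c && free_p) ps[2])
      o <- if (length(q0) == 1L) {
        stats::optim(q0, function(q) -obj(q), method = "Brent",
                     lower = lo, upper = hi)
      } else {
        stats::optim(q0, function(q) -obj(q), method = "L-BFGS-B",
                     lower = lo, upper = hi,
                     control = list(factr = 1e5, maxit = 200))
      }
      if (is.null(best) || o$value < best$value) best <- o
    }
    d <- decode(best$par)
    list(logL = -best$value, p1 = if (has_y) d$p1 else NA_real_,
         p2 = if (has_c) d$p2 else NA_real_,
         lambda1 = if (has_y) d$lam1 else 0,
         lambda2 = if (has_c) d$lam2 else 0)
  }

  cand <- c(ev_t, Inf)
  prof <- vector("list", length(cand))
  fits <- vector("list", length(cand))
  for (i in seq_along(cand)) {
    st <- threshold_stats(cand[i])
    fit <- maximise(st)
    fits[[i]] <- fit
    prof[[i]] <- data.frame(threshold = cand[i], n_entities = st$n_entities,
                            logL = fit$logL)
  }
  profile <- do.call(rbind, prof)
  logL0 <- profile$logL[length(cand)]      # above-root = single coalescent
  best_i <- which.max(profile$logL)
  best <- fits[[best_i]]
  structure(list(threshold = cand[best_i], lambda1 = best$lambda1,
                 p1 = best$p1, lambda2 = best$lambda2, p2 = best$p2,
                 logL = profile$logL[best_i], logL0 = logL0,
                 n_entities = profile$n_entities[best_i],
                 profile = profile, df = df, tree = tree,
                 age = aget),
            class = "gmyc_fit")
}

#' @export
print.gmyc_fit <- function(x, ...) {
  lrt <- gmyc_lrt(x)
  ci <- gmyc_confidence_set(x)
  cat(sprintf(
    "GMYC fit: %d entities at threshold %.6g (CI %d-%d)\nlogL %.4f vs null %.4f; LR = %.3f, df = %d, p = %.4g %s\n",
    x$n_entities, x$threshold, ci[1], ci[2], x$logL, x$logL0,
    lrt$LR, lrt$df, lrt$p, lrt$stars))
  invisible(x)
}

#' Likelihood-ratio test against the single-coalescent null
#'
#' @param fit A `gmyc_fit`.
#' @return List with `LR` (= 2 (logL - logL0)), `df`, `p` (chi-square upper
#'   tail) and `stars` in `ns`/`*`/`**`/`***` at 0.05 / 0.01 / 0.001.
#' @export
gmyc_lrt <- function(fit) {
  LR <- max(0, 2 * (fit$logL - fit$logL0))
  p <- stats::pchisq(LR, df = fit$df, lower.tail = FALSE)
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
  list(LR = LR, df = fit$df, p = p, stars = stars)
}

#' Confidence set of entity counts from the likelihood profile
#'
#' All candidate thresholds whose profiled log-likelihood is within `delta`
#' of the maximum form the confidence set; its entity-count range is
#' returned (the classic 2-log-likelihood interval at `delta = 2`).
#'
#' @param fit A `gmyc_fit`.
#' @param delta Log-likelihood drop defining the set.
#' @return Integer vector `c(min_entities, max_entities)`.
#' @export
gmyc_confidence_set <- function(fit, delta = 2.0) {
  if (nrow(fit$profile) == 0L) stop("empty profile")
  keep <- fit$profile$logL >= max(fit$profile$logL) - delta
  range(fit$profile$n_entities[keep])
}

#' Extract the delimited entities at a threshold
#'
#' Each maximal subtree whose root age is younger than the threshold is one
#' entity; tips attaching above the threshold are singleton entities.
#'
#' @param fit A `gmyc_fit`.
#' @param threshold Threshold age (defaults to the ML threshold).
#' @return Named character vector tip label -> entity label.
#' @export
gmyc_partition <- function(fit, threshold = fit$threshold) {
  phy <- fit$tree$phylo
  n <- length(phy$tip.label)
  aget <- fit$age
  par <- parent_vec(phy)
  ints <- internal_ids(phy)
  clades <- clade_list(phy)
  is_int <- rep(FALSE, n + phy$Nnode); is_int[ints] <- TRUE
  yule <- is_int & aget >= threshold
  ent_int <- ints[!yule[ints] & (par[ints] == 0L | yule[pmax(par[ints], 1L)])]
  ent_tip <- which(par[seq_len(n)] != 0L & yule[par[seq_len(n)]])
  out <- character(n)
  k <- 0L
  for (v in ent_int) {
    k <- k + 1L
    out[clades[[v]][clades[[v]] <= n]] <- paste0("ent", k)
  }
  for (v in ent_tip) {
    k <- k + 1L
    out[v] <- paste0("ent", k)
  }
  stats::setNames(out, phy$tip.label)
}
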