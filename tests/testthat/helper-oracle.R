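# Brute-force GMYC likelihood oracle, independent of the package internals:
# counts are re-derived by slicing the tree at interval midpoints and walking
# edges with ape primitives; nothing is shared with interval_table() or the
# C++ kernel beyond the model definition.

# node ages of a phylo (tips at 0), by node id
brute_ages <- function(phy) {
  depth <- ape::node.depth.edgelength(phy)
  max(depth[seq_along(phy$tip.label)]) - depth
}

# log-likelihood for given threshold, exponents and rates; rates NULL means
# maximize them numerically (independently of the closed-form profile)
brute_loglik <- function(phy, T, p_yule, p_coal,
                         lambda_yule = NULL, lambda_coal = NULL,
                         attribution = c("event", "combined")) {
  attribution <- match.arg(attribution)
  if (inherits(phy, "gmyc_tree")) phy <- phy$phy
  n <- length(phy$tip.label)
  ages <- brute_ages(phy)
  int_nodes <- (n + 1):(2 * n - 1)
  ranked <- int_nodes[order(ages[int_nodes], decreasing = TRUE)]
  t <- ages[ranked]
  m <- n - 1
  spec_nodes <- ranked[seq_len(T - 1)]  # the T-1 oldest events are speciations
  parent_of <- integer(2 * n - 1)
  parent_of[phy$edge[, 2]] <- phy$edge[, 1]

  # entity root of an edge's segment: walk up from the edge's child until the
  # parent node is a speciation node; intraspecific iff the edge's immediate
  # parent is NOT a speciation node (the root is always a speciation node)
  nint <- m - 1
  A <- C <- numeric(nint)      # Yule count^p, sum of coalescent (s(s-1))^p
  coal_groups <- vector("list", nint)
  for (i in seq_len(nint)) {
    s_time <- (t[i] + t[i + 1]) / 2  # slice inside interval i
    crossing <- which(ages[phy$edge[, 1]] > s_time & ages[phy$edge[, 2]] < s_time)
    stopifnot(length(crossing) == i + 1)
    kind <- character(length(crossing))
    group <- integer(length(crossing))
    for (e in seq_along(crossing)) {
      par <- phy$edge[crossing[e], 1]
      if (par %in% spec_nodes) {
        kind[e] <- "yule"
      } else {
        kind[e] <- "coal"
        g <- par
        while (!(parent_of[g] %in% spec_nodes)) g <- parent_of[g]
        group[e] <- g
      }
    }
    ny <- sum(kind == "yule")
    A[i] <- if (ny > 0) ny^p_yule else 0
    cc <- table(group[kind == "coal"])
    C[i] <- if (length(cc)) sum((as.numeric(cc) * (as.numeric(cc) - 1))^p_coal) else 0
    coal_groups[[i]] <- as.numeric(cc)
  }
  x <- t[seq_len(nint)] - t[seq_len(nint) + 1]
  is_yule_event <- seq_len(nint) <= T - 1  # event rank i terminates interval i

  ll_given <- function(ly, lc) {
    if (attribution == "event") {
      own <- ifelse(is_yule_event, ly * A, lc * C)
      sum(log(own)) - sum((ly * A + lc * C) * x)
    } else {
      b <- ly * A + lc * C
      sum(log(b) - b * x)
    }
  }
  if (is.null(lambda_yule) || is.null(lambda_coal)) {
    # independent numeric maximization (1-D each for "event": separable)
    if (attribution == "event") {
      ey <- sum(is_yule_event)
      ec <- nint - ey
      oy <- if (ey > 0)
        exp(optimize(function(l) ey * l - exp(l) * sum(A * x),
                     c(log(1e-8), log(1e8)), maximum = TRUE,
                     tol = 1e-10)$maximum) else 0
      oc <- if (ec > 0)
        exp(optimize(function(l) ec * l - exp(l) * sum(C * x),
                     c(log(1e-8), log(1e8)), maximum = TRUE,
                     tol = 1e-10)$maximum) else 0
      ly <- if (is.null(lambda_yule)) oy else lambda_yule
      lc <- if (is.null(lambda_coal)) oc else lambda_coal
    } else {
      fit <- optim(c(0, 0), function(lp) -ll_given(exp(lp[1]), exp(lp[2])),
                   method = "Nelder-Mead",
                   control = list(maxit = 5000, reltol = 1e-14))
      ly <- exp(fit$par[1]); lc <- exp(fit$par[2])
      if (!is.null(lambda_yule)) ly <- lambda_yule
      if (!is.null(lambda_coal)) lc <- lambda_coal
    }
  } else {
    ly <- lambda_yule; lc <- lambda_coal
  }
  structure(ll_given(ly, lc), lambda_yule = ly, lambda_coal = lc,
            A = A, C = C, x = x, coal_groups = coal_groups)
}

# enumerated posterior P(T) on a small tree: flat priors, exponents
# integrated by Simpson quadrature on a grid, likelihood from the oracle
brute_posterior_T <- function(phy, p_bounds = c(0, 2), grid = 21) {
  if (inherits(phy, "gmyc_tree")) phy <- phy$phy
  n <- length(phy$tip.label)
  ps <- seq(p_bounds[1], p_bounds[2], length.out = grid)
  wts <- rep(c(2, 4), length.out = grid); wts[1] <- wts[grid] <- 1  # Simpson
  lls <- lapply(2:n, function(T)
    outer(seq_along(ps), seq_along(ps), Vectorize(function(a, b)
      brute_loglik(phy, T, ps[a], ps[b]))))
  gmx <- max(vapply(lls, max, numeric(1)))
  lik <- vapply(lls, function(ll) sum(exp(ll - gmx) * outer(wts, wts)),
                numeric(1))
  lik / sum(lik)
}

# small random ultrametric test trees
random_test_tree <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gmyc_tree(ape::rcoal(n))
}
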