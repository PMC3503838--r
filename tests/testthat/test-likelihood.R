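test_that("process hazards follow their closed forms", {
  expect_equal(yule_rate(1, 5, 1), 5)
  expect_equal(yule_rate(2, 1, 0), 2)
  expect_equal(coal_rate(1, 2, 1), 2)
  expect_equal(coal_rate(1, 1, 1), 0)   # a single lineage cannot coalesce
  expect_equal(coal_rate(0.5, 4, 1), 6)
  expect_error(yule_rate(1, 0, 1), "n")
  expect_error(coal_rate(1, 0.5, 1), "n")

  ## combined hazard: Yule over interspecific + sum over species processes
  expect_equal(combined_rate(3, integer(0), 1, 1, 1, 1), 3)
  expect_equal(combined_rate(1, c(3L), 1, 1, 2, 1), 1 + 2 * 6)
  ## p = 0: lambda_y + (number of active processes) * lambda_c
  expect_equal(combined_rate(2, c(3L, 2L), 1.5, 0, 0.7, 0), 1.5 + 2 * 0.7)
  expect_warning(combined_rate(0, c(1L), 1, 1, 1, 1), "degenerate")
})

test_that("interval log-density is the exponential log-density", {
  expect_equal(interval_loglik(1, 1), -1)
  expect_equal(interval_loglik(1e-12, 1), -1e-12)
  expect_warning(expect_identical(interval_loglik(1, 0), -Inf), "degenerate")
  ## normalization: the density integrates to one for any hazard
  for (b in c(0.2, 1, 7)) {
    z <- integrate(function(x) exp(interval_loglik(x, b)), 0, Inf)
    expect_equal(z$value, 1, tolerance = 1e-6)
  }
  ## sum over a toy table equals the log product of exponential densities
  x <- c(0.5, 1.2, 0.3); b <- c(2, 0.7, 4)
  expect_equal(sum(interval_loglik(x, b)), log(prod(b * exp(-b * x))))
})

test_that("profile rate estimates have closed form and maximize the likelihood", {
  ## pure-Yule toy: intervals (n=2, x=1), (n=3, x=0.5), p=1, 2 events
  tr <- gmyc_tree(ape::read.tree(text =
    "(((a:0.5,b:0.5):0.5,c:1):1,d:2);"))
  tab <- interval_table(tr, 4)
  expect_equal(tab$x, c(1, 0.5))
  expect_equal(tab$n_yule, c(2L, 3L))
  prof <- profile_lambdas(tab, 1, 1)
  expect_equal(prof$lambda_yule, 2 / 3.5, tolerance = 1e-12)
  expect_true(prof$coal_dropped)

  ## single coalescent event: a pair with exposure 2 * x gives the
  ## exponential MLE 1/(2x)
  tr3 <- gmyc_tree(ape::read.tree(text = "(((a:1,b:1):1,c:2):2,d:4);"))
  tab3 <- interval_table(tr3, 2)
  prof3 <- profile_lambdas(tab3, 1, 1)
  expect_equal(prof3$n_events_coal, 1L)
  expect_equal(prof3$lambda_coal, 1 / (2 * tab3$x[2]), tolerance = 1e-12)

  ## profile MLEs agree with independent numeric maximization, and any
  ## +/-1% perturbation lowers the attributed log-likelihood
  for (seed in 1:25) {
    rt <- random_test_tree(sample(5:9, 1), seed = seed)
    T <- sample(2:rt$n_tips, 1)
    py <- runif(1, 0, 2); pc <- runif(1, 0, 2)
    prof <- profile_lambdas(interval_table(rt, T), py, pc)
    br <- brute_loglik(rt$phy, T, py, pc)
    expect_equal(prof$lambda_yule, attr(br, "lambda_yule"), tolerance = 1e-6)
    if (prof$n_events_coal > 0)
      expect_equal(prof$lambda_coal, attr(br, "lambda_coal"),
                   tolerance = 1e-6)
    ll <- function(ly, lc) as.numeric(gmyc_loglik(rt, T, py, pc, ly, lc))
    l0 <- ll(prof$lambda_yule, prof$lambda_coal)
    expect_lt(ll(prof$lambda_yule * 1.01, prof$lambda_coal), l0)
    expect_lt(ll(prof$lambda_yule * 0.99, prof$lambda_coal), l0)
    if (prof$n_events_coal > 0) {
      expect_lt(ll(prof$lambda_yule, prof$lambda_coal * 1.01), l0)
      expect_lt(ll(prof$lambda_yule, prof$lambda_coal * 0.99), l0)
    }
  }
})

test_that("mixed log-likelihood matches the brute-force slicing oracle", {
  for (seed in 1:20) {
    rt <- random_test_tree(sample(5:8, 1), seed = 100 + seed)
    py <- runif(1, 0, 2); pc <- runif(1, 0, 2)
    ly <- runif(1, 0.1, 3); lc <- runif(1, 0.1, 3)
    for (T in 2:rt$n_tips) {
      expect_equal(as.numeric(gmyc_loglik(rt, T, py, pc, ly, lc)),
                   as.numeric(brute_loglik(rt$phy, T, py, pc, ly, lc)),
                   tolerance = 1e-10)
      expect_equal(as.numeric(gmyc_loglik(rt, T, py, pc, ly, lc,
                                          attribution = "combined")),
                   as.numeric(brute_loglik(rt$phy, T, py, pc, ly, lc,
                                           attribution = "combined")),
                   tolerance = 1e-10)
      ## profiled rates against independent numeric maximization
      expect_equal(as.numeric(gmyc_loglik(rt, T, py, pc)),
                   as.numeric(brute_loglik(rt$phy, T, py, pc)),
                   tolerance = 1e-8)
    }
  }
})

test_that("fast kernel agrees with the plain-R likelihood at every threshold", {
  sp <- sim_yule_species_tree(40, 15, 60, seed = 21)
  gt <- gmyc_tree(sim_msc_gene_tree(sp, alleles = 3, seed = 21))
  pre <- gmycbayes:::.precompute(gt)
  for (T in 2:gt$n_tips) {
    for (p in list(c(1, 1), c(0.3, 1.7), c(2, 0), c(0, 1))) {
      expect_equal(gmycbayes:::.eval_fast(pre, T, p[1], p[2])$loglik,
                   as.numeric(gmyc_loglik(gt, T, p[1], p[2])),
                   tolerance = 1e-9)
    }
  }
})

test_that("limiting cases recover the pure processes", {
  ## T = n_tips: equals an independently coded pure-Yule waiting-time logL
  rt <- random_test_tree(12, seed = 41)
  n <- rt$n_tips
  t <- ranked_branching_times(rt)
  x <- t[-length(t)] - t[-1]
  nl <- seq_along(x) + 1
  py <- 1.3
  lam <- (length(x)) / sum(nl^py * x)
  pure_yule <- sum(log(lam * nl^py) - lam * nl^py * x)
  expect_equal(as.numeric(gmyc_loglik(rt, n, py, 1)), pure_yule,
               tolerance = 1e-10)

  ## T = 2, p_c = 1, given rates: coalescent events carry exact Kingman
  ## hazards (lambda * n(n-1)) over the inter-event intervals
  tr <- gmyc_tree(ape::read.tree(text =
    "(((a:1,b:1):0.5,c:1.5):1.5,(d:2,e:2):1);"))
  lc <- 0.5; ly <- 0.25
  got <- as.numeric(gmyc_loglik(tr, 2, 1, 1, ly, lc))
  br <- brute_loglik(tr$phy, 2, 1, 1, ly, lc)
  expect_equal(got, as.numeric(br), tolerance = 1e-12)
  ## hand check: root interval is a pure Yule term; each coalescent event
  ## contributes log(lc * s(s-1)) with s its cluster's lineage count
  A <- attr(br, "A"); C <- attr(br, "C"); x <- attr(br, "x")
  hand <- log(ly * A[1]) + sum(log(lc * C[-1])) - sum((ly * A + lc * C) * x)
  expect_equal(got, hand, tolerance = 1e-12)

  ## label symmetry: relabeling tips leaves the likelihood unchanged
  rt2 <- rt
  rt2$phy$tip.label <- sample(rt$phy$tip.label)
  rt2 <- gmyc_tree(rt2$phy)
  for (T in c(2, 6, 12))
    expect_equal(as.numeric(gmyc_loglik(rt2, T, 0.8, 1.2)),
                 as.numeric(gmyc_loglik(rt, T, 0.8, 1.2)), tolerance = 1e-10)
})

test_that("single-process null model is the one-entity likelihood", {
  rt <- random_test_tree(15, seed = 77)
  nll <- null_loglik(rt, p = 1)
  ## independent: one coalescent process over all inter-event intervals
  t <- ranked_branching_times(rt)
  x <- t[-length(t)] - t[-1]
  nl <- seq_along(x) + 1
  C <- nl * (nl - 1)
  lam <- length(x) / sum(C * x)
  expect_equal(as.numeric(nll), sum(log(lam * C) - lam * C * x),
               tolerance = 1e-10)
  ## optimized exponent stays within its box
  nopt <- null_loglik(rt)
  expect_gte(attr(nopt, "p"), 0)
  expect_lte(attr(nopt, "p"), 2)
  expect_gte(as.numeric(nopt), as.numeric(nll))
})
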