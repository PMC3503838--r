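test_that("fixed seed gives bitwise-identical traces", {
  rt <- random_test_tree(12, seed = 2)
  a <- gmyc_mcmc(rt, n_steps = 2000, burnin = 200, thin = 5, seed = 7)
  b <- gmyc_mcmc(rt, n_steps = 2000, burnin = 200, thin = 5, seed = 7)
  expect_identical(a$trace, b$trace)
  expect_identical(a$acceptance, b$acceptance)
  ## multi-tree runs derive per-tree substreams from the one seed
  trees <- list(rt, random_test_tree(12, seed = 3))
  m1 <- gmyc_mcmc(trees, n_steps = 1000, burnin = 100, thin = 10, seed = 5)
  m2 <- gmyc_mcmc(trees, n_steps = 1000, burnin = 100, thin = 10, seed = 5)
  expect_identical(m1$trace, m2$trace)
})

test_that("trace rows respect the model contracts", {
  rt <- random_test_tree(15, seed = 8)
  fit <- gmyc_mcmc(rt, n_steps = 3000, burnin = 300, thin = 3, seed = 11)
  tr <- fit$trace
  expect_equal(tr$n_species, tr$threshold)
  expect_true(all(tr$threshold >= 2 & tr$threshold <= 15))
  expect_true(all(tr$p_yule >= 0 & tr$p_yule <= 2))
  expect_true(all(tr$p_coal >= 0 & tr$p_coal <= 2))
  expect_equal(tr$threshold_time, rt$ranked_ages[tr$threshold - 1L])
  ## narrower prior support is honored
  pr <- gmyc_priors(threshold = c(3, 8), p_yule = c(0, 1.2))
  fit2 <- gmyc_mcmc(rt, n_steps = 2000, burnin = 200, thin = 2, seed = 1,
                    priors = pr)
  expect_true(all(fit2$trace$threshold >= 3 & fit2$trace$threshold <= 8))
  expect_true(all(fit2$trace$p_yule <= 1.2))
  ## out-of-support states have zero posterior density
  expect_identical(log_posterior(rt, 9, 1, 1, priors = pr), -Inf)
  expect_identical(log_posterior(rt, 5, 1.5, 1, priors = pr), -Inf)
  ## flat priors: log-posterior differences equal log-likelihood differences
  d1 <- log_posterior(rt, 5, 1, 1) - log_posterior(rt, 4, 1, 1)
  d2 <- as.numeric(gmyc_loglik(rt, 5, 1, 1)) -
    as.numeric(gmyc_loglik(rt, 4, 1, 1))
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("sampler matches the exhaustively enumerated posterior", {
  rt <- random_test_tree(6, seed = 42)
  ## fixed exponents: posterior over T by direct normalization
  py <- 0.8; pc <- 1.1
  lp <- vapply(2:6, function(T) log_posterior(rt, T, py, pc), numeric(1))
  post_fixed <- exp(lp - max(lp)); post_fixed <- post_fixed / sum(post_fixed)
  br <- vapply(2:6, function(T) as.numeric(brute_loglik(rt$phy, T, py, pc)),
               numeric(1))
  post_br <- exp(br - max(br)); post_br <- post_br / sum(post_br)
  expect_equal(post_fixed, post_br, tolerance = 1e-6)

  ## full posterior: long chain vs quadrature-enumerated marginal P(T)
  enum <- brute_posterior_T(rt$phy, grid = 21)
  fit <- gmyc_mcmc(rt, n_steps = 60000, burnin = 5000, thin = 2, seed = 9)
  emp <- tabulate(fit$trace$threshold - 1L, nbins = 5) / nrow(fit$trace)
  expect_lt(sum(abs(emp - enum)) / 2, 0.02)   # total variation
})

test_that("with the likelihood off the sampler recovers its priors", {
  rt <- random_test_tree(20, seed = 4)
  ## wide proposals + heavy thinning: the tests assume near-independent draws
  fit <- gmyc_mcmc(rt, n_steps = 600000, burnin = 2000, thin = 300, seed = 21,
                   p_window = 0.6, likelihood_off = TRUE)
  tr <- fit$trace
  ## threshold: discrete uniform on 2..20
  counts <- tabulate(tr$threshold - 1L, nbins = 19)
  expect_gt(suppressWarnings(chisq.test(counts)$p.value), 0.001)
  ## exponents: continuous uniform on (0, 2)
  ks <- suppressWarnings(stats::ks.test(tr$p_yule, "punif", 0, 2))
  expect_gt(ks$p.value, 0.001)
  ks2 <- suppressWarnings(stats::ks.test(tr$p_coal, "punif", 0, 2))
  expect_gt(ks2$p.value, 0.001)
})

test_that("multi-tree pooling follows the stated protocol", {
  trees <- replicate(5, ape::rcoal(8), simplify = FALSE)
  tl <- lapply(trees, function(x) { x$tip.label <- paste0("t", 1:8); x })
  fit <- gmyc_mcmc(tl, seed = 3)   # default 10000/1000/100: 90 per tree
  expect_equal(nrow(fit$trace), 5L * 90L)
  expect_equal(sort(unique(fit$trace$tree_id)), 1:5)
  ## identical trees pool to the single-tree posterior
  same <- replicate(4, tl[[1L]], simplify = FALSE)
  pooled <- gmyc_mcmc(same, n_steps = 20000, burnin = 2000, thin = 10,
                      seed = 13)
  single <- gmyc_mcmc(tl[[1L]], n_steps = 80000, burnin = 8000, thin = 10,
                      seed = 14)
  p1 <- tabulate(pooled$trace$threshold - 1L, nbins = 7) / nrow(pooled$trace)
  p2 <- tabulate(single$trace$threshold - 1L, nbins = 7) / nrow(single$trace)
  expect_lt(sum(abs(p1 - p2)) / 2, 0.05)
  ## differing tip sets are rejected
  bad <- list(tl[[1L]], ape::rcoal(9))
  expect_error(gmyc_mcmc(bad, seed = 1), "tip set")
})

test_that("effective sample size matches closed forms", {
  set.seed(10)
  iid <- rnorm(2000)
  expect_lt(abs(ess(iid) - 2000) / 2000, 0.2)
  ## AR(1): ESS/n = (1 - phi) / (1 + phi)
  phi <- 0.9
  n <- 20000
  x <- as.numeric(stats::arima.sim(list(ar = phi), n))
  theory <- n * (1 - phi) / (1 + phi)
  expect_lt(abs(ess(x) - theory) / theory, 0.4)
  cst <- ess(rep(3.2, 500))
  expect_true(isTRUE(attr(cst, "degenerate")))
  expect_equal(as.numeric(cst), 500)
  expect_error(ess(rnorm(5)), "10 samples")
})

test_that("summary, plotting and trace export run end to end", {
  rt <- random_test_tree(10, seed = 6)
  fit <- gmyc_mcmc(rt, n_steps = 4000, burnin = 400, thin = 4, seed = 2)
  expect_output(print(fit), "HPD")
  ## short demonstration chain: the low-ESS warning is expected here
  s <- suppressWarnings(summary(fit))
  expect_output(print(s), "effective sample sizes")
  f <- withr::local_tempfile(fileext = ".csv")
  write_trace(fit, f)
  expect_true(file.exists(f))
  man <- jsonlite::read_json(sub("\\.csv$", ".manifest.json", f))
  expect_equal(man$seed, 2L)
  expect_equal(man$config$n_steps, 4000L)
  back <- read.csv(f)
  expect_equal(nrow(back), nrow(fit$trace))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
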