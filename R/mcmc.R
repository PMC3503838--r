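## Metropolis-Hastings sampler for the GMYC posterior on one tree, and
## pooling across a posterior sample of trees.

#' Prior specification for the Bayesian GMYC
#'
#' Uniform priors: discrete uniform on the threshold rank and continuous
#' uniform on the two rate-change exponents. An informative (narrower)
#' exponent prior can be used to exclude biologically implausible rate
#' accelerations.
#'
#' @param threshold integer bounds (inclusive) for the threshold rank;
#'   `NULL` uses `c(2, n_tips)` of the analyzed tree.
#' @param p_yule,p_coal numeric bounds for the exponents.
#' @return an object of class `gmyc_priors`.
#' @export
gmyc_priors <- function(threshold = NULL, p_yule = c(0, 2), p_coal = c(0, 2)) {
  chk <- function(b, name) {
    if (length(b) != 2L || b[1] >= b[2])
      stop(sprintf("'%s' must be c(lower, upper) with lower < upper", name))
  }
  if (!is.null(threshold)) chk(threshold, "threshold")
  chk(p_yule, "p_yule"); chk(p_coal, "p_coal")
  structure(list(threshold = threshold, p_yule = p_yule, p_coal = p_coal),
            class = "gmyc_priors")
}

#' @export
print.gmyc_priors <- function(x, ...) {
  thr <- if (is.null(x$threshold)) "U(2, n_tips)" else
    sprintf("U(%d, %d)", x$threshold[1], x$threshold[2])
  cat(sprintf("GMYC priors: threshold ~ %s, p_yule ~ U(%g, %g), p_coal ~ U(%g, %g)\n",
              thr, x$p_yule[1], x$p_yule[2], x$p_coal[1], x$p_coal[2]))
  invisible(x)
}

#' Unnormalized log-posterior of the GMYC model
#'
#' Flat-prior log-posterior: the profiled log-likelihood within the prior
#' support and `-Inf` outside. The branching rates are profiled at their
#' conditional MLEs rather than sampled.
#'
#' @inheritParams gmyc_loglik
#' @param priors a [gmyc_priors()] object.
#' @return unnormalized log posterior density.
#' @export
log_posterior <- function(tree, threshold, p_yule, p_coal,
                          priors = gmyc_priors()) {
  tree <- gmyc_tree(tree)
  tb <- if (is.null(priors$threshold)) c(2L, tree$n_tips) else priors$threshold
  if (threshold < tb[1] || threshold > tb[2] ||
      p_yule < priors$p_yule[1] || p_yule > priors$p_yule[2] ||
      p_coal < priors$p_coal[1] || p_coal > priors$p_coal[2]) return(-Inf)
  as.numeric(gmyc_loglik(tree, threshold, p_yule, p_coal))
}

#' Bayesian GMYC fit by Markov chain Monte Carlo
#'
#' Runs a Metropolis-Hastings chain over the threshold rank and the two
#' rate-change exponents for each input tree (branching rates are profiled at
#' each step) and pools the post-burn-in, thinned samples. Pooling chains run
#' on many trees drawn from a Bayesian tree posterior yields marginal species
#' limits that integrate over phylogenetic uncertainty; a single tree gives
#' the fixed-tree (e.g. MCC-tree) analysis.
#'
#' Moves are symmetric and reflected at the prior bounds: an integer random
#' walk of step `<= t_step` on the threshold and sliding-window proposals of
#' width `p_window` on the exponents; each step updates one of the three
#' parameters chosen uniformly at random. Defaults follow common practice for
#' tree-posterior pooling (10,000 steps, 1,000 burn-in, thin 100, i.e. 90
#' retained samples per tree); single-tree simulation-style analyses
#' typically use longer chains (e.g. 100,000/10,000/100).
#'
#' @param x a `gmyc_tree`/`phylo` or a list of them (all with identical tip
#'   sets).
#' @param n_steps,burnin,thin chain length, discarded initial steps, and the
#'   interval at which post-burn-in samples are retained (per tree).
#' @param priors a [gmyc_priors()] object.
#' @param seed integer seed; a per-tree substream is derived from it so
#'   multi-tree runs are reproducible. `NULL` draws one and records it.
#' @param t_step,p_window proposal widths (threshold step bound, exponent
#'   window).
#' @param t_jump_prob probability that a threshold move is an independence
#'   draw from the uniform threshold prior instead of a random-walk step.
#'   The likelihood surface typically has a weak local optimum at the
#'   all-singletons corner `T = n_tips`; the occasional independent jump
#'   lets the chain cross the barrier in both directions (the proposal is
#'   symmetric, so the acceptance rule is unchanged). Set to 0 for a pure
#'   random walk.
#' @param init `"prior"` (default) draws the initial state from the priors
#'   (overdispersed starts); `"profile"` starts at the threshold maximizing
#'   the profiled likelihood under neutral exponents (`p = 1`).
#' @param likelihood_off internal test hook: sample from the prior only.
#' @return an object of class `gmyc_mcmc`: a list with `trace` (data frame:
#'   `tree_id`, `step`, `threshold`, `p_yule`, `p_coal`, `lambda_yule`,
#'   `lambda_coal`, `log_posterior`, `n_species`, `threshold_time`),
#'   `acceptance` (per tree and move type), `config`, `priors`, `seed` and
#'   `trees`.
#' @examples
#' \donttest{
#' tr <- sim_yule_species_tree(12, 8, depth = 10, seed = 1)
#' fit <- gmyc_mcmc(tr, n_steps = 2000, burnin = 200, thin = 10, seed = 1)
#' summary(fit)
#' }
#' @export
gmyc_mcmc <- function(x, n_steps = 10000, burnin = 1000, thin = 100,
                      priors = gmyc_priors(), seed = NULL,
                      t_step = 3L, p_window = 0.2, t_jump_prob = 0.1,
                      init = c("prior", "profile"),
                      likelihood_off = FALSE) {
  init <- match.arg(init)
  trees <- if (inherits(x, "gmyc_tree") || inherits(x, "phylo")) list(x) else x
  trees <- lapply(trees, gmyc_tree)
  if (length(trees) == 0L) stop("no trees supplied")
  tips <- sort(trees[[1L]]$phy$tip.label)
  for (tr in trees)
    if (!identical(sort(tr$phy$tip.label), tips))
      stop("all trees must share the same tip set (marginal probabilities are undefined otherwise)")
  if (burnin >= n_steps) stop("'burnin' must be smaller than 'n_steps'")
  if (thin < 1L) stop("'thin' must be >= 1")
  n <- trees[[1L]]$n_tips
  tb <- if (is.null(priors$threshold)) c(2L, n) else as.integer(priors$threshold)
  if (tb[1] < 2L || tb[2] > n) stop("threshold prior bounds must lie in [2, n_tips]")

  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, length(trees))

  traces <- vector("list", length(trees))
  acc <- vector("list", length(trees))
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    pre <- .precompute(tr)
    set.seed(sub_seeds[i])
    if (init == "profile" && !likelihood_off) {
      cand <- tb[1]:tb[2]
      ll <- vapply(cand, function(T) .eval_fast(pre, T, 1, 1)$loglik,
                   numeric(1))
      init_T <- cand[which.max(ll)]
      init_py <- min(max(1, priors$p_yule[1]), priors$p_yule[2])
      init_pc <- min(max(1, priors$p_coal[1]), priors$p_coal[2])
    } else {
      init_T <- sample(tb[1]:tb[2], 1L)
      init_py <- runif(1, priors$p_yule[1], priors$p_yule[2])
      init_pc <- runif(1, priors$p_coal[1], priors$p_coal[2])
    }
    res <- gmyc_chain_cpp(pre, as.integer(n_steps), as.integer(burnin),
                          as.integer(thin), tb[1], tb[2],
                          priors$p_yule[1], priors$p_yule[2],
                          priors$p_coal[1], priors$p_coal[2],
                          as.integer(t_step), p_window, t_jump_prob,
                          !likelihood_off, init_T, init_py, init_pc)
    s <- as.data.frame(res$samples)
    if (sum(res$accepted) == 0L)
      stop("chain accepted no proposals; retune proposal widths (t_step, p_window)")
    s$tree_id <- i
    s$n_species <- as.integer(s$threshold)
    s$threshold_time <- tr$ranked_ages[s$n_species - 1L]
    traces[[i]] <- s
    acc[[i]] <- data.frame(tree_id = i,
                           move = c("threshold", "p_yule", "p_coal"),
                           proposed = res$proposed, accepted = res$accepted,
                           rate = ifelse(res$proposed > 0,
                                         res$accepted / res$proposed, NA))
  }
  trace <- do.call(rbind, traces)
  trace <- trace[, c("tree_id", "step", "threshold", "p_yule", "p_coal",
                     "lambda_yule", "lambda_coal", "log_posterior",
                     "n_species", "threshold_time")]
  rownames(trace) <- NULL
  structure(list(
    trace = trace,
    acceptance = do.call(rbind, acc),
    config = list(n_steps = n_steps, burnin = burnin, thin = thin,
                  t_step = t_step, p_window = p_window,
                  likelihood_off = likelihood_off),
    priors = priors,
    seed = seed,
    sub_seeds = sub_seeds,
    trees = trees
  ), class = "gmyc_mcmc")
}

#' @export
print.gmyc_mcmc <- function(x, ...) {
  cat(sprintf(
    "Bayesian GMYC fit: %d tree(s), %d pooled samples (%d steps, %d burn-in, thin %d; seed %d)\n",
    length(x$trees), nrow(x$trace), x$config$n_steps, x$config$burnin,
    x$config$thin, x$seed))
  s <- species_number_summary(x)
  cat(sprintf("  posterior mean number of species: %.2f; 95%% HPD [%d, %d]\n",
              s$mean, s$hpd[1], s$hpd[2]))
  invisible(x)
}

#' @export
summary.gmyc_mcmc <- function(object, ...) {
  out <- list(species = species_number_summary(object),
              ess = ess(object),
              acceptance = object$acceptance,
              config = object$config, seed = object$seed,
              n_trees = length(object$trees))
  class(out) <- "summary.gmyc_mcmc"
  out
}

#' @export
print.summary.gmyc_mcmc <- function(x, ...) {
  cat(sprintf("Bayesian GMYC posterior over %d tree(s)\n", x$n_trees))
  cat(sprintf("  species number: mean %.2f, mode %d, 95%% HPD [%d, %d]\n",
              x$species$mean, x$species$mode, x$species$hpd[1], x$species$hpd[2]))
  cat("  effective sample sizes (pooled):\n")
  print(x$ess$pooled, row.names = FALSE, digits = 4)
  cat("  mean acceptance rates:\n")
  a <- stats::aggregate(rate ~ move, data = x$acceptance, FUN = mean)
  print(a, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
as.data.frame.gmyc_mcmc <- function(x, ...) x$trace

#' @export
plot.gmyc_mcmc <- function(x, ...) {
  op <- par(mfrow = c(1, 2)); on.exit(par(op))
  plot(seq_len(nrow(x$trace)), x$trace$n_species, type = "l",
       xlab = "retained sample", ylab = "number of species", ...)
  pmf <- species_number_summary(x)$pmf
  plot(pmf$n_species, pmf$probability, type = "h",
       xlab = "number of species", ylab = "posterior probability", ...)
  invisible(x)
}

#' Effective sample size
#'
#' Autocorrelation-based ESS using Geyer's initial monotone positive
#' sequence estimator: `ESS = n / (1 + 2 sum rho_k)` with the sum truncated
#' where consecutive autocorrelation pairs stop being positive and
#' monotone. A constant trace is flagged (`degenerate`) and reported at the
#' number of samples.
#'
#' @param x a numeric vector, or a `gmyc_mcmc` fit.
#' @param ... passed to methods.
#' @return for vectors, a single number (attribute `degenerate` when the
#'   trace is constant); for fits, a list with per-tree and pooled ESS per
#'   parameter.
#' @export
ess <- function(x, ...) UseMethod("ess")

#' @export
ess.numeric <- function(x, ...) {
  n <- length(x)
  if (n < 10L) stop("need at least 10 samples")
  if (var(x) == 0) return(structure(as.numeric(n), degenerate = TRUE))
  max_lag <- min(n - 1L, max(50L, floor(10 * log10(n))))
  rho <- as.numeric(acf(x, lag.max = max_lag, plot = FALSE,
                        demean = TRUE)$acf)[-1L]
  ## Geyer: sums of adjacent pairs must stay positive and non-increasing
  npair <- floor(length(rho) / 2)
  gsum <- 0
  prev <- Inf
  for (k in seq_len(npair)) {
    pair <- rho[2 * k - 1] + rho[2 * k]
    if (pair < 0) break
    pair <- min(pair, prev)
    gsum <- gsum + pair
    prev <- pair
  }
  max(1, min(n, n / (1 + 2 * gsum)))
}

#' @export
ess.gmyc_mcmc <- function(x, ...) {
  pars <- c("n_species", "p_yule", "p_coal", "threshold_time")
  per_tree <- do.call(rbind, lapply(split(x$trace, x$trace$tree_id), function(d) {
    data.frame(tree_id = d$tree_id[1L],
               parameter = pars,
               ess = vapply(pars, function(p) as.numeric(ess(d[[p]])), numeric(1)),
               n = nrow(d))
  }))
  rownames(per_tree) <- NULL
  pooled <- data.frame(parameter = pars,
                       ess = vapply(pars, function(p)
                         as.numeric(ess(x$trace[[p]])), numeric(1)),
                       n = nrow(x$trace))
  low <- per_tree$ess < 150 & per_tree$n >= 150
  if (any(low))
    warning(sprintf("ESS below 150 for %d per-tree parameter trace(s); consider longer chains",
                    sum(low)))
  list(per_tree = per_tree, pooled = pooled)
}

#' Export an MCMC trace as CSV plus a JSON run manifest
#'
#' Writes one row per retained sample and a manifest (seed, priors, chain
#' configuration, tree digests) sufficient to reproduce the run.
#'
#' @param x a `gmyc_mcmc` fit.
#' @param path output CSV file; the manifest is written alongside with
#'   extension `.manifest.json`.
#' @return `path`, invisibly.
#' @export
write_trace <- function(x, path) {
  stopifnot(inherits(x, "gmyc_mcmc"))
  write.csv(x$trace, path, row.names = FALSE)
  manifest <- list(
    seed = x$seed, config = x$config,
    priors = list(threshold = x$priors$threshold, p_yule = x$priors$p_yule,
                  p_coal = x$priors$p_coal),
    n_trees = length(x$trees),
    tree_digest = vapply(x$trees, function(tr)
      sprintf("%d tips, root %.12g", tr$n_tips, tr$ranked_ages[1L]), character(1)))
  jsonlite::write_json(manifest, sub("\\.csv$", ".manifest.json", path),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
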