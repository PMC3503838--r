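## The GMYC likelihood: per-process hazards, interval density, profile MLEs
## for the branching rates, and the mixed log-likelihood.

#' Branching-process hazards
#'
#' `yule_rate()` is the instantaneous speciation hazard
#' \eqn{\lambda n^p} of `n` species-level lineages; `coal_rate()` is the
#' within-species coalescence hazard \eqn{\lambda (n(n-1))^p} of `n` sampled
#' lineages in one species (zero for a single lineage, which cannot
#' coalesce). Under neutral scaling `p = 1`, and for the coalescent
#' \eqn{\lambda} is interpretable as \eqn{1/(N_e \mu)} in the branch-length
#' units of the tree. The exponent `p` absorbs temporal change in
#' diversification rate (Yule) or population size (coalescent).
#'
#' @param lambda branching rate, events per unit branch length; `> 0`.
#' @param n number of lineages in the interval; `>= 1`.
#' @param p rate-change exponent; `>= 0`.
#' @return the hazard (rate of the next event).
#' @examples
#' yule_rate(1, 44, 1.9) / yule_rate(1, 44, 1)  # ~30-fold rate increase
#' coal_rate(1, 1, 1)                           # 0: singletons cannot coalesce
#' @export
yule_rate <- function(lambda, n, p) {
  .check_rate_args(lambda, n, p)
  lambda * n^p
}

#' @rdname yule_rate
#' @export
coal_rate <- function(lambda, n, p) {
  .check_rate_args(lambda, n, p)
  lambda * (n * (n - 1))^p
}

.check_rate_args <- function(lambda, n, p) {
  if (any(n < 1)) stop("'n' must be >= 1")
  if (any(lambda < 0)) stop("'lambda' must be positive")
  if (any(p < 0)) stop("'p' must be >= 0")
  invisible(NULL)
}

#' Combined hazard of one waiting interval
#'
#' The total branching hazard `b` of an interval: the Yule hazard of its
#' interspecific lineages plus the coalescent hazard summed over the active
#' within-species processes. Intervals in which no process has two lineages
#' are degenerate (`b = 0`) and flagged with a warning.
#'
#' @param n_yule number of interspecific (Yule-process) lineages.
#' @param coal_counts integer vector of within-species lineage counts, one
#'   entry per coalescent process active in the interval.
#' @param lambda_yule,p_yule Yule rate and exponent.
#' @param lambda_coal,p_coal shared coalescent rate and exponent.
#' @return the combined hazard `b`.
#' @export
combined_rate <- function(n_yule, coal_counts, lambda_yule, p_yule,
                          lambda_coal, p_coal) {
  b <- 0
  if (n_yule >= 1) b <- b + yule_rate(lambda_yule, n_yule, p_yule)
  for (s in coal_counts) b <- b + coal_rate(lambda_coal, s, p_coal)
  if (b <= 0)
    warning("degenerate interval: combined hazard b = 0")
  b
}

#' Log-density of one exponential waiting time
#'
#' \eqn{\log(b) - b x}: the log of the exponential density of a waiting time
#' `x` under hazard `b`. Returns `-Inf` with a warning for `b <= 0`.
#'
#' @param x waiting time, `> 0`.
#' @param b hazard.
#' @return log density.
#' @export
interval_loglik <- function(x, b) {
  if (any(x <= 0)) stop("'x' must be > 0")
  n <- max(length(x), length(b))
  x <- rep_len(x, n)
  b <- rep_len(b, n)
  out <- rep(-Inf, n)
  ok <- b > 0
  out[ok] <- log(b[ok]) - b[ok] * x[ok]
  if (any(!ok)) warning("degenerate assignment: b <= 0 gives -Inf")
  out
}

#' Closed-form profile estimates of the branching rates
#'
#' Conditional maximum-likelihood estimates of the Yule and coalescent
#' branching rates given a threshold and the rate-change exponents, under the
#' event-attribution convention (each branching event contributes the hazard
#' of its own process; survival uses the combined hazard):
#' \deqn{\hat\lambda_{proc} = E_{proc} / \sum_i c_{i,proc}\, x_i}
#' where \eqn{E_{proc}} counts the events attributed to the process and
#' \eqn{c_{i,yule} = n_{i,k+1}^{p}}, \eqn{c_{i,coal} = \sum_j
#' (n_{ij}(n_{ij}-1))^{p}}. A process with zero attributed events has its
#' rate profiled at 0 (it drops from the likelihood) and is flagged.
#'
#' @param table a `gmyc_intervals` object from [interval_table()].
#' @param p_yule,p_coal rate-change exponents.
#' @return list with `lambda_yule`, `lambda_coal`, event counts and the
#'   weighted exposure sums; entries for a process with no events carry
#'   `dropped = TRUE` flags.
#' @export
profile_lambdas <- function(table, p_yule, p_coal) {
  stopifnot(inherits(table, "gmyc_intervals"))
  A <- ifelse(table$n_yule > 0, table$n_yule^p_yule, 0)
  C <- vapply(table$coal_counts, function(s) {
    if (!length(s)) 0 else sum((s * (s - 1))^p_coal)
  }, numeric(1))
  ey <- sum(table$event_process == "yule")
  ec <- sum(table$event_process == "coalescent")
  sumAx <- sum(A * table$x)
  sumCx <- sum(C * table$x)
  list(lambda_yule = if (ey > 0) ey / sumAx else 0,
       lambda_coal = if (ec > 0) ec / sumCx else 0,
       n_events_yule = ey, n_events_coal = ec,
       exposure_yule = sumAx, exposure_coal = sumCx,
       yule_dropped = ey == 0, coal_dropped = ec == 0)
}

#' GMYC log-likelihood of a tree
#'
#' The mixed Yule-coalescent log-likelihood of the inter-event waiting times
#' of an ultrametric tree for a given threshold rank and rate-change
#' exponents.
#'
#' With `attribution = "event"` (default) each branching event contributes
#' the log-hazard of its own process while survival uses the combined hazard;
#' the branching rates then have closed-form profile MLEs
#' ([profile_lambdas()]) which are used when `lambda_yule`/`lambda_coal` are
#' `NULL`. With `attribution = "combined"` every interval contributes
#' \eqn{\log b - b x} with the combined hazard `b` regardless of which
#' process the terminating event belongs to; rates are then maximized
#' numerically when not supplied. The two modes agree whenever only one
#' process is active in every interval.
#'
#' @inheritParams interval_table
#' @param p_yule,p_coal rate-change exponents (`>= 0`).
#' @param lambda_yule,lambda_coal branching rates; `NULL` profiles/maximizes
#'   them.
#' @param attribution `"event"` or `"combined"`, see Details.
#' @return the log-likelihood, with attributes `lambda_yule`, `lambda_coal`.
#' @export
gmyc_loglik <- function(tree, threshold, p_yule = 1, p_coal = 1,
                        lambda_yule = NULL, lambda_coal = NULL,
                        attribution = c("event", "combined")) {
  attribution <- match.arg(attribution)
  tab <- interval_table(tree, threshold)
  .gmyc_loglik_table(tab, p_yule, p_coal, lambda_yule, lambda_coal,
                     attribution)
}

.gmyc_loglik_table <- function(tab, p_yule, p_coal, lambda_yule, lambda_coal,
                               attribution) {
  A <- ifelse(tab$n_yule > 0, tab$n_yule^p_yule, 0)
  C <- vapply(tab$coal_counts, function(s) {
    if (!length(s)) 0 else sum((s * (s - 1))^p_coal)
  }, numeric(1))
  is_yule <- tab$event_process == "yule"
  if (attribution == "event") {
    prof <- profile_lambdas(tab, p_yule, p_coal)
    ly <- if (is.null(lambda_yule)) prof$lambda_yule else lambda_yule
    lc <- if (is.null(lambda_coal)) prof$lambda_coal else lambda_coal
    own <- ifelse(is_yule, ly * A, lc * C)
    ll <- sum(ifelse(own > 0, log(own), -Inf)) -
      sum((ly * A + lc * C) * tab$x)
    if (any(own <= 0))
      warning("event with zero own-process hazard: log-likelihood is -Inf")
  } else {
    obj <- function(loglam) {
      b <- exp(loglam[1]) * A + exp(loglam[2]) * C
      -sum(ifelse(b > 0, log(b) - b * tab$x, -Inf))
    }
    if (is.null(lambda_yule) || is.null(lambda_coal)) {
      prof <- profile_lambdas(tab, p_yule, p_coal)  # starting values
      start <- log(pmax(c(prof$lambda_yule, prof$lambda_coal), 1e-8))
      free_c <- any(C > 0)
      if (!free_c) {
        fit <- optimize(function(l) obj(c(l, -50)), lower = start[1] - 12,
                        upper = start[1] + 12)
        ly <- exp(fit$minimum); lc <- 0
        ll <- -fit$objective
      } else {
        fit <- optim(start, obj, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-12))
        ly <- exp(fit$par[1]); lc <- exp(fit$par[2])
        ll <- -fit$value
      }
      if (!is.null(lambda_yule) || !is.null(lambda_coal)) {
        ly <- if (is.null(lambda_yule)) ly else lambda_yule
        lc <- if (is.null(lambda_coal)) lc else lambda_coal
        b <- ly * A + lc * C
        ll <- sum(ifelse(b > 0, log(b) - b * tab$x, -Inf))
      }
    } else {
      ly <- lambda_yule; lc <- lambda_coal
      b <- ly * A + lc * C
      ll <- sum(ifelse(b > 0, log(b) - b * tab$x, -Inf))
    }
  }
  structure(ll, lambda_yule = ly, lambda_coal = lc)
}

#' Single-process null log-likelihood
#'
#' Treats the whole tree as one coalescent process (a single panmictic
#' population): every inter-event interval with `n` lineages has hazard
#' \eqn{\lambda (n(n-1))^p}, the single rate is profiled in closed form and,
#' when `p = NULL`, the exponent is maximized within `p_bounds`.
#'
#' @inheritParams gmyc_loglik
#' @param p the rate-change exponent; `NULL` maximizes it.
#' @param p_bounds box constraint for the exponent search.
#' @return log-likelihood with attributes `p` and `lambda`.
#' @export
null_loglik <- function(tree, p = NULL, p_bounds = c(0, 2)) {
  tree <- gmyc_tree(tree)
  m <- tree$n_tips - 1L
  nint <- m - 1L
  x <- tree$ranked_ages[seq_len(nint)] - tree$ranked_ages[seq_len(nint) + 1L]
  n <- seq_len(nint) + 1L
  ll_at <- function(p) {
    C <- (n * (n - 1))^p
    lam <- nint / sum(C * x)
    sum(log(C)) + nint * (log(lam) - 1)
  }
  if (is.null(p)) {
    fit <- optimize(ll_at, lower = p_bounds[1], upper = p_bounds[2],
                    maximum = TRUE)
    p <- fit$maximum
    ll <- fit$objective
  } else {
    ll <- ll_at(p)
  }
  C <- (n * (n - 1))^p
  structure(ll, p = p, lambda = nint / sum(C * x))
}

## C++ fast path on a precomputed tree; same conventions as gmyc_loglik
.eval_fast <- function(pre, threshold, p_yule, p_coal, return_rates = FALSE) {
  gmyc_eval_cpp(pre, as.integer(threshold), p_yule, p_coal, return_rates)
}
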