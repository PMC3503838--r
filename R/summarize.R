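## Posterior summaries: species-number distribution and HPD, pairwise
## co-conspecificity, consensus partitions, and the comparison between
## Akaike weights and posterior probabilities.

#' Smallest contiguous discrete HPD interval
#'
#' The shortest contiguous run of integer values holding at least `level`
#' probability mass; ties are broken toward the narrower interval and then
#' toward the smaller lower endpoint. Appropriate for an ordinal parameter
#' such as the threshold rank.
#'
#' @param values integer samples.
#' @param level target mass.
#' @return `c(lower, upper)`.
#' @export
discrete_hpd <- function(values, level = 0.95) {
  stopifnot(length(values) > 0)
  v <- sort(unique(values))
  lo <- min(v); hi <- max(v)
  support <- lo:hi
  pmf <- tabulate(values - lo + 1L, nbins = length(support)) / length(values)
  cum <- c(0, cumsum(pmf))
  best <- c(lo, hi)
  best_w <- hi - lo
  for (i in seq_along(support)) {
    for (j in i:length(support)) {
      if (cum[j + 1L] - cum[i] >= level - 1e-12) {
        w <- j - i
        if (w < best_w) {
          best <- c(support[i], support[j])
          best_w <- w
        }
        break
      }
    }
  }
  best
}

#' Posterior summary of the number of species
#'
#' Mean, mode, 95% HPD (smallest contiguous interval, [discrete_hpd()]),
#' full probability mass function and a per-tree decomposition of the
#' species-number posterior.
#'
#' @param x a `gmyc_mcmc` fit (or a data frame with columns `n_species` and
#'   `tree_id`).
#' @param level HPD mass.
#' @return a list with `mean`, `mode`, `hpd`, `pmf` (data frame `n_species`,
#'   `probability`) and `per_tree` (per-tree posterior means).
#' @export
species_number_summary <- function(x, level = 0.95) {
  trace <- if (inherits(x, "gmyc_mcmc")) x$trace else x
  if (is.null(trace$n_species) || nrow(trace) == 0L)
    stop("empty trace")
  ns <- trace$n_species
  tab <- table(ns)
  pmf <- data.frame(n_species = as.integer(names(tab)),
                    probability = as.numeric(tab) / length(ns))
  per_tree <- if (!is.null(trace$tree_id))
    stats::aggregate(n_species ~ tree_id, data = trace, FUN = mean)
  else NULL
  list(mean = mean(ns),
       mode = pmf$n_species[which.max(pmf$probability)],
       hpd = discrete_hpd(ns, level),
       pmf = pmf,
       per_tree = per_tree)
}

#' Marginal pairwise co-conspecificity probabilities
#'
#' For every retained MCMC sample, two sequences are conspecific exactly
#' when their most recent common ancestor on that sample's tree is younger
#' than the sample's threshold time; the matrix entry is the fraction of
#' pooled samples in which the pair is conspecific. Because each sample is
#' evaluated on its own tree, the matrix marginalizes over phylogenetic
#' uncertainty; off-diagonal structure (when rows are ordered by a single
#' reference tree) visualizes that uncertainty.
#'
#' @param x a `gmyc_mcmc` fit.
#' @return a symmetric matrix of class `gmyc_coconspec` with unit diagonal,
#'   rows/columns named by tip label (ordered as in the first tree).
#' @export
coconspecificity <- function(x) {
  stopifnot(inherits(x, "gmyc_mcmc"))
  tips <- x$trees[[1L]]$phy$tip.label
  n <- length(tips)
  P <- matrix(0, n, n, dimnames = list(tips, tips))
  total <- 0L
  for (i in seq_along(x$trees)) {
    d <- x$trace[x$trace$tree_id == i, ]
    if (nrow(d) == 0L) next
    tr <- x$trees[[i]]
    mr <- ape::mrca(tr$phy)                  # node numbers, tip order of tr
    M <- matrix(tr$ages[mr], n, n)
    idx <- match(tips, tr$phy$tip.label)
    M <- M[idx, idx]
    for (tt in unique(d$threshold_time)) {
      cnt <- sum(d$threshold_time == tt)
      P <- P + cnt * (M < tt)
      total <- total + cnt
    }
  }
  P <- P / total
  diag(P) <- 1
  structure(P, class = c("gmyc_coconspec", "matrix"))
}

#' @export
print.gmyc_coconspec <- function(x, ...) {
  cat(sprintf("Pairwise co-conspecificity matrix: %d sequences\n", nrow(x)))
  cat(sprintf("  mean off-diagonal probability %.3f\n",
              mean(x[upper.tri(x)])))
  invisible(x)
}

#' @export
plot.gmyc_coconspec <- function(x, ...) {
  n <- nrow(x)
  image(seq_len(n), seq_len(n), unclass(x)[, n:1], axes = FALSE,
        xlab = "", ylab = "", ...)
  invisible(x)
}

#' Consensus partition from a co-conspecificity matrix
#'
#' Single-linkage clustering of all pairs with co-conspecificity probability
#' at or above `cutoff`. This is an export convenience and is lossy relative
#' to the marginal matrix: with `cutoff > 0.5` the clusters can be
#' non-transitive (a chained pair may fall below the cutoff); any such pairs
#' are reported in the `conflicts` attribute and a warning.
#'
#' @param matrix a `gmyc_coconspec` matrix.
#' @param cutoff probability cutoff in `(0.5, 1]`.
#' @return a `gmyc_partition` data frame (tip, entity) with attribute
#'   `conflicts`: a data frame of within-cluster pairs below the cutoff.
#' @export
consensus_partition <- function(matrix, cutoff = 0.95) {
  if (cutoff <= 0.5 || cutoff > 1)
    stop("'cutoff' must be in (0.5, 1]")
  n <- nrow(matrix)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    if (matrix[i, j] >= cutoff) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  root <- vapply(seq_len(n), find, integer(1))
  entity <- match(root, unique(root))
  conflicts <- NULL
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    if (entity[i] == entity[j] && matrix[i, j] < cutoff)
      conflicts <- rbind(conflicts,
                         data.frame(tip1 = rownames(matrix)[i],
                                    tip2 = rownames(matrix)[j],
                                    probability = matrix[i, j]))
  if (!is.null(conflicts) && nrow(conflicts) > 0L)
    warning(sprintf(
      "single-linkage consensus is non-transitive: %d within-cluster pair(s) below the cutoff",
      nrow(conflicts)))
  sizes <- tabulate(entity)
  structure(data.frame(tip = rownames(matrix), entity = entity,
                       stringsAsFactors = FALSE),
            n_entities = max(entity),
            n_clusters = sum(sizes >= 2L),
            n_singletons = sum(sizes == 1L),
            threshold = NA_integer_,
            threshold_time = NA_real_,
            conflicts = conflicts,
            class = c("gmyc_partition", "data.frame"))
}

#' Compare Akaike weights with posterior threshold probabilities
#'
#' Pairs the per-threshold Akaike weights of a maximum-likelihood scan with
#' the marginal posterior probabilities of an MCMC fit (same tree, or an
#' MCC-tree scan against a pooled multi-tree posterior). Both columns sum
#' to 1.
#'
#' @param ml a `gmyc_ml` fit.
#' @param mcmc a `gmyc_mcmc` fit.
#' @return data frame with columns `threshold`, `akaike_weight`,
#'   `posterior_prob`.
#' @export
compare_akaike_posterior <- function(ml, mcmc) {
  stopifnot(inherits(ml, "gmyc_ml"), inherits(mcmc, "gmyc_mcmc"))
  pmf <- species_number_summary(mcmc)$pmf
  Ts <- sort(union(ml$table$threshold, pmf$n_species))
  data.frame(
    threshold = Ts,
    akaike_weight = ifelse(is.na(match(Ts, ml$table$threshold)), 0,
                           ml$table$akaike_weight[match(Ts, ml$table$threshold)]),
    posterior_prob = ifelse(is.na(match(Ts, pmf$n_species)), 0,
                            pmf$probability[match(Ts, pmf$n_species)]))
}

#' Write a partition as a two-column OTU table
#'
#' @param x a `gmyc_partition`.
#' @param path output CSV (columns `tip`, `entity`).
#' @return `path`, invisibly.
#' @export
write_partition <- function(x, path) {
  stopifnot(inherits(x, "gmyc_partition"))
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
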