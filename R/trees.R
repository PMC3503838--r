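## Tree ingestion and the branching-time data structures the likelihood uses.

#' Validate an ultrametric tree for GMYC analysis
#'
#' Wraps an [ape::phylo] object, checks that it is rooted, binary (polytomies
#' are resolved into zero-length branches and then handled by the tie rule),
#' has at least 3 tips and is ultrametric within a relative tolerance, and
#' computes node ages (time before present; tips at age 0, root oldest).
#' Trees are renormalized so that every tip sits exactly at age 0.
#'
#' Branching-time ties (typically caused by duplicate sequences or resolved
#' polytomies) make the inter-event waiting times degenerate and would lead
#' the model to over-partition the data. They are rejected unless
#' `jitter_ties = TRUE`, in which case tied node ages are perturbed by at most
#' `1e-8 * root age` while preserving parent-child age ordering.
#'
#' @param phy an object of class `phylo` (rooted, with branch lengths).
#' @param units character label recording the branch-length units
#'   (e.g. `"N-generations"`, `"substitutions/site"`). Metadata only; branch
#'   lengths are never rescaled silently.
#' @param tolerance maximum allowed relative spread of root-to-tip path
#'   lengths.
#' @param jitter_ties resolve tied branching times by a deterministic
#'   perturbation of at most `1e-8 *` root age instead of raising an error.
#' @return an object of class `gmyc_tree`: a list with elements `phy`
#'   (renormalized `phylo`), `ages` (age of every node, tips first),
#'   `ranked_ages` (internal-node ages, decreasing; the branching times
#'   \eqn{t_1 > t_2 > \dots > t_m}), `rank_node` (node id of each ranked
#'   event), `n_tips`, and `units`.
#' @examples
#' tr <- gmyc_tree(ape::read.tree(text = "((A:1,B:1):1,C:2);"))
#' ranked_branching_times(tr)
#' @export
gmyc_tree <- function(phy, units = "unknown", tolerance = 1e-6,
                      jitter_ties = FALSE) {
  if (inherits(phy, "gmyc_tree")) return(phy)
  if (!inherits(phy, "phylo")) stop("'phy' must be an object of class 'phylo'")
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  if (!ape::is.binary(phy)) phy <- ape::multi2di(phy)
  n <- length(phy$tip.label)
  if (n < 3L) stop("need at least 3 tips (no inter-event waiting time exists)")
  if (anyDuplicated(phy$tip.label))
    stop("tip labels must be unique")
  if (any(phy$edge.length < 0))
    stop("negative branch lengths are not allowed")

  depth <- ape::node.depth.edgelength(phy)  # distance from root, all nodes
  tipd <- depth[seq_len(n)]
  D <- max(tipd)
  if (D <= 0) stop("tree has zero depth")
  spread <- (D - min(tipd)) / D
  if (spread > tolerance) {
    hi <- phy$tip.label[which.max(tipd)]
    lo <- phy$tip.label[which.min(tipd)]
    stop(sprintf(paste0(
      "tree is not ultrametric: root-to-tip lengths differ by a relative ",
      "%.3g (tolerance %.3g); worst tip pair: '%s' (%.6g) vs '%s' (%.6g)"),
      spread, tolerance, hi, depth[which.max(tipd)], lo, depth[which.min(tipd)]))
  }

  ages <- D - depth
  ages[seq_len(n)] <- 0  # renormalize: tips exactly at the present

  ages <- .resolve_tied_ages(phy, ages, n, jitter_ties)

  ## rebuild edge lengths from the (possibly adjusted) ages
  phy$edge.length <- ages[phy$edge[, 1L]] - ages[phy$edge[, 2L]]

  int_ages <- ages[(n + 1L):(2L * n - 1L)]
  ord <- order(int_ages, decreasing = TRUE)
  structure(list(
    phy = phy,
    ages = ages,
    ranked_ages = int_ages[ord],
    rank_node = ((n + 1L):(2L * n - 1L))[ord],
    n_tips = n,
    units = units
  ), class = "gmyc_tree")
}

## Reject or deterministically resolve equal branching times. Ancestors must
## stay strictly older than descendants, so among ties the node with fewer
## descendants (deeper in the tree) receives the smaller age.
.resolve_tied_ages <- function(phy, ages, n, jitter_ties) {
  int_id <- (n + 1L):(2L * n - 1L)
  a <- ages[int_id]
  if (!anyDuplicated(a)) return(ages)
  if (!jitter_ties)
    stop(paste0(
      "tied branching times detected (duplicate sequences or polytomies). ",
      "Prune the alignment to unique sequences, or set jitter_ties = TRUE ",
      "to perturb ties by <= 1e-8 * root age."))
  ndesc <- ape::node.depth(phy)[int_id]  # number of descendant tips
  eps <- 1e-8 * max(a) / length(a)
  ord <- order(a, ndesc)                 # ascending age, small clades first
  a_s <- a[ord]
  for (k in 2:length(a_s))
    if (a_s[k] <= a_s[k - 1L]) a_s[k] <- a_s[k - 1L] + eps
  a[ord] <- a_s
  ages[int_id] <- a
  ages
}

#' Read trees for GMYC analysis
#'
#' Reads one or more rooted ultrametric trees from a Newick file or a NEXUS
#' trees file (translate tables as written by Bayesian clock-tree software are
#' resolved by [ape::read.nexus()]), optionally discards a burn-in fraction
#' and thins the remainder, and validates each tree with [gmyc_tree()].
#'
#' @param path path to the tree file.
#' @param format `"auto"` (NEXUS if the file starts with `#NEXUS`),
#'   `"newick"`, or `"nexus"`.
#' @param burnin_fraction proportion in `[0, 1)` of initial trees to discard.
#' @param thin keep every `thin`-th tree after burn-in.
#' @inheritParams gmyc_tree
#' @return a list of `gmyc_tree` objects, in file order.
#' @export
read_gmyc_trees <- function(path, format = c("auto", "newick", "nexus"),
                            burnin_fraction = 0, thin = 1L,
                            units = "unknown", tolerance = 1e-6,
                            jitter_ties = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (burnin_fraction < 0 || burnin_fraction >= 1)
    stop("'burnin_fraction' must be in [0, 1)")
  thin <- as.integer(thin)
  if (thin < 1L) stop("'thin' must be a positive integer")
  if (format == "auto") {
    first <- toupper(trimws(readLines(path, n = 1L, warn = FALSE)))
    format <- if (startsWith(first, "#NEXUS")) "nexus" else "newick"
  }
  trees <- if (format == "nexus") ape::read.nexus(path) else ape::read.tree(path)
  if (inherits(trees, "phylo")) trees <- structure(list(trees),
                                                   class = "multiPhylo")
  n0 <- length(trees)
  if (n0 == 0L) stop("no trees found in ", path)
  keep <- seq_len(n0)
  if (burnin_fraction > 0) keep <- keep[-seq_len(floor(burnin_fraction * n0))]
  if (thin > 1L) keep <- keep[seq.int(thin, length(keep), by = thin)]
  ## [[ on a multiPhylo restores compressed tip labels (NEXUS translate)
  lapply(keep, function(i) gmyc_tree(trees[[i]], units = units,
                                     tolerance = tolerance,
                                     jitter_ties = jitter_ties))
}

#' Ranked branching times
#'
#' The ages of the `n_tips - 1` branching events of an ultrametric tree,
#' strictly decreasing (root first). These define the inter-event waiting
#' times that are the data of the GMYC likelihood.
#'
#' @param tree a `gmyc_tree` (or a `phylo`, validated on the fly).
#' @return numeric vector \eqn{t_1 > t_2 > \dots > t_m}, `m = n_tips - 1`.
#' @export
ranked_branching_times <- function(tree) {
  gmyc_tree(tree)$ranked_ages
}

#' @export
print.gmyc_tree <- function(x, ...) {
  cat(sprintf("GMYC-ready ultrametric tree: %d tips, root age %.6g (%s)\n",
              x$n_tips, x$ranked_ages[1L], x$units))
  invisible(x)
}

## ---- threshold bookkeeping -------------------------------------------------

## For threshold rank T in 2..n_tips the T-1 oldest branching events are
## speciations. Entities are the subtrees hanging from speciation nodes whose
## own root event (if any) is younger than the threshold; equivalently, the
## lineages crossing the gap between ranked events T-1 and T.

## ranks (1-based, by decreasing age) of every internal node, and the rank of
## each internal node's parent (0 for the root)
.node_ranks <- function(tree) {
  n <- tree$n_tips
  rank_of_node <- integer(2L * n - 1L)
  rank_of_node[tree$rank_node] <- seq_len(n - 1L)
  parent <- integer(2L * n - 1L)
  parent[tree$phy$edge[, 2L]] <- tree$phy$edge[, 1L]
  list(rank_of_node = rank_of_node, parent = parent)
}

#' Species partition implied by a threshold
#'
#' Cuts the tree at the gap between the `T-1`-th and `T`-th ranked branching
#' events: the `T-1` oldest events are speciations and exactly `T` lineages
#' cross the threshold, each subtending one entity (putative species).
#'
#' @param x a `gmyc_tree`, or a fitted model object.
#' @param threshold integer threshold rank `T` in `[2, n_tips]`.
#' @param ... passed to methods.
#' @return an object of class `gmyc_partition`: a data frame with columns
#'   `tip` and `entity`, with attributes `n_entities`, `n_clusters`
#'   (entities with >= 2 tips), `n_singletons`, `threshold` and
#'   `threshold_time` (age of the `T-1`-th ranked event).
#' @export
species_partition <- function(x, ...) UseMethod("species_partition")

#' @rdname species_partition
#' @export
species_partition.gmyc_tree <- function(x, threshold, ...) {
  n <- x$n_tips
  T <- as.integer(threshold)
  if (length(T) != 1L || is.na(T) || T < 2L || T > n)
    stop(sprintf("'threshold' must be an integer in [2, %d]", n))
  nr <- .node_ranks(x)
  phy <- x$phy
  ## entity roots: nodes (tip or internal) whose parent is a speciation node
  ## and which are not themselves speciation nodes
  is_spec <- function(node) node > n && nr$rank_of_node[node] <= T - 1L
  roots <- integer(0)
  for (node in c(seq_len(n), (n + 1L):(2L * n - 1L))) {
    if (node == n + 1L) next  # the root node is always a speciation node
    if (!is_spec(node) && is_spec(nr$parent[node]))
      roots <- c(roots, node)
  }
  tips_of <- function(node) {
    if (node <= n) return(node)
    unlist(phangorn::Descendants(phy, node, type = "tips"))
  }
  assignment <- integer(n)
  for (j in seq_along(roots)) assignment[tips_of(roots[j])] <- j
  sizes <- tabulate(assignment, nbins = length(roots))
  out <- data.frame(tip = phy$tip.label, entity = assignment,
                    stringsAsFactors = FALSE)
  structure(out,
            n_entities = length(roots),
            n_clusters = sum(sizes >= 2L),
            n_singletons = sum(sizes == 1L),
            threshold = T,
            threshold_time = x$ranked_ages[T - 1L],
            class = c("gmyc_partition", "data.frame"))
}

#' @export
print.gmyc_partition <- function(x, ...) {
  cat(sprintf(
    "GMYC partition: %d entities (%d clusters + %d singletons), threshold T = %d (age %.6g)\n",
    attr(x, "n_entities"), attr(x, "n_clusters"), attr(x, "n_singletons"),
    attr(x, "threshold"), attr(x, "threshold_time")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Waiting-time and lineage-count table for a threshold
#'
#' Decomposes the tree into its `m - 1` inter-event waiting times
#' (`m = n_tips - 1` branching events) and, for a given threshold rank,
#' counts in every interval the lineages assigned to the Yule process and to
#' each within-species coalescent process. Interval `i` spans the ages
#' `[t_{i+1}, t_i]`, contains `i + 1` lineages, and is terminated (backward
#' in time) by branching event `i`; events ranked `1..T-1` are speciations.
#'
#' @inheritParams species_partition.gmyc_tree
#' @param tree a `gmyc_tree`.
#' @param threshold integer threshold rank `T` in `[2, n_tips]`.
#' @return an object of class `gmyc_intervals`: a list with `ranked_ages`,
#'   `x` (waiting times, length `m - 1`), `n_yule` (interspecific lineage
#'   count per interval), `coal_counts` (list: per interval, the integer
#'   vector of within-species lineage counts, one per coalescent process
#'   active in that interval), `event_process` (`"yule"`/`"coalescent"` of
#'   each interval's terminating event) and `threshold`.
#' @export
interval_table <- function(tree, threshold) {
  tree <- gmyc_tree(tree)
  n <- tree$n_tips
  m <- n - 1L
  T <- as.integer(threshold)
  if (length(T) != 1L || is.na(T) || T < 2L || T > n)
    stop(sprintf("'threshold' must be an integer in [2, %d]", n))
  pc <- .precompute(tree)
  nint <- m - 1L
  croots <- which(seq_len(m) >= T & pc$parent_rank <= T - 1L)
  coal_counts <- rep(list(integer(0)), nint)
  n_coal_tot <- integer(nint)
  for (r in croots) {
    if (r > nint) next
    dr <- pc$desc_ranks[[r]]  # ranks strictly inside the cluster, ascending
    s <- 2L                   # event r splits the crossing branch in two
    ptr <- 1L
    for (i in r:nint) {
      while (ptr <= length(dr) && dr[ptr] <= i) {
        s <- s + 1L
        ptr <- ptr + 1L
      }
      coal_counts[[i]] <- c(coal_counts[[i]], s)
      n_coal_tot[i] <- n_coal_tot[i] + s
    }
  }
  n_total <- seq_len(nint) + 1L
  out <- list(
    ranked_ages = tree$ranked_ages,
    x = tree$ranked_ages[seq_len(nint)] - tree$ranked_ages[seq_len(nint) + 1L],
    n_total = n_total,
    n_yule = n_total - n_coal_tot,
    coal_counts = coal_counts,
    event_rank = seq_len(nint),
    event_process = ifelse(seq_len(nint) <= T - 1L, "yule", "coalescent"),
    threshold = T,
    threshold_time = tree$ranked_ages[T - 1L],
    n_tips = n
  )
  class(out) <- "gmyc_intervals"
  out
}

#' @export
print.gmyc_intervals <- function(x, ...) {
  cat(sprintf("GMYC interval table: %d waiting times, threshold T = %d\n",
              length(x$x), x$threshold))
  df <- as.data.frame(x)
  print(utils::head(df, 10L))
  if (nrow(df) > 10L) cat("...", nrow(df) - 10L, "more intervals\n")
  invisible(x)
}

#' @export
as.data.frame.gmyc_intervals <- function(x, ...) {
  data.frame(
    interval = seq_along(x$x),
    age_older = x$ranked_ages[seq_along(x$x)],
    age_younger = x$ranked_ages[seq_along(x$x) + 1L],
    x = x$x,
    n_total = x$n_total,
    n_yule = x$n_yule,
    n_coal = vapply(x$coal_counts, sum, integer(1)),
    k_active = vapply(x$coal_counts, length, integer(1)),
    event_process = x$event_process
  )
}

## ---- fast-path precomputation ----------------------------------------------

## Per-tree arrays consumed by the C++ likelihood kernel:
##   t            ranked ages (decreasing), length m
##   x            waiting times, length m-1
##   parent_rank  rank of each ranked event's parent event (0 for the root)
##   desc_ranks   per rank, the ascending ranks of internal nodes strictly
##                inside that node's subtree (self excluded)
.precompute <- function(tree) {
  env <- attr(tree, ".precomp")
  if (!is.null(env)) return(env)
  n <- tree$n_tips
  m <- n - 1L
  nr <- .node_ranks(tree)
  parent_rank <- integer(m)
  for (r in seq_len(m)) {
    node <- tree$rank_node[r]
    p <- nr$parent[node]
    parent_rank[r] <- if (p == 0L) 0L else nr$rank_of_node[p]
  }
  desc <- phangorn::Descendants(tree$phy, (n + 1L):(2L * n - 1L), type = "all")
  desc_ranks <- vector("list", m)
  for (r in seq_len(m)) {
    d <- desc[[tree$rank_node[r] - n]]
    d <- d[d > n]
    desc_ranks[[r]] <- sort(nr$rank_of_node[d])
  }
  list(t = tree$ranked_ages,
       x = tree$ranked_ages[seq_len(m - 1L)] - tree$ranked_ages[2:m],
       parent_rank = parent_rank,
       desc_ranks = desc_ranks,
       n_tips = n)
}
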