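## Synthetic-data generators: Yule species trees and multispecies-coalescent
## gene trees in N-generation units (N = diploid effective population size;
## the haploid/organellar convention halves coalescent times).

#' Simulate a Yule species tree with incomplete taxon sampling
#'
#' Grows a pure-birth tree to `n_grow` species, retains `n_sample` of them
#' uniformly at random (mimicking an environmental sample that misses part of
#' the clade) and rescales the tree so the root age equals `depth`
#' N-generations exactly. The growth rate is immaterial because of the final
#' rescaling.
#'
#' @param n_grow number of species in the full clade.
#' @param n_sample number of species retained (`2 <= n_sample <= n_grow`).
#' @param depth root age of the returned tree, in N-generation units.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return an ultrametric `phylo` with `n_sample` tips and root age `depth`.
#' @export
sim_yule_species_tree <- function(n_grow = 150L, n_sample = 50L, depth = 80,
                                  seed = NULL) {
  if (n_sample < 2L) stop("'n_sample' must be >= 2")
  if (n_sample > n_grow) stop("'n_sample' must be <= 'n_grow'")
  if (depth <= 0) stop("'depth' must be > 0")
  if (!is.null(seed)) set.seed(seed)
  phy <- ape::rphylo(n_grow, birth = 1, death = 0)
  if (n_sample < n_grow)
    phy <- ape::keep.tip(phy, sample(phy$tip.label, n_sample))
  d <- max(ape::node.depth.edgelength(phy))
  phy$edge.length <- phy$edge.length * (depth / d)
  phy
}

#' Allele sampling schemes
#'
#' `sampling_scheme()` describes how many alleles (sequences) are sampled
#' per species: either a fixed number per species, or a lognormal draw
#' (discretized by ceiling, so every species receives at least one allele).
#' The lognormal defaults `meanlog = sdlog = 1` give a mean of about 5
#' alleles per species with roughly 16% of species represented by a single
#' allele, approximating real species-abundance distributions.
#'
#' @param kind `"fixed"` or `"lognormal"`.
#' @param k alleles per species for the fixed scheme.
#' @param meanlog,sdlog log-scale parameters of the lognormal scheme.
#' @return an object of class `gmyc_sampling_scheme`.
#' @export
sampling_scheme <- function(kind = c("fixed", "lognormal"), k = 5L,
                            meanlog = 1, sdlog = 1) {
  kind <- match.arg(kind)
  if (kind == "fixed" && k < 1L) stop("'k' must be >= 1")
  structure(list(kind = kind, k = as.integer(k), meanlog = meanlog,
                 sdlog = sdlog), class = "gmyc_sampling_scheme")
}

#' @rdname sampling_scheme
#' @param scheme a `gmyc_sampling_scheme`.
#' @param n_species number of species to draw counts for.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return `draw_allele_counts()`: an integer vector of per-species allele
#'   counts, all `>= 1`.
#' @export
draw_allele_counts <- function(scheme, n_species, seed = NULL) {
  stopifnot(inherits(scheme, "gmyc_sampling_scheme"))
  if (!is.null(seed)) set.seed(seed)
  if (scheme$kind == "fixed") return(rep(scheme$k, n_species))
  as.integer(ceiling(rlnorm(n_species, scheme$meanlog, scheme$sdlog)))
}

#' Simulate a gene tree under the multispecies coalescent
#'
#' Runs an independent Kingman coalescent within every branch of an
#' ultrametric species tree (branch lengths in N-generation units, all
#' species sharing constant population size N), merging lineage pools at
#' speciation times and continuing above the root until all lineages
#' coalesce. Under the diploid convention a pair of lineages in one
#' population coalesces at rate 1/2 per N generations (mean pairwise time
#' 2 N); the haploid/organellar convention doubles the rate (halving all
#' coalescent times).
#'
#' @param species_tree an ultrametric `phylo` in N-generation units, or
#'   `NULL` for a single panmictic population.
#' @param alleles alleles sampled per species: a scalar, a vector (one entry
#'   per species-tree tip, in `tip.label` order), or a
#'   [sampling_scheme()].
#' @param ploidy `"diploid"` or `"haploid"`.
#' @param n_alleles number of lineages when `species_tree = NULL`.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param summary_only return only `list(tmrca, n_tips)` without assembling
#'   the tree (faster for distributional checks).
#' @return an ultrametric `phylo` whose tips are labelled
#'   `<species>_<allele>`, with attribute `tmrca` (root age, N-generation
#'   units); or the summary list.
#' @export
sim_msc_gene_tree <- function(species_tree = NULL, alleles = 5L,
                              ploidy = c("diploid", "haploid"),
                              n_alleles = NULL, seed = NULL,
                              summary_only = FALSE) {
  ploidy <- match.arg(ploidy)
  rate_pair <- if (ploidy == "diploid") 0.5 else 1
  if (!is.null(seed)) set.seed(seed)

  events <- list()   # each: list(age, c1, c2, id)
  next_id <- 0L
  new_id <- function() {
    next_id <<- next_id + 1L
    next_id
  }

  ## Kingman coalescence of `ids` from age t0 to t1 (Inf allowed)
  coalesce_along <- function(ids, t0, t1) {
    t <- t0
    while (length(ids) >= 2L) {
      k <- length(ids)
      t <- t + rexp(1L, rate_pair * k * (k - 1) / 2)
      if (t > t1) break
      pick <- sample.int(k, 2L)
      id <- new_id()
      events[[length(events) + 1L]] <<- list(age = t, c1 = ids[pick[1L]],
                                             c2 = ids[pick[2L]], id = id)
      ids <- c(ids[-pick], id)
    }
    ids
  }

  if (is.null(species_tree)) {
    if (is.null(n_alleles)) n_alleles <- if (length(alleles) == 1L &&
      is.numeric(alleles)) alleles else stop("supply 'n_alleles'")
    G <- as.integer(n_alleles)
    if (G < 2L) stop("need at least 2 lineages")
    tip_ids <- vapply(seq_len(G), function(i) new_id(), integer(1))
    tip_labels <- paste0("pop1_", seq_len(G))
    coalesce_along(tip_ids, 0, Inf)
  } else {
    phy <- species_tree
    ns <- length(phy$tip.label)
    counts <- if (inherits(alleles, "gmyc_sampling_scheme"))
      draw_allele_counts(alleles, ns)
    else if (length(alleles) == 1L) rep(as.integer(alleles), ns)
    else as.integer(alleles)
    if (length(counts) != ns || any(counts < 1L))
      stop("'alleles' must give a count >= 1 for every species")
    depth <- ape::node.depth.edgelength(phy)
    age <- max(depth[seq_len(ns)]) - depth
    age[seq_len(ns)] <- 0
    parent <- integer(ns + phy$Nnode)
    parent[phy$edge[, 2L]] <- phy$edge[, 1L]
    tip_labels <- unlist(lapply(seq_len(ns), function(i)
      paste0(phy$tip.label[i], "_", seq_len(counts[i]))))
    pool <- vector("list", ns + phy$Nnode)
    for (i in seq_len(ns))
      pool[[i]] <- vapply(seq_len(counts[i]), function(j) new_id(), integer(1))
    G <- sum(counts)
    ## process species-tree internal nodes from youngest to oldest
    int_nodes <- (ns + 1L):(ns + phy$Nnode)
    for (v in int_nodes[order(age[int_nodes])]) {
      kids <- phy$edge[phy$edge[, 1L] == v, 2L]
      surv <- unlist(lapply(kids, function(c)
        coalesce_along(pool[[c]], age[c], age[v])))
      pool[[v]] <- surv
    }
    root <- ns + 1L
    coalesce_along(pool[[root]], age[root], Inf)
  }

  ages <- vapply(events, `[[`, numeric(1), "age")
  tmrca <- max(ages)
  if (summary_only) return(list(tmrca = tmrca, n_tips = G))

  ## assemble an ape phylo: tips 1..G, internal ids G+1.. by decreasing age
  stopifnot(length(events) == G - 1L)
  ord <- order(ages, decreasing = TRUE)
  ape_id <- integer(next_id)
  ape_id[seq_len(G)] <- seq_len(G)  # tip temp ids were created first
  node_age <- numeric(2L * G - 1L)
  for (k in seq_along(ord)) {
    ev <- events[[ord[k]]]
    ape_id[ev$id] <- G + k
    node_age[G + k] <- ev$age
  }
  edge <- matrix(0L, nrow = 2L * (G - 1L), ncol = 2L)
  elen <- numeric(nrow(edge))
  r <- 0L
  for (ev in events) {
    for (child in c(ev$c1, ev$c2)) {
      r <- r + 1L
      edge[r, ] <- c(ape_id[ev$id], ape_id[child])
      elen[r] <- ev$age - node_age[ape_id[child]]
    }
  }
  out <- structure(list(edge = edge, edge.length = elen,
                        tip.label = tip_labels, Nnode = G - 1L),
                   class = "phylo")
  out <- ape::reorder.phylo(out, "cladewise")
  attr(out, "tmrca") <- tmrca
  out
}
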