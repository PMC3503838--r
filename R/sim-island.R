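## Structured-coalescent simulation under a finite island model, used to
## probe how metapopulation structure masquerades as species structure.

#' Simulate a genealogy under the finite island model
#'
#' Structured coalescent with `n_demes` demes of constant size N (the time
#' unit: N generations), per-lineage migration rate `Nm` per N generations
#' (i.e. `Nm` migrants per deme per generation), uniform migration target,
#' and within-deme pairwise coalescence at rate 1/2 per N generations
#' (diploid; doubled for haploid). A sample of `lineages_per_deme` lineages
#' is taken from each of `demes_sampled` demes. Such genealogies show a fast
#' "scattering" phase (coalescence and migration within the sampled demes)
#' followed by a very long "collecting" phase once every surviving lineage
#' occupies its own deme.
#'
#' @param n_demes number of demes `D`.
#' @param Nm migrants per deme per generation (`> 0`).
#' @param demes_sampled number of demes sampled (`<= n_demes`).
#' @param lineages_per_deme lineages sampled per sampled deme.
#' @param ploidy `"diploid"` or `"haploid"`.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param return_tree also assemble the genealogy as a `phylo`.
#' @return a list with `tmrca` (N-generation units), `scattering_end` (first
#'   time every surviving lineage occupies a distinct deme), `n_lineages_at_scattering_end`,
#'   and optionally `tree`.
#' @export
sim_island_genealogy <- function(n_demes = 200L, Nm = 0.07,
                                 demes_sampled = 10L, lineages_per_deme = 5L,
                                 ploidy = c("diploid", "haploid"),
                                 seed = NULL, return_tree = FALSE) {
  ploidy <- match.arg(ploidy)
  if (Nm <= 0) stop("'Nm' must be > 0")
  if (demes_sampled < 1L || demes_sampled > n_demes)
    stop("'demes_sampled' must be in [1, n_demes]")
  rate_pair <- if (ploidy == "diploid") 0.5 else 1
  if (!is.null(seed)) set.seed(seed)

  k0 <- demes_sampled * lineages_per_deme
  deme <- rep(seq_len(demes_sampled), each = lineages_per_deme)
  ids <- seq_len(k0)
  next_id <- k0
  events <- vector("list", k0 - 1L)
  n_ev <- 0L
  t <- 0
  scattering_end <- NA_real_
  n_at_scatter <- NA_integer_
  repeat {
    k <- length(ids)
    if (k == 1L) break
    if (is.na(scattering_end) && !anyDuplicated(deme)) {
      scattering_end <- t
      n_at_scatter <- k
    }
    cnt <- table(deme)
    pairs <- cnt * (cnt - 1) / 2
    r_coal <- rate_pair * sum(pairs)
    r_mig <- if (n_demes == 1L) 0 else Nm * k
    t <- t + rexp(1L, r_coal + r_mig)
    if (runif(1L) < r_coal / (r_coal + r_mig)) {
      d <- as.integer(names(pairs))[sample.int(length(pairs), 1L,
                                               prob = as.numeric(pairs))]
      in_d <- which(deme == d)
      pick <- in_d[sample.int(length(in_d), 2L)]
      next_id <- next_id + 1L
      n_ev <- n_ev + 1L
      events[[n_ev]] <- list(age = t, c1 = ids[pick[1L]], c2 = ids[pick[2L]],
                             id = next_id)
      ids <- c(ids[-pick], next_id)
      deme <- c(deme[-pick], d)
    } else {
      l <- sample.int(k, 1L)
      new_deme <- sample.int(n_demes - 1L, 1L)
      if (new_deme >= deme[l]) new_deme <- new_deme + 1L
      deme[l] <- new_deme
    }
  }
  out <- list(tmrca = t, scattering_end = scattering_end,
              n_lineages_at_scattering_end = n_at_scatter)
  if (return_tree) {
    ages <- vapply(events, `[[`, numeric(1), "age")
    G <- k0
    ord <- order(ages, decreasing = TRUE)
    ape_id <- integer(next_id)
    ape_id[seq_len(G)] <- seq_len(G)
    node_age <- numeric(2L * G - 1L)
    for (j in seq_along(ord)) {
      ev <- events[[ord[j]]]
      ape_id[ev$id] <- G + j
      node_age[G + j] <- ev$age
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
    tip_lab <- paste0("d", rep(seq_len(demes_sampled), each = lineages_per_deme),
                      "_", sequence(rep(lineages_per_deme, demes_sampled)))
    tr <- structure(list(edge = edge, edge.length = elen, tip.label = tip_lab,
                         Nnode = G - 1L), class = "phylo")
    out$tree <- ape::reorder.phylo(tr, "cladewise")
  }
  out
}

#' Convert a TMRCA in N generations to substitutions per site
#'
#' With per-deme (or per-population) scaled mutation rate
#' `theta = 4 N mu` per site, the per-generation per-site mutation rate is
#' `theta / (4N)`, so a depth of `tmrca` N generations corresponds to
#' `tmrca * theta / 4` substitutions per site. When a total `theta` is split
#' evenly across `demes` demes, pass the number of demes to divide by.
#'
#' @param tmrca depth in N-generation units (`N` = one deme's size).
#' @param theta scaled mutation rate `4 N mu` per site (per deme when
#'   `demes = 1`, total when `demes > 1`).
#' @param demes number of demes sharing `theta`.
#' @return depth in substitutions per site.
#' @examples
#' tmrca_to_substitutions(3940, 0.01)        # per-deme theta
#' tmrca_to_substitutions(3940, 0.01, 200)   # theta split across 200 demes
#' @export
tmrca_to_substitutions <- function(tmrca, theta, demes = 1L) {
  if (theta <= 0) stop("'theta' must be > 0")
  tmrca * (theta / demes) / 4
}
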