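## HKY+G sequence simulation on a gene tree under a strict clock.

#' Simulate sequences on a gene tree (HKY + discrete gamma)
#'
#' Simulates an alignment on an ultrametric gene tree in N-generation units
#' under a strict clock: branch lengths are converted to expected
#' substitutions per site via `mu = theta / 4` per N generations (diploid
#' `theta = 4 N mu` per site), sites are assigned to `n_cat` discrete-gamma
#' rate categories (category rates are the analytic bin means of a
#' mean-one gamma with shape `gamma_shape`), and characters evolve under the
#' HKY model with transition/transversion parameter `kappa`.
#'
#' @param gene_tree an ultrametric `phylo` in N-generation units.
#' @param length alignment length in bp.
#' @param theta scaled mutation rate `4 N mu` per site.
#' @param kappa HKY transition/transversion rate ratio parameter.
#' @param gamma_shape shape of the gamma rate distribution across sites.
#' @param n_cat number of discrete gamma categories.
#' @param base_freq equilibrium base frequencies (A, C, G, T).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return a `DNAbin` matrix (tips x sites), with attribute
#'   `subs_per_unit = theta / 4` recording the time-to-substitutions
#'   conversion.
#' @export
sim_sequences <- function(gene_tree, length = 600L, theta = 0.015, kappa = 4,
                          gamma_shape = 0.5, n_cat = 4L,
                          base_freq = rep(0.25, 4), seed = NULL) {
  if (length < 1L) stop("'length' must be > 0")
  if (theta <= 0) stop("'theta' must be > 0")
  if (!is.null(seed)) set.seed(seed)
  phy <- gene_tree
  phy$edge.length <- phy$edge.length * (theta / 4)
  Q <- c(1, kappa, 1, 1, kappa, 1)  # AC, AG, AT, CG, CT, GT
  rates <- .discrete_gamma_rates(gamma_shape, n_cat)
  cat_of_site <- sample.int(n_cat, length, replace = TRUE)
  out <- matrix("a", nrow = length(phy$tip.label), ncol = length)
  for (k in seq_len(n_cat)) {
    nk <- sum(cat_of_site == k)
    if (nk == 0L) next
    sim <- phangorn::simSeq(phy, l = nk, Q = Q, bf = base_freq,
                            rate = max(rates[k], 1e-12), type = "DNA")
    chars <- as.character(sim)
    out[, cat_of_site == k] <- chars[phy$tip.label, , drop = FALSE]
  }
  rownames(out) <- phy$tip.label
  aln <- ape::as.DNAbin(out)
  attr(aln, "subs_per_unit") <- theta / 4
  aln
}

## mean rate of each of k equal-probability bins of a mean-one gamma(shape a)
.discrete_gamma_rates <- function(a, k) {
  b <- qgamma(seq(0, 1, length.out = k + 1L), shape = a, rate = a)
  r <- k * diff(pgamma(b, shape = a + 1, rate = a))
  r / mean(r) * 1  # guard rounding; bin means of a mean-1 gamma average to 1
}

#' Write an alignment to FASTA
#'
#' @param aln a `DNAbin` matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  ape::write.FASTA(aln, path)
  invisible(path)
}
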