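## End-to-end simulation experiment driver: simulate -> fit -> summarize.

#' Run a GMYC simulation experiment
#'
#' Drives the full pipeline for one of three experiment designs over
#' replicate datasets: `"depth"` varies the species-tree depth at a fixed
#' sampling scheme; `"sampling"` varies the allele-sampling scheme at a
#' fixed depth; `"seqlen"` simulates alignments of varying length on gene
#' trees (tree re-estimation is an external upstream step: the Bayesian
#' GMYC is fit either to externally supplied tree samples or, by default, to
#' the true simulated gene tree). Every replicate simulates a Yule species
#' tree (grown to `n_grow` species, `n_sample` retained), a
#' multispecies-coalescent gene tree, runs the MCMC fit and records the
#' posterior mean and 95% HPD of the species number and the fraction of
#' post-burn-in MCMC steps whose threshold time is younger than 4 N
#' generations (the expected panmictic coalescence span, below which
#' thresholds should carry little probability). Failed replicates are
#' recorded with `ok = FALSE`, never silently dropped.
#'
#' @param experiment `"depth"`, `"sampling"`, or `"seqlen"`.
#' @param depths species-tree depths (N-generation units) for the depth
#'   experiment.
#' @param schemes list of sampling schemes for the sampling experiment
#'   (integers or [sampling_scheme()] objects).
#' @param seqlens alignment lengths (bp) for the seqlen experiment.
#' @param depth fixed depth for the sampling and seqlen experiments.
#' @param replicates replicate datasets per condition.
#' @param n_grow,n_sample species-tree growth and retention sizes.
#' @param alleles sampling scheme for the depth and seqlen experiments.
#' @param n_steps,burnin,thin MCMC protocol per replicate.
#' @param priors passed to [gmyc_mcmc()].
#' @param theta,seq_dir for `"seqlen"`: scaled mutation rate and, if
#'   non-`NULL`, a directory where the simulated FASTA alignments are
#'   written.
#' @param trees_files for `"seqlen"`: optional named list mapping
#'   `"<seqlen>_<replicate>"` to a trees file produced by external clock-tree
#'   software; when present those trees are analyzed instead of the true
#'   gene tree.
#' @param seed top-level seed; per-replicate substreams are derived from it.
#' @return a data frame with one row per (condition, replicate):
#'   `experiment`, `condition`, `replicate`, `n_true` (true species count),
#'   `posterior_mean`, `hpd_lower`, `hpd_upper`, `covered` (HPD contains the
#'   truth), `frac_below_4N`, `n_samples`, `ok`, `note`.
#' @export
run_gmyc_experiment <- function(experiment = c("depth", "sampling", "seqlen"),
                                depths = c(20, 40, 80, 160),
                                schemes = list(2L, 5L, 10L,
                                               sampling_scheme("lognormal")),
                                seqlens = c(300L, 600L, 1200L, 2400L),
                                depth = 80,
                                replicates = 50L,
                                n_grow = 150L, n_sample = 50L, alleles = 5L,
                                n_steps = 100000L, burnin = 10000L,
                                thin = 100L,
                                priors = gmyc_priors(),
                                theta = 0.015, seq_dir = NULL,
                                trees_files = NULL,
                                seed = 1L) {
  experiment <- match.arg(experiment)
  conditions <- switch(experiment,
    depth = depths,
    sampling = schemes,
    seqlen = seqlens)
  cond_label <- switch(experiment,
    depth = as.character(depths),
    sampling = vapply(schemes, function(s)
      if (inherits(s, "gmyc_sampling_scheme")) s$kind else as.character(s),
      character(1)),
    seqlen = as.character(seqlens))
  set.seed(seed)
  rep_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                 length(conditions) * replicates),
                      nrow = replicates)
  rows <- vector("list", length(conditions) * replicates)
  ri <- 0L
  for (ci in seq_along(conditions)) {
    for (rep in seq_len(replicates)) {
      ri <- ri + 1L
      rows[[ri]] <- tryCatch({
        s <- rep_seeds[rep, ci]
        d <- if (experiment == "depth") conditions[[ci]] else depth
        al <- if (experiment == "sampling") conditions[[ci]] else alleles
        sp <- sim_yule_species_tree(n_grow, n_sample, d, seed = s)
        gt <- sim_msc_gene_tree(sp, alleles = al)
        fit_trees <- gt
        if (experiment == "seqlen") {
          aln <- sim_sequences(gt, length = conditions[[ci]], theta = theta)
          if (!is.null(seq_dir))
            write_alignment(aln, file.path(seq_dir,
              sprintf("seqlen_%s_rep%02d.fasta", cond_label[ci], rep)))
          key <- sprintf("%s_%d", cond_label[ci], rep)
          if (!is.null(trees_files) && !is.null(trees_files[[key]]))
            fit_trees <- read_gmyc_trees(trees_files[[key]],
                                         units = "substitutions/site")
        }
        fit <- gmyc_mcmc(fit_trees, n_steps = n_steps, burnin = burnin,
                         thin = thin, priors = priors, seed = s)
        sm <- species_number_summary(fit)
        data.frame(experiment = experiment, condition = cond_label[ci],
                   replicate = rep, n_true = n_sample,
                   posterior_mean = sm$mean,
                   hpd_lower = sm$hpd[1], hpd_upper = sm$hpd[2],
                   covered = sm$hpd[1] <= n_sample & n_sample <= sm$hpd[2],
                   frac_below_4N = mean(fit$trace$threshold_time < 4),
                   n_samples = nrow(fit$trace),
                   ok = TRUE, note = "", stringsAsFactors = FALSE)
      }, error = function(e) {
        data.frame(experiment = experiment, condition = cond_label[ci],
                   replicate = rep, n_true = n_sample,
                   posterior_mean = NA_real_, hpd_lower = NA_integer_,
                   hpd_upper = NA_integer_, covered = NA,
                   frac_below_4N = NA_real_, n_samples = 0L,
                   ok = FALSE, note = conditionMessage(e),
                   stringsAsFactors = FALSE)
      })
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
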