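test_that("Yule species trees have the requested size and depth", {
  tr <- sim_yule_species_tree(2, 2, depth = 7, seed = 1)
  expect_equal(length(tr$tip.label), 2L)
  expect_equal(max(ape::node.depth.edgelength(tr)), 7, tolerance = 1e-12)
  tr2 <- sim_yule_species_tree(150, 50, depth = 40, seed = 2)
  expect_equal(length(tr2$tip.label), 50L)
  expect_equal(max(ape::node.depth.edgelength(tr2)), 40, tolerance = 1e-9)
  expect_true(ape::is.ultrametric(tr2, tol = 1e-8))
  expect_error(sim_yule_species_tree(10, 1, 10), "n_sample")
  expect_error(sim_yule_species_tree(10, 20, 10), "n_sample")
  ## determinism
  a <- sim_yule_species_tree(30, 10, 5, seed = 9)
  b <- sim_yule_species_tree(30, 10, 5, seed = 9)
  expect_identical(ape::write.tree(a), ape::write.tree(b))
})

test_that("allele sampling schemes match their distributions", {
  expect_equal(draw_allele_counts(sampling_scheme("fixed", k = 5), 50),
               rep(5L, 50))
  set.seed(3)
  x <- draw_allele_counts(sampling_scheme("lognormal"), 1e5)
  expect_true(all(x >= 1L))
  ## E[ceiling(X)] ~ e^{1.5} + 0.5 for X ~ Lognormal(1, 1)
  expect_equal(mean(x), exp(1.5) + 0.5, tolerance = 0.05)
  ## singleton fraction ~ P(X <= 1) = Phi(-1)
  expect_equal(mean(x == 1L), pnorm(-1), tolerance = 0.02)
})

test_that("coalescent gene trees reproduce Kingman expectations", {
  set.seed(11)
  ## pairwise within one diploid population: mean 2 N
  tm <- replicate(3000, sim_msc_gene_tree(n_alleles = 2,
                                          summary_only = TRUE)$tmrca)
  expect_equal(mean(tm), 2, tolerance = 0.08)
  ## haploid convention halves coalescent times
  th <- replicate(3000, sim_msc_gene_tree(n_alleles = 2, ploidy = "haploid",
                                          summary_only = TRUE)$tmrca)
  expect_equal(mean(th), 1, tolerance = 0.08)
  ## assembled trees are valid, ultrametric, correctly labelled
  sp <- sim_yule_species_tree(20, 10, 50, seed = 13)
  g <- sim_msc_gene_tree(sp, alleles = 3, seed = 13)
  expect_equal(length(g$tip.label), 30L)
  expect_true(ape::is.ultrametric(g, tol = 1e-8))
  expect_true(all(grepl("^t\\d+_\\d+$", g$tip.label)))
  expect_gt(attr(g, "tmrca"), 50)   # the MRCA predates the species root
  expect_s3_class(gmyc_tree(g), "gmyc_tree")
  ## species monophyly is possible only below the species MRCA: every
  ## within-species coalescence is younger than the gene tree root
  expect_identical(ape::write.tree(sim_msc_gene_tree(sp, alleles = 3, seed = 4)),
                   ape::write.tree(sim_msc_gene_tree(sp, alleles = 3, seed = 4)))
})

test_that("gene-tree depths match an independent coalescent simulator", {
  ## distributional cross-check against msprime on identical configurations
  n <- 800
  set.seed(17)
  ours <- replicate(n, sim_msc_gene_tree(n_alleles = 10,
                                         summary_only = TRUE)$tmrca)
  script <- paste(
    "import msprime, json, sys",
    "out = [msprime.sim_ancestry(samples=5, population_size=1.0, ploidy=2,",
    "       random_seed=1 + i).max_root_time for i in range(800)]",
    "print(json.dumps(out))", sep = "\n")
  res <- tryCatch(system2("python", "-", input = script, stdout = TRUE,
                          stderr = FALSE), error = function(e) NULL)
  skip_if(is.null(res) || length(res) == 0, "python/msprime unavailable")
  theirs <- unlist(jsonlite::fromJSON(res[length(res)]))
  expect_gt(suppressWarnings(stats::ks.test(ours, theirs)$p.value), 0.001)
})

test_that("island-model genealogies match structured-coalescent theory", {
  set.seed(19)
  ## D = 1 collapses to the panmictic Kingman: E[TMRCA] = 4N(1 - 1/n)
  tm <- replicate(400, sim_island_genealogy(1, 0.5, 1, 20)$tmrca)
  expect_equal(mean(tm), 4 * (1 - 1 / 20), tolerance = 0.12)
  ## pairwise between-deme expectation 2ND + (D-1)/(2 Nm), in N units
  p <- replicate(1500, sim_island_genealogy(3, 0.5, 2, 1)$tmrca)
  expect_equal(mean(p), 2 * 3 + 2 / (2 * 0.5), tolerance = 0.6)
  ## scattering phase ends before the MRCA and is flagged
  g <- sim_island_genealogy(50, 0.1, 5, 4, seed = 23, return_tree = TRUE)
  expect_lt(g$scattering_end, g$tmrca)
  expect_true(ape::is.ultrametric(g$tree, tol = 1e-8))
  expect_equal(length(g$tree$tip.label), 20L)
})

test_that("TMRCA converts to substitutions per site via theta", {
  expect_equal(tmrca_to_substitutions(3940, 0.01), 9.85)
  expect_equal(tmrca_to_substitutions(3940, 0.01, 200), 0.049,
               tolerance = 0.01)
  expect_equal(tmrca_to_substitutions(0, 0.02), 0)
  expect_error(tmrca_to_substitutions(10, -1), "theta")
})

test_that("sequence simulation respects the clock and the HKY model", {
  sp <- ape::read.tree(text = "(A:0,B:0);")
  aln <- sim_sequences(sp, length = 50, seed = 1)
  expect_identical(as.character(aln)[1, ], as.character(aln)[2, ])
  ## expected pairwise difference ~ 2 * depth * mu in the small-branch limit
  t_half <- 0.01 / (2 * 0.015 / 4)  # so 2 t mu = 0.01
  tr2 <- ape::read.tree(text = sprintf("(A:%f,B:%f);", t_half, t_half))
  set.seed(2)
  d <- replicate(12, {
    a <- as.character(sim_sequences(tr2, length = 2000, gamma_shape = 100))
    mean(a[1, ] != a[2, ])
  })
  expect_equal(mean(d), 0.01, tolerance = 0.25)
  ## kappa -> infinity: differences are transitions only
  set.seed(3)
  big <- sim_sequences(ape::read.tree(text = "(A:20,B:20);"), length = 400,
                       kappa = 1e9, gamma_shape = 100)
  ch <- as.character(big)
  diffs <- which(ch[1, ] != ch[2, ])
  pair <- apply(ch[, diffs, drop = FALSE], 2, function(z)
    paste(sort(z), collapse = ""))
  expect_gt(length(diffs), 10)
  expect_true(all(pair %in% c("ag", "ct")))
  ## determinism and FASTA round trip
  s1 <- sim_sequences(tr2, length = 100, seed = 5)
  s2 <- sim_sequences(tr2, length = 100, seed = 5)
  expect_identical(as.character(s1), as.character(s2))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(s1, f)
  back <- ape::read.FASTA(f)
  expect_equal(length(back), 2L)
})

test_that("the experiment driver returns one audited row per replicate", {
  r <- run_gmyc_experiment("depth", depths = c(40, 160), replicates = 2,
                           n_grow = 30, n_sample = 10, alleles = 3,
                           n_steps = 1500, burnin = 300, thin = 5, seed = 77)
  expect_equal(nrow(r), 4L)
  expect_true(all(r$ok))
  expect_true(all(r$hpd_lower <= r$posterior_mean &
                    r$posterior_mean <= r$hpd_upper))
  expect_true(all(r$frac_below_4N >= 0 & r$frac_below_4N <= 1))
  expect_equal(r$n_true, rep(10L, 4))
  ## reproducible under the same seed
  r2 <- run_gmyc_experiment("depth", depths = c(40, 160), replicates = 2,
                            n_grow = 30, n_sample = 10, alleles = 3,
                            n_steps = 1500, burnin = 300, thin = 5, seed = 77)
  expect_identical(r, r2)
})
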