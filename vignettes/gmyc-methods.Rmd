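---
title: "Species delimitation with the mixed Yule-coalescent model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Species delimitation with the mixed Yule-coalescent model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model and its assumptions

Given a rooted, ultrametric gene tree for `n` sequences sampled from
multiple species (several individuals per species where possible), the
mixed Yule-coalescent model assumes each of the `n - 1` branching events
is either a speciation among species-level lineages — a Yule pure-birth
process with hazard `lambda_yule * k^p_yule` for `k` current lineages — or
a coalescence among sequences within one species, with hazard
`lambda_coal * (s(s-1))^p_coal` for `s` lineages of that species. Because
within-species coalescence is typically much faster than cladogenesis,
the two regimes separate in time, and a single threshold age classifies
the events. The threshold is represented here as a rank `T` in
`[2, n]`: the `T - 1` oldest events are speciations, exactly `T` lineages
cross the threshold, and each crossing lineage subtends one putative
species. The likelihood depends only on this classification, not on the
continuous position of the threshold inside an inter-event gap, so the
rank is the natural parameter; the reported "threshold time" is the age
of the `T - 1`-th ranked event, which can differ from other software by
up to one inter-node gap.

Key assumptions inherited from the model family: a single locus whose
genealogy stands in for the species history; panmictic,
constant-size populations within species (the exponents `p` absorb
modest departures — population growth, diversification-rate change);
complete lineage classification by one time threshold (no
per-species thresholds); and an ultrametric input tree. Population
structure within species violates the model in a specific, documented
way: a finite island model produces genealogies whose fast "scattering"
phase mimics coalescence and whose long "collecting" phase mimics
cladogenesis, so metapopulation samples can yield confident but spurious
clusters. The island-model simulator (`sim_island_genealogy()`) exists to
quantify exactly this scenario.

## Waiting times, counts, and the event-attribution convention

`interval_table()` decomposes a tree into intervals between the ranked
branching times `t_1 > ... > t_m`. Interval `i` spans `[t_{i+1}, t_i]`,
holds `i + 1` lineages, and (in the backward-time convention used
throughout) is terminated at its older end by event rank `i`. Only the
`m - 1` inter-event waiting times enter the likelihood; the segment above
the root and the segment from the youngest event to the present carry no
waiting time between events. Under this convention the youngest event
terminates no interval, the root event is always a (Yule) event, and
within-species terms are exactly Kingman coalescent hazards.

The printed form of the model gives each interval the combined hazard
`b_i` and density `b_i exp(-b_i x_i)` without saying which process an
event belongs to; that form admits no closed-form rate estimate, yet the
branching rates are classically profiled rather than sampled. We resolve
this by event attribution: each event contributes the log-hazard of its
own process (Yule if its rank is `<= T - 1`, else coalescent), while
survival uses the combined hazard. The conditional MLEs are then

    lambda_hat_proc = (#events of the process) / sum_i c_{i,proc} x_i

with `c_{i,yule} = n_{i,k+1}^p_yule` and
`c_{i,coal} = sum_j (n_{ij}(n_{ij}-1))^p_coal`. The two conventions
coincide whenever a single process is active in an interval and differ
only through cross-process survival terms. Because the choice is a
genuine modelling decision, the strict combined-hazard form is shipped as
`attribution = "combined"` in `gmyc_loglik()` and `gmyc_ml()` (rates then
maximized numerically) for sensitivity analysis; the event-attribution
form with profiled rates is the default everywhere, including the MCMC.

Tied branching times (duplicate sequences, resolved polytomies) would
create zero waiting times; they are rejected with advice to deduplicate
(`dedupe_alignment()`), or deterministically perturbed by at most
`1e-8 * root age` under `jitter_ties = TRUE`.

## Parameters that matter

* `p_yule`, `p_coal` (dimensionless, default support `[0, 2]`, optimizer
  start 1): rate-change exponents; 1 is the neutral no-change case. The
  fold-change in speciation rate from root to threshold is `n^p/n`, so an
  informative prior such as `U(0, 1.2)` (about a two-fold acceleration
  over ~44 species) can exclude implausibly strong accelerations.
* `lambda_yule`, `lambda_coal` (events per branch-length unit): profiled,
  never user-set in normal use; `lambda_coal ~ 1/(N_e mu)`.
* Priors (`gmyc_priors()`): discrete uniform on the threshold rank
  (default `[2, n]`), continuous uniform on the exponents.
* Chain (`gmyc_mcmc()`): `n_steps`/`burnin`/`thin` default to
  10,000/1,000/100 — 90 retained samples per tree, matching the common
  protocol of pooling 100 posterior trees into 9,000 samples; single-tree
  simulation studies here use 20,000 steps with 10% burn-in. Proposals:
  threshold random walk of step `<= t_step = 3` (out-of-support proposals
  rejected in place — reflecting a *discrete* walk at a boundary is not
  symmetric and provably distorts the stationary distribution, which our
  enumeration test catches), an independence draw from the threshold
  prior with probability `t_jump_prob = 0.1`, and sliding windows of
  width `p_window = 0.2` on the exponents, reflected at the bounds
  (symmetric for continuous variables). One parameter, chosen uniformly,
  is updated per step.
* LR test: `2 (logL_GMYC - logL_null)` against chi-square with `df = 3`
  (threshold + one extra rate + one extra exponent), configurable.

## Why the independence jump exists

The likelihood surface over `T` routinely shows a weak local optimum at
the all-singletons corner `T = n`: with a strongly accelerating Yule rate
the pure-birth model imitates coalescent clustering. On deep simulated
trees this corner sits tens of log-units below the global mode yet is
locally uphill, so a bounded random walk that starts (or wanders) above
roughly `T = 0.9 n` never leaves it at realistic chain lengths. The
independence component (10% of threshold moves propose uniformly from the
prior) crosses the barrier in both directions with the correct acceptance
rule, making the sampled distribution initialization-independent. Chains
start from the prior by default (`init = "prior"`, overdispersed);
`init = "profile"` starts at the profile-likelihood argmax under neutral
exponents.

## What the simulators emulate — and what they do not

`sim_yule_species_tree()` grows a pure-birth tree to `n_grow` species
(rate immaterial), keeps a uniform subsample (`n_sample`) to mimic
incomplete taxon sampling, and rescales the root to a stated depth in
N-generation units (N = diploid effective size; the haploid/organellar
convention halves coalescent times). `sim_msc_gene_tree()` nests
independent Kingman coalescents in the species-tree branches (pairwise
rate 1/2 per N generations, diploid), with fixed or lognormal allele
counts per species: `ceiling(Lognormal(meanlog = 1, sdlog = 1))`, giving
mean ~5 and ~16% singletons. The ceiling discretization is the one rule
consistent with both of those targets (rounding would give mean 4.5 and
~28% singletons). `sim_sequences()` adds HKY+G sites under a strict clock
(`mu = theta/4` per N generations; defaults `theta = 0.015`, `kappa = 4`,
gamma shape 0.5 with 4 analytic bin-mean categories, equal base
frequencies — only `theta`, the model family and the lengths are
standard; the rest are stated defaults, all configurable).
`sim_island_genealogy()` is a Gillespie structured coalescent over `D`
demes of size N (per-lineage migration `Nm` per N generations, uniform
target deme); the default sample of 5 lineages from each of 10 demes is a
stated choice — the all-lineage TMRCA is collecting-phase dominated and
insensitive to it. The simulators are cross-checked against analytic
expectations (pairwise and many-lineage Kingman means, the island-model
pairwise formula `2ND + (D-1)/(2m)` generations) and distributionally
against an independent coalescent simulator (msprime) in the test suite.

Not emulated: recombination, selection, migration between *species*,
rate heterogeneity among lineages (no relaxed clock), sequencing error,
and the upstream estimation of clock trees from sequences (a BEAST-style
`.trees` file is consumed, not produced — so the sequence-length
experiment, run without an external tree-estimation step, varies only the
alignment it writes, not the fitted tree). Passing tests therefore
validate the inference machinery on clean ultrametric genealogies; they
do not certify behavior on real data with phylogenetic error beyond what
pooling externally estimated tree samples captures.

## Numerical choices

Ultrametricity is checked as the relative spread of root-to-tip path
lengths (tolerance `1e-6`) and trees are renormalized so tips sit exactly
at age zero. Exponents are maximized with box-constrained quasi-Newton
(fallback: Nelder-Mead on the projected objective). The profile-rate
formulas drop a process with zero attributed events (its rate tends to
zero). The discrete 95% HPD is the smallest contiguous run of threshold
values with at least 0.95 mass (ties: narrower, then smaller lower end) —
appropriate for an ordinal parameter reported as contiguous ranges.
Effective sample sizes use Geyer's initial monotone positive-sequence
estimator, validated against the AR(1) closed form. All simulators and
chains are deterministic given a seed; multi-tree runs derive per-tree
substreams from one top-level seed.

Ties between `T = n - 1` and `T = n` (both all-Yule classifications with
identical likelihood) are broken toward the smaller threshold, as are any
other exact likelihood ties in the scan.

## Problem sizes used in the shipped validation

The acceptance script and test suite run the full pipeline at sizes
chosen for a single CPU: coalescent expectations from 10,000 genealogies;
the branch-length statistic from 50 species trees; the depth study at
160/80/40/20 N with 50 (script) or 10 (tests) replicate datasets of 50
species x 5 alleles and 20,000-step chains with 10% burn-in (the original
study also used 50 replicates, with 100,000-step chains); the island model from
150 genealogies (the original used 10, so its published mean TMRCA of
3,940 N carries a standard error of several hundred N; our larger runs
and msprime agree on ~3,500-3,600 N, within sampling error of the
published figure). Reanalysis of published empirical barcode
datasets (GenBank download, deduplication, external clock-tree
estimation, pooled MCMC over the resulting tree sample) follows the same
pipeline but is deliberately not automated here: it requires network
access and an external Bayesian tree program.

## Known limitations

The posterior is conditioned on profiled (not sampled) branching rates,
a deliberate mirror of standard practice; a fully Bayesian treatment of
the rates would need explicit priors on them. The single-threshold model
cannot represent variation in divergence depth or population size among
species — a multiple-threshold extension would require reversible-jump
MCMC and is out of scope. At shallow species-tree depths (rapid recent
radiations) the Yule and coalescent regimes genuinely overlap; the model
then produces wide, multimodal, and sometimes misleading posteriors, and
the shipped depth experiment demonstrates precisely that failure mode.
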