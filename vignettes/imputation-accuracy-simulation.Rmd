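---
title: "Simulating and scoring genotype imputation in structured pig populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and scoring genotype imputation in structured pig populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(impsim)
```

## The question the package answers

Genotype imputation infers the unobserved genotypes of sparsely typed
individuals from a densely typed, phased reference panel. Its accuracy
controls the quality of every downstream analysis (GWAS, genomic
prediction), and depends on design choices a study can actually control:
how many markers are typed (SNP-chip density or low-coverage sequencing
yield), how large the reference panel is, and how genetically close the
reference population is to the target population. `impsim` evaluates these
factors jointly by simulation: it generates sequence-resolution haplotypes
under a four-population pig demography, hides a controlled fraction of
variants, imputes them, and scores the result locus by locus.

The pipeline has four stages, each usable on its own:

1. **Simulate** (`pig_demography()`, `simulate_panel()`) — a structured
   coalescent with recombination, migration, bottleneck-scale population
   sizes and splits, producing phased 0/1 haplotypes at segregating sites.
2. **Ascertain** (`filter_target_universe()`, `select_evenly_spaced()`,
   `select_random()`, `mask_panel()`) — build the biallelic,
   MAF-filtered variant universe and split it into observed scaffold
   markers and hidden imputation targets.
3. **Impute** (`impute_genotypes()`) — a Li–Stephens haplotype-copying
   hidden Markov model; external tools are pluggable through a VCF
   adapter (`external_impute()`).
4. **Evaluate** (`reliability()`, `error_rate()`, `run_scenario()`,
   `summarize_scenarios()`) — per-locus reliability and allelic error
   rate, MAF binning, factorial aggregation, regression of accuracy on
   factor levels, and coefficient-of-variation factor ranking.

## The demographic model

`pig_demography()` encodes the packaged demography: an ancestral
population of diploid effective size 10,873 and four descendant
populations P1–P4 (Ne 1,600, 1,200, 1,000, 1,400) on a 10 Mb chromosome
with mutation and recombination rates of 1e-7 per bp per generation.
Backward in time the default topology is a chain of merges — P4 into P3
at 20 generations, P3 into P2 at 200, P2 into P1 at 3,000, P1 into the
ancestral deme at 9,000 — with symmetric migration active while both
demes of a pair exist (ANC–P1 2.1e-5, P1–P2 1.1e-3, P1–P4 3.7e-4,
P2–P3 5.2e-5, P3–P4 1.6e-3).

The published description of this demography fixes the event times,
sizes, and migration rates but not the split tree, so the chain topology
is this package's documented interpretation, chosen for consistency with
the stated event order; it is configurable through the `splits` argument.
Two features of the parameterization deserve note. First, under the chain
reading the ANC–P1 migration rate never applies (the two demes never
coexist); it is retained in the model object for completeness. Second,
the direct P1–P4 migration makes P4 not strictly the most distant deme
from P1 in realized kinship — P3 and P4 always form the closest pair
(their block kinship is the largest between-population value, which the
test suite checks), while the P2 > P3 ~ P4 gradient away from P1 holds on
average rather than replicate by replicate. The accuracy trends are
asserted accordingly (pooled means and majority-of-replicates
directions).

```{r model}
m <- pig_demography(sequence_length = 5e4)
m
```

## The coalescent engine

`simulate_ancestry()` is a Hudson-style backward simulation of the
structured coalescent with recombination. Lineages carry their ancestral
material as half-open bp segment sets; coalescence in deme *j* occurs at
rate C(k_j, 2)/(2 N_j), migration of a lineage from *x* to *y* at rate
m_xy, and recombination at rate r times the lineage's ancestral extent,
with a uniformly placed breakpoint. Tree edges are recorded over the
overlapping material of each coalescence, and an interval is retired as
soon as a single lineage carries it (its marginal most recent common
ancestor has been reached). Time is continuous, in generations, with the
diploid pair-coalescence rate 1/(2N).

`overlay_mutations()` adds infinite-sites mutations as a Poisson process
(rate mu per bp per generation) on each marginal tree; each mutation
takes a continuous uniform position inside its tree interval, floored to
an integer bp, with integer collisions re-drawn so sites stay unique.
Coordinates are 0-based half-open internally; VCF export is 1-based.

One run seed drives both stages through deterministically derived
sub-seeds, so ancestry and mutations are independently reproducible, and
identical `(model, samples, seed)` triples are bit-identical.

The engine is validated against closed-form coalescent theory rather
than against another simulator: mean pair coalescence time 2N, total
tree length 4N·H(n−1), Watterson's expected segregating sites, and mean
pairwise diversity 4Nμ, all as seeded Monte-Carlo checks with
standard-error tolerances.

```{r sim}
pan <- simulate_panel(m, c(P1 = 12, P2 = 6, P3 = 6, P4 = 6), seed = 11)
summary(pan)
```

## Marker ascertainment

The variant universe for an experiment is the set of biallelic sites
with minor allele frequency at least 0.01 *in the target individuals*
(the threshold is inclusive; infinite-sites simulation guarantees
biallelism). A density level *p* places `floor(p * S)` markers on the
scaffold — the flooring rule reproduces the published marker counts for
every density level and population total exactly.

Two schemes mimic the two data types. SNP-chip data takes markers
*evenly spaced in site rank* (deterministic half-up rounding of ranks
`j(S-1)/(count-1)`); rank spacing rather than bp spacing is used because
it is deterministic and density-exact, and because the evenness convention
of the emulated chips is not published — a bp-spaced option would slot in
behind the same interface. Low-coverage sequencing (LCWGS) data takes a
uniform random subset of true genotypes: no read-depth or
genotype-likelihood model is applied, matching how the emulated study
derived its LCWGS panels from simulated variants (a deliberate
simplification; see Limitations).

## The imputation engine

The imputer is a faithful, unreduced Li–Stephens haplotype-copying HMM:
each target haplotype is modeled as an imperfect mosaic of the K
reference haplotypes. Over a distance of d bp the copying state switches
with mass `q = 1 - exp(-rho d / K)` spread uniformly over all K states;
emissions match the copied allele with probability `1 - eps`. Defaults
are `eps = 1e-3` and `rho = 4 Ne r` with `Ne = 1600` (the largest
descendant deme) — both overridable via `ls_params()`. Production
imputation tools (Beagle5.1, Minimac4) are state-space-reduced
implementations of this same model family; their reductions
(IBD-segment subsetting, genomic-block compression) are engineering
accelerations that this package deliberately does not reproduce, so
absolute accuracy values are comparable only in trend, not in level.
The `external_impute()` adapter runs any such tool through VCF files and
a command template, returning results in the same layout.

Numerics: the forward–backward pass is scaled (per-site normalizers
retained) rather than log-space, which keeps it vectorizable over K;
tests assert agreement with a log-space reference implementation to
1e-9 and with exhaustive path enumeration (small K, few sites) to
1e-10. Hidden sites are imputed by exact propagation: the transition
kernel is a semigroup in distance, so advancing the forward vector from
the left scaffold neighbor and the backward vector from the right one
and renormalizing reproduces the exact posterior a silent site would
have had inside the chain (one-sided at the flanks).

Targets are phased by simulation truth, and each haplotype is imputed
independently (K states, not the K² diploid chain) — this exercises the
same accuracy mechanics at desk scale; an unphased-diploid mode would be
an extension, not a default. Genotype dosage is the sum of the two
haploid dosages; the best-guess genotype is the nearest integer with
half-to-even tie-breaking, clipped to {0, 1, 2} (error rates depend on
this rule, hence it is fixed and documented).

```{r impute}
vt <- filter_target_universe(pan, "P1", maf_min = 0.01)
sel <- select_random(vt, marker_count(nrow(vt), 0.3), seed = 21)
sp <- mask_panel(pan, sel)
tgt <- subset_individuals(sp$scaffold, 1:4)
ref <- subset_individuals(subset_sites(pan, vt$site), 5:30)
loc <- impsim:::.new_selection("lcwgs", seq_len(nrow(vt)),
                               match(sel$observed, vt$site))
imp <- impute_genotypes(tgt, ref, loc)
imp
```

## Scoring

Two criteria are computed per hidden locus, both on best-guess 0/1/2
genotypes. **Reliability** is the squared Pearson correlation between
imputed and true genotypes, with population (divide-by-n) moments; it is
undefined when either vector is constant (mono-allelic loci), and such
loci are *excluded* from averages, never scored zero. **Allelic error
rate** is the percentage of wrongly imputed alleles,
`sum(|G_imp - G_true|) / (2 n) * 100`, using the minimal unphased allele
mismatch per genotype pair. Loci are binned by MAF with half-open bins
(default edges 0.01, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5 — the emulated study
names no edges, so these are package defaults).

Factor influence is summarized two ways: ordinary least-squares
regression of accuracy on factor levels (raw and standardized slopes
with the slope t-test p-value — the scale of published slope values is
not stated, so both are reported and neither is asserted against them),
and the coefficient of variation of per-level marginal means, using the
population standard deviation. The CV convention is validated by exact
reproduction of the published CV values (1.508, 0.262, 0.320) from the
packaged benchmark cells. Between-population genetic distance is
summarized by a VanRaden-style genomic relationship halved to kinship
scale, reported as population-block means; the published kinship table
names no estimator, so its absolute values are treated as qualitative
structure only.

## The factorial experiment

`study_grid()` enumerates the packaged design: reference sizes
{100, 1k, 3k, 5k, 10k} for P1 and {100, 1k, 3k} for P2–P4, six density
levels (1–90%), two schemes and two method slots — 336 scenarios.
`run_scenario()` executes one cell: the first `n_target` P1 individuals
are the fixed imputation targets (the target set is not re-drawn across
scenarios), the reference is drawn uniformly without replacement from
the stated population excluding all targets, and every hidden locus is
scored. Everything is deterministic given the panel and the scenario
seed.

Full scale (20,000 diploids × 10 Mb) is cluster work. The package's desk
profile scales the design proportionally — a factor-0.01 panel
(P1 = 110, P2–P4 = 30 diploids, 10 targets) with reference sizes mapped
by `scale_grid()` (`max(2, round(size * factor))`, capped by the
available pool) and sequence lengths of 0.15–0.3 Mb. The test suite runs
reduced grids of this profile: panel sizes of 50/25/25/25 diploids over
150 kb with three replicate panels, four density levels, three reference
sizes and all four reference populations, asserting the study's trend
directions — reliability rising with density and reference size, falling
from P1 to P4 — on pooled means with majority-of-replicates backing.
Saturation at 90% density is checked on an "easy" panel (low
recombination, large conspecific reference) as a Monte-Carlo bound,
since the exact saturation values of the full-scale study are not
reproducible at these sample sizes.

```{r scenario}
r <- run_scenario(pan, "P2", 5, 0.3, "lcwgs", seed = 3,
                  target_population = "P1", n_target = 4)
r
```

## Packaged benchmark tables

`load_fixture()` ships the printed cells of the emulated study's
headline tables: per-population marker counts by density level ("T4"),
and the mean reliability ("T5") and allelic error rate ("T6") of
Beagle5.1 and Minimac4 for LCWGS panels by reference size and density.
They exist so the aggregation layer (marginal means, CV ranking) can be
verified against published arithmetic exactly — those cells are outputs
of the full-scale study, not of this package's engine, and are never
presented as such.

```{r fixtures}
er <- fixture_cells("T6")
be <- er[er$method == "beagle5.1", ]
marginal_mean(be, "reference_size", 100, "value")   # mean error %, ref 100
factor_cvs(be, "value")
```

## Numerical and design choices, in one place

- Population (divide-by-n) moments for reliability (n-invariant anyway)
  and CV (validated against the published 1.508/0.262).
- Best-guess rounding half-to-even, clipped to {0,1,2}.
- Mutation position collisions re-drawn within the same tree interval;
  a duplicate that cannot be placed after many attempts is dropped with
  a warning (effectively never at realistic densities).
- Scenario sub-seeds (reference draw, random ascertainment, stage
  streams) are derived from the run seed by fixed integer maps, keeping
  every stage independently reproducible below 2^31.
- Degenerate inputs are errors, not silent defaults: density 1 (nothing
  to impute), count exceeding the universe, hidden sites colliding with
  scaffold sites, reference requests exceeding the pool, unphased VCF
  input without the explicit flag.

## Limitations

- LCWGS is modeled as a random subset of true genotypes; read-level
  coverage, base error and genotype likelihoods are out of scope, so
  conclusions about very low coverage transfer only qualitatively.
- The internal engine is unreduced Li–Stephens: accuracy *levels* of
  Beagle5.1/Minimac4 are not reproduced, only factor trends; runtime
  comparisons of the production tools are likewise out of scope.
- Desk-scale panels have far fewer haplotypes than the full-scale study,
  which lowers site density (about 7 SNPs/kb versus 21.4 full-scale,
  within the order-of-magnitude the smoke test requires) and makes
  per-locus reliability brittle at rare loci; tests therefore assert
  directions and Monte-Carlo-bounded levels, not printed values.
- Phasing is taken from simulation truth; phasing error, a real
  contributor to imputation error, is not modeled.
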