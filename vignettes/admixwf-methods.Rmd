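---
title: "Simulating admixed populations with AdmixWF: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating admixed populations with AdmixWF: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AdmixWF)
```

## The model

AdmixWF is an individual-based, forward-time simulator for admixed
populations under an extended Wright-Fisher model: generations are discrete
and non-overlapping, population sizes and admixture-proportion vectors may
change every generation, and mating is random apart from fitness weighting.
Every chromosome of every founder individual receives a unique integer
label `0 .. 2N-1` (populations own consecutive label ranges), and each
descendant chromosome is represented as an ordered list of *segments*
`(start, end, founder label)` that tile the chromosome, plus a list of
accumulated crossover positions, a list of de novo mutation positions, and
the allele state at each position under selection.  Founder sequence data
are consulted only at output time, when segments are materialised into
alleles — so simulation cost is independent of SNV density.

Reproduction of one offspring proceeds as follows.

1. A source population for each parent is drawn from the
   admixture-proportion vector by the cumulative-threshold rule: with
   proportions (0.2, 0.1, 0.7), a uniform draw below 0.2 selects the first
   source, between 0.2 and 0.3 the second, otherwise the third.  A draw
   exactly equal to a threshold (a measure-zero event) falls to the right
   cell, fixed for reproducibility.
2. Within a source, each individual is drawn with probability proportional
   to its fitness: one plus the sum of the coefficients of every satisfied
   selection condition, negative totals rescaled to zero.  Under a single
   additive rule this gives fitness 1, 1+s, 1+2s for 0, 1, 2 carrier
   haplotypes.  A multi-locus rule is satisfied per haplotype only when
   *all* of its positions carry the required allele.  In monoecious
   populations the two parents must be distinct individuals (a population
   of one cannot reproduce); in dioecious populations one mother and one
   father are drawn, each from their own proportion vector when sex-biased
   admixture (`from_f`/`from_m`) is specified.  We resolve the dialect
   ambiguity of sex-specific proportions by applying them to the *parent*
   draws (mother and father source), not to the offspring's sex, which
   matches the usual meaning of sex-biased admixture.
3. Each parent contributes one gamete.  The number of crossovers is
   Poisson(genetic length in Morgan); crossover locations are drawn
   uniformly on the genetic scale and mapped to physical coordinates
   through the (piecewise-linear, possibly SNV-table-derived) genetic map.
   Crossovers may fall at any base pair, not only between SNVs; ties at an
   identical position collapse to one crossover.  The gamete starts on
   either parental haplotype by fair coin and alternates at each crossover,
   inheriting segments, accumulated breakpoints, mutation positions and
   selected-site states region by region.  Adjacent same-label segments
   created by back-crossovers are *not* merged: the breakpoint list is the
   record of crossovers, segments are the record of ancestry.
4. De novo mutations are Poisson(total mutation rate); under the uniform
   model positions are uniform integers on `[0, L)`, under the
   locus-specific model they are the SNV-file sites sampled proportional to
   their rates.  A second hit at an occupied position reverts the allele
   (two-allele model).  De novo mutations never enter fitness.

On an X chromosome, recombination happens only in female meioses: sons
receive their mother's recombinant X and no paternal X; daughters receive
the maternal recombinant plus the father's X copied intact.  An X lineage
therefore recombines in two-thirds of its meioses, which is why X
breakpoint counts converge to 2/3 of the autosomal expectation and why the
X tract-length rate carries a 2/3 factor.  Because sex-specific
transmission differs per chromosome type, an X chromosome is simulated in
its own run rather than alongside autosomes.

Only the current and the previous generation are held in memory; states
requested by output directives (and the final generation) are deep-copied
out before the discard.

## Parameters and defaults

* `recRate` — uniform recombination rate, Morgan/bp; default `1e-8`
  (1 cM/Mb, the usual human-scale value).  Overridden by a `gpos` column
  (Morgan) in the SNV table, which defines a piecewise-linear map anchored
  at (0, 0) and extended to the chromosome end at `recRate`.
* `mutRate` — mutation probability per site per generation; default
  `1e-8`.  Overridden by a `mut_rate` column, in which case the de novo
  process acts on the listed sites only, with total rate equal to the
  column sum.  Command-line overrides beat SNV-file columns, which beat the
  defaults.
* Chromosome length `L` (bp) defaults to the last SNV position; scenarios
  state it explicitly (3e8 bp at `1e-8` Morgan/bp is a 3-Morgan
  chromosome).
* Population sizes, proportions, selection coefficients and output samples
  all live in the model file; a population absent from a generation's block
  persists with the same size and 100% self-contribution — note this is a
  Wright-Fisher resampling, so it drifts.  A continuing population may mix
  self- and external sources in the same generation.
* Selection coefficients may vary over generations by giving several rules
  with disjoint `@g1-g2` windows; rules active at generation `g` weight the
  parents sampled to *produce* generation `g`.

## Reproducibility and the draw order

All randomness flows through R's global RNG from a single seed.  Draws are
consumed in a fixed order (per generation, per population in declaration
order, per offspring: sex coin if needed; mother source, mother; father
source, father; then per chromosome maternal gamete before paternal, each
as crossover count, crossover positions, start coin, mutation count,
mutation positions).  The same order is implemented twice: in the C++
segment engine that `runSimulation()` uses, and in `perSiteSimulate()`, a
pure-R brute-force simulator that stores every haplotype as an explicit
per-site allele vector and applies crossovers site by site.  Because both
replay identical decisions, their output sequences must agree *exactly*;
the test suite asserts this across 50 seeds on fixtures covering neutral,
selected, dioecious, X-linked, nonuniform-map and locus-specific-rate
runs.  This is the package's primary correctness argument: the segment
arithmetic is validated against an implementation too simple to be wrong
in the same way.

## Closed-form expectations used for validation

* Additive selection: `selectionRecursion()` gives the deterministic
  next-generation frequency
  `x' = ((1+2s)x^2 + x(1-x)(1+s)) / ((1+2s)x^2 + 2x(1-x)(1+s) + (1-x)^2)`;
  its fixed points are exactly 0 and 1 for `s != 0`.
* Breakpoints accumulate at (genetic length) per meiosis, hence
  `L_gen x g` after `g` generations, and `(2/3) L_gen x g` on the X.
* Mutation counts after `g` generations are Poisson(`mu L g`);
  `poissonGof()` pools bins until every expectation reaches 5 (the
  binning is our choice) and applies a chi-square test.
* Under hybrid isolation, tracts of an ancestry with proportion `m` have
  approximately exponential genetic length with rate `(1-m)T` per Morgan
  after `T` generations (`expectedTractRate()`); on the X the rate scales
  by 2/3, reflecting the smaller effective recombination rate.  The law is
  stated for the single-pulse model only; for multi-wave histories the
  package deliberately makes no approximation.

## The synthetic founder generator and scenarios

`simulateFounderPanel()` draws founder alleles per site from
population-specific derived-allele frequencies: a shared per-site base
frequency pushed toward a population-private pole by a `divergence` knob
(1 = fully diagnostic sites, which make ancestry recoverable per site and
are convenient for testing).  This emulates allele-frequency divergence
between source populations but none of the linkage disequilibrium,
site-frequency-spectrum shape or mutation-age structure of real panels —
so passing tests demonstrate the correctness of the transmission machinery,
not realism of the founder haplotypes themselves, which in real use come
from phased reference data (native dialect or phased VCF).

`buildScenario()` bundles the validation settings used throughout:
hybrid isolation with 4:1 contributions, size 5000, 3-Morgan chromosome,
50 generations (autosomal and X variants); two-, three- and four-way
single-pulse models with contributions 0.246/0.754 (11 generations,
2.49e8 bp), 0.512/0.052/0.436 (18 generations, 2.48e8 bp) and
0.35/0.15/0.35/0.15 (150 generations, 2.48e8 bp); and a selection grid
(1:1 pulse, 100 founders per source, size 5000, 1-cM chromosome,
`x0 in {5, 10, 15, 20}%`, `s in 0.01..0.1`).  Founder sizes default to 100
per population and admixed sizes to 5000 where the scenario does not pin
them.  The multi-way histories are built as single pulses with the stated
total contributions; the selected scenario uses a single diagnostic locus,
whose carriers are placed on random haplotype slots so founder genotypes
are Hardy-Weinberg-like (placing them on consecutive rows would make every
carrier homozygous and visibly bias the first post-admixture generation
away from the recursion — we measured exactly that and fixed the design
accordingly).

## Numerical and edge-case choices

* Coordinates are 0-based half-open internally, 1-based inclusive in
  files, matching VCF conventions externally and simplifying interval
  arithmetic internally.  Crossover positions are continuous; mutation
  positions are integer bp.
* Proportion vectors must sum to 1 within `1e-9`; violations are parse
  errors naming the line.
* A selection rule referencing a position absent from the SNV table fails
  at setup, not mid-run; founders must carry states at rule positions.
* Zero-fitness pools, missing sexes, extinct sources and oversampling
  directives raise errors naming the population and generation.
* `stopOnFixation` ends a run once every tracked position is fixed in
  every population; it is opt-in because later gene flow from a
  differently-fixed population could in principle re-polymorphise a locus.

## Validation scale

The shipped checks run at desk scale chosen to finish in minutes on one
CPU while keeping sampling error well below the acceptance bands: 6 seeds
for the 50-generation breakpoint means (all final haplotypes), population
size 1000 for the mutation-law and ancestry-proportion runs (the means are
size-independent), 200 replicates over a 50-generation horizon for the
selection trajectory, 20 replicates per cell at size 1000 for the
fixation-time grid, and Fisher-combined Kolmogorov-Smirnov tests over
three replicate simulations for the tract-length law (a single 1%-level
KS test on a stochastic run flakes at the percent level by design).

## Known limitations

Generations are non-overlapping; there is no mate choice, phenotype-based,
epistatic or balancing selection; no Y chromosome or mitochondrial
inheritance; no tree-sequence recording; multiallelic sites are not
modelled (a double mutation reverts); and the exponential tract check does
not extend to multi-wave demographies.  The per-site oracle is exponential
in nothing but linear in sites times individuals times generations, yet
still only sensible at toy scale.
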