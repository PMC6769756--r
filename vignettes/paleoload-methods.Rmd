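---
title: "Methods: mutational load, allele-frequency trajectories and inbreeding from ancient and modern genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutational load, allele-frequency trajectories and inbreeding from ancient and modern genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

paleoload implements a re-usable pipeline for studying the origin and
recent dynamics of deleterious variation in a domesticated species,
built around four statistical components: a conservation-weighted
mutational-load estimator computed from strict homozygous genotype
calls; maximum-likelihood allele-frequency trajectories estimated from
ancient-DNA read counts in sliding temporal windows; drift phylogenetics
on pseudo-haploid data; and inbreeding/purging diagnostics based on a
two-state identity-by-descent (IBD) hidden Markov model and a dN−dS
divergence proxy. A Wright–Fisher synthetic-data generator produces
horse-like panels with full ground truth, so every stage can be
validated end to end. This vignette describes the models, their
assumptions, the tunable parameters, and the design decisions taken
where more than one reasonable choice existed.

## Deleterious-allele annotation

Evolutionary conservation predicts fitness effects: positions that
stayed constrained across a deep multi-species alignment tolerate few
substitutions, so a rare allele segregating there is likely harmful.
Each site carries a phyloP score; sites with `phylop >= 1.5` (the
default `phylop_threshold`) are treated as constrained. The source
literature uses both "minimum score of 1.5" and "greater than 1.5";
we standardize on the inclusive boundary (`classify_constraint()`),
record the threshold in `pl_config()`, and note that no site in
practice sits exactly at the boundary after rounding.

The deleterious allele at a site is the allele that is rarer than, or
absent from, the alignment column, provided at most two variants
segregate across the column and the sampled genomes together
(`assign_deleterious_allele()`). Three conventions complete the rule
where the definition is silent:

* tied column counts (e.g. 23:23) leave the site unassigned and it is
  dropped from numerators;
* more than two variants overall always disqualify the site;
* overlapping region annotations resolve by specificity: coding >
  upstream2kb > downstream2kb > intron > intergenic.

Substitutions are classified as transitions (A/G, C/T) or
transversions; every trajectory analysis can be restricted to
transversions, which post-mortem cytosine deamination cannot mimic.

## Genotype likelihoods and strict homozygous calling

Per-read model: a read from template allele $A$ reports base $b$ with
probability $1-e$ if $b=A$ and $e/3$ otherwise; for a heterozygote each
read is drawn from either allele with probability $\tfrac12$. The site
likelihood of a genotype is the product over reads, normalized over the
three genotypes of the biallelic site. A genotype is *called* only when
it is homozygous **and** its normalized likelihood strictly exceeds
`call_threshold = 0.99` ("exceeded" is read as a strict inequality);
otherwise the site is masked with a reason code (`heterozygous`,
`below_threshold`, `no_data`). Heterozygous sites are never used
downstream because the dominance of the variants is unknown. Whether the
published 0.99 cutoff was applied to raw or normalized likelihoods is
not stated; we use the normalized value (a flat-prior posterior), which
is the scale on which a threshold close to 1 is meaningful. Read-level
quality filtering (mapping quality, BAQ, duplicates) is assumed to have
happened upstream; the package starts from per-site counts of
deleterious-allele reads $r$ and total depth $d$.

## The load statistic

For one genome and a set of sites, the mutational load is

$$\mathrm{load} = \frac{\sum_i \mathrm{phyloP}_i}{\#\,\text{homozygous}},$$

where $i$ runs over called-homozygous positions carrying the
deleterious allele with $\mathrm{phyloP}_i$ at or above the threshold,
and the denominator counts **all** called homozygous sites in the set,
deleterious-carrying or not. Two points were genuinely open:

* *Denominator scope.* Reported per-genome homozygous-site totals in
  the tens of millions indicate the denominator is the total number of
  homozygous calls, not the deleterious subset; we implement that, and
  for region-class loads we use the region-specific denominator (the
  genome-wide alternative would only rescale all classes by a shared
  constant per genome).
* *Unassigned sites* (no deleterious allele) still count in the
  denominator — they were genotyped — but can never contribute to the
  numerator.

The statistic is linear in the phyloP scores and its numerator is
additive over any partition of the site set; both properties are
asserted exactly in the test suite against a per-site brute-force
oracle. Group contrasts use the two-sample Wilcoxon rank-sum test
(exact enumeration when the pooled size is at most 12 and tie-free),
and cross-region agreement uses Spearman rank correlation; both default
to two-sided alternatives since no directional hypothesis is
pre-registered by the estimator itself.

## Temporal allele-frequency trajectories

For a set of individuals within a time bin, the frequency of a
deleterious allele is estimated from raw read counts by maximizing

$$f = \arg\max_p \prod_{i=1}^{n} \binom{d_i}{r_i} p^{r_i}(1-p)^{d_i-r_i},$$

whose maximizer is the pooled ratio $\sum r_i / \sum d_i$; the package
keeps an independent numerical route (`method = "optimize"`, a root of
the score function) and the two agree to $10^{-9}$ on randomized
configurations. Working directly on reads rather than genotypes uses
low-coverage ancient genomes efficiently, at the price of a small
upward bias at truly monomorphic sites from sequencing error
(about $e/3$), which cancels in ancient-versus-modern *differences*
because both pools share the error floor.

Ancient samples are binned in sliding windows of `bin_width_years =
1000` stepped every `bin_step_years = 250`. Bin membership uses
half-open intervals $[c - 500, c + 500)$ so a sample at the upper edge
belongs to the next bin only. A bin contributes an estimate at a site
only when at least `min_bin_n = 10` individuals are genotyped
($d_i > 0$) **at that site** — the stricter per-site reading of the
minimum-sample rule. The modern panel enters as its own bin at 0 BP.

Each variant's trajectory is classified as *fixed* (every available
estimate $\ge 0.99$), *absent* (every estimate $< 0.01$) or *dynamic*.
Frequency shifts $\Delta$ are computed between consecutive
non-overlapping bins (centers 3250, 2250, 1250, 250 BP by default),
reported at the younger bin's center, because overlapping windows share
most of their samples and would produce nearly identical estimates,
deflating $\Delta$. Medians of $|\Delta|$ are summarized over the
dynamic class.

*Ascertainment.* Pooled modern-versus-ancient comparisons condition, by
default, on variants carried as a called homozygous genotype by at
least one modern sample. This mirrors a variant set discovered in
modern genomes, and it cannot be done from raw counts: at pooled depths
of a thousand reads, sequencing error alone places a few
deleterious-allele reads at nearly every site, which would make a
count-based discovery rule vacuous. Conditioning on modern presence is
what gives the modern pool its expected frequency excess; without
ascertainment the neutral-drift expectation of the difference is zero
and slightly negative under selection.

## Drift phylogenetics

Genomes are pseudo-haploidized — one read-backed allele drawn per site
with probability proportional to read counts — which puts high- and
low-coverage genomes on the same footing. Distances are mismatch
fractions over shared non-missing sites, restricted to nearly-neutral
positions (phyloP below threshold) with at most one missing call across
the panel. Trees are built by neighbor joining, which is consistent on
additive matrices; the test suite verifies exact recovery of topology
and branch lengths for up to six taxa against an exhaustive
all-topologies least-squares oracle. Negative branch lengths, which NJ
can produce on noisy input, are clamped to zero with the deficit
shifted to the sibling branch. The published pipeline adds a
minimum-evolution NNI refinement pass; we omit it since plain NJ
already recovers the additive regime exactly, and note that midpoint
and outgroup rooting are exposed as separate options because "mid-point
rooted using the outgroup" conflates two schemes. Internal (stem)
branch lengths of named clades serve as drift proxies — long stems flag
lineages that went through strong bottlenecks — and support values come
from site bootstrap over NJ replicates.

## Inbreeding, IBD tracts and purging

SNPs are first thinned to approximate linkage equilibrium: $r^2$
(squared dosage correlation) is computed for all pairs less than
`ld_max_dist_bp = 50000` apart, pairs at or above `ld_r2_threshold =
0.2` define edges of a graph, connected components form LD blocks, and
the block's most central SNP — maximum degree, leftmost position on
ties — represents it. The published pipeline used Markov clustering
here without stating its inflation parameter or an $r^2$ cutoff;
connected components with a degree-central representative are the
simplest deterministic counterpart, and 0.2 is a conventional pruning
default (configurable).

The IBD model is a two-state HMM along each chromosome. At a SNP with
population frequency $p$, a heterozygote is emitted with probability
$2p(1-p)(1-\varepsilon)$ in the non-IBD state and with a small leak
$\varepsilon$ (genotype error, recent mutation) in the IBD state.
Between consecutive SNPs separated by $\delta$ bp the chain switches
with scale $1 - e^{-a\delta}$, directed into the two states
proportionally to the stationary distribution $(1-F, F)$, so $F$ is at
once the inbreeding coefficient and the long-run fraction of the genome
in IBD tracts, and $1/a$ sets the mean tract length. The three
parameters $(F, a, \varepsilon)$ are estimated by EM. The M-step
maximizes the expected complete-data log-likelihood numerically
(Nelder–Mead on logit/log-transformed $(F, a)$ starting at the current
values, plus a one-dimensional search for $\varepsilon$), which makes
the procedure a generalized EM whose observed-data likelihood is
non-decreasing — asserted in the tests. Iteration stops when the
largest parameter change falls below `em_epsilon = 1e-7`, or earlier
when the likelihood has stabilized, which matters near the boundaries
$F \to 0$ and $F \to 1$ where parameters crawl along a flat ridge.
Tracts are reported by posterior decoding (IBD probability above 0.5),
and the decoded genome fraction agrees with the fitted $F$ within the
resolution of a single tract. The published tool works from genotype
likelihoods rather than hard het/hom indicators; a likelihood-weighted
emission is a straightforward extension hook but is not needed for the
properties validated here.

Purging is diagnosed two ways: (i) the Spearman correlation between
per-genome load and $F$ — strong positive under inbreeding without
effective selection, attenuated when selection removes the recessive
variants that inbreeding exposes; and (ii) the divergence proxy
$dN - dS$, the difference between mismatch rates to an outgroup at
constrained versus neutral sites, more negative under stronger
selection. A breeding stock of $N_m$ males and $N_f$ females has
effective size $N_e = 4N_mN_f/(N_m+N_f)$
(`effective_population_size()`); tract-length distributions are
reported on a log2 scale, with `log2_to_kb()` converting back to
decimal kilobases (18 → 262 Kb).

## The synthetic-data generator

`scenario_params()`/`generate_dataset()` emulate the study conditions
the analysis assumes:

| parameter | default | rationale |
|---|---|---|
| `n_sites` | 20,000 | ~10,000 constrained (deleterious) sites after the 0.5 constrained fraction; enough for stable medians at desk scale |
| `ancestral_Ne` | 10,000 | a large pre-modern population, so deleterious frequencies are nearly steady across the sampled millennia — the regime the temporal analysis is designed to detect departures from |
| `bottleneck_Ne`, `bottleneck_time_years` | 80 at 250 BP | the effective size implied by a breeding stock of 20 stallions and 5000 mares, starting at the onset of modern breed management; 31 generations at this size reproduce a heterozygosity drop near the reported ~16% |
| `generation_time_years` | 8 | standard for horses |
| `sample_schedule` | age points every ~250 y over 50–3700 BP, equal shares of 150 ancient genomes, depth ramp 1–39× within each age group | a deterministic design: panel composition is part of the study conditions, not noise to be redrawn per run |
| `n_modern`, `modern_depth` | 150 at 10× | comparable ancient/modern panel sizes |
| `error_rate` | 0.005 | typical post-filtering base error |
| `damage_rate`, `user_treated` | 0.02, TRUE | C→T/G→A template damage for ancient samples; USER treatment modeled as a tenfold reduction |
| selection | $s = -0.001\,\mathrm{phyloP}$, recessive ($h=0$) | slightly deleterious, recessive variation — the class argued to carry the load |
| `modern_F_ranges` | working 0.15–0.35, hotblood 0–0.10, warmblood 0–0.15 | the recent inbreeding burst, strongest in working/draft management |
| `init_beta`, `prop_start_fixed` | Beta(0.25, 8), 0.10 | rare standing variation plus a minority of anciently fixed deleterious alleles |
| `purging_strength` | 0 (off) | paired runs switch it on to probe the load–F correlation |

phyloP scores are simulated (neutral Gaussian bulk below 1.5; an
exponential tail above it whose mean varies by region class, highest
for protein-coding sites); they are inputs to the pipeline, never
computed from alignments. Genotypes are drawn through the same
two-state IBD chain the HMM assumes, autozygous inside tracts and
Hardy–Weinberg outside; purging, when enabled, replaces a deleterious
autozygous draw with the non-carrier allele with the given probability.
Outgroup divergence at a site is the neutral rate shrunk by
$e^{-|s| \cdot 500}$, a stylized fixation-probability reduction that
makes $dN < dS$ under selection and $dN \approx dS$ without it; it is a
device for direction checks, not a calibrated substitution model.

**What the generator does not emulate.** A single panmictic population
(no breed structure, no admixture, no migration); sites drift
independently (no linkage between variant sites, hence LD exists only
through the IBD chain); no recombination map, no coalescent history, no
pedigrees, no indels; ages are exact (no radiocarbon error); damage is
applied only to the recorded biallelic counts. Passing the end-to-end
checks therefore shows the *estimators* recover the generative signals
they model — it does not certify behavior under breed structure,
reference bias, or correlated sites, which real data add on top.

## Numerical choices and degenerate inputs

* Boundary conventions: constraint is inclusive (`>= 1.5`); the call
  threshold is strict (`> 0.99`); age windows are half-open.
* `ml_frequency()` returns exact 0/1 at the boundary configurations and
  missing when total depth is zero; zero-depth individuals are dropped
  before pooling.
* Ties: NJ joins and LD representatives break ties deterministically
  (lowest index / leftmost position), so outputs are reproducible.
* EM: parameters live in transformed space (logit F, log rate);
  emissions are floored at 1e-300 before logs; the iteration cap
  (default 100) returns the best estimate with `converged = FALSE`.
* Loads with an empty denominator are missing, not zero; Wilcoxon on
  fully tied data returns p = 1.
* All randomness flows from explicit seeds; dataset generation is
  byte-reproducible given the scenario.

## Validation problem sizes

The test suite validates the ML estimator on 1000 random count
configurations and 1000-replicate bias/RMSE panels at 50 individuals ×
depth 10; genotype calling on 50 × 10,000 genotypes at 10× and
e = 0.005; the load statistic against a brute-force oracle on 100
random fixtures; NJ on all additive matrices up to six taxa; the IBD
HMM on 100,000-site genomes at F ∈ {0, 0.1, 0.3}; and the full
generator–pipeline loop on the default scenario (20,000 sites, 150 + 150
genomes), with and without purging. These sizes were chosen so the
whole suite runs comfortably on a single CPU while leaving each check
statistically sharp.

## Known limitations

The simplified IBD HMM is not a drop-in replacement for
likelihood-based tools on low-coverage data (it consumes called
genotypes); the graph-based LD clustering is a deterministic stand-in
for Markov clustering; NJ is used without topology refinement; and the
dN−dS generator mechanism is directional rather than calibrated.
Absolute load values depend on the phyloP distribution and genotyping
depth of a given dataset, so only relative comparisons across genomes
processed identically are meaningful.
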