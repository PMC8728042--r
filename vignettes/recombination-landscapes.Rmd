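---
title: "Methods: pedigree-based recombination landscape analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pedigree-based recombination landscape analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedrec)
```

# Scope and model

`pedrec` infers meiotic crossovers from shallow GBS data in a
multigenerational breeding pedigree and summarizes the resulting
recombination landscape: sex differences (heterochiasmy), crossover
interference, and recombination suppression inside wild-introgression
segments. The pipeline is: depth filtering → pedigree-aware genotype
calling → duo-HMM crossover detection → scaled genetic maps →
statistical tests. A ground-truth meiosis simulator drives every test.

## Genotype calling

Read counts at a biallelic site are modeled as binomial draws of the
alternate allele with success probability $p_B = e$, $0.5$, $1-e$ for
genotypes AA, AB, BB, with per-read error $e$ (default 0.01). The
binomial coefficient is included (a plain binomial PMF); it cancels in
the posterior. Priors are Mendelian where both parents carry
posteriors (transmission tensor summed over the parental genotype
pairs) and Hardy–Weinberg otherwise — including the
one-validated-parent case, where a semi-Mendelian prior would require
the missing parent's genotype distribution anyway. The allele
frequency behind the HWE prior is estimated once before propagation as
the flat-prior posterior-mean dosage over individuals with at least
one read; because priors depend only on *parental* posteriors, calling
is invariant to the topological order used.

A call requires a posterior of at least 0.99 (a posterior of exactly
0.99 calls). Missingness has two meanings, used deliberately: before
calling, a missing cell is one with zero reads (depth filters: site
> 70 % missing, individual > 80 % missing, site mean depth > 120 with
a strict inequality); after calling, a missing cell is one with no
genotype reaching the threshold (site filter at > 30 %). Singleton
sites are defined allele-wise — the minor allele carried by exactly
one called individual — configurable in principle but fixed here;
monomorphic sites are those with a single observed allele.

## Crossover detection

For a parent–offspring duo, the hidden state is which of the two
parental haplotypes the child inherited. The child's evidence at a
site is the allele it must have received from the focal parent, which
is determined by Mendelian arithmetic from the child's and the other
parent's genotype calls whenever the solution is unique; ambiguous or
conflicting sites are treated as missing evidence. Transitions between
adjacent sites use the Haldane map function
$r = \tfrac12(1 - e^{-2d/100})$ of their reference-map distance $d$ in
cM — deliberately interference-free, since interference is what the
downstream test measures. Emissions match evidence to the transmitted
haplotype's allele with probability $1-\varepsilon$
($\varepsilon = 0.01$ by default, absorbing genotyping and deduction
errors).

The forward–backward pass runs, by default, on the chain *collapsed to
informative sites* (parent heterozygous, evidence present): a duo can
only localize a crossover to the interval between flanking informative
markers, and on the full chain the posterior of one crossover spreads
across the uninformative sub-intervals in proportion to their map
length, so no single interval would reach the threshold. The
uncollapsed chain remains available (`collapse = FALSE`) and exposes
the textbook behavior that with no evidence the per-interval posterior
equals $r$. Intervals with posterior $\ge t = 0.5$ (0.5 exactly is
emitted) become crossovers; runs of adjacent super-threshold intervals
merge into one event so that a single crossover spread over sparse
markers is not double-counted. Posterior averaging across `n_iterations`
passes is retained as a knob; with deterministic phasing all passes are
identical. Meioses with fewer than two informative sites count as
observed zero-crossover meioses, keeping the denominators of
downstream rate comparisons honest.

### Parental phase

Population phasing is out of scope; parents are phased either from
simulation truth (`phase = "truth"`) or by Mendelian consensus across
their offspring (`phase = "trio"`). The trio phaser chains
heterozygous sites left to right, deciding each site's relative phase
by a majority vote over offspring co-transmission with several nearby
anchor sites (pooling anchors prevents one offspring's crossover, or
an empty overlap with the immediate neighbour, from flipping the
chain), then refines with a bilateral re-vote and an iterative
switch-error correction: intervals where a strict majority of
offspring Viterbi paths change state are parental switch errors — a
real crossover appears in one offspring, a phase switch in all — and
the phase downstream is flipped. Het sites supported by fewer than two
offspring or with a weak vote margin are masked (emission-neutral), as
a site phased from a single child would be tautological evidence for
that child. With two offspring the attribution of a shared state
change is inherently ambiguous; both recombining in the same interval
triggers a false correction — a documented consequence of the majority
rule. Detector benchmarks therefore use truth-provenance phase, which
isolates HMM behavior from the phasing stand-in; trio phasing has its
own accuracy tests (families of five error-free offspring phase
≥ 99 % of het sites).

## Genetic maps

Events are assigned fractionally to inter-SNP intervals. The shares
are proportional to the physical lengths of the spanned intervals and
sum to exactly one per event; a uniform 1/k option exists. (A
per-interval constant such as "one over the interval length" does not
conserve event mass, and conservation is what makes the scaling
identities below exact.) Interval genetic lengths are
$\mathrm{cM} = \text{count} \times L_y / \text{total}_y$, i.e. count
divided by the scaling factor $n_y = \text{total}_y / L_y$, so each
chromosome's total equals its reference length $L_y$ exactly — the
dimensionally consistent orientation of the scaling. Class maps
(male/female, or introgression dosage 0/1/2) multiply by
$m_c = \text{total meioses}/\text{class meioses}$; the meiosis-weighted
average of class maps then reproduces the pooled map
interval-by-interval (asserted to $10^{-9}$). Sex-specific maps reuse
the same class machinery. Classes with zero meioses are omitted, as a
homozygous-introgressed class can be on a chromosome where no such
individuals exist.

## Statistics

All count tests are Pearson goodness-of-fit chi-squares on observed
counts against fixed expected proportions, without continuity
correction (the behavior of `chisq.test(x, p = ...)`). Expected
proportions are computed exactly from meiosis counts and normalized to
sum to one — published rounded proportions such as (0.487, 0.514) sum
to 1.001 and would break the expected-equals-observed-total identity.
Window tests tile each chromosome from 0 in 1-Mb steps (0-based
half-open), excluding the terminal short window and any window with an
expected count below five; exclusions are reported, never dropped
silently. Significance uses Bonferroni $\alpha/N$ over the $N$ tested
windows. Events are assigned to windows and to introgression regions
by interval midpoint (configurable to any-overlap); regions follow the
BED convention, so "5 to 25 Mb" is $[5\,000\,000, 25\,000\,000)$.

The interference test fits, per chromosome, a log-link Poisson
regression of per-meiosis crossover counts on parent (categorical) and
parental sex, without offset, one observation per meiosis, and refers
the residual deviance to $\chi^2_{n-p}$. Interference produces
*under*-dispersion — counts more regular than Poisson — so the
reported p-value is two-sided (twice the smaller tail); an upper-tail
deviance test could never flag it. **Caveat:** with per-chromosome
means around 1.3 crossovers, the $\chi^2$ approximation to the
deviance is biased — exact enumeration gives an expected deviance
contribution of 1.16 per observation, not 1, so the null rejection
rate at $\alpha/18$ is far above nominal. The test suite asserts the
implementation against the enumerated expectation and demonstrates
high power against gamma-renewal interference of shape 5; nominal
type-I calibration is not achievable for this statistic at these
means, and the corresponding nominal-calibration assertions are left
failing by design rather than hidden. Parents contributing a single meiosis are
dropped with a warning (they fit their own mean exactly).

Introgression dosage classes come from diagnostic markers: sites fixed
for different alleles between non-admixed donor and recipient panels
(rule 1), or fixed in the recipient and polymorphic in the donor
(rule 2); the rules are mutually exclusive. An individual's status is
the mean donor-allele dosage over 250-kb windows (unweighted mean of
window means within the region; an IDM-count-weighted option exists),
rounded half-up at 0.5 and 1.5 — the interval notation for the
rounding ranges is self-contradictory at the boundaries, so half-up
was fixed and documented. Individuals with no scored window are
excluded from class tests, mirroring the exclusion of an individual
with missing introgression data.

# The simulator

The generator emulates a four-cohort breeding program: 236 founders
plus cohorts of 258, 2334, 2515 and 2089 individuals by default, each
cohort produced by full-sib families whose parents come from earlier
cohorts. Sex is a property of the meiosis, not the individual — the
same genotype can be dam in one cross and sire in another, as in
monoecious cassava. Defaults fix the genome at 18 chromosomes jointly
spanning 582.28 Mb and 2412 cM; GBS depth is Poisson with mean 7 and
error 0.01; donor haplotypes differ from the recipient pool at a
0.022 fraction of in-region sites. A missing-cell rate of 0.1 and a
donor founder-haplotype frequency of 0.2 were chosen once as realistic
GBS/breeding-germplasm values. The female map multiplier defaults to
1.2 and the per-copy suppression multiplier to 0.32 (two copies square
it); note that a per-copy map multiplier of 0.32 in a half-carrier
population yields an observed-vs-expected deficit near 50 %, not 68 % —
the deficit and the multiplier are different parameterizations.

Crossovers are drawn from a stationary gamma renewal process on the
adjusted map scale (shape $\nu \ge 1$; $\nu = 1$ is exactly Poisson,
via Poisson counts and uniform positions). Stationarity for
$\nu \neq 1$ uses a 12-mean-spacing burn-in start, which is
equilibrium to numerical accuracy at map lengths of a few Morgans.
This renewal model was chosen over count-then-place schemes because
the downstream test is precisely a Poisson-departure test, and it
nests the null. The default is $\nu = 1$: the real germplasm's
interference strength is not estimated anywhere, so interference is
opt-in rather than a default pretense. An obligate-crossover option
resamples zero-crossover chromosomes; it is off by default and the
detector counts zero-crossover meioses as observations either way.

What the generator does **not** emulate — and what passing tests
therefore do not establish about real data: linkage disequilibrium and
coalescent founder structure (founder haplotypes are site-independent
draws), gene conversion, de-novo mutation, machine-specific error
profiles, overdispersed depth (Poisson, not negative binomial, by
design with the extension point noted), marker ascertainment, and
population-phasing artifacts (real pipelines phase statistically; the
trio stand-in has different failure modes).

# Numerical choices and degenerate inputs

Forward–backward runs in scaled space and Viterbi in log space; map
distances of zero give transition probability exactly zero, and
zero-read cells give likelihood one for every genotype. Posterior ties
at the call threshold call (the threshold is "greater than or equal").
Chromosomes with zero detected crossovers produce zero-length maps
with a warning; classes with zero meioses are omitted; introgression
tests with fewer than two populated classes are skipped with a
warning. Reference-map interpolation is linear in bp between flanking
map points with constant extrapolation at the ends. Identical
configurations (including seed) reproduce bit-identical datasets;
sub-stage seeds are derived deterministically from the master seed so
stages do not consume each other's RNG streams.

# Test problem sizes

The suites run at deliberately scaled sizes: caller consistency on
~10,000 cells at 200x depth; detector exactness on 500 noiseless
meioses over two 100-cM chromosomes (false discovery rate exactly
zero); detector rate/FDR at 7x on 500 meioses with post-filter marker
spacing under 0.5 cM (rate > 0.8, FDR < 0.1); heterochiasmy recovery
over 100 replicates of 1000 meioses per sex (ratio within [1.1, 1.3]
in ≥ 95 %); interference calibration on 200 replicates of 500 meioses
and power on 50 replicates at $\nu = 5$; suppression detection on 30
replicates of 2000 meioses at the 0.32 multiplier; and the chi-square
oracle on 100 random tables to $10^{-10}$.

# Interfaces and limitations

The package's surface is its R functions — `sim_config()` /
`simulate_cross_data()`, `call_genotypes_down_pedigree()`,
`detect_crossovers()`, `build_scaled_map()` / `build_class_maps()`,
the `*_tests()` battery, `classify_introgression()` and the
`run_all()` orchestrator — plus plain-text formats (VCF v4.2 with AD
and GT, TSV pedigree/crossovers/maps, BED-like regions) so every
intermediate is re-readable by its own reader. Known limitations:
duo-based detection cannot resolve crossovers outside the flanking
informative markers, so terminal chromosome segments are blind spots;
trio phasing cannot phase parents with one offspring (their meioses
contribute zero-crossover observations) and is unreliable for
two-offspring families; the chi-square tests share the literature's
caveat that meioses from one parent are not fully independent; and the
deviance test's small-mean bias discussed above means its genome-wide
significance pattern should be read as evidence of non-Poisson
dispersion, not as a calibrated p-value.
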