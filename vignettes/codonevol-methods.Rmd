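---
title: "Models and methods behind codonevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind codonevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonevol)
```

codonevol quantifies three forces acting on coding sequences — the
S→W (G/C → A/T) mutation bias, GC-biased gene conversion (gBGC), and
selection on codon usage — and the imprint they leave on substitution
rates. This vignette is the package's own account of the models, the
parameters that matter, the design decisions taken where the design
was genuinely open, and what the simulation-based validation does and
does not show.

## Strong/weak classes and site degeneracy

G and C pair with three hydrogen bonds (strong, S); A and T with two
(weak, W). Every single-base change is S→W, W→S, or GC-conservative
(S→S or W→W). Site degeneracy (0-, 2-, 3-, 4-fold) is computed under
the standard nuclear genetic code by substituting all three
alternative bases and translating; the code table is injectable for
future use but only the standard code is shipped. The 3-fold class
(isoleucine third positions) is kept as its own class and excluded
from the 0-fold/4-fold population-genetic contrasts. Codons containing
gaps or ambiguity codes are masked from GC and degeneracy computation
rather than raising errors, matching alignment-wide trimming
semantics; how ambiguous bases were treated is a choice of this
package, since masking conventions differ between tools.

## Alignment hygiene

`qc_alignments()` applies, in order: a frame-integrity check
(interspersed stop codons, or gap runs that are not codon multiples,
discard the alignment), removal of codon columns with *strictly more
than* 50% gaps across lineages, and rejection of alignments with more
than 50% missing codons in any lineage, a mean per-sequence gap
fraction above 25%, or fewer than 300 bp after trimming. Rates from
saturated genes (dS > 30) or genes without synonymous substitutions
(omega ≥ 999) are excluded downstream. Two unit choices were open and
are fixed as: the column rule counts *codons* (gap codons per column);
the 25% rule counts *nucleotides* (gap characters per sequence); the
300-bp rule is applied to the trimmed alignment, since the length
filter targets the analyzable alignment. Filtering is idempotent, and
on generator-planted batches the rejected set equals the planted set
exactly.

## Codon usage: RSCU and the effective number of codons

RSCU divides a codon's count by its family's equal-usage expectation
(`k · n_codon / n_family`); per-lineage per-1,000 frequencies are
computed from pooled counts, not means of per-gene frequencies.
`ENC_obs` uses Wright's homozygosity formulation: per family,
`F = (n Σp² − 1)/(n − 1)`, combined as
`ENC = 2 + 9/F̄₂ + 1/F̄₃ + 5/F̄₄ + 3/F̄₆` and clamped to [20, 61]. A
degeneracy class with no estimable family (all n < 2) has its mean
imputed from the estimated classes — Wright's convention, which keeps
short genes defined — and a gene with no estimable family at all is
undefined and excluded.

`ENC_exp` is a function of GC3 alone,
`a + GC3 + b/(GC3² + (c − GC3)²)`. The published rendering of this
curve is typographically ambiguous, and with the simulation-optimized
constants (a = 6, b = 34, c = 1.025) the unclamped value exceeds 61
across mid-range GC3. We therefore expose the functional form and
constants through `enc_config()` (Wright's classic curve is
`enc_config(2, 29, 1)`) and clamp to [20, 61] rather than guess an
unstated variant. Consequence: under composition-only codon usage,
`ENC_diff` is near 0 at mid GC3 (where both observed and expected sit
near 61) but becomes mildly positive (~0.07) at AT-rich compositions
where the clamped expectation cannot follow the observed decline; the
test suite asserts the null only in the 0.45–0.55 GC3 band for this
reason.

## Substitution counting on a fixed tree

The paper-scale analyses this package emulates used probabilistic
substitution mapping under a nonstationary codon model. codonevol
deliberately replaces that machinery with a transparent counting
method: Fitch parsimony on codon states over a fixed rooted topology,
pathway-averaged classification of parent→child codon changes
(orderings through stop codons excluded, remaining orderings equally
weighted — the Nei–Gojobori convention), and fractional site
opportunities in which each of a codon's nine single-base mutations
contributes 1/3 site to its (syn/nonsyn × S→W/W→S/conservative) cell,
with mutations to stops excluded from both counts and opportunities.
Rates are `d_c = N_c/L_c`; these are *counting-scale* estimates, a
third scale next to codeml- and mapping-based omegas, so only
relative and ordinal patterns are comparable across methods.

Three properties of this estimator matter in practice and are
documented in the output metadata:

- **Root-adjacent orientation.** Parsimony cannot orient a
  substitution that maps to the two edges incident to the root (the
  root state is reconstructed from an even split and resolved at
  random). Directional S→W/W→S contrasts must therefore be pooled with
  `drop_root_edges = TRUE`; leaving those edges in shrinks a true 3:1
  rate ratio toward 2 on a quartet-plus-outgroup tree.
- **Ambiguous columns.** Columns with several most-parsimonious
  reconstructions are resolved uniformly at random under a recorded
  seed (`mode = "random"`) or masked (`mode = "strict"`). Random
  resolution is unbiased for rate magnitudes; for *directional*
  contrasts the misoriented share dilutes the signal, so strict
  masking is the recommended setting there. Both modes were verified
  unbiased for their recommended use at the 480,000-codon scale.
- **Divergence domain.** Multiple hits are partially collapsed by
  parsimony, and the orientation-error share grows roughly
  quadratically with branch length. The counting estimator is accurate
  for per-branch divergence up to ~0.02 substitutions/site (within-
  genus scale); at 0.05+/site per branch, high-rate categories are
  differentially undercounted. Validation simulations therefore use a
  five-taxon tree (ingroup quartet plus outgroup) with 0.01/site
  branches.

The simulation validation uses rate-preserving multipliers
(S→W : W→S : conservative = 1.5 : 0.5 : 1 for a 3:1 bias), 200
replicates of 500-codon genes for the symmetry check (paired two-sided
t-test on per-replicate `d_SW − d_WS`; the invariant is a statement
about expectations, so a mean test is the appropriate instrument), and
100 replicates of 2,500-codon blocks for the planted-bias check. The
block size keeps the per-replicate W→S count above ~10; the median of
a ratio of small Poisson counts is not calibrated below ~5 counts, and
a lineage in a real data set pools thousands of genes.

## The gBGC–mutation–drift equilibrium model

For a class of sites with scaled mutation intensity θ and fixation
bias B acting on the derived allele, the expected unfolded spectrum at
sample size n is

$$E_i(\theta, B) = \theta \binom{n}{i} \int_0^1
  x^i (1-x)^{n-i} \frac{1 - e^{-B(1-x)}}{(1 - e^{-B})\, x(1-x)}\, dx,$$

the classical semidominant fixed-bias equilibrium density; the B → 0
limit is the neutral `θ/i` law and is taken analytically below
|B| < 1e−8. W→S mutations experience +B, S→W mutations −B, and
GC-conservative mutations B = 0. The source analyses do not print
their likelihood, so the exact objective is this package's own
construction: independent Poisson bins with means
`r_i · θ_class · φ_i(±B)`, where the `r_i` are per-frequency-class
distortion terms shared across the three classes (anchored at
`r₁ = 1`), absorbing demography and ascertainment; the GC-conservative
class, which carries no B, ties them down. Optional polarization error
mixes `(1−e) E_i + e E_{n−i}` in every class. The mutation-bias ratio
is `λ = (θ_SW/L_S)/(θ_WS/L_W)`, with L_S and L_W the strong/weak site
totals of the class taken from the reference composition (the
alternative, genome-wide normalization is a caller choice: supply
different L's). A single pooled λ is reported per degeneracy class;
GC-stratified sub-models are out of scope.

Numerics: `φ_i(B)` is evaluated by fixed 64-node Gauss–Legendre
quadrature on [0, 1] — the integrand is a degree-(n−2) polynomial
times an entire function, so the rule is exact to machine precision
for n ≤ 50 and was cross-checked against adaptive quadrature and a
200,000-cell midpoint Riemann sum (≤ 1e−6 relative). For fixed (B, e)
the likelihood is concave in (log θ, log r); the inner problem is
solved by closed-form coordinate ascent, profiled inside a bounded
one-dimensional search over B (golden-section/parabolic, default
bounds ±5; boundary estimates are flagged). Bootstrap confidence
intervals resample *sites* with replacement, implemented as one
multinomial draw over the full per-site category table (all
segregating bins plus monomorphic W and S cells), and are bit-
reproducible under a recorded seed.

Polarization uses two outgroups by parsimony: both outgroups must
agree and match an ingroup allele (one suffices in relaxed mode);
discordant or non-matching outgroups leave the site unpolarized, and
unpolarized counts are reported. Sites with missing genotypes can be
projected to a common n by expectation-based hypergeometric
down-sampling (`project_sfs()`), under which the neutral spectrum is
exactly invariant.

## Synthetic data: what it emulates, and what it does not

The generators define the study conditions; their defaults were fixed
once, before the validation suite was finalized, from an a priori
power analysis (the estimator's sampling SD against the recovery
tolerances asserted in the tests):

- **Polymorphism** (`simulate_polymorphism()`): n = 20 chromosomes
  (10 diploid males), 1e6 sites per degeneracy class — the order of
  the 4-fold site count in a lepidopteran CDS complement — per-site
  θ₀ = 0.01 (a typical insect synonymous-site diversity), strong-base
  fraction 0.469 at 4-fold sites (the observed GC3) and 0.451 at
  0-fold sites (the GC1/GC2 mean), conservative-class intensity 0.5×
  baseline, polarization error e = 0. At these sizes the sampling SD
  of the fitted B is ≈ 0.035 and of λ ≈ 0.04. Counts are drawn as
  Poisson bins from the model's own expected spectrum: the generator
  tests estimator self-consistency first; there is no coalescent, no
  linkage, no demography, and no ascertainment, so passing recovery
  tests demonstrates correctness of the inference machinery, not
  robustness to demographic misspecification (the `r_i` terms exist to
  absorb such distortion in real data, and the polarization-error
  mixing is available, but neither is exercised against a process
  model here).
- **Alignments** (`simulate_alignment()`): root codons drawn to a GC3
  target with uniform first/second positions, evolved site-
  independently with per-category hazards and stop avoidance. No codon
  autocorrelation, no indels, no selection among amino acids — adequate
  for validating a counting estimator, silent about alignment error.
- **tRNA tables** (`simulate_trnascan_fixture()`): syntactically valid
  tRNAscan-SE 2.x rows with planted copy numbers, pseudogene/truncated
  decoys and minus-strand coordinate inversion.

Test problem sizes (500–2,500-codon genes, 1e5–1e6 sites, 50–200
replicates, 200 bootstrap resamples) were chosen as the smallest sizes
at which the asserted tolerances are comfortably powered.

## tRNA repertoire

tRNAscan-SE 2.x tables are parsed with strand normalization
(minus-strand rows arrive with inverted coordinates); rows flagged
`pseudo` or truncated are removed before counting. RAIT is defined
exactly like RSCU with family size k = the number of synonymous
*codons* of the amino acid — not the number of represented anticodons —
because the repertoire statistic is meant to be comparable to RSCU.
Wobble pairing is *not* modeled: each anticodon maps only to its
reverse-complement codon, and repertoire GC3 is copy-weighted by
default (a per-unique-anticodon toggle exists, since either convention
is defensible). Copy-number outliers are flagged above the
`Q3 + 3·IQR` fence and all summaries accept an exclusion list, because
exceptionally high-copy anticodons can reflect repeat proliferation
rather than functional gene dosage.

## Known limitations

- Counting-scale rates are not comparable in absolute value to
  model-based omegas; only orderings and ratios are.
- Directional rate contrasts discard root-adjacent edges and (in
  strict mode) MP-ambiguous columns; on short alignments this can
  remove a noticeable fraction of the signal.
- The ENC_exp curve with the default constants saturates at the clamp
  across mid GC3; ENC_diff should be read as a relative, not absolute,
  bias score.
- The gBGC model assumes equilibrium, free recombination between
  sites, and a single B per class; linked selection and finite-sites
  effects are unmodeled.
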