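---
title: "CNV-weighted linkage analysis in small pedigrees: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CNV-weighted linkage analysis in small pedigrees: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvlink)
```

# The problem

Family studies of bipolar-spectrum disorders face two forms of
heterogeneity at once: clinical (the boundary between bipolar I, the
schizoaffective bipolar type, bipolar II and recurrent unipolar depression
is uncertain) and genetic (different loci segregate in different
families). `cnvlink` implements a strategy for such data that (i) runs
classical multipoint linkage under several nested phenotype definitions
and parametric models, and (ii) restricts and re-weights the linkage
evidence to genomic regions where copy-number variants (CNVs) are shared
by relatives — the hypothesis being that an inherited CNV segregating
with disease marks a risk haplotype that linkage alone is underpowered to
single out.

# The linkage model

## Inheritance vectors

For one family with $n$ non-founders, inheritance at a locus is the
binary vector $v \in \{0,1\}^{2n}$: one bit per non-founder meiosis,
indicating whether the parent transmitted the allele on their own
paternal or maternal haplotype. Under no linkage all $2^{2n}$ vectors are
equally likely. Along a chromosome $v$ evolves as a Markov chain in which
each bit flips independently between adjacent markers with the
recombination fraction $\theta$ from Haldane's map function
$\theta = (1-e^{-2d/100})/2$ (no interference — the choice implied by the
HMM's independent-flip transition kernel; the map function is not itself
a data-driven quantity here).

Marker evidence enters through the singlepoint likelihood
$P(\text{genotypes at } m \mid v)$, computed by summing founder-allele
assignments: given $v$, every individual's two alleles map to two of the
$2F$ founder-allele slots; homozygous genotypes pin slots to an allele,
heterozygous genotypes add a "must differ" constraint between two slots,
and the likelihood is a product over constraint components of the two
admissible colourings weighted by allele frequencies. This is exact and,
because it runs per vector, costs $O(2^{2n})$ per marker — the package
caps families at 16 meiosis bits and raises a capacity error beyond that,
trading scale for exactness and testability (the cohorts this targets
average eight members per family). Forward–backward over the marker chain
gives the posterior of $v$ at every marker; the package evaluates scores
at marker positions only, matching the marker-indexed worked example the
scoring convention is anchored to. A max-product pass with
per-bit factorised transitions gives the most likely inheritance path
(ties broken toward the smallest vector index — a deterministic,
documented policy), from which phased haplotypes and recombination
breakpoints are read off.

Mendelian-inconsistent markers (zero likelihood for every vector) are
flagged per family and treated as uninformative rather than aborting the
scan. Fully untyped families contribute a uniform posterior.

## Non-parametric scores

The NPL(all) statistic $S_{all}(v)$ picks one allele from each affected
relative in all $2^a$ ways and averages the products of factorials of
founder-allele multiplicities; it rewards any clustering of alleles
identical by descent among affecteds, not just pairwise sharing. Per
family, $Z_i(x) = (E[S_{all}\mid \text{markers}] - \mu_i)/\sigma_i$ with
$\mu_i, \sigma_i$ the exact null moments over the uniform vector
distribution (computable because all $2^{2n}$ values are enumerated).
Families with fewer than two affected members, or a degenerate $S_{all}$
distribution, are excluded from the combination with a notice. The
combined score uses equal weights, $Z = \sum_i Z_i/\sqrt{k}$.

The Kong–Cox linear model turns per-family scores into a LOD:
$\ell(\delta) = \sum_i \log_{10}(1 + \delta Z_i)$ maximised over
$\delta \in [0, \delta_{max}]$, where
$\delta_{max} = 0.999\,(-1/\min_i Z_i)$ when some $Z_i<0$ (keeping every
argument positive, with a 0.1% numerical margin) and 10 otherwise — the
bound convention is a package decision, documented rather than inferred,
since no printed toy example pins it. The one-sided p-value is the
half-chi-squared mixture $p = \tfrac12 P(\chi^2_1 > 2\ln 10\,\mathrm{LOD})$,
with $p = 0.5$ at LOD 0.

## Parametric scores

The dominant (risk allele frequency 0.0045, penetrances 0.001/0.50/0.75)
and recessive (0.065, penetrances 0.0015/0.0015/0.50) single-locus models
give per-family
$\mathrm{LOD}_i(x) = \log_{10} \frac{E_{v\sim\text{posterior}}[P(\text{phen}\mid v)]}{E_{v\sim\text{uniform}}[P(\text{phen}\mid v)]}$,
where $P(\text{phen}\mid v)$ sums founder disease-allele configurations at
frequency $q$ and applies the penetrances to each individual's implied
genotype. Phenotypes coded unknown contribute a factor 1 (the standard
treatment; affected-only variants are not implemented). Heterogeneity is
handled by
$\mathrm{HLOD} = \max_{\alpha\in[0,1]} \sum_i \log_{10}(\alpha 10^{\mathrm{LOD}_i} + 1 - \alpha)$
via bounded scalar search (tolerance $10^{-6}$), with the endpoints
checked explicitly.

## Phenotype definitions

Three nested affection-status models handle the diagnostic uncertainty:
ASM1 = {BP-I, SABP}; ASM2 adds BP-II; ASM3 adds RUDD. A
bipolar-spectrum diagnosis outside the active set is coded *unknown* (not
unaffected), never-ill relatives are unaffected, and other mental
disorders are unknown — the latter is a package policy where the source
conventions are silent. `apply_asm()` is purely a labelling layer, so the
nesting of affected sets holds for any pedigree.

# The CNV-weighted score

CNV calls (PennCNV-style intervals with copy-number states; 0/1 collapse
to deletion, 3/4 to duplication, state 2 is rejected as "not a variant")
are first filtered to ≥ 10 kb. "Shared" means a non-empty genomic
intersection among the calls of at least two relatives in one family —
*not* identical breakpoints; array-based calls of one event differ at the
edges, and requiring identity would make cross-family segmentation
meaningless. Deletions and duplications may share by default (both states
are observed on one risk haplotype in practice); a `match_state` switch
restores strict state matching. The two-carrier threshold reflects the
small pedigrees the method targets and is configurable upward.
Single-carrier (possibly de novo) calls never contribute.

Maximal mutually-overlapping carrier sets are found by sweeping candidate
points (in one dimension, every maximal clique of intervals is the set of
intervals covering some call's start — the Helly property). Overlapping
non-nested triples therefore produce several shared regions per family;
all are kept, and the cross-family segmentation resolves them: all
shared-region boundaries on a chromosome cut it into minimal disjoint
segments, each annotated with the families whose region covers it, and
adjacent segments with identical family sets merged. Coordinates are
1-based closed on every user surface, half-open inside the sweep.

Before scoring, each carrier's genotypes at markers inside their own CNV
are set to missing (non-carrier relatives keep theirs) — deleted or
duplicated regions genotype unreliably, and this is how the per-family
curves feeding the score are computed. A `global_remove` mode drops such
markers for everyone, which is the appropriate hygiene for the plain
genome-wide scan.

The segment score is a sum over covering families of that family's
*average* per-marker linkage score (parametric $\mathrm{LOD}_i$ or
non-parametric $Z_i$) across the markers inside the **family's own shared
region** — averaging over the family region and then assigning the
average to every segment it covers reproduces the canonical worked
example (family averages 0.9 and 0.23 summing to 1.13) and the observed
behaviour of one region splitting into two adjacent scored segments.
Scores enter signed; negative contributions are not floored. Two
edge policies: a region containing no marker falls back to the mean of
the two flanking markers' scores (reported whenever used; multipoint
curves are defined between markers, and a hard error would make sparse
maps brittle), and if several regions of one family cover the same
segment the family contributes the mean of their averages (one
contribution per family preserves the additivity of the sum). Rounding
to two decimals happens only at presentation.

# Empirical significance

Under the null, genotypes are re-simulated by gene dropping: founder
alleles drawn per marker from the founder allele frequencies, haplotypes
transmitted with Haldane recombination, the observed missingness pattern
re-applied, and phenotypes, pedigree structure and CNV positions held
fixed (the null randomises genotypes only — CNV calls act as fixed
covariates). Each replicate records the genome-wide maximum of the chosen
statistic; each replicate draws its RNG stream from a seed derived from
the master seed and the replicate index, so runs are reproducible and
order-independent.

Thresholds are order statistics of the replicate maxima: for a target
family-wise error rate $f$ the package takes the smallest order statistic
whose exceedance fraction is at most $f$, i.e. $x_{(n+1-\lfloor nf
\rfloor)}$ — with 1000 replicates and $f = 0.05$ the 951st. Suggestive
linkage uses $f = 1 - e^{-1} = 0.632$, the probability that a Poisson
variable with mean one is positive, i.e. one expected false peak per
genome scan; significance uses $f = 0.05$. Correction is applied within
each model × phenotype definition, not across them (the models are
nested and strongly correlated; a Bonferroni across them would be
conservative). The default empirical p-value is the permutation-valid
$(1+r)/(n+1)$; a plugin $r/n$ estimator is available for literal
compatibility with printed values such as $33/1000 = 0.033$.

# The synthetic cohort generator

`sim_config()` defaults encode the cohort structure the package targets:
46 families totalling 366 individuals (147 founders, 219 non-founders,
mean size 7.96, built deterministically from couples with two children,
one or two married-in spouses and their own children), 22 autosomes with
~942 markers at 0.169 cM spacing, founder allele frequencies uniform on
(0.2, 0.8) (a typical informative-SNP panel; the source data do not print
a frequency distribution), ~61 CNV events per family with lognormal
lengths truncated at 10,046 bp (matching the printed minimum and ~110 kb
mean length), an even deletion/duplication split, the printed diagnosis
mixture among affecteds, and 97/366 of individuals without DNA. Units
and defaults are chosen once, before any testing against outcomes, and
scaled-down configurations used in tests state their sizes explicitly.

Mechanically: founder haplotypes are drawn marker-independently (no
linkage disequilibrium — a deliberate non-goal), meioses simulated with
Haldane recombination, and a latent disease locus inserted into the
transmission chain but never written to the marker output, so linkage
must be recovered through flanking markers, as with real data. In a
*linked* family one founder haplotype is designated the risk carrier and,
under `cnv_placement = "on_risk_haplotype"`, a CNV is planted on it
overlapping the locus and transmitted with it (co-segregation is exact by
construction); *unlinked* families segregate an independent,
off-map risk locus, so the fraction of linked families maps directly onto
the heterogeneity parameter $\alpha$. Diagnosis subtype labels are drawn
independently of genotype given affected status — the ASM hierarchy is a
labelling layer with no subtype-specific genetics. Families are re-drawn
until at least `min_affected_per_family` members are affected (default
2), emulating multiplex ascertainment; per-carrier breakpoint jitter
shrinks each call by up to 3% per side so that within-family
intersections stay non-empty while breakpoints differ. A truth table
(planted locus, risk haplotypes, linked families, every CNV event with
its carriers) is emitted alongside; the analysis pipeline never reads it.

What passing tests on these cohorts do **not** show: robustness to LD
between markers, genotyping error, CNV-calling error beyond boundary
jitter, population stratification, or pedigrees beyond the 16-bit cap.

# Numerical choices and degenerate inputs

* Likelihood chains are renormalised per position; posterior columns sum
  to 1 within $10^{-9}$.
* Markers with no typed founder fall back to allele frequency 0.5 with a
  warning (flagged in the frequency table for audit).
* Monotonicity violations in the genetic map (bp order disagreeing with
  cM order, duplicate positions) drop the offending marker with a
  warning; positions outside the mapped range clamp to the terminal
  marker during bp→cM interpolation.
* Support intervals are reported on the marker grid (the last grid point
  within `drop` of the peak; no interpolation); a flat curve returns the
  whole chromosome with a warning.
* With no shared CNV anywhere the CNV-weighted track is empty and null
  replicate maxima are $-\infty$ with a warning.
* Malformed CNV rows are dropped with a logged count by default and raise
  a format error under `strict = TRUE`.

# Test problem sizes

The test suite verifies the engine against independent oracles (full
founder-configuration enumeration, exhaustive inheritance-path sums) on
pedigrees of 2–4 meiosis bits and up to 4 markers; calibrates the
combined NPL Z on 500 gene-dropped replicates of a 10-family fixture
(mean within ±0.1, variance within [0.8, 1.2]); checks type-I control of
the CNV-weighted scan with 200 null cohorts × 100 inner replicates
against a 99% binomial band around 5%; and verifies that a dominant locus
planted on a shared CNV haplotype in 5 of 20 families is the top-ranked
segment in a majority of 7 runs. These sizes are the package's chosen
study conditions for its own validation and are stated here so they can
be scaled up by users with more patience.

# Known limitations

* Exact computation caps at 16 meiosis bits per family; no
  founder-couple symmetry reduction is applied.
* Autosomes only; biallelic markers only; no interference-aware map
  functions; no two-point LOD tables.
* The CNV-weighted score does not weight families by CNV frequency;
  rare, strongly disease-correlated CNVs in few families can rank below
  common, weakly correlated ones. Frequency-aware weighting is an
  extension point, deliberately unimplemented.
* Whether sharing should require identical deletion/duplication states
  is genuinely ambiguous; both behaviours ship (`match_state`).
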