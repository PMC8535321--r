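---
title: "Methods: family-based linkage and rare-variant prioritization with pedscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: family-based linkage and rare-variant prioritization with pedscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedscan)
```

## The problem

A multiplex disease family — one with several affected relatives — supports
two complementary genetic questions. First, do the affected members carry an
unusually heavy load of the *common* susceptibility alleles already known for
the disease? That is answered with a weighted genetic risk score (wGRS).
Second, do the affected members share *rare* functional variants that common
variants cannot explain? That is pursued by non-parametric linkage analysis
(which genomic segments do all affecteds co-inherit?), a prioritization
cascade over sequencing-derived variant annotations, replication through
family-based burden testing, and gene-set over-representation analysis.

pedscan implements this whole pipeline in a form that runs end-to-end on
synthetic data, so every stage can be exercised, calibrated and tested
without access to patient genotypes.

## Non-parametric linkage: the model

### Inheritance vectors

For a pedigree with $n$ non-founders, each non-founder receives one allele
from each parent, and each such meiosis either transmits the grand-paternal
or the grand-maternal allele. The vector of these $2n$ binary outcomes — the
inheritance vector $v$ — fully determines which founder alleles every member
carries. Under Mendelian segregation all $2^{2n}$ vectors are equally
likely. `inheritance_space()` enumerates the space exactly; the default cap
is 16 bits (8 non-founders) because the dense per-state tables the engine
keeps grow as $2^{\mathrm{bits}}$ — the reference family here has 12 bits
(4,096 states), far inside the cap.

### The NPL-all sharing statistic

Excess allele sharing among affected members is scored with the
Whittemore–Halpern "all" statistic. With $a$ affected members, consider
every way $h$ of picking one allele from each affected; if $b_f(h)$ counts
how often founder allele $f$ appears in the pick,

$$S_\mathrm{all}(v) = 2^{-a} \sum_h \prod_f b_f(h)!$$

This rewards configurations in which one founder allele is carried by many
affecteds. The exact null mean $\mu_0$ and standard deviation $\sigma_0$
over the uniform vector distribution give the normalized score
$Z(v) = (S_\mathrm{all}(v) - \mu_0)/\sigma_0$; the package verifies
$\sum_v P_0(v) Z = 0$ and $\sum_v P_0(v) Z^2 = 1$ to $10^{-9}$.

### Marker likelihoods and the multipoint chain

A biallelic marker with alternate-allele frequency $q$ contributes
$P(\text{genotypes} \mid v)$: the sum over all founder-allele assignments
consistent with $v$ and the observed dosages of the product of per-allele
priors $q$ / $1-q$. Missing calls and untyped members impose no constraint.
Across a chromosome, `multipoint_npl()` runs the usual hidden Markov chain
over inheritance vectors: each meiosis bit flips independently between
adjacent markers with the Haldane recombination fraction
$\theta = (1 - e^{-2d/100})/2$ of their cM gap, and forward–backward
recursion yields posterior vector weights at every marker. Genetic-map
positions come from 3-column map files with linear interpolation between
anchors and constant extrapolation beyond them. Sex chromosomes are excluded
by default: the autosomal transmission model does not describe X
inheritance.

Two modelling simplifications are deliberate: founder alleles are
independent across markers (no linkage disequilibrium between markers), and
founders are assumed unrelated and non-inbred.

### The Kong–Cox exponential LOD

Evidence is summarized with a one-parameter exponential tilting of the null
inheritance distribution:

$$L(\delta) = \frac{\sum_v w(v)\, e^{\delta Z(v)}}{E_0[e^{\delta Z}]},
\qquad \mathrm{exLOD} = \log_{10} L(\hat\delta),$$

with $w$ the marker's posterior vector weights and $\delta \ge 0$ (the
model is one-sided; negative sharing evidence gives exLOD 0). The tail
probability is $p = 1 - \Phi(\sqrt{2\ln 10 \cdot \mathrm{exLOD}})$, so an
uninformative marker gives exLOD 0 and $p = 0.5$. $\delta$ is maximized on
$[0, 10]$ by golden-section search to a tolerance of $10^{-6}$; when the
maximizer lands on the boundary — which happens with complete data, where
the likelihood increases without bound — the supremum is reported instead,
namely the posterior-to-null mass ratio of the maximal sharing class. For a
family with complete data this equals $-\log_{10} P_0(\text{maximal
class})$. For the reference pedigree (four affected siblings plus an
affected grandchild) the probability that all four siblings share both
parental alleles identical-by-descent is $1/64$, so the family's ceiling is
$\log_{10} 64 = 1.806$ with tail probability $0.00196$ —
`max_attainable_exlod()` computes this from any pedigree.

### Peaks, shores and regions

`call_linkage_regions()` implements the peak-and-shore rule: peaks are the
markers whose exLOD lies within $\varepsilon = 10^{-6}$ of the track's
global maximum; each peak extends left and right to the nearest marker
where the exLOD drops to zero (read as $\le 0$, the floating-point-safe
version of "drops to 0"), whose position becomes the region endpoint;
chromosome ends terminate regions, and regions that overlap or share a
shore marker are merged. Coordinates are 1-based and inclusive throughout.

## The weighted genetic risk score

The wGRS of a subject is $\sum_\ell w_\ell d_\ell$ over panel loci, with
$w_\ell = \ln \mathrm{OR}_\ell$ and $d_\ell$ the risk-allele dosage. For a
protective allele the reciprocal rule applies: every non-protective allele
counts as a risk allele with weight $\ln(1/\mathrm{OR})$. Missing dosages
are skipped by default — skipping never fabricates risk — with
mean-imputation ($2 \times$ panel frequency) available behind a flag, since
the appropriate policy is data-dependent and both are defensible. Groups
are compared with the classical equal-variance two-sample t test (Welch
behind a flag); at the group sizes this pipeline targets the two differ
negligibly, and degenerate zero-variance input falls back to the
$t = 0, p = 1$ convention.

## The prioritization cascade

Five independent predicates, conjoined:

* **Segregation** — every affected member among the variant's carriers.
  Healthy carriage does not exclude a variant; "absent from the unaffected
  member" is kept as an optional annotation flag, never a filter.
* **Frequency** — strictly below the MAF threshold (default 5%) in *every
  populated* column among 1000G-EUR, GnomAD-NFE and ExAC-NFE, or absent
  from all three. The stricter all-populated-sources reading is the
  default because a single contradicting database usually flags an
  allele-matching problem; a one-source-suffices mode is available.
* **Functional impact**, by category: high-impact categories (splicing,
  frameshift and non-frameshift indels, stopgain, stoploss) always pass;
  missense needs CADD-Phred > 10 or damaging calls from ≥ 2 of SIFT,
  PolyPhen, MutationTaster, MutationAssessor and FATHMM (each tool's
  standard damaging labels are recognized); synonymous — and non-coding in
  the exome context — need any of CADD > 10, GWAVA > 0.5, GERP > 4,
  |SPIDEX| > 4, SpliceAI > 0.4; non-coding in the whole-genome context
  needs SpliceAI > 0.4. Absent scores never count toward a pass: a missing
  prediction is not evidence of impact.
* **Linkage regions** (optional) — position inside a called region,
  1-based inclusive.
* **Association evidence** — nominally significant ($p < 0.05$) in at
  least one external cohort where the variant's key is present, or absent
  from every cohort. Keys match by exact normalized
  chromosome:position:ref:alt; allele-flip rescue is deliberately out of
  scope to avoid silent strand errors.

## Kinship-adjusted burden testing

Within a gene, qualifying variants collapse to a per-subject burden
$b_i = \sum_v w_v g_{iv}$ (unit weights by default; Madsen–Browning
frequency weights behind a flag). With affection $y_i \in \{0, 1\}$ and
$c_i = y_i - \bar y$, the score statistic is

$$U = \sum_i c_i b_i, \qquad
V = \Big(\sum_v w_v^2\, 2 \hat p_v (1 - \hat p_v)\Big)\, c^\top (2\Phi)\, c,
\qquad \mathrm{stat} = U/\sqrt{V},$$

where $\Phi$ is the block-diagonal kinship matrix of the family cohort, so
genotype covariance between relatives is priced into the null variance.
Allele frequencies $\hat p_v$ are estimated from one member per family
(deterministically seeded) plus the unrelated subjects, to avoid
kinship-inflated estimates. The p-value is two-sided normal; a
within-family label-permutation mode exists as a cross-check (its null is
conditional on family affection counts, so only loose agreement with the
unconditional normal approximation should be expected). Positive statistics
mean qualifying alleles are enriched in affected subjects. Genes with a
single qualifying variant are never tested; they are reported descriptively
with one-subject-per-family carrier counts. This test is a re-derivation in
the spirit of pedigree-aware burden tools, not a re-implementation of any
specific tool's internals.

## Over-representation analysis

`hypergeometric_enrichment()` computes the standard upper tail
$P(X \ge k)$ for the overlap $k$ between a query of $n$ genes and a term
annotated to $K$ genes in a universe of $N$. The universe size is a
required choice (default 20,000 protein-coding genes): web enrichment
services use undocumented per-category backgrounds, so their printed
p-values can be matched only in order of magnitude, never exactly.
Bonferroni adjustment multiplies by the user-supplied per-category
annotation count. The colocation sensitivity rerun drops, for each linkage
region contributing two or more of a term's overlapping query genes, all
but the lowest-positioned gene (a deterministic tie-break) and recomputes
the tail — two genes in one co-inherited segment are one signal, not two.

## What the synthetic-data generator emulates

`gene_drop()` draws founder alleles from the configured frequency and
transmits them with map-based recombination, so simulated genotypes have
exactly the IBD covariance the linkage and burden models assume. An
optional disease locus conditions the drop, by rejection sampling of whole
inheritance realizations, on all affected members sharing a founder
haplotype there. `simulate_annotated_variants()` builds cascade fixtures in
which every variant passes or fails exactly one designated stage by
construction, with scores drawn from ranges that cannot cross the
thresholds by jitter. `simulate_wgrs_cohort()` draws case/control panels
under a logistic liability model with the panel's log-odds weights.
`simulate_burden_cohort()` assembles nuclear families (two founders, two
children, three of four affected) plus unrelated controls — mirroring a
replication cohort of 28 multiplex families and 30 unrelated healthy
subjects — and gene-drops unlinked variants through them.

What the generator does **not** emulate: linkage disequilibrium between
markers, genotyping or sequencing error, population stratification,
phenocopies and incomplete penetrance, and sequence-level reads. Passing
tests therefore demonstrate the statistical machinery under its own model
assumptions, not robustness to the artefacts of real data.

### Study scales used by the test suite

The packaged checks run at sizes chosen to finish in minutes on one core:
null calibration of the linkage scan uses 1,000 gene-drop replicates of the
reference pedigree with 5 markers at 10 cM spacing and frequency 0.5;
locus recovery uses 200 replicates of a 41-marker, 1 cM-spacing chromosome
with the conditioned locus at the center — the dense spacing reflects the
merged sequencing-plus-chip panels this design targets, whose average
marker distance is far below 1 cM, and matters: at microsatellite-era 5 cM
spacing single biallelic markers frequently cannot reveal the conditioned
sharing; burden-test calibration uses 2,000 null genes of 3 variants
(frequency 0.02–0.10) over the 28-family cohort; cascade truth-recovery
uses 100 seeds of 20-variant fixtures.

## Numerical and interface choices

* Coordinates are 1-based GRCh37 everywhere; variant keys are normalized
  to minimal form (shared suffix trimmed, then shared prefix with position
  advanced) before any join.
* Missing genotypes are `NA`, never dosage 0.
* Allele-frequency assignment takes the first populated source in the
  order GnomAD-NFE, ExAC-NFE, 1000G-EUR, with a configurable floor
  (default 0.001) when all are missing, keeping monomorphic-in-reference
  variants usable in likelihoods.
* Merging genotype sources keeps the priority source's record for shared
  keys and warns when the two sources' allele frequencies differ by more
  than 0.2 — a generous bound that flags probable strand or allele
  mismatches without firing on ordinary estimation noise.
* The Kong–Cox search bound $\delta_{\max} = 10$, tolerance $10^{-6}$ and
  boundary-supremum reporting reproduce complete-data maxima to three
  decimals; the marker-emission kernel is compiled (Rcpp), which is what
  makes thousand-replicate calibration studies practical.
* An uninformative family ($\sigma_0 = 0$) scores $Z = 0$ everywhere with
  a warning; a family with fewer than two affected members is rejected.

## Known limitations

* Exact enumeration limits pedigrees to the bit cap (default 16 meiosis
  bits); no approximate sampling fallback is provided.
* Per-chromosome forward–backward tables are held in memory, which bounds
  practical marker counts per chromosome to the tens of thousands.
* No X-linked inheritance, no haplotype output, no parametric linkage,
  no multi-family weighting of the NPL statistic.
* The burden test offers no covariate adjustment and no kernel (SKAT-type)
  alternative.
* Enrichment results depend materially on the chosen universe; packaged
  defaults make that dependence explicit rather than hiding it.
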