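---
title: "Joint allelic and dosage QTL mapping in an interspecific F1 hybrid population"
author: "duoQTL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint allelic and dosage QTL mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duoQTL)
```

## The problem

An interspecific F1 hybrid poplar population — a wild-type
*P. deltoides* mother crossed with gamma-irradiated *P. nigra* pollen —
segregates two very different sources of heritable variation at the
same time:

* **natural allelic variation**: sequence differences between the two
  haplotypes *within* each outbred parent.  Every F1 inherits one of
  the two maternal haplotypes (D1 or D2) and one of the two paternal
  haplotypes (N1 or N2) at every locus;
* **induced dosage variation**: large radiation-induced deletions and
  insertions on the paternally inherited chromosomes, so each locus
  carries 0, 1 or 2 paternal copies.

Because the lines were sequenced at very low coverage (~0.5x) and only
a modest subset has deep (RNA-derived, >= 20x) data, neither haplotype
nor dosage genotypes can be read off directly: they have to be
reconstructed through phasing, binning and coverage normalization
before any trait mapping is possible.  duoQTL implements that whole
chain, channel-by-channel QTL scans, and a joint 10-state model that
asks which *mechanism* — deletion, insertion, maternal haplotype,
paternal haplotype, or a combination — drives each association.
Species-diagnostic differences (*P. deltoides* vs *P. nigra* fixed
differences) are deliberately out of scope: every F1 carries one
chromosome set from each species, so those sites cannot vary among
siblings.

## Genotype reconstruction

### Informative SNPs

A site can reveal which focal-parent haplotype an F1 inherited only if
the focal parent is heterozygous there and the other parent does not
mimic the same allele pair: the other parent must be homozygous, or
heterozygous with a *different* unordered pair
(`selectInformativeSnps()`).  A shared A/G-vs-A/G heterozygote is
useless: seeing A or G in a read cannot tell the parental haplotypes
apart.  Parental genotypes are called from high-coverage counts with a
conventional presence rule (an allele counts if it has >= 20% of reads
and >= 3 reads; heterozygous iff exactly two alleles present); both
thresholds are exposed as arguments.

### Phasing from a deep progeny subset

Each deep line inherits exactly one focal allele per informative SNP.
`inferInheritedAlleles()` explains the observed allele set at each
line x SNP (total depth >= 20) as {focal allele, other-parent allele};
if exactly one focal allele is consistent it is recorded, otherwise
the cell is missing.  This subtraction logic covers both informative
site classes with one rule — e.g. at a Pd A/G site with Pn = A/A,
reads of 12xA + 9xG imply the line inherited G (A is explainable by
the paternal transmission), while an all-A column at depth >= 20
implies A.

`phaseChromosome()` then links adjacent SNPs: every line observed at
both sites votes *cis* (first-listed alleles co-inherited) or *trans*,
and a link is accepted when the majority orientation is supported by
at least `floor(0.9 * N)` of the `N` voting lines.  The floor
semantics deliberately reproduce an acceptance count of 109 when
N = 122.  Denominators are per link: lines missing either site do not
vote.  Accepted links chain SNPs into phase blocks; a rejected link
starts a new block, and blocks are never stitched back together.  At
the package's default scale (122 deep lines at 30x) essentially every
link is accepted and blocks span whole chromosomes; phasing quality is
measured as the fraction of accepted links whose orientation matches
the simulated truth.

### Low-coverage genotyping

At 0.5x, a read is useful only when its allele is
*haplotype-diagnostic* — not carried by the other parent
(`callSnpHaplotypes()`).  Reads matching neither parental allele are
treated as sequencing error and ignored; 0.5x data cannot support an
explicit error model.  Sparse per-SNP observations are pooled into
bins of 50 consecutive informative SNPs (`binGenotypes()`); the bin
genotype is the majority of diagnostic-read counts, with ties and
empty bins missing.  Majority voting is the minimal robust combiner
and a tie is genuinely ambiguous.  A bin that straddles a phase-block
break votes only with its dominant block's SNPs, because haplotype-1
anchors are arbitrary across blocks and mixing them would scramble the
vote.

### Line QC

The original line selection was partly visual; `qcSelectLines()`
automates it as a reproducible two-criterion rule.  Among lines with
both low-coverage and deep genotypes, the smallest per-line depth is
found at which every deeper line (a) agrees with its reference
genotypes in >= 90% of doubly-called bins and (b) shows at most
`maxSwitches` haplotype switches per chromosome (default
2 x expected crossovers + 2).  Concordance is judged away from
recombination breakpoints: the bin pair flanking each reference
haplotype switch is masked, because a crossover inside a bin makes its
majority call legitimately depth-dependent.

### Dosage calling

`normalizeCoverage()` converts per-bin read counts to copy ratios by
dividing each line's bin coverage by its genome-wide mean (library
size) and then by the population mean of that normalized value at the
bin — computed *leave-one-out*, so a large indel cannot bias its own
baseline in a small population.  A euploid line sits near ratio 1, a
deletion at 0.5, an insertion at 1.5; `callDosage()` cuts at
0.75/1.25, the maximum-margin midpoints between those states.  Two
noise guards: isolated non-regular calls shorter than `minRun = 2`
bins are reset to 1 (real indels span hundreds of kb, i.e. multiple
bins), and dosage is capped at 2 — the genotype model admits only
{0, 1, 2} paternal copies.  Known residual bias: a line's own indels
shift its genome-wide mean slightly (bounded by the indel fraction of
the genome), which is negligible at the default scale but visible if
indels cover a large genome fraction.

### The common marker table

`buildCommonMarkers()` puts all three channels on the maternal binned
markers.  Between-bin gaps are imputed from flanking markers
(`imputeBetweenFlanks()`): a gap inherits a genotype only when both
flanks agree (N1 at `Chr01_1_10000` and N1 at `Chr01_20000_30000`
imputes N1 across `Chr01_10001_19999`); unequal or missing flanks, and
chromosome ends, stay NA — there is no evidence to extrapolate from.
All intervals are 1-based and inclusive on both ends.  Cross-channel
lookup uses the marker midpoint (symmetric, and bins are small
relative to indels).  The structural invariant `dose = 0 implies
Pn = NA` — a deleted paternal segment carries no haplotype — is
enforced by the container's validity method.

## Single-channel QTL scans

The model is the single-marker regression

$$Y_i = \beta_0 + \beta_1\,gt_i + \varepsilon_i$$

with `gt` coded D1 -> 0 / D2 -> 1 (Pd), N1 -> 0 / N2 -> 1 (Pn, missing
inside deletions), or the paternal copy number 0/1/2 (dosage).
Genome-wide significance uses a permutation null computed per trait
and channel: the trait is shuffled among lines, all markers refitted,
and the maximum |t| recorded; the 95th and 99th percentiles of 1,000
maxima give the 5% ("significant") and 1% ("confirmed") thresholds.
The two-sided maximum is used because trait orientations are
arbitrary — deletions frequently *lower* biomass-type traits, and a
one-sided maximum would miss them.  Markers with fewer than 20
complete pairs or fewer than 5 lines in the minor genotype class are
skipped with an explicit reason: rare indels genuinely limit power and
the floors make that auditable.  Missing phenotypes are dropped per
trait before permuting, keeping the permutation exchangeable within
observed lines.

Runs of adjacent significant markers merge into one QTL
(`callQtls()`), and the variance explained is the adjusted R^2 of a
multivariate OLS on all markers under the QTL; the joint variance of
all QTLs of a trait refits on the per-QTL peak markers
(`varianceExplained()`, `allQtlVariance()`).  Aliased (collinear)
columns are dropped by the fit.  The scan internals are closed-form
vectorized OLS (needed to refit every marker 1,000 times); the test
suite pins them to `stats::lm` and to the pooled two-sample t-test
(for binary markers the two are algebraically identical), so the fast
path can never drift from the reference implementations.

## The combined 10-state model

Combining the three channels gives each line x marker a joint state
`Pd.Pn.dose`.  Two modelling commitments close the state universe at
exactly 10: a deleted paternal segment has no haplotype (dose 0 forces
the Pn slot to NA), and an insertion is a duplication of the
transmitted paternal copy, so a dose-2 state keeps a single Pn
haplotype label.  The universe is
{D1, D2} x ({NA} x {0} u {N1, N2} x {1, 2}), and with every state
present pairwise testing yields choose(10, 2) = 45 comparisons.

Each present state pair with >= 5 lines per side is tested by a
two-group Monte-Carlo permutation test of the absolute mean difference
(pair-subset reshuffling, add-one estimator
`p = (1 + #{perm >= obs}) / (1 + B)`, default B = 1000).  The
resampling loop is a small C++ kernel driven by R's RNG, so results
are seed-reproducible; the suite validates it against exhaustive
enumeration of all group splits at small n.  P-values are
BH-adjusted, by default one family per comparison pair across all
markers genome-wide (a per-marker scope is available as a switch).
Markers with any significant adjusted pair merge by adjacency into
QTLs.

### Classifying the mechanism

Each significant pair is read as evidence only when it is a clean
contrast:

* doses 0 vs 1 on an equal haplotype background — deletion evidence;
* doses 1 vs 2 on an equal haplotype background — insertion evidence;
* equal dose, exactly one haplotype differing — Pd or Pn evidence;
* equal dose, both haplotypes differing — joint Pd+Pn evidence.

Three contrasts carry *no* weight because they are confounded.  Pairs
differing in both dose and haplotype mix mechanisms by construction.
The 0-vs-2 contrast contains no regular-dose anchor: it is
simultaneously a deletion-state and an insertion-state difference, so
crediting it to either mechanism would systematically misclassify
single-mechanism loci.  And 0-vs-1 contrasts are discounted whenever
direct Pn evidence exists: the dose-0 state pools lines of both
(unknowable) paternal haplotypes, so a pure Pn-haplotype effect shifts
it to the midpoint of the N1 and N2 groups and fakes deletion
signal at half strength.  The converse leak cannot occur — under a
pure deletion effect every equal-dose pair is null — so the guard is
one-directional.  Finally, parsimony governs the allelic labels:
both-haplotype contrasts are expected whenever either single haplotype
has an effect, so they yield the joint "P. deltoides + P. nigra" label
only when no single-haplotype contrast is significant.  A multiplicity
floor makes the label robust to the false discoveries that FDR control
tolerates: a strong QTL produces dozens of true significant pairs and
hence an expected handful of false ones, so a mechanism counts only
with at least two supporting pairs — unless only one pair of its type
was testable at the QTL, where a single pair is all the evidence that
can exist.  Dosage evidence, when present, takes precedence
(deletion / insertion / deletion+insertion); a QTL whose significant
pairs are all confounded is reported as "ambiguous" rather than forced
into a group.  In the
rare case of a genuinely mixed deletion + Pn locus the guard votes for
the allelic label; the population that motivated this design showed no
overlap between allelic and dosage QTLs, so the cost is theoretical.

## The synthetic experiment

`simulateParents()` / `simulateF1()` / `simulateAlleleCounts()` /
`simulateBinCoverage()` / `simulatePhenotypes()` generate a complete
in-silico experiment with a truth ledger, so every stage above can be
scored against known answers.  The defaults are the study conditions
the package is designed around, scaled to a desk-size genome:

* 5 chromosomes x 2 Mb (a ~1/40-scale stand-in for a ~400 Mb,
  19-chromosome genome; `nChrom = 19` reproduces the full karyotype
  when wanted);
* per-parent heterozygous-site density 2e-4/bp, giving ~2,000
  informative SNPs per parent and ~40 binned markers at 50 SNPs/bin;
* 343 F1 lines at 0.5x, a 122-line deep subset at 30x, parents at
  45x/65x, per-read error 0.005;
* Poisson crossovers (mean 1/chromosome/meiosis), uniform breakpoints,
  no interference — the simplest process consistent with the expected
  recombination pattern; the real recombination map is unknown and no
  claim is made about it;
* Poisson(2.5) indels per line, 66.5% deletions, sizes 250 kb - 1 Mb
  (the real minimum indel size, with the upper end scaled to the
  2 Mb chromosomes), placed only on paternal chromosomes;
  within-line overlaps are redrawn so paternal copy number stays in
  {0, 1, 2};
* insertions duplicate the transmitted paternal segment — the
  semantics that close the 10-state universe;
* phenotypes are the forward model: planted effects x genotype codes
  plus Gaussian noise.  Planted effect sizes are *standardized*:
  an effect `e` means `beta = e * noiseSd / sd(code)`, i.e. a slope of
  `e` residual-SDs per SD of the genotype code, making power
  comparable across channels with very different code variances.
  Recovery experiments plant effects at a marker midpoint, so they
  measure the scan rather than attenuation from marker-grid mismatch.

What the generator does **not** emulate: mapping and GC bias,
allele-specific expression in the deep (RNA-derived) subset, linkage
disequilibrium beyond the cross itself, crossover interference,
mosaicism, small indels and point mutations, and sub-bin dosage
breakpoints.  Green recovery tests therefore demonstrate that the
algorithms are correct under the stated statistical model, not that
real sequencing artefacts are handled; on real data the QC and
noise-suppression layers carry that burden.

## Numerical choices and degenerate inputs

* Ties: a tied majority vote in a bin is NA; a 50/50 cis/trans split
  rejects a phasing link; equal-valued permutation statistics count as
  exceedances (the C++ kernel compares with a 1e-9 relative tolerance
  so summation order cannot break exact ties, and identical groups get
  p = 1).
* Quantiles of permutation maxima use R's default (type 7) definition.
* A permutation with no valid marker contributes a maximum of 0, with
  a warning.
* Chromosomes with fewer than two informative SNPs phase as
  single-site blocks, with a warning.
* A zero-coverage line is flagged NA throughout dosage calling and
  excluded from population baselines.
* All randomness flows from one root seed through named per-stage
  substreams (`runPipeline()`), so stage outputs are reproducible
  independently of execution order; seeds stay below 2^31.
* Test and acceptance workloads use the default desk scale above with
  permutation counts of 200 (thresholds) and 1,000 (pair tests), and
  20-50 replicates per recovery experiment — sizes chosen so the full
  verification run completes in minutes on one CPU while leaving clear
  statistical margins.

## Limitations

* Bins are fixed runs of 50 informative SNPs; breakpoint-aligned
  dosage bins from a prior indel catalogue are not reconstructed.
* The depth threshold chosen by `qcSelectLines()` is a reproducible
  surrogate for what was originally a partly visual decision; on real
  data its two criteria should be inspected, not trusted blindly.
* Variance-explained figures are in-sample adjusted R^2 values, not
  cross-validated predictions.
* The combined model tests mean differences between state groups; it
  does not fit explicit dose x haplotype interaction coefficients, and
  epistasis across markers is out of scope.
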