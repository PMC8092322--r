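---
title: "Methods: detecting and scoring tRNA anticodon switches"
author: "trnaswitch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and scoring tRNA anticodon switches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trnaswitch)
```

## The biological problem

A tRNA delivers the amino acid matching its anticodon: the codon read is the
reverse complement of the 3-nt anticodon at canonical positions 34–36. A
point mutation in the anticodon can therefore convert a tRNA of one identity
into a functional tRNA of another — an *anticodon switch* — provided the
acceptor-stem identity elements of the new synthetase are present. In
budding yeast the threonine codon ACG is read by a single-copy tRNA gene
(*TRT2*, 72 bp); strains in which that tRNA is structurally destabilised can
be rescued by a switch in a multicopy lysine (anticodon CUU) or elongator
methionine (CAU) family, each donating one CGU-anticodon copy. This package
implements the computational chain around that observation: finding switches
in gene pools and population variant sets, quantifying the heat-shock demand
for the ACG codon, scoring variant tRNA stability, testing proteomes for
mistranslation, and computing the Mendelian expectations of suppressed
crosses. Everything runs on synthetic data with exported ground truth.

## Anticodon localisation

The anticodon is located as the middle three bases of the *second hairpin
loop* (5'→3') of the cloverleaf rather than by the fixed offset 34, because
gene lengths vary — on the packaged 72-nt threonine-tRNA-like template the
anticodon sits at 33–35, on the 76-nt template at 34–36. For a loop of
length $L \ge 5$ the middle triplet starts at loop position
$\lfloor (L-3)/2 \rfloor + 1$; loops shorter than 5 nt are rejected as
ambiguous. Without a structure, the anticodon is parsed from the gene
identifier (gtRNAdb dash dialect or the yeast locus dialect) and verified to
occur in the sequence; if it occurs more than once the occurrence nearest
position 34 is taken. Indices in the R API are 1-based throughout (the
R/Bioconductor convention); BED output remains 0-based half-open on disk.

## Closest-nonequal-neighbour switch scan

Each gene is compared to every other pool member by exact global edit
distance (unit costs, computed by `utils::adist`); the *closest nonequal
neighbour* is the nearest member whose sequence differs, so identical
duplicate copies never match themselves. A gene is a switch candidate when
its decoded amino acid differs from its neighbour's. Ties are broken by
lexicographically smallest gene id (a deterministic choice the underlying
method leaves open). Because switch detection is symmetric — a pristine
family parent may reciprocally have the switched copy as *its* nearest
nonequal neighbour — the scan reports per-gene events plus a deduplicated
pair count, and tests score recovery as: every planted gene flagged, every
flagged pair containing a planted gene.

Per-family trees use Jukes–Cantor distances
$d = -\tfrac{3}{4}\ln(1 - \tfrac{4p}{3})$ on the proportion of differing
sites $p$ (saturated $p \ge 0.75$ mapped to a configurable cap, default 5
substitutions/site), neighbour joining (`ape::nj`), and column bootstrap
with bipartition support counted by `ape::prop.clades`. Negative NJ branch
lengths, which arise on non-additive inputs, are clamped to zero with the
deficit moved to the sister branch; the clamp is off by default nowhere but
can be disabled.

## Variant scanning

Anticodon transcript positions map to genomic coordinates directly on the
plus strand and in descending order on the minus strand, where allele
comparison uses the reverse complement. The scan decomposes multi-allelic
VCF records, considers single-nucleotide substitutions only (indels go to a
skipped-records log), verifies the VCF reference allele against the
annotated anticodon base, and reports carriers as samples with at least
`min_allele_count` alternate alleles (1 by default, so heterozygotes count —
the population-matrix convention is not documented anywhere authoritative,
hence the knob). Events carried by no sample are dropped unless requested,
synonymous anticodon changes are flagged but kept, and intron-containing
genes are rejected rather than mis-mapped. A warning about chromosome naming
fires only when *no* record matches the annotation, since an annotation
covering a subset of chromosomes is normal.

## Codon demand under heat shock

For each gene the *relative* usage of a codon is its share within the
synonymous family of its amino acid (ACG among the four threonine codons),
so composition and expression level cannot leak into each other; genes
lacking the amino acid are flagged `NA` and excluded from means, never
propagated. The demand statistic at a time point is the unweighted mean
share over the top-`N` (default 25) most induced genes divided by the mean
over all genes; the background includes the top set by default
(`exclude_top` available, which necessarily raises the ratio). Top-`N`
selection is per time point with lexicographic tie-breaks, making the
statistic invariant to adding a constant to all log2 fold changes.
Group comparisons use the tie-corrected Kruskal–Wallis test with the usual
star thresholds (0.05, 0.01, 0.001, 0.0001). qPCR fold changes follow
$2^{-\Delta\Delta C_t}$ with reference genes aggregated by the arithmetic
mean of their $C_t$ (equivalent to a geometric mean of efficiencies at
efficiency 2).

## Temperature-dependent stability

The energy model evaluates a *fixed* secondary structure:
$\Delta G(T) = \sum_\text{stacks}(\Delta H - T\Delta S) +
\sum_\text{loops}(\Delta H - T\Delta S)$, $T$ in kelvin, parameters from a
small packaged table with Turner-style magnitudes (all 36 Watson–Crick and
G·U stack doublets; hairpin/bulge/internal initiation by size with
logarithmic extrapolation; a linear multibranch term; loop terms are purely
entropic). Wobble-containing stacks are approximated as the corresponding
A–U stacks scaled by 0.6. Dangling ends and coaxial stacking are omitted;
structure prediction is out of scope — the structure is an input. A pair
whose bases cannot pair (for example the U·C apposition created by a stem
mutation) is dissolved and absorbed into the surrounding loop. These
simplifications mean absolute energies are not comparable to full
thermodynamic evaluators, and no absolute value is claimed anywhere; the
model commits to *sign and ordering* statements, which is what the biology
needs: the destabilised allele lies above both the reference and the
re-stabilised allele at 30, 35 and 42 °C on the packaged fixtures, and the
suite checks a rank correlation of at least 0.9 against an external
evaluator when one is on the PATH. The packaged allele fixtures are
synthetic molecules reproducing the pairing topology of the three alleles
(intact G28–C40 pair, U28·C40 mismatch, restored U28–A40 pair), not database
sequences. Destabilisations with $\Delta\Delta G$ strictly greater than
2.65 kcal/mol are flagged as rapid-tRNA-decay substrates; the boundary value
itself is not flagged.

## Proteome statistics

Filtering keeps features with at least 3 valid values in at least one strain
group. Missing values are then imputed per sample from
$\mathcal N(\bar x - 1.8 s,\ (0.3 s)^2)$ of that sample's observed log2
intensities — the convention of mainstream label-free pipelines; the
constants are arguments, not magic. Substitution fractions count substituted
peptide observations against observations of threonine-containing base
peptides (count mode default; an intensity-weighted mode exists), and are
reported relative to a control strain, where the no-mistranslation
expectation is a ratio of 1.

The differential test is the S0-moderated two-sample statistic
$t = (\bar x_A - \bar x_B)/(\text{se}_\text{pooled} + s_0)$ with $s_0 = 1$
by default, assessed by permutation of group labels: all distinct balanced
assignments when there are at most 2000 (20 for triplicates), sampled
otherwise. For each observed $|t|$ cutoff the estimated false positives are
the median across permutations of permuted statistics exceeding it;
$q = \text{FP}/\text{positives}$, capped at 1 and monotonised so $q$ never
decreases as $|t|$ decreases. No null-proportion ($\pi_0$) correction is
applied, which makes the estimate conservative.

The threonine-shift statistic is
$\mathrm{median}(\text{subset}) - \mathrm{median}(\text{all})$ with a
Kolmogorov–Smirnov statistic against the complement and a two-sided
permutation p-value over subset membership. Note that when the subset is a
substantial fraction of "all" (about 20% at the realistic 3,663-of-18,059
scale), depressing the subset also moves the overall median, so the
statistic's population value is attenuated relative to the raw depression
(about −0.40 for a −0.5 shift); tests compare the estimate against that
analytic mixture value, not against the raw shift.

## Tetrad expectations

Meiosis is modelled without crossover interference or gene conversion: each
heterozygous linkage group assigns its alternate alleles to one of the six
2-of-4 spore subsets uniformly (which reproduces the 1:1:4
parental-ditype : non-parental-ditype : tetratype ratio for unlinked pairs),
`same_locus` partners co-segregate in coupling, and a spore dies exactly
when it carries an essential-gene deletion and no functional suppressor
allele (no partial penetrance — the all-or-none grids justify this).
Expectations are exact enumerations over joint patterns; the simulator draws
the same patterns and agrees within binomial error.

## The generators and what passing tests show

The generators define the study conditions: cloverleaf tRNA families with
four reserved diagnostic substitutions per family (cross-family distance ≥ 8
by construction) and per-copy noise Poisson(0.02·L) truncated at 3 to keep
the family margin ≥ 3; genomes with non-overlapping gene placement on both
strands and VCFs with planted anticodon variants plus decoys;
expression courses over 4/11/16/26/40 min with the top-25 induced set built
at a deterministically allocated (largest-remainder) codon enrichment so the
planted ratio is recoverable up to rounding; and peptide tables with
log2-normal intensities (replicate sd 0.5, a realistic label-free CV),
logistic intensity-dependent missingness (uniform missingness would make
detection-limit imputation untestable), substitution observations drawn
conditional on the base peptide being observed (so the planted
per-observation rate is identifiable), and a planted differential set
(default scale 2,047 features with 132 effects of 2 log2 units, 60% down).
Problem sizes in the tests — pools up to 200 genes, 50-seed round trips,
2,000-row differential matrices, 10,000 simulated tetrads — were chosen as
the smallest sizes at which the statistical assertions have comfortable
margins.

What passing tests do *not* show: real tRNA pools contain modified bases,
introns and alignment ambiguity the generator omits; real VCFs have
genotype-quality noise and reference blocks; real proteomes have correlated
peptides, shared peptides across proteins, and non-normal missingness. The
suite demonstrates correctness of the statistics and plumbing under known
ground truth, not robustness to every artefact of real data.

## Design choices that were genuinely open

* Pairwise similarity uses exact edit distance rather than a short-read
  aligner's hit list: deterministic, parameter-free and strictly more
  complete at these pool sizes; a banded variant was considered and dropped
  because the exact C implementation is already fast at the sizes in scope.
* "Nonequal" is interpreted at sequence level, so duplicate gene copies
  cannot shadow the informative cross-family neighbour.
* The carrier definition counts any alternate allele; a `min_allele_count`
  knob exposes the stricter reading.
* The background of the demand ratio includes the top set by default, with
  `exclude_top` provided, since either reading is defensible.
* Substitution fractions default to count mode, with intensity mode
  available, since quantified counts and intensities are both in use.
* Reference-gene aggregation for ddCt uses the arithmetic Ct mean; with two
  reference genes any other convention differs only by a constant shift.

## Known limitations

The energy model's absolute values are not meaningful; only comparisons
under the same structure template are. The variant scan refuses intronic
tRNA genes rather than handling split coordinates. Protein-level rollup of
peptides (razor/unique assignment) is out of scope — the statistics operate
on the provided quantification table. The tetrad model has no finer linkage
than `unlinked`/`same_locus`, which is all the modelled crosses need.
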