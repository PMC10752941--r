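---
title: "Inbreeding coefficients and effective population size: models, parameters and design choices"
author: "inbreedNe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inbreeding coefficients and effective population size}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inbreedNe)
```

# The problem

In a closed population bred over discrete generations, inbreeding
accumulates and genetic variability is lost. Two families of measures
track this. Pedigree inbreeding $F_{PED}$ is the *expected* fraction of
an animal's genome that is identical by descent (IBD), given the
recorded parentage and the convention that pedigree founders are
unrelated and non-inbred. Marker-based coefficients measure the
*realised* state of the genome, which differs from the expectation
through Mendelian sampling and linkage, and which confounds IBD with
identity by state (IBS) to a degree that depends on the estimator.
From either family, a per-generation rate of inbreeding $\Delta F$
gives a realised effective population size $N_e = 1/(2\bar{\Delta F})$.
This package computes all of these on one dataset, under one set of
quality-control rules, so the routes can be compared like for like —
and ships a breeding-design simulator whose gene-dropped genotypes
carry *true* IBD labels, so every estimator can be validated against
ground truth.

# Estimators

## Pedigree route

$F_{PED}$ uses the Meuwissen–Luo recursion (`pedInbreeding()`), an
$O(\text{ancestors})$ traversal that reproduces the diagonal of the
additive relationship matrix exactly; the test suite checks it against
the full tabular recursion on hundreds of random pedigrees at
$10^{-12}$. Founders, and animals with an unknown parent, get $F = 0$.

Two rates are derived. The classic parent-referenced rate
$$\Delta F_{PEDt} = \frac{F_t - \bar F_{par}}{1 - \bar F_{par}}$$
is local and volatile: one unusual mating moves it strongly, and it can
be negative. The individual rate
$$\Delta F_{PEDi} = 1 - (1 - F)^{1/(t-1)}$$
standardises an animal's inbreeding by its pedigree depth. Our
generation convention sets $t$ = discrete generation index + 1, so
founders have $t=1$ and their offspring ($t=2$) use exponent 1, which
makes $\Delta F_{PEDi} = F$ after one generation of inbreeding — the
property that anchors the definition. Animals with one unknown parent
get a missing $\Delta F_{PEDt}$ by default (`unknownParentZero = FALSE`):
in a complete experimental pedigree, a missing parent signals a data
problem rather than a founder.

## Marker routes

With $x_{ij} \in \{0,1,2\}$ counting the reference allele and $p_j$ the
reference-allele frequency *in the declared reference population*:

* $F_{NEJ}$ — fraction of non-missing SNPs that are homozygous; pure
  IBS, bounded in $[0,1]$, frequency-free.
* $F_{L\&H} = (H_{obs} - H_{exp})/(1 - H_{exp})$ with
  $H_{exp} = \overline{1 - 2p_j(1-p_j)}$; may be negative.
* $F_{VR1} = \sum_j (x_{ij}-2p_j)^2 \big/ 2\sum_j p_j(1-p_j) - 1$.
* $F_{VR2} = \frac1m \sum_j (x_{ij}-2p_j)^2/(2p_j(1-p_j)) - 1$.
* $F_{YAN} = \frac1m \sum_j [x_{ij}^2-(1+2p_j)x_{ij}+2p_j^2]/(2p_j(1-p_j))$;
  note a heterozygous locus contributes $-1$ identically, and no global
  offset is subtracted — the per-locus term already estimates $F$.

All sums run over the SNPs *non-missing in that individual* (no
imputation): per-individual means stay unbiased, at the price of small
denominator differences between individuals — a documented source of
divergence from implementations that mean-impute. SNPs fixed in the
reference population ($p \in \{0,1\}$) cannot enter the standardised
sums of $F_{VR2}$/$F_{YAN}$; they are excluded with a logged count
rather than an error, because drift after the reference generation can
fix SNPs that passed the MAF filter there.

$F_{ROH}$ is the summed length of runs of homozygosity over the covered
autosome length (distance from first to last scanned SNP per
chromosome). The scanner (`detectRoh()`) is the sliding-window dialect:

| parameter | default | meaning |
|---|---|---|
| `windowSnps` | 50 | window size (SNPs) |
| `windowHetMax` | 1 | max heterozygous calls per homozygous window |
| `windowMissingMax` | 5 | max missing calls per homozygous window |
| `windowHitThreshold` | 0.5 | min fraction (inclusive) of overlapping homozygous windows for an in-run SNP |
| `minLenKb` | 1000 | min run length, kb (inclusive) |
| `minSnps` | 100 | min SNPs per run (inclusive) |
| `maxKbPerSnp` | 50 | max run kb per SNP (inclusive) |
| `maxGapKb` | 1000 | max gap between consecutive in-run SNPs, kb |

Numerical conventions the tests pin down: SNPs near chromosome ends
are covered by fewer windows and the hit fraction uses the *actual*
count of overlapping windows; chromosomes shorter than one window
yield no runs rather than an error; there is no per-run heterozygote
cap (heterozygotes act only through the window rule); the density rule
passes on boundary equality; run coordinates are the bp of the first
and last in-run SNP, not window edges; and the hit threshold is
inclusive at exactly 0.5. The scanner is deterministic and
order-invariant across animals, and is tested for exact segment-set
equality against an exhaustive enumeration oracle across seeds and
parameterisations. A consequence of the window-fraction rule worth
knowing: a homozygous run bordered by dense heterozygosity loses about
half a window of SNPs at each such edge, so a run needs roughly
`minSnps + windowSnps/2` homozygous SNPs beside a het boundary before
it is reported.

## Reference-generation adjustment

$F_{NEJ}$, $F_{L\&H}$ and $F_{ROH}$ carry a baseline of ancient IBS
that predates the study. Re-anchoring
$$F_0 = \frac{F - \bar F_{ref}}{1 - \bar F_{ref}}$$
(`adjustToReference()`) makes the reference generation average exactly
zero (a tested identity, to $10^{-12}$), turning these coefficients
into estimates of IBD *relative to the reference cohort* — the same
base that the molecular rates below use. On complete data
$F_{NEJ0}$ and $F_{L\&H0}$ coincide algebraically: both reduce to
$(H_{obs,i} - \bar H_{obs,ref})/(1 - \bar H_{obs,ref})$; with missing
genotypes they differ only through per-individual SNP sets. Their
derived $N_e$ series agreeing to well under 1% is therefore a
consistency check, not new information.

# Rates, $N_e$ and founder distance

Molecular rates use $\Delta F = 1 - (1-F)^{1/t}$ with $t$ = generations
since the reference generation; the reference generation itself has no
molecular rate (its table entries are missing). Negative $F$ gives a
negative rate through a base above 1 — allowed and reported. $F \ge 1$
(possible for adjusted values when an animal is fully homozygous) is
clamped to $1 - 10^{-12}$ with a warning. Grouping by generation,
$N_e = 1/(2\bar{\Delta F})$, with negative $N_e$ reported as printed
evidence of estimator instability, not clipped; the across-generation
summary (mean, SD of $N_e$) excludes only undefined entries.
Expected-homozygosity $N_e$ uses consecutive-generation differences of
$F_{EXP} = \overline{1-2p(1-p)}$, computed per generation and per line;
the per-SNP transform is averaged across SNPs (averaging $p$ first
would differ by Jensen's inequality). $F_{EXP}$ is computed on the GRM
marker set, whose frequencies also feed the estimators it is compared
with.

The founder distance inverts compounding:
$t = \ln(1-F_{ref})/\ln(1-\Delta F)$, with $\Delta F$ taken from the
sex-ratio $N_{e,s} = 4MF/(M+F)$ of the base breeding design for the
molecular coefficients, or from the mean $\Delta F_{PEDi}$ for the
pedigree. The contrast is diagnostic: IBS-laden coefficients place the
founders many tens of generations back (they see the whole coalescent
history of the founder lines), while the pedigree — truncated at its
recorded founders — places them a couple of generations back.

# Quality control

The pipeline fixes the filter order: individuals → ROH SNP set → GRM
SNP set. Individuals with call rate strictly below 0.97 are removed
(an individual at exactly 0.97 is kept; all "lower than" thresholds
are strict). The ROH set keeps autosomal SNPs with at most 3% missing
calls and applies **no** MAF filter — rare and monomorphic SNPs carry
real homozygosity signal and removing them would punch artificial
holes in runs. The GRM set starts from the ROH set and applies two
sequential MAF filters (≥ 0.05 in the reference population, then
≥ 0.05 overall), because the frequency-standardised estimators are
undefined or explosive at extreme $p$. Both filters log their removal
counts; all thresholds are configurable through the pipeline config.

# The simulator

`breedingDesign()` encodes the emulated history; the defaults *are*
the study conditions:

* founder pool: 3 fully inbred lines × 32 animals — each line is one
  homozygous haplotype;
* 40 generations of unrecorded panmictic burn-in at census 96;
* 5 recorded random-mating generations, 32 males × 64 females, two
  females per male, three offspring per female;
* 26 generations of 2 closed lines, 43 dams and 13 sires per line,
  matings rejected while a sire and dam share a grandparent;
* candidate offspring thinned at random to the recorded, genotyped 50
  females + 20 males per line (`selectedProportion = 0.30` of born
  candidates) — enough selected females to field 43 dams every
  generation;
* genome: 5 autosomes × 1,000 SNPs at 25 kb spacing, uniform 1 cM/Mb
  (≈ 125 cM total); at 70% of SNPs one random founder line carries the
  alternate allele, the rest are monomorphic.

Design choices and the reasoning behind them:

* **No trait is simulated.** The selection criterion of the emulated
  experiment acts on a trait this package does not model; the
  inbreeding/$N_e$ machinery depends on the *mating structure*, so
  `selectedProportion` thins candidates at random.
* **13 sires per line** is an assumption (≈ 30% of male candidates);
  the number of breeding males per line is a free design parameter.
* **Discriminating fraction 0.7** keeps the reference-generation MAF
  spectrum polymorphic enough (MAF ≈ 1/3 at discriminating SNPs) to
  survive the 0.05 filter while leaving a realistic monomorphic
  remainder for the ROH set.
* **Breeder redraws.** Breeders are drawn at random from the selected
  candidates; if a draw admits no grandparent-avoiding mating plan,
  breeders are redrawn (up to 50 times) before the run errors with
  advice to raise the census — mirroring how a breeding programme
  picks its breeders so the rule can be honoured. With few sires the
  rule becomes genuinely infeasible within two generations, which the
  error reports rather than silently relaxing.
* **Genome scale.** 5,000 SNPs on 125 cM keeps a full 26-generation
  run (simulation + QC + all estimators + ROH + rates + correlations)
  under a minute on one CPU. The price is Mendelian sampling noise:
  with ~125 cM, an individual's realised autozygosity scatters widely
  around its pedigree expectation, so pedigree–molecular correlations
  are lower than a 500k-SNP, 1,400-cM mouse array would give. Tests
  and the acceptance script therefore check *slopes, stability and
  agreement between routes*, not the correlation magnitudes of a dense
  real-data study.
* **Recorded census.** 70 genotyped animals per line per generation
  (140 total) — the smallest census that sustains 43 dams + 13 sires
  per line with stratified sexes.

## Truth labels and the base population

Every haplotype carries two labels through meiosis: the founder *line*
it descends from, and the recorded-founder *gamete* it descends from.
These yield two true autozygosities per animal, and the distinction is
the base-population relativity that runs through the whole package:

* `autoz_line` — fraction of the genome where both haplotypes descend
  from the same fully inbred founder line. This is IBD relative to the
  line foundation: a single-founder-line design gives 1 everywhere; an
  F1 between two lines gives 0. With 3 lines it has a baseline around
  1/3 even among "unrelated" animals — exactly the ancient IBS that
  the 0-adjusted estimators subtract.
* `autoz_ped` — fraction where both haplotypes coalesce to the same
  recorded-founder gamete. This is the quantity $F_{PED}$ estimates,
  because the recorded pedigree treats its founders as unrelated and
  non-inbred. Validation regresses `autoz_ped` on $F_{PED}$ and
  expects slope 1; using `autoz_line` there would flatten the slope by
  the line-sharing baseline, a base-population mismatch rather than an
  estimator failure.

Because whole cohorts share ancestors, Mendelian sampling deviations
are correlated within a replicate; the slope is therefore assessed on
data pooled across replicate simulations (or on the large default
design), not on one small cohort.

## Drift calibration

The random-mating phase is also checked for the right *amount* of
drift. Two textbook corrections to $\mathrm{Var}(\Delta p) =
p(1-p)/(2N_{e,s})$ apply a priori to this design: fully inbred
founders transmit perfectly correlated allele pairs, inflating early
drift by $(1+F)$ with $F$ the parents' line-autozygosity; and the
equalisation of maternal litters damps family-size variance, raising
the effective size at most towards the full-equalisation limit
($\approx 2N_{e,s}$). The test asserts that observed cumulative drift
across replicates lies between these two limits around the sex-ratio
prediction, and that the mean frequency change is zero (drift, not
bias).

# Numerical and interface conventions

Pedigrees are validated (unique ids, no orphan parents, acyclic graph
with a cycle member named on failure, parent generations strictly
below offspring, sexes consistent with parental roles) and
topologically sorted with a deterministic (generation, id) tie-break,
so results are invariant to on-disk record order. PLINK text and
binary dialects are both read and written (magic bytes `6c 1b 01`,
SNP-major); the counted allele is `A1` of the `.bim`, while the text
`.map` carries no alleles, so the reader takes an explicit
`refAlleles` vector or defaults to the lexicographically smallest
observed allele — the simulated fixtures name alleles so that this
default round-trips exactly. Correlations are pairwise-complete
(rates are undefined in the reference generation, and listwise
deletion would discard those animals everywhere) with a minimum of 3
pairs per cell; generation groups outside the observed span are
skipped. All pipeline figures are rendered from the written tables,
never from in-memory state, so the tables remain the single source of
truth. Every stochastic step flows from one seed; reruns are
byte-identical.

# Problem sizes

The test suite exercises scaled designs (hundreds of SNPs, tens of
animals per generation) chosen so the full suite runs in about two
minutes, with the default 26-generation design run once end-to-end;
oracle-equivalence tests use hundreds of small random fixtures, where
brute-force enumeration is exact. The acceptance script runs the
default design once (~1 minute). These sizes are the package's own
balance of resolution against convenience; all of them are parameters,
not constants.

# Known limitations

* $F_{PED}$ inherits the unrelated-founder convention; where founders
  are in truth related (as in the emulated history), it understates
  absolute autozygosity — visible here as the gap between `autoz_line`
  and `autoz_ped`.
* The simulator omits mutation, sex chromosomes, genotyping error and
  litter-size biology, and models selection only as random thinning;
  conclusions about trait-coupled selection pressure are out of reach
  by construction.
* The scaled genome makes per-animal molecular coefficients noisier
  than dense-array data; magnitudes of pedigree–molecular correlations
  from small simulated genomes should not be read as estimates of
  their real-data counterparts.
* ROH calling depends on its parameter dialect; results are comparable
  only under identical `rohParams()`.
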