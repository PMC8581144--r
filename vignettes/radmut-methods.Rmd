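---
title: "Models and methods behind radmut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind radmut}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

radmut analyses seed-irradiation mutagenesis experiments: dose--survival
assays in the M1 generation, small-mutation and structural-variant (SV)
call sets from whole-genome sequencing of M2 individuals, and the
Sanger-validated junction sequences of rearrangements. This vignette
documents the models, the tunable parameters, the numerical choices, and
what the synthetic-data tests do and do not establish.

## The single-hit multitarget survival model

Survival after an absorbed dose $D$ (Gy) is modelled as

$$S(D) = 1 - \left(1 - e^{-D/D_0}\right)^m,$$

the classical radiobiology form in which a cell dies when all $m$ targets
are hit, and $D_0$ (Gy) is the dose reducing survival to $1/e$ on the
exponential limb. Two derived summaries matter for mutation breeding:
the shoulder dose $D_q = D_0 \ln m$, where the flat shoulder of the curve
ends, and the LD50, which has the closed form
$-D_0 \ln(1 - 0.5^{1/m})$.

`fit_multitarget()` minimises the residual sum of squares on the linear
survival-fraction scale. The experimental description pins down only
"least squares", so the scale was an open choice: the linear scale is
defined for fractions of exactly 0 or 1 (a semilog transform is not), and
is therefore the default; the classical alternative --- regressing
$\log S$ on dose over the terminal limb and reading $m$ off the
back-extrapolated intercept --- is available as `method = "semilog"`.
Replicates are averaged to one fraction per dose before fitting
(`weight_replicates = TRUE` pools counts instead; the two agree whenever
replicate sizes are equal).

Numerics: a coarse grid ($D_0$ over $[\max D/20, \max D]$ in 50 steps,
$m$ log-spaced in $[1, 1000]$ in 20 steps) seeds Nelder--Mead
(`reltol` $10^{-15}$) followed by an L-BFGS-B polish with box constraints
$m \in [1, 1000]$ on the log scale. On noiseless model-generated data the
round trip is exact to better than $10^{-6}$ relative error (tested). The
fit refuses ill-posed inputs: fewer than three distinct doses, no dose
with survival above 0.8, or none below 0.5.

`solve_from_dq_ld50()` inverts a printed $(D_q, \mathrm{LD50})$ pair:
the ratio $\mathrm{LD50}/D_q = -\ln(1-0.5^{1/m})/\ln m$ is strictly
decreasing in $m$ (from $+\infty$ at $m \to 1$ to $\approx 1.05$ at
$m = 1000$), so `uniroot()` on $[1.0001, 1000]$ finds the unique $m$, and
$D_0 = D_q/\ln m$. Pairs whose ratio falls outside that range are
rejected as inconsistent.

## The threshold-burden model

The qualitative hypothesis linking survival to mutation load is made
generative: irradiation at dose $D$ gives each individual a mutation
burden $X$ drawn from a right-skewed distribution with linear-scale mean
$\kappa D$ and constant coefficient of variation $c_v$; the individual
survives iff $X < T$, a fixed tolerable burden. Survival is then
$P(X < T)$ and the survivor mean burden is the truncated mean
$E[X \mid X < T]$, which saturates toward $T$ as dose rises while
survival keeps falling.

Design choices, all open in the verbal model and fixed here:

* **Family: lognormal** with $\sigma^2 = \ln(1 + c_v^2)$ and
  $\mu(D) = \ln(\kappa D) - \sigma^2/2$, so the linear-scale mean is
  exactly $\kappa D$. The lognormal gives closed-form truncated means
  ($E[X]\,\Phi(z-\sigma)/\Phi(z)$ with $z = (\ln T - \mu)/\sigma$); a
  gamma family with the same mean/CV is available behind
  `family = "gamma"`. Nothing in the data identifies the family.
* **Mean linear in dose**, no saturation term --- the simplest form
  consistent with burden rising with dose.
* **Sharp threshold** (step survival), matching the verbal model; no
  soft selection.
* **Defaults**: $\kappa = 0.08$ mutations/genome/Gy (so a
  $\sim$1000 Gy exposure carries a mean burden near the $\sim$80
  mutations per genome seen in sequenced survivors) and $c_v = 0.5$.

`calibrate_threshold_model()` maps a fitted $(D_q, \mathrm{LD50})$ onto
the model. Survival depends on dose only through $T/(\kappa D)$, so with
$c_v$ fixed only one dose can be matched exactly; the calibrator places
$T$ at the median burden of the LD50 dose (survival exactly 0.5 there).
With `match_shoulder = TRUE` the remaining degree of freedom is spent
instead of left to the user: $\sigma$ solves
$\Phi(\ln(\mathrm{LD50}/D_q)/\sigma) = S(D_q)$ so that shoulder-dose
survival also matches the multitarget curve.

The model's headline qualitative behaviour --- the mutation gained per
unit of survival lost, $(\Delta \bar X)/(-\Delta S)$, is smaller across
the shoulder$\to$LD50 step than across the
$\tfrac{2}{3}$shoulder$\to$shoulder step --- is asserted by the tests for
the calibrated configuration. Degenerate constant-survival steps yield
`NaN` gain ratios with a warning rather than a division by zero.

## Small-mutation classification

* **Zygosity** from the mutant-read fraction: $\ge 0.80$ homozygous,
  $[0.25, 0.80)$ heterozygous, below 0.25 uncalled. The boundaries are
  inclusive exactly as stated by the calling protocol.
* **Ti/Tv**: purine$\leftrightarrow$purine and
  pyrimidine$\leftrightarrow$pyrimidine changes are transitions.
* **InDel length classes**: 1 bp, 2--9 bp, 10--99 bp; $\ge$ 100 bp
  belongs to SV handling. VCF-style anchored alleles are accepted.
* **Junction context**: the protocol gives no definitions, so common
  conventions are used and exposed as knobs: a homopolymer is a
  single-base run $\ge 3$ bp formed by the allele plus adjacent bases; a
  polynucleotide repeat is a tandem tract with unit 2--6 bp and $\ge 2$
  full copies that contains the allele and extends into at least one
  flank. Homopolymer takes precedence. Flanks of $\ge 10$ bp per side are
  required.
* **Coding consequence** against single-transcript gene models
  (non-overlapping CDS intervals, in-frame, ATG start): SBSs are
  classified by translating the affected codon (silent / missense /
  premature stop; start loss in codon 1), InDels by whether the number of
  CDS bases gained or lost is a multiple of 3. A substitution in the
  terminal stop codon is reported as missense (there is no stop-loss
  category); UTRs, splice sites and multi-transcript annotation are out
  of scope. The test suite checks every call against an independent
  oracle that rebuilds and translates the whole mutant CDS.
* **Per-bp frequencies** are defined as
  count / (genome length $\times$ individuals). Published per-bp
  frequencies in this field are sometimes printed on scales that cannot
  be reconstructed from counts and genome size alone; radmut documents
  its own definition and makes no attempt to match any other scale.

## SV junction reconstruction

An inversion of reference segment $[b_1, b_2]$ yields
$R[1..b_1-1] \,\|\, \mathrm{revcomp}(R[b_1..b_2]) \,\|\, R[b_2+1..]$.
If a tract $M$ of length $L$ satisfies
$R[b_1..b_1+L-1] = \mathrm{revcomp}(R[b_2-L+1..b_2])$, then for every
shift $k \in [0, L]$ the breakpoints $(b_1+k, b_2-k)$ produce the
*identical* product (write the segment as $M \cdot m \cdot
\mathrm{rc}(M)$; the product is $A\,M\,\mathrm{rc}(m)\,\mathrm{rc}(M)\,B$
for every $k$). That $L$ is the event's microhomology --- one number per
inversion, which is how validated junctions are reported.

`analyze_junction()` aligns product to reference by maximal exact
extension from the two outer anchors (which must match for $\ge 20$ bp;
otherwise the product is inconsistent with the hypothesis), locates the
inverted block via a unique 20-mer seed in the reverse-complemented
reference, and then searches breakpoint pairs near the block bounds for a
microhomologous tract consistent with the observed extensions. Deletions
are split into *on-overlap* (tract bases missing from the product) and
*adjacent* (non-tract bases missing at either junction); unattributable
product bases are the junction insertion.

Identifiability is the central numerical subtlety. For clean junctions
the anchor extensions pin the tract uniquely. Once end-processing has
deleted the junction ambiguity, every placement of the tract inside the
deleted window explains the product equally well --- the total deletion
is constant across placements --- and chance 2-bp inverted repeats inside
such windows are common in random sequence. The analyzer therefore
prefers the placement nearest the case's nominal breakpoints (which any
SV caller supplies), then the longest tract, then the least total
deletion, and raises an `"ambiguous junction"` error listing candidates
only when genuinely distinct placements tie exactly. Repeat-containing
anchors likewise error rather than guess, mirroring what manual curation
of Sanger traces would refuse to call.

Classification conventions:

* reportable microhomology starts at 2 bp (a single shared base is
  uninformative);
* `mh_length` is the tract length in the *original* molecule ---
  junction tables count an event as "with overlapped sequence" even when
  the overlap was partially deleted in the product --- while `mh_seq` /
  `mh_retained` give the portion still present;
* archetypes: **A** no microhomology; **B** microhomology, no deletion;
  **C** microhomology with deletions of a few nucleotides (every
  adjacent deletion $\le 10$ bp); **D** microhomology with an adjacent
  deletion $> 10$ bp. A report with a large on-overlap deletion but no
  adjacent deletion is classed C: on-overlap loss is bounded by the
  tract length, and the 10-bp rule concerns resection *around* the
  tract;
* mechanism: microhomology with zero adjacent deletion implies breaks on
  or at the tract ends, i.e. microhomology-guided classical NHEJ
  (`cNHEJ-MH`) --- including events whose only deletions sit on the
  joined tract itself; adjacent deletions $> 10$ bp beside a tract are
  the MMEJ signature (`MMEJ-candidate`); everything else is compatible
  with plain `cNHEJ`.

Deletion junctions use the same two-anchor machinery with a
forward-orientation tract ($R[b_1..b_1+L-1] = R[b_2+1..b_2+L]$).
Duplication and translocation junctions are analyzed by presenting each
junction as a deletion-type case whose reference concatenates the donor
and acceptor flanks; complex multi-event reconstruction beyond paired
inversion junctions is out of scope.

## The synthetic-data generator

The generator emulates the *outputs* of the sequencing pipeline, not the
reads: called-variant tables, survival assays and junction cases, each
with retained ground truth. Defaults are the study conditions: the proton
survival curve ($D_0 = 632.16$ Gy, $m = 3.2961$, i.e. the parameters
consistent with a 754 Gy shoulder and 1051 Gy LD50) assayed as 4
replicates of 50 seeds on the 113.7--1188.4 Gy proton dose grid; 40x
read depth (the assays averaged $\sim$47x) with binomial read-fraction
sampling at $p = 1$ (hom) or $0.5$ (het) and no overdispersion --- the
simplest model that exercises the 0.25/0.80 thresholds; a mutation mix of
68% SBS and deletions $4\times$ more frequent than insertions;
microhomologies of 2--23 bp and adjacent junction deletions of 1--61 bp,
the ranges seen at validated junctions; and a junction archetype mix
weighted (A, B, C, D) = (3, 12, 6, 4) after the validated inversion set.

Junction references are rejection-sampled until the planted structure is
the only alignment the reference supports: exact outer anchors of the
planted length, no chance extension of the planted tract or block
boundaries, and a unique block seed. This screening is what makes exact
recovery a designed invariant of the generator/analyzer pair; the tests
then verify 100% recovery of planted microhomology, deletions and
insertions across hundreds of randomized cases.

What passing these tests shows: the algebra and algorithms are correct on
data that satisfy the generative assumptions. What it does not show:
robustness to overdispersed read counts, mapping artefacts, repetitive
genomes (Arabidopsis-like composition is emulated only through GC content
and gene density), multi-event rearrangements, or miscalled breakpoints
far from the truth.

## Problem sizes and reproducibility

The packaged analyses run at desk scale: 100 kb genomes with a few dozen
genes, 200-variant call sets, tens to hundreds of junction cases,
$10^5$-draw Monte Carlo checks of the threshold-model closed forms (3
standard-error agreement), and survival fits on 10--16 dose grids. Every
stochastic step takes an explicit integer seed, and identical
configuration plus seed reproduces outputs bit for bit. The published
summary tables travel with the package as plain TSV fixtures; three
printed fragment sizes disagree with their own breakpoint coordinates by
more than the tables' 0.1 kb rounding and are flagged
(`size_consistent`) rather than silently corrected, and printed
gene-impact totals are reproduced from their components to within the
0.01 rounding of the published means.
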