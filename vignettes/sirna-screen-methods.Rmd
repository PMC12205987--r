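---
title: "Models and methods behind siRNAscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind siRNAscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siRNAscreen)
```

# The problem

Fully chemically modified siRNAs silence a target mRNA through RISC, but
observed efficacy mixes two kinds of causes: properties of the duplex
itself (sequence, modification pattern, structure) and properties of the
native target transcript (which isoforms are expressed, which
polyadenylation site is used, how heavily the mRNA is translated).
`siRNAscreen` implements the computational side of a screening workflow
that separates these causes: target-site design, normalization and QC of
plate screens in both a *native* (endogenous mRNA) and a *reporter*
(luciferase fusion) context, transcript-context analysis from 3'-end tag
and coverage data, positional thermodynamic comparisons, and a
random-forest sequence classifier scored by a prevalence-adjusted
precision--recall area.

# Target-site design

All possible 20-nt target sites of a merged transcript are enumerated
(`enumerateCandidates()`) and filtered (`filterCandidates()`) in a fixed
order, with the first failing rule recorded:

1. **GC content** — a site with GC fraction $\ge 0.60$ is removed
   (12 of 20 fails; 11 of 20 passes). High GC impairs silencing.
2. **Homopolymers** — `CCCC` or `GGGG` stretches are removed for
   synthesis reasons.
3. **Off-target homology** — the 16-mer at target positions 4--19
   (complementary to guide positions 2--17, the region that licenses
   Ago2 cleavage) must not occur exactly, in sense orientation, in any
   other gene's transcript. This is an exact transcriptome match by
   design: it is the minimal faithful reading of the rule, and
   mismatch-tolerant or seed-based off-target prediction is out of
   scope.

Three panel strategies are implemented: the primary panel
(`selectOriginalPanel()`: every 50th remaining sequence plus all
`AAUAAA`-containing sequences, from which a 48-site panel with a 5-site
poly(A)-signal quota is drawn), a *walk around hits*
(`designWalk()`: new starts within $\pm 10$ nt of an effective start at
2-nt steps, the seeding start excluded) and a *3'-UTR-selective* panel
(`designUtrSelective()`: 3'UTR sites ending before the first poly(A)
site, every other survivor kept). The wording "every 50th remaining
sequence" admits a second reading ("spaced at least 50 nt apart"); the
package implements the list reading and exposes the spacing as a
parameter. Guides are plain reverse complements
(`guideFromTarget()`); modification patterns are annotation only and
never enter sequence computations.

# Screen processing

Raw two-channel plate signals become percent-of-untreated expression via

$$\mathrm{percent} = 100 \cdot
  \frac{(S - \bar B)\,/\,(N - \bar B_N)}
       {\overline{\left[(S_u - \bar B)/(N_u - \bar B_N)\right]}},$$

with blank means subtracted from both channels, the normalization
control in the denominator, and untreated wells defining 100 %
(`normalizePlate()`). Negative numerators clamp to 0; a nonpositive
normalization denominator marks the record invalid. Replicates then pass
a single two-sided Grubbs test at $\alpha = 0.2$ (`grubbsFilter()`,
critical value from the $t$ formula; at most one value removed per
record, matching the named single-outlier test), and summaries cap
values at 100 % before the mean and SD (`summarizeRecord()`). Capping
only affects values above 100, so it can never change a label, which is
why the order of capping and QC is immaterial for classification.

Classification is trichotomous (`classifyHit()`): mean expression
$\le 35\%$ is *effective*, $> 55\%$ *ineffective*, anything between
*undefined*. A scaffold pair is *permissive* when both means are
$\le 35\%$ and *restrictive* toward the silencing scaffold when the
other mean exceeds 50 % (`classifyScaffoldPair()`). The 15-point gap
between the effective and restrictive cutoffs exceeds the assays'
average replicate SDs (~9--11.5 %), which is what makes the pair calls
robust to noise. Hit rates are compared by Fisher's exact test
(`compareHitRates()`), assay agreement by Pearson correlation
(`assayCorrelation()`), and dose-response candidates selected by the
union of three criteria (best responders $\le 30\%$, per-scaffold top
decile $\le 40\%$, cross-scaffold range $\ge 20$ points below 60 %).

**Hotspots** (`findHotspots()`) chain effective start sites
transitively while consecutive starts are within 50 nt; every chain of
two or more hits spans an interval from 15 nt before the first start to
35 nt after the last (the 20-nt site plus a 15-nt flank — the same
50-mer context used everywhere else). A single isolated hit never forms
a hotspot: the defining phrase "hit 1 ... hit 2+" implies a pair.

# Transcript context

`mergeIsoforms()` builds one merged "transcript" per gene by widening
overlapping exons to their most extreme annotated bounds and
concatenating the blocks 5'→3'; region extents (5'UTR/ORF/3'UTR) are
likewise the most extreme across isoforms (`assignRegions()`), and a
site is assigned to a region by its start with 5'→3' priority at shared
boundaries. `consensusFromAligned()` marks positions where prominently
expressed isoforms (those carrying $\ge 5\%$ of reads — the convention
used for "expressed") disagree with `?`; `common50mer()` reads the
15 + 20 + 15 window from that consensus, flagging truncation at
transcript ends.

**Poly(A) sites** (`callPolyASites()`) are consolidated greedily from
the highest-count tag position outward: positions within 20 nt of an
already-founded site merge into it. A consolidated site qualifies when
it carries $\ge 10\%$ of the gene's tags and at least one merged
position shows a terminal 3' adenosine run of $\ge 4$ (the evidence
that a tag marks a real cleavage/polyadenylation event rather than
internal priming). The prose rule is ambiguous about whether the 10 %
threshold applies before or after consolidation; the default is
merge-then-threshold, with `mode = "threshold_first"` exposing the
alternative (the two agree on all worked examples in the test suite).

Sites are flagged *unexpressed* (`flagUnexpressedTargets()`) when their
20-mer is absent from every prominently expressed isoform or their
start lies downstream of the 3'-most qualified poly(A) site — such
sites can look RISC-competent in a reporter yet cannot silence the
expressed mRNA. Translation efficiency is the plain TPM ratio
`ribo_tpm / rna_tpm` (`ribosomeDensity()`), and coverage tracks
normalize by mapped reads in millions (`normalizeCoverage()`).

# Thermodynamics

`stackingProfile()` assigns each adjacent nucleotide pair (1--2, 2--3,
..., $L{-}1$--$L$) its nearest-neighbor Watson--Crick helix-propagation
free energy $\Delta G^\circ_{37}$, from an editable table shipped in
`inst/extdata/stacking_dg37.tsv` (the canonical Xia/Turner parameter
set; substitute any published set with the same 16-dinucleotide
schema). Only stacking terms are used — no initiation, terminal-AU or
dangling-end corrections — because the quantity of interest is a
*positional profile*, one value per pair, not a duplex folding energy.
Pairs touching a `?` are missing.

`groupDdg()` compares two sequence groups position by position:
$\Delta\Delta G^\circ_{37}(i) = \overline{\Delta G}_A(i) -
\overline{\Delta G}_B(i)$, with a per-position two-sample $t$-test
(Welch by default — the unequal-variance form is the safer default when
group sizes differ; a flag restores the pooled test) and
Benjamini--Hochberg correction across positions. Note the sign
convention: AU-rich (less stable) contexts have *less negative*
stacking energies, so destabilization of group A appears as a
**positive** $\Delta\Delta G$. `frequencyShift()` gives the per-position,
per-base frequency differences with Fisher exact tests. Profiles default
to the 50-mer window used in the figures; a 20-mer mode covers the
methods-text variant. Robustness variants of the ineffective cutoff
(60 %, 70 %) are plain threshold arguments.

# The efficacy classifier

Windows are one-hot encoded (`encodeWindow()`): per position
`A=[1,0,0,0]`, `U=[0,1,0,0]`, `C=[0,0,1,0]`, `G=[0,0,0,1]`, and `?`
contributes a zero block, preserving the fixed
$4 \times 50 = 200$-dimensional feature space while carrying no base
information — the vector mechanics for "excluded from analysis" that
keeps every example the same length. Undefined-class examples are
retained in tables but excluded from fitting and evaluation (the PR
framing is binary).

The forest (`trainForest()`, via `randomForest`) uses 200 trees, depth
$\le 3$ (enforced as $\le 8$ terminal nodes) and one sample per leaf;
the score is the fraction of trees voting *effective*. The assessment
protocol (`repeatPipeline()`) repeats, under one master seed: a
stratified 85/15 train/holdout split (`splitBalanced()`), stratified
10-fold cross-validation on the training set (`kfoldAssign()`), a final
fit, and holdout evaluation.

**AUCPR_adj.** The PR curve is traced over decreasing score thresholds
with ties collapsed into one threshold group, and the area accumulated
stepwise, $\mathrm{AUCPR} = \sum_i (R_i - R_{i-1}) P_i$
(right-continuous interpolation; the degenerate cases pin the
convention — a perfect ranker gives area 1, constant scores give the
prevalence). Because precision at maximum recall equals the
positive-class prevalence, subtracting that rectangle,
$\mathrm{AUCPR_{adj}} = \mathrm{AUCPR} - \pi$, makes scores comparable
across datasets with different hit proportions: a perfect ranker
scores $1 - \pi$, an uninformative one 0. `undersamplePositives()`
supports the prevalence-matching control. One caveat the package's own
null tests quantify: stepwise average precision has a positive
small-sample bias on tiny evaluation sets (a few positives in a
27-example holdout biases the null upward by ~0.1), so null
calibrations here use evaluation sets of several hundred examples,
where the bias is below 0.05.

# The synthetic-data generator

`simConfig()`/`simulateStudy()` generate a fully known study so every
stage is testable without downloads. Defaults describe the screening
conditions the pipeline is built for, chosen once:

* **4 genes**, merged transcripts with 5'UTR (100--180 nt), ORF
  (700--1100 nt) and 3'UTR (900--1400 nt); four exons of which the
  second, inside the ORF, is alternative; two isoforms, the minor one
  (20 % of expression, `isoform_dilution`) skipping it; rare isoform
  SNPs (rate 0.002) drive `?` consensus positions.
* **Two poly(A) sites** in the 3'UTR with 70/30 usage and planted
  `AAUAAA` motifs ~30 nt upstream.
* **Three planted hotspots per gene** of width 240 nt: two in
  constitutively expressed regions, one downstream of the first
  poly(A) site, where dilution masks native efficacy. Hotspot intervals
  receive AU-rich sequence (A/U fraction 0.75) — effective regions carry
  the thermodynamically less stable, accessible context that real
  effective sites show, which is also what gives the sequence
  classifier a learnable signal. This coverage reproduces the screen's
  observed hit-rate scale (reporter ≈ 35--40 %, native ≈ 10--16 % for
  the permissive scaffold).
* **Ground-truth expression**: reporter truth reflects RISC competence
  only (hotspot sites ~10--30 %, others ~55--95 %). Native truth
  composes it one-sidedly with a per-site inaccessibility factor
  $\ge 1$ (lognormal, SD 0.5) and the fraction $d$ of expression
  lacking the site: $\mathrm{native} = 100\,d + (1-d)\min(100,
  \mathrm{reporter}\cdot f)$. A site absent from all expressed
  transcripts therefore floors at 100 % — silencing is impossible —
  while reporter truth is untouched, reproducing the one-sided
  reporter/native asymmetry.
* **Scaffolds**: a permissive and a restrictive pattern; the
  restrictive one adds +30 percentage points on a designated 60 % of
  sites, yielding scaffold-restrictive pairs at the screen's scale.
* **Noise**: Gaussian on the percent scale, SD 10 (the assays' average
  SDs are 9.1--11.5 %), truncated at 0, three replicates, with blank,
  untreated and normalization wells emitted so normalization is
  exercised end to end. At SD 0 the pipeline recovers truth exactly.
* **Tags and coverage**: multinomial 3'-end tags with 2-nt jitter and
  terminal-A evidence at genuine sites; coverage tracks follow the
  isoform mixture; TPM tables encode translation efficiency exactly
  (defaults 2.6/1.6/1.0/0.6 across the four genes).

What the generator does **not** emulate: read-level sequencing error,
alignment artifacts, secondary structure, seed-mediated off-targeting,
plate position effects, or any real correlation structure between
sequence and chemistry beyond the planted AU signal. Passing recovery
tests therefore demonstrate that the pipeline's inference is correct
under its own model, not that the biological effect sizes are
predictive for real screens.

# Numerical choices and problem sizes

Coordinates are 1-based inclusive everywhere; BED-like exports convert
to 0-based half-open at the writer. Hotspot recovery is checked against
reporter-context hits, since the planted truth is defined by RISC
competence and one planted hotspot is deliberately invisible to the
native assay. Default test problem sizes — a ~190-site panel for
recovery checks, a ~540-site panel and 200 repeats for the null
calibration, 50 repeats for holdout summaries, 10 000 tags per gene —
were chosen to put Monte-Carlo error comfortably below the tolerances
being asserted. Ties in PR scoring are one threshold group; Grubbs is
skipped below three replicates or at zero variance; region assignment
at shared boundaries is 5'→3' priority.

# Known limitations

The homology filter is an exact 16-mer match, not an alignment; the
restrictive-scaffold mechanism is a flat additive penalty; the walk
panel is starts-only (filtering happens downstream); and the
random-forest analysis inherits the small-sample bias of average
precision on very small holdouts, which is why reported averages come
from repeated segmentation and null-calibrated evaluation sizes.
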