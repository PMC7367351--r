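---
title: "Quantifying cardiac rhythm and CRISPR dosage effects in zebrafish embryos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cardiac rhythm and CRISPR dosage effects in zebrafish embryos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beatcall)
```

beatcall implements a forward-genetic screening pipeline for zebrafish
embryos: video recordings of the beating atrium are converted into heart
rate, heart-rate-variability (HRV) metrics and sinoatrial pause/arrest
calls; deep amplicon sequencing of CRISPR/Cas9-targeted sites is converted
into allele-specific variant calls and impact-weighted dosage scores; and
the two are joined in mutually adjusted association models. This vignette
explains the models behind each stage, the tunable parameters, the
synthetic fixtures used to validate them, and the design decisions taken
where the underlying protocol leaves room.

## Cardiac quantification

A recording is a stack of grayscale frames (nominally 30 s at 152
frames/s) showing the atrium of an anaesthetised embryo. The pipeline is
template correlation: each frame is flattened to a pixel vector and
Pearson-correlated with a fixed template frame. Because the heart's motion
is periodic, the correlation trace is periodic with the cardiac cycle, and
its peaks mark the times at which the heart revisits the template's phase.

**Template selection.** Among the first 100 frames, the pair with the
lowest mutual correlation captures the two opposite extremes of the cycle
(end-systole vs end-diastole). One member must become the template. The
two are not interchangeable in practice: an end-diastolic template
produces a trace that sits on a flat plateau near 1 for the whole
diastolic interval (diastole occupies a large fraction of the cycle and
diastolic frames are nearly identical), which leaves peak timing
ill-defined. The package therefore picks, within the minimum-correlation
pair, the frame with the *lower mean correlation to the rest of the
window*: the systolic extreme is brief and rare among frames, so it
correlates poorly with the bulk of the window, and a systolic template
yields one sharp correlation peak per beat, aligned with the beat itself.
Ties break toward the earlier frame. Zero-variance frames are defined to
correlate 0 with everything; an all-constant window is rejected as a
degenerate recording.

**Peak detection.** The trace is smoothed with a 5-frame centred moving
average; local maxima are kept if their topographic prominence is at least
30% of the smoothed trace's range and they are at least 0.15 s apart
(a refractory bound corresponding to 400 beats/min, above any credible
embryonic rate). These defaults are exposed as arguments; they were chosen
so that ground-truth beat times of rendered fixtures are recovered across
the physiological range (RR 0.25–0.6 s) at pixel-noise levels up to 10%
of the signal amplitude. Timing is two-stage: peaks are *detected* on the
lightly smoothed trace, then *timed* on a matched-filter version (moving
average scaled to ~15% of the inter-beat interval) with parabolic
sub-frame interpolation. Light smoothing keeps distinct beats separable;
the heavier, IBI-scaled smoothing suppresses pixel-noise wobble on broad
correlation peaks, taking the timing quantisation from ~6.6 ms at 152
frames/s to well under a millisecond — which is what makes SDNN meaningful
on low-jitter recordings.

**Gap classification.** With inter-beat intervals (IBIs) in hand, a gap
longer than 2 s is a sinoatrial *arrest*; otherwise a gap longer than 3x
the embryo's median IBI is a sinoatrial *pause*. Arrest takes precedence
when a gap satisfies both definitions, and each gap yields exactly one
event. Flagged gaps are removed from the normal-to-normal (NN) set, which
is kept as contiguous segments so that successive-difference statistics
never span a gap.

**Metrics.** Heart rate is `60 / mean(NN)` beats/min — the inverse of the
mean RR interval, the standard HRV-field convention, which is stable under
jitter (the alternative, averaging per-interval rates, is biased upward by
Jensen's inequality). SDNN is the population standard deviation of the NN
intervals; using the population rather than sample convention changes the
value by under 1% at the ~70 beats of a standard recording, and the choice
is recorded in the output (`sd_convention`). RMSSD is the root mean square
of successive NN differences within segments. Both are reported in
milliseconds. The composite HRV endpoint is the average of SDNN and RMSSD,
which are strongly correlated in this preparation. For i.i.d. Gaussian RR
jitter the RMSSD/SDNN ratio tends to sqrt(2), a property the test suite
checks on synthetic NN arrays.

**Missed-beat QC.** A missed beat manifests as an interval near twice the
typical one. Recordings are flagged `suspect_missed_beat` when any NN
interval falls in (1.7x, 3x] the median IBI, or when more than 5% exceed
1.7x the median. This automates a quality-control step that was originally
a manual review of the correlation graphs; true pauses are excluded from
the NN set before the check so they do not trigger it.

## Synthetic recordings

Fixtures are generated from a known beat schedule: RR intervals are drawn
i.i.d. as `mean_rr + N(0, rr_jitter_sd^2)`, truncated below at
`0.1 * mean_rr` to stay physical, with optional gap events splicing a
pause/arrest of chosen length after a chosen beat. No RR autocorrelation
is modelled — the quantifier makes no use of RR dynamics, so i.i.d. jitter
is the simplest structure that exercises it. Frames render the atrium as a
soft-edged filled ellipse whose radius follows a raised-cosine contraction
pulse of width 0.6x the median RR centred on each beat (any smooth
unimodal pulse would do; the raised cosine guarantees distinct
systole/diastole frames and a smooth correlation trace), plus i.i.d.
Gaussian pixel noise. The first beat falls at t = 0 and beats are kept in
`[0, duration)`; a 30-s schedule at RR 0.4 s therefore holds 75 beats and
74 observed intervals.

What the fixtures do *not* emulate: optics and point-spread realism,
ventricular motion, drift, photo-bleaching, or the manually annotated
morphological abnormalities of real screens. Passing the recovery tests
shows the quantifier is correct on its own model of the data, not that it
is robust to every artefact of real microscopy.

Fixture recovery is judged against the generated truth: heart rate within
1% across RR 0.25–0.6 s, SDNN within 25% of the generated NN SD with a
1.5 ms absolute floor — a quarter frame at 152 frames/s, the a-priori
timing resolution of frame-locked peak estimates, which matters only for
near-zero-jitter schedules where a purely relative tolerance degenerates.

## Allele-specific amplicon calling

Each embryo x target yields merged amplicon reads spanning a 100–400 bp
wildtype reference with a known Cas9 cut site. The caller proceeds:

1. **Global alignment** of each unique read sequence to the reference
   under affine-gap scoring (match +2, mismatch −3, gap open −6 for the
   first base, −1 per additional base) by a Gotoh dynamic program in C++.
   Merged amplicon reads span the full reference, so global (not local)
   alignment is appropriate and soft-clipping is unsupported. Tie-breaks
   are deterministic: substitutions preferred over gaps, deletions over
   insertions, equivalent gaps placed leftmost. `N` matches nothing and
   scores as a mismatch. Reads scoring below −0.5x their length are
   discarded as unmappable and counted.
2. **Haplotype clustering**: reads are grouped by their implied variant
   set within ±30 bp of the cut site; groups supported by at least
   `max(5 reads, 10% of reads)` survive. One surviving group is a
   homozygous call (recorded as two identical alleles), two a heterozygous
   call; more than two passing groups is a missing call (`ambiguous`),
   none a missing call (`low support`). The thresholds are not dictated by
   the protocol; they were chosen so that 1% per-base error cannot spawn a
   phantom allele at depths up to ~500 (a spurious cluster would need 5+
   reads with identical errors), and they are configurable. F1 embryos
   carry exactly two alleles; mosaic F0 genotypes are out of scope. A
   consequence of accepting single-cluster calls as homozygous is that
   true allele dropout (one allele's amplicon failing, e.g. through a
   large deletion) presents as homozygosity — a recorded limitation.
3. **Variant extraction**: variants are read off the alignment operations,
   left-normalised and anchor-based following the VCF convention, kept
   only if the nearest *affected base* lies within ±30 bp of the cut site
   (the inclusive reading of the window; measuring from the anchor would
   silently shift the boundary for indels), and filtered against a
   blacklist of naturally occurring variants.
4. **Consequence annotation**: indels with length change not divisible by
   3 are frameshift (HIGH impact); divisible by 3, in-frame (MODERATE).
   SNVs are translated in the annotated reading frame — on the
   reverse-complemented sequence for minus-strand targets — giving
   stop_gained or stop_lost (HIGH), missense (MODERATE) or synonymous
   (LOW). Variants without a complete codon in the amplicon are noncoding
   (MODIFIER). Impacts map to weights 1 / 0.66 / 0.33 / 0; the MODIFIER
   weight of 0 extends the three-tier scheme downward, synonymous being
   the lowest tier with a stated weight.
5. **Dosage**: per allele the maximum variant weight (0 if wildtype), then
   the sum over the two alleles — a score in [0, 2] that weighs the number
   of mutated alleles by their predicted functional impact.

Read fixtures are full-length copies of two constructed haplotypes with
uniform allele choice and i.i.d. substitution errors (indel sequencing
errors are off by default to keep haplotype clusters crisp; base
qualities are constant because the caller does not use them). Read names
encode the true allele, so tests can score genotype recovery exactly.

## Association models

Dosage scores for all targeted sites enter one model as independent
exposures — mutually adjusted — together with time-of-day and batch (and
experiment) fixed effects: linear regression for continuous outcomes,
logistic for the presence of sinoatrial pauses. Continuous outcomes are
first rank-transformed to normality (Blom offsets:
`qnorm((rank - 3/8)/(n + 1/4))`, average ranks for ties), so effect sizes
read as z-scores. Wald 95% intervals and p-values are reported; collinear
dosage columns are dropped with a warning, and logistic fits with
implausible standard errors are flagged as possible separation rather than
crashing.

The original design nested embryos in batches and experiments as random
effects; with only a handful of batches, random-effect variances are
weakly identified, so the package deliberately uses batch/experiment
fixed-effect indicators instead and records the divergence in the model
descriptor (`_fixed_batch_effects`). Time of day is taken as a continuous
covariate when numeric, categorical otherwise; data from multiple
experiments pool raw rows with an experiment indicator.

The "2 vs 0" contrast compares embryos carrying HIGH-impact (nonsense:
frameshift or stop-gained) variants on *both* alleles of a gene with
embryos free from induced variants at that site, adjusting for the other
genes' dosages; it refuses to fit (returns `not_testable`) when fewer than
five embryos qualify for the both-alleles group, matching the screening
rule. Missingness follows the same protocol: embryos with more than two
missing site calls are excluded, the remaining missing entries imputed to
the per-target mean over called embryos (which conserves the per-target
mean). A one-degree-of-freedom chi-square checks genotype counts against
Hardy–Weinberg proportions, as used to confirm that nonsense mutations are
not lethal across the observation window.

Cohort fixtures draw genotypes binomially at chosen mutant allele
frequencies and generate phenotypes from the same additive linear/logistic
structure the models assume. The default baseline pause probability is
10%: the fixed-effects logistic model implemented here corresponds to the
single-experiment F1 screening design, whose 2-dpf cohort showed ~13%
pause prevalence overall; a 10% dosage-0 baseline reproduces that margin
once dosage effects are included. (The lower ~7% prevalence of pooled
multi-experiment data belongs to the mixed-model analyses this package
deliberately does not reimplement.) Test
conditions mirror the screen's scale: coverage of the pause log-odds
effect (ln 2.5 per dosage unit) at n = 700 over 100 replicates, type-I
error pooled over nine null genes at n = 300 over 200 replicates, and
linear effect recovery (0.3 SD per unit) at n = 300. No multiple-testing
correction is applied, matching the screening convention of nominal
p < 0.05.

## qPCR

Relative expression uses the Pfaffl ratio
`E_t^(Cq_cal,t − Cq_s,t) / E_r^(Cq_cal,r − Cq_s,r)` with per-gene
amplification efficiencies, an uninjected-control calibrator and a
reference gene. Technical triplicates are averaged before the ratio, with
a warning when replicate SD exceeds 0.5 cycles. Condition contrasts are
fit by linear regression with a batch fixed effect, on the log scale by
default for variance stability (the raw scale is retained as an option,
since the upstream protocol does not state which was used).

## Numerical choices and degenerate inputs

- Correlation of a zero-variance frame is defined as 0 (with a warning in
  the trace); an all-constant stack errors as a degenerate recording.
- Fewer than two detected peaks yields a phenotype flagged
  `too_few_beats` with missing metrics, not an exception; SDNN/RMSSD
  additionally require three NN intervals.
- Peak prominence at the stack boundary uses the interior side only, so
  the first/last beats of a recording are not discarded.
- The aligner's scores are integer-valued under the default scoring, so
  floating-point ties in traceback are exact.
- Monomorphic genotype tables return Hardy–Weinberg p = 1 by convention.
- All generators and the pipeline flow their randomness from explicit
  integer seeds; identical seeds give bit-identical schedules, stacks,
  read sets and CSVs.

## Problem sizes

The validation suite runs entirely on synthetic data at sizes chosen to
exercise the statistical properties it asserts: twenty 30-s recordings at
152 frames/s for rate/SDNN recovery; a 200-pair random panel (reads <= 12
bp, references <= 14 bp) for alignment-score optimality against an
independent recursive oracle; 200 simulated embryos at depth 50 and 1%
base error for genotype recovery; 100 cohort replicates at n = 700 for
logistic CI coverage and 200 at n = 300 for type-I error.

## Known limitations

- The quantifier assumes one dominant periodic structure; arrhythmias
  beyond pauses/arrests (fibrillation-like chaos, morphological
  abnormalities) are out of scope and were manually annotated in the
  original screen.
- Allele dropout masquerades as homozygosity (see above).
- Fixed-effect batch adjustment slightly understates uncertainty relative
  to a true nested random-effects fit when batch effects are large and
  batches many.
- Consequence annotation is a minimal coding classifier (no splice sites,
  no multi-transcript logic); it covers the variant classes that CRISPR
  indels and SNVs near an exonic cut site produce.
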