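---
title: "Methods: circadian proteomics and proteogenomic annotation refinement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circadian proteomics and proteogenomic annotation refinement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ProteoRhythm)
```

# The experimental design being modelled

Whole-animal samples are collected every 4 h from several staggered time
courses under a 12:12 light:dark cycle; time of day is expressed in
zeitgeber time (ZT), hours since lights-on. `makeTimeCourseDesign()`
defaults to three courses of 44, 36 and 28 h starting at ZT0, ZT0 and ZT16:
30 samples, exactly five biological replicates at each of the six ZT bins
0, 4, 8, 12, 16, 20, with ten animals pooled per sample. The start offsets
are the package's own choice — the sampling protocol fixes the durations and
the five-replicate target but not the offsets, and `starts = c(0, 0, 16)` is
the arrangement that balances all six bins. Note one bookkeeping subtlety
the design surface makes explicit rather than resolving: 4-h sampling over a
24-h day yields **six** ZT bins, even though the sampled day is sometimes
described as five times-of-day; all package defaults use six bins.

# The simulation model

No public raw data accompany this type of experiment at desk scale, so the
synthetic-data module defines the study conditions for every test. The
model is the minimal one that exhibits each phenomenon the analysis stages
measure:

* **Signal.** A rhythmic protein follows
  `baseline * (1 + A cos(2π (ZT − φ)/24))` with relative amplitude
  `A ~ U(0.3, 0.8)` and phase φ drawn from the 2-h grid; non-rhythmic
  proteins are flat. Baselines are lognormal (`meanlog log(5e5)`,
  `sdlog 1.5`), spanning the orders of magnitude typical of label-free
  intensity data.
* **Noise.** Multiplicative lognormal measurement noise,
  `exp(N(0, noiseSd))`, default `noiseSd = 0.25` (~25% CV, a mid-range
  value for label-free quantitation).
* **Dropout.** Each measurement is censored to "not detected"
  independently with probability `plogis((log m − log x)/s)` — a decreasing
  logistic in the true intensity x, 50% at the midpoint m (default: the
  median baseline) with log-scale width s = 1. Dropout acts on the raw
  intensity before normalization, because detection happens at
  acquisition. This reproduces the two diagnostic patterns the
  detectability stage quantifies: proteins seen at more times of day have
  higher average abundance, and a sizeable fraction of proteins is
  detectable only at one or a few ZT bins.
* **Fraction rhythmic.** Default `fracRhythmic = 0.2`: large enough that
  sensitivity and realized-FDR estimates have usable denominators at the
  simulation sizes used in tests, and of the order suggested by
  transcriptome-wide rhythmicity studies in insects.

What the generator does **not** emulate: correlated noise across proteins,
batch/run-order effects, missed-cleavage-dependent peptide response,
retention-time structure, or spectral interference. Passing tests therefore
demonstrate correctness of the algorithms under the stated model, not
robustness to every artifact of real LC-MS data.

Seeding: one master seed; each generator derives an independent sub-stream
via a counter-based split (`deriveSeed`), and all generators restore the
caller's RNG state, so identical arguments + seed give bit-identical
outputs anywhere in a session.

# Quantitation

Only 2+, 3+ and 4+ features are retained and only the five most intense
spectra per feature (`filterFeatures`). Normalization divides every
intensity by its sample's median summed-feature intensity and rescales by
the grand median of those medians (`normalizeFeatures`); the reference
level is the package's choice — it preserves the global intensity scale and
makes the operation idempotent. Medians are computed over features (summed
spectra), a documented and configurable choice.

Protein abundance is the sum of **unique** peptide ion intensities
(peptides mapping to exactly one protein; shared peptides are excluded —
standard label-free practice), transformed with `arcsinh(x) =
log(x + sqrt(x²+1))`. The inverse hyperbolic sine behaves like `log(2x)`
for large x but is defined and smooth at 0, which matters because
not-detected values are stored as raw 0 / transformed 0 with an explicit
`detected` mask and are never imputed. The order is sum-then-transform;
tests pin this, since transform-then-sum is not equivalent. Proteins with
fewer than two distinct component peptides are not quantifiable and are
dropped. Target-decoy FDR is `100·d/t`, rounded half-up to two decimals to
match conventional reporting.

# Detectability profiling

A protein is detectable at a ZT bin if detected in at least one replicate
at that bin (configurable to a stricter rule), pooling replicates across
courses. `detectionBreadth` counts bins per protein; `abundanceByBreadth`
computes per-protein means over detected samples only and groups them by
breadth; `peakTimeHistogram` assigns each ever-detected protein the bin of
its maximal mean detected abundance, breaking exact ties to the earliest ZT
with a logged flag. These are descriptive summaries; no test is attached,
by design.

# Rhythm detection

**Eligibility and prefilter.** Rhythm testing is restricted to proteins
detected at every ZT bin (≥ 2 detected replicates per bin; optionally ≥ 2
distinct peptides behind each sample where that assay is present). The
prefilter is the fixed-effects one-way ANOVA with ZT bin as the group
factor on transformed values, retaining p < 0.1. The F statistic is
computed vectorized across proteins with `stats::pf`; tests verify equality
with `stats::oneway.test(var.equal = TRUE)` per protein. A protein whose
replicates are identical within every bin but differ between bins is a
perfect time-of-day effect (F = ∞) and is retained with p = 0 — the
noise-free limit of the simulation exercises exactly this case; only
proteins with no variance at all are degenerate and excluded with a
reason.

**JTK_CYCLE.** For each lag on a 2-h grid over the 24-h period, the
reference ordering is `cos(2π(t − lag)/24)` converted to tied ranks
(replicates at a time point share a rank, as do time points whose cosine
values coincide). The statistic S counts concordant minus discordant pairs
over reference-untied pairs; data ties contribute zero (a tau-b-style
numerator, while the null assumes continuous data — a documented
approximation). The grid step is 2 h rather than the 4-h sampling interval
because estimated peak phases can fall between sampling times.

**Exact null.** Under exchangeability, the concordance count against a
tied reference is a Jonckheere–Terpstra statistic, distributed as the
convolution of independent Mann–Whitney null distributions over the
reference tie groups. The package computes the Mann–Whitney counts by the
classic conditioning recursion and convolves across groups — exact up to 60
observations (the default limit; the 30-sample default design is exact),
with a tie-corrected normal approximation with continuity correction
beyond. Exhaustive permutation enumeration verifies the pmf and tail
probabilities for every tie structure from up to four time points at
series length ≤ 8.

**Reported p and phase.** Per lag, the two-sided exact tail
`P(|S*| ≥ |S|)`; the reported p-value is the minimum over lags times the
number of distinct reference orderings (a reference and its reversal count
once, since two-sided tails make them equivalent), capped at 1 — a
Bonferroni bound, so under the null `P(p < α) ≤ α` (verified by
simulation). The phase is the lag attaining the minimum (ties: largest S,
then earliest lag); a constant series gets p = 1 and a missing phase. On
noise-free cosines sampled by the default design, the estimated phase
equals the planted phase exactly for all twelve grid phases.

**Calls.** Rhythmic ⇔ JTK p < 0.1 among ANOVA-passing proteins, with BH
q-values across the tested set (BH is the package's choice of q-value
method). Both the per-lag-Bonferroni p (the "ADJ.P"-style quantity) and
the BH q are reported, since either adjustment convention may be wanted
downstream.

# Proteogenomics

The workflow operates at the peptide-identification level (scored PSM
tables), not on spectra. Filtering keeps rank-1 collection hits with score
above the identity threshold; removes peptides with a target match of
identical score (exact equality by default — search-engine scores are
discrete — with a configurable absolute tolerance) or an I/L-equivalent
target match (isoleucine/leucine are isobaric); and removes peptides whose
only collection evidence is in excluded databases (e.g. a conspecific
strain). Exclusion is applied before grouping (configurable). Containment
grouping merges peptides where one is an I/L-equivalent substring of the
other, closed transitively; the representative is the longest member
(ties: lexicographically first, flagged).

Classification searches all six reading frames of all scaffolds under I/L
equivalence with precedence: perfect full-length hit inside an annotated
transcript in a different frame/strand → `TRANSCRIPT_FRAME_OVERLAP`;
perfect hit outside any transcript → `SCAFFOLD_HIT`; exactly one mismatch,
or a full-length match at peptide length ±1 from a 1-nt frameshift →
`WOBBLY_SCAFFOLD` (the subtype — substitution, frameshift insertion or
deletion — is reported, since either criterion may fire); otherwise
`NO_HIT`. A perfect in-frame hit inside a transcript means the peptide was
not actually missing; it is reported as `"annotated"` with a consistency
flag rather than forced into an error class. The scan is an exact/1-
mismatch six-frame search (plus the explicit 1-nt frameshift case) rather
than tblastn: for ≤ 50-residue queries at ≤ 1 mismatch the two agree on the
full-query-length criterion, and the scan is deterministic and
dependency-free. Numerical conventions: coordinates are 0-based half-open
on the forward strand (minus-strand hits report forward intervals with
strand "−"); stop codons inside a candidate window invalidate the hit;
frameshift detection anchors exact half-peptide matches and then tests all
split points and both indel polarities at ±1-nt offsets.

The toy-genome generator plants each defect type so its true class is
recoverable by construction: overlap genes are encoded at a +1-nt frame
offset inside a stop-free host transcript whose frame-0 translation is the
annotated protein; uncalled genes sit on transcript-free scaffolds; wobbly
plants split between one amino-acid substitution (never I↔L, which would
vanish under collapsing) and a 1-nt indel at an interior codon; gap plants
are simply never placed. Planted peptides are screened against the
proteome so they cannot occur by coincidence.

# Problem sizes and numerical choices

Test and acceptance runs use deliberately modest sizes chosen to make the
statistical assertions sharp rather than to stress throughput: 10,000 null
proteins for ANOVA calibration (±3 SE band), ~1,200–1,500 null series for
the JTK conservatism bound, 150–800 proteins for sensitivity curves, a
(2, 25, 94, 120) planted-defect genome over a 20-protein base proteome for
classification recovery, and hundreds of randomized instances for the
digest/grouping/six-frame brute-force oracles. Exact-null computation is
cached per tie structure within a run. Cosine reference values are rounded
to 9 decimals before ranking so that analytically equal values compare
equal in floating point.

One subtlety the noise-free limit exposes: median normalization rescales
each sample by a factor that, in the absence of measurement noise, is an
exact function of time of day (the per-sample median moves as rhythmic
features cross it). Perfectly flat proteins therefore acquire a faint but
deterministic ZT dependence through the full pipeline and can be flagged by
an exact test. With any realistic noise the ripple is far below the noise
floor; the end-to-end truth test asserts complete recovery of the planted
rhythms with phases agreeing to within one grid step (the ripple also
breaks the exact within-grid data ties of a pure cosine, which can move the
best lag by 2 h).

# Known limitations

* The exact null assumes continuous data; heavily tied series make the
  test conservative.
* The ANOVA prefilter conditions rhythm testing on detection at all bins,
  so rhythmic proteins that drop out at their trough are systematically
  missed — an inherent property of the analysis being modelled, visible
  here as reduced sensitivity under strong dropout.
* The frameshift scan targets single 1-nt events; multi-nucleotide or
  compound defects classify as `NO_HIT`.
* The PSM simulator draws one score per peptide (shared across databases);
  it does not model score dependence on peptide length or charge.
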