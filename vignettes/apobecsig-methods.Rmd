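---
title: "Methods: APOBEC context statistics, signature refitting and CIN metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: APOBEC context statistics, signature refitting and CIN metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apobecsig)
```

`apobecsig` bundles the computational pieces of an APOBEC-mutagenesis study
of lung cancer under targeted therapy: sequence-context statistics,
mutational-signature refitting, somatic filter cascades, copy-number
intratumor heterogeneity (ITH) and chromosome-missegregation summaries, and
the exact small-sample tests used to compare them. This vignette explains
each model, its assumptions, the tunable parameters, and the numerical and
design choices made where a choice was genuinely open.

## Sequence-context model

Every somatic SNV is oriented so its reference base is a pyrimidine: when
the reference shows a purine, the substitution and its window are
reverse-complemented. The APOBEC classes are then pattern matches on the
oriented penta-/trinucleotide: TCN (C>T or C>G at a cytosine preceded by T),
TCW (3' base W ∈ {A, T}), and the pentanucleotide refinement by the base 5'
of TCW — RTCW (R ∈ {A, G}, the APOBEC3B-preferred substrate) versus YTCW
(Y ∈ {C, T}, APOBEC3A-preferred). RTCW and YTCW partition TCW because the 5'
base is always one of A/C/G/T. IUPAC codes are fixed to their standard
meanings.

Context fractions divide by **all** classified mutations in the sample, not
only C>T/G — so "fraction of mutations in an APOBEC context" is comparable
across samples with different substitution mixes. Mutations whose
pentanucleotide window runs off the contig or contains N are excluded from
numerator *and* denominator and surfaced in a QC counter; exclusion is the
conservative convention when the context is unknowable. Dinucleotide and
longer substitutions are treated as non-SNVs and skipped by the context
engine (a documented choice; counting them would require a separate DBS
catalog).

## 96-channel catalogs and signature refitting

Catalogs count SNVs over 96 channels in a substitution-major order (C>A,
C>G, C>T, T>A, T>C, T>G; flanks alphabetical; zero-based index
`16*sub + 4*five_prime + three_prime`). Refitting expresses a catalog's
channel fractions as a nonnegative mixture of reference signature profiles
by **forward selection**: seed with the single signature minimizing squared
reconstruction error, then repeatedly re-optimize one signature weight at a
time with a bounded golden-section line search, keeping the best
single-weight update per sweep. After convergence, weights below the
contribution cutoff (default 6%) are zeroed **once** and the remainder
renormalized to sum 1; iterative re-application of the cutoff is
deliberately not done, matching the single-pass behavior the cutoff was
calibrated for. Samples with fewer than 10 mutations are excluded outright —
with a handful of mutations the refit cannot discriminate signatures.

Numerical choices: the line search runs to tolerance 1e-6 and the sweep
loop stops when the best achievable error improvement falls below 1e-9
(capped at 1000 sweeps). These are tighter than forward selection strictly
needs, but they make the fit agree with a nonnegative-least-squares solution
to ~1e-4 per weight on exactly representable catalogs, so the cutoff rule —
not convergence noise — is the only thing that distinguishes the two. NNLS
itself is used only as an independent oracle in the test suite, because the
6% cutoff is defined within the forward-selection procedure.

Derived quantities: APOBEC burden = (SBS2 + SBS13 weight) × total
mutations, rounded half-up; dominant signature = argmax weight with
numeric-aware tie-breaking (SBS2 before SBS13) and an explicit tie flag;
per-mutation attribution = posterior P(s | channel) ∝ w_s · profile_s[channel].
The clonal-vs-subclonal comparison refits clonal and subclonal catalogs
separately per patient (default) and tests the per-patient APOBEC weight
differences with the one-sided exact signed-rank test; an alternative
`attribution` mode labels each mutation individually under a whole-sample
refit — subset-refit is the default because it mirrors how per-compartment
exposures are usually reported, and both modes are exposed for comparison.

No trinucleotide-abundance normalization (genome vs exome correction) is
applied by default: the bundled synthetic reference is GC-balanced, where
the correction is flat, and the signature fixture is defined on the same
scale. The signature matrix is configurable, so a real COSMIC file and an
abundance correction can be swapped in; the bundled
`signatures_synthetic.tsv` carries SBS1/2/5/13/40-**like** profiles that are
explicitly approximations (concentrated on the right channel blocks, with
controlled smooth variation; all pairwise cosines ≤ 0.55 so refits are
well-conditioned), not COSMIC data.

## Somatic filter cascades

The cascades are literal operator translations of their wording: "minimum
X" and "at least X" mean ≥; "over X", "greater than X", "more than X" mean
strict >; p-value thresholds are strict <. Concretely: SNVs (mouse WES
preset) pass at depth ≥ 30, alt reads ≥ 5, somatic p < 0.01, VAF ≥ 5%, with
calls in the 2–5% VAF window rescued only when the second caller also
detected them; indels require both callers, p < 0.001, depth ≥ 50, alt ≥ 10,
VAF ≥ 2%; the germline filter removes calls with normal alt reads > 5 or
normal VAF > 1%; the cell-line WGS preset requires the caller's own PASS,
depth > 30, alt ≥ 4, VAF > 0.05. Whether the 5% SNV minimum is inclusive is
not stated anywhere authoritative; ≥ is used and the boundary is unit-tested
so the choice is visible. Every decision lists the rules it failed; records
lacking required evidence produce error decisions rather than silent passes,
and pass + fail + error always sums to the input count. Upstream caller
parameters are documented context only — the cascades consume caller output,
they never re-call variants.

## CIN metrics

**SCNA ITH** overlays all regions of a tumor into disjoint intervals of
constant per-region copy number (bases not covered by a segment take the
baseline, default 2). A base is *altered* if any region deviates from
baseline and *heterogeneous* if the regions additionally disagree on the
copy-number state there. The metric is heterogeneous bp / altered bp. Two
consequences of judging heterogeneity per-base on CN state rather than on
event boundaries: the metric is invariant to re-splitting segments, and the
"same" event present at different amplitudes in two regions counts as
heterogeneous. The base-pair-weighted reading of "percentage of the genome"
is the natural one for segment tables; a ploidy-adjusted variant would need
per-tumor ploidy estimates that the segment tables do not carry.

**Missegregation**: per subject, percent = 100 · errors/anaphases, divided
by a recombination efficiency when only that fraction of cells expresses
the transgene (8.2% observed at 82% efficiency → 10% normalized; capped at
100%). The group summary is the **harmonic** mean of per-subject
percentages, which is undefined at 0 — the default policy errors on
zero-error subjects (making the issue explicit), and a `pooled` policy falls
back to pooled errors/anaphases with a warning. How zero-error animals were
handled historically is not stated, so both behaviors are explicit options.

## Exact tests

The Mann–Whitney U null distribution is built by dynamic programming over
the pooled order statistics; two-sided p doubles the smaller tail,
`min(1, 2·P(U ≤ min(u, n₁n₂ − u)))` — with n = 6 vs 6 this yields the
familiar printed values 2/924 ≈ 0.0022 at U = 0, 4/924 ≈ 0.0043 at U = 1,
86/924 ≈ 0.0931 at U = 7. Tail-doubling (rather than summing equally
extreme point masses) is chosen precisely because it reproduces those
conventional values. The signed-rank test enumerates the 2^n sign patterns
(zero differences dropped by default, Pratt handling available); Fisher's
test enumerates the hypergeometric support, two-sided p summing tables no
more probable than the observed. Exact paths expose the rational
numerator/denominator; ties switch to mid-rank normal approximations with
tie correction, flagged `exact = FALSE`. Bootstrapped Spearman resamples
pairs (default B = 1000, percentile 95% CI, explicit seed); since the
derivation of a bootstrap p-value is not standardized, only the
t-approximate p is reported and flagged approximate.

## Synthetic data: what it emulates, and what it does not

The generators produce data with the statistical structure the analyses
assume: i.i.d. reference bases at a chosen GC; mutation catalogs drawn by
sampling a 96-channel from the signature-mixture spectrum *reweighted by the
reference's trinucleotide availability* and then a uniform site carrying
that context on either strand (so rebuilding the catalog through the
context engine reproduces the sampled channel counts exactly — the core
cross-module consistency check); paired cohorts whose post-treatment sample
adds a TCW-restricted burst with C>T:C>G odds 2:1 (exercising both the
C>T-dominated SBS2-like and C>G-dominated SBS13-like channels); caller
evidence with Poisson depths, Beta VAFs by clonality and VAF-dependent
detection; and multi-region copy-number plans with planted clonal and
region-restricted events whose ITH is known by construction.

Default study conditions (the `sim_spec()` defaults): 100 kb GC-balanced
reference, 500-mutation catalogs from a 0.2/0.1/0.7 SBS2/SBS13/SBS5
mixture, 70% clonal mutations, ~60× depth, two regions with four clonal and
two subclonal 5 Mb events on a 100 Mb genome, seed 17. On a GC-balanced
i.i.d. reference all 32 pyrimidine-centered trinucleotides are equally
available, so availability reweighting is flat and signature recovery is
exact in expectation; recovery tests use 5,000-mutation catalogs over 20
seeds, sizes at which the median weight error stays well under 0.03 while
the whole check runs in well under a minute.

What the simulator does **not** model: mutation rate heterogeneity along
the genome, replication-timing and transcription-strand biases, kataegis
clustering, subclonal copy-number interaction with VAF, indel spectra
beyond placement for filter tests, and sequencing artifacts (OxoG/FFPE).
Passing tests therefore demonstrate the correctness of the computations on
data satisfying their stated assumptions — not robustness to every
real-data pathology; on real catalogs the signature fixture should also be
replaced by a real COSMIC matrix.

## Degenerate inputs and determinism

Zero-mutation samples are undefined for fractions (explicit error), excluded
from refitting below the mutation floor, and zero catalogs are valid but
unfittable. A tumor with no altered base has undefined ITH (NA, not 0).
Every stochastic operation takes an explicit seed, restores the caller's RNG
state, and `run_pipeline()` output is a pure function of (config, seed) —
rerunning with the same seed produces byte-identical JSON summaries. The
workflow scripts under `analysis/` default to seed 17 via `ANALYSIS_SEED`.

## Known limitations

The forward-selection refit, like any greedy scheme, can in principle lodge
in a local optimum when signatures are strongly collinear; the bundled
fixture avoids that regime by construction, and the NNLS oracle in the test
suite guards the exactly representable cases. The exact Mann–Whitney path
requires tie-free data; percent-scale data with few distinct values will
silently use the (tie-corrected) approximation, visible via `exact = FALSE`.
SCNA ITH consumes segment tables as given — it does not infer ploidy or
call copy number. Clonality labels are consumed as input from an external
clonality pipeline, never inferred.
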