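---
title: "Models and methods behind delscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind delscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delscreen)
```

`delscreen` models an activity-based DEL screen run in droplets: beads
carrying one library member each are encapsulated with an IVTT reporter,
translation inhibitors suppress droplet fluorescence, low droplets are
sorted, and the collected beads' DNA tags are sequenced to identify the
active structures. This vignette documents the models, the parameters that
matter, the numerical choices, and what the synthetic data can and cannot
establish.

## Library design

The library is the full cross product of cycle-1 starters and cycle-2
carboxylic acids, enumerated after building-block QC:

* **MW cutoff is strict** (`mw < max_mw`, default 200 Da): a block at
  exactly the cutoff is excluded. Keeping building blocks small keeps the
  assembled members lead-like.
* **Stereochemistry** is filtered as a cap on *unassigned* stereocenters
  (default 0 allowed). Undefined stereocenters are the standard DEL QC
  concern: a tag cannot distinguish epimers made in one well.
* **Structural flags** are an input column matched against a configurable
  ban list (default empty), so any alert set can be applied upstream.

`member_id` is `"<starter>-<acid>"` — deterministic and human-readable; the
enumeration order (acids fastest) is fixed so runs are comparable.

### Codon scheme

The DNA tag architecture of real libraries varies and is rarely published,
so the codebook here is a clean stand-in with stated guarantees: per cycle,
random codons (default length 8) are placed greedily subject to a minimum
pairwise Hamming distance `d_min` (default 3), so any single substitution
is uniquely correctable (`floor((d_min - 1)/2) = 1`). A reserved control
codon, grown with the cycle-1 code, marks positive-control beads — in a
real campaign control beads are identified by activity, not tags, so this
labeling is a convention of the simulator, not a claim about real data.
Placement is greedy-random under a seed: a Singleton-bound check rejects
impossible requests up front, and a bounded attempt count turns a crowded
code into an explicit capacity error rather than an endless loop. Length 8
with `d_min = 3` holds the needed ~400 codons with enormous slack
(the bound allows 4^6 = 4096).

### Similarity stand-in

3D shape/color overlap scoring against a reference inhibitor needs
conformer generation and commercial overlap software; it is out of scope.
`similarity_profile()` is a clearly labeled 2D stand-in: Tanimoto
similarity of binary atom-pair fingerprints (ChemmineR), with an
injectable fingerprint function so the arithmetic is testable on toy
fingerprints. Its values rank 2D feature overlap and are not comparable to
3D shape Tanimoto numbers.

## Droplet screen simulator

The generator produces the statistical structure the sorter assumes:

* **Bead occupancy** is Poisson. The default `bead_lambda = 0.06` is the
  published operating regime of roughly 90,000 beads across ~1.5 million
  droplets; occupied fraction `1 - exp(-0.06) ≈ 5.8%`.
* **Fluorescence** of a droplet is Normal with mean
  `neg_mu * (1 - max inhibition among its beads)` and SD `neg_sigma`.
  Multi-bead droplets take the **maximum** inhibition of their occupants:
  inhibitors act independently on a shared reporter, and the dominant
  effect is the conservative choice. Values are *not* clipped at zero —
  the RFU offset of a detector is arbitrary — so downstream code must
  tolerate small negative fluorescence.
* **Calibration**: `neg_mu = 100`, `neg_sigma = 5` RFU were chosen once so
  that a full-inhibition positive control gives
  `Z' = 1 - 3(5 + 5)/100 = 0.70`, the quality regime reported for the real
  assay. This is a calibration of the simulator, not a measured value.
* **Controls**: a fraction of beads (default 1%) are positive-control
  beads at full inhibition, giving every window a visible active band for
  QC cadence.
* **Ground truth** labels a droplet an expected hit iff it contains a bead
  with inhibition above `detect_min_inhibition` (default 0.5 — at the
  default calibration, 50% inhibition sits 10σ below the negative mean, so
  anything above it is comfortably detectable at 5σ).
* **Reads**: each bead emits `reads_per_bead` amplicons
  (`const5–codon1–spacer–codon2–const3`) with i.i.d. per-base substitution
  errors (default 1%). No PCR bias, indels, or quality modeling — those
  are out of scope, and the decoder is Hamming-based.

What passing tests on this generator show: the sorter's thresholding,
calibration, and the full decode→k-class chain behave correctly under the
screen's assumed statistics. What they do not show: robustness to drifting
negative populations beyond the windowing model, non-Gaussian detector
artifacts, bead autofluorescence, coalescence, or amplification bias in
real sequencing.

## Sorting analytics

Windows are **tumbling 30 s blocks**, matching the transient binning
(30 s × 7 RFU) used for screen visualization; the histogram is
visualization only and never feeds the sort decision. Per window the
negative population is estimated by **median/MAD**
(`sigma_hat = 1.4826 * MAD`) rather than mean/SD: the estimator was left
unspecified for the real screen, and the robust pair is insensitive to a
few-percent low-fluorescence hit tail that would otherwise drag the
threshold toward the hits. The threshold is `mu_hat - k_sigma * sigma_hat`
(default 5σ) and the hit rule is **strictly below** — "k σ below the mean"
describes droplets beyond the bound, so a droplet exactly at the threshold
is not sorted. Thresholds are computed from *all* droplets in a window,
not just occupied ones, since occupancy is unknown at sort time; at 6%
occupancy and percent-level hit rates the contamination is far inside the
robust estimator's breakdown point. Under-populated windows (default
< 100 droplets) inherit the previous window's statistics with a warning;
an under-populated *first* window is an error because no threshold exists
yet. Z′ uses the 3σ screening-window convention,
`1 - 3(σ₊ + σ₋)/|μ₊ − μ₋|`; equal means are an undefined-separation error,
and negative Z′ is valid output that fails QC. Cadence QC flags any window
whose hit rate — or control-bead occupancy, the signature of a
bead-introduction failure — deviates from the screen-wide value by more
than `flag_k` (default 4) binomial standard errors.

## Deconvolution

Per read, each codon slot decodes as: exact match; else the unique codon
within `max_mismatch` (default 1) → corrected; equidistant candidates →
ambiguous; none → fail; wrong-length reads fail without exception. Per
bead, the plurality (codon1, codon2) pair among non-failed reads wins if
its support is at least `min_support` (default 0.5); an exact tie is a
no-call — beads are cheap, so the deterministic conservative choice beats
a coin flip.

The **k class** of a structure is its distinct-bead count in a screen's
hit collection; a summed view across screens feeds the starter × acid
heat map. The **false discovery matrix** draws replicate null samples
(default 3 × 1,500 beads) *uniformly with replacement over structures* and
reports, per k threshold, the fraction of observed structures at ≥ k.
Uniform-with-replacement is an assumption: a bead pool at ~100k bead
equivalents over ~5,300 members carries ≈ 19 beads per structure, deep
enough that replacement effects are negligible for 1,500-bead draws. The
per-structure null count is then essentially Poisson with
`λ = sample_size / library_size`, giving the closed-form cross-check
`FDR(k) ≈ P(X ≥ k)/P(X ≥ 1)` used by the test suite; at 1,500 from 5,348,
FDR(3) ≈ 1.2% — the quantitative basis for calling structures at k ≥ 3.
FDR(1) is identically 1 and the matrix is nonincreasing in k; k values
with no support in any replicate are reported as 0 and flagged as
degenerate.

**Enrichment** tests each building block with the one-sided
hypergeometric tail on the *distinct-structure* hit set (default the
k ≥ 3 set) — bead-weighted counts would count replicate beads of one
structure as independent evidence for its blocks. Correction is
Bonferroni across all blocks of both cycles: conservative and simple,
appropriate for a few hundred tests where the interesting signals are
orders of magnitude below the threshold.

## End-to-end recovery and problem sizes

The round-trip property — simulate → sort → read → decode → call →
k class — is exercised at 10⁵ droplets (λ = 0.06, ≈ 6,000 beads) with
planted actives at ≥ 70% inhibition over a 200-member library. At zero
sequencing error every sorted bead decodes to its true structure; the
k ≥ 3 hit set equals the planted set exactly, while the occasional
passenger bead (an inactive bead co-encapsulated with an active one in a
multi-bead droplet) appears at k = 1 and is removed by the k threshold —
that separation is precisely what the k class is for. At 1% substitution
error with single-mismatch correction, ≥ 99% of beads are still called
correctly. Simulation sizes throughout the suite (10⁴–10⁵ droplets,
50–200 null replicates where distributional agreement is asserted) were
chosen so that 3-standard-error tolerances are decisive for the effects
being tested.

## Pipeline determinism

One global seed deterministically derives per-stage seeds by hashing the
stage name (`stage_seed()`), so a stage re-run in isolation from its
serialized inputs reproduces its in-pipeline output, and identical
config + seed gives byte-identical artifacts. Config files (YAML/JSON)
are validated before any stage runs and unknown keys are rejected.

## Known limitations

* The codon scheme, amplicon layout, and control-bead tagging are artifact
  conventions; real tag architectures differ.
* The error model is i.i.d. substitutions only — no indels, chimeras, or
  position-dependent quality.
* The null for the FDR matrix assumes uniform library representation;
  synthesis yield skew in a real bead pool would need an abundance-weighted
  null.
* 3D similarity to a reference pharmacophore is out of scope; the 2D
  profile is a ranking aid only.
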