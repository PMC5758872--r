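---
title: "Models and methods behind dletools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dletools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dletools)
```

This vignette explains the models implemented in dletools, the choices
made where the design was genuinely open, and what the synthetic
benchmarks do and do not establish about real data.

## The element and its grammar

The dorsal localization element (DLE) is a bipartite cis-regulatory
element in the 3′UTRs of Nodal-pathway mRNAs: a short GCAC sequence
motif (in several transcripts preceded by an A), a spacer of a few
nucleotides, and a stem-loop. `dle_descriptor()` parameterizes this
grammar; `dle_preset()` provides the two published variants:

* **relaxed** — GCAC anchor, spacer 2–5 nt of any base, stem of at least
  3 bp, variable loop. Loop bounds are not stated for this variant; we
  default to 3–30 nt (3 is the steric minimum for a hairpin loop, 30
  covers the observed elements with margin) and make them configurable.
  The stem maximum defaults to 20 bp, matching the strict variant, so
  every strict match is also a relaxed match.
* **strict** — GCAC anchor, spacer of 2–3 pyrimidines, stem 3–20 bp,
  loop 5–12 nt; the definition used for orthologue screens.

A single anchor usually admits several overlapping (spacer, stem, loop)
decompositions. By default `match_dle()` collapses these to one
representative per (anchor, loop start): the decomposition with the most
stem pairs, breaking remaining ties by the shortest loop. This gives a
stable, non-redundant hit set; `enumerate_all = TRUE` exposes the full
set, and the test suite checks it against a brute-force decomposition
oracle. G·U wobble pairs are allowed in stems by default (standard RNA
pairing); `allow_GU = FALSE` mimics a strict Watson–Crick descriptor.
Scanning is sense-strand only — the element lives in mRNA — and the
3′UTR sequences are assumed to carry no poly-A tail.

## The folding model

`partition_function()` and `constrained_probability()` work on the
Boltzmann ensemble of nested secondary structures (no pseudoknots),
with hard constraints: the probability that the DLE stem forms in
context is

$$p = \frac{Z_\text{constrained}}{Z_\text{total}},\qquad
  Z = \sum_S e^{-E(S)/RT},$$

where the constrained sum runs over structures containing every required
stem pair. Two backends are provided:

* **simple** (default): \(E(S)\) is the sum of base-pair energies
  (defaults G-C −3, A-U −2, G·U −1 kcal/mol), with a minimum hairpin
  loop of 3 nt and no stacking, dangle or loop terms. This model is
  deliberately minimal: every number it produces can be verified by
  exhaustive enumeration, and the suite requires agreement to a relative
  1e-10 on sequences up to 14 nt (and on constrained queries for
  constructs up to 40 nt via restricted enumeration). The dynamic
  program is the standard conditioning on the fate of the leftmost base,
  run in log space so that long UTRs cannot overflow; hard constraints
  enter as forced partner assignments. Exact base-pair probability
  matrices come from the matching inside–outside recursion and are
  cross-checked two ways (enumeration, and the constrained/total ratio).
* **turner**: ensemble free energies are delegated to an external
  `RNAfold` executable with and without `--enforceConstraint`, and
  \(p = \exp(-(G_c - G)/RT)\). This is the backend for analyses of
  natural sequences where nearest-neighbor thermodynamics matter; exact
  values are backend-specific, and the suite only asserts agreement of
  qualitative orderings between backends.

One property of the simple model deserves emphasis because it shapes
everything downstream: **without stacking terms, helices have no
cooperativity**. A 6-pair helix weighs exactly as much as any six
disjoint, mutually compatible pairs of the same types, and an isolated
pair is essentially free (an isolated G-C forms with probability
\(w/(1+w) \approx 0.99\) at 37 °C if nothing competes for either base).
Consequently the probability of a *specific* helix is governed almost
entirely by how many alternative partners its bases have in the region
of interest. Dilution of this kind — not the paired state itself — is
what the element's sequence context controls, and it is precisely the
effect the masking and conservation analyses measure.

An impossible constraint (non-complementary, crossing, or violating the
hairpin minimum) is a validation error, deliberately distinct from a
legal-but-unfavorable constraint, which simply yields a small p.

## Repeat masking

`find_repeats()` reports maximal (CA)ₙ runs (default at least 4 units —
no threshold is prescribed for the *cyc* run, which is far longer; the
value is configurable). `masking_analysis()` computes p(stem) before and
after an in-silico deletion across a temperature grid (default 25–28 °C,
the zebrafish rearing range) and reports the per-temperature fold change
with a min/max summary, mirroring the range form in which such results
are reported. The deletion must leave the motif intact; after deletion
the element is re-located by re-scanning and matching its local
sequence, which is robust to deletions 5′ of the motif without any
coordinate arithmetic. `pairs_mode = "innermost"` restricts the
constraint to the innermost `stem_min_bp` pairs for sensitivity
analyses.

The bundled masked construct (`plant_masked_dle()`) places a planted
strict element in a U-free context with a downstream (CA)₈ run whose C
residues can pair the G-rich stem arm; the inert control replaces the
run with poly-A, which can pair nothing in that context, so its deletion
changes p by exactly nothing — a sharp null. The construct stays under
40 nt so the enumeration oracle can verify the fold change end to end.
Note that this construct's masking operates through isolated pairs and
is therefore visible only to the simple backend; the Turner-backend
demonstration uses a variant whose repeat forms a contiguous helix
against a GU-rich stem arm, which both energy models register.

## Conservation surrogate

`scan_orthologues()` runs the strict grammar over each orthologue's
3′UTR plus up to 100 nt of trailing CDS (using what is available, with a
message, when the annotated context is shorter).
`align_motif_regions()` aligns the motif regions ±10 nt of flank
(configurable; no value is prescribed) by progressive profile
Needleman–Wunsch with match +2, mismatch −1, gap open −4, gap extend −1,
guide order = input order — deterministic, and checked against an
independent pairwise implementation. Phylogeny-aware alignment and
manual gap curation are out of scope; a curated alignment can be
supplied via `read_alignment()`.

`consensus_structure()` is a deliberately simple consensus surrogate:
each row's exact base-pair probabilities (enumeration up to 25 nt,
inside–outside DP beyond) are mapped through alignment columns and
averaged over rows, a gap contributing zero; the consensus dot-bracket
is the greedy maximum-weight nested matching over column pairs with
average reliability ≥ 0.5. It uses no phylogenetic weighting and is
documented as a surrogate for tree-aware consensus folding, not a
reimplementation of it.

## Reporter quantification

The imaging pipeline mirrors a standard two-channel reporter protocol:

* **Projection** — the slices "in sharp focus" are chosen automatically
  as the contiguous window (default 4 slices) with maximal total
  intensity on the rhodamine channel, with a manual `slices` override;
  both channels are projected over the same window by elementwise
  maximum.
* **Segmentation** — Otsu threshold on the rhodamine projection (no
  threshold value is prescribed; a fixed value can be supplied), keeping
  the largest connected component as the blastoderm ROI.
* **Background** — the same pipeline applied to un-injected control
  stacks (ROI-matched); controls with no segmentable signal fall back to
  a centered rectangle covering a quarter of the frame. Whole-image
  background is a matter of one argument change if preferred.
* **Ratio** — (mean GFP − background GFP) / (mean RFP − background
  RFP) per embryo. Embryos with a non-positive background-subtracted
  rhodamine signal, or no segmentable ROI, are returned flagged — never
  silently dropped.
* **Statistics** — `compare_groups()` fits ratio ~ group × stage by
  two-way ANOVA and reports per-stage pairwise group contrasts using the
  pooled residual variance with Bonferroni adjustment over all contrasts
  at α = 0.05 — the post-hoc convention of common biostatistics
  packages.

## Synthetic benchmarks: what they do and do not show

Every generator is deterministic under its seed and emits ground truth
alongside the data.

* `gen_planted_utrs()` plants one random strict-grammar element per
  i.i.d. background and rejection-screens each sequence so no unplanted
  strict match exists; recall and precision are then exact quantities.
  The cost is that screened backgrounds are very slightly non-i.i.d.
* `gen_orthologue_family()` is a *constructed* benchmark. Because the
  simple energy model has no helix cooperativity (above), a planted stem
  is recoverable from consensus reliabilities only if its bases have
  essentially no alternative partners in the scored region. The
  construction therefore uses a 6 bp G/C stem whose 5′ arm starts with
  C, a poly-A loop and (by default) an inert poly-A background, and a UU
  spacer. The spacer U's matter: they pair distant background A's in
  arrangements that cross — and so exclude — every competing pairing of
  the anchor G against the stem arms, leaving the planted register
  dominant. The ancestor is rejection-screened (every planted pair
  ≥ 0.6, every other pair ≤ 0.5 in its region) before descendants are
  derived by per-site substitution, compensatory at stem sites when
  requested. Passing this benchmark shows the consensus machinery
  recovers a conserved dominant helix from diverged homologs; it does
  not show that natural elements are dominant folds of their regions —
  under this energy model they generally are not.
* `gen_embryo_cohort()` renders geometric discs with a known focus
  block, amplitude ratio and multiplicative noise; it emulates none of
  the real optics (no point-spread function, attenuation or morphology),
  so passing tests certify the measurement arithmetic and segmentation
  logic, not robustness to real microscopy artifacts.
* `gen_ratio_cohort()` simulates at the measurement level (Gaussian
  ratios, CV × mean) for ANOVA calibration: 100 cohorts of 34 embryos
  per group × stage cell for both the null and the 1.5× effect setting.
  Image rendering is validated separately on small cohorts; rendering
  hundreds of full cohorts would add nothing to the statistical
  question.

Problem sizes used throughout the tests and the acceptance script:
enumeration fixtures to 14 nt (constrained constructs to 40 nt), 200
planted UTRs of 200 nt, 7-species families of 120 nt at divergence 0.2,
imaging cohorts of 64×64×15 stacks, and 2 × 100 simulated ANOVA cohorts.

## Known limitations

* The simple backend is not a thermodynamic model of real RNA; it is an
  exactly-verifiable surrogate. Conclusions about natural sequences
  (e.g. the *ndr2/cyc* masking fold change) require the Turner backend
  and the natural sequence, which is not bundled.
* No pseudoknots, no base-pair probability dot-plots as a user feature,
  no reverse-strand scanning, no Ensembl fetching.
* The consensus surrogate ignores phylogeny; deep, unevenly sampled
  families would need tree weighting.
* Alignment is a simple progressive scheme; families with long indels
  near the motif should be aligned externally and supplied via
  `read_alignment()`.
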