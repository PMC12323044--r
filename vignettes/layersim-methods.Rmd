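---
title: "Simulating epigenomic state layers: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating epigenomic state layers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(layersim)
```

## The model

layersim runs rules-based simulations of epigenetic state change on a genome
sequence.  The state model is deliberately minimal:

* A **layer set** couples an immutable genome (chromosome sequences over
  `ACGTN`) with any number of named **layers**.  A layer is a binary
  annotation track — a set of merged, sorted intervals; a base either carries
  the mark or it does not.  There are no scores, strands or levels within a
  layer: graded signal emerges only when many replicate simulations are
  summed into per-base coverage.
* A **binding factor** is an agent with (i) a *profile* that matches the
  genome sequence — an IUPAC consensus, a position weight matrix (PWM), or a
  regular expression — and/or a *predicate* over layer states (a conjunction
  of "layer L present" / "layer L absent" terms); (ii) a set of
  *modifications*, each setting one layer present or absent; (iii) a
  *statewidth*, the width in bp of the region it modifies, independent of the
  width of its match; and optionally (iv) an *offset sampler* that displaces
  each modification from its match.
* A **cycle** matches every factor, in declared order, against the current
  state; each factor applies at most its **abundance** of modifications
  (hits are subsampled uniformly when more candidates match than the
  abundance allows), modelling finite molecule numbers.  A **simulation** is
  a seeded sequence of cycles; **replicates** rerun it under derived seeds.

This is a caricature of chromatin biology — no kinetics, no energetics, no
3D contacts — but it captures the two ingredients that make epigenome
dynamics hard to reason about informally: contingency (factors read the
state other factors wrote) and competition for finite machinery genome-wide.

## Matching semantics

Sequence scanning conventions differ by pattern language, matching what
users of each language expect:

* **Consensus / PWM**: every matching window is reported, overlapping
  occurrences included, on both strands by default (transcription factors
  bind either strand); palindromic double-counts are collapsed to one hit
  per position.  PWM thresholds are expressed as a fraction of the maximum
  attainable score (default 0.90); JASPAR-style count matrices are converted
  to log-odds with a +0.25 pseudocount per cell against a uniform
  background.
* **Regex**: non-overlapping, leftmost matches on the forward strand only —
  the standard regex-engine contract.  The CpG-island pattern used in the
  reprogramming model is strand-symmetric in practice, so forward-only
  scanning loses nothing there.
* `N` in the genome matches only a literal `N` in a consensus (PWM columns
  give it weight 0), so assembly gaps never spuriously recruit factors.
* Because the four counting conventions (forward/both strand,
  overlapping/disjoint) all appear in the literature, `count_sequence_hits()`
  exposes them as flags rather than hard-coding one.

Layer predicates use ≥ 1 bp overlap semantics by default: a "present" term
is satisfied if the candidate footprint touches the layer at all.  Spreading
models depend on this — recruitment at the *edge* of an existing mark is what
lets marks grow.  A strict containment mode is available per predicate for
models that need it.

Factors whose profile is `none` (pure state-readers, e.g. spreaders and
cleaners) take one candidate per maximal interval of the first
`present` layer of their predicate, filtered by the remaining terms.

## The cycle: ordering, placement, idempotence

Three design points were genuinely open and are worth recording:

* **Sequential-asynchronous update.**  Factors apply in declared order and
  each sees the updates of its predecessors *within the same cycle*.  The
  alternative (all factors matching a frozen cycle-start state) would force a
  recruitment chain like RAP1 → potential → bound → spread to take one cycle
  per link.  Order sensitivity is real and surfaced, not hidden: the test
  suite constructs an antagonistic writer/eraser pair whose outcome flips
  with order.
* **Placement.**  Modifications are centred on the match midpoint:
  `centre = floor((start + end) / 2) + signed offset`, spanning
  `statewidth` bases from `centre - floor(statewidth / 2)`, clipped to the
  chromosome.  Offset samplers return magnitudes; each draw gets a uniformly
  random sign, so spreading is bidirectional.  A placement pushed entirely
  off the chromosome is dropped (the abundance is still spent).
* **Idempotence.**  Re-marking an already marked region is a no-op by
  interval algebra, but the abundance spent on it is consumed, not refunded —
  the finite-molecules reading.  Consequently a factor's realised effect per
  cycle can be far below its abundance once its targets saturate.

All randomness flows through one Mersenne-Twister stream per simulation
(`set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
sample.kind = "Rejection")`), recorded in run manifests; replicate `r` uses
`base_seed + r`, so any replicate can be reproduced in isolation.

## The SIR telomeric-silencing models

Both variants model recruitment and spreading of the yeast SIR complex:

| factor | matches | writes |
|---|---|---|
| RAP1 | `GGTGT` (variant 1) or `GGTGT.{0,3}GGTGT` (variant 2) | `sir3_potential` |
| Sir3p | `sir3_potential` present ∧ `sir3_bound` absent | `sir3_bound` |
| Sir3.spreader | `sir3_bound` present | `sir3_bound`, displaced by \|N(147, 30)\| bp, random sign |

The 147/30 spreading distribution — roughly one nucleosome of DNA — is the
model's standard parameterisation, as are 200 cycles, snapshots every 10
and 100 replicates.  No standard abundances exist; the package default of
500 per factor at ~12 Mbp genome scale is a package choice, exposed as a
parameter and marked as such.  RAP1's statewidth (10 bp, a motif-scale
mark) and Sir3p's (147 bp) are likewise package defaults.

Because the spreader is anchored on interval midpoints, an isolated mark
grows until its half-width exceeds the typical displacement and then stalls
at roughly `2 * (mean + statewidth / 2)` ≈ 600 bp; sustained domain growth
requires fresh seeds or mark mergers shifting the midpoint.  This is a
knowable consequence of the midpoint-anchoring choice and is visible in the
demo's coverage profiles.

## The OSKM reprogramming model

Seven factors on layers `active` and `repressed`: four activators (OCT4
`ATGCAAAT`, SOX2 `WTTGT`, KLF4 `GCCAMGCCTC`, MYC `CACGTG`; consensus, both
strands, abundance 5000 each, shared statewidth — the swept parameter),
a CpG-island repressor (regex `(CG.{0,20}){4}CG`, abundance 20000, blocked
by `active`), a repression spreader (abundance 20000, blocked by `active`),
and a cleaner (abundance 10^10) that resolves active/repressed conflicts.
Activators ignore repression entirely; repressors yield to activation —
the model's defining interaction logic.

Two of that model's components are underdetermined and get explicit
treatments here:

* **Cleaner semantics.**  Read literally, removing all regions in both
  active and repressed states erases every mark every cycle, which would
  contradict the cumulative state trajectories the model is meant to
  produce.  layersim's default reads it as a *conflict resolver*: the
  cleaner targets intervals carrying both marks and erases exactly the
  intersection from both layers (`placement = "intersection"`).  The
  literal whole-interval behaviour remains available
  (`build_oskm_model(cleaner = "footprint")`).  The cleaner runs last in
  the cycle, so no base ends a cycle both active and repressed — an
  invariant the test suite asserts.
* **Repression spreading.**  `bf.RepSpread` has no standard statewidth or
  displacement; the default is a 1000 bp mark displaced by a uniform
  1..1000 bp magnitude with random sign, i.e. spreading adjacent to
  existing repressed intervals.  Both values are parameters.

## The synthetic genomes and what they do (not) show

Reference assemblies are deliberately not bundled; the generator builds
genomes with known ground truth instead.  Background bases are i.i.d. from
a configurable composition; planted features (motifs, gapped double motifs,
CpG-island-like segments) overwrite background at collision-free positions
found by rejection sampling (1000 retries, then a hard error — deterministic
failure beats silent overlap).  Island sequence emits `CG` with probability
`density / (1 - density)` per step, giving the requested expected CG
dinucleotides per bp.  Telomeric placements alternate chromosome ends so
clusters stay balanced.

The demo study designs are fixed once, from rate arithmetic, as the
package's stand-ins for the full-genome studies:

* **SIR demo** — one 100-kb chromosome, 2-kb telomere windows holding 3
  gapped doubles + 4 singles each, 20 interior singles; 30 replicates × 50
  cycles.  Abundances scale the 500-per-factor default by genome size
  (100 kb / 12.07 Mbp ≈ 1/121, rounded up to 4).  Uniform background means
  ~100 chance `GGTGT` occurrences, so variant 1 seeds everywhere — exactly
  the failure mode the double-motif variant corrects; chance gapped doubles
  (expected ≪ 1) occasionally produce the interior artefact peaks the
  full-genome runs also show.
* **OSKM demo** — one 200-kb chromosome at 40 % GC, 60 TSS ~3.3 kb apart,
  500-bp islands (CG density 0.12) centred on 40 of them (exactly 2/3), an
  OCT4 motif 0.6–1.2 kb from every TSS.  Abundances scale the full-genome
  values by 200 kb / 3.1 Gbp with a floor of one action per cycle,
  preserving the 4:1 repressor-to-single-activator ratio (activators 1
  each, repressor 4, spreader 4, cleaner 10^9).  The statewidth sweep uses
  200 / 1000 / 5000 bp: with four activator placements per cycle over 100
  cycles, expected naive coverage `1 - exp(-400·w / 2·10^5)` is ~0.33,
  ~0.86 and ~1.0 — an unsaturated low end, a distinguishable middle, and a
  saturated top, which is the property the full-genome sweep (200–50,000 bp
  on 3.1 Gbp) exhibits.

What passing the desk-scale suites shows: the engine's interval algebra,
matching, sampling and replicate machinery reproduce the models'
*qualitative* signatures (telomere-restricted vs chromosome-wide SIR binding;
activation increasing with statewidth; CpG-island TSS preferentially
repressed at small statewidth) under conditions a single CPU can run in
minutes.  What it does not show: agreement with experimental ChIP data,
behaviour on real genome heterogeneity (repeats, GC structure, real
telomeric repeat arrays), or the full-genome site counts — those require
user-supplied assemblies and the full configurations, which the package
accepts but does not ship.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive internally; conversion to 0-based
  half-open happens only at the BED/bedGraph boundary.
* Adjacent intervals (`[10,20]`,`[21,30]`) merge: binary marks have no
  meaningful internal boundary.
* Statewidth samplers returning values < 1 are redrawn up to 100 times,
  then error; offset draws are rounded to integer bp.
* A pattern longer than every chromosome yields an empty hit list, not an
  error; an abundance of 0 is a legal no-op; subtracting from an empty
  layer is a no-op.
* Non-`ACGTN` input bases become `N` with a warning count, because real
  assemblies contain gaps and ambiguity codes.

## Problem sizes in the shipped checks

The test-suite study sizes are the package's chosen desk-scale designs:
scanning oracles run on hundreds of random sequences up to 10 kb;
interval-algebra oracles on 10-kb chromosomes; the SIR contrast on the
100-kb demo (2 models × 30 replicates × 50 cycles); the OSKM direction
check on the 200-kb demo (3 statewidths × 100 cycles); and the spreading
sampler is checked on 100,000 draws.

## Known limitations

* Layers are strictly binary; graded occupancy exists only across
  replicates.
* Midpoint-anchored spreading stalls on isolated marks (above); models
  needing long-range domain growth should seed densely or raise the offset
  mean.
* Abundance schedules may vary by cycle but cannot yet respond to the
  simulated state (no expression feedback).
* Diploid genomes and trans interactions (3D contacts, sink competition
  between chromosomes beyond shared abundance pools) are out of scope.
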