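---
title: "Methods: triplex-forming motif analysis and the cooperative binding model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: triplex-forming motif analysis and the cooperative binding model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triplexmotif)
```

## The problem

Long noncoding RNAs that drive X-chromosome inactivation (mouse Xist, human
XIST, opossum Rsx) coat their chromosome without any known high-affinity
sequence-specific binding site. One proposed mechanism is redundant, weak
RNA·DNA-DNA triplex formation: many short pyrimidine (UC/TC) or purine (AG)
stretches in the lncRNA pairing with complementary stretches in genomic DNA
— particularly in LINE-1 retrotransposons, which are enriched on eutherian X
chromosomes — via Hoogsteen (parallel third strand) or reverse Hoogsteen
(antiparallel) hydrogen bonds. This package implements the computational
side of that analysis: a motif scanner, the summary statistics used to
fingerprint sequences, a secondary-structure accessibility filter, a
paired-element divergence comparison, a kinetic Monte Carlo model of
cooperative multi-site binding, and synthetic-data generators so that every
stage runs, and is tested, with known ground truth.

## Motif definition

A *redundant UC (r-UC/TC) motif* is a window of at least `min_length = 5`
nucleotides over the two-letter alphabet {U/T, C} that

1. has at least `min_internal_gap = 3` nucleotides strictly between the
   first and the last U(T) — the *anchor* base;
2. has no more than `max_anchor_run = 3` consecutive U(T);
3. has at most `max_partner_run = 2` consecutive C.

The purine *r-AG motif* mirrors this with U→A and C→G; in reverse Hoogsteen
mode (the default for the purine class) the consecutive-G limit is lifted,
because G runs increase reverse Hoogsteen triplex affinity. U and T are
interchangeable internally (one DNA-alphabet representation; RNA motifs
derive from genomic sequence), `N` and any base of the opposite
purine/pyrimidine category break a motif, and IUPAC ambiguity codes
collapse to `N` on input.

Two counting conventions coexist and must not be conflated:

* a **site** (`find_motif_sites()`) is a *maximal* valid window — not
  contained in any longer valid window of the same class. A same-class run
  that violates a run-length rule is not discarded wholesale; its maximal
  valid sub-windows are reported (`"UCUUUUC"` still yields `"UCUUU"`).
* **windows including overlaps** (`enumerate_motif_windows()`) count every
  valid window, nested ones included: the 10-mer `uuucuuccuu` is itself a
  motif and contains four valid 5-mers (`uuucu`, `uucuu`, `uuccu`,
  `uccuu`). Cumulative short-motif ratios (the share of 5–7-nt windows)
  use this convention.

Two scanner details are genuinely underdetermined by the published rules,
and are exposed as flags rather than guessed silently:

* whether motifs must begin and end on the anchor base
  (`anchor_bounded`, default `FALSE` — the published criteria say nothing
  about boundary bases, and the worked 10-mer example is consistent with
  either reading);
* the consecutive-G setting differs between the Hoogsteen parameterisation
  used for eutherian scans and the reverse Hoogsteen one used for the
  marsupial scan, without printed values; the mapping used here is
  Hoogsteen mode → max G run 2, reverse Hoogsteen mode → unlimited.

```{r scan-example}
uc <- motif_criteria("pyrimidine")
find_motif_sites("aaUUUCUaa", uc)
enumerate_motif_windows("uuucuuccuu", uc, length_range = 5L)$sequence
```

## Summary statistics

`profile_sequence()` reports, per class: the number of maximal sites,
*occupancy* (fraction of nucleotides covered by the union of sites —
overlapping sites are never double-counted; the denominator is the full
sequence length including `N` runs), *frequency* (sites per kb), and the
r-UC/r-AG *ratio* of occupancies — the lncRNA fingerprint that separates
Xist/XIST (ratio > 1.5) from Rsx and most other long lncRNAs (< 0.8). The
ratio is computed from unrounded occupancies and rounded only for display,
because rounding first is inconsistent at the printed precision.

Motif-length distributions are compared by the Kolmogorov–Smirnov
*distance*: the supremum of the absolute difference of the two discrete
empirical CDFs, evaluated on the union of observed lengths, with no
continuity correction and no hypothesis test attached. The conventional
similarity threshold is 0.100, used descriptively.

RepeatMasker summaries use 0-based half-open coordinates internally
(converted from the `.out` file's 1-based inclusive convention on read;
strand `C` becomes `-`). Element-length bins are right-closed — (0,100],
(100,200], …, (900,1000], (1000,2000], … — matching the conventional
"≤100", "101–200", "1,001–2,000" labels. Per-bin random sampling
(`sample_by_length_bin()`) draws up to *k* elements uniformly without
replacement (50 for L1-type surveys, 30 for L2s); bins holding fewer than
*k* return all their elements. Overlapping annotations are summed raw with
a warning — RepeatMasker output essentially never overlaps, so no
resolution policy is imposed.

## Secondary-structure accessibility filter

Folding itself is out of scope: structures enter as dot-bracket or CT
files produced by any external tool. `classify_positions()` labels every
position with the standard loop taxonomy (paired, hairpin, internal,
bulge, multibranch, exterior), rejecting pseudoknots by name rather than
silently breaking them — the structure sources this filter is meant for
are pseudoknot-free.

A motif's *usable length* is the longest run of consecutive motif
positions that are unpaired, in an eligible loop type, and in the *same
loop instance*; a motif is retained when its usable length still reaches
`min_length`. Defaults and their rationale:

* eligible loops default to hairpin + internal + bulge (a bulge is an
  internal loop with one empty side); multibranch and exterior positions
  are excluded by default but switchable, since the manual counts this
  reproduces refer to hairpin or internal single-stranded loops and are
  silent on the other types.
* contiguity within one loop is required by default (`contiguous = TRUE`);
  the relaxed "total unpaired positions anywhere in the motif" count is
  available as a flag. A motif spanning two loops separated by even a
  1-bp helix therefore contributes only its larger single-loop stretch —
  an edge case the original manual procedure does not document, resolved
  here by the contiguity rule rather than guessed intent.

When several predicted structures exist for a region, each is filtered
separately and results are reported per structure.

## Paired-element comparison

Two copies of a repeat element are aligned with an affine-gap global
(Needleman–Wunsch–Gotoh) aligner — default scoring match +1, mismatch −2,
gap open −5, gap extend −2, a BLASTN-like set; a length-*L* gap costs
`gap_open + (L-1) * gap_extend`. Identity is the percentage of alignment
columns with identical residues and the gap fraction the percentage of
columns containing a gap; these definitions differ slightly from BLAST's
local-alignment statistics, so published BLAST identities are reference
points rather than exact targets. A motif of element A is *completely
matched* when its full span projects through the alignment gap-free and
residue-identical; boundary shifts are not tolerated (strict full-span
matching, with no ±1-nt slack). The matched fraction — the *motif
identity* — falls much faster with divergence than overall sequence
identity does, because a single hit anywhere in a motif's span unmatches
it: at a 5–10% substitution rate an 11-nt motif survives intact with
probability only `0.95^11 ≈ 0.57` to `0.9^11 ≈ 0.31`.

## The kinetic Monte Carlo binding model

The RNA is reduced to `N` two-state binding sites. Per step, a dissociated
site binds with probability `k_on`, a bound site unbinds with `k_off`, and
binding is accelerated to `A * k_on` whenever at least one site was bound
at the start of the step — the linkers connecting sites tether free sites
near the DNA once any site anchors. Acceleration never applies out of the
all-dissociated state, so `N = 1` is `A`-independent. The observable is
`P_diss`: the fraction of observed steps with *all* sites dissociated.
Defaults `k_on = 0.002`, `k_off = 0.2` per step correspond to the weakest
measured dissociation constant (~10⁻³ M).

Design choices:

* **Update scheme.** The default is synchronous (all sites redrawn each
  step, acceleration gated on the state at step start). An asynchronous
  single-site-per-step variant is kept because its bound-site count is an
  exact birth–death chain, `π(m+1)/π(m) = ((N−m)·k_on′)/((m+1)·k_off)`
  with `k_on′ = k_on` only for the first binding — an independent solver
  (`birth_death_stationary()`) that the tests check the simulator against.
* **Closed-form anchors.** `N = 1` must reproduce
  `k_off/(k_on+k_off) = 0.990099…`, and `A = 1` (no cooperativity) must
  follow the independence product `P_diss(N) = 0.990099^N`; both are
  asserted within 3 standard errors.
* **Run layout.** 10 independent runs of 20,000 steps from the
  all-dissociated state, no burn-in, per-run seeds derived from one master
  seed. `P_diss` pools per-step observations within a run; the standard
  error is the SD of the 10 run means divided by √10.
* **A caveat on standard errors.** In the cooperative corner of the
  `(N, A)` grid the per-step dissociation indicator is strongly
  autocorrelated — the chain alternates between bound and empty phases
  with dwell times of hundreds of steps — so run-to-run standard errors
  reach the 10⁻²-scale there (the test suite measures this on the full
  grid). Treating the 200,000 pooled steps as independent samples would
  suggest errors an order of magnitude smaller; that independence
  assumption does not hold at these run lengths, and the package reports
  the honest run-to-run figure.

```{r mc-example}
run_simulation(kinetic_params(N = 1, A = 1, steps = 5000, runs = 5,
                              seed = 7))
```

The grid study uses `N, A ∈ {1, 2, 5, 10, 15, 20}` (`sweep_pdiss()`);
`P_diss` decreases monotonically in `A` at fixed `N ≥ 2` and in `N` at
fixed `A`, and at `N = 20, A = 20` the mean falls below 30%. Continuous
time (Gillespie) dynamics and any geometric model of the linkers are out
of scope; `A` is held constant.

## Synthetic data: what it emulates and what it does not

The generators make every pipeline stage testable offline with known
ground truth; all are deterministic under a seed.

* `generate_motif_sequence()` plants valid motifs in random background at
  a target per-class occupancy. Plants are isolated by forcing the
  immediately flanking bases to the opposite purine/pyrimidine category,
  so each plant is recovered by the scanner as exactly one maximal site
  (recall is 100% by construction); chance background motifs are allowed
  and show up as extra sites beyond the ledger. The default planted
  length distribution decays geometrically (ratio 0.6) over 5–17 nt:
  real motif-length histograms are bottom-heavy, with minimum-length
  motifs dominating and 15–17-nt motifs rare, and a uniform default would
  overweight the rare long motifs. Background composition defaults to
  uniform.
* [generate_l1_family()] derives elements from one motif-planted
  consensus as 3′-anchored suffixes — 5′ truncation, the dominant mode of
  LINE-1 truncation — with lengths from a configurable distribution
  (default uniform from 30 bp to full length, giving every length bin
  mass), plus a RepeatMasker-dialect annotation fixture. Because all
  elements share one consensus, pooled motif statistics are
  length-independent by construction, which is the property the real L1
  analysis observes. What is *not* modelled: target-site duplications,
  poly-A tails, 3′ transduction, subfamily phylogeny, or real inter-locus
  variation — so passing tests show the pipeline measures
  length-independence correctly, not that real L1s have it.
* `mutate_pair()` applies independent per-site substitutions (transitions
  with probability 2/3, the usual genomic bias) and optional indels,
  returning an edit list that reconstructs the mutant exactly.
* `generate_structure_fixture()` builds balanced, pseudoknot-free
  dot-bracket strings with a target paired fraction; forced unpaired
  windows become hairpin loops with stems placed directly on both flanks,
  so accessibility tests can pin usable lengths exactly. Windows too
  close to the sequence ends for a stem on both sides remain exterior.

## Numerical and degenerate-input conventions

All coordinates are 0-based half-open; RepeatMasker input is converted on
read, BED export needs no conversion. Scanning is deterministic: sites are
sorted by start, and containment removal keeps the unique longest window
per reachable end position. Empty inputs are errors where a statistic
would be undefined (empty length distribution in a KS comparison, zero
windows in a cumulative ratio, zero-length sequence in a profile) and
empty results otherwise (a scan with no hits returns a zero-row table
that still writes a header-only TSV). The r-UC/r-AG ratio is `NA` when
purine occupancy is zero. Alignment traceback follows the C library's
deterministic tie-breaking.

## Problem sizes used by the tests

The shipped suite runs entirely on generated data: scanner-vs-oracle
equivalence on 1,000+ random sequences of ≤ 60 nt, synthetic L1 families
of 120–400 elements from 4–6-kb consensuses, mutated pairs of 4–5 kb, and
the full 6×6 kinetic grid at the study's 10 × 20,000-step layout. The
published per-transcript counts (site numbers, occupancies, the
1.60 ratio, the 0.092 KS distance) require the real XIST/Xist/Rsx
reference transcripts; the corresponding check runs only when those
sequences are supplied locally (see `fetch_transcript()`), since they are
not redistributable with the package.

## Known limitations

* The scanner reproduces documented criteria; where the original
  software's undocumented boundary behaviour differs, the `anchor_bounded`
  flag is the intended triage knob.
* The structure filter is only as good as the supplied structure; it does
  not fold, average over ensembles, or weight by base-pair probabilities.
* Alignment identities are global-alignment figures, not BLAST local
  statistics.
* The kinetic model deliberately ignores linker geometry, site
  heterogeneity and concentration effects; it isolates the cooperative
  acceleration mechanism and nothing else.
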