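# triplexmotif

Scanning and statistics for short triplex-forming sequence motifs in long
noncoding RNAs and LINE retrotransposons, plus a kinetic Monte Carlo model
of cooperative multi-site RNA–DNA binding.

## What it is for

The lncRNAs that drive X-chromosome inactivation (mouse Xist, human XIST,
opossum Rsx) coat a whole chromosome without any known high-affinity
binding site. One candidate mechanism is redundant triplex formation:
many short pyrimidine (r-UC/TC) or purine (r-AG) motifs in the RNA pairing
weakly with complementary stretches of duplex DNA — especially LINE-1
elements — via Hoogsteen or reverse Hoogsteen bonds. This package is for
computational biologists who want to run or extend that analysis:

* **Motif scanning.** An r-UC motif is ≥ 5 nt over {U/T, C} with ≥ 3 nt
  between the first and last U(T), ≤ 3 U(T) in a row and ≤ 2 C in a row;
  the r-AG class mirrors it (U→A, C→G) with the G-run limit lifted in
  reverse Hoogsteen mode. `find_motif_sites()` returns maximal sites;
  `enumerate_motif_windows()` counts every window including overlaps.
* **Statistics.** Per-sequence occupancy, sites/kb and the r-UC/r-AG
  occupancy ratio (`profile_sequence()`); motif-length distributions
  compared by the Kolmogorov–Smirnov distance
  `KS(F₁, F₂) = maxₓ |F₁(x) − F₂(x)|` with 0.100 as the descriptive
  similarity threshold (`ks_distance()`); RepeatMasker family/length-bin
  summaries and reproducible per-bin sampling.
* **Structure filter.** Given a dot-bracket/CT structure, the usable
  (single-stranded, in hairpin/internal/bulge loops, contiguous in one
  loop) length of each motif (`classify_positions()`, `filter_sites()`).
* **Paired-element comparison.** Affine-gap global alignment and the
  fraction of "completely matched" motifs — full-span, gap-free,
  residue-identical (`compare_pair()`).
* **Kinetic MC model.** `N` two-state sites with per-step probabilities
  `k_on`/`k_off` and cooperative acceleration `A·k_on` once any site is
  bound; the dissociation probability `P_diss` (all sites unbound) obeys
  `P_diss = k_off/(k_on+k_off) = 0.99` at `N = 1` and drops below 30% at
  `N = A = 20` (`run_simulation()`, `sweep_pdiss()`).
* **Synthetic data.** Ground-truth generators for motif-planted
  sequences, 5′-truncated L1-like families with RepeatMasker fixtures,
  mutated sequence pairs, and structure fixtures, so the whole pipeline
  runs and is tested offline.

## Worked example

```r
library(triplexmotif)

# a 10-kb synthetic lncRNA with planted motifs at known positions
gen <- generate_motif_sequence(10000, c(uc = 0.09, ag = 0.055), seed = 42)
p <- profile_sequence(gen$sequence, seq_id = "synthetic_lncRNA")
p
#> Motif profile of synthetic_lncRNA (10000 nt)
#>   r-UC: 178 sites, occupancy 11.7%, 17.8 sites/kb
#>   r-AG: 133 sites, occupancy 8.7%, 13.3 sites/kb
#>   r-UC/r-AG ratio: 1.34

d_uc <- length_distribution(p$uc$sites)
d_ag <- length_distribution(p$ag$sites)
round(ks_distance(d_uc, d_ag), 3)
#> [1] 0.033

run_simulation(kinetic_params(N = 20, A = 20, seed = 1))
#> Kinetic MC: N = 20, A = 20, k_on = 0.002, k_off = 0.2 (synchronous)
#>   10 runs x 20000 steps: P_diss = 0.2879 (SE 0.0065)
```

The profile says more of the sequence is covered by pyrimidine than purine
motifs (ratio 1.34 — Xist-like rather than Rsx-like, where the ratio is
far below 1), and the scan finds slightly more than the planted 9%/5.5%
because valid motifs also arise in random background. The two motif-length
distributions are similar (KS 0.033 < 0.100). The simulation shows the
cooperative effect: a single site would dissociate 99% of the time, but
twenty linked sites with twenty-fold binding acceleration stay attached
over 70% of the time.

Real-data mode works from FASTA/RepeatMasker/structure files
(`read_fasta()`, `read_repeatmasker_out()`, `read_structure()`); the
reference transcripts used for per-lncRNA tables can be retrieved with
`fetch_transcript("NR_001564")` etc. when network access is available.

## Layout

* `R/` — scanner, statistics, structure filter, pair comparison, kinetic
  model, synthetic generators, I/O.
* `tests/testthat/` — unit, property and acceptance tests (brute-force
  oracles for the scanner and aligner, an exact birth–death solver for
  the asynchronous simulator).
* `vignettes/triplexmotif-methods.Rmd` — model assumptions, parameter
  choices and limitations.
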