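---
title: "Heavy-ion mutagenesis analysis with ionmut: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heavy-ion mutagenesis analysis with ionmut}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionmut)
```

## The problem

Accelerated heavy ions (for example carbon, `12C6+`) deposit energy densely
along each particle track, quantified by the linear energy transfer (LET,
keV/µm). In plant mutagenesis this concentrated damage produces
double-strand breaks whose error-prone repair leaves a characteristic
footprint: mostly base substitutions and small indels, plus a minority of
large rearrangements whose junctions show microhomology or short filler-DNA
insertions. `ionmut` implements the analytical chain of such a screen:

1. **Dosimetry** — converting between absorbed dose and particle fluence
   per cell nucleus.
2. **Junction calling** — inferring the single mutation event from a
   wild-type/mutant amplicon pair, with placement ambiguity and junction
   microhomology.
3. **Spectrum statistics** — transition/transversion and
   small-versus-rearrangement summaries, plus screening mutation
   frequencies.
4. **Synthetic data** — ground-truthed generators so every stage is
   testable without any external download.

## Dosimetry model

A fluence $\Phi$ (particles/µm²) of LET $L$ (keV/µm) traversing material of
specific gravity $\rho$ deposits, per µm of path,

$$ D \;[\mathrm{Gy}] \;=\; \frac{\Phi \, L \, k}{\rho \times 10^{-15}\,
\mathrm{kg/µm^3}}, \qquad k = 1.602\times10^{-16}\,\mathrm{J/keV}, $$

i.e. $D = 0.1602\, L\, \Phi$ for unit-density water. Fluence is reported
per nucleus cross-section, by convention 100 µm².

```{r}
condition_table(list(c(22.5, 250), c(22.5, 450), c(30.0, 400)))
```

**Numerical note.** Published particle numbers for these three conditions
(6,933; 12,480; 8,320 per 100 µm²) differ from the values recomputed with
the standard constant by ≈0.04%, presumably a rounding in the original
conversion. We deliberately do **not** tune $k$ to match; the package
reports unrounded values plus a nearest-integer convention, and tests
accept 0.1% relative. No particle-hit stochastic model (e.g. Poisson hits
per nucleus) is implemented — none is defined for this analysis.

## The junction caller

For a wild-type sequence $w$ and mutant sequence $m$ differing by one
contiguous event, let $P$ and $S$ be the longest common prefix and suffix
lengths. With $n_s = \min(|w|, |m|)$:

* equal lengths and $P + S = |w| - 1$: a **substitution** at position $P$;
* $|w| \ne |m|$ and $P + S \ge n_s$: an **indel** of size
  $d = \bigl||w|-|m|\bigr|$ whose valid placements form the contiguous
  0-based interval $[\,n_s - S,\; P\,]$;
* anything else: **complex** (two or more mismatch blocks), excluded from
  spectrum tallies.

The number of placements minus one, $P + S - n_s$, is reported as both the
**ambiguity span** and the **junction microhomology** (`mh_length`): a
deletion whose flank repeats the start of the deleted segment can be placed
at several positions precisely because the repeated bases are
microhomologous. `enumerate_placements()` is a brute-force enumerator kept
deliberately independent of the closed-form rule; the test suite asserts
their agreement on the packaged catalogue and on thousands of random pairs.

Conventions and edge cases:

* **Left alignment.** `canonical_start` is the left-most valid placement
  (the convention of VCF-style variant normalisation). Published
  catalogues do not always state their alignment, so genomic coordinates
  are compared by interval membership, not identity.
* **Ambiguity vs size.** For a deletion inside a long repeat the ambiguity
  span can exceed the deletion size (deleting one unit of a $k$-unit
  homopolymer has $k$ placements). We therefore do not assert
  `mh_length <= size`; the *generator* does reject planting requests with
  `mh > size`, because it engineers the repeat inside the deleted segment.
* **Printed markup vs enumeration.** One catalogued 4-bp deletion
  (`C30-155-hy1`) marks a single microhomologous base in print, but
  exhaustive enumeration yields three placements (mh 2). The fixture keeps
  both values; the caller reports the enumerated one.
* **N bases.** An `N` within `max(mh, 5)` bp of the event invalidates the
  call (error, flagged for manual review) rather than guessing.
* **Case.** Input is uppercased on ingest; lowercase deletion markup in
  printed tables is preserved only in fixture truth columns and never
  parsed.

### Partially printed junctions

Long deletions are often catalogued as
`left_flank  del_prefix ... del_suffix  right_flank`. The microhomology is
still exact: count left shifts $L$ (trailing bases of `del_suffix` equal to
trailing bases of `left_flank`) and right shifts $R$ (leading bases of
`del_prefix` equal to leading bases of `right_flank`); `mh = L + R`. Each
count is capped at the printed fragment length, and reaching the cap
without a mismatch yields an explicit *undetermined (≥ k)* result instead
of a number.

```{r}
mh_from_partial("AGTGGTCTT", "cttcgc", "ctcctt", "AGAGTT", 51)
```

### Rearrangement joints

`analyze_rearrangement()` classifies a junction-spanning read against its
two donor segments by the **maximal-anchor rule**: the longest prefix of
the read occurring in the 5′ donor and the longest suffix occurring in the
3′ donor (each must reach the `min_anchor`, default 10 bp exact match, or
the junction is *unresolved*). Overlapping matches ⇒ microhomology joint;
abutting ⇒ blunt; a gap ⇒ filler DNA. Breakpoint deletions are measured
against nominal breakpoints assuming maximal retention on each side — with
microhomology the shared bases cannot be attributed to one donor, so
"maximal retention" is a stated convention, not an inference. Ties between
equally long anchor placements go to the left-most occurrence.

## Spectrum and frequency statistics

* **Small vs rearrangement.** "Small" means base substitutions and indels
  *strictly* below the threshold (default 100 bp, from the "less than
  100 bp" convention; a 100-bp deletion is a rearrangement). Translocation
  (`RTL`) and complex (`CR`) rows are rearrangements; `NM` rows are
  excluded, not counted.
* **Rounding.** Percentages: 1 decimal; per-mil frequencies: 2 decimals;
  both half-away-from-zero (matching printed values such as 83.3 and
  0.78). Base R's banker's rounding is not used.
* **Frequencies.** The denominator is M2 plants screened; M1 counts are
  metadata. The point estimate is $1000k/n$ per-mil. The attached 95%
  Clopper–Pearson interval and the Fisher exact test in
  `frequency_ratio()` are *additions*, labelled as not part of the
  published arithmetic (which reports point estimates only). The ratio CI
  conditions on the total mutant count: given $k_a + k_b$, $k_a$ is
  binomial with odds proportional to the frequency ratio times the cohort
  size ratio.
* **Two-fold comparisons.** Which baseline a "two-fold higher" claim uses
  can be ambiguous; `frequency_ratio()` takes explicit cohort pairs so all
  candidate baselines can be reported side by side.
* **Dose–response.** `interpolate_fluence()` does piecewise-linear
  interpolation of fluence at a response level and refuses to extrapolate
  outside the observed range.

## The synthetic-data generator

`spectrum_spec()` fixes the stated world of the generator:

| parameter | default | rationale |
|---|---|---|
| class mixture | 4 : 13 : 1 : 1 : 3 / 22 | empirical catalogue of 22 identified alleles (BS, small del, small ins, large del, translocation) |
| Ti/Tv expectation | 1/3 | 1 transition : 3 transversions observed |
| small indel sizes | 1–51 bp | observed small-indel range |
| large deletion sizes | 100–35,000 bp | spans the one observed 32,335-bp deletion |
| simple-deletion mh | 0–3 bp | observed junction microhomology range |
| junction mh | 2–5 bp | observed at rearrangement joints |
| filler DNA | 3–16 bp | observed filler range |
| breakpoint deletions | 9–28 bp, P(present) = 0.8 | 4 of 5 observed breakpoints deleted |
| amplicon length | 400–900 bp | typical Sanger amplicons (not stated in the source screen) |
| GC fraction | 0.36 | *A. thaliana* genomic GC |

Two design choices matter:

* **Retry-and-verify, not analytic construction.** `plant_deletion()`
  engineers a repeat of the requested microhomology length plus stop bases,
  then *re-measures* the finished pair with the caller and the brute-force
  enumerator, retrying (up to 100 times) on accidental extra homology. The
  recorded truth is the realised value, which is what makes the
  generator→caller closed loop exact by construction rather than
  approximately right.
* **Single seeded RNG stream per dataset.** `generate_dataset()` takes one
  seed, records it in the truth-file header, and identical seeds give
  byte-identical output files.

What the generator does **not** emulate — so a green closed-loop test does
not establish it: sequencing errors or chromatograms, heterozygosity,
multi-event alleles, genome-scale context (amplicons are i.i.d. random),
particle-track physics, or batch structure among mutant isolates
(deduplication of sibling isolates is an input-side concern and off by
default).

Cohort simulation is plain binomial sampling of mutants among M2 plants at
a per-mil frequency; the coverage of the Clopper–Pearson interval at the
catalogue's largest cohort (n = 29,595, 0.78 ‰) is 96.4% analytically,
and the Monte Carlo check in the test suite (1,000 replicates, fixed seed)
must land in 93–97%.

## Known limitations

* The caller assumes at most one contiguous event per pair; anything else
  is `complex` and excluded from spectra. This mirrors per-allele
  single-event catalogues but cannot describe, e.g., two nearby
  substitutions.
* Insertions are not sub-classified into filler vs tandem duplication (no
  published rule to follow); their ambiguity span is reported the same way
  as for deletions.
* Breakpoint-deletion sizes at microhomology joints depend on the
  maximal-retention convention described above.
* The dosimetry module covers fluence–dose bookkeeping only: no
  depth–dose/Bragg-peak modelling, no LET spectra, no survival mechanism.
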