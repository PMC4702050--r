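---
title: "Degradome-guided discovery of miRNA–miRNA* duplexes"
author: "degradomir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degradome-guided discovery of miRNA–miRNA* duplexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

miRNA biogenesis ends with an RNase III cut: Dicer (DCL1 in plants)
releases the miRNA–miRNA\* duplex from the precursor hairpin with two
staggered double-strand cuts that leave 2-nt 3′ overhangs. Every cut
produces a downstream RNA fragment with an uncapped 5′ monophosphate — the
molecule degradome/PARE sequencing is designed to capture. The 5′ ends of
degradome tags therefore accumulate at four positions per duplex: the
mature's 5′ end, one past its 3′ end, the star's 5′ end and one past the
star's 3′ end. `degradomir` turns this observation into a discovery
pipeline: find genomic positions where degradome 5′ ends dominate their
neighbourhood, ask whether a plausible hairpin surrounds them, and then ask
whether small-RNA reads form the duplex that those cuts would have
produced.

The chain of filters deliberately moves from cheap and permissive to
expensive and strict: signal calling (string matching and counting) →
windowed folding (RNAfold) → stem complementarity (pair-table counting) →
duplex geometry (overhang rule + sRNA evidence) → optional AGO enrichment.

## Coordinates

Genomic coordinates are 0-based half-open internally and 1-based inclusive
in every report. Positions *within* a candidate or precursor are 1-based
inclusive in transcript orientation (the natural indexing for R strings and
pair tables); the pair table maps position *i* to its partner or `NA`.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `fragment_len` / `overlap` | 10,000 / 500 nt | genome scanning windows; the overlap exceeds any candidate-anchoring distance so no signal is lost at fragment joins |
| `ratio` | 5 | local dominance: position mean RPM ≥ ratio × flank baseline |
| `flank_w` | 50 nt | flank half-width for the baseline; brackets a full miRNA-sized neighbourhood on each side |
| `rank_k` | 12 | the strongest tag at a signal must rank in the fragment's top-k distinct tags (per strand, competition ranking) |
| `L` | longest registered hairpin | candidate window size is 30 + L |
| `stem_threshold` | 0.70 (strict >) | fraction of a 30-nt anchor-flanking region paired outside itself |
| `len_min`–`len_max` | 18–25 nt | sRNA lengths considered miRNA-plausible |
| `max_unpaired` | 0.5 | tolerated unpaired fraction inside mature/star spans (plant duplexes contain bulges) |
| `ago_min_rpm`, `ago_fold` | 1 RPM, 3× | AGO-IP floor and enrichment over control |

`ratio`, `rank_k`, `stem_threshold`, the AGO defaults and the fragment
geometry are the published operating points of the underlying extraction
criteria; `flank_w`, `max_unpaired` and the anchoring window below are
package choices, exposed as configuration.

### Choices the criteria leave open

* **Flank baseline.** "The surrounding region" is implemented as the mean
  RPM over *tag-bearing* positions within ±`flank_w`; positions with no
  tags do not enter the baseline, and an empty flank passes the criterion
  vacuously. A `stat = "sum"` variant is available for sensitivity
  analysis.
* **Ranking scope.** Fragment prominence is computed per strand, so a
  hotspot on one strand cannot mask signals on the other; ties share a
  competition rank.
* **Threshold ties.** "Five times *or more*" must pass at exact equality.
  Integer read counts make exact ties common, so the comparison carries a
  `1e-9` relative guard; otherwise the decision would depend on
  floating-point association order.
* **Anchoring.** A mature cluster is tied back to its signal when the
  cluster's 5′ end, or the position one past its 3′ end, lies within 3 nt
  of the signal — the same −3..+3 migration the end-support profiler
  measures. Either end qualifies; the matched end is recorded.
* **Multi-mapping tags** contribute their full RPM at every locus (no
  apportioning rule is defensible without a mapping model), and signals
  rediscovered inside fragment overlaps are deduplicated by genomic key.
* **Stem regions at candidate edges** are scored over their actual
  (truncated) length.
* **One-sidedness.** A passing 30-nt region must send all its outside
  partners to one side; this is the cheap surrogate for "classic stem-loop"
  retention and rejects pseudoknot-like pairing scatter.
* **Mean per distinct tag.** The "averaged" abundance at a position is the
  mean over distinct tag sequences, not the sum; with fixed-length PARE
  tags the distinction only matters where tags of different lengths share a
  5′ end.

## Folding

RNAfold (ViennaRNA) computes the MFE structure; sequences are handled
DNA-side and RNAfold's default T→U conversion applies. The pluggable
fallback engine is a Nussinov base-pair maximization (canonical + wobble
pairs, minimum loop 3) whose `mfe` is the negated pair count — a surrogate
score used for dependency-free testing, not an energy. Stem
complementarity of a region is the fraction of its positions paired
*outside* the region on the MFE pair table; G:U wobbles count as paired
because the engine pairs them. Duplex geometry is re-verified after
trimming (duplex ± 5 nt) on the refolded precursor: exactly for
overhang-mode calls, within 3 nt for isomiR\*-fallback calls.

## What the generator emulates

`plant_spec()` describes a seeded world: a uniform random genome;
`n_hairpins` perfect inverted repeats (default 30-bp stem, 8-nt loop) each
hosting a 21-nt mature at stem offset 5 with the star at exact 2-nt 3′
overhang coordinates; one 20-nt degradome tag per duplex end with raw count
`scar_rpm_fold` (10); singleton 20-nt background tags as a Poisson process
at `background_tag_rate` (600 per kb per strand); sRNA isomiR clouds with
geometrically decaying counts (ratio 0.5, spread ±2) over mature (100) and
star (30) reads plus scattered background; and an AGO/control pair in which
planted matures are ≥ 3× enriched.

Two generator constants deserve justification:

* **20-nt tags.** PARE signatures have a fixed length. This matters beyond
  realism: with variable-length tags, a background tag sharing a scar's 5′
  end would be a *distinct* sequence and the per-distinct-tag mean would
  halve the scar's apparent abundance; with a fixed length it is the same
  sequence and the counts collapse at pre-treatment, as in real libraries.
* **Background density.** The 2–3 sibling scar positions of a duplex fall
  inside each other's 50-nt flanks, so with no background the baseline at a
  scar would equal the scar abundance and nothing would pass a 5×
  criterion. With *m* tag-bearing flank positions of unit count and *k*
  sibling scars of abundance 10, the baseline is ≈ (10k + m)/(m + k); at
  0.6 tags/nt/strand, E[m] ≈ 45 keeps it below 2 — half the 10/5 operating
  point — with large margin.

The generator does **not** emulate: imperfect stems and bulged duplexes,
expression-correlated (transcript-shaped) degradome background, sequencing
error, multi-mapping repeat families, or non-miRNA sRNA classes (phased
siRNAs, tRFs). Passing the planted-recovery tests therefore demonstrates
the pipeline's geometry and bookkeeping, not its behaviour on the messier
backgrounds of real libraries. One fixture artifact is worth knowing:
a *perfect* inverted repeat reads as a hairpin on both strands, so planted
duplexes are also discovered in mirror orientation, and star-anchored
signals yield the arm-swapped record; these are genuine duplicates of the
same duplex, not false positives.

## Problem sizes

The shipped tests run the full pipeline on a 500-kb genome with 20 planted
hairpins (the package's standard demonstration world), a matched
background-only genome, an 80-kb five-hairpin world for the end-to-end and
resume tests, and 200 sub-2-kb fragments for the signal-caller/brute-force
equivalence suite. These sizes were chosen so the whole suite exercises
every stage at realistic per-fragment densities (~0.6 background tags per
nt per strand) while remaining a desk-scale computation.

## Degenerate inputs and numeric details

* Libraries that are empty after pre-treatment raise an error naming the
  library; candidate windows truncated below 60 nt, windows containing
  `N`, and matures whose duplex ends are unpaired produce recorded
  no-calls, not errors.
* A signal position must carry at least one tag 5′ end; mean RPM is over
  distinct tags.
* Ties in cluster ordering are broken by RPM, then start, then sequence,
  making every report deterministically ordered by (chrom, start, strand)
  regardless of worker count or fragment scheduling.
* Checkpoints are per fragment; a corrupted checkpoint is reprocessed with
  a warning. Manifests contain parameters and input MD5 sums, never
  timestamps, so resumed and restarted runs rewrite byte-identical
  outputs.

## Known limitations

* Exact-match mapping only: no mismatches, no spliced alignment, no
  quality handling — inputs are assumed pre-processed collapsed reads.
* One duplex per precursor; loop-derived and phased sRNAs are out of
  scope.
* The AGO filter tests the called mature/star sequences only, not their
  isomiRs.
* The end-support profiler requires the mature to occur verbatim in its
  hairpin record and skips (with a warning) records where it does not.
* Stem complementarity is measured on a single MFE structure; suboptimal
  ensembles and partition-function pairing probabilities are not
  consulted.
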