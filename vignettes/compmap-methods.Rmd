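---
title: "Methods: competitive mapping, PMD scoring and the simulated world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: competitive mapping, PMD scoring and the simulated world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the model behind
each stage, the tunable parameters and their defaults, what the simulator
does and does not emulate, the numerical choices, and the limitations. It
states no empirical result that the test suite or `scripts/acceptance.R` do
not themselves compute.

## 1. Competitive mapping and read fates

The method's premise is that an aligner given a reference containing *both*
the target-species genome and the human genome will resolve each read's
origin by fit. A read from a region identical in both genomes has two
equally good placements; standard aligners encode that ambiguity as a low
mapping quality (MAPQ ~0), so the routine `MAPQ > 30` filter is precisely
what discards dual-part reads. compmap therefore never re-implements
alignment arbitration — it classifies finished alignment records:

1. `UNMAPPED` — flagged unmapped;
2. `TOO_SHORT` — read (query) length `< min_length` (default 30 bp). The
   length filter keys on the read sequence, not the alignment span, because
   it stands in for the post-merging length cutoff applied to reads, and it
   outranks the MAPQ test so that a short read is reported as short rather
   than ambiguous;
3. `AMBIGUOUS` — `mapq <= mq_threshold` (default 30, strict `>` to pass);
4. `TARGET` / `CONTAMINANT` — by the manifest part of the reference
   sequence.

Part attribution relies on a written 4-column manifest
(`sequence_name, part_label, original_name, length`), with the
`"<label>|<name>"` prefix kept as a human-readable convenience. The
manifest is authoritative because aligners truncate sequence names at
whitespace and `|` may appear in accessions; the separator is configurable.
Chromosome names collide between mammalian assemblies (`chr1` exists in
both), so prefixing at concatenation time is unavoidable; names are
restored to their originals when `split_by_fate` writes per-part files, so
downstream tools see ordinary coordinates.

The `AMBIGUOUS` class is always *counted* but there is no dedicated output
file by default: the class is defined by the MQ filter, and callers that
need the records can subset by the returned fate factor. Secondary and
supplementary records are dropped before counting so the unit is reads,
not alignments.

Duplicate removal keys on (reference, start, end, strand). Start-only
duplicate marking over-collapses ancient libraries, where genuinely
distinct short molecules often share a 5′ endpoint; requiring both
fragment ends to match avoids that. Among copies, the record with the
highest summed base quality is kept (ties: first in file order) — a
deterministic rule that retains the best-evidenced molecule. Strand can be
excluded from the key (`ignore_strand = TRUE`) for protocols where
opposite-strand records are known artifacts.

## 2. The PMD score

Deamination converts cytosines in single-stranded overhangs to uracils,
read as C→T near the 5′ end and G→A near the 3′ end. The per-position
damage probability is geometric with a constant floor:

$$D(z) = p\,(1-p)^{z-1} + c, \qquad z = 1, 2, \dots$$

Defaults `p = 0.3`, `c = 0.01` are the conventional single-stranded-library
values of the tool that introduced PMD scoring; the polymorphism baseline
is `pi = 0.001`. All three are exposed as arguments/flags because the
appropriate `p` varies with sample age and library chemistry.

Per read, the score sums over *informative sites* — aligned positions whose
reference base is C (z measured from the 5′ end of the molecule) or G
(z from the 3′ end) — the log-ratio of the damage likelihood to a null
likelihood. With mismatch probability $m(z) = D(z) + \pi - D(z)\pi$ and
base-call error $\varepsilon = 10^{-Q/10}$:

$$L(\mathrm{T}\mid \mathrm{ref\,C}) = m(1-\varepsilon) + (1-m)\varepsilon/3,
\qquad
L(\mathrm{C}\mid \mathrm{ref\,C}) = (1-m)(1-\varepsilon) + m\varepsilon/3,$$

the null model using $m = \pi$. Reference-G sites mirror with G→A.
Numerical choices:

* **Strand.** Damage is a property of molecule ends, not reference
  orientation, so minus-strand alignments are flipped (complemented,
  position-reversed) before scoring. A property test asserts a read scores
  identically under both storage orientations.
* **Indels/clips.** z is the position in the stored query sequence, so
  insertions and soft-clips advance z but are never scored; deleted
  reference bases are skipped without recalibrating z. This matches a
  substitution-only damage model and keeps results reproducible.
* **Other observed bases** (e.g. ref C, obs G) contribute zero and are not
  counted as informative; a read with no informative site scores exactly 0.
* **Degenerate models.** With `p = 0, c = 0` the damage and null models
  coincide and every score is exactly 0 (tested).

The per-sample summaries are **PMD^R** — the fraction of reads with score
strictly greater than 5 (the conventional authenticity threshold; strict
by definition) — and **mRL**, the median alignment length (mean of central
values for even n).

## 3. Conserved-region calling

One genome (operationally: human) is tiled into all overlapping k-mers
(`k = 30`, `step = 1`) and each tile is placed on the other genome. The
published procedure maps tiles with a production aligner and keeps
placements with MAPQ ≥ 30; for a 30 bp read that filter effectively means
"placed exactly once". The internal mapper makes that criterion literal: a
tile is kept iff it has **exactly one placement across both strands** with
at most `max_mismatches` (default 0) mismatches. This is exhaustively
verifiable — the test oracle slides every k-mer and string-searches the
destination — which an external aligner's MAPQ is not. Users who prefer
the aligner route can feed a tile SAM to `conserved_from_sam()`, which
applies the literal MAPQ ≥ 30 filter.

Design points: N-containing tiles never match; hits are reported on the
destination's forward strand; intervals are the union of `[start,
start+k)` over unique hits, merged to maximal sorted non-overlapping
BED-style intervals *in destination (target-genome) coordinates*, because
loss accounting intersects target-genome alignments. Mismatch-tolerant
mapping falls back to a per-tile scan and is intended for small genomes
only — production-scale tiling of a mammalian genome belongs to the
external-SAM path.

Loss accounting compares MQ-passing reads before (single-reference) and
after (TARGET fate) competitive mapping: `loss = 1 − n_after/n_before`,
genome-wide and restricted to reads overlapping a conserved interval by
≥ 1 bp. An empty original set makes the ratio undefined (`NA` + warning),
never a division by zero.

## 4. The simulated world

The simulator emulates the single feature mix that matters to this
pipeline: **short damaged fragments from the target genome diluted with
fragments from a contaminant genome**, with truth labels carried through.
The stated defaults are fixed once:

| parameter | default | rationale |
|---|---|---|
| target fragment length | lognormal(meanlog = log 55, sdlog = 0.35), truncated 25–150 bp | typical ancient-DNA size distribution with a ~55 bp median |
| contaminant fragment length | lognormal(log 120, 0.3), 35–300 bp | modern library fragments |
| target damage | p = 0.3, c = 0.01 | matches the PMD default |
| contaminant damage | p = 0, c = 0 | modern DNA is undamaged |
| error rate | 0.001 (flat Q30) | Illumina-like base quality |
| contamination fraction | 0.05 | a visibly contaminated but plausible library |

The contaminant length model is deliberately a knob: real faunal BAM files
show the *opposite* pattern — contaminant human reads are shorter than
endogenous ones, because only short human fragments align to conserved
regions of a foreign genome — and lowering the contaminant
`min_len`/`meanlog` reproduces that regime for tests of the mechanism.

Each dataset yields a FASTQ, a truth TSV and a **truth SAM** that places
every read at its true origin with MAPQ 60 against the concatenated
reference. The truth SAM exists so the classifier can be exercised without
an external aligner; for end-to-end tests of the *ambiguity* mechanism the
package ships a minimal exact-match read mapper (`map_reads_exact`) that
assigns MAPQ 60 to uniquely placed reads and MAPQ 0 to multi-placed ones —
reads simulated from a segment shared between the genome parts then fall
to the MQ filter exactly as with a real aligner.

Determinism: a single Mersenne-Twister stream (R's default, pinned
explicitly) drives origin choice, placement, damage and errors in a fixed
order; the same seed reproduces byte-identical FASTQ/TSV/SAM on any
platform.

What the simulator does **not** emulate — and hence what a green test does
not establish: paired-end reads and overlap merging, microbial background,
reference bias, indel errors, position-dependent quality profiles, PCR
duplicates, and real genome repeat structure (random i.i.d. genomes are
repeat-free, so unique placement is easier than in real mammalian
sequence). Conclusions about real-data contamination *rates* cannot be
drawn from simulation; the tests establish correctness of the machinery,
not field performance.

## 5. Statistics

`wilcoxon_rank_sum` computes midranks, the Mann–Whitney U and an exact
p-value from the exact U distribution when `n1 + n2 ≤ 10` and the pooled
data are tie-free, otherwise a normal approximation with tie correction
and (by default, toggleable) continuity correction. Conventional software
prints U under the name "W"; the result carries `U`, `W` (= U) and the
rank-sum of the first sample explicitly, and the orientation (which group
is `x`) is the caller's, stated in the output rather than guessed.
`linear_fit_r2_f` is ordinary least squares with the `(1, n−2)` F test;
with one predictor F = t² of the slope, which the tests verify
numerically. Raw p-values are reported; no multiple-testing correction is
applied, matching the one-comparison-at-a-time usage.

## 6. Known limitations

* The recovered contaminant fraction is a **lower bound**: an unknown share
  of the discarded ambiguous reads is also contaminant, and nothing at the
  read level can apportion it.
* The internal mappers are exact-match tools for desk-scale genomes; real
  datasets should be aligned externally and ingested as SAM/BAM.
* PMD parameters are not estimated from data (no EM fit); users supply
  them.
* SAM ingestion keeps primary records only and assumes single-end reads
  (pair merging happens upstream).
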