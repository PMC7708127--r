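# compmap

Competitive mapping against a concatenated two-species reference to detect
and exclude **human contaminant reads from ancient faunal sequencing
data**, with the authentication statistics used to characterise what was
removed.

## The problem

Ancient-DNA libraries from non-human animals (mammoths, ancient dogs, …)
almost always carry some human DNA picked up during excavation and
laboratory handling. A fraction of those human reads aligns confidently to
the faunal reference genome — concentrated in evolutionarily conserved
regions — and therefore survives the standard mapping pipeline, ending up
inside the "endogenous" BAM file where it can distort heterozygosity,
runs-of-homozygosity and rare-variant analyses.

The remedy implemented here is *competitive mapping*: build one reference
FASTA containing every chromosome of the target species **and** of the
human genome, and map the raw reads against it. The aligner then
arbitrates each read:

* reads fitting only the **target part** — endogenous, kept;
* reads fitting only the **human part** — contamination, removed;
* reads fitting **both parts** (conserved or identical regions, plus short
  microbial hits) — assigned low mapping quality by the aligner, hence
  discarded by the standard `MAPQ > 30` filter.

compmap provides every piece of that workflow downstream of the aligner,
plus a simulator so the whole pipeline is testable from first principles:

| module      | what it does |
|-------------|--------------|
| `build_concatenated_reference` | concatenated FASTA + part manifest (`target|chrN`, `human|chrN`) |
| `split_by_fate`, `assign_fate` | classify records into TARGET / CONTAMINANT / AMBIGUOUS / UNMAPPED / TOO_SHORT and split per-part SAMs |
| `deduplicate_alignments` | PCR-duplicate removal keyed on *both* fragment ends (and strand) |
| `pmd_score`, `pmd_ratio`, `median_read_length` | per-read post-mortem-damage likelihood scores; per-sample PMD^R and mRL |
| `conserved_regions` | conserved-region discovery: 30 bp k-mer tiling of one genome, uniquely placed on the other, merged to BED |
| `compute_loss` | data lost to competitive mapping, genome-wide vs in conserved regions |
| `simulate_dataset` | deterministic simulator: short damaged target fragments + longer undamaged contaminant fragments, with truth FASTQ/TSV/SAM |
| `wilcoxon_rank_sum`, `linear_fit_r2_f` | group comparisons (exact rank-sum for small samples; OLS r², F) |

## The damage model

A read from an authentic ancient molecule shows an excess of C→T
substitutions near its 5′ end (and G→A near the 3′ end) from cytosine
deamination in single-stranded overhangs. The per-position damage
probability is

```
D(z) = p (1 − p)^(z−1) + c        z = 1, 2, … distance from the fragment end
```

with defaults `p = 0.3`, `c = 0.01`. The per-read **PMD score** is the
log-likelihood ratio, summed over aligned reference-C positions (z from
the 5′ end) and reference-G positions (z from the 3′ end), of a damage
model with mismatch probability `m(z) = D(z) + π − D(z)π` against a null
model with `m = π` (polymorphism rate, default 0.001), both weighted by
the base-call error `ε = 10^(−Q/10)`. A sample's **PMD^R** is the fraction
of its reads with score > 5; **mRL** is the median read length. Authentic
ancient read sets have high PMD^R and low mRL.

## Worked example

```r
library(compmap)

set.seed(100)
target <- random_genome(c(chrT = 50000L))      # stand-in mammoth chromosome
human  <- random_genome(c(chr1 = 50000L))      # stand-in human chromosome

cfg <- sim_config(target, human, n_reads = 5000, contamination_fraction = 0.05)
sim <- simulate_dataset(cfg, "simout", seed = 42)

aln <- read_alignments(sim$truth_sam)
res <- split_by_fate(aln$alignments, aln$seqinfo, sim$manifest,
                     target_out = "endogenous.sam",
                     contaminant_out = "contaminant.sam")
print(res$counts)
#> read fates (n = 5000 ):
#>   target       4606
#>   contaminant  256
#>   ambiguous    0
#>   unmapped     0
#>   too_short    138

ref <- build_concatenated_reference(target, human)$sequences
scores <- pmd_score(transform(res$target, rname = paste0("target|", rname)),
                    damage_model(p = 0.3, c = 0.01, pi = 0.001), ref)
cat(sprintf("PMD ratio (scores > 5): %.3f\n", pmd_ratio(scores)))
#> PMD ratio (scores > 5): 0.182
cat(sprintf("median read length:     %.0f bp\n", median_read_length(res$target)))
#> median read length:     56 bp
```

Reading the numbers: of 5,000 simulated reads, 256 (5.1%) were recovered
as human contamination — the simulator planted 5% — 138 fell below the
30 bp length filter, and none were ambiguous because the two random
genomes share no 30-mer. The retained endogenous reads show PMD^R ≈ 0.18
(damage was simulated at `p = 0.3`; undamaged modern sets score ≈ 0) and a
56 bp median fragment length, both typical of authentic ancient DNA.

Comparing PMD^R between groups of samples:

```r
w <- wilcoxon_rank_sum(c(0.21, 0.18, 0.25, 0.19), c(0.01, 0.00, 0.02, 0.01))
print(w)
#> Wilcoxon rank-sum: W = 16 (rank sum of x = 26), p = 0.0294 [normal_approx, two_sided]
```

## Command line

```sh
compmap build-ref --target mammoth.fa --human human.fa -o concat.fa --manifest concat.parts.tsv
compmap classify  --bam sample.sam --manifest concat.parts.tsv --mq 30 --min-len 30 -o out/
compmap pmd       --bam out/sample.target.sam --ref mammoth.fa -o pmd.tsv
compmap conserved --source human.fa --dest mammoth.fa -k 30 --step 1 -o conserved.bed
compmap loss      --original single.sam --competitive out/sample.target.sam --bed conserved.bed -o loss.json
compmap simulate  --config sim.cfg -o simout/ --seed 42
```

(`compmap` is installed at `<library>/compmap/exec/compmap`.)

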