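---
title: "Methods: species identification and authentication of parchment mtDNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: species identification and authentication of parchment mtDNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Parchment is prepared animal skin — usually calf, sheep, or goat — and the
DNA it retains is scarce, fragmented, and mixed with human touch DNA from
centuries of handling. Given capture-enriched paired-end sequencing reads
from a parchment sample and a panel of candidate mitochondrial reference
genomes, `parchmentid` answers two questions: *which species furnished the
skin*, and *how much should that call be trusted*. The mitogenome is the
practical target because its high copy number survives the lime baths and
scraping of parchment making, and it is well characterized across the
candidate species.

The workflow is: merge overlapping read pairs → quality-trim → map each
merged read competitively against every panel reference → remove PCR
duplicates by coordinates → build a consensus mitogenome on the top
non-human reference → pass it through a four-criterion sequential
authentication gate, with a Kimura-80/UPGMA bootstrap tree as the final
placement check → report human contamination alongside.

## Pipeline stages and their assumptions

### Read merging and trimming

Degraded endogenous fragments (mean ≈ 119 bp) are shorter than twice the
151 bp read length, so genuine parchment fragments produce overlapping
pairs. `merge_pair()` scans every overlap length ≥ `min_overlap` (default
15 bp), scores it as matches − mismatches, and accepts the best overlap
whose mismatch rate is ≤ 0.2; within the overlap each base comes from the
higher-quality mate. **Only merged reads continue** — an unmerged pair is
far more likely adapter chatter, long contaminant DNA, or an unpaired
artifact than authentic parchment DNA. The merge parameters are
conventional values for short degraded inserts and are fully configurable;
no published parameterization exists for the original workstation workflow
this emulates, so the defaults are our own and are logged in every run.

`mott_trim()` is the modified-Mott algorithm: each base contributes
`limit − 10^(−Q/10)` (error-probability limit 0.05 by default) and the
retained segment is the contiguous run maximizing the sum. Ties go to the
leftmost segment (smallest start, then smallest end) for determinism; N
bases count as quality 0. The implementation is checked against an
exhaustive all-substrings oracle in the tests.

### Competitive mapping

Each merged read is aligned to *every* panel reference — k-mer seeding
(k = 13) followed by affine-gap local dynamic programming on the seeded
windows (match +1, mismatch −2, gap of length *g* costs 3 + *g*), both
strands, with a minimum score of 0.8 × read length. Mitogenomes are
circular: each reference is extended by one read length so origin-spanning
reads get one contiguous hit, and coordinates are reported modulo the
reference length.

A read is assigned only when exactly one reference achieves the maximal
score; reads scoring equally against two or more references are **ignored,
not placed arbitrarily** — with several closely related candidate species
in one panel, an arbitrary placement would manufacture false support.
Score ties are exact integer equality, evaluated after indel
left-normalization (every gap run shifted to its leftmost score-equivalent
position, so homopolymer indels are placed consistently — the local
realignment step). PCR duplicates are then removed per reference: hits
sharing (start, stop, read length) collapse to one representative, chosen
by highest mean quality then smallest read id — the survivor choice is
arbitrary in principle, so it must at least be deterministic.

Counting convention: `per_reference_counts` are pre-deduplication assigned
counts, so assigned + ties + unmapped always equals the reads that entered
mapping; the retained hit table is post-deduplication and is what the
consensus is built from.

### Consensus and the authentication gate

The consensus stays in the reference coordinate frame: per position, no
coverage (depth < 1) gives N, a strict base majority gives that base, an
exact tie gives the IUPAC code of the tied bases; insertions relative to
the reference are logged but not emitted, and majority deletions are
annotated while the sequence stays reference-length. The frame choice
matters because criterion 2 ("percentage of the mtGenome covered") is
reference-relative. With the default depth floor of 1, positions with ≥ 1
read and non-N consensus positions coincide, which resolves an ambiguity
in how breadth could be counted. A depth floor of 1 is deliberate: the
workflow this models reported ~80–100% breadth even for low-coverage
samples, which is only possible without a high floor.

The gate evaluates strictly in order and stops at the first failure
(later criteria are `not_evaluated`, and a species is assigned only on a
full pass):

1. mean mapping coverage > 10×;
2. breadth (non-N fraction of the reference) > 90%;
3. best database match with E-value < 0.001 **and** identity > 99%
   **and** query coverage > 95%;
4. the consensus clusters in the tree with the assigned species.

All boundaries are strict inequalities, exactly as stated. Criterion 3
runs against the *local panel* rather than a live online search:
determinism and offline reproducibility outweigh database breadth here,
and any near-full-length, high-identity match yields an E-value many
orders of magnitude below 0.001, so the criterion is insensitive to that
substitution. The E-value is Karlin–Altschul, `E = K·m·n·e^(−λS)`, with
ungapped defaults λ = 1.33, K = 0.621 for the +1/−2 scheme (configurable);
a hook writes the consensus FASTA for an optional external search but
never blocks or fetches.

### Phylogenetic placement

K80 distances are computed from a MAFFT multiple alignment of the
consensus plus all panel references. We use MAFFT (deterministic
progressive alignment, on PATH) rather than an internal progressive
aligner: it is the practitioner-standard tool, and the tests validate the
alignment against direct pairwise dynamic programming, which keeps the
choice honest. Columns with a gap, N, or ambiguity code in either
sequence are excluded from the transition/transversion counts, because
K80 is defined on unambiguous bases. Saturated pairs (log argument ≤ 0)
are flagged undefined and must be excluded before tree building.

UPGMA is used because the original analysis used it; it yields a rooted
ultrametric tree (checked to 10⁻⁹), with ties in the minimal distance
broken by matrix order. The human reference appears as an outgroup in
practice purely because it is the most distant leaf — UPGMA has no rooting
option. Bootstrap support resamples alignment columns (default 1000
replicates; desk-scale runs use 100) and counts exact tip-set matches of
each original clade. The criterion-4 "clusters with" is operationalized
as: *the reference leaf with minimal patristic distance to the sample
leaf belongs to the assigned species* — a documented choice, since
"clusters with" is qualitative; the nearest-leaf reading is the strictest
one that is still well defined on any tree.

### Contamination profiling

`human_fraction()` is the percentage of *all reads entering mapping* (not
just assigned reads) that were assigned to the human reference — the
denominator choice mirrors how "percentage of total reads per sample" is
naturally read. The length contrast compares mapped-read lengths of the
human-assigned and source-assigned fractions with a pooled-variance
Student's t (Welch available behind a flag; the pooled form is what the
name "Student's t" means). Human touch DNA is modern and longer
(≈ 149 ± 18 bp) than the degraded endogenous fraction (≈ 119 ± 21 bp), so
a significant contrast is itself a mark of authenticity. No
multiple-testing correction is applied to these descriptive comparisons.

## The synthetic generator: what it emulates, what it does not

`simulate_sample()` is a first-class module, not a test shim. Its
defaults *are* the study conditions the package targets:

| parameter | default | meaning |
|---|---|---|
| endogenous fragment length | 119 ± 21 bp (truncated normal, ≥ 30 bp) | degraded skin DNA |
| contaminant fragment length | 149 ± 18 bp | human touch DNA |
| duplicate fraction | 0.34 | PCR re-emissions at identical coordinates |
| human read fraction | brushing 0.241 / rubbing 0.119 / cutting 0.002 | sampling-method presets |
| divergence | 0.002 | historical haplotype vs modern reference |
| reads | 2 × 151 bp, Q30 baseline, per-base error 0.001 | sequencing model |

Choices worth knowing about:

* **Truncated normal, not lognormal, fragment lengths.** Only mean ± SD
  is available to fit; the normal is the minimal assumption, truncated at
  30 bp to avoid degenerate fragments.
* **The 21 bp spread is treated as within-sample SD.** In the source
  data it is the spread of *per-sample means* (range 86–175 bp); the two
  are not distinguishable from published numbers, and this is the
  conservative reading for testing the machinery.
* **Historical-haplotype substitutions use a 2:1
  transition:transversion bias**, the mammalian mtDNA norm.
* **No cytosine-deamination damage model.** The workflow this package
  implements performs no damage analysis, so simulating C→T ends would
  test code that does not exist. Consequently, passing tests say nothing
  about damage-aware mapping.
* **An optional dropout region** (default off) models coverage gaps over
  the hypervariable control region; it is how the breadth-failure path is
  exercised.
* Quality strings are a constant Q30 with an optional low-quality 3′
  tail (`quality_dropoff`), and substitution errors are injected
  *independently* of the written qualities so that trimming and
  merging are exercised separately.

What the generator does **not** emulate: bacterial/fungal background,
PhiX, adapters (enriched inserts are simulated directly), indel
sequencing errors, and damage patterns. Tests passing on synthetic data
therefore demonstrate the correctness of the algorithms under the stated
read model, not robustness to every artifact of real historical
libraries.

## Numerical and degenerate-input choices

* Mott tie-break: leftmost segment; alignment tie-break: forward strand,
  then smallest start; UPGMA tie-break: current-matrix order; duplicate
  representative: quality then id. Every arbitrary choice is
  deterministic, and one master seed drives all stochastic stages through
  named substreams (`derive_seed`), so a fixed config + seed reproduces
  every artifact byte for byte.
* Zero reads are a result, not an error: the report says "no assignable
  species" and all four criteria are `not_evaluated`.
* An all-N consensus refuses the database search ("nothing to search").
* Degenerate statistics are explicit: zero pooled variance with equal
  means gives t = 0, p = 1; with unequal means, infinite t; groups
  smaller than 2 get descriptive output only.

## Problem sizes

The mini-panel used throughout the tests and the acceptance script is
four synthetic 2 kb circular mini-genomes (cow-like anchor; sheep-like at
10% divergence from cow; goat-like at 6% from sheep; human-like at 20%
from cow — the divergence cap of the degraded-DNA regime modelled here).
Simulated samples use 1 200 read pairs for end-to-end runs (≈ 35×
coverage after duplicates and contamination) and 5 000 pairs for
contamination-recovery checks; bootstrap trees use 100 replicates. These
sizes were chosen so that every statistical recovery check has
comfortable power at mini-genome scale; all of them are plain arguments,
and full-length (~16.5 kb) references work unchanged.

## Known limitations

* Criterion 3 searches the local panel; a genuinely novel species not in
  the panel can only fail criteria, never be discovered.
* The nearest-leaf placement check can be ambiguous when two references
  are nearly identical; ties resolve by panel order and real
  disagreements flag the sample for further investigation rather than
  silently passing.
* UPGMA assumes a molecular clock; for the shallow divergences of a
  candidate-species panel this is adequate, but deep or rate-varying
  panels would warrant a different tree method than the one being
  reproduced here.
* The simulator's independence of written quality and injected error is
  a modelling convenience; real base callers correlate the two.
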