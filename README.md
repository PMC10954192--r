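# parchmentid

Species identification and authentication of parchment DNA from
mitochondrial capture sequencing.

## The problem

Parchment — animal skin (typically calf, sheep, or goat) prepared as a
writing surface — retains DNA from its source animal, but that DNA is
fragmented, scarce, and mixed with human touch DNA deposited through
handling. Given capture-enriched paired-end reads and a panel of candidate
mitochondrial reference genomes, `parchmentid` determines which species
furnished the skin and grades how much that call should be trusted. It is
aimed at biocodicology: labs and archives analysing manuscripts, legal
documents, and bookbindings without access to (or appetite for) ad hoc
workstation pipelines.

## The method

The pipeline implements the full desk-side workflow:

1. **Merge** overlapping read pairs (degraded inserts are shorter than
   2 × 151 bp, so authentic fragments overlap); only merged reads continue.
2. **Trim** with the modified-Mott algorithm at error-probability limit
   0.05.
3. **Competitive mapping**: every merged read is aligned to *every* panel
   reference (k-mer seeded local alignment, affine gaps, both strands,
   circular references unwrapped). A read is assigned only to a unique
   best-scoring reference — reads mapping equally to several references
   are ignored rather than placed arbitrarily.
4. **Deduplicate** PCR copies by identical (start, stop, read length).
5. **Consensus** mitogenome on the top non-human reference (majority
   calls, IUPAC codes on ties, N below the depth floor), with mean
   coverage and breadth.
6. **Authenticate** through a sequential four-criterion gate — the first
   failure stops evaluation:
   mean coverage > 10×; breadth > 90%; best local-database match with
   E-value < 0.001, identity > 99%, query coverage > 95% (Karlin–Altschul
   `E = K·m·n·e^(−λS)`); and consistent placement in a Kimura-80/UPGMA
   bootstrap tree (K80: `d = −½ ln[(1 − 2P − Q)·√(1 − 2Q)]`).
7. **Contamination report**: percentage of reads mapping to the human
   mitogenome and a Student's-t contrast of read lengths — human touch
   DNA runs long (≈ 149 ± 18 bp) against the degraded endogenous fraction
   (≈ 119 ± 21 bp).

A first-class synthetic-data module simulates capture-enriched parchment
libraries (fragment-length models, PCR duplicates, per-sampling-method
human contamination presets, a slightly diverged historical haplotype)
with a ground-truth manifest, so the whole pipeline is testable offline.
See `vignettes/parchment-authentication.Rmd` for the methods account.

## Worked example

Simulate a brushing-sampled sheep parchment on a four-species synthetic
mini-panel and run the full pipeline:

```r
library(parchmentid)

fx  <- make_fixtures("fixtures", seed = 42, n_fragments = 0)   # panel only
cfg <- run_config(fx$panel_fasta, fx$panel_metadata, out_dir = "run",
                  sample_id = "parchment_01", sampling_method = "brushing",
                  simulation = simulation_config("syn_sheep_mt", 1200,
                                                 sampling_method = "brushing",
                                                 seed = 42),
                  bootstrap_replicates = 100, seed = 42)
res <- run_pipeline(cfg)
print(res$mapping); print(res$consensus); print(res$auth)
```

```
Competitive mapping of 1200 reads
  assigned: 1193 | ties ignored: 7 | unmapped: 0
  duplicates removed: 400 (rate 0.335)
  syn_cow_mt        0
  syn_sheep_mt    904
  syn_goat_mt       0
  syn_human_mt    289
Consensus on syn_sheep_mt: 2000 bp, 600 reads, mean coverage 35.5X, breadth 100.0%
Authentication report
  1. mean_coverage   pass
  2. breadth         pass
  3. db_match        pass
  4. tree_placement  pass
  assigned species: Ovis aries
```

Reading it: of 1200 simulated read pairs, 904 merged reads were uniquely
assigned to the sheep reference and 289 to the human reference (the
brushing preset deposits ~24% human touch DNA); 7 reads scored equally
against two references and were ignored. After removing 400 PCR
duplicates (recovered rate 0.335 against the configured 0.34), the 600
sheep-assigned reads give a 35.5× consensus covering 100% of the 2 kb
mini-genome, which clears all four authentication criteria, and the
sample is assigned *Ovis aries* — the species the reads were simulated
from. `res$report$human_read_pct` is 24.08 and every clade in the
placement tree has 100% bootstrap support. Artifacts (merged FASTQ, SAM,
consensus FASTA, Newick tree, TSV/JSON reports, run log) land in `run/`.

A thin command-line wrapper with `fixtures` / `simulate` / `run`
subcommands is installed at `inst/cli/parchmentid`.

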