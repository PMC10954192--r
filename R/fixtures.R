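# Desk-scale synthetic fixtures: a four-species mini-panel of 2 kb
# mitogenome stand-ins plus one simulated sample per sampling-method preset.
# Everything is generated from a seed at run time; nothing is downloaded.

random_dna <- function(len, seed) {
  with_seed(seed, paste(sample(DNA_BASES, len, replace = TRUE), collapse = ""))
}

#' Generate the synthetic mini-panel
#'
#' Four 2 kb circular mini-genomes standing in for the panel species: a
#' cow-like anchor sequence, a sheep-like sequence at 10% divergence from
#' cow, a goat-like sequence at 6% divergence from sheep, and a human-like
#' sequence at 20% divergence from cow (the most diverged the degraded-DNA
#' regime this package models allows).  All sequences are synthetic; ids
#' carry a `syn_` prefix to say so.
#'
#' @param seed integer seed.
#' @param len mini-genome length (bp, default 2000).
#' @return a `ref_panel`.
#' @export
mini_panel <- function(seed = 1L, len = 2000L) {
  cow <- random_dna(len, derive_seed(seed, "panel_cow"))
  sheep <- mutate_reference(cow, 0.10, derive_seed(seed, "panel_sheep"))
  goat <- mutate_reference(sheep, 0.06, derive_seed(seed, "panel_goat"))
  human <- mutate_reference(cow, 0.20, derive_seed(seed, "panel_human"))
  reference_panel(data.frame(
    id = c("syn_cow_mt", "syn_sheep_mt", "syn_goat_mt", "syn_human_mt"),
    species_scientific = c("Bos taurus", "Ovis aries", "Capra hircus",
                           "Homo sapiens"),
    species_common = c("cow", "sheep", "goat", "human"),
    is_human = c(FALSE, FALSE, FALSE, TRUE),
    is_bait_species = c(TRUE, TRUE, TRUE, FALSE),
    circular = TRUE,
    sequence = c(cow, sheep, goat, human),
    stringsAsFactors = FALSE
  ))
}

#' Write the mini-panel and one simulated sample per sampling method
#'
#' Emits the [mini_panel()] as FASTA + metadata TSV under `dir/panel/` and a
#' simulated sheep-origin sample for each sampling-method preset (brushing,
#' rubbing, cutting) under `dir/samples/<method>/`, at the generator's
#' default study conditions.
#'
#' @param dir output directory.
#' @param seed integer seed; fixture content is a pure function of it.
#' @param n_fragments read pairs per sample (default 1500, roughly 35X on a
#'   2 kb mini-genome after duplicates and contamination).
#' @return invisible list: `panel_fasta`, `panel_metadata`, `samples`
#'   (named list of per-method directories), `panel`.
#' @export
make_fixtures <- function(dir, seed = 1L, n_fragments = 1500L) {
  panel <- mini_panel(seed)
  panel_dir <- file.path(dir, "panel")
  dir.create(panel_dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(panel_dir, "panel.fasta")
  md <- file.path(panel_dir, "panel.tsv")
  write_panel(panel, fa, md)
  methods <- c("brushing", "rubbing", "cutting")
  samples <- list()
  for (m in methods) {
    cfg <- simulation_config(
      source_reference_id = "syn_sheep_mt", n_fragments = n_fragments,
      sampling_method = m, seed = derive_seed(seed, paste0("sample_", m))
    )
    sdir <- file.path(dir, "samples", m)
    simulate_sample(cfg, panel, sdir)
    samples[[m]] <- sdir
  }
  invisible(list(panel_fasta = fa, panel_metadata = md, samples = samples,
                 panel = panel))
}
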